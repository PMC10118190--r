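#' Subset a structure by atom indices
#'
#' @param s a `gef_structure`.
#' @param idx integer atom indices.
#' @return a `gef_structure` containing the selected atoms, in order.
#' @export
subset_structure <- function(s, idx) {
  stopifnot(inherits(s, "gef_structure"))
  a <- s$atoms[idx, , drop = FALSE]
  rownames(a) <- NULL
  new_structure(a, label = s$label)
}

three_to_one <- function(resname) {
  tab <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
           GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
           LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
           SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
           SEP = "S", TPO = "T", PTR = "Y", MSE = "M", HSD = "H",
           HSE = "H", HID = "H", HIE = "H")
  out <- unname(tab[toupper(resname)])
  out[is.na(out)] <- "X"
  out
}

# CA residue table (chain, resno, one-letter code, CA atom index) for a
# selection of a structure
ca_residue_table <- function(s, sel) {
  idx <- select_atoms(s, sel, quiet = TRUE)
  a <- s$atoms[idx, , drop = FALSE]
  ca <- a$name == "CA"
  data.frame(chain = a$chain[ca], resno = a$resno[ca],
             aa = three_to_one(a$resname[ca]),
             atom_index = idx[ca], stringsAsFactors = FALSE)
}

#' Map anchor residues between a mobile model and a template complex
#'
#' To place each ensemble frame into the frame of reference of a
#' template GEF:GTPase complex, the mobile anchor domain (e.g. the DH-PH
#' module) must be paired residue-by-residue with the corresponding
#' template chain. In `"user"` mode the pairing is supplied explicitly;
#' in `"auto"` mode the two anchor sequences are globally aligned and CA
#' atoms at aligned non-gap columns are paired — the right choice when
#' the mobile protein and the template GEF are homologous but not
#' identical (obscurin anchored on Dbs, say).
#'
#' @param mobile,template `gef_structure`s.
#' @param mobile_sel,template_sel `atom_selection`s delimiting the anchors.
#' @param mode `"auto"` (sequence alignment) or `"user"`.
#' @param pairs for `"user"` mode: data.frame with columns
#'   `mobile_chain`, `mobile_resno`, `template_chain`, `template_resno`.
#' @return object of class `residue_map`: data.frame of paired residues
#'   with their CA atom indices, plus a `source` attribute.
#' @export
build_residue_map <- function(mobile, mobile_sel, template, template_sel,
                              mode = c("auto", "user"), pairs = NULL) {
  mode <- match.arg(mode)
  mtab <- ca_residue_table(mobile, mobile_sel)
  ttab <- ca_residue_table(template, template_sel)
  if (mode == "user") {
    if (is.null(pairs)) stop("mode 'user' requires a pairs data.frame")
    mi <- match(paste(pairs$mobile_chain, pairs$mobile_resno),
                paste(mtab$chain, mtab$resno))
    ti <- match(paste(pairs$template_chain, pairs$template_resno),
                paste(ttab$chain, ttab$resno))
    if (any(is.na(mi)) || any(is.na(ti))) {
      stop("user pairs reference residues absent from the anchors")
    }
    map <- data.frame(mobile_chain = pairs$mobile_chain,
                      mobile_resno = pairs$mobile_resno,
                      mobile_atom = mtab$atom_index[mi],
                      template_chain = pairs$template_chain,
                      template_resno = pairs$template_resno,
                      template_atom = ttab$atom_index[ti])
  } else {
    if (!nrow(mtab) || !nrow(ttab)) stop("anchor selection has no CA atoms")
    aln <- global_align(paste(mtab$aa, collapse = ""),
                        paste(ttab$aa, collapse = ""))
    am <- strsplit(aln$aligned_a, "")[[1]]
    at <- strsplit(aln$aligned_b, "")[[1]]
    pm <- cumsum(am != "-")
    pt <- cumsum(at != "-")
    both <- which(am != "-" & at != "-")
    map <- data.frame(mobile_chain = mtab$chain[pm[both]],
                      mobile_resno = mtab$resno[pm[both]],
                      mobile_atom = mtab$atom_index[pm[both]],
                      template_chain = ttab$chain[pt[both]],
                      template_resno = ttab$resno[pt[both]],
                      template_atom = ttab$atom_index[pt[both]])
  }
  if (nrow(map) < 3) stop("too few mapped residue pairs (need >= 3)")
  if (anyDuplicated(map$mobile_atom) || anyDuplicated(map$template_atom)) {
    stop("residue map must be one-to-one")
  }
  class(map) <- c("residue_map", "data.frame")
  attr(map, "source") <- mode
  map
}

cross_distances <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' Detect steric clashes between two atom sets
#'
#' A pair of atoms clashes when their distance falls short of the sum of
#' their van der Waals radii by at least `overlap_threshold` (0.4 A by
#' default, the conventional serious-overlap cutoff). A plain
#' distance-cutoff mode is available for sensitivity checks.
#'
#' @param a,b `gef_structure`s (typically region subsets).
#' @param overlap_threshold minimum vdW overlap counted as a clash (A).
#' @param mode `"vdw"` (default) or `"distance"` (clash iff distance
#'   < `cutoff`).
#' @param cutoff distance cutoff in A for `mode = "distance"`.
#' @return object of class `clash_report`: data.frame `pairs`
#'   (`a_index`, `b_index`, `distance_A`, `overlap_A`), plus
#'   `n_clashes`, `min_distance`, `is_compatible`.
#' @export
detect_clashes <- function(a, b, overlap_threshold = 0.4,
                           mode = c("vdw", "distance"), cutoff = 4.0) {
  mode <- match.arg(mode)
  stopifnot(inherits(a, "gef_structure"), inherits(b, "gef_structure"))
  if (!nrow(a$atoms) || !nrow(b$atoms)) stop("empty selection in clash check")
  d <- cross_distances(coords(a), coords(b))
  if (mode == "vdw") {
    ra <- vdw_radius(a$atoms$element, quiet = TRUE)
    rb <- vdw_radius(b$atoms$element, quiet = TRUE)
    overlap <- outer(ra, rb, "+") - d
    hit <- which(overlap >= overlap_threshold, arr.ind = TRUE)
  } else {
    overlap <- cutoff - d
    hit <- which(d < cutoff, arr.ind = TRUE)
  }
  pairs <- data.frame(a_index = hit[, 1], b_index = hit[, 2],
                      distance_A = d[hit], overlap_A = overlap[hit])
  pairs <- pairs[order(pairs$a_index, pairs$b_index), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs,
                 n_clashes = nrow(pairs),
                 min_distance = min(d),
                 is_compatible = nrow(pairs) == 0L),
            class = "clash_report")
}

#' @export
print.clash_report <- function(x, ...) {
  cat(sprintf("<clash_report> %d clashing pair(s), min distance %.2f A -> %s\n",
              x$n_clashes, x$min_distance,
              if (x$is_compatible) "compatible" else "clash"))
  invisible(x)
}

#' Fraction of ensemble frames sterically compatible with GTPase binding
#'
#' For every frame: superpose the frame onto the template complex using
#' the CA atoms of the mapped anchor residues, transform the frame's
#' coordinates, and test the mobile "clashing region" against the
#' template GTPase region for van der Waals clashes. A frame is
#' binding-compatible when it has at most `max_clashes` clashing pairs
#' (zero by default — "does not clash"). Heavy atoms only by default.
#'
#' @param e a `gef_ensemble`.
#' @param template a `gef_structure` holding the template complex.
#' @param map a `residue_map` from [build_residue_map()].
#' @param region_mobile `atom_selection` of the mobile clashing region
#'   (e.g. the loop residues 62-78 in the obscurin analysis).
#' @param region_template `atom_selection` of the template partner
#'   region (e.g. RhoA residues 120-133).
#' @param overlap_threshold vdW overlap (A) counted as a clash.
#' @param heavy_only drop hydrogens from both regions (default TRUE).
#' @param max_clashes clashing pairs tolerated per compatible frame.
#' @param stride analyse every `stride`-th frame (default 1: all).
#' @param mode,cutoff clash criterion, see [detect_clashes()].
#' @return object of class `compatibility_result`: `species`, `n_frames`,
#'   `n_compatible`, `percent_compatible`, and `per_frame` (data.frame
#'   frame, n_clashes, min_distance_A, compatible) plus `reports`
#'   (full clash reports per analysed frame).
#' @export
compatibility_fraction <- function(e, template, map, region_mobile,
                                   region_template, overlap_threshold = 0.4,
                                   heavy_only = TRUE, max_clashes = 0L,
                                   stride = 1L, mode = "vdw", cutoff = 4.0) {
  stopifnot(inherits(e, "gef_ensemble"), inherits(template, "gef_structure"),
            inherits(map, "residue_map"))
  anchor_mob <- map$mobile_atom
  anchor_tmp <- map$template_atom
  if (max(anchor_mob) > nrow(e$topology$atoms)) {
    stop("residue map references atoms beyond the ensemble topology")
  }
  tmp_anchor_xyz <- coords(template)[anchor_tmp, , drop = FALSE]

  idx_mob <- select_atoms(e, region_mobile, quiet = TRUE)
  idx_tmp <- select_atoms(template, region_template, quiet = TRUE)
  if (!length(idx_mob) || !length(idx_tmp)) {
    stop("a clash region selection resolved to zero atoms")
  }
  if (heavy_only) {
    idx_mob <- idx_mob[toupper(e$topology$atoms$element[idx_mob]) != "H"]
    idx_tmp <- idx_tmp[toupper(template$atoms$element[idx_tmp]) != "H"]
    if (!length(idx_mob) || !length(idx_tmp)) {
      stop("clash region contains no heavy atoms")
    }
  }
  region_tmp_struct <- subset_structure(template, idx_tmp)
  mob_template_struct <- subset_structure(e$topology, idx_mob)

  keep <- seq(1L, n_frames(e), by = stride)
  reports <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    f <- e$frames[[keep[i]]]
    fit <- kabsch(f[anchor_mob, , drop = FALSE], tmp_anchor_xyz)
    placed <- mob_template_struct
    placed$atoms[, c("x", "y", "z")] <-
      apply_transform(f[idx_mob, , drop = FALSE], fit)
    rep_i <- detect_clashes(placed, region_tmp_struct,
                            overlap_threshold = overlap_threshold,
                            mode = mode, cutoff = cutoff)
    rep_i$frame <- keep[i]
    rep_i$is_compatible <- rep_i$n_clashes <= max_clashes
    reports[[i]] <- rep_i
  }
  per_frame <- data.frame(
    frame = keep,
    n_clashes = vapply(reports, `[[`, 0L, "n_clashes"),
    min_distance_A = vapply(reports, `[[`, 0, "min_distance"),
    compatible = vapply(reports, `[[`, TRUE, "is_compatible")
  )
  n_comp <- sum(per_frame$compatible)
  structure(list(species = e$species,
                 n_frames = length(keep),
                 n_compatible = n_comp,
                 percent_compatible = 100 * n_comp / length(keep),
                 per_frame = per_frame,
                 reports = reports,
                 overlap_threshold = overlap_threshold),
            class = "compatibility_result")
}

#' @export
print.compatibility_result <- function(x, ...) {
  cat(sprintf("<compatibility_result> %s: %d/%d frames binding-compatible (%.1f%%)\n",
              if (nzchar(x$species)) x$species else "(unlabelled)",
              x$n_compatible, x$n_frames, x$percent_compatible))
  invisible(x)
}

#' Write a per-frame compatibility report to CSV
#' @param x a `compatibility_result`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_compatibility_csv <- function(x, path) {
  tab <- cbind(species = x$species, x$per_frame)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
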