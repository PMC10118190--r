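#' Van der Waals radii used for clash detection
#'
#' Standard element radii in Angstrom: C 1.70, N 1.55, O 1.52, S 1.80,
#' H 1.20, P 1.80. Elements absent from the table fall back to 1.70 A
#' (the carbon radius) with a warning, so that structures with exotic or
#' missing element fields never abort an analysis silently.
#'
#' @param element character vector of element symbols (case-insensitive).
#' @param fallback radius in Angstrom assigned to unknown elements.
#' @param quiet suppress the unknown-element warning.
#' @return numeric vector of radii in Angstrom.
#' @examples
#' vdw_radius(c("C", "N", "O"))
#' @export
vdw_radius <- function(element, fallback = 1.70, quiet = FALSE) {
  tab <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
           F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90,
           MG = 1.73, ZN = 1.39, FE = 1.40, CA = 2.31, "NA" = 2.27, K = 2.75)
  key <- toupper(trimws(element))
  r <- unname(tab[key])
  unknown <- is.na(r)
  if (any(unknown)) {
    if (!quiet) {
      warning(sprintf("unknown element(s) %s: using fallback vdW radius %.2f A",
                      paste(unique(key[unknown]), collapse = ", "), fallback),
              call. = FALSE)
    }
    r[unknown] <- fallback
  }
  r
}

new_structure <- function(atoms, label = "") {
  stopifnot(is.data.frame(atoms))
  structure(list(atoms = atoms, label = label), class = "gef_structure")
}

#' Construct a structure from an atom table
#'
#' A structure is an ordered atom table plus a free-text label. The
#' combination (chain, residue number, atom name) must be unique.
#'
#' @param atoms data.frame with columns `serial`, `name`, `resname`,
#'   `chain`, `resno`, `x`, `y`, `z` and optionally `element`.
#' @param label free-text label.
#' @return an object of class `gef_structure`.
#' @export
gef_structure <- function(atoms, label = "") {
  required <- c("name", "resname", "chain", "resno", "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols)) {
    stop("atoms table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  if (is.null(atoms$element)) atoms$element <- guess_element(atoms$name)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite coordinates in atom table")
  key <- paste(atoms$chain, atoms$resno, atoms$name)
  if (anyDuplicated(key)) {
    stop("duplicate (chain, resno, name) atom keys; altloc duplicates must be resolved")
  }
  new_structure(atoms, label)
}

#' @export
print.gef_structure <- function(x, ...) {
  cat(sprintf("<gef_structure> %s\n", if (nzchar(x$label)) x$label else "(unlabelled)"))
  cat(sprintf("  %d atoms, %d residues, chains: %s\n",
              nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$resno))),
              paste(unique(x$atoms$chain), collapse = " ")))
  invisible(x)
}

# Element from PDB atom name when the element column is blank: strip leading
# digits (e.g. "1HB"), take the leading alphabetic run, and recognise
# two-letter elements only when they match the radius table.
guess_element <- function(name) {
  nm <- toupper(gsub("^[0-9 ]+", "", trimws(name)))
  first <- substr(nm, 1, 1)
  two <- substr(nm, 1, 2)
  known2 <- c("CL", "BR", "SE", "MG", "ZN", "FE", "NA")
  ifelse(two %in% known2, two, first)
}

#' Coordinates of a structure as an n x 3 matrix
#'
#' @param x a `gef_structure`.
#' @return numeric matrix with columns x, y, z (Angstrom).
#' @export
coords <- function(x) {
  UseMethod("coords")
}

#' @export
coords.gef_structure <- function(x) {
  as.matrix(x$atoms[, c("x", "y", "z")])
}

#' Read one model from a PDB file
#'
#' Parses ATOM/HETATM records with the package's own fixed-column reader.
#' Multi-model files are split on MODEL/ENDMDL; `model` selects which block
#' to return (default the first). Only the first alternate location of each
#' atom is kept; insertion codes are rejected because the intended inputs
#' (predicted models and MD snapshots) never carry them.
#'
#' @param path path to a PDB file.
#' @param model 1-based model index for multi-model files.
#' @param label label for the returned structure (defaults to the file name).
#' @return a `gef_structure`.
#' @export
read_structure <- function(path, model = 1L, label = basename(path)) {
  models <- read_pdb_models(path)
  if (model < 1L || model > length(models)) {
    stop(sprintf("model index %d out of range (file has %d model(s))",
                 model, length(models)))
  }
  gef_structure(models[[model]], label = label)
}

# Internal: parse a PDB file into a list of atom data.frames, one per model.
read_pdb_models <- function(path) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  is_model <- startsWith(lines, "MODEL")
  is_end <- startsWith(lines, "ENDMDL")
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)

  model_id <- cumsum(is_model)
  if (!any(is_model)) model_id[] <- 1L
  model_id[model_id == 0L] <- 1L
  # atoms after an ENDMDL but before the next MODEL belong nowhere useful;
  # treat them as part of the previous model (harmless for conforming files)
  atom_lines <- lines[is_atom]
  atom_model <- model_id[is_atom]

  parse_block <- function(bl) {
    icode <- trimws(substr(bl, 27, 27))
    if (any(nzchar(icode))) {
      stop("insertion codes are not supported (found in ATOM records)")
    }
    altloc <- substr(bl, 17, 17)
    atoms <- data.frame(
      serial  = suppressWarnings(as.integer(substr(bl, 7, 11))),
      name    = trimws(substr(bl, 13, 16)),
      altloc  = altloc,
      resname = trimws(substr(bl, 18, 20)),
      chain   = substr(bl, 22, 22),
      resno   = as.integer(trimws(substr(bl, 23, 26))),
      x = as.numeric(substr(bl, 31, 38)),
      y = as.numeric(substr(bl, 39, 46)),
      z = as.numeric(substr(bl, 47, 54)),
      element = trimws(substr(bl, 77, 78)),
      stringsAsFactors = FALSE
    )
    if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
      stop("unparseable coordinates in PDB file")
    }
    # first altloc wins
    atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resno, atoms$name)), ]
    atoms$altloc <- NULL
    blank_el <- !nzchar(atoms$element)
    if (any(blank_el)) atoms$element[blank_el] <- guess_element(atoms$name[blank_el])
    rownames(atoms) <- NULL
    atoms
  }
  lapply(split(atom_lines, atom_model), parse_block)
}

#' Write a structure (or ensemble) to a PDB file
#'
#' Coordinates are written at the PDB format's 0.001 A precision, so a
#' read/write round trip preserves them to that precision.
#'
#' @param x a `gef_structure` or `gef_ensemble`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  UseMethod("write_structure")
}

format_atom_lines <- function(atoms, xyz) {
  name4 <- ifelse(nchar(atoms$name) < 4, sprintf(" %-3s", atoms$name),
                  sprintf("%-4s", atoms$name))
  sprintf("ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          atoms$serial %% 100000L, name4, atoms$resname, atoms$chain,
          atoms$resno, xyz[, 1], xyz[, 2], xyz[, 3], 1, 0,
          toupper(atoms$element))
}

#' @export
write_structure.gef_structure <- function(x, path) {
  writeLines(c(format_atom_lines(x$atoms, coords(x)), "END"), path)
  invisible(path)
}

#' @export
write_structure.gef_ensemble <- function(x, path) {
  atoms <- x$topology$atoms
  n <- length(x$frames)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    out[[i]] <- c(sprintf("MODEL     %4d", i),
                  format_atom_lines(atoms, x$frames[[i]]),
                  "ENDMDL")
  }
  writeLines(c(unlist(out), "END"), path)
  invisible(path)
}

new_ensemble <- function(topology, frames, species = "") {
  structure(list(topology = topology, frames = frames, species = species),
            class = "gef_ensemble")
}

#' Build an ensemble from a topology and a list of coordinate frames
#'
#' An ensemble is an ordered set of conformations sharing one topology
#' (the atom metadata of the first frame). Used to hold merged MD
#' snapshots of one molecular species.
#'
#' @param topology a `gef_structure` providing atom metadata.
#' @param frames list of n_atoms x 3 coordinate matrices (Angstrom).
#' @param species species label, e.g. "WT", "pSer", "pThr", "pSer/pThr".
#' @return a `gef_ensemble`.
#' @export
gef_ensemble <- function(topology, frames, species = "") {
  stopifnot(inherits(topology, "gef_structure"))
  if (!length(frames)) stop("an ensemble needs at least one frame")
  n_atoms <- nrow(topology$atoms)
  frames <- lapply(frames, function(f) {
    f <- as.matrix(f)
    if (nrow(f) != n_atoms || ncol(f) != 3) {
      stop("topology mismatch: every frame must be ", n_atoms, " x 3")
    }
    unname(f)
  })
  new_ensemble(topology, frames, species)
}

#' @export
print.gef_ensemble <- function(x, ...) {
  cat(sprintf("<gef_ensemble> %s: %d frames x %d atoms\n",
              if (nzchar(x$species)) x$species else "(unlabelled)",
              length(x$frames), nrow(x$topology$atoms)))
  invisible(x)
}

#' Number of frames in an ensemble
#' @param e a `gef_ensemble`.
#' @return integer frame count.
#' @export
n_frames <- function(e) length(e$frames)

#' Read a conformational ensemble from multi-model PDB file(s)
#'
#' Each MODEL block becomes one frame; several files are concatenated in
#' argument order (the way replicate trajectories of one species are
#' merged). All models must share the topology of the first.
#'
#' @param paths character vector of PDB file paths.
#' @param species species label stored on the ensemble.
#' @return a `gef_ensemble`.
#' @export
read_ensemble <- function(paths, species = "") {
  stopifnot(length(paths) >= 1)
  frames <- list()
  topo <- NULL
  for (p in paths) {
    models <- read_pdb_models(p)
    for (m in models) {
      if (is.null(topo)) {
        topo <- gef_structure(m, label = basename(paths[1]))
      } else if (nrow(m) != nrow(topo$atoms)) {
        stop(sprintf("topology mismatch: %s has a model with %d atoms, expected %d",
                     p, nrow(m), nrow(topo$atoms)))
      }
      frames[[length(frames) + 1L]] <- as.matrix(m[, c("x", "y", "z")])
    }
  }
  gef_ensemble(topo, frames, species)
}

#' Atom selection specification
#'
#' Selects atoms by chain, inclusive author residue-number range and/or
#' atom names. Residue numbering is taken verbatim from the input file;
#' ranges such as the clashing-loop residues 62-78 are therefore
#' file-local.
#'
#' @param chain single chain identifier, or NULL for any chain.
#' @param resno inclusive `c(start, end)` residue-number range, or NULL.
#' @param atom_names character vector of atom names (e.g. "CA"), or NULL.
#' @return an object of class `atom_selection`.
#' @examples
#' atom_selection(chain = "A", resno = c(62, 78), atom_names = "CA")
#' @export
atom_selection <- function(chain = NULL, resno = NULL, atom_names = NULL) {
  if (!is.null(resno)) {
    stopifnot(length(resno) == 2)
    if (resno[1] > resno[2]) stop("residue range start must be <= end")
  }
  structure(list(chain = chain, resno = resno, atom_names = atom_names),
            class = "atom_selection")
}

#' Indices of atoms matching a selection
#'
#' @param s a `gef_structure` (or `gef_ensemble`, whose topology is used).
#' @param sel an `atom_selection`.
#' @param quiet suppress the empty-selection message.
#' @return integer vector of atom indices in structure order (may be empty).
#' @export
select_atoms <- function(s, sel = atom_selection(), quiet = FALSE) {
  if (inherits(s, "gef_ensemble")) s <- s$topology
  stopifnot(inherits(s, "gef_structure"), inherits(sel, "atom_selection"))
  a <- s$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(sel$chain)) keep <- keep & a$chain == sel$chain
  if (!is.null(sel$resno)) keep <- keep & a$resno >= sel$resno[1] & a$resno <= sel$resno[2]
  if (!is.null(sel$atom_names)) keep <- keep & a$name %in% sel$atom_names
  idx <- which(keep)
  if (!length(idx) && !quiet) message("atom selection matched no atoms")
  idx
}
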