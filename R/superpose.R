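#' Kabsch least-squares rigid superposition
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' two paired point sets, via singular value decomposition of the
#' cross-covariance matrix. Reflections are excluded, so the returned
#' rotation always has determinant +1.
#'
#' The rotation acts on row vectors: `fitted = mobile %*% rotation`, then
#' `+ translation` (recycled over rows), i.e. use [apply_transform()].
#'
#' @param mobile n x 3 coordinate matrix to move (Angstrom).
#' @param reference n x 3 coordinate matrix to fit onto.
#' @return object of class `kabsch_fit`: list with `rotation` (3 x 3,
#'   det +1), `translation` (length-3), and `rmsd` (Angstrom).
#' @examples
#' x <- matrix(rnorm(30), 10, 3)
#' fit <- kabsch(x, x)
#' fit$rmsd  # 0
#' @export
kabsch <- function(mobile, reference) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3) {
    stop("mobile and reference must be matching n x 3 matrices")
  }
  n <- nrow(mobile)
  if (n < 3) stop("ill-posed fit: at least 3 paired points are required")
  cm <- colMeans(mobile)
  cr <- colMeans(reference)
  xc <- sweep(mobile, 2, cm)
  yc <- sweep(reference, 2, cr)
  # collinear (or coincident) point sets leave the rotation unidentified
  for (m in list(xc, yc)) {
    d <- svd(m, nu = 0, nv = 0)$d
    if (d[2] <= 1e-10 * max(d[1], 1e-12)) {
      stop("ill-posed fit: degenerate (collinear) point set")
    }
  }
  h <- crossprod(xc, yc)
  sv <- svd(h)
  s <- sign(det(sv$u %*% t(sv$v)))
  rot <- sv$u %*% diag(c(1, 1, s)) %*% t(sv$v)
  fitted <- xc %*% rot
  rmsd <- sqrt(mean(rowSums((fitted - yc)^2)))
  structure(list(rotation = rot,
                 translation = as.numeric(cr - cm %*% rot),
                 rmsd = rmsd),
            class = "kabsch_fit")
}

#' @export
print.kabsch_fit <- function(x, ...) {
  cat(sprintf("<kabsch_fit> rmsd = %.4f A, det(R) = %+.6f\n",
              x$rmsd, det(x$rotation)))
  invisible(x)
}

#' Apply a rigid transform to coordinates
#'
#' @param xyz n x 3 coordinate matrix.
#' @param fit a `kabsch_fit`.
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(xyz, fit) {
  stopifnot(inherits(fit, "kabsch_fit"))
  sweep(as.matrix(xyz) %*% fit$rotation, 2, fit$translation, "+")
}

#' Per-frame RMSD of an ensemble against a reference
#'
#' Each frame is independently superposed onto the reference over the
#' selected atoms (CA only by default, robust to side-chain noise) and
#' the minimized RMSD is recorded, giving the familiar RMSD-vs-frame
#' trace used to judge simulation stability.
#'
#' @param e a `gef_ensemble`.
#' @param reference reference coordinates: a `gef_structure`, an
#'   n_atoms x 3 matrix, or NULL for frame 1 of the ensemble.
#' @param sel an `atom_selection`; default CA atoms.
#' @return numeric vector of per-frame RMSDs (class `rmsd_series`), with
#'   the mean available via `mean()` and shown by `print()`.
#' @export
rmsd_series <- function(e, reference = NULL,
                        sel = atom_selection(atom_names = "CA")) {
  stopifnot(inherits(e, "gef_ensemble"))
  idx <- select_atoms(e, sel, quiet = TRUE)
  if (!length(idx)) stop("selection matched no atoms")
  ref_xyz <- if (is.null(reference)) {
    e$frames[[1]]
  } else if (inherits(reference, "gef_structure")) {
    coords(reference)
  } else {
    as.matrix(reference)
  }
  if (nrow(ref_xyz) != nrow(e$topology$atoms)) {
    stop("reference atom count does not match the ensemble topology")
  }
  ref_sel <- ref_xyz[idx, , drop = FALSE]
  out <- vapply(e$frames, function(f) {
    kabsch(f[idx, , drop = FALSE], ref_sel)$rmsd
  }, numeric(1))
  structure(out, class = "rmsd_series", species = e$species)
}

#' @export
print.rmsd_series <- function(x, ...) {
  cat(sprintf("<rmsd_series> %d frames, mean RMSD = %.4f A (sd %.4f)\n",
              length(x), mean(unclass(x)), stats::sd(unclass(x))))
  invisible(x)
}

# mean structure of selected atoms after superposing every frame to ref_sel
mean_after_fit <- function(frames_sel, ref_sel) {
  fitted <- lapply(frames_sel, function(f) apply_transform(f, kabsch(f, ref_sel)))
  Reduce(`+`, fitted) / length(fitted)
}

#' Per-residue RMSF profile of an ensemble
#'
#' Frames are superposed to the ensemble-average structure over the
#' selected atoms; the average structure is refined iteratively
#' (superpose, recompute mean; 2 iterations by default). The fluctuation
#' of atom i is `sqrt(mean_frames |x_i - <x_i>|^2)`; residues with several
#' selected atoms get the mean over those atoms.
#'
#' @param e a `gef_ensemble` with at least 2 frames.
#' @param sel an `atom_selection`; default CA atoms.
#' @param iterations mean-structure refinement passes.
#' @return data.frame (class `rmsf_profile`) with columns `chain`,
#'   `resno`, `rmsf` (Angstrom), in residue order of the selection.
#' @export
rmsf_profile <- function(e, sel = atom_selection(atom_names = "CA"),
                         iterations = 2L) {
  stopifnot(inherits(e, "gef_ensemble"))
  if (n_frames(e) < 2) stop("RMSF needs at least 2 frames")
  idx <- select_atoms(e, sel, quiet = TRUE)
  if (!length(idx)) stop("selection matched no atoms")
  frames_sel <- lapply(e$frames, function(f) f[idx, , drop = FALSE])
  ref <- frames_sel[[1]]
  for (it in seq_len(iterations)) {
    ref <- mean_after_fit(frames_sel, ref)
  }
  fitted <- lapply(frames_sel, function(f) apply_transform(f, kabsch(f, ref)))
  mean_xyz <- Reduce(`+`, fitted) / length(fitted)
  msf <- Reduce(`+`, lapply(fitted, function(f) rowSums((f - mean_xyz)^2))) /
    length(fitted)
  atom_rmsf <- sqrt(msf)
  a <- e$topology$atoms[idx, ]
  key <- paste(a$chain, a$resno, sep = ":")
  agg <- tapply(atom_rmsf, factor(key, levels = unique(key)), mean)
  parts <- do.call(rbind, strsplit(names(agg), ":", fixed = TRUE))
  out <- data.frame(chain = parts[, 1], resno = as.integer(parts[, 2]),
                    rmsf = as.numeric(agg), stringsAsFactors = FALSE)
  class(out) <- c("rmsf_profile", "data.frame")
  out
}

#' One-way ANOVA across groups of RMSD means
#'
#' Classic fixed-effects one-way analysis of variance, as used to compare
#' mean RMSD between molecular species. Delegates to a linear-model fit;
#' an eta-squared effect size is reported alongside the F statistic, and
#' the degenerate all-values-identical case is flagged rather than
#' returning 0/0.
#'
#' @param groups named or unnamed list of numeric vectors, each length >= 2.
#' @return list of class `oneway_anova`: `statistic` (F), `p.value`,
#'   `df` (between, within), `eta_sq`, `degenerate`.
#' @export
anova_oneway <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("need a list of at least 2 groups")
  }
  if (any(vapply(groups, length, 0L) < 2)) {
    stop("every group needs at least 2 values")
  }
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  value <- unlist(groups, use.names = FALSE)
  grp <- factor(rep(names(groups), vapply(groups, length, 0L)))
  if (stats::var(value) == 0) {
    return(structure(list(statistic = NaN, p.value = NA_real_,
                          df = c(length(groups) - 1L, length(value) - length(groups)),
                          eta_sq = NA_real_, degenerate = TRUE),
                     class = "oneway_anova"))
  }
  tab <- stats::anova(stats::lm(value ~ grp))
  structure(list(statistic = tab$`F value`[1],
                 p.value = tab$`Pr(>F)`[1],
                 df = tab$Df,
                 eta_sq = tab$`Sum Sq`[1] / sum(tab$`Sum Sq`),
                 degenerate = FALSE),
            class = "oneway_anova")
}

#' @export
print.oneway_anova <- function(x, ...) {
  if (x$degenerate) {
    cat("<oneway_anova> degenerate: all values identical, F undefined\n")
  } else {
    cat(sprintf("<oneway_anova> F(%d, %d) = %.4g, p = %.4g, eta^2 = %.3f\n",
                x$df[1], x$df[2], x$statistic, x$p.value, x$eta_sq))
  }
  invisible(x)
}

#' Write a per-frame RMSD series to CSV
#' @param x an `rmsd_series`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_rmsd_csv <- function(x, path) {
  utils::write.csv(data.frame(frame = seq_along(x), rmsd_A = as.numeric(x)),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a per-residue RMSF profile to CSV
#' @param x an `rmsf_profile`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_rmsf_csv <- function(x, path) {
  utils::write.csv(data.frame(chain = x$chain, resnum = x$resno,
                              rmsf_A = x$rmsf),
                   path, row.names = FALSE)
  invisible(path)
}
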