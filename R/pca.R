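#' Cartesian-coordinate PCA of a conformational ensemble
#'
#' Principal component analysis of superposed Cartesian coordinates:
#' frames are subsampled by `stride` (every 5th frame by default, the
#' usual choice for long merged trajectories), superposed onto an
#' iteratively refined ensemble-average structure over the selected
#' atoms, flattened to 3N-vectors, mean-centred, and decomposed. The
#' covariance (not correlation) of unweighted CA coordinates is used.
#'
#' Eigenvalues are variances along each component (Angstrom^2), in
#' decreasing order; `variance_fraction[k]` is the eigenvalue divided by
#' the total coordinate variance, so fractions over all components sum
#' to 1 up to the small residual left by removing rigid-body motion.
#' Component signs follow the convention that the largest-magnitude
#' coefficient is positive, for reproducible output.
#'
#' @param e a `gef_ensemble`.
#' @param sel an `atom_selection`; default CA atoms.
#' @param stride keep every `stride`-th frame (default 5).
#' @param n_components number of components to retain (default 20;
#'   clipped with a warning if it exceeds 3 x n_selected_atoms).
#' @return object of class `ensemble_pca`: `components` (3N x k),
#'   `eigenvalues`, `variance_fraction`, `center` (3N mean vector),
#'   `ref_sel` (superposition target), `stride_used`, `n_frames_used`.
#' @export
fit_pca <- function(e, sel = atom_selection(atom_names = "CA"),
                    stride = 5L, n_components = 20L) {
  stopifnot(inherits(e, "gef_ensemble"), stride >= 1)
  idx <- select_atoms(e, sel, quiet = TRUE)
  if (!length(idx)) stop("selection matched no atoms")
  keep <- seq(1L, n_frames(e), by = stride)
  frames_sel <- lapply(e$frames[keep], function(f) f[idx, , drop = FALSE])
  n_used <- length(frames_sel)
  max_k <- 3L * length(idx)
  if (n_components > max_k) {
    warning(sprintf("n_components clipped from %d to 3 x n_atoms = %d",
                    n_components, max_k), call. = FALSE)
    n_components <- max_k
  }
  if (n_used <= n_components) {
    stop(sprintf("too few frames after stride (%d) for %d components",
                 n_used, n_components))
  }
  ref <- frames_sel[[1]]
  for (it in 1:2) ref <- mean_after_fit(frames_sel, ref)
  fitted <- lapply(frames_sel, function(f) apply_transform(f, kabsch(f, ref)))
  x <- do.call(rbind, lapply(fitted, function(f) as.numeric(t(f))))
  center <- colMeans(x)
  xc <- sweep(x, 2, center)
  sv <- svd(xc, nu = 0)
  eig_all <- sv$d^2 / (n_used - 1)
  total_var <- sum(eig_all)
  k <- min(n_components, length(eig_all))
  comp <- sv$v[, seq_len(k), drop = FALSE]
  # sign convention: largest-magnitude coefficient positive
  for (j in seq_len(k)) {
    i_max <- which.max(abs(comp[, j]))
    if (comp[i_max, j] < 0) comp[, j] <- -comp[, j]
  }
  structure(list(components = comp,
                 eigenvalues = eig_all[seq_len(k)],
                 variance_fraction = eig_all[seq_len(k)] / total_var,
                 total_variance = total_var,
                 center = center,
                 ref_sel = ref,
                 atom_index = idx,
                 stride_used = as.integer(stride),
                 n_frames_used = n_used),
            class = "ensemble_pca")
}

#' @export
print.ensemble_pca <- function(x, ...) {
  k <- length(x$eigenvalues)
  cat(sprintf("<ensemble_pca> %d components from %d frames (stride %d)\n",
              k, x$n_frames_used, x$stride_used))
  cat(sprintf("  variance explained: PC1 %.1f%%, PC2 %.1f%%, total (all %d) %.1f%%\n",
              100 * x$variance_fraction[1],
              if (k >= 2) 100 * x$variance_fraction[2] else NA,
              k, 100 * sum(x$variance_fraction)))
  invisible(x)
}

#' Project ensemble frames onto fitted principal components
#'
#' Each frame is superposed onto the model's reference structure over the
#' model's atom selection, mean-centred with the model's centre, and
#' dotted with the components. Projecting the fitting ensemble (same
#' stride) reproduces the training scores, whose per-component variance
#' equals the eigenvalue; independent ensembles (other species) can be
#' projected for cross-species score maps.
#'
#' @param e a `gef_ensemble`.
#' @param model an `ensemble_pca`.
#' @param sel an `atom_selection` resolving to the same number of atoms
#'   the model was fitted on; default CA atoms.
#' @param stride frame subsampling (default 1: project every frame).
#' @return data.frame (class `pc_projection`) with `frame` and one
#'   `PCk` column per retained component (scores in Angstrom).
#' @export
project_frames <- function(e, model, sel = atom_selection(atom_names = "CA"),
                           stride = 1L) {
  stopifnot(inherits(e, "gef_ensemble"), inherits(model, "ensemble_pca"))
  idx <- select_atoms(e, sel, quiet = TRUE)
  if (length(idx) != nrow(model$ref_sel)) {
    stop(sprintf("selection resolves to %d atoms but the model expects %d",
                 length(idx), nrow(model$ref_sel)))
  }
  keep <- seq(1L, n_frames(e), by = stride)
  scores <- t(vapply(e$frames[keep], function(f) {
    fs <- f[idx, , drop = FALSE]
    fitted <- apply_transform(fs, kabsch(fs, model$ref_sel))
    as.numeric((as.numeric(t(fitted)) - model$center) %*% model$components)
  }, numeric(ncol(model$components))))
  if (ncol(model$components) == 1L) scores <- matrix(scores, ncol = 1L)
  out <- data.frame(frame = keep, scores)
  names(out) <- c("frame", paste0("PC", seq_len(ncol(model$components))))
  class(out) <- c("pc_projection", "data.frame")
  attr(out, "species") <- e$species
  out
}

#' @export
predict.ensemble_pca <- function(object, newdata,
                                 sel = atom_selection(atom_names = "CA"),
                                 ...) {
  project_frames(newdata, object, sel = sel)
}

#' Frames at the extremes of one principal component
#'
#' Returns the frames attaining the minimum and maximum score on the
#' chosen component, as structures ready to be written out as
#' representative conformations. Ties are broken by the lowest frame
#' index and flagged.
#'
#' @param e the `gef_ensemble` the projections refer to.
#' @param proj a `pc_projection` from [project_frames()].
#' @param pc_index which component (1-based).
#' @return list with `min_frame`, `max_frame` (frame indices), `min`,
#'   `max` (`gef_structure`s) and `tie` (logical).
#' @export
extrema_structures <- function(e, proj, pc_index = 1L) {
  stopifnot(inherits(proj, "pc_projection"), nrow(proj) >= 1)
  col <- paste0("PC", pc_index)
  if (!col %in% names(proj)) stop("pc_index out of range")
  s <- proj[[col]]
  i_min <- which.min(s)
  i_max <- which.max(s)
  tie <- (max(s) == min(s))
  if (tie) message("all scores equal on ", col, "; returning frame ",
                   proj$frame[1], " for both extremes")
  frame_structure <- function(i) {
    a <- e$topology$atoms
    a[, c("x", "y", "z")] <- e$frames[[proj$frame[i]]]
    gef_structure(a, label = sprintf("%s %s frame %d", e$species, col,
                                     proj$frame[i]))
  }
  list(min_frame = proj$frame[i_min], max_frame = proj$frame[i_max],
       min = frame_structure(i_min), max = frame_structure(i_max),
       tie = tie)
}

#' Write the PCA eigenvalue table to CSV
#' @param model an `ensemble_pca`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_pca_csv <- function(model, path) {
  utils::write.csv(data.frame(
    component = seq_along(model$eigenvalues),
    eigenvalue_A2 = model$eigenvalues,
    variance_fraction = model$variance_fraction,
    cumulative = cumsum(model$variance_fraction)
  ), path, row.names = FALSE)
  invisible(path)
}

#' Write PC projections to CSV
#' @param proj a `pc_projection` (or list of them, rbound with species).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_projection_csv <- function(proj, path) {
  if (inherits(proj, "pc_projection")) proj <- list(proj)
  tabs <- lapply(proj, function(p) {
    cbind(species = attr(p, "species") %||% "", as.data.frame(p))
  })
  utils::write.csv(do.call(rbind, tabs), path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
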