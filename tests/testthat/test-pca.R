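# ensemble whose frames move along fixed directions in coordinate space,
# with optional random rigid transforms layered on top
mode_ensemble <- function(amplitudes, directions, seed, rigid = FALSE) {
  topo <- make_toy_ensemble(10, 0, 2, seed = 1)$topology
  base <- coords(topo)
  n <- nrow(base) * 3
  set.seed(seed)
  frames <- lapply(seq_len(nrow(amplitudes)), function(i) {
    delta <- as.numeric(directions %*% amplitudes[i, ])
    f <- base + matrix(delta, ncol = 3, byrow = TRUE)
    if (rigid) {
      q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
      if (det(q) < 0) q[, 1] <- -q[, 1]
      f <- sweep(f %*% q, 2, runif(3, -5, 5), "+")
    }
    f
  })
  gef_ensemble(topo, frames)
}

unit_dirs <- function(n_coord, k, seed) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(n_coord * k), n_coord, k)))
  q[, seq_len(k), drop = FALSE]
}

test_that("a rank-1 ensemble concentrates all variance on PC1", {
  # displacement along the breathing mode (scaling of centred coords) is
  # exactly neutral to superposition, so the covariance is exactly rank 1
  topo <- make_toy_ensemble(10, 0, 2, seed = 1)$topology
  base <- coords(topo)
  base_c <- sweep(base, 2, colMeans(base))
  set.seed(2)
  amp <- rnorm(40, sd = 0.05)
  frames <- lapply(amp, function(a) base + a * base_c)
  e <- gef_ensemble(topo, frames)
  m <- fit_pca(e, stride = 1, n_components = 1)
  expect_equal(m$variance_fraction[1], 1, tolerance = 1e-8)
})

test_that("stride subsampling keeps every 5th frame", {
  e <- make_toy_ensemble(10, 0.3, 100, seed = 4)
  m <- fit_pca(e, stride = 5, n_components = 3)
  expect_identical(m$n_frames_used, 20L)
  expect_identical(m$stride_used, 5L)
})

test_that("two-mode ensemble with 4:1 variances yields 0.8/0.2 fractions", {
  # modes orthogonal to the rigid-body subspace, so superposition does
  # not siphon variance out of the generating directions
  topo <- make_toy_ensemble(10, 0, 2, seed = 1)$topology
  d <- nonrigid_dirs(coords(topo), 2, seed = 5)
  set.seed(6)
  amp <- cbind(rnorm(5000, sd = 0.4), rnorm(5000, sd = 0.2))
  e <- mode_ensemble(amp, d, seed = 7)
  m <- fit_pca(e, stride = 1, n_components = 2)
  expect_lt(abs(m$variance_fraction[1] - 0.8), 0.02)
  expect_lt(abs(m$variance_fraction[2] - 0.2), 0.02)
})

test_that("projection reproduces training scores and PCA identities", {
  e <- make_toy_ensemble(10, 0.4, 60, seed = 8)
  m <- fit_pca(e, stride = 1, n_components = 5)
  proj <- project_frames(e, m)
  sc <- as.matrix(proj[, -1])
  # score variance along PC k equals the eigenvalue
  v <- apply(sc, 2, var)
  expect_equal(v, m$eigenvalues, tolerance = 1e-6, ignore_attr = TRUE)
  # scores are uncorrelated
  cc <- cov(sc)
  expect_true(max(abs(cc[upper.tri(cc)])) < 1e-8)

  # projecting the mean structure gives zero scores
  mean_struct <- gef_ensemble(e$topology,
                              list(matrix(m$center, ncol = 3, byrow = TRUE)))
  expect_true(all(abs(project_frames(mean_struct, m)[, -1]) < 1e-8))

  # explicit matrix-multiply oracle for an independent ensemble
  e2 <- make_toy_ensemble(10, 0.4, 10, seed = 9)
  p2 <- project_frames(e2, m)
  for (i in c(1, 5, 10)) {
    f <- e2$frames[[i]]
    fit <- kabsch(f, m$ref_sel)
    vec <- as.numeric(t(apply_transform(f, fit))) - m$center
    expect_equal(as.numeric(p2[i, -1]), as.numeric(vec %*% m$components),
                 tolerance = 1e-9)
  }
})

test_that("full-rank reconstruction returns the centred coordinates", {
  e <- make_toy_ensemble(8, 0.3, 40, seed = 10)
  m <- fit_pca(e, stride = 1, n_components = 24)  # 3N = 24
  proj <- project_frames(e, m)
  sc <- as.matrix(proj[, -1])
  for (i in c(1, 17, 40)) {
    f <- e$frames[[i]]
    fitted <- apply_transform(f, kabsch(f, m$ref_sel))
    centred <- as.numeric(t(fitted)) - m$center
    recon <- as.numeric(m$components %*% sc[i, ])
    expect_equal(recon, centred, tolerance = 1e-6)
  }
  # variance fractions of all 3N-6 nontrivial components sum to ~1
  expect_equal(sum(m$variance_fraction), 1, tolerance = 1e-6)
})

test_that("PCA spectra are invariant to a global rigid transform", {
  # well-separated spectrum so components are identified up to sign
  topo <- make_toy_ensemble(10, 0, 2, seed = 1)$topology
  d <- nonrigid_dirs(coords(topo), 3, seed = 11)
  set.seed(12)
  amp <- cbind(rnorm(200, sd = 0.8), rnorm(200, sd = 0.4), rnorm(200, sd = 0.2))
  e <- mode_ensemble(amp, d, seed = 13)
  m1 <- fit_pca(e, stride = 1, n_components = 3)
  rot <- qr.Q(qr(matrix(c(1, 2, 0, -1, 1, 3, 2, 0, 1), 3, 3)))
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  e2 <- gef_ensemble(e$topology,
                     lapply(e$frames, function(f) sweep(f %*% rot, 2, c(3, 1, -2), "+")))
  m2 <- fit_pca(e2, stride = 1, n_components = 3)
  expect_equal(m2$eigenvalues, m1$eigenvalues, tolerance = 1e-6)
  expect_equal(m2$variance_fraction, m1$variance_fraction, tolerance = 1e-6)
  # projections agree up to per-component sign
  s1 <- as.matrix(project_frames(e, m1)[, -1])
  s2 <- as.matrix(project_frames(e2, m2)[, -1])
  for (j in 1:3) {
    agree <- max(abs(s2[, j] - s1[, j]))
    flip <- max(abs(s2[, j] + s1[, j]))
    expect_lt(min(agree, flip), 1e-6)
  }
})

test_that("component count is clipped and frame shortage errors", {
  e <- make_toy_ensemble(5, 0.3, 40, seed = 12)
  expect_warning(m <- fit_pca(e, stride = 1, n_components = 50), "clipped")
  expect_lte(length(m$eigenvalues), 15)
  expect_error(fit_pca(e, stride = 20, n_components = 10), "too few frames")
})

test_that("extrema frames match a linear-scan oracle and break ties low", {
  d <- unit_dirs(30, 1, seed = 13)
  amp <- matrix(c(-2, 0, 5, 1, -1), ncol = 1)
  e <- mode_ensemble(amp, d, seed = 14)
  m <- fit_pca(e, stride = 1, n_components = 1)
  proj <- project_frames(e, m)
  ex <- extrema_structures(e, proj, 1)
  s <- proj$PC1
  lo <- proj$frame[which(s == min(s))[1]]
  hi <- proj$frame[which(s == max(s))[1]]
  expect_equal(ex$min_frame, lo)
  expect_equal(ex$max_frame, hi)
  expect_equal(sort(c(ex$min_frame, ex$max_frame)), c(1, 3))
  expect_false(ex$tie)
  expect_error(extrema_structures(e, proj, 5), "out of range")

  # all-equal scores: frame 1 for both, tie flagged
  e0 <- make_toy_ensemble(10, 0, 6, seed = 15)
  m0 <- fit_pca(make_toy_ensemble(10, 0.5, 30, seed = 16), stride = 1,
                n_components = 2)
  p0 <- project_frames(e0, m0)
  p0$PC1 <- rep(0, nrow(p0))
  expect_message(ex0 <- extrema_structures(e0, p0, 1), "scores equal")
  expect_true(ex0$tie)
  expect_equal(ex0$min_frame, 1)
  expect_equal(ex0$max_frame, 1)
})

test_that("random-score extrema match brute-force argmin/argmax", {
  set.seed(17)
  e <- make_toy_ensemble(10, 0.5, 30, seed = 18)
  m <- fit_pca(e, stride = 1, n_components = 3)
  proj <- project_frames(e, m)
  for (pc in 1:3) {
    ex <- extrema_structures(e, proj, pc)
    s <- proj[[paste0("PC", pc)]]
    best_lo <- Inf; best_hi <- -Inf; ilo <- NA; ihi <- NA
    for (i in seq_along(s)) {
      if (s[i] < best_lo) { best_lo <- s[i]; ilo <- i }
      if (s[i] > best_hi) { best_hi <- s[i]; ihi <- i }
    }
    expect_equal(ex$min_frame, proj$frame[ilo])
    expect_equal(ex$max_frame, proj$frame[ihi])
  }
})
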