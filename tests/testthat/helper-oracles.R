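# Independent oracles used to cross-check the implementation. Each is a
# deliberately different algorithm or a brute-force enumeration.

# Minimal superposition RMSD via Horn's quaternion method: the largest
# eigenvalue of the 4x4 quaternion matrix gives the optimal correlation,
# from which the residual follows in closed form. Shares no code with
# the SVD-based Kabsch path.
qcp_rmsd <- function(a, b) {
  a <- sweep(a, 2, colMeans(a))
  b <- sweep(b, 2, colMeans(b))
  m <- crossprod(a, b)
  sxx <- m[1, 1]; sxy <- m[1, 2]; sxz <- m[1, 3]
  syx <- m[2, 1]; syy <- m[2, 2]; syz <- m[2, 3]
  szx <- m[3, 1]; szy <- m[3, 2]; szz <- m[3, 3]
  k <- matrix(c(
    sxx + syy + szz, syz - szy,        szx - sxz,        sxy - syx,
    syz - szy,       sxx - syy - szz,  sxy + syx,        szx + sxz,
    szx - sxz,       sxy + syx,       -sxx + syy - szz,  syz + szy,
    sxy - syx,       szx + sxz,        syz + szy,       -sxx - syy + szz
  ), 4, 4, byrow = TRUE)
  lam <- max(eigen(k, symmetric = TRUE, only.values = TRUE)$values)
  e <- sum(a^2) + sum(b^2) - 2 * lam
  sqrt(max(e, 0) / nrow(a))
}

# All-pairs O(n*m) clash enumeration with explicit loops.
brute_force_clashes <- function(xyz_a, radii_a, xyz_b, radii_b, threshold) {
  hits <- NULL
  for (i in seq_len(nrow(xyz_a))) {
    for (j in seq_len(nrow(xyz_b))) {
      d <- sqrt(sum((xyz_a[i, ] - xyz_b[j, ])^2))
      if (radii_a[i] + radii_b[j] - d >= threshold) {
        hits <- rbind(hits, c(i, j, d))
      }
    }
  }
  if (is.null(hits)) {
    return(data.frame(a_index = integer(0), b_index = integer(0),
                      distance_A = numeric(0)))
  }
  data.frame(a_index = as.integer(hits[, 1]), b_index = as.integer(hits[, 2]),
             distance_A = hits[, 3])
}

# Exhaustive diagonal-square cluster oracle: tabulate which squares
# [i, j] satisfy the criterion by direct enumeration, then walk left to
# right taking the largest satisfying square at each start.
oracle_clusters <- function(im, threshold, criterion) {
  n <- nrow(im)
  sat <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (i == j) {
        sat[i, j] <- TRUE
      } else {
        vals <- c()
        for (p in i:j) for (q in i:j) if (p != q) vals <- c(vals, im[p, q])
        stat <- if (criterion == "mean_offdiag") mean(vals) else min(vals)
        sat[i, j] <- stat >= threshold
      }
    }
  }
  res <- NULL
  i <- 1
  while (i <= n) {
    j <- max(which(sat[i, i:n])) + i - 1
    res <- rbind(res, c(i, j))
    i <- j + 1
  }
  data.frame(start = res[, 1], end = res[, 2])
}

random_identity_matrix <- function(n, seed) {
  set.seed(seed)
  m <- matrix(runif(n * n, 0, 100), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 100
  m
}

# Affine-gap global alignment score by Gotoh's three-state DP; a gap of
# length L costs open + L * extend (both penalties positive).
gotoh_score <- function(a, b, submat, open, extend) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  neg <- -1e18
  M <- matrix(neg, n + 1, m + 1)
  X <- matrix(neg, n + 1, m + 1)  # gap in b (a against '-')
  Y <- matrix(neg, n + 1, m + 1)  # gap in a
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -(open + (i - 1) * extend)
  for (j in 2:(m + 1)) Y[1, j] <- -(open + (j - 1) * extend)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- submat[a[i - 1], b[j - 1]]
      M[i, j] <- s + max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      X[i, j] <- max(M[i - 1, j] - open - extend, X[i - 1, j] - extend)
      Y[i, j] <- max(M[i, j - 1] - open - extend, Y[i, j - 1] - extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# A hand-written 3-atom PDB snippet with known coordinates.
write_tiny_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  N   ALA A   1      11.104  13.207   2.100  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      12.560  13.300   2.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1      13.000  14.700   1.500  1.00  0.00           C",
    "END"), path)
  path
}

# deterministic small ensemble for reuse across tests
toy_scenario_ensemble <- function(n_res = 20, sigma = 0.3, n_frames = 30,
                                  seed = 7) {
  make_toy_ensemble(n_res, sigma, n_frames, seed)
}

# directions in 3N coordinate space orthogonal to the 6 rigid-body modes
# of a base structure (flattening convention x1,y1,z1,x2,...)
nonrigid_dirs <- function(base, k, seed) {
  n <- nrow(base)
  cen <- sweep(base, 2, colMeans(base))
  trans <- kronecker(rep(1, n), diag(3)) / sqrt(n)   # 3N x 3
  rots <- sapply(1:3, function(ax) {
    e <- c(0, 0, 0); e[ax] <- 1
    as.numeric(t(t(apply(cen, 1, function(x) pracma_cross(e, x)))))
  })
  rigid <- qr.Q(qr(cbind(trans, rots)))
  set.seed(seed)
  d <- matrix(rnorm(3 * n * k), 3 * n, k)
  d <- d - rigid %*% crossprod(rigid, d)
  qr.Q(qr(d))[, seq_len(k), drop = FALSE]
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
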