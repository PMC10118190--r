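test_that("percent identity follows the stated gap conventions", {
  m <- gef_msa(c(a = "ACDEFGHIKL", b = "ACDEFGHIKL"))
  expect_equal(pairwise_identity_matrix(m)["a", "b"], 100)

  m2 <- gef_msa(c(a = "ACDEFGHIKL", b = "ACDEFGHIKV"))
  expect_equal(pairwise_identity_matrix(m2)["a", "b"], 90)

  m3 <- gef_msa(c(a = "AC-DE", b = "ACQDE"))
  expect_equal(pairwise_identity_matrix(m3, "both_ungapped")["a", "b"], 100)
  expect_equal(pairwise_identity_matrix(m3, "alignment_length")["a", "b"], 80)

  expect_error(pairwise_identity_matrix(gef_msa(c(x = "ACDE"))), "at least 2")
})

test_that("identity matrix is symmetric and permutation-consistent", {
  m <- make_synthetic_msa(c(3, 2), 70, 20, 120, seed = 31)
  im <- pairwise_identity_matrix(m)
  expect_equal(as.matrix(im), t(as.matrix(im)), tolerance = 1e-9)
  expect_equal(unname(diag(as.matrix(im))), rep(100, 5))
  perm <- c(4, 1, 5, 2, 3)
  mp <- gef_msa(setNames(m$rows[perm], m$names[perm]))
  imp <- pairwise_identity_matrix(mp)
  expect_equal(as.matrix(imp), as.matrix(im)[perm, perm], tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(rownames(imp), m$names[perm])
})

test_that("diagonal square clusters handle the limiting matrices", {
  all100 <- matrix(100, 5, 5)
  cs <- diagonal_square_clusters(all100, threshold = 35)
  expect_equal(nrow(cs), 1)
  expect_equal(c(cs$start, cs$end), c(1, 5))

  none <- diag(100, 5)
  cs0 <- diagonal_square_clusters(none, threshold = 35)
  expect_equal(nrow(cs0), 5)
  expect_equal(cs0$start, 1:5)
  expect_equal(cs0$end, 1:5)
})

test_that("block matrix yields the designed clusters under both criteria", {
  im <- matrix(10, 6, 6)
  im[1:3, 1:3] <- 50
  im[4:6, 4:6] <- 60
  diag(im) <- 100
  for (crit in c("mean_offdiag", "min_pairwise")) {
    cs <- diagonal_square_clusters(im, threshold = 35, criterion = crit)
    expect_equal(cs$start, c(1, 4))
    expect_equal(cs$end, c(3, 6))
    orc <- oracle_clusters(im, 35, crit)
    expect_equal(cs$start, orc$start)
    expect_equal(cs$end, orc$end)
  }
})

test_that("cluster finder matches the exhaustive oracle on random matrices", {
  for (s in 1:60) {
    im <- random_identity_matrix(8, seed = 1000 + s)
    for (crit in c("mean_offdiag", "min_pairwise")) {
      got <- diagonal_square_clusters(im, 35, crit)
      want <- oracle_clusters(im, 35, crit)
      expect_identical(got$start, as.integer(want$start))
      expect_identical(got$end, as.integer(want$end))
    }
  }
})

test_that("raising the threshold never grows a leading cluster", {
  # for a greedy left-to-right scan the guaranteed monotonicity is on the
  # first interval: its square-satisfaction is monotone in the threshold
  for (s in 1:20) {
    im <- random_identity_matrix(8, seed = 2000 + s)
    for (crit in c("mean_offdiag", "min_pairwise")) {
      ends <- vapply(c(20, 35, 50, 65, 80), function(th) {
        diagonal_square_clusters(im, th, crit)$end[1]
      }, numeric(1))
      expect_true(all(diff(ends) <= 0))
    }
  }
})

test_that("average identity finds the family outlier", {
  im <- matrix(40, 3, 3); diag(im) <- 100
  rownames(im) <- colnames(im) <- c("x", "y", "z")
  avg <- average_identity(structure(im, class = c("identity_matrix", "matrix", "array")))
  expect_equal(as.numeric(avg), rep(40, 3))

  im2 <- matrix(c(100, 10, 20, 10, 100, 70, 20, 70, 100), 3, 3,
                dimnames = list(c("obs", "b", "c"), c("obs", "b", "c")))
  avg2 <- average_identity(im2)
  expect_equal(unname(avg2["obs"]), 15)
  expect_equal(attr(avg2, "min_label"), "obs")

  # random symmetric matrix vs direct row-sum oracle
  im3 <- random_identity_matrix(7, seed = 33)
  rownames(im3) <- colnames(im3) <- letters[1:7]
  avg3 <- average_identity(im3)
  oracle <- (rowSums(im3) - 100) / 6
  expect_equal(as.numeric(avg3), unname(oracle), tolerance = 1e-12)
})

test_that("key-residue divergence counts deviations from the majority", {
  m <- gef_msa(c(s1 = "MKTAY", s2 = "MKTAY", s3 = "MKTAY", q = "MKTAY"))
  d0 <- key_residue_divergence(m, "q", 1:5)
  expect_equal(attr(d0, "count"), 0)

  # query deviates from a unanimous majority at columns 2 and 4 of 5
  m2 <- gef_msa(c(s1 = "MKTAY", s2 = "MKTAY", s3 = "MKTAY", q = "MGTCY"))
  d2 <- key_residue_divergence(m2, "q", 1:5)
  expect_equal(attr(d2, "count"), 2)
  expect_equal(d2$column[d2$deviates], c(2, 4))

  # a column below quorum is excluded as not conserved
  m3 <- gef_msa(c(s1 = "MA", s2 = "MC", s3 = "MD", s4 = "ME", q = "MK"))
  d3 <- key_residue_divergence(m3, "q", 1:2, quorum = 0.8)
  expect_equal(attr(d3, "n_conserved"), 1)
  expect_equal(attr(d3, "count"), 0)
  expect_false(d3$conserved[d3$column == 2])

  expect_error(key_residue_divergence(m3, "q", 7), "out of range")
  expect_error(key_residue_divergence(m3, "nope", 1), "not found")
})

test_that("reference-numbered positions map through gaps", {
  m <- gef_msa(c(ref = "MK-TAY", q = "MKQTCY", o1 = "MK-TAY", o2 = "MK-TAY"))
  # position 4 of ref's ungapped sequence (A) is alignment column 5
  d <- key_residue_divergence(m, "q", 4, reference_label = "ref")
  expect_equal(d$column, 5)
  expect_true(d$deviates)
})

test_that("global alignment matches an independent Gotoh oracle", {
  id <- global_align("ACDEFGHIKL", "ACDEFGHIKL")
  expect_equal(id$identity, 100)
  expect_false(grepl("-", id$aligned_a))

  b62 <- getFromNamespace("get_substitution_matrix", "gefprobe")("BLOSUM62")
  got <- global_align("HEAGAWGHEE", "PAWHEAE", gap_open = 10, gap_extend = 0.5)
  want <- gotoh_score("HEAGAWGHEE", "PAWHEAE", b62, 10, 0.5)
  expect_equal(got$score, want, tolerance = 1e-9)

  for (s in 1:10) {
    set.seed(s)
    aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    x <- paste(sample(aa, 12, replace = TRUE), collapse = "")
    y <- paste(sample(aa, 9, replace = TRUE), collapse = "")
    expect_equal(global_align(x, y)$score,
                 gotoh_score(x, y, b62, 10, 0.5), tolerance = 1e-9)
    # score symmetry and identity bounds
    expect_equal(global_align(x, y)$score, global_align(y, x)$score,
                 tolerance = 1e-9)
    idn <- global_align(x, y)$identity
    expect_gte(idn, 0); expect_lte(idn, 100)
  }
  expect_error(global_align("", "ACD"), "empty")
})

test_that("bundled synthetic ortholog pair shows >= 90% identity", {
  fa <- system.file("extdata", "rhoa_orthologs_synthetic.fasta",
                    package = "gefprobe")
  seqs <- read_fasta_sequences(fa)
  expect_length(seqs, 2)
  aln <- global_align(seqs[[1]], seqs[[2]])
  expect_gte(aln$identity, 90)
})

test_that("MSA readers round-trip FASTA alignments", {
  m <- make_synthetic_msa(c(2, 2), 80, 20, 60, seed = 34)
  p <- tempfile(fileext = ".fasta")
  writeLines(paste0(">", m$names, "\n", m$rows), p)
  m2 <- read_msa(p)
  expect_equal(m2$rows, m$rows)
  expect_equal(m2$names, m$names)
})
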