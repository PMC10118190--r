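carbon_pair <- function(d) {
  mk <- function(x, resno) gef_structure(data.frame(
    serial = 1, name = "CA", resname = "ALA", chain = "A", resno = resno,
    x = x, y = 0, z = 0, element = "C"))
  list(a = mk(0, 1), b = mk(d, 2))
}

test_that("vdW overlap arithmetic decides clashes", {
  p <- carbon_pair(4.0)          # sum of radii 3.4, no overlap
  r <- detect_clashes(p$a, p$b)
  expect_equal(r$n_clashes, 0)
  expect_true(r$is_compatible)

  p2 <- carbon_pair(2.0)         # overlap 1.4 >= 0.4
  r2 <- detect_clashes(p2$a, p2$b)
  expect_equal(r2$n_clashes, 1)
  expect_equal(r2$pairs$overlap_A, 1.4, tolerance = 1e-9)
  expect_false(r2$is_compatible)

  # just below the threshold: overlap 0.39 is tolerated
  p3 <- carbon_pair(3.4 - 0.39)
  expect_equal(detect_clashes(p3$a, p3$b)$n_clashes, 0)
})

test_that("clash set equals brute-force enumeration on random clouds", {
  set.seed(21)
  mk_cloud <- function(n, offset, chain) gef_structure(data.frame(
    serial = seq_len(n), name = "CA", resname = "ALA", chain = chain,
    resno = seq_len(n), x = runif(n, 0, 10) + offset,
    y = runif(n, 0, 10), z = runif(n, 0, 10),
    element = sample(c("C", "N", "O", "S"), n, replace = TRUE)))
  a <- mk_cloud(50, 0, "A")
  b <- mk_cloud(50, 5, "B")
  got <- detect_clashes(a, b)$pairs
  want <- brute_force_clashes(coords(a), vdw_radius(a$atoms$element, quiet = TRUE),
                              coords(b), vdw_radius(b$atoms$element, quiet = TRUE),
                              0.4)
  want <- want[order(want$a_index, want$b_index), ]
  expect_equal(got$a_index, want$a_index)
  expect_equal(got$b_index, want$b_index)
  expect_equal(got$distance_A, want$distance_A, tolerance = 1e-9)
})

test_that("residue maps pair anchors correctly in both modes", {
  sc <- make_binding_scenario(0, 3, seed = 22)
  # user mode identity pairing built by the scenario
  expect_s3_class(sc$map, "residue_map")
  expect_equal(nrow(sc$map), 30)
  expect_equal(sc$map$mobile_resno, sc$map$template_resno)

  # auto mode on identical sequences pairs residue i <-> i
  sel <- atom_selection(chain = "A", resno = c(1, 30))
  auto <- build_residue_map(sc$ensemble$topology, sel, sc$template, sel,
                            mode = "auto")
  expect_equal(auto$mobile_resno, auto$template_resno)
  expect_equal(nrow(auto), 30)
})

test_that("auto mapping skips an insertion and rejects too-few pairs", {
  mk_seq_structure <- function(resnames) gef_structure(data.frame(
    serial = seq_along(resnames), name = "CA", resname = resnames,
    chain = "A", resno = seq_along(resnames),
    x = 3.8 * seq_along(resnames), y = sin(seq_along(resnames)),
    z = cos(seq_along(resnames)), element = "C"))
  base <- c("MET", "ALA", "GLY", "LYS", "THR", "TRP", "GLU", "LEU", "PHE", "VAL")
  with_ins <- append(base, c("PRO", "PRO"), after = 4)  # 2-residue insertion
  s1 <- mk_seq_structure(with_ins)
  s2 <- mk_seq_structure(base)
  sel1 <- atom_selection(resno = c(1, length(with_ins)))
  sel2 <- atom_selection(resno = c(1, length(base)))
  map <- build_residue_map(s1, sel1, s2, sel2, mode = "auto")
  expect_equal(nrow(map), length(base))     # inserted PROs unmapped
  expect_false(any(map$mobile_resno %in% c(5, 6)))
  # mapped pairs preserve the sequence correspondence
  expect_equal(map$template_resno, seq_along(base))

  short_a <- mk_seq_structure(c("ALA", "GLY"))
  short_b <- mk_seq_structure(c("TRP", "PHE"))
  expect_error(build_residue_map(short_a, atom_selection(resno = c(1, 2)),
                                 short_b, atom_selection(resno = c(1, 2)),
                                 mode = "auto"),
               "too few|one-to-one")
})

test_that("compatibility fraction reproduces constructed ground truth", {
  clear <- make_binding_scenario(0, 20, seed = 23)
  r0 <- compatibility_fraction(clear$ensemble, clear$template, clear$map,
                               clear$region_mobile, clear$region_template)
  expect_equal(r0$percent_compatible, 100)

  full <- make_binding_scenario(1, 20, seed = 24)
  r1 <- compatibility_fraction(full$ensemble, full$template, full$map,
                               full$region_mobile, full$region_template)
  expect_equal(r1$percent_compatible, 0)

  sc <- make_binding_scenario(0.3, 100, seed = 25, n_intrude = 30)
  r <- compatibility_fraction(sc$ensemble, sc$template, sc$map,
                              sc$region_mobile, sc$region_template)
  expect_equal(r$percent_compatible, 70)
  expect_equal(r$per_frame$compatible, !sc$intruded)

  # infinite threshold declares everything compatible
  rinf <- compatibility_fraction(sc$ensemble, sc$template, sc$map,
                                 sc$region_mobile, sc$region_template,
                                 overlap_threshold = Inf)
  expect_equal(rinf$percent_compatible, 100)
})

test_that("compatibility is invariant to rigid transforms and frame order", {
  sc <- make_binding_scenario(0.4, 30, seed = 26)
  base <- compatibility_fraction(sc$ensemble, sc$template, sc$map,
                                 sc$region_mobile, sc$region_template)
  rot <- qr.Q(qr(matrix(c(2, 1, 1, -1, 3, 0, 1, 0, 2), 3, 3)))
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  move <- function(f) sweep(f %*% rot, 2, c(4, -7, 2), "+")

  e_mov <- gef_ensemble(sc$ensemble$topology, lapply(sc$ensemble$frames, move),
                        species = sc$ensemble$species)
  t_mov <- sc$template
  t_mov$atoms[, c("x", "y", "z")] <- move(coords(sc$template))
  r2 <- compatibility_fraction(e_mov, t_mov, sc$map,
                               sc$region_mobile, sc$region_template)
  expect_equal(r2$per_frame$compatible, base$per_frame$compatible)
  expect_equal(r2$per_frame$min_distance_A, base$per_frame$min_distance_A,
               tolerance = 1e-9)

  perm <- c(17, 3, 28, seq_len(30)[-c(17, 3, 28)])
  e_perm <- gef_ensemble(sc$ensemble$topology, sc$ensemble$frames[perm])
  r3 <- compatibility_fraction(e_perm, sc$template, sc$map,
                               sc$region_mobile, sc$region_template)
  expect_equal(r3$percent_compatible, base$percent_compatible)
})

test_that("raising the overlap threshold never lowers compatibility", {
  sc <- make_binding_scenario(0.5, 40, seed = 27)
  ths <- c(0.1, 0.4, 1, 2, 5)
  pc <- vapply(ths, function(th) {
    compatibility_fraction(sc$ensemble, sc$template, sc$map,
                           sc$region_mobile, sc$region_template,
                           overlap_threshold = th)$percent_compatible
  }, numeric(1))
  expect_true(all(diff(pc) >= 0))
})

test_that("estimated compatibility converges to 100*(1-p) under Bernoulli truth", {
  p <- 0.3
  sc <- make_binding_scenario(p, 400, seed = 28)
  r <- compatibility_fraction(sc$ensemble, sc$template, sc$map,
                              sc$region_mobile, sc$region_template)
  expect_equal(r$percent_compatible, 100 * mean(!sc$intruded))
  # binomial 3-sigma band around the generating probability
  expect_lt(abs(r$percent_compatible / 100 - (1 - p)),
            3 * sqrt(p * (1 - p) / 400))
})
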