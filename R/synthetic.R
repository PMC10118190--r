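AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# run code under a fixed seed without clobbering the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", .GlobalEnv)) rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# idealized CA helix: ~2.3 A radius, 1.5 A rise, 100 deg/residue gives the
# canonical ~3.8 A CA-CA spacing with a gentle curve
helix_backbone <- function(n_res, origin = c(0, 0, 0)) {
  i <- seq_len(n_res) - 1
  th <- i * 100 * pi / 180
  cbind(2.3 * cos(th) + origin[1],
        2.3 * sin(th) + origin[2],
        1.5 * i + origin[3])
}

ca_topology <- function(resno, chain = "A", origin = c(0, 0, 0),
                        label = "synthetic") {
  xyz <- helix_backbone(length(resno), origin)
  gef_structure(data.frame(
    serial = seq_along(resno), name = "CA", resname = "ALA",
    chain = chain, resno = resno,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], element = "C",
    stringsAsFactors = FALSE), label = label)
}

#' Synthetic flexible-chain ensemble with a known RMSF profile
#'
#' Emulates an MD ensemble of a multidomain chain: an idealized CA
#' backbone (3.8 A spacing, gentle helical curve) is jittered per
#' residue with isotropic Gaussian noise of the requested per-residue
#' sigma, and each frame then receives a random rigid transform so that
#' downstream superposition is genuinely exercised. The expected RMSF of
#' residue i is `sigma_i * sqrt(3)`.
#'
#' @param n_res number of residues (>= 4).
#' @param sigma_profile per-residue jitter sigma in A (scalar recycled).
#' @param n_frames number of frames (>= 2).
#' @param seed integer seed; identical seeds give identical ensembles.
#' @param species species label.
#' @param all_atom add dummy CB and O atoms per residue (for clash-mode
#'   testing); they inherit the residue's jitter.
#' @return a `gef_ensemble`; the generating sigma profile and seed are
#'   attached as attributes `sigma_profile` and `seed`.
#' @export
make_toy_ensemble <- function(n_res, sigma_profile, n_frames, seed,
                              species = "WT", all_atom = FALSE) {
  stopifnot(n_res >= 4, n_frames >= 2)
  sigma <- rep_len(sigma_profile, n_res)
  if (any(sigma < 0)) stop("sigma_profile must be non-negative")
  base_ca <- helix_backbone(n_res)
  if (all_atom) {
    atoms <- do.call(rbind, lapply(seq_len(n_res), function(i) {
      data.frame(name = c("CA", "CB", "O"), resname = "ALA", chain = "A",
                 resno = i, x = base_ca[i, 1] + c(0, 1.0, -0.8),
                 y = base_ca[i, 2] + c(0, 0.9, 0.6),
                 z = base_ca[i, 3] + c(0, -0.5, 0.9),
                 element = c("C", "C", "O"), stringsAsFactors = FALSE)
    }))
    atoms$serial <- seq_len(nrow(atoms))
    topo <- gef_structure(atoms, label = species)
    atom_sigma <- rep(sigma, each = 3)
  } else {
    topo <- ca_topology(seq_len(n_res), label = species)
    atom_sigma <- sigma
  }
  base <- coords(topo)
  n_atoms <- nrow(base)
  frames <- with_seed(seed, {
    lapply(seq_len(n_frames), function(f) {
      jit <- matrix(stats::rnorm(n_atoms * 3, sd = rep(atom_sigma, 3)),
                    n_atoms, 3)
      moved <- base + jit
      sweep(moved %*% random_rotation(), 2, stats::runif(3, -10, 10), "+")
    })
  })
  e <- gef_ensemble(topo, frames, species = species)
  attr(e, "sigma_profile") <- sigma
  attr(e, "seed") <- seed
  e
}

#' Synthetic template-binding scenario with known compatibility truth
#'
#' Ground truth for the binding-compatibility statistic: a template
#' complex (anchor chain A, residues 1-30, plus partner chain B,
#' residues 120-133 at a fixed offset) and a mobile ensemble sharing the
#' anchor geometry, whose loop region (chain A, residues 62-78) is
#' either kept clear of the partner (> 6 A separation) or displaced
#' into it (vdW overlap > 1 A guaranteed) frame by frame. Intruding
#' frames are drawn as seeded Bernoulli trials with probability
#' `p_intrude`, or fixed exactly with `n_intrude`. Every frame carries a
#' random rigid transform.
#'
#' @param p_intrude probability a frame's loop intrudes (0..1).
#' @param n_frames number of frames.
#' @param seed integer seed.
#' @param n_intrude optional exact number of intruding frames
#'   (overrides the Bernoulli draw; which frames intrude is still seeded).
#' @return list with `ensemble`, `template`, `map` (a `residue_map`),
#'   `region_mobile`, `region_template` (`atom_selection`s),
#'   `intruded` (logical ground-truth labels) and `seed`.
#' @export
make_binding_scenario <- function(p_intrude, n_frames, seed,
                                  n_intrude = NULL) {
  stopifnot(p_intrude >= 0, p_intrude <= 1, n_frames >= 1)
  n_anchor <- 30L
  loop_resno <- 62:78
  partner_resno <- 120:133

  anchor_xyz <- helix_backbone(n_anchor)
  partner_xyz <- helix_backbone(length(partner_resno), origin = c(20, 0, 0))
  template <- gef_structure(data.frame(
    serial = seq_len(n_anchor + length(partner_resno)),
    name = "CA", resname = "ALA",
    chain = rep(c("A", "B"), c(n_anchor, length(partner_resno))),
    resno = c(seq_len(n_anchor), partner_resno),
    x = c(anchor_xyz[, 1], partner_xyz[, 1]),
    y = c(anchor_xyz[, 2], partner_xyz[, 2]),
    z = c(anchor_xyz[, 3], partner_xyz[, 3]),
    element = "C", stringsAsFactors = FALSE), label = "template complex")

  # mobile topology: anchor + loop, all chain A
  loop_clear <- helix_backbone(length(loop_resno), origin = c(-20, 0, 0))
  # intruding loop: first atoms sit essentially on top of partner atoms
  loop_hit <- partner_xyz[rep_len(seq_len(nrow(partner_xyz)),
                                  length(loop_resno)), , drop = FALSE] +
    matrix(0.2, length(loop_resno), 3)
  mobile_topo <- gef_structure(data.frame(
    serial = seq_len(n_anchor + length(loop_resno)),
    name = "CA", resname = "ALA", chain = "A",
    resno = c(seq_len(n_anchor), loop_resno),
    x = c(anchor_xyz[, 1], loop_clear[, 1]),
    y = c(anchor_xyz[, 2], loop_clear[, 2]),
    z = c(anchor_xyz[, 3], loop_clear[, 3]),
    element = "C", stringsAsFactors = FALSE), label = "mobile model")

  out <- with_seed(seed, {
    intruded <- if (is.null(n_intrude)) {
      stats::runif(n_frames) < p_intrude
    } else {
      stopifnot(n_intrude >= 0, n_intrude <= n_frames)
      seq_len(n_frames) %in% sample.int(n_frames, n_intrude)
    }
    frames <- lapply(seq_len(n_frames), function(f) {
      loop <- if (intruded[f]) loop_hit else loop_clear
      xyz <- rbind(anchor_xyz, loop)
      sweep(xyz %*% random_rotation(), 2, stats::runif(3, -15, 15), "+")
    })
    list(frames = frames, intruded = intruded)
  })
  ensemble <- gef_ensemble(mobile_topo, out$frames, species = "synthetic")
  anchor_sel <- atom_selection(chain = "A", resno = c(1, n_anchor))
  map <- build_residue_map(mobile_topo, anchor_sel, template, anchor_sel,
                           mode = "user",
                           pairs = data.frame(mobile_chain = "A",
                                              mobile_resno = seq_len(n_anchor),
                                              template_chain = "A",
                                              template_resno = seq_len(n_anchor)))
  list(ensemble = ensemble, template = template, map = map,
       region_mobile = atom_selection(chain = "A",
                                      resno = range(loop_resno)),
       region_template = atom_selection(chain = "B",
                                        resno = range(partner_resno)),
       intruded = out$intruded, seed = seed)
}

#' Synthetic MSA with designed block-identity structure
#'
#' Builds an alignment whose sequences fall into blocks: members of one
#' block share about `within_identity` percent identity (exact mutation
#' counts at disjoint positions), while sequences from different blocks
#' share about `between_identity` percent (a fixed set of conserved
#' columns, block-specific letters elsewhere). The realized identity
#' matrix is attached for self-validation; realized values land within
#' a few points of the targets.
#'
#' @param block_sizes integer vector, sequences per block.
#' @param within_identity target within-block percent identity.
#' @param between_identity target between-block percent identity
#'   (must be below `within_identity`).
#' @param length alignment length (columns).
#' @param seed integer seed.
#' @return a `gef_msa` with attributes `realized` (identity matrix),
#'   `block` (block index per sequence) and `seed`.
#' @export
make_synthetic_msa <- function(block_sizes, within_identity,
                               between_identity, length, seed) {
  stopifnot(all(block_sizes >= 1), length >= 20)
  if (within_identity <= between_identity) {
    stop("within_identity must exceed between_identity")
  }
  if (within_identity > 100 || between_identity < 0) stop("identities must be in [0, 100]")
  n_blocks <- base::length(block_sizes)
  L <- length
  m_within <- round(L * (100 - within_identity) / 100 / 2)
  n_conserved <- round(L * between_identity / 100)
  if (max(block_sizes) * m_within > L - n_conserved) {
    stop("alignment too short for the requested within-block divergence")
  }
  seqs <- with_seed(seed, {
    conserved <- sample.int(L, n_conserved)
    common <- sample(AA20, L, replace = TRUE)
    base_idx <- sample.int(20, L, replace = TRUE)
    block_anc <- lapply(seq_len(n_blocks), function(b) {
      s <- AA20[(base_idx + b - 1) %% 20 + 1]
      s[conserved] <- common[conserved]
      s
    })
    mutable <- setdiff(seq_len(L), conserved)
    out <- list()
    for (b in seq_len(n_blocks)) {
      s <- block_sizes[b]
      mut_pos <- if (m_within > 0) {
        # disjoint per-member mutation sets, kept off the conserved
        # columns so the between-block identity design is untouched
        split(sample(mutable, s * m_within),
              rep(seq_len(s), each = m_within))
      } else rep(list(integer(0)), s)
      for (j in seq_len(s)) {
        sq <- block_anc[[b]]
        for (p in mut_pos[[j]]) {
          # avoid every block ancestor's letter at this column, so a
          # mutation cannot accidentally raise between-block identity
          forbidden <- unique(vapply(block_anc, `[`, "", p))
          sq[p] <- sample(setdiff(AA20, forbidden), 1)
        }
        out[[sprintf("block%d_seq%d", b, j)]] <- paste(sq, collapse = "")
      }
    }
    out
  })
  msa <- gef_msa(unlist(seqs))
  attr(msa, "realized") <- pairwise_identity_matrix(msa)
  attr(msa, "block") <- rep(seq_len(n_blocks), block_sizes)
  attr(msa, "seed") <- seed
  msa
}

#' Synthetic mant-GDP exchange trace with known rate
#'
#' A flat baseline of `baseline_s` seconds at `a0` (with multiplicative
#' Gaussian noise), then the mono-exponential decay
#' `(a0 - a_plateau) * exp(-k_obs * t') + a_plateau` with additive
#' Gaussian noise, sampled every `sampling_s` seconds — the shape of a
#' plate-reader exchange experiment.
#'
#' @param a0 pre-reaction signal level.
#' @param a_plateau end-point signal (must not exceed `a0`).
#' @param k_obs decay rate constant, per second (>= 0; 0 gives the flat
#'   GEF-inactive-like trace).
#' @param noise_sd Gaussian noise sd (normalized units).
#' @param baseline_s baseline duration, s (default 300).
#' @param duration_s post-reaction recording time, s.
#' @param sampling_s sampling interval, s (1-60).
#' @param seed integer seed.
#' @param condition trace condition label.
#' @return a `kinetic_trace` with attribute `truth`
#'   (list a0, a_plateau, k_obs) and `seed`.
#' @export
make_trace <- function(a0 = 1.0, a_plateau = 0.4, k_obs = 0.01,
                       noise_sd = 0.01, baseline_s = 300,
                       duration_s = 3600, sampling_s = 2, seed = 1,
                       condition = "intrinsic") {
  if (k_obs < 0) stop("k_obs must be >= 0")
  if (a_plateau > a0) stop("a_plateau must not exceed a0 (decay model)")
  if (sampling_s < 1 || sampling_s > 60) stop("sampling_s must be in [1, 60] s")
  time_s <- seq(0, baseline_s + duration_s, by = sampling_s)
  pre <- time_s < baseline_s
  tp <- pmax(time_s - baseline_s, 0)
  signal <- with_seed(seed, {
    s <- numeric(length(time_s))
    s[pre] <- a0 * (1 + stats::rnorm(sum(pre), sd = noise_sd))
    model <- (a0 - a_plateau) * exp(-k_obs * tp[!pre]) + a_plateau
    s[!pre] <- model + stats::rnorm(sum(!pre), sd = noise_sd)
    s
  })
  tr <- kinetic_trace(time_s, signal, t_reaction_start_s = baseline_s,
                      condition = condition, gtpase = "synthetic")
  attr(tr, "truth") <- list(a0 = a0, a_plateau = a_plateau, k_obs = k_obs)
  attr(tr, "seed") <- seed
  tr
}

#' Write a synthetic scenario to disk in the formats the analyses read
#'
#' Generates one scenario kind and writes the same PDB/FASTA/CSV files
#' the analysis functions consume, plus a `ground_truth.json` recording
#' the generating parameters and labels.
#'
#' @param kind `"ensemble"`, `"binding"`, `"msa"` or `"trace"`.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed.
#' @param params named list of generator arguments overriding defaults.
#' @return invisible list of the generated objects.
#' @export
export_synthetic <- function(kind = c("ensemble", "binding", "msa", "trace"),
                             out_dir, seed, params = list()) {
  kind <- match.arg(kind)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gt <- list(kind = kind, seed = seed)
  objs <- switch(kind,
    ensemble = {
      a <- utils::modifyList(list(n_res = 40, sigma_profile = 0.3,
                                  n_frames = 50), params)
      e <- make_toy_ensemble(a$n_res, a$sigma_profile, a$n_frames, seed)
      write_structure(e, file.path(out_dir, "ensemble.pdb"))
      gt$parameters <- a
      list(ensemble = e)
    },
    binding = {
      a <- utils::modifyList(list(p_intrude = 0.3, n_frames = 100), params)
      sc <- make_binding_scenario(a$p_intrude, a$n_frames, seed,
                                  n_intrude = a$n_intrude)
      write_structure(sc$ensemble, file.path(out_dir, "ensemble.pdb"))
      write_structure(sc$template, file.path(out_dir, "template.pdb"))
      gt$parameters <- a
      gt$intruded <- sc$intruded
      gt$percent_compatible_truth <- 100 * mean(!sc$intruded)
      sc
    },
    msa = {
      a <- utils::modifyList(list(block_sizes = c(3, 3), within_identity = 60,
                                  between_identity = 10, length = 200), params)
      m <- make_synthetic_msa(a$block_sizes, a$within_identity,
                              a$between_identity, a$length, seed)
      writeLines(paste0(">", m$names, "\n", m$rows),
                 file.path(out_dir, "alignment.fasta"))
      gt$parameters <- a
      gt$block <- attr(m, "block")
      list(msa = m)
    },
    trace = {
      a <- utils::modifyList(list(a0 = 1.0, a_plateau = 0.4, k_obs = 0.01,
                                  noise_sd = 0.01, duration_s = 3600,
                                  sampling_s = 2), params)
      tr <- make_trace(a$a0, a$a_plateau, a$k_obs, a$noise_sd,
                       duration_s = a$duration_s, sampling_s = a$sampling_s,
                       seed = seed)
      write_trace_csv(tr, file.path(out_dir, "trace.csv"))
      gt$parameters <- a
      list(trace = tr)
    })
  jsonlite::write_json(gt, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(objs)
}
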