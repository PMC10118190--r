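# gefprobe

Tools for deciding whether a candidate Dbl-family guanine nucleotide
exchange factor (GEF) is competent to activate a Rho GTPase, from three
independent directions:

1. **Conformational ensembles.** Kabsch least-squares superposition,
   per-frame RMSD, per-residue RMSF, Cartesian-coordinate PCA, and the
   package's headline statistic: the *fraction of ensemble frames that
   are sterically compatible with GTPase binding*. Each frame is aligned
   onto a template GEF:GTPase complex (e.g. the Dbs:RhoA crystal
   structure) through an anchor-domain residue map, and a predefined
   loop region is tested against the GTPase for van der Waals clashes
   (overlap ≥ 0.4 Å, heavy atoms, both configurable). A frame "binds"
   when it has zero clashing pairs.
2. **Sequences.** Percent-identity matrices from MSAs, subfamily
   clustering as the largest diagonal square neighborhoods holding at
   least a threshold identity (35% by default), per-member average
   identity, divergence counts of one sequence at key interface columns,
   and Needleman–Wunsch global alignment (BLOSUM62, affine gaps) for
   cross-species identity.
3. **Exchange kinetics.** Plate-reader mant-GDP fluorescence traces are
   normalized by the mean signal of the 300 s baseline before the
   reaction start, the decay phase is fitted to

   f(t) = (a₀ − a_plateau)·e^(−k_obs·t) + a_plateau,

   and GEF arms are classified against intrinsic exchange by the fold
   change of k_obs with a bootstrap confidence interval: *active* when
   fold ≥ 2 and the CI excludes 1, *inactive* when the CI upper bound is
   below 2, otherwise *indeterminate*.

Every analysis has a seeded synthetic-data generator with known ground
truth (ensembles with designed flexibility, binding scenarios with
planted loop intrusions, block-structured MSAs, exchange traces), so the
whole pipeline is testable end to end without any external data.

Readers for single- and multi-model PDB, FASTA/Clustal MSAs and trace
CSVs are included; a YAML-configured `run_pipeline()` orchestrates all
stages and writes CSV artifacts plus a deterministic JSON report.

## Worked example

```r
library(gefprobe)

# a binding scenario with exactly 30 of 100 frames intruding the GTPase site
sc <- make_binding_scenario(p_intrude = 0.3, n_frames = 100,
                            seed = 40001, n_intrude = 30)
res <- compatibility_fraction(sc$ensemble, sc$template, sc$map,
                              sc$region_mobile, sc$region_template)
res
#> <compatibility_result> synthetic: 70/100 frames binding-compatible (70.0%)

# exchange kinetics: simulate an intrinsic-rate trace and refit it
tr  <- make_trace(a0 = 1.0, a_plateau = 0.4, k_obs = 0.01,
                  noise_sd = 0.01, duration_s = 3600, sampling_s = 5, seed = 101)
fit <- fit_monoexponential(normalize_trace(tr))
fit
#> <exchange_fit> k_obs = 0.009884 /s (se 9.8e-05), a0 = 0.9985, plateau = 0.3998
```

The compatibility percentage is exactly the planted truth (70 of 100
frames were constructed clash-free), and the fitted rate recovers the
generating k_obs = 0.01 s⁻¹ to a fraction of a percent with an honest
standard error.

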