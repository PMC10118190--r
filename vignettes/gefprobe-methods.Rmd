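---
title: "Methods: steric, kinetic and sequence probes of Rho GEF competence"
author: "gefprobe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: steric, kinetic and sequence probes of Rho GEF competence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gefprobe)
```

# The scientific question

Dbl-family GEFs activate Rho GTPases through their tandem DH-PH module.
Whether an unusual family member — obscurin's RhoGEF region is the
motivating case — can actually catalyse nucleotide exchange is asked
here from three independent directions: does its conformational
ensemble leave the GTPase-binding surface sterically accessible, does
its sequence retain the interface residues the subfamily conserves, and
do fluorescence exchange assays show any acceleration over the
intrinsic rate? This vignette documents the models, defaults and
numerical choices behind each analysis, and what the synthetic
benchmarks do and do not demonstrate.

# Structures and ensembles

Structures are ordered atom tables parsed from PDB ATOM/HETATM records
by the package's own fixed-column reader; multi-model files (MODEL /
ENDMDL) become ensembles, one frame per model, with several files
concatenated in argument order the way replicate trajectories of one
species are merged. Author residue numbering is authoritative and never
remapped, so residue ranges such as a clashing loop "62–78" are local
to the input file. The first alternate location wins; insertion codes
are rejected outright because the intended inputs (predicted models,
MD snapshots) never carry them. Unknown elements fall back to a 1.70 Å
van der Waals radius with a warning; the table itself uses the standard
values (C 1.70, N 1.55, O 1.52, S 1.80, H 1.20 Å).

# Superposition, RMSD, RMSF

Rigid-body fits use the Kabsch algorithm (SVD of the cross-covariance,
reflection branch excluded), and the independent test oracle is Horn's
quaternion eigenvalue method. RMSD series superpose each frame on a
reference — frame 1 by default, since trajectory starts are the usual
anchor when no minimized reference exists — over CA atoms, a selection
robust to side-chain noise. RMSF uses an iteratively refined average
structure (superpose, re-average; two passes) as reference, then
reports per-residue `sqrt(mean |x - <x>|^2)` averaged over the selected
atoms of each residue. Because every atom participates in the fit, a
single highly mobile residue pulls the frame slightly toward itself;
with ~40 residues this deflates its apparent RMSF by ~3–4% relative to
the generative σ√3, which is why the closed-form benchmark is asserted
at a 5% band. The iterative reference makes the profile invariant to
frame order only up to fit convergence (~1e-6 relative), which the
tests reflect.

Mean RMSDs across species are compared with classic one-way ANOVA
(delegated to a linear-model fit); because p-values alone say little at
MD sample sizes, the η² effect size is always reported alongside, and
the all-values-identical case is flagged as degenerate rather than
returning 0/0.

# Coordinate PCA

PCA is run on superposed, mean-centred Cartesian CA coordinates —
covariance, not correlation, and mass-unweighted, matching common
trajectory practice. Frames are subsampled with a stride of 5 by
default (the conventional thinning for long merged trajectories; the
stride used is recorded in the model). Components follow the sign
convention that their largest-magnitude coefficient is positive, making
outputs platform-stable. Projection superposes new frames onto the
model's reference and dots the centred coordinates with the components;
because the average of optimally superposed frames is itself optimally
aligned, projecting the mean structure gives exactly zero scores, and
training-frame score variances equal the eigenvalues to numerical
precision. Variance fractions are eigenvalues over the total coordinate
variance; after superposition the six rigid-body modes carry (numerically)
zero variance, so fractions over all components sum to 1 up to a
residual below 1e-6 on the benchmarks. Replicates of one species are
concatenated before fitting; a joint fit over several species (with
per-species projection bookkeeping) supports cross-species score maps.

# Binding-compatibility statistic

The headline statistic asks, frame by frame: if the GEF's anchor domain
is superposed onto the corresponding domain of a template GEF:GTPase
complex, does a defined mobile region collide with the GTPase? The
anchor correspondence is a one-to-one residue map, either supplied or
derived by global sequence alignment of the anchor sequences with CA
atoms paired at aligned non-gap columns — the right tool when the
mobile protein and the template GEF are homologous but not identical.
Superposition uses the mapped CA atoms only. A clash is a van der Waals
overlap of at least 0.4 Å (the conventional serious-clash cutoff),
heavy atoms only by default; both the threshold, an all-atom toggle and
a plain distance-cutoff mode are exposed because published "clash"
criteria vary and the choice should be visible. A frame is compatible
with zero clashing pairs (`max_clashes` relaxes this), and the statistic
is the percentage of compatible frames per species. All per-frame
transforms act on copies; inputs are never mutated. The stride is 1
here by default — clash counting is cheap and there is no reason to
discard frames.

The synthetic binding scenario plants loop intrusions with guaranteed
overlap (> 1 Å) or guaranteed clearance (> 6 Å), so the statistic must
reproduce the planted percentage *exactly*, and every frame's clash set
is checked against an all-pairs brute-force oracle. Benchmark sizes:
100 frames, 47 mobile atoms against a 14-atom target region — small
enough to enumerate, large enough to exercise every code path.

# MSA identity, clustering, divergence

Percent identity counts columns where both sequences carry the same
non-gap residue, divided by the number of columns where both are
ungapped (default; the full alignment length is the alternative, both
reported with the matrix). Subfamily clusters are the largest possible
square neighborhoods along the matrix diagonal satisfying the identity
threshold, found by a greedy left-to-right scan that takes the largest
satisfying square at each start; sequence order is the MSA input order,
as in a heatmap. "At least 35% identity" is ambiguous between the
square's mean off-diagonal identity and its minimum pairwise identity;
the mean is the default, the minimum is offered as a strict mode, and
the finder is verified against exhaustive enumeration under both. Two
caveats worth knowing: with block identities of 60 within / 10 between,
a square spanning a 3-block plus one outsider has a mean of exactly
35, so the mean criterion merges at that boundary where the strict mode
does not; and for an order-dependent greedy partition, raising the
threshold is only guaranteed to shrink the leading cluster — a
higher-threshold cluster can straddle a lower-threshold boundary
further down the diagonal.

Key-residue divergence audits a set of alignment columns (supplied
directly or in the ungapped numbering of a named reference row): the
majority residue among the non-query sequences must reach a
conservation quorum (0.8 by default — "highly conserved" made
operational) for the column to count, and the query is flagged where it
differs from that majority. Global alignment delegates to Biostrings'
Needleman–Wunsch with BLOSUM62, gap open 10 and extend 0.5 (a gap of
length L costs open + L·extend, the EMBOSS-needle-like convention); an
independent Gotoh dynamic program verifies scores in the tests. The
bundled ortholog FASTA used for the ≥ 90% cross-species identity check
is a synthetic pair (190 residues, 12 substitutions, ~93.7% identity),
clearly labelled as such — it stands in for user-supplied ortholog
sequences, which the reader accepts in plain FASTA.

# Exchange kinetics

Traces are normalized by the mean signal over the 300 s window
preceding the reaction start, which is explicit metadata: the reagent
addition time is known experimentally, and inferring it from the data
risks silent misalignment (a changepoint utility exists but is off by
default). Only the decay phase (t ≥ start, optionally masking a mixing
artifact via `skip_s`) is fitted to the mono-exponential. The fit
itself is Levenberg–Marquardt least squares; initialization uses
variable projection — for fixed k the model is linear in the two
amplitudes, so the profiled SSE is minimized over a log-spaced rate
grid (10⁻⁶–10⁰·⁵ s⁻¹) and refined before the nonlinear fit. This makes
recovery robust from plateau-free slow decays (k·T < 1 over a 2 h
record) to near-instant ones, with median relative error under 5% at
σ = 0.01 noise across the 10⁻⁴–10⁻¹ s⁻¹ grid (100 traces per rate in
the benchmarks; sampling 2–15 s and records of 1–2 h, matched to the
rate as an experimenter would choose them). A trace whose head-to-tail
drop is within 3 standard deviations of the tail noise is flagged
`no_decay` with k_obs = 0 and `converged = FALSE` — the signature of an
inactive GEF arm, not an error.

Activation calls compare arms by the fold change of mean k_obs.
Replicates are fitted individually and then aggregated (fitting the
averaged trace is available but hides replicate scatter). The 95% CI of
the fold comes from a nonparametric bootstrap over replicate fits when
each arm has ≥ 3, else from delta-method propagation of fit standard
errors. The decision rule — active iff fold ≥ 2 and the CI excludes 1;
inactive iff the CI upper bound is below 2 — replaces eyeballed
"indistinguishable from intrinsic" with a tunable, documented
threshold. In 200-replicate simulations the null (equal generating
rates, n = 3 per arm) is called inactive and the 10-fold scenario
active in ≥ 95% of runs each.

# Synthetic data: what it shows, what it does not

All generators are pure functions of an integer seed (R's
Mersenne-Twister, used inside a scope that restores the caller's RNG
state) and return their ground truth alongside the data. The toy
ensemble is an idealized CA helix (2.3 Å radius, 1.5 Å rise, 100°
per residue — the canonical ~3.8 Å CA spacing) with per-residue
isotropic Gaussian jitter and a random rigid transform per frame, so
superposition is always genuinely exercised. The MSA generator realizes
target identities through exact mutation counts at disjoint,
non-conserved positions, with mutation letters chosen so they cannot
accidentally raise between-block identity. Trace generation follows the
decay model with a flat noisy baseline.

These benchmarks validate the *estimators*: that RMSF recovers known
σ√3, that PCA partitions known variances, that the clash statistic is
exact against planted truth, that k_obs is recovered without bias. They
do not emulate real MD ensembles (no correlated motions, no anharmonic
basins), real alignments (no indel structure beyond what the reader
accepts), or real plate-reader pathologies (drift, photobleaching,
mixing artifacts beyond the maskable first points) — passing them shows
the arithmetic is right, not that any particular biological conclusion
follows from any particular dataset.

# Pipeline and reproducibility

`run_pipeline()` takes a single YAML (or list) configuration, executes
the enabled stages in dependency order, writes every stage's CSV
artifacts and a consolidated JSON report, and dumps the effective
configuration next to them. Stage seeds derive from the master seed, so
identical configurations reproduce the report byte for byte; the report
records the package version and a hash of the configuration (excluding
the output location). A failing stage aborts with the stage name and
leaves a FAILED marker beside any partial outputs. Default benchmark
sizes throughout (30–100 frames, 40-residue chains, 5 000-frame PCA
checks, 200-replicate call simulations) were chosen so the whole suite
exercises every path in a couple of minutes on one core while keeping
Monte-Carlo error well inside each asserted tolerance.
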