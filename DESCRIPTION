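Package: gefprobe
Title: Steric, Kinetic and Sequence Analysis of Rho GEF Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for asking whether a candidate Dbl-family guanine
    nucleotide exchange factor (GEF) is structurally and kinetically
    competent to act on a Rho GTPase. Reads single- and multi-model PDB
    files into light-weight structure and ensemble containers; performs
    Kabsch least-squares superposition, per-frame RMSD series,
    per-residue RMSF profiles and Cartesian-coordinate principal
    component analysis of conformational ensembles; scores each ensemble
    frame for steric compatibility with GTPase binding by aligning it
    onto a template GEF:GTPase complex and detecting van der Waals
    clashes between defined regions; computes percent-identity matrices,
    diagonal square-neighborhood clusters and key-residue divergence from
    multiple sequence alignments; and fits mono-exponential mant-GDP
    exchange traces to extract observed rate constants and classify GEF
    activation against intrinsic exchange. Seeded synthetic-data
    generators with known ground truth accompany every analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    Biostrings,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
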