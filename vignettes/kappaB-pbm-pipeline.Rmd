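---
title: "Designing and analysing kappaB protein binding microarrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and analysing kappaB protein binding microarrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kappaBarray)
```

## The measurement and the model

A protein binding microarray (PBM) presents a transcription factor
with thousands of double-stranded DNA probes and reads two
fluorescence channels per spot: Cy5 for the bound protein and Cy3 for
the double-stranding reaction that made the probe double-stranded in
the first place. The Cy3 value is a per-spot nuisance scale — a spot
that double-stranded poorly offers less binding substrate in exact
proportion — so the Cy5/Cy3 ratio, not Cy5 alone, carries the binding
signal.

`kappaBarray` implements the full loop for NF-κB-family dimers:
design a probe set that covers the κB consensus space, simulate
realistic two-channel intensities from known binding models, recover
per-protein binding profiles, and compare dimers by correlation,
clustering and sequence "barcodes". Because the simulator's generative
model is explicit, every downstream stage has a checkable ground
truth.

## Probe design

The κB site family is written as the degenerate IUPAC consensus
`RGGRNNHHYYB` (11 nt). Its k-mer space — all 6,912 concrete 11-mers —
is too large for one array once flanks and replicates multiply it, so
a representative subset is chosen geometrically:

* **Distance.** Hamming distance between cores. The metric is the
  minimal defensible choice for fixed-length k-mers and is exposed as
  a function (`hamming_matrix()`) rather than hard-wired, so any other
  k-mer metric can be substituted.
* **Embedding.** Classical PCoA (Gower): double-centre −½D², take the
  eigendecomposition, keep positive-eigenvalue axes up to a retained
  mass fraction (default 90%). Hamming matrices are not Euclidean;
  their negative eigenvalues are dropped, per the classical treatment,
  and a warning reports the negative mass (≈45% for this space —
  large, but only the relative geometry of the retained axes is used
  downstream).
* **Selection.** k-medoids in the retained coordinate space, default
  k = 803. Tiny instances are solved exactly by enumeration; moderate
  ones by PAM (build + swap, FastPAM acceleration); large ones by
  seeded CLARA. Points enter in lexicographic k-mer order, so PAM's
  lowest-index tie-break is the lexicographic tie-break. Whether the
  original 803-probe set was a fixed count or a threshold in
  coordinate space is not recoverable; `k` is simply a parameter.
* **Assembly.** Cores × flanks × replicates, default 4 flank variants
  and 3 technical replicates (9,636 features ≤ 15,000). Flank f1
  reproduces the constant context of the κB pulldown oligo
  (`AGCTGGGCAT·core·AACTCT`); f2–f4 are arbitrary GC-balanced
  10/6-mers. Flanks are crossed with cores by default; a nested mode
  is available since the original assignment is unknown. Probes are
  stored 5′→3′ top strand with no reverse-complement deduplication.

The analysis scripts embed a seeded 2,000-k-mer subsample of the space
rather than all 6,912 points; the space is highly redundant under
Hamming distance and the subsample keeps the eigendecomposition and
medoid search cheap on a single core while still covering the
geometry. The test suite and the acceptance script use a 200-core
design from an 800-k-mer subsample for the same reason.

## The synthetic generator

Each protein is an *energy PWM*: a 4 × 10 log-odds matrix plus a
chemical potential μ. A probe's occupancy sums the two-state Boltzmann
term `logistic(score − μ)` over every window on both strands; μ
defaults to 2 score units below the best attainable window score, so
consensus sites are strongly but not saturatingly bound and ranks stay
graded. With noise off, Cy5 is an exact affine function of occupancy —
the closed form the unit tests check.

Intensities follow

$$Cy3_{ir} = \gamma\,\delta_i\,\varepsilon_{ir},\qquad
  Cy5_{ir} = \delta_i\,(\beta_0 + \beta_1\,occ_i)\,\varepsilon'_{ir}$$

with δ ~ LogNormal(0, σ²_ds) drawn once per spot and shared between
channels and replicates (a physical property of the spot), and ε, ε′ ~
LogNormal(0, σ²_meas) independent per row. Defaults: σ_meas = 0.05,
σ_ds = 0.3, β₀ = 100, β₁ = 5000, γ = 1000. The model is built so the
Cy3 normalisation is *exactly* the right correction: δ cancels from
Cy5/Cy3, which the suite verifies by regenerating data at σ_ds = 0 and
0.5 with identical measurement-noise substreams. Per-protein δ, Cy3
and Cy5 noise vectors come from separate seeds derived from the master
seed, so that property holds draw-for-draw, and identical seeds give
bit-identical tables.

What the generator does **not** emulate: spot morphology, scanner
saturation, spatial artifacts, sequence-dependent double-stranding
bias, or cross-hybridisation. Passing tests therefore demonstrate the
correctness of the analysis chain under the stated statistical
assumptions, not instrument-level realism; the real arrays' dynamic
range and noise level are unknown, and the defaults were chosen once
to be discriminating rather than to match hardware.

### The four-dimer suite

No binding models for the four dimers are published, so
`default_dimer_suite()` constructs them to encode the qualitative
biology: `nv_p50_like` and `hs_p52_like` are near-identical symmetric
GGG(R)…CCC κB models with a G-tilted centre; `hs_p50_like` is
5′-indifferent with a strong 3′ CCCC(T/C) preference (so its top
binders include reverse-complement GGGG… matches and T-bearing 3′
ends, degrading the GG..CC half-site symmetry); `relA_like` keeps the
half-site anchors but prefers an A-rich centre, making it the most
divergent. The Frobenius ordering d(nv, p52) < d(nv, p50) <
d(nv, relA) (0.44 < 9.75 < 11.09) is asserted in the tests, and the
end-to-end correlation ordering it induces is checked over 20 seeded
simulations.

## The processing chain

Order of operations: **ratio → log₂ → median → z**.

* Cy5/Cy3 per (feature, protein, replicate); missing partners and zero
  Cy3 are hard errors (the design is a complete factorial by
  construction — no imputation).
* Median of the log₂ ratios per core, pooling the 3 replicates and, by
  default, the 4 flank variants (the symmetric choice when the
  original per-probe summarisation is ambiguous); `per_flank = TRUE`
  keeps flank variants separate. Even counts use the mean-of-middle
  median convention.
* z = (x − median(array)) / sd(array), per protein, with the sample
  (n − 1) standard deviation — at n = 803 the n vs n − 1 choice is
  numerically immaterial, but it is fixed and documented. Every
  produced profile has median(z) = 0 exactly and sd(z) = 1 exactly;
  whether z-scoring should instead be grouped per physical subarray is
  exposed through the grouping of the input table (default: per
  protein).

The chain is invariant to per-protein gain rescaling of either
channel and to σ_ds — both asserted as tests.

## Comparison and barcodes

Profile similarity is Pearson correlation on z-scores (a scatter of
one z-profile against another with a single coefficient is the natural
reading, and Pearson on z equals Pearson on the log₂ summaries up to
centering). Clustering is complete-linkage on Euclidean distances
between z-vectors — "Euclidean distance" and "complete linkage" are
the two compatible named choices — with correlation distance (1 − r)
available as a switch; merge heights are monotone by construction and
are checked against a brute-force O(n³) agglomerative oracle.

A protein's barcode is the position frequency matrix of its top-20
cores by z-score (ties at the cutoff broken lexicographically so the
barcode is deterministic), with no pseudocounts — 20 sequences give
exact frequencies. Information content is 2 + Σ f log₂ f bits per
position. The half-site symmetry score compares the 5′ GG signature
(G frequencies at positions 2–3) with the 3′ CC signature
(C frequencies at positions 9–10) as min/max of the two products,
defined as 1 when both vanish.

## Plate-level statistics

Three closed-form fold statistics accompany the array pipeline:
LUMIER fold-binding ((eluate/lysate) normalised to the control pair),
reporter fold-induction (firefly/renilla per well, means over
triplicates relative to the control mean, sd on the per-replicate
folds), and ChIP fold-enrichment over IgG (efficiency^ΔCt, efficiency
default 2 under a shared-efficiency model, as primer sets validated
for equal efficiency imply). All three are invariant to common
instrument-gain rescaling, and controls map to exactly 1.

## Numerical choices and degenerate inputs

* Eigenvalues below 10⁻⁹ of the spectral radius are treated as zero;
  an all-zero distance matrix yields an empty embedding, and
  `select_representatives` then returns the first k indices.
* Constant arrays (zero sd) and profiles with fewer than 3 cores are
  rejected rather than silently propagated.
* Medoid, sort and top-N ties all resolve lexicographically.
* All randomness flows from one master seed through fixed derived
  substreams; `run_all()` writes a manifest with md5 hashes of every
  artifact, and identical configs give byte-identical outputs.

## Problem sizes

The bundled test fixture is a 32-core × 2-flank × 3-replicate design
from a 256-k-mer subsample; the acceptance script and the stability
checks use 200 cores from an 800-k-mer subsample with 20 simulation
seeds; the analysis scripts run the full 803-core, 9,636-feature
design from a 2,000-k-mer embedding. These sizes were chosen so each
context exercises the same code paths at a cost proportionate to its
role.

## Known limitations

The selected 803 cores are *a* representative set, not *the* original
one — the original selection internals are not recoverable, and no
claim is made of probe-identity reproduction. The simulator's
occupancy model is a standard biophysical stand-in, not a fitted
model; correlation magnitudes from synthetic data depend on the
constructed PWM suite and should be read as structural
(orderings, contrasts), not as estimates of the published
coefficients. Spatial normalisation, quantile normalisation across
arrays and outlier-spot flagging are out of scope.
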