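---
title: "Methods: two-construct DMS analysis of SHP2 auto-inhibition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-construct DMS analysis of SHP2 auto-inhibition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shp2dms)
```

## The scientific problem

SHP2 is a three-domain tyrosine phosphatase whose catalytic (PTP) domain
is auto-inhibited by its N-SH2 domain. A missense variant can change the
enzyme's cellular activity along two distinct axes: by altering the
intrinsic catalytic machinery, or by shifting the closed/open
conformational equilibrium. A single activity assay cannot distinguish
the two. Running the same growth-rescue selection on full-length SHP2
(`FL`) and on the isolated catalytic domain (`PTP`) separates them: the
isolated domain has no auto-inhibition, so only catalytic effects
register there, while the full-length readout convolves both.

This package implements that comparative analysis end to end, together
with a mechanistic simulator that generates sequencing-count data with
known ground truth, so every stage of the analysis can be validated
against planted effects.

## The latent two-axis model

Each variant carries:

* `alpha` — intrinsic catalytic activity relative to wild type;
* `phi` in (0, 1] — the open fraction of the full-length protein. Wild
  type is `phi_wt = 0.05`: predominantly closed, but with enough basal
  activity to support growth under the weak kinase.

Construct activities are `a_FL = alpha * phi` and `a_PTP = alpha`, on a
scale where a fully open wild-type domain has activity 1. This product
structure is what generates the funnel: full-length enrichment can exceed
the catalytic-only expectation by at most the release budget
`log2(1 / phi_wt)` (about 4.3 doublings-per-unit-rate with the default),
because `phi` cannot exceed 1.

## Growth, selection and sequencing noise

Growth is exponential at a Hill-law rate,
`g(a) = g_max * a^h / (a^h + K_half^h)`, with defaults `g_max = 0.35`
divisions/h, `h = 2`, and a 24 h outgrowth. The two kinase pressures
differ only in `K_half`: 0.05 for the weak kinase (`cSrc_KD`) and 0.5
for the strong one (`vSrc_FL`). These values place wild-type FL activity
(`phi_wt = 0.05`) exactly at the weak-kinase midpoint and wild-type PTP
activity (1) near the strong-kinase dynamic range, which is why the
FL+weak and PTP+strong pairings are the informative ones: the derivative
of expected enrichment with respect to log-activity peaks at
`a = K_half`, so each pairing is most discriminating where its library
actually lives.

Sequencing is modeled as independent multinomial draws of `depth` reads
per tile and timepoint (default 1e5), from pre-selection abundances
(expression weight x a log-normal library skew, sdlog 0.3) and
post-selection abundances (pre x `2^(g*T)`). Wild type is present in
every tile at 10x the weight of a single variant — a deliberate stand-in
for the substantial wild-type fraction of real tile libraries, which
also stabilizes the per-tile normalization. There is no PCR-jackpot or
read-error model: reads emitted by `emit_reads()` are error-free and the
counting stage is exact-match by design, which keeps the
reads-to-counts round trip exact and testable.

Randomness is organized as one master seed with per-(construct, tile,
replicate, phase) streams derived by a fixed counter, so identical
configurations reproduce byte-identical outputs and replicates differ
only in their skew and sampling streams.

## The planted landscape

Six mechanistic classes cover the ways a substitution can move the two
axes: `neutral`, `catalytic_dead` (`alpha ~ lognormal(log 0.005, 0.5)`),
`autoinhibition_release` (`phi ~ phi_wt + (1-phi_wt) Beta(10, 2)`),
`dual_activating` (release plus `alpha ~ lognormal(log 3, 0.15)`),
`interface_stabilizing` (`phi ~ phi_wt Beta(2, 18)`), and
`catalytic_up` (`alpha ~ lognormal(log 3, 0.15)`, `phi` unchanged).

The default class mix is 88% neutral with 2–3% in each mechanistic
class. Two considerations fixed these numbers, both decided before any
end-to-end run. First, realism: in a growth assay with a bounded dynamic
range, the large majority of single substitutions in a 593-residue
multi-domain protein read out near neutral, with mechanistic hotspots a
small minority. Second, internal consistency with the analysis scheme:
the full-length score distribution is summarized by a *single* Gaussian
whose +/-2 sigma band sets the significance thresholds, so the planted
tails must remain a small enough fraction that this summary is a
sensible description — exactly the situation the single-Gaussian
treatment presumes. Neutral-class `alpha` gets sdlog 0.1, a modest but
real activity dispersion typical of "tolerated" substitutions; it also
dominates the width of the wild-type-centered score component.

The class assignment is positionally uniform. Real mechanistic classes
cluster in structural space (interface residues, catalytic loops); the
simulator makes no attempt to emulate that, so passing tests demonstrate
statistical recovery of planted effects, not structural realism.

## Scoring

The estimator is the standard DMS ratio of ratios,
`log2((post_v + p)/(pre_v + p)) - log2((post_WT + p)/(pre_WT + p))`,
computed within each tile and replicate against the tile-internal wild
type, with pseudocount `p = 0.5` and a minimum of 10 pre-selection reads
per variant per replicate (both exposed in the configuration). Wild type
scores exactly zero by construction. Cross-tile comparability rests
entirely on the per-tile wild-type anchor; no additional inter-tile
scaling is applied. Missing data propagate as masks and are never
imputed.

Two numerical notes. With `p = 0` the scores are exactly invariant to
rescaling all counts in a tile; with a fixed additive pseudocount the
invariance is only approximate (the shift is of order `p / (count ln 2)`,
i.e. ~0.007 at 100 reads), which is the price of a finite estimator at
zero counts. And replicate QC retains a replicate when it correlates at
Pearson r >= 0.6 with at least one other replicate: this keeps a
concordant pair intact when a third replicate is pure noise (a
median-based rule would not), drops the noise replicate, and degenerates
to "both pass or hard error" with exactly two replicates.

## Distribution fits and significance thresholds

The full-length score distribution is fitted with one Gaussian and the
PTP-domain distribution with a two-component mixture; the component
counts are fixed configuration values, not model-selected, because the
bimodality of the isolated-domain distribution (functional vs
catalytically dead) is a structural feature of the assay, not something
to rediscover per dataset. The two-component fit is a hand-written EM:
k-means initialization, log-space responsibilities, tolerance 1e-8 on
the log-likelihood, at most 500 iterations, best of 10 seeded restarts;
collapsed components (vanishing weight or sd) abort a restart. The EM
monotonicity of the log-likelihood is asserted in tests, and the fit is
cross-checked against an independent mixture implementation (mclust) on
simulated draws.

The wild-type-centered component is the one with mean closest to zero,
and calls are strict: a variant is `up`/`down` only when its score is
strictly more than 2 standard deviations from that component's mean; a
score exactly at the boundary is neutral. Degenerate inputs (all scores
equal, fewer than 50 observations) are hard errors. No multiple-testing
correction is applied — the scheme is a fixed-threshold classification,
not hypothesis testing.

Stop variants are enumerated on request but excluded by default from
fitting and classification; their handling is flag-controlled.

## Funnel regions

The (FL call, PTP call) pair maps to mechanistic regions as: both up →
IV; FL up with PTP neutral or down → I; FL neutral with PTP down → I
(catalytic loss fully compensated by release); FL neutral with PTP up →
IV; both down → II; FL down with PTP neutral → III; both neutral →
neutral. FL down with PTP up has no defined mechanism in this framework
and is reported `unclassified`, never silently binned, as is any pair
involving a missing call. The mapping is total over the 4 x 4 call
space and frozen by an exhaustive oracle in the tests.

## Tiles and genetic accessibility

Tiling is an equal-as-possible ceiling partition with a default capacity
of 42 codons — the unique simple ceiling rule that yields 15 tiles for a
593-codon construct and 7 for a 289-codon one. Earlier tiles take the
remainder codon; downstream code treats boundaries as data, so real tile
tables can be substituted. The accessibility utilities enumerate the
nine single-nucleotide neighbors of each wild-type codon under the
standard genetic code, flagging which amino-acid substitutions are one
mutation away — the relevant constraint when asking why strongly
activating substitutions are absent from clinical databases.

## Structural order parameters

`read_structure()` parses (multi-MODEL) PDB files via bio3d, keeping the
highest-occupancy alternate location per atom, and the metric layer
computes Euclidean distances, set-minimum distances, and signed
dihedrals (psi, chi1) with the standard atan2 formulation; collinear
triplets are errors. The built-in SHP2 metric set encodes, in 4DGP/6CRF
numbering: the R111–E249/E250 terminal-N-to-carboxylate-O minimum
distance, H114–T218 C-alpha distance, T218 psi, W423 CZ3–P429 CG,
F469 chi1, P424 CG–V428 carbonyl, and the D425–C459 C-alpha distance
that tracks WPD-loop closure. State cutoffs (salt bridge < 4.0 A, WPD
closed < 10.0 A) are configuration values flagged as assumptions — no
experimental cutoff is available — and are therefore exercised only on
synthetic structures. The packaged PDB fragment is synthetic (invented
coordinates carrying exactly the atoms the metric set needs); all
geometric operations are validated against independent brute-force
oracles and rigid-motion invariance on random frames instead.

## Problem sizes and runtime

The end-to-end validation runs at the study's own scale: a 593-residue
construct (11,267 missense variants, 15 tiles) and a 289-residue window
(5,491 variants, 7 tiles), 3 replicates, depth 1e5 reads per tile and
timepoint. This completes in a few seconds, so no scaled-down surrogate
is needed; smaller toy proteins appear in unit tests only to keep
fixtures readable.

## Known limitations

* The simulator's classes are positionally uniform and its noise model
  is multinomial-only; recovery rates on synthetic data are upper bounds
  for real libraries with PCR jackpots, read errors and
  expression-level artifacts.
* The single-Gaussian FL summary is adequate only while non-neutral
  tails are a small fraction of the library; a landscape dominated by
  loss-of-function would inflate the 2 sigma band and blunt the calls.
* Scores saturate at both ends of the Hill response, so very large
  catalytic gains compress; ordering among strongly activating variants
  near saturation is not meaningful.
* Only pre/post timepoints are supported (no multi-timepoint
  regression), and only PDB input for structures.
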