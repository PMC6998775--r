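---
title: "Assembling microcrystal diffraction data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembling microcrystal diffraction data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xtalmerge)
```

## The problem

Protein microcrystals rarely survive long enough in an X-ray beam to
yield a complete rotation data set: radiation damage destroys
high-resolution diffraction after a small wedge of perhaps 1-30 degrees
(10-100 frames at 0.1-0.3 degrees per frame). A usable data set must
therefore be assembled from many partial wedges collected on many
crystals. Two obstacles dominate: each crystal's late frames are
progressively damaged, and crystals are not perfectly isomorphous — their
unit cells (and hence their structure factors) vary, sometimes in
discrete classes. Merging incompatible crystals or damaged frames
degrades both the resolution-limiting statistics and any weak anomalous
signal one hopes to phase from.

`xtalmerge` implements a three-step assembly workflow over a table of
integrated, unmerged intensities (one row per observation: crystal,
frame, Miller index, intensity, sigma):

1. **Progressive wedges.** Each crystal's frames are divided into
   `q_total` contiguous base wedges; cumulative wedge *q* contains base
   wedges 1..*q*. Every cumulative wedge is scored by the half-dataset
   correlation CC~1/2~ and the crystal is trimmed to the wedge with the
   maximum score, cutting off damaged tails while keeping as much
   multiplicity as the data support.
2. **Unit-cell classification.** The trimmed crystals are clustered on
   their six cell parameters (agglomerative, single or Ward linkage) and
   cut into *N* classes, so only near-isomorphous crystals are merged
   together.
3. **Iterative rejection.** Within each sufficiently complete class,
   crystals are repeatedly scored by their mean smoothed per-frame
   R~merge~ (⟨SmRmerge⟩) against the current merged reference and the
   worst `xtal_step` removed per iteration; optionally each iteration
   also emits frame-rejected variants over a grid of decay cutoffs. Every
   iteration/decay combination is emitted as a candidate data set, and
   the best is picked by CC~1/2~ (resolution work) or by the
   anomalous-difference correlation DelAnom (phasing work).

## The statistics engine

All quantities the assembly logic consumes are computed internally, so
every decision in the workflow is reproducible from the observation
table alone.

**Scaling.** One multiplicative scale per crystal, fitted in closed form
against a reference crystal (the first by sorted id): *k* minimizes
Σ(I_ref − k·I_crys)² over the per-reflection mean intensities the two
crystals share. There is no B-factor or per-frame term: the rejection
logic needs relative consistency, not absolute scale, and the
closed-form model keeps every downstream number deterministic. Crystals
sharing no reflection with the reference keep *k* = 1 with a warning.

**Merging.** Observations are mapped to a canonical asymmetric unit —
the lexicographic maximum of the orbit under the point-group rotations
and their Friedel images — and combined by the inverse-variance weighted
mean, with merged sigma 1/√(Σ1/σ²). The canonical index always folds a
Bijvoet pair onto one index; a Friedel sign (+1 when a proper rotation
reaches the canonical index, −1 when the inversion is needed) separates
the mates in anomalous mode. This convention needs no per-group
asymmetric-unit tables, is idempotent, and is internally consistent; it
is not claimed to match any external program's ASU choice.

**R factors.** R~merge~ = ΣΣ|I_i − ⟨I⟩| / ΣΣI_i over reflections
measured at least twice, with unweighted means; R~meas~ applies the
multiplicity correction √(n/(n−1)) per reflection. Reflections observed
once contribute to completeness and to the merged output but not to the
R factors or CC~1/2~. Negative intensities are retained everywhere —
they are the post-background-subtraction reality — and are only clamped
at the final amplitude-export step.

**CC~1/2~ and DelAnom.** Both use an explicit random half-split of each
reflection's observations (balanced, seeded, reproducible bit for bit)
rather than the analytic σ²-τ² estimator: the direct construction
matches the definition of a half-dataset correlation and is easy to
verify against closed-form expectations. CC~1/2~ is the Pearson
correlation of the two half-dataset mean vectors. DelAnom is interpreted
as CCanom: the I(+) and I(−) observations of each Bijvoet pair are
halved independently, ΔI = ⟨I(+)⟩ − ⟨I(−)⟩ is formed per half, and the
two ΔI vectors are correlated. Fewer than three usable reflections (or
pairs) yields an explicit undefined value, never a sentinel.

**SmRmerge.** The per-frame trace scores each frame against the merged
class reference: raw(f) = Σ|I_obs − I_ref| / ΣI_ref over the frame's
observations whose reflection exists in the reference. Using the
reference mean in the denominator keeps the statistic defined for frames
whose reflections were observed only once in that crystal. The trace is
smoothed with a Gaussian kernel over frame number (default σ = 2 frames,
truncated at ±3σ, weights renormalized at the series edges and across
gaps). The kernel is a package choice — the upstream definition of the
smoothing is not public — and is configurable; σ = 0 disables smoothing.
Frames with no matchable observations stay undefined: they are skipped
by the kernel, kept by frame rejection (no evidence against them), and
only an entirely undefined profile penalizes its crystal (score +∞,
rejected first).

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `reso` | 2.5 Å | merging/assembly resolution cutoff |
| `reso_cchalf` | `reso` + 1 Å | resolution for wedge CC~1/2~ scoring; lower resolution keeps more frames |
| `wedges` | 10 | progressive wedges per crystal; remainder frames go to the earliest (least damaged) wedges |
| `n_classes` | user | number of unit-cell classes; chosen from the dendrogram |
| `linkage` | ward | `single` keeps the largest class together (anomalous work); `ward` separates classes |
| `xtal_step` | 10 | crystals removed per rejection iteration; the loop stops once the surviving count is ≤ this |
| `decay_sequence` | 5, 3, 2, 1 | frame-rejection grid; cutoff = min(SmRmerge) × (1 + decay), i.e. 6, 4, 3, 2 × the minimum |
| `completeness_threshold` | 90% | classes at or below the gate emit their merged data set but skip both rejection loops |
| `kernel_sigma` | 2 frames | SmRmerge smoothing width |

Tie-breaking is deterministic throughout: equal wedge CC~1/2~ prefers
the larger wedge (multiplicity at equal quality); equal crystal scores
reject in ascending id order; equal criterion values in the final
selection prefer fewer rejections (earlier iteration, then larger decay,
then more crystals); clustering ties follow `hclust`'s deterministic
merge order on the standardized features.

Cell features are z-scored per parameter before clustering, which
removes the angle-versus-length unit problem; parameters with zero
variance (symmetry-fixed angles) become zero columns rather than
division errors. The choice of raw-versus-normalized features is a
design decision of this package, documented here rather than inherited.

The stopping rule emits the final (≤ `xtal_step` crystals) data set
rather than discarding it: data sets at different crystal counts are the
product of the workflow, and the last point of the ladder is often the
most aggressive rejection worth inspecting.

## The synthetic microcrystal generator

The simulator produces the study conditions the workflow targets: *M*
crystals (default 20), each a contiguous rotation wedge of 10-100 frames
at 0.1-0.3 degrees per frame, with class-structured unit cells, Wilson
(exponential) true intensities with mean `intensity_scale` ×
exp(−B·s²/2) (default B = 15 Å²), per-frame damage B(f) = b0 + β·max(0,
f − onset) (default β = 0.3 Å² per frame, onset 0), Gaussian noise with
sd √(I/gain + σ0²) reported honestly in the sigma column, optional
antisymmetric Bijvoet perturbations of relative scale
`anomalous_fraction`, and optional "bad" crystals whose noise (and
sigma) is multiplied.

Wedge geometry is emulated combinatorially, not with an Ewald-sphere
model: the full ± index sphere is laid out in a seeded random sweep
order, and each frame observes a contiguous window of it, consecutive
frames overlapping (`overlap` = 2 by default) so reflections recur on
neighboring frames as they do while crossing the diffracting condition.
The assembly logic consumes only (crystal, frame, hkl, I, σ), so full
rotation geometry would add nothing testable. Consequences worth
knowing: coverage of the unique set grows as 1 − (1 − L/T)^M for M
random arcs of fractional length L/T, sharpened by the point-group
multiplicity folding the sphere onto the unique set; and partiality,
absorption, detector geometry and site-specific radiation chemistry are
absent. Passing tests on this substrate demonstrate the correctness of
the assembly logic and statistics, not robustness to integration
artifacts of real detector data.

All randomness descends from one master seed; crystal *i* draws from
derived seed `seed + i`, so editing one crystal's specification never
perturbs another crystal's data. A zero noise model (`noise_gain = Inf`,
`sigma0 = 0`) produces exact intensities with unit sigmas reported, which
gives the exact end-to-end oracles: R~merge~ = 0, CC~1/2~ = 1, DelAnom =
1 when anomalous signal is planted. The simulator's self-consistency
oracle is parameter recovery: regressing log(I_obs/I_true) on f·s²
recovers β within 10% at default noise.

## Numerical choices and degenerate inputs

- Index enumeration bounds each axis by ⌊length/dmin⌋, which cannot miss
  a reflection because |h| ≤ a/d always.
- Undefined statistics are `NA`, never 0 or −∞: a wedge with no repeated
  observation, an R factor with no multiply-observed reflection, a
  correlation with fewer than three points.
- Classes with fewer than two crystals, or failing the completeness
  gate, emit their iteration-0 merged data set and skip the loops;
  empty or unscalable classes are logged and skipped, never fatal.
- Amplitude export is the clamped square root F = √max(I, 0) with
  σF = σI/(2F) — deliberately *not* a French-Wilson estimate; it exists
  so a complete run ends in amplitudes with a seeded 5% free set, and is
  documented as a simplification.
- Frames are 1-based and contiguous on input, matching rotation-series
  image numbering; frame rejection may leave gaps in derived data sets,
  which are handled throughout.
- Monoclinic cells use unique axis b, the crystallographic convention.

## Problem sizes

The test suite and the acceptance script run studies of 1-25 crystals
with cells of 10-50 Å, resolution limits of 2.2-4 Å, and 10-60 frames
per crystal — a few thousand to a few tens of thousands of observations
per study. These sizes were chosen so that every property (including the
5-seed damage-onset localization and the 50-cell completeness sweep)
reruns in well under a minute each while keeping per-wedge reflection
counts large enough for stable correlation statistics.

## Known limitations

- The canonical-ASU convention is internally consistent but not aligned
  with external merging programs; exported tables should be re-indexed
  before comparison with other pipelines.
- The single-scale model ignores per-frame scale variation and B-factor
  differences; strongly non-isomorphous crystals are handled by the
  classification step, not by the scale model.
- DelAnom follows the CCanom interpretation; other definitions (e.g.
  mid-slope of the anomalous normal-probability plot) would rank
  data sets differently in edge cases.
- Space-group determination, systematic absences, cell reduction and
  automatic choice of the class count are out of scope; the dendrogram
  is exported precisely so the user can choose *N*.
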