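---
title: "Methods: calling GPCR-RAMP complexes from multiplexed bead arrays"
author: "RAMPscreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling GPCR-RAMP complexes from multiplexed bead arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RAMPscreen)
```

# The assay and its data

A suspension bead array (SBA) screen of GPCR-RAMP complex formation
measures, in each well, the median fluorescence intensity (MFI) of every
capture-antibody bead in a pooled panel. Lysates come from cells expressing
one dual-epitope-tagged receptor either alone ("mock" co-transfection) or
together with one of the three RAMPs. Five *epitope-based* capture-detection
schemes probe every pair: capture of the GPCR tag (1D4 or FLAG) with
detection of the RAMP tag (OLLAS), capture of the RAMP tag (HA or OLLAS)
with detection of the GPCR tag (1D4), and RAMP-specific polyclonal capture
with GPCR-tag detection (counted as epitope-based because it generalizes to
all receptors). A variable number of *protein-based* schemes — validated
anti-GPCR antibodies, zero to a handful per receptor — capture the native
receptor sequence with RAMP-tag detection. All of these produce one signal
per (well, bead, detection antibody): a complex is observable only by
sandwich pairs whose capture binds one partner and whose detection binds the
other.

The package's data model is deliberately tabular: a long MFI table keyed by
(sample, capture antibody, detection antibody), an antibody panel, a sample
sheet, and a scheme table, bundled in the `SBAScreen` class and validated on
construction. All measurement tables read and write as CSV/TSV with a JSON
metadata sidecar (configuration, seed, package version — no timestamps, so
reruns are byte-identical).

# Scoring

Raw MFI from different antibodies are not comparable: affinities and
baselines differ by orders of magnitude. Scores are therefore standardized
as robust Z-scores,

$$\mathrm{R.Z}(x_i) = \frac{x_i - \mathrm{median}(x)}{1.4826 \cdot
\mathrm{MAD}(x)},$$

computed separately per capture-detection scheme and RAMP for the epitope
family (so the RAMP-specific scheme, whose capture antibody differs per
RAMP, is standardized within antibody) and separately per capture antibody
for the protein family, across **all** lysate wells measured on that bead.
For a protein-capture antibody the overwhelming majority of wells contain
other receptors, so its score distribution's bulk is the expected negative
population — the basis of the per-antibody threshold below. The MAD is the
raw median absolute deviation with the normal-consistency constant 1.4826
applied once. A zero MAD is a degenerate-scale error; callers that can fall
back (threshold derivation) substitute the sample SD.

The companion `zScore()` uses the population (divide-by-*n*) standard
deviation, so that e.g. `c(0, 0, 2, 2)` maps exactly to `c(-1, -1, 1, 1)`;
for the large, contamination-free samples where a plain Z-score is
appropriate the two conventions are indistinguishable.

# Threshold selection

**Epitope-based schemes** are calibrated against literature knowledge: each
(RAMP, scheme) has pair scores joined to a truth set of known interacting
and non-interacting pairs. Over a candidate grid — the sorted unique scores
plus midpoints between consecutive unique scores — sensitivity (fraction of
known interactors called) and specificity (fraction of known
non-interactors rejected) are traced, and the threshold is their
intersection. On a step-function grid the curves may touch over an interval
or never exactly cross, so the selection is operationalized as: minimize
|sensitivity − specificity|, break ties by maximal sensitivity +
specificity, then by the smallest threshold. The comparison is done in
exact integer arithmetic on the confusion counts (cross-multiplied to a
common denominator), which makes the selection immune to floating-point
ties; a brute-force enumeration oracle in the test suite confirms exact
agreement on 1,000 random instances. Calibration is in-sample (the screen
that is being thresholded supplies the scores), matching how a
literature-anchored screen is actually calibrated; no cross-validation is
attempted.

**Protein-based antibodies** get individual thresholds with no truth set:
the threshold is the antibody's score-density peak plus six scaled MADs,
`mode + 6 × 1.4826 × MAD`. The mode is the argmax of a Gaussian kernel
density estimate with Silverman's rule-of-thumb bandwidth, evaluated by
direct kernel summation on a 512-point grid spanning the observed range
(direct evaluation rather than FFT binning, so the estimator is exactly the
documented formula). At least 8 scores per antibody are required in the
pipeline; the primitive itself works from 2.

**Hits are strict**: a pair is called when its score is strictly greater
than the threshold, everywhere in the package — a score exactly at the
threshold is not a hit.

**Endogenous screens** use a fixed cutoff instead of calibration, because
wild-type lysates have no engineered positive set. Per cell line: MFI is
divided by the median buffer-well MFI of the same (capture, detection)
combination (SNR), replicate columns are quantile-normalized (the limma
implementation; ties share the mean reference value), each replicate column
is transformed to robust Z-scores across capture antibodies per detection
antibody, and the replicate-mean R.Z is thresholded at 3.5. Averaging
replicate R.Z-scores before thresholding means independent replicate noise
shrinks the null spread, making 3.5 a conservative cutoff; with correlated
biological replicates it approaches the single-replicate tail.

# Evidence classes and integration

Per (pair, capture family) the fraction *f* of schemes calling a hit maps
to an evidence class: strong if *f* > 2/3, weak if *f* < 1/3, medium
otherwise. The boundary convention — exactly 1/3 or 2/3 is medium — follows
the strict-inequality reading of "more than two-thirds" / "less than
one-third"; the alternative percentage phrasing ("> 66%", "< 33%") only
disagrees at exact thirds, which first occur with 6 schemes. A family with
no data (a receptor without protein-capture antibodies) is *absent*, never
weak.

The two family classes integrate into the final annotation:

| epitope \\ protein | strong | medium | weak | absent |
|---|---|---|---|---|
| **strong** | yes | yes | inconclusive | yes |
| **medium** | yes | inconclusive | no | inconclusive |
| **weak**  | inconclusive | no | no | no |

The medium+absent cell is not forced by the strong/weak rules and is
resolved to inconclusive by elimination: with a single equivocal family
there is no definitive evidence either way. Epitope evidence is never
absent (every receptor carries the five tag schemes), and passing `absent`
as the epitope class is an error.

# The synthetic-data generator

No raw screen is distributed, so the generator is a first-class module that
emulates the screen design: `nGpcrs` receptors × (mock + each RAMP) wells,
one biological replicate each, plus one mock-only sample and buffer wells;
all capture beads see all wells. On the natural-log scale a record is

```
log MFI = baseline(bead) + affinity(capture Ab) + affinity(detection Ab)
          + logEffect · 1[probed complex present] + Normal(0, noiseSd)
```

and MFI is its exponential — a lognormal noise model, which guarantees
positive intensities and reproduces the heavy-tailed bulk of real
bead-array data. Antibody affinity offsets are drawn once per antibody and
reused across wells, which is what makes per-antibody thresholds
meaningful, and buffer wells are baseline-only so SNR denominators behave.
RAMP-expression QC readouts (RAMP-tag capture with RAMP-tag detection,
which see free RAMP regardless of complex formation) are simulated
alongside the interaction schemes.

Defaults: `interactProb = 0.5`, `logEffect = 2.0` (about 7.4-fold),
`noiseSd = 0.5`, `abAffinitySd = 0.3`, `nProteinAbsRange = c(0, 6)`,
8 buffer wells. The effect-to-noise ratio of 4 gives sensitivity/specificity
curves a well-defined intersection while leaving visible overlap — the
regime in which threshold calibration is actually interesting. These are
stand-ins for a plausible screen, not estimates of any real screen's effect
sizes. The endogenous generator reuses the same noise model with
technical-duplicate × biological-triplicate wells per cell line and a small
`interactFraction` (default 0.05) so the negative bulk dominates each
detection channel.

What the generator does **not** emulate: plate-position and carryover
effects, bead aggregation, per-receptor expression differences (which in
real screens correlate scores of the same receptor across schemes),
cross-reactive antibodies, and correlated biological replicate noise.
Passing recovery tests therefore demonstrate the correctness of the
analysis chain under the stated noise model — not screen-level performance
on real lysates, where calibration quality is bounded by the truth set and
antibody behavior.

# Statistical components

* RAMP-expression QC and the RCP comparisons use one-way ANOVA (`aov`)
  followed by Dunnett many-to-one comparisons against the mock/control
  group via `multcomp::glht` — the standard single-step multivariate-t
  procedure; no resampling fallback is needed since the closed form is
  always available here.
* Replicate reproducibility and the expression-ratio comparisons use
  Wilcoxon rank-sum tests (`wilcox.test`; exact for small untied samples —
  the test suite checks `{5,6,7}` vs `{1,2,3}` against full enumeration,
  p = 0.05 one-sided).
* Transducer-coupling enrichment uses `fisher.test` (conditional-MLE odds
  ratio for 2×2; p only for the r×c primary-coupling-count comparison);
  beta-arrestin couplings binarize at log(Emax/EC50) > 0, and a receptor
  absent from the coupling table counts as non-coupled. The suite verifies
  the 2×2 p-values against hypergeometric enumeration for all tables with
  margins ≤ 15.
* Expression analyses gate strictly at nTPM > 1, compute one GPCR/RAMP
  ratio observation per (receptor, context) — the per-receptor-median
  alternative is deliberately not the default, as pooling contexts weights
  receptors by their expression breadth exactly as the per-context
  percentages do — and cluster log2 expression with Euclidean distance and
  complete linkage (configurable), zeroing non-expressed cells.
* Expression-quartile bias summaries use type-7 sample quartiles with ties
  to the lower bin.
* MolBoolean RCP tables are summarized as counts/nuclei, blank-subtracted
  (negative nets clamped at 0 with a logged count), with percent complexed
  signal defined against the per-image net total of the three channels.

# Numerical conventions and degenerate inputs

* Strict `>` at every threshold; exact thirds are medium; population SD in
  `zScore`; raw MAD with a single 1.4826 factor.
* Intersection selection in integer arithmetic (see above); quantile
  normalization ties averaged per the reference distribution.
* Zero MAD: error in `robustZ`; SD fallback in `densityMadThreshold`
  (error only if the SD is also zero).
* Missing MFI/nTPM values are dropped with a logged count at validation;
  all other missing values are validation errors, as are duplicate keys
  and unparsable numerics — malformed input never degrades silently.
* All simulation functions accept a seed, restore the caller's RNG state,
  and produce byte-identical tables for identical (configuration, seed).

# Problem sizes in the shipped checks

The test suite and `scripts/acceptance.R` exercise: end-to-end recovery on
a 50-receptor screen (150 pairs, ~30k MFI records) at a 4-SD effect, where
all five epitope schemes reach ≥ 95% in-sample sensitivity and specificity
and the decidable annotation matches ground truth; endogenous null
calibration on 250 antibodies × 3 detections × 3 cell lines (2,250
scores), where the call count at 3.5 is compared with the standard-normal
tail by a binomial interval; a 6-SD endogenous effect recovered completely;
1,000-instance threshold-oracle equivalence; and 1,000-replicate null
simulations holding the Dunnett familywise error at its nominal 5%. These
sizes were chosen as the smallest at which the stochastic checks are
well-powered.

# Known limitations

In-sample calibration slightly flatters per-scheme sensitivity/specificity
relative to held-out evaluation; per-(RAMP, scheme) operating points on a
50-receptor screen fluctuate by a few percent around their expected ~97.7%
at a 4-SD effect. The yes/no integration inherits the truth set's biases:
a systematically wrong literature set shifts thresholds, which the
anti-calibration property test (flipped labels cannot beat chance) bounds
but does not eliminate. The endogenous 3.5 cutoff is fixed, not estimated;
with heavy-tailed (high-CV) lysate noise the single-replicate R.Z tail
exceeds the normal tail, and only replicate averaging keeps the false-call
rate near nominal. The generator's independence assumptions (no
per-receptor expression effects) make the simulated screen easier than a
real one in ways the recovery tests cannot detect.
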