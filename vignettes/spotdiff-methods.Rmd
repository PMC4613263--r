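---
title: "Differential 2DE spot analysis with spotdiff: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential 2DE spot analysis with spotdiff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spotdiff)
```

## Scope

`spotdiff` analyses two-dimensional gel electrophoresis (2DE) experiments
at the *spot-table* level: one TSV per gel listing each detected spot's
identifier, isoelectric point (pI), molecular weight (kDa) and integrated
stain volume. Everything upstream of that table — scanning, warping,
segmentation, peak picking of MALDI spectra — is image- or signal-level
work performed by instrument software and is out of scope here. The
package covers:

1. a synthetic-data generator for multi-stage replicate experiments and
   PMF search cases,
2. spot-table IO, volume normalisation, reference-gel selection and
   cross-gel matching,
3. SVQ-based differential calling with a multi-gel coverage rule, absence
   detection, an exact Mann-Whitney U-test and multi-spot aggregation,
4. a simplified peptide-mass-fingerprint search engine,
5. functional-category summaries and reproducible run manifests.

## The differential model

### Normalisation

Spot volumes are normalised within each gel to parts per million of the
summed spot volume: `norm = raw / sum(raw) * 1e6`. This is the standard
total-volume convention for 2DE; it removes loading and staining
differences between gels while preserving within-gel ratios exactly, and
it is idempotent. Its known weakness is *compositional*: when a few large
spots change between stages, the totals shift and every other spot's
normalised volume shifts with them. With hundreds of spots per gel the
effect is small; in small simulated experiments (tens of spots spanning
three volume decades) it is visible as spurious moderate quotients in
stages with strong regulation. This is a property of the method, not of
the implementation, and the null-calibration suite (no true changes)
confirms the false-call rate is driven to ~0 when totals are stable.

### The spot volume quotient and its cut-offs

For a matched spot, with six baseline gels and six stage gels,

$$\mathrm{SVQ} = \frac{\overline{v}_{\text{baseline}}}{\overline{v}_{\text{stage}}}$$

over detected volumes. The cut-offs are **inclusive**: `SVQ <= 0.6` is
up-regulation in the compared stage and `SVQ >= 1.67` is down-regulation.
Two remarks:

* The quotient is inverted relative to intuition — the baseline sits in
  the numerator, so a *small* quotient means the compared stage is *up*.
* The pair (0.6, 1.67) is almost but not exactly reciprocal
  (1/1.67 = 0.599). We do not assume reciprocity anywhere; the
  near-antisymmetry `classify(1/s) = "up"` for `s >= 1.67` holds at the
  default pair and is asserted only there.

Both cut-offs are `diff_config()` knobs, since published descriptions of
this family of protocols vary between inclusive 0.6/1.67 and strict
0.67/1.67 variants; the inclusive pair is the default because it is the
one printed alongside tabulated results.

### The coverage rule (H)

A quotient alone is fragile with n = 6. The coverage rule demands that the
per-gel quotients

$$q_i = \overline{v}_{\text{baseline}} / v_{\text{stage},i}$$

pass the same cut-off on the consensus side in at least `min_gels = 4` of
the stage gels; the count is the `H` statistic. Defining the per-gel
quotient against the baseline *mean* (rather than all 36 gel pairs) yields
exactly one quotient per stage gel and hence `H` in {0..6}, matching how
`H` is tabulated in practice (values 4-6 for reported spots). The fully
pairwise variant — a stage gel counts when at least half of its six
pairwise quotients pass — is available via
`diff_config(pairwise_coverage = TRUE)` but makes no claim to reproduce
tabulated `H` values.

### The Mann-Whitney test

`mann_whitney_exact()` computes `U` from rank sums with mid-ranks and, for
pooled sizes up to 14, the exact two-sided p-value by complete
enumeration: the fraction of all `choose(n+m, n)` assignments of the
pooled ranks whose `|U - nm/2|` is at least the observed deviation. For
6-vs-6 data this is 924 assignments and the smallest achievable two-sided
p-value is 2/924 = 0.00216. Larger samples fall back to the
tie-corrected, continuity-corrected normal approximation. The null
distribution is memoised per rank multiset, so scanning thousands of
groups costs little. The test is *reported, never gating*: the coverage
method is the calling criterion, which is why no multiple-testing
correction is applied (none would change any call); this is noted in the
output rather than silently assumed.

### Absence and aggregation

A spot detected in at least `min_gels` gels on one side and in none on the
other is an absence call (`absent_in_stage` / `absent_in_baseline`); no
quotient is emitted for it. Fewer detections than `min_gels` on the
detected side leave the group uncalled — two detections are not evidence
of anything. Multi-spot proteins are aggregated by the arithmetic mean of
member SVQs and re-classified; opposite member directions (or an absence
call next to a quotient) raise a `conflict` flag, the machine-readable
equivalent of the asterisk such proteins receive in published tables.

## Spot matching

`match_spots()` works in (pI, log10 MW) space — the gel's two native
separation axes — with a greedy mutual-nearest-neighbour linkage seeded
from the reference gel (the gel with the most spots; image-quality
criteria are not computable from tables). Candidate links must fall inside
the tolerance box (`tol_pi = 0.1` pH units, `tol_logmw = 0.02` by
default); they are accepted in order of increasing normalised distance,
ties going to the higher-volume spot, with at most one spot per gel per
group. Unmatched spots seed new groups that later gels can join. The
defaults are several times the generator's default positional jitter
(sd 0.02 pH, 0.005 log10 MW), chosen so that true replicate scatter links
while neighbouring spots do not.

Matching is validated against ground truth: synthetic spots carry stable
identifiers, so `group_by_spot_id()` is an oracle grouping. Recovery is
only well-posed when distinct spots are separable — two proteins landing
within the jitter scale of each other are indistinguishable by position in
principle. The generator therefore offers `min_separation` (rejection
sampling) for matcher validation, while its default leaves placement
uniform, as on a real crowded gel.

## The synthetic-data generator

The generator emulates the design such studies share: 3 stages x 6
replicate gels, with `P90` as baseline. Defaults and rationale:

| parameter | default | why |
|---|---|---|
| `n_proteins` | 100 | enough groups for stable rates at second-scale runtime |
| `frac_regulated_per_stage` | 0.2 | of the order seen in developmental contrasts |
| `fold_change_range` | (2, 5) | magnitudes clear of the 1.67 cut-off; log-uniform, up/down coin |
| `cv` | 0.2 | typical replicate CV of normalised 2DE volumes |
| `volume_range` | 1e3-1e6 | three decades, faint to near-saturated spots, log-uniform |
| `frac_multispot` | 0.1 | isoform/PTM trains of 2-3 spots |
| `frac_mixed` | 0.05 | co-migrating two-protein spots, merged on the gel |
| `frac_absent` | 0.05 | of regulated proteins; split between stage- and baseline-absence |
| `pi_range` | 3-10 | immobilised pH 3-10 strips |
| `mw_range_kda` | 10-100 | separable window of a 12% gel |

Replicate noise is multiplicative lognormal with mean 1 and the given CV:
spot volumes are positive and right-skewed, and a multiplicative model
keeps regulated and unregulated spots on the same relative-noise footing.
Stage volumes are `baseline x fold-change x noise`; spots below the
detection floor, or belonging to a protein absent in that stage, are
omitted from the table. The number of regulated proteins per stage is
exactly `round(frac * n_proteins)` drawn with `sample()`, which makes the
truth count replayable in tests. All randomness is confined under the
config's seed and the ambient RNG state is restored afterwards, so two
calls with one config are byte-identical on disk.

What the generator does **not** emulate: streaking and other spatially
correlated artifacts, saturation nonlinearity of stain response, the
stage-dependent spot counts seen in real ontogeny series (exposed as
`n_proteins` if wanted, not guessed), correlated abundances between
functionally related proteins, and any image-level property. Passing
tests on this generator therefore demonstrates the *statistical* pipeline
is sound, not that it compensates for image-processing failures.

## The PMF engine

Digestion follows trypsin's rule (cleave after K/R, not before P) with up
to one missed cleavage by default and a 4-residue length floor. Masses
are monoisotopic (MALDI reflector convention): residue-table sum + one
water (18.010565 Da) + fixed carbamidomethyl-C (+57.021464 Da), with
variable oxidation-M (+15.994915 Da) enumerated over 0..k sites, capped
at `max_variable_sites = 5` sites per peptide to bound the combinatorics
(a 2^5-state ceiling; peptides with more methionines than that are rare
and their fully oxidised states negligible). Observed peaks are neutral
masses by default; `peaks_are_mz = TRUE` subtracts a proton
(1.007276 Da). Trypsin-autolysis/matrix masses can be excluded via
`exclusion_masses`.

Matching assigns each peak to at most one candidate within the ppm
window, closest relative error first, exact ties to the lower mass. `Qm`
counts distinct matched peaks — whether modified and missed-cleavage
variants should count separately is not decidable from published tables,
and counting peaks makes `Qm <= n_peaks` structural.

Scoring: for each candidate the per-peak random-match probability `q` is
the measure of the union of its +-tolerance windows, clipped to the
observed mass range, divided by that range's width — an empirical density
estimate over the digested database that avoids the classic fixed-bin
MOWSE matrix while keeping its frequency logic. The score is
`-10*log10 P(X >= Qm)`, `X ~ Binomial(n_peaks, q)`, capped at 350. The
significance bound `floor(-10*log10(alpha/N))` is Bonferroni-like in the
database size `N`; the per-candidate binomial null then makes the
family-wise false-identification rate approximately `alpha`, which the
null-calibration suite checks empirically (contaminant-only peak lists,
100 seeded runs). Mascot's own scoring is proprietary; this engine is a
documented probability-based variant, not a re-implementation, and scores
are comparable in spirit, not digit-for-digit.

## Numerical and degenerate-input choices

* Normalising an all-zero gel, comparing against an unknown stage label,
  empty peak lists, empty databases and non-standard residues are hard
  errors naming the offender (and the line number for file input).
* Exact-test tie handling compares `|U - E[U]|` with a 1e-9 fuzz because
  mid-ranks make `U` a multiple of 0.5.
* `compute_svq` refuses zero-detection sides; absence is a separate code
  path, so no division by zero can produce a call.
* Matching tie-breaks are documented and deterministic (distance, then
  spot volume, then insertion order), so identical inputs give identical
  groupings.
* Scores cap at 350 (the binomial tail underflows around 1e-35 for
  perfect matches); the cap only ever affects the top of the ranking.

## Problem sizes used in the checks

The property suites run 200 simulated experiments for null calibration
(100 proteins each, cv 0.2, no true changes; observed regulated fraction
must stay at or below 1%), 200 for parameter recovery (fold change 3,
cv 0.2; correct-direction recovery at or above 90%, absences exact), 200
for coverage-rule soundness (40 proteins, 30% regulated), 1000 randomised
exact-test cases against a bitmask-enumeration oracle, and 100 seeded
null PMF searches against a 500-protein database. These sizes give stable
rates while keeping the default test run in the minutes range on one
core.

## Known limitations

* Total-volume normalisation is compositional (see above); consider it
  when interpreting moderate quotients in heavily regulated contrasts.
* Position-based matching cannot separate truly co-migrating proteins;
  mixed spots are reported as single merged spots, exactly as a gel shows
  them.
* The PMF engine scores peak counts only — no intensity weighting, no
  MS/MS fragment evidence, no protein inference across spots.
* The exact test's enumeration is limited to pooled sizes of 14; beyond
  that the normal approximation is used (and labelled as such in the
  return value).
* Absence calls conflate "not expressed" with "below detection"; the
  detection floor is a modelling choice, not a biochemical fact.
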