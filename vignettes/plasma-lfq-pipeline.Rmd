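---
title: "Cross-run label-free quantification of plasma peptide exports"
author: "plasmaquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-run label-free quantification of plasma peptide exports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmaquant)
```

## The problem

Label-free LC-MS/MS quantification compares peptide peak areas across many
separately acquired runs. Two instrumental artifacts stand in the way:
retention times drift from run to run (column ageing, gradient and
temperature variation), and a peptide identified confidently in one run may
go unidentified in another even though its signal is present. Before any
case/control comparison, the per-run peptide exports therefore have to be
*harmonized*: retention times calibrated onto a common scale, and
equivalent features — (monoisotopic mass, retention time) pairs — matched
across runs into a single study-wide cluster list with one sequence and one
protein per cluster.

`plasmaquant` implements that harmonization and the downstream
differential-abundance analysis for a two-arm plasma study design: a
*discovery* set in which candidate proteins are found, and an independent
*test* set in which they must re-show the same direction of change.

## Pipeline model, stage by stage

**1. Export filtering.** Peptide-level exports carry every candidate match;
only records with rank up to 5 and an accepted identification confidence
(high/medium/low, i.e. FDR below 10%) enter the pipeline.

**2. Retention-time calibration.** One run — flagged in the study design,
ideally one covering the full mass and rt range (`suggest_reference()`
scores this) — serves as the reference scale. For every other run, peptides
whose sequence text occurs exactly once in both that run and the reference
are paired, and the reference rt is regressed on the sample rt with robust
LOWESS (`stats::lowess`, span 0.3, 3 robustifying iterations). The span was
chosen wide enough to average over tens of matched peptides at typical
match counts (hundreds of pairs) yet narrow enough to follow the smooth,
slowly varying drift a long gradient produces; it is configurable. Two
numerical guards make the fitted map total and monotone: the curve is made
non-decreasing by isotonic regression on the fitted knots (LOWESS itself
can wiggle below monotonicity in sparse regions), and outside the observed
pair range the map extrapolates by a constant offset from the nearest
endpoint, which keeps order and avoids runaway linear extrapolation. A
third guard falls back to the non-robust fit when the initial fit is
near-interpolating, because the bisquare reweighting is undefined at zero
residual spread. Calibration requires at least 10 matched pairs and fails
loudly otherwise.

**3. Feature clustering.** All calibrated records are placed on the
(mass, rt) plane and grouped by a deterministic mode-seeking procedure. A
cluster window is ±5 ppm in mass and ±5% of the center's rt — relative
windows, because both mass accuracy and chromatographic dispersion scale
with the measured value. A candidate center starts at every point and moves
to the mean of the points inside its window until the largest
window-normalized movement drops below `1e-6` (at most 50 iterations).
Converged centers closer than half a window in both dimensions merge; the
center capturing more points survives, ties resolved toward lower mass then
lower rt. Points are then assigned to the admissible center with the
smallest window-normalized Euclidean distance, centers are recomputed once,
and members falling outside the recomputed window are re-homed or dropped,
so the containment invariant holds against the final centers
(`check_cluster_invariants()` asserts it on every pipeline run). Points are
sorted by mass then rt before seeding, which makes the whole procedure
independent of input order. Clusters seen in fewer than 2 records carry no
cross-run information and are discarded.

**4. Annotation.** Each cluster's representative sequence is the modal
sequence of its members; a frequency tie goes to the sequence attaining the
highest Xcorr, and an exact further tie to the lexicographically smallest
sequence (determinism, not biology). Members whose measured mass deviates
from the sequence's theoretical mass by 5 ppm or more are then removed
(strict `< 5` ppm retained), cascading clusters below 2 members out of the
list. Shared peptides — candidate lists with several accessions — resolve
to the accession represented most frequently across the *whole* cluster
list. By default frequency counts clusters whose candidate sets include the
accession; counting member records instead is available via
`protein_count_by = "record"`. Cluster counting was chosen as the default
because the assignment is a property of the cluster list, and it makes the
rule independent of how often individual runs re-observe a peptide. Note
the corollary, covered by a dedicated test: editing one cluster's
candidates can legitimately flip an unrelated shared peptide's protein.

**5. Quantification.** Performed separately per set. Each cluster/sample
cell is classified as *detected* (member with an area; multiple members in
one run are summed), *identified without area* (a known quirk of
search-software exports), or *absent*. In the discovery set, only peptides
identified in at least 50% of the cases or at least 50% of the controls are
kept; the test set is deliberately unfiltered so that verification cannot
be biased by a second selection step. Identified-without-area cells are
imputed with the mean of the peptide's observed areas in the sample's group
(zero when the group has no observation — a documented fallback); absent
cells are zero. The group mean is computed on raw areas before
normalization, mirroring the order of the imputation and normalization
steps. Peak areas are then ppm-normalized — each column scaled so included
peptide areas sum to 10^6 — and protein abundance is the sum of the
normalized areas of the protein's peptides, with the peptide count per
protein recorded as its number of distinct representative sequences in the
set. Because every peptide maps to exactly one protein, per-sample protein
totals conserve the 10^6 budget, a property the tests assert to 1e-6
relative.

**6. Differential abundance.** Per protein, the case/control ratio of
group means and a two-sided Mann-Whitney p-value are computed in the
discovery set. Group means (not medians) are used for the ratio, consistent
with the mean-based imputation, and they give the natural sentinel
behavior: a zero control mean with signal in cases yields "only in cases"
(ratio `Inf`), the reverse "only in controls" (ratio 0); both satisfy the
fold criterion in their direction. A protein is differentially abundant
when it has at least 2 peptides, p ≤ 0.05 and at least a twofold change in
either direction. No multiple-testing correction enters the decision — the
replication design, the fold and the peptide-count filters carry that
burden — but a Benjamini-Hochberg column is emitted for information.
Verification in the test set requires the same direction of change at
twofold; test-set significance (p ≤ 0.05) is reported as a separate flag.

The Mann-Whitney branch rule: the exact null distribution when there are no
ties and n₁+n₂ ≤ 30 (which covers the 13-vs-8 and 6-vs-5 group sizes of the
target design), otherwise the normal approximation with tie and continuity
correction; the branch used is recorded per protein. Forcing `mode =
"exact"` with ties enumerates all labelings directly (small n only). Two
fully tied groups carry no separation and return p = 1.

**Concordance.** `spearman_log()` supports the validity checks of this kind
of study: rank correlation of protein abundances against an external
concentration catalogue, or between discovery and test sets, computed on
log10-transformed positive pairs (non-positive pairs dropped and counted).

## The synthetic-study generator

Because raw multi-run plasma data are impractical as test fixtures, the
package ships a generator (`generate_study()`) that emulates exactly the
statistical structure the pipeline assumes, with full ground truth:

* a catalogue of true features (protein, sequence, theoretical mass
  600–5000 Da, true rt) whose masses are kept pairwise > 25 ppm apart so
  distinct features never share a clustering window;
* per-run monotone rt drift — affine plus a clamped smooth sinusoid, with
  the amplitude bounded so the derivative stays strictly positive — plus
  0.1 min per-observation jitter;
* measured mass = theoretical mass × (1 + ε), ε ~ N(0, 2 ppm), matching
  modern Orbitrap event-detection precision;
* log-normal peak areas (meanlog 16, sdlog 1.2 across peptides, 0.3
  multiplicative per-observation noise) with a protein-level group effect
  (default 8 spiked proteins at |log2 effect| 1.5, alternating direction)
  inherited multiplicatively by all of a protein's peptides;
* identification dropout (10%), identified-without-area cells (2%),
  run-unique decoy singletons (5% of the feature count) and shared-peptide
  annotations (5%);
* the target study design: 13 + 8 discovery and 6 + 5 test samples, with
  the first discovery control as the rt reference.

The default 50 proteins with 2–6 peptides each (≈ 200 features, ≈ 6000
records across 32 runs) keep one full simulated study at about a second of
runtime, so the whole test battery — including 20-seed operating-
characteristic checks — runs in well under a minute per property; these
sizes are the package's own choice of a desk-scale study.

What the generator does *not* emulate: chromatographic peak shapes and
intensity-dependent detection, correlated protein abundances and shared
biological covariation, search-engine score distributions and FDR
structure, charge states, or abundance-dependent missingness. Passing the
recovery tests therefore demonstrates that the pipeline's algorithms
implement their specification and undo the artifacts they model — not that
the pipeline is robust to every pathology of real plasma data.

With all noise, dropout and decoys set to zero
(`synth_config_zero_noise()`), the pipeline is required by test to recover
the ground truth *exactly*: one pure cluster per true feature, protein
matrices in perfect per-sample rank agreement with truth, and a
differential-abundance call set identical to the spiked proteins. One
subtlety makes this test meaningful rather than trivial: ppm normalization
is compositional, so spiking some proteins up in cases pushes every other
protein's normalized abundance down, and the complete-separation
Mann-Whitney p-values are tiny for *all* proteins in a noise-free study. It
is the twofold-change criterion that keeps the unspiked proteins out of the
call set — which it does as long as spiked proteins hold a modest share of
total signal, as in the default configuration.

## Defaults and degenerate inputs at a glance

| parameter | default | meaning |
|---|---|---|
| `max_rank` / confidence | 5, all three | export admission |
| `lowess_fraction`, iterations | 0.3, 3 | calibration span / robustness |
| `min_calibration_pairs` | 10 | below → calibration error |
| `mass_window_ppm`, `rt_window_frac` | 5 ppm, 5% | cluster window half-widths |
| `cluster_max_iter`, `cluster_tol` | 50, 1e-6 | mode-seeking stop rule |
| `min_members` | 2 | cluster-list admission |
| `mass_accuracy_ppm` | 5 (strict `<`) | theoretical-mass filter |
| `detection_fraction` | 0.5 | discovery detection filter (≥, one group) |
| `min_peptides`, `fold`, `alpha` | 2, 2, 0.05 | differential-abundance rule |
| split rule | 2/3 per group, round half up | when the design has no set labels |

The detection threshold is applied as ≥ 50% (a stated "more than 50%"
reading would drop exactly-half detections; the ≥ reading matches the
"at least 50%" phrasing under which the headline dataset of this kind of
analysis is defined). The discovery/test split rounds 2n/3 half-up per
group when labels are absent; pre-labeled designs — including the 13/8/6/5
default — pass through untouched. Degenerate inputs fail loudly rather
than silently: empty groups, all-zero normalization columns (named in the
error), sub-minimum calibration pair counts, non-monotone drift
specifications and unknown configuration keys are all errors.

## Known limitations

* Protein inference is deliberately naive — no parsimony grouping; the
  frequency rule mirrors a workflow in which search-engine protein grouping
  is disabled.
* Mass is taken as charge-resolved neutral monoisotopic mass; no charge
  handling or mass recalibration is attempted.
* The mode-seeking clustering is greedy and windowed; features closer than
  a window merge irrecoverably, which is why the generator (and any
  sensible acquisition) needs features separated beyond it.
* Mean-based imputation shrinks within-group variance for
  identified-without-area cells; with the default 2% rate this is
  negligible, but the rate is worth checking on real exports.
* Raw p ≤ 0.05 with replication is a screening rule, not an error-rate
  guarantee; the emitted BH column should accompany any reported list.
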