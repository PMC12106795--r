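---
title: "Spike-in enhanced DIA phosphoproteomics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spike-in enhanced DIA phosphoproteomics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spieddia)
```

# The measurement model

A multichannel DIA precursor report carries, per run and precursor, the
intensities of the endogenous light channel (`L`), the heavy spike-in
channel (`H`), and channel-specific identification confidences
(q-values), together with phospho-modification q-values and site
localisation confidences. The heavy spike-in is the same synthetic
peptide amount in every sample, so `H` varies only with injection and
ionisation efficiency. Two consequences drive the whole design:

1. **Detection anchoring.** If the heavy channel is confidently
   identified, the precursor's retention time and mobility are known, so
   the light intensity can be extracted ("rescued") even when the light
   channel's own q-value is far above the usual 5% cut-off. Detection
   and quantification are uncoupled.
2. **Ratio quantification.** `L / H` cancels run-level nuisance
   variation. Multiplying by the per-precursor rescaling factor
   `r = median(H)` restores an intensity-like scale, giving the working
   quantity `y = log10((L / H) * r)`.

## Filtering rules and their thresholds

All inequalities are strict; boundary values fail.

| parameter | default | role |
|---|---|---|
| heavy channel q | < 0.05 | anchor identification confidence |
| phospho q | < 0.05 | modification-level FDR |
| site localisation confidence | > 0.5 | phosphate on the reported residue |
| heavy intensity | > 1000 | spike-in must be comfortably above background |
| anchor run count | >= ceil(0.8 n_runs) | "consistently detected" heavy spike (10 of 12 in a 12-run study) |
| light intensity | > 900 | endogenous signal above the noise floor |
| light q (relaxed) | < 0.5 in >= 3 runs | minimal evidence the light peptide is real |
| presence rule | > 900 in >= 2 replicates of >= 1 condition | comparisons are signal-vs-signal or signal-vs-noise, never noise-vs-noise |

The intensity floors (900 / 1000, arbitrary MS1 units) exist because
these reports have an additive background: at zero analyte the reported
intensity fluctuates around a few hundred units, and a ratio between two
background draws is meaningless. Anchored features that fail the
presence rule in *every* condition are reported as **confident absence
calls**: the heavy beacon proves the run was technically fine, so the
light peptide's absence is attributable to biology.

Two readings of the printed rules were possible and we document our
choice rather than assert the original intent:

* **Rescaling-factor scope.** `r` is computed per precursor (median of
  that precursor's heavy intensities over the runs where heavy is
  present), which restores each feature to its own intensity scale; a
  `global` switch is available. The median is taken over all runs with
  heavy intensity present, i.e. filter-then-median over the full vector,
  not only over runs that passed the anchor filter.
* **Presence rule.** "Above the floor in at least one condition" is
  implemented as *at least 2 replicates above the floor within at least
  one condition* (configurable), which reconciles the per-condition
  phrasing with the two-of-three-replicates phrasing and is robust to a
  single spurious spike.

## Missingness

Intensities of exactly zero are converted to missing at parse time: a
zero MS1 area is indistinguishable from non-detection. No imputation is
performed at any stage; the model fit handles missingness explicitly
(below). Decoy-channel rows are retained by the reader and excluded by
the analysis filters, so diagnostic FDR summaries remain possible.

# Normalization

Column (run) loading bias is removed by cyclic loess on MA coordinates
via `limma::normalizeCyclicLoess` (`fast` mode by default: each column
is corrected against the row-mean reference, cycling for 3 iterations
with span 0.7 — the cited function's documented defaults, exposed as
parameters). Missing cells are untouched and the missingness pattern is
preserved exactly.

One behaviour worth knowing: loess normalization assumes most features
are unregulated. When a sizeable fraction of features is regulated in
one direction (e.g. 10% of features carrying a +0.3 interaction effect),
the affected columns' means shift and normalization reabsorbs roughly
0.01–0.02 log10 units of the real effect. Our parameter-recovery test
therefore measures estimator accuracy on the un-normalized route (no
loading bias is simulated there), and the calibration tests inject bias
and signal separately.

# The factorial model and moderated statistics

Features x runs matrices (rescued ratios or label-free `log10(Ms1.Area)`)
are modelled per feature by ordinary least squares on a **cell-means**
parameterization of the 2x2 design (one indicator per
MEKi x growth-factor-mix combination). Cell means avoid aliasing
ambiguity: every contrast is a plain difference of cell means.

The five reported contrasts are the growth-factor effect with and
without MEK inhibition, the MEK-inhibition effect with and without
growth factors, and the synergy contrast
`Interaction = (mu11 - mu10) - (mu01 - mu00)`, identically equal to the
difference of the two growth-factor effects and of the two
MEK-inhibition effects. The stacked contrast set has rank 3.

Per feature, only observed runs enter the fit; features with more than
5 missing cells (default), with an observed design that loses a cell
(rank loss), or with no residual degrees of freedom are excluded and
logged, never imputed. Deleting a run from a feature and refitting is
identical to fitting the reduced design — an invariant the tests assert.

Variance moderation follows the standard empirical-Bayes moment-matching
on log residual variances: with residual variances `s2_g` on `d_g`
degrees of freedom, the prior `(d0, s02)` solves the digamma/trigamma
moment equations (handling unequal `d_g`), the posterior variance is
`s2_post = (d0 s02 + d_g s2_g) / (d0 + d_g)`, and moderated t statistics
have `d0 + d_g` degrees of freedom. Degenerate branches are explicit:
underdispersed log-variances give `d0 = Inf` (all posterior variances
equal `s02` = the mean variance); injected `d0 = 0` reproduces ordinary
t statistics exactly; zero sample variances are offset to `1e-5` of the
median variance for the moment matching and flagged. The moderated F
over the five dependent contrasts orthogonalizes the estimates through
the eigendecomposition of their unscaled covariance and uses the rank
(3) as numerator degrees of freedom — computing over all five contrasts
or any full-rank subset gives the identical statistic. With a single
contrast, F equals t squared to machine precision. On complete data the
whole construction agrees with `limma::eBayes` to 1e-10; under
missingness our F uses the exact per-pattern covariance where limma
approximates with a single design-level matrix.

Raw p-values with fixed cut-offs are the primary outputs (moderated-F
p < 0.1 selects "regulated" features); Benjamini-Hochberg adjusted
columns are emitted alongside for users who prefer them.

Aggregation to phosphopeptides keeps, per modified sequence, the
precursor with the smallest moderated-F p; exact ties break
deterministically by higher average intensity, then lexicographically
smaller precursor id.

# Clustering and kinase-signature enrichment

Regulated features are z-scored row-wise over observed cells (zero
variance rows are excluded with a warning), summarized to per-condition
means, and clustered agglomeratively (complete linkage, Euclidean
distance on condition-mean profiles; both configurable — the original
analysis chose the cluster count by eye, so `k` is a free parameter
here). An optional helper scores each cluster's cosine similarity to the
ideal synergy profile (response only in the combined-treatment cell); it
is a convenience beyond the core procedure.

Over-representation of kinase-substrate signatures (GMT files keyed by
14-residue site flanking windows, uppercase, `_`-padded at protein
termini) in a cluster is tested with the one-sided hypergeometric upper
tail — Fisher's exact test for enrichment — against the universe of all
quantified, signature-mappable identifiers. Signatures disjoint from the
universe get p = 1 with zero overlap rather than an error.

# Benchmark analytics

For a dilution series with factor `f`, the expected log2 ratio of the
diluted over the reference channel is `-log2(f)` (the convention is
stated in output headers). Observations are binned into equal-count bins
(sizes differ by at most one; ties broken by stable input order) by
reference-channel intensity; per bin x dilution the median ratio and the
spread of ratios aggregated at the modified-sequence level are reported.
With an additive background `b`, the observed ratio is
`log2((S/f + b) / (S + b))`, which is compressed toward zero as `S`
approaches `b` — low-intensity bins therefore show larger bias at high
dilutions, while high-intensity bins track the expected line. The
positional-isomer module classifies heavy/light combinations of one
stripped sequence as pairs (same localized site) or isomers (different
site); isomers report two different analytes, so their cross-channel
ratio spread exceeds that of genuine pairs.

# The synergy screen module

Antibody-based 2x2 screens (ligand x inhibitor, multiple cell lines and
analytes) are processed as: multivariate outlier removal (a replicate is
dropped only when |z| >= 3 for *all* analytes simultaneously; z is
computed per cell line and analyte across all conditions' replicates —
with 4 replicates per condition a |z| >= 3 is arithmetically impossible
within one condition, which rules out the narrower scope), log2 fold
changes against the solvent-control mean, the interaction fold change as
a difference of differences (it vanishes identically under additive
effects), and a two-way ANOVA with interaction on the fold changes. A
synergy call requires all three of: interaction p <= 0.05 (inclusive,
unlike the strict proteomic thresholds), positive interaction fold
change, and receptor dependency (the ligand's interaction fold change
exceeds the reference stimulus's). Note the solvent control's
interaction fold change versus itself is structurally zero, so with the
default reference the third criterion coincides with the second; it
becomes informative when pointed at another stimulus (e.g. full serum).
On balanced data the ANOVA interaction p equals the squared-t p of the
interaction contrast; after outlier removal the interaction term is
tested from the full model fit (partial sums of squares).

# What the synthetic generator emulates — and what it does not

`simulate_channel_report()` draws, per feature: a constant heavy spike
intensity (log10 ~ N(4.5, 0.5)) with small multiplicative run noise
(0.05 log10 units); a light base intensity (log10 ~ N(3.8, 0.6))
multiplied by treatment effects in log10 units (defaults: 10% of
features with a +0.3 growth-factor effect, 10% with a -0.3
MEK-inhibition effect, 10% with a +0.3 pure interaction effect, 5%
truly absent) and log-normal noise (0.05); an additive background drawn
uniformly from 0.5–1.5x the 600-unit floor (this is what makes the
900/1000 thresholds meaningful and produces ratio compression); and a
logistic detection model in log10 signal-to-background, so q-values are
monotone in abundance (missingness not at random). Site-localisation
failures (10%), decoy rows (5%) and SILAC-style modified-sequence
bookkeeping are included for realism. All draws derive from one seed;
regeneration is byte-identical.

The generator does **not** emulate: correlated interference between
co-eluting precursors, retention-time drift, charge-state-dependent
detectability, peptide-specific ionisation response, or heavy/light
channel cross-talk. Passing tests on simulated data therefore validate
the *logic* of filtering, rescue, rescaling, calibration of the
statistics and the direction of compression effects — not
instrument-level quantitative accuracy on real samples.

# Numerical choices and problem sizes

* Eigenvalues below `1e-9` of the leading eigenvalue are treated as null
  space when pseudo-inverting contrast covariances.
* Trigamma inversion uses Newton iteration to relative precision 1e-10.
* Equal-count bins and per-sequence aggregation break ties by stable
  input order, making all outputs order-independent up to the documented
  tie-break keys.
* Test problem sizes were chosen to make Monte-Carlo error small
  relative to the asserted margins while keeping the suite fast:
  5000 features for the type-I calibration of the interaction test
  (binomial 95% interval around 5%), 2000 features x 6 dilutions x 3
  replicates for coverage and compression, 100 seeded replicates for
  screen power and false-call rate, 20 replicates for prior-parameter
  recovery.

# Known limitations

* The rescue step operates purely on report-level intensities and
  q-values; it cannot re-extract chromatograms from raw data.
* Ratio compression is mitigated only by reporting provenance
  (detected vs rescued cells) and intensity-binned diagnostics; no
  background-subtraction correction is applied to `y`.
* The moderated model assumes Gaussian noise on the log scale and a
  common 2x2 design across features; mixed models and array weights are
  out of scope.
* Cyclic loess slightly attenuates genuine effects when regulation is
  widespread and one-sided (see Normalization above).
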