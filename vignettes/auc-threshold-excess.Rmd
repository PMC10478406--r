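---
title: "Detecting threshold excesses in published AUC values"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting threshold excesses in published AUC values}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aucexcess)
```

## The problem

The area under the receiver operating characteristic curve (AUC, also
reported as AUROC, c-statistic or c-index) is the standard summary of a
clinical prediction model's discrimination. Working folklore grades it
against round cut-offs — 0.7 "acceptable", 0.8 "good", 0.9 "excellent" —
which creates an incentive to re-analyse (add predictors, prune outliers,
switch algorithms, re-split the data) until the reported value clears the
next threshold. If that happens at scale, the distribution of published
AUC values should show a *caliper signature* at each threshold: a deficit
of values just below it and an excess just above it, relative to a smooth
null.

`aucexcess` implements the full pipeline for measuring that signature in
abstract text, together with a synthetic corpus generator that makes every
stage testable without any large download.

## Pipeline

### Corpus filtering

`parse_pubmed_xml()` reads MEDLINE-citation XML (the PubMed baseline
dialect, plain or gzip-compressed) into `abstract_record` objects that
keep structured-abstract section labels. `apply_exclusions()` then runs a
fixed-order cascade — (1) empty abstract or ten words or fewer, (2)
pharmacokinetic study by MeSH/publication-type indicator, (3)
meta-analysis or pooled analysis, (4) tutorial — so that every abstract
receives exactly one decision and `flow_counts()` conserves the corpus.
The indicator lists are configuration data (`auc_config()`, overridable
from YAML via `load_config()`), not code: the exact pharmacokinetic MeSH
list is a judgement call, and shipping it as data keeps that judgement
visible and editable.

### Value extraction

`extract_values()` finds AUC-family cues (phrases case-insensitively;
bare acronyms AUC/AUROC/AUROCC case-sensitively with word boundaries) and
associates nearby numbers with them. The association rule is: a number
belongs to the nearest statistic cue to its left within 250 characters,
where "statistic cue" includes competing statistics (sensitivity,
specificity, accuracy, Brier score, p-values, ...) precisely so that the
dense statistic lists common in abstracts do not leak into the AUC sample.
The window does not cross a sentence boundary into a sentence that
carries a competing cue. Interval patterns after a point value —
`0.704 (95% CI 0.603 to 0.806)` and the bracket/separator variants — are
classified point / ci_lower / ci_upper; a reversed interval is flagged
`ci_reversed`, never silently swapped.

Four guards reject candidates, each logged with a machine-readable
reason: trailing measurement units (pharmacokinetic exposures such as
`AUC0-24 was 412 ng·h/mL`); competing-cue claims; sentences that define
the AUC scale rather than report a value ("The AUC ranges between 0.5 and
1"); and the range filter — after percent conversion, values below 0 or
at or above 1 are dropped, so a reported AUC of exactly 1 never enters
the data. A bare number above 1 is only interpreted as a percentage when
its sentence mentions percent *outside* a "95% CI" label; otherwise it is
rejected rather than silently rescaled. These choices deliberately lean
towards missing unusual presentations rather than including wrong
numbers.

`decimal_places()` counts digits as printed, with percent tokens counted
two deeper ("80%" is comparable to "0.80"). We count decimals on the
printed token, before percent conversion plus the +2 offset; counting
after conversion would be equivalent for the styles the generator covers.

### Histogram and smooth

`build_histogram()` uses 100 half-open bins `(lower, upper]` of width
0.01 on `(0, 1]`: a printed `0.70` lands in `(0.69, 0.70]`, i.e. *below*
the threshold, which is the conservative direction for an excess-above
test. Values printed with one decimal place are excluded (rounding alone
would spike the tenths bins); confidence-interval limits are excluded
from the default histogram and can be histogrammed separately via
`histogram_spec(roles = "ci_lower")`.

`fit_poisson_spline()` fits, by iteratively reweighted least squares, a
log-linear Poisson regression of the counts on an intercept plus a
natural cubic spline of the bin midpoints with 4 degrees of freedom
(interior knots at the 25th/50th/75th percentiles of the fitted
midpoints, boundary knots at the extreme fitted midpoints). Convergence
is declared at a relative deviance change below 1e-8 (at most 100
iterations); because the intercept is in the model, the Poisson score
equations force the fitted counts to resum to the observed total, which
the tests assert to 1e-6 relative. Residuals are **observed − fitted**,
so an excess is positive. `threshold_report()` reads off the bins
adjacent to each threshold and adds `excess_ratio_above`
(observed/fitted), a convenience summary not part of the residual
analysis itself.

The covariate is the bin midpoint; with equally spaced bins any affine
recoding (lower edge, bin index) spans the same model, so only the
coefficient values, not the fit, depend on this choice. The fit domain
defaults to all 100 bins for real corpora; for synthetic corpora the
workflow restricts it to the generator's support (0.4, 1), because
log-link fitting of structural zeros far outside the support is
meaningless and only destabilises the IRLS.

### Validation statistics

`exact_binomial_ci()` is the Clopper–Pearson interval in its beta-quantile
form. It is the natural choice here because a 100-abstract manual check
with 100/100 agreement gives the interval 0.964 to 1.000 and 99/100 gives
0.946 to 1.000, exactly reproducible; tests verify it against independent
bisection of the binomial tails. `limits_of_agreement()` implements
classic Bland–Altman limits, default 90% coverage, applied to the
per-abstract difference in the number of values found (algorithm minus
manual, over abstracts where either side found at least one value).
`compare_annotations()` conditions the predictive values on the
algorithm's call: NPV = both-absent / algorithm-absent, PPV =
both-present / algorithm-present.

## The synthetic corpus generator

`generate_corpus()` is first-class, tested code, not a fixture. Defaults
(all in `synthetic_config()`):

* **Values per abstract**: `1 + Geometric(p = 0.35)`, giving median 2
  with quartiles 1 to 4 — the pattern typical of abstracts that compare
  several candidate models.
* **Base distribution**: scaled Beta(4.5, 3.5) on (0.4, 1) — smooth,
  unimodal with mode near 0.75, a realistic envelope for published
  discrimination values.
* **Promotion model**: the generator's operationalisation of hacking. A
  value in `(t − δ, t]` below a threshold `t ∈ {0.7, 0.8, 0.9}` is, with
  probability `h`, replaced by a uniform draw from `(t, t + ε]`, with
  δ = 0.03 (a plausible reach for re-analysis) and ε = 0.01 (the first
  bin above, where the signature is predicted). `h = 0` is a smooth
  null; `h` is the single knob the simulation studies vary.
* **Reporting styles**: plain point values (2–3 decimals), point with a
  symmetric 95% CI (half-width uniform on 0.03–0.12, clipped to (0, 1)),
  percents, one-decimal values, and values equal to 1 — in proportions
  0.45/0.30/0.10/0.10/0.05.
* **Decoys**: pharmacokinetic AUCs with units (half of them also carrying
  a pharmacokinetic MeSH heading, exercising the upstream exclusion;
  the other half must be caught by the extraction guards),
  sensitivity/specificity lists (also injected into 30% of AUC-reporting
  abstracts), scale-definition sentences, and numberless filler; plus 2%
  deliberately short abstracts.

The ground-truth table records, for every rendered number, its role,
style, pre-promotion value, promotion flag, and whether it should be
extracted (`AUC of 1` should not) and should enter the histogram
(one-decimal values and CI limits should not). Recall and precision are
computed as multiset agreement on (pmid, value, role).

What the generator does *not* emulate: real abstract prose and its long
tail of idiosyncratic formats, secular trends in AUC reporting, journal-
and field-level composition, correlated values within an abstract, and
publication bias as a separate mechanism. Passing the fidelity tests
therefore shows the grammar implements the stated rules, not that it
would achieve the same recall on real MEDLINE text.

## Calibration of the residual diagnostic

A 4-degree-of-freedom natural spline is a deliberately stiff null; no
fixed smooth density off its span is fitted without bias. Simulation at
200 replicates × 20,000 values resolves bin-level bias of a fraction of a
percent, and at that resolution even the scaled-Beta base shows a
deterministic lack-of-fit of roughly ±1–5% per bin near the thresholds
(quantified in `analysis/05_simulation_study.R`) — with *alternating*
signs, unlike the one-sided above-threshold excess the promotion
mechanism produces. The null-calibration test therefore draws from the
`smooth_null` base family, whose log-density *is* a 4-df natural spline
(calibrated once, deterministically, to the Beta shape): under it the
mean above-threshold residuals are centred at zero within Monte-Carlo
error, which is the property the diagnostic needs. Detection in the
simulation study flags a bin when its residual exceeds
`qnorm(0.975) · sqrt(fitted)`, the Poisson sampling-noise envelope; at
`h = 0.3` with 20,000–50,000 values the excess is detected in
effectively every replicate, and detection frequency is monotone in `h`.

## Problem sizes and numerical choices

The test suite and the acceptance script use: 5,000-abstract corpora for
extraction fidelity; 200 replicates of 20,000 values for null
calibration; 100 replicates of 50,000 values for signal recovery; these
sizes make the Monte-Carlo error small relative to the effects of
interest while keeping a full run in the low minutes. Degenerate inputs
are handled explicitly: all-zero histograms and sub-minimal fit domains
are hard errors; IRLS non-convergence returns the fit with
`converged = FALSE` and a warning; a value of exactly 0 (never produced
by the filters, which keep `[0, 1)`) is counted in the first bin; ties in
`max_per_abstract()` go to the first occurrence.

## Known limitations

* The extraction grammar is a reconstruction of the described behaviour,
  validated behaviourally on the synthetic corpus; real-world recall will
  be lower on unusual formats (e.g. "±" spreads, which are deliberately
  treated as point values only).
* The residual analysis is descriptive, as in the underlying study
  design: no formal caliper hypothesis test is provided.
* Reproducing literature-scale counts requires the full PubMed baseline,
  which the package can parse but does not download.
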