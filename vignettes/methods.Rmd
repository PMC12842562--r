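---
title: "IRT-based scale abbreviation: models, procedure, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{IRT-based scale abbreviation: models, procedure, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gdsirt)
```

## The measurement model

`gdsirt` treats each yes/no screening item as a two-parameter logistic
(2PL) item: conditional on a unidimensional latent severity $\theta$,

$$P(X_j = 1 \mid \theta) = \frac{1}{1 + e^{-a_j(\theta - b_j)}},$$

with discrimination $a_j > 0$ (unitless slope) and difficulty $b_j$ (in
latent-trait standard deviations; the severity at which endorsement
probability is exactly one half). The parameterization is deliberately
$a(\theta - b)$ rather than slope–intercept so that $b$ keeps its
50%-endorsement interpretation on output; slope–intercept form is used
only inside the optimizer, where it is numerically better behaved, and
converted back.

Assumptions worth stating plainly: unidimensionality of the latent
trait, local independence of items given $\theta$, a standard-normal
calibration population, and monotone item response functions. Screening
scales with strong secondary factors (e.g. somatic clusters) violate the
first two; the package does not test dimensionality.

## Calibration

`fit_2pl()` maximizes the marginal likelihood by Bock–Aitkin EM. The
latent trait is integrated over a fixed quadrature grid
(`latent_grid()`): 61 equally spaced nodes on $[-6, 6]$ with
standard-normal density weights renormalized to sum to one. For 30
binary items this grid's integration error is negligible relative to
sampling error, and a fixed grid keeps the E-step a single matrix
product. The M-step maximizes each item's expected complete-data
log-likelihood by damped Newton iteration (step-halving on any decrease),
which keeps the marginal log-likelihood non-decreasing across EM cycles —
a property the test suite asserts rather than assumes.

Numerical choices:

* **Start values**: $a_j = 1$, $b_j = -\mathrm{logit}(\bar x_j)$ clamped
  to bounds — the marginal endorsement rate back-transformed at unit
  slope.
* **Bounds**: $a \in [0.05, 6]$, $|b| \le 8$. Quasi-Guttman items
  otherwise diverge; hitting a bound raises a warning and the item is
  flagged in the returned bank.
* **Convergence**: largest absolute parameter change below `tol = 1e-4`,
  or 500 EM cycles.
* **Degenerate items** (endorsed by everyone or no one) carry no 2PL
  information and are excluded with a warning; non-binary values are an
  error, not a coercion.
* **Missing responses** are dropped item-wise from the likelihood
  (missing at random); all-missing rows are dropped. The synthetic
  generator itself produces complete data — missingness handling exists
  for imported cohorts.
* **Standard errors** come from the expected complete-data information at
  the solution (delta method back to $(a, b)$); they are approximate and
  intended for diagnostics, not inference.

Calibration uses the development half only, and the resulting parameters
are frozen for every downstream step, so validation-set results are not
contaminated by item selection.

## The reduction procedure

Items are ranked by fitted discrimination (`rank_items()`; ties broken by
per-item AUC, then item index). For each size $k$ from the full pool down
to `k_min = 4` — the smallest published GDS variant, so every published
short-form size is covered — the top-$k$ unit-weighted sum score is
compared against the full-scale sum score by the paired DeLong test in
the development and validation halves separately, and across halves by
the Hanley–McNeil independent z-test. Scale scores are integer sums, not
IRT trait estimates: screening practice uses integer cutoffs, and IRT is
used here only to *choose* items.

The dual-criterion stopping rule (`select_minimum()`): size $k$ passes
when its DeLong p-value exceeds $\alpha = 0.05$ (two-sided) in **both**
halves; the selected $k^\*$ is the smallest passing size whose next
reduction step fails in at least one half. A development-only variant is
available (`rule = "dev_only"`). Two readings of the stopping rule were
considered during design: stopping at the first failure walking down from
the full scale, and the smallest passing size overall. The first is
dominated by an artifact of unit weighting — removing near-zero-
discrimination items *raises* the true AUC of a sum score (they
contribute pure Bernoulli noise), so with a two-sided test, mid-size
scales are regularly *significantly better* than the diluted full scale
and the walk stops almost immediately. The smallest-passing reading, by
contrast, is exactly "the fewest items with no significant difference",
and is what the package implements.

`elbow_detection()` reports the size at which the marginal expected-test-
information gain $\Delta_k = I(k) - I(k-1)$ drops the most
($\max_k \Delta_k - \Delta_{k+1}$); a linear information profile (all
second differences below $10^{-9}$) returns a no-elbow flag. The elbow is
descriptive and never overrides the inferential rule.

## ROC machinery

AUCs are Mann–Whitney statistics with ties counted one half; variances
and the paired test use DeLong placement values (the test suite checks
exact agreement with exhaustive pair enumeration at small $n$, and
agreement with pROC's DeLong implementation to near machine precision).
Confidence intervals are Wald on the AUC scale with the DeLong SE,
clipped to $[0, 1]$ — matching pROC's default. Youden cutoffs use the
"positive if score ≥ t" convention with ties broken toward the higher
cutoff (favoring specificity, the scarcer commodity at low prevalence).
McNemar's test switches from the exact binomial to the continuity-
corrected chi-square at 25 discordant pairs. Predictive values are plain
Bayes' rule; `cutoff_sweep()` tabulates them at 3.8%, 13%, and 20%
prevalence — community screening, geriatric clinic, and high-prevalence
settings respectively.

A calibration caveat the tests document: with very few cases (around ten)
the asymptotic DeLong test is anti-conservative (its variance is
estimated from the case placements), so null rejection rates near 10%
at that design are a property of the method, not an implementation
defect; at 50 cases the empirical size is nominal.

## Efficiency ratio

The scale-economy statistic is AUC divided by the number of items.
Within-sample comparisons resample subjects with replacement (pairing of
the two scales preserved), recompute both efficiency ratios per
resample, and decide by the 95% percentile interval of the difference
over `B = 1000` iterations; an approximate two-sided bootstrap p-value
is reported alongside but the interval is the criterion. Resamples that
lose a diagnosis class are redrawn up to ten times, then skipped and
counted. Cross-half stability uses
$z = (E_{dev} - E_{val})/\sqrt{SE^2_{dev} + SE^2_{val}}$ with bootstrap
SEs computed independently per half.

## Differential item and test functioning

`mh_dif()` stratifies on the audited scale's total score (including the
studied item — the classical Mantel–Haenszel DIF default; the matcher is
an argument for users who prefer rest-scores), merging strata with fewer
than five subjects into the nearest score stratum. The common odds ratio
adds the 0.5 continuity correction only in strata containing a zero
cell; strata lacking a group or item variation are non-informative and
dropped (all dropped is an error). The p-value is the continuity-
corrected MH chi-square. Effect size is the ETS delta
$\Delta_{MH} = -2.35 \ln \alpha_{MH}$ — the ETS convention, adopted here
because the A/B/C classification is defined on that metric — with A/B/C
thresholds at 1.0 and 1.5 and significance required for B/C. Signed
deltas and an explicit favored-group label are reported, since an
absolute delta alone loses direction. Scale-level invariance
(`dtf_auc()`) compares subgroup AUCs; the age dichotomy defaults to 75
years (young-old vs old-old).

DIF is audited on the combined sample by default (power), with a
validation-only option.

## The synthetic cohort

`generate_cohort()` emulates the statistical structure the analysis
assumes: a binary diagnosis at 3.8% overall prevalence; recruitment
source (6.1% clinic) acting on prevalence only, at a fixed
clinic-to-community rate ratio of 0.132/0.032 rescaled to the overall
target; latent severity $\mathcal N(0,1)$ for non-cases and
$\mathcal N(1.7, 1)$ for cases (placing the latent-trait AUC near 0.89
and the full-scale sum-score AUC in the high 0.8s, the regime of a
well-validated screening instrument); 2PL responses from the packaged
30-item bank; and optional per-group difficulty shifts for DIF studies.
Sex and age-group margins (56.9% female, 30% old-old) exist so DIF/DTF
grouping variables are available.

What it does **not** emulate — and therefore what passing tests cannot
show about real data: item nonresponse, multidimensionality or local
dependence among items, diagnosis-conditional trait distributions other
than normal (the source study reports no such distributions, so the case
trait was calibrated to AUC, not to moments), longitudinal structure,
or response styles (acquiescence, reverse-wording artifacts: the
generator emits already-keyed items, and reverse-keying is purely a
reader concern via `read_response_csv(keymap = )`).

`stratified_split()` partitions on diagnosis × source with
largest-remainder integer allocation, so a 6525-subject cohort splits
into exactly 3262/3263 at ratio 0.5, and per-stratum case counts differ
by at most one between halves.

## Orchestration

`run_pipeline()` chains the stages, records every p-value the stopping
rule consulted (the selection is inference-driven and should be
auditable), stamps all outputs with a configuration hash, and is
byte-identical across reruns with the same seeds. The command-line
surface is intentionally thin — the package's users work in R, so the
exported functions *are* the interface, and `scripts/acceptance.R` shows
the minimal Rscript pattern for shell use.

## Problem sizes used by the test suite

The suite favors a few deep, parameterised checks over many shallow
ones. Simulation sizes were chosen as the smallest that make the checked
property unambiguous: ICC convergence at $n = 50{,}000$; two-item
difficulty recovery at $n = 50{,}000$; 30-item bank recovery at
$n = 5000$ over 10 seeds; DeLong size at 1000 null datasets of $n = 200$;
end-to-end selection at the full cohort design ($n = 6525$, 50 seeds);
DIF power and size at 20 cohorts each. Bootstrap checks use
$B$ between 200 and 1000 depending on whether the verdict or the
distribution shape is under test.

## Known limitations

* Unit-weighted sum scoring means near-zero-discrimination items are
  pure noise; the full-scale comparator is therefore *diluted*, and
  "equivalence with the full scale" is a weaker target than "maximal
  AUC". This is intrinsic to the published procedure the package
  implements, and the reduction trace makes it visible.
* The equivalence boundary $k^\*$ is a noisy estimate: across simulation
  seeds of the default cohort it ranges widely around 10. Single-cohort
  selections should be reported with their full trace, not just $k^\*$.
* The 2PL fitter is a fixed-grid EM without acceleration; it is fast for
  tens of items but not designed for item banks in the hundreds.
* No 1PL/3PL or polytomous models, no multidimensional IRT, no
  IRT-based scoring of individuals, and no dimensionality diagnostics.
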