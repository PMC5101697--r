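---
title: "Measuring care-process quality from two data sources: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring care-process quality from two data sources: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qicompare)
```

## The measurement problem

Process quality indicators (QIs) for physical therapy score how completely a
therapist documents the clinical reasoning process — screening and
diagnostics, goal setting, intervention, evaluation, and communication with
the patient — across their patient cases. The same indicator set can be fed
from two very different data sources:

* a **provider survey**, in which the therapist retrospectively scores at
  least 30 of their own closed patient cases on polytomous items
  (e.g. no / somewhat / completely), and
* a **direct EHR extraction**, in which structured record fields can only
  reveal *whether* a step was documented, so every item is binary.

`qicompare` implements both scoring frameworks, the harmonization between
them, and the matched-therapist comparison of the two sources on
**completeness** (proportion of a therapist's cases without missing item
values) and **correctness** (agreement of mean indicator scores, with the
survey as benchmark in the absence of a gold standard).

## Scoring frameworks

For one case and one indicator with item values $x_1,\dots,x_k$ and maxima
$M_1,\dots,M_k$:

* **proportional** (survey): $s = \sum_i x_i \big/ \sum_i M_i$, the degree
  to which the steps were followed. Items 1 (of 1) and 1 (of 2) give
  $2/3 = 0.67$.
* **dichotomous** (EHR): each item is recoded to $\mathbf{1}[x_i > 0]$ and
  the case scores 1 only when every item recodes to 1 — all steps followed,
  or not. The same case scores 1, because "somewhat" still counts as the
  step having been performed.

At therapist level the indicator score is the mean of the defined case
scores; under the dichotomous framework this is the proportion of cases in
which the therapist followed all the steps (8 all-steps cases out of 10
score 0.8).

Missing responses are kept distinct from the value 0: a blank cell means
*not recorded*, while 0 means *assessed and not performed*. Under the
default `exclude_incomplete` policy a case with any missing applicable item
has an undefined score (it still counts in the completeness denominator);
`available_items` instead restricts both sums to the observed items. One
deliberate asymmetry: in the dichotomous framework a recorded 0 is decisive
by default even when other items are missing — one failed step already
means "not all steps followed". Setting `zero_decisive = FALSE` makes any
missingness dominate instead. The printed comparison tables motivated the
default policy: the correctness Ns are visibly smaller than the
completeness Ns, implying that incomplete cases were dropped from score
means but not from completeness.

Two further conventions for degenerate inputs: a fixed-item indicator whose
columns are present in a file expects *every* item per case (absent cells
are missing), whereas the per-goal indicators (6 and 7, up to 15 goals)
treat slots beyond the recorded goal count as absent **by design** — they
never enter a denominator. A case with zero recorded goals is incomplete
with an undefined score: documenting nothing is missing documentation.

## Indicator registry

The shipped registry (`qi_registry()`) fixes the item counts
(5, 4, 4, 5, 1, ≤15, ≤15, 7 for QI1–QI8), the applicability rules (QI1
only for direct-access patients, QI2 only for referred patients, all others
universal), and the EHR-extractability flags (QI4 and QI7 cannot be
extracted: narrative intervention registration and the non-mandated use of
measurement instruments). The per-item response maxima of the original
survey instrument are not published item by item; the registry therefore
ships *assumed* maxima — administrative yes/no items are binary, one
"determined systematically" item in QI1/QI2 is three-level as in the
canonical worked example, and the per-goal result items are four-level
(not at all / somewhat / largely / completely). These assumptions are
visible, documented, and overridable via `registry_from_yaml()`; they are
chosen so that exactly QI1 and QI2 require item recoding during
harmonization, consistent with the published comparability overview.

## The comparison

Therapists are matched across sources by id; only therapists present in
both sources are compared (a therapist with survey records from two cohort
years contributes the most recent one by default — the pooled survey years
publish no selection rule, so the rule is explicit and configurable). Per
indicator and metric, the paired values feed a **matched-pairs Wilcoxon
signed-rank test**: differences of zero are dropped (and counted — ceiling
effects make them common), absolute differences are midranked under ties,
and $W$ is the positive-rank sum.

* For at most `exact_threshold` (default 12) nonzero pairs the two-sided p
  comes from full enumeration of all $2^n$ sign assignments of the observed
  ranks. This is exact *under ties*, where the classical exact distribution
  does not apply.
* Otherwise the tie-corrected normal approximation is used,
  $z = (W - n(n+1)/4)\big/\sqrt{n(n+1)(2n+1)/24 - \sum_t (t^3 - t)/48}$.
  The reported `z_score` is this uncorrected statistic (directly comparable
  to published Z values); the p-value applies a 0.5 continuity correction,
  which keeps it within ~0.02 of the exact enumeration already at a dozen
  pairs, where the uncorrected p can be off by ~0.05.

Group differences are summarized as the **relative change**
$(\mathrm{EHR} - \mathrm{Survey})/\mathrm{Survey} \times 100\,\%$;
$|\mathrm{RC}| \ge 5\,\%$ is a *relevant* difference and $p < 0.001$ a
*significant* one. The relevance boundary follows the strict "< 5 % means
the same" convention, so exactly 5 % counts as different. No
multiple-testing correction is applied across indicators: the single
per-test $\alpha$ is part of the measurement convention being reproduced,
and changing it would break comparability.

Indicators can drop out of the comparison for three reasons, each logged
with a machine-readable code: not extractable from EHRs
(`not_extractable_from_ehr`), absent from a dataset, or failing the
**validity filter** (`extraction_deviation`): when fewer than
`min_valid_fraction` (default 0.50) of the applicable EHR cases have a
defined score — the signature of suppliers deviating from the extraction
algorithm — the indicator cannot be trusted. The published exclusion
happened at an 11.6 % valid fraction without a stated cut-off; 0.50 is this
package's explicit default, exposed in configuration and reported in the
log, and any fraction at or above the threshold is kept.

## The synthetic cohort generator

No public dataset exists at item level, so `generate_cohort()` makes the
entire pipeline testable. It emulates:

* the hierarchy of ~2,400 practices with the published practice-size mix,
  each therapist present in both sources, ≥30 survey cases per therapist
  and fewer EHR cases;
* source-specific case mix: direct-access rates, gender and age-band
  rates, and chronic patients underrepresented in the EHR source (short
  extraction windows favour closed acute episodes);
* **ceiling effects**: each therapist's per-indicator step-following
  probability $\theta$ is drawn from a mixture — probability 0.7 of
  sitting essentially at ceiling ($\theta = 0.995$) and otherwise a
  Beta(12, 1.5) tail. Item successes are independent Bernoulli($\theta$),
  so the dichotomous case score succeeds with probability $\theta^k$;
* survey polytomy: a successful step reports the maximum level with
  probability 0.7, a partial level otherwise; EHR items are binary;
* **per-item missingness** $m$ per source and indicator, applied after the
  response draw, so expected completeness of a $k$-item indicator is
  $(1-m)^k$. Defaults are back-derived from the published per-source
  completeness marginals through exactly this formula (indicators without
  a published marginal default to 0.98); they are illustrative
  calibrations, not estimates;
* **supplier structure**: practices are assigned to 15 EHR suppliers with
  the published market concentration (two suppliers at 68.4 %, five at
  92.5 %), and `inject_supplier_deviation()` invalidates a configured,
  exactly-rounded fraction of flagged suppliers' cases on one indicator.

All randomness flows from one master seed through per-practice and
per-therapist streams, so enlarging the cohort never perturbs the draws of
existing units — regression tests stay stable as configurations grow.
The ground truth ($\theta$ per therapist and indicator, $m$ per source,
supplier map) is returned alongside the data for recovery tests.

What the generator does **not** emulate: correlation between items within
a case beyond the shared $\theta$, therapist drift between cohort years, a
time effect between sources, supplier-specific user-interface effects on
missingness, and narrative free-text fields. Passing tests therefore
demonstrate that the *pipeline arithmetic and test calibration* are
correct under the assumed structure, not that real survey and EHR data
would agree.

## Numerical and design choices

* All computation is unrounded; rounding happens only in display columns
  (percentages to 1 decimal, scores to 2, matching table conventions) and
  rounds half away from zero so printed values match hand-rounded tables.
* The validity and relevance thresholds use closed lower bounds
  (`>=` keeps, `>=` is relevant); both boundaries are unit-tested.
* Statistical checks in the test suite run at reduced problem sizes chosen
  for tight Monte-Carlo bounds at interactive runtimes: 1,000 replicates of
  50 matched therapists for the type-I-error calibration of the Wilcoxon
  path at $\alpha = 0.001$, 200 therapists × 30 cases for completeness
  recovery against $(1-m)^k$, and 500 therapists for unbiasedness of the
  dichotomous score as an estimator of $\theta^k$.
* Published therapist-level Z-scores and Ns cannot be recomputed without
  the item-level study data; the package reproduces the published worked
  examples and table arithmetic exactly, and validates the statistical
  machinery by property-based simulation instead.

## Limitations

The comparison treats the survey as the benchmark; nothing in the package
can detect a bias shared by both sources. The combined QI5+QI6 outcome
indicator is registered behind a configuration flag but, reflecting its
fate in practice, is never compared by default. Practice-level clustering
is ignored by the matched-pairs test (therapists within a practice are
treated as independent pairs); a multilevel sensitivity analysis is out of
scope here.
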