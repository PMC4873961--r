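---
title: "Case-mix adjusted CS-rate benchmarking: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Case-mix adjusted CS-rate benchmarking: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmodel)
```

## The model and its assumptions

The package's core is a set of four fixed logistic scores for the
probability that an individual delivery ends in caesarean section (CS).
For woman $i$,

$$\mathrm{logit}\,p_i = \beta_0 + \sum_j \beta_j x_{ij}, \qquad
  p_i = \frac{e^{\mathrm{logit}\,p_i}}{1 + e^{\mathrm{logit}\,p_i}},$$

where the $x_j$ encode parity (indicator of multiparity), previous CS,
multiple pregnancy, provider-initiated childbirth (induction *or* prelabour
CS), presentation (0 cephalic / 1 breech / 2 transverse, oblique or other),
preterm birth, maternal age, organ dysfunction or ICU admission, and six
complications (placenta praevia, abruptio placentae, chronic hypertension,
pre-eclampsia scored 0/1/2 with eclampsia at 2, renal disease, HIV).
The four versions form a ladder of data requirements: v1.0 uses the six
obstetric covariates; v1.1 adds maternal age; v1.2 adds organ
dysfunction/ICU; v1.3 swaps preterm birth out and the six complications in.
`best_version()` always applies the richest version the data supports,
because more covariates mean finer case-mix adjustment of the expected
rate.

The coefficients are *shipped constants*, estimated elsewhere on a
multi-country reference population of deliveries at facilities with both
low CS use and low intrapartum-related perinatal mortality. The package
deliberately does not re-derive them; `refit_cmodel()` exists so that users
with their own reference population can re-estimate the same functional
form and compare.

Key modelling assumptions a user should be aware of:

* **The reference standard is a population, not a norm.** The expected rate
  answers "how often would facilities with good outcomes and conservative
  CS use operate on *this* case mix", nothing more. Deviation above the
  range is a trigger for inquiry, not a verdict: it may reflect practice,
  case-mix variables the model does not capture, or data quality.
* **Indications are not modelled.** The score uses maternal characteristics
  knowable at admission; it cannot see dystocia, fetal distress, or
  caesareans performed for convenience.
* **Covariates act additively on the logit scale**, with no interactions —
  the cost of a score simple enough to compute from routine registries.

## Benchmark quantities

For a dataset of $n$ predictable deliveries with outcomes known, the
package reports, via `cs_benchmark()`:

* expected rate $E = 100\cdot\frac{1}{n}\sum_i p_i$ (percent);
* observed rate $O$ (percent), over the *same* records — any record
  excluded from prediction (missing covariate) is excluded from the
  observed rate too, so deviation never conflates missingness with
  practice; the exclusion count is always reported;
* deviation $O - E$ in percentage points, and the standardised CS ratio
  $\mathrm{SCR} = O/E$ (equivalently, observed CS count over the sum of
  predicted probabilities);
* an uncertainty range $[0.8E,\, 1.2E]$. The 20 % half-width is a
  convention inherited from the published benchmark (there described as
  arbitrary); it is exposed as the `range` argument.

Both the deviation (absolute, percentage points) and the SCR (relative) are
reported, so either reading of "deviation from expected" is served.

## Tunable parameters

| parameter | where | default | units | rationale |
|---|---|---|---|---|
| `age_cutoff` | `encode_covariates()` and downstream | 35 | years | the x7 coefficient is a single indicator but the published coding rules never state its age boundary; 35 is the conventional advanced-maternal-age threshold. This is an assumption, prominently flagged — set it to your registry's definition. |
| `range` | `cs_benchmark()` | 0.20 | relative fraction | the published ±20 % uncertainty band. |
| `min_n` | `cs_benchmark_by_group()` | 20 | records | below this, group-level rates are reported as `low_n` noise guards rather than numbers. |
| `fraction`, `seed` | `split_reference()` | 0.9, none | — | 90/10 build/test split; the seed is mandatory so splits are reproducible. |
| `continuity` | `classification_table()` | FALSE | — | 0.5 added to all cells for the DOR only, on request, when a cell is zero. |
| `cluster_boot` | `refit_cmodel()` | 0 | replicates | facility-level bootstrap SEs when deliveries cluster within facilities. |

Two encoding directions are fixed by design and documented rather than
guessed silently: x1 is 1 for *multiparous* women (the negative parity
coefficient then reproduces the lower CS rates of multiparous spontaneous
labour, Robson groups 3–4 vs 1–2), and prelabour CS encodes x4 = 1 exactly
like induction (provider-initiated childbirth is the published proxy for
both).

## Robson classification details

`robson_classify()` applies the ten group definitions in the standard
precedence order that makes them mutually exclusive: multiple pregnancy
(8), transverse/oblique lie (9), breech by parity (6/7), single cephalic at
$\le 36$ weeks (10), previous uterine scar at term (5), then parity ×
onset (1–4, with provider-initiated = induced or prelabour CS). Choices
worth noting: "multiparous" is parity $\ge 1$; "previous uterine scar" is
previous CS $\ge 1$ (scars from other uterine surgery are not in the data
model — a documented limitation); term is $\ge 37$ completed weeks, so
36 weeks + 6 days is 36 completed weeks and falls in group 10;
presentation "other" is grouped with transverse/oblique, consistent with
the x5 = 2 coding rule. A record missing the field needed at the decision
node actually reached is `UNCLASSIFIABLE` (`NA`), and the group table
reports that count separately — fields never reached (e.g. gestational age
of a twin pregnancy) do not block classification.

## Validation machinery: numerical choices

* **AUC** is the rank (Mann–Whitney) statistic with average ranks, so ties
  count one half; the test suite checks it against an $O(n^2)$ pairwise
  concordance oracle at $10^{-12}$.
* **AUC standard error** uses Hanley–McNeil. The published validation
  predates routine DeLong reporting, and Hanley–McNeil needs only the AUC
  and class counts; for pooling across studies it is the natural input.
* **Cut-off**: the criterion behind "cut-off points derived from ROC
  curves" is not stated in the source; we use Youden's
  $J = \text{sens} + \text{spec} - 1$, the standard choice, with ties
  broken toward higher specificity and the returned value placed mid-gap
  between adjacent distinct scores (classification-equivalent, but
  stabler to report). Prediction at the cut-off uses $\ge$, which matters
  at tied scores and is therefore documented.
* **Calibration** uses quintiles of predicted probability; when $n$ is not
  divisible by 5 the remainder goes to the lowest bins.
* **Meta-analysis** of per-study AUCs is DerSimonian–Laird:
  $\tau^2 = \max\!\big(0, (Q - df)/C\big)$,
  random-effects weights $1/(se^2+\tau^2)$, normal 95 % CI,
  $I^2 = \max(0, (Q-df)/Q)$. The estimator is frozen against
  hand-computed values in the tests.
* **Logistic fitting** (`fit_logistic()`) is IRLS/Newton on the
  log-likelihood: convergence at max |score| < 1e-8 or relative
  log-likelihood change < 1e-10, at most 100 iterations, SEs from the
  inverse observed information; a coefficient norm above 50 aborts with a
  separation error; constant covariates and rank-deficient designs error
  before iteration. Non-convergence is reported in the result, never
  silent.
* **Logit arithmetic** sums coefficient terms in ascending covariate index
  for bit-stable results; probabilities are never rounded internally
  (display rounds to 4 decimals, table rates to 1).

## Reference-population construction

`facility_indicators()` aggregates per facility: CS rate (% of women with
recorded mode), intrapartum-related perinatal mortality (intrapartum
stillbirths + neonatal deaths on the first postpartum day, per 1000
livebirths), maternal mortality (per 100,000 livebirths), near-miss and
severe-maternal-outcome rates (per 1000). `select_reference()` computes the
across-facility medians of the first two (even counts: midpoint of the two
central order statistics) and keeps facilities *strictly* below both — the
strictness mirrors the "below the 50th percentile" rule, and means a set of
identical facilities selects nothing (warned, not hidden).

`split_reference()` is a record-level simple random split,
$\lceil 0.9n \rceil$ to the build half. The published reference split
(38,324 / 4,313 of 42,637) is visibly *not* an exact 90/10 partition —
consistent with per-record Bernoulli allocation or post-hoc exclusions; we
implement the exact-fraction split and note the difference rather than
emulating an unstated mechanism.

Coefficient estimation here is **fixed-effects** maximum likelihood, where
the published score came from a facility-random-intercept model. The
package's acceptance surface is recovery of fixed coefficient values and
reproduction of published constants, not variance components; facility
clustering can be acknowledged through the optional cluster bootstrap.
With a non-zero `facility_effect_sd` in simulation one can study exactly
what this simplification costs.

## What the synthetic generator does and does not emulate

`simulate_deliveries()` draws covariates *independently* per woman from
configurable prevalences, with two consistency constraints enforced
(previous CS only in multiparous women; prelabour-CS onset only for
caesarean births), computes each woman's true probability under a chosen
version's coefficients (plus an optional normal per-facility logit shift),
and draws the outcome from it. Default prevalences were chosen once so that
the Robson relative group sizes of a large simulated dataset approximate a
multi-country low-intervention reference population — about 29 % group 1,
40 % group 3, 7 % group 5, 0.9 % multiple pregnancies, 0.4 % transverse
lies, 4 % preterm cephalic singletons — with severity/complication
prevalences at textbook obstetric magnitudes (advanced maternal age 9 %,
organ dysfunction 0.3 %, placenta praevia 0.5 %, abruption 1 %,
pre-eclampsia 2.5 %, eclampsia 0.3 %, chronic hypertension 0.5 %, renal
disease 0.4 %, HIV 1 %, intrapartum-related perinatal mortality 3.0/1000,
maternal mortality 23.6/100,000, near miss 2.6/1000).

What this means for green tests: the generator produces data in which the
scoring model is *correctly specified*. Tests of calibration, parameter
recovery and CI coverage therefore establish that the machinery is
implemented correctly — they cannot establish that the shipped score fits
any real population, where covariates correlate (previous CS with age,
pre-eclampsia with nulliparity), onset depends on presentation, and
facility effects are not symmetric noise. Real-data heterogeneity across
countries, convenience caesareans, and registry-specific variable
definitions are explicitly not emulated.

## Input handling and degradation rules

Parsing is total: any CSV with a header yields a dataset; a cell that
cannot be read as its field's type becomes missing with a counted warning,
never a crash or a dropped row. Gestational ages outside 22–44 weeks and
maternal ages outside 10–60 years are treated as registry noise → missing.
Enumerations parse case-insensitively through an extensible synonym table
("cesarean", "CS", "vertex", "transverse lie", …). `previous_cs` accepts a
count or a 0/1 flag. Missingness is explicit everywhere; the package never
imputes — a record missing a required covariate is excluded with a logged
reason, and the exclusion count always travels with the result. The schema
documents operational definitions (e.g. parity as count of previous
births) without claiming fidelity to any particular case-report form.

## Known limitations

* The maternal-age cutoff (35) and the multiparity direction of x1 are
  package assumptions where the published coding rules are silent; both are
  configurable and flagged.
* Uterine scars from non-caesarean surgery are invisible to the data model,
  slightly undercounting Robson groups 5/7/8/9 membership by scar.
* v1.2 and v1.3 assign visibly different coefficients to organ
  dysfunction/ICU (1.499462 vs 0.661417); we treat them as the same
  covariate with version-specific weights, as printed, without
  reinterpreting the variable.
* Fixed-effects refitting understates uncertainty when deliveries cluster
  strongly within facilities; use `cluster_boot` or treat SEs as
  approximate.
* The headline external-validation results of the published benchmark
  (summary AUCs, diagnostic odds ratios in the high teens) were obtained on
  confidential multi-country databases and are not reproducible here; the
  package validates the *machinery* on synthetic data and small exact
  oracles instead, and nothing in this vignette states an empirical result
  the test suite or acceptance script does not itself compute.
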