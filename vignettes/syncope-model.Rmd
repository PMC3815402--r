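---
title: "A literature-based naive Bayes model of cardiac syncope: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A literature-based naive Bayes model of cardiac syncope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model and its assumptions

`syncopenb` estimates the probability that a syncope patient's faint has a
cardiac cause, using nothing but categorical clinical history. The model is
a naive Bayes classifier over a fixed vocabulary of predictors — age band
(<40, 40–60, ≥60 years), sex, structural heart disease, number of prior
spells (≤2 vs >2), long prodrome, nausea, diaphoresis, blurred vision,
supine syncope, effort syncope — each characterised by a conditional
probability table (CPT) of level frequencies given the diagnosis class.
For a patient in population $g$ with observed values $x_1,\dots,x_k$,

$$
p \;=\; \frac{\pi_g \prod_j P(x_j \mid \text{cardiac})}
             {\pi_g \prod_j P(x_j \mid \text{cardiac})
              + (1-\pi_g) \prod_j P(x_j \mid \text{non-cardiac})},
$$

where $\pi_g$ is the population's prior prevalence of cardiac syncope.

Two assumptions do all the work. First, *conditional independence*:
predictors are treated as independent given the diagnosis class. This is
known to be wrong in detail (age, structural heart disease and spell count
are correlated), and dependence is deliberately not modelled. Second,
*transportability*: CPTs pooled from derivation-study counts are assumed to
apply to new populations, with only the prior adapted per centre. Both
assumptions are what make a literature-based model possible at all, since
no patient-level derivation data exist.

Missing values are marginalized by omission from the product. Under
conditional independence this is exact — summing the joint model over the
unobserved variables cancels their factors — and the same rule is applied
whether a single patient lacks a value or a whole centre never collected
the variable. A patient with no observed predictors therefore scores
exactly the prior.

## Derivation from pooled literature counts

CPTs are raw pooled relative frequencies: per predictor, the per-study
diagnosis-by-level counts are summed across the studies that reported it
and divided by the pooled class totals. No smoothing or pseudocounts are
applied, because the tables are meant to reproduce the published pooled
frequencies exactly; zero cells are legal and propagate as genuine zeros
at prediction time (a patient whose observed values are impossible under
*both* classes is an error, not a silent 0/0).

Candidate predictors enter the model through a two-part selection rule:
reported as significantly associated with the diagnosis in at least 3
source studies, and pooled Pearson $\chi^2$ (no continuity correction)
significant at $\alpha = 0.05$. The per-study significance sets are
*metadata*, not recomputed: several source studies reported multivariable
significance without publishing a cross-tabulation, so recomputation from
counts is impossible in principle. The bundled significance file is a
synthetic reconstruction (labelled as such) consistent with the narrative
record: all eleven candidates are credited with ≥3 significant studies,
and palpitations — whose direction of association genuinely differs
between studies — is then excluded by its pooled p of 0.06. Bystander-
observed signs never enter the candidate list because their availability
is conditional on a bystander.

Diagnostic likelihood ratios are computed from exact pooled counts and
only rounded for reporting. Rounding intermediate percentages first gives
visibly different values (e.g. effort syncope: 6.92 from exact counts vs
6.5 from rounded percentages), so intermediate rounding is never used.

### Fixture transcription notes

The bundled count fixtures transcribe the published per-study overview
table. Three rows of that table are internally inconsistent, and the
package resolves each in favour of the printed pooled totals:

* **Age**: the per-study cells sum to (2, 65, 227 | 323, 427, 363) while
  the printed totals are (3, 65, 226 | 234, 427, 363). The printed
  non-cardiac "<40" total (234) disagrees with its own printed
  percentage (29% ≈ 323/1113), yet the printed totals — not the cell
  sums — reproduce the published pooled $\chi^2$ of 171.7. The fixture
  carries the printed totals as a single pooled row.
* **Diaphoresis**: the per-study yes/no cells are swapped relative to the
  totals and contain an apparent digit typo; the printed totals
  (86/382 | 753/1015) are self-consistent and reproduce $\chi^2 = 92.6$
  and LR 1.42, so the fixture carries the totals.
* **Palpitations**: one non-cardiac cell printed as 372 must be 672 for
  the row to add to its class total; with 672 the printed total, $\chi^2$
  of 3.4, p of 0.06 and LR of 1.03 all reproduce. The fixture carries 672.

One published pair of values is *not* reproducible from any reading of
the published counts: the structural-heart-disease $\chi^2$ (printed
283.7) and likelihood ratio (printed 3.00). Independent recomputation
from the printed counts (118/18 | 85/243) gives 144.6 and 3.35. The
package reports the recomputed values and the test suite documents the
mismatch rather than forcing agreement.

Age bins are reconstructed from reported mean ± SD where a source gave no
cross-tabulation: patients are allocated by the normal CDF, rounded per
bin, with the rounding residual reconciled into the largest bin so totals
are exact (the source does not state its rounding rule; this one is
deterministic and total-preserving). The bin edge at 60 belongs to the
upper bin, matching the "≥60" labelling; the edges are a configurable
argument.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `cutoff` | 0.02 | posterior threshold for a cardiac call; deliberately low to favour sensitivity over specificity; a posterior exactly at the cutoff is called cardiac |
| `min_studies` | 3 | minimum source studies reporting significance |
| `alpha` | 0.05 | pooled significance threshold |
| `bin_edges` | 40, 60 years | age-bin cut points |
| priors | per population | exact class-size fractions (e.g. calgary 138/663 ≈ 0.208), not rounded percentages |

## Numerical choices

Posterior products are accumulated in log space so that cohorts scored
with many small conditional probabilities cannot underflow; the result is
identical to the direct product within 1e-12 (tested). `log(0) = -Inf`
flows through correctly for zero CPT cells, and the both-classes-zero case
is detected and raised as an error. The c-statistic is computed from
midranks, which equals exhaustive cross-class pair counting with ties
worth one half, and makes the identity $U = c \cdot n_1 n_0$ with the
Mann–Whitney statistic exact. ROC thresholds are the unique observed
scores, descending, with a $+\infty$ sentinel, so the curve always runs
from (0,0) to (1,1) and its trapezoidal area equals the c-statistic.
Stratum targets are converted to integer counts by the largest-remainder
method (floor, then distribute the residual by decreasing fractional
remainder), so replicate sizes are met exactly.

## Stratified standardization

To attenuate accrual bias — centres differ strongly in age and in how many
prior spells their patients have had — a cohort can be resampled with
replacement *within* age × spells strata so that every replicate matches a
reference joint distribution exactly. The source literature prints only
the pooled *marginals* of age and spells, not their joint distribution,
so the default plan uses the product of the class-combined pooled margins
(age 237/492/589 of 1318; spells 238/254 of 492). The cardiac-only margins
(1%/22%/77%) were considered and rejected: the stated intent is to
standardize to the overall literature distribution, and conditioning the
reference on the outcome class would build the outcome into the design.
This gap is the reason the plan is a first-class, fully overridable
object (JSON/YAML round-trip included). All resampling randomness flows
from the plan's single seed and is bit-reproducible.

## The synthetic cohort generator

No patient-level test data are deposited, so the generator emulates the
four test centres from their published distribution tables: true class
from the centre's prior, then each collected predictor drawn independently
from its class-conditional level distribution, then patient-level
missingness (the shortfall of a predictor's published counts against the
centre size) applied independently of class. Centre quirks are
represented explicitly: Milan's spell count was published only as
one-vs-more-than-one and is generated under that proxy coding (flagged on
the spec); blurred vision in Rochester came from free-text comments
rather than a questionnaire item and is excluded from the collected set
by default; Milan's spells row is internally inconsistent in the source
(its printed totals are the class cells swapped), and the fixtures carry
the class cells.

What the generator deliberately does **not** emulate: predictor–predictor
dependence given class (outside the model family), class-dependent
missingness, and the diagnostic misclassification real reference
standards suffer. Synthetic cohorts are therefore a *best case* for the
model: passing tests demonstrate the pipeline's correctness and the
model's behaviour under its own assumptions, not real-world accuracy.
Simulated c-statistics (≈0.92 for a Calgary-like centre at its case mix)
accordingly sit above the moderate discrimination expected on real data,
and published real-data c-statistics are not reproduction targets.

## Problem sizes used by the test suite

The suite checks the posterior against brute-force joint enumeration on
all $3 \cdot 2^9 = 1536$ complete predictor assignments for each of the
four populations (tolerance 1e-12); parameter recovery on a
100,000-patient synthetic cohort (every CPT cell within 3 binomial SEs);
the c-statistic against exhaustive pair counting on 400-patient cohorts;
and 1000 standardized replicates of 1000 patients for exact stratum
matching and bit-reproducibility. These sizes keep every check
comfortably inside interactive runtimes while leaving Monte-Carlo error
far below the asserted tolerances.

## Known limitations

* Conditional independence is assumed, not tested; correlated predictors
  (age, heart disease, spell count) make the posterior overconfident.
* The CPTs inherit every definitional inconsistency of the source
  studies ("structural heart disease" in particular varied between
  sources).
* Priors must be supplied per population; the model does not estimate
  them from unlabelled data.
* The selection rule's per-study significance sets are reconstructed
  metadata, not recomputed statistics.
* The model is a risk stratification aid, not a diagnosis: at the 0.02
  cutoff it is designed to miss few cardiac cases at the price of many
  false positives.
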