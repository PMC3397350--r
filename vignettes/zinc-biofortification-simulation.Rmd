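---
title: "Simulating zinc intake under rice biofortification: models, calibration and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating zinc intake under rice biofortification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zincsim)
```

## The question and the modelling strategy

Rice-staple populations draw a large share of their zinc from a food that
is naturally low in it. Biofortified rice raises grain zinc density; its
population effect depends entirely on the joint distribution of rice
intake, total zinc intake and the demographic strata that set the
reference cutoffs. `zincsim` models that effect for an adult cohort in
three layers:

1. a **substitution identity** that maps each subject's intake to a new
   rice zinc concentration,
2. **adequacy rules** that classify the resulting intakes against Chinese
   dietary reference values, and
3. **dietary-pattern stratification** that localises the effect in the
   population segments that eat the most or least rice.

A synthetic-cohort generator supplies study populations with the
statistical structure this analysis needs, because the individual-level
survey data such analyses are run on are generally not public.

## The substitution model

For a scenario with rice zinc concentration $c_\text{new}$ replacing
$c_\text{old}$ (default 1.7 mg/100 g, the food-composition-table value for
raw polished rice):

$$Z^{rice}_{new,i} = Z^{rice}_i \cdot \frac{c_\text{new}}{c_\text{old}},
\qquad
Z^{tot}_{new,i} = Z^{tot}_i + Z^{rice}_i\left(\frac{c_\text{new}}{c_\text{old}} - 1\right).$$

The design choice here is to scale each subject's *observed* zinc-from-rice
rather than recompute `rice_g x c_new / 100`. Survey datasets often carry a
raw/cooked (or edible-portion) conversion between reported rice grams and
the rice-zinc intake computed from them, so the implied effective
concentration of the recorded grams need not equal the nominal density; the
ratio form is exact per subject whatever that conversion was, and it makes
the scenario means an exact multiple of the baseline mean. Its invariants
are load-bearing and tested: increments are linear in
$c_\text{new} - c_\text{old}$, the SD of the rice component scales by the
ratio exactly, non-consumers are fixed points, and the per-subject total
never decreases when the concentration rises.

The rice share of total zinc is reported under **both** aggregations — the
mean of per-subject shares and the ratio of population means — because the
two differ in skewed cohorts and published tables rarely say which was
used. Neither is privileged; both are labelled in the output.

## Adequacy rules

All rules are data (a JSON fixture), not code:

| quantity | men 20–49 | men 50+ | women 20+ |
|---|---|---|---|
| RNI (mg/day) | 15.0 | 11.5 | 11.5 |
| insufficiency cutoff (2/3 RNI) | 10.0 | 23/3 | 23/3 |
| UL (mg/day) | 45.0 (20–50) | 37.0 (51+) | 37.0 |
| absorption fraction | 0.26 | 0.26 | 0.34 |
| absorbed-inadequacy cutoff (mg/day) | 2.69 | 2.69 | 1.86 |

Two deliberate quirks are preserved from the reference values rather than
harmonized. First, the male RNI strata split at 49/50 years while the male
UL strata split at 50/51; a 50-year-old man has RNI 11.5 but UL 45.
Second, intake insufficiency and absorbed-zinc inadequacy are separate
rule systems that need not agree: a man aged 20–49 exactly at the 10.0
mg/day intake cutoff absorbs $0.26 \times 10.0 = 2.60$ mg/day, below the
2.69 mg/day absorbed cutoff. Inequalities are strict on both sides
(insufficient *below* the cutoff, excess *above* the UL), following the
wording of the definitions.

The phytate:zinc molar ratio — the standard index of zinc bioavailability —
uses molar masses 660.04 g/mol (phytic acid) and 65.38 g/mol (zinc); the
reference values do not state molar masses, so these are documented
package constants. Only this aggregate utility is provided: per-individual
phytate intake is not modelled, and absorption fractions are held at the
IZiNCG mixed-diet defaults in every scenario, including for biofortified
rice itself.

## Pattern scores and quartiles

Scores follow the published construction: standardize each food's weekly
FFQ intake across the cohort ($z$-scores with the $n-1$ SD denominator, a
convention fixed so exact tests are possible), then
$S_{ik} = \sum_j L_{jk} z_{ij}$ over the foods with $|L_{jk}| \ge 0.20$.
The loading matrix is a packaged fixture holding the published table
exactly (41 retained item–pattern loadings over four patterns); deriving
loadings by principal-component extraction from raw FFQ data is explicitly
out of scope, as is reproducing the original explained-variance figures,
which are properties of the original survey data. A food column with zero
variance cannot be standardized; its $z$ is set to 0 with a warning, which
removes it from all scores.

The canonical FFQ vocabulary is 25 items: every item retained in some
pattern, plus cheese (on the questionnaire, below threshold everywhere).
The original survey merged 33 foods into 25 but did not publish the full
merged list, so this vocabulary is a documented reconstruction — the one
assumption in the fixture.

Quartiles are rank-based: sort ascending, cut at ranks
$\lceil n/4 \rceil, \lceil n/2 \rceil, \lceil 3n/4 \rceil$, ties broken by
original input order (a stable radix sort). This guarantees group sizes
differing by at most one — "quartiles" as population fourths — and is
bit-for-bit reproducible, unlike interpolated percentile cutpoints, at the
cost of splitting tied scores across groups deterministically by row
order. At $n = 2819$ the sizes are 705/705/705/704.

Trends over quartiles use OLS on the quartile index 1–4 with
treatment-coded covariates (fixed reference levels: male, north, urban,
low SES, primary education; zinc outcomes adjust additionally for energy)
for continuous outcomes, and the Cochran–Armitage score test
(`stats::prop.trend.test`) for prevalences — published tables of this kind
rarely state which trend test the prevalence columns used, so the choice
is documented here. One simplification is declared in the report itself:
survey analyses can adjust for household clustering, but synthetic cohorts
have no households, so no household term is fitted.

## The synthetic cohort generator

The generator's defaults are the study conditions of the 2002 Jiangsu
adult survey: $n = 2819$, 46.0% male, the published five-band age margins
(10.9/20.9/21.6/18.7/27.9%), about 5% rice non-consumers, rice intake
averaging 250.1 g/day overall with SD 145.8 among consumers, and total
zinc 12.0 ± 3.7 mg/day. SES and education margins are normalized from the
published counts (the printed SES percentages sum to 99% because of
missing data in the source cross-tabulation). Demographics are drawn
independently from their margins; reproducing the full demographic
cross-tabulations is a non-goal.

**Rice.** The positive part is gamma-distributed — intake data are
right-skewed and only a mean and SD are published, so a two-parameter
right-skewed family is the natural choice — multiplied by
$\exp\{\tau (f_{trad} - f_{sweet})\}$ with $\tau = 0.15$, which ties rice
intake positively to the latent traditional factor and negatively to the
sweet-tooth factor (correlation about 0.27 each way) while preserving
positivity exactly. The gamma base parameters are derived in closed form
so the product still has the configured mean and SD; intakes are capped at
1200 g/day (an implausible-intake guard that in practice trims nothing at
the default scale). The induced rice–pattern correlation is a modelling
choice with the right sign, not an estimate of the survey's true value,
which was never published.

**Zinc.** `zinc_rice = rice_g x 1.7/100`. The non-rice component is an
independent normal truncated at zero with mean 7.75 and SD 2.6 mg/day,
calibrated once, analytically, from the published targets: with 95%
consumers at 263.3 ± 145.8 g/day, zero-inflation gives rice grams a mean
of 250.1 and SD of 153.5, so the rice term contributes 4.25 ± 2.61 mg/day,
leaving $12.0 - 4.25 = 7.75$ and $\sqrt{3.7^2 - 2.61^2} = 2.62$ for the
remainder (`analysis/00_calibration.R` prints the derivation and a pilot
check). Energy is a normal base (1500 ± 350 kcal) plus 3.46 kcal per rice
gram, floored at 800 kcal/day, giving means near 2350 kcal/day.

**FFQ.** Weekly grams follow
$w_{ij} = \max(0,\; \mu_j + s \sum_k L_{jk} f_{ik} + \varepsilon_{ij})$
with independent standard-normal latent factors $f$ (the published
patterns come from an orthogonal decomposition, so independent factors are
the natural analogue), the packaged loading matrix $L$, factor scale
$s = 120$ g/week, noise SD 80 g/week, and baseline means $\mu_j$ set to
round, plausible weekly intakes for a rice-staple adult diet (e.g. rice
1750, fresh vegetables 2100, milk 350 g/week). The rectification at zero
produces realistic point masses at zero for rarely eaten foods (liver,
cheese, milk powder) and mildly attenuates their loadings. At the default
scale the computed pattern scores correlate with their generating factors
at about 0.87–0.89; the 0.7 acceptance floor for this parameter-recovery
check was fixed from pilot simulations of exactly this design.

One seed drives the entire cohort through R's default RNG stream, so a
seed determines the cohort byte-for-byte (the cohort CSV writes doubles
with 17 significant digits, the shortest representation guaranteed to
round-trip; reading uses base R's exact `strtod` parser). The latent
factors travel in a JSON sidecar, not in the cohort CSV, because they are
simulation metadata no real survey would have.

**What the generator does not emulate** — and therefore what passing tests
do not show about real data: household clustering and multistage sampling
design (intakes are exchangeable here; design effects and household trend
adjustment cannot be studied); survey weights; correlation between the
FFQ and the recall-based intakes beyond what the shared latent factors
induce (rice FFQ grams and recall rice grams are conditionally independent
given the factors); demographic dependence of diet (age, sex and SES do
not shift intakes); seasonal and day-to-day variation; and measurement
error/misreporting. Results on synthetic cohorts demonstrate that the
pipeline computes the right quantities and responds monotonically to
concentration, not that any particular prevalence equals the survey's.

## Numerical and degenerate-input choices

* Quartile ties: stable by input order; documented above.
* `n < 4` subjects cannot be quartiled; `n < 2` cannot be standardized;
  empty cohorts have no prevalence — all are errors, not NA results.
* A paired comparison with all-zero differences is an identity: $t = 0$,
  $p = 1$ exactly; zero-variance but non-zero differences are an error.
* Chi-square requires all expected counts positive; it is Pearson's
  statistic without continuity correction, $df = k - 1$ for a $2 \times k$
  table.
* Rank-deficient trend designs error and name the aliased columns rather
  than silently dropping them.
* Prevalence intervals are Clopper–Pearson exact 95% (via
  `stats::binom.test`), chosen over asymptotic intervals because scenario
  prevalences can be near zero.
* Unknown food items in recall lines are an error listing the offenders;
  silent dropping would bias intakes downward invisibly.

## Problem sizes used in the checks

The test suite exercises full-size cohorts ($n = 2819$) where the claim
is about survey-scale structure (marginal targets, factor recovery,
quartile sizes) and smaller cohorts (n = 400–800) for property checks run
across several seeds (monotonicity of prevalence in concentration,
recovery monotonicity in the factor scale); oracle-equivalence checks use
5–80 subjects where a brute-force loop is the reference. These sizes were
chosen so each check is decisive for the property it tests.

## Known limitations

* The published prevalences themselves (15.4% → 6.5% → 4.4% insufficiency;
  16.2% → 7.3% → 5.2% absorbed inadequacy) require the original
  individual-level survey data and are not reproduction targets; the
  package asserts the identities that are checkable from published
  aggregates (substitution scaling of the mean rice-zinc, gender-weighted
  absorption, the molar ratio) and the qualitative dose–response on
  synthetic cohorts, whose baseline insufficiency brackets the published
  value in (5%, 30%).
* Published mean zinc-from-rice and mean rice grams imply an effective
  concentration slightly below the nominal 1.7 mg/100 g (likely a
  raw/cooked conversion); the substitution identity sidesteps this, but
  `compute_intakes()` — which is grams x density — will not exactly
  reproduce such a survey's rice-zinc column from its rice-gram column.
* Supplement use, nutrients other than zinc and energy, children and
  adolescents, EAR-based probability-of-inadequacy methods, and mixed
  dishes containing rice are all out of scope.
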