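# zincsim

Simulation of dietary zinc intake under rice biofortification scenarios.

## The problem

Zinc deficiency is widespread in populations whose staple is a refined
cereal. Breeding rice with a higher grain zinc density ("biofortification")
raises zinc intake without asking anyone to change what they eat — but how
much it helps depends on how much rice each person actually eats, which
varies strongly across dietary patterns. `zincsim` is for nutrition
epidemiologists who want to ask, for an adult survey cohort: *if the rice
in this population carried `c_new` mg zinc/100 g instead of `c_old`, what
would happen to the prevalence of insufficient zinc intake — overall, and
in the population segments that eat the most or least rice?*

Because individual-level survey intake data are rarely public, the package
includes a first-class synthetic-cohort generator that reproduces the
statistical structure such an analysis needs (demographic margins, a
right-skewed rice intake distribution, a calibrated total-zinc
distribution, and food-frequency intakes driven by four latent dietary
factors), so the whole pipeline is testable end to end.

## The model

**Substitution.** Each subject's observed zinc-from-rice is scaled by the
concentration ratio:

```
Zn_rice_new(i) = Zn_rice(i) * c_new / c_old
Zn_total_new(i) = Zn_total(i) + Zn_rice(i) * (c_new / c_old - 1)
```

Rice non-consumers are unchanged. Scaling the observed rice-zinc component
(rather than recomputing grams x density) makes the substitution exact per
subject regardless of any raw/cooked conversion between reported rice
grams and rice zinc.

**Adequacy.** Intake is *insufficient* below 2/3 of the age/sex-specific
RNI (Chinese DRIs: 15 mg/day for men 20–49, 11.5 mg/day otherwise, so the
cutoffs are 10.0 and 23/3 mg/day); *excess* above the tolerable upper
intake level (45 mg/day for men 20–50, 37 otherwise). Absorbed zinc is
0.26 x intake for men and 0.34 x intake for women (IZiNCG mixed-diet
fractions), with absorbed-zinc inadequacy below 2.69 / 1.86 mg/day.

**Dietary patterns.** A subject's score on pattern *k* is
`S_ik = sum_j L_jk z_ij` over the foods with |loading| ≥ 0.20, where
`z_ij` is the standardized weekly FFQ intake and `L` is the published
four-pattern loading matrix (traditional, macho, sweet tooth, healthy)
shipped as a fixture. Scores are cut into population quartiles Q1–Q4, and
intake/prevalence trends over quartiles are tested with covariate-adjusted
OLS (intakes) and Cochran–Armitage chi-square (prevalences).

## Worked example

The `analysis/` directory is a numbered workflow over the package
(`01_simulate_cohort.R` → `04_quartile_tables.R`, writing under
`results/`). Its core in a few lines:

```r
library(zincsim)

cohort <- generate_cohort(generator_config(seed = 2026))
scenario_summary(cohort, default_scenarios())
```

which prints (seed 2026):

```
scenario     rice Zn mg/100g  Zn from rice   insufficiency  absorbed     absorbed-inadequacy
normal       1.7              4.3 (2.6)      15.8%          3.7 (1.3)    18.2%
intermediate 2.7              6.8 (4.1)       8.8%          4.4 (1.6)    10.4%
high         3.8              9.6 (5.7)       5.2%          5.3 (2.1)     6.2%
```

Read: at baseline, rice supplies 4.3 mg zinc/day (about a third of total
intake) and 15.8% of the cohort falls below its insufficiency cutoff;
replacing normal rice by the high-zinc variety more than doubles the rice
contribution and cuts insufficiency to 5.2%. `quartile_report()` breaks
the same quantities down by dietary-pattern quartile: the gain concentrates
in the top quartile of the traditional (rice-rich) pattern and shrinks
along the sweet-tooth pattern, whose adherents eat the least rice.

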