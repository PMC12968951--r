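# trapsurv

Design and analysis of multi-trap surveillance networks for bark- and
wood-boring beetles (BWBB: Cerambycidae, Scolytinae) around points of entry
such as ports and airports. Plant-protection agencies deploy grids of baited
multi-funnel traps in the landscapes surrounding entry points; `trapsurv`
answers the two design questions such programs face: *how many traps does a
landscape need*, and *where should they go* when budgets force a reduction.

## What it computes

**Trap-scale urbanization index.** Each trap carries two covariates measured
in a 250-m buffer: tree cover (%) and the angular percentage of the
surroundings free of artificial barriers (roads, buildings). The index is
the Euclidean distance from the full-natural state (100, 100), rescaled to
[0, 100]:

```
U = sqrt((100 - tree)^2 + (100 - barrier)^2) / sqrt(2)
```

so 0 is a trap in continuous forest with no barriers and 100 a fully
built-up site.

**Incidence-based diversity, per landscape.** From the binary species × trap
matrix with T traps, incidence frequencies Y_i, U = ΣY_i, uniques Q1 and
duplicates Q2:

- Chao2 richness: `S_obs + ((T-1)/T) * Q1^2 / (2*Q2)` (bias-corrected form
  when Q2 = 0);
- sample completeness (q = 0): `S_obs / Chao2`;
- sample coverage (q = 1): `1 - (Q1/U) * A`, with
  `A = (T-1)Q1 / ((T-1)Q1 + 2Q2)`, plus rarefied coverage for fewer traps
  and extrapolated coverage beyond T (up to 2T);
- replacement (turnover) component of beta diversity per trap pair,
  `2*min(b,c) / (a+b+c)`, averaged within each landscape.

**Sampling-effort reduction.** Traps are removed sequentially — uniformly at
random (100 randomizations by default) or ordered by the urbanization index
in either direction — and the percent of the landscape's species pool lost
at each retained-trap count is tracked, compared across policies with a
landscape-blocked ANOVA, and regressed on landscape tree cover.

**Catch models.** Per-trap species richness (Poisson) and abundance
(negative binomial) are modelled against the urbanization index with a
landscape random intercept, testing the fixed effect by 1-df likelihood
ratio.

**Synthetic studies.** A seeded generator emulates the full design — 13
landscapes × 16 traps on a 10–80% tree-cover gradient, calibrated covariate
correlations (trap tree cover vs. barrier angle ≈ 0.85; landscape-mean trap
cover vs. landscape cover ≈ 0.81), a lognormal species-abundance
distribution partitioned over a 150-species pool, and negative-binomial
catches declining log-linearly with urbanization — so every stage of the
pipeline can be validated without field data.

## Worked example

```r
library(trapsurv)

study <- generate_study(synthetic_config(), seed = 42)
run <- run_pipeline(study$traps, study$landscapes, study$captures, seed = 7)
print(run)
```

```
trapsurv pipeline run: 13 landscapes, 208 traps (seed 7)
  covariate correlations: trap tree~barrier r = 0.816; cross-scale r = 0.779
  mean completeness 0.905, mean observed coverage 0.957, mean turnover 0.641
  mean loss at k = 8: least_urbanized_first 18.8%, most_urbanized_first 14.0%, random 16.3%
  mean loss at k = 4: least_urbanized_first 41.5%, most_urbanized_first 31.1%, random 37.1%
  richness catch model: slope -0.0071, LRT chi-sq 28.65, p 8.69e-08
```

Reading: the generated covariates hit their calibration targets; halving the
trap number (k = 8 of 16) loses ~16% of each landscape's species under
random removal, and removing the *most* urbanized traps first loses fewer
species than removing the least urbanized first — trap surroundings matter.
The richness model recovers the negative urbanization effect (slope on the
log link, strongly significant).

Individual stages are available directly: `urbanization_index()`,
`incidence_freq()`, `chao2()`, `sample_completeness()`,
`coverage_observed()` / `coverage_rarefied()` / `coverage_extrapolated()` /
`coverage_profile()`, `rarefied_richness()`, `pairwise_replacement()`,
`mean_turnover()`, `removal_order()`, `species_loss()`,
`random_mean_loss()`, `scenario_table()`, `compare_scenarios()`,
`landscape_regression()`, `trap_responses()`, `fit_catch_model()`.

A thin command-line front end is installed at `inst/cli/trapsurv`
(subcommands `generate`, `index`, `run`).

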