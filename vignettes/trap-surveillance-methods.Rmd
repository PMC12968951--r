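---
title: "Methods: multi-scale analysis of trap-based beetle surveillance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-scale analysis of trap-based beetle surveillance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trapsurv)
```

## The problem

Generic surveillance for bark- and wood-boring beetles (BWBB) places grids
of baited multi-funnel traps in the landscapes around points of entry.
Budgets limit trap numbers, so two questions recur: how many traps a
landscape needs for an acceptable fraction of its species pool to be
detected, and which trap locations to keep when effort must shrink.
`trapsurv` treats each trap as an incidence sampling unit, characterizes its
surroundings by a single urbanization score, and quantifies what is lost as
traps are removed.

## The urbanization index

Each trap carries two 250-m-buffer covariates: tree cover (%) and the
angular percentage of the buffer free of artificial barriers. Because the
two are strongly collinear in real deployments, they are combined into one
score: the Euclidean distance of `(tree, barrier)` from the full-natural
state `(100, 100)`, divided by `sqrt(2)` so the score spans [0, 100].

Two design choices were genuinely open here. First, the mapping from the raw
distance range `[0, 100*sqrt(2)]` to `[0, 100]`: we divide by `sqrt(2)`
globally rather than min–max rescaling within a dataset, so the index of a
trap does not change when other traps are added or dropped, and indices are
comparable across studies. Second, the two deficits are equally weighted;
nothing in the design motivates an asymmetry, and the index stays symmetric
under exchange of the two components (a property the test suite asserts).

## Incidence-based diversity estimation

All landscape-level estimation works from the sufficient statistics of the
binary species × trap matrix: `T` traps, incidence frequencies `Y_i`, their
sum `U`, uniques `Q1` and duplicates `Q2`. Estimators follow the standard
incidence framework:

- **Chao2 richness**, with the `(T-1)/T` small-sample correction in both
  branches and the `Q1*(Q1-1)/2` bias-corrected form when `Q2 = 0`. The
  correction is the convention of the estimation software family this
  mirrors, which matters for comparability of completeness values.
- **Sample completeness (q = 0)** is `S_obs / Chao2`. The full order-q
  completeness profile is deliberately out of scope; at q = 0 the two
  coincide under defaults.
- **Sample coverage (q = 1)**: `1 - (Q1/U) * A` with
  `A = (T-1)Q1 / ((T-1)Q1 + 2Q2)`; when `Q2 = 0` the `(Q1-1)` substitution
  is used, and `Q1 = 0` gives coverage exactly 1. Rarefied coverage for
  `t < T` uses the combinatorial expectation with binomial coefficients
  taken as zero when the upper index is below `t`; extrapolated coverage
  for `t > T` multiplies the unseen mass by `A^(t*+1)`. The stitched
  profile is nondecreasing in `t`, asserted numerically on 100 random
  matrices per test run.
- **Expected rarefied richness** `S(t) = Σ_i [1 - C(T-Y_i, t)/C(T, t)]`
  doubles as the analytic oracle for random trap removal: the mean percent
  species loss at `k` retained traps equals `100 * (1 - S(k)/S_obs)`
  exactly. Binomial-coefficient ratios are evaluated in log space
  (`lchoose`) so profiles remain stable for sampling-unit counts far above
  field sizes.

**Turnover.** Beta diversity between two traps is decomposed into a richness
difference and a replacement component; only the latter is used:
`2*min(b, c) / (a + b + c)` with the Jaccard-family denominator. The
within-landscape summary is the mean over all unordered trap pairs. A pair
of two empty traps has an undefined ratio; such pairs are excluded from the
mean and counted in a diagnostics field rather than silently treated as 0.

## Effort-reduction simulation

A removal scenario is an ordering of a landscape's traps. "Reducing to k
traps" keeps the **last k traps of the removal sequence** — stepwise removal
needs an explicit retained-set convention, and this one makes the ordered
policies' curves nested in k. The random policy draws full permutations
(not independent subsets per k), matching one-trap-at-a-time removal, with
100 randomizations by default and a mandatory seed. Ordered policies sort by
the urbanization index, ties broken lexicographically by trap id, so they
are deterministic. Published descriptions of ascending/descending ordering
are ambiguous about which end is removed first, so the policies here are
named semantically (`most_urbanized_first` / `least_urbanized_first`) and
summaries that need a direction-free statement report the min and max of the
two ordered means.

Scenario comparison uses a landscape-blocked linear model
(`loss ~ policy + landscape`) with a likelihood-ratio chi-square on
`#policies - 1` df, plus pairwise paired t-tests without multiplicity
correction. A random-effect formulation for the block would also be
defensible; with every policy observed in every landscape the fixed-block
likelihood ratio is the simpler exactly-specified choice. Landscapes with
fewer traps than a requested k are flagged (`feasible = FALSE`) rather than
dropped, and percentages normalize out differing trap counts.

## Catch models

Per-trap species richness and abundance are modelled as
`count ~ urbanization_index + (1 | landscape)` on the log link, richness
with Poisson and abundance with negative-binomial noise (the season-pooled
abundance counts are strongly overdispersed; a Pearson chi-square/df ratio
above 1.5 on a Poisson fit triggers a recommendation to switch). The fixed
effect is tested by a 1-df likelihood ratio against the
intercept-plus-random-intercept null. Estimation is standard machinery
(lme4's Laplace approximation for Poisson; glmmTMB for the negative
binomial); the package's own content here is the response construction, the
LRT protocol and the simulation-calibration harness
(`simulate_catch_counts()`), which draws trap-level counts from exactly the
model the GLMM assumes and therefore gives correctly sized reference
distributions for interval coverage and type-I error.

## The synthetic-study generator

The generator emulates the statistical structure the analyses assume, at the
scale of the motivating design: 13 landscapes × 16 traps, landscape tree
cover uniform on 10–80%.

- **Covariates.** Trap tree cover = landscape cover + a landscape-level
  bias (sd 14) + trap-level noise (sd 12), clipped to [0, 100]; the
  barrier-free angle mixes trap cover (weight 0.63) with independent
  uniform noise. The two sds and the weight were derived analytically from
  the variance components so that the correlation of per-landscape mean
  trap cover with landscape cover is ≈ 0.81 and the per-trap tree–barrier
  correlation ≈ 0.85, the balanced-design values a well-deployed grid
  exhibits. Clipping attenuates both slightly; the calibration is asserted
  loosely (±0.08, averaged over 20 seeds).
- **Community.** A 150-species pool with a lognormal species-abundance
  distribution (log-sd 1.2) partitioning a community-level expected catch
  of 140 individuals per trap at urbanization 0. Partitioning a fixed
  community rate — rather than giving each species an independent rate —
  reflects the energetic constraint that a richer pool means rarer species,
  and gives the generator the property that enlarging the pool at fixed
  effort lowers sample completeness. Counts are negative binomial (size
  0.8, the strong clumping typical of aggregation pheromone-baited
  catches), with a log-linear urbanization effect (default slope −0.015
  per index unit, chosen so expected catches roughly halve across the
  observed index range), a landscape random intercept (sd 0.3), and
  occupancy thinning (each species present in each landscape with
  probability 0.6). 7% of species are labelled non-native — a label only,
  with no distinct dynamics, mirroring the share typical of port-area
  BWBB communities.

What the generator does **not** emulate: collection-interval phenology
(captures are season totals by design), spatial autocorrelation among traps
beyond the landscape intercept, barrier-mediated dispersal limitation as a
mechanism (urbanization acts directly on expected catch), and
species-specific trap affinities. Tests passing on synthetic studies
therefore validate the estimators and the pipeline plumbing, not the field
realism of any particular parameter value.

## Numerical and degenerate-input choices

- Binomial coefficient ratios via `lchoose`, exact for the fixture scales
  and overflow-free to T ~ 1000.
- Chao2 and coverage are undefined on a single sampling unit; T < 2 errors.
- A matrix with zero captures in some traps keeps those traps as all-zero
  columns — a zero-catch trap is still a sampling unit and must count in T.
- The scenario-comparison chi-square guards against taking logs of
  rounding-level residual sums when both models fit perfectly (returns 0).
- All stochastic stages require an explicit integer seed and restore the
  caller's RNG state, so library use never perturbs a session's random
  stream.

## Problem sizes used in validation

The shipped tests validate estimators by exhaustive enumeration on matrices
with up to 8 traps (all subsets) and 5 traps (all 120 permutations),
Monte-Carlo convergence at 1000 randomizations, GLMM slope recovery on 50
replicate default-scale studies, and LRT type-I calibration on 200
simulated datasets; these sizes give the property checks comfortable power
while keeping a full validation run in the minutes range.

## Known limitations

- Completeness and coverage inherit Chao2's sensitivity to very rare
  species; with many singletons the richness denominator (and hence
  completeness) is itself an estimate with high variance.
- The replacement-turnover mean treats trap pairs as exchangeable and
  ignores their spatial arrangement.
- The paper-style "ANOVA χ²" comparison assumes the per-landscape mean
  losses are approximately normal; with 13 landscapes this is adequate for
  the scales involved but not exact.
- GIS extraction of the covariates (tree cover, barrier angle) is out of
  scope: the package consumes them precomputed.
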