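# irsabc

Coalescent ABC reconstruction of mosquito effective population size (Ne)
across indoor-residual-spraying (IRS) rounds.

## The problem

IRS campaigns suppress *Anopheles gambiae* populations, but trapping counts
are a noisy readout of how deeply and for how long.  Temporally spaced
microsatellite samples offer a genetic alternative: the rate of allele
frequency drift between sampling dates is set by the effective population
size, so a time series of genotypes carries a record of population crashes
and rebounds.  `irsabc` reconstructs a piecewise-constant Ne trajectory
from such data by approximate Bayesian computation (ABC): six competing
demographic scenarios (constant Ne; spray-driven crash with or without
recovery; rainfall-driven fluctuation, concordant or discordant; delayed
recovery) are encoded as constraint sets over interval Ne parameters, a
heterochronous coalescent with a generalized stepwise microsatellite
mutation model simulates reference data under each, and scenario choice
uses the retained nearest simulations with a multinomial logistic
regression evaluated at the observed summary statistics.

The statistic vector combines, per temporal sample, the locus means of the
number of alleles A, Nei's unbiased expected heterozygosity
He = c/(c-1)(1 - Σ p²), the unbiased allele-size variance, and the
Garza–Williamson M = A/(range+1); and per adjacent pair of samples, the
pooled versions of the first three plus the Weir–Cockerham F_ST (ratio of
sums over loci and alleles).  Parameter posteriors for the chosen scenario
report the median and the 2.5–97.5% quantile interval (a density-threshold
interval is reported alongside).

A second, independent component is a density-dependent stage-structured
(Lefkovitch) projection model used for a what-if analysis: could a one-day
washout of aquatic stages (a rainfall deluge) explain an observed Ne crash?
The update scales the growth increment (M − I)N by the logistic factor in
total abundance relative to the carrying-capacity vector K, whose adult
entry is the target Ne.

Because the study genotypes are not publicly deposited, the package
includes a first-class synthetic-data module that generates pseudo-observed
studies under the inferred trajectory (six samples of
125/142/137/147/146/95 diploid individuals, 13 loci), calibrated to the
reported diversity (mean He ≈ 0.61–0.63, mean alleles ≈ 7.7–8.2), plus
GenePop input/output and the study's missingness filter.

## Worked example

```r
library(irsabc)

# generate a pseudo-observed study under the canonical scenario-2 truth
study <- generate_study(seed = 1)
obs <- stat_vector(study$dataset)
round(mean(obs[grep("^He_", names(obs))]), 3)
#> [1] 0.624

# arithmetic on the five interval Ne values (oldest first)
unlist(interval_changes(c(5692, 428, 1782, 12060, 4204)))
#> decline_round1_pct decline_round2_pct        rebound_pct
#>           92.48067           65.14096         2817.75701

# a scaled-down ABC fit: 6 scenarios x 2,000 simulations, top 1% retained
specs <- lapply(1:6, build_scenario, design = default_design())
names(specs) <- paste0("scenario_", 1:6)
set.seed(1)
tab <- simulate_reference_table(specs, 2000)
scenario_posteriors(retain_nearest(tab, obs, fraction = 0.01))$logistic

# the deluge what-if: 99% one-day aquatic mortality at step 5
sm <- summarize_trajectory(project(stage_model(), 100, aquatic_shock(5, 0.99)))
round(unlist(sm), 1)
#> min_adult percent_reduction recovery_step recovery_days
#>    4950.5              13.0          12.0          12.0
```

The first spray round cuts Ne by ~92%, the second by ~65%, and the
population rebounds to ~2818% of its crash size between rounds — while the
projection model shows a one-day deluge can only dent the adult class by
~13% for under two weeks, so rainfall shocks cannot explain a months-long
crash.

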