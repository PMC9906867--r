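# nsum

Network scale-up estimation of hidden population sizes in R.

Public-health programmes for hard-to-reach groups — female sex workers,
people who inject drugs, men who have sex with men — need size estimates
that direct enumeration cannot provide: stigma makes censuses and household
surveys underestimate, when they are feasible at all. The network scale-up
method (NSUM) sidesteps this by interviewing the *general* population about
its social networks. Each respondent reports `m_i`, the number of
hidden-population members they know; with personal network size (degree)
`c_i` and reference population total `t`, the crude estimator is

```
e = (Σ m_i / Σ c_i) × t
```

— the hidden population's share of respondents' networks, scaled up to the
population. Two standard multiplicative corrections address the method's
known biases for stigmatized behaviours: the **visibility factor**
(VF = 1/detection probability; respondents don't know every acquaintance's
hidden status) and the **popularity factor** (PF = 1/degree ratio;
hidden-population members have smaller networks than average).

The package is aimed at epidemiologists running or re-analysing
aggregated-relational-data surveys. It provides:

* validated CSV I/O for respondent-level and alter-level survey tables,
  and YAML/JSON configuration (`read_survey`, `read_alters`, `read_config`);
* the crude and corrected estimators and prevalence conversion
  (`crude_estimate`, `apply_adjustments`, `prevalence`);
* Monte Carlo and gender-stratified bootstrap uncertainty intervals
  (`monte_carlo_interval`, `bootstrap_interval`);
* degree sensitivity analysis (`sensitivity_scan`);
* demographic tabulation (`summarize_demographics`);
* a seeded synthetic survey generator with visibility thinning and
  popularity distortion, plus a parameter-recovery harness
  (`synthetic_truth`, `generate_survey`, `recover_parameters`);
* a file-in/report-out pipeline (`run_full_analysis`, JSON + Markdown) and
  a thin command-line wrapper (`inst/scripts/nsum.R`).

## Worked example

A street-intercept survey of 1000 adults (495 men, 505 women) in a city
with 406,916 adult women reported 434 female sex workers across all
respondents' networks. Degrees of 90 (men) and 120 (women) are borrowed
from an external known-population study; the visibility factor is 1/0.45
and the popularity factor 1/0.77 (reciprocals of midpoint detection
probability and degree ratio).

```r
library(nsum)

m <- integer(1000); m[c(1:215, 496:714)] <- 1L   # 434 reports in total
survey <- survey_respondents(
  id     = sprintf("p%04d", 1:1000),
  gender = rep(c("male", "female"), c(495, 505)),
  m      = m)
config <- network_config()   # degrees 90/120, t = 406916, VF/PF defaults

est <- apply_adjustments(crude_estimate(survey, config), config)
est
#> Network scale-up estimate
#>   respondents: 495 male, 505 female
#>   sum m = 434, sum c = 105150, t = 406,916
#>   crude estimate:              1680
#>   adjusted for visibility:     3732  (VF = 2.2222)
#>   adjusted for popularity:     2181  (PF = 1.2987)
#>   fully adjusted:              4847
#>   prevalence per 1000:        11.91
```

The crude estimate says respondents' networks imply ~1680 female sex
workers; correcting for hidden status (×2.22) and smaller networks (×1.30)
raises this to ~4847, i.e. about 11.9 per 1000 adult women. Uncertainty and
degree sensitivity:

```r
monte_carlo_interval(survey, config, n_replicates = 10000, seed = 42)
#> Monte Carlo uncertainty interval (10000 replicates, seed 42)
#>   point 4847.1, [2.5%, 97.5%] interval: 3764.5 - 6797.6

bootstrap_interval(survey, config, n_replicates = 10000, seed = 42)
#> Bootstrap uncertainty interval (10000 replicates, seed 42)
#>   point 4847.1, [2.5%, 97.5%] interval: 4512.0 - 5193.3

sensitivity_scan(survey, config, scales = c(0.9, 1, 1.1))
#>   scale e_adjusted prevalence_per_1000
#> 1   0.9   5385.667            13.23533
#> 2   1.0   4847.100            11.91180
#> 3   1.1   4406.455            10.82890
```

The Monte Carlo interval samples VF and PF uniformly over their plausible
ranges by default, so it is dominated by correction-factor uncertainty;
pass `sample_factors = FALSE` to isolate sampling noise. The sensitivity
rows show the exact reciprocal law: a ±10% error in the borrowed degrees
moves the estimate to 4406–5386.

The design's sample size: `required_sample_size(p = 0.015, d = 0.008,
confidence = 0.95, nonresponse = 0.10)` returns `976`, consistent with a
1000-respondent survey.

See `vignette("nsum-methods")` (source in `vignettes/`) for the model,
the correction-factor conventions, and what the simulation-based
validation does and does not demonstrate.

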