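---
title: "Network scale-up estimation: model, corrections, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network scale-up estimation: model, corrections, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nsum)
```

## The estimator

The network scale-up method (NSUM) estimates the size of a hidden
population from what a general-population sample reports about its social
networks. Respondent $i$ reports $m_i$, the number of hidden-population
members among their acquaintances; with personal network size (degree)
$c_i$ and reference population total $t$, the crude estimator is

$$ e = \frac{\sum_i m_i}{\sum_i c_i} \times t. $$

The logic is that the hidden population's share of respondents' networks
estimates its share of the whole reference population. `nsum` assumes
degrees are supplied as gender-specific constants ($c_{male}$,
$c_{female}$), the common design when degrees are borrowed from an external
known-population study rather than estimated in-survey; estimating degrees
from the survey itself is deliberately out of scope.

Two assumptions of the basic method fail predictably for stigmatized
populations, and two multiplicative corrections address them:

* **Visibility factor (VF)** — the transparency barrier. Respondents know
  some acquaintances without knowing their hidden-population membership, so
  $m_i$ is thinned by a detection probability $d$ and the estimate is
  multiplied by $VF = 1/d$.
* **Popularity factor (PF)** — the barrier effect. Hidden-population
  members tend to have smaller networks than average, so their share of
  respondents' networks under-represents their share of the population; the
  estimate is multiplied by $PF = 1/r$ where $r$ is the degree ratio.

Both are pure products, so the fully adjusted estimate
$e \cdot VF \cdot PF$ does not depend on the order of application, and the
identity $e_{adj} = e_{VF} \, e_{PF} / e$ holds exactly — a property the
test suite exercises numerically.

## Default parameters

The packaged defaults describe the street-intercept survey design the
package's examples reproduce: a city where the 2016 census counted
$t = 406{,}916$ women aged 18 and over, 495 male and 505 female
respondents, and degrees of 90 (men) and 120 (women) — the number of adult
women a respondent of each gender knows on average, borrowed from an
external known-population study.

The correction-factor defaults deserve a note, because published point
values are often rounded. The visibility range is stated as $1/0.55$ to
$1/0.35$; the package takes the point value as the reciprocal of the
midpoint detection probability, $VF = 1/0.45 = 2.2\overline{2}$ (sometimes
printed as 2.22). The popularity range $1.15$–$1.49$ is likewise
$1/0.87$–$1/0.67$, giving the midpoint-reciprocal point value
$PF = 1/0.77 \approx 1.299$. These reciprocal-of-midpoint conventions — not
the midpoints of the factor ranges themselves — are what reproduce the
published adjusted estimates (3733, 2182, 4848 from a crude 1680), so they
are the defaults; both are plain `network_config()` fields and fully
configurable. All chained computation is kept at full precision; rounding
happens only at report time.

## Uncertainty

The paper trail for published NSUM intervals is usually too thin to
replicate exactly (replicate counts, percentile conventions and the
factor-sampling scheme are rarely stated, and respondent-level $m_i$ are
rarely deposited), so `nsum` treats uncertainty procedurally and exposes
every choice as a parameter.

**Monte Carlo** (`monte_carlo_interval`). Per replicate, the alter total is
drawn as $\sum m^* \sim \text{Poisson}(\sum m_{obs})$ and the network total
as the sum of two Poisson draws with means $n_g c_g$ — equivalent to
per-respondent Poisson degrees summed, implemented as aggregate draws
because the Poisson family is closed under convolution. With
`sample_factors = TRUE` (default) VF and PF are drawn uniformly over their
configured ranges; with `FALSE` they are held at their point values, which
isolates pure sampling noise. For the fixed-factor case a delta-method
closed form,
$CV^2 \approx 1/\sum m + 1/\sum c$, gives an interval of roughly
$\pm 1.96\,CV$ around the point estimate — with the default survey about
$\pm 9\%$ — and the test suite checks the simulated interval against this
oracle. Note that sampling the factors over their stated ranges widens the
interval far beyond that, which is why published intervals that are
narrower than their own stated factor ranges imply fixed factors; both
behaviours are available and neither is hard-coded.

**Bootstrap** (`bootstrap_interval`). Nonparametric percentile bootstrap
over respondents, stratified by gender by default because degrees are
gender-specific (unstratified resampling is a flag). Within a stratum the
network total is invariant, so each replicate only resamples the $m$
values — the implementation exploits this.

Defaults: 10,000 replicates and percentiles $(2.5, 97.5)$. Both functions
take an explicit seed, record it in the result, and restore the caller's
RNG state, so identical calls are bit-identical and a fixed-seed pipeline
regenerates byte-identical JSON reports (the wall-clock timestamp is
excluded from JSON output by default for the same reason).

## Sensitivity to degrees

Because degrees are imported, `sensitivity_scan` rebuilds the adjusted
estimate with both degrees multiplied by each requested scale. The
estimator is a ratio, so the exact reciprocal law
$e(\text{scale}) = e(1)/\text{scale}$ holds to machine precision; a
$\pm 10\%$ degree error maps to roughly $\mp 9$–$11\%$ of the estimate.
Per-gender scaling is available via the `genders` argument for asymmetric
what-ifs.

## The synthetic generator and what it does (not) show

`generate_survey` simulates a survey with exactly the statistical structure
the estimator assumes, plus its two classic violations:

$$ m_{true,i} \sim \text{Binomial}\!\left(c_g,\; \tfrac{k_{true}}{t}\, r\right),
   \qquad m_i \sim \text{Binomial}(m_{true,i},\; d), $$

with $d$ the visibility and $r$ the popularity ratio. Binomial rather than
Poisson alter counts are used because degrees are small integers and the
membership probability is tiny; the Poisson is then an accurate limit, and
the Monte Carlo module's Poisson assumption being tested against this
binomial generator is itself a (mild, documented) model discrepancy.
Default truth parameters mirror the study conditions: $t = 406{,}916$,
495/505 respondents, degrees 90/120, visibility 0.45, popularity ratio
0.77, $k_{true} = 4850$ — under which
$E[\sum m] = 0.45 \times 0.77 \times (4850/406916) \times 105150 \approx 434$,
the observed scale of the study's alter total.

Alter demographics are drawn independently per alter from fixed categorical
marginals (the published tables report only marginals, never a joint
distribution), and respondents with zero $m$ simply contribute no alter
rows.

`recover_parameters` closes the loop: simulate, estimate with
$VF = 1/d$ and $PF = 1/r$, and compare to $k_{true}$. At the default
conditions the adjusted estimator recovers the truth with relative bias
well under 5% over 200 simulations, and the fixed-factor Monte Carlo
interval covers the truth at roughly its nominal rate. What this does *not*
show: the generator has no network topology, no homophily, no recall error
and no respondent-level degree heterogeneity, so passing recovery tests
validates the estimator chain's internal consistency, not the method's
robustness to real-world violations beyond the two it models.

## Numerical and design choices

* **Degenerate inputs.** An all-zero $m$ vector yields an estimate of
  exactly 0 with a warning flag (a legitimate, if uninformative, survey
  outcome), not an error; an empty survey errors.
* **Percent tabulation.** Demographic percentages are computed at full
  precision and rounded half-even to one decimal. Published tables mix
  rounding conventions, so tests compare within ±0.15 percentage points
  rather than pinning digits. The denominator is the full record count by
  default (`percent_denominator = "all"`), with a `"nonmissing"` switch.
* **Sample-size formula.** $n = \lceil z^2 p(1-p)/d^2 \rceil$ with
  nonresponse inflation by multiplying by $(1 + nr)$ by default — the
  convention consistent with a 1000-respondent design at
  $p = 0.015, d = 0.008$, 95% confidence, 10% nonresponse (976) — with the
  divide-by-$(1-nr)$ convention available.
* **Problem sizes in the test suite.** Properties are tested at the study
  scale itself (1000 respondents); simulation-based checks use 60–200
  simulated surveys and $10^3$–$10^4$ replicates, sizes at which Monte
  Carlo error is far below the asserted tolerances.
* **Seeds.** Every stochastic function takes and records a seed;
  sub-simulations derive seeds by small integer offsets.

## Limitations

Degrees are inputs, never estimated; correction factors are inputs, never
re-derived (transporting them between cities is a known threat to
validity); the generator models no network structure; and the method's
known fragilities — recall error, definition-of-knowing effects, barrier
effects beyond a scalar degree ratio — are outside what this package can
detect or correct.
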