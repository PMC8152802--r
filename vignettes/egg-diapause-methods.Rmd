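---
title: "Methods: egg diapause phenology from ovitrap surveillance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: egg diapause phenology from ovitrap surveillance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eggdiapause)
```

## The problem

Container-breeding *Aedes* mosquitoes overwinter in temperate climates as
diapausing eggs: fully embryonated eggs that refuse to hatch even under
repeated immersion, under hormonal control triggered by the shortening
maternal photoperiod. Ovitrap surveillance yields per-egg records — did the
egg hatch, and if not, what did bleaching reveal (full embryo, partial
embryo, or no fertilisation)? From such records this package estimates when
a field population switches to diapause production and what maternal day
length that switch corresponds to (the critical photoperiod, CPP), and
characterises the morphometric signature of diapausing eggs.

## Egg-status model and rates

Each tested egg lands in one of four analysis classes: hatched (H),
embryonated unhatched (E; the operational marker of diapause), partially
embryonated (P) and unfertilised (U). Eggs damaged, dried, or hatched
before collection are marked EXCLUDED and kept in the files for audit, but
they never enter any denominator. The four rates per weekly cohort are

- hatching success $= 100\,H/(H+E)$,
- diapause incidence $= 100\,E/(H+E) = 100 -$ hatching success,
- viability $= 100\,(H+E)/(H+E+P+U)$,
- mortality $= 100\,(P+U)/(H+E+P+U)$.

The first pair is defined over *viable* eggs only; a cohort with no viable
eggs has undefined diapause incidence, and the package raises an explicit
"no viable eggs" error rather than reporting 0. Weekly cohorts smaller
than `min_n = 6` tested eggs are dropped and logged; the default reflects
the judgement that a five-egg week carries too little information for a
percentage.

## Cut-off detection and critical photoperiod

The 50% cut-off week is the earliest week at or above the threshold whose
next `sustain = 2` observed weeks (or all remaining weeks, if fewer) stay
at or above it; exact equality counts as a crossing. Field incidence
series are noisy around the rise, and the sustained rule keeps an isolated
early spike (e.g. a single 55% week in July) from being mistaken for the
seasonal switch. Because females commit their eggs to diapause based on
the photoperiod they themselves experienced, the maternal CPP is the mean
day length of week `cutoff_week − delay_weeks`. The default maternal delay
is one week: the cut-off weeks reported for this system (36 in 2019, 37 in
2020) combine with a one-week delay to give CPPs near 13 h 31 min and
13 h 14 min, averaging 13 h 23 min, which is the headline value for the
population; delays of 0 and 2 weeks are always reported alongside. During
the declining-photoperiod season the CPP is strictly increasing in the
assumed delay, which the tests assert.

## Day-length astronomy

Day length is computed from the standard truncated solar-position series
(mean solar longitude, equation of centre, apparent longitude and true
obliquity as polynomial/harmonic functions of the Julian century), with
declination evaluated once per day at local solar noon, and the sunrise
equation
$\cos \omega_0 = (\cos z - \sin\phi\,\sin\delta)/(\cos\phi\,\cos\delta)$;
day length is $2\omega_0/15^\circ \times 60$ minutes, clipped to
$[0, 1440]$ for polar cases. Weekly photoperiod is the mean over the seven
Monday–Sunday days of an ISO week.

The zenith angle $z$ defining sunrise is a convention, not a constant of
nature. The package default is $90^\circ 34'$ ($90.567^\circ$): the
*centre* of the solar disc at the refracted horizon. At Strasbourg this
convention reproduces the published weekly day lengths for this
surveillance system (13 h 07 min in week 36/2019, 12 h 49 min in week
37/2020, and the delay-1/delay-2 CPP values) to within ±2.3 minutes,
whereas the upper-limb almanac convention ($90.833^\circ$) runs 3–6
minutes long and the purely geometric $90^\circ$ runs 5–8 minutes short.
Both alternatives remain available through the `zenith_deg` argument.
Sub-minute effects (intra-day declination drift, longitude of the
observer) are deliberately ignored; they are an order of magnitude below
the minute-rounded values the analysis consumes.

ISO 8601 week dates are used throughout (weeks start Monday; week 1 holds
the year's first Thursday), with the week-year, not the calendar year, as
the season index; the mapping is tested against a brute-force
Thursday-rule oracle over 2018–2021.

## Morphometrics

Each egg's length and width are measured three times; the triplicates are
averaged per axis and the volume follows the prolate-spheroid formula
$V = (\pi/6)\,L\,W^2$, reported in $10^{-3}\,\mathrm{mm}^3$
(µm³ divided by $10^6$). Seasonal drift is quantified by ordinary least
squares of the *weekly median* width (or volume) on the week number,
$y = \beta_0 + \beta_1\,\mathrm{week} + \varepsilon$. Weekly medians are
the default unit of analysis because weekly boxplot summaries are what
such series report and because medians are insensitive to duplicated or
outlying eggs within a week (a property the tests assert); a per-egg fit
is a one-line variant the user can run on the per-egg table. The season
is split into an early regime (default weeks 20–24) and a late rising
regime (weeks 26–43), fitted separately.

Diapause groups around a cut-off week $n$: ND (weeks $< n-1$), M (weeks
$n-1$ to $n+1$, a mixture zone), D (weeks $> n+1$). Width and volume
contrasts between D and ND use a one-tailed Wilcoxon rank-sum test with
average ranks; the p-value is exact by enumeration of all
$\binom{n_x+n_y}{n_x}$ labelings when $n_x + n_y \le 12$ and a
tie-corrected normal approximation (no continuity correction) otherwise.
Week-homogeneity within a group is checked with the tie-corrected
Kruskal–Wallis statistic against $\chi^2_{k-1}$. Spearman correlations
rank both variables (average ranks) and take the Pearson correlation of
ranks; for series shorter than 10 the p-value is an exact permutation
tail, otherwise the $t$ approximation on $n-2$ degrees of freedom. These
rank procedures are implemented in the package because their branch rules
(exact thresholds, tie handling, one-tailed direction D > ND) are part of
the analysis contract; `wilcox.test`, `kruskal.test` and `cor.test` serve
as independent oracles in the test suite.

## The logistic diapause-probability model

For viable, measured eggs the per-egg diapause indicator is modelled as

$$\log \frac{p}{1-p} = \beta_0 + \beta_1 x_1 + \beta_2 x_2 +
\beta_3 x_1 x_2 \;(+\; \text{year effects}),$$

with $x_1$ the week of collection and $x_2$ the egg width (µm). Fitting
is by iteratively reweighted least squares with convergence declared at a
relative log-likelihood change below $10^{-8}$ (at most 100 iterations);
complete or quasi-complete separation is detected and flagged, never
silently accepted, and a rank-deficient design errors naming the
collinear columns. Model choice is an exhaustive AIC scan over
hierarchical term subsets (the interaction only enters with both main
effects), returning the full ranking table, with
$\mathrm{AIC} = 2k - 2\log L$ holding exactly. Predictors stay in
natural units so coefficients read as log-odds per week and per µm. The
per-egg Bernoulli likelihood is identical (up to constants) to the
grouped weekly binomial likelihood, which a test asserts; year enters as
an additive categorical effect by default. Fitted and predicted
probabilities are strictly inside (0, 1): the model never certifies
diapause or its absence.

## The synthetic season generator

`simulate_season()` draws complete two-year surveillance seasons (weeks
20–45, 12 traps) with known truth, so every stage has recovery targets:

- **Abundance**: per-trap weekly counts are
  Poisson$(\lambda_w/n_\text{traps})$ with $\lambda_w$ a bimodal Gaussian
  mixture — a summer peak (week 28, 2000 eggs/week) and a lower autumn
  peak (week 40, 600 eggs/week) over a small baseline — emulating the
  bimodal seasonal pattern of this species.
- **Diapause**: the probability is a mixture
  $p(w) = p_0 + (1-p_0)\,\mathrm{logistic}(k(w - w_0))$ of a constitutive
  floor $p_0 = 0.10$ and a photoperiodically driven logistic ($k = 0.9$
  per week). A pure logistic cannot hold a persistent ~10% early-season
  incidence, hence the mixture. $w_0$ is placed so that $p = 0.5$ exactly
  at the start of the configured crossing week (36). Each simulated egg
  receives a laying time uniform within its collection week and its
  Bernoulli probability at that time; the cohort-average probability of
  the crossing week is therefore ≈ 0.60, making the crossing week the
  first collection week whose aggregate incidence exceeds one half — the
  generative counterpart of an observed cut-off week, and the reason
  detection is robust rather than a coin flip at the boundary.
- **Morphometry**: a 10% subsample carries triplicate measurements; the
  weekly mean width follows $151.24 + 0.7474\,w$ µm (per-egg SD 7 µm,
  replicate SD 1.5 µm) with a +3 µm offset in the early regime (weeks
  ≤ 24) standing in for the distinct spring regime; lengths are
  N(616, 29²) µm. The early offset's sign and size are qualitative — only
  the existence of a second regime matters to the pipeline.
- **Mortality**: each egg is non-viable with probability 0.17, split
  evenly between partially embryonated and unfertilised.
- **Meteorology**: daily series are seasonal sinusoids plus noise,
  constructed so that tmin ≤ tmax, sunshine ≥ 0 and rainfall ≥ 0 always
  hold; only these ordering invariants are promised, not climatological
  realism.

Identical seeds give byte-identical output, and the generator restores
the caller's RNG state. What passing recovery tests on these seasons
shows is that the *pipeline* is correct under its assumed sampling model
(binomial cohorts, linear drift, constant mortality); they cannot attest
to trap-level clustering, weather-driven laying gaps, or measurement
drift in real field data, which the generator does not emulate.

## Numerical and design choices

- Rates are exact rational arithmetic in double precision; the
  complementarity identities (hatching + diapause = 100, viability +
  mortality = 100) hold to machine precision and are asserted over 10⁴
  randomized cohorts.
- Two-week abundance bins start at the first observed week of each
  season and pair consecutive ISO weeks, matching the biweekly
  presentation of the reference season totals without assuming week
  parity. Binning conserves totals at every width.
- `detect_cutoff` with an all-sub-threshold series returns an explicit
  "no cutoff" result object, distinct from an error; an empty season is
  an error only where a rate is genuinely undefined.
- Durations are formatted with half-up rounding (802.5 min → "13 h 23
  min") as almanac tables do; IEEE half-even would print 13 h 22 min.
- The AIC scan retains the active predictor essentially always in the
  selection-consistency simulation, while excluding an inert one at the
  rate AIC theory dictates, $1 - P(\chi^2_1 > 2) \approx 84\%$ — not
  more; tests check the binomial band around that value rather than an
  unattainable higher rate.
- Problem sizes in the test suite (e.g. ~9,000-egg two-year seasons for
  end-to-end recovery, n = 5,000 for GLM recovery, 200 seasons for
  cut-off detection, 1,000 replicates for test size) were chosen so each
  suite answers its statistical question with comfortable Monte-Carlo
  margins while staying quick to run.

## Known limitations

- The CPP is astronomical, not micro-climatic: canopy shading, twilight
  sensitivity and temperature modulation of the photoperiodic response
  are outside the model.
- The logistic model treats eggs as independent; trap-level random
  effects are deliberately out of scope.
- Group contrasts pool eggs across years with year-specific group
  labels; a year-stratified contrast is possible from the per-egg table
  but is not the default report.
- The incidence series pools all traps within a week; per-trap weighting
  is available by summarising upstream but is not the default, as the
  reference analysis reports pooled weekly incidence.
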