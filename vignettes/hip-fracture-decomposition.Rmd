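---
title: "Decomposing hip-fracture trends: model, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing hip-fracture trends: model, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hipimpact)
```

## The model and its assumptions

`hipimpact` explains the change in sex-stratified hip-fracture counts
between a baseline year (BY) and an end year (EY) as a sum of component
contributions. The method is a deterministic comparative risk assessment in
the IMPACT tradition: no individual-level data, no regression fitting — the
model is a fixed arithmetic pipeline over published aggregate inputs.

The excess to explain is the observed end-year count minus the count
expected had baseline rates persisted:

$$NX^{est} = NO_{EY} - NE, \qquad NE = r_{BY} \times \mathrm{pop}_{EY} / 10^4.$$

Each binary exposure $i$ (prevalence $P$, relative risk $RR$) contributes
through the change in its population attributable risk fraction,

$$\mathrm{PARF} = \frac{P\,(RR-1)}{P\,(RR-1)+1}, \qquad
NX_i = NE \times (\mathrm{PARF}_{EY} - \mathrm{PARF}_{BY}),$$

and the osteoporosis-medication component is
$NX^{med} = -\,OM \times \Delta RR_{OM} \times r_{OP}/10^4$ for $OM$ treated
users, treatment relative risk reduction $\Delta RR_{OM}$, and $r_{OP}$ the
fracture rate in osteoporosis patients. Because individually estimated
attributable fractions overlap in the population, the factor sum is scaled
by $AF = CR/AR$ with $CR = 1-\prod_i(1-R_i)$ and $AR = \sum_i R_i$. The
modeled excess is $NX^{mod} = NX^{med} + AF\sum_i NX_i$, reported as a
percent of $NX^{est}$.

Standing assumptions inherited from this model family: exposures act
multiplicatively and independently on fracture risk (the AF corrects
summation overlap, not effect-modification); prevalence changes act without
lag within the BY–EY interval; relative risks are constant over the period
and transportable from the literature to the study population; and observed
counts are Poisson, appropriate for rare events at national scale.

## Sign convention

The package uses the *table* convention throughout: **positive = fractures
generated, negative = prevented**, implemented as
$NE \times (\mathrm{PARF}_{EY} - \mathrm{PARF}_{BY})$. The alternative
convention (the same difference with opposite order, "positive = decrease")
appears in some write-ups of this model family; every run log records the
convention so tables cannot be misread. The medication term is always
non-positive — in this model medication only prevents.

## Parameters and units

| Parameter | Units / range | Notes |
|---|---|---|
| populations, user counts | persons | counts > 0 (users ≥ 0) |
| observed counts | fractures | may be non-integer in synthetic noise-free mode |
| rates | per 10,000 persons | the package-wide denominator; `incidence_rate()` / `rate_to_count()` convert |
| prevalences | proportions in [0, 1] | published tables usually print %; the reader converts, the run log records it |
| relative risks | > 0 | shared-across-sex values are expanded and flagged |
| `rrr` | [0, 1] | treatment relative risk reduction |
| `osteo_rr` | ≥ 1 | osteoporosis vs whole-population fracture RR |
| interval `level` | (0, 1), default 0.95 | Poisson interval coverage |

Display rounding is half-away-from-zero: rates to 2 decimals, percents to 1,
expected counts to integers. Rounding is applied per stratum *before*
summation of expected counts, which is the arithmetic national reports use
(it reproduces per-sex and total expected counts exactly). Internal
computation is never rounded; only tables and display values are.

## Decisions where the method description is open

Several operational details of this model family are not pinned down in the
literature; the package fixes them as follows and records each in the run
log.

**Which rate enters the medication term.** $r_{OP}$ is the *baseline-year*
population rate times the osteoporosis RR. The end-year rate is a function
of the end-year observed counts — the very quantity the model explains —
so using it would make the medication term circular (and would break the
exactness of synthetic forward–inverse closure). The end-year osteoporosis
rate is still computed and printed in the medication table, since it is a
standard descriptive quantity.

**Which user count enters the medication term.** The end-year users
$OM_{EY}$: they are the population actually under treatment in the year
being explained.

**The $R_i$ of the overlap adjustment.** Default `delta_parf`:
$R_i = |\mathrm{PARF}_{EY} - \mathrm{PARF}_{BY}|$ per factor — the quantity
that actually flows through the attribution — computed per sex and pooled as
an unweighted mean across sexes, giving one $R_i$ per factor. The
alternative `parf_ey` ($R_i = |\mathrm{PARF}_{EY}|$) and `none` ($AF = 1$)
are selectable; the choice is recorded in output. One AF is computed over
*all* exposures (risk factors, preventive measures and drug classes) and
applied to both the risk-factor and the drug component, never to the
medication component.

**Two aggregation tracks.** Published national tables of this model's
results carry per-row contributions that rest on age-stratified expectations
whose inputs were not published; recomputing rows from whole-population
expectations gives systematically different values. The pipeline therefore
reports both tracks side by side: *published* (aggregate the annotated
per-row values; reproduces published totals exactly; the AF is computed and
reported but not re-applied, since published rows already sum to their
published totals) and *equations* (full recomputation). Blending them would
misattribute provenance, so nothing is interpolated between the tracks.

**Known inconsistencies in the packaged scenario.** The published per-sex
2018 populations sum to 23,209k while the separately published national
total is 22,209k; the per-sex values are authoritative here because they
reproduce the published expected counts. The packaged baseline rates are the
printed 6.5 and 3.87 per 10,000 (not the unrounded quotients 6.509 / 3.878)
for the same reason, carried as explicit `rate_by` overrides in the fixture.

## Sensitivity analysis

Extremes analysis assigns every parameter a lower and upper feasible value —
a supplied 95% CI where available, otherwise ±20% of the central value, with
prevalences clipped to [0, 1] — and moves parameters *jointly* to corners of
the bound hypercube. Observed counts and populations are data, not estimated
parameters, and are never varied, so the excess is fixed.

Two modes: `enumeration` evaluates all $2^k$ corners (refused above 20
parameters) and is exact; `monotone` probes each parameter's direction at
the central point and evaluates only the assembled minimizing / maximizing
corners. The two agree exactly whenever the output is monotone in each
parameter over its bounds; the overlap AF and sign-flips of a prevalence
change inside its bounds can break that, in which case the monotone bracket
is still contained in the enumerated one (its corners are hypercube
corners). Bounds of the same factor's BY and EY prevalences are varied
independently — a documented limitation, since their uncertainties are
likely correlated, making joint-corner brackets conservative. A
per-component one-at-a-time table (each component over its own corners) is
emitted as a tornado-style diagnostic.

## Numerical choices and degenerate inputs

- Exact Poisson intervals invert the tail probabilities via the gamma
  identity (`qgamma(a/2, m)`, `qgamma(1-a/2, m+1)`), the continuous
  generalization for non-integer expected counts; the normal method
  ($m \pm z\sqrt m$, clipped at 0) is available by option. At expected
  counts above ~1000 the two agree within 2% in width.
- $AF$ with all $R_i = 0$ is defined as 1 by continuity and logged.
- The PARF denominator $1 - P + P \cdot RR$ is positive on the whole valid
  domain ($P \in [0,1]$, $RR > 0$); the guard against non-positive
  denominators is kept for malformed inputs.
- A zero total excess makes percent-explained undefined and is an error,
  not a silent `NaN`.
- A scenario with a single stratum skips the goodness-of-fit test (it needs
  at least two cells).
- JSON and CSV output contain no timestamps and fixed-precision numbers, so
  identical inputs give byte-identical artifacts.

## What the synthetic generator emulates — and what it does not

`generate_scenario()` draws two sex strata at national scale (default
population 10⁷ per stratum), baseline rates uniform in [2, 12] per 10,000,
prevalences uniform in [0.02, 0.8] with end-year shifts uniform in
[−0.15, 0.15] (clipped), relative risks log-uniform in [0.5, 2] shared
across sexes, about one factor in three tagged as a drug class, and
Romania-like medication groups. `synthetic_truth()` then *forward-closes*
any scenario: end-year observed counts are set to exactly
$NE + AF\sum NX_i + NX^{med}$ per stratum (kept non-integer so the closure
is exact), and `add_poisson_noise()` replaces them with Poisson draws.

Ground truth is thus defined by the same forward equations the engine
inverts. Passing recovery tests therefore validates the plumbing, sign
conventions, adjustment scope and aggregation — *not* the epidemiological
validity of the model: no confounding, no age structure, no lag, no
correlated exposures, and no real-world misreporting are simulated. The
noise experiment uses a fixed two-sex scenario with decade-scale exposure
shifts (expected counts ≈ 10⁴, injected excess ≈ 1.5 × 10³) so the injected
signal is an order of magnitude above the Poisson noise floor — the regime
in which the mean recovered percent-explained is expected within one point
of 100%.

Problem sizes throughout the test suite are kept small by design — 100
generator seeds for exact recovery, 200 noise replicates, toy scenarios with
≤ 8 varied parameters for corner enumeration — because the properties under
test (exact closure, corner equality, unbiasedness) are scale-free.

## Known limitations

- The model cannot attribute the unexplained remainder; it is a residual
  containing omitted factors and input error alike.
- The published-track per-row values are carried as annotations and are not
  derivable from the packaged whole-population inputs; the equations track
  makes the gap visible rather than hiding it.
- Extremes brackets are worst-case corner products, not confidence
  intervals; with many parameters they are wide by construction.
- No age standardization, no lag modelling, no Monte Carlo propagation —
  all out of scope for this model family as implemented here.
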