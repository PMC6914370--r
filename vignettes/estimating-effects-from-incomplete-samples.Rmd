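---
title: "Estimating complementarity and selection effects from incomplete species samples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating complementarity and selection effects from incomplete species samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(befpart)
library(dplyr)
```

## The model

A mixture community contains `Q` species. Species `i` produces biomass
`M_i` (g/m²) in monoculture and `Y_i` (g/m²) in the mixture. Under
proportional sowing the null expectation for its mixture yield is
`M_i/Q`, so its deviation in relative yield is

$$\Delta RY_i = \frac{Y_i}{M_i} - \frac{1}{Q}.$$

Because the expectation of a product is the product of expectations
plus a covariance, the net biodiversity effect decomposes additively
over the `N` species with monoculture data:

$$\Delta Y \;=\; \sum_i \Delta RY_i\, M_i
 \;=\; \underbrace{N\,\overline{\Delta RY}\,\overline{M}}_{CE}
 \;+\; \underbrace{N\,\mathrm{Cov}(\Delta RY, M)}_{SE}.$$

`CE` (complementarity) is community-wide overyielding unrelated to
which species are productive; `SE` (selection) is overyielding
concentrated in (or avoided by) high-monoculture-biomass species. An
equivalent ordinary-least-squares view regresses $\Delta RY$ on $M$:
the fitted value at $\bar M$ carries `CE` (`partition_via_ols()`
computes $CE = N \bar M(\beta_0 + \beta_1 \bar M)$) and the slope
carries `SE` ($SE = N \beta_1 \mathrm{Var}(M)$). Both routes are exposed
and agree to floating precision; the OLS route refuses a zero-variance
regressor rather than silently dividing by zero.

### Covariance conventions

Two denominators for the covariance are legitimate and used for
different jobs, so every result records which one it carries:

* **partition** (denominator `N`): makes `CE + SE = ΔY` an exact
  identity. This is the convention for describing a fully observed
  community.
* **estimator** (denominator `N − 1`, as `stats::cov`): the form the
  bias corrections below require. `SE` differs between the two by
  exactly `N/(N−1)`.

Whether the *population-level* `SE` of a finite pool should itself use
`Q` or `Q − 1` is a genuine ambiguity (the two differ by `(Q−1)/Q`,
negligible for large pools). We compute and label both — `partition()`
takes a `convention` argument, and generated communities report both
`se` and `se_bessel` — instead of silently choosing. The SE estimator
averages to the **Bessel form** (`Q − 1`), which is therefore the
reference in all bias experiments.

## Estimation from an incomplete sample

When only `N` of the `Q` species have monoculture data, sample-level
statistics `CE^S`, `SE^S` are computed over the sampled species — with
two rules that are easy to get wrong and are enforced in code:

1. the `1/Q` inside $\Delta RY$ keeps the **pool** size `Q`, never `N`,
   otherwise subsample statistics are not commensurate with the full
   community; `Q` must therefore be supplied by the caller, never
   inferred from row counts;
2. the covariance uses the `N − 1` denominator.

The corrected estimators are

$$\widehat{SE}^P = \frac{Q}{N} SE^S, \qquad
  \widehat{CE}^P = \frac{Q}{N}\Big(CE^S -
  \frac{Q-N}{Q}\cdot\frac{SE^S}{N}\Big).$$

The `CE` correction subtracts the covariance between the sample means
of `M` and $\Delta RY$ induced by sampling without replacement from a
finite pool — the source of the naive statistic's bias, which is
proportional to `SE` and decays as `1/N`. A large-pool variant
(`correction = "large_Q"`, dropping the `(Q−N)/Q` factor) is provided
for comparison; the finite-pool form is the default for all pool sizes
because it is *exactly* unbiased: the test suite verifies by exhaustive
enumeration that its average over all `choose(Q, N)` subsets equals the
population `CE` to 1e−9 relative tolerance, while the large-pool form's
deficit equals the population Bessel covariance $S_{xz}$ exactly.
`predicted_bias()` gives the closed-form expected bias of the
uncorrected statistic, $\frac{Q-N}{Q}\cdot\frac{S_{xz}}{N}$.

The estimators assume the sampled species are a **simple random
subset** of the pool. Preferentially sampling, say, dominant species
violates this and is not corrected for.

## Species bookkeeping and degenerate inputs

* Species with missing monoculture data, or measured `M = 0`, stay in
  `Q` but leave `N` ($\Delta RY$ is undefined at `M = 0`). A species
  with `M = 0` but `Y > 0` raises an error naming the species, with
  the remedy (mark it pool-only) in the message.
* Species with `M > 0` and `Y = 0` participate, at
  $\Delta RY = -1/Q$: absence from the mixture is information.
* `N ≥ 2` is required wherever a covariance appears; `N ≥ 3` for
  sampling-error intervals.
* Algebraic identities are asserted at 1e−9 relative tolerance with a
  1e−12 absolute fallback near zero.
* An optional per-species `expected_ry` vector replaces the `1/Q` null
  to support other sowing designs; no alternative null models ship.

## The synthetic-community generator

No external dataset is needed anywhere: `generate_community()` builds
communities with *known* true effects. Its construction —

* `M ~ lognormal(m_log_mean, m_log_sd)`: strictly positive,
  right-skewed biomass, as field data are;
* $\Delta RY = a + b\,(M - \bar M) + \varepsilon$,
  $\varepsilon \sim N(0, \texttt{resid\_sd}^2)$: a linear-plus-noise
  law, giving closed-form control (`a` sets `CE = Q·a·mean(M)`; `b`
  sets `SE = Q·b·Var(M)` when noise-free);
* `Y = M(ΔRY + 1/Q)`, truncated at 0 —

is a deliberate choice, not an emulation of any particular experiment.
Negative implied yields are truncated rather than resampled (resampling
would silently distort the `M`–$\Delta RY$ law); truncation events are
counted and the realized truth is recomputed *after* truncation, so
`comm$truth` is exact, never nominal, and `CE + SE = ΔY` holds on the
delivered data always.

Defaults describe the study conditions used throughout the validation:
`Q = 100`, `m_log_mean = log(100)` (median monoculture biomass
100 g/m²), `m_log_sd = 0.8` (roughly order-of-magnitude spread between
the 10th and 90th percentile species, typical of grassland biomass),
`a = 0.05`, `b = 5e-4`, `resid_sd = 0.1`. These give a selection effect
comparable in magnitude to the complementarity effect — deliberately a
worst case, since `CE` bias scales with `SE`; weaker selection only
makes estimation easier.

What the generator does **not** emulate: species interactions beyond
the linear mean trend, heteroscedastic residuals, phylogenetic or
functional structure, spatial layout, or the species list of any real
experiment. Passing tests therefore demonstrate the statistical
properties of the estimators under the stated sampling model, not that
any particular field system satisfies that model.

## Observation error

`add_observation_error()` multiplies every biomass by independent
lognormal noise with mean exactly 1 and a chosen CV (`sdlog² =
log(1+cv²)`, `meanlog = −sdlog²/2`). Multiplicative mean-one noise is
used because biomass is positive and replicate spread scales with the
mean; additive noise can go negative. `m_reps > 1` averages that many
independent measurements per species (homogeneous replication),
shrinking the noise SD by about $1/\sqrt{m}$. `calibrate_cv()` recovers
the CV from replicate measurements as the root-mean-square of
per-species SD/mean — RMS pooling weights species equally and is
consistent with the RMS role CV² plays in the noise law. The
distribution family and pooling rule are documented stand-ins; only
the first two moments matter for the quantities studied here.

## Simulation machinery and problem sizes

`subsampling_experiment()` draws species subsets (uniform, without
replacement within a draw, independent across draws), computes
uncorrected and corrected statistics per draw, and reports mean bias,
SD across draws, SD across means of consecutive blocks of `n`
heterogeneous replicates, the Monte-Carlo standard error, and the
analytic predicted bias. Uncorrected variants are reported on the
per-pool-species scale (`CE^S/N − CE^P/Q`) so the analytic curve
applies directly; corrected variants on the population scale.

Numerical/design choices:

* **Exhaustive auto-activation.** When `choose(N_avail, N)` is at or
  below the design's `exhaustive_threshold` (default 1e5), every subset
  is enumerated once, making unbiasedness checks exact rather than
  stochastic. The reduced-scale validation experiment instead sets the
  threshold to 0 (pure Monte-Carlo at every `N`, including `N` near
  `Q`) so that all points share the 2000-draw design.
* **Substreams.** One experiment seed deterministically spawns one
  substream per subsample size, so enlarging the grid does not perturb
  existing points.
* **Blocks.** Heterogeneous-replicate summaries cut the draw sequence
  into consecutive non-overlapping blocks, keeping blocks independent.
* **Problem sizes.** The shipped validation uses `Q = 100` with 2000
  draws per `N` over a 15-point grid, exhaustive enumeration for pools
  up to 10, 1000 random communities for the identity checks, and 200
  iterations for the observation-error study — sizes chosen so the
  statistical assertions have comfortable Monte-Carlo margins while the
  whole suite runs in well under a minute.

`sampling_error_interval()` estimates, from a *single* observed sample,
the SD of the corrected estimates attributable to incomplete sampling.
The exact reference procedure is not fixed by the estimator theory, so
the implementation is a parameterised approximation, documented as
such: draw sub-subsamples of size `N′ = max(2, ⌊N/2⌋)` (configurable)
from the observed species, re-correct each to the full pool, and scale
the spread by the design-based factor
$(1/N - 1/Q)/(1/N' - 1/N)$ — exact for sample means under sampling
without replacement, approximate for the product and covariance terms
in `CE`/`SE`. A calibration test checks the resulting intervals stay
within a factor two of the true between-subset SD; at `N = Q` the
factor is zero, matching the absence of sampling error in a complete
census.

## Limitations

* Corrections assume random subsets; no protection against biased
  species selection.
* The sampling-error interval is approximate (above) and requires
  `N ≥ 3`; it reflects sampling error only, not observation error.
* Observation error is modelled as independent mean-one multiplicative
  noise; correlated measurement error (e.g. shared harvest dates) is
  out of scope.
* The partition itself takes the proportional-sowing null as given;
  alternative nulls enter only through `expected_ry`.
* Tripartite and other finer decompositions of the selection effect
  are not implemented.
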