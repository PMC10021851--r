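---
title: "Calibrated district-level maternal mortality estimation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrated district-level maternal mortality estimation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmrcal)
```

## The estimation problem

Facility-based health information systems record live births and maternal
deaths at district resolution, but the recording of deaths is incomplete
to a degree that varies by state. A sample-registration reference system
provides reliable *state-level* mortality — and for many smaller states
not even that, only an infant mortality rate. `mmrcal` turns these
ingredients into calibrated district estimates in four steps.

**1. Raw rates.** For district $d$,
$\mathrm{MMR}_d = \dfrac{\text{maternal deaths}_d}{\text{live births}_d}
\times 100{,}000$, with counts cumulated over the full analysis window.
State-level facility rates pool numerator and denominator counts across
the state's districts; they are never averages of district rates, which
would be biased whenever denominators differ.

**2. Calibration factor.** For state $s$ with a reference MMR,
$C_f(s) = \mathrm{MMR}^{\mathrm{ref}}_s / \mathrm{MMR}^{\mathrm{fac}}_s$.
Where the reference publishes no MMR, the infant mortality rate stands in
as a proxy: $C_f(s) = \mathrm{IMR}^{\mathrm{ref}}_s /
\mathrm{IMR}^{\mathrm{fac}}_s$. The reference MMR always wins when both
are available, and the provenance (`mmr_based` / `imr_proxy`) is recorded
per state. The ratio — not the component counts — is calibrated, so a
state that under-records deaths by a uniform factor is corrected exactly
in expectation.

**3. District adjustment.**
$\mathrm{MMR}^{\mathrm{adj}}_d = \mathrm{MMR}_d \times C_f(s(d))$.
A district with zero recorded deaths stays at zero; a district with zero
live births has an *undefined* rate — it is flagged, excluded from
classification and aggregation, and reported, rather than silently set
to zero.

**4. State aggregation.** Adjusted district rates are combined with
population weights $pw_d = P_d / \sum_{d' \in s} P_{d'}$, where $P_d$ is
the district's female population aged 15–49, giving
$\mathrm{MMR}^{\mathrm{adj}}_s = \sum_d \mathrm{MMR}^{\mathrm{adj}}_d \,
pw_d$. Weights sum to one within each state by construction.

Estimates are carried at full floating precision throughout; integer
rounding happens only in displays. SDG-3.1 classification uses half-open
bins $[0,70)$, $[70,140)$, $[140,210)$, $[210,\infty)$ — 70 is the 2030
target, 140 the secondary target, and the further cut-offs continue the
same interval.

### Degenerate calibration

A state whose facility MMR is zero against a positive reference would
need an infinite factor. This never arises in realistic inputs, so it is
an error by default; `allow_imr_fallback_on_degenerate = TRUE` reroutes
such a state through the IMR-proxy path instead, which is the only
defensible automatic alternative.

## What the synthetic generator emulates

`generate_system()` builds a multi-state district system with known
truth, standing in for the four real sources (facility counts, reference
rates, census populations, survey covariates):

* **Geometry.** Districts sit on a rectangular lattice with
  queen contiguity; states are contiguous row-major blocks. The default is
  640 districts in 32 states — the size of the Indian district system the
  method targets.
* **True surface.** Log true MMR is a state base effect (drawn from
  `base_mmr_range`, default 60–250 per 100,000, spanning the published
  state range) plus an iterated $\rho$-weighted neighbour average of white
  noise approximating a spatial autoregressive field, plus covariate
  effects and independent noise.
* **Observation.** Maternal deaths are
  $\mathrm{Binomial}(\text{births}, \mathrm{MMR}^{\mathrm{true}}/10^5)$
  thinned binomially by the state's reporting fraction (drawn from
  `reporting_fraction_range`, default $[0.5, 1]$). Binomial sampling
  guarantees deaths never exceed births; thinning deaths (not births)
  mirrors a system that registers births well but misses deaths. Infant
  deaths follow the same scheme from a true-IMR surface with the *same*
  state reporting fraction, so the proxy path recovers the same factor.
* **Reference.** State reference rates equal births-weighted true rates
  (optional lognormal noise via `reference_noise_sd` for robustness
  experiments). The reference MMR is withheld for
  `missing_reference_fraction` of states — default 0.5, because the real
  reference system publishes MMR for only about half of the states —
  forcing those states through the proxy path.
* **Covariates.** One standard-normal covariate per named effect, linked
  to log true MMR through the configured coefficients; defaults are
  modest maternal-care and socioeconomic effects of both signs.

What it does **not** emulate: real administrative geography, period
mismatches between sources, non-uniform within-state under-reporting,
covariate measurement error, or correlated covariates. Passing tests
therefore demonstrate that the *procedure* is correct under its own
assumptions — not that real facility data satisfy those assumptions.

### Problem sizes and the recovery tolerance

The recovery experiment uses 8 states × 10 districts with death
reporting drawn in $[0.5, 1]$ and reference equal to truth, and asks the
calibrated estimates to land within 2% mean absolute relative error of
the truth. The only stochastic error left in that design is binomial:
a district with $B$ births, true rate $m$ and reporting $r$ yields
$\mathbb{E}|\hat m - m|/m \approx 0.798/\sqrt{B (m/10^5) r}$, and the
expectation must be taken over the generator's log-normal district
spread, whose low tail dominates. Births are therefore drawn in
$[2, 4] \times 10^6$ per district, which bounds the expected error near
1.5% — comfortably inside the tolerance without being sensitive to the
seed. The type-I-error study uses a 20×20 lattice with 999 conditional
permutations and 50 replicates; the coefficient-coverage study uses 200
replicates of the default 640-district system.

## Spatial statistics

Weights are queen contiguity (any shared boundary point), symmetrised,
zero diagonal, and row-standardised for all statistics — the convention
of the standard cluster-mapping workflow; islands are retained in the
weights but excluded from statistics with a warning. With deviations
$z_i$ and row-standardised weights $w^*_{ij}$:

$$I = \frac{n}{S_0}\frac{\sum_{ij} w^*_{ij} z_i z_j}{\sum_i z_i^2},
\qquad
I_i = \frac{z_i}{m_2} \sum_j w^*_{ij} z_j,\quad m_2 = \tfrac{1}{n}\sum_i z_i^2,$$

so $\sum_i I_i / n = I$ under row standardisation (asserted to 1e-10 in
the tests, with the global statistic checked against a brute-force
double-sum oracle to 1e-12). $\mathbb{E}[I] = -1/(n-1)$ under no
autocorrelation; on a complete graph $I$ equals that value identically.
The bound $I \in [-1, 1]$ often quoted is not guaranteed in general and
is deliberately not enforced.

Inference is by permutation with 999 draws by default, pseudo p-value
$(\text{extreme} + 1)/(B + 1)$, floor $1/(B+1) = 0.001$ — the value a
strongly clustered field reports. Global inference is one-sided toward
the observed departure from $\mathbb{E}[I]$, ties counted as extreme.
Local (LISA) inference is *conditional*: unit $i$'s value is held fixed,
the others are permuted among the remaining units, and extremeness is
magnitude exceedance $|I_i^{\mathrm{perm}}| \ge |I_i|$. Choosing the
tail from the observed sign instead would roughly double the share of
units flagged at $\alpha$ under an independent field; with magnitude
exceedance the pseudo p is uniform under the null and the flagged share
sits at the nominal level (checked at $0.05 \pm 0.02$). Cluster
direction (HH/LL hot and cold spots, HL/LH outliers) comes from the
signs of $z_i$ and its spatial lag, not from the tail. Per-unit draws
are taken in sorted-id order from one seeded stream, so results are
reproducible and invariant to unit relabelling. No multiple-testing
correction is applied by default, matching standard LISA cluster maps;
a Benjamini–Hochberg option exists. The bivariate form replaces the lag
of $z$ with the lag of a second standardised field and reduces exactly
to the univariate statistic when the two fields coincide.

## Health Infrastructure Index

Each facility/personnel indicator (district hospitals, CHCs, PHCs,
sub-centres, doctors, nurses, ANMs, ASHAs, AWWs — per 1,000 population)
is normalised HDI-style, $(x - \min)/(\max - \min)$, clamped to
$[0, 1]$. Goalposts default to the observed cross-district min/max —
standard HDI practice — with fixed goalposts available since published
applications of this index evidently used a different, unstated scale.
Aggregation is the arithmetic mean (the classic HDI convention;
geometric available). The urban adjustment is a convex combination with
an urban component imputed at the upper goalpost,
$(1-u)\,\mathrm{HII} + u$: the simplest reading of weighting by urban
population share, documented as a convention. It makes the adjusted
index monotone in both arguments and never below the raw index.

## Regression models

The correlate models are log-linear OLS,
$\log \mathrm{MMR} = a + \sum_k b_k x_k + \varepsilon$, with
heteroskedasticity-robust (sandwich) standard errors. HC1 is the
default flavour — the common small-sample degrees-of-freedom correction
— recorded in the output. Zero-MMR districts are dropped by default
(each drop reported), consistent with observation counts falling
slightly short of the district count in published applications; an
offset policy is available. Covariates may enter logged per the spec of
each model. Rows with missing fields are deleted listwise and reported.
A pairwise Pearson screen refuses models containing a covariate pair
with $|r| > 0.60$ unless explicitly overridden. "Area dummy" rows in
published tables cannot mean one dummy per district (one observation
each); they are implemented as state fixed effects and documented as an
interpretation. Model validity is established by simulation: exact
recovery at zero noise, robust-CI coverage near nominal at realistic
noise, sign recovery at strong effects.

## Numerical and degenerate-input choices

* Rates carry full double precision; the only rounding is at display.
* Zero live births → undefined rate error (or flagged `NA` in the
  fitted object), never silently zero; zero deaths → rate 0.
* Constant fields are an error for all Moran statistics (zero variance).
* Classification rejects negative or non-finite MMR; bins are half-open
  so every finite non-negative value falls in exactly one bin.
* Degenerate goalposts (max = min) are an error rather than a 0/0.
* Ties in permutation inference count as extreme (conservative).
* All stochastic stages derive their stream from one master seed;
  rerunning a pipeline configuration reproduces artifacts byte for byte.

## Known limitations

* Point estimates only: the calibration gives no uncertainty intervals,
  and binomial noise in small districts can be large.
* The calibration assumes under-reporting is uniform within a state and
  affects the ratio multiplicatively; heterogeneous within-state
  reporting biases district estimates even after calibration.
* The IMR-proxy path assumes maternal and infant deaths are
  under-recorded to a similar degree.
* Ecological regressions on district aggregates support association
  statements only, not individual-level or causal claims.
* The published index scale for the infrastructure composite cannot be
  reproduced exactly (its goalposts were never stated); only the
  construction is reproduced.
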