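---
title: "Methods: probabilistic benzene cancer risk from gasoline fueling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: probabilistic benzene cancer risk from gasoline fueling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pumprisk)
```

# The risk model

Benzene is a Group 1 carcinogen and a regulated constituent of gasoline;
anyone fueling a vehicle inhales volatilized benzene for the few minutes
the pump runs. pumprisk quantifies the excess lifetime cancer risk that
this short, repeated exposure implies, using the linear inhalation
unit-risk chain

$$\mathrm{Risk} = s \cdot UR \cdot CA \cdot \frac{ET}{8760} \cdot \frac{ED}{AT},$$

with $UR$ the inhalation unit risk (excess lifetime cancer probability
per unit of continuous lifetime concentration), $CA$ the benzene
concentration, $ET$ exposure hours per year ($8760$ hours in a year),
$ED/AT$ the fraction of a lifetime exposed, and $s$ the reporting scale
(per $10^6$ people for the general population, per $10^4$ for
occupational comparisons, matching the 1:1,000,000 and 1:10,000
risk-management levels).

Assumptions inherited from this construction:

* **Linear no-threshold dose response.** Risk is proportional to the
  lifetime-averaged concentration; no uncertainty is placed on $UR$
  itself (default $2.2 \times 10^{-6}$ per µg/m³, the most conservative
  published inhalation unit risk for benzene).
* **Exposure duration 15 years against a 70-year averaging time**,
  reflecting the 10–20-year latency window within which benzene exposure
  is thought causative for acute myeloid leukemia.
* **Inhalation only.** Dermal uptake and co-exposures (traffic PM₂.₅,
  smoking) are out of scope.

The probabilistic version replaces $CA$ and $ET$ with distributions and
Monte Carlo samples the chain, by default $10^5$ times.

# Exposure factors and their parameterization

## Concentration (both scenarios)

Near-pump benzene concentrations are treated as lognormal. Fitting is
done on the natural log of the concentration **in ppm**
(`fit_lognormal()` divides ppb input by 1000), so a geometric mean of
3.24 ppb corresponds to a log-location of $\ln(0.00324) \approx -5.73$.
The reference parameterization shipped in
`default_consumer_distributions()` is $\ln\mathcal{N}(-5.73, 0.98)$.
Note a small internal tension in the reference values: a geometric SD of
2.72 implies $\sigma = \ln 2.72 \approx 1.00$, not 0.98; the package
always computes $\sigma$ from data when fitting and carries the reference
value verbatim only for reproduction runs.

Because $UR$ is quoted per µg/m³, concentration draws in ppm are
converted with the ideal-gas factor
$1\ \mathrm{ppm} = \frac{78.11}{24.45}\ \mathrm{mg/m^3}$ at 25 °C
(`convert_concentration()`; a 0 °C convention with molar volume
22.414 L/mol is available, and unit-risk values quoted per ppb or ppm
can be used directly via `ur_basis`).

## Fill time (consumer)

Sampling canisters lose vacuum at a constant 5 mmHg per minute while
open, up to a six-minute operational limit, so the fill time is
`(initial − final) / 5` minutes (`estimate_fill_time()`). The fitted
distribution is a truncated normal on $[0.5, 6]$ minutes: the bounds are
the shortest plausible fill and the hardware limit. Deliberately, the
mean and SD are the **raw sample moments** of the calculated fill times,
not a truncated-likelihood fit — this mirrors how the reference study
parameterized the factor, and `fit_truncnorm()` documents it. Observed
values outside the bounds still contribute to the moments; the bounds
constrain sampling only.

## Fill frequency (consumer)

Fills per month are counts with no zeros (every participant fills up),
modeled as a zero-truncated ("positive") Poisson. The default
parameterization sets $\lambda$ to the **raw mean of the counts** —
again the reference study's stated choice — which slightly overshoots
the parent $\lambda$ when the data truly are zero-truncated draws
(raw mean targets $\lambda/(1-e^{-\lambda})$). For parameter-recovery
uses, `fit_positive_poisson(counts, method = "mle")` inverts the
truncated mean equation instead.

## Occupational factors

Attendants reuse the consumer concentration distribution (their
breathing zone is the same pump environment) with
$ET = \text{hours/day} \times \text{days/year}$,
$\mathcal{N}(7, 0.5)$ and $\mathcal{N}(260, 10)$ by default: a
conservative near-full workday at the pump and a standard work year.
Draws are resampled if nonpositive, a guard with probability around
$\Phi(-14)$ at the defaults — negligible, but it keeps the support
physical for user-supplied parameters.

# Numerical choices

* **Truncated-normal sampling** uses the inverse-CDF method: a uniform
  draw is mapped through the normal quantile restricted to
  $[\Phi(\frac{a-\mu}{\sigma}), \Phi(\frac{b-\mu}{\sigma})]$. Exact
  support, no rejection loop, vectorized. The degenerate $\sigma = 0$
  case returns the mean (which must lie inside the bounds).
* **Zero-truncated Poisson sampling** maps a uniform draw on
  $[P(X{=}0), 1]$ through `qpois()` — the exact inverse CDF of the
  truncated pmf; it can never emit zero.
* **Percentiles** are linear-interpolation quantiles (R type 7) of
  $\log_{10}$ risk; **exceedance** fractions use strict `>`, and limit
  comparisons (`compare_to_limits()`) use strict `<`, so boundary values
  are never counted as exceeding or complying by rounding luck.
* **Censored concentrations** (below the limit of detection) are
  replaced by $LOD/\sqrt{2}$, the conventional substitution for
  left-censored exposure data; the operation is idempotent and errors on
  a missing or nonpositive LOD.
* **Seeding**: every simulation function takes an explicit seed; the
  pipeline derives one seed per stage from a single root seed, so whole
  runs are bit-reproducible.

## The unit-convention catalog

The published percentile sets for this problem cannot be reproduced from
the printed inputs under a single self-evident unit convention — the
probabilistic equations omit the per-day/per-year normalizers, so the
effective duration weighting is under-determined. `risk_params()`
therefore makes the convention explicit:

* `"as_printed"` (default): $ED/AT = 15/70 \approx 0.214$.
* `"calibrated"`: the duration ratio is overridden to $0.5$. Under IUR
  $2.2\times10^{-6}$ per µg/m³ and the 25 °C conversion, this single
  adjustment jointly reproduces all published consumer **and**
  occupational percentiles to within a few hundredths of a log₁₀ unit
  (the as-printed ratio leaves both sets uniformly
  $\log_{10}(0.5/0.214) \approx 0.37$ low).

This is documented as a calibration finding, not a claim about intent;
both modes are recorded in every result's provenance, and any explicit
`ed_at_override` wins over the convention keyword.

# Quality control

`qc_filter()` partitions samples with three reason codes:

* **LEAK** — the optional `leaked` field note is set (a transport leak
  is known from handling, not always recoverable from the data: a
  full-window fill and a total leak can produce the same vacuum pair),
  the final vacuum exceeds the initial, or the drop exceeds the
  operational window (`5 mmHg/min × 6 min`).
* **CONTAMINATION_OUTLIER** — any BTEX concentration more than
  `outlier_factor` (default 100, i.e. two orders of magnitude) above
  that compound's geometric mean across the plausible samples. The
  multiplicative rule operationalizes "orders of magnitude above the
  rest" on data whose natural scale is geometric.
* **UNUSED** — zero vacuum change; the canister was never opened.

Kept and excluded rows always partition the input, and the exclusion
report is persisted for audit.

# Ambient contextualization

Ambient benzene cancer risk is available per census tract (per million).
Each contextualization draw selects a **home** tract with probability
proportional to population and a **work** tract uniformly, weights them
0.8/0.2 (an approximate 40-hour week away from home), and forms
$\log_{10}(\text{pumping}/\text{ambient})$ against a bootstrap resample
of the stored pumping-risk draws — equivalent in distribution to
re-simulating, and much cheaper. Occupational draws are rescaled ×100 to
the per-1M scale before the ratio so both scenarios are compared on the
ambient scale. The ratio orientation (pumping over ambient; positive
means pumping dominates) is a flag, since the opposite orientation is
also seen in the literature's prose.

# The synthetic-data generator

No raw samples ship with the package, so `generate_samples()` and
`generate_tracts()` emulate the study conditions:

* concentrations per compound drawn lognormally at the reference
  geometric means/GSDs (benzene 3.24 ppb / 2.72; toluene, ethylbenzene,
  xylene and TVOC are generated to exercise the descriptive surface but
  never enter risk math, which is benzene-only);
* fill minutes from the truncated normal, encoded as a canister vacuum
  pair (`final = 30 − 5·minutes`) so `estimate_fill_time()` inverts the
  encoding exactly;
* fills/month from the zero-truncated Poisson;
* LODs default below the observed concentration minima (e.g. benzene
  0.25 ppb), so censoring is rare unless raised — real LODs for the
  reference data are unpublished;
* optional injected anomalies (leaks, ×1000 contamination) recorded in
  a truth sidecar so QC can be tested against ground truth;
* a tract table with 200 city tracts at $\mathcal{N}(4.4, 0.31)$ and
  214 county tracts at $\mathcal{N}(3.76, 0.39)$ per million (truncated
  positive), **equal populations** by default. Equal weighting gives a
  pooled ambient mean near 4.07 per million, which jointly matches the
  published consumer and occupational ratio statistics; the real tract
  populations are unpublished, so a `population_skew` knob exposes the
  sensitivity. With skewed populations the occupational exceedance of
  ambient shifts by several percentage points — worth remembering when
  supplying real NATA extracts.

What the generator does **not** emulate: temperature–concentration
relationships (reported null in the field data), station covariates,
spatial structure of stations versus roadways, within-person
correlation of repeated fills, or seasonality. Passing tests on
synthetic data therefore demonstrate the pipeline's statistical
correctness under the stated generating model, not robustness to every
feature of real campaigns.

# Problem sizes and runtime

Headline simulations use $10^5$ iterations (Monte Carlo standard error
on a median log₁₀ risk ≈ 0.002, far below reporting precision).
Property tests use $10^4$–$2\times10^5$ draws, chosen so sampling noise
sits an order of magnitude below each asserted tolerance; the whole
suite runs in a few seconds on one CPU.

# Known limitations

* The calibrated convention reproduces published percentiles but the
  authors' exact convention is unrecoverable; treat cross-convention
  comparisons with care.
* The raw-moment truncated-normal and raw-mean positive-Poisson
  parameterizations are faithful to the reference methodology but are
  not maximum-likelihood fits; at these sample sizes the difference is
  visible (e.g. the fill-frequency λ overshoot above).
* Median "additivity" across log factors is only approximate: the
  discrete fill-frequency factor shifts the median of the product ~0.04
  log₁₀ below the sum of factor medians.
* Ambient contextualization assumes home and work tracts are drawn from
  one pooled region and ignores commute exposure.
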