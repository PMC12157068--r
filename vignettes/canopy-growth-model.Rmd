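---
title: "A canopy light-attenuation growth model for floating duckweed mats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A canopy light-attenuation growth model for floating duckweed mats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lemnagrow)
```

## The model and its assumptions

Duckweed mats in recirculating culture are well mixed horizontally, so the
growth-limiting effect of crowding is taken to be *mutual shading* alone: as
areal dry-weight density $D$ (gDW m$^{-2}$) rises, the mat thickens and light
penetrates a smaller fraction of the biomass. The package models

$$\frac{dD}{dt} = D\left(E\,r_{phot,i}\,\bar f_{phot}(I_S, D) - r_{resp}\right)$$

with photoperiod fraction $E$, intrinsic photosynthesis rate $r_{phot,i}$
(d$^{-1}$, the rate at saturating light without self-shading), and a constant
respiration rate $r_{resp}$ (d$^{-1}$). Light decays with depth in the mat by
Beer–Lambert attenuation; assuming layer thickness proportional to $D$, the
optical depth of the whole mat is $\hat\varepsilon D$, where
$\hat\varepsilon$ (m$^2$ gDW$^{-1}$) is the *product* of the per-thickness
attenuation coefficient and the thickness-per-density constant. Only this
product is identifiable from growth data, so it is the quantity stored and
fitted. Local photosynthesis saturates with intensity as a Monod factor
$I/(k+I)$; averaging it over the layer yields the closed form

$$\bar f_{phot}(I_S, D) =
  \frac{\ln(k + I_S) - \ln\!\left(k + I_S e^{-\hat\varepsilon D}\right)}
       {\hat\varepsilon D} \in [0, 1).$$

Assumptions worth keeping in mind: temperature, CO$_2$, pH and nutrients are
held constant (a well-controlled recirculating system); the photoperiod acts
only through the constant factor $E$ (no day/night switching is simulated);
there is no photoinhibition, so the Monod response keeps rising at intensities
where real plants may suffer light stress; and frond-level morphology is
outside scope.

The *limit density* $D_L(I_S)$ — the carrying capacity — is the unique
positive root of the per-capita rate. It exists exactly when
$E\,r_{phot,i}\,I_S/(k+I_S) > r_{resp}$, i.e. above the compensation
intensity $I_c = r_{resp}k/(E\,r_{phot,i}-r_{resp})$ (about
2.9 µmol m$^{-2}$ s$^{-1}$ at the reference parameters). A logistic × Monod
comparator (`vandyck_params()`) is included because it is the natural
benchmark from batch-culture work; its density term is phenomenological where
the canopy model's is mechanistic.

## Parameters

| Symbol | Code | Unit | Reference value | Meaning |
|---|---|---|---|---|
| $r_{phot,i}$ | `r_phot_i` | d$^{-1}$ | 0.6965 | photosynthesis at saturation, no shading |
| $r_{resp}$ | `r_resp` | d$^{-1}$ | 0.0583 | maintenance loss, light-independent |
| $\hat\varepsilon$ | `eps_hat` | m$^2$ gDW$^{-1}$ | 0.1209 | optical depth per areal density |
| $k$ | `k` | µmol m$^{-2}$ s$^{-1}$ | 17.2640 | Monod half-saturation intensity |
| $E$ | `E` | – | 14/24 | illuminated fraction of the day (fixed, not fitted) |

The comparator reference values are $r_{phot,i} = 0.4602$,
$r_{resp} = 0.0788$, $h_D = 223.7906$, $K_I = 50.4300$. Note the
carrying-capacity parameter $h_D$ is used with unit gDW m$^{-2}$: its
published unit (m$^2$ gDW$^{-1}$) is inconsistent with its logistic role, and
is treated here as a misprint — flagged, not silently altered.

## Numerical choices

* **Closed form vs 0/0.** $\bar f_{phot}$ is a $0/0$ expression as
  $\hat\varepsilon D \to 0$; below $\hat\varepsilon D < 10^{-8}$ the analytic
  limit $I_S/(k+I_S)$ is returned. The main branch is evaluated through
  `log1p`/`expm1`, which removes the catastrophic cancellation of the naive
  difference of logarithms, so the two branches agree to machine-level
  accuracy at the switch.
* **Integration.** Trajectories use an embedded Dormand–Prince 5(4) pair
  (compiled, `src/dp45.cpp`) with adaptive error control at `rtol` $10^{-8}$ /
  `atol` $10^{-10}$, reported on a 0.05 d grid — the conventional fixed
  reporting step, but with accuracy guaranteed by the embedded error estimate
  rather than assumed. The suite cross-checks terminal densities against an
  independent fixed-step RK4 oracle at $10^{-6}$ relative.
* **Limit density.** Bracketed root-finding on the per-capita rate
  (residual below $10^{-9}$); a 2000 d simulation plateau is retained as a
  cross-check only. Zero respiration means no finite limit and is signalled
  (`lemnagrow_no_finite_limit`), not returned as `Inf`.
* **Fitting.** The four free parameters are estimated in log space
  (positivity by construction) by Nelder–Mead from the conventional initial
  estimates, polished by BFGS, with a final Nelder–Mead pass guarding against
  finite-difference gradient noise. Standard errors use the Gauss–Newton
  $\hat\sigma^2 (J^\top J)^{-1}$ approximation — the standard least-squares
  reading of "Hessian approximation" — with a full finite-difference Hessian
  behind `hessian = "full"`; p-values use $t_{n-p}$ (the choice of reference
  distribution is not documented for the original fits; $t$ is the
  conservative default). A singular information matrix yields `NA` standard
  errors with a warning, never fabricated values.
* **Harvest optima.** $D_{opt}$ maximization screens a 61-point coarse grid
  over $(0, D_L)$ for local maxima before bounded scalar refinement
  (absolute tolerance $\sim10^{-6}$) — unimodality is verified, not assumed.
  $I_{LUE\max}$ is found the same way on a log-spaced intensity grid over
  $(0, 500]$, the conventional simulated range.
* **LUE convention.** The published definition divides yield by $I_S$ with
  units gDW mmol$^{-1}$, leaving the time base unresolved. The default
  converts $I_S$ to a daily photon dose $I_S \cdot E \cdot 86400/1000$
  mmol m$^{-2}$ d$^{-1}$ (photons counted during the lit fraction only);
  `convention = "raw"` gives the bare ratio. The two differ by a constant, so
  every argmax-derived quantity is convention-invariant.
* **Variogram fitting.** Weighted least squares (weights = pair counts) over
  nugget, partial sill, both ranges and the anisotropy angle, with
  multi-start over angles and ranges. Fitted ranges are bounded at 2.5× the
  maximum binned lag: beyond the sampled extent a spherical range is not
  identifiable (only the slope/sill ratio is), and unbounded fits diverge.
  Ring SDs use the sample ($n-1$) convention.

## What the synthetic generators emulate — and what they do not

`generate_trials()` reproduces the factorial design of the reference growth
experiment (6 initial densities × 4 intensities × 5 replicates, 7 d), with
three mean-one multiplicative lognormal noise sources: observation noise on
the final density (CV 5%), subarea intensity jitter (CV 5%), and
initial-density jitter (CV 2%, mimicking the post hoc dry-weight-content
correction of stocking weights). The CVs are placeholders — the true
replicate-level variability is unpublished — and are recorded as such in each
dataset's manifest. Noise sits on the *observations*: the fitting target is
the end-of-trial density, and no process-noise structure is available to
emulate. `generate_longterm()` produces the biweekly 8-week validation
series; `generate_light_survey()` samples an invented sum-of-lamp-kernels
PPFD field at 65 points (no published basin geometry exists; the ground-truth
field function is retained for oracle comparisons).

Consequently, a green test establishes *self-consistency*: that the pipeline
recovers parameters it generated data from, under noise of the assumed form.
It cannot establish that the noise model, the constancy of `E`, or the absence
of wall-adhesion and nutrient-drawdown effects hold in a real basin.

A related honesty note on the variogram tests: one 65-point survey cannot
identify a five-parameter anisotropic variogram to 15% — the sampling SD of
the empirical sill on a basin-sized domain is of order 13% by itself. The
recovery test therefore pools lag bins over 10–12 replicate simulated fields,
which tests the fitter against a well-estimated empirical variogram; the
single-survey case is covered by looser Monte-Carlo agreement checks.

## Design choices where the design was open

* The respiration term of the comparator model is placed inside the
  per-capita bracket; the printed comparator equation is typographically
  ambiguous, and this placement mirrors the canopy model's structure and the
  source model's logistic-minus-respiration form.
* Long-term validation starts each simulated trajectory at the first
  *observed* density (initial stocking weights were corrected post hoc in the
  reference experiment), and parameters are copied unchanged — no refitting.
* Per-trial intensities are used exactly as supplied; the package does not
  re-average them inside fitting (ring-averaging belongs to the light-field
  stage).
* The kriging grid's bounding box defaults to the measurements' extent
  (configurable); no universal kriging, cross-validation or 3-D fields.

## A known red mark

With the rounded reference parameters, the continuous-harvest
($\Delta t_H = 0$) LUE-maximizing intensity computes to
27.04 µmol m$^{-2}$ s$^{-1}$ — verified against a brute-force grid — while
the published account states the peak lies below 27 for every interval. The
longer intervals do fall below (26.5, 25.3, 22.2 at 5, 10, 20 d). The most
plausible cause is that the published curves were produced with unrounded
internal parameter values or a coarser intensity grid. The corresponding
acceptance test asserts the published bound as stated and is allowed to fail
by this margin (0.16%) rather than being widened; `scripts/acceptance.R`
reports the computed value.

## Limitations

Constant-environment kinetics only: no temperature, CO$_2$ or nutrient
response surfaces, no photoinhibition at high intensity, no protein-content
coupling, no wall-adhesion edge effects, no stochastic harvest scheduling,
and no economics — the light-use efficiency is a pure photon ratio, so the
economically optimal intensity will generally sit above $I_{LUE\max}$ once
fixed costs are included. Parameter values are clone- and system-specific;
transfer to other species, clones or open-pond conditions requires refitting.
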