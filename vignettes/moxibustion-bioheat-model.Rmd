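---
title: "A bioheat model of mild moxibustion: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A bioheat model of mild moxibustion: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moxitherm)
```

## The physical problem

In mild moxibustion a glowing moxa stick is held a few centimetres above an
acupoint so the patient feels warmth without pain. Therapeutically the
interesting quantity is *thermal penetration*: whether tissue a few
millimetres below the surface reaches roughly 42.5 °C while the skin surface
stays below the discomfort band around 46–48 °C. `moxitherm` models the
process end to end: a layered tissue block heated radiatively from above,
with probes at the moxibustion point (the surface point under the stick
axis), over a 5 mm-radius surface disk, and at the subsurface reference
point 5 mm below the surface.

## Model

### Tissue

The block is a cylinder of three homogeneous layers — skin (2.2 mm), fat
(12.4 mm), muscle (10.4 mm), 25 mm deep and 50 mm in radius — with the
standard material values for skin/fat/muscle (conductivity 0.37/0.21/0.49
W m⁻¹ K⁻¹, etc.; see `default_tissue_block()`). Temperature obeys the
Pennes bioheat equation

$$\rho c\,\partial_t T \;=\; \nabla\!\cdot\!(k\nabla T)
  \;+\; \omega_b C_b (T_b - T) \;+\; q_m \;+\; q_r ,$$

where the perfusion term relaxes tissue toward the arterial blood
temperature $T_b$ (37 °C) at rate $\omega_b C_b$, $q_m$ is metabolic heat,
and $q_r$ is the radiative surface source. Perfusion rates and metabolic
heats for the three layers are not part of the published material set;
the defaults (ω = 0.5/0.3/0.7 kg m⁻³ s⁻¹, q_m = 368/180/420 W m⁻³,
C_b = 3617 J kg⁻¹ K⁻¹) are literature-typical starting values and are the
free parameters of `calibrate()`.

### Source and radiative exchange

The burning end is a sphere of the stick radius whose temperature follows a
harmonic burning law, peak 600 °C, amplitude 200 °C, period 500 s — a
surrogate for ash progressively covering the ember. Ash is cleaned once per
minute: for 5 s the stick is withdrawn and the source is held at 50 °C
(warm air). Two phase conventions are implemented
(`burn_schedule(reset_on_clean = )`):

* **reset (default)** — the harmonic restarts from its peak after each
  cleaning, since ash accumulation begins anew on the cleaned end. With a
  60 s cleaning interval only the first 60 s of the cosine is ever
  traversed, so the source stays in roughly 546–600 °C. This is the
  reading consistent with a once-per-minute cleaning of a 500 s decay (one
  cleans *before* the trough) and it validates far better against the
  measured series (best achievable maximum deviation ≈ 9% vs ≈ 15%).
* **absolute time** — the cosine is evaluated on elapsed time regardless
  of cleaning, sweeping the full 200–600 °C range.

A skin surface element at radial offset $r$ sees the sphere (radius $R$,
centre height $H$) under the exact view factor
$F(r) = R^2 H / (H^2+r^2)^{3/2}$; the remaining $1-F$ of its view is
blackbody surroundings at the ambient temperature. Irradiation is
$G = F\,\varepsilon_s e_b(T_a) + (1-F)\,e_b(T_{amb})$ with
$e_b(T) = n^2\sigma T^4$, and the absorbed flux is
$q_r = \varepsilon_{skin}(G - e_b(T_{skin}))$. The closure is single-bounce:
with a skin reflectance of ~0.02, multi-bounce corrections are below 0.1%.
(The isothermal-enclosure identity $q_r = 0$ holds exactly for a black
source; with a grey source and no returned reflection it is approximate,
which is why the corresponding property test uses ε_source = 1.)
Emissivities are unstated in the source material; defaults are 0.90
(glowing ember) and 0.98 (skin), both exposed to calibration. Radiation to
the room is the only surface loss — air convection is deliberately ignored,
matching the scenario definition.

### Discretization

The geometry is rotationally symmetric, so the solver works on an
axisymmetric (r, z) finite-volume grid rather than a 3D block — identical
physics, orders of magnitude cheaper. Defaults: 0.5 mm background spacing,
refined to 0.25 mm radially inside the 5 mm probe disk and to ~0.24 mm
vertically through the skin layer; layer interfaces coincide with cell
faces and interface conductances use the series (harmonic-mean) rule,
which is exact for steady slabs. Time stepping is a θ-scheme (backward
Euler by default, dt = 0.5 s) with the nonlinear $T^4$ surface flux handled
by Picard iteration (tolerance 10⁻⁶ relative, ≤ 10 iterations; in practice
2–3). The bottom face is Dirichlet at the 37 °C core, the axis and lateral
faces are zero-flux. The conduction operator is symmetric positive
semidefinite and assembled once per run; each step reuses a cached sparse
Cholesky factorization. Halving dr, dz and dt moves the standard run's
reference-point temperature by < 0.01 °C, comfortably inside the 0.1 °C
convergence check the tests enforce. With insulated boundaries and no
sources the scheme conserves total enthalpy to solver precision.

### Resting state

`initial_state()` solves the steady model without the stick (ambient
radiative exchange only). When a target resting disk-average temperature is
set (34.3 °C for the validation scenario), all perfusion rates are rescaled
by one common factor, found by bisection on the log scale, until the disk
average matches within 0.1 °C. Sweeps and the orthogonal experiment tune
this scale once at the standard condition and share it across runs, so runs
differ only in the swept factor while the resting state still responds
physically to, e.g., ambient temperature.

The validation experiment does not report its ambient temperature; the
package uses 20 °C, a typical indoor value with the useful property that
the implied resting perfusion scale stays near physiological resting
values (at 25 °C the radiative resting loss is so small that matching
34.3 °C forces implausibly low perfusion).

## Calibration and what the validation shows

`calibrate()` minimizes the maximum absolute percent deviation (denominator:
the simulated value, the convention under which the published deviation
column reproduces) between the simulated disk-average series and the
measured one, over bounded emissivities, perfusion rates and metabolic
heats — bounded Nelder-Mead on a scaled-logit reparameterization, searching
on a coarse grid (~1 mm, dt = 2 s) and polishing and reporting at full
resolution. It is deterministic given its seed.

The achieved maximum deviation is about 9%, above the 5% the original
validation claims for its own (differently parameterized, incompletely
specified) simulation. The gap is structural, not numerical: matching the
measured 5.7 °C surface rise within the first 30 s requires a sustained
absorbed flux near 750 W m⁻², while the resting-state constraint pins the
tissue's effective surface-to-blood resistance at a value for which any
sustained flux above ~250 W m⁻² overshoots the measured ~44 °C plateau.
With constant tissue properties and purely radiative exchange no parameter
set can do both; the measured behaviour (fast rise, low flat plateau)
is the signature of temperature-dependent perfusion (vasodilation), which
constant-property models exclude by design. The trajectory *shape* —
monotone rise flattening after about five minutes — is reproduced, and the
univariate directions all hold: hotter ember, wider stick, shorter
distance and warmer room each raise the reference-point temperature, and
the temperature field decays faster with depth than laterally.

## Orthogonal experiment and statistics

`build_L9()` is the standard L9(3⁴) array over maximum burning temperature
(600/625/650 °C), stick diameter (12/15/18 mm), distance (25/30/35 mm) and
ambient (17/25/32 °C). `range_analysis()` reports per-factor level sums K,
level means K/3, normalized sums K/9, ranges R and the larger-is-better
optimal levels; displayed values are rounded half-up to two decimals while
full precision is kept internally. Fed the published response column it
reproduces every printed K, K̄ and R value and the optimum A3B3C1D3;
simulating the nine runs with this package's own solver (uncalibrated
defaults) yields hotter absolute temperatures but the same optimal
combination.

The design is saturated, so `doe_anova()` has no residual degrees of
freedom and constructs an error mean square explicitly: by default the mean
of the four factor mean squares (equivalently total SS / 8), alternatively
by pooling the smallest-SS factor. F ratios from a saturated design are
descriptive; the star markers replicate the published display convention
(rank 1 `***`, ranks 2–3 `**`) and are not inferential claims. The factor
sums of squares always add up to the total SS (orthogonality), and the
published F values themselves are not reproducible under either strategy —
only the ordering (stick size dominant, burning temperature least) is
treated as meaningful.

`synthetic_doe_spec()` / `generate_doe_responses()` generate response
tables from the additive model the analysis assumes (grand mean + zero-sum
level effects + Gaussian noise). They emulate the statistical structure
only — not solver nonlinearities or run-to-run correlation — so the
recovery property they support (≥ 95% recovery of planted optima at
noise σ ≤ 0.2 °C and effect gaps ≥ 1 °C over 200 seeded replicates) is a
statement about the analysis machinery, not about real moxibustion data.

## Numerical and scope notes

* Problem sizes: default runs use a 110 × 55 cell grid and 1800 steps
  (~3.5 s each); calibration searches on ~55 × 28 cells at dt = 2 s.
* Temperatures are stored in °C throughout and converted to K only inside
  the Stefan–Boltzmann law.
* Degenerate inputs are rejected with the offending field named; cleaning
  windows of zero duration disable cleaning; an amplitude of zero gives a
  constant source.
* Out of scope: curved anatomy, epidermis/dermis distinction,
  temperature-dependent tissue properties, combustion chemistry, smoke and
  spectral radiation, tissue-damage kinetics.
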