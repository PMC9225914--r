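# moxitherm

Bioheat simulation of **mild moxibustion** — the traditional thermal
therapy in which the glowing end of a moxa stick is held a fixed distance
above the skin — for researchers studying how treatment parameters shape
the temperature field in tissue.

The package couples two classical models:

* **Pennes bioheat equation** in a three-layer skin/fat/muscle block,

  ρc ∂T/∂t = ∇·(k∇T) + ω_b C_b (T_b − T) + q_m + q_r,

  solved on an axisymmetric finite-volume grid with implicit time stepping;
* **surface-to-surface radiation** from the spherical burning end
  (J = ε e_b(T) + ρ_d G, e_b = n²σT⁴) with exact element-to-sphere view
  factors F(r) = R²H/(H²+r²)^{3/2}, driven by a harmonic burning curve
  (peak 600 °C, amplitude 200 °C, period 500 s) interrupted once per minute
  by ash-cleaning windows at 50 °C.

On top of the solver it implements the full study workflow: univariate
sweeps of burning temperature, stick size, stick-to-skin distance and
ambient temperature; calibration/validation against a published in-vivo
temperature series; and a Taguchi **L9(3⁴) orthogonal experiment** with
range analysis (R-method) and saturated-design ANOVA ranking the factors
that control thermal penetration to the reference point 5 mm below the
moxibustion point.

## Worked example

Simulate the standard condition (600 °C peak, 18 mm stick, 35 mm distance,
25 °C ambient, 15 min):

```r
library(moxitherm)
run_simulation(standard_condition())
#> <simulation_result>
#>   duration 900 s, 31 recorded timepoints
#>   final moxibustion-point temperature: 61.16 C
#>   final 5 mm disk-average temperature: 60.94 C
#>   reference point (5 mm depth): 51.47 C
```

The surface under the stick ends just above 61 °C and the subsurface reference
point near 51 °C with the uncalibrated default emissivities (these are the
hot end of the plausible range; `calibrate()` fits them to measurements).
Temperature is maximal at the moxibustion point, decays outward along the
surface and — much faster — with depth.

Range analysis of the published orthogonal-experiment responses:

```r
print(range_analysis(build_L9(), load_fixture("table7")$temperature_C))
#> <range_analysis>
#>  factor    K1    K2    K3 Kbar1 Kbar2 Kbar3    R optimal_level
#>       A 40.29 40.91 41.76 13.43 13.64 13.92 1.48             3
#>       B 39.22 41.37 42.37 13.07 13.79 14.12 3.14             3
#>       C 42.41 40.84 39.71 14.14 13.61 13.24 2.70             1
#>       D 39.82 40.99 42.14 13.27 13.66 14.05 2.32             3
#> optimal combination: A3B3C1D3; influence ranking: B > C > D > A
```

Stick size (B) dominates thermal penetration, then distance (C), ambient
(D), and burning temperature (A) least; the best combination is the widest
stick, closest distance, warmest room and hottest ember — matching the
published analysis digit for digit.

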