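# pcthresh

Energy-threshold optimization for effective atomic number (*Z*) estimation
with two-bin photon-counting x-ray detectors.

Photon-counting detectors classify each detected photon into an energy bin
by comparator thresholds. With two bins — BIN1 = [*Ea*, *Eb*) and
BIN2 = [*Eb*, *Ec*) keV — the attenuation measured per bin yields a
thickness-independent index that identifies the effective atomic number of
the absorber, the quantity behind soft-tissue/bone discrimination (*Z* ≈ 6.5
for PMMA, 13 for Al). The threshold *Eb* controls how the photons are shared
between the bins and hence the statistical uncertainty σ(Z) of the estimate.
`pcthresh` simulates the full chain — filtered tungsten-anode spectra,
Beer–Lambert transmission, per-channel Poisson counting noise, the
three-step estimation algorithm, and first-order error propagation — and
sweeps *Eb* at 1 keV resolution over tube voltages 50–120 kV to locate the
minimum-uncertainty threshold per voltage.

The estimator, per bin *b*:

* attenuation factor: μ′<sub>b</sub>t = ln(C<sub>b</sub>/C′<sub>b</sub>)
  (air counts over object counts);
* beam-hardening correction: invert the pre-computed polychromatic curve
  μ′t(ρt) at the measurement, then μ<sub>b</sub>t =
  (μ/ρ)(E<sub>eff,b</sub>) · ρt;
* calibration inversion: X = μ₂t/μ₁t → Z via the monotone X–Z relation
  tabulated over elements Z = 4–20.

Uncertainty: σ(C) = √C propagated by the delta method through the chain to
σ(Z), cross-checked by seeded Monte-Carlo repetition of the noisy pipeline.

Intended for medical-physics simulation work: threshold selection studies,
counting-statistics budgets, and as a reference implementation of the
two-bin effective-Z algorithm. All user-facing results are tibbles; sweep
objects have `tidy()`/`glance()`/`autoplot()` methods.

## Worked example

```r
library(pcthresh)

# one condition: 60 kV, threshold 35 keV, 80 mm PMMA, noise-free
estimate_condition(60, 35, "pmma", 80)
#>   z = 6.467,  x = 0.6294          # vs. nominal Z = 6.5

# the same condition with Poisson noise at 1e5 incident photons,
# five Monte-Carlo repeats (seeded)
mc_summary(60, 35, "pmma", 80, n_total = 1e5, master_seed = 1)
#>   z_mean = 6.42,  z_sd = 0.069

# the full study grid at 1e5 counts
sw <- run_sweep(sweep_config(n_totals = 1e5))
threshold_summary(sw)
#>   tube_voltage_kv optimal_e_b sigma_min   (max-rule combination)
#>                50          31     0.695
#>                60          34     0.601
#>                70          36     0.502
#>                80          37     0.498
#>                90          38     0.490
#>               100          38     0.482
#>               110          38     0.475
#>               120          38     0.471
threshold_range(sw)
#>   min max
#>    31  38
```

Reading: the noise-free pipeline recovers the nominal *Z* at any threshold,
but with counting noise the uncertainty has a clear interior minimum per
voltage. With the default spectrum model the minimum-uncertainty thresholds
span 31–38 keV over 50–120 kV, and at those thresholds σ(Z) stays below 0.7
at 10⁵ incident photons for the full PMMA-to-Al range — so a detector
threshold placed in the low 30s keV is statistically efficient across the
whole diagnostic voltage range.

A thin CLI wraps the same functions:

```sh
inst/exec/pcthresh sweep --kv 50,80,120 --n-totals 1e5 --seed 1 --out results/
inst/exec/pcthresh estimate --kv 60 --eb 35 --material pmma --thickness 80
inst/exec/pcthresh curves --kv 60 --eb 35 --material al --out curves.json
```

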