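# mesosaxs

Quantitative analysis of lyotropic liquid-crystalline nanoparticles
(hexosomes and cubosomes) used as drug nanocarriers, for scattering and
formulation scientists. The package implements, end to end:

* a **composite SAXS model** `I(q) = I1 + I2 + I3 + I4`: a one-level
  Guinier–Porod term for the overall particle (`G exp(-q²Rg²/3)` /
  `D q^-d`), a two-level Guinier–Porod cylinder term for the internal water
  channels, Lorentzian lattice peaks, and a flat background — with all
  crossovers and dependent scales fixed by value/slope continuity
  (`q1 = √(3d/2)/Rg`, `q2 = [(2/3)Rg2² − Rg1²]^-1/2`,
  `G2 = (G1/q2)e^{1/2}`, …), multistart weighted least-squares fitting, and
  derived metrics `Dsphere = 2√(5/3)·Rg`, `Rc = √2·Rg1`,
  `L = √(12Rg2² − 6Rc²)`, `d = 2π/q`, `a_hex = 4π/(√3·q100)`,
  `l_c = 2π/σ`;
* **mesophase indexing** of Bragg-peak positions against hexagonal HII
  (1:√3:2), cubic Pn3m/Im3m/Ia3d (√N ratios) and lamellar tables, with
  lattice constants and temperature-series phase-transition detection;
* **formulation assays**: CAC from the log-log breakpoint of a
  light-scattering dilution series, linear calibration + inversion,
  encapsulation efficiency (EE% = 100·measured/total), and cumulative
  release with the withdraw-and-replace dialysis correction;
* **image metrics**: lattice row spacing from the windowed 2D power
  spectrum, gray-profile light/dark segmentation, and the planar→spatial
  2/√3 correction;
* **seeded synthetic-data generators** for all of the above, including
  presets that reproduce the published unloaded / LEF / LEF G structural
  parameters by construction.

## Worked example

Generate a noiseless curve from the unloaded preset, fit it blind, and read
off the structure:

```r
library(mesosaxs)

truth <- saxs_preset("unloaded")
curve <- synth_saxs_curve(truth, noise = noise_spec(level = 0))
fit   <- fit_composite(curve, initialize_model(curve), opts = list(seed = 1))
derived_metrics(fit$model)
#> <structural_report>
#>   Rg       20 nm
#>   Dsphere  51.64 nm
#>   Rc       1.27 nm
#>   L        20.3 nm
#>   peaks:
#>   q_max d_spacing a_hex l_c
#>  0.9398     6.686  7.72  67
#>  1.1301     5.560  6.42  67
```

The fit recovers the generator: an overall radius of gyration of 20 nm
(scatter-equivalent sphere diameter 51.6 nm), internal cylinders of radius
1.27 nm and length 20.3 nm, and two lattice peaks whose (100)-equivalent
constants are 6.42 and 7.72 nm with 67 nm correlation lengths.

Index measured peak positions (nm⁻¹) and locate a thermotropic transition:

```r
index_peaks(c(1.140, 1.974, 2.280))[[1]]
#> <phase_assignment> hexagonal_HII: 3 matched, score 0.000157, a = 6.364 nm
#>  q_obs index q_expected    rel_dev d_spacing
#>  1.140   100      1.140  0.0000000     5.512
#>  1.974   110      1.975 -0.0002724     3.183
#>  2.280   200      2.280  0.0000000     2.756
```

`bragg_spacing(1.140)` gives the 5.511 nm d-spacing of that first peak, and
`fit_cac(synth_cac_series(noise_level = 0))` returns the generator's
2.1e-4 M breakpoint exactly.

There is also a CLI (`inst/exec/mesosaxs`) with `fit`, `index`,
`transitions`, `cac`, `ee`, `release`, `image` and `synth` subcommands; every
run writes a JSON report embedding the resolved configuration and seed.

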