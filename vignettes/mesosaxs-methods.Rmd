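---
title: "Models and methods in mesosaxs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in mesosaxs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesosaxs)
```

# The scientific problem

Lyotropic liquid-crystalline nanoparticles — hexosomes (internal inverse
hexagonal H~II~ phase) and cubosomes (bicontinuous cubic phases such as Pn3m)
— are drug carriers whose internal order is characterised mainly by
small-angle X-ray scattering (SAXS), supported by cryo-TEM image analysis and
standard formulation assays (critical aggregation concentration,
encapsulation efficiency, in-vitro release). `mesosaxs` packages that entire
quantitative workflow: a composite scattering model with constrained fitting
and derived structural metrics, mesophase peak indexing, the assay
calculations, spectral spacing estimation for micrograph-like images, and
seeded generators that synthesise every input the pipeline consumes.

# The composite scattering model

The measured intensity is modelled as

$$I(q) = I_1(q) + I_2(q) + I_3(q) + I_4,$$

with $q$ in nm^-1^ throughout (Å^-1^ accepted on input and multiplied by 10).

**Overall particle, $I_1$** — a one-level Guinier–Porod term:
$G\exp(-q^2R_g^2/3)$ for $q \le q_1$ and $Dq^{-d}$ above. Continuity of value
and slope at the crossover fixes $q_1 = \sqrt{3d/2}/R_g$ and
$D = G e^{-d/2}(3d/2)^{d/2} R_g^{-d}$; neither is a free parameter. $R_g$ is
the overall radius of gyration and $d$ the Porod exponent ($d = 4$: sharp,
smooth interface).

**Internal cylinders, $I_2$** — a two-level Guinier–Porod term with an
overall-Guinier, a rod ($\propto q^{-1}\exp(-q^2R_{g1}^2/2)$), and a Porod
regime. The low crossover is $q_2 = [(2/3)R_{g2}^2 - R_{g1}^2]^{-1/2}$, which
makes the rod-to-Guinier continuity exponent identically $1/2$, so
$G_2 = (G_1/q_2)e^{1/2}$. The rod-to-Porod crossover follows from value and
slope continuity: $q_1 = \sqrt{d-1}/R_{g1}$,
$D = G_1 q_1^{d-1} e^{-(d-1)/2}$. These closed forms were re-derived here
because the published rendering of the dependent-scale equation is corrupt;
the reconstruction is validated two ways: an independent brute-force oracle
(numeric root-finding of the continuity conditions) agrees to 1e-10 relative,
and the published derived values ($R_c$, $L$, lattice constants) round-trip
exactly.

**Lattice peaks, $I_3$** — Lorentzian (Cauchy) profiles
$k\sigma/[\pi(\sigma^2 + (q - q_{max})^2)]$, area-normalised so $k$ is the
integrated peak weight. $\sigma$ is interpreted as the half-width at
half-maximum, the reading under which the correlation lengths
$l_c = 2\pi/\sigma$ reproduce the published 33–67 nm range.

**Background, $I_4$** — a flat constant.

Derived metrics: $D_{sphere} = 2\sqrt{5/3}R_g$, $R_c = \sqrt2 R_{g1}$,
$L = \sqrt{12R_{g2}^2 - 6R_c^2}$, per-peak $d = 2\pi/q_{max}$,
$a_{hex} = 4\pi/(\sqrt3 q_{max})$ and $l_c = 2\pi/\sigma$. The `a_hex` column
assumes the peak is the hexagonal (100) reflection; any other indexing must
go through the phase-assignment machinery. One published sphere diameter
(68.6 nm for $R_g$ = 26.6 nm) disagrees with the closed form in the last
digit (2√(5/3)·26.6 = 68.68); checks therefore accept one unit of the last
printed digit.

```{r}
m <- saxs_preset("unloaded")
derived_metrics(m)
```

# Fitting

The published analysis this pipeline emulates does not document an
optimizer, weighting, or fitting range, so those were design choices:

* **Objective.** Weighted least squares over the full q range jointly.
  Weights are $1/\sigma_i^2$ when the curve carries uncertainties; otherwise
  Poisson-like $1/\max(I_i, \varepsilon)^2$ with
  $\varepsilon = 10^{-12}\max I$, which equalises the leverage of the five
  intensity decades. An uncertainty column that is only the generator's
  epsilon floor is treated as absent.
* **Parameterisation.** Scales and radii are fitted on the log scale
  (positivity by construction); $R_{g2}$ is represented as
  $\sqrt{1.5R_{g1}^2 + e^u}$ so the $q_2$-real invariant can never be
  violated; the continuity-derived scales ($q_1$, $q_2$, $D$, $G_2$) are
  computed, not penalised. Peak positions are box-bounded to the observed q
  range. The Porod exponent is fixed at $d = 4$ by default (shared between
  $I_1$ and $I_2$; `fix_d = FALSE` frees it in [1.5, 4]).
* **Optimizer.** `stats::nlminb` with a numeric gradient, 8 jittered
  restarts from the data-driven initialisation (seeded, so runs are
  bit-reproducible). The composite is genuinely multimodal — on noiseless
  unloaded-preset data single starts reliably stop in a local basin with
  $R_{g2}$ inflated ~2.4x, while the 8-start default reaches the global
  optimum to machine precision — hence multistart is not optional polish.
* **Initialisation.** $R_g$ from an iteratively restricted Guinier fit
  ($qR_g \lesssim 1.3$); background from the 5th percentile of the top q
  decade; peaks from prominence-screened local maxima of a running-median
  detrended curve; cylinder seeds $R_{g2} = R_g/3$, $R_{g1} = 1$ nm.
* **Uncertainties.** Gauss–Newton standard errors from the numeric Jacobian
  at the optimum, delta-method mapped to natural parameters;
  $\chi^2/\mathrm{dof}$ reported alongside.

# Phase indexing

Peak-position ratios identify the mesophase: H~II~ at $1:\sqrt3:2$, Pn3m at
$\sqrt2:\sqrt3:\sqrt4:\sqrt6:\ldots$, plus Im3m, Ia3d and lamellar tables.
The first observed peak is anchored to each allowed reflection in turn,
remaining reflections are matched greedily within a 2% relative tolerance
(missing weak reflections are allowed — the published higher-order hexagonal
peaks are "very small"), and hypotheses are ranked by matches, then by a
parsimony penalty (predicted reflections inside the observed span that went
unmatched), then by RMS deviation. The parsimony term matters: hexagonal
$1:\sqrt3:2$ is exactly the Pn3m subset $\sqrt2:\sqrt6:\sqrt8$, and some
cubic-cubic subset coincidences (Pn3m $\sqrt2:\sqrt3:\sqrt4$ vs Im3m
$\sqrt4:\sqrt6:\sqrt8$) are strictly unresolvable from positions alone; the
ranked list, not a single label, is the honest output, and coexisting phases
(the unloaded sample's two lattice constants) are reported, not adjudicated.

Lattice constants use the anchored first reflection by default
(deterministic for single-strong-peak data); a least-squares mode over all
matched reflections is available. Temperature series are assigned
per-temperature and a transition is reported at the first temperature whose
phase differs from the previous assignable one; unassignable points are
skipped rather than treated as transitions.

# Assays

**CAC.** In log-log space the dilution series is a horizontal line (solvent
scattering) followed by a positive-slope line (aggregate scattering). Every
interior split with ≥ 2 points per side is scored by least squares and the
CAC is the intersection of the two winning lines — the graphical
intersection method, made deterministic. Noiseless two-regime series are
recovered exactly; slopes below 1e-6 are treated as numerically zero so flat
series raise a no-aggregation error instead of returning an edge breakpoint.

**EE%.** Defined as 100·measured/total (the cited supplementary equation is
not available; this is the standard reading consistent with quantifying drug
retained in the dialysis tube). Both amounts are explicit inputs since the
choice of denominator (nominal vs recovered total) is an upstream decision.

**Release.** The withdraw-and-replace dialysis correction:
$M_n = C_nV_{medium} + \sum_{i<n} C_iV_{aliquot}$, fraction
$= 100M_n/M_{loaded}$, with a mass-balance error beyond 100% + tolerance.
The generator samples a first-order profile ($k$ = 0.1 h^-1^, 45 mL medium,
1 mL aliquots, 300 µg load) through the same bookkeeping, and reconstruction
agrees to < 1% at every timepoint.

# Image metrics

Row spacing comes from the Hann-windowed 2D power spectrum: the strongest
bin outside a 3-bin DC guard gives the spatial frequency, and one frequency
bin maps to the quoted uncertainty. Rotating the lattice moves the spots
around a ring of constant radius, so the estimate is orientation-free. Gray
profiles are thresholded at a user-supplied (default: median, logged)
background level; interior above/below runs give the light/dark subdivision
lengths and their paired sums the period. The projected row spacing converts
to the 3D tube-to-tube distance by $2/\sqrt3 \approx 1.155$. No binary image
formats are read — the R environment here ships no TIFF/PNG reader — so
images enter as matrices or plain-text grids; only synthetic images are in
the validated surface.

# Synthetic data: the stated world

The three presets pin every parameter the published analysis prints:

| preset | $R_g$ | $R_c$ | $L$ | $a_1$ | $l_c$ | extra |
|---|---|---|---|---|---|---|
| unloaded | 20.0 | 1.27 | 20.3 | 6.42 | 67 | second peak at $a_2$ = 7.72 |
| LEF | 26.6 | 1.09 | 20.6 | 6.48 | 33 | |
| LEF_G | 30.3 | 1.13 | 18.7 | 6.48 | 65 | |

Shape parameters are back-computed ($R_{g1} = R_c/\sqrt2$,
$R_{g2} = \sqrt{(L^2+6R_c^2)/12}$, $q = 4\pi/(\sqrt3 a)$,
$\sigma = 2\pi/l_c$), so `derived_metrics()` reproduces the table by
construction — that check is the packaged link between the published numbers
and the test suite. Values the publication does not constrain were fixed
once: $G = 1$, $G_1 = 0.01$, background $10^{-4}$ (arbitrary intensity
units), primary-peak contrast 10x the local continuum (a "very sharp" first
peak), and for the unloaded sample's unresolved second peak a contrast of 5
and the same correlation length as the primary (67 nm) — the second peak is
clearly resolved in the published curve, and a broader choice would merge
the two peaks into one bump, which is not what the data show. Default noise
is 1% multiplicative Gaussian; a `poisson_like` mode scales the SD with
$\sqrt I$ for counting realism. The default q grid is the Kratky camera's
0.074–1.70 nm^-1^ with 400 log-spaced points.

What the generators do *not* emulate: slit smearing, instrumental
resolution, polydispersity, beamstop artifacts, or real-micrograph texture.
A green round-trip therefore establishes correctness of the estimators under
the model's own assumptions — not instrument-grade validation.

# Numerical choices and limitations

* Unit heuristic: header regex first, else max(q) < 0.5 implies Å^-1^;
  always logged and overridable.
* Peak-matching tolerance 2% relative; indexing tie-breaks documented above.
* Lorentzian tails are heavy: ±50σ holds only 98.7% of the area; area
  checks integrate ±200σ.
* Fit budget: 8 restarts × `nlminb` with numeric gradients; a 400-point
  two-peak fit takes a few seconds on one CPU.
* Per-curve fitting only — no global multi-curve or temperature-coupled
  models; no Bayesian uncertainty; no absolute-intensity calibration.
* The published analysis of its own raw curves cannot be reproduced (the
  curves are not deposited); parameter-recovery claims are therefore made on
  the synthetic presets above.
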