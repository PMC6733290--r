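---
title: "Methods: mobility and structure analysis of lyophilised protein formulations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mobility and structure analysis of lyophilised protein formulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lyoglass)
```

`lyoglass` analyses the spectroscopic measurements used to characterise
freeze-dried (lyophilised) protein–excipient glasses: variable-temperature
terahertz time-domain spectroscopy (THz-TDS) for molecular mobility, FTIR
amide-I deconvolution and far-UV circular dichroism for secondary
structure, and solid-state NMR relaxation for protein–sugar phase
homogeneity. This vignette explains the models behind each stage, the
tunable parameters and their defaults, what the synthetic-data generator
does and does not emulate, and the numerical design choices.

## Terahertz optical constants

A terahertz transmission measurement yields a reference waveform (empty
cell) and a sample waveform (pellet of thickness $d$). In the frequency
domain their ratio is the transfer function of a plane dielectric slab.
Neglecting etalon (Fabry–Pérot) reflections,

$$H(\omega) = \frac{4n}{(n+1)^2}\, e^{-\alpha d / 2}\,
  e^{-i \omega (n - 1) d / c},$$

where $n(\omega)$ is the refractive index and $\alpha(\omega)$ the power
absorption coefficient in cm$^{-1}$ (the field decays as $\alpha/2$).
`thz_extract_constants()` inverts this in closed form:
$n = 1 + c\,|\phi|/(\omega d)$ from the unwrapped phase and
$\alpha = -(2/d)\,\ln\!\big[|H|(n+1)^2/(4n)\big]$ from the magnitude.

Assumptions and numerical choices:

* **Etalon terms are neglected** in both the forward model
  (`simulate_thz_pair()`) and the inversion. For pellets of 300–700 µm the
  first echo is well separated from the main pulse, and the temperature
  analysis uses only the relative change of $\alpha$ at the probe
  frequency, so the omission is common-mode. The quartz sample windows are
  likewise treated as common-mode and cancelled by the reference.
* **Phase unwrapping and anchoring.** The one-sided phase is unwrapped
  along frequency, a line is fitted over 0.2–0.8 THz, and the whole phase
  is shifted by the integer multiple of $2\pi$ nearest the extrapolated
  zero-frequency intercept. This fixes the unwrapping ambiguity without
  touching the phase slope that carries $n$.
* **Probe evaluation.** `thz_absorption_at()` averages $\alpha$ over
  ±0.05 THz (configurable) around the 1 THz probe instead of reading a
  single bin, which makes the result insensitive to bin placement; below
  three usable bins it falls back to the nearest bin.
* Bins where the reference magnitude falls below 1% of its peak, or where
  $|H|$ would imply $\alpha < 0$ or $n < 1$, are masked as unusable
  rather than raising errors.

The reference pulse in the generator is a Gaussian-derivative single-cycle
pulse (width 0.15 ps), giving usable signal over roughly 0.2–2.5 THz. On
noiseless synthetic slabs the forward/inverse round trip recovers $n$ and
$\alpha$ to well under 1% across 0.3–2.0 THz, which the test suite checks
over a 3×3 grid of $(n, \alpha)$.

## Three-region transition analysis

In amorphous molecular solids the absorption coefficient at 1 THz grows
roughly linearly with temperature, with slope changes at two
characteristic temperatures: the lower transition $T_{g,\beta}$
(onset of local, Johari–Goldstein-type mobility) and the glass transition
$T_{g,\alpha}$ (cooperative, large-scale mobility). `fit_three_regions()`
fits

* three independent straight lines to three contiguous temperature
  regions, chosen by **exhaustive search** over all ordered breakpoint
  pairs with at least `min_pts = 3` points per region, minimising the
  total (weighted) sum of squared errors;
* ties are broken towards the most balanced segmentation, making the
  degenerate single-line case deterministic;
* weighted least squares (weights $1/\mathrm{SD}^2$) is used when
  replicate standard deviations are present, ordinary least squares
  otherwise; the choice is recorded in the result.

The transition temperatures are the **intersections of adjacent fitted
lines**, not the breakpoint grid positions: $T_{g,\beta}$ from regions 1
and 2, $T_{g,\alpha}$ from regions 2 and 3. Near-parallel lines (relative
slope difference below $10^{-8}$) raise a dedicated condition, and the
orchestrated fit reports `NA` for that intersection.

The exhaustive search is the design answer to an open procedural question:
published three-region analyses typically delimit the regions by eye. A
least-squares scan is deterministic and reproducible, and coincides with
the visual segmentation whenever the regions are distinct.

**Confinement classification.** Above $T_{g,\alpha}$ the slope either
keeps increasing (ordinary supercooled-liquid behaviour) or collapses to a
plateau, read as confinement of the protein's mobility in its matrix.
`classify_mobility()` calls "confined" iff $m_3 < m_2$ (ratio threshold
configurable) *and* the decrease exceeds the combined standard error
$\sqrt{SE_2^2 + SE_3^2}$ — the statistical support requirement prevents
confinement calls on slope differences within noise.

*Known limitation:* the classifier sees only the fitted slopes and their
uncertainties. Two formulations with numerically identical $(m_2, m_3)$
necessarily receive the same call, even if other evidence (e.g. the raw
curves or replicate scatter) suggests different physical behaviour. Any
slope-based rule shares this limit; the per-formulation fits and plots are
exposed so such cases can be inspected.

**Cycle comparison.** `compare_cycles()` fits two heating cycles
independently and flags hysteresis when the mobility classes differ or the
region-3 slope changes by more than $z = 2$ combined standard errors —
the signature of a sample that is confined on first heating but follows a
different trajectory after quench cooling.

## FTIR secondary structure

The chain in `ftir_secondary_structure()` follows the standard amide-I
protocol: scaled excipient subtraction, total-area normalisation,
Savitzky–Golay (SG) second derivative, ten-Gaussian band fit, class
assignment by band centre, and area-ratio fractions.

* **Excipient subtraction** scales the pure-excipient spectrum by the
  ratio of baseline-corrected peak heights at the 851 cm$^{-1}$ excipient
  marker band (search window ±5 cm$^{-1}$, local linear baseline). A
  missing anchor band in the excipient spectrum is an error; a missing
  peak in the sample simply gives scale 0.
* **Amide-I window.** 1600–1700 cm$^{-1}$, the standard definition. The
  window is a configuration value because narrower conventions exist in
  the literature.
* **Second derivative.** SG filter spanning 14 cm$^{-1}$ (15 points at
  1 cm$^{-1}$ resolution), polynomial order 3. Edges where the window is
  unsupported are truncated.
* **Band fit.** The trace is modelled as a sum of ten Gaussian absorbance
  components *passed through the same SG second-derivative filter as the
  data*. Using filter-matched profiles instead of analytic second
  derivatives matters: the SG filter broadens the trace, and fitting
  unfiltered profiles biases widths and therefore areas (area
  $= A\,w\sqrt{2\pi}$ amplifies width errors). With matched profiles the
  forward model is exact for Gaussian bands and noiseless synthetic
  mixtures are recovered to machine precision.
* **Initialisation.** Initial centres come from the positive maxima of
  the SG *fourth* derivative of the absorbance spectrum (parabolic
  sub-grid interpolation), a classical band-finding device that resolves
  overlapping components considerably better than second-derivative
  minima. Without an absorbance spectrum the fit falls back to the k
  deepest second-derivative minima, padded with evenly spaced centres.
* **Optimisation.** Two-stage variable projection: amplitudes are solved
  linearly inside the residual; widths are refined first with centres
  pinned, then centres and widths together (Levenberg–Marquardt with box
  constraints); final amplitudes by non-negative least squares. A short
  ladder of initial widths (3.5, 2.6, 5, 8 cm$^{-1}$) guards against
  occasional local minima.
* **Width bounds.** $\sigma \in [2, 12]$ cm$^{-1}$ (≈5–28 cm$^{-1}$
  FWHM), the physical range of amide-I component bands. Allowing much
  broader components creates a near-null-space — bands almost invisible
  in the second derivative but huge in absorbance area — that makes the
  area decomposition ill-posed.
* **Class boundaries.** Sheet ≤ 1640.5 < random < 1645.5 ≤ helix ≤
  1664.5 < turn ≤ 1680.5 < sheet ≤ 1700 (half-integer boundaries so
  integer-grid bands never sit on an edge). This respects the canonical
  anchors: 1658 helix, ~1640 sheet main band, ~1670 turn, ~1690 sheet
  shoulder. The table is an argument of `ftir_assign_bands()` and can be
  overridden.

Fractions are class areas over the total fitted area, in percent; they sum
to 100 over assigned classes, and the whole chain is invariant under
positive scaling of the input spectrum.

## Circular dichroism

`cd_mean_residue_ellipticity()` implements
$[\theta](\lambda) = \theta_{obs}(\lambda) / (l\,c\,n)$ with the path
length $l$ in **millimetres**, $c$ the molar protein concentration and $n$
the residue count (583 for BSA, 1330 for the IgG1 antibody). The
millimetre convention embeds the conventional factor of ten relative to
centimetre-based formulas, so the normalisation constants are recorded on
the result to avoid silent unit misuse. Blank (water) subtraction is exact
pointwise on a common grid; accumulation averaging is a pointwise mean
with SD and no outlier rejection.

`cd_classify()` reads the gross signature: helix-rich spectra show the
double minimum at 222 and 208 nm with a positive band at 193 nm;
sheet-rich spectra a single broad negative band near 218 nm; anything else
is indeterminate. The call is invariant under positive scaling, so it can
be applied before or after the mean-residue normalisation. No quantitative
CD basis-set deconvolution is attempted.

## NMR relaxation and phase homogeneity

Magnetisation series integrated over the protein carbonyl region
(165–185 ppm) and the sugar alcohol/anomeric region (67–102 ppm) are
fitted to

$$M(t) = M_0\,(1 - 2 A e^{-t/T_1}) \qquad
  M(t_{SL}) = M_0\, e^{-t_{SL}/T_{1\rho}}$$

by bounded Levenberg–Marquardt least squares. For the inversion-recovery
fit, $A$ is a **free** correction factor bounded in $(0, 1.2]$ (ideal
inversion gives $A = 1$; the bound is configurable); whether such fits
traditionally fix $A$ is ambiguous, so floating it with a bound is the
disclosed default. Initialisation uses the zero-crossing of the recovery
curve ($T_1 = t_0/\ln 2$, falling back to the median delay) and, for the
spin-lock decay, a log-linear regression when all points are positive.
Standard errors come from the fit covariance; noiseless self-generated
data are recovered with zero residual across a grid of parameter
combinations.

`nmr_phase_homogeneity()` compares protein and sugar relaxation times:
equal times (within $z = 2$ combined standard errors) indicate a
homogeneous mixed phase at the length scale probed by the experiment —
20–50 nm for $T_1$, 2–5 nm for $T_{1\rho}$ — while significantly
different times imply phase separation. `nmr_compare_heating()` applies
the same significance rule to before/after-heating pairs, so a drop in
$T_{1\rho}$ with unchanged $T_1$ (a few-nanometre mobility change) is
isolated explicitly. The default delay grids are the eight-point
experimental grids (0.01–5 s for $T_1$, 0.1–50 ms for $T_{1\rho}$).

## The synthetic-data generator

Because no raw instrument data accompany the study design, every input
modality has a generator with known ground truth:

* `simulate_temperature_series()` draws from a **continuous** three-region
  piecewise-linear model plus white Gaussian noise. Continuity is imposed
  so that line intersections coincide exactly with the generating
  breakpoints, which makes transition-temperature recovery well defined;
  the fit itself never assumes continuity. The default grid is a 10 K
  ramp over 100–380 K, the typical increment of variable-temperature
  terahertz experiments; the published per-formulation parameters are
  available via `reference_transition_params()`.
* `simulate_thz_pair()` is the slab forward model described above —
  deliberately sharing the etalon-free approximation with the inversion,
  so the pair forms a closed oracle.
* `simulate_ftir()` sums Gaussian bands plus optional excipient bands
  (one anchored at 851 cm$^{-1}$) and noise. The default ten-band amide-I
  template (`amide_band_template()`) places components ~9 cm$^{-1}$ apart
  with $\sigma = 3.2$ cm$^{-1}$; the spacing was chosen from the measured
  resolution limit of the 14 cm$^{-1}$ SG second derivative so that every
  component is resolvable — the premise of the deconvolution method. The
  main sheet band sits at 1636.5 cm$^{-1}$, the closest resolvable
  position to the ~1640 cm$^{-1}$ anchor given the adjacent random-coil
  interval; the helix pair straddles 1658 cm$^{-1}$ and the sheet
  shoulders sit near 1671.5 and 1689 cm$^{-1}$.
* `simulate_relaxation()` evaluates the two relaxation models exactly on
  the experimental delay grids plus noise.
* `simulate_cd()` mixes parameterised basis curves with the canonical
  helix, sheet, turn and random-coil signatures over 190–250 nm at 0.5 nm
  steps.

All noise is additive white Gaussian; heteroscedastic noise, baseline
drift, water-vapour lines, detector response and etalon echoes are *not*
emulated. Seeds are explicit arguments everywhere, outputs are
bit-reproducible for a fixed seed, and the caller's RNG state is never
touched. Passing tests on these fixtures therefore demonstrates
correctness of the algorithms under the stated models, not robustness to
every artefact of real instrument data (sloping baselines and non-Gaussian
band shapes being the most important omissions for the FTIR chain).

## Orchestration

`run_formulation()` applies the strict residual-moisture gate
(< 2.5% w/w; failing or unknown records are analysed but flagged), runs
every stage for which inputs are present, records per-stage errors without
aborting the run, and returns a JSON-serialisable report
(`report_to_json()` / `report_from_json()` round-trip losslessly).
`summarise_study()` assembles the cross-formulation table of slopes,
transitions, mobility class and QC status. All analysis constants live in
`lyoglass_config()` with the defaults above.

## Problem sizes in the test suite

The suite runs on one CPU in a few minutes: temperature fits use 29–141
point grids; Monte-Carlo checks use 20–50 seeds for breakpoint and band
recovery and 200 seeds for the relaxation estimators; terahertz waveforms
are 1401 samples at 0.05 ps. These sizes were chosen so each statistical
check has enough replication to be stable while the whole suite stays
fast.
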