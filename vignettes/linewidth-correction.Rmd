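---
title: "Linewidth-based correction of CPMG NMR metabolite concentrations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linewidth-based correction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CPMGcorrect)
```

## The physical model

A CPMG echo train of total duration $T$ attenuates transverse
magnetization by $\exp(-T/T_2)$. Free small molecules have long $T_2$ and
survive; protein protons do not, which is why CPMG spectra of plasma show
clean metabolite signals. A metabolite that spends a fraction $f$ of its
time bound to protein, exchanging fast on the NMR timescale, shows a
single population-averaged resonance with

$$\Gamma_{obs} = (1-f)\,\Gamma_{free} + f\,\Gamma_{bound},
\qquad \Gamma = \mathrm{FWHM} = \frac{1}{\pi T_2},$$

so the *excess* linewidth $\Delta\Gamma = \Gamma_{obs} - \Gamma_{free}$
is proportional to the bound fraction, and the same exchange-averaged
relaxation that broadens the line attenuates it during the echo train.
Measuring each signal's broadening in each sample therefore predicts that
signal's loss, without any additional experiment.

The correction is a linear calibration between the signal-loss factor
(area without protein over area with protein) and the broadening:

$$C_b = 0.567\,L_{sMb} + 0.9984,$$

with $L_{sMb}$ in Hz. `publishedCalibration()` ships these coefficients;
`fitCalibration()` refits them from any titration. The total
concentration is the CPMG-measured free concentration times $C_b$.

Two practical layers make $L_{sMb}$ measurable:

* **Shim correction.** Field inhomogeneity broadens every line equally.
  A non-binding reference (formic acid) calibrates it per sample:
  $S_c = L_{sF} - L_{oF}$ is subtracted from every metabolite linewidth.
  Because the offset is common, it cancels exactly in the correction
  chain — a property the test suite asserts to $10^{-9}$.
* **Reference linewidths.** $L_{oM}$ and $L_{oF}$ are measured once on an
  optimally shimmed, protein-free sample and stored in a signal library
  (`readSignalLibrary()`; the packaged CSV carries the documented TSP
  0.78 Hz and formate 0.70 Hz values plus synthetic placeholder rows that
  users should replace with values from their own instrument).

### Assumptions, and what happens when they fail

* *Fast exchange* is assumed, never checked; intermediate exchange would
  distort lineshapes beyond the population-average model.
* *Fixed state linewidths*: inherently flexible compounds (branched-chain
  amino acids) relax more slowly in the bound state than a rigid-limit
  picture suggests, deflating the measured broadening.
* *Linearity*: the loss is exponential in the excess relaxation rate; the
  linear calibration is its initial, small-broadening regime. The
  published intercept (0.9984, slightly below the physical limit of 1) is
  an artifact of that linear fit and is honored verbatim. The
  `floor_factor_at_one` switch (default off) exposes the alternative
  convention of flooring factors at 1.
* *Temperature*: reference linewidths are temperature-dependent.
  `quantifySpectrum()` warns when a spectrum's acquisition temperature
  differs from 298 K rather than attempting any transfer correction.

## Measurement layer

* **Baseline**: polynomial fitted to the outermost 10% of points on each
  edge of the analysis window (edges of an isolated-signal window are
  signal-free by construction), any small order; order 1 default.
* **Direct FWHM** (`measureFwhmDirect()`): apex refined by a three-point
  parabola, half-height crossings by linear interpolation between
  bracketing samples — deterministic, lineshape-agnostic, and accurate to
  well under 1% at ≥ 8 points per FWHM, which is also the hard floor the
  function enforces.
* **Deconvolution** (`deconvolve()`): Levenberg–Marquardt least squares
  (via `minpack.lm`) of a sum of Lorentzians, optional local linear
  baseline. Lorentzians are the correct family here: the 0.3 Hz
  exponential apodization applied during processing adds uniform
  Lorentzian broadening, preserving the shape. Bounds
  $\Gamma > 0.01$ Hz and area $> 0$; convergence at relative residual
  change $< 10^{-10}$ or 500 iterations; components whose centers land
  within $0.1\,\Gamma$ of each other are merged and the reduced model
  refitted once. Crowded regions are fitted jointly: `quantifySpectrum()`
  groups targets whose windows would overlap and deconvolves each group
  with one component per expected line, which is what keeps closely
  spaced aliphatic signals unbiased.
* **Multiplets**: no coupling model is fitted; the convention
  (`tallestComponent()`) is to take the linewidth of the tallest resolved
  component of the deconvolved multiplet. This is a documented
  convention, not a claim of correctness for strongly second-order
  patterns.
* **Integration**: trapezoidal, in intensity × Hz units; deconvolved
  areas are preferred for quantification because they capture the full
  Lorentzian tails regardless of window width.

Whether the processing line broadening is included in both reference and
sample linewidths is immaterial as long as it is applied identically: it
cancels in the $L_{sM} - L_{oM}$ difference, like the shim term.

## Quantification and LLOQ

Concentrations come from the per-proton area ratio against the internal
standard (formate, 1 proton, known concentration). The lower limit of
quantification is the lowest level of a dilution series whose replicate
RSD (sample SD over mean, $n-1$ denominator — replicate counts are small)
is below 20%. The default reading is literal ("lowest qualifying level",
even past a failing intermediate level); a stricter monotone mode is
available because non-monotone noise can make the literal rule
optimistic.

## The simulator

`simulateSpectrum()` renders a sample description into a spectrum by
composing exactly the physics above:

1. bound fraction from the exact 1:1 isotherm with ligand depletion
   (`boundFraction()`; a fixed-stoichiometry linear model was rejected
   because it breaks down when ligand and protein pools are comparable);
2. fast-exchange averaged linewidth (`observedFwhm()`);
3. exponential CPMG loss
   $\exp(T_{eff}\,\pi\,\Delta\Gamma)$ (`cpmgLossFactor()`);
4. Lorentzian rendering with area ∝ concentration × protons / loss, plus
   a uniform shim broadening on every signal (the internal standard
   included — exactly what shim correction assumes), a linear baseline,
   and seeded Gaussian noise. Same seed, same spectrum, bit for bit.

**The effective echo time.** The default $T_{eff} = 0.1805$ s makes the
small-broadening linearization $1 + T_{eff}\pi\Delta\Gamma$ reproduce the
published slope of 0.567/Hz; the physical 80 ms echo train (which would
give 0.251/Hz) is available by setting `effective_echo_time_s = 0.08`.
The slope is treated as empirical: the package does not attempt to
reconcile it with naive mono-exponential physics, and the simulator's
role is to be *consistent* with the published calibration in the regime
where that calibration is used.

**Working regime.** An ordinary least-squares line fitted to an
exponential over $[0, x_{max}]$ acquires an upward slope bias of roughly
$28\%\cdot x_{max}$ (in Hz), so "slope ≈ $T_{eff}\pi$" only holds for
narrow titrations, and linear-vs-exponential residuals grow quadratically
with the spanned broadening. The defaults therefore keep everything in
the small-broadening regime where the method's own linearity assumption
holds: the TSP titration (Kd 0.27 mM, bound linewidth 22 Hz, 6.025 mM
TSP, 14 albumin levels from 0 to 18 g/L) spans broadenings 0–0.91 Hz, and
the plasma-like validation mixture has correction factors 1.07–1.42
(broadenings ≤ 0.75 Hz) — the range typical plasma metabolites actually
show. Within that regime the linear calibration tracks the exponential
loss to within ~2%, which is what bounds the end-to-end recovery error.

**Fixture binding constants are synthetic.** Per-metabolite Kd values and
bound-state linewidths are not published quantities. The plasma-like
mixture (`plasmaMixture()`) back-computes each Kd from the 1:1 isotherm
so that, at 18 g/L albumin, each metabolite exhibits a prescribed,
realistic correction factor; bound linewidths sit a uniform 15 Hz above
the free ones. The fixtures reproduce the qualitative binding ranking
(aromatic ring compounds and TSP strong; glycine weak) without claiming
measured constants.

**What the simulator does not emulate** — and hence what passing tests do
not demonstrate about real data: J-coupled multiplet structure (signals
are singlet Lorentzians), macromolecular background humps, chemical-shift
drift with pH and ionic strength, binding competition between
metabolites, multi-site binding, intermediate exchange, and spectrometer
artifacts (phase error, baseline roll). The noise condition used in the
validation study — Gaussian noise with SD equal to 1% of the smallest
quantified peak's apex height — is the package's own definition of a
conservative high-signal-to-noise acquisition, consistent with
quantification being feasible for all fixture analytes.

## Numerical and interface choices

* Spectra store the axis high→low ppm (display convention); all windows
  are `(ppm_high, ppm_low)`, closed intervals, so point counts are
  deterministic.
* The `internal_record` dialect writes `%.17g`, so write/read round
  trips are bit-exact; `two_column_text` is the lossy interchange format
  (metadata falls back to 600 MHz / 298 K / 80 ms defaults).
* Negative broadenings clamp to zero with a diagnostic; negative shim
  corrections pass through (a sample can be better shimmed than the
  reference); a nonpositive shim-corrected linewidth is an error, because
  it indicates inconsistent measurements rather than noise.
* Report rounding (linewidths 2 dp, factors and concentrations 3 dp) is a
  display policy only; all internal arithmetic is full precision.
* Correction factors are computed per signal; aggregating across a
  metabolite's signals is left to the caller, since no aggregation rule
  is canonical.

## Problem sizes

The test suite and the acceptance script run the full pipeline at the
design sizes of the study: 14 titration spectra plus one reference and
two validation spectra on a 0.045 Hz/point grid over 8.7 to −0.3 ppm
(~120,000 points each), 16 metabolites plus TSP and formate. The whole
suite completes in well under a minute on a single core.

## Known limitations

Strongly binding metabolites may broaden beyond detection in highly
proteinaceous samples; overlapping signals limit linewidth accuracy even
with joint deconvolution; multiplet linewidths rely on the
tallest-component convention; and the linear calibration must not be
extrapolated far beyond the broadening range it was fitted on — the
quadratic divergence from the underlying exponential is the dominant
systematic error outside it.
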