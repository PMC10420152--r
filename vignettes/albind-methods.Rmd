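---
title: "Models and methods behind albind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind albind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(albind)
```

`albind` implements the complete spectroscopic inference chain used in
ligand–serum-albumin binding studies. This vignette is the package's own
account of the underlying models, the defaults it ships, the design of
its synthetic-data generators, and what its validation does and does not
establish about real instrument data.

## Fluorescence quenching

Serum albumin fluoresces around 337 nm when excited at 280 nm (its
tryptophan and tyrosine residues). A bound or colliding ligand quenches
that emission, and the concentration dependence of the peak ratio
carries the mechanism:

$$F_0/F = 1 + K_{sv}[Q] = 1 + K_q \tau_0 [Q]$$

* **Peak extraction.** All members of a titration are read at the *same*
  grid point — the emission maximum of the ligand-free spectrum
  (`quench_ratios()`). Reading each spectrum at its own maximum would
  conflate peak shifts (a microenvironment effect) with quenching.
  Lookup is nearest-grid-point with no interpolation: on the ≤ 1 nm
  grids of this field the quantisation is below analysis sensitivity and
  the result is exactly reproducible.
* **Inner-filter correction.** When the ligand absorbs at the excitation
  or emission wavelength, observed intensities are corrected as
  $F_{cor} = F_{obs}\,e^{(A_{ex}+A_{em})/2}$ (`ife_correct()`). The
  bracket placement follows the universal form of this correction: both
  absorbances attenuated over half the effective path.
* **Stern–Volmer fit.** OLS with a *free* intercept; $K_{sv}$ is the
  slope. Forcing the intercept to 1 would silently absorb inner-filter
  under-correction; instead an intercept deviating from 1 by more than
  5 % raises a data-quality warning. A negative fitted slope is reported
  with a flag, not an exception. Duplicate concentrations are averaged
  before fitting (equivalent for OLS, cleaner reporting).
* **Lifetime.** $\tau_0$ defaults to $10^{-8}$ s, the accepted order of
  magnitude for tryptophan in albumin, and is overridable. The identity
  $K_q = K_{sv}/\tau_0$ holds exactly in every result object.
* **Mechanism rule table** (`classify_mechanism()`): every
  $K_q > 2\times10^{10}$ L mol⁻¹ s⁻¹ (the diffusion-controlled limit)
  evidences a static component; $K_{sv}$ strictly increasing with
  temperature evidences a dynamic component; both together give
  `"mixed"`. With a single temperature only the $K_q$ magnitude is
  available and the verdict is flagged low-confidence.

## Binding constants

The static binding isotherm is fitted in double-logarithm form,

$$\log\frac{F_0-F}{F} = \log K_a + n \log[Q],$$

with base-10 logarithms (the conventional reading when the intercept is
an antilog) and $[Q]$ in mol L⁻¹, so $K_a$ is in M⁻¹. Points with
$[Q]=0$ or $F \ge F_0$ carry no signal for the left-hand side; they are
excluded and counted in the result. The fit is invariant to common
rescaling of all intensities.

A caution this package deliberately surfaces: $K_a$ is the intercept of
that line at $\log[Q] = 0$, i.e. at 1 M — typically 3–5 decades beyond
the measured concentrations. Small intensity errors therefore amplify
into large $K_a$ uncertainty (see *Validation*, below), while $n$ (the
slope) is robust. Fitted $n$ is reported as-is and never rounded to an
integer site count.

## Van't Hoff thermodynamics

`vant_hoff_fit()` regresses $\ln K_a$ on $1/T$:

$$\ln K = -\frac{\Delta H^0}{RT} + \frac{\Delta S^0}{R}, \qquad
  \Delta G^0 = \Delta H^0 - T\Delta S^0,$$

with $R = 8.314$ J mol⁻¹ K⁻¹. This assumes $\Delta H^0$ constant over
the (narrow, ~14 K) temperature range — the standard linear Van't Hoff
treatment; curvature from a nonzero $\Delta C_p$ is out of scope. A
two-point fit is an exact line and is flagged as such.

Binding forces are classified from the signs: both changes negative →
hydrogen bonding and van der Waals; both positive → hydrophobic;
enthalpy negative with entropy positive → electrostatic. The fourth
quadrant (endothermic, entropy-opposed) lies outside the conventional
rule table and is reported `"unclassified"` rather than guessed.

## Förster resonance energy transfer

The overlap of donor emission with acceptor absorption,

$$J = \frac{\sum F(\lambda)\,\varepsilon(\lambda)\,\lambda^4\,\Delta\lambda}
          {\sum F(\lambda)\,\Delta\lambda},$$

is evaluated with $\lambda$ in cm and $\varepsilon$ in L mol⁻¹ cm⁻¹, so
$J$ carries cm³ L mol⁻¹ — the only convention under which the
$8.8\times10^{-25}$ prefactor of $R_0^6 = 8.8\times10^{-25} K^2 N^{-4}
\varphi J$ is dimensionally standard. The acceptor spectrum is linearly
interpolated onto the donor grid (zero outside its support): the donor
emission defines the integration measure. The discrete weights are
composite-trapezoid, so the sum agrees with an independent trapezoid
oracle to rounding error. Defaults $K^2 = 2/3$ (isotropic dipoles),
$N = 1.336$, $\varphi = 0.118$ (tryptophan in albumin) are overridable.

Efficiency and distance are linked by
$E = 1 - F/F_0 = R_0^6/(R_0^6 + r^6)$; `transfer_efficiency()` and
`binding_distance()` are exact inverses. Distances under 8 nm set a
non-radiative-transfer flag. Because published critical distances are
not always reproducible from published overlap integrals (unit
conventions vary across papers), `fret_analysis()` accepts a
user-supplied $R_0$ and always reports the $J$-derived value alongside.

## Amide-I deconvolution

The amide-I band (1600–1700 cm⁻¹, backbone C=O stretch) is modelled as a
sum of Gaussian components (the band shape is a package choice; the
field uses Gaussian, Lorentzian or Voigt, and Gaussian keeps the
generator/analyser round trip well-posed). The procedure:

1. Linear baseline through the region endpoints, each anchor averaging a
   few edge points so endpoint noise cannot tilt the region.
2. Initial centers from minima of the second derivative of the
   Savitzky–Golay smoothed spectrum (quadratic local polynomial, window
   ~8 cm⁻¹; the derivative is taken on the smoothed signal). Minima
   where the smoothed intensity is below 1 % of the maximum, or whose
   curvature is below 3 % of the deepest minimum, are ignored;
   candidates closer than 4 cm⁻¹ merge into the deeper one.
3. Bounded Levenberg–Marquardt fit: each center may move at most
   5 cm⁻¹ from its seed, component widths are bounded to 2–8 cm⁻¹
   (s.d., ≈ 5–19 cm⁻¹ FWHM — the accepted range for amide-I
   components), areas are kept positive via a log transform. The bounds
   matter: heavily overlapped Gaussian sums admit degenerate
   one-wide-band solutions that the bounds exclude.
4. Shoulders too blended to produce their own derivative minimum are
   recovered by residual-driven addition: while the fit residual exceeds
   the estimated noise floor (from second differences of the signal), a
   band is seeded at the residual maximum — but kept only if its fit
   converges and improves the residual materially. Anything else (e.g.
   baseline wiggle) is rolled back.
5. Bands fitted outside 1600–1700 cm⁻¹ are dropped with a warning and
   the remainder refitted.

Fitted bands are assigned by center — β-sheet [1600, 1640), random coil
[1640, 1650), α-helix [1650, 1658), β-turn [1658, 1700] — left-closed
intervals so every center maps to exactly one class. The 1658–1660 nm
gap left between the conventional helix and turn ranges goes to β-turn,
and 1600–1610 joins β-sheet (low-wavenumber intermolecular sheet
components are standard there). Class fractions are class areas over
total area and always sum to 1.

`compare_structures()` reports per-class changes between a free and a
ligand-bound composition and flags "loosening" — the classic signature
of helix converting to sheet/turn/coil on ligand binding.

## Circular dichroism

$$\mathrm{MRE} = \frac{\theta_{obs}\ (\mathrm{mdeg})}{10\, C_p\, n\, l},
\qquad
\alpha\text{-helix}\,(\%) =
\frac{(-\mathrm{MRE}_{208} - 4000)\times100}{33000 - 4000}$$

with the path length converted to cm (1 mm → 0.1 cm) — the only reading
that puts MRE at the $10^4$ magnitude the −4000/−33000 calibration
anchors assume. Defaults: $C_p = 2\times10^{-6}$ M, 585 residues (HSA),
1 mm cell. The helix mapping is affine and decreasing in MRE; outputs
are clamped to [0, 100] % and clamping is reported.

## Peak-shift analysis

`track_peak()` locates the window maximum of each titration member by
parabolic interpolation through the three grid points around the argmax
— exactly translation-equivariant, and necessary because real shifts
(e.g. 214 → ~216 nm) can be below the grid step. Direction is "red"
toward longer wavelength. The intensity trend uses all pairwise
comparisons (Kendall-style), not endpoints alone, so a non-monotone
series reports "flat" rather than whatever its endpoints suggest.
Spectra with no interior maximum in the window are flagged and excluded
from the shift. No numeric threshold is imposed for "slight" changes;
raw shifts are reported and interpretation is left to the caller.

## Synthetic data: what it emulates, and what not

The generators exist so that every analyser can be validated against
known ground truth; binding studies of this kind rarely deposit raw
spectra.

* `generate_titration()` produces Gaussian emission bands (center
  337 nm, s.d. 25 nm by default) whose peak follows the mixed law
  $F_0/F = (1 + K_D[Q])(1 + K_a[Q]^n)$; with one factor switched off it
  satisfies the Stern–Volmer or double-log law *exactly*, which is what
  makes recovery tests sharp. Ligand absorbance is Beer–Lambert linear
  in $[Q]$ (1 cm path) and attenuates the observed spectra by
  $e^{-(A_{ex}+A_{em})/2}$, with the emission absorbance taken at the
  band center. Noise is multiplicative Gaussian (photomultiplier shot
  noise is signal-proportional at these intensities), 1 % by default.
* `generate_amide_i()` sums Gaussian component bands on the amide-I
  grid; noise is additive Gaussian scaled to the envelope maximum, as in
  transmission FT-IR.
* `generate_cd()` inverts the MRE/helix mapping algebraically, so the
  CD round trip is exact by construction.

Not emulated: excitation–emission matrices (3D fluorescence is treated
as two 1D profiles through `track_peak()`), wavelength-dependent
inner-filter attenuation across the emission band, instrument drift,
detector saturation, scattering baselines, and H/D-exchange effects in
FT-IR. Passing round-trip tests therefore demonstrates correctness of
the estimators under the stated noise model, not robustness to every
artefact of real instruments.

## Validation design and known limitations

Parameter-recovery validation uses 20 ground-truth sets: ten
pure-dynamic titrations ($K_{sv}$ from $5\times10^3$ to $10^5$ M⁻¹,
eight concentrations spanning $F_0/F$ up to 2.5) and ten pure-static
ones ($K_a$ from $10^3$ to $3\times10^4$ M⁻¹, $n$ 0.85–1.05, eight
concentrations placed so the quench ratio $(F_0-F)/F$ spans 1–50, i.e.
the titration brackets the binding transition — standard design
practice). At 1 % multiplicative noise, $K_{sv}$ and $n$ recover within
a few percent per set; $K_a$, being an intercept extrapolated several
decades, recovers within ~2–3 % *on average* but its per-set error can
reach 2–3 times that. Noiseless recovery is exact to well below 0.1 %
for all three. The amide-I validation envelope uses seven component
bands at the wavenumbers typical of free albumin with s.d. 4 cm⁻¹;
class-fraction recovery is within 2 percentage points noiseless and
5 points at 1 % noise. Wider components (s.d. ≳ 4.5 cm⁻¹ at ~11 cm⁻¹
spacing) make the decomposition intrinsically ill-conditioned — a
physical resolution limit, not an algorithmic one, worth remembering
when interpreting fits to real protein spectra.

Two further limitations deserve note. First, weak binding at high
temperature (e.g. $K_a \sim 10^2$ M⁻¹ at 310 K) puts the double-log
line at $(F_0-F)/F \lesssim 0.2$ over feasible concentrations, where
intensity noise dominates; binding constants from such titrations are
order-of-magnitude, and thermodynamic parameters chained from them
inherit that uncertainty. Second, the Gaussian band shape and the
class boundary wavenumbers are conventions; amide-I fractions are
comparable *within* a protocol, not absolute structure determinations.

## Orchestration

`run_study()` runs whichever stages a YAML config names — quenching and
binding fits per temperature, Van't Hoff thermodynamics (from fitted
constants or a supplied table), FRET, FT-IR deconvolution, CD — each
independently, recording per-stage errors without aborting the rest,
and logging every default in force. All randomness (simulation only)
flows from the single config seed; analysis stages are deterministic,
and a rerun with the same config and seed is byte-identical.
`simulate_study()` writes a complete synthetic study to disk for
end-to-end round trips. The package's functions are its interface; the
scripts directory holds a runnable example of the derived-chain
computation.
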