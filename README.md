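# albind

Spectroscopic analysis of small-molecule binding to serum albumin.

Fluorescence titrations of a protein against a quenching ligand carry a
remarkable amount of physical chemistry: how the ligand quenches (by
collision or by complex formation), how tightly it binds, what forces
drive the binding, how far the ligand sits from the intrinsic tryptophan
fluorophore, and how much the protein's secondary structure rearranges on
binding. `albind` implements that full inference chain for
fluorescence / UV-vis / FT-IR / CD studies of ligand–serum-albumin
systems (pesticides, drugs, metabolites against HSA or BSA), the kind of
study run routinely in toxicology and pharmacokinetics labs.

## What it computes

**Quenching mechanism and binding constants.** After inner-filter
correction `F_cor = F_obs · exp[(A_ex + A_em)/2]`, peak ratios follow the
Stern–Volmer law

    F0/F = 1 + Ksv [Q] = 1 + Kq τ0 [Q]

fitted by OLS (`stern_volmer_fit()`); `Kq > 2×10¹⁰ L mol⁻¹ s⁻¹` evidences
static (complex-forming) quenching, a `Ksv` rising with temperature
evidences dynamic quenching, both together give a mixed verdict
(`classify_mechanism()`). Binding constants and the number of binding
sites come from the double-logarithm isotherm

    log[(F0 − F)/F] = log Ka + n log[Q]

(`double_log_fit()`).

**Thermodynamics.** `vant_hoff_fit()` regresses `ln Ka` on `1/T`
(`ln K = −ΔH⁰/RT + ΔS⁰/R`, R = 8.314 J mol⁻¹ K⁻¹), evaluates
`ΔG⁰ = ΔH⁰ − TΔS⁰`, and classifies the dominant binding forces from the
signs (both negative → hydrogen bonds / van der Waals; both positive →
hydrophobic; ΔH⁰ < 0 < ΔS⁰ → electrostatic).

**Förster energy transfer.** `overlap_integral()` evaluates
`J = Σ F(λ) ε(λ) λ⁴ Δλ / Σ F(λ) Δλ` (λ in cm, J in cm³ L mol⁻¹),
`forster_radius()` applies `R0⁶ = 8.8×10⁻²⁵ K² N⁻⁴ φ J`, and
`E = 1 − F/F0 = R0⁶/(R0⁶ + r⁶)` links efficiency and donor–acceptor
distance (`transfer_efficiency()`, `binding_distance()`).

**Secondary structure.** `deconvolve_amide_i()` fits Gaussian component
bands to the amide-I region (1600–1700 cm⁻¹), assigns them by center
(β-sheet 1610–1640, random coil 1640–1650, α-helix 1650–1658, β-turn
1658–1700) and reports class fractions; `cd_helix()` converts CD
ellipticity to mean residue ellipticity (`MRE = θ/(10 Cp n l)`) and helix
content (`helix% = (−MRE₂₀₈ − 4000)·100/29000`). `track_peak()` follows
UV-vis / synchronous-fluorescence peak shifts with sub-grid resolution.

**Synthetic data.** `generate_titration()`, `generate_amide_i()` and
`generate_cd()` produce spectra with known ground truth under the same
laws, so every analyser is validated by generator/analyser round trips —
no instrument data needed. `simulate_study()` + `run_study()` exercise
the whole chain from a single YAML config.

## Worked example

```r
library(albind)

# a simulated 310 K titration: Ksv = 1.832e4 /M, 1 % noise, with an
# inner-filter effect from ligand absorbance at the 280 nm excitation
gt <- quenching_ground_truth(Ksv_dynamic_per_M = 1.832e4, Ka_per_M = 0,
                             noise_sd_rel = 0.01, ligand_eps_ex = 2000,
                             ligand_eps_em = 200, seed = 11)
series <- generate_titration(gt, seq(0, 1.05e-5, length.out = 9))
analyze_titration(series, eps_ex = 2000, eps_em = 200)$quenching
#> <quenching_result> T = 310 K: Ksv = 1.98e+04 +/- 1e+03 /M (r2 = 0.9812), Kq = 1.98e+12 /(M s)

# Van't Hoff analysis of binding constants measured at three temperatures
vant_hoff_fit(c(296, 303, 310), c(4923, 664, 158))
#> <thermo_result> dH0 = -187.608 kJ/mol, dS0 = -563.79 J/(mol K), forces: hbond_vdw (spontaneous)
#>   dG0(296 K) = -20.727 kJ/mol
#>   dG0(303 K) = -16.780 kJ/mol
#>   dG0(310 K) = -12.833 kJ/mol

# donor-acceptor distance from a 3.67 % transfer efficiency
binding_distance(E = 0.0367, R0_nm = 1.170)
#> [1] 2.016981    # nm, i.e. 20.17 Angstrom

# CD helix quantification (2e-6 M protein, 585 residues, 1 mm cell)
cd_helix(generate_cd(0.5585))
#> <cd_result> MRE208 = -20196.5 deg cm2/dmol, alpha-helix = 55.85 %
```

The fitted `Kq ≈ 2×10¹² L mol⁻¹ s⁻¹` sits far above the diffusion limit
(static component present); the negative enthalpy and entropy indicate
hydrogen-bond / van-der-Waals-driven binding that is spontaneous at all
three temperatures; the 2.02 nm donor–acceptor distance is well under
8 nm, consistent with non-radiative energy transfer.

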