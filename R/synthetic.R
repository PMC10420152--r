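# Synthetic spectra with known ground truth.  Every analysis stage in the
# package is validated against these generators, since binding studies of
# this kind rarely deposit raw instrument exports.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Ground truth for a simulated quenching titration
#'
#' Parameters of the forward model behind [generate_titration()].  The peak
#' ratio follows the mixed static/dynamic law
#' `F0/F = (1 + Ksv_dynamic * Q) * (1 + Ka * Q^n)`: with `Ka = 0` it reduces
#' exactly to the Stern-Volmer line, with `Ksv_dynamic = 0` to the
#' double-logarithm binding isotherm, so pure-regime fixtures satisfy the
#' fitted laws exactly.
#'
#' Defaults describe a serum-albumin titration of the kind the analysers
#' target: emission band at 337 nm, Stern-Volmer constant ~1.8e4 per M,
#' 1 % multiplicative intensity noise, and a ligand that absorbs at the
#' 280 nm excitation (inner-filter effect) much more than at the emission.
#'
#' @param Ksv_dynamic_per_M Dynamic (collisional) Stern-Volmer constant, 1/M.
#' @param Ka_per_M Association constant of the static component, 1/M.
#' @param n_sites Hill-type exponent of the binding isotherm.
#' @param F0_peak Unquenched peak intensity (arbitrary units).
#' @param emission_center_nm,emission_width_nm Gaussian emission band centre
#'   and standard deviation, nm.
#' @param noise_sd_rel Relative s.d. of multiplicative Gaussian noise
#'   (photomultiplier shot noise is signal-proportional at these levels).
#' @param ligand_eps_ex,ligand_eps_em Ligand molar absorptivity at the
#'   excitation and emission wavelengths, L/(mol cm).
#' @param seed RNG seed; a fixed seed gives bit-identical output.
#' @return An object of class `"quenching_ground_truth"`.
#' @export
quenching_ground_truth <- function(Ksv_dynamic_per_M = 1.832e4,
                                   Ka_per_M = 158,
                                   n_sites = 0.577,
                                   F0_peak = 1000,
                                   emission_center_nm = 337,
                                   emission_width_nm = 25,
                                   noise_sd_rel = 0.01,
                                   ligand_eps_ex = 2000,
                                   ligand_eps_em = 200,
                                   seed = 1L) {
  gt <- list(Ksv_dynamic_per_M = Ksv_dynamic_per_M, Ka_per_M = Ka_per_M,
             n_sites = n_sites, F0_peak = F0_peak,
             emission_center_nm = emission_center_nm,
             emission_width_nm = emission_width_nm,
             noise_sd_rel = noise_sd_rel,
             ligand_eps_ex = ligand_eps_ex, ligand_eps_em = ligand_eps_em,
             seed = as.integer(seed))
  vals <- unlist(gt[setdiff(names(gt), "seed")])
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("ground-truth parameters must be finite and non-negative",
         call. = FALSE)
  }
  if (gt$emission_width_nm <= 0) stop("emission_width_nm must be > 0",
                                      call. = FALSE)
  if (gt$n_sites <= 0) stop("n_sites must be > 0", call. = FALSE)
  structure(gt, class = "quenching_ground_truth")
}

#' Ground truth for a simulated amide-I envelope
#'
#' @param bands Data frame (or coercible) with columns `center_cm1` (within
#'   \[1600, 1700\]), `width_cm1` (Gaussian s.d., > 0) and `area` (> 0).
#'   Zero rows give a flat zero spectrum.
#' @param noise_sd_rel Relative s.d. of multiplicative Gaussian noise.
#' @param seed RNG seed.
#' @return An object of class `"amide_ground_truth"`.
#' @export
amide_ground_truth <- function(bands, noise_sd_rel = 0, seed = 1L) {
  bands <- as.data.frame(bands)
  if (nrow(bands) > 0L) {
    names(bands) <- c("center_cm1", "width_cm1", "area")
    if (any(bands$center_cm1 < 1600) || any(bands$center_cm1 > 1700)) {
      stop("band centers must lie within [1600, 1700] cm-1", call. = FALSE)
    }
    if (any(bands$width_cm1 <= 0) || any(bands$area <= 0)) {
      stop("band widths and areas must be > 0", call. = FALSE)
    }
  }
  structure(list(bands = bands, noise_sd_rel = noise_sd_rel,
                 seed = as.integer(seed)),
            class = "amide_ground_truth")
}

#' Simulate a fluorescence quenching titration
#'
#' Forward model: a Gaussian emission band whose peak is quenched according
#' to the mixed law `F0/F = (1 + Ksv_dynamic*Q) * (1 + Ka*Q^n)`, then
#' attenuated by the inner-filter factor `exp(-(A_ex + A_em)/2)` with
#' `A = eps * Q * 1 cm` (Beer-Lambert), then perturbed by multiplicative
#' Gaussian noise.  [ife_correct()] applied with the same absorbances
#' recovers the pre-attenuation signal exactly (noiselessly).
#'
#' @param gt A [quenching_ground_truth()].
#' @param concentrations_M Ligand concentrations, ascending, starting at 0.
#' @param temperature_K Temperature recorded on the series.
#' @param grid_nm Emission axis grid (default 300-500 nm at 1 nm).
#' @param protein_concentration_M Protein concentration recorded on the
#'   series (default 5e-7 M).
#' @return A [titration_series()].
#' @export
generate_titration <- function(gt, concentrations_M, temperature_K = 310,
                               grid_nm = seq(300, 500, by = 1),
                               protein_concentration_M = 5e-7) {
  stopifnot(inherits(gt, "quenching_ground_truth"))
  q <- as.numeric(concentrations_M)
  if (length(q) < 1L || q[1L] != 0 || any(diff(q) <= 0)) {
    stop("concentrations must start at 0 and be strictly increasing",
         call. = FALSE)
  }
  shape <- exp(-(grid_nm - gt$emission_center_nm)^2 /
                 (2 * gt$emission_width_nm^2))
  ratio <- (1 + gt$Ksv_dynamic_per_M * q) *
    (1 + gt$Ka_per_M * q^gt$n_sites)
  ife <- exp(-(gt$ligand_eps_ex * q + gt$ligand_eps_em * q) / 2)
  spectra <- with_seed(gt$seed, lapply(seq_along(q), function(i) {
    y <- gt$F0_peak / ratio[i] * shape * ife[i]
    if (gt$noise_sd_rel > 0) {
      y <- y * (1 + stats::rnorm(length(y), 0, gt$noise_sd_rel))
    }
    spectrum(grid_nm, y, "wavelength_nm",
             label = sprintf("Q=%.4g M", q[i]))
  }))
  titration_series(temperature_K, q, spectra, protein_concentration_M)
}

#' Simulate an amide-I envelope as a sum of Gaussian component bands
#'
#' @param gt An [amide_ground_truth()].
#' @param grid Wavenumber grid covering at least \[1595, 1705\] cm-1.
#' @return A [spectrum()] on a wavenumber axis; the integral of the
#'   noiseless curve equals the summed band areas up to quadrature error.
#' @export
generate_amide_i <- function(gt, grid = seq(1595, 1705, by = 0.5)) {
  stopifnot(inherits(gt, "amide_ground_truth"))
  grid <- as.numeric(grid)
  if (min(grid) > 1595 || max(grid) < 1705) {
    stop("grid must cover [1595, 1705] cm-1", call. = FALSE)
  }
  y <- rep(0, length(grid))
  if (nrow(gt$bands) > 0L) {
    for (i in seq_len(nrow(gt$bands))) {
      b <- gt$bands[i, ]
      y <- y + b$area / (b$width_cm1 * sqrt(2 * pi)) *
        exp(-(grid - b$center_cm1)^2 / (2 * b$width_cm1^2))
    }
  }
  if (gt$noise_sd_rel > 0) {
    peak <- max(y)
    y <- with_seed(gt$seed,
                   y + peak * stats::rnorm(length(y), 0, gt$noise_sd_rel))
  }
  spectrum(grid, y, "wavenumber_cm-1", label = "amide I (synthetic)")
}

#' Observed CD signal at 208 nm for a known helix fraction
#'
#' Inverts the mean-residue-ellipticity mapping: returns the ellipticity
#' theta (mdeg) such that `helix_fraction(mre(theta, ...))` reproduces
#' `helix_fraction` exactly.  MRE at 208 nm is -4000 deg cm^2/dmol for pure
#' random coil and -33000 for pure alpha-helix, interpolated linearly.
#'
#' @param helix_fraction Fraction of alpha-helix in \[0, 1\].
#' @param Cp_M Protein molar concentration (default 2e-6 M).
#' @param n_residues Number of amino-acid residues (585 for HSA).
#' @param path_mm Cell path length in mm (default 1).
#' @return Observed CD at 208 nm in millidegrees (a single number).
#' @export
generate_cd <- function(helix_fraction, Cp_M = 2e-6, n_residues = 585,
                        path_mm = 1) {
  if (!is.finite(helix_fraction) || helix_fraction < 0 || helix_fraction > 1) {
    stop("`helix_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (Cp_M <= 0 || n_residues <= 0 || path_mm <= 0) {
    stop("Cp_M, n_residues and path_mm must be positive", call. = FALSE)
  }
  mre_208 <- -(4000 + (33000 - 4000) * helix_fraction)
  mre_208 * (10 * Cp_M * n_residues * path_mm / 10)
}
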