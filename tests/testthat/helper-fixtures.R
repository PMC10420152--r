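# Fixture builders shared across test files.

gaussian_spectrum <- function(center, width, height = 1,
                              grid = seq(300, 500, by = 1),
                              axis_kind = "wavelength_nm") {
  spectrum(grid, height * exp(-(grid - center)^2 / (2 * width^2)), axis_kind)
}

# Seven-component amide-I fixture: free-HSA band centers with synthetic
# areas giving class fractions close to a typical albumin composition.
amide7_bands <- function(width = 4) {
  data.frame(
    center_cm1 = c(1610.96, 1623.22, 1634.95, 1645.22, 1655.67, 1666.79,
                   1679.42),
    width_cm1 = rep(width, 7),
    area = c(5, 12, 17, 16.8, 22, 15, 12.5))
}

# ground-truth class fractions implied by a band table
class_fractions <- function(bands) {
  cls <- albind:::assign_band_class(bands$center_cm1)
  out <- vapply(c("alpha_helix", "beta_sheet", "beta_turn", "random_coil"),
                function(cl) sum(bands$area[cls == cl]) / sum(bands$area),
                numeric(1))
  out
}

# pure-regime titration generators used in recovery tests
dynamic_titration <- function(ksv, noise = 0, seed = 1,
                              concentrations = seq(0, 1.5 / ksv,
                                                   length.out = 8)) {
  gt <- quenching_ground_truth(Ksv_dynamic_per_M = ksv, Ka_per_M = 0,
                               noise_sd_rel = noise, ligand_eps_ex = 0,
                               ligand_eps_em = 0, seed = seed)
  generate_titration(gt, concentrations)
}

static_titration <- function(ka, n_sites, noise = 0, seed = 1,
                             rho = exp(seq(log(1), log(50),
                                           length.out = 7))) {
  gt <- quenching_ground_truth(Ksv_dynamic_per_M = 0, Ka_per_M = ka,
                               n_sites = n_sites, noise_sd_rel = noise,
                               ligand_eps_ex = 0, ligand_eps_em = 0,
                               seed = seed)
  generate_titration(gt, c(0, (rho / ka)^(1 / n_sites)))
}
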