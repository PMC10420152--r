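# Van't Hoff analysis of binding constants and binding-force classification.

R_GAS <- 8.314  # J/(mol K)

#' Van't Hoff fit of binding constants across temperatures
#'
#' Ordinary least squares of `ln(Ka)` on `1/T`:
#' `ln K = -dH0/(R T) + dS0/R`, so `dH0 = -slope * R` and
#' `dS0 = intercept * R`, with R = 8.314 J/(mol K).  Gibbs free energy is
#' evaluated at each input temperature as `dG0 = dH0 - T * dS0`.
#'
#' @param temperatures_K Absolute temperatures (>= 2 distinct values).
#' @param Ka_per_M Binding constants in 1/M at those temperatures (all > 0).
#' @return An object of class `"thermo_result"`: `dH_kJ_per_mol`,
#'   `dS_J_per_mol_K`, `dG_kJ_per_mol_by_T` (named by temperature),
#'   `force_class`, `spontaneous`, `r_squared`, and `exact_two_point` when
#'   the line is determined by exactly two points (zero residual).
#' @export
vant_hoff_fit <- function(temperatures_K, Ka_per_M) {
  tt <- as.numeric(temperatures_K)
  ka <- as.numeric(Ka_per_M)
  if (length(tt) != length(ka)) stop("length mismatch", call. = FALSE)
  if (length(tt) < 2L) {
    stop("insufficient data: Van't Hoff fit needs >= 2 temperatures",
         call. = FALSE)
  }
  if (any(tt <= 0) || any(ka <= 0)) {
    stop("temperatures and binding constants must be positive", call. = FALSE)
  }
  exact <- length(tt) == 2L
  if (exact) {
    warning("two-point Van't Hoff fit: exact line, no residual information",
            call. = FALSE)
  }
  fit <- stats::lm(log(ka) ~ I(1 / tt))
  dH <- -unname(stats::coef(fit)[2L]) * R_GAS / 1000  # kJ/mol
  dS <- unname(stats::coef(fit)[1L]) * R_GAS          # J/(mol K)
  dG <- stats::setNames(gibbs(dH, dS, tt), tt)
  structure(
    list(dH_kJ_per_mol = dH,
         dS_J_per_mol_K = dS,
         dG_kJ_per_mol_by_T = dG,
         force_class = classify_forces(dH, dS),
         spontaneous = all(dG < 0),
         r_squared = summary(fit)$r.squared,
         exact_two_point = exact),
    class = "thermo_result"
  )
}

#' @export
print.thermo_result <- function(x, ...) {
  cat(sprintf(
    "<thermo_result> dH0 = %.3f kJ/mol, dS0 = %.2f J/(mol K), forces: %s%s\n",
    x$dH_kJ_per_mol, x$dS_J_per_mol_K, x$force_class,
    if (x$spontaneous) " (spontaneous)" else ""))
  for (i in seq_along(x$dG_kJ_per_mol_by_T)) {
    cat(sprintf("  dG0(%s K) = %.3f kJ/mol\n",
                names(x$dG_kJ_per_mol_by_T)[i], x$dG_kJ_per_mol_by_T[i]))
  }
  invisible(x)
}

#' Gibbs free energy change
#'
#' `dG0 = dH0 - T * dS0`, with the entropy converted from J to kJ so the
#' result is in kJ/mol.
#'
#' @param dH_kJ_per_mol Enthalpy change, kJ/mol.
#' @param dS_J_per_mol_K Entropy change, J/(mol K).
#' @param T_K Absolute temperature(s), > 0.
#' @return Gibbs free energy change(s) in kJ/mol.
#' @export
gibbs <- function(dH_kJ_per_mol, dS_J_per_mol_K, T_K) {
  if (any(T_K <= 0)) stop("T_K must be positive", call. = FALSE)
  dH_kJ_per_mol - T_K * dS_J_per_mol_K / 1000
}

#' Classify the dominant binding forces from thermodynamic signs
#'
#' Sign rule for macromolecule-ligand association: both dH0 and dS0
#' negative indicates hydrogen bonding and van der Waals forces; both
#' positive, hydrophobic interactions; dH0 negative with dS0 positive,
#' electrostatic forces.  The remaining quadrant (dH0 > 0, dS0 < 0) falls
#' outside the rule table and is reported as `"unclassified"` with a
#' warning.
#'
#' @param dH Enthalpy change (any consistent unit; only the sign is used).
#' @param dS Entropy change (sign only).
#' @return `"hbond_vdw"`, `"hydrophobic"`, `"electrostatic"` or
#'   `"unclassified"`.
#' @export
classify_forces <- function(dH, dS) {
  if (!is.finite(dH) || !is.finite(dS)) {
    stop("dH and dS must be finite", call. = FALSE)
  }
  if (dH < 0 && dS < 0) "hbond_vdw"
  else if (dH > 0 && dS > 0) "hydrophobic"
  else if (dH < 0 && dS > 0) "electrostatic"
  else {
    warning("dH > 0 with dS < 0 is outside the sign-rule table",
            call. = FALSE)
    "unclassified"
  }
}
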