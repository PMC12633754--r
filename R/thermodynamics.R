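#' Two-point van't Hoff enthalpy
#'
#' `dH = R * ln(K2/K1) / (1/T1 - 1/T2)`, reported in kJ/mol with
#' R = 8.314 J/(mol K).
#'
#' @param k1,k2 Association constants (L/mol, > 0) at `t1` and `t2`.
#' @param t1,t2 Temperatures in K (`t1 != t2`).
#' @return Enthalpy change in kJ/mol.
#' @export
vant_hoff_two_point <- function(k1, t1, k2, t2) {
  if (k1 <= 0 || k2 <= 0)
    stop_specbind("association constants must be > 0", "malformed_input")
  if (t1 <= 0 || t2 <= 0)
    stop_specbind("temperatures must be > 0 K", "malformed_input")
  if (t1 == t2)
    stop_specbind("t1 and t2 must differ", "degenerate_input")
  .R_GAS * log(k2 / k1) / (1 / t1 - 1 / t2) / 1000
}

#' Van't Hoff regression of binding thermodynamics
#'
#' Least squares of `ln K` against `1/T` (`ln K = -dH/(R*T) + dS/R`):
#' `dH = -R * slope`, `dS = R * intercept`. The Gibbs energy at each input
#' temperature is computed as `dG = dH - T*dS` and the dominant binding
#' force is classified from the signs of (dH, dS) via [ross_classify()].
#'
#' With exactly two temperatures the regression line passes through both
#' points and `dH` coincides with [vant_hoff_two_point()].
#'
#' @param k Association constants, L/mol (> 0).
#' @param temperatures Matching temperatures in K. May be omitted when `k`
#'   is a named vector (names are temperatures).
#' @return Object of class `thermo_result`: `dH` (kJ/mol), `dS`
#'   (J/(mol K)), `dG_by_T` (named, kJ/mol), `fit_r`, `method`,
#'   `force_class`, `model`.
#' @examples
#' ka <- c(`298` = 4.07e4, `303` = 3.38e4, `310` = 3.19e4)
#' vant_hoff_regression(ka)
#' @export
vant_hoff_regression <- function(k, temperatures = NULL) {
  if (is.null(temperatures)) {
    if (is.null(names(k)))
      stop_specbind("temperatures missing and k is unnamed",
                    "malformed_input")
    temperatures <- as.numeric(names(k))
  }
  k <- as.numeric(k)
  temperatures <- as.numeric(temperatures)
  if (length(k) != length(temperatures))
    stop_specbind("k and temperatures lengths differ", "malformed_input")
  if (length(unique(temperatures)) < 2L)
    stop_specbind("need >= 2 distinct temperatures", "insufficient_data")
  if (any(k <= 0)) stop_specbind("K values must be > 0", "malformed_input")
  inv_t <- 1 / temperatures
  lnk <- log(k)
  fit <- stats::lm(lnk ~ inv_t)
  dH <- -.R_GAS * unname(stats::coef(fit)[2L]) / 1000     # kJ/mol
  dS <- .R_GAS * unname(stats::coef(fit)[1L])             # J/(mol K)
  fit_r <- if (stats::sd(lnk) == 0) NA_real_ else stats::cor(inv_t, lnk)
  dG <- gibbs_from_HS(dH, dS, temperatures)
  names(dG) <- as.character(temperatures)
  method <- if (length(k) == 2L) "two_point" else "regression"
  structure(list(dH = dH, dS = dS, dG_by_T = dG, fit_r = fit_r,
                 method = method, gas_constant = .R_GAS,
                 force_class = ross_classify(dH, dS), model = fit),
            class = "thermo_result")
}

#' @export
print.thermo_result <- function(x, ...) {
  cat(sprintf("Van't Hoff thermodynamics (%s)\n", x$method))
  cat(sprintf("  dH = %.4g kJ/mol, dS = %.4g J/(mol K)\n", x$dH, x$dS))
  for (tn in names(x$dG_by_T))
    cat(sprintf("  dG(%s K) = %.4g kJ/mol\n", tn, x$dG_by_T[[tn]]))
  cat(sprintf("  dominant force: %s\n", x$force_class))
  invisible(x)
}

#' @export
coef.thermo_result <- function(object, ...) {
  c(dH = object$dH, dS = object$dS)
}

#' Gibbs energy from enthalpy and entropy
#'
#' `dG = dH - T*dS`, with dH in kJ/mol and dS in J/(mol K) (the mixed unit
#' convention of spectroscopic binding tables).
#'
#' @param dH Enthalpy change, kJ/mol.
#' @param dS Entropy change, J/(mol K).
#' @param temperature Temperature(s), K (> 0).
#' @return Gibbs energy change in kJ/mol (vectorised over `temperature`).
#' @examples
#' gibbs_from_HS(-7.954, 45.6521, 298)  # -21.56
#' @export
gibbs_from_HS <- function(dH, dS, temperature) {
  if (any(temperature <= 0))
    stop_specbind("temperature must be > 0 K", "malformed_input")
  dH - temperature * dS / 1000
}

#' Gibbs energy from an association constant
#'
#' `dG = -R*T*ln(K)`, reported in kJ/mol. This is thermodynamically
#' equivalent to [gibbs_from_HS()] when K itself obeys the van't Hoff
#' relation, but the two routes are kept distinct and never silently
#' substituted for one another.
#'
#' @param k Association constant, L/mol (> 0).
#' @param temperature Temperature, K (> 0).
#' @return Gibbs energy change in kJ/mol.
#' @export
gibbs_from_K <- function(k, temperature) {
  if (any(k <= 0)) stop_specbind("K must be > 0", "malformed_input")
  if (any(temperature <= 0))
    stop_specbind("temperature must be > 0 K", "malformed_input")
  -.R_GAS * temperature * log(k) / 1000
}

#' Classify the dominant binding force from (dH, dS) signs
#'
#' Sign-rule classification of the principal non-covalent force stabilising
#' a protein-ligand complex: hydrophobic if dH > 0 and dS > 0; hydrogen
#' bonding or van der Waals if dH < 0 and dS < 0; electrostatic if dH < 0
#' and dS > 0. Values inside the near-zero tolerance band on either axis
#' are classified `indeterminate`, as is the (dH > 0, dS < 0) quadrant,
#' which the rule table does not cover.
#'
#' @param dH Enthalpy change, kJ/mol.
#' @param dS Entropy change, J/(mol K).
#' @param tol_dH Near-zero band half-width for dH, kJ/mol (default 1).
#' @param tol_dS Near-zero band half-width for dS, J/(mol K) (default 1).
#' @return One of `"hydrophobic"`, `"hbond_vdw"`, `"electrostatic"`,
#'   `"indeterminate"`.
#' @examples
#' ross_classify(-27.511, -4.108)  # hbond_vdw
#' ross_classify(-7.954, 45.6521)  # electrostatic
#' @export
ross_classify <- function(dH, dS, tol_dH = 1, tol_dS = 1) {
  if (abs(dH) < tol_dH || abs(dS) < tol_dS) return("indeterminate")
  if (dH > 0 && dS > 0) return("hydrophobic")
  if (dH < 0 && dS < 0) return("hbond_vdw")
  if (dH < 0 && dS > 0) return("electrostatic")
  "indeterminate"
}
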