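#' Inner-filter correction of fluorescence intensities
#'
#' Corrects observed fluorescence for attenuation of the excitation and
#' emission beams by sample absorbance:
#' `F_corr = F_obs * 10^((A_ex + A_em) / 2)`.
#' The correction becomes unreliable at high absorbance; when
#' `A_ex + A_em > 0.6` a warning is attached.
#'
#' @param f_obs Observed fluorescence (arbitrary units).
#' @param a_ex Absorbance at the excitation wavelength (>= 0).
#' @param a_em Absorbance at the emission wavelength (>= 0).
#' @return Corrected fluorescence (vectorised).
#' @export
inner_filter_correct <- function(f_obs, a_ex = 0, a_em = 0) {
  a_ex <- as.numeric(a_ex)
  a_em <- as.numeric(a_em)
  if (any(a_ex < 0, na.rm = TRUE) || any(a_em < 0, na.rm = TRUE))
    stop_specbind("absorbances must be >= 0", "malformed_input")
  tot <- a_ex + a_em
  if (any(tot > 0.6, na.rm = TRUE))
    warn_specbind("A_ex + A_em > 0.6: inner-filter correction unreliable",
                  "high_absorbance")
  as.numeric(f_obs) * 10^(tot / 2)
}

#' Apply inner-filter correction to a titration series
#'
#' Uses the per-point `a_ex`/`a_em` columns; points without absorbance data
#' are left unchanged.
#'
#' @param series A [titration_series()].
#' @return A corrected [titration_series()].
#' @export
correct_titration <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  pts <- series$points
  has <- is.finite(pts$a_ex) & is.finite(pts$a_em)
  f <- pts$fluorescence
  if (any(has))
    f[has] <- inner_filter_correct(f[has], pts$a_ex[has], pts$a_em[has])
  titration_series(series$temperature, series$protein_conc,
                   pts$ligand_conc, f,
                   a_ex = pts$a_ex, a_em = pts$a_em)
}

#' Stern-Volmer quenching analysis
#'
#' Ordinary least squares of `F0/F` against quencher concentration `[Q]`:
#' `F0/F = Ksv*[Q] + 1 = Kq*tau0*[Q] + 1`. The intercept is left free
#' rather than forced to 1; its deviation from 1 is kept as a baseline
#' diagnostic and does not bias the slope. The bimolecular quenching rate
#' constant is `Kq = Ksv / tau0`, with `tau0` the unquenched fluorescence
#' lifetime (1e-8 s is the customary value for biological macromolecules).
#'
#' A quenching rate constant above the diffusion-controlled limit
#' (about 2e10 L/(mol s)) indicates static quenching by ground-state
#' complex formation rather than collisional quenching; see
#' [classify_quenching()].
#'
#' @param series A [titration_series()] (one temperature).
#' @param tau0 Unquenched fluorescence lifetime in s (default 1e-8).
#' @return Object of class `sv_fit`: `ksv` (L/mol), `kq` (L/(mol s)),
#'   `tau0`, `intercept`, `fit_r` (Pearson correlation of the regression),
#'   `temperature`, `flags`, `model`.
#' @examples
#' s <- gen_titration(noise = noise_model(0))[[1]]
#' stern_volmer_fit(s)
#' @export
stern_volmer_fit <- function(series, tau0 = 1e-8) {
  stopifnot(inherits(series, "titration_series"))
  if (tau0 <= 0) stop_specbind("tau0 must be > 0", "malformed_input")
  f0 <- titration_f0(series)
  pts <- series$points[series$points$ligand_conc > 0, , drop = FALSE]
  if (nrow(pts) < 3L)
    stop_specbind("need >= 3 non-zero ligand points", "insufficient_data")
  q <- pts$ligand_conc
  ratio <- f0 / pts$fluorescence
  fit <- stats::lm(ratio ~ q)
  ksv <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  flags <- character(0)
  if (ksv <= 0) {
    flags <- c(flags, "non_quenching")
    warn_specbind("non-positive Stern-Volmer slope: no quenching detected",
                  "non_quenching")
  }
  fit_r <- if (stats::sd(ratio) == 0) NA_real_ else stats::cor(q, ratio)
  structure(list(ksv = ksv, kq = ksv / tau0, tau0 = tau0,
                 intercept = intercept, fit_r = fit_r,
                 temperature = series$temperature, flags = flags,
                 model = fit),
            class = "sv_fit")
}

#' @export
print.sv_fit <- function(x, ...) {
  cat(sprintf("Stern-Volmer fit at %g K\n", x$temperature))
  cat(sprintf("  Ksv = %.4g L/mol, Kq = %.4g L/(mol s) [tau0 = %.2g s]\n",
              x$ksv, x$kq, x$tau0))
  cat(sprintf("  intercept = %.4f (expected ~1), r = %.4f\n",
              x$intercept, x$fit_r))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.sv_fit <- function(object, ...) {
  c(ksv = object$ksv, intercept = object$intercept)
}

#' @export
plot.sv_fit <- function(x, ...) {
  d <- x$model$model
  graphics::plot(d$q * 1e6, d$ratio, xlab = "[Q] (uM)", ylab = "F0/F",
                 main = sprintf("Stern-Volmer, %g K", x$temperature), ...)
  graphics::abline(x$model)
  invisible(x)
}

#' Bimolecular quenching rate constant
#'
#' `Kq = Ksv / tau0`.
#'
#' @param ksv Stern-Volmer constant, L/mol.
#' @param tau0 Unquenched fluorescence lifetime, s (> 0; default 1e-8).
#' @return Kq in L/(mol s).
#' @examples
#' quenching_rate_constant(5.47e4)  # 5.47e12
#' @export
quenching_rate_constant <- function(ksv, tau0 = 1e-8) {
  if (any(tau0 <= 0)) stop_specbind("tau0 must be > 0", "malformed_input")
  as.numeric(ksv) / tau0
}

#' Classify the quenching mechanism from multi-temperature fits
#'
#' Rule table over the temperature trend of Ksv and the magnitude of Kq
#' relative to the diffusion-controlled limit (2e10 L/(mol s)):
#' \itemize{
#'   \item Ksv non-increasing with temperature AND every Kq above the
#'     limit: `static` (ground-state complex, dissociating on warming);
#'   \item Ksv strictly increasing AND every Kq at or below the limit:
#'     `dynamic` (collisional, enhanced by diffusion);
#'   \item anything else: `ambiguous`, with the rule outcomes recorded.
#' }
#'
#' @param fits A list of [stern_volmer_fit()] results at >= 2 temperatures
#'   (any order), or a data frame with columns `temperature`, `ksv`, `kq`.
#' @param kq_threshold Diffusion limit in L/(mol s) (default 2e10).
#' @return Object of class `quench_classification` with `verdict`
#'   (`"static"`, `"dynamic"` or `"ambiguous"`) and `evidence`.
#' @export
classify_quenching <- function(fits, kq_threshold = 2e10) {
  if (is.data.frame(fits)) {
    d <- fits[, c("temperature", "ksv", "kq")]
  } else {
    stopifnot(all(vapply(fits, inherits, TRUE, "sv_fit")))
    d <- data.frame(temperature = vapply(fits, `[[`, 1, "temperature"),
                    ksv = vapply(fits, `[[`, 1, "ksv"),
                    kq = vapply(fits, `[[`, 1, "kq"))
  }
  if (nrow(d) < 2L)
    stop_specbind("need fits at >= 2 temperatures", "insufficient_data")
  d <- d[order(d$temperature), ]
  ksv_nonincreasing <- all(diff(d$ksv) <= 0)
  ksv_increasing <- all(diff(d$ksv) > 0)
  kq_all_above <- all(d$kq > kq_threshold)
  kq_all_at_or_below <- all(d$kq <= kq_threshold)
  verdict <- if (ksv_nonincreasing && kq_all_above) "static"
  else if (ksv_increasing && kq_all_at_or_below) "dynamic"
  else "ambiguous"
  structure(list(verdict = verdict,
                 evidence = list(ksv_nonincreasing_with_T = ksv_nonincreasing,
                                 ksv_increasing_with_T = ksv_increasing,
                                 kq_all_above_threshold = kq_all_above,
                                 kq_all_at_or_below_threshold = kq_all_at_or_below,
                                 kq_threshold = kq_threshold,
                                 table = d)),
            class = "quench_classification")
}

#' @export
print.quench_classification <- function(x, ...) {
  cat(sprintf("Quenching mechanism: %s\n", x$verdict))
  ev <- x$evidence
  cat(sprintf("  Ksv non-increasing with T: %s; strictly increasing: %s\n",
              ev$ksv_nonincreasing_with_T, ev$ksv_increasing_with_T))
  cat(sprintf("  all Kq > %.2g: %s; all Kq <= %.2g: %s\n",
              ev$kq_threshold, ev$kq_all_above_threshold,
              ev$kq_threshold, ev$kq_all_at_or_below_threshold))
  invisible(x)
}

#' Double-logarithmic binding fit
#'
#' Estimates the association constant Ka and binding-site number n from a
#' static-quenching titration via the ligand-depletion-corrected double-log
#' relation: regressing `log10((F0-F)/F)` on
#' `log10([Q0] - [P0]*(F0-F)/F0)` gives slope `n` and intercept
#' `n*log10(Ka)`, so `Ka = 10^(intercept/slope)`. The abscissa is the free
#' ligand concentration implied by the fraction of quenched (complexed)
#' protein.
#'
#' Points with `F >= F0` or a non-positive free-ligand estimate have no
#' defined logarithm; they are excluded from the regression and reported in
#' the result (`excluded`).
#'
#' @param series A [titration_series()] (one temperature).
#' @return Object of class `binding_fit`: `ka` (L/mol), `n_sites`,
#'   `fit_r`, `temperature`, `excluded` (row indices of `series$points`),
#'   `model`.
#' @examples
#' s <- gen_titration(noise = noise_model(0), mode = "exact")[[1]]
#' double_log_binding_fit(s)
#' @export
double_log_binding_fit <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  f0 <- titration_f0(series)
  pts <- series$points
  idx <- which(pts$ligand_conc > 0)
  q0 <- pts$ligand_conc[idx]
  f <- pts$fluorescence[idx]
  qfree <- q0 - series$protein_conc * (f0 - f) / f0
  usable <- f < f0 & qfree > 0
  excluded <- idx[!usable]
  if (sum(usable) < 3L)
    stop_specbind("fewer than 3 usable points after exclusions",
                  "insufficient_data")
  y <- log10((f0 - f[usable]) / f[usable])
  x <- log10(qfree[usable])
  fit <- stats::lm(y ~ x)
  n <- unname(stats::coef(fit)[2L])
  if (n <= 0)
    stop_specbind("non-positive double-log slope: binding fit failed",
                  "fit_failure")
  ka <- 10^(unname(stats::coef(fit)[1L]) / n)
  structure(list(ka = ka, n_sites = n, fit_r = stats::cor(x, y),
                 temperature = series$temperature,
                 excluded = excluded, model = fit),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("Double-log binding fit at %g K\n", x$temperature))
  cat(sprintf("  Ka = %.4g L/mol, n = %.3f, r = %.4f\n",
              x$ka, x$n_sites, x$fit_r))
  if (length(x$excluded))
    cat("  excluded points (F >= F0 or non-positive free ligand):",
        paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.binding_fit <- function(object, ...) {
  c(ka = object$ka, n = object$n_sites)
}
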