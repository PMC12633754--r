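#' Enzyme inhibition rate from relative fluorescence
#'
#' Percent inhibition of an enzyme activity assay read out as relative
#' fluorescence units (RFU):
#' `100 * (RFU_enzyme - RFU_enzyme_plus_drug) / RFU_enzyme`.
#' A drug that raises the fluorescence yields a negative rate; this is
#' flagged with a warning but never clipped.
#'
#' @param rfu_enzyme RFU of the uninhibited enzyme reaction (> 0).
#' @param rfu_enzyme_plus_drug RFU with inhibitor present (>= 0).
#' @return Inhibition rate(s) in percent (vectorised).
#' @examples
#' inhibition_rate(1000, 457.4)  # 54.26
#' @export
inhibition_rate <- function(rfu_enzyme, rfu_enzyme_plus_drug) {
  rfu_enzyme <- as.numeric(rfu_enzyme)
  rfu_enzyme_plus_drug <- as.numeric(rfu_enzyme_plus_drug)
  if (any(!is.finite(rfu_enzyme)) || any(rfu_enzyme == 0))
    stop_specbind("rfu_enzyme must be finite and non-zero",
                  "division_by_zero")
  if (any(rfu_enzyme < 0) || any(rfu_enzyme_plus_drug < 0))
    stop_specbind("RFU values must be >= 0", "malformed_input")
  out <- 100 * (rfu_enzyme - rfu_enzyme_plus_drug) / rfu_enzyme
  if (any(out < 0))
    warn_specbind("negative inhibition rate: drug raised the fluorescence",
                  "negative_inhibition")
  out
}

#' Fit an IC50 dose-response curve
#'
#' Least-squares fit of the two-parameter logistic
#' `inhibition(c) = 100 * c^h / (c^h + IC50^h)` (floor 0, ceiling 100,
#' matching a 0-100 percent inhibition scale) to a dose-response table.
#' The concentration axis is handled on the log10 scale; zero-concentration
#' rows are used only to check the floor and are excluded from the
#' regression. The Hill slope is constrained positive, which guarantees a
#' monotone fitted curve. A 4-parameter logistic (free floor and ceiling)
#' is available via `four_param = TRUE` for assays with incomplete
#' inhibition.
#'
#' If all responses lie on one side of 50 percent the IC50 is an
#' extrapolation and a warning is attached (`extrapolated` flag).
#'
#' @param dose_table Data frame with columns `conc` (mol/L) and
#'   `inhibition` (percent), e.g. from [gen_dose_response()]. An optional
#'   `sd` column provides inverse-variance weights.
#' @param hill_fixed Optional fixed Hill slope; when given only IC50 is
#'   estimated.
#' @param four_param Fit floor and ceiling as well.
#' @return Object of class `ic50_fit` with elements `ic50`, `ic50_se`,
#'   `hill`, `fit_r2`, `curve` (all fitted parameters), `flags`, `model`
#'   (the underlying `nls` object) and `data`.
#' @examples
#' d <- gen_dose_response(3e-5, hill = 1)
#' fit <- fit_ic50(d)
#' coef(fit)
#' @export
fit_ic50 <- function(dose_table, hill_fixed = NULL, four_param = FALSE) {
  stopifnot(is.data.frame(dose_table),
            all(c("conc", "inhibition") %in% names(dose_table)))
  d <- dose_table[is.finite(dose_table$conc) & is.finite(dose_table$inhibition), ]
  pos <- d[d$conc > 0, , drop = FALSE]
  if (length(unique(pos$conc)) < 4L)
    stop_specbind("need >= 4 distinct non-zero concentrations",
                  "insufficient_data")
  flags <- character(0)
  zero <- d[d$conc == 0, , drop = FALSE]
  if (nrow(zero) > 0L && any(abs(zero$inhibition) > 5))
    flags <- c(flags, "nonzero_floor")
  if (all(pos$inhibition < 50) || all(pos$inhibition > 50)) {
    flags <- c(flags, "extrapolated")
    warn_specbind("all responses on one side of 50%: IC50 is extrapolated",
                  "extrapolation")
  }
  lx <- log10(pos$conc)
  y <- pos$inhibition
  w <- if ("sd" %in% names(pos) && all(is.finite(pos$sd)) && all(pos$sd > 0))
    1 / pos$sd^2 else rep(1, nrow(pos))
  # start: interpolate the 50% crossing for log10(IC50)
  start_l50 <- tryCatch(stats::approx(y, lx, xout = 50, ties = mean)$y,
                        error = function(e) NA_real_)
  if (!is.finite(start_l50)) start_l50 <- stats::median(lx)
  ctrl <- minpack.lm::nls.lm.control(maxiter = 200)
  fit <- tryCatch({
    if (four_param) {
      minpack.lm::nlsLM(
        y ~ floor + (ceiling - floor) / (1 + 10^(h * (l50 - lx))),
        start = list(l50 = start_l50, h = hill_fixed %||% 1,
                     floor = 0, ceiling = 100),
        lower = c(-Inf, 1e-3, -Inf, -Inf), weights = w, control = ctrl)
    } else if (!is.null(hill_fixed)) {
      h <- hill_fixed
      minpack.lm::nlsLM(y ~ 100 / (1 + 10^(h * (l50 - lx))),
                        start = list(l50 = start_l50), weights = w,
                        control = ctrl)
    } else {
      minpack.lm::nlsLM(y ~ 100 / (1 + 10^(h * (l50 - lx))),
                        start = list(l50 = start_l50, h = 1),
                        lower = c(-Inf, 1e-3), weights = w, control = ctrl)
    }
  }, error = function(e) {
    stop_specbind(paste0("IC50 fit failed to converge: ",
                         conditionMessage(e)), "fit_failure")
  })
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(cf)))
  ic50 <- 10^cf[["l50"]]
  ic50_se <- log(10) * ic50 * unname(se["l50"])
  hill <- if (!is.null(hill_fixed) && !four_param) hill_fixed else cf[["h"]]
  resid <- stats::residuals(fit)
  fit_r2 <- 1 - sum(w * resid^2) / sum(w * (y - stats::weighted.mean(y, w))^2)
  structure(list(ic50 = ic50, ic50_se = ic50_se, hill = unname(hill),
                 fit_r2 = fit_r2,
                 curve = c(as.list(cf),
                           list(floor = if (four_param) cf[["floor"]] else 0,
                                ceiling = if (four_param) cf[["ceiling"]] else 100)),
                 flags = flags, model = fit, data = d),
            class = "ic50_fit")
}

#' @export
print.ic50_fit <- function(x, digits = 4, ...) {
  cat("Two-parameter logistic IC50 fit\n")
  cat(sprintf("  IC50 = %.*g mol/L (%.4g uM), se = %.2g mol/L\n", digits,
              x$ic50, x$ic50 * 1e6, x$ic50_se))
  cat(sprintf("  Hill slope = %.*g, R^2 = %.4f\n", digits, x$hill, x$fit_r2))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.ic50_fit <- function(object, ...) {
  c(ic50 = object$ic50, hill = object$hill)
}

#' @export
predict.ic50_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$data$conc else
    if (is.data.frame(newdata)) newdata$conc else as.numeric(newdata)
  cv <- object$curve
  fl <- cv$floor
  ce <- cv$ceiling
  out <- ifelse(conc <= 0, fl,
                fl + (ce - fl) / (1 + 10^(object$hill * (cv$l50 - log10(conc)))))
  as.numeric(out)
}

#' @export
summary.ic50_fit <- function(object, ...) {
  cat(sprintf("IC50 = %.6g mol/L (se %.2g), Hill = %.4g, R^2 = %.4f, n = %d\n",
              object$ic50, object$ic50_se, object$hill, object$fit_r2,
              nrow(object$data)))
  invisible(object)
}

#' @export
plot.ic50_fit <- function(x, ...) {
  pos <- x$data[x$data$conc > 0, ]
  graphics::plot(pos$conc * 1e6, pos$inhibition, log = "x",
                 xlab = "concentration (uM)", ylab = "inhibition (%)",
                 main = "Dose-response", ...)
  cg <- 10^seq(log10(min(pos$conc)), log10(max(pos$conc)), length.out = 200)
  graphics::lines(cg * 1e6, predict(x, cg))
  graphics::abline(h = 50, lty = 3)
  graphics::abline(v = x$ic50 * 1e6, lty = 3)
  invisible(x)
}
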