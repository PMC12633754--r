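#' Constants for Forster energy-transfer calculations
#'
#' @param k2 Orientation factor kappa^2 (default 2/3, the isotropic
#'   dynamic average; must be in (0, 4]).
#' @param phi Donor fluorescence quantum yield (default 0.15, the customary
#'   value for protein tryptophan emission).
#' @param n_refractive Refractive index of the medium (default 1.336, an
#'   average of water and dissolved organic matter).
#' @return Object of class `fret_constants`.
#' @export
fret_constants <- function(k2 = 2 / 3, phi = 0.15, n_refractive = 1.336) {
  if (k2 <= 0 || k2 > 4)
    stop_specbind("k2 must be in (0, 4]", "malformed_input")
  if (phi <= 0 || phi > 1)
    stop_specbind("phi must be in (0, 1]", "malformed_input")
  if (n_refractive <= 0)
    stop_specbind("n_refractive must be > 0", "malformed_input")
  structure(list(k2 = k2, phi = phi, n_refractive = n_refractive),
            class = "fret_constants")
}

#' Energy-transfer efficiency from fluorescence intensities
#'
#' `E = 1 - F/F0`, the fraction of donor excitation transferred to the
#' acceptor, from donor fluorescence without (`f0`) and with (`f`) the
#' acceptor present at equimolar concentration.
#'
#' @param f0 Donor fluorescence without acceptor (> 0).
#' @param f Donor fluorescence with acceptor (0 <= f <= f0; `f > f0` is an
#'   error, not clamped).
#' @return Efficiency E in `[0, 1]`.
#' @export
transfer_efficiency <- function(f0, f) {
  if (any(f0 <= 0)) stop_specbind("f0 must be > 0", "malformed_input")
  if (any(f < 0)) stop_specbind("f must be >= 0", "malformed_input")
  if (any(f > f0))
    stop_specbind("f > f0 would give negative efficiency",
                  "negative_efficiency")
  1 - f / f0
}

#' Spectral overlap integral
#'
#' Discrete overlap of the donor emission spectrum `F_D(lambda)` and the
#' acceptor molar absorptivity `eps_A(lambda)`:
#' `J = sum(F_D * eps_A * lambda^4 * dlambda) / sum(F_D * dlambda)`,
#' a donor-normalised lambda^4-weighted mean of the acceptor absorptivity.
#' Both spectra are linearly interpolated onto the union of their axis
#' grids restricted to the overlap region (no extrapolation); midpoint
#' quadrature widths handle non-uniform grids. With lambda in nm and
#' eps in L/(mol cm) the nm^4-basis sum converts to M^-1 cm^3 by the
#' factor 1e-28 (nm^4 = 1e-28 cm^4).
#'
#' @param donor [spectrum_series()] on a wavelength axis (donor emission).
#' @param acceptor [spectrum_series()] on a wavelength axis with unit
#'   `molar_absorptivity`.
#' @return J in M^-1 cm^3 (scalar). The nm^4-basis value
#'   (M^-1 cm^-1 nm^4) is attached as attribute `"J_nm4"`. Disjoint
#'   spectra give `J = 0`.
#' @examples
#' pair <- gen_fret_pair()
#' overlap_integral(pair$donor, pair$acceptor)
#' @export
overlap_integral <- function(donor, acceptor) {
  stopifnot(inherits(donor, "spectrum_series"),
            inherits(acceptor, "spectrum_series"))
  if (donor$axis_kind != "wavelength_nm" ||
      acceptor$axis_kind != "wavelength_nm")
    stop_specbind("overlap integral requires wavelength_nm axes",
                  "unit_error")
  if (acceptor$unit != "molar_absorptivity")
    stop_specbind("acceptor must be in molar absorptivity units",
                  "unit_error")
  lo <- max(min(donor$axis), min(acceptor$axis))
  hi <- min(max(donor$axis), max(acceptor$axis))
  if (lo >= hi) {
    out <- 0
    attr(out, "J_nm4") <- 0
    return(out)
  }
  grid <- sort(unique(c(donor$axis, acceptor$axis)))
  grid <- grid[grid >= lo & grid <= hi]
  fd <- stats::approx(donor$axis, donor$values, xout = grid)$y
  ea <- stats::approx(acceptor$axis, acceptor$values, xout = grid)$y
  w <- grid_widths(grid)
  denom <- sum(fd * w)
  if (denom <= 0) {
    out <- 0
    attr(out, "J_nm4") <- 0
    return(out)
  }
  j_nm4 <- sum(fd * ea * grid^4 * w) / denom
  out <- j_nm4 * 1e-28
  attr(out, "J_nm4") <- j_nm4
  out
}

#' Forster radius from the overlap integral
#'
#' `R0^6 = 8.8e-25 * k2 * phi * n^-4 * J` with J in M^-1 cm^3 gives R0^6
#' in cm^6; R0 is returned in nm (1 cm = 1e7 nm). R0 is the donor-acceptor
#' distance at which transfer efficiency is 50 percent.
#'
#' @param J Overlap integral, M^-1 cm^3 (>= 0).
#' @param constants A [fret_constants()].
#' @return R0 in nm.
#' @examples
#' forster_radius(1.758e-15)  # about 1.91 nm
#' @export
forster_radius <- function(J, constants = fret_constants()) {
  stopifnot(inherits(constants, "fret_constants"))
  J <- as.numeric(J)
  if (any(J < 0)) stop_specbind("J must be >= 0", "malformed_input")
  r0_cm6 <- 8.8e-25 * constants$k2 * constants$phi *
    constants$n_refractive^-4 * J
  r0_cm6^(1 / 6) * 1e7
}

#' Donor-acceptor distance from efficiency and Forster radius
#'
#' Inverts `E = R0^6 / (R0^6 + r^6)`: `r = R0 * (1/E - 1)^(1/6)`.
#'
#' @param E Transfer efficiency, strictly between 0 and 1.
#' @param R0 Forster radius, nm (> 0).
#' @return Binding distance r in nm.
#' @examples
#' binding_distance(0.088, 1.91)  # about 2.82 nm
#' @export
binding_distance <- function(E, R0) {
  if (any(R0 <= 0)) stop_specbind("R0 must be > 0", "malformed_input")
  if (any(E <= 0) || any(E >= 1))
    stop_specbind("E must be strictly between 0 and 1 (boundaries imply zero or infinite distance)",
                  "boundary")
  R0 * (1 / E - 1)^(1 / 6)
}

#' Plausibility windows for a FRET-derived distance
#'
#' Boolean flags: `non_radiative_plausible` when r < 7 nm (non-radiative
#' transfer is credible), `static_range` when 2 <= r <= 8 nm (the range
#' associated with static quenching), and the advisory
#' `within_half_to_1.5_R0` when 0.5*R0 <= r <= 1.5*R0 (distance estimates
#' are most reliable near R0).
#'
#' @param r Donor-acceptor distance, nm (> 0).
#' @param R0 Forster radius, nm (> 0).
#' @return Named logical list of the three flags.
#' @export
assess_validity <- function(r, R0) {
  if (any(r <= 0) || any(R0 <= 0))
    stop_specbind("r and R0 must be > 0", "malformed_input")
  list(non_radiative_plausible = r < 7,
       static_range = r >= 2 & r <= 8,
       within_half_to_1.5_R0 = r >= 0.5 * R0 & r <= 1.5 * R0)
}

#' Full Forster energy-transfer analysis
#'
#' Chains [transfer_efficiency()], [overlap_integral()],
#' [forster_radius()], [binding_distance()] and [assess_validity()] into a
#' single result.
#'
#' @param f0,f Donor fluorescence without / with acceptor.
#' @param donor,acceptor Spectra for the overlap integral (see
#'   [overlap_integral()]).
#' @param constants A [fret_constants()].
#' @return Object of class `fret_result`: `efficiency`, `J` (M^-1 cm^3),
#'   `J_nm4`, `R0` (nm), `r` (nm), `flags`, `constants`.
#' @export
fret_analysis <- function(f0, f, donor, acceptor,
                          constants = fret_constants()) {
  E <- transfer_efficiency(f0, f)
  J <- overlap_integral(donor, acceptor)
  R0 <- forster_radius(as.numeric(J), constants)
  r <- binding_distance(E, R0)
  structure(list(efficiency = E, J = as.numeric(J),
                 J_nm4 = attr(J, "J_nm4"), R0 = R0, r = r,
                 flags = assess_validity(r, R0), constants = constants),
            class = "fret_result")
}

#' @export
print.fret_result <- function(x, ...) {
  cat("Forster energy-transfer analysis\n")
  cat(sprintf("  E = %.4f, J = %.4g M^-1 cm^3\n", x$efficiency, x$J))
  cat(sprintf("  R0 = %.3f nm, r = %.3f nm\n", x$R0, x$r))
  fl <- x$flags
  cat(sprintf("  non-radiative plausible (r < 7 nm): %s\n",
              fl$non_radiative_plausible))
  cat(sprintf("  static-quenching range (2-8 nm): %s\n", fl$static_range))
  cat(sprintf("  within 0.5-1.5 R0 advisory: %s\n",
              fl$within_half_to_1.5_R0))
  invisible(x)
}
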