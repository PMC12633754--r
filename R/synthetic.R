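#' Multiplicative measurement-noise model
#'
#' Fluorescence noise scales with signal, so noise is applied as
#' `x * (1 + cv * z)` with `z` standard normal truncated at +/- 5 sigma.
#' A fixed seed makes generated tables bit-reproducible.
#'
#' @param cv Coefficient of variation (>= 0). `cv = 0` disables noise.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(cv = 0, seed = NULL) {
  cv <- as.numeric(cv)
  if (length(cv) != 1L || !is.finite(cv) || cv < 0)
    stop_specbind("cv must be a single value >= 0", "malformed_input")
  structure(list(cv = cv, seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "noise_model")
}

apply_noise <- function(x, noise) {
  if (noise$cv == 0) return(x)
  x * (1 + noise$cv * rnorm_trunc5(length(x)))
}

#' Ground truth for a 1:1 binding simulation
#'
#' Defines the thermodynamics of a simulated 1:1 protein-ligand complex.
#' The association constant at temperature T follows the van't Hoff
#' relation `Ka(T) = exp(-dH*1000/(R*T) + dS/R)` with R = 8.314 J/(mol K),
#' so a single (dH, dS) pair fixes Ka at every temperature. Under the
#' static-quenching forward model the effective Stern-Volmer constant
#' equals Ka.
#'
#' Defaults describe a flavonoid-class ligand binding a 2 uM protein with
#' Ka(298 K) of about 4e4 L/mol, enthalpy-driven (dH < 0, dS < 0).
#'
#' @param dH Binding enthalpy change, kJ/mol.
#' @param dS Binding entropy change, J/(mol K).
#' @param protein_conc Total protein concentration, mol/L.
#' @param f0 Unquenched fluorescence amplitude, arbitrary units.
#' @return Object of class `binding_truth`.
#' @seealso [ka_at()], [gen_titration()]
#' @export
binding_truth <- function(dH = -27.511, dS = -4.108, protein_conc = 2e-6,
                          f0 = 1000) {
  if (protein_conc <= 0) stop_specbind("protein_conc must be > 0",
                                       "malformed_input")
  if (f0 <= 0) stop_specbind("f0 must be > 0", "malformed_input")
  structure(list(dH = as.numeric(dH), dS = as.numeric(dS),
                 protein_conc = as.numeric(protein_conc),
                 n_sites = 1, f0 = as.numeric(f0)),
            class = "binding_truth")
}

#' Association constant implied by a binding ground truth
#'
#' @param truth A [binding_truth()].
#' @param temperature Temperature(s) in K.
#' @return Ka in L/mol (vectorised over `temperature`).
#' @export
ka_at <- function(truth, temperature) {
  stopifnot(inherits(truth, "binding_truth"))
  exp(-truth$dH * 1000 / (.R_GAS * temperature) + truth$dS / .R_GAS)
}

# Free-ligand concentration from the exact 1:1 equilibrium:
# Ka*Qf^2 + (1 + Ka*(P0 - Q0))*Qf - Q0 = 0, positive root.
free_ligand_1to1 <- function(ka, q_total, p_total) {
  b <- 1 + ka * (p_total - q_total)
  (-b + sqrt(b^2 + 4 * ka * q_total)) / (2 * ka)
}

#' Simulate fluorescence quenching titrations
#'
#' Forward model of static quenching by ground-state 1:1 complex formation:
#' only free protein fluoresces, so `F = F0 / (1 + Ka(T)*[Q])`. In the
#' default `"approx"` mode `[Q]` is the total ligand concentration (ligand
#' in excess over protein), which makes `F0/F` exactly linear in total
#' ligand with slope Ka — the regime Stern-Volmer analysis assumes. In
#' `"exact"` mode the free-ligand concentration is obtained from the 1:1
#' equilibrium quadratic, which is what the double-log binding plot
#' linearises exactly.
#'
#' An optional `"dynamic"` mode simulates collisional quenching instead:
#' Ksv grows linearly with temperature
#' (`Ksv(T) = ksv_dyn_298 * T / 298`) and fluorescence follows the same
#' hyperbolic law in total ligand. It exists so that quenching-mode
#' classification can be exercised against a known dynamic ground truth.
#'
#' @param truth A [binding_truth()].
#' @param temperatures Temperatures in K (default the study design
#'   298/303/310 K).
#' @param ligand_concs Total ligand concentrations in mol/L, including 0
#'   (default 0, 10, 30, 40, 50, 70, 80 uM).
#' @param noise A [noise_model()].
#' @param mode `"approx"`, `"exact"` or `"dynamic"` (see Details).
#' @param ksv_dyn_298 Dynamic-mode Stern-Volmer constant at 298 K, L/mol.
#' @return A list of [titration_series()], one per temperature, in the
#'   given order.
#' @examples
#' sims <- gen_titration(binding_truth(), noise = noise_model(0))
#' stern_volmer_fit(sims[[1]])
#' @export
gen_titration <- function(truth = binding_truth(),
                          temperatures = c(298, 303, 310),
                          ligand_concs = c(0, 10, 30, 40, 50, 70, 80) * 1e-6,
                          noise = noise_model(),
                          mode = c("approx", "exact", "dynamic"),
                          ksv_dyn_298 = 5e3) {
  mode <- match.arg(mode)
  stopifnot(inherits(truth, "binding_truth"), inherits(noise, "noise_model"))
  if (length(temperatures) == 0L)
    stop_specbind("temperatures must be non-empty", "malformed_input")
  if (!any(ligand_concs == 0))
    stop_specbind("ligand_concs must include 0 (the F0 reference)",
                  "malformed_input")
  with_preserved_seed(noise$seed, {
    lapply(temperatures, function(tt) {
      k <- switch(mode,
                  approx = ka_at(truth, tt),
                  exact = ka_at(truth, tt),
                  dynamic = ksv_dyn_298 * tt / 298)
      q_eff <- if (mode == "exact")
        free_ligand_1to1(k, ligand_concs, truth$protein_conc)
      else ligand_concs
      f <- truth$f0 / (1 + k * q_eff)
      f <- apply_noise(f, noise)
      titration_series(tt, truth$protein_conc, ligand_concs, f)
    })
  })
}

#' Simulate a dose-response inhibition table
#'
#' Noiseless inhibition follows the two-parameter logistic
#' `inhibition(c) = 100 * c^h / (c^h + IC50^h)` (floor 0, ceiling 100), so
#' inhibition at `c = IC50` is exactly 50 percent. Noise is multiplicative
#' on the inhibition values.
#'
#' @param ic50 Half-maximal inhibitory concentration, mol/L (> 0).
#' @param hill Hill slope (> 0).
#' @param concs Ligand concentrations, mol/L.
#' @param noise A [noise_model()].
#' @return A data frame with columns `conc` (mol/L) and `inhibition`
#'   (percent).
#' @export
gen_dose_response <- function(ic50, hill = 1,
                              concs = c(0, 5, 10, 20, 30, 45, 60, 80) * 1e-6,
                              noise = noise_model()) {
  if (ic50 <= 0) stop_specbind("ic50 must be > 0", "malformed_input")
  if (hill <= 0) stop_specbind("hill must be > 0", "malformed_input")
  inh <- ifelse(concs == 0, 0,
                100 * concs^hill / (concs^hill + ic50^hill))
  inh <- with_preserved_seed(noise$seed, apply_noise(inh, noise))
  data.frame(conc = as.numeric(concs), inhibition = inh)
}

#' Gaussian band specification
#'
#' @param center Band centre (nm or cm^-1).
#' @param width Gaussian sigma, same unit as `center` (> 0).
#' @param amplitude Peak amplitude (>= 0).
#' @return Object of class `band_spec`.
#' @export
band_spec <- function(center, width, amplitude = 1) {
  if (width <= 0) stop_specbind("width must be > 0", "malformed_input")
  if (amplitude < 0) stop_specbind("amplitude must be >= 0", "malformed_input")
  structure(list(center = as.numeric(center), width = as.numeric(width),
                 amplitude = as.numeric(amplitude)),
            class = "band_spec")
}

#' Simulate a band spectrum
#'
#' Sum of Gaussian bands evaluated on the axis, with multiplicative noise.
#' An empty band list yields an all-zero spectrum.
#'
#' @param bands A list of [band_spec()] (a single `band_spec` is accepted).
#' @param axis Numeric axis vector (must cover all band centres).
#' @param noise A [noise_model()].
#' @inheritParams spectrum_series
#' @return A [spectrum_series()].
#' @export
gen_band_spectrum <- function(bands, axis = seq(285, 500, by = 1),
                              noise = noise_model(),
                              axis_kind = c("wavelength_nm", "wavenumber_cm-1"),
                              unit = c("arbitrary_fluorescence", "absorbance",
                                       "molar_absorptivity"),
                              label = "synthetic band spectrum") {
  axis_kind <- match.arg(axis_kind)
  unit <- match.arg(unit)
  if (inherits(bands, "band_spec")) bands <- list(bands)
  vals <- numeric(length(axis))
  for (b in bands) {
    stopifnot(inherits(b, "band_spec"))
    if (b$center < min(axis) || b$center > max(axis))
      stop_specbind("axis must cover every band centre", "malformed_input")
    vals <- vals + b$amplitude * exp(-(axis - b$center)^2 / (2 * b$width^2))
  }
  vals <- with_preserved_seed(noise$seed, apply_noise(vals, noise))
  spectrum_series(axis, vals, axis_kind = axis_kind, unit = unit,
                  label = label)
}

#' Simulate a donor-emission / acceptor-absorption spectrum pair
#'
#' Produces a donor fluorescence emission spectrum (arbitrary units) and an
#' acceptor molar-absorptivity spectrum (L mol^-1 cm^-1) on a shared
#' wavelength axis, each a single Gaussian band. This is the input pair for
#' the spectral overlap integral in Forster energy-transfer analysis.
#'
#' Defaults: donor emission centred at 336 nm (tryptophan-dominated protein
#' emission), acceptor absorption centred at 370 nm with peak molar
#' absorptivity 2e4 L/(mol cm), typical of a flavonoid band-I absorption.
#'
#' @param donor_center,donor_width Donor emission centre and sigma, nm.
#' @param acceptor_center,acceptor_width Acceptor absorption centre and
#'   sigma, nm.
#' @param eps_max Acceptor peak molar absorptivity, L/(mol cm).
#' @param axis Shared wavelength axis, nm.
#' @param noise A [noise_model()] applied to the donor emission.
#' @return A list with elements `donor` and `acceptor`
#'   ([spectrum_series()] objects).
#' @export
gen_fret_pair <- function(donor_center = 336, donor_width = 25,
                          acceptor_center = 370, acceptor_width = 30,
                          eps_max = 2e4, axis = seq(285, 500, by = 1),
                          noise = noise_model()) {
  donor <- gen_band_spectrum(band_spec(donor_center, donor_width, 1000),
                             axis = axis, noise = noise,
                             unit = "arbitrary_fluorescence",
                             label = "donor emission")
  acceptor <- gen_band_spectrum(band_spec(acceptor_center, acceptor_width,
                                          eps_max),
                                axis = axis,
                                unit = "molar_absorptivity",
                                label = "acceptor absorption")
  list(donor = donor, acceptor = acceptor)
}
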