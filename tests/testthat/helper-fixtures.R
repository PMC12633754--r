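# Shared fixtures: published reference values for a four-flavonoid /
# elastase binding study, used as inputs to desk-level checks.

# Stern-Volmer constants (L/mol) by temperature (K) for each system.
ref_ksv <- list(
  quercetin   = c(`298` = 0.59e4, `303` = 0.58e4, `310` = 0.52e4),
  hyperoside  = c(`298` = 5.47e4, `303` = 4.85e4, `310` = 4.78e4),
  luteolin    = c(`298` = 1.15e4, `303` = 1.04e4, `310` = 0.98e4),
  luteoloside = c(`298` = 1.79e4, `303` = 1.66e4, `310` = 1.57e4))

# Reported (dH kJ/mol, dS J/(mol K)) with the force each implies.
ref_thermo <- data.frame(
  system = c("quercetin", "hyperoside", "luteolin", "luteoloside"),
  dH = c(-7.954, -27.511, -25.241, -2.924),
  dS = c(45.6521, -4.108, -6.585, 72.107),
  force = c("electrostatic", "hbond_vdw", "hbond_vdw", "electrostatic"))

# CD secondary-structure fractions (%): free protein then complexes.
ref_cd <- list(
  free        = c(7.50, 51.50, 41.00),
  quercetin   = c(6.36, 49.05, 44.59),
  hyperoside  = c(6.30, 47.36, 46.34),
  luteolin    = c(6.54, 46.53, 46.53),
  luteoloside = c(5.51, 50.58, 43.91))

# Reported IC50s (mol/L) in potency order luteolin < hyperoside <
# quercetin < luteoloside.
ref_ic50 <- c(quercetin = 53.2e-6, hyperoside = 31.01e-6,
              luteolin = 18.22e-6, luteoloside = 61.32e-6)

# Standard study design: 2 uM protein, 0-80 uM ligand, 3 temperatures.
study_ligand_concs <- c(0, 10, 30, 40, 50, 70, 80) * 1e-6
study_temps <- c(298, 303, 310)

# Write a small two-column spectrum file.
write_spec_file <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}

# Collinear titration constructed so F0/F = slope*[Q] + 1 exactly.
make_linear_titration <- function(slope, q = c(0, 1, 2, 3, 4) * 1e-5,
                                  f0 = 1000, temperature = 298,
                                  protein_conc = 2e-6) {
  titration_series(temperature, protein_conc, q, f0 / (slope * q + 1))
}
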