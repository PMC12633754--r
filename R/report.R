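#' Run a full per-ligand binding study
#'
#' Orchestrates the complete analysis sequence for each ligand of a study
#' configuration: IC50 fitting from a dose-response file, per-temperature
#' Stern-Volmer and double-log binding fits from titration files,
#' quenching-mode classification, van't Hoff thermodynamics with force
#' classification, Forster energy-transfer analysis from a donor/acceptor
#' spectrum pair, and CD secondary-structure bookkeeping. Stages are
#' independent: a ligand configured with only titration files yields a
#' report containing only the quenching/binding/thermodynamics sections.
#'
#' Per-stage errors are collected into a failure manifest rather than
#' aborting the study; the partial report is still returned (and written).
#'
#' The configuration is a YAML file or an equivalent nested list:
#' \preformatted{
#' seed: 1
#' output_dir: out            # optional; JSON written when present
#' constants:                 # optional overrides
#'   tau0: 1.0e-8
#'   k2: 0.6667
#'   phi: 0.15
#'   refractive_index: 1.336
#' ligands:
#'   - label: hyperoside
#'     dose_file: dose.csv            # conc,inhibition (mol/L, %)
#'     titration_files: [t298.csv, t303.csv, t310.csv]
#'     fret:
#'       donor_file: emission.csv     # 2-column nm spectrum
#'       acceptor_file: absorption.csv
#'       f0: 1000
#'       f: 912
#'     cd:
#'       free: [7.50, 51.50, 41.00]   # alpha, beta, coil (%)
#'       complexed: [6.30, 47.36, 46.34]
#' }
#'
#' @param config Path to a YAML study configuration, or the equivalent
#'   list.
#' @return Object of class `study_report`: `ligands` (named list of
#'   per-ligand reports), `summary` (data frame with IC50 and random-coil
#'   rankings), `failures` (manifest of stage errors), `config`.
#' @export
run_study <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$ligands))
  consts <- config$constants %||% list()
  tau0 <- consts$tau0 %||% 1e-8
  fconst <- fret_constants(k2 = consts$k2 %||% (2 / 3),
                           phi = consts$phi %||% 0.15,
                           n_refractive = consts$refractive_index %||% 1.336)
  if (!is.null(config$seed)) set.seed(as.integer(config$seed))
  failures <- list()
  note_failure <- function(label, stage, e) {
    failures[[length(failures) + 1L]] <<-
      list(ligand = label, stage = stage, message = conditionMessage(e))
    message(sprintf("[%s/%s] stage failed: %s", label, stage,
                    conditionMessage(e)))
    NULL
  }
  reports <- list()
  for (lig in config$ligands) {
    label <- lig$label %||% "unnamed"
    rep <- list(label = label)

    if (!is.null(lig$dose_file)) {
      rep$ic50 <- tryCatch({
        d <- utils::read.csv(lig$dose_file)
        fit <- fit_ic50(d)
        list(ic50_M = fit$ic50, ic50_se_M = fit$ic50_se, hill = fit$hill,
             fit_r2 = fit$fit_r2, flags = fit$flags,
             input_digest = content_digest(d))
      }, error = function(e) note_failure(label, "ic50", e))
    }

    if (!is.null(lig$titration_files)) {
      stage <- tryCatch({
        series <- lapply(lig$titration_files, read_titration)
        series <- lapply(series, correct_titration)
        sv <- lapply(series, stern_volmer_fit, tau0 = tau0)
        bind <- lapply(series, double_log_binding_fit)
        cls <- classify_quenching(sv)
        temps <- vapply(series, `[[`, 1, "temperature")
        ka <- vapply(bind, `[[`, 1, "ka")
        thermo <- if (length(temps) >= 2L)
          vant_hoff_regression(ka, temps) else NULL
        dig <- content_digest(lapply(series, function(s)
          list(s$temperature, s$protein_conc, s$points)))
        list(
          quenching = lapply(sv, function(f)
            list(temperature_K = f$temperature, ksv_L_per_mol = f$ksv,
                 kq_L_per_mol_s = f$kq, intercept = f$intercept,
                 fit_r = f$fit_r, flags = f$flags)),
          binding = lapply(bind, function(f)
            list(temperature_K = f$temperature, ka_L_per_mol = f$ka,
                 n_sites = f$n_sites, fit_r = f$fit_r,
                 excluded = f$excluded)),
          classification = list(verdict = cls$verdict,
                                evidence = cls$evidence[
                                  setdiff(names(cls$evidence), "table")]),
          thermodynamics = if (!is.null(thermo))
            list(dH_kJ_per_mol = thermo$dH, dS_J_per_mol_K = thermo$dS,
                 dG_kJ_per_mol_by_T = as.list(thermo$dG_by_T),
                 fit_r = thermo$fit_r, force_class = thermo$force_class),
          input_digest = dig)
      }, error = function(e) note_failure(label, "quenching_binding", e))
      if (!is.null(stage)) rep[names(stage)] <- stage
    }

    if (!is.null(lig$fret)) {
      rep$fret <- tryCatch({
        donor <- read_spectrum(lig$fret$donor_file,
                               unit = "arbitrary_fluorescence")
        acceptor <- read_spectrum(lig$fret$acceptor_file,
                                  unit = "molar_absorptivity")
        fr <- fret_analysis(lig$fret$f0, lig$fret$f, donor, acceptor,
                            constants = fconst)
        list(efficiency = fr$efficiency, J_M_cm3 = fr$J, R0_nm = fr$R0,
             r_nm = fr$r, flags = fr$flags,
             input_digest = content_digest(list(donor$values,
                                                acceptor$values,
                                                lig$fret$f0, lig$fret$f)))
      }, error = function(e) note_failure(label, "fret", e))
    }

    if (!is.null(lig$cd)) {
      rep$cd <- tryCatch({
        fr <- as.numeric(unlist(lig$cd$free))
        cx <- as.numeric(unlist(lig$cd$complexed))
        ch <- cd_change(cd_fractions(fr[1], fr[2], fr[3], "free"),
                        cd_fractions(cx[1], cx[2], cx[3], label))
        list(alpha_helix_decrease_pct = ch$alpha_helix_decrease,
             random_coil_increase_pct = ch$random_coil_increase,
             deltas = as.list(ch$deltas), flags = ch$flags,
             input_digest = content_digest(list(fr, cx)))
      }, error = function(e) note_failure(label, "cd", e))
    }

    reports[[label]] <- rep
  }

  ic50s <- vapply(reports, function(r)
    if (is.null(r$ic50)) NA_real_ else r$ic50$ic50_M, 1)
  coils <- vapply(reports, function(r)
    if (is.null(r$cd)) NA_real_ else r$cd$random_coil_increase_pct, 1)
  summary <- data.frame(label = names(reports),
                        ic50_M = unname(ic50s),
                        random_coil_increase_pct = unname(coils))
  summary$potency_rank <- rank(summary$ic50_M, na.last = "keep",
                               ties.method = "min")
  summary$coil_rank <- rank(-summary$random_coil_increase_pct,
                            na.last = "keep", ties.method = "min")
  out <- structure(list(ligands = reports, summary = summary,
                        failures = failures, config = config),
                   class = "study_report")
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    for (label in names(reports))
      jsonlite::write_json(reports[[label]],
                           file.path(config$output_dir,
                                     paste0(label, ".json")),
                           auto_unbox = TRUE, digits = NA, null = "null",
                           pretty = TRUE)
    jsonlite::write_json(list(summary = summary, failures = failures),
                         file.path(config$output_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  }
  out
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d ligand(s), %d stage failure(s)\n",
              length(x$ligands), length(x$failures)))
  print(x$summary)
  invisible(x)
}

fmt_row <- function(...) paste(c(...), collapse = " | ")

#' Render a study report as markdown
#'
#' Produces a human-readable markdown document with one section per
#' ligand: quenching constants by temperature (T, Ksv, Kq, r), binding
#' constants (T, Ka, n, r), thermodynamics (dH, dS, dG with force class),
#' FRET quantities and CD fractions. Flags are rendered as footnotes and
#' stage failures as a manifest.
#'
#' @param report A `study_report` from [run_study()], or a single
#'   per-ligand report list.
#' @return A single markdown string (invisibly also of class character).
#' @export
render_report <- function(report) {
  ligands <- if (inherits(report, "study_report")) report$ligands
  else list(report)
  lines <- c("# Binding study report", "")
  notes <- character(0)
  for (rep in ligands) {
    lines <- c(lines, sprintf("## %s", rep$label %||% "ligand"), "")
    if (!is.null(rep$ic50)) {
      lines <- c(lines, sprintf(
        "IC50 = %.4g uM (Hill %.3g, R^2 %.4f)", rep$ic50$ic50_M * 1e6,
        rep$ic50$hill, rep$ic50$fit_r2), "")
      notes <- c(notes, unlist(rep$ic50$flags))
    }
    if (!is.null(rep$quenching)) {
      lines <- c(lines, "### Quenching (Stern-Volmer)", "",
                 fmt_row("T (K)", "Ksv (L/mol)", "Kq (L/mol/s)", "r"),
                 fmt_row("---", "---", "---", "---"))
      for (q in rep$quenching) {
        lines <- c(lines, fmt_row(sprintf("%g", q$temperature_K),
                                  sprintf("%.4g", q$ksv_L_per_mol),
                                  sprintf("%.4g", q$kq_L_per_mol_s),
                                  sprintf("%.3f", q$fit_r)))
        notes <- c(notes, unlist(q$flags))
      }
      lines <- c(lines, "",
                 sprintf("Quenching mode: **%s**",
                         rep$classification$verdict), "")
    }
    if (!is.null(rep$binding)) {
      lines <- c(lines, "### Binding (double-log)", "",
                 fmt_row("T (K)", "Ka (L/mol)", "n", "r"),
                 fmt_row("---", "---", "---", "---"))
      for (b in rep$binding)
        lines <- c(lines, fmt_row(sprintf("%g", b$temperature_K),
                                  sprintf("%.4g", b$ka_L_per_mol),
                                  sprintf("%.3f", b$n_sites),
                                  sprintf("%.3f", b$fit_r)))
      lines <- c(lines, "")
    }
    if (!is.null(rep$thermodynamics)) {
      th <- rep$thermodynamics
      lines <- c(lines, "### Thermodynamics", "",
                 sprintf("dH = %.4g kJ/mol, dS = %.4g J/(mol K), force: **%s**",
                         th$dH_kJ_per_mol, th$dS_J_per_mol_K,
                         th$force_class), "",
                 fmt_row("T (K)", "dG (kJ/mol)"), fmt_row("---", "---"))
      for (tn in names(th$dG_kJ_per_mol_by_T))
        lines <- c(lines, fmt_row(tn, sprintf("%.4g",
                                              th$dG_kJ_per_mol_by_T[[tn]])))
      lines <- c(lines, "")
    }
    if (!is.null(rep$fret)) {
      lines <- c(lines, "### Energy transfer", "",
                 sprintf("E = %.4f, J = %.4g M^-1 cm^3, R0 = %.3f nm, r = %.3f nm",
                         rep$fret$efficiency, rep$fret$J_M_cm3,
                         rep$fret$R0_nm, rep$fret$r_nm), "")
      notes <- c(notes, names(Filter(isTRUE, rep$fret$flags)))
    }
    if (!is.null(rep$cd)) {
      lines <- c(lines, "### Secondary structure (CD)", "",
                 sprintf("alpha-helix decrease %.2f%%, random-coil increase %.2f%%",
                         rep$cd$alpha_helix_decrease_pct,
                         rep$cd$random_coil_increase_pct), "")
      notes <- c(notes, unlist(rep$cd$flags))
    }
  }
  if (inherits(report, "study_report") && length(report$failures)) {
    lines <- c(lines, "## Failure manifest", "")
    for (f in report$failures)
      lines <- c(lines, sprintf("- %s / %s: %s", f$ligand, f$stage,
                                f$message))
    lines <- c(lines, "")
  }
  notes <- unique(notes[nzchar(notes)])
  if (length(notes))
    lines <- c(lines, "---", "", paste0("[^flag]: flags raised: ",
                                        paste(notes, collapse = ", ")), "")
  paste(lines, collapse = "\n")
}
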