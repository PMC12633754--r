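#' Construct a spectrum series
#'
#' The universal spectral container used throughout the package: an ordered
#' axis (wavelength in nm or wavenumber in cm^-1) with one intensity-like
#' value per position. Values may be fluorescence intensities (arbitrary
#' units), absorbances, or molar absorptivities (L mol^-1 cm^-1).
#'
#' The axis is sorted ascending on construction (values are carried along);
#' duplicate axis positions are rejected because they make interpolation and
#' peak analysis ill-defined.
#'
#' @param axis Numeric vector of axis positions (nm or cm^-1), length >= 3.
#' @param values Numeric vector of the same length as `axis`.
#' @param axis_kind `"wavelength_nm"` or `"wavenumber_cm-1"`.
#' @param unit `"arbitrary_fluorescence"`, `"absorbance"` or
#'   `"molar_absorptivity"` (L mol^-1 cm^-1). Absorbance and molar
#'   absorptivity must be non-negative.
#' @param label Free-text label.
#' @return An object of class `spectrum_series` with elements `axis`,
#'   `values`, `axis_kind`, `unit`, `label`.
#' @examples
#' s <- spectrum_series(336:340, c(10, 30, 50, 30, 10))
#' peak_position(s)
#' @export
spectrum_series <- function(axis, values,
                            axis_kind = c("wavelength_nm", "wavenumber_cm-1"),
                            unit = c("arbitrary_fluorescence", "absorbance",
                                     "molar_absorptivity"),
                            label = "") {
  axis_kind <- match.arg(axis_kind)
  unit <- match.arg(unit)
  axis <- as.numeric(axis)
  values <- as.numeric(values)
  if (length(axis) != length(values))
    stop_specbind("axis and values must have the same length", "malformed_input")
  if (length(axis) < 3L)
    stop_specbind("a spectrum needs at least 3 points", "malformed_input")
  if (anyNA(axis) || anyNA(values) || any(!is.finite(axis)) ||
      any(!is.finite(values)))
    stop_specbind("axis and values must be finite", "malformed_input")
  if (anyDuplicated(axis))
    stop_specbind("duplicate axis positions", "duplicate_axis")
  ord <- order(axis)
  axis <- axis[ord]
  values <- values[ord]
  if (unit %in% c("absorbance", "molar_absorptivity") && any(values < 0))
    stop_specbind(sprintf("%s values must be >= 0", unit), "malformed_input")
  structure(list(axis = axis, values = values, axis_kind = axis_kind,
                 unit = unit, label = as.character(label)[1L]),
            class = "spectrum_series")
}

#' @export
print.spectrum_series <- function(x, ...) {
  cat(sprintf("<spectrum_series> %s\n", if (nzchar(x$label)) x$label else "(unlabelled)"))
  cat(sprintf("  %d points, %s %.4g..%.4g, unit: %s\n",
              length(x$axis), x$axis_kind, min(x$axis), max(x$axis), x$unit))
  invisible(x)
}

#' Construct a fluorescence titration series
#'
#' One temperature's quenching titration: fluorescence of a fixed protein
#' concentration at increasing total ligand (quencher) concentration,
#' including exactly one zero-ligand point that defines the unquenched
#' intensity F0. All concentrations are in mol/L.
#'
#' @param temperature Temperature in K (single value).
#' @param protein_conc Total protein concentration, mol/L (> 0).
#' @param ligand_conc Numeric vector of total ligand concentrations, mol/L,
#'   unique, containing exactly one zero.
#' @param fluorescence Positive fluorescence intensities, same length.
#' @param a_ex,a_em Optional absorbances at the excitation and emission
#'   wavelengths for inner-filter correction (recycled if length 1).
#' @return Object of class `titration_series`: `temperature`, `protein_conc`,
#'   and a `points` data frame ordered by ligand concentration.
#' @seealso [stern_volmer_fit()], [double_log_binding_fit()],
#'   [correct_titration()]
#' @export
titration_series <- function(temperature, protein_conc, ligand_conc,
                             fluorescence, a_ex = NULL, a_em = NULL) {
  temperature <- as.numeric(temperature)
  if (length(temperature) != 1L || !is.finite(temperature) || temperature <= 0)
    stop_specbind("temperature must be a single positive value (K)",
                  "malformed_input")
  protein_conc <- as.numeric(protein_conc)
  if (length(protein_conc) != 1L || !is.finite(protein_conc) ||
      protein_conc <= 0)
    stop_specbind("protein_conc must be a single positive value (mol/L)",
                  "malformed_input")
  ligand_conc <- as.numeric(ligand_conc)
  fluorescence <- as.numeric(fluorescence)
  if (length(ligand_conc) != length(fluorescence))
    stop_specbind("ligand_conc and fluorescence lengths differ",
                  "malformed_input")
  if (any(!is.finite(ligand_conc)) || any(ligand_conc < 0))
    stop_specbind("ligand concentrations must be finite and >= 0",
                  "malformed_input")
  if (any(!is.finite(fluorescence)) || any(fluorescence <= 0))
    stop_specbind("fluorescence values must be finite and > 0",
                  "malformed_input")
  if (anyDuplicated(ligand_conc))
    stop_specbind("ligand concentrations must be unique", "malformed_input")
  if (sum(ligand_conc == 0) != 1L)
    stop_specbind("exactly one zero-ligand point (F0) is required",
                  "missing_reference")
  pts <- data.frame(ligand_conc = ligand_conc, fluorescence = fluorescence)
  n <- nrow(pts)
  pts$a_ex <- if (is.null(a_ex)) NA_real_ else rep_len(as.numeric(a_ex), n)
  pts$a_em <- if (is.null(a_em)) NA_real_ else rep_len(as.numeric(a_em), n)
  pts <- pts[order(pts$ligand_conc), , drop = FALSE]
  rownames(pts) <- NULL
  structure(list(temperature = temperature, protein_conc = protein_conc,
                 points = pts),
            class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("<titration_series> T = %g K, [P0] = %.3g mol/L, %d points\n",
              x$temperature, x$protein_conc, nrow(x$points)))
  cat(sprintf("  F0 = %.6g, [Q] up to %.3g mol/L\n",
              titration_f0(x), max(x$points$ligand_conc)))
  invisible(x)
}

#' Unquenched reference intensity of a titration series
#'
#' @param series A [titration_series()].
#' @return The fluorescence at zero ligand (F0).
#' @export
titration_f0 <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  series$points$fluorescence[series$points$ligand_conc == 0]
}

# ---------------------------------------------------------------------------
# Readers

detect_delim <- function(lines) {
  if (any(grepl("\t", lines))) "\t" else ","
}

#' Read a two-column spectrum file
#'
#' Parses a delimited (comma or tab, auto-detected) two-column table of axis
#' position vs intensity. A header line is allowed and detected by failing
#' numeric parsing; rows with any non-numeric entry are dropped. The Unicode
#' minus sign (U+2212) is normalised before parsing and scientific notation
#' is accepted. Rows are re-sorted into ascending axis order.
#'
#' @param path Path to the file.
#' @inheritParams spectrum_series
#' @return A [spectrum_series()].
#' @export
read_spectrum <- function(path,
                          axis_kind = c("wavelength_nm", "wavenumber_cm-1"),
                          unit = c("arbitrary_fluorescence", "absorbance",
                                   "molar_absorptivity"),
                          label = basename(path)) {
  axis_kind <- match.arg(axis_kind)
  unit <- match.arg(unit)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    stop_specbind("empty spectrum file", "malformed_input")
  sep <- detect_delim(lines)
  parts <- strsplit(lines, sep, fixed = TRUE)
  ok <- vapply(parts, length, 1L) >= 2L
  ax <- val <- rep(NA_real_, length(lines))
  ax[ok] <- parse_numeric(vapply(parts[ok], `[[`, "", 1L))
  val[ok] <- parse_numeric(vapply(parts[ok], `[[`, "", 2L))
  keep <- is.finite(ax) & is.finite(val)
  if (sum(keep) < 3L)
    stop_specbind("fewer than 3 valid numeric rows", "malformed_input")
  ax <- ax[keep]
  val <- val[keep]
  if (anyDuplicated(ax))
    stop_specbind("duplicate axis positions in spectrum file",
                  "duplicate_axis")
  spectrum_series(ax, val, axis_kind = axis_kind, unit = unit, label = label)
}

#' Read a fluorescence titration file
#'
#' Expects a delimited table (comma or tab, auto-detected) with named columns
#' `temperature_K`, `protein_conc_M`, `ligand_conc_M`, `fluorescence` and
#' optional `a_ex`, `a_em`. Concentration columns may instead carry a `_uM`
#' suffix (`protein_conc_uM`, `ligand_conc_uM`), in which case they are
#' converted to mol/L on read. One temperature per file; the zero-ligand row
#' defines F0.
#'
#' @param path Path to the file.
#' @return A [titration_series()].
#' @export
read_titration <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop_specbind("titration file needs a header and data rows",
                  "malformed_input")
  sep <- detect_delim(lines)
  df <- utils::read.table(text = lines, sep = sep, header = TRUE,
                          colClasses = "character",
                          check.names = TRUE, strip.white = TRUE)
  pick <- function(base) {
    if (base %in% names(df)) return(parse_numeric(df[[base]]))
    alt <- sub("_M$", "_uM", base)
    if (alt != base && alt %in% names(df))
      return(parse_numeric(df[[alt]]) * 1e-6)
    NULL
  }
  temp <- pick("temperature_K")
  prot <- pick("protein_conc_M")
  lig <- pick("ligand_conc_M")
  fl <- if ("fluorescence" %in% names(df)) parse_numeric(df$fluorescence) else NULL
  if (is.null(temp) || is.null(prot) || is.null(lig) || is.null(fl))
    stop_specbind(paste("missing required column(s): need temperature_K,",
                        "protein_conc_M (or _uM), ligand_conc_M (or _uM),",
                        "fluorescence"), "malformed_input")
  if (length(unique(temp)) != 1L)
    stop_specbind("more than one temperature in a single titration file",
                  "mixed_series")
  if (length(unique(prot)) != 1L)
    stop_specbind("more than one protein concentration in a titration file",
                  "mixed_series")
  if (!any(lig == 0))
    stop_specbind("no zero-ligand row: F0 reference is missing",
                  "missing_reference")
  a_ex <- if ("a_ex" %in% names(df)) parse_numeric(df$a_ex) else NULL
  a_em <- if ("a_em" %in% names(df)) parse_numeric(df$a_em) else NULL
  titration_series(temp[1L], prot[1L], lig, fl, a_ex = a_ex, a_em = a_em)
}

#' Write a spectrum series to a two-column CSV
#'
#' @param s A [spectrum_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path) {
  stopifnot(inherits(s, "spectrum_series"))
  utils::write.table(data.frame(axis = s$axis, value = s$values), path,
                     sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a titration series to CSV
#'
#' Columns mirror what [read_titration()] expects, in mol/L.
#'
#' @param series A [titration_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_titration <- function(series, path) {
  stopifnot(inherits(series, "titration_series"))
  pts <- series$points
  df <- data.frame(temperature_K = series$temperature,
                   protein_conc_M = series$protein_conc,
                   ligand_conc_M = pts$ligand_conc,
                   fluorescence = pts$fluorescence)
  if (any(is.finite(pts$a_ex))) df$a_ex <- pts$a_ex
  if (any(is.finite(pts$a_em))) df$a_em <- pts$a_em
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Result envelopes

#' Build a result envelope
#'
#' A uniform JSON-serialisable wrapper for analysis outputs: the analysis
#' name, a content digest of the inputs, the parameters used, the named
#' numeric outputs (each carrying an explicit unit tag) and free-form
#' diagnostics.
#'
#' @param analysis_name Short name of the analysis stage.
#' @param outputs Named list; every element must be a list with elements
#'   `value` (finite numeric scalar) and `unit` (non-empty string, use
#'   `"dimensionless"` where appropriate).
#' @param parameters Named list of parameters used.
#' @param inputs Object(s) the analysis consumed; hashed into `input_digest`.
#' @param diagnostics Named list (fit correlation, residual summaries, ...).
#' @return Object of class `result_envelope`.
#' @export
result_envelope <- function(analysis_name, outputs, parameters = list(),
                            inputs = NULL, diagnostics = list()) {
  if (length(outputs) == 0L || is.null(names(outputs)) ||
      any(!nzchar(names(outputs))))
    stop_specbind("outputs must be a non-empty named list", "validation")
  for (nm in names(outputs)) {
    o <- outputs[[nm]]
    if (!is.list(o) || is.null(o$value) || is.null(o$unit) ||
        !is.numeric(o$value) || length(o$value) != 1L ||
        !nzchar(as.character(o$unit)[1L]))
      stop_specbind(sprintf("output '%s' must carry a numeric value and a unit tag", nm),
                    "validation")
  }
  structure(list(analysis_name = as.character(analysis_name)[1L],
                 package_version = as.character(utils::packageVersion("specbind")),
                 input_digest = content_digest(inputs),
                 parameters = parameters,
                 outputs = outputs,
                 diagnostics = diagnostics),
            class = "result_envelope")
}

#' Write a result envelope to JSON
#'
#' Numeric fields are written at full precision so that
#' `read_result(write_result(x))` reproduces them bit-exactly.
#'
#' @param env A [result_envelope()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result <- function(env, path) {
  stopifnot(inherits(env, "result_envelope"))
  jsonlite::write_json(unclass(env), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a result envelope from JSON
#'
#' @param path Path to a JSON file written by [write_result()].
#' @return A [result_envelope()].
#' @export
read_result <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                          simplifyMatrix = FALSE)
  structure(x, class = "result_envelope")
}

#' @export
print.result_envelope <- function(x, ...) {
  cat(sprintf("<result_envelope> %s (specbind %s)\n", x$analysis_name,
              x$package_version))
  for (nm in names(x$outputs))
    cat(sprintf("  %s = %.8g [%s]\n", nm, x$outputs[[nm]]$value,
                x$outputs[[nm]]$unit))
  invisible(x)
}
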