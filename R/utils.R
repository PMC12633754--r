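# Internal helpers shared across modules.

# Gas constant, J mol^-1 K^-1 (exact by convention here).
.R_GAS <- 8.314

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random stream. seed = NULL means "use the current stream".
with_preserved_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  expr
}

# Standard-normal draws truncated at +/- 5 sigma (inverse-CDF method, so a
# single uniform draw per value keeps the stream usage deterministic).
rnorm_trunc5 <- function(n) {
  lo <- stats::pnorm(-5)
  hi <- stats::pnorm(5)
  stats::qnorm(stats::runif(n, lo, hi))
}

# Numeric parsing that tolerates the Unicode minus (U+2212) found in
# instrument exports and typeset tables, plus surrounding whitespace.
parse_numeric <- function(x) {
  x <- gsub("\u2212", "-", trimws(as.character(x)))
  suppressWarnings(as.numeric(x))
}

# Midpoint quadrature widths for a (possibly non-uniform) sorted grid.
grid_widths <- function(g) {
  n <- length(g)
  if (n == 1L) return(1)
  w <- numeric(n)
  w[1L] <- (g[2L] - g[1L]) / 2
  w[n] <- (g[n] - g[n - 1L]) / 2
  if (n > 2L) w[2:(n - 1L)] <- (g[3:n] - g[1:(n - 2L)]) / 2
  w
}

stop_specbind <- function(msg, class) {
  stop(structure(class = c(class, "specbind_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1L))))
}

warn_specbind <- function(msg, class) {
  warning(structure(class = c(class, "specbind_warning", "warning", "condition"),
                    list(message = msg, call = sys.call(-1L))))
}

# MD5 of the canonical JSON rendering of an object; used as input digest in
# result envelopes so re-runs on identical inputs are recognisable.
content_digest <- function(x) {
  json <- jsonlite::toJSON(x, digits = NA, auto_unbox = TRUE, force = TRUE,
                           null = "null")
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf), add = TRUE)
  writeLines(as.character(json), tf, useBytes = TRUE)
  unname(tools::md5sum(tf))
}
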