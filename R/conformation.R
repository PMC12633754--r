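#' Locate a spectral peak
#'
#' Finds the maximum of a spectrum, optionally restricted to an axis
#' window. `method = "argmax"` returns the grid position of the maximum;
#' `"quadratic_interp"` (default) refines it by fitting a parabola through
#' the maximum and its two neighbours, which recovers the centre of a
#' smooth band to a small fraction of the grid step.
#'
#' A maximum on the window edge cannot be refined and raises an edge-peak
#' warning (the edge position is returned). Ties on a flat maximum are
#' broken to the smallest axis value and flagged.
#'
#' For FT-IR amide I work use `window = c(1600, 1700)` (the C=O stretching
#' region on a wavenumber axis).
#'
#' @param s A [spectrum_series()].
#' @param window Optional `c(lo, hi)` axis range.
#' @param method `"quadratic_interp"` or `"argmax"`.
#' @return Object of class `peak_estimate`: `position`, `height`,
#'   `method`, `flags`.
#' @export
peak_position <- function(s, window = NULL,
                          method = c("quadratic_interp", "argmax")) {
  stopifnot(inherits(s, "spectrum_series"))
  method <- match.arg(method)
  ax <- s$axis
  val <- s$values
  if (!is.null(window)) {
    window <- sort(as.numeric(window))
    keep <- ax >= window[1L] & ax <= window[2L]
    if (!any(keep))
      stop_specbind("window does not intersect the spectrum axis",
                    "malformed_input")
    ax <- ax[keep]
    val <- val[keep]
  }
  flags <- character(0)
  mx <- max(val)
  im <- which(val == mx)
  if (length(im) > 1L) {
    flags <- c(flags, "tie")
    im <- im[1L]               # smallest axis value wins
  }
  pos <- ax[im]
  height <- val[im]
  used <- method
  if (im == 1L || im == length(ax)) {
    flags <- c(flags, "edge_peak")
    warn_specbind("spectrum maximum lies on the window edge", "edge_peak")
    used <- "argmax"
  } else if (method == "quadratic_interp" && !("tie" %in% flags)) {
    x1 <- ax[im - 1L]; x2 <- ax[im]; x3 <- ax[im + 1L]
    y1 <- val[im - 1L]; y2 <- val[im]; y3 <- val[im + 1L]
    # vertex of the parabola through three (possibly non-uniform) points
    denom <- (x2 - x1) * (y2 - y3) - (x2 - x3) * (y2 - y1)
    if (denom != 0) {
      pos <- x2 - 0.5 * ((x2 - x1)^2 * (y2 - y3) -
                           (x2 - x3)^2 * (y2 - y1)) / denom
      height <- y2    # height refinement is not needed downstream
    }
  } else if ("tie" %in% flags) {
    used <- "argmax"
  }
  structure(list(position = pos, height = height, method = used,
                 flags = flags),
            class = "peak_estimate")
}

#' @export
print.peak_estimate <- function(x, ...) {
  cat(sprintf("Peak at %.4f (height %.4g, method %s)%s\n", x$position,
              x$height, x$method,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ", "), "]")
              else ""))
  invisible(x)
}

#' Peak shift between free and complexed spectra
#'
#' `delta = complex_position - free_position`. On a wavelength (nm) axis a
#' positive delta is a red shift (longer wavelength, more polar/exposed
#' fluorophore environment); on a wavenumber (cm^-1) axis a positive delta
#' is a shift to higher wavenumber. Channels name the measurement:
#' synchronous fluorescence at delta-lambda = 15 nm (`tyr_delta15`, Tyr) or
#' 60 nm (`trp_delta60`, Trp), UV-vis absorption (`uv`), or the FT-IR
#' amide I band (`amide_I`).
#'
#' @param free,complexed [spectrum_series()] of the free and complexed
#'   protein (matching axis kinds).
#' @param channel One of `"tyr_delta15"`, `"trp_delta60"`, `"uv"`,
#'   `"amide_I"`.
#' @param window,method Passed to [peak_position()]. For `channel =
#'   "amide_I"` on a wavenumber axis the window defaults to 1600-1700
#'   cm^-1.
#' @return Object of class `shift_report`: `free_position`,
#'   `complex_position`, `delta`, `channel`, `flags`.
#' @export
peak_shift <- function(free, complexed,
                       channel = c("trp_delta60", "tyr_delta15", "uv",
                                   "amide_I"),
                       window = NULL,
                       method = c("quadratic_interp", "argmax")) {
  channel <- match.arg(channel)
  method <- match.arg(method)
  stopifnot(inherits(free, "spectrum_series"),
            inherits(complexed, "spectrum_series"))
  if (free$axis_kind != complexed$axis_kind)
    stop_specbind("free and complexed spectra have different axis kinds",
                  "unit_error")
  if (is.null(window) && channel == "amide_I" &&
      free$axis_kind == "wavenumber_cm-1")
    window <- c(1600, 1700)
  pf <- peak_position(free, window = window, method = method)
  pc <- peak_position(complexed, window = window, method = method)
  structure(list(free_position = pf$position,
                 complex_position = pc$position,
                 delta = pc$position - pf$position,
                 channel = channel,
                 flags = unique(c(pf$flags, pc$flags))),
            class = "shift_report")
}

#' @export
print.shift_report <- function(x, ...) {
  dir <- if (x$delta > 0) "red/up" else if (x$delta < 0) "blue/down" else "none"
  cat(sprintf("Peak shift [%s]: %.4f -> %.4f (delta %+.4f, %s)\n",
              x$channel, x$free_position, x$complex_position, x$delta, dir))
  invisible(x)
}

#' UV-vis additivity test for complex formation
#'
#' Compares the absorbance of the protein-ligand mixture with the sum of
#' the components measured separately. For a non-interacting mixture the
#' absorbances are additive; `(A_free + A_ligand) > A_complex` indicates
#' ground-state complex formation.
#'
#' @param a_free Protein absorbance (>= 0).
#' @param a_ligand Ligand absorbance (>= 0).
#' @param a_complex Mixture absorbance (>= 0).
#' @return List with `difference` (`a_free + a_ligand - a_complex`) and
#'   `interaction_flag` (`difference > 0`).
#' @export
uv_additivity <- function(a_free, a_ligand, a_complex) {
  if (any(c(a_free, a_ligand, a_complex) < 0))
    stop_specbind("absorbances must be >= 0", "malformed_input")
  diff <- a_free + a_ligand - a_complex
  list(difference = diff, interaction_flag = diff > 0)
}

#' Circular-dichroism secondary-structure fractions
#'
#' Holds deconvolved secondary-structure percentages for one sample. The
#' three fractions should sum to about 100; sums outside 99-101 are
#' flagged (`sum_deviation`) but not rejected, since published
#' deconvolutions do not always close exactly.
#'
#' @param alpha_helix,beta_sheet,random_coil Percentages in `[0, 100]`.
#' @param label Sample label.
#' @return Object of class `cd_fractions`.
#' @export
cd_fractions <- function(alpha_helix, beta_sheet, random_coil, label = "") {
  v <- c(alpha_helix, beta_sheet, random_coil)
  if (any(!is.finite(v)) || any(v < 0) || any(v > 100))
    stop_specbind("fractions must be percentages in [0, 100]",
                  "malformed_input")
  s <- sum(v)
  flags <- if (s < 99 || s > 101) "sum_deviation" else character(0)
  structure(list(alpha_helix = as.numeric(alpha_helix),
                 beta_sheet = as.numeric(beta_sheet),
                 random_coil = as.numeric(random_coil),
                 total = s, flags = flags,
                 label = as.character(label)[1L]),
            class = "cd_fractions")
}

#' @export
print.cd_fractions <- function(x, ...) {
  cat(sprintf("CD fractions%s: alpha %.2f%%, beta %.2f%%, coil %.2f%% (sum %.2f)%s\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              x$alpha_helix, x$beta_sheet, x$random_coil, x$total,
              if (length(x$flags)) " !sum" else ""))
  invisible(x)
}

#' Secondary-structure change between free and complexed protein
#'
#' Per-fraction deltas between two [cd_fractions()]. `deltas` holds
#' `free - complexed` for each fraction (so the three deltas sum to the
#' difference of the row sums). The conventional readout quantities are
#' also reported directly: `alpha_helix_decrease = free - complexed` and
#' `random_coil_increase = complexed - free`. Sum-deviation flags from
#' either input are propagated.
#'
#' @param free,complexed [cd_fractions()] of the free and complexed
#'   protein.
#' @return Object of class `cd_change`.
#' @examples
#' ppe <- cd_fractions(7.50, 51.50, 41.00, "free")
#' cpx <- cd_fractions(5.51, 50.58, 43.91, "complex")
#' cd_change(ppe, cpx)$alpha_helix_decrease  # 1.99
#' @export
cd_change <- function(free, complexed) {
  stopifnot(inherits(free, "cd_fractions"), inherits(complexed, "cd_fractions"))
  deltas <- c(alpha_helix = free$alpha_helix - complexed$alpha_helix,
              beta_sheet = free$beta_sheet - complexed$beta_sheet,
              random_coil = free$random_coil - complexed$random_coil)
  structure(list(deltas = deltas,
                 alpha_helix_decrease = unname(deltas["alpha_helix"]),
                 random_coil_increase = -unname(deltas["random_coil"]),
                 flags = unique(c(free$flags, complexed$flags)),
                 labels = c(free = free$label, complexed = complexed$label)),
            class = "cd_change")
}

#' @export
print.cd_change <- function(x, ...) {
  cat(sprintf("CD change %s -> %s\n", x$labels[["free"]],
              x$labels[["complexed"]]))
  cat(sprintf("  alpha-helix decrease: %.2f%%, random-coil increase: %.2f%%\n",
              x$alpha_helix_decrease, x$random_coil_increase))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Rank ligands by induced random-coil increase
#'
#' Orders ligand labels by decreasing random-coil increase (the
#' disorder-inducing potency ordering). Ties are broken lexicographically
#' and flagged.
#'
#' @param changes Named numeric vector (label -> random-coil increase, in
#'   percentage points) or a named list of [cd_change()] objects.
#' @return Character vector of labels in descending order; attribute
#'   `"tie"` is `TRUE` when any two increases were equal.
#' @export
rank_by_random_coil <- function(changes) {
  if (is.list(changes) && all(vapply(changes, inherits, TRUE, "cd_change")))
    changes <- vapply(changes, `[[`, 1, "random_coil_increase")
  if (length(changes) < 2L || is.null(names(changes)))
    stop_specbind("need a named vector of >= 2 random-coil increases",
                  "malformed_input")
  ord <- order(-changes, names(changes), method = "radix")
  out <- names(changes)[ord]
  attr(out, "tie") <- anyDuplicated(changes) > 0L
  out
}
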