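# The cw-ESR spectrum container used throughout the package.

#' Create a cw-ESR spectrum object
#'
#' A spectrum is a first-derivative intensity sampled on a strictly
#' increasing, uniformly spaced magnetic-field axis (Gauss), together with
#' the microwave frequency (GHz) needed to convert field positions to g
#' values, and free-form provenance metadata.
#'
#' @param field Magnetic-field axis in Gauss; strictly increasing, uniform
#'   spacing (relative spacing variation below `1e-6` is tolerated).
#' @param intensity First-derivative signal amplitude (arbitrary units);
#'   same length as `field`.
#' @param mw_freq_GHz Microwave frequency in GHz, or `NA` if unknown
#'   (g-value conversion then fails downstream with an explicit error).
#' @param meta Named list of provenance metadata.
#' @return An object of class `esr_spectrum`.
#' @export
esr_spectrum <- function(field, intensity, mw_freq_GHz = NA_real_,
                         meta = list()) {
  field <- as.numeric(field)
  intensity <- as.numeric(intensity)
  if (length(field) != length(intensity)) {
    stop("field and intensity must have the same length")
  }
  if (length(field) >= 2L) {
    d <- diff(field)
    if (any(d <= 0)) stop("field axis must be strictly increasing")
    if (diff(range(d)) > 1e-6 * mean(d)) {
      stop("field axis must be uniformly spaced (use read_spectrum() to resample)")
    }
  }
  structure(
    list(field = field, intensity = intensity,
         mw_freq_GHz = as.numeric(mw_freq_GHz), meta = meta),
    class = "esr_spectrum"
  )
}

#' @export
print.esr_spectrum <- function(x, ...) {
  n <- length(x$field)
  cat("<esr_spectrum> ", n, " points", sep = "")
  if (n) {
    cat(sprintf(", field %.2f..%.2f G (step %.4f G)",
                x$field[1], x$field[n], if (n > 1) x$field[2] - x$field[1] else NA))
  }
  if (!is.na(x$mw_freq_GHz)) cat(sprintf(", %.4g GHz", x$mw_freq_GHz))
  cat("\n")
  if (length(x$meta)) {
    cat("  meta: ", paste(names(x$meta), unlist(lapply(x$meta, format)),
                          sep = "=", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
plot.esr_spectrum <- function(x, ..., xlab = "Magnetic field (G)",
                              ylab = "dA/dB (arb. u.)", type = "l") {
  graphics::plot(x$field, x$intensity, type = type, xlab = xlab, ylab = ylab, ...)
  graphics::abline(h = 0, col = "grey70", lty = 3)
  invisible(x)
}

#' @export
length.esr_spectrum <- function(x) length(x$field)

# replace the intensity, keep axis/metadata; internal
spectrum_with <- function(spec, intensity, note = NULL) {
  meta <- spec$meta
  if (!is.null(note)) meta$derived <- note
  esr_spectrum(spec$field, intensity, spec$mw_freq_GHz, meta)
}

# field step in Gauss
field_step <- function(spec) {
  if (length(spec$field) < 2L) stop("spectrum has fewer than 2 points")
  (spec$field[length(spec$field)] - spec$field[1]) / (length(spec$field) - 1L)
}

rms <- function(x) sqrt(mean(x^2))

# accept either an esr_spectrum or a bare numeric vector; returns intensity
as_intensity <- function(x) {
  if (inherits(x, "esr_spectrum")) x$intensity else as.numeric(x)
}
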