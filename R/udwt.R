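# Undecimated (a-trous / stationary) discrete wavelet transform.
#
# The transform is stored in "signal-domain" (zero-phase) form: at every
# level j the Detail D_j and Approximation A_j are obtained by circular
# convolution of the running approximation A_{j-1} with the zero-phase
# band kernels (g~ * g)/2 and (h~ * h)/2, where h, g are the analysis
# filters upsampled by 2^(j-1) and h~, g~ their time-reversed (synthesis)
# partners.  For an orthogonal pair |H(w)|^2 + |G(w)|^2 = 2 at every
# frequency, so A_{j-1} = A_j + D_j holds exactly (to rounding) and the
# inverse transform is a plain sum of retained components.  Components are
# zero-phase aligned with the input, so peak positions do not shift
# between levels.

#' Maximum number of UDWT decomposition levels
#'
#' For a signal of length `p` the deepest usable level is
#' `floor(log2(p))`: beyond it the upsampled filter support exceeds the
#' signal length.
#'
#' @param p Signal length (positive integer).
#' @return Integer level count, `floor(log2(p))`.
#' @examples
#' max_levels(1024)  # 10
#' max_levels(1000)  # 9
#' @export
max_levels <- function(p) {
  p <- as.numeric(p)
  if (length(p) != 1L || !is.finite(p) || p < 1 || p != floor(p)) {
    stop("p must be a single integer >= 1")
  }
  n <- 0L
  q <- 1
  while (2 * q <= p) {
    q <- 2 * q
    n <- n + 1L
  }
  n
}

#' Undecimated discrete wavelet transform
#'
#' Decomposes a signal into per-level Detail and Approximation components,
#' each of full input length (no downsampling; the a-trous scheme upsamples
#' the filters by `2^(j-1)` at level `j` instead).  Components satisfy the
#' additive telescoping identity `A[j-1] = A[j] + D[j]` (with `A[0]` the
#' input), so partial reconstruction by [iudwt()] is a sum of retained
#' components and "subtracting the Detail spectra" is identical to
#' "keeping the Approximation".
#'
#' @param signal An [esr_spectrum] or a numeric vector (finite values).
#' @param wavelet Wavelet name (see [wavelet_filter()]); default `"db6"`.
#' @param levels Number of levels; default (and maximum) `max_levels(p)`.
#' @param boundary `"periodic"` (circular; makes reconstruction and shift
#'   covariance exact) or `"symmetric"` (whole-sample reflection, for
#'   signals whose ends do not match).
#' @return An object of class `udwt_decomp`: list with `details` and
#'   `approximations` (each a list of length-`p` numeric vectors),
#'   `p`, `levels`, `wavelet`, `boundary`, `j0` (default reconstruction
#'   level, set to `levels`), and the input `field`/`mw_freq_GHz`/`meta`
#'   when an `esr_spectrum` was supplied.
#' @export
udwt <- function(signal, wavelet = "db6", levels = NULL,
                 boundary = c("periodic", "symmetric")) {
  boundary <- match.arg(boundary)
  spec <- if (inherits(signal, "esr_spectrum")) signal else NULL
  x <- as_intensity(signal)
  p <- length(x)
  if (p < 2L) stop("signal must have at least 2 samples")
  if (!all(is.finite(x))) stop("signal contains non-finite samples")
  nmax <- max_levels(p)
  if (is.null(levels)) levels <- nmax
  levels <- as.integer(levels)
  if (levels < 1L) stop("levels must be >= 1")
  if (levels > nmax) {
    stop("levels = ", levels, " exceeds max_levels(", p, ") = ", nmax)
  }
  wf <- wavelet_filter(wavelet)

  # zero-phase kernels: autocorrelations of the analysis filters, halved
  rh <- filter_autocorr(wf$lowpass) / 2
  rg <- filter_autocorr(wf$highpass) / 2
  span <- wf$n_taps - 1L   # kernel lags run -span..span

  if (boundary == "symmetric") {
    xe <- c(x, rev(x))     # whole-sample reflection, periodized
    pe <- 2L * p
  } else {
    xe <- x
    pe <- p
  }

  details <- vector("list", levels)
  approximations <- vector("list", levels)
  a <- xe
  for (j in seq_len(levels)) {
    up <- 2^(j - 1L)
    d <- circ_apply(a, rg, span, up, pe)
    a <- circ_apply(a, rh, span, up, pe)
    details[[j]] <- d[seq_len(p)]
    approximations[[j]] <- a[seq_len(p)]
    if (boundary == "symmetric") {
      # keep the extended running approximation consistent with its crop
      a_crop <- a[seq_len(p)]
      a <- c(a_crop, rev(a_crop))
    }
  }

  structure(
    list(details = details, approximations = approximations,
         p = p, levels = levels, wavelet = wf$name, boundary = boundary,
         j0 = levels,
         field = spec$field, mw_freq_GHz = spec$mw_freq_GHz,
         meta = spec$meta),
    class = "udwt_decomp"
  )
}

# symmetric autocorrelation r[m] = sum_t f[t] f[t+|m|], lags -(L-1)..(L-1)
filter_autocorr <- function(f) {
  L <- length(f)
  r <- numeric(2L * L - 1L)
  for (m in -(L - 1L):(L - 1L)) {
    t1 <- max(1L, 1L - m):min(L, L - m)
    r[m + L] <- sum(f[t1] * f[t1 + m])
  }
  r
}

# circular convolution of x (length p) with a symmetric kernel of lags
# -span..span upsampled by `up` (taps at lag m*up)
circ_apply <- function(x, kernel, span, up, p) {
  y <- numeric(p)
  idx0 <- seq_len(p) - 1L
  for (m in -span:span) {
    c_m <- kernel[m + span + 1L]
    if (c_m == 0) next
    src <- ((idx0 - m * up) %% p) + 1L
    y <- y + c_m * x[src]
  }
  y
}

#' Inverse UDWT with component selection
#'
#' Reconstructs a signal from a [udwt()] decomposition using only the
#' selected Detail levels and, optionally, the deepest Approximation.
#' Keeping everything returns the input (perfect reconstruction); keeping
#' nothing returns the zero signal with a warning.  The operation is
#' linear in the retained components.
#'
#' @param decomp A `udwt_decomp`.
#' @param keep_details Integer vector of Detail levels to retain
#'   (subset of `1:levels`); default all.
#' @param keep_approx Retain the level-`levels` Approximation? Default
#'   `TRUE`.
#' @return Numeric vector of length `decomp$p`, or an [esr_spectrum] if
#'   the decomposition was built from one.
#' @export
iudwt <- function(decomp, keep_details = seq_len(decomp$levels),
                  keep_approx = TRUE) {
  stopifnot(inherits(decomp, "udwt_decomp"))
  keep_details <- as.integer(keep_details)
  if (length(keep_details) &&
      (any(keep_details < 1L) || any(keep_details > decomp$levels))) {
    stop("keep_details must be a subset of 1..", decomp$levels)
  }
  y <- numeric(decomp$p)
  if (!length(keep_details) && !keep_approx) {
    warning("empty component selection: returning the zero signal")
  }
  for (j in keep_details) y <- y + decomp$details[[j]]
  if (keep_approx) y <- y + decomp$approximations[[decomp$levels]]
  if (!is.null(decomp$field)) {
    esr_spectrum(decomp$field, y, decomp$mw_freq_GHz, decomp$meta)
  } else {
    y
  }
}

#' @export
print.udwt_decomp <- function(x, ...) {
  cat("<udwt_decomp> ", x$levels, " levels, p = ", x$p,
      ", wavelet = ", x$wavelet, ", boundary = ", x$boundary, "\n", sep = "")
  e <- vapply(x$details, function(d) sqrt(mean(d^2)), numeric(1))
  cat("  Detail RMS by level: ",
      paste(sprintf("%.3g", e), collapse = " "), "\n", sep = "")
  invisible(x)
}
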