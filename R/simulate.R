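# First-order cw-ESR spectrum simulator: isotropic solution spectra and
# axial frozen-powder spectra with first-derivative lineshapes.

# CODATA 2018 constants
PLANCK_H <- 6.62607015e-34     # J s
BOHR_MAGNETON <- 9.2740100783e-24  # J/T
TESLA_TO_GAUSS <- 1e4

#' Resonance field for a g value
#'
#' Electron-Zeeman resonance condition `h nu = g mu_B B`, solved for the
#' field and expressed in Gauss.
#'
#' @param g g factor (> 0); isotropic value or effective orientation value.
#' @param mw_freq_GHz Microwave frequency in GHz (> 0).
#' @return Field in Gauss.
#' @examples
#' center_field(2.0023, 9.8)  # ~ 3497 G
#' @export
center_field <- function(g, mw_freq_GHz) {
  if (any(!is.finite(g)) || any(g <= 0)) stop("g must be positive")
  if (any(!is.finite(mw_freq_GHz)) || any(mw_freq_GHz <= 0)) {
    stop("mw_freq_GHz must be positive")
  }
  PLANCK_H * mw_freq_GHz * 1e9 / (g * BOHR_MAGNETON) * TESLA_TO_GAUSS
}

#' Define a group of equivalent magnetic nuclei
#'
#' @param A Hyperfine coupling in Gauss: a scalar (isotropic), a pair
#'   `c(Aperp, Apar)` (axial), or a triple `c(Ax, Ay, Az)` with
#'   `Ax == Ay` (axial, principal-values notation).  Signs are kept but
#'   only magnitudes affect first-order splittings.
#' @param I Nuclear spin: a non-negative half-integer (1/2, 1, 3/2, ...).
#' @param n Number of equivalent nuclei in the group (>= 1).  The group
#'   splits a line into `2 n I + 1` components with multinomial weights.
#' @param label Optional nucleus label (e.g. `"14N"`).
#' @return An object of class `nucleus_group` with fields `A` (length-1 or
#'   length-2 `c(Aperp, Apar)`), `I`, `n`, `label`, `axial`.
#' @export
nucleus_group <- function(A, I, n = 1L, label = NULL) {
  A <- as.numeric(A)
  if (length(A) == 3L) {
    if (abs(A[1] - A[2]) > 1e-9 * max(abs(A), 1)) {
      stop("only axial tensors are supported: need Ax == Ay")
    }
    A <- A[c(1L, 3L)]
  }
  if (!length(A) %in% c(1L, 2L)) stop("A must have length 1, 2 or 3")
  I <- as.numeric(I)
  if (length(I) != 1L || I < 0 || abs(2 * I - round(2 * I)) > 1e-9) {
    stop("I must be a non-negative half-integer")
  }
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  structure(
    list(A = A, I = I, n = n, label = label, axial = length(A) == 2L),
    class = "nucleus_group"
  )
}

#' Define a spin system
#'
#' @param g g factor: a scalar (isotropic), a pair `c(gperp, gpar)`
#'   (axial), or an axial triple.
#' @param nuclei List of [nucleus_group()] objects (possibly empty).
#' @param lineshape `"gaussian"` or `"lorentzian"`.
#' @param linewidth Width parameter in Gauss (> 0).
#' @param linewidth_convention `"fwhm"` -- `linewidth` is the full width at
#'   half maximum of the absorption profile -- or `"pp"` -- `linewidth` is
#'   the peak-to-peak width of the first-derivative line.
#' @param label Optional system label.
#' @return An object of class `spin_system`.
#' @export
spin_system <- function(g, nuclei = list(), lineshape = c("gaussian", "lorentzian"),
                        linewidth, linewidth_convention = c("fwhm", "pp"),
                        label = NULL) {
  lineshape <- match.arg(lineshape)
  linewidth_convention <- match.arg(linewidth_convention)
  g <- as.numeric(g)
  if (length(g) == 3L) {
    if (abs(g[1] - g[2]) > 1e-9) stop("only axial g tensors are supported")
    g <- g[c(1L, 3L)]
  }
  if (!length(g) %in% c(1L, 2L)) stop("g must have length 1, 2 or 3")
  if (any(g <= 0)) stop("g values must be positive")
  if (!is.list(nuclei)) nuclei <- list(nuclei)
  ok <- vapply(nuclei, inherits, logical(1), what = "nucleus_group")
  if (length(nuclei) && !all(ok)) stop("nuclei must be nucleus_group objects")
  linewidth <- as.numeric(linewidth)
  if (length(linewidth) != 1L || !is.finite(linewidth) || linewidth <= 0) {
    stop("linewidth must be a positive scalar (Gauss)")
  }
  structure(
    list(g = g, nuclei = nuclei, lineshape = lineshape,
         linewidth = linewidth, linewidth_convention = linewidth_convention,
         label = label, axial = length(g) == 2L),
    class = "spin_system"
  )
}

#' @export
print.spin_system <- function(x, ...) {
  cat("<spin_system>", if (!is.null(x$label)) x$label else "", "\n")
  cat("  g:", paste(format(x$g), collapse = ", "),
      if (x$axial) "(axial: gperp, gpar)" else "(isotropic)", "\n")
  for (ng in x$nuclei) {
    cat(sprintf("  %d x I=%s, A = %s G%s\n", ng$n, format(ng$I),
                paste(format(ng$A), collapse = ", "),
                if (!is.null(ng$label)) paste0("  [", ng$label, "]") else ""))
  }
  cat(sprintf("  %s lineshape, width %.4g G (%s)\n", x$lineshape,
              x$linewidth, x$linewidth_convention))
  invisible(x)
}

# multiplet of one equivalent group: total m = -nI..nI (step 1), weights =
# n-fold discrete self-convolution of rep(1, 2I+1)
group_multiplet <- function(I, n) {
  w <- 1
  for (k in seq_len(n)) w <- conv_full(w, rep(1, round(2 * I + 1)))
  m <- seq(-n * I, n * I, by = 1)
  list(m = m, w = as.numeric(w))
}

#' First-order stick pattern of a set of nucleus groups
#'
#' Enumerates all first-order resonance offsets
#' `sum_k m_k A_k` over the total nuclear magnetic quantum numbers of each
#' equivalent group, with weights given by products of the per-group
#' multinomial multiplicities.  Degenerate offsets are *not* merged: the
#' number of rows is always `prod(2 n_k I_k + 1)`.
#'
#' @param nuclei List of [nucleus_group()] objects (isotropic couplings;
#'   for axial groups pass effective couplings per orientation).
#' @param normalize Normalize weights to sum 1 (default) or leave them as
#'   raw multiplicities summing `prod((2 I_k + 1)^(n_k))`.
#' @param max_lines Combinatorial guard on the number of sticks
#'   (default 1e6).
#' @param A Optional numeric vector overriding each group's coupling
#'   (used internally for orientation-dependent effective couplings).
#' @return Data frame with columns `offset` (Gauss) and `weight`.
#' @export
stick_pattern <- function(nuclei, normalize = TRUE, max_lines = 1e6, A = NULL) {
  if (!length(nuclei)) {
    return(data.frame(offset = 0, weight = if (normalize) 1 else 1))
  }
  sizes <- vapply(nuclei, function(ng) round(2 * ng$n * ng$I + 1), numeric(1))
  if (prod(sizes) > max_lines) {
    stop("stick pattern would have ", prod(sizes), " lines (cap ", max_lines, ")")
  }
  Avals <- if (is.null(A)) {
    vapply(nuclei, function(ng) {
      if (ng$axial) stop("axial coupling needs an explicit effective A")
      ng$A
    }, numeric(1))
  } else {
    as.numeric(A)
  }
  offset <- 0
  weight <- 1
  for (k in seq_along(nuclei)) {
    gm <- group_multiplet(nuclei[[k]]$I, nuclei[[k]]$n)
    offset <- rep(offset, each = length(gm$m)) +
      rep(gm$m * abs(Avals[k]), times = length(offset))
    weight <- rep(weight, each = length(gm$w)) *
      rep(gm$w, times = length(weight))
  }
  if (normalize) weight <- weight / sum(weight)
  data.frame(offset = offset, weight = weight)
}

# first-derivative lineshape values at field offsets x (Gauss).
# gaussian: absorption exp(-x^2 / 2 sigma^2) / (sigma sqrt(2 pi));
#   fwhm convention: sigma = W / (2 sqrt(2 log 2)); pp: sigma = W / 2.
# lorentzian: absorption (Gamma/pi) / (x^2 + Gamma^2);
#   pp convention: Gamma = sqrt(3) W / 2; fwhm: Gamma = W / 2.
deriv_lineshape <- function(x, lineshape, width, convention) {
  if (lineshape == "gaussian") {
    sigma <- if (convention == "fwhm") width / (2 * sqrt(2 * log(2))) else width / 2
    -x / sigma^2 * exp(-x^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi))
  } else {
    gamma <- if (convention == "pp") sqrt(3) * width / 2 else width / 2
    -(2 / pi) * gamma * x / (x^2 + gamma^2)^2
  }
}

# Deposit weighted sticks onto the grid by linear (two-bin) splitting and
# convolve with the derivative lineshape via zero-padded FFT.
convolve_sticks <- function(field, positions, weights, lineshape, width,
                            convention) {
  p <- length(field)
  step <- (field[p] - field[1]) / (p - 1)
  u <- (positions - field[1]) / step
  if (any(u < 0) || any(u > p - 1)) {
    stop(sprintf(
      "field grid [%.6g, %.6g] G does not span all resonance positions [%.6g, %.6g] G",
      field[1], field[p], min(positions), max(positions)))
  }
  i0 <- pmin(floor(u), p - 2)
  frac <- u - i0
  binned <- numeric(p)
  acc1 <- tapply(weights * (1 - frac), i0 + 1, sum)
  acc2 <- tapply(weights * frac, i0 + 2, sum)
  binned[as.integer(names(acc1))] <- binned[as.integer(names(acc1))] + acc1
  binned[as.integer(names(acc2))] <- binned[as.integer(names(acc2))] + acc2

  np <- stats::nextn(3L * p, 2)
  kern <- numeric(np)
  lags <- c(0:(p - 1), -(p - 1):-1)   # wrap-around layout, center at index 1
  kern[c(seq_len(p), np - (p - 2):0)] <-
    deriv_lineshape(lags * step, lineshape, width, convention)
  xpad <- c(binned, numeric(np - p))
  y <- Re(stats::fft(stats::fft(xpad) * stats::fft(kern), inverse = TRUE)) / np
  y[seq_len(p)]
}

# resolve a grid spec (list(start, stop, points) or numeric axis) to a field
# axis; default spans the stick range plus `margin_widths` linewidths
resolve_grid <- function(grid, stick_range, width, points = 4096,
                         margin_widths = 10) {
  if (is.null(grid)) {
    lo <- stick_range[1] - margin_widths * width
    hi <- stick_range[2] + margin_widths * width
    return(seq(lo, hi, length.out = points))
  }
  if (is.list(grid)) {
    return(seq(grid$start, grid$stop, length.out = grid$points))
  }
  as.numeric(grid)
}

#' Simulate an isotropic first-order cw-ESR spectrum
#'
#' Places the first-order stick pattern around the resonance field
#' `center_field(g, mw_freq_GHz)` and convolves it with the system's
#' first-derivative lineshape.  The result integrates to ~0, as the
#' derivative of an absorption must.
#'
#' @param sys A [spin_system()] with isotropic `g` and couplings.
#' @param mw_freq_GHz Microwave frequency in GHz.
#' @param grid `NULL` (automatic: stick range plus 10 linewidths on a
#'   `points`-sample axis), a `list(start, stop, points)` in Gauss, or an
#'   explicit numeric field axis.  The grid must span every stick position
#'   with at least 5 linewidths of margin.
#' @param points Grid length used when `grid` is `NULL`.
#' @return An [esr_spectrum].
#' @export
simulate_isotropic <- function(sys, mw_freq_GHz, grid = NULL, points = 4096) {
  stopifnot(inherits(sys, "spin_system"))
  if (sys$axial) stop("sys has an axial g tensor; use simulate_axial_powder()")
  B0 <- center_field(sys$g, mw_freq_GHz)
  sticks <- stick_pattern(sys$nuclei)
  pos <- B0 + sticks$offset
  field <- resolve_grid(grid, range(pos), sys$linewidth, points)
  if (field[1] > min(pos) - 5 * sys$linewidth ||
      field[length(field)] < max(pos) + 5 * sys$linewidth) {
    stop(sprintf(
      "grid too narrow: need at least [%.4f, %.4f] G (sticks + 5 linewidths)",
      min(pos) - 5 * sys$linewidth, max(pos) + 5 * sys$linewidth))
  }
  intensity <- convolve_sticks(field, pos, sticks$weight, sys$lineshape,
                               sys$linewidth, sys$linewidth_convention)
  esr_spectrum(field, intensity, mw_freq_GHz,
               meta = list(system = if (is.null(sys$label)) "isotropic" else sys$label,
                           kind = "simulated_isotropic"))
}

#' Simulate an axial frozen-powder first-order cw-ESR spectrum
#'
#' First-order powder average over molecular orientations.  For each
#' orientation `theta` (angle between the symmetry axis and the field) on
#' a Gauss-Legendre grid in `cos(theta)`:
#' `g(theta) = sqrt(gpar^2 cos^2 + gperp^2 sin^2)`, each effective
#' coupling `A(theta) = sqrt(Apar^2 gpar^2 cos^2 + Aperp^2 gperp^2 sin^2)
#' / g(theta)`, and resonance fields `B = h nu / (g(theta) mu_B) +
#' sum_k m_k A_k(theta)`.  Orientations are weighted uniformly in
#' `cos(theta)` (isotropic powder); the stick accumulation is convolved
#' once with the derivative lineshape.
#'
#' @param sys A [spin_system()] with axial `g = c(gperp, gpar)`; nucleus
#'   groups may be axial or isotropic.
#' @param mw_freq_GHz Microwave frequency in GHz.
#' @param grid As in [simulate_isotropic()].
#' @param points Grid length used when `grid` is `NULL`.
#' @param n_orient Number of Gauss-Legendre orientation nodes in
#'   `cos(theta)` over [0, 1]; default 201.
#' @return An [esr_spectrum].
#' @export
simulate_axial_powder <- function(sys, mw_freq_GHz, grid = NULL,
                                  points = 4096, n_orient = 201) {
  stopifnot(inherits(sys, "spin_system"))
  if (!sys$axial) stop("sys has an isotropic g; use simulate_isotropic()")
  gperp <- sys$g[1]; gpar <- sys$g[2]
  Aperp <- vapply(sys$nuclei, function(ng) abs(ng$A[1]), numeric(1))
  Apar <- vapply(sys$nuclei, function(ng) abs(ng$A[length(ng$A)]), numeric(1))

  gl <- pracma::gaussLegendre(n_orient, 0, 1)   # nodes in cos(theta)
  ct2 <- gl$x^2
  st2 <- 1 - ct2
  g_eff <- sqrt(gpar^2 * ct2 + gperp^2 * st2)
  B0 <- center_field(g_eff, mw_freq_GHz)

  # per-group total-m patterns, combined across groups into an explicit
  # m-combination matrix (rows = stick combos, cols = groups)
  mlist <- lapply(sys$nuclei, function(ng) group_multiplet(ng$I, ng$n))
  combos <- expand.grid(lapply(mlist, function(gm) seq_along(gm$m)))
  M <- if (length(sys$nuclei)) {
    vapply(seq_along(mlist), function(k) mlist[[k]]$m[combos[[k]]],
           numeric(nrow(combos)))
  } else {
    matrix(0, nrow = 1, ncol = 0)
  }
  M <- matrix(M, nrow = max(nrow(combos), 1L))
  wgt <- if (length(sys$nuclei)) {
    Reduce(`*`, lapply(seq_along(mlist),
                       function(k) mlist[[k]]$w[combos[[k]]]))
  } else 1
  wgt <- wgt / sum(wgt)

  if (length(sys$nuclei)) {
    # n_orient x n_groups effective couplings
    A_eff <- sqrt(outer(ct2, Apar^2 * gpar^2, `*`) +
                  outer(st2, Aperp^2 * gperp^2, `*`)) / g_eff
    positions <- rep(B0, each = nrow(M)) + as.numeric(tcrossprod(M, A_eff))
  } else {
    positions <- B0
  }
  weights <- as.numeric(outer(wgt, gl$w))
  if (is.null(grid)) {
    field <- resolve_grid(NULL, range(positions), sys$linewidth, points)
  } else {
    field <- resolve_grid(grid, range(positions), sys$linewidth, points)
  }
  intensity <- convolve_sticks(field, positions, weights, sys$lineshape,
                               sys$linewidth, sys$linewidth_convention)
  esr_spectrum(field, intensity, mw_freq_GHz,
               meta = list(system = if (is.null(sys$label)) "axial_powder" else sys$label,
                           kind = "simulated_axial_powder"))
}

#' Add seeded white Gaussian noise to a spectrum
#'
#' @param spec An [esr_spectrum].
#' @param sigma Noise standard deviation as a fraction of
#'   `max(abs(intensity))`; `0` returns the input unchanged.
#' @param seed Integer seed; the global RNG state is restored afterwards.
#' @return An [esr_spectrum].
#' @export
add_noise <- function(spec, sigma, seed = NULL) {
  stopifnot(inherits(spec, "esr_spectrum"))
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(spec)
  scale <- sigma * max(abs(spec$intensity))
  noise <- with_seed(seed, stats::rnorm(length(spec$intensity), sd = scale))
  spectrum_with(spec, spec$intensity + noise, note = "noise_added")
}

# run expr under a temporary RNG seed, restoring global state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
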