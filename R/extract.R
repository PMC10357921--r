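# Turn decoupled components into numbers: derivative-line detection,
# peak-to-peak splitting measurement, splitting binning, g values.

#' Convert a resonance field to a g value
#'
#' Inverse of [center_field()]: `g = h nu / (mu_B B)`.
#'
#' @param B Field in Gauss (> 0).
#' @param mw_freq_GHz Microwave frequency in GHz (> 0).
#' @return g factor.
#' @export
g_from_field <- function(B, mw_freq_GHz) {
  if (any(!is.finite(B)) || any(B <= 0)) stop("B must be positive")
  if (any(!is.finite(mw_freq_GHz)) || any(mw_freq_GHz <= 0)) {
    stop("mw_freq_GHz must be positive")
  }
  PLANCK_H * mw_freq_GHz * 1e9 / (BOHR_MAGNETON * B / TESLA_TO_GAUSS)
}

#' Detect derivative lines in a spectral component
#'
#' Finds the alternating sequence of local maxima and minima, then prunes
#' it by *topographic prominence*: adjacent maximum/minimum pairs whose
#' amplitude swing is below `min_prominence` times the component's
#' maximum absolute amplitude are merged away, smallest swing first.  Each
#' surviving maximum-then-minimum pair is one *line*; its center is the
#' falling zero crossing between the two extrema when the signal changes
#' sign there (the usual case for a resolved derivative line), otherwise
#' the point of steepest descent (the same inflection, for shoulder lines
#' riding on a larger neighbor that keep the signal one-signed).
#'
#' @param component An [esr_spectrum] or numeric vector (then indices are
#'   used as the axis).
#' @param min_prominence Detection threshold as a fraction of the maximum
#'   absolute amplitude, in (0, 1); default 0.02.
#' @return An object of class `peak_set`: list with `maxima`, `minima`
#'   (fields, Gauss), `crossings` (one line-center per line),
#'   `prominences` (per-extremum swing fractions) and `lines`, a data
#'   frame with `max_field`, `min_field`, `crossing`, `amplitude`
#'   (half peak-to-trough swing as a fraction of the component maximum)
#'   and `zero_cross` (logical: center from a true sign change).
#'   An all-zero component yields an empty `peak_set`.
#' @export
find_lines <- function(component, min_prominence = 0.02) {
  if (min_prominence <= 0 || min_prominence >= 1) {
    stop("min_prominence must be in (0, 1)")
  }
  field <- if (inherits(component, "esr_spectrum")) component$field
           else seq_along(as.numeric(component))
  y <- as_intensity(component)
  empty <- function() {
    lines <- data.frame(max_field = numeric(0), min_field = numeric(0),
                        crossing = numeric(0), amplitude = numeric(0),
                        zero_cross = logical(0))
    structure(list(maxima = numeric(0), minima = numeric(0),
                   crossings = numeric(0), prominences = numeric(0),
                   lines = lines),
              class = "peak_set")
  }
  if (length(y) < 3L) return(empty())
  ymax <- max(abs(y))
  if (ymax == 0) return(empty())

  ext <- local_extrema(y)
  idx <- prune_extrema(ext$idx, y, min_prominence * ymax)
  if (length(idx) < 2L) return(empty())
  # extremum type from comparison with its pruned neighbors
  is_max <- logical(length(idx))
  for (k in seq_along(idx)) {
    nb <- c(if (k > 1L) y[idx[k - 1L]], if (k < length(idx)) y[idx[k + 1L]])
    is_max[k] <- y[idx[k]] > mean(nb)
  }

  lines <- list()
  for (k in seq_len(length(idx) - 1L)) {
    if (is_max[k] && !is_max[k + 1L]) {
      i1 <- idx[k]; i2 <- idx[k + 1L]
      ctr <- line_center(y, field, i1, i2)
      lines[[length(lines) + 1L]] <- data.frame(
        max_field = field[i1], min_field = field[i2],
        crossing = ctr$x, amplitude = (y[i1] - y[i2]) / (2 * ymax),
        zero_cross = ctr$zero_cross)
    }
  }
  lines <- if (length(lines)) do.call(rbind, lines) else empty()$lines
  prom <- abs(diff(y[idx])) / ymax
  structure(
    list(maxima = field[idx[is_max]],
         minima = field[idx[!is_max]],
         crossings = lines$crossing,
         prominences = pmin(c(prom, Inf), c(Inf, prom)),
         lines = lines),
    class = "peak_set"
  )
}

# indices of strict local extrema (alternating by construction)
local_extrema <- function(y) {
  d <- diff(y)
  s <- sign(d)
  # carry the last nonzero slope across plateaus
  nz <- s != 0
  if (!any(nz)) return(list(idx = integer(0)))
  s_f <- s
  last <- 0
  for (i in seq_along(s_f)) {
    if (s_f[i] == 0) s_f[i] <- last else last <- s_f[i]
  }
  turns <- which(diff(s_f) != 0) + 1L
  list(idx = turns)
}

# merge away adjacent extremum pairs whose swing is below `thr`
# (smallest first); keeps the sequence alternating
prune_extrema <- function(idx, y, thr) {
  idx <- as.integer(idx)
  repeat {
    if (length(idx) < 2L) return(idx)
    gaps <- abs(diff(y[idx]))
    k <- which.min(gaps)
    if (gaps[k] >= thr) return(idx)
    idx <- idx[-c(k, k + 1L)]
  }
}

# line center between a maximum at i1 and minimum at i2: falling zero
# crossing when the sign changes, else the steepest-descent point
# (parabolic refinement on the discrete slope)
line_center <- function(y, field, i1, i2) {
  seg <- y[i1:i2]
  sc <- which(seg[-length(seg)] > 0 & seg[-1] <= 0)
  if (length(sc)) {
    a <- i1 + sc[1] - 1L
    x0 <- field[a] + (field[a + 1L] - field[a]) * y[a] / (y[a] - y[a + 1L])
    return(list(x = x0, zero_cross = TRUE))
  }
  d <- diff(seg)
  k <- which.min(d)              # steepest falling segment
  x0 <- (field[i1 + k - 1L] + field[i1 + k]) / 2
  if (k > 1L && k < length(d)) {
    # parabolic interpolation of the slope minimum
    denom <- d[k - 1L] - 2 * d[k] + d[k + 1L]
    if (denom > 0) {
      delta <- 0.5 * (d[k - 1L] - d[k + 1L]) / denom
      delta <- max(min(delta, 1), -1)
      x0 <- x0 + delta * (field[2] - field[1])
    }
  }
  list(x = x0, zero_cross = FALSE)
}

#' @export
print.peak_set <- function(x, ...) {
  cat("<peak_set> ", nrow(x$lines), " lines (",
      length(x$maxima), " maxima, ", length(x$minima), " minima)\n", sep = "")
  if (nrow(x$lines)) print(x$lines, row.names = FALSE)
  invisible(x)
}

#' Peak-to-peak splittings of a detected line set
#'
#' Measures the splitting families used to read coupling constants off a
#' derivative multiplet: `"spacing"` -- distances between consecutive line
#' centers, the fundamental comb spacing -- `"spacing2"` -- line-center
#' distances at neighbor order 2.  When two couplings are nearly
#' degenerate (one about half the other, as with ortho/meta ring protons)
#' the resolved comb runs at the *smaller* coupling and the larger one
#' appears at order 2, so both orders are needed before binning.  `"pp"`
#' is the within-line maximum-to-minimum distance, the classical
#' derivative peak-to-peak width (a lineshape measure, not a coupling
#' estimator).
#'
#' @param peaks A `peak_set` from [find_lines()].
#' @param max_lag Highest neighbor order of line-center distances to
#'   include; default 2.
#' @return Data frame with columns `kind` (`"spacing"`, `"spacing2"`,
#'   ..., `"pp"`) and `value` (Gauss).
#' @export
splittings <- function(peaks, max_lag = 2L) {
  stopifnot(inherits(peaks, "peak_set"))
  n <- nrow(peaks$lines)
  if (n < 2L) stop("need at least 2 detected lines, got ", n)
  out <- data.frame(kind = "spacing", value = diff(peaks$lines$crossing))
  for (lag in seq_len(max_lag)[-1]) {
    if (n > lag) {
      out <- rbind(out, data.frame(kind = paste0("spacing", lag),
                                   value = diff(peaks$lines$crossing, lag = lag)))
    }
  }
  rbind(out,
        data.frame(kind = "pp",
                   value = peaks$lines$min_field - peaks$lines$max_field))
}

#' Bin similar splittings
#'
#' Single-linkage clustering on sorted values: a new bin starts wherever
#' the gap between consecutive sorted values exceeds `tol`.  Deterministic
#' (values are pre-sorted ascending); bins are returned sorted by
#' decreasing mean.
#'
#' @param values Numeric splittings (Gauss).
#' @param tol Gap tolerance in Gauss (> 0).  Practical defaults: ~0.3 G
#'   for radical spectra, ~3 G for metal-center spectra.
#' @return Data frame of class `splitting_bins` with columns `mean`,
#'   `count`, `spread` (max - min) and a list column `members`; empty
#'   input gives zero rows.
#' @export
bin_splittings <- function(values, tol = 0.3) {
  if (tol <= 0) stop("tol must be > 0")
  values <- sort(as.numeric(values))
  if (!length(values)) {
    out <- data.frame(mean = numeric(0), count = integer(0),
                      spread = numeric(0))
    out$members <- list()
    class(out) <- c("splitting_bins", "data.frame")
    return(out)
  }
  grp <- cumsum(c(1, diff(values) > tol))
  bins <- split(values, grp)
  out <- data.frame(
    mean = vapply(bins, mean, numeric(1)),
    count = vapply(bins, length, integer(1)),
    spread = vapply(bins, function(v) diff(range(v)), numeric(1))
  )
  out$members <- bins
  out <- out[order(-out$mean), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("splitting_bins", "data.frame")
  out
}

# dominant bin: most members; ties broken toward the smaller mean (the
# fundamental comb spacing rather than its higher orders)
dominant_bin <- function(bins) {
  if (!nrow(bins)) return(NULL)
  bins[order(-bins$count, bins$mean), ][1, , drop = FALSE]
}

#' Extract coupling constants and g values from a decoupling result
#'
#' Isotropic mode: the primary coupling is the largest splitting bin of
#' the hyperfine component's line spacings; super-hyperfine couplings are
#' the splitting bins of the super-hyperfine component; the isotropic g
#' value is taken at the multiplet centroid (mean of hyperfine-line
#' crossings).
#'
#' Axial mode (metal center, e.g. Cu(II) with an `I = 3/2` parallel
#' quartet): the parallel metal coupling and `g_par` come from the
#' quartet -- the three lowest-field lines fix the spacing, the fourth is
#' matched near its predicted position, and `g_par` is taken at the
#' quartet centroid; `g_perp` is taken at the crossing of the
#' maximum-amplitude hyperfine feature; ligand (e.g. nitrogen)
#' super-hyperfine couplings are measured as mean crossing spacings of the
#' super-hyperfine component in two field windows -- `low` around the
#' perpendicular feature and `high` around the highest-field quartet
#' line -- each of half-width `3 *` the dominant super-hyperfine splitting
#' unless overridden via `windows`.
#'
#' @param result A `decouple_result` from [pseudo_decouple()].
#' @param mode `"isotropic"` or `"axial"`.
#' @param min_prominence Line-detection threshold (fraction); default 0.02
#'   (isotropic) and 0.01 (axial: parallel powder features are weak).
#' @param tol Splitting-bin tolerance in Gauss; default 0.3 (isotropic) or
#'   3 (axial).
#' @param windows Optional list with elements `low` and `high`, each
#'   `c(from, to)` in Gauss, overriding the automatic windows (axial mode).
#' @return An object of class `extraction_report`: list with data frames
#'   `g_values` (`label`, `g`, `field_G`) and `A_values` (`label`, `A_G`,
#'   `uncertainty_G`, `source`, `n`), plus `j_star`, `warnings` and
#'   `details` (intermediate peak sets and bins).
#' @export
extract_report <- function(result, mode = c("isotropic", "axial"),
                           min_prominence = NULL, tol = NULL,
                           windows = NULL) {
  stopifnot(inherits(result, "decouple_result"))
  mode <- match.arg(mode)
  if (is.null(min_prominence)) {
    min_prominence <- if (mode == "isotropic") 0.02 else 0.01
  }
  if (is.null(tol)) tol <- if (mode == "isotropic") 0.3 else 3
  nu <- result$input$mw_freq_GHz
  warn <- character(0)
  g_values <- data.frame(label = character(0), g = numeric(0),
                         field_G = numeric(0))
  A_values <- data.frame(label = character(0), A_G = numeric(0),
                         uncertainty_G = numeric(0), source = character(0),
                         n = integer(0))
  add_A <- function(label, bin, source) {
    rbind(A_values, data.frame(label = label, A_G = bin$mean,
                               uncertainty_G = bin$spread / 2,
                               source = source, n = bin$count))
  }
  hf_peaks <- find_lines(result$hyperfine, min_prominence)
  # a super-hyperfine component carrying less than 0.1% of the input RMS is
  # reconstruction leakage, not structure: report nothing from it
  shf_rms <- sqrt(mean(result$superhyperfine$intensity^2))
  in_rms <- sqrt(mean(result$input$intensity^2))
  if (shf_rms < 1e-3 * in_rms) {
    shf_peaks <- find_lines(numeric(0))
    warn <- c(warn, "super-hyperfine component is negligible (< 0.1% of input RMS)")
  } else {
    shf_peaks <- find_lines(result$superhyperfine, min_prominence)
  }
  details <- list(hf_peaks = hf_peaks, shf_peaks = shf_peaks)

  if (mode == "isotropic") {
    if (nrow(hf_peaks$lines) >= 2L) {
      sp <- splittings(hf_peaks)
      spc <- sp$value[sp$kind == "spacing"]
      details$hf_bins <- bin_splittings(spc, tol)
      # primary coupling = mean spacing of the full multiplet (component
      # smoothing spreads individual spacings around the coupling)
      A_values <- rbind(A_values, data.frame(
        label = "A_primary", A_G = mean(spc),
        uncertainty_G = diff(range(spc)) / 2, source = "hyperfine",
        n = length(spc)))
    } else {
      warn <- c(warn, "hyperfine component has fewer than 2 lines; no primary coupling")
    }
    if (nrow(hf_peaks$lines) >= 1L && !is.na(nu)) {
      Bc <- mean(hf_peaks$lines$crossing)
      g_values <- rbind(g_values,
                        data.frame(label = "g_iso", g = g_from_field(Bc, nu),
                                   field_G = Bc))
    } else if (is.na(nu)) {
      warn <- c(warn, "no microwave frequency on the spectrum; g values skipped")
    }
    if (nrow(shf_peaks$lines) >= 2L) {
      sp <- splittings(shf_peaks)
      shf_bins <- bin_splittings(sp$value[grepl("^spacing", sp$kind)], tol)
      details$shf_bins <- shf_bins
      for (i in seq_len(nrow(shf_bins))) {
        A_values <- add_A(paste0("A_shf", i), shf_bins[i, ], "superhyperfine")
      }
    } else {
      warn <- c(warn, "super-hyperfine component has fewer than 2 lines")
    }
  } else {
    ax <- extract_axial(result, hf_peaks, shf_peaks, nu, tol, windows)
    g_values <- ax$g_values
    A_values <- rbind(A_values, ax$A_values)
    warn <- c(warn, ax$warnings)
    details <- c(details, ax$details)
  }

  structure(
    list(g_values = g_values, A_values = A_values, j_star = result$j_star,
         mode = mode, warnings = warn, details = details),
    class = "extraction_report"
  )
}

# axial-mode workhorse; returns g_values / A_values / warnings / details
#
# Field-position conventions for axial powder derivatives: a parallel
# turning point (theta = 0 edge) appears as an absorption-like cusp, so
# quartet positions are read at the line *maxima*; the perpendicular
# turning point is a derivative-like feature, so g_perp is read at the
# zero crossing nearest the absorption maximum (cumulative integral) of
# the hyperfine component.
extract_axial <- function(result, hf_peaks, shf_peaks, nu, tol, windows,
                          metal_min_G = 50, rel_amp = 0.05) {
  warn <- character(0)
  g_values <- data.frame(label = character(0), g = numeric(0),
                         field_G = numeric(0))
  A_values <- data.frame(label = character(0), A_G = numeric(0),
                         uncertainty_G = numeric(0), source = character(0),
                         n = integer(0))
  details <- list()
  lines <- hf_peaks$lines
  if (nrow(lines) < 3L) {
    return(list(g_values = g_values, A_values = A_values,
                warnings = "fewer than 3 hyperfine lines; axial extraction aborted",
                details = details))
  }
  # quartet candidates: lines above a relative amplitude floor (keeps the
  # weak parallel cusps, drops residual noise bumps)
  strong <- lines[lines$amplitude >= rel_amp * max(lines$amplitude), ,
                  drop = FALSE]
  pos <- strong$max_field

  # quartet anchors: the first consecutive pair of line maxima spaced by a
  # metal-scale splitting
  gaps <- diff(pos)
  a1 <- which(gaps > metal_min_G)[1]
  quartet_fit <- NULL
  if (!is.na(a1)) {
    q1 <- pos[a1]; d <- gaps[a1]
    ks <- c(1, 2)
    matched <- c(q1, pos[a1 + 1L])
    for (k in 3:4) {
      pred <- q1 + (k - 1) * d
      cand <- pos[abs(pos - pred) <= 0.2 * d]
      if (length(cand)) {
        ks <- c(ks, k)
        matched <- c(matched, cand[which.min(abs(cand - pred))])
      }
    }
    if (length(ks) >= 3L) {
      fit <- stats::lm(matched ~ ks)
      quartet_fit <- list(positions = matched, ks = ks,
                          A = unname(stats::coef(fit)[2]),
                          centroid = unname(stats::coef(fit)[1] +
                                            2.5 * stats::coef(fit)[2]),
                          resid = stats::sd(stats::residuals(fit)))
    } else {
      warn <- c(warn, "only two parallel-quartet lines matched; metal coupling from their spacing, quartet centroid not used")
      A_values <- rbind(A_values, data.frame(
        label = "A_par_metal", A_G = d, uncertainty_G = NA_real_,
        source = "hyperfine", n = 1L))
    }
  } else {
    warn <- c(warn, "no metal-scale line spacing found; no parallel quartet identified")
  }
  if (!is.null(quartet_fit)) {
    details$quartet <- quartet_fit
    A_values <- rbind(A_values, data.frame(
      label = "A_par_metal", A_G = quartet_fit$A,
      uncertainty_G = quartet_fit$resid,
      source = "hyperfine", n = length(quartet_fit$ks)))
    if (!is.na(nu)) {
      g_values <- rbind(g_values, data.frame(
        label = "g_par", g = g_from_field(quartet_fit$centroid, nu),
        field_G = quartet_fit$centroid))
    }
  }

  # g_perp: crossing nearest the absorption maximum
  absorb <- cumsum(result$hyperfine$intensity)
  Babs <- result$hyperfine$field[which.max(absorb)]
  Bperp <- lines$crossing[which.min(abs(lines$crossing - Babs))]
  details$absorption_max_G <- Babs
  if (!is.na(nu)) {
    g_values <- rbind(g_values, data.frame(
      label = "g_perp", g = g_from_field(Bperp, nu), field_G = Bperp))
  } else {
    warn <- c(warn, "no microwave frequency on the spectrum; g values skipped")
  }

  # ligand super-hyperfine splittings in the two field windows
  if (nrow(shf_peaks$lines) >= 3L) {
    sp <- splittings(shf_peaks)
    spc <- sp$value[sp$kind == "spacing"]
    mids <- (shf_peaks$lines$crossing[-1] +
             shf_peaks$lines$crossing[-nrow(shf_peaks$lines)]) / 2
    shf_bins <- bin_splittings(spc, tol)
    details$shf_bins <- shf_bins
    a_ref <- dominant_bin(shf_bins)$mean
    if (is.null(windows)) {
      windows <- list(low = Bperp + c(-3, 3) * a_ref)
      # high window anchored at the highest-field prominent hyperfine
      # feature (the m = +3/2 parallel turning point), which is far more
      # noise-stable than the fitted quartet centroid; mostly one-sided
      # because below it the ligand comb overlaps the perpendicular
      # envelope
      q4_anchor <- max(strong$max_field)
      if (q4_anchor > Bperp + 3 * a_ref) {
        windows$high <- q4_anchor + c(-1, 5) * a_ref
      }
    }
    details$windows <- windows
    # representative splitting in a window: the median of the consecutive
    # crossing spacings whose midpoints fall inside (robust against an
    # occasional spurious or missed crossing at the window edge)
    win_mean <- function(w, lab) {
      v <- spc[mids >= w[1] & mids <= w[2]]
      if (length(v) < 1L) {
        warn <<- c(warn, paste0("no super-hyperfine spacings in the ", lab, " window"))
        return(NULL)
      }
      data.frame(label = paste0("A_ligand_", lab),
                 A_G = stats::median(v),
                 uncertainty_G = diff(range(v)) / 2,
                 source = "superhyperfine", n = length(v))
    }
    if (!is.null(windows$low)) {
      r <- win_mean(windows$low, "low")
      if (!is.null(r)) A_values <- rbind(A_values, r)
    }
    if (!is.null(windows$high)) {
      r <- win_mean(windows$high, "high")
      if (!is.null(r)) A_values <- rbind(A_values, r)
    }
  } else {
    warn <- c(warn, "super-hyperfine component has fewer than 3 lines")
  }
  list(g_values = g_values, A_values = A_values, warnings = warn,
       details = details)
}

#' @export
print.extraction_report <- function(x, ...) {
  cat("<extraction_report> mode =", x$mode, ", level j* =", x$j_star, "\n")
  if (nrow(x$g_values)) {
    cat("g values:\n")
    print(transform(x$g_values, g = round(g, 4), field_G = round(field_G, 2)),
          row.names = FALSE)
  }
  if (nrow(x$A_values)) {
    cat("A values (Gauss):\n")
    print(transform(x$A_values, A_G = round(A_G, 3),
                    uncertainty_G = round(uncertainty_G, 3)),
          row.names = FALSE)
  }
  if (length(x$warnings)) {
    cat("warnings:\n")
    for (w in x$warnings) cat("  -", w, "\n")
  }
  invisible(x)
}
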