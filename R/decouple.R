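# Pseudo-decoupling: split a cw-ESR spectrum into hyperfine and
# super-hyperfine components by selective retention of UDWT components.

#' Pseudo-decouple a spectrum at a decomposition level
#'
#' Zeroes the low-level Detail components (noise and structure finer than
#' the feature of interest), then splits the spectrum at level `j_star`
#' into a *hyperfine* component -- the level-`j_star` Approximation path,
#' i.e. everything coarser than the super-hyperfine structure -- and a
#' *super-hyperfine* component -- the Detail(s) at `j_star` (optionally a
#' band of levels via `shf_levels`).  The three outputs
#' `hyperfine + superhyperfine + discarded` reconstruct the input exactly
#' when, as by default, `removed_levels` and `shf_levels` partition
#' `1:j_star`.
#'
#' The decomposition level is a user choice (inspect [level_scan()] for
#' guidance); it is not selected automatically.
#'
#' @param spec An [esr_spectrum].
#' @param j_star Decomposition level at which the split is made.
#' @param shf_levels Detail levels forming the super-hyperfine component;
#'   default `j_star`.  Use e.g. `5:7` when the super-hyperfine couplings
#'   span more than one frequency octave.
#' @param removed_levels Detail levels zeroed (discarded); default all of
#'   `1:(j_star-1)` not in `shf_levels`.  Must be a subset of
#'   `1:(j_star-1)`.
#' @param wavelet,boundary Passed to [udwt()].
#' @return An object of class `decouple_result`: list with `hyperfine`,
#'   `superhyperfine`, `discarded` (each an [esr_spectrum] on the input
#'   field axis), `j_star`, `removed_levels`, `shf_levels`, `decomp` (the
#'   full [udwt()] decomposition) and `input`.
#' @export
pseudo_decouple <- function(spec, j_star, shf_levels = j_star,
                            removed_levels = NULL,
                            wavelet = "db6",
                            boundary = c("periodic", "symmetric")) {
  stopifnot(inherits(spec, "esr_spectrum"))
  boundary <- match.arg(boundary)
  p <- length(spec$field)
  nmax <- max_levels(p)
  j_star <- as.integer(j_star)
  if (j_star < 1L || j_star > nmax) {
    stop("j_star = ", j_star, " out of range 1..", nmax)
  }
  shf_levels <- sort(unique(as.integer(shf_levels)))
  if (any(shf_levels < 1L) || any(shf_levels > j_star)) {
    stop("shf_levels must be a subset of 1..j_star")
  }
  if (is.null(removed_levels)) {
    removed_levels <- setdiff(seq_len(j_star - 1L), shf_levels)
  }
  removed_levels <- sort(unique(as.integer(removed_levels)))
  if (length(removed_levels) &&
      (any(removed_levels >= j_star) || any(removed_levels < 1L))) {
    stop("removed_levels must be a subset of 1..(j_star - 1)")
  }
  if (length(intersect(removed_levels, shf_levels))) {
    stop("removed_levels and shf_levels must be disjoint")
  }

  dec <- udwt(spec, wavelet = wavelet, levels = nmax, boundary = boundary)
  hf_levels <- setdiff(seq_len(nmax), seq_len(j_star))
  hyperfine <- iudwt(dec, keep_details = hf_levels, keep_approx = TRUE)
  superhyperfine <- iudwt(dec, keep_details = shf_levels, keep_approx = FALSE)
  discarded <- if (length(removed_levels)) {
    iudwt(dec, keep_details = removed_levels, keep_approx = FALSE)
  } else {
    spectrum_with(spec, numeric(p))
  }
  # levels in 1..j_star assigned to neither pile stay in the hyperfine path
  leftover <- setdiff(seq_len(j_star), c(removed_levels, shf_levels))
  if (length(leftover)) {
    extra <- iudwt(dec, keep_details = leftover, keep_approx = FALSE)
    hyperfine$intensity <- hyperfine$intensity + extra$intensity
  }

  structure(
    list(hyperfine = hyperfine, superhyperfine = superhyperfine,
         discarded = discarded, j_star = j_star,
         removed_levels = removed_levels, shf_levels = shf_levels,
         decomp = dec, input = spec),
    class = "decouple_result"
  )
}

#' @export
print.decouple_result <- function(x, ...) {
  cat("<decouple_result> level j* = ", x$j_star, "\n", sep = "")
  cat("  super-hyperfine from Detail level(s): ",
      paste(x$shf_levels, collapse = ", "), "\n", sep = "")
  cat("  removed Detail level(s): ",
      if (length(x$removed_levels)) paste(x$removed_levels, collapse = ", ")
      else "none", "\n", sep = "")
  cat(sprintf("  RMS: hyperfine %.3g, super-hyperfine %.3g, discarded %.3g\n",
              rms(x$hyperfine$intensity), rms(x$superhyperfine$intensity),
              rms(x$discarded$intensity)))
  invisible(x)
}

#' Per-level decoupling diagnostics
#'
#' Computes, for every level `j = 1..j_max`, the candidate
#' hyperfine/super-hyperfine pair of a level-`j` split, the number of
#' resolved derivative lines in each (see [find_lines()]) and residual RMS
#' values.  This is a diagnostic table supporting the (visual, per-user)
#' choice of the working level; it does not itself pick one.
#'
#' @param spec An [esr_spectrum].
#' @param j_max Deepest level to scan; default `max_levels(p)`.
#' @param min_prominence Line-detection threshold, as a fraction of the
#'   component's maximum absolute amplitude; default 0.02.
#' @param wavelet,boundary Passed to [udwt()].
#' @return A data frame with one row per level: `level`, `n_lines_hf`,
#'   `n_lines_shf`, `rms_hf`, `rms_shf`, `rms_removed` (RMS of the sum of
#'   Details below the level, i.e. what a default [pseudo_decouple()] at
#'   that level would discard) and `resolved` (logical: both candidate
#'   components carry at least one line).
#' @export
level_scan <- function(spec, j_max = NULL, min_prominence = 0.02,
                       wavelet = "db6",
                       boundary = c("periodic", "symmetric")) {
  stopifnot(inherits(spec, "esr_spectrum"))
  boundary <- match.arg(boundary)
  p <- length(spec$field)
  nmax <- max_levels(p)
  if (is.null(j_max)) j_max <- nmax
  j_max <- as.integer(j_max)
  if (j_max < 1L || j_max > nmax) stop("j_max out of range 1..", nmax)
  dec <- udwt(spec, wavelet = wavelet, levels = nmax, boundary = boundary)

  step <- field_step(spec)
  removed <- numeric(p)
  out <- vector("list", j_max)
  for (j in seq_len(j_max)) {
    hf <- iudwt(dec, keep_details = setdiff(seq_len(nmax), seq_len(j)),
                keep_approx = TRUE)
    shf <- iudwt(dec, keep_details = j, keep_approx = FALSE)
    if (j > 1L) removed <- removed + dec$details[[j - 1L]]
    n_hf <- nrow(find_lines(hf, min_prominence)$lines)
    shf_peaks <- find_lines(shf, min_prominence)
    n_shf <- nrow(shf_peaks$lines)
    spacing <- if (n_shf >= 3L) {
      stats::median(diff(shf_peaks$lines$crossing))
    } else {
      NA_real_
    }
    out[[j]] <- data.frame(
      level = j, n_lines_hf = n_hf, n_lines_shf = n_shf,
      spacing_shf = spacing,
      # a Detail whose typical line spacing falls inside its own frequency
      # octave carries genuine structure of that scale (as opposed to,
      # e.g., lineshape-edge wiggles riding at a much coarser spacing)
      in_octave = !is.na(spacing) &&
        spacing >= 2^j * step && spacing < 2^(j + 1L) * step,
      rms_hf = rms(hf$intensity), rms_shf = rms(shf$intensity),
      rms_removed = rms(removed),
      resolved = n_hf >= 1L && n_shf >= 1L
    )
  }
  out <- do.call(rbind, out)
  raw <- find_lines(spec, min_prominence)
  attr(out, "raw_spacing_G") <- if (nrow(raw$lines) >= 3L) {
    stats::median(diff(raw$lines$crossing))
  } else {
    NA_real_
  }
  attr(out, "step_G") <- step
  out
}

#' Heuristic working-level suggestion from a level scan
#'
#' Convenience companion to [level_scan()].  The finest splitting the
#' input spectrum itself resolves (the median spacing of its detected
#' line centers) fixes the octave of the fine structure; the first
#' decomposition level whose Detail band lies above that octave,
#' `floor(log2(spacing / step)) + 1`, is the natural split point -- the
#' resolved comb goes to the Detail path while coarser structure stays in
#' the Approximation.  When the input has too few resolved lines for a
#' spacing estimate, falls back to the deepest-populated in-octave Detail
#' of the scan (`in_octave` column, i.e. Details whose line spacing is
#' genuine structure of their scale) plus one.  This is a starting point
#' for inspection, not a substitute for it.
#'
#' @param scan A data frame from [level_scan()].
#' @param min_lines Minimum line count for a fallback Detail level to
#'   count as carrying structure; default 3.
#' @return A level (integer), or `NA` if no rule applies.
#' @export
suggest_level <- function(scan, min_lines = 3L) {
  s <- attr(scan, "raw_spacing_G")
  step <- attr(scan, "step_G")
  jmax <- max(scan$level)
  if (!is.null(s) && !is.na(s) && !is.null(step) && s > 0) {
    j <- floor(log2(s / step)) + 1L
    return(as.integer(min(max(j, 1L), jmax)))
  }
  ok <- scan$in_octave & scan$n_lines_shf >= min_lines
  if (!any(ok)) return(NA_integer_)
  j <- scan$level[ok][which.max(scan$n_lines_shf[ok])]
  as.integer(min(j + 1L, jmax))
}

#' Wavelet-domain denoising by Detail removal
#'
#' Returns the spectrum with the listed Detail levels zeroed (all other
#' components retained).  Removing levels 1, 2, ... strips the fastest
#' field variations -- where white measurement noise concentrates -- while
#' leaving structure wider than a few grid steps essentially intact.
#' Idempotent for a fixed level set.
#'
#' @param spec An [esr_spectrum].
#' @param noise_levels Integer vector of Detail levels to remove; empty
#'   selection returns the input unchanged.
#' @param wavelet,boundary Passed to [udwt()].
#' @return An [esr_spectrum].
#' @export
denoise <- function(spec, noise_levels = c(1L, 2L), wavelet = "db6",
                    boundary = c("periodic", "symmetric")) {
  stopifnot(inherits(spec, "esr_spectrum"))
  boundary <- match.arg(boundary)
  noise_levels <- sort(unique(as.integer(noise_levels)))
  if (!length(noise_levels)) return(spec)
  nmax <- max_levels(length(spec$field))
  if (any(noise_levels < 1L) || any(noise_levels > nmax)) {
    stop("noise_levels must be a subset of 1..", nmax)
  }
  dec <- udwt(spec, wavelet = wavelet, levels = nmax, boundary = boundary)
  iudwt(dec, keep_details = setdiff(seq_len(nmax), noise_levels),
        keep_approx = TRUE)
}
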