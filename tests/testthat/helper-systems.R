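# Shared generators for property-style tests.

# random two-coupling isotropic proton system with well-separated scales
# (ratio >= 3) and resolvable lines (width <= A2/4)
make_two_coupling <- function(seed) {
  set.seed(seed)
  A1 <- runif(1, 6, 15)
  ratio <- runif(1, 4, 8)
  A2 <- A1 / ratio
  n1 <- sample(1:2, 1)
  n2 <- sample(1:2, 1)
  width <- A2 / 5
  sys <- spin_system(2.003,
                     list(nucleus_group(A1, 0.5, n1),
                          nucleus_group(A2, 0.5, n2)),
                     "gaussian", width, "fwhm")
  span <- (n1 * A1 + n2 * A2) / 2 + 10 * width
  pts <- ceiling(2 * span / (A2 / 20))
  B0 <- center_field(2.003, 9.8)
  spec <- simulate_isotropic(sys, 9.8,
                             grid = list(start = B0 - span, stop = B0 + span,
                                         points = pts))
  list(A1 = A1, A2 = A2, n1 = n1, n2 = n2, spec = spec)
}

# the documented recovery procedure: scan-selected level, amplitude-floored
# line sets, dominant-bin fine coupling from the complement component
recover_couplings <- function(case) {
  sc <- level_scan(case$spec)
  js <- suggest_level(sc)
  res <- pseudo_decouple(case$spec, js)
  hf <- find_lines(res$hyperfine, 0.05)$lines
  hf <- hf[hf$amplitude >= 0.4 * max(hf$amplitude), , drop = FALSE]
  A1_est <- if (nrow(hf) >= 2) mean(diff(hf$crossing)) else NA_real_
  compl <- esr_spectrum(case$spec$field,
                        case$spec$intensity - res$hyperfine$intensity,
                        case$spec$mw_freq_GHz)
  sl <- find_lines(compl, 0.02)$lines
  sl <- sl[sl$amplitude >= 0.4 * max(sl$amplitude), , drop = FALSE]
  A2_est <- if (nrow(sl) >= 2) {
    v <- diff(sl$crossing)
    dominant_bin(bin_splittings(v, tol = 0.25 * stats::median(v)))$mean
  } else NA_real_
  list(A1 = A1_est, A2 = A2_est, j_star = js)
}

# effective |transfer|^2 of the level-j Detail / Approximation paths of the
# a-trous cascade, evaluated directly in the frequency domain -- the
# independent oracle for band-separation checks
udwt_transfer <- function(wavelet, j, omega, kind = c("detail", "approx")) {
  kind <- match.arg(kind)
  wf <- wavelet_filter(wavelet)
  t_lo <- function(w) {
    Mod(vapply(w, function(x) sum(wf$lowpass * exp(-1i * x * (0:(wf$n_taps - 1)))),
               complex(1)))^2 / 2
  }
  t_hi <- function(w) {
    Mod(vapply(w, function(x) sum(wf$highpass * exp(-1i * x * (0:(wf$n_taps - 1)))),
               complex(1)))^2 / 2
  }
  out <- rep(1, length(omega))
  for (i in seq_len(j - 1)) out <- out * t_lo(2^(i - 1) * omega)
  if (kind == "detail") out * t_hi(2^(j - 1) * omega) else out * t_lo(2^(j - 1) * omega)
}
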