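# First-order cw-ESR simulator.

test_that("stick patterns reproduce multiplet combinatorics", {
  # 6 equivalent protons: septet with binomial weights
  s <- stick_pattern(list(nucleus_group(7.91, 0.5, 6)), normalize = FALSE)
  expect_identical(nrow(s), 7L)
  expect_equal(s$weight[order(s$offset)], choose(6, 0:6))
  # 4 equivalent I = 1 nuclei: nonet, weights = fourfold self-convolution
  # of (1,1,1) -- frozen from that independent convolution
  s <- stick_pattern(list(nucleus_group(15, 1, 4)), normalize = FALSE)
  expect_identical(nrow(s), 9L)
  expect_equal(s$weight[order(s$offset)], c(1, 4, 10, 16, 19, 16, 10, 4, 1))
  # one I = 3/2 nucleus: equal-weight quartet
  s <- stick_pattern(list(nucleus_group(198, 1.5, 1)))
  expect_identical(nrow(s), 4L)
  expect_equal(s$weight, rep(0.25, 4))
  expect_equal(diff(sort(s$offset)), rep(198, 3))
})

test_that("stick counts multiply across groups and the cap triggers", {
  r1 <- esr_fixture("R1", "L")$system$nuclei
  expect_identical(nrow(stick_pattern(r1)), 175L)   # 7 x 5 x 5
  r2 <- esr_fixture("R2", "S")$system$nuclei
  expect_identical(nrow(stick_pattern(r2)), 405L)   # 3 x 5 x 3 x 3 x 3
  expect_equal(sum(stick_pattern(r1)$weight), 1)
  expect_error(stick_pattern(list(nucleus_group(1, 0.5, 50),
                                  nucleus_group(2, 0.5, 50)),
                             max_lines = 1000),
               "cap")
})

test_that("center_field implements the resonance condition", {
  # independent hand computation: B[G] = 714.4775 * nu[GHz] / g
  expect_equal(center_field(2.0023, 9.8), 3496.9, tolerance = 1e-4)
  expect_equal(center_field(2 * 2.0023, 9.8), center_field(2.0023, 9.8) / 2)
  expect_equal(center_field(2.0023, 3.3) / center_field(2.0023, 9.8), 3.3 / 9.8)
  expect_error(center_field(-1, 9.8), "positive")
  expect_error(center_field(2, 0), "positive")
})

test_that("isotropic simulation places and shapes lines correctly", {
  sys <- spin_system(2.0, list(nucleus_group(10, 0.5, 1)),
                     "gaussian", 0.3, "fwhm")
  spec <- simulate_isotropic(sys, 9.8, points = 8192)
  pk <- find_lines(spec, 0.1)
  expect_identical(nrow(pk$lines), 2L)
  expect_equal(diff(pk$lines$crossing), 10, tolerance = 0.01)
  expect_equal(mean(pk$lines$crossing), center_field(2.0, 9.8),
               tolerance = 0.01)
  # derivative spectrum integrates to ~0
  expect_lt(abs(sum(spec$intensity)), 1e-6 * max(abs(spec$intensity)))
  # grid must cover sticks + 5 linewidths
  expect_error(simulate_isotropic(sys, 9.8,
                                  grid = list(start = center_field(2, 9.8) - 5,
                                              stop = center_field(2, 9.8) + 5,
                                              points = 512)),
               "grid too narrow")
})

test_that("linewidth conventions match their definitions", {
  B0 <- center_field(2.0, 9.8)
  grid <- list(start = B0 - 20, stop = B0 + 20, points = 16384)
  pp_width <- function(lineshape, conv, w) {
    sys <- spin_system(2.0, list(), lineshape, w, conv)
    spec <- simulate_isotropic(sys, 9.8, grid = grid)
    l <- find_lines(spec, 0.5)$lines
    l$min_field - l$max_field
  }
  # "pp" convention: derivative peak-to-peak distance equals the width
  expect_equal(pp_width("gaussian", "pp", 2), 2, tolerance = 0.01)
  expect_equal(pp_width("lorentzian", "pp", 2), 2, tolerance = 0.01)
  # gaussian fwhm W: pp = W / sqrt(2 log 2)
  expect_equal(pp_width("gaussian", "fwhm", 2), 2 / sqrt(2 * log(2)),
               tolerance = 0.01)
  # lorentzian fwhm W (= 2 Gamma): pp = 2 Gamma / sqrt(3)
  expect_equal(pp_width("lorentzian", "fwhm", 2), 2 / sqrt(3),
               tolerance = 0.01)
})

test_that("axial powder patterns have turning points at the canonical fields", {
  sys <- spin_system(c(2.05, 2.19), list(), "lorentzian", 6, "pp")
  spec <- simulate_axial_powder(sys, 9.8, points = 4096)
  Bpar <- center_field(2.19, 9.8)
  Bperp <- center_field(2.05, 9.8)
  pk <- find_lines(spec, 0.02)
  # parallel edge: absorption-like cusp (a maximum) within one linewidth
  expect_lt(min(abs(pk$maxima - Bpar)), 6)
  # perpendicular edge: dominant derivative feature within one linewidth
  big <- pk$lines[which.max(pk$lines$amplitude), ]
  expect_lt(abs(big$crossing - Bperp), 6)
})

test_that("the degenerate axial system equals its isotropic limit", {
  ng_iso <- nucleus_group(12, 1, 2)
  sys_ax <- spin_system(c(2.1, 2.1), list(nucleus_group(c(12, 12), 1, 2)),
                        "gaussian", 1.5, "fwhm")
  sys_iso <- spin_system(2.1, list(ng_iso), "gaussian", 1.5, "fwhm")
  B0 <- center_field(2.1, 9.8)
  grid <- list(start = B0 - 60, stop = B0 + 60, points = 2048)
  ax <- simulate_axial_powder(sys_ax, 9.8, grid = grid, n_orient = 64)
  iso <- simulate_isotropic(sys_iso, 9.8, grid = grid)
  expect_lt(max(abs(ax$intensity - iso$intensity)),
            1e-6 * max(abs(iso$intensity)))
})

test_that("M-II parallel quartet spacing matches the first-order positions", {
  spec <- simulate_fixture("M2", "X")
  # theta = 0 first-order positions: B(par) + m * A_par(Cu)
  Bpar <- center_field(2.19, 9.8)
  pk <- find_lines(spec, 0.005)
  for (m in c(-1.5, -0.5)) {   # low-field lines clear of the perp region
    pred <- Bpar + m * 198.68
    expect_lt(min(abs(pk$maxima - pred)), 2)
  }
})

test_that("add_noise is seeded, scaled and restores the RNG state", {
  spec <- simulate_fixture("R1", "L")
  expect_identical(add_noise(spec, 0), spec)
  n1 <- add_noise(spec, 0.02, seed = 9)
  n2 <- add_noise(spec, 0.02, seed = 9)
  expect_identical(n1$intensity, n2$intensity)
  resid <- n1$intensity - spec$intensity
  expect_equal(stats::sd(resid), 0.02 * max(abs(spec$intensity)),
               tolerance = 0.05)
  set.seed(123); before <- rnorm(5)
  set.seed(123); invisible(add_noise(spec, 0.01, seed = 77)); after <- rnorm(5)
  expect_identical(before, after)
})

test_that("doubling grid density leaves extracted splittings unchanged", {
  # grid convergence: twice the density shifts every octave by one, so the
  # working level moves up by one and the measured couplings must agree
  fx <- esr_fixture("R1", "L")
  g2 <- fx$grid; g2$points <- 2L * g2$points
  v <- function(spec, j) {
    res <- pseudo_decouple(spec, j)
    hf <- find_lines(res$hyperfine, 0.02)
    shf <- find_lines(res$superhyperfine, 0.02)
    cr <- shf$lines$crossing
    b <- bin_splittings(c(diff(cr), diff(cr, lag = 2)), 0.3)
    c(mean(diff(hf$lines$crossing)), max(b$mean), min(b$mean))
  }
  v1 <- v(simulate_fixture("R1", "L"), 7)
  v2 <- v(simulate_isotropic(fx$system, fx$mw_freq_GHz, grid = g2), 8)
  expect_lt(max(abs(v1 - v2)), 0.02)
})
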