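# Line detection, splitting measurement, binning, g conversion.

test_that("a single derivative Gaussian gives one line centered at its origin", {
  x <- seq(-50, 50, length.out = 2048)
  step <- x[2] - x[1]
  spec <- esr_spectrum(x + 3400, -x * exp(-x^2 / (2 * 4)), 9.8)
  pk <- find_lines(spec, 0.02)
  expect_identical(nrow(pk$lines), 1L)
  expect_lt(abs(pk$lines$crossing - 3400), step)
  expect_true(pk$lines$zero_cross)
})

test_that("all-zero and tiny components give an empty peak set", {
  expect_identical(nrow(find_lines(rep(0, 100))$lines), 0L)
  expect_identical(nrow(find_lines(c(0, 1, 0))$lines), 0L)
  expect_error(find_lines(rnorm(10), min_prominence = 0), "min_prominence")
})

test_that("shoulder lines of an overlapped multiplet are detected", {
  # the outer lines of the R-I methyl septet keep the composite derivative
  # one-signed (no zero crossing) yet must be counted and located
  spec <- simulate_fixture("R1", "L")
  res <- pseudo_decouple(spec, 7)
  pk <- find_lines(res$hyperfine, 0.02)
  expect_identical(nrow(pk$lines), 7L)
  expect_true(any(!pk$lines$zero_cross))
  expect_true(any(pk$lines$zero_cross))
})

test_that("a true line is singled out of seeded noise at high prominence", {
  set.seed(55)
  x <- seq(-50, 50, length.out = 512)
  line <- -x / 4 * exp(-x^2 / 8)
  line <- line / max(abs(line))
  ok <- vapply(1:100, function(i) {
    pk <- find_lines(line + rnorm(512, sd = 0.05), 0.5)
    nrow(pk$lines) == 1 && abs(pk$lines$crossing - 257) < 5
  }, logical(1))
  expect_gte(mean(ok), 0.95)
  # raising the threshold can only reduce the line count
  set.seed(56)
  y <- line + rnorm(512, sd = 0.1)
  n_by_thr <- vapply(c(0.05, 0.2, 0.5, 0.8), function(p) {
    nrow(find_lines(y, p)$lines)
  }, numeric(1))
  expect_true(all(diff(n_by_thr) <= 0))
})

test_that("splittings separates spacing orders and peak-to-peak widths", {
  # seven equally spaced derivative lines, 8 G apart
  x <- seq(-40, 40, length.out = 8192)
  y <- rowSums(sapply((-3:3) * 8, function(c0) {
    -(x - c0) * exp(-(x - c0)^2 / (2 * 0.25))
  }))
  pk <- find_lines(esr_spectrum(x + 500, y, 1.4), 0.02)
  expect_identical(nrow(pk$lines), 7L)
  sp <- splittings(pk)
  expect_equal(sp$value[sp$kind == "spacing"], rep(8, 6), tolerance = 1e-3)
  expect_equal(sp$value[sp$kind == "spacing2"], rep(16, 5), tolerance = 1e-3)
  expect_identical(sum(sp$kind == "pp"), 7L)
  expect_error(splittings(find_lines(rep(0, 64))), "at least 2")
})

test_that("bin_splittings clusters by gap threshold deterministically", {
  b <- bin_splittings(c(8.1, 7.9, 2.6, 2.5, 1.3), tol = 0.3)
  expect_identical(nrow(b), 3L)
  expect_equal(b$mean, c(8.0, 2.55, 1.3))
  expect_identical(b$count, c(2L, 2L, 1L))
  expect_identical(nrow(bin_splittings(c(1.0, 1.1, 1.2), tol = 0.3)), 1L)
  expect_identical(nrow(bin_splittings(numeric(0), tol = 0.3)), 0L)
  expect_error(bin_splittings(1:3, tol = 0), "tol")
})

test_that("binning recovers three seeded generator means", {
  set.seed(77)
  v <- c(rnorm(400, 8, 0.05), rnorm(300, 2.6, 0.05), rnorm(300, 1.3, 0.05))
  b <- bin_splittings(v, tol = 0.3)
  expect_identical(nrow(b), 3L)
  expect_equal(b$mean, c(8, 2.6, 1.3), tolerance = 0.02 / 1.3)
})

test_that("g_from_field inverts center_field exactly", {
  for (g in c(1.9, 2.0023, 2.2)) {
    for (nu in c(1.4, 3.3, 9.8)) {
      expect_equal(g_from_field(center_field(g, nu), nu), g,
                   tolerance = 1e-12)
    }
  }
  expect_equal(g_from_field(3496.9, 9.8), 2.0023, tolerance = 1e-4)
  expect_equal(g_from_field(1748.45, 9.8), 2 * g_from_field(3496.9, 9.8))
  expect_error(g_from_field(-5, 9.8), "positive")
})

test_that("a zero-coupling isotropic system reports its g and no A values", {
  sys <- spin_system(2.07, list(), "gaussian", 0.5, "fwhm")
  spec <- simulate_isotropic(sys, 9.8, points = 4096)
  res <- pseudo_decouple(spec, 3)
  rep <- extract_report(res, mode = "isotropic")
  expect_identical(nrow(rep$A_values), 0L)
  expect_identical(rep$g_values$label, "g_iso")
  expect_lt(abs(rep$g_values$g - 2.07), 5e-4)
  expect_gt(length(rep$warnings), 0L)
})

test_that("extraction is stable under the prominence threshold", {
  # super-hyperfine couplings: stable across [0.01, 0.05]; the primary
  # (its outermost binomial lines swing ~6-9% relative) across [0.01, 0.03]
  spec <- simulate_fixture("R1", "L")
  res <- pseudo_decouple(spec, 7)
  shf_vals <- sapply(c(0.01, 0.03, 0.05), function(p) {
    r <- extract_report(res, min_prominence = p)
    r$A_values$A_G[r$A_values$source == "superhyperfine"]
  })
  expect_lt(max(abs(shf_vals - rowMeans(shf_vals))), 0.05)
  prim <- sapply(c(0.01, 0.02, 0.03), function(p) {
    r <- extract_report(res, min_prominence = p)
    r$A_values$A_G[r$A_values$label == "A_primary"]
  })
  expect_lt(diff(range(prim)), 0.05)
})

test_that("reported g values land on detected crossings of the components", {
  spec <- simulate_fixture("M2", "X")
  res <- pseudo_decouple(spec, 4)
  rep <- extract_report(res, mode = "axial")
  step <- spec$field[2] - spec$field[1]
  gperp <- rep$g_values[rep$g_values$label == "g_perp", ]
  B_back <- center_field(gperp$g, spec$mw_freq_GHz)
  crossings <- find_lines(res$hyperfine, 0.01)$lines$crossing
  expect_lt(min(abs(crossings - B_back)), step)
})

test_that("axial extraction warns instead of inventing a quartet", {
  # isotropic-like single feature passed through axial mode
  sys <- spin_system(c(2.05, 2.06), list(), "lorentzian", 4, "pp")
  spec <- simulate_axial_powder(sys, 9.8, points = 2048)
  res <- pseudo_decouple(spec, 3)
  rep <- extract_report(res, mode = "axial")
  expect_false("A_par_metal" %in% rep$A_values$label)
  expect_gt(length(rep$warnings), 0L)
})

test_that("the pipeline recovers both couplings of random two-scale systems", {
  fails <- 0L
  for (seed in 1:50) {
    case <- make_two_coupling(seed)
    est <- recover_couplings(case)
    ok <- !is.na(est$A1) && !is.na(est$A2) &&
      abs(est$A1 - case$A1) / case$A1 <= 0.05 &&
      abs(est$A2 - case$A2) / case$A2 <= 0.05
    if (!ok) fails <- fails + 1L
  }
  expect_identical(fails, 0L)
})
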