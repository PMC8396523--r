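# EICC extraction, integration, fractional abundances, quality
# attributes, confidence intervals.

test_that("theoretical m/z follows the proton-adduct formula", {
  expect_equal(theoretical_mz(147000, 25), 5881.0073, tolerance = 1e-4)
  expect_equal(theoretical_mz(100, 1), 101.007276, tolerance = 1e-6)
  mz <- theoretical_mz(147000, 22:32)
  expect_true(all(diff(mz) < 0))  # strictly decreasing in z
  expect_error(theoretical_mz(147000, 0), "positive integer")
  expect_error(theoretical_mz(-1, 5), "positive")
})

test_that("EICC extraction is linear and zero on empty runs", {
  flat <- ms_run(list(list(rt = 1, mz = c(3000, 4000), intensity = c(0, 0)),
                      list(rt = 2, mz = numeric(0), intensity = numeric(0))))
  ch <- extract_eicc(flat, 120000, quant_config(charges = 30:40))
  expect_equal(ch$intensity, c(0, 0))

  sim <- clean_copy_sim()
  cfg <- quant_config()
  m <- sim$truth$mass[1]
  ch1 <- extract_eicc(sim$run, m, cfg)
  run2 <- sim$run
  run2$scans <- lapply(run2$scans, function(s) {
    s$intensity <- 2 * s$intensity; s
  })
  ch2 <- extract_eicc(run2, m, cfg)
  expect_equal(ch2$intensity, 2 * ch1$intensity, tolerance = 1e-12)
})

test_that("EICC apex matches the simulated retention center", {
  sim <- clean_copy_sim()
  cfg <- quant_config()
  scan_gap <- diff(scan_times(sim$run))[1]
  for (i in c(1, 10, 25)) {
    ch <- extract_eicc(sim$run, sim$truth$mass[i], cfg)
    apex <- ch$rt[which.max(ch$intensity)]
    expect_lt(abs(apex - sim$truth$rt[i]), scan_gap + 1e-9)
  }
})

test_that("charges leaving the acquisition range are dropped with warning", {
  cfg <- quant_config(charges = 18:32, mz_range = c(2500, 8000))
  sim <- clean_copy_sim()
  # a ~148 kDa species at z=18 sits near 8230 Th, outside the range
  expect_warning(ch <- extract_eicc(sim$run, 148000, cfg), "dropping charge")
  expect_false(18L %in% ch$charges)
  cfg_bad <- quant_config(charges = 5:8)
  expect_error(suppressWarnings(extract_eicc(sim$run, 148000, cfg_bad)),
               "no usable charges")
})

test_that("trapezoidal integration matches closed forms and the Riemann oracle", {
  # constant intensity 1 over a 2-minute window -> area 2
  ch <- structure(list(rt = seq(0, 3, by = 0.1), intensity = rep(1, 31)),
                  class = "chromatogram")
  expect_equal(integrate_eicc(ch, c(0.5, 2.5)), 2, tolerance = 1e-12)

  # window outside the peak -> ~0
  g <- structure(list(rt = seq(0, 10, by = 0.05),
                      intensity = stats::dnorm(seq(0, 10, by = 0.05), 5, 0.2)),
                 class = "chromatogram")
  expect_lt(integrate_eicc(g, c(9, 10)), 1e-8)
  expect_error(integrate_eicc(g, c(20, 21)), "does not overlap")

  # random piecewise-linear traces vs brute-force Riemann sums
  set.seed(21)
  for (i in 1:10) {
    rt <- sort(stats::runif(40, 0, 10))
    it <- stats::runif(40, 0, 100)
    win <- sort(stats::runif(2, 0, 10))
    if (diff(win) < 0.5) win <- c(win[1], win[1] + 0.5)
    ch <- structure(list(rt = rt, intensity = it), class = "chromatogram")
    a <- integrate_eicc(ch, win)
    b <- riemann_area(rt, it, win)
    expect_lt(abs(a - b) / max(b, 1e-12), 1e-3)
  }
})

test_that("fractional abundances normalize and scale-invariantly", {
  fa <- fractional_abundances(c(a = 10, b = 30, c = 60))
  expect_equal(fa$fraction, c(0.10, 0.30, 0.60))
  expect_equal(fractional_abundances(c(x = 5))$fraction, 1)
  expect_error(fractional_abundances(c(a = 0, b = 0)), "positive")
  expect_error(fractional_abundances(c(a = -1, b = 2)), "negative")

  set.seed(9)
  for (i in 1:20) {
    areas <- stats::runif(sample(2:12, 1), 0, 1e6)
    names(areas) <- paste0("s", seq_along(areas))
    f1 <- fractional_abundances(areas)$fraction
    expect_lt(abs(sum(f1) - 1), 1e-12)
    f2 <- fractional_abundances(areas * stats::runif(1, 0.1, 1e4))$fraction
    expect_lt(max(abs(f1 - f2)), 1e-12)
  }
})

test_that("galactosylation level reproduces its closed-form cases", {
  mk <- function(fracs) {
    tibble::tibble(
      label = names(fracs), fraction = unname(fracs),
      gal_count = c(0L, 1L, 2L, 3L, 4L)[seq_along(fracs)],
      is_main = TRUE, is_sialylated = FALSE, is_afucosylated = FALSE,
      is_oligomannose = FALSE
    )
  }
  expect_equal(galactosylation_level(mk(c(g0 = 1))), 0)
  t4 <- mk(c(g0 = 0, g1 = 0, g2 = 0, g3 = 0, g4 = 1))
  expect_equal(galactosylation_level(t4), 100)
  # equal mix of G0F/G0F and G1F/G1F: (0 + 2) / (4 * 2) = 25%
  mix <- tibble::tibble(label = c("g0", "g2"), fraction = c(0.5, 0.5),
                        gal_count = c(0L, 2L), is_main = TRUE,
                        is_sialylated = FALSE, is_afucosylated = FALSE,
                        is_oligomannose = FALSE)
  expect_equal(galactosylation_level(mix), 25)
  expect_error(galactosylation_level(mix[0, ]), "scope")
})

test_that("class fractions cover the trivial and predicate cases", {
  tab <- tibble::tibble(
    label = c("a", "b", "c"), fraction = c(0.5, 0.3, 0.2),
    is_sialylated = c(FALSE, TRUE, TRUE), is_afucosylated = FALSE,
    is_oligomannose = c(TRUE, FALSE, FALSE)
  )
  expect_equal(class_fraction(tab, "sialylated"), 50)
  expect_equal(class_fraction(tab, "afucosylated"), 0)
  expect_equal(class_fraction(tab, rep(TRUE, 3)), 100)
  expect_equal(class_fraction(tab, function(r) r$label == "a"), 50)
})

test_that("replicate confidence intervals use the t quantile", {
  expect_equal(triplicate_ci(c(10, 10, 10)),
               c(mean = 10, halfwidth = 0))
  ci <- triplicate_ci(c(1, 2, 3))
  expect_equal(ci[["mean"]], 2)
  expect_equal(ci[["halfwidth"]], 2.484, tolerance = 1e-3)
  expect_equal(ci[["halfwidth"]], stats::qt(0.975, 2) / sqrt(3), tolerance = 1e-9)
  # halfwidth scales linearly with the sample SD
  ci10 <- triplicate_ci(10 * c(1, 2, 3))
  expect_equal(ci10[["halfwidth"]], 10 * ci[["halfwidth"]], tolerance = 1e-9)
  expect_error(triplicate_ci(5), "two replicates")
})

test_that("auto windows bracket the simulated retention centers", {
  sim <- clean_copy_sim()
  wins <- auto_rt_windows(sim$run, unique(sim$truth$mass), quant_config())
  covered <- vapply(sim$truth$rt, function(r) {
    any(vapply(wins, function(w) r >= w[1] && r < w[2], TRUE))
  }, TRUE)
  expect_true(all(covered))
})
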