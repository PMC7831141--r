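test_that("noiseless simulation returns the exact model expectation", {
  tr <- simulate_decay(650, 1e4, baseline = 0, noise = "none")
  expect_equal(tr$counts, 1e4 * exp(-tr$time_ns / 650))
  tr2 <- simulate_decay(650, 9500, baseline = 3, tau2 = 20000,
                        amplitude2 = 500, noise = "none")
  expect_equal(tr2$counts, 9500 * exp(-tr2$time_ns / 650) +
                 500 * exp(-tr2$time_ns / 20000) + 3)
})

test_that("simulation is reproducible under a fixed seed and flags short windows", {
  a <- simulate_decay(700, 1e4, seed = 5)
  b <- simulate_decay(700, 1e4, seed = 5)
  expect_identical(a$counts, b$counts)
  expect_false(identical(a$counts, simulate_decay(700, 1e4, seed = 6)$counts))
  expect_error(simulate_decay(700, 1e4), "seed")
  expect_true(isTRUE(simulate_decay(700, 1e4, t_max = 1400,
                                    noise = "none")$meta$short_window))
  expect_error(simulate_decay(-5, 10, noise = "none"), "finite and > 0")
})

test_that("background subtraction floors at zero and leaves the input alone", {
  tr <- decay_trace(c(1, 2, 3), c(10, 5, 2))
  out <- subtract_background(tr, 2)
  expect_equal(out$counts, c(8, 3, 0))
  expect_equal(tr$counts, c(10, 5, 2))
  expect_equal(subtract_background(tr, 0)$counts, tr$counts)
  expect_error(subtract_background(tr, -1), ">= 0")
})

test_that("background subtraction of the true baseline leaves tau unchanged", {
  tr <- simulate_decay(700, 4e4, baseline = 20, seed = 17)
  f_raw <- fit_mono(tr)
  f_sub <- fit_mono(subtract_background(tr, 20))
  expect_equal(f_sub$tau1, f_raw$tau1, tolerance = 0.01)
})

test_that("mono fits recover noiseless generating parameters exactly", {
  for (tau in c(400, 650, 710.8, 900)) {
    tr <- simulate_decay(tau, 1e4, baseline = 7, noise = "none")
    f <- fit_mono(tr)
    expect_true(f$converged)
    expect_equal(f$tau1, tau, tolerance = 1e-6)
    expect_equal(f$amplitude1, 1e4, tolerance = 1e-6)
    expect_equal(f$baseline, 7, tolerance = 1e-4)
    expect_lt(f$chi2_reduced, 1e-10)
  }
})

test_that("mono fit agrees with the log-linear closed form on clean traces", {
  tr <- simulate_decay(555, 2e4, baseline = 0, noise = "none")
  slope <- coef(lm(log(tr$counts) ~ tr$time_ns))[[2]]
  expect_equal(-1 / slope, 555, tolerance = 1e-9)
  expect_equal(fit_mono(tr)$tau1, -1 / slope, tolerance = 1e-6)
})

test_that("fitted lifetime chains into the published oxygenation value", {
  f <- fit_mono(simulate_decay(710.8, 1e4, noise = "none"))
  o2 <- tau_to_oxygen(f$tau1)$percent_o2
  expect_equal(truncate_decimals(o2, 2), 10.80)
})

test_that("fit bias shrinks as counts grow and close lifetimes stay ordered", {
  est <- function(total, tau, seed) {
    fit_mono(simulate_decay(tau, amplitude_for_total(total, tau),
                            seed = seed))$tau1
  }
  err_small <- abs(vapply(1:12, function(i) est(1e4, 700, i), 0) / 700 - 1)
  err_big <- abs(vapply(1:12, function(i) est(1e6, 700, 100 + i), 0) / 700 - 1)
  expect_lt(mean(err_big), mean(err_small))
  expect_lt(mean(err_big), 0.01)

  # lifetimes separated by the peroxide-in-solution span keep their order
  for (i in 1:5) {
    expect_lt(est(1e6, 560, 200 + i), est(1e6, 575, 300 + i))
  }
})

test_that("bi-exponential fit with fixed second lifetime recovers mixtures", {
  # degenerate: pure mono trace -> vanishing second amplitude
  tr <- simulate_decay(650, 1e4, noise = "none")
  fb <- fit_bi_fixed(tr)
  fm <- fit_mono(tr)
  expect_equal(fb$tau1, fm$tau1, tolerance = 1e-3)
  expect_equal(fb$tau2, 20000)
  expect_lt(abs(fb$amplitude_fraction2), 1e-3)

  # exact synthetic mixture, 5% slow component
  mix <- simulate_decay(650, 9500, tau2 = 20000, amplitude2 = 500,
                        noise = "none", t_max = 4000)
  fx <- fit_bi_fixed(mix)
  expect_equal(fx$tau1, 650, tolerance = 1e-6)
  expect_equal(fx$amplitude_fraction2, 0.05, tolerance = 1e-4)

  # Poisson mixture at high counts
  mixp <- simulate_decay(650, 9500 * 20, tau2 = 20000, amplitude2 = 500 * 20,
                         seed = 41, t_max = 4000)
  expect_equal(fit_bi_fixed(mixp)$tau1, 650, tolerance = 0.03)
})

test_that("degenerate fit inputs fail loudly, not silently", {
  t <- seq(10, 1000, by = 10)
  expect_error(fit_mono(decay_trace(t, rep(0, length(t)))), "all-zero")
  few <- decay_trace(1:10, c(5, 3, 1, 0, 0, 0, 0, 0, 0, 0))
  expect_error(fit_mono(few), ">= 5 bins")
  expect_error(fit_bi_fixed(decay_trace(t, rep(0, length(t)))), "all-zero")
  expect_error(decay_trace(c(3, 2, 1), c(1, 1, 1)), "strictly increasing")
  expect_error(decay_trace(1:3, c(1, -1, 1)), "non-negative")
})

test_that("gated fit windows restrict the fitted range", {
  tr <- simulate_decay(650, 1e4, baseline = 0, noise = "none")
  f <- fit_mono(tr, fit_window = c(500, 3000))
  expect_equal(f$tau1, 650, tolerance = 1e-6)
  expect_true(all(f$time_ns >= 500 & f$time_ns <= 3000))
})

test_that("decay traces round-trip through delimited text", {
  tr <- simulate_decay(650, 1e3, seed = 9)
  tr$meta$condition <- "0% O2, 5 min, in"
  path <- tempfile(fileext = ".txt")
  write_decay_trace(tr, path)
  back <- read_decay_trace(path)
  expect_equal(back$time_ns, tr$time_ns)
  expect_equal(back$counts, tr$counts)
  expect_equal(back$meta$condition, "0% O2, 5 min, in")
})
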