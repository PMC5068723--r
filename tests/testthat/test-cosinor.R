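test_that("a noiseless cosine is recovered to machine precision", {
  sch <- ld6()
  y <- cosine_counts(864, mesor = 10, amplitude = 3, acrophase = 18)
  fit <- cosinor_fit(as_binned(y, sch), trial_period = 24)
  expect_equal(fit$mesor, 10, tolerance = 1e-10)
  expect_equal(fit$amplitude, 3, tolerance = 1e-10)
  expect_equal(fit$acrophase_zt, 18, tolerance = 1e-8)
  expect_equal(fit$percent_rhythm, 1, tolerance = 1e-10)
})

test_that("a constant series has zero amplitude and an undefined acrophase", {
  sch <- ld6()
  fit <- cosinor_fit(as_binned(rep(7, 864), sch), trial_period = 24)
  expect_equal(fit$mesor, 7)
  expect_identical(fit$amplitude, 0)
  expect_false(fit$acrophase_defined)
  expect_true(is.na(fit$acrophase_zt))
})

test_that("amplitude is translation invariant and acrophase shifts with time", {
  sch <- ld6()
  y <- cosine_counts(864, 10, 3, 18) + 0.3 * sin(2 * pi * seq_len(864) / 77)
  f0 <- cosinor_fit(as_binned(y, sch), 24)
  # start the window 5 h later: same series values, later ZT axis
  lag_ep <- 60                              # 5 h of 5-min epochs
  f1 <- cosinor_fit(as_binned(y, sch, start = T0 + lag_ep * 300), 24)
  expect_equal(f1$amplitude, f0$amplitude, tolerance = 1e-9)
  expect_equal((f1$acrophase_zt - f0$acrophase_zt) %% 24, 5, tolerance = 1e-6)
})

test_that("the fit matches a dense grid-search least-squares oracle on noisy data", {
  sch <- ld6()
  set.seed(42)
  t_h <- (seq_len(864) - 1) / 12
  y <- 10 + 3 * cos(2 * pi * (t_h - 18) / 24) + stats::rnorm(864, sd = 1)
  fit <- cosinor_fit(as_binned(y, sch), 24)
  or <- cosinor_oracle(t_h, y, 24)
  expect_equal(fit$mesor, or$mesor, tolerance = 1e-6)
  expect_equal(fit$amplitude, or$amplitude, tolerance = 1e-6)
  expect_equal(fit$acrophase_zt, or$acrophase %% 24, tolerance = 1e-5)
})

test_that("residuals are orthogonal to the cosinor regressors", {
  sch <- ld6()
  set.seed(7)
  y <- 5 + 2 * cos(2 * pi * ((seq_len(864) - 1) / 12 - 16) / 24) + stats::rnorm(864)
  fit <- cosinor_fit(as_binned(y, sch), 24)
  w <- 2 * pi / 24
  tt <- (seq_len(864) - 1) / 12
  yy <- fit$mesor + fit$amplitude * cos(w * (tt - fit$peak_offset_hours))
  res <- y - yy
  expect_lt(abs(sum(res)), 1e-8 * length(y))
  expect_lt(abs(sum(res * cos(w * tt))), 1e-8 * length(y))
  expect_lt(abs(sum(res * sin(w * tt))), 1e-8 * length(y))
})

test_that("sparse expression courses are fitted exactly in the noiseless case", {
  ec <- simulate_expression(mesor = 4, amplitude = 1.5, acrophase_hours = 18,
                            damping = 0, noise_sd = 0,
                            sample_times = seq(6, 36, by = 6))
  fit <- cosinor_fit(ec, trial_period = 24)
  expect_equal(fit$mesor, 4, tolerance = 1e-10)
  expect_equal(fit$amplitude, 1.5, tolerance = 1e-10)
  expect_equal(fit$acrophase_zt, 18, tolerance = 1e-8)
})

test_that("insufficient phase coverage is an error", {
  # three points all at the same circadian phase
  bad <- data.frame(time = c(0, 24, 48, 72), value = c(1, 2, 1, 2))
  expect_error(cosinor_fit(bad, 24), "phase coverage")
  expect_error(cosinor_fit(data.frame(time = 1:3, value = 1:3), 24), "4 points")
})
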