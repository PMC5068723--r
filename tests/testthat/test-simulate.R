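test_that("simulation is bit-identical under a fixed seed", {
  sch <- ld3()
  cfg <- simulation_config(sch, list(m1 = preset("control"), m2 = preset("dex")), seed = 5)
  a <- simulate_activity(cfg)
  b <- simulate_activity(cfg)
  expect_identical(lapply(a, unclass), lapply(b, unclass))
  c2 <- simulate_activity(simulation_config(sch, cfg$animals, seed = 6))
  expect_false(identical(a$m1$timestamp, c2$m1$timestamp))
})

test_that("an unmodulated white-noise animal is a homogeneous Poisson process", {
  sch <- ld3()
  pr <- preset("control", rhythm_amplitude = 0, gate_floor = 1,
               hurst_exponent = 0.5, noise_sd = 0)
  disp <- sapply(1:10, function(sd) {
    ev <- simulate_activity(simulation_config(sch, list(a = pr), seed = sd))
    counts <- bin_events(ev$a, sch, T0, T0 + 3 * 86400, epoch_seconds = 3600)$counts
    stats::var(counts) / mean(counts)
  })
  expect_lt(abs(mean(disp) - 1), 0.15)
  # and the hourly rate matches the preset's mean rate
  ev <- simulate_activity(simulation_config(sch, list(a = pr), seed = 1))
  expect_lt(abs(length(ev$a$timestamp) / 72 - pr$mean_rate) / pr$mean_rate, 0.1)
})

test_that("rigid gating confines events to the dark phase", {
  sch <- ld3()
  frac <- sapply(1:5, function(sd) {
    ev <- simulate_activity(simulation_config(sch, list(d = preset("dex")), seed = sd))
    zt <- zt_of(ev$d$timestamp, sch)
    mean(zt >= 12 | zt < 0.2)
  })
  expect_true(all(frac > 0.95))
})

test_that("the control preset starts its active phase before dark onset", {
  sch <- ld3()
  onsets <- sapply(1:5, function(sd) {
    ev <- simulate_activity(simulation_config(sch, list(c = preset("control")), seed = sd))
    b <- bin_events(ev$c, sch, T0, T0 + 3 * 86400)
    active_phase_summary(
      detect_active_phases(classify_active_epochs(gaussian_smooth(b)), sch))$onset
  })
  expect_true(all(onsets < 12))
})

test_that("the deterministic rate profile encodes the gate geometry", {
  sch <- ld3()
  st <- T0 + (0:863) * 300
  zt <- zt_of(st, sch)
  rd <- rate_profile(preset("dex"), sch, st)
  # light phase (away from the 0.2-h edges) sits at the gate floor
  lightmask <- zt > 2 & zt < 10
  expect_true(all(rd[lightmask] <= 0.03 * 60 * 1.9))
  expect_true(all(rd[zt > 13 & zt < 23] >= 0.5 * 60 * 0.2))
  rc <- rate_profile(preset("control"), sch, st)
  # anticipation: the control gate is fully open ahead of dark onset
  i115 <- which(abs(zt - 11.5) < 1e-9)
  expect_gt(rc[i115][1], 0.95 * 60 * (1 + 0.85 * cos(2 * pi * (11.5 - 16.5) / 24)))
})

test_that("raising rhythm amplitude strictly raises the cosinor amplitude estimate", {
  sch <- ld3()
  amps <- sapply(c(0, 0.25, 0.5, 0.75, 1), function(a) {
    pr <- preset("control", gate_floor = 1, rhythm_amplitude = a)
    ev <- simulate_activity(simulation_config(sch, list(x = pr), seed = 7))
    cosinor_fit(bin_events(ev$x, sch, T0, T0 + 3 * 86400), 24)$amplitude
  })
  expect_true(all(diff(amps) > 0))
})

test_that("expression simulation follows the damped-cosine model", {
  # amplitude 0, no noise -> constant at the mesor
  flat <- simulate_expression(mesor = 3, amplitude = 0, noise_sd = 0)
  expect_equal(flat$value, rep(3, 6))
  # noiseless sustained oscillation is recovered exactly by the cosinor
  ec <- simulate_expression(mesor = 5, amplitude = 2, acrophase_hours = 14,
                            damping = 0, noise_sd = 0,
                            sample_times = seq(6, 36, by = 3))
  fit <- cosinor_fit(ec, 24)
  expect_equal(fit$amplitude, 2, tolerance = 1e-9)
  expect_equal(fit$acrophase_zt, 14, tolerance = 1e-7)
  # attenuated-oscillation group shows a lower amplitude estimate
  set.seed(12)
  ctrl <- simulate_expression(mesor = 1, amplitude = 0.5, damping = 0.02,
                              noise_sd = 0.05, replicates = 3, seed = 1)
  dexg <- simulate_expression(mesor = 1, amplitude = 0.15, damping = 0.02,
                              noise_sd = 0.05, replicates = 3, group = "dex", seed = 2)
  expect_gt(cosinor_fit(ctrl, 24)$amplitude, cosinor_fit(dexg, 24)$amplitude)
  expect_true(all(ctrl$value > 0) && all(dexg$value > 0))
})

test_that("invalid configurations are rejected", {
  sch <- ld3()
  expect_error(phenotype_preset("x", rhythm_amplitude = 1.2), "amplitude")
  expect_error(phenotype_preset("x", hurst_exponent = 1), "hurst")
  expect_error(phenotype_preset("x", mean_rate = 0), "mean_rate")
  expect_error(simulation_config(sch, list()), "no animals")
  expect_error(simulation_config(sch, list(preset("control"))), "named")
  expect_error(simulate_expression(mesor = -1, amplitude = 1), "non-negative")
  expect_error(simulate_expression(1, 1, sample_times = c(6, 40)), "window")
})

test_that("a JSON config file round-trips into an identical simulation", {
  f <- withr::local_tempfile(fileext = ".json")
  seg <- data.frame(start = "2020-01-01T06:00:00", regime = "LD",
                    lights_on = 6, photoperiod = 12, cycle_length = 24)
  jsonlite::write_json(list(
    schedule = list(segments = seg, end = "2020-01-04T06:00:00"),
    animals = list(m1 = list(name = "control", rhythm_amplitude = 0.5)),
    epoch_seconds = 300, seed = 9
  ), f, auto_unbox = TRUE, digits = NA)
  cfg <- read_simulation_config(f)
  expect_s3_class(cfg, "simulation_config")
  expect_equal(cfg$animals$m1$rhythm_amplitude, 0.5)
  direct <- simulation_config(ld3(), list(m1 = preset("control", rhythm_amplitude = 0.5)),
                              seed = 9)
  expect_identical(simulate_activity(cfg)$m1$timestamp,
                   simulate_activity(direct)$m1$timestamp)
  expect_error(read_simulation_config({writeLines("{}", f); f}), "configuration error")
})
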