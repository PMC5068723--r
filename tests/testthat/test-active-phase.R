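test_that("the normalized Gauss kernel preserves constants and reproduces itself on an impulse", {
  sch <- ld6()
  sm <- gaussian_smooth(as_binned(rep(4, 576), sch))
  expect_equal(sm$values, rep(4, 576), tolerance = 1e-12)
  expect_equal(sm$kernel$sigma_hours, 1)   # 4-h span, sigma = span / 4
  imp <- c(rep(0, 287), 1, rep(0, 288))
  smi <- gaussian_smooth(as_binned(imp, sch))$values
  pk <- which.max(smi)
  expect_equal(pk, 288)
  expect_equal(smi[pk - 1], smi[pk + 1], tolerance = 1e-12)  # symmetric
  # away from the edges the output IS the normalized kernel
  half <- 24
  w <- stats::dnorm((-half:half) / 12, 0, 1)
  expect_equal(smi[(pk - half):(pk + half)], w / sum(w), tolerance = 1e-12)
})

test_that("smoothing equals a brute-force renormalized convolution", {
  sch <- ld6()
  set.seed(4)
  y <- stats::rpois(20, 5)
  # small kernel: 0.5-h span on 5-min epochs -> 7 points
  sm <- gaussian_smooth(as_binned(y, sch), span_hours = 0.5)$values
  half <- 3
  w <- stats::dnorm((-half:half) * (1 / 12), 0, 0.5 / 4)
  ref <- sapply(seq_along(y), function(i) {
    j <- (i - half):(i + half)
    ok <- j >= 1 & j <= length(y)
    sum(y[j[ok]] * w[ok]) / sum(w[ok])
  })
  expect_equal(sm, ref, tolerance = 1e-12)
  expect_error(gaussian_smooth(as_binned(y, sch), span_hours = 0.1), "3 epochs")
})

test_that("above-mean classification halves a square wave and is scale equivariant", {
  sch <- ld6()
  b <- as_binned(dark_box_counts(2, high = 6, low = 2), sch)
  m1 <- classify_active_epochs(gaussian_smooth(b))
  expect_equal(mean(m1$mask), 0.5, tolerance = 0.01)
  b10 <- as_binned(10 * dark_box_counts(2, high = 6, low = 2), sch)
  m10 <- classify_active_epochs(gaussian_smooth(b10))
  expect_identical(m1$mask, m10$mask)
  expect_warning(classify_active_epochs(gaussian_smooth(as_binned(rep(2, 576), sch))),
                 "zero-variance")
})

make_mask <- function(active_epochs, n = 288, sch = ld3()) {
  mask <- rep(FALSE, n)
  mask[active_epochs] <- TRUE
  structure(list(mask = mask, threshold = 0.5,
                 epoch_start = T0 + (seq_len(n) - 1L) * 300,
                 epoch_seconds = 300, zt = zt_of(T0 + (seq_len(n) - 1L) * 300, sch),
                 animal_id = "m"), class = "active_mask")
}

test_that("gaps of at most one hour merge, longer gaps split", {
  sch <- ld3()
  # two 2-h blocks around ZT 13-17 separated by a 45-min gap -> one phase
  blocks45 <- c(157:180, 190:213)       # gap = 9 epochs = 45 min
  ph <- detect_active_phases(make_mask(blocks45), sch)
  expect_equal(nrow(ph), 1)
  # 90-min gap -> two phases
  blocks90 <- c(157:180, 199:222)       # gap = 18 epochs = 90 min
  ph2 <- detect_active_phases(make_mask(blocks90), sch)
  expect_equal(nrow(ph2), 2)
  expect_equal(sum(ph2$is_primary), 1)  # same cycle: longest is primary
  # exactly 12 epochs (1 h) still merges: the rule is inclusive
  blocks60 <- c(157:180, 193:216)
  expect_equal(nrow(detect_active_phases(make_mask(blocks60), sch)), 1)
  # all-inactive mask -> empty result, not an error
  expect_equal(nrow(detect_active_phases(make_mask(integer(0)), sch)), 0)
})

test_that("gap merging is idempotent", {
  set.seed(31)
  for (i in 1:20) {
    mask <- stats::runif(288) < 0.4
    m <- make_mask(which(mask))
    ph1 <- detect_active_phases(m, ld3())
    # rebuild a mask filled over the detected merged runs and re-detect
    if (!nrow(ph1)) next
    filled <- rep(FALSE, 288)
    for (r in seq_len(nrow(ph1))) {
      i0 <- round((ph1$onset[r] - 12) * 12) + which(zt_of(m$epoch_start, ld3()) == 12)[ph1$cycle_index[r]]
      filled[max(1, i0):min(288, i0 + round(ph1$duration[r] * 12) - 1)] <- TRUE
    }
    ph2 <- detect_active_phases(make_mask(which(filled)), ld3())
    expect_equal(nrow(ph2), nrow(ph1))
    expect_equal(ph2$duration, ph1$duration, tolerance = 1e-9)
  }
})

test_that("raising the merge gap never increases the number of phases", {
  set.seed(17)
  for (i in 1:10) {
    m <- make_mask(which(stats::runif(288) < 0.35))
    n_ph <- sapply(c(0.25, 0.5, 1, 1.5, 2), function(g)
      nrow(detect_active_phases(m, ld3(), max_gap_hours = g)))
    expect_true(all(diff(n_ph) <= 0))
  }
})

test_that("a dark-locked box yields ~12-h phases at onset ZT 12, stable under scaling", {
  sch <- ld3()
  b <- as_binned(dark_box_counts(3, high = 10, low = 0), sch)
  ph <- detect_active_phases(classify_active_epochs(gaussian_smooth(b)), sch)
  ph <- ph[ph$is_primary, ]
  expect_equal(nrow(ph), 3)
  expect_true(all(ph$duration >= 11.5 & ph$duration <= 12.5))
  expect_true(all(abs(ph$onset - 12) <= 0.5))
  expect_true(all(abs(ph$offset - 24) <= 0.5))
  # whole-pipeline scale invariance
  b2 <- as_binned(7 * dark_box_counts(3, high = 10, low = 0), sch)
  ph2 <- detect_active_phases(classify_active_epochs(gaussian_smooth(b2)), sch)
  expect_equal(ph2$onset, detect_active_phases(classify_active_epochs(gaussian_smooth(b)), sch)$onset)
  # summary of identical phases equals the per-cycle values
  s <- active_phase_summary(ph)
  expect_equal(s$n_cycles, 3)
  expect_equal(s$duration, mean(ph$duration))
  expect_equal(s$duration, s$offset - s$onset, tolerance = 1e-9)
})

test_that("offsets past lights-on are reported unwrapped", {
  sch <- ld3()
  # active block ZT 13 to ZT 25 (1 h past lights-on of the next cycle)
  ph <- detect_active_phases(make_mask(157:300, n = 432), sch)
  expect_equal(nrow(ph), 1)
  expect_gt(ph$offset, 24)
  expect_equal(ph$offset_zt, ph$offset - 24, tolerance = 1e-9)
  expect_equal(ph$duration, ph$offset - ph$onset)
})
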