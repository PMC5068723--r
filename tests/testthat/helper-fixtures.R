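# shared fixtures: schedules, synthetic series, independent oracles

T0 <- as.POSIXct("2020-01-01 06:00:00", tz = "UTC")

ld6 <- function() ld_schedule(T0, days = 6)
ld3 <- function() ld_schedule(T0, days = 3)

# LD day 1 then DD, so DD analyses have an entrained reference
dd_after_ld <- function(dd_days = 6) {
  light_schedule(
    data.frame(start = c(T0, T0 + 86400), regime = c("LD", "DD"),
               lights_on = 6, photoperiod = 12, cycle_length = 24),
    end = T0 + (1 + dd_days) * 86400
  )
}

# wrap a plain numeric vector as a binned series on a given schedule
as_binned <- function(counts, schedule, start = T0, epoch_seconds = 300,
                      animal_id = "synthetic") {
  starts <- start + (seq_along(counts) - 1L) * epoch_seconds
  structure(list(animal_id = animal_id, epoch_seconds = epoch_seconds,
                 start = start, epoch_start = starts, counts = counts,
                 zt = zt_of(starts, schedule),
                 regime = regime_of(starts, schedule)),
            class = "binned_series")
}

# cosine series sampled on the 5-min epoch grid, in ZT hours from T0
cosine_counts <- function(n_epochs, mesor, amplitude, acrophase, period = 24,
                          epoch_seconds = 300) {
  t_h <- (seq_len(n_epochs) - 1L) * epoch_seconds / 3600  # elapsed = ZT here
  mesor + amplitude * cos(2 * pi * (t_h - acrophase) / period)
}

# 12 h high / 12 h low box locked to the dark phase (high for ZT in [12, 24))
dark_box_counts <- function(days, high = 10, low = 0, epoch_seconds = 300) {
  per_day <- 86400 / epoch_seconds
  zt <- ((seq_len(days * per_day) - 1L) * epoch_seconds / 3600) %% 24
  ifelse(zt >= 12, high, low)
}

# --- independent oracles ------------------------------------------------

# direct per-window DFA-1, no vectorization: the reference implementation
dfa_naive <- function(x, scales, order = 1) {
  N <- length(x)
  prof <- cumsum(x - mean(x))
  fl <- sapply(scales, function(n) {
    nw <- N %/% n
    ss <- 0; cnt <- 0
    idx_sets <- c(lapply(seq_len(nw), function(w) ((w - 1) * n + 1):(w * n)),
                  lapply(seq_len(nw), function(w) (N - w * n + 1):(N - (w - 1) * n)))
    for (ii in idx_sets) {
      tt <- seq_len(n)
      fit <- stats::lm(prof[ii] ~ stats::poly(tt, order, raw = TRUE))
      ss <- ss + sum(stats::residuals(fit)^2); cnt <- cnt + n
    }
    sqrt(ss / cnt)
  })
  stats::coef(stats::lm(log(fl) ~ log(scales)))[[2]]
}

# dense grid + refinement least-squares cosinor oracle (independent of the
# closed-form fit): minimizes RSS of y ~ a + b*cos(2*pi*(t - phi)/tau) over phi
cosinor_oracle <- function(t, y, tau = 24) {
  rss_at <- function(phi) {
    X <- cbind(1, cos(2 * pi * (t - phi) / tau))
    sum(stats::lm.fit(X, y)$residuals^2)
  }
  grid <- seq(0, tau, length.out = 2001)[-2001]
  phi0 <- grid[which.min(vapply(grid, rss_at, numeric(1)))]
  opt <- stats::optimize(rss_at, c(phi0 - 0.05, phi0 + 0.05), tol = 1e-10)
  phi <- opt$minimum %% tau
  X <- cbind(1, cos(2 * pi * (t - phi) / tau))
  cf <- stats::lm.fit(X, y)$coefficients
  if (cf[2] < 0) { cf[2] <- -cf[2]; phi <- (phi + tau / 2) %% tau }
  list(mesor = unname(cf[1]), amplitude = unname(cf[2]), acrophase = phi)
}

# direct fold-variance chi-square statistic at one trial period (in epochs),
# all-points fold with unequal column counts
qp_oracle <- function(x, p) {
  idx <- rep_len(seq_len(p), length(x))
  mh <- tapply(x, idx, mean)
  nh <- tabulate(idx, p)
  length(x) * sum(nh * (mh - mean(x))^2) / sum((x - mean(x))^2)
}
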