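#' Simulation configuration
#'
#' Bundles a light schedule, a set of animals (each with a phenotype preset),
#' the epoch grid of the rate model and the master seed. The seed is recorded
#' in the run metadata so a run can be replayed exactly.
#'
#' @param schedule a [light_schedule].
#' @param animals a named list of [phenotype_preset] objects; names are the
#'   animal ids.
#' @param epoch_seconds grid on which the event rate (circadian modulation,
#'   photic gate, noise multiplier) is piecewise constant; default 300 s.
#' @param seed master integer seed.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(schedule, animals, epoch_seconds = 300, seed = 1L) {
  stopifnot(inherits(schedule, "light_schedule"))
  if (!length(animals)) .stopf("configuration error: no animals")
  if (is.null(names(animals)) || any(names(animals) == ""))
    .stopf("'animals' must be a named list (names = animal ids)")
  ok <- vapply(animals, inherits, logical(1), "phenotype_preset")
  if (!all(ok)) .stopf("all animals must carry a phenotype_preset")
  structure(list(schedule = schedule, animals = animals,
                 epoch_seconds = epoch_seconds, seed = as.integer(seed)),
            class = "simulation_config")
}

# Deterministic per-epoch effective parameters and rate (visits/h, no noise).
# Transients:
#  - an LD segment following DD ("forced synchronization") blends, cycle by
#    cycle with weight w = exp(-(c+1)/k), a rigid-gating parameter set
#    (acrophase at mid-dark, no anticipation, raised amplitude, strong photic
#    suppression) into the animal's entrained preset;
#  - an LD segment whose lights-on differs from the previous LD segment (a
#    phase shift) decays the phase lag exponentially on the onset side while
#    light masking takes the offset to the new lights-on immediately.
.rate_profile <- function(preset, schedule, epoch_start) {
  seg <- schedule$segments
  zt <- zt_of(epoch_start, schedule)
  si <- .segment_index(epoch_start, schedule)
  n <- length(epoch_start)
  rate <- numeric(n)
  for (i in unique(si)) {
    idx <- which(si == i)
    cyc <- seg$cycle_length[i]
    pp <- seg$photoperiod[i]
    e <- .hours(epoch_start[idx], seg$start[i])      # hours into segment
    c_idx <- floor(e / cyc)                          # cycle index within segment
    k <- max(preset$reentrainment_rate_cycles, 1e-6)
    amp <- rep(preset$rhythm_amplitude, length(idx))
    acro <- rep(preset$acrophase_zt_hours, length(idx))
    ant <- rep(preset$anticipation_hours, length(idx))
    off <- rep(preset$offset_lag_hours, length(idx))
    floor_ <- rep(preset$gate_floor, length(idx))
    period <- preset$entrained_period_hours
    gated <- seg$regime[i] == "LD"
    if (seg$regime[i] == "DD") {
      period <- preset$intrinsic_period_hours
    } else if (i > 1L && seg$regime[i - 1L] == "DD") {
      # forced synchronization after constant darkness
      w <- exp(-(c_idx + 1) / k)
      acro <- w * (pp + (cyc - pp) / 2) + (1 - w) * acro
      ant <- (1 - w) * ant
      off <- w * 0.05 + (1 - w) * off
      amp <- w * pmax(amp, 0.85) + (1 - w) * amp
      floor_ <- w * pmin(floor_, 0.05) + (1 - w) * floor_
    } else if (i > 1L && seg$regime[i - 1L] == "LD" &&
               seg$lights_on[i] != seg$lights_on[i - 1L]) {
      # phase shift of the LD schedule
      shift <- .wrap_diff(seg$lights_on[i - 1L] - seg$lights_on[i], 24)
      w <- exp(-(c_idx + 1) / k)
      lag <- shift * w
      acro <- acro + lag
      ant <- ant * (1 - w) - lag  # negative: onset lags behind the new dark onset
      off <- off * (1 - w)        # offset side is masked by the new lights-on
    }
    # circadian modulation: peak anchored at the acrophase ZT of the first
    # cycle, then advancing with the expressed period
    if (all(abs(period - cyc) < 1e-9)) {
      modl <- 1 + amp * cos(2 * pi * (zt[idx] - acro) / cyc)
    } else {
      # peak at the first instant of the segment where ZT == acro, then
      # recurring every 'period' hours (relative coordination / free run)
      e_peak0 <- .wrap(acro - zt[idx][1L], cyc) + e[1L]
      modl <- 1 + amp * cos(2 * pi * (e - e_peak0) / period)
    }
    if (gated) {
      on <- pp - ant
      offz <- cyc + off
      # raised-cosine edges of total duration gate_ramp_hours, centred on the
      # nominal on/off boundaries; 0 gives an abrupt box
      r <- preset$gate_ramp_hours
      d <- .wrap(zt[idx] - on, cyc)          # hours since gate-on
      len <- offz - on
      ramp <- function(u) 0.5 - 0.5 * cos(pi * pmin(pmax(u, 0), 1))
      if (r > 0) {
        up <- ramp((ifelse(d > cyc - r / 2, d - cyc, d) + r / 2) / r)
        down <- 1 - ramp((d - (len - r / 2)) / r)
        frac <- pmin(up, down)
      } else {
        frac <- as.numeric(d < len)
      }
      gate <- floor_ + (1 - floor_) * frac
    } else {
      gate <- 1
    }
    rate[idx] <- preset$mean_rate * modl * gate
  }
  pmax(rate, 0)
}

#' Deterministic expected-rate profile of a preset under a schedule
#'
#' The noise-free event rate (visits per hour) of the simulator's rate model,
#' evaluated at each epoch start: circadian modulation x photic gate x mean
#' rate, including the re-entrainment transients. Useful for inspecting what
#' a preset encodes and as ground truth in tests.
#'
#' @param preset a [phenotype_preset].
#' @param schedule a [light_schedule].
#' @param epoch_start POSIXct vector of epoch starts (within the schedule).
#' @return numeric vector of rates (visits/h).
#' @export
rate_profile <- function(preset, schedule, epoch_start) {
  stopifnot(inherits(preset, "phenotype_preset"))
  .rate_profile(preset, schedule, epoch_start)
}

#' Simulate visit event streams
#'
#' Draws per-animal visit events from an inhomogeneous Poisson process whose
#' rate is the deterministic profile of [rate_profile()] multiplied by a
#' log-normal long-range-correlated noise factor
#' `exp(sigma * z - sigma^2 / 2)`, with `z` fractional Gaussian noise with the
#' preset's Hurst exponent on the epoch grid. Events are drawn by thinning a
#' homogeneous Poisson upper bound (the max epoch rate), which is exact for a
#' piecewise-constant rate. Fixed seed gives bit-identical streams.
#'
#' @param config a [simulation_config].
#' @return a named list of [event_stream] objects with attribute `metadata`
#'   (schedule, presets, seed, epoch length).
#' @export
simulate_activity <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  sched <- config$schedule
  ep <- config$epoch_seconds
  n_ep <- as.integer(round(as.numeric(difftime(sched$end, sched$start, units = "secs")) / ep))
  if (n_ep < 64) .stopf("schedule too short for simulation (< 64 epochs)")
  starts <- sched$start + (seq_len(n_ep) - 1L) * ep
  seeds <- .child_seeds(config$seed, length(config$animals))
  out <- vector("list", length(config$animals))
  names(out) <- names(config$animals)
  for (a in seq_along(config$animals)) {
    pr <- config$animals[[a]]
    set.seed(seeds[a])
    z <- generate_fractional_noise(n_ep, pr$hurst_exponent)
    lam <- .rate_profile(pr, sched, starts) *
      exp(pr$noise_sd * z - pr$noise_sd^2 / 2)      # visits per hour, per epoch
    lam_max <- max(lam)
    t_hours <- n_ep * ep / 3600
    n_prop <- stats::rpois(1L, lam_max * t_hours)
    u <- sort(stats::runif(n_prop, 0, t_hours))
    ki <- pmin(floor(u * 3600 / ep) + 1L, n_ep)
    keep <- stats::runif(n_prop) < lam[ki] / lam_max
    tt <- sched$start + u[keep] * 3600
    ant <- sample.int(8L, sum(keep), replace = TRUE)
    out[[a]] <- event_stream(names(config$animals)[a], tt, ant)
  }
  attr(out, "metadata") <- list(
    seed = config$seed, epoch_seconds = ep,
    schedule = sched$segments[, c("start", "regime", "lights_on", "photoperiod", "cycle_length")],
    presets = lapply(config$animals, unclass)
  )
  out
}

#' Write simulation run metadata as JSON
#'
#' @param result the return value of [simulate_activity()].
#' @param path output JSON path.
#' @export
write_run_metadata <- function(result, path) {
  md <- attr(result, "metadata")
  if (is.null(md)) .stopf("no metadata attached to this result")
  md$schedule$start <- format(md$schedule$start, "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  jsonlite::write_json(md, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Simulate sparse clock-gene expression time courses
#'
#' Generates relative expression values following a damped cosine,
#' `mesor + amplitude * exp(-damping * t) * cos(2 * pi * (t - acrophase) / 24)`
#' plus Gaussian noise, truncated to stay positive — the model class of
#' synchronized clock-gene (e.g. *Bmal1*) oscillations in fibroblast cultures
#' sampled 6-36 h after synchronization.
#'
#' @param mesor,amplitude non-negative model parameters (arbitrary expression
#'   units).
#' @param acrophase_hours peak time in hours post-synchronization.
#' @param damping exponential damping rate (1/h); 0 = sustained oscillation.
#' @param noise_sd Gaussian noise SD; 0 gives the noiseless model.
#' @param sample_times hours post-synchronization, strictly increasing, within
#'   `window`.
#' @param replicates number of replicate courses.
#' @param window allowed sampling window (default 6-36 h).
#' @param group,gene labels carried into the output.
#' @param seed integer seed.
#' @return a `data.frame` with columns `gene`, `group`, `replicate`, `time`,
#'   `value` (positive), usable directly with [cosinor_fit()].
#' @export
simulate_expression <- function(mesor, amplitude, acrophase_hours = 18,
                                damping = 0, noise_sd = 0,
                                sample_times = seq(6, 36, by = 6),
                                replicates = 1L, window = c(6, 36),
                                group = "control", gene = "Bmal1", seed = NULL) {
  if (amplitude < 0 || mesor < 0) .stopf("amplitude and mesor must be non-negative")
  if (replicates < 1L) .stopf("replicates must be >= 1")
  if (is.unsorted(sample_times, strictly = TRUE)) .stopf("sample times must be strictly increasing")
  if (any(sample_times < window[1] | sample_times > window[2]))
    .stopf("sample times must lie within the window [%g, %g] h", window[1], window[2])
  if (!is.null(seed)) set.seed(as.integer(seed))
  out <- do.call(rbind, lapply(seq_len(replicates), function(r) {
    mu <- mesor + amplitude * exp(-damping * sample_times) *
      cos(2 * pi * (sample_times - acrophase_hours) / 24)
    v <- mu + if (noise_sd > 0) stats::rnorm(length(mu), 0, noise_sd) else 0
    data.frame(gene = gene, group = group, replicate = r,
               time = sample_times, value = pmax(v, .Machine$double.eps))
  }))
  rownames(out) <- NULL
  out
}

#' Read a simulation configuration from a JSON file
#'
#' The file mirrors [write_run_metadata()]'s layout: a `schedule` block (rows
#' of `start` ISO-8601, `regime`, `lights_on`, `photoperiod`, `cycle_length`,
#' plus `end`), an `animals` block mapping animal id to preset parameters
#' (any subset of [phenotype_preset()]'s arguments), `epoch_seconds` and
#' `seed`.
#'
#' @param path JSON config path.
#' @return a [simulation_config].
#' @export
read_simulation_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("schedule", "animals", "seed")) if (is.null(cfg[[f]]))
    .stopf("configuration error: missing '%s' block in %s", f, path)
  seg <- as.data.frame(cfg$schedule$segments)
  seg$start <- as.POSIXct(seg$start, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  sched <- light_schedule(seg, end = as.POSIXct(cfg$schedule$end,
                                                format = "%Y-%m-%dT%H:%M:%OS",
                                                tz = "UTC"))
  animals <- lapply(cfg$animals, function(a) do.call(phenotype_preset, as.list(a)))
  simulation_config(sched, animals,
                    epoch_seconds = cfg$epoch_seconds %||% 300,
                    seed = cfg$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
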