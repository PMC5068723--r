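#' Segment a recording into the protocol's analysis windows
#'
#' Returns the named, half-open absolute-time analysis windows of an
#' experimental protocol. Acclimation (the first three LD cycles) is excluded
#' from all analyses; baseline is the following three LD cycles; the
#' free-running window is the last 72 h of constant darkness; forced
#' synchronization is the first three cycles after the LD cycle resumes; in a
#' phase-advance design the post-shift windows are per-cycle, indexed from
#' the first new lights-on.
#'
#' @param schedule a [light_schedule].
#' @param protocol `"baseline"`, `"dd_reentrain"` or `"phase_advance"`.
#' @param acclimation_cycles cycles discarded at the start (default 3).
#' @param baseline_cycles cycles in the baseline window (default 3).
#' @param dd_hours length of the free-running analysis window (default 72).
#' @param forced_sync_cycles cycles analyzed after LD resumes (default 3).
#' @param post_cycles per-cycle windows after a phase shift (default all
#'   available).
#' @return an object of class `experiment_segments`: a named list of POSIXct
#'   `c(from, to)` windows.
#' @export
segment_experiment <- function(schedule,
                               protocol = c("baseline", "dd_reentrain", "phase_advance"),
                               acclimation_cycles = 3, baseline_cycles = 3,
                               dd_hours = 72, forced_sync_cycles = 3,
                               post_cycles = NULL) {
  protocol <- match.arg(protocol)
  seg <- schedule$segments
  win <- list()
  need_ld1 <- function(cycles_needed) {
    if (seg$regime[1L] != "LD") .stopf("protocol error: recording must start with an LD segment")
    len_h <- .hours(seg$end[1L], seg$start[1L])
    if (len_h < cycles_needed * seg$cycle_length[1L] - 1e-9)
      .stopf("protocol error: first LD segment covers %.1f h, %g cycles (%g h) required",
             len_h, cycles_needed, cycles_needed * seg$cycle_length[1L])
  }
  cyc_s <- seg$cycle_length[1L] * 3600
  if (protocol %in% c("baseline", "dd_reentrain")) {
    need_ld1(acclimation_cycles + baseline_cycles)
    a0 <- seg$start[1L]
    win$acclimation <- c(a0, a0 + acclimation_cycles * cyc_s)
    win$baseline_LD <- c(win$acclimation[2L], win$acclimation[2L] + baseline_cycles * cyc_s)
  }
  if (protocol == "dd_reentrain") {
    di <- which(seg$regime == "DD")
    if (!length(di)) .stopf("protocol error: no DD segment in the schedule")
    di <- di[1L]
    dd_len <- .hours(seg$end[di], seg$start[di])
    if (dd_len < dd_hours - 1e-9)
      .stopf("protocol error: DD segment covers %.1f h, %g h required", dd_len, dd_hours)
    win$free_running_DD <- c(seg$end[di] - dd_hours * 3600, seg$end[di])
    if (di < nrow(seg) && seg$regime[di + 1L] == "LD") {
      fs_len <- .hours(seg$end[di + 1L], seg$start[di + 1L])
      if (fs_len < forced_sync_cycles * seg$cycle_length[di + 1L] - 1e-9)
        .stopf("protocol error: resumed LD covers %.1f h, %g cycles required",
               fs_len, forced_sync_cycles)
      win$forced_sync_LD <- c(seg$start[di + 1L],
                              seg$start[di + 1L] + forced_sync_cycles *
                                seg$cycle_length[di + 1L] * 3600)
    } else .stopf("protocol error: no LD segment after DD (forced synchronization missing)")
  }
  if (protocol == "phase_advance") {
    if (nrow(seg) < 2L || any(seg$regime[1:2] != "LD") ||
        seg$lights_on[1L] == seg$lights_on[2L])
      .stopf("protocol error: need two LD segments with shifted lights-on")
    pre_len <- floor(.hours(seg$end[1L], seg$start[1L]) / seg$cycle_length[1L])
    if (pre_len < 1) .stopf("protocol error: no complete pre-shift cycle")
    n_pre <- min(pre_len, baseline_cycles)
    win$baseline_LD <- c(seg$end[1L] - n_pre * seg$cycle_length[1L] * 3600, seg$end[1L])
    cyc2_s <- seg$cycle_length[2L] * 3600
    avail <- floor(.hours(seg$end[2L], seg$start[2L]) / seg$cycle_length[2L])
    if (is.null(post_cycles)) post_cycles <- avail
    if (avail < post_cycles)
      .stopf("protocol error: %d post-shift cycles available, %d required", avail, post_cycles)
    for (kk in seq_len(post_cycles))
      win[[sprintf("phase_advance_cycle_%d", kk)]] <-
        c(seg$start[2L] + (kk - 1L) * cyc2_s, seg$start[2L] + kk * cyc2_s)
  }
  structure(win, class = "experiment_segments")
}

#' @export
print.experiment_segments <- function(x, ...) {
  cat("<experiment_segments>\n")
  for (nm in names(x))
    cat(sprintf("  %-22s %s to %s\n", nm, format(x[[nm]][1L]), format(x[[nm]][2L])))
  invisible(x)
}

#' Run every metric for every animal and analysis window
#'
#' For each animal and each non-acclimation window: bins the events into
#' 5-min epochs and computes the chi-square periodogram peak period, the
#' cosinor fit (at a fixed 24-h trial period for LD windows; at the
#' periodogram peak period for the free-running DD window), the DFA scaling
#' exponent, and (LD windows only) the active-phase summary. A failing metric
#' is recorded as NA and logged; the batch continues.
#'
#' @param streams a named list of [event_stream] objects.
#' @param schedule a [light_schedule].
#' @param segments an [segment_experiment()] result.
#' @param epoch_seconds epoch length (default 300 s).
#' @param groups optional named character vector mapping animal id to group
#'   label.
#' @param smooth_span_hours,max_gap_hours active-phase parameters.
#' @param dfa_min_scale,dfa_max_scale DFA fit range in epochs (default 8-48,
#'   i.e. 40 min to 4 h on 5-min epochs: below the circadian scale, so the
#'   exponent measures the fractal noise structure rather than the rhythm).
#' @return a `data.frame` (the metrics table): one row per animal x window
#'   with `amplitude`, `acrophase_zt`, `mesor`, `percent_rhythm`,
#'   `period_hours`, `scaling_exponent`, `onset`, `offset`, `duration`,
#'   `n_cycles`, `n_events`; attribute `log` holds any metric-level errors.
#' @export
run_all_metrics <- function(streams, schedule, segments, epoch_seconds = 300,
                            groups = NULL, smooth_span_hours = 4,
                            max_gap_hours = 1, dfa_min_scale = 8, dfa_max_scale = 48) {
  stopifnot(inherits(segments, "experiment_segments"))
  wins <- segments[names(segments) != "acclimation"]
  logs <- character()
  note <- function(aid, wn, metric, e) {
    logs[[length(logs) + 1L]] <<- sprintf("%s/%s/%s: %s", aid, wn, metric, conditionMessage(e))
    NULL
  }
  rows <- list()
  for (aid in names(streams)) {
    for (wn in names(wins)) {
      w <- wins[[wn]]
      row <- data.frame(animal_id = aid,
                        group = if (!is.null(groups)) unname(groups[aid]) else NA_character_,
                        window = wn, amplitude = NA_real_, acrophase_zt = NA_real_,
                        mesor = NA_real_, percent_rhythm = NA_real_,
                        period_hours = NA_real_, scaling_exponent = NA_real_,
                        onset = NA_real_, offset = NA_real_, duration = NA_real_,
                        n_cycles = NA_integer_, n_events = NA_integer_)
      bs <- tryCatch(bin_events(streams[[aid]], schedule, w[1L], w[2L], epoch_seconds),
                     error = function(e) note(aid, wn, "binning", e))
      if (!is.null(bs)) {
        row$n_events <- sum(bs$counts)
        is_dd <- any(bs$regime == "DD")
        pg <- tryCatch(chi_square_periodogram(bs), error = function(e) note(aid, wn, "periodogram", e))
        if (!is.null(pg)) row$period_hours <- pg$peak_period
        tau <- if (is_dd && !is.null(pg)) pg$peak_period else 24
        cf <- tryCatch(cosinor_fit(bs, trial_period = tau),
                       error = function(e) note(aid, wn, "cosinor", e))
        if (!is.null(cf)) {
          row$amplitude <- cf$amplitude
          row$acrophase_zt <- cf$acrophase_zt
          row$mesor <- cf$mesor
          row$percent_rhythm <- cf$percent_rhythm
        }
        de <- tryCatch(dfa(bs, min_scale = dfa_min_scale, max_scale = dfa_max_scale),
                       error = function(e) note(aid, wn, "dfa", e))
        if (!is.null(de)) row$scaling_exponent <- de$scaling_exponent
        if (!is_dd) {
          ap <- tryCatch({
            sm <- gaussian_smooth(bs, span_hours = smooth_span_hours)
            ph <- detect_active_phases(classify_active_epochs(sm), schedule,
                                       max_gap_hours = max_gap_hours)
            active_phase_summary(ph)
          }, error = function(e) note(aid, wn, "active_phase", e))
          if (!is.null(ap)) {
            row$onset <- ap$onset
            row$offset <- ap$offset
            row$duration <- ap$duration
            row$n_cycles <- ap$n_cycles
          }
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "log") <- unlist(logs)
  attr(out, "parameters") <- list(epoch_seconds = epoch_seconds,
                                  smooth_span_hours = smooth_span_hours,
                                  max_gap_hours = max_gap_hours,
                                  periodogram = c(20, 25), dfa_order = 1,
                                  dfa_scales = c(dfa_min_scale, dfa_max_scale))
  out
}

#' Per-cycle response to a phase shift
#'
#' Active-phase metrics and per-cycle cosinor acrophase for the cycles before
#' and after a shift of the LD schedule, with ZT referred to the new schedule
#' from its first lights-on.
#'
#' @param streams named list of [event_stream] objects.
#' @param schedule a [light_schedule] containing a shift (two LD segments with
#'   different lights-on).
#' @param n_pre,n_post number of pre-/post-shift cycles to report.
#' @param epoch_seconds epoch length (default 300 s).
#' @return a `data.frame` with one row per animal x cycle; `cycle` is negative
#'   before the shift and 1, 2, ... after it; columns `onset`, `offset`,
#'   `duration` (unwrapped, dark onset = ZT 12) and `acrophase_zt` from a
#'   24-h cosinor on that cycle.
#' @export
phase_shift_response <- function(streams, schedule, n_pre = 3, n_post = 3,
                                 epoch_seconds = 300) {
  seg <- schedule$segments
  if (nrow(seg) < 2L || any(seg$regime[1:2] != "LD"))
    .stopf("design error: schedule must contain two LD segments around the shift")
  avail_post <- floor(.hours(seg$end[2L], seg$start[2L]) / seg$cycle_length[2L])
  if (avail_post < 2) .stopf("design error: need at least 2 post-shift cycles")
  n_post <- min(n_post, avail_post)
  cyc1_s <- seg$cycle_length[1L] * 3600
  cyc2_s <- seg$cycle_length[2L] * 3600
  # pre-shift cycles are anchored to the old lights-on; a truncated stub at
  # the segment end (the shortened light phase) is excluded
  last_on <- seg$zt_anchor[1L] +
    floor(.hours(seg$end[1L], seg$zt_anchor[1L]) / seg$cycle_length[1L]) * cyc1_s
  avail_pre <- floor(.hours(last_on, seg$start[1L]) / seg$cycle_length[1L])
  n_pre <- min(n_pre, avail_pre)
  pre_start <- last_on - n_pre * cyc1_s
  cycles <- c(-(n_pre:1), seq_len(n_post))
  rows <- list()
  for (aid in names(streams)) {
    # detect phases over the whole span so smoothing is continuous per segment
    span <- list(pre = c(pre_start, last_on),
                 post = c(seg$start[2L], seg$start[2L] + n_post * cyc2_s))
    phs <- lapply(span, function(w) {
      bs <- bin_events(streams[[aid]], schedule, w[1L], w[2L], epoch_seconds)
      detect_active_phases(classify_active_epochs(gaussian_smooth(bs)), schedule)
    })
    for (ci in seq_along(cycles)) {
      k <- cycles[ci]
      if (k < 0) {
        w0 <- pre_start + (n_pre + k) * cyc1_s
        w <- c(w0, w0 + cyc1_s)
        prim <- phs$pre[phs$pre$is_primary, , drop = FALSE]
        idx <- nrow(prim) + k + 1L
        p <- if (idx >= 1L && idx <= nrow(prim)) prim[idx, , drop = FALSE]
             else prim[0L, , drop = FALSE]
      } else {
        w0 <- seg$start[2L] + (k - 1L) * cyc2_s
        w <- c(w0, w0 + cyc2_s)
        prim <- phs$post[phs$post$is_primary, , drop = FALSE]
        ucyc <- sort(unique(prim$cycle_index))
        p <- if (k <= length(ucyc)) prim[prim$cycle_index == ucyc[k], , drop = FALSE]
             else prim[0L, , drop = FALSE]
      }
      cf <- tryCatch(cosinor_fit(bin_events(streams[[aid]], schedule, w[1L], w[2L],
                                            epoch_seconds), trial_period = 24),
                     error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        animal_id = aid, cycle = k,
        onset = if (nrow(p)) p$onset else NA_real_,
        offset = if (nrow(p)) p$offset else NA_real_,
        duration = if (nrow(p)) p$duration else NA_real_,
        acrophase_zt = if (!is.null(cf)) cf$acrophase_zt else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Double-plotted actogram matrix
#'
#' Rebins a series into `bin_minutes` bins and lays out row `d` as the
#' concatenation of day `d` and day `d + 1` (the conventional double plot),
#' so the second half of each row equals the first half of the next. A
#' light/dark annotation track (1 = light) for the same layout is attached.
#'
#' @param series a [binned_series] covering at least 2 days, starting on a
#'   day boundary of the plot (usually lights-on).
#' @param schedule the [light_schedule].
#' @param bin_minutes actogram bin width (default 15 min).
#' @return a numeric matrix (days - 1 rows, `2 * 1440 / bin_minutes` columns)
#'   with attribute `light` (same shape, 1 = lights on).
#' @export
export_actogram <- function(series, schedule, bin_minutes = 15) {
  stopifnot(inherits(series, "binned_series"))
  bin_s <- bin_minutes * 60
  if (bin_s %% series$epoch_seconds != 0)
    .stopf("actogram bin must be a multiple of the epoch length")
  f <- bin_s %/% series$epoch_seconds
  n_use <- (length(series$counts) %/% f) * f
  x <- colSums(matrix(series$counts[seq_len(n_use)], nrow = f))
  per_day <- as.integer(1440 / bin_minutes)
  n_days <- length(x) %/% per_day
  if (n_days < 2) .stopf("need at least 2 full days for a double plot")
  day <- matrix(x[seq_len(n_days * per_day)], nrow = per_day)
  mat <- t(rbind(day[, -n_days, drop = FALSE], day[, -1L, drop = FALSE]))
  starts <- series$start + (seq_len(n_days * per_day) - 1L) * bin_s
  lt <- as.integer(zt_of(starts, schedule) <
                     schedule$segments$photoperiod[.segment_index(starts, schedule)] &
                     regime_of(starts, schedule) == "LD")
  ld <- matrix(lt, nrow = per_day)
  light <- t(rbind(ld[, -n_days, drop = FALSE], ld[, -1L, drop = FALSE]))
  dimnames(mat) <- list(paste0("day", seq_len(n_days - 1L)), NULL)
  attr(mat, "light") <- light
  attr(mat, "bin_minutes") <- bin_minutes
  mat
}
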