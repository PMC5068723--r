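#' Light schedules and zeitgeber time
#'
#' A light schedule is an ordered, contiguous set of segments, each either
#' light-dark (`"LD"`) or constant darkness (`"DD"`). Zeitgeber time (ZT) is
#' anchored to lights-on: ZT 0 is the onset of the light phase, so under a
#' 12:12 schedule the dark phase spans ZT 12-24. During DD the ZT axis is
#' extrapolated from the most recent LD segment, and after a shift of the
#' schedule the ZT axis follows the new schedule from its first lights-on.
#'
#' @param segments a `data.frame` with one row per segment and columns
#'   `start` (POSIXct, UTC recommended), `regime` (`"LD"` or `"DD"`),
#'   `lights_on` (clock hour of lights-on, in `[0, 24)`; ignored for DD),
#'   `photoperiod` (light-phase length in hours) and `cycle_length`
#'   (zeitgeber period in hours, 24 for clock-locked LD segments).
#' @param end POSIXct end of the schedule (end of the last segment).
#' @return an object of class `light_schedule`.
#' @examples
#' s0 <- as.POSIXct("2020-01-01 06:00:00", tz = "UTC")
#' sched <- ld_schedule(s0, days = 6)
#' zt_of(s0 + 3600 * 18, sched)  # midnight -> ZT 18
#' @export
light_schedule <- function(segments, end) {
  stopifnot(is.data.frame(segments), nrow(segments) >= 1L)
  need <- c("start", "regime", "lights_on", "photoperiod", "cycle_length")
  miss <- setdiff(need, names(segments))
  if (length(miss)) .stopf("schedule segments lack columns: %s", paste(miss, collapse = ", "))
  if (!.is_posixct(segments$start)) .stopf("segment 'start' must be POSIXct")
  if (!.is_posixct(end)) .stopf("'end' must be POSIXct")
  if (is.unsorted(as.numeric(segments$start), strictly = TRUE))
    .stopf("segment starts must be strictly increasing")
  if (end <= segments$start[nrow(segments)]) .stopf("'end' must lie after the last segment start")
  if (!all(segments$regime %in% c("LD", "DD"))) .stopf("regime must be 'LD' or 'DD'")
  bad <- segments$photoperiod <= 0 | segments$photoperiod >= segments$cycle_length
  if (any(bad)) .stopf("photoperiod must lie strictly inside (0, cycle_length)")
  if (segments$regime[1L] == "DD" && is.na(segments$lights_on[1L]))
    .stopf("a leading DD segment needs 'lights_on' to define its extrapolated ZT axis")
  seg <- segments[, need]
  seg$end <- c(segments$start[-1L], end)
  # ZT anchor: an absolute lights-on instant for each segment. DD segments
  # inherit the anchor (and cycle length) of the most recent LD segment.
  anchor <- as.POSIXct(rep(NA_real_, nrow(seg)), origin = "1970-01-01", tz = attr(seg$start, "tzone"))
  acyc <- numeric(nrow(seg))
  for (i in seq_len(nrow(seg))) {
    if (seg$regime[i] == "LD" || i == 1L) {
      day0 <- as.POSIXct(trunc(seg$start[i], units = "days"))
      a <- day0 + seg$lights_on[i] * 3600
      # move anchor to the last lights-on at or before the segment start
      k <- floor(.hours(seg$start[i], a) / seg$cycle_length[i])
      anchor[i] <- a + k * seg$cycle_length[i] * 3600
      acyc[i] <- seg$cycle_length[i]
    } else {
      anchor[i] <- anchor[i - 1L]
      acyc[i] <- acyc[i - 1L]
    }
  }
  seg$zt_anchor <- anchor
  seg$anchor_cycle <- acyc
  structure(list(segments = seg, start = seg$start[1L], end = end),
            class = "light_schedule")
}

#' @rdname light_schedule
#' @param start POSIXct start of the schedule (a lights-on instant is cleanest).
#' @param days number of 24-h cycles.
#' @param lights_on clock hour of lights-on (default 6, i.e. 06:00).
#' @param photoperiod light-phase length in hours (default 12).
#' @export
ld_schedule <- function(start, days, lights_on = 6, photoperiod = 12) {
  light_schedule(
    data.frame(start = start, regime = "LD", lights_on = lights_on,
               photoperiod = photoperiod, cycle_length = 24),
    end = start + days * 86400
  )
}

#' Standard experimental schedules
#'
#' `dd_protocol_schedule()` builds the entrainment/free-running/resynchronization
#' design: LD cycles (acclimation + baseline), constant darkness, then LD
#' resumed (forced synchronization). `phase_advance_schedule()` builds a
#' jet-lag design in which lights-on is advanced by `shift_hours` (the dark
#' phase preceding the first shifted cycle is shortened).
#'
#' @inheritParams ld_schedule
#' @param acclimation_days,baseline_days,dd_days,resync_days segment lengths in
#'   24-h cycles.
#' @return a `light_schedule`.
#' @export
dd_protocol_schedule <- function(start, acclimation_days = 3, baseline_days = 3,
                                 dd_days = 14, resync_days = 3,
                                 lights_on = 6, photoperiod = 12) {
  ld1 <- acclimation_days + baseline_days
  seg <- data.frame(
    start = c(start, start + ld1 * 86400, start + (ld1 + dd_days) * 86400),
    regime = c("LD", "DD", "LD"),
    lights_on = lights_on, photoperiod = photoperiod, cycle_length = 24
  )
  light_schedule(seg, end = start + (ld1 + dd_days + resync_days) * 86400)
}

#' @rdname dd_protocol_schedule
#' @param pre_days,post_days cycles before and after the shift.
#' @param shift_hours size of the phase advance in hours (default 6).
#' @export
phase_advance_schedule <- function(start, pre_days = 3, post_days = 5,
                                   shift_hours = 6, lights_on = 6,
                                   photoperiod = 12) {
  stopifnot(shift_hours > 0, shift_hours < photoperiod)
  new_on <- (lights_on - shift_hours) %% 24
  # the advance truncates the light phase preceding the first shifted dark
  # onset, so every dark phase (and active phase) stays complete
  seg <- data.frame(
    start = c(start, start + pre_days * 86400 + (photoperiod - shift_hours) * 3600),
    regime = "LD",
    lights_on = c(lights_on, new_on),
    photoperiod = photoperiod, cycle_length = 24
  )
  light_schedule(seg, end = seg$start[2L] + post_days * 86400)
}

# index of the segment containing each timestamp
.segment_index <- function(t, schedule) {
  seg <- schedule$segments
  if (any(t < schedule$start | t > schedule$end))
    .stopf("timestamp outside the schedule span (%s to %s)",
           format(schedule$start), format(schedule$end))
  i <- findInterval(as.numeric(t), as.numeric(seg$start))
  pmin(pmax(i, 1L), nrow(seg))
}

#' Zeitgeber time of a timestamp
#'
#' ZT is the number of hours since the most recent lights-on, modulo the cycle
#' length. In DD the axis is extrapolated from the last LD segment.
#'
#' @param t POSIXct vector within the schedule span.
#' @param schedule a [light_schedule].
#' @return numeric vector of ZT hours in `[0, cycle_length)`.
#' @export
zt_of <- function(t, schedule) {
  stopifnot(inherits(schedule, "light_schedule"))
  i <- .segment_index(t, schedule)
  seg <- schedule$segments
  .wrap(.hours(t, seg$zt_anchor[i]), seg$anchor_cycle[i])
}

#' @rdname zt_of
#' @return `regime_of()`: character vector, `"LD"` or `"DD"`.
#' @export
regime_of <- function(t, schedule) {
  schedule$segments$regime[.segment_index(t, schedule)]
}

#' Absolute times of dark onsets within a window
#'
#' Dark onset is ZT = photoperiod. For DD segments the subjective dark onsets
#' of the extrapolated ZT axis are returned.
#'
#' @param schedule a [light_schedule].
#' @param from,to POSIXct window (half-open, `[from, to)`).
#' @return POSIXct vector of dark-onset times, sorted.
#' @export
dark_onsets <- function(schedule, from = schedule$start, to = schedule$end) {
  seg <- schedule$segments
  out <- list()
  for (i in seq_len(nrow(seg))) {
    lo <- max(seg$start[i], from)
    hi <- min(seg$end[i], to)
    if (lo >= hi) next
    cyc <- seg$anchor_cycle[i]
    d0 <- seg$zt_anchor[i] + seg$photoperiod[i] * 3600
    k0 <- ceiling(.hours(lo, d0) / cyc - 1e-9)
    kk <- k0
    repeat {
      tt <- d0 + kk * cyc * 3600
      if (tt >= hi) break
      if (tt >= lo) out[[length(out) + 1L]] <- tt
      kk <- kk + 1
    }
  }
  if (!length(out)) return(schedule$start[0])
  sort(do.call(c, out))
}

#' @export
print.light_schedule <- function(x, ...) {
  seg <- x$segments
  cat(sprintf("<light_schedule> %s to %s\n", format(x$start), format(x$end)))
  for (i in seq_len(nrow(seg))) {
    cat(sprintf("  [%d] %s  %s", i, seg$regime[i], format(seg$start[i])))
    if (seg$regime[i] == "LD")
      cat(sprintf("  lights-on %02.0f:00, %g:%g",
                  seg$lights_on[i], seg$photoperiod[i],
                  seg$cycle_length[i] - seg$photoperiod[i]))
    cat("\n")
  }
  invisible(x)
}
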