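#' Gaussian smoothing of a binned activity series
#'
#' Weighted moving average with a sliding, truncated Gaussian window of total
#' span `span_hours` (default 4 h, i.e. +/- 2 h around each epoch). The kernel
#' standard deviation is `span_hours / 4` (truncation at 2 sigma) unless
#' `sigma_hours` is given. Weights are renormalized to sum to one where the
#' window is clipped at the edges of the record, so a constant series maps to
#' itself everywhere.
#'
#' @param series a [binned_series].
#' @param span_hours total kernel span in hours; must cover at least 3 epochs.
#' @param sigma_hours kernel SD in hours (default `span_hours / 4`).
#' @return an object of class `smoothed_series`: the input axis plus `values`
#'   (the smoothed counts) and `kernel` metadata.
#' @export
gaussian_smooth <- function(series, span_hours = 4, sigma_hours = span_hours / 4) {
  stopifnot(inherits(series, "binned_series"))
  ep_h <- series$epoch_seconds / 3600
  half <- floor(span_hours / 2 / ep_h + 1e-9)
  if (2 * half + 1 < 3) .stopf("kernel span must cover at least 3 epochs")
  off_h <- (-half:half) * ep_h
  w <- stats::dnorm(off_h, 0, sigma_hours)
  w <- w / sum(w)
  x <- as.numeric(series$counts)
  n <- length(x)
  xp <- c(rep(0, half), x, rep(0, half))
  ip <- c(rep(0, half), rep(1, n), rep(0, half))
  num <- as.numeric(stats::filter(xp, w, sides = 2))[(half + 1):(half + n)]
  den <- as.numeric(stats::filter(ip, w, sides = 2))[(half + 1):(half + n)]
  out <- series
  out$values <- num / den
  out$counts <- NULL
  out$kernel <- list(span_hours = 2 * half * ep_h + ep_h, sigma_hours = sigma_hours,
                     half_width_epochs = half)
  class(out) <- "smoothed_series"
  out
}

#' @export
print.smoothed_series <- function(x, ...) {
  cat(sprintf("<smoothed_series> animal %s: %d epochs, Gauss kernel span %g h (sigma %g h)\n",
              x$animal_id, length(x$values), x$kernel$span_hours, x$kernel$sigma_hours))
  invisible(x)
}

#' Classify active epochs
#'
#' Epochs whose smoothed activity exceeds the individual's average over the
#' analysis window are "active". The threshold (the window mean of the
#' smoothed series) is recorded in the result.
#'
#' @param smoothed a [gaussian_smooth()] result.
#' @param window optional POSIXct `c(from, to)` restricting the analysis
#'   window (half-open); default is the whole series.
#' @return an object of class `active_mask`: logical `mask` per retained
#'   epoch, `threshold`, plus the epoch axis.
#' @export
classify_active_epochs <- function(smoothed, window = NULL) {
  stopifnot(inherits(smoothed, "smoothed_series"))
  keep <- rep(TRUE, length(smoothed$values))
  if (!is.null(window))
    keep <- smoothed$epoch_start >= window[1] & smoothed$epoch_start < window[2]
  if (!any(keep)) .stopf("window contains no epochs")
  v <- smoothed$values[keep]
  thr <- mean(v)
  if (stats::var(v) == 0) {
    warning("zero-variance window: no epoch classified active", call. = FALSE)
    mask <- rep(FALSE, length(v))
  } else {
    mask <- v > thr
  }
  structure(list(mask = mask, threshold = thr,
                 epoch_start = smoothed$epoch_start[keep],
                 epoch_seconds = smoothed$epoch_seconds,
                 zt = smoothed$zt[keep], animal_id = smoothed$animal_id),
            class = "active_mask")
}

# merge runs of TRUE separated by FALSE gaps of <= gap_epochs (inclusive)
.merge_gaps <- function(mask, gap_epochs) {
  r <- rle(mask)
  nr <- length(r$lengths)
  if (nr >= 3L) {
    for (j in 2:(nr - 1L)) {
      if (!r$values[j] && r$lengths[j] <= gap_epochs &&
          r$values[j - 1L] && r$values[j + 1L])
        r$values[j] <- TRUE
    }
  }
  inverse.rle(r)
}

#' Detect active phases
#'
#' An active phase is a sequence of active epochs that are contiguous or
#' separated by gaps no larger than `max_gap_hours` (inclusive; default 1 h).
#' Onset is the ZT of the first epoch of the merged run and offset the ZT of
#' the start of the epoch after the last. Each phase is assigned to the LD
#' cycle whose window (dark onset - 6 h, dark onset + 18 h) contains the
#' phase midpoint; when several phases land in one cycle the longest is that
#' cycle's (primary) active phase and the others are flagged secondary.
#' Onset and offset are reported unwrapped relative to the assigned cycle
#' (dark onset = ZT `photoperiod`, so an offset running past the next
#' lights-on exceeds 24), keeping `duration = offset - onset` linear; the
#' wrapped ZT values are also given.
#'
#' @param mask a [classify_active_epochs()] result.
#' @param schedule the [light_schedule] the mask is aligned to.
#' @param max_gap_hours largest inactive gap merged into a phase (default 1).
#' @return a `data.frame` of class `active_phases` with columns `animal_id`,
#'   `cycle_index`, `onset`, `offset`, `duration` (hours, unwrapped),
#'   `onset_zt`, `offset_zt` (mod 24), `is_primary`. An all-inactive mask
#'   gives zero rows.
#' @export
detect_active_phases <- function(mask, schedule, max_gap_hours = 1) {
  stopifnot(inherits(mask, "active_mask"), inherits(schedule, "light_schedule"))
  ep_h <- mask$epoch_seconds / 3600
  gap_epochs <- floor(max_gap_hours / ep_h + 1e-9)
  m <- .merge_gaps(mask$mask, gap_epochs)
  empty <- data.frame(animal_id = character(), cycle_index = integer(),
                      onset = numeric(), offset = numeric(), duration = numeric(),
                      onset_zt = numeric(), offset_zt = numeric(),
                      is_primary = logical())
  if (!any(m)) return(structure(empty, class = c("active_phases", "data.frame")))
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  act <- which(r$values)
  dk <- dark_onsets(schedule, from = mask$epoch_start[1L] - 20 * 3600,
                    to = mask$epoch_start[length(mask$epoch_start)] + 20 * 3600)
  if (!length(dk)) .stopf("no dark onsets found near the analysis window")
  pp <- schedule$segments$photoperiod[.segment_index(mask$epoch_start[1L], schedule)]
  rows <- lapply(act, function(j) {
    t_on <- mask$epoch_start[starts[j]]
    t_off <- mask$epoch_start[ends[j]] + mask$epoch_seconds
    mid <- t_on + as.numeric(difftime(t_off, t_on, units = "secs")) / 2
    rel <- .hours(mid, dk)
    ci <- which(rel > -6 & rel <= 18)
    if (!length(ci)) return(NULL)
    ci <- ci[1L]
    onset <- pp + .hours(t_on, dk[ci])
    offset <- pp + .hours(t_off, dk[ci])
    data.frame(animal_id = mask$animal_id, cycle_index = ci,
               onset = onset, offset = offset, duration = offset - onset,
               onset_zt = .wrap(onset, 24), offset_zt = .wrap(offset, 24),
               is_primary = TRUE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(structure(empty, class = c("active_phases", "data.frame")))
  # one primary phase per cycle: the longest
  for (ci in unique(out$cycle_index)) {
    sel <- which(out$cycle_index == ci)
    if (length(sel) > 1L) out$is_primary[sel[-which.max(out$duration[sel])]] <- FALSE
  }
  out <- out[order(out$cycle_index, out$onset), ]
  rownames(out) <- NULL
  structure(out, class = c("active_phases", "data.frame"))
}

#' Summarize active phases over cycles
#'
#' Per-animal arithmetic means of onset, offset and duration over the primary
#' phases of the analysis window (under steady entrainment, three consecutive
#' LD cycles). Means are taken on the unwrapped axis, so mean duration equals
#' mean offset minus mean onset when every cycle has a phase.
#'
#' @param phases a [detect_active_phases()] result.
#' @return a one-row `data.frame`: `animal_id`, `n_cycles`, `onset`, `offset`,
#'   `duration` (all NA with `n_cycles = 0` when no phase was detected).
#' @export
active_phase_summary <- function(phases) {
  stopifnot(inherits(phases, "active_phases"))
  p <- phases[phases$is_primary, , drop = FALSE]
  if (!nrow(p))
    return(data.frame(animal_id = NA_character_, n_cycles = 0L,
                      onset = NA_real_, offset = NA_real_, duration = NA_real_))
  data.frame(animal_id = p$animal_id[1L], n_cycles = nrow(p),
             onset = mean(p$onset), offset = mean(p$offset),
             duration = mean(p$duration))
}
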