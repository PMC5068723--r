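#' Single-component cosinor rhythmometry
#'
#' Least-squares fit of \eqn{y(t) = M + \beta_c \cos(2\pi t/\tau) + \beta_s
#' \sin(2\pi t/\tau)} at a fixed trial period \eqn{\tau}. The fit is linear in
#' the parameters, so it is exact on noiseless cosine input. Reported
#' quantities are the mesor \eqn{M} (rhythm-adjusted mean), the amplitude
#' \eqn{A = \sqrt{\beta_c^2 + \beta_s^2}} (half the peak-to-trough range) and
#' the acrophase, the time of the fitted peak, expressed here in zeitgeber-time
#' hours (ZT of the peak, in `[0, 24)`) rather than the classical
#' negative-radians convention.
#'
#' @param series input series: a [binned_series] (counts on a ZT-aware axis),
#'   or a `data.frame` with columns `time` (hours) and `value` (e.g. an
#'   expression time course, with `time` hours after synchronization).
#' @param trial_period trial period \eqn{\tau} in hours (default 24).
#' @param ... passed to methods.
#' @return an object of class `cosinor_fit` with fields `mesor`, `amplitude`,
#'   `acrophase_zt` (NA, flagged, for a rhythm-free constant series),
#'   `trial_period`, `residual_variance`, `percent_rhythm` (fraction of
#'   variance explained, in `[0, 1]`) and `n`.
#' @examples
#' t <- seq(0, 72, by = 1 / 12)
#' y <- 10 + 3 * cos(2 * pi * (t - 18) / 24)
#' cosinor_fit(data.frame(time = t, value = y))
#' @export
cosinor_fit <- function(series, trial_period = 24, ...) UseMethod("cosinor_fit")

#' @rdname cosinor_fit
#' @export
cosinor_fit.data.frame <- function(series, trial_period = 24, ...) {
  stopifnot(all(c("time", "value") %in% names(series)))
  .cosinor_core(series$time, series$value, trial_period, zt0 = series$time[1] %% 24)
}

#' @rdname cosinor_fit
#' @export
cosinor_fit.binned_series <- function(series, trial_period = 24, ...) {
  t_h <- (seq_along(series$counts) - 1L) * series$epoch_seconds / 3600
  .cosinor_core(t_h, as.numeric(series$counts), trial_period, zt0 = series$zt[1L])
}

.cosinor_core <- function(t_hours, y, trial_period, zt0) {
  stopifnot(length(t_hours) == length(y), trial_period > 0)
  ok <- is.finite(t_hours) & is.finite(y)
  t_hours <- t_hours[ok]; y <- y[ok]
  n <- length(y)
  if (n < 4L) .stopf("cosinor needs at least 4 points")
  if (diff(range(t_hours)) < trial_period &&
      length(unique(round(.wrap(t_hours, trial_period), 6))) < 3L)
    .stopf("insufficient phase coverage for a cosinor fit")
  w <- 2 * pi / trial_period
  # time measured from the first sample so that zt0 anchors the phase
  tt <- t_hours - t_hours[1L]
  X <- cbind(1, cos(w * tt), sin(w * tt))
  qr_ <- qr(X)
  if (qr_$rank < 3L) .stopf("insufficient phase coverage for a cosinor fit")
  beta <- qr.coef(qr_, y)
  res <- y - X %*% beta
  amp <- sqrt(beta[2L]^2 + beta[3L]^2)
  sst <- sum((y - mean(y))^2)
  ssr <- sum(res^2)
  if (amp < sqrt(.Machine$double.eps) * max(1, abs(beta[1L]))) {
    amp <- 0
    peak <- NA_real_
    acro <- NA_real_
  } else {
    # peak of beta_c cos(wt) + beta_s sin(wt) is at wt = atan2(beta_s, beta_c)
    peak <- .wrap(atan2(beta[3L], beta[2L]) / w, trial_period)
    acro <- .wrap(zt0 + peak, 24)
  }
  structure(list(
    mesor = unname(beta[1L]), amplitude = unname(amp),
    acrophase_zt = unname(acro), peak_offset_hours = unname(peak),
    acrophase_defined = is.finite(acro),
    trial_period = trial_period, n = n,
    residual_variance = ssr / max(1L, n - 3L),
    percent_rhythm = if (sst > 0) max(0, 1 - ssr / sst) else 0
  ), class = "cosinor_fit")
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat(sprintf("<cosinor_fit> tau = %g h, n = %d\n", x$trial_period, x$n))
  cat(sprintf("  mesor %.4g  amplitude %.4g  acrophase %s\n",
              x$mesor, x$amplitude,
              if (x$acrophase_defined) sprintf("ZT %.3f", x$acrophase_zt) else "undefined"))
  cat(sprintf("  percent rhythm %.1f%%\n", 100 * x$percent_rhythm))
  invisible(x)
}
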