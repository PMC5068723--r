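#' Event streams of RFID visits
#'
#' An event stream holds the timestamped antenna reads of one animal: a
#' "visit" is the interval during which the animal is detected constantly by
#' the same antenna, and each visit onset is one activity count. Events are
#' kept time-ordered; exact duplicates (same timestamp and antenna) are
#' collapsed.
#'
#' @param animal_id label of the animal.
#' @param timestamp POSIXct vector of visit onsets.
#' @param antenna_id integer or character antenna labels (recycled).
#' @return an object of class `event_stream`.
#' @export
event_stream <- function(animal_id, timestamp, antenna_id = 1L) {
  stopifnot(.is_posixct(timestamp))
  antenna_id <- rep_len(antenna_id, length(timestamp))
  o <- order(timestamp)
  timestamp <- timestamp[o]; antenna_id <- antenna_id[o]
  dup <- duplicated(data.frame(t = as.numeric(timestamp), a = antenna_id))
  structure(list(animal_id = as.character(animal_id),
                 timestamp = timestamp[!dup],
                 antenna_id = antenna_id[!dup]),
            class = "event_stream")
}

#' @export
print.event_stream <- function(x, ...) {
  cat(sprintf("<event_stream> animal %s: %d events", x$animal_id, length(x$timestamp)))
  if (length(x$timestamp))
    cat(sprintf(" (%s to %s)", format(min(x$timestamp)), format(max(x$timestamp))))
  cat("\n")
  invisible(x)
}

#' Read visit event streams from a delimited text file
#'
#' Expects one row per visit with animal, timestamp and antenna columns (the
#' ASCII export convention of RFID home-cage systems). Rows whose timestamp
#' cannot be parsed are dropped and the drop count reported via a message.
#'
#' @param path file path.
#' @param sep field delimiter.
#' @param col_animal,col_time,col_antenna column names in the file header.
#' @param time_format a `strptime` format for the timestamp column.
#' @param tz time zone of the timestamps (default UTC).
#' @return a named list of [event_stream] objects, one per animal.
#' @export
read_events <- function(path, sep = ",",
                        col_animal = "animal_id", col_time = "timestamp",
                        col_antenna = "antenna_id",
                        time_format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC") {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  df <- tryCatch(utils::read.table(path, sep = sep, header = TRUE,
                                   stringsAsFactors = FALSE),
                 error = function(e) .stopf("cannot parse '%s': %s", path, conditionMessage(e)))
  if (!nrow(df)) .stopf("no data rows in '%s'", path)
  for (cn in c(col_animal, col_time)) if (!cn %in% names(df))
    .stopf("column '%s' missing in '%s'", cn, path)
  ts <- as.POSIXct(df[[col_time]], format = time_format, tz = tz)
  bad <- is.na(ts)
  if (all(bad))
    .stopf("no parseable timestamps in '%s' (first failure at data row %d: '%s')",
           path, which(bad)[1L], df[[col_time]][which(bad)[1L]])
  if (any(bad))
    message(sprintf("read_events: dropped %d row(s) with unparseable timestamps (first at data row %d)",
                    sum(bad), which(bad)[1L]))
  df <- df[!bad, , drop = FALSE]
  ts <- ts[!bad]
  ant <- if (col_antenna %in% names(df)) df[[col_antenna]] else 1L
  out <- lapply(split(seq_len(nrow(df)), df[[col_animal]]), function(i)
    event_stream(df[[col_animal]][i[1L]], ts[i], if (length(ant) > 1L) ant[i] else ant))
  out[order(names(out))]
}

#' Write event streams to a delimited text file
#'
#' One row per visit, columns `animal_id`, `timestamp` (ISO-8601) and
#' `antenna_id`; the inverse of [read_events()].
#'
#' @param streams a list of [event_stream] objects (or a single one).
#' @param path output file path.
#' @export
write_events <- function(streams, path) {
  if (inherits(streams, "event_stream")) streams <- list(streams)
  rows <- do.call(rbind, lapply(streams, function(s)
    data.frame(animal_id = s$animal_id,
               timestamp = format(s$timestamp, "%Y-%m-%dT%H:%M:%OS3", tz = "UTC"),
               antenna_id = s$antenna_id)))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Bin an event stream into equal epochs on the ZT axis
#'
#' Counts visit onsets in non-overlapping half-open epochs
#' `[start, start + epoch)` (the convention the active-phase onsets depend
#' on: an event exactly at an epoch boundary belongs to the later epoch) and
#' annotates each epoch with the zeitgeber time of its start and the lighting
#' regime. The standard epoch is 5 min.
#'
#' @param stream an [event_stream].
#' @param schedule a [light_schedule].
#' @param from,to POSIXct window; the window length must be a whole number of
#'   epochs and lie within the schedule.
#' @param epoch_seconds epoch length in seconds; must divide 24 h evenly
#'   (default 300 s = 5 min).
#' @return an object of class `binned_series`: `animal_id`, `epoch_seconds`,
#'   `start`, `counts`, `zt` (ZT hours of each epoch start), `regime`.
#' @export
bin_events <- function(stream, schedule, from, to, epoch_seconds = 300) {
  stopifnot(inherits(stream, "event_stream"), inherits(schedule, "light_schedule"))
  if (86400 %% epoch_seconds != 0) .stopf("epoch length must divide 24 h evenly")
  span_s <- as.numeric(difftime(to, from, units = "secs"))
  if (span_s <= 0) .stopf("empty window")
  if (abs(span_s / epoch_seconds - round(span_s / epoch_seconds)) > 1e-9)
    .stopf("window must span a whole number of epochs")
  if (from < schedule$start || to > schedule$end)
    .stopf("window outside the schedule span")
  n <- as.integer(round(span_s / epoch_seconds))
  starts <- from + (seq_len(n) - 1L) * epoch_seconds
  ts <- stream$timestamp
  ts <- ts[ts >= from & ts < to]
  k <- floor(as.numeric(difftime(ts, from, units = "secs")) / epoch_seconds) + 1L
  counts <- tabulate(k, nbins = n)
  structure(list(
    animal_id = stream$animal_id, epoch_seconds = epoch_seconds,
    start = from, epoch_start = starts, counts = counts,
    zt = zt_of(starts, schedule), regime = regime_of(starts, schedule)
  ), class = "binned_series")
}

#' @export
print.binned_series <- function(x, ...) {
  cat(sprintf("<binned_series> animal %s: %d x %gs epochs from %s (%d events)\n",
              x$animal_id, length(x$counts), x$epoch_seconds,
              format(x$start), sum(x$counts)))
  invisible(x)
}

#' @export
as.data.frame.binned_series <- function(x, ...) {
  data.frame(animal_id = x$animal_id, epoch_start = x$epoch_start,
             zt = x$zt, regime = x$regime, count = x$counts)
}
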