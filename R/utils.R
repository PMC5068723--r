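# internal helpers

# hours between two POSIXct, as numeric
.hours <- function(t1, t0) as.numeric(difftime(t1, t0, units = "hours"))

.wrap <- function(x, period = 24) x %% period

# wrap a phase difference into (-period/2, period/2]
.wrap_diff <- function(x, period = 24) {
  y <- (x + period / 2) %% period - period / 2
  ifelse(y == -period / 2, period / 2, y)
}

.is_posixct <- function(x) inherits(x, "POSIXct")

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# derive a stream of per-animal 32-bit seeds from one master seed
.child_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed %% .Machine$integer.max))
  sample.int(.Machine$integer.max - 1L, n)
}
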