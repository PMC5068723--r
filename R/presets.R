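#' Phenotype presets for the actigraphy simulator
#'
#' A phenotype preset collects the generative parameters of one simulated
#' animal class: circadian period (intrinsic = free-running, entrained = under
#' LD), relative modulation depth of the circadian rhythm, acrophase (ZT of
#' peak modulation), photic-gating geometry (how far activity onset leads dark
#' onset, how far it persists past lights-on, and the residual activity level
#' during the gated-off phase), the Hurst exponent of the long-range
#' correlated noise, the mean visit rate, and the re-entrainment time constant
#' (in cycles) after a change of the light schedule.
#'
#' @param name preset label.
#' @param intrinsic_period_hours free-running circadian period (DD).
#' @param entrained_period_hours period expressed under LD.
#' @param rhythm_amplitude relative modulation depth, in `[0, 1]`.
#' @param acrophase_zt_hours ZT of the circadian modulation peak, `[0, 24)`.
#' @param anticipation_hours how far activity onset leads dark onset (>= 0;
#'   0 = rigid gating on the dark phase).
#' @param offset_lag_hours how far activity persists past lights-on (>= 0).
#' @param gate_floor residual rate multiplier during the gated-off (light)
#'   phase, in `[0, 1]`; 1 disables photic gating.
#' @param gate_ramp_hours duration of the raised-cosine transition at the gate
#'   edges; near 0 = abrupt on/off switching (rigid light masking), larger =
#'   gradual build-up and wind-down of activity.
#' @param hurst_exponent Hurst exponent of the multiplicative noise, (0, 1).
#' @param mean_rate expected visits per hour.
#' @param noise_sd standard deviation of the log-rate noise (scale of the
#'   fractional-Gaussian multiplier).
#' @param reentrainment_rate_cycles time constant, in cycles, of the
#'   exponential phase relaxation after a schedule change; small = fast.
#' @return an object of class `phenotype_preset` (a named list).
#' @seealso [preset()] for the built-in phenotype classes.
#' @export
phenotype_preset <- function(name,
                             intrinsic_period_hours = 23.7,
                             entrained_period_hours = 24,
                             rhythm_amplitude = 0.85,
                             acrophase_zt_hours = 16.5,
                             anticipation_hours = 1.5,
                             offset_lag_hours = 1,
                             gate_floor = 0.7,
                             gate_ramp_hours = 2,
                             hurst_exponent = 0.8,
                             mean_rate = 60,
                             noise_sd = 0.25,
                             reentrainment_rate_cycles = 3) {
  if (rhythm_amplitude < 0 || rhythm_amplitude > 1) .stopf("rhythm_amplitude must be in [0, 1]")
  if (hurst_exponent <= 0 || hurst_exponent >= 1) .stopf("hurst_exponent must be in (0, 1)")
  if (mean_rate <= 0) .stopf("mean_rate must be positive")
  if (anticipation_hours < 0 || offset_lag_hours < 0)
    .stopf("anticipation and offset lag must be non-negative")
  if (gate_floor < 0 || gate_floor > 1) .stopf("gate_floor must be in [0, 1]")
  if (gate_ramp_hours < 0) .stopf("gate_ramp_hours must be non-negative")
  if (acrophase_zt_hours < 0 || acrophase_zt_hours >= 24)
    .stopf("acrophase_zt_hours must be in [0, 24)")
  structure(list(
    name = name,
    intrinsic_period_hours = intrinsic_period_hours,
    entrained_period_hours = entrained_period_hours,
    rhythm_amplitude = rhythm_amplitude,
    acrophase_zt_hours = acrophase_zt_hours,
    anticipation_hours = anticipation_hours,
    offset_lag_hours = offset_lag_hours,
    gate_floor = gate_floor,
    gate_ramp_hours = gate_ramp_hours,
    hurst_exponent = hurst_exponent,
    mean_rate = mean_rate,
    noise_sd = noise_sd,
    reentrainment_rate_cycles = reentrainment_rate_cycles
  ), class = "phenotype_preset")
}

#' Built-in phenotype presets
#'
#' Three simulated animal classes covering the phenomenology the analysis
#' pipeline is meant to separate:
#'
#' * `"control"` — healthy entrainment: a strong endogenous rhythm (modulation
#'   depth 0.85) that persists unchanged in constant darkness, mild photic
#'   gating (gate floor 0.7, gradual 2-h edges), activity onset anticipating
#'   dark onset by 1.5 h and persisting ~1 h past lights-on, acrophase before
#'   mid-dark (ZT 16.5), Hurst 0.8, slow re-entrainment (3 cycles).
#' * `"dex"` — rigid photic gating: no anticipation, activity confined to the
#'   dark phase (gate floor 0.03, offset lag 0.1 h), acrophase at mid-dark
#'   (ZT 18), high modulation depth (0.8), fast re-entrainment (0.3 cycles);
#'   with `age = "old"` the period expressed under steady entrainment drifts
#'   to 23.6 h.
#' * `"mehg"` — control-like timing (anticipation, acrophase, gating) with
#'   reduced modulation depth (0.3).
#'
#' @param name `"control"`, `"dex"` or `"mehg"`.
#' @param age `"young"` or `"old"` (affects only `"dex"`).
#' @param ... overrides passed to [phenotype_preset()].
#' @return a [phenotype_preset].
#' @export
preset <- function(name = c("control", "dex", "mehg"), age = c("young", "old"), ...) {
  name <- match.arg(name)
  age <- match.arg(age)
  args <- switch(name,
    control = list(name = "control"),
    dex = list(name = "dex", rhythm_amplitude = 0.8, acrophase_zt_hours = 18,
               anticipation_hours = 0, offset_lag_hours = 0.1, gate_floor = 0.03,
               gate_ramp_hours = 0.2, reentrainment_rate_cycles = 0.3,
               entrained_period_hours = if (age == "old") 23.6 else 24),
    mehg = list(name = "mehg", rhythm_amplitude = 0.3)
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(phenotype_preset, args)
}

#' @export
print.phenotype_preset <- function(x, ...) {
  cat(sprintf("<phenotype_preset> %s\n", x$name))
  cat(sprintf("  period %g h (intrinsic %g h), amplitude %g, acrophase ZT %g\n",
              x$entrained_period_hours, x$intrinsic_period_hours,
              x$rhythm_amplitude, x$acrophase_zt_hours))
  cat(sprintf("  gate: onset -%g h, offset +%g h, floor %g; H %g; %g visits/h\n",
              x$anticipation_hours, x$offset_lag_hours, x$gate_floor,
              x$hurst_exponent, x$mean_rate))
  invisible(x)
}
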