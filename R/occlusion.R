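# Carrier frequencies of the two modulated LED channels (Hz).
.f_590 <- 1100
.f_780 <- 1000

#' Describe a synthetic venous-occlusion recording scenario
#'
#' A scenario defines the amplitude envelopes of the two modulated LED
#' channels over a baseline / cuff-occlusion / release protocol, plus the
#' carrier sampling and noise model.  Three ways to pin the envelopes are
#' supported:
#' \itemize{
#'   \item `"drops"` (default): each channel ramps down by its fractional
#'     drop during occlusion (a step of `biphasic_jump_fraction` of the
#'     drop followed by a ramp for biphasic shapes) and recovers
#'     exponentially after release.
#'   \item `"rpf"`: the 590 nm envelope follows its drop shape and the
#'     780 nm envelope is slaved to it so that the log-attenuation ratio,
#'     and hence the implied differential pathlength factor, equals
#'     `rpf_true` exactly at every instant.
#'   \item `"lrbc"`: a target red-blood-cell pathlength trajectory
#'     (baseline value plus a linear rise during occlusion) is specified
#'     and the 590 nm envelope is obtained by inverting the voltage
#'     estimator while the 780 nm envelope keeps its small fixed drop;
#'     recovery tests then have exact ground truth.
#' }
#'
#' @param baseline_duration,occlusion_duration,release_duration Phase
#'   durations in s.
#' @param drop_590,drop_780 Fractional envelope decreases reached at the
#'   end of occlusion.
#' @param shape `"monophasic"` or `"biphasic"`.
#' @param biphasic_jump_fraction Fraction of the drop taken as the initial
#'   step of a biphasic occlusion.
#' @param recovery_time_constant Exponential recovery time constant after
#'   cuff release, s.
#' @param noise_sd Relative (envelope-proportional) standard deviation of
#'   the additive white Gaussian noise.
#' @param seed Integer seed; recordings are bit-reproducible per seed.
#' @param sample_rate Samples per second; the default matches the
#'   instrument's 50 k-samples/s digitizer.  Any rate for which the 20 ms
#'   lock-in window holds an integer number of samples and of both carrier
#'   cycles is accepted.
#' @param amplitude_590,amplitude_780 Baseline envelope amplitudes
#'   (arbitrary units; the estimators are gain-invariant).
#' @param mode Envelope mode, see above.
#' @param rpf_true Differential pathlength factor imposed in `"rpf"` mode.
#' @param mueff_ratio Attenuation-coefficient ratio used in `"rpf"` and
#'   `"lrbc"` modes.
#' @param lrbc_baseline_um,lrbc_slope_um_per_min Target pathlength
#'   trajectory in `"lrbc"` mode: baseline value (um) and linear rise rate
#'   during occlusion (um/min).  Defaults follow typical forearm values
#'   (17 um, 4 um/min).
#' @param constants [lrbc_constants()] used to invert the estimator in
#'   `"lrbc"` mode.
#' @return An object of class `occlusion_scenario`.
#' @export
occlusion_scenario <- function(baseline_duration = 180,
                               occlusion_duration = 180,
                               release_duration = 180,
                               drop_590 = 0.25, drop_780 = 0.03,
                               shape = c("monophasic", "biphasic"),
                               biphasic_jump_fraction = 0.5,
                               recovery_time_constant = 10,
                               noise_sd = 0.01, seed = 1,
                               sample_rate = 50000,
                               amplitude_590 = 1, amplitude_780 = 1,
                               mode = c("drops", "rpf", "lrbc"),
                               rpf_true = NULL, mueff_ratio = 14.87,
                               lrbc_baseline_um = 17,
                               lrbc_slope_um_per_min = 4,
                               constants = lrbc_constants()) {
  shape <- match.arg(shape)
  mode <- match.arg(mode)
  if (any(c(baseline_duration, occlusion_duration, release_duration) <= 0)) {
    stop("phase durations must be positive")
  }
  if (drop_590 < 0 || drop_590 >= 1 || drop_780 < 0 || drop_780 >= 1) {
    stop("fractional drops must lie in [0, 1)")
  }
  if (biphasic_jump_fraction < 0 || biphasic_jump_fraction > 1) {
    stop("biphasic_jump_fraction must lie in [0, 1]")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  w <- sample_rate / 50  # 20 ms lock-in window
  if (w != round(w) || (w * .f_590) %% sample_rate != 0 ||
      (w * .f_780) %% sample_rate != 0) {
    stop("sample_rate must give a 20 ms window with an integer number of ",
         "samples and of both carrier cycles")
  }
  if (mode == "rpf" && is.null(rpf_true)) stop("rpf_true required in rpf mode")
  structure(list(baseline_duration = baseline_duration,
                 occlusion_duration = occlusion_duration,
                 release_duration = release_duration,
                 drop_590 = drop_590, drop_780 = drop_780, shape = shape,
                 biphasic_jump_fraction = biphasic_jump_fraction,
                 recovery_time_constant = recovery_time_constant,
                 noise_sd = noise_sd, seed = seed,
                 sample_rate = sample_rate,
                 amplitude_590 = amplitude_590,
                 amplitude_780 = amplitude_780,
                 mode = mode, rpf_true = rpf_true,
                 mueff_ratio = mueff_ratio,
                 lrbc_baseline_um = lrbc_baseline_um,
                 lrbc_slope_um_per_min = lrbc_slope_um_per_min,
                 constants = constants),
            class = "occlusion_scenario")
}

# Relative (baseline = 1) envelope following the drop/shape/recovery rules.
.relative_envelope <- function(t, sc, drop) {
  tb <- sc$baseline_duration
  tr <- tb + sc$occlusion_duration
  e <- rep(1, length(t))
  occ <- t >= tb & t < tr
  u <- (t[occ] - tb) / sc$occlusion_duration
  e[occ] <- if (sc$shape == "monophasic") {
    1 - drop * u
  } else {
    j <- sc$biphasic_jump_fraction
    1 - drop * (j + (1 - j) * u)
  }
  rel <- t >= tr
  e[rel] <- 1 - drop * exp(-(t[rel] - tr) / sc$recovery_time_constant)
  e
}

# Target pathlength trajectory (um) in "lrbc" mode.
.lrbc_trajectory <- function(t, sc) {
  tb <- sc$baseline_duration
  tr <- tb + sc$occlusion_duration
  l <- rep(sc$lrbc_baseline_um, length(t))
  occ <- t >= tb & t < tr
  l[occ] <- sc$lrbc_baseline_um +
    sc$lrbc_slope_um_per_min * (t[occ] - tb) / 60
  l_end <- sc$lrbc_baseline_um +
    sc$lrbc_slope_um_per_min * sc$occlusion_duration / 60
  rel <- t >= tr
  l[rel] <- sc$lrbc_baseline_um + (l_end - sc$lrbc_baseline_um) *
    exp(-(t[rel] - tr) / sc$recovery_time_constant)
  l
}

# Run code with a locally seeded RNG, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Synthesize a modulated dual-wavelength reflectometer recording
#'
#' Produces the four digitized waveforms of the instrument: two AC photo
#' channels, `envelope(t) * sin(2 pi f t)` with envelope-proportional white
#' Gaussian noise, modulated at 1100 Hz (590 nm) and 1000 Hz (780 nm), and
#' the two unit-amplitude sinusoidal reference signals.  The generating
#' envelopes (and, in `"lrbc"` mode, the target pathlength trajectory) are
#' retained for recovery testing.
#'
#' @param scenario An [occlusion_scenario()].
#' @return An object of class `reflectometry_recording`: list with
#'   `sample_rate`, `channel_590`, `channel_780`, `ref_590`, `ref_780`,
#'   `true_envelopes` (list `e_590`, `e_780`, optionally `lrbc_um`), and
#'   the `scenario`.
#' @export
generate_recording <- function(scenario) {
  stopifnot(inherits(scenario, "occlusion_scenario"))
  sc <- scenario
  fs <- sc$sample_rate
  n <- round(fs * (sc$baseline_duration + sc$occlusion_duration +
                     sc$release_duration))
  t <- (seq_len(n) - 1) / fs
  lrbc_um <- NULL
  if (sc$mode == "lrbc") {
    e780 <- sc$amplitude_780 * .relative_envelope(t, sc, sc$drop_780)
    lrbc_um <- .lrbc_trajectory(t, sc)
    # invert the voltage estimator: ln V590 = ln v0r + ln V780 - D * L(mm)
    e590 <- sc$constants$v0_ratio * e780 *
      exp(-sc$constants$denominator * lrbc_um / 1000)
  } else {
    rel590 <- .relative_envelope(t, sc, sc$drop_590)
    e590 <- sc$amplitude_590 * rel590
    if (sc$mode == "rpf") {
      e780 <- sc$amplitude_780 * rel590^(sc$rpf_true / sc$mueff_ratio)
    } else {
      e780 <- sc$amplitude_780 * .relative_envelope(t, sc, sc$drop_780)
    }
  }
  ref_590 <- sin(2 * pi * .f_590 * t)
  ref_780 <- sin(2 * pi * .f_780 * t)
  ch <- .with_seed(sc$seed, {
    list(c590 = e590 * ref_590 + stats::rnorm(n, sd = 1) * sc$noise_sd * e590,
         c780 = e780 * ref_780 + stats::rnorm(n, sd = 1) * sc$noise_sd * e780)
  })
  structure(list(sample_rate = fs,
                 channel_590 = ch$c590, channel_780 = ch$c780,
                 ref_590 = ref_590, ref_780 = ref_780,
                 true_envelopes = c(list(e_590 = e590, e_780 = e780),
                                    if (!is.null(lrbc_um))
                                      list(lrbc_um = lrbc_um)),
                 scenario = sc),
            class = "reflectometry_recording")
}

#' Software lock-in demodulation of a recording
#'
#' Splits each channel into consecutive windows of `window_length` samples
#' and extracts the carrier amplitude per window as
#' `2 * sqrt(mean(x * sin)^2 + mean(x * cos)^2)` with in-phase/quadrature
#' references at the channel's carrier frequency.  The default 20 ms
#' window holds exactly 22 cycles of the 1100 Hz carrier and 20 cycles of
#' the 1000 Hz carrier, so the two channels are mutually orthogonal and
#' the output rate is 50 samples/s.
#'
#' @param recording A [generate_recording()] result.
#' @param window_length Window length in samples; must divide the record
#'   length and span an integer number of both carrier periods.
#' @return A `demodulated_series`: data.frame with `time` (window centers,
#'   s), `ve_590`, `ve_780` and `phase`, with `occlusion_start`,
#'   `release_start` and `rate` attributes.
#' @export
lock_in_demodulate <- function(recording,
                               window_length = recording$sample_rate / 50) {
  stopifnot(inherits(recording, "reflectometry_recording"))
  fs <- recording$sample_rate
  w <- window_length
  n <- length(recording$channel_590)
  if (w != round(w) || n %% w != 0) {
    stop("window_length must divide the recording length")
  }
  if ((w * .f_590) %% fs != 0 || (w * .f_780) %% fs != 0) {
    stop("window must span an integer number of both carrier periods")
  }
  nwin <- n %/% w
  tw <- (seq_len(w) - 1) / fs
  demod1 <- function(x, f) {
    s <- sin(2 * pi * f * tw)
    co <- cos(2 * pi * f * tw)
    dim(x) <- c(w, nwin)
    2 * sqrt(as.vector(crossprod(x, s) / w)^2 +
               as.vector(crossprod(x, co) / w)^2)
  }
  time <- (seq_len(nwin) - 0.5) * w / fs
  sc <- recording$scenario
  t_occ <- sc$baseline_duration
  t_rel <- sc$baseline_duration + sc$occlusion_duration
  phase <- ifelse(time < t_occ, "baseline",
                  ifelse(time < t_rel, "occlusion", "release"))
  out <- data.frame(time = time,
                    ve_590 = demod1(recording$channel_590, .f_590),
                    ve_780 = demod1(recording$channel_780, .f_780),
                    phase = phase, stringsAsFactors = FALSE)
  attr(out, "occlusion_start") <- t_occ
  attr(out, "release_start") <- t_rel
  attr(out, "rate") <- fs / w
  class(out) <- c("demodulated_series", "data.frame")
  out
}
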