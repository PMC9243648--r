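#' Incident-intensity calibration readings
#'
#' The six bench readings of the two-stage calibration: with a low-gain
#' detection system, the probe output abutted to each optical filter
#' (`v0p_*`) and the diffuse reflection off a Delrin block (`vrp_*`); with
#' the high-gain primary system, the Delrin reflection (`vr_*`).  The
#' incident voltage each system would see is then
#' `V0 = VR * V0' / VR'` per wavelength.
#'
#' @param v0p_590,v0p_780 Low-gain probe-to-filter voltages.
#' @param vrp_590,vrp_780 Low-gain Delrin-reflection voltages.
#' @param vr_590,vr_780 High-gain Delrin-reflection voltages.
#' @return An object of class `calibration_readings`.
#' @export
calibration_readings <- function(v0p_590, vrp_590, v0p_780, vrp_780,
                                 vr_590, vr_780) {
  v <- c(v0p_590, vrp_590, v0p_780, vrp_780, vr_590, vr_780)
  if (length(v) != 6L || any(!is.finite(v)) || any(v <= 0)) {
    stop("all six calibration readings must be strictly positive scalars")
  }
  structure(list(v0p_590 = v0p_590, vrp_590 = vrp_590, v0p_780 = v0p_780,
                 vrp_780 = vrp_780, vr_590 = vr_590, vr_780 = vr_780),
            class = "calibration_readings")
}

#' Incident-intensity voltage ratio V0(590)/V0(780)
#'
#' Combines the calibration readings into the ratio used by the voltage
#' form of the pathlength estimator:
#' `(vr_590 / vr_780) * (v0p_590 / vrp_590) / (v0p_780 / vrp_780)`.
#' The result is invariant to any common rescaling of the readings.
#'
#' @param readings A [calibration_readings()] object.
#' @return The dimensionless ratio.
#' @export
v0_ratio <- function(readings) {
  stopifnot(inherits(readings, "calibration_readings"))
  with(readings, (vr_590 / vr_780) * (v0p_590 / vrp_590) /
         (v0p_780 / vrp_780))
}

#' Estimate the differential pathlength factor from an occlusion trace
#'
#' During a venous occlusion the log-voltage changes at the two
#' wavelengths, each referenced to its pre-inflation baseline mean, are
#' proportional; the OLS slope of `dln Ve(780)` on `dln Ve(590)` over the
#' occlusion window, multiplied by the attenuation-coefficient ratio
#' `mueff(590)/mueff(780)`, is the differential pathlength factor
#' RPF = PF(780)/PF(590).  The first 10 s after inflation are excluded by
#' default to blank the inflation transient.
#'
#' @param demod A demodulated series (columns `time`, `ve_590`, `ve_780`).
#' @param inflation_time Cuff-inflation time (s) on the series time axis;
#'   defaults to the `occlusion_start` attribute set by the synthesizer.
#' @param baseline_window Length-2 window (s) over which baseline voltages
#'   are averaged; default `c(0, inflation_time)`.
#' @param occlusion_window Length-2 window (s) of post-inflation times used
#'   for the regression, relative to `inflation_time`; default `c(10, 70)`.
#' @param mueff_ratio Ratio `mueff(590)/mueff(780)`; default 14.87.
#' @return The RPF estimate (dimensionless), with the regression slope and
#'   number of samples as attributes.
#' @export
estimate_rpf <- function(demod, inflation_time = attr(demod, "occlusion_start"),
                         baseline_window = c(0, inflation_time),
                         occlusion_window = c(10, 70),
                         mueff_ratio = 14.87) {
  req <- c("time", "ve_590", "ve_780")
  if (!all(req %in% names(demod))) {
    stop("demod must have columns time, ve_590, ve_780")
  }
  if (is.null(inflation_time)) {
    stop("inflation_time is required when the series carries no ",
         "occlusion_start attribute")
  }
  base <- demod$time >= baseline_window[1] & demod$time < baseline_window[2]
  occl <- demod$time >= inflation_time + occlusion_window[1] &
    demod$time <= inflation_time + occlusion_window[2]
  if (sum(base) < 2 || sum(occl) < 2) {
    stop("baseline and occlusion windows must each contain >= 2 samples")
  }
  if (any(demod$ve_590[base | occl] <= 0) ||
      any(demod$ve_780[base | occl] <= 0)) {
    stop("voltages must be positive over the analysis windows")
  }
  dln590 <- log(demod$ve_590[occl]) - log(mean(demod$ve_590[base]))
  dln780 <- log(demod$ve_780[occl]) - log(mean(demod$ve_780[base]))
  if (stats::var(dln590) < .Machine$double.eps) {
    stop("degenerate regression: no 590 nm attenuation change over the ",
         "occlusion window")
  }
  slope <- unname(stats::coef(stats::lm(dln780 ~ dln590))[2])
  structure(slope * mueff_ratio, slope = slope, n = sum(occl))
}
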