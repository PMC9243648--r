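# CSV dialect used package-wide: comma separators, header row, '.' decimal,
# UTF-8, floats at 9 significant digits.
.fmt_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 9, format = "g"))
}

.write_csv9 <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  out[num] <- lapply(df[num], .fmt_num)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a radial reflectance profile to CSV
#'
#' Columns: `bin_center`, `value` and, when present, `sd` and `stderr`.
#'
#' @param profile A `radial_profile` (from [run_transport()] or the
#'   `profile` element of [average_runs()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  if (inherits(profile, "mc_run_set")) profile <- profile$profile
  .write_csv9(as.data.frame(profile), path)
}

#' Read a radial reflectance profile from CSV
#' @param path CSV written by [write_profile_csv()].
#' @return A `radial_profile` data.frame.
#' @export
read_profile_csv <- function(path) {
  out <- utils::read.csv(path)
  class(out) <- c("radial_profile", "data.frame")
  out
}

#' Write a pathlength time series to CSV
#'
#' Columns `t_s`, `lrbc_um` and `phase` (when annotated).
#'
#' @param series An `lrbc_series` from [lrbc_from_voltages()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lrbc_series_csv <- function(series, path) {
  df <- data.frame(t_s = series$time, lrbc_um = series$lrbc_um)
  if (!is.null(series$phase)) df$phase <- series$phase
  .write_csv9(df, path)
}

#' Write a demodulated two-channel series to CSV
#' @param demod A `demodulated_series`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_demodulated_csv <- function(demod, path) {
  .write_csv9(as.data.frame(demod), path)
}

#' Read a demodulated two-channel series from CSV
#'
#' @param path CSV with columns `time`, `ve_590`, `ve_780` (and optionally
#'   `phase`).
#' @param occlusion_start Optional cuff-inflation time (s) to attach.
#' @return A `demodulated_series` data.frame.
#' @export
read_demodulated_csv <- function(path, occlusion_start = NULL) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time", "ve_590", "ve_780") %in% names(out))) {
    stop("expected columns time, ve_590, ve_780 in ", path)
  }
  if (!is.null(occlusion_start)) {
    attr(out, "occlusion_start") <- occlusion_start
  }
  class(out) <- c("demodulated_series", "data.frame")
  out
}

#' Write a run manifest
#'
#' Records the parameters, seeds, package version and output paths of a
#' command-line run as JSON, sufficient to re-run it bit-identically.
#'
#' @param path Manifest path.
#' @param command Subcommand name.
#' @param params Named list of parameters (including every seed).
#' @param outputs Character vector of files the run wrote.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, params, outputs) {
  manifest <- list(
    package = "lrbc",
    version = as.character(utils::packageVersion("lrbc")),
    command = command,
    parameters = params,
    outputs = outputs,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
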