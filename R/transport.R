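#' Transport configuration
#'
#' Settings for the weighted-photon-packet Monte Carlo kernel.
#'
#' @param n_packets Number of incident packets to launch.
#' @param seed Integer seed for the kernel's Mersenne generator; identical
#'   `(model, config)` pairs give bit-identical results.
#' @param roulette_threshold Packet weight below which Russian roulette is
#'   played.
#' @param roulette_m Roulette survival factor: survive with probability
#'   `1/roulette_m`, weight multiplied by `roulette_m`.
#' @param max_radius Largest exit radius (mm) resolved by the radial
#'   histogram; weight beyond it goes into an overflow bin.
#' @param bin_width Radial bin width in mm (bins centered on multiples of
#'   `bin_width`).
#' @return An object of class `transport_config`.
#' @export
transport_config <- function(n_packets = 1e5, seed = 1,
                             roulette_threshold = 1e-4, roulette_m = 10,
                             max_radius = 5, bin_width = 0.1) {
  if (n_packets < 1) stop("n_packets must be >= 1")
  if (roulette_threshold <= 0 || roulette_threshold >= 1) {
    stop("roulette_threshold must lie in (0, 1)")
  }
  if (roulette_m < 2) stop("roulette_m must be >= 2")
  if (max_radius <= 0 || bin_width <= 0) stop("radii must be positive")
  structure(list(n_packets = as.integer(n_packets), seed = seed,
                 roulette_threshold = roulette_threshold,
                 roulette_m = as.integer(roulette_m),
                 max_radius = max_radius, bin_width = bin_width),
            class = "transport_config")
}

#' Histogram raw exit radii into annular bins
#'
#' Bins are `bin_width` wide and centered on integer multiples of
#' `bin_width` (edges at `(k +/- 1/2) * bin_width`); weight beyond
#' `max_radius` is kept in a separate overflow bin.
#'
#' @param exit_r,exit_w Exit radii (mm) and packet weights.
#' @param n_packets Number of incident packets (the normalization).
#' @param bin_width,max_radius Bin geometry in mm.
#' @return A `radial_profile`: data.frame with `bin_center` (mm) and
#'   `value` (exited weight per incident packet per annulus), with the
#'   overflow weight and `n_packets` as attributes.
#' @export
radial_profile <- function(exit_r, exit_w, n_packets, bin_width = 0.1,
                           max_radius = 5) {
  k_max <- round(max_radius / bin_width)
  k <- floor(exit_r / bin_width + 0.5)
  over <- k > k_max
  v <- numeric(k_max + 1L)
  if (any(!over)) {
    agg <- vapply(split(exit_w[!over], k[!over]), sum, numeric(1))
    v[as.integer(names(agg)) + 1L] <- agg
  }
  out <- data.frame(bin_center = bin_width * (0:k_max),
                    value = v / n_packets)
  attr(out, "overflow") <- sum(exit_w[over]) / n_packets
  attr(out, "n_packets") <- n_packets
  class(out) <- c("radial_profile", "data.frame")
  out
}

#' Run one Monte Carlo transport simulation
#'
#' Launches `config$n_packets` weighted packets normally incident at the
#' origin of a layered model, with MCML-convention hop/drop/spin steps,
#' Henyey-Greenstein scattering, unpolarized Fresnel reflection/refraction
#' at every refractive-index mismatch and Russian roulette termination.
#'
#' @param model A [skin_model()].
#' @param config A [transport_config()].
#' @param n_below Refractive index below the last layer (only relevant for
#'   finite-depth models); defaults to the ambient index.
#' @return An object of class `transport_result` with the specular
#'   reflectance `rsp`, total diffuse reflectance `rd`, transmittance `tt`,
#'   absorbed fraction `aa`, net roulette imbalance `roulette_net` (all per
#'   incident packet; they sum to 1 up to rounding), the raw exit radii and
#'   weights, and the binned radial `profile`.
#' @export
run_transport <- function(model, config = transport_config(),
                          n_below = model$n_above) {
  stopifnot(inherits(model, "skin_model"), inherits(config, "transport_config"))
  m <- as.matrix(model$layers[, c("d", "mua", "mus", "g", "n")])
  raw <- .mc_transport(m, model$n_above, n_below, config$n_packets,
                       config$seed, config$roulette_threshold,
                       config$roulette_m)
  prof <- radial_profile(raw$exit_r, raw$exit_w, config$n_packets,
                         config$bin_width, config$max_radius)
  structure(list(rsp = raw$rsp, rd = raw$rd, tt = raw$tt, aa = raw$aa,
                 roulette_net = raw$roulette_net,
                 exit_r = raw$exit_r, exit_w = raw$exit_w,
                 profile = prof, n_packets = config$n_packets,
                 config = config, wavelength = model$wavelength),
            class = "transport_result")
}

#' @export
print.transport_result <- function(x, ...) {
  cat(sprintf(paste0("Monte Carlo transport result (N0 = %d)\n",
                     "  Rsp = %.5f  Rd = %.5f  T = %.5f  A = %.5f",
                     "  roulette net = %.2e\n"),
              x$n_packets, x$rsp, x$rd, x$tt, x$aa, x$roulette_net))
  invisible(x)
}

#' Average several independent transport runs
#'
#' Per-run seeds are `config$seed + 0:(n_runs - 1)`.  The returned profile
#' holds the arithmetic mean of the per-run binned profiles together with
#' the per-bin standard deviation and standard error of the mean.
#'
#' @param model A [skin_model()].
#' @param config A [transport_config()]; its seed is the base seed.
#' @param n_runs Number of independent runs.
#' @return An object of class `mc_run_set`: list with `profile`
#'   (`bin_center`, `value`, `sd`, `stderr`) and `runs`, the list of
#'   per-run [run_transport()] results.
#' @export
average_runs <- function(model, config = transport_config(), n_runs = 10) {
  if (n_runs < 1) stop("n_runs must be >= 1")
  runs <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    cfg <- config
    cfg$seed <- config$seed + (i - 1)
    runs[[i]] <- run_transport(model, cfg)
  }
  vals <- vapply(runs, function(r) r$profile$value,
                 numeric(nrow(runs[[1]]$profile)))
  vals <- matrix(vals, ncol = n_runs)
  prof <- data.frame(bin_center = runs[[1]]$profile$bin_center,
                     value = rowMeans(vals),
                     sd = apply(vals, 1, stats::sd),
                     stderr = apply(vals, 1, stats::sd) / sqrt(n_runs))
  attr(prof, "n_packets") <- config$n_packets
  class(prof) <- c("radial_profile", "data.frame")
  structure(list(profile = prof, runs = runs, n_runs = n_runs),
            class = "mc_run_set")
}

#' Detected weight in an exit annulus
#'
#' Sums the exited packet weight with exit radius in `[r_min, r_max]`,
#' normalized per incident packet, from the raw exit radii (not from the
#' binned histogram).  This is the simulated analogue of the detected
#' intensity `Ne` at a source-detector separation spanned by the annulus.
#'
#' @param x A [run_transport()] result or an [average_runs()] run set.
#' @param r_min,r_max Annulus bounds in mm (defaults: the 0.5-1.2 mm
#'   detection window).
#' @param ... Unused.
#' @return For a single run, the detected weight per incident packet.  For
#'   a run set, a list with the per-run values, their `mean`, `sd` and
#'   `stderr`.
#' @export
annulus_intensity <- function(x, r_min = 0.5, r_max = 1.2, ...) {
  UseMethod("annulus_intensity")
}

#' @export
annulus_intensity.transport_result <- function(x, r_min = 0.5, r_max = 1.2,
                                               ...) {
  if (r_min < 0 || r_min >= r_max) stop("need 0 <= r_min < r_max")
  sel <- x$exit_r >= r_min & x$exit_r <= r_max
  sum(x$exit_w[sel]) / x$n_packets
}

#' @export
annulus_intensity.mc_run_set <- function(x, r_min = 0.5, r_max = 1.2, ...) {
  per <- vapply(x$runs, annulus_intensity, numeric(1),
                r_min = r_min, r_max = r_max)
  list(per_run = per, mean = mean(per), sd = stats::sd(per),
       stderr = stats::sd(per) / sqrt(length(per)))
}
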