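#' Configuration for the synthetic-data generators
#'
#' Bundles the ground-truth parameters, stimulation protocol, observation
#' noise levels and sampling for the generators [gen_region_traces()],
#' [gen_density_profile_1d()] and [gen_nuclei_points()]. Defaults emulate
#' the structure of published MDCK monolayer electrotaxis experiments:
#' 3 V/cm step stimulation (1 h off, 3 h on, 3 h off), 5-minute sampling of
#' region velocities with 2 um/h Gaussian noise, and density observation
#' noise of 10 cells/mm on the y-averaged profile.
#'
#' @param region_truth A [region_params()] used as generating truth.
#' @param continuum_truth A [continuum_params()] used as generating truth.
#' @param protocol A [stimulus_protocol()].
#' @param sigma_v Velocity observation noise (um/h).
#' @param sigma_rho Density observation noise (cells/mm).
#' @param dt_obs Observation sampling interval (h); default 5 minutes.
#' @param seed Integer seed recorded in every generated object.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(region_truth = default_region_params(),
                             continuum_truth = default_continuum_params(),
                             protocol = step_protocol(),
                             sigma_v = 2, sigma_rho = 10, dt_obs = 1 / 12,
                             seed = 1) {
  check_number(sigma_v, "sigma_v", nonnegative = TRUE)
  check_number(sigma_rho, "sigma_rho", nonnegative = TRUE)
  check_number(dt_obs, "dt_obs", positive = TRUE)
  stopifnot(inherits(region_truth, "region_params"))
  stopifnot(inherits(continuum_truth, "continuum_params"))
  stopifnot(inherits(protocol, "stimulus_protocol"))
  structure(
    list(
      region_truth = region_truth, continuum_truth = continuum_truth,
      protocol = protocol, sigma_v = sigma_v, sigma_rho = sigma_rho,
      dt_obs = dt_obs, seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

#' Synthetic four-region velocity traces
#'
#' Simulates the region model at the configured truth from its
#' pre-stimulation steady state and adds i.i.d. Gaussian observation noise
#' `sigma_v` to every region. With `sigma_v = 0` the output is exactly the
#' deterministic model trace. The generating truth, noise level and seed
#' are attached as attributes for recovery tests.
#'
#' @param config A [synthetic_config()].
#' @return A `region_traces` tibble (see [simulate_regions()]).
#' @export
gen_region_traces <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  t_end <- max(config$protocol$breakpoints)
  times <- seq(0, t_end, by = config$dt_obs)
  tr <- simulate_regions(config$region_truth, config$protocol, times = times)
  if (config$sigma_v > 0) {
    set.seed(config$seed)
    for (col in c("v_bulk", "v_leading", "v_trailing", "v_top")) {
      tr[[col]] <- tr[[col]] + rnorm(nrow(tr), sd = config$sigma_v)
    }
  }
  attr(tr, "truth") <- config$region_truth
  attr(tr, "sigma_v") <- config$sigma_v
  attr(tr, "seed") <- config$seed
  tr
}

#' Synthetic 1D density profile and kymograph
#'
#' Builds an initial y-averaged density profile on the standard
#' `[-3.5, 3.5]` mm field of view: a plateau at the carrying capacity with
#' smooth sigmoidal ramps at the tissue edges, optionally perturbed by
#' small-scale multiplicative noise (epithelial monolayers show large local
#' density fluctuations). If `times` are requested, the profile is evolved
#' with [solve_rad_1d()] at the configured continuum truth and i.i.d.
#' Gaussian observation noise `sigma_rho` is added to each observed
#' profile (never to the returned initial condition).
#'
#' @param config A [synthetic_config()].
#' @param n_cells Number of grid cells (default 141).
#' @param half_width Half-width of the tissue (mm): edge midpoints sit at
#'   `x = -half_width` and `x = +half_width`. Default 2.5.
#' @param ramp Edge ramp width (mm), default 0.2.
#' @param noise_rel Relative amplitude of multiplicative density noise on
#'   the initial profile (default 0).
#' @param times Optional observation times (h) starting at 0.
#' @return With `times = NULL`, a [density_field_1d()]. Otherwise a list
#'   with `initial` (clean `density_field_1d`) and `kymograph` (long tibble
#'   `time_h`, `x`, `rho` with observation noise).
#' @export
gen_density_profile_1d <- function(config, n_cells = 141, half_width = 2.5,
                                   ramp = 0.2, noise_rel = 0, times = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  p <- config$continuum_truth
  h <- 7 / n_cells
  x <- seq(-3.5 + h / 2, 3.5 - h / 2, length.out = n_cells)
  u <- if (ramp <= 0) {
    as.numeric(abs(x) <= half_width)
  } else {
    stats::plogis((x + half_width) / ramp) * stats::plogis((half_width - x) / ramp)
  }
  set.seed(config$seed)
  if (noise_rel > 0) {
    u <- pmax(u * (1 + noise_rel * rnorm(n_cells)), 0)
  }
  init <- density_field_1d(x, u * p$K, time = 0)
  if (is.null(times)) {
    attr(init, "seed") <- config$seed
    return(init)
  }
  check_times(times)
  kym <- solve_rad_1d(p, init, config$protocol, output_times = times)
  if (config$sigma_rho > 0) {
    obs <- kym$time_h > min(times)
    kym$rho[obs] <- kym$rho[obs] +
      rnorm(sum(obs), sd = config$sigma_rho)
  }
  attr(kym, "truth") <- p
  attr(kym, "sigma_rho") <- config$sigma_rho
  attr(kym, "seed") <- config$seed
  list(initial = init, kymograph = kym)
}

#' Synthetic nuclei point cloud
#'
#' Draws a spatial Poisson point process whose intensity is proportional to
#' a target density surface: per-cell counts are Poisson with mean
#' `n_expected * rho / sum(rho)` and points are placed uniformly within
#' their cell. Reproducible given the config seed.
#'
#' @param config A [synthetic_config()].
#' @param surface A `density_field_2d` giving the (relative) intensity
#'   surface; zero-intensity cells produce no points.
#' @param n_expected Expected total number of nuclei.
#' @return A tibble with columns `x`, `y` (mm); `attr(, "seed")` records
#'   the seed. Zero total intensity yields an empty cloud with a warning.
#' @export
gen_nuclei_points <- function(config, surface, n_expected = 1e4) {
  stopifnot(inherits(config, "synthetic_config"))
  stopifnot(inherits(surface, "density_field_2d"))
  check_number(n_expected, "n_expected", positive = TRUE)
  tot <- sum(surface$rho)
  if (tot <= 0) {
    rlang::warn("Intensity surface is identically zero; returning no points.")
    out <- tibble::tibble(x = numeric(0), y = numeric(0))
    attr(out, "seed") <- config$seed
    return(out)
  }
  set.seed(config$seed)
  lam <- n_expected * surface$rho / tot
  counts <- rpois(length(lam), lam)
  h <- attr(surface, "spacing")
  idx <- rep.int(seq_along(counts), counts)
  out <- tibble::tibble(
    x = surface$x[idx] + runif(length(idx), -h / 2, h / 2),
    y = surface$y[idx] + runif(length(idx), -h / 2, h / 2)
  )
  attr(out, "seed") <- config$seed
  out
}
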