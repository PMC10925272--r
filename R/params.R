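#' Timescales of the adaptation-excitation signal model
#'
#' The intracellular response to a direct-current field is modelled by two
#' coupled species: an effective signal `s_eff` that excites motility on a
#' fast timescale `tau_e`, and an inhibitor `I` that rises on a slow
#' timescale `tau_a` and cancels the signal (perfect adaptation):
#' \deqn{\tau_e \dot s_{eff} = s - s_{eff} - I, \qquad \tau_a \dot I = s - I.}
#' Under any sustained stimulus `s`, `s_eff` returns to zero while `I`
#' approaches `s`. The regime of interest has `tau_e < tau_a`.
#'
#' @param tau_e Excitation timescale in hours. Default 0.26 h, the value
#'   calibrated for MDCK monolayers.
#' @param tau_a Adaptation timescale in hours. Default 2.04 h.
#' @return An object of class `signal_params`.
#' @examples
#' signal_params()
#' @export
signal_params <- function(tau_e = 0.26, tau_a = 2.04) {
  check_number(tau_e, "tau_e", positive = TRUE)
  check_number(tau_a, "tau_a", positive = TRUE)
  if (tau_e >= tau_a) {
    rlang::abort(
      "`tau_e` must be smaller than `tau_a`: excitation is fast, adaptation slow.",
      class = "voltaxis_invalid_parameter"
    )
  }
  structure(list(tau_e = tau_e, tau_a = tau_a), class = "signal_params")
}

#' @export
print.signal_params <- function(x, ...) {
  cat(sprintf(
    "<signal_params> tau_e = %g h (excitation), tau_a = %g h (adaptation)\n",
    x$tau_e, x$tau_a
  ))
  invisible(x)
}

#' Parameters of the four-region velocity model
#'
#' Force balance per unit mass for the x-velocity of four monolayer regions
#' (bulk, leading edge, trailing edge, top edge): viscous friction
#' `-gamma * v`, an electrotactic active force proportional to the positive
#' part of the effective signal, and a constant outward edge force at the
#' leading/trailing edges:
#' \deqn{\dot v_{bulk} = -\gamma v + \alpha_\parallel s_{eff}^+}
#' \deqn{\dot v_{lead} = -\gamma v + \delta\alpha_\parallel s_{eff}^+ + \alpha_{edge}}
#' \deqn{\dot v_{trail} = -\gamma v + \delta\alpha_\parallel s_{eff}^+ - \alpha_{edge}}
#' \deqn{\dot v_{top} = -\gamma v + \delta\alpha_\perp s_{eff}^+}
#' Edge regions are less sensitive to the field by the factor `delta` in
#' `[0, 1]`. Velocities are in um/h throughout this model.
#'
#' @param gamma Friction rate, 1/h. Must be positive.
#' @param alpha_par Bulk field-response magnitude (um/h^2), polarity parallel
#'   to the field.
#' @param alpha_perp Field-response magnitude for regions whose endogenous
#'   polarity is perpendicular to the field (top/bottom edges), um/h^2.
#' @param delta Edge sensitivity relative to the bulk, dimensionless in
#'   `[0, 1]`.
#' @param alpha_edge Outward edge-force magnitude, um/h^2.
#' @param signal A [signal_params()] object for the driving signal.
#' @return An object of class `region_params`.
#' @seealso [default_region_params()] for the calibrated MDCK values.
#' @export
region_params <- function(gamma, alpha_par, alpha_perp, delta, alpha_edge,
                          signal = signal_params()) {
  check_number(gamma, "gamma", positive = TRUE)
  check_number(alpha_par, "alpha_par", nonnegative = TRUE)
  check_number(alpha_perp, "alpha_perp", nonnegative = TRUE)
  check_number(alpha_edge, "alpha_edge", nonnegative = TRUE)
  check_number(delta, "delta", nonnegative = TRUE)
  if (delta > 1) {
    rlang::abort("`delta` must lie in [0, 1].",
      class = "voltaxis_invalid_parameter"
    )
  }
  stopifnot(inherits(signal, "signal_params"))
  structure(
    list(
      gamma = gamma, alpha_par = alpha_par, alpha_perp = alpha_perp,
      delta = delta, alpha_edge = alpha_edge, signal = signal
    ),
    class = "region_params"
  )
}

#' Calibrated region-model parameters for MDCK monolayers
#'
#' Posterior-mean parameter set obtained by calibrating the four-region
#' velocity model to published MDCK monolayer electrotaxis recordings at
#' 3 V/cm: `gamma = 1.765` 1/h (fitted directly from post-stimulation
#' exponential decay of the bulk velocity), `alpha_par = 171.95` um/h^2,
#' `alpha_perp = 217.08` um/h^2, `delta = 0.31`, `alpha_edge = 24.93` um/h^2,
#' with signal timescales `tau_e = 0.26` h and `tau_a = 2.04` h.
#'
#' @return A `region_params` object.
#' @examples
#' default_region_params()
#' @export
default_region_params <- function() {
  region_params(
    gamma = 1.765, alpha_par = 171.95, alpha_perp = 217.08,
    delta = 0.31, alpha_edge = 24.93, signal = signal_params()
  )
}

#' @export
print.region_params <- function(x, ...) {
  cat("<region_params>\n")
  cat(sprintf(
    "  gamma = %g 1/h, alpha_par = %g, alpha_perp = %g um/h^2\n",
    x$gamma, x$alpha_par, x$alpha_perp
  ))
  cat(sprintf("  delta = %g, alpha_edge = %g um/h^2\n", x$delta, x$alpha_edge))
  cat(sprintf(
    "  signal: tau_e = %g h, tau_a = %g h\n",
    x$signal$tau_e, x$signal$tau_a
  ))
  invisible(x)
}

#' Parameters of the continuum density model
#'
#' Reaction-advection-diffusion model for the cell density `rho(x, t)` of an
#' electrotaxing monolayer, solved in the normalised density `u = rho / K`:
#' \deqn{\partial_t u = \nabla\cdot(D u \nabla u) -
#'   \nabla\cdot\left(u\,\alpha s_{eff} (\delta + (1-\delta)u)\,E\right) +
#'   r u (1 - u),}
#' where `E` is the (dimensionless) electric field vector. Diffusion is
#' density-dependent and degenerate at `u = 0` (sharp spreading fronts),
#' electrotactic advection is strongest in the bulk (`u` near 1) and reduced
#' by the factor `delta` at the low-density edge, and proliferation is
#' logistic. Lengths are in mm, times in hours.
#'
#' @param D Diffusion coefficient, mm^2/h (acting on the normalised density).
#' @param alpha Bulk electrotactic response, mm/h per unit dimensionless
#'   field.
#' @param delta Edge-to-bulk sensitivity ratio in `[0, 1]`.
#' @param r Logistic proliferation rate, 1/h.
#' @param K Carrying capacity, i.e. the density scale, in cells/mm of
#'   y-averaged linear density.
#' @param signal [signal_params()] driving the shared effective signal.
#' @return An object of class `continuum_params`.
#' @seealso [default_continuum_params()] for the calibrated MDCK values.
#' @export
continuum_params <- function(D, alpha, delta, r, K,
                             signal = signal_params()) {
  check_number(D, "D", positive = TRUE)
  check_number(alpha, "alpha", nonnegative = TRUE)
  check_number(r, "r", nonnegative = TRUE)
  check_number(K, "K", positive = TRUE)
  check_number(delta, "delta", nonnegative = TRUE)
  if (delta > 1) {
    rlang::abort("`delta` must lie in [0, 1].",
      class = "voltaxis_invalid_parameter"
    )
  }
  stopifnot(inherits(signal, "signal_params"))
  structure(
    list(D = D, alpha = alpha, delta = delta, r = r, K = K, signal = signal),
    class = "continuum_params"
  )
}

#' Calibrated continuum-model parameters for MDCK monolayers
#'
#' Posterior-mean parameter set obtained by calibrating the one-dimensional
#' continuum model to y-averaged density profiles of electrotaxing MDCK
#' monolayers: `alpha = 0.837` mm/h, `D = 13.30` mm^2/h, `delta = 0.625`,
#' `r = 0.180` 1/h, `K = 260.29` cells/mm, with the signal timescales fixed
#' at the region-model values.
#'
#' @return A `continuum_params` object.
#' @export
default_continuum_params <- function() {
  continuum_params(
    D = 13.30, alpha = 0.837, delta = 0.625, r = 0.180, K = 260.29,
    signal = signal_params()
  )
}

#' @export
print.continuum_params <- function(x, ...) {
  cat("<continuum_params>\n")
  cat(sprintf(
    "  D = %g mm^2/h, alpha = %g mm/h, delta = %g\n", x$D, x$alpha, x$delta
  ))
  cat(sprintf("  r = %g 1/h, K = %g cells/mm\n", x$r, x$K))
  cat(sprintf(
    "  signal: tau_e = %g h, tau_a = %g h\n",
    x$signal$tau_e, x$signal$tau_a
  ))
  invisible(x)
}

# --- internal validation helpers ---------------------------------------------

check_number <- function(x, name, positive = FALSE, nonnegative = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    rlang::abort(sprintf("`%s` must be a single finite number.", name),
      class = "voltaxis_invalid_parameter"
    )
  }
  if (positive && x <= 0) {
    rlang::abort(sprintf("`%s` must be > 0.", name),
      class = "voltaxis_invalid_parameter"
    )
  }
  if (nonnegative && x < 0) {
    rlang::abort(sprintf("`%s` must be >= 0.", name),
      class = "voltaxis_invalid_parameter"
    )
  }
  invisible(x)
}

check_times <- function(times) {
  if (!is.numeric(times) || length(times) < 2L || anyNA(times) ||
    any(diff(times) <= 0)) {
    rlang::abort("`times` must be a strictly increasing numeric grid.",
      class = "voltaxis_invalid_input"
    )
  }
  invisible(times)
}
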