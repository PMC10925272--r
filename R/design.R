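#' Design a 1D field profile for a uniform target velocity
#'
#' Inverts the continuum velocity relation
#' `v = -D u' + alpha s_eff (delta + (1-delta) u) E` (with `u = rho/K`) for
#' the potential gradient `E(x)` that makes the tissue move at `v_star`
#' everywhere:
#' \deqn{E(x) = \frac{v^* + D\,\partial_x u}
#'                   {\alpha s_{eff} (\delta + (1-\delta)u)}.}
#' The `+D u'` term strengthens the field against outward spreading at the
#' leading edge and weakens it at the trailing edge. Because the signal
#' adapts (`s_eff -> 0` both at start-up and at long times), the raw
#' expression diverges there; the returned gradient is therefore clamped to
#' the physiologically tolerable magnitude `s_max`
#' (`sign(E) * min(|E|, s_max)`). With `s_eff <= 0` the design is undefined
#' and a fully capped field in the direction of `v_star` is returned with a
#' warning; start stimulation with a constant field until the signal has
#' risen (see Details).
#'
#' @details The recommended start-up policy is to stimulate with the
#'   constant field `s_max` until `s_eff` exceeds a threshold (0.2 by
#'   default in [solve_rad_1d()] workflows) and only then switch to the
#'   designed gradient; the design can be re-evaluated against the current
#'   density profile at a configurable cadence (quasi-static design).
#'
#' @param params A [continuum_params()].
#' @param rho A [density_field_1d()] (cells/mm): the frozen current profile.
#' @param s_eff Scalar effective signal at design time.
#' @param v_star Target velocity (mm/h).
#' @param s_max Maximum tolerable field magnitude (dimensionless field
#'   units; 1 = 3 V/cm).
#' @return A tibble of class `design_1d` with columns `x`, `gradient`
#'   (clamped), `gradient_raw` (uncapped) and `capped` (logical).
#' @export
design_gradient_1d <- function(params, rho, s_eff, v_star, s_max = 1) {
  stopifnot(inherits(params, "continuum_params"))
  stopifnot(inherits(rho, "density_field_1d"))
  check_number(s_max, "s_max", positive = TRUE)
  check_number(v_star, "v_star")
  h <- attr(rho, "spacing")
  u <- rho$rho / params$K
  if (s_eff <= 0) {
    rlang::warn(paste(
      "`s_eff` <= 0: the designed gradient is undefined;",
      "returning a fully capped field along sign(v_star).",
      "Stimulate with a constant field first to raise the signal."
    ))
    g <- rep(sign(v_star) * s_max, length(u))
    out <- tibble::tibble(
      x = rho$x, gradient = g, gradient_raw = sign(v_star) * Inf,
      capped = TRUE
    )
  } else {
    raw <- (v_star + params$D * grad_central(u, h)) /
      (params$alpha * s_eff * (params$delta + (1 - params$delta) * u))
    g <- sign(raw) * pmin(abs(raw), s_max)
    out <- tibble::tibble(
      x = rho$x, gradient = g, gradient_raw = raw,
      capped = abs(raw) > s_max
    )
  }
  class(out) <- c("design_1d", class(out))
  attr(out, "spacing") <- h
  attr(out, "v_star") <- v_star
  attr(out, "s_max") <- s_max
  out
}

#' Closed-form 1D design potential
#'
#' The potential whose gradient is the (uncapped) 1D design field of
#' [design_gradient_1d()], anchored at `phi(x0) = 0`:
#' \deqn{\phi(x) = \frac{1}{\alpha s_{eff}}\left[
#'   v^* \int_{x_0}^{x} \frac{d\xi}{\delta + (1-\delta)u(\xi)} +
#'   \frac{D}{1-\delta}\,
#'   \ln\frac{\delta + (1-\delta)u(x)}{\delta + (1-\delta)u(x_0)}\right].}
#' The density-gradient part integrates in closed form (the log term); only
#' the target-velocity part requires quadrature (trapezoidal on the grid).
#' For `delta = 1` the log expression degenerates and the potential is
#' obtained by direct trapezoidal integration of the gradient; `delta = 0`
#' requires `rho > 0` wherever the log is evaluated.
#'
#' @inheritParams design_gradient_1d
#' @param x0 Anchor position (mm) at which the potential is zero.
#' @return A tibble of class `design_potential_1d` with columns `x`, `phi`.
#' @export
design_potential_1d <- function(params, rho, s_eff, v_star, x0 = 0) {
  stopifnot(inherits(params, "continuum_params"))
  stopifnot(inherits(rho, "density_field_1d"))
  if (s_eff <= 0) {
    rlang::abort("`s_eff` must be > 0 for the closed-form potential.",
      class = "voltaxis_invalid_input"
    )
  }
  if (x0 < min(rho$x) || x0 > max(rho$x)) {
    rlang::abort("`x0` must lie inside the grid.",
      class = "voltaxis_invalid_input"
    )
  }
  u <- rho$rho / params$K
  de <- params$delta
  denom <- de + (1 - de) * u
  if (any(denom <= 0)) {
    rlang::abort(
      "delta + (1 - delta) * rho/K must be positive everywhere (rho = 0 with delta = 0 is singular).",
      class = "voltaxis_invalid_input"
    )
  }
  x <- rho$x
  if (de == 1) {
    g <- design_gradient_1d(params, rho, s_eff, v_star,
      s_max = .Machine$double.xmax
    )$gradient_raw
    phi <- cumtrapz(x, g)
  } else {
    term_v <- v_star * cumtrapz(x, 1 / denom)
    term_d <- params$D / (1 - de) * log(denom / denom[1])
    phi <- (term_v + term_d) / (params$alpha * s_eff)
  }
  phi <- phi - approx(x, phi, xout = x0)$y
  out <- tibble::tibble(x = x, phi = phi)
  class(out) <- c("design_potential_1d", class(out))
  attr(out, "spacing") <- attr(rho, "spacing")
  out
}

cumtrapz <- function(x, y) {
  c(0, cumsum(diff(x) * (y[-1] + y[-length(y)]) / 2))
}

#' Optimal 2D potential gradient for a target velocity
#'
#' Vector version of [design_gradient_1d()]: the field
#' \deqn{s^*(x, y) = \frac{v^* + D\nabla u}
#'                        {\alpha s_{eff} (\delta + (1-\delta)u)}}
#' drives every point of the tissue at `v_star`. The `D grad u` correction
#' opposes the outward spreading of the monolayer, so for instance at the
#' top boundary of a tissue the y-component of `s*` points against the
#' outward normal. Requires `s_eff > 0`; use [heuristic_field()] when the
#' signal level is unknown or waning.
#'
#' @param params A [continuum_params()].
#' @param rho A [density_field_2d()] (cells/mm).
#' @param s_eff Scalar effective signal, > 0.
#' @param v_star Length-2 target velocity (mm/h).
#' @return A tibble of class `field_map` with columns `x`, `y`, `ex`, `ey`,
#'   `magnitude`, `mask`.
#' @export
design_gradient_2d <- function(params, rho, s_eff, v_star) {
  stopifnot(inherits(params, "continuum_params"))
  stopifnot(inherits(rho, "density_field_2d"))
  if (s_eff <= 0) {
    rlang::abort(
      "`s_eff` must be > 0; use heuristic_field() for a fixed-magnitude design.",
      class = "voltaxis_invalid_input"
    )
  }
  if (length(v_star) != 2L) {
    rlang::abort("`v_star` must be a length-2 velocity.",
      class = "voltaxis_invalid_input"
    )
  }
  fm <- field_matrix(rho)
  u <- fm$rho / params$K
  gx <- masked_grad(u, fm$mask, fm$h, dim = 1)
  gy <- masked_grad(u, fm$mask, fm$h, dim = 2)
  denom <- params$alpha * s_eff * (params$delta + (1 - params$delta) * u)
  ex <- (v_star[1] + params$D * gx) / denom
  ey <- (v_star[2] + params$D * gy) / denom
  new_field_map(rho, ex, ey, fm$mask)
}

#' Fixed-magnitude heuristic field
#'
#' A practical 2D design that sidesteps the signal-level dependence of
#' [design_gradient_2d()]: the field magnitude is fixed at `s_max`
#' everywhere in the mask and only the direction follows the optimal
#' gradient `s*` (computed at a nominal `s_eff`; the direction of `s*` does
#' not depend on its value). Cells where `s*` vanishes default to the
#' direction of `v_star` (with a notice).
#'
#' @inheritParams design_gradient_2d
#' @param s_max Fixed field magnitude (dimensionless; 1 = 3 V/cm).
#' @param s_eff Nominal positive signal level used to evaluate `s*`
#'   (direction only; default 1).
#' @return A `field_map` tibble with `|field| = s_max` inside the mask and
#'   zero outside.
#' @export
heuristic_field <- function(params, rho, v_star, s_max = 1, s_eff = 1) {
  check_number(s_max, "s_max", positive = TRUE)
  opt <- design_gradient_2d(params, rho, s_eff, v_star)
  mag <- sqrt(opt$ex^2 + opt$ey^2)
  zero <- mag == 0
  if (any(zero & opt$mask)) {
    rlang::inform(sprintf(
      "%d cells have a vanishing optimal gradient; using the target direction there.",
      sum(zero & opt$mask)
    ))
  }
  vhat <- v_star / sqrt(sum(v_star^2))
  ex <- ifelse(zero, vhat[1], opt$ex / ifelse(zero, 1, mag)) * s_max
  ey <- ifelse(zero, vhat[2], opt$ey / ifelse(zero, 1, mag)) * s_max
  ex[!opt$mask] <- 0
  ey[!opt$mask] <- 0
  dims <- attr(rho, "dims")
  new_field_map(
    rho, matrix(ex, dims["nx"], dims["ny"]),
    matrix(ey, dims["nx"], dims["ny"]),
    matrix(opt$mask, dims["nx"], dims["ny"])
  )
}

new_field_map <- function(rho, ex, ey, mask) {
  out <- tibble::tibble(
    x = rho$x, y = rho$y,
    ex = as.numeric(ex), ey = as.numeric(ey),
    magnitude = sqrt(as.numeric(ex)^2 + as.numeric(ey)^2),
    mask = as.logical(mask)
  )
  class(out) <- c("field_map", class(out))
  attr(out, "spacing") <- attr(rho, "spacing")
  attr(out, "dims") <- attr(rho, "dims")
  out
}

#' Extract 1D transect profiles from a 2D field map
#'
#' Values of the field components along a horizontal (`y = at`) or vertical
#' (`x = at`) line, for plotting edge-reversal bands of designed fields.
#'
#' @param fmap A `field_map`.
#' @param direction `"horizontal"` or `"vertical"`.
#' @param at Coordinate of the transect (mm); the nearest grid line is
#'   used.
#' @return A tibble with the transect coordinate, `ex`, `ey`, `magnitude`.
#' @export
field_transect <- function(fmap, direction = c("horizontal", "vertical"),
                           at = 0) {
  direction <- match.arg(direction)
  stopifnot(inherits(fmap, "field_map"))
  if (direction == "horizontal") {
    yv <- unique(fmap$y)
    y0 <- yv[which.min(abs(yv - at))]
    dplyr::select(
      dplyr::filter(fmap, .data$y == y0),
      "x", "ex", "ey", "magnitude"
    )
  } else {
    xv <- unique(fmap$x)
    x0 <- xv[which.min(abs(xv - at))]
    dplyr::select(
      dplyr::filter(fmap, .data$x == x0),
      "y", "ex", "ey", "magnitude"
    )
  }
}
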