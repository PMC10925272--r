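#' Cell-density fields on uniform grids
#'
#' A `density_field_1d` is a tibble with columns `x` (cell centres, mm) and
#' `rho` (cells/mm); a `density_field_2d` additionally has `y` and an
#' optional logical `mask` column marking the tissue / region of interest.
#' Grid spacing and the field time are carried as attributes (`spacing`,
#' `time_h`).
#'
#' @param x,y Cell-centre coordinates (mm), uniformly spaced.
#' @param rho Densities: a vector for 1D, an `nx` x `ny` matrix (or long
#'   vector in x-fastest order) for 2D. Must be finite and non-negative.
#' @param mask Optional logical matrix/vector matching `rho`.
#' @param time Field time in hours.
#' @return A tibble of class `density_field_1d` or `density_field_2d`.
#' @export
density_field_1d <- function(x, rho, time = 0) {
  check_uniform_grid(x, "x")
  rho <- as.numeric(rho)
  if (length(rho) != length(x) || anyNA(rho) || any(!is.finite(rho))) {
    rlang::abort("`rho` must be finite and match `x`.",
      class = "voltaxis_invalid_input"
    )
  }
  if (any(rho < 0)) {
    rlang::abort("`rho` must be non-negative.",
      class = "voltaxis_invalid_input"
    )
  }
  out <- tibble::tibble(x = as.numeric(x), rho = rho)
  class(out) <- c("density_field_1d", class(out))
  attr(out, "spacing") <- x[2] - x[1]
  attr(out, "time_h") <- time
  out
}

#' @rdname density_field_1d
#' @export
density_field_2d <- function(x, y, rho, mask = NULL, time = 0) {
  check_uniform_grid(x, "x")
  check_uniform_grid(y, "y")
  nx <- length(x)
  ny <- length(y)
  rho <- matrix(as.numeric(rho), nx, ny)
  if (anyNA(rho) || any(!is.finite(rho)) || any(rho < 0)) {
    rlang::abort("`rho` must be finite and non-negative.",
      class = "voltaxis_invalid_input"
    )
  }
  if (is.null(mask)) mask <- matrix(TRUE, nx, ny)
  mask <- matrix(as.logical(mask), nx, ny)
  out <- tibble::tibble(
    x = rep(as.numeric(x), times = ny),
    y = rep(as.numeric(y), each = nx),
    rho = as.numeric(rho),
    mask = as.logical(mask)
  )
  class(out) <- c("density_field_2d", class(out))
  attr(out, "spacing") <- x[2] - x[1]
  attr(out, "time_h") <- time
  attr(out, "dims") <- c(nx = nx, ny = ny)
  out
}

check_uniform_grid <- function(x, name) {
  if (!is.numeric(x) || length(x) < 2L || any(diff(x) <= 0)) {
    rlang::abort(sprintf("`%s` must be an increasing grid.", name),
      class = "voltaxis_invalid_input"
    )
  }
  d <- diff(x)
  if (max(d) - min(d) > 1e-9 * max(d)) {
    rlang::abort(sprintf("`%s` must be uniformly spaced.", name),
      class = "voltaxis_invalid_input"
    )
  }
  invisible(x)
}

# matrix view of a 2D field
field_matrix <- function(field) {
  dims <- attr(field, "dims")
  list(
    x = unique(field$x), y = unique(field$y),
    rho = matrix(field$rho, dims["nx"], dims["ny"]),
    mask = matrix(field$mask %||% TRUE, dims["nx"], dims["ny"]),
    h = attr(field, "spacing")
  )
}

# kymograph tibble (time_h, x, rho) -> x-by-time matrix
kymograph_matrix <- function(kym) {
  times <- sort(unique(kym$time_h))
  xg <- sort(unique(kym$x))
  wide <- tidyr::pivot_wider(
    dplyr::arrange(kym, .data$time_h, .data$x),
    id_cols = "x", names_from = "time_h", values_from = "rho"
  )
  m <- as.matrix(wide[, -1, drop = FALSE])
  dimnames(m) <- list(NULL, NULL)
  m
}

# internal: fine-grid signal + field modulation series for the C++ core.
# The advective drive is alpha * s_eff_plus(t) * E(x, t) with
# E = (mx(t) Ex(x), my(t) Ey(x)); for the uniform case Ex = Ey = 1 and
# (mx, my) = magnitude * direction from the protocol.
solver_forcing <- function(protocol, signal, t0, t_end, dt_fine = 2e-3) {
  grid <- refine_grid(
    sort(unique(c(t0, protocol$breakpoints[
      protocol$breakpoints > t0 & protocol$breakpoints < t_end
    ], t_end))),
    dt_fine
  )
  sig <- integrate_signal(protocol, signal, grid)
  mag <- protocol_magnitude(protocol, grid)
  dirs <- protocol_direction(protocol, grid)
  list(
    t = grid, s_plus = sig$s_eff_plus,
    mx = mag * dirs[, 1], my = mag * dirs[, 2]
  )
}

#' Solve the 1D continuum model
#'
#' Advances the density-dependent reaction-advection-diffusion model (see
#' [continuum_params()]) on the grid of `initial` under a stimulation
#' protocol, with no-flux boundaries. The solver is a conservative
#' finite-volume scheme: explicit first-order upwind advection with CFL
#' safety factor `cfl`, implicit (backward-Euler) nonlinear diffusion with
#' lagged face coefficient, and an exact per-step logistic proliferation
#' update. Densities are handled internally in normalised units `u = rho/K`
#' and rescaled on output.
#'
#' @param params A [continuum_params()].
#' @param initial A [density_field_1d()] in cells/mm.
#' @param protocol A [stimulus_protocol()]; drives the shared effective
#'   signal and, if `field` is `NULL`, the spatially uniform field
#'   `magnitude x direction`.
#' @param output_times Increasing times (h) at which to report profiles;
#'   the first must be the initial time.
#' @param field Optional static per-cell field profile (numeric, length
#'   `nrow(initial)`): the designed potential gradient. When given it
#'   replaces the uniform protocol field in the advective flux (the signal
#'   is still driven by the protocol magnitude).
#' @param dt_max Upper bound on the solver step (h).
#' @param cfl Advective CFL safety factor in (0, 1).
#' @return A long tibble of class `kymograph_1d` with columns `time_h`, `x`,
#'   `rho`.
#' @export
solve_rad_1d <- function(params, initial, protocol, output_times,
                         field = NULL, dt_max = 0.01, cfl = 0.4) {
  stopifnot(inherits(params, "continuum_params"))
  stopifnot(inherits(initial, "density_field_1d"))
  check_times(output_times)
  nx <- nrow(initial)
  h <- attr(initial, "spacing")
  u0 <- matrix(initial$rho / params$K, nx, 1)

  frc <- solver_forcing(
    protocol, params$signal, output_times[1],
    output_times[length(output_times)]
  )
  if (is.null(field)) {
    Ex <- matrix(1, nx, 1)
    mx <- frc$mx
  } else {
    if (length(field) != nx) {
      rlang::abort("`field` must have one value per grid cell.",
        class = "voltaxis_invalid_input"
      )
    }
    Ex <- matrix(as.numeric(field), nx, 1)
    mx <- rep(1, length(frc$t))
  }
  sol <- solve_rad_cpp(
    u0, matrix(1L, nx, 1), h, params$D, params$alpha, params$delta, params$r,
    frc$t, frc$s_plus, frc$t, mx, rep(0, length(frc$t)),
    Ex, matrix(0, nx, 1), output_times, dt_max, cfl
  )
  out <- purrr::map2_dfr(sol, output_times, function(m, tt) {
    tibble::tibble(time_h = tt, x = initial$x, rho = as.numeric(m) * params$K)
  })
  class(out) <- c("kymograph_1d", class(out))
  attr(out, "spacing") <- h
  attr(out, "params") <- params
  out
}

#' Solve the 2D continuum model
#'
#' Two-dimensional version of [solve_rad_1d()] on the rectangular grid of
#' `initial`, by dimensional operator splitting (x sweep, y sweep,
#' reaction). The `mask` column of `initial` defines the computational
#' domain containing the monolayer: faces crossing the mask boundary carry
#' zero flux (no-flux conditions on the domain boundary) and cells outside
#' the mask are inert. A y-invariant problem on a full-rectangle mask under
#' an x-directed field reproduces the 1D solver row by row.
#'
#' @inheritParams solve_rad_1d
#' @param initial A [density_field_2d()] in cells/mm (y-averaged density
#'   scale); its `mask` is the computational domain.
#' @param field Optional list with matrices `ex`, `ey` (per-cell static
#'   field components, e.g. from [heuristic_field()]); replaces the uniform
#'   protocol field.
#' @return A list of `density_field_2d` objects, one per output time.
#' @export
solve_rad_2d <- function(params, initial, protocol, output_times,
                         field = NULL, dt_max = 0.01, cfl = 0.4) {
  stopifnot(inherits(params, "continuum_params"))
  stopifnot(inherits(initial, "density_field_2d"))
  check_times(output_times)
  fm <- field_matrix(initial)
  nx <- length(fm$x)
  ny <- length(fm$y)
  u0 <- fm$rho / params$K

  frc <- solver_forcing(
    protocol, params$signal, output_times[1],
    output_times[length(output_times)]
  )
  if (is.null(field)) {
    Ex <- matrix(1, nx, ny)
    Ey <- matrix(1, nx, ny)
    mx <- frc$mx
    my <- frc$my
  } else {
    Ex <- matrix(field$ex, nx, ny)
    Ey <- matrix(field$ey, nx, ny)
    mx <- my <- rep(1, length(frc$t))
  }
  sol <- solve_rad_cpp(
    u0, matrix(as.integer(fm$mask), nx, ny), fm$h,
    params$D, params$alpha, params$delta, params$r,
    frc$t, frc$s_plus, frc$t, mx, my, Ex, Ey, output_times, dt_max, cfl
  )
  purrr::map2(sol, output_times, function(m, tt) {
    density_field_2d(fm$x, fm$y, m * params$K, mask = fm$mask, time = tt)
  })
}

#' Migration velocity implied by the continuum model
#'
#' Evaluates the velocity field
#' \deqn{v = -D\nabla u + \alpha s_{eff}^+ (\delta + (1-\delta)u) E,
#'       \quad u = \rho/K,}
#' on a density field: outward spreading down density gradients plus
#' electrotactic advection along the field `E`, reduced at the low-density
#' edge. Gradients are central differences (one-sided at the boundary).
#' Velocities are zero where the field mask is `FALSE`.
#'
#' @param params A [continuum_params()].
#' @param rho A `density_field_1d` or `density_field_2d` (cells/mm).
#' @param s_eff Scalar value of the effective signal (its positive part is
#'   used).
#' @param field For 1D a scalar or per-cell numeric field; for 2D a list
#'   with `ex`, `ey` matrices or scalars. Default: unit field along +x.
#' @return A tibble of class `velocity_field` with `x`, (`y`,) `vx`, (`vy`,)
#'   and `speed` in mm/h.
#' @export
velocity_field <- function(params, rho, s_eff, field = NULL) {
  stopifnot(inherits(params, "continuum_params"))
  s <- max(s_eff, 0)
  if (inherits(rho, "density_field_1d")) {
    h <- attr(rho, "spacing")
    u <- rho$rho / params$K
    E <- if (is.null(field)) 1 else field
    if (length(E) != 1L && length(E) != length(u)) {
      rlang::abort("`field` length must be 1 or the number of cells.",
        class = "voltaxis_invalid_input"
      )
    }
    vx <- -params$D * grad_central(u, h) +
      params$alpha * s * (params$delta + (1 - params$delta) * u) * E
    out <- tibble::tibble(x = rho$x, vx = vx, speed = abs(vx))
  } else if (inherits(rho, "density_field_2d")) {
    fm <- field_matrix(rho)
    u <- fm$rho / params$K
    ex <- 1
    ey <- 0
    if (!is.null(field)) {
      ex <- field$ex
      ey <- field$ey
    }
    gx <- masked_grad(u, fm$mask, fm$h, dim = 1)
    gy <- masked_grad(u, fm$mask, fm$h, dim = 2)
    chi <- params$alpha * s * (params$delta + (1 - params$delta) * u)
    # a cell with no in-mask neighbour along a dimension has no open faces
    # there: it cannot advect in that direction (all its fluxes vanish)
    vx <- -params$D * gx + chi * ex * mask_open(fm$mask, dim = 1)
    vy <- -params$D * gy + chi * ey * mask_open(fm$mask, dim = 2)
    vx[!fm$mask] <- 0
    vy[!fm$mask] <- 0
    out <- tibble::tibble(
      x = rho$x, y = rho$y, vx = as.numeric(vx), vy = as.numeric(vy),
      speed = sqrt(as.numeric(vx)^2 + as.numeric(vy)^2)
    )
    attr(out, "dims") <- attr(rho, "dims")
  } else {
    rlang::abort("`rho` must be a density field.",
      class = "voltaxis_invalid_input"
    )
  }
  class(out) <- c("velocity_field", class(out))
  attr(out, "spacing") <- attr(rho, "spacing")
  attr(out, "s_eff") <- s
  out
}

grad_central <- function(v, h) {
  n <- length(v)
  g <- numeric(n)
  if (n >= 3) g[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * h)
  g[1] <- (v[2] - v[1]) / h
  g[n] <- (v[n] - v[n - 1]) / h
  g
}

# 1 where a masked cell has at least one in-mask neighbour along `dim`,
# 0 elsewhere.
mask_open <- function(mask, dim) {
  if (dim == 2) {
    return(t(mask_open(t(mask), dim = 1)))
  }
  nx <- nrow(mask)
  pad <- rbind(FALSE, mask, FALSE)
  open <- (pad[3:(nx + 2), , drop = FALSE] | pad[1:nx, , drop = FALSE]) & mask
  matrix(as.numeric(open), nx, ncol(mask))
}

# Gradient of a 2D grid that respects the computational-domain mask:
# central differences where both neighbours along `dim` are in the mask,
# one-sided differences at the mask boundary, zero where no in-mask
# neighbour exists (consistent with the solver's no-flux boundary).
masked_grad <- function(u, mask, h, dim) {
  if (dim == 2) {
    return(t(masked_grad(t(u), t(mask), h, dim = 1)))
  }
  nx <- nrow(u)
  pad_u <- rbind(u[1, ], u, u[nx, ])
  pad_m <- rbind(FALSE, mask, FALSE)
  up <- pad_u[3:(nx + 2), , drop = FALSE] # east neighbour
  um <- pad_u[1:nx, , drop = FALSE] # west neighbour
  mp <- pad_m[3:(nx + 2), , drop = FALSE]
  mm <- pad_m[1:nx, , drop = FALSE]
  g <- matrix(0, nx, ncol(u))
  both <- mp & mm
  g[both] <- (up[both] - um[both]) / (2 * h)
  east <- mp & !mm
  g[east] <- (up[east] - u[east]) / h
  west <- !mp & mm
  g[west] <- (u[west] - um[west]) / h
  g[!mask] <- 0
  g
}

#' Tissue geometry masks
#'
#' Builds a uniform cell-centred grid covering a tissue shape plus padding,
#' and marks cells inside the shape. Circles are parameterised by diameter;
#' triangles are equilateral with the given base length, base parallel to
#' the x axis and centroid at the origin; rectangles by side length(s).
#'
#' @param shape One of `"circle"`, `"triangle"`, `"rectangle"`.
#' @param size Diameter / base length / side (mm). For rectangles a length-2
#'   `c(width, height)` is accepted.
#' @param spacing Grid spacing (mm).
#' @param pad Padding added on every side of the shape's bounding box (mm).
#' @param rotate Rotation of the shape about its centroid, degrees
#'   counter-clockwise.
#' @return A `density_field_2d` whose `mask` column marks the tissue and
#'   whose `rho` column is 0; see [uniform_tissue()] to fill it.
#' @export
geometry_mask <- function(shape = c("circle", "triangle", "rectangle"),
                          size, spacing = 0.05, pad = 1, rotate = 0) {
  shape <- match.arg(shape)
  if (any(size <= 0)) {
    rlang::abort("`size` must be > 0.", class = "voltaxis_invalid_input")
  }
  half <- switch(shape,
    circle = c(size / 2, size / 2),
    triangle = c(size / 2, sqrt(3) / 2 * size * 2 / 3),
    rectangle = {
      s <- if (length(size) == 2L) size else c(size, size)
      s / 2
    }
  )
  lim <- max(half) + pad
  x <- seq(-lim + spacing / 2, lim - spacing / 2, by = spacing)
  y <- x
  xy <- expand.grid(x = x, y = y)
  th <- rotate * pi / 180
  xr <- cos(th) * xy$x + sin(th) * xy$y
  yr <- -sin(th) * xy$x + cos(th) * xy$y
  inside <- switch(shape,
    circle = xr^2 + yr^2 <= (size / 2)^2,
    rectangle = {
      s <- if (length(size) == 2L) size else c(size, size)
      abs(xr) <= s[1] / 2 & abs(yr) <= s[2] / 2
    },
    triangle = point_in_equilateral(xr, yr, size)
  )
  if (!any(inside)) {
    rlang::abort("Grid does not resolve the shape; reduce `spacing`.",
      class = "voltaxis_domain_error"
    )
  }
  density_field_2d(x, y, matrix(0, length(x), length(y)),
    mask = matrix(inside, length(x), length(y))
  )
}

# equilateral triangle, base b parallel to x, centroid at origin
point_in_equilateral <- function(px, py, b) {
  hgt <- sqrt(3) / 2 * b
  v <- list(
    c(-b / 2, -hgt / 3), c(b / 2, -hgt / 3), c(0, 2 * hgt / 3)
  )
  sgn <- function(p1, p2) {
    (px - p2[1]) * (p1[2] - p2[2]) - (p1[1] - p2[1]) * (py - p2[2])
  }
  d1 <- sgn(v[[1]], v[[2]])
  d2 <- sgn(v[[2]], v[[3]])
  d3 <- sgn(v[[3]], v[[1]])
  neg <- (d1 < 0) | (d2 < 0) | (d3 < 0)
  pos <- (d1 > 0) | (d2 > 0) | (d3 > 0)
  !(neg & pos)
}

#' Fill a geometry mask with a uniform tissue at carrying capacity
#'
#' Sets `rho = K` inside the mask and 0 outside. When the tissue boundary
#' lies inside a larger computational domain, one pass of
#' nearest-neighbour smoothing (`smooth = TRUE`) avoids a discontinuous
#' initial condition; when the mask itself is the computational domain
#' (the default simulation setup, see [solve_rad_2d()]) the uniform profile
#' has no interior discontinuity and no smoothing is needed.
#'
#' @param mask A `density_field_2d` from [geometry_mask()].
#' @param K Carrying capacity (density scale, cells/mm).
#' @param smooth Apply the one-cell boundary smoothing (default `FALSE`).
#' @return A `density_field_2d` initial condition.
#' @export
uniform_tissue <- function(mask, K, smooth = FALSE) {
  fm <- field_matrix(mask)
  u <- matrix(as.numeric(fm$mask), nrow(fm$mask), ncol(fm$mask))
  if (smooth) {
    nx <- nrow(u)
    ny <- ncol(u)
    padded <- matrix(0, nx + 2, ny + 2)
    padded[2:(nx + 1), 2:(ny + 1)] <- u
    # replicate edges so smoothing is mass-neutral in the interior
    sm <- (padded[2:(nx + 1), 2:(ny + 1)] * 4 +
      padded[1:nx, 2:(ny + 1)] + padded[3:(nx + 2), 2:(ny + 1)] +
      padded[2:(nx + 1), 1:ny] + padded[2:(nx + 1), 3:(ny + 2)]) / 8
    u <- sm
  }
  density_field_2d(fm$x, fm$y, u * K, mask = fm$mask)
}

#' Maximum electrotaxis velocity across tissue sizes
#'
#' For each tissue size, simulates the 2D continuum model on the tissue
#' shape (the mask is the computational domain, with no-flux boundaries at
#' the tissue edge) from a uniform `rho = K` initial condition under the
#' stimulation protocol, and records the maximum over space and time of the
#' velocity magnitude ([velocity_field()]) during the stimulation window.
#' The maximum is taken over cells whose density exceeds 10% of the
#' instantaneous spatial maximum, i.e. over the tissue proper.
#'
#' @param shape `"circle"` or `"triangle"` (or `"rectangle"`).
#' @param sizes Numeric vector of diameters / base lengths (mm).
#' @param params A [continuum_params()].
#' @param protocol A [stimulus_protocol()]; default 1 h off / 3 h on.
#' @param spacing Grid spacing (mm).
#' @param pad Domain padding around the shape (mm).
#' @param dt_output Spacing of velocity snapshots inside the stimulation
#'   window (h).
#' @param dt_max,cfl Solver controls, see [solve_rad_1d()].
#' @return A tibble with columns `size_mm`, `v_max_mm_h`, `v_max_um_h` and
#'   `error` (NA on success; failed sizes are collected, not fatal).
#' @export
size_sweep <- function(shape, sizes, params, protocol = step_protocol(),
                       spacing = 0.05, pad = 0.1, dt_output = 0.1,
                       dt_max = 0.01, cfl = 0.4) {
  stopifnot(inherits(params, "continuum_params"))
  win <- stimulation_window(protocol)
  if (anyNA(win)) {
    rlang::abort("Protocol never turns the field on.",
      class = "voltaxis_invalid_input"
    )
  }
  res <- purrr::map(sizes, function(sz) {
    tryCatch(
      {
        msk <- geometry_mask(shape, sz, spacing = spacing, pad = pad)
        init <- uniform_tissue(msk, params$K)
        out_t <- unique(c(0, seq(win["on"], win["off"], by = dt_output)))
        sols <- solve_rad_2d(params, init, protocol, out_t,
          dt_max = dt_max, cfl = cfl
        )
        sig <- integrate_signal(protocol, params$signal, out_t)
        vmax <- 0
        for (k in seq_along(sols)) {
          if (out_t[k] < win["on"] - 1e-9) next
          dirs <- protocol_direction(protocol, out_t[k])
          vf <- velocity_field(params, sols[[k]], sig$s_eff_plus[k],
            field = list(ex = dirs[1, 1], ey = dirs[1, 2])
          )
          in_tissue <- sols[[k]]$rho >= 0.1 * max(sols[[k]]$rho)
          if (any(in_tissue)) {
            vmax <- max(vmax, max(vf$speed[in_tissue]))
          }
        }
        list(v = vmax, err = NA_character_)
      },
      error = function(e) list(v = NA_real_, err = conditionMessage(e))
    )
  })
  tibble::tibble(
    size_mm = sizes,
    v_max_mm_h = purrr::map_dbl(res, "v"),
    v_max_um_h = purrr::map_dbl(res, "v") * 1000,
    error = purrr::map_chr(res, "err")
  )
}

#' y-averaged density profile of a central strip
#'
#' Averages a 2D density field over y within a horizontal strip that stays
#' `margin` mm away from the top and bottom edges of the domain, giving a
#' one-dimensional profile per x. This mirrors the standard processing of
#' monolayer nuclei histograms, where y-averaging away from the top/bottom
#' edges removes artefacts from migration at those edges.
#'
#' @param rho2d A `density_field_2d`.
#' @param margin Distance (mm) excluded from the top and the bottom of the
#'   domain.
#' @return A `density_field_1d` of the strip mean per x.
#' @export
strip_average <- function(rho2d, margin) {
  stopifnot(inherits(rho2d, "density_field_2d"))
  check_number(margin, "margin", nonnegative = TRUE)
  fm <- field_matrix(rho2d)
  keep <- fm$y >= (min(fm$y) + margin) & fm$y <= (max(fm$y) - margin)
  if (!any(keep)) {
    rlang::abort("`margin` leaves an empty strip.",
      class = "voltaxis_invalid_input"
    )
  }
  prof <- rowMeans(fm$rho[, keep, drop = FALSE])
  density_field_1d(fm$x, prof, time = attr(rho2d, "time_h"))
}

#' Two-dimensional histogram density of nuclei positions
#'
#' Bins segmented nuclei coordinates into an `bins x bins` grid over
#' `extent` and converts counts to areal densities (counts per mm^2).
#' Points outside the extent are dropped with a message.
#'
#' @param points Data frame with columns `x`, `y` (mm).
#' @param bins Number of bins per axis (default 150).
#' @param extent Length-4 numeric `c(xmin, xmax, ymin, ymax)`.
#' @return A `density_field_2d` whose `rho` column holds densities; the raw
#'   counts are in the `count` column and `attr(, "n_retained")` gives the
#'   number of binned points.
#' @export
histogram_density <- function(points, bins = 150,
                              extent = c(-3.5, 3.5, -3.5, 3.5)) {
  if (!all(c("x", "y") %in% names(points))) {
    rlang::abort("`points` needs `x` and `y` columns.",
      class = "voltaxis_invalid_input"
    )
  }
  if (extent[2] <= extent[1] || extent[4] <= extent[3]) {
    rlang::abort("`extent` must have positive area.",
      class = "voltaxis_invalid_input"
    )
  }
  inside <- points$x >= extent[1] & points$x <= extent[2] &
    points$y >= extent[3] & points$y <= extent[4]
  n_drop <- sum(!inside)
  if (n_drop > 0) {
    rlang::inform(sprintf("Dropped %d points outside the extent.", n_drop))
  }
  px <- points$x[inside]
  py <- points$y[inside]
  bx <- seq(extent[1], extent[2], length.out = bins + 1)
  by <- seq(extent[3], extent[4], length.out = bins + 1)
  ix <- pmin(pmax(findInterval(px, bx, rightmost.closed = TRUE), 1L), bins)
  iy <- pmin(pmax(findInterval(py, by, rightmost.closed = TRUE), 1L), bins)
  counts <- matrix(0, bins, bins)
  tab <- table(factor(ix, levels = 1:bins), factor(iy, levels = 1:bins))
  counts[] <- as.numeric(tab)
  area <- diff(bx)[1] * diff(by)[1]
  xc <- (bx[-1] + bx[-length(bx)]) / 2
  yc <- (by[-1] + by[-length(by)]) / 2
  out <- density_field_2d(xc, yc, counts / area)
  out$count <- as.numeric(counts)
  attr(out, "n_retained") <- length(px)
  out
}
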