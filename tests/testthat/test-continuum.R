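make_1d_bump <- function(n = 81, K = 260) {
  h <- 7 / n
  x <- seq(-3.5 + h / 2, 3.5 - h / 2, length.out = n)
  u <- exp(-(x / 0.8)^2)
  density_field_1d(x, u * K)
}

test_that("a uniform tissue at carrying capacity is a fixed point", {
  p <- continuum_params(D = 2, alpha = 0.5, delta = 0.5, r = 0.3, K = 100)
  n <- 41
  h <- 7 / n
  x <- seq(-3.5 + h / 2, 3.5 - h / 2, length.out = n)
  init <- density_field_1d(x, rep(100, n))
  # no field: advective flux is uniform (zero divergence) only with the
  # field off, diffusion flat, logistic at its fixed point
  kym <- solve_rad_1d(p, init, stimulus_protocol(c(0, 5), 0), c(0, 2, 4))
  expect_equal(kym$rho, rep(100, 3 * n), tolerance = 1e-12)
})

test_that("mass is conserved without proliferation (1D and 2D)", {
  p <- continuum_params(D = 13.3, alpha = 0.837, delta = 0.625, r = 0, K = 260)
  init <- make_1d_bump()
  kym <- solve_rad_1d(p, init, step_protocol(), c(0, 2, 5))
  m <- matrix(kym$rho, ncol = 3)
  mass <- colSums(m)
  expect_lt(max(abs(mass - mass[1])) / mass[1], 1e-10)

  # 2D on a circular masked domain
  msk <- geometry_mask("circle", 1.5, spacing = 0.1, pad = 0.2)
  init2 <- uniform_tissue(msk, 260)
  sols <- solve_rad_2d(p, init2, step_protocol(), c(0, 1.5, 3))
  mass2 <- vapply(sols, function(s) sum(s$rho), 0)
  expect_lt(max(abs(mass2 - mass2[1])) / mass2[1], 1e-10)
})

test_that("pure logistic growth matches the closed form", {
  K <- 260.29
  r <- 0.18
  p <- continuum_params(D = 1e-12, alpha = 0, delta = 0.5, r = r, K = K)
  n <- 31
  h <- 7 / n
  x <- seq(-3.5 + h / 2, 3.5 - h / 2, length.out = n)
  rho0 <- K / 10
  init <- density_field_1d(x, rep(rho0, n))
  times <- c(0, 1, 2, 5, 10)
  kym <- solve_rad_1d(p, init, stimulus_protocol(c(0, 11), 0), times)
  m <- matrix(kym$rho, ncol = length(times))
  expected <- K / (1 + (K / rho0 - 1) * exp(-r * times))
  expect_equal(m[1, ], expected, tolerance = 1e-6)
  expect_equal(m[n, ], expected, tolerance = 1e-6)
})

test_that("density stays non-negative through stimulation", {
  p <- default_continuum_params()
  init <- make_1d_bump(n = 101)
  kym <- solve_rad_1d(p, init, step_protocol(magnitude = 3), seq(0, 6, 1))
  expect_true(all(kym$rho >= 0))
})

test_that("y-uniform 2D problems reduce to the 1D solver", {
  p <- default_continuum_params()
  init1 <- make_1d_bump(n = 71)
  ny <- 15
  h <- attr(init1, "spacing")
  y <- seq(0, by = h, length.out = ny)
  init2 <- density_field_2d(init1$x, y, matrix(rep(init1$rho, ny), ncol = ny))
  out_t <- c(0, 1.5, 3)
  kym1 <- matrix(solve_rad_1d(p, init1, step_protocol(), out_t)$rho, ncol = 3)
  sols2 <- solve_rad_2d(p, init2, step_protocol(), out_t)
  for (k in 2:3) {
    fm <- voltaxis:::field_matrix(sols2[[k]])
    expect_lt(max(abs(fm$rho - kym1[, k])) / max(kym1[, k]), 1e-8)
    # every row identical
    expect_lt(max(apply(fm$rho, 1, function(r) diff(range(r)))), 1e-8)
  }
})

test_that("radially symmetric spreading stays radially symmetric", {
  p <- continuum_params(D = 5, alpha = 0.8, delta = 0.6, r = 0.1, K = 100)
  msk <- geometry_mask("circle", 2, spacing = 0.1, pad = 0.1)
  init <- uniform_tissue(msk, 100)
  # field off: no advection breaks the symmetry
  sols <- solve_rad_2d(p, init, stimulus_protocol(c(0, 3), 0), c(0, 2))
  fm <- voltaxis:::field_matrix(sols[[2]])
  sym_x <- max(abs(fm$rho - fm$rho[rev(seq_len(nrow(fm$rho))), ]))
  sym_y <- max(abs(fm$rho - fm$rho[, rev(seq_len(ncol(fm$rho)))]))
  sym_t <- max(abs(fm$rho - t(fm$rho)))
  expect_lt(max(sym_x, sym_y, sym_t), 1e-9 * max(fm$rho))
})

test_that("an x-directed field drifts the centre of mass in +x only", {
  p <- continuum_params(D = 0.5, alpha = 0.837, delta = 0.625, r = 0, K = 260)
  n <- 101
  h <- 7 / n
  x <- seq(-3.5 + h / 2, 3.5 - h / 2, length.out = n)
  init <- density_field_1d(x, 260 * exp(-(x / 0.6)^2))
  com <- function(kym, k) {
    m <- matrix(kym$rho, ncol = k)
    colSums(m * x) / colSums(m)
  }
  on <- solve_rad_1d(p, init, step_protocol(pre = 0), c(0, 1, 2))
  expect_true(all(diff(com(on, 3)) > 1e-3))
  off <- solve_rad_1d(p, init, stimulus_protocol(c(0, 3), 0), c(0, 1, 2))
  expect_lt(max(abs(diff(com(off, 3)))), 1e-10)
})

test_that("halving the grid spacing converges the final profile", {
  p <- default_continuum_params()
  pr <- step_protocol()
  profile_at <- function(n) {
    h <- 7 / n
    x <- seq(-3.5 + h / 2, 3.5 - h / 2, length.out = n)
    u <- stats::plogis((x + 2.5) / 0.2) * stats::plogis((2.5 - x) / 0.2)
    init <- density_field_1d(x, u * p$K)
    kym <- solve_rad_1d(p, init, pr, c(0, 2), dt_max = 0.002)
    list(x = x, rho = matrix(kym$rho, ncol = 2)[, 2])
  }
  f1 <- profile_at(60)
  f2 <- profile_at(120)
  f3 <- profile_at(240)
  # successive differences, measured on the coarse grid, decrease
  d12 <- max(abs(f1$rho - approx(f2$x, f2$rho, f1$x, rule = 2)$y))
  d23 <- max(abs(f2$rho - approx(f3$x, f3$rho, f2$x, rule = 2)$y))
  expect_lt(d23, d12)
})

test_that("velocity field obeys the degenerate-density identities", {
  p <- default_continuum_params()
  n <- 51
  h <- 7 / n
  x <- seq(-3.5 + h / 2, 3.5 - h / 2, length.out = n)
  # uniform rho = K: delta + (1 - delta) = 1, no gradient
  vf <- velocity_field(p, density_field_1d(x, rep(p$K, n)), s_eff = 1)
  expect_equal(vf$vx, rep(p$alpha, n), tolerance = 1e-12)
  # delta = 1: advection independent of density
  p1 <- continuum_params(D = p$D, alpha = p$alpha, delta = 1, r = p$r, K = p$K)
  vf1 <- velocity_field(p1, density_field_1d(x, 100 + 50 * sin(x)), s_eff = 0.5)
  adv <- vf1$vx + p1$D * voltaxis:::grad_central((100 + 50 * sin(x)) / p1$K, h)
  expect_equal(adv, rep(p1$alpha * 0.5, n), tolerance = 1e-10)
  # edge-to-bulk advective speed ratio equals delta at vanishing density
  chi_edge <- p$alpha * 1 * (p$delta + (1 - p$delta) * 0)
  chi_bulk <- p$alpha * 1 * (p$delta + (1 - p$delta) * 1)
  expect_equal(chi_edge / chi_bulk, 0.625)
})

test_that("geometry masks recover the analytic areas", {
  h <- 0.02
  circ <- geometry_mask("circle", 1.5, spacing = h, pad = 0.1)
  area_c <- sum(circ$mask) * h^2
  expect_lt(abs(area_c - pi * 1.5^2 / 4) / (pi * 1.5^2 / 4), 0.02)
  tri <- geometry_mask("triangle", 2, spacing = h, pad = 0.1)
  area_t <- sum(tri$mask) * h^2
  expect_lt(abs(area_t - sqrt(3) / 4 * 4) / (sqrt(3) / 4 * 4), 0.02)
  rect <- geometry_mask("rectangle", 5, spacing = 0.05, pad = 0.2)
  expect_lt(abs(sum(rect$mask) * 0.05^2 - 25) / 25, 0.02)
  expect_error(geometry_mask("circle", -1), class = "voltaxis_invalid_input")
})

test_that("size sweep: field off leaves only spreading speeds", {
  p <- default_continuum_params()
  off <- stimulus_protocol(c(0, 4), c(0))
  expect_error(size_sweep("circle", 1, p, protocol = off),
    class = "voltaxis_invalid_input"
  )
  sw <- size_sweep("circle", 0.5, p, spacing = 0.1)
  expect_equal(nrow(sw), 1)
  expect_true(is.finite(sw$v_max_mm_h))
})

test_that("maximum electrotaxis velocity grows with circle size", {
  p <- default_continuum_params()
  sw <- size_sweep("circle", c(0.25, 1, 2.5, 4), p, spacing = 0.1)
  expect_true(all(is.na(sw$error)))
  expect_gt(cor(sw$size_mm, sw$v_max_um_h, method = "spearman"), 0.7)
  expect_gt(sw$v_max_um_h[4], sw$v_max_um_h[1])
})

test_that("strip averaging reproduces analytic y-averages", {
  nx <- 30
  ny <- 40
  x <- seq(-1.45, 1.45, length.out = nx)
  y <- seq(-1.95, 1.95, length.out = ny)
  # y-uniform: strip average equals any row
  f <- density_field_2d(x, y, matrix(rep(50 + 10 * cos(x), ny), nx, ny))
  prof <- strip_average(f, margin = 1)
  expect_equal(prof$rho, 50 + 10 * cos(x), tolerance = 1e-12)
  # y-gradient confined to the excluded margins
  ramp <- ifelse(abs(y) > 0.95, 99, 7)
  f2 <- density_field_2d(x, y, outer(rep(1, nx), ramp))
  prof2 <- strip_average(f2, margin = 1)
  expect_equal(prof2$rho, rep(7, nx))
  # known analytic y-average
  g <- outer(sin(x), y^2)
  f3 <- density_field_2d(x, y, g - min(g))
  keep <- abs(y) <= max(y) - 0.5
  expected <- rowMeans((g - min(g))[, keep])
  expect_equal(strip_average(f3, margin = 0.5)$rho, expected,
    tolerance = 1e-12
  )
  expect_error(strip_average(f3, margin = 5), class = "voltaxis_invalid_input")
})

test_that("histogram density bins points with the standard 150-bin grid", {
  pts <- tibble::tibble(x = 0.31, y = -0.77)
  hst <- histogram_density(pts, bins = 150, extent = c(-3.5, 3.5, -3.5, 3.5))
  expect_equal(sum(hst$count), 1)
  expect_equal(sum(hst$count > 0), 1)
  expect_equal(attr(hst, "dims"), c(nx = 150L, ny = 150L))
  # counts sum to retained points; outsiders dropped with a message
  set.seed(31)
  pts2 <- tibble::tibble(x = runif(500, -4, 4), y = runif(500, -4, 4))
  expect_message(
    hst2 <- histogram_density(pts2, bins = 150, extent = c(-3.5, 3.5, -3.5, 3.5))
  )
  inside <- sum(abs(pts2$x) <= 3.5 & abs(pts2$y) <= 3.5)
  expect_equal(sum(hst2$count), inside)
  expect_equal(attr(hst2, "n_retained"), inside)
})

test_that("uniform random points fill bins within Poisson bounds", {
  set.seed(77)
  n <- 1e5
  bins <- 20
  pts <- tibble::tibble(x = runif(n), y = runif(n))
  hst <- histogram_density(pts, bins = bins, extent = c(0, 1, 0, 1))
  lambda <- n / bins^2
  # all counts within 6 sigma of the Poisson expectation
  expect_true(all(abs(hst$count - lambda) < 6 * sqrt(lambda)))
  expect_error(histogram_density(pts, extent = c(0, 0, 0, 1)),
    class = "voltaxis_invalid_input"
  )
})
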