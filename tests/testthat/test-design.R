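design_profile <- function(n = 141, K = 260.29) {
  h <- 7 / n
  x <- seq(-3.5 + h / 2, 3.5 - h / 2, length.out = n)
  u <- stats::plogis((x + 2.2) / 0.35) * stats::plogis((2.2 - x) / 0.35)
  density_field_1d(x, pmax(u, 1e-4) * K)
}

test_that("uniform density gives the uniform design gradient v*/alpha/s_eff", {
  p <- default_continuum_params()
  n <- 61
  h <- 7 / n
  x <- seq(-3.5 + h / 2, 3.5 - h / 2, length.out = n)
  rho <- density_field_1d(x, rep(p$K, n))
  g <- design_gradient_1d(p, rho, s_eff = 1, v_star = 0.047, s_max = 10)
  expect_equal(g$gradient, rep(0.047 / p$alpha, n), tolerance = 1e-12)
  expect_false(any(g$capped))
})

test_that("with v* = 0 the gradient is the pure anti-spreading correction", {
  p <- default_continuum_params()
  rho <- design_profile()
  g <- design_gradient_1d(p, rho, s_eff = 0.5, v_star = 0, s_max = 1e6)
  u <- rho$rho / p$K
  du <- voltaxis:::grad_central(u, attr(rho, "spacing"))
  expect_equal(g$gradient_raw == 0, du == 0)
  expect_true(all(abs(g$gradient_raw[abs(du) > 1e-8]) > 0))
})

test_that("the cap engages as the signal wanes", {
  p <- default_continuum_params()
  rho <- design_profile()
  g <- design_gradient_1d(p, rho, s_eff = 1e-9, v_star = 0.047, s_max = 1)
  expect_true(all(abs(g$gradient) <= 1 + 1e-12))
  expect_true(all(g$capped))
  expect_warning(
    g0 <- design_gradient_1d(p, rho, s_eff = 0, v_star = 0.047, s_max = 1),
    "capped"
  )
  expect_equal(g0$gradient, rep(1, nrow(rho)))
})

test_that("closed-form potential is flat-density linear and anchored at x0", {
  p <- default_continuum_params()
  n <- 81
  h <- 7 / n
  x <- seq(-3.5 + h / 2, 3.5 - h / 2, length.out = n)
  rho <- density_field_1d(x, rep(p$K, n))
  pot <- design_potential_1d(p, rho, s_eff = 0.8, v_star = 0.047, x0 = 0)
  slope <- diff(pot$phi) / diff(pot$x)
  expect_equal(slope, rep(0.047 / (p$alpha * 0.8), n - 1), tolerance = 1e-10)
  expect_lt(abs(approx(pot$x, pot$phi, xout = 0)$y), 1e-12)
})

test_that("potential derivative matches the design gradient to discretisation order", {
  p <- default_continuum_params()
  err_at <- function(n) {
    rho <- design_profile(n)
    g <- design_gradient_1d(p, rho, s_eff = 0.6, v_star = 0.047,
      s_max = .Machine$double.xmax
    )
    pot <- design_potential_1d(p, rho, s_eff = 0.6, v_star = 0.047)
    dphi <- diff(pot$phi) / diff(pot$x)
    mid <- (g$gradient_raw[-1] + g$gradient_raw[-n]) / 2
    max(abs(dphi - mid)) / max(abs(mid))
  }
  e1 <- err_at(100)
  e2 <- err_at(200)
  e3 <- err_at(400)
  expect_lt(e2, e1)
  expect_lt(e3, e2)
  expect_lt(e3, 0.01)
})

test_that("delta = 1 potential falls back to direct integration", {
  p1 <- continuum_params(D = 13.3, alpha = 0.837, delta = 1, r = 0.18, K = 260)
  rho <- design_profile()
  pot <- design_potential_1d(p1, rho, s_eff = 0.5, v_star = 0.047)
  g <- design_gradient_1d(p1, rho, s_eff = 0.5, v_star = 0.047,
    s_max = .Machine$double.xmax
  )
  dphi <- diff(pot$phi) / diff(pot$x)
  mid <- (g$gradient_raw[-1] + g$gradient_raw[-nrow(rho)]) / 2
  expect_equal(dphi, mid, tolerance = 1e-8)
})

test_that("delta = 0 with vanishing density is rejected", {
  p0 <- continuum_params(D = 1, alpha = 0.8, delta = 0, r = 0.1, K = 100)
  n <- 41
  h <- 7 / n
  x <- seq(-3.5 + h / 2, 3.5 - h / 2, length.out = n)
  rho <- density_field_1d(x, c(rep(0, 5), rep(100, n - 5)))
  expect_error(design_potential_1d(p0, rho, s_eff = 0.5, v_star = 0.01),
    class = "voltaxis_invalid_input"
  )
})

test_that("uncapped designed field drives the solver velocity to v* exactly", {
  # closed loop on a frozen density snapshot: the velocity expression
  # evaluated with the designed field returns v* wherever the cap is
  # inactive
  p <- default_continuum_params()
  cfg <- synthetic_config()
  init <- gen_density_profile_1d(cfg, n_cells = 141)
  kym <- solve_rad_1d(p, init, step_protocol(), c(0, 1.6))
  frozen <- density_field_1d(init$x, matrix(kym$rho, ncol = 2)[, 2])
  s_eff <- integrate_signal(step_protocol(), p$signal, c(0, 1.6))$s_eff_plus[2]
  g <- design_gradient_1d(p, frozen, s_eff, v_star = 0.047,
    s_max = .Machine$double.xmax
  )
  vf <- velocity_field(p, frozen, s_eff, field = g$gradient_raw)
  expect_lt(max(abs(vf$vx - 0.047)), 1e-8)
})

test_that("2D optimal gradient is uniform on flat density and scales with 1/s_eff", {
  p <- default_continuum_params()
  x <- seq(-1, 1, length.out = 21)
  rho <- density_field_2d(x, x, matrix(p$K, 21, 21))
  fm1 <- design_gradient_2d(p, rho, s_eff = 0.5, v_star = c(0.047, 0))
  expect_equal(fm1$ex, rep(0.047 / (p$alpha * 0.5), 441), tolerance = 1e-12)
  expect_equal(fm1$ey, rep(0, 441))
  fm2 <- design_gradient_2d(p, rho, s_eff = 1, v_star = c(0.047, 0))
  expect_equal(fm2$ex, fm1$ex / 2, tolerance = 1e-12)
  expect_error(design_gradient_2d(p, rho, s_eff = 0, v_star = c(1, 0)),
    class = "voltaxis_invalid_input"
  )
})

test_that("edge y-components of the optimal gradient oppose the outward normal", {
  p <- default_continuum_params()
  msk <- geometry_mask("circle", 3.5, spacing = 0.05, pad = 0.2)
  init <- uniform_tissue(msk, p$K, smooth = TRUE)
  fmap <- design_gradient_2d(p, init, s_eff = 0.7, v_star = c(0.047, 0))
  # top boundary band of the tissue: outward normal has +y component, so
  # wherever the density gradient is felt the design field's y component
  # must be negative (anti-spreading); deeper cells see no gradient
  top <- fmap$mask & fmap$y > 1.4 & abs(fmap$x) < 0.5 & fmap$ey != 0
  expect_true(any(top))
  expect_true(all(fmap$ey[top] < 0))
})

test_that("heuristic field has fixed magnitude and edge direction reversal", {
  p <- default_continuum_params()
  msk <- geometry_mask("circle", 3.5, spacing = 0.05, pad = 0.2)
  init <- uniform_tissue(msk, p$K, smooth = TRUE)
  hf <- heuristic_field(p, init, v_star = c(0.047, 0), s_max = 1)
  inside <- hf$mask
  expect_lt(max(abs(hf$magnitude[inside] - 1)), 1e-12)
  expect_true(all(hf$magnitude[!inside] == 0))
  # interior: field along +x
  core <- inside & hf$x^2 + hf$y^2 < 0.5^2
  expect_true(all(hf$ex[core] > 0.99))
  # top edge band: y-component negative (points against outgrowth) where
  # the boundary density gradient is felt
  top <- inside & hf$y > 1.4 & abs(hf$x) < 0.5 & hf$ey != 0
  expect_true(any(top))
  expect_true(all(hf$ey[top] < 0))
  # triangle case builds without error and keeps the fixed magnitude
  mskt <- geometry_mask("triangle", 3, spacing = 0.05, pad = 0.2)
  initt <- uniform_tissue(mskt, p$K, smooth = TRUE)
  hft <- heuristic_field(p, initt, v_star = c(0.047, 0), s_max = 1)
  expect_lt(max(abs(hft$magnitude[hft$mask] - 1)), 1e-12)
})

test_that("heuristic direction is invariant under joint rho, K rescaling", {
  p <- default_continuum_params()
  msk <- geometry_mask("circle", 2, spacing = 0.1, pad = 0.2)
  init <- uniform_tissue(msk, p$K, smooth = TRUE)
  hf1 <- heuristic_field(p, init, v_star = c(0.047, 0), s_max = 1)
  c_scale <- 3.7
  p2 <- continuum_params(
    D = p$D, alpha = p$alpha, delta = p$delta, r = p$r,
    K = c_scale * p$K
  )
  init2 <- density_field_2d(
    unique(init$x), unique(init$y),
    matrix(c_scale * init$rho, length(unique(init$x))),
    mask = matrix(init$mask, length(unique(init$x)))
  )
  hf2 <- heuristic_field(p2, init2, v_star = c(0.047, 0), s_max = 1)
  expect_equal(hf1$ex, hf2$ex, tolerance = 1e-10)
  expect_equal(hf1$ey, hf2$ey, tolerance = 1e-10)
})

test_that("field transects extract the requested grid line", {
  p <- default_continuum_params()
  msk <- geometry_mask("circle", 2, spacing = 0.1, pad = 0.2)
  init <- uniform_tissue(msk, p$K)
  hf <- heuristic_field(p, init, v_star = c(0.047, 0), s_max = 1)
  tr <- field_transect(hf, "horizontal", at = 0)
  expect_equal(nrow(tr), length(unique(hf$x)))
  expect_true(all(c("x", "ex", "ey", "magnitude") %in% names(tr)))
  tv <- field_transect(hf, "vertical", at = 0.35)
  expect_equal(nrow(tv), length(unique(hf$y)))
})
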