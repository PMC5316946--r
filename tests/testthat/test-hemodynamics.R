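p0 <- load_defaults()

test_that("hindrance function matches its closed form", {
  expect_equal(hindrance(0), 0)
  expect_equal(hindrance(0.1), 0.165)
  expect_equal(hindrance(1), 7.5)
  phi <- seq(0, 1, by = 0.01)
  expect_true(all(diff(hindrance(phi)) > 0))
  expect_error(hindrance(1.2), "0, 1")
  expect_error(hindrance(-0.1), "0, 1")
})

test_that("resistance force is -C2 f(phi) v", {
  expect_equal(resistance_force(0.1, 1e-3, p0), -2e9 * 0.165 * 1e-3)
  expect_equal(resistance_force(0.1, 1e-3, p0), -3.3e5)
  expect_equal(resistance_force(0, 1, p0), 0)
  ## anti-parallel to the velocity
  expect_lt(resistance_force(0.5, 2e-3, p0), 0)
  expect_gt(resistance_force(0.5, -2e-3, p0), 0)
})

test_that("pressure-driven tube flow reproduces Hagen-Poiseuille", {
  fx <- make_fixture("poiseuille", geometry = "tube", n = 64L, nz = 24L)
  fl <- solve_flow(fx$grid, params = p0, tol = 1e-9, du_tol = 2e-7,
                   max_outer = 20000)
  ucc <- 0.5 * (fl$u[-1, ] + fl$u[-nrow(fl$u), ])
  prof <- ucc[12, ]
  g <- fx$grid
  w <- g$dy * g$yc
  Um <- sum(prof * w) / sum(w)
  expect_equal(Um, fx$U_mean, tolerance = 0.01)
  ## centreline/mean ratio 2 within 1% (reference at the cell centre)
  expect_equal(max(prof) / Um, 2.0, tolerance = 0.01)
  ## wall shear rate 4U/R (one-sided, first order)
  expect_equal(fl$gamma[12, ncol(fl$gamma)], fx$wall_shear_rate,
               tolerance = 0.08)
  ## profile matches the analytic parabola
  l2 <- sqrt(sum((prof - fx$reference(g$yc))^2 * w) / sum(w)) / fx$U_mean
  expect_lt(l2, 0.005)
})

test_that("plane channel flow gives the 1.5 maximum-to-mean ratio", {
  fx <- make_fixture("poiseuille", geometry = "plates", n = 64L, nz = 24L)
  fl <- solve_flow(fx$grid, params = p0, tol = 1e-9, du_tol = 2e-7,
                   max_outer = 20000)
  ucc <- 0.5 * (fl$u[-1, ] + fl$u[-nrow(fl$u), ])
  prof <- ucc[12, ]
  Um <- mean(prof)
  expect_equal(Um, fx$U_mean, tolerance = 0.01)
  expect_equal(max(prof) / Um, 1.5, tolerance = 0.01)
})

test_that("velocity error decreases under mesh refinement", {
  errs <- vapply(c(16L, 32L), function(n) {
    fx <- make_fixture("poiseuille", geometry = "tube", n = n, nz = 12L)
    fl <- solve_flow(fx$grid, params = p0, tol = 1e-10, du_tol = 1e-8,
                     max_outer = 20000)
    ucc <- 0.5 * (fl$u[-1, ] + fl$u[-nrow(fl$u), ])
    g <- fx$grid
    w <- g$dy * g$yc
    sqrt(sum((ucc[6, ] - fx$reference(g$yc))^2 * w) / sum(w)) / fx$U_mean
  }, numeric(1))
  expect_lt(errs[2], errs[1] / 1.8)   # at least first-order convergence
})

test_that("flow is strongly damped inside a dense deposit", {
  fx <- make_fixture("phi_spanning_disc", n = 16L, nz = 32L)
  g <- fx$grid
  U0 <- 800e-6
  g$side_bc$west$p <- 8 * p0$mu_f * max(g$xf) * U0 / (30e-6)^2
  fl <- solve_flow(g, fx$phi, p0, tol = 1e-9)
  ucc <- 0.5 * (fl$u[-1, ] + fl$u[-nrow(fl$u), ])
  vcc <- 0.5 * (fl$v[, -1] + fl$v[, -ncol(fl$v)])
  speed <- sqrt(ucc^2 + vcc^2)
  expect_lt(max(speed[fx$phi > 0]) / U0, 0.01)
  ## and the flow rate at fixed driving pressure collapses
  expect_lt(abs(fl$Q_in) / (U0 * (30e-6)^2 / 2), 0.02)
})

test_that("flow rate responds monotonically to added deposit", {
  fx <- make_fixture("phi_plug", n = 12L, nz = 20L)
  g <- fx$grid
  g$side_bc$west$p <- 8 * p0$mu_f * max(g$xf) * 800e-6 / (30e-6)^2
  Q <- vapply(c(0, 0.3, 0.6, 0.9), function(level) {
    solve_flow(g, fx$phi * level, p0, tol = 1e-9)$Q_in
  }, numeric(1))
  expect_true(all(diff(Q) < 0))
})

test_that("mass is conserved across the domain boundaries", {
  fx <- make_fixture("poiseuille", geometry = "tube", n = 24L, nz = 16L)
  fl <- solve_flow(fx$grid, params = p0, tol = 1e-9)
  g <- fx$grid
  Qout <- sum(fl$u[nrow(fl$u), ] * g$dy * g$yc)
  expect_equal(Qout, fl$Q_in, tolerance = 1e-6)
})

test_that("shear fields vanish in uniform flow and scale as tau = mu gamma", {
  ## uniform stream between two shear-free boundaries
  g <- make_grid(seq(0, 1e-3, length.out = 21), seq(0, 1e-4, length.out = 6),
                 mode = "planar",
                 side_bc = list(west = list(type = "inlet", u = 1e-3),
                                east = list(type = "pressure", p = 0),
                                south = list(type = "symmetry"),
                                north = list(type = "symmetry")))
  fl <- solve_flow(g, params = p0, tol = 1e-10)
  expect_lt(max(fl$gamma), 1e-6 * 1e-3 / 1e-4)
  ## tau = mu gamma in Pa, and the dyne/cm^2 field is 10x the Pa field
  fx <- make_fixture("poiseuille", geometry = "tube", n = 24L, nz = 16L)
  fl2 <- solve_flow(fx$grid, params = p0, tol = 1e-9)
  sf <- shear_fields(fl2, fx$grid, p0)
  expect_equal(sf$tau, p0$mu_f * sf$gamma)
  expect_equal(sf$tau_dyne, 10 * sf$tau)
})

test_that("transient stepping relaxes toward the steady profile", {
  fx <- make_fixture("poiseuille", geometry = "plates", n = 16L, nz = 10L)
  steady <- solve_flow(fx$grid, params = p0, tol = 1e-10, du_tol = 1e-8,
                       max_outer = 20000)
  fl <- NULL
  for (k in 1:40)
    fl <- step_flow(fl, matrix(0, fx$grid$nx, fx$grid$ny), fx$grid, p0,
                    dt = 5e-3, max_outer = 200)
  expect_equal(max(abs(fl$u - steady$u)) / max(abs(steady$u)), 0,
               tolerance = 0.02)
})
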