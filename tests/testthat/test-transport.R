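p0 <- load_defaults()

## a quiescent flow object for transport-only tests
still_flow <- function(grid) {
  structure(list(u = matrix(0, grid$nx + 1, grid$ny),
                 v = matrix(0, grid$nx, grid$ny + 1),
                 gamma = matrix(0, grid$nx, grid$ny)),
            class = "thrombo_flow")
}

test_that("platelet diffusivity is shear-enhanced, others constant", {
  expect_equal(platelet_diffusivity(0, p0), 1.58e-13)
  expect_equal(platelet_diffusivity(100, p0), 1.58e-13 + 6.0e-11)
  expect_equal(platelet_diffusivity(100, p0), 6.016e-11, tolerance = 1e-3)
  expect_equal(p0$D[["a_pr"]], 2.57e-10)   # ADP, independent of gamma
  g <- seq(0, 1000, by = 10)
  expect_true(all(diff(platelet_diffusivity(g, p0)) > 0))
})

test_that("a top-hat advects with the flow at exactly v dt per step", {
  fx <- make_fixture("advect1d")
  fl <- solve_flow(fx$grid, params = p0, tol = 1e-10)
  st <- species_state(a_pr = 0)
  st$a_pr <- fx$C0
  dt <- 0.8 * fx$grid$dx[1] / fx$v
  n <- 100L
  out <- step_species(st, fl, fx$grid, p0, dt = dt, nsteps = n)
  com0 <- sum(fx$grid$xc * fx$C0) / sum(fx$C0)
  com1 <- sum(fx$grid$xc * out$a_pr) / sum(out$a_pr)
  expect_equal(com1 - com0, n * dt * fx$v, tolerance = 1e-10)
})

test_that("a point release diffuses with variance 2 D t", {
  fx <- make_fixture("diffuse1d")
  g <- fx$grid
  st <- species_state(a_pr = 0)
  st$a_pr <- fx$C0
  dt <- 0.4 * g$dx[1]^2 / (2 * fx$D)
  ## override the ADP diffusivity to the fixture value (it already is)
  n <- 500L
  out <- step_species(st, still_flow(g), g, p0, dt = dt, nsteps = n)
  tt <- n * dt
  mu <- sum(g$xc * out$a_pr) / sum(out$a_pr)
  v1 <- sum((g$xc - mu)^2 * out$a_pr) / sum(out$a_pr)
  expect_equal(v1, fx$variance(tt), tolerance = 0.02)
  ## total mass conserved exactly
  expect_equal(sum(out$a_pr) * g$dx[1], 1, tolerance = 1e-12)
})

test_that("closed-domain transport conserves every species to 1e-10", {
  g <- make_grid(seq(0, 1e-4, length.out = 13),
                 seq(0, 0.5e-4, length.out = 9), mode = "planar")
  set.seed(7)
  st <- species_state(RP = 1, AP = 1)
  for (s in c("RP", "AP", "a_pr", "a_ps", "PT", "TB", "AT"))
    st[[s]] <- matrix(runif(g$nx * g$ny, 0.5, 2) * 1e12, g$nx, g$ny)
  V <- cell_volumes(g)
  tot0 <- vapply(st[1:7], function(m) sum(m * V), numeric(1))
  dt <- 0.2 * min(g$dx, g$dy)^2 / (2 * max(p0$D))
  out <- step_species(st, still_flow(g), g, p0, dt = dt, nsteps = 1000L)
  tot1 <- vapply(out[1:7], function(m) sum(m * V), numeric(1))
  expect_true(all(abs(tot1 - tot0) / tot0 < 1e-10))
})

test_that("deposited species never advect", {
  fx <- make_fixture("advect1d")
  fl <- solve_flow(fx$grid, params = p0, tol = 1e-10)
  st <- species_state(RP_d = 0)
  st$RP_d <- fx$C0 * 1e15
  st$AP_d <- fx$C0 * 2e15
  out <- step_species(st, fl, fx$grid, p0,
                      dt = 0.5 * fx$grid$dx[1] / fx$v, nsteps = 50L)
  expect_identical(out$RP_d, st$RP_d)
  expect_identical(out$AP_d, st$AP_d)
  expect_identical(out$AP_s, st$AP_s)
})

test_that("a time step beyond the stability bound is rejected with advice", {
  fx <- make_fixture("advect1d")
  fl <- solve_flow(fx$grid, params = p0, tol = 1e-10)
  st <- species_state(a_pr = 0)
  st$a_pr <- fx$C0
  dt_bad <- 10 * fx$grid$dx[1] / fx$v
  expect_error(step_species(st, fl, fx$grid, p0, dt = dt_bad),
               "stability")
})

test_that("operator splitting error shrinks at least first order in dt", {
  ## uniform advection of a decaying pulse: C(x,t) = C0(x - vt) exp(-k t)
  fx <- make_fixture("advect1d", n = 100L)
  fl <- solve_flow(fx$grid, params = p0, tol = 1e-10)
  k1 <- 0.5
  pdec <- apply_scenario_overrides(p0, list(k1 = c(TxA2 = k1), s_pj = 0))
  st <- species_state(a_ps = 0)
  st$a_ps <- fx$C0
  run <- function(nsteps) {
    dt <- 0.1 / nsteps
    out <- st
    rates <- rate_bundle()
    for (i in seq_len(nsteps))
      out <- step_species(out, fl, fx$grid, pdec, dt = dt, rates = rates)
    out$a_ps
  }
  ## reference: very fine steps
  ref <- run(256L)
  e1 <- max(abs(run(16L) - ref))
  e2 <- max(abs(run(32L) - ref))
  expect_lt(e2, e1 / 1.5)
})

test_that("thrombus fraction tracks the deposited species", {
  st <- species_state(RP_d = 0)
  expect_equal(update_thrombus_fraction(st, p0)$phi, 0)
  st$AP_d <- p0$PLT_max
  expect_equal(update_thrombus_fraction(st, p0)$phi, 1)
  st$AP_d <- 2.518e15
  expect_equal(update_thrombus_fraction(st, p0)$phi, 0.1, tolerance = 1e-3)
  ## mask uses the propagation threshold by default
  st$AP_d <- 0.3 * p0$PLT_max
  expect_true(update_thrombus_fraction(st, p0)$mask)
  st$AP_d <- 0.1 * p0$PLT_max
  expect_false(update_thrombus_fraction(st, p0)$mask)
})

test_that("species injection adds mass and respects zero rate", {
  st <- species_state(a_pr = 5)
  port <- boundary_patch(9, kind = "injection_port")
  same <- inject_species(st, port, "a_pr", rate = 0)
  expect_identical(same$a_pr, st$a_pr)
  more <- inject_species(st, port, "a_pr", rate = 10, dt = 2,
                         area = 3, volume = 4)
  expect_equal(more$a_pr, st$a_pr + 10 * 2 * 3 / 4)
  expect_error(inject_species(st, port, "RP_d", rate = 1), "unknown")
})
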