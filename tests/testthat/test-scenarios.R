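p0 <- load_defaults()

test_that("vessel scenario encodes the benchmark conditions", {
  sc <- build_vessel_scenario()
  expect_equal(sc$config$cin[["AP"]] / sc$config$cin[["RP"]], 0.01)
  expect_equal(sc$config$cin[["RP"]], 6e14)
  expect_equal(sc$config$cin[["PT"]], 1.1e6)
  expect_equal(sc$config$cin[["AT"]], 2.844e6)
  ## injury patch carries the published material coefficients
  inj <- sc$grid$patches[sc$grid$patches$kind == "injury", ]
  expect_equal(inj$k_rpd_b, 4.0e-5)
  expect_equal(inj$k_apd_b, 4.0e-4)
  expect_equal(inj$tau_emb_b, 1.0)
  ## healthy endothelium deposits nothing
  wall <- sc$grid$patches[sc$grid$patches$kind == "wall", ]
  expect_equal(wall$k_rpd_b + wall$k_apd_b, 0)
  ## one injection port face
  expect_equal(sum(sc$grid$wall_faces$patch == 3L), 1L)
  ## mesh scale halves cell counts in each direction
  a <- build_vessel_scenario(mesh_scale = 0.5)
  b <- build_vessel_scenario(mesh_scale = 0.25)
  expect_equal(a$grid$nx, 2L * b$grid$nx)
  expect_equal(a$grid$ny, 2L * b$grid$ny)
  ## pressure drive sized for the mean velocity at phi = 0
  expect_equal(sc$config$pressure_drop,
               8 * sc$params$mu_f * 0.5e-3 * 800e-6 / (0.06e-3 / 2)^2)
  expect_error(build_vessel_scenario(overrides = list(bogus = 1)),
               "unknown")
})

test_that("blocking all agonists forces Omega to zero everywhere", {
  sc <- build_vessel_scenario(
    overrides = list(blocked_agonists = c("ADP", "TxA2", "TB")))
  expect_equal(agonist_weight(1e9, 1e9, 1e9, sc$params), 0)
})

test_that("crevice scenario encodes the benchmark conditions", {
  sc <- build_crevice_scenario(L_c = 0.075e-3)
  expect_equal(sc$config$cin[["RP"]], 2.5e14)
  expect_equal(sc$config$cin[["AP"]], 1e13)
  ti <- sc$grid$patches
  expect_equal(ti$k_rpd_b, 1.0e-20)
  expect_equal(ti$k_apd_b, 1.0e-5)
  expect_equal(ti$tau_emb_b, 0.1)
  ## heparinized in-vitro blood
  expect_equal(sc$params$H, 0.1e6)
  ## crevice depth carved below the channel floor
  expect_lt(min(sc$grid$yf), -0.12e-3)
  expect_true(any(sc$grid$solid))
  ## the long-crevice variant has a wider fluid notch
  lc2 <- build_crevice_scenario(L_c = 0.137e-3)
  open1 <- sum(!sc$grid$solid[, sc$grid$yc < 0])
  expect_gt(sum(!lc2$grid$solid[, lc2$grid$yc < 0]), open1)
  expect_error(build_crevice_scenario(L_c = -1))
  ## resting-platelet wall flux is negligible next to the activated flux
  patch <- boundary_patch(1, k_rpd_b = ti$k_rpd_b, k_apd_b = ti$k_apd_b,
                          tau_emb_b = ti$tau_emb_b)
  st <- species_state(RP = 2.5e14, AP = 1e13)
  bf <- boundary_fluxes(patch, st, 0, sc$params)
  expect_lt(abs(bf$flux$RP) / abs(bf$flux$AP), 1e-10)
})

test_that("a zero-length run returns the initial state unchanged", {
  sc <- build_vessel_scenario()
  res <- run_simulation(sc, t_end = 0)
  expect_false(res$occluded)
  expect_equal(res$morphometrics$height, 0)
  expect_equal(res$state$RP[2, 2], 6e14)
  expect_equal(sum(res$state$AP_d), 0)
})

test_that("healthy endothelium without injection grows no thrombus", {
  sc <- build_vessel_scenario(inject_adp = FALSE,
                              injury_k_rpd_b = 0, injury_k_apd_b = 0)
  res <- run_simulation(sc, t_end = 30)
  expect_false(res$occluded)
  expect_equal(max(res$phi), 0)
  expect_equal(utils::tail(res$morphometrics$volume, 1), 0)
})

test_that("morphometrics measure synthetic deposits exactly", {
  g <- make_grid(seq(0, 100e-6, length.out = 41),
                 seq(0, 30e-6, length.out = 16), mode = "axisymmetric")
  phi <- matrix(0, 40, 15)
  expect_equal(morphometrics(phi, g)$height, 0)
  expect_equal(morphometrics(phi, g)$volume, 0)
  ## rectangular plug: 10 columns x 4 rows at the wall, phi = 1
  phi[11:20, 12:15] <- 1
  m <- morphometrics(phi, g, threshold = 0.2)
  expect_equal(m$height, 4 * 2e-6)
  expect_equal(m$length, 10 * 2.5e-6)
  expect_equal(m$aspect, 25e-6 / 8e-6)
  ## volume: phi-weighted axisymmetric integral with the 2 pi factor
  V <- cell_volumes(g)
  expect_equal(m$volume, 2 * pi * sum(phi * V))
})

test_that("occlusion detection distinguishes mural from spanning deposits", {
  fx <- make_fixture("phi_spanning_disc", n = 16L, nz = 32L)
  g <- fx$grid
  expect_false(detect_occlusion(fx$phi * 0, grid = g)$occluded)
  expect_true(detect_occlusion(fx$phi, grid = g)$occluded)
  ## a mural deposit that leaves a free lumen is not occlusive
  mural <- fx$phi
  mural[, 1:8] <- 0
  expect_false(detect_occlusion(mural, grid = g)$occluded)
})

test_that("simulations are deterministic and restartable", {
  sc <- build_vessel_scenario()
  a <- run_simulation(sc, t_end = 12)
  b <- run_simulation(sc, t_end = 12)
  expect_identical(a$morphometrics, b$morphometrics)
  expect_identical(a$state$AP_d, b$state$AP_d)
  ## bitwise-exact restart from a checkpoint
  half <- run_simulation(sc, t_end = 6)
  init <- list(C = unname(half$state), u = half$flow$u, v = half$flow$v,
               p = half$flow$p)
  cont <- run_simulation(sc, t_end = 12, init = init, t0 = 6)
  expect_identical(cont$state$AP_d, a$state$AP_d)
  expect_equal(utils::tail(cont$morphometrics$volume, 1),
               utils::tail(a$morphometrics$volume, 1), tolerance = 1e-12)
})

test_that("the blocking experiment tabulates cases deterministically", {
  sc <- build_vessel_scenario(inject_adp = FALSE)
  tab <- blocking_experiment(sc, cases = list(none = character(0),
                                              all = c("ADP", "TxA2", "TB")),
                             t_max = 30)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$case, c("none", "all"))
  expect_true(all(is.na(tab$occlusion_time)))   # far too short a horizon
  expect_gt(tab$volume_final[1], tab$volume_final[2])
})
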