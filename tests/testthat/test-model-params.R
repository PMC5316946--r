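test_that("defaults reproduce the published parameter set", {
  p <- load_defaults()
  expect_equal(p$tau_emb, 30)
  expect_equal(unname(p$w), c(1, 3.3, 30))
  expect_equal(unname(p$a_crit), c(1.0e6, 1.2e6, 0.1e6))
  expect_equal(p$k_ra, 3.0e-6)
  expect_equal(p$k_aa, 3.0e-5)
  expect_equal(p$lambda_j, 2.4e-8)
  expect_equal(p$theta, 1.0)
  expect_equal(p$eps, 9.11e-3)
  expect_equal(p$phi_at, 3.69e-15)
  expect_equal(p$phi_rt, 6.5e-16)
  expect_equal(p$k1_T, 13.333)
  expect_equal(p$K_AT, 1.0e5)
  expect_equal(p$K_T, 3.5e4)
  expect_equal(p$PLT_s_max, 7e10)
  expect_equal(p$Dia_PLT, 2.78e-6)
  expect_equal(p$PLT_max, 7e10 / 2.78e-6, tolerance = 1e-12)
  expect_equal(p$PLT_max, 2.518e16, tolerance = 1e-3)
  expect_equal(p$f_stb, 0)
  expect_equal(p$C2, 2e9)
  expect_equal(p$mu_f, 3.5e-3)
  expect_equal(p$rho_f0, 1060)
  expect_equal(p$t_ct, 1)
  expect_equal(unname(p$D[c("a_pr", "PT", "AT")]),
               c(2.57e-10, 3.32e-11, 3.49e-11))
})

test_that("scenario overrides apply, validate, and reject bad input", {
  p <- load_defaults()
  q <- apply_scenario_overrides(
    p, list(k_rpd_b = 4.0e-5, k_apd_b = 4.0e-4, tau_emb_b = 1.0))
  expect_equal(q$k_rpd_b, 4.0e-5)
  expect_equal(q$k_apd_b, 4.0e-4)
  expect_equal(q$tau_emb_b, 1.0)
  ## untouched fields keep their values
  expect_equal(q$k_ra, p$k_ra)
  ## empty overrides are the identity
  expect_identical(apply_scenario_overrides(p, list()), p)
  ## partial named-vector override
  r <- apply_scenario_overrides(p, list(w = c(TB = 15)))
  expect_equal(unname(r$w), c(1, 3.3, 15))
  expect_error(apply_scenario_overrides(p, list(nonsense = 1)), "unknown")
  expect_error(apply_scenario_overrides(p, list(k_ra = -1)),
               "non-negative")
  expect_error(apply_scenario_overrides(p, list(theta = 2)), "theta")
  expect_error(apply_scenario_overrides(p, list(blocked_agonists = "XXX")),
               "blocked")
})

test_that("blocking an agonist disables both its weight and its source", {
  p <- apply_scenario_overrides(load_defaults(),
                                list(blocked_agonists = "ADP"))
  ## ADP no longer contributes to the activation number
  expect_equal(agonist_weight(1e9, 0, 0, p), 0)
  ## and its release source is zeroed in the bulk network
  st <- species_state(RP = 6e14, a_pr = 0)
  rates <- rate_bundle(k_apa = 1)
  expect_equal(bulk_sources(st, rates, p)$a_pr, 0)
  ## thrombin blocking zeroes generation
  pTB <- apply_scenario_overrides(load_defaults(),
                                  list(blocked_agonists = "TB"))
  st2 <- species_state(AP = 6e14, PT = 1.1e6)
  expect_equal(bulk_sources(st2, rate_bundle(), pTB)$TB, 0)
})

test_that("parameters round-trip through YAML value-identically", {
  p <- apply_scenario_overrides(
    load_defaults(), list(k_rpd_b = 4.0e-5, H = 0.1e6,
                          blocked_agonists = c("ADP", "TB")))
  q <- params_from_yaml(text = params_to_yaml(p))
  expect_equal(q, p)
})

test_that("shear-stress unit conversions are exact inverses", {
  x <- c(0, 0.35, 3, 30)
  expect_identical(dyne_to_pa(pa_to_dyne(x)), x)
  expect_equal(pa_to_dyne(0.373), 3.73)
})
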