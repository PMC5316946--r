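p0 <- load_defaults()

test_that("weighted agonist number matches hand-evaluated sums", {
  expect_equal(agonist_weight(0, 0, 0, p0), 0)
  expect_equal(agonist_weight(1.0e6, 0, 0, p0), 1.0)
  expect_equal(agonist_weight(0, 0, 0.1e6, p0), 30)
  ## mixed: 1*0.5 + 3.3*(0.6e6/1.2e6) + 30*(0.05e6/0.1e6)
  expect_equal(agonist_weight(0.5e6, 0.6e6, 0.05e6, p0),
               0.5 + 3.3 * 0.5 + 30 * 0.5)
  ## linear in each argument
  expect_equal(agonist_weight(2e6, 0, 0, p0),
               2 * agonist_weight(1e6, 0, 0, p0))
})

test_that("chemical activation switches at Omega = 1 and is capped", {
  expect_equal(chemical_activation_rate(0.5, p0), 0)
  expect_equal(chemical_activation_rate(0.999, p0), 0)
  expect_equal(chemical_activation_rate(2, p0), 2)      # t_ct = 1 s
  cap <- log(100) / p0$t_act
  expect_equal(chemical_activation_rate(100, p0), cap)
  expect_equal(cap, 9.2103, tolerance = 1e-4)
  ## monotone non-decreasing
  om <- seq(0, 50, length.out = 200)
  expect_true(all(diff(chemical_activation_rate(om, p0)) >= 0))
})

test_that("shear activation follows the empirical power-law time", {
  expect_equal(shear_activation_rate(0, p0), 0)
  ## characteristic time at 100 dyne/cm^2 is 4e6 * 100^-2.3 ~ 100.5 s
  t_ct_spa <- 4.0e6 * 100^-2.3
  expect_equal(t_ct_spa, 100.48, tolerance = 1e-3)
  expect_equal(shear_activation_rate(100, p0), 1 / t_ct_spa)
  expect_lt(shear_activation_rate(50, p0), shear_activation_rate(100, p0))
  ## capped at the same physical-activation ceiling
  expect_equal(shear_activation_rate(1e6, p0), log(100) / p0$t_act)
})

test_that("embolization rate matches an independent evaluation and scales", {
  expect_equal(embolization_rate(0, 30, p0), 0)
  ## independently coded copy of the law
  f_ref <- function(tau, tc) {
    0.5 * (tau / 10 / 3.5e-3) * (tau / tc) * (1 - exp(-0.0095 * tau))
  }
  taus <- seq(0, 500, by = 2.5)
  expect_equal(embolization_rate(taus, 30, p0), f_ref(taus, 30))
  ## monotone non-decreasing over the sweep
  expect_true(all(diff(embolization_rate(taus, 30, p0)) >= 0))
  ## weaker surfaces shed faster
  expect_true(all(embolization_rate(taus[-1], 1, p0) >
                    embolization_rate(taus[-1], 30, p0)))
  ## pluggable law
  expect_equal(embolization_rate(10, 30, p0,
                                 law = function(tau, tc, p) tau / tc),
               1 / 3)
})

test_that("Griffith template inhibition matches an independent evaluation", {
  expect_equal(thrombin_inhibition_rate(2.844e6, 0, p0), 0)  # H = 0 default
  pH <- apply_scenario_overrides(p0, list(H = 0.1e6))
  expect_equal(thrombin_inhibition_rate(0, 0, pH), 0)
  ## independent one-line evaluation of the rapid-equilibrium template form
  g_ref <- function(AT, TBU, H = 1e5, a = 1, KAT = 1e5, KT = 3.5e4,
                    k1 = 13.333, eps = 9.11e-3) {
    Tn <- eps * TBU
    k1 * H * AT / (a * KAT * KT) /
      (1 + AT / KAT + Tn / KT + AT * Tn / (a * KAT * KT))
  }
  for (AT in c(1e4, 2.844e6)) {
    for (TB in c(0, 1e4, 5e5)) {
      expect_equal(thrombin_inhibition_rate(AT, TB, pH), g_ref(AT, TB))
    }
  }
  ## order of magnitude: strongly heparinized plasma clears thrombin fast
  expect_gt(thrombin_inhibition_rate(2.844e6, 0, pH), 10)
})

test_that("bulk sources conserve platelets for arbitrary states and rates", {
  set.seed(42)
  for (rep in 1:25) {
    st <- species_state(RP = runif(1, 0, 1e15), AP = runif(1, 0, 1e14),
                        a_pr = runif(1, 0, 1e7), a_ps = runif(1, 0, 1e6),
                        PT = runif(1, 0, 1.1e6), TB = runif(1, 0, 1e5),
                        AT = runif(1, 0, 2.8e6), RP_d = runif(1, 0, 1e16),
                        AP_d = runif(1, 0, 1e16), AP_s = runif(1, 0, 1e15))
    rates <- rate_bundle(k_apa = runif(1, 0, 9), k_spa = runif(1, 0, 1),
                         f_emb = runif(1, 0, 5), Gamma = runif(1, 0, 40),
                         k_rpd = runif(1, 0, 2), k_apd = runif(1, 0, 20))
    d <- bulk_sources(st, rates, p0)
    tot <- d$RP + d$AP + d$RP_d + d$AP_d + d$AP_s
    scale <- max(abs(unlist(d[c("RP", "AP", "RP_d", "AP_d", "AP_s")])), 1)
    expect_lt(abs(tot) / scale, 1e-12)
  }
})

test_that("bulk sources honor stated stoichiometry and signs", {
  ## no thrombin -> no ATIII consumption
  st <- species_state(RP = 6e14, AP = 6e12, PT = 1.1e6, AT = 2.844e6)
  d <- bulk_sources(st, rate_bundle(Gamma = 30), p0)
  expect_equal(d$AT, 0)
  ## closed system: activation only inter-converts RP and AP
  d2 <- bulk_sources(st, rate_bundle(k_apa = 2), p0)
  expect_equal(d2$RP + d2$AP, 0)
  ## thrombin stoichiometry: with Gamma = 0, dTB (U) = -dPT / eps
  st3 <- species_state(RP = 6e14, AP = 6e14, PT = 1.1e6, RP_d = 1e15,
                       AP_d = 5e15)
  d3 <- bulk_sources(st3, rate_bundle(), p0)
  expect_equal(d3$TB, -d3$PT / p0$eps)
  ## deposition is packing-limited: a saturated cell accepts nothing
  st4 <- species_state(RP = 6e14, AP = 6e14, AP_d = p0$PLT_max)
  d4 <- bulk_sources(st4, rate_bundle(k_rpd = 1, k_apd = 1), p0)
  expect_equal(d4$RP, 0)
  expect_equal(d4$AP, 0)
})

test_that("well-mixed network integrates with conservation and known limits", {
  ## all rates zero (resting platelets only, no agonists): state constant
  stc <- species_state(RP = 6e14, PT = 1.1e6, AT = 2.844e6)
  tr0 <- integrate_wellmixed(stc, p0, t_end = 5)
  expect_equal(tr0[nrow(tr0), -1], tr0[1, -1], tolerance = 1e-10,
               ignore_attr = TRUE)

  ## sustained Omega >> 1: RP decays at the activation cap
  stA <- make_fixture("wellmixed0d")$state
  stA$a_pr <- 1e9      # Omega = 1000, far above the cap
  trA <- integrate_wellmixed(stA, p0, t_end = 0.6, dt_max = 0.05)
  cap <- log(100) / p0$t_act
  ref <- stA$RP * exp(-cap * trA$time)
  expect_equal(trA$RP, as.numeric(ref), tolerance = 1e-6)

  ## ADP release bookkeeping: activating N platelets releases lambda * N
  pNoInh <- apply_scenario_overrides(p0, list(k1 = c(ADP = 0)))
  stB <- species_state(RP = 6e14, a_ps = 2e6)  # TxA2 drives activation
  trB <- integrate_wellmixed(stB, pNoInh, t_end = 30, dt_max = 0.1)
  n_act <- trB$RP[1] - trB$RP[nrow(trB)]
  expect_equal(trB$a_pr[nrow(trB)] - trB$a_pr[1], p0$lambda_j * n_act,
               tolerance = 1e-6)

  ## platelet-count conservation in a closed 0D system
  tot <- trB$RP + trB$AP + trB$RP_d + trB$AP_d + trB$AP_s
  expect_lt(max(abs(tot - tot[1])) / tot[1], 1e-10)
})
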