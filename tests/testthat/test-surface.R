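p0 <- load_defaults()

test_that("surface coverage is the free fraction of the wall", {
  expect_equal(surface_coverage(boundary_patch(1)), 1)
  full <- boundary_patch(1, RP_d_s = 3e10, AP_d_s = 3e10, AP_s_s = 1e10)
  expect_equal(surface_coverage(full), 0)
  half <- boundary_patch(1, AP_d_s = 3.5e10)
  expect_equal(surface_coverage(half), 0.5)
  expect_error(boundary_patch(1, RP_d_s = 8e10), "exceed")
})

test_that("boundary fluxes implement the wall reaction set", {
  injury <- boundary_patch(2, kind = "injury", k_rpd_b = 4.0e-5,
                           k_apd_b = 4.0e-4, tau_emb_b = 1.0)
  st <- species_state(RP = 6e14, AP = 6e12, PT = 1.1e6, AT = 2.844e6)
  bf <- boundary_fluxes(injury, st, tau_wall = 0, params = p0)
  ## resting-platelet adhesion flux on a pristine injured wall
  expect_equal(bf$flux$RP, -4.0e-5 * 6e14)
  expect_equal(bf$flux$RP, -2.4e10)
  expect_equal(bf$flux$AP, -4.0e-4 * 6e12)
  ## no ATIII wall reaction, ever
  expect_equal(bf$flux$AT, 0)
  stZ <- species_state(RP = 1e15, AP = 1e14, a_pr = 1e9, TB = 1e6,
                       PT = 1e6, AT = 1e6)
  expect_equal(boundary_fluxes(injury, stZ, 50, p0)$flux$AT, 0)
  ## saturated surface: adhesion stops
  sat <- boundary_patch(2, kind = "injury", k_rpd_b = 4.0e-5,
                        k_apd_b = 4.0e-4, tau_emb_b = 1.0,
                        AP_d_s = 7e10)
  bfs <- boundary_fluxes(sat, st, tau_wall = 0, params = p0)
  expect_equal(bfs$S, 0)
  expect_equal(bfs$flux$RP, 0)
  ## contact activation (theta = 1) routes deposited RP to AP_d_s and
  ## releases ADP
  expect_equal(bf$ddt_surface$RP_d_s, 0)
  expect_equal(bf$ddt_surface$AP_d_s, 2.4e10 + 4.0e-4 * 6e12)
  expect_equal(bf$flux$a_pr, p0$lambda_j * 2.4e10)
})

test_that("wall platelet balance closes: free loss equals surface gain", {
  patch <- boundary_patch(3, kind = "wall", k_rpd_b = 1e-5, k_apd_b = 2e-5,
                          tau_emb_b = 0.5, RP_d_s = 1e10, AP_d_s = 2e10)
  st <- species_state(RP = 3e14, AP = 2e13, a_pr = 5e5, PT = 1e6,
                      AT = 2e6)
  bf <- boundary_fluxes(patch, st, tau_wall = 2.5, params = p0)
  net <- bf$flux$RP + bf$flux$AP +
    bf$ddt_surface$RP_d_s + bf$ddt_surface$AP_d_s + bf$ddt_surface$AP_s_s
  expect_lt(abs(net) / abs(bf$flux$RP), 1e-10)
})

test_that("boundary embolization uses the material characteristic stress", {
  injury <- boundary_patch(2, k_rpd_b = 4e-5, k_apd_b = 4e-4,
                           tau_emb_b = 1.0)
  crevice <- boundary_patch(4, k_rpd_b = 1e-20, k_apd_b = 1e-5,
                            tau_emb_b = 0.1)
  expect_equal(boundary_embolization_rate(0, injury, p0), 0)
  tau <- c(0.5, 2, 10)
  expect_true(all(boundary_embolization_rate(tau, crevice, p0) >
                    boundary_embolization_rate(tau, injury, p0)))
  ## healthy endothelium: zero deposition regardless of embolization
  healthy <- boundary_patch(1, k_rpd_b = 0, k_apd_b = 0, tau_emb_b = 30)
  st <- species_state(RP = 6e14, AP = 6e12)
  bf <- boundary_fluxes(healthy, st, tau_wall = 3.7, params = p0)
  expect_equal(bf$flux$RP, 0)
  expect_equal(bf$ddt_surface$AP_d_s, 0)
})

test_that("propagation rates act on one cell layer around the thrombus", {
  n <- 7L
  h <- 2e-6
  g <- make_grid(seq(0, n * h, by = h), seq(0, n * h, by = h),
                 mode = "planar")
  phi <- matrix(0, n, n)
  pr0 <- propagation_rates(phi, g, p0)
  expect_true(all(pr0$k_rpd == 0))

  phi[4, 4] <- 0.5   # one thrombus cell
  pr <- propagation_rates(phi, g, p0)
  ## exactly the four face neighbours receive k_ra / h
  hits <- which(pr$k_rpd > 0, arr.ind = TRUE)
  expect_equal(nrow(hits), 4L)
  expect_setequal(paste(hits[, 1], hits[, 2]),
                  c("3 4", "5 4", "4 3", "4 5"))
  expect_equal(unname(pr$k_rpd[3, 4]), p0$k_ra / h)
  ## activated-platelet rate is 10x the resting one everywhere
  nz <- pr$k_rpd > 0
  expect_equal(pr$k_apd[nz] / pr$k_rpd[nz],
               rep(p0$k_aa / p0$k_ra, sum(nz)))
  expect_equal(p0$k_aa / p0$k_ra, 10)
  ## locality: cells two layers away receive nothing
  expect_equal(pr$k_rpd[1, 1], 0)
  expect_equal(pr$k_rpd[4, 6], 0)
  ## sub-threshold deposits do not propagate
  phi2 <- matrix(0.15, n, n)
  expect_true(all(propagation_rates(phi2, g, p0)$k_rpd == 0))
})

test_that("axisymmetric propagation uses true face areas and volumes", {
  g <- make_grid(seq(0, 20e-6, by = 2e-6), seq(0, 10e-6, by = 2e-6),
                 mode = "axisymmetric")
  phi <- matrix(0, g$nx, g$ny)
  phi[5, 3] <- 0.5
  pr <- propagation_rates(phi, g, p0)
  ## axial neighbours: A/V = (dy * rc) / (dx * dy * rc) = 1/dx
  expect_equal(unname(pr$k_rpd[4, 3]), p0$k_ra / g$dx[4])
  ## radial neighbour above: A/V = dx * rf[4] / (dx * dy * rc[4])
  rf <- g$yf[4]
  expect_equal(unname(pr$k_rpd[5, 4]),
               p0$k_ra * rf / (g$dy[4] * g$yc[4]))
})
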