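## Bulk (volumetric) reaction network: activation, embolization, thrombin
## kinetics and the full 10-species source vector. All functions are pure and
## vectorized over fields; the compiled PDE driver evaluates the same
## formulas cell-wise (cross-checked in the test suite).

SPECIES <- c("RP", "AP", "a_pr", "a_ps", "PT", "TB", "AT",
             "RP_d", "AP_d", "AP_s")

#' Create a species state
#'
#' A named container for the ten model species: free-stream resting and
#' activated platelets (`RP`, `AP`, PLT/m^3), ADP (`a_pr`), thromboxane A2
#' (`a_ps`), prothrombin (`PT`) and antithrombin III (`AT`) in nmol/m^3,
#' thrombin (`TB`, U/m^3), and the non-advecting deposited states
#' (`RP_d`, `AP_d`, `AP_s`, PLT/m^3). Each entry may be a scalar (0D) or a
#' field over grid cells.
#'
#' @param ... named species values; unspecified species default to 0.
#' @return a named list of class `species_state`.
#' @export
species_state <- function(...) {
  args <- list(...)
  bad <- setdiff(names(args), SPECIES)
  if (length(bad))
    stop("unknown species: ", paste(bad, collapse = ", "), call. = FALSE)
  n <- if (length(args)) max(lengths(args)) else 1L
  s <- stats::setNames(lapply(SPECIES, function(k) {
    v <- args[[k]]
    if (is.null(v)) rep(0, n) else rep(v, length.out = n)
  }), SPECIES)
  if (any(unlist(s) < 0))
    stop("species concentrations must be non-negative", call. = FALSE)
  structure(s, class = "species_state")
}

#' Weighted agonist activation number
#'
#' Omega = sum_j w_j [a_j] / a_crit_j over the non-blocked agonists
#' (ADP, TxA2, thrombin). Resting platelets activate chemically when
#' Omega >= 1.
#'
#' @param a_pr ADP concentration, nmol/m^3.
#' @param a_ps TxA2 concentration, nmol/m^3.
#' @param TB thrombin concentration, U/m^3.
#' @param params a `thrombo_params` object.
#' @return dimensionless Omega (vectorized).
#' @export
agonist_weight <- function(a_pr, a_ps, TB, params) {
  eff <- effective_kinetics(params)
  w <- eff$w
  ac <- params$a_crit
  w[["ADP"]] * a_pr / ac[["ADP"]] +
    w[["TxA2"]] * a_ps / ac[["TxA2"]] +
    w[["TB"]] * TB / ac[["TB"]]
}

## 99%-activation ceiling: the reaction cannot outpace the physical
## activation procedure, so rates are capped at -ln(0.01)/t_act.
activation_cap <- function(params) log(100) / params$t_act

#' Chemical platelet activation rate
#'
#' Zero below the activation threshold (Omega < 1); Omega/t_ct above it,
#' capped at ln(100)/t_act so that at most 99% of platelets activate within
#' the physical activation time t_act.
#'
#' @param Omega weighted agonist number from [agonist_weight()].
#' @param params a `thrombo_params` object.
#' @return k_apa in 1/s (vectorized).
#' @export
chemical_activation_rate <- function(Omega, params) {
  k <- ifelse(Omega < 1, 0, Omega / params$t_ct)
  pmin(k, activation_cap(params))
}

#' Shear-induced platelet activation rate
#'
#' Built from the empirical characteristic time t_ct_spa = 4.0e6 tau^-2.3
#' with tau in dyne/cm^2: k_spa = 1/t_ct_spa = tau^2.3/4.0e6, capped by the
#' same ln(100)/t_act ceiling as chemical activation. Vanishes as tau -> 0
#' and increases monotonically with tau.
#'
#' @param tau scalar shear stress in dyne/cm^2.
#' @param params a `thrombo_params` object.
#' @return k_spa in 1/s (vectorized).
#' @export
shear_activation_rate <- function(tau, params) {
  stopifnot(all(tau >= 0))
  pmin(tau^2.3 / 4.0e6, activation_cap(params))
}

#' Shear-driven embolization rate
#'
#' Clearance rate of deposited platelets by the flowing fluid. The default
#' law is built from the slip velocity of the flow at the mid-height of a
#' surface platelet (gamma Dia_PLT / 2, with gamma = tau/mu_f the local
#' shear rate) normalized by the platelet diameter, scaled by the excess of
#' the acting shear stress over the characteristic embolization stress of
#' the deposit or material (tau/tau_char) and by the empirical non-adhesion
#' fraction 1 - exp(-0.0095 tau) with tau in dyne/cm^2:
#'
#'   f_emb = (gamma / 2) * (tau_dyne / tau_char) * (1 - exp(-0.0095 tau_dyne))
#'
#' Zero at tau = 0, monotone increasing in tau, and scaling with
#' 1/tau_char so weaker surfaces shed faster. The functional body is
#' pluggable via `law`.
#'
#' @param tau shear stress in dyne/cm^2.
#' @param tau_char characteristic embolization shear stress in dyne/cm^2
#'   (`tau_emb` for bulk thrombus, `tau_emb_b` for a wall material).
#' @param params a `thrombo_params` object.
#' @param law optional replacement function `(tau, tau_char, params)`.
#' @return f_emb in 1/s (vectorized).
#' @export
embolization_rate <- function(tau, tau_char, params, law = NULL) {
  stopifnot(all(tau >= 0), all(tau_char > 0))
  if (!is.null(law)) return(law(tau, tau_char, params))
  gamma <- dyne_to_pa(tau) / params$mu_f
  0.5 * gamma * (tau / tau_char) * (1 - exp(-0.0095 * tau))
}

#' Heparin-catalyzed thrombin inhibition rate (Griffith template model)
#'
#' First-order neutralization rate Gamma of thrombin by antithrombin III,
#' catalyzed by heparin, in the rapid-equilibrium template form: heparin
#' binds ATIII (dissociation constant K_AT) and thrombin (K_T), the ternary
#' complex (affinity modulation alpha) reacts at k1_T, and the rate is
#' normalized per unit thrombin:
#'
#'   Gamma = k1_T [H] ([AT] T' / (alpha K_AT K_T)) /
#'           (1 + [AT]/K_AT + T'/K_T + [AT] T'/(alpha K_AT K_T)) / T'
#'
#' with T' = eps [TB] the thrombin concentration in nmol/m^3. Gamma = 0
#' whenever heparin or ATIII is absent.
#'
#' @param AT antithrombin III concentration, nmol/m^3.
#' @param TB thrombin concentration, U/m^3 (enters the template occupancy;
#'   the limiting rate at TB -> 0 is well defined and used there).
#' @param params a `thrombo_params` object.
#' @return Gamma in 1/s (vectorized).
#' @export
thrombin_inhibition_rate <- function(AT, TB = 0, params) {
  stopifnot(all(AT >= 0), all(TB >= 0))
  Tn <- params$eps * TB  # nmol/m^3
  num <- params$k1_T * params$H * AT / (params$alpha * params$K_AT * params$K_T)
  den <- 1 + AT / params$K_AT + Tn / params$K_T +
    AT * Tn / (params$alpha * params$K_AT * params$K_T)
  num / den
}

#' Bundle of local reaction rates
#'
#' @param k_apa,k_spa chemical and shear activation rates, 1/s.
#' @param f_emb embolization rate, 1/s.
#' @param Gamma thrombin inhibition rate, 1/s.
#' @param k_rpd,k_apd bulk deposition (propagation) rates, 1/s, supplied by
#'   [propagation_rates()] near the thrombus interface and zero elsewhere.
#' @return a named list of class `rate_bundle`.
#' @export
rate_bundle <- function(k_apa = 0, k_spa = 0, f_emb = 0, Gamma = 0,
                        k_rpd = 0, k_apd = 0) {
  r <- list(k_apa = k_apa, k_spa = k_spa, f_emb = f_emb, Gamma = Gamma,
            k_rpd = k_rpd, k_apd = k_apd)
  if (any(unlist(r) < 0)) stop("all rates must be non-negative", call. = FALSE)
  structure(r, class = "rate_bundle")
}

#' Volumetric source terms for all ten species
#'
#' The reaction right-hand side S_i of the coupled network. Platelet states
#' inter-convert by chemical/shear activation (k_apa, k_spa), deposit near
#' the thrombus interface (k_rpd, k_apd, packing-limited by
#' psi = 1 - (RP_d+AP_d+AP_s)/PLT_max), embolize back to the free stream
#' (f_emb) and stabilize (f_stb). Contact activation converts the fraction
#' theta of depositing resting platelets directly to AP_d. ADP is released
#' by every activation event (lambda_j per platelet), TxA2 is synthesized by
#' activated platelets, thrombin is generated from prothrombin on
#' procoagulant platelet membranes — free and deposited activated platelets
#' at phi_at, deposited resting platelets at phi_rt (eps converts U to nmol
#' for the prothrombin and ATIII budgets) — and neutralized at rate Gamma.
#' The platelet states sum to zero: total platelet count is conserved by
#' the reactions.
#'
#' @param state a [species_state()].
#' @param rates a [rate_bundle()].
#' @param params a `thrombo_params` object.
#' @return named list of dC/dt, same shapes as `state`.
#' @export
bulk_sources <- function(state, rates, params) {
  eff <- effective_kinetics(params)
  th <- params$theta
  psi <- pmax(0, pmin(1, 1 - (state$RP_d + state$AP_d + state$AP_s) /
                        params$PLT_max))
  kact <- rates$k_apa + rates$k_spa
  dep_RP <- psi * rates$k_rpd * state$RP   # resting deposition flux
  dep_AP <- psi * rates$k_apd * state$AP   # activated deposition flux
  act_RPd <- kact * state$RP_d             # activation of deposited resting
  ## thrombin generation requires the procoagulant platelet membrane:
  ## activated platelets (free or deposited) at phi_at, and deposited
  ## resting platelets at phi_rt; free resting platelets do not contribute
  ## (their inclusion would make resting blood self-activate in transit,
  ## contrary to the localized thrombin fields the model is meant to give)
  gen_TB <- state$PT * (eff$phi_at * (state$AP + state$AP_d) +
                          eff$phi_rt * state$RP_d)  # U/m^3/s
  list(
    RP = -kact * state$RP - dep_RP + rates$f_emb * state$RP_d,
    AP = kact * state$RP - dep_AP + rates$f_emb * state$AP_d,
    a_pr = eff$lambda_j * (kact * state$RP + act_RPd + th * dep_RP) -
      params$k1[["ADP"]] * state$a_pr,
    a_ps = eff$s_pj * (state$AP + state$AP_d) -
      params$k1[["TxA2"]] * state$a_ps,
    PT = -params$eps * gen_TB,
    TB = gen_TB - rates$Gamma * state$TB,
    AT = -rates$Gamma * params$eps * state$TB,
    RP_d = (1 - th) * dep_RP - act_RPd - rates$f_emb * state$RP_d,
    AP_d = th * dep_RP + dep_AP + act_RPd -
      (rates$f_emb + params$f_stb) * state$AP_d,
    AP_s = params$f_stb * state$AP_d
  )
}

#' Integrate the well-mixed (0D) reaction network
#'
#' Advances the ten-species network as a stiff ODE system at fixed shear
#' stress and fixed bulk deposition rates, with activation and inhibition
#' rates updated from the evolving state. Uses `deSolve::lsoda`.
#'
#' @param state0 initial [species_state()] (scalars).
#' @param params a `thrombo_params` object.
#' @param t_end end time, s.
#' @param dt_max maximal output/integrator step, s.
#' @param tau ambient shear stress, dyne/cm^2.
#' @param k_rpd,k_apd fixed bulk deposition rates, 1/s.
#' @param embolize_to_free if `FALSE`, embolized platelets are discarded
#'   instead of returning to the free stream (open-system variant).
#' @return data.frame with `time` and one column per species.
#' @export
integrate_wellmixed <- function(state0, params, t_end, dt_max = 0.1,
                                tau = 0, k_rpd = 0, k_apd = 0,
                                embolize_to_free = TRUE) {
  stopifnot(t_end > 0, dt_max > 0)
  y0 <- vapply(SPECIES, function(k) state0[[k]][1], numeric(1))
  kspa <- shear_activation_rate(tau, params)
  femb <- if (tau > 0) embolization_rate(tau, params$tau_emb, params) else 0
  deriv <- function(t, y, parms) {
    s <- as.list(pmax(y, 0))
    names(s) <- SPECIES
    Om <- agonist_weight(s$a_pr, s$a_ps, s$TB, params)
    rates <- rate_bundle(
      k_apa = chemical_activation_rate(Om, params), k_spa = kspa,
      f_emb = femb,
      Gamma = thrombin_inhibition_rate(s$AT, s$TB, params),
      k_rpd = k_rpd, k_apd = k_apd)
    d <- bulk_sources(s, rates, params)
    if (!embolize_to_free) {
      d$RP <- d$RP - femb * s$RP_d
      d$AP <- d$AP - femb * s$AP_d
    }
    list(vapply(SPECIES, function(k) d[[k]], numeric(1)))
  }
  times <- seq(0, t_end, by = min(dt_max, t_end))
  if (times[length(times)] < t_end) times <- c(times, t_end)
  out <- deSolve::lsoda(y0, times, deriv, parms = NULL,
                        rtol = 1e-10, atol = 1e-6, hmax = dt_max)
  df <- as.data.frame(out)
  names(df)[1] <- "time"
  if (any(vapply(df[SPECIES], function(x) any(x < -1e-12 * max(abs(x), 1)),
                 logical(1))))
    warning("negative concentrations beyond integrator tolerance")
  df
}
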