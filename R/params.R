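#' Default model parameters
#'
#' Builds the complete parameter set of the thrombosis model: platelet
#' activation times and agonist weights/thresholds, platelet-thrombus
#' aggregation and platelet-wall deposition rates, embolization
#' characteristic shear stresses, agonist release/synthesis/inhibition
#' kinetics, thrombin generation and Griffith-template inhibition constants,
#' surface and volumetric platelet capacities, the thrombus resistance
#' coefficient and fluid properties, and per-species diffusivities.
#'
#' Internal units are SI throughout; shear stress is converted to
#' dyne/cm^2 (1 Pa = 10 dyne/cm^2) only inside the empirical rate laws
#' whose printed coefficients assume those units
#' (see [shear_activation_rate()], [embolization_rate()]).
#'
#' @param overrides named list of parameter overrides (see
#'   [apply_scenario_overrides()]).
#' @return an object of class `thrombo_params` (a validated named list).
#' @examples
#' p <- load_defaults()
#' p$tau_emb     # 30 dyne/cm^2
#' p$w["TB"]     # thrombin weight, 30
#' @export
load_defaults <- function(overrides = list()) {
  p <- list(
    ## activation timing
    t_ct    = 1.0,    # s, chemical-activation characteristic time
    t_act   = 0.5,    # s, physical activation time (0.1-0.5 s range)
    ## agonist weights and critical concentrations
    w       = c(ADP = 1.0, TxA2 = 3.3, TB = 30.0),       # dimensionless
    a_crit  = c(ADP = 1.0e6, TxA2 = 1.2e6, TB = 0.1e6),  # nmol/m^3 (TB: U/m^3)
    ## aggregation (thrombus propagation) and wall deposition rates
    k_ra    = 3.0e-6,  # m/s, resting platelet-thrombus aggregation
    k_aa    = 3.0e-5,  # m/s, activated platelet-thrombus aggregation
    k_rpd_b = 0.0,     # m/s, resting platelet-wall deposition (per material)
    k_apd_b = 0.0,     # m/s, activated platelet-wall deposition (per material)
    ## embolization characteristic shear stresses, dyne/cm^2
    tau_emb   = 30.0,
    tau_emb_b = 30.0,
    ## agonist kinetics
    lambda_j = 2.4e-8,           # nmol ADP released per platelet activated
    theta    = 1.0,              # contact-activation fraction on deposition
    k1       = c(ADP = 0.0, TxA2 = log(2) / 30),  # 1/s first-order inhibition
    s_pj     = 9.5e-12,          # nmol/PLT/s TxA2 synthesis by activated PLTs
    ## thrombin generation / inhibition (Griffith template model)
    eps     = 9.11e-3,   # nmol/U, NIH-unit to SI conversion for thrombin
    phi_at  = 3.69e-15,  # m^3/nmol/PLT * U/s, generation on activated PLTs
    phi_rt  = 6.5e-16,   # m^3/nmol/PLT * U/s, generation on resting PLTs
    k1_T    = 13.333,    # 1/s, Griffith first-order rate constant
    H       = 0.0,       # nmol/m^3 heparin (0 in vivo; 0.1e6 in vitro)
    alpha   = 1.0,       # heparin affinity modulation factor
    K_AT    = 0.1e6,     # nmol/m^3, heparin/ATIII dissociation constant
    K_T     = 3.5e4,     # nmol/m^3, heparin/thrombin dissociation constant
    ## capacities and geometry of the deposit
    PLT_s_max = 7e10,     # PLT/m^2, surface capacity
    Dia_PLT   = 2.78e-6,  # m, platelet hydraulic diameter
    PLT_max   = 7e10 / 2.78e-6,  # PLT/m^3, volumetric packing limit
    f_stb     = 0.0,      # 1/s, stabilization rate (neglected)
    ## fluid and thrombus-drag properties
    C2     = 2e9,      # kg/m^3/s, resistance coefficient
    mu_f   = 3.5e-3,   # Pa s, asymptotic dynamic viscosity
    rho_f0 = 1060,     # kg/m^3, fluid density
    b_f    = 0.0,      # N/m^3, body force (zero in all scenarios)
    ## diffusivities, m^2/s; platelets are shear-enhanced: base + slope*gamma
    D_plt_base  = 1.58e-13,
    D_plt_slope = 6.0e-13,   # multiplies the shear-rate magnitude in 1/s
    D = c(a_pr = 2.57e-10, a_ps = 2.14e-10, PT = 3.32e-11,
          TB = 4.16e-11, AT = 3.49e-11),
    ## numerical/model controls shared across scenarios
    phi_prop = 0.2,    # deposit fraction triggering propagation
    phi_occ  = 0.2,    # deposit fraction counted as occlusive
    blocked_agonists = character(0)
  )
  class(p) <- "thrombo_params"
  if (length(overrides)) p <- apply_scenario_overrides(p, overrides)
  validate_params(p)
  p
}

#' @rdname load_defaults
#' @export
thrombo_params <- load_defaults

#' Apply scenario-specific parameter overrides
#'
#' Returns a new parameter set with the given fields replaced and all
#' invariants re-checked. `blocked_agonists` accepts any subset of
#' `c("ADP","TxA2","TB")`; blocking an agonist removes it from the
#' activation weight and zeroes its generation pathway (ADP release,
#' TxA2 synthesis, or thrombin generation respectively).
#'
#' @param params a `thrombo_params` object.
#' @param overrides named list; names must be existing parameter fields.
#'   Named vectors (`w`, `a_crit`, `k1`, `D`) may be overridden per element
#'   by passing a partial named vector.
#' @return a new `thrombo_params` object.
#' @export
apply_scenario_overrides <- function(params, overrides) {
  stopifnot(inherits(params, "thrombo_params"))
  if (length(overrides) == 0L) return(params)
  nm <- names(overrides)
  if (is.null(nm) || any(nm == ""))
    stop("overrides must be a fully named list", call. = FALSE)
  unknown <- setdiff(nm, names(unclass(params)))
  if (length(unknown))
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (k in nm) {
    if (k %in% c("w", "a_crit", "k1", "D") && !is.null(names(overrides[[k]]))) {
      bad <- setdiff(names(overrides[[k]]), names(params[[k]]))
      if (length(bad))
        stop("unknown element(s) in '", k, "': ", paste(bad, collapse = ", "),
             call. = FALSE)
      params[[k]][names(overrides[[k]])] <- overrides[[k]]
    } else if (k == "blocked_agonists") {
      params[[k]] <- as.character(overrides[[k]])
    } else {
      params[[k]] <- overrides[[k]]
    }
  }
  validate_params(params)
  params
}

#' Validate a parameter set
#'
#' Checks non-negativity of all rates, times, concentrations and thresholds,
#' `theta` in [0,1], `alpha > 0`, and that blocked agonist names are known.
#' Called automatically by [load_defaults()] and
#' [apply_scenario_overrides()].
#'
#' @param params a `thrombo_params` object.
#' @return `params`, invisibly, if valid; otherwise an error.
#' @export
validate_params <- function(params) {
  p <- unclass(params)
  nonneg <- c("t_ct", "t_act", "k_ra", "k_aa", "k_rpd_b", "k_apd_b",
              "tau_emb", "tau_emb_b", "lambda_j", "s_pj", "eps",
              "phi_at", "phi_rt", "k1_T", "H", "K_AT", "K_T",
              "PLT_s_max", "Dia_PLT", "PLT_max", "f_stb", "C2",
              "mu_f", "rho_f0", "D_plt_base", "D_plt_slope")
  for (k in nonneg)
    if (!is.numeric(p[[k]]) || length(p[[k]]) != 1L || is.na(p[[k]]) ||
        p[[k]] < 0)
      stop("parameter '", k, "' must be a single non-negative number",
           call. = FALSE)
  if (any(p$w < 0) || any(p$a_crit <= 0) || any(p$k1 < 0) || any(p$D < 0))
    stop("agonist weights/thresholds, inhibition rates and diffusivities ",
         "must be non-negative (thresholds positive)", call. = FALSE)
  if (p$theta < 0 || p$theta > 1)
    stop("theta must lie in [0, 1]", call. = FALSE)
  if (p$alpha <= 0) stop("alpha must be positive", call. = FALSE)
  if (p$phi_prop <= 0 || p$phi_prop >= 1 || p$phi_occ <= 0 || p$phi_occ >= 1)
    stop("phi_prop and phi_occ must lie in (0, 1)", call. = FALSE)
  bad <- setdiff(p$blocked_agonists, c("ADP", "TxA2", "TB"))
  if (length(bad))
    stop("unknown blocked agonist(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  invisible(params)
}

#' Shear-stress unit conversion
#'
#' 1 Pa = 10 dyne/cm^2; the conversions are exact inverses.
#'
#' @param tau shear stress.
#' @return converted shear stress.
#' @export
pa_to_dyne <- function(tau) tau * 10

#' @rdname pa_to_dyne
#' @export
dyne_to_pa <- function(tau) tau / 10

#' Serialize / restore parameters (YAML)
#'
#' Round-trip safe: `params_from_yaml(params_to_yaml(p))` is value-identical
#' to `p`. Used to record the fully resolved parameter set of a run.
#'
#' @param params a `thrombo_params` object.
#' @param path optional file path; if `NULL` the YAML text is returned.
#' @export
params_to_yaml <- function(params, path = NULL) {
  stopifnot(inherits(params, "thrombo_params"))
  txt <- yaml::as.yaml(params_serializable(params), precision = 17)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

## named vectors must become maps or YAML drops their names
params_serializable <- function(params) {
  p <- unclass(params)
  for (k in c("w", "a_crit", "k1", "D")) p[[k]] <- as.list(p[[k]])
  p
}

## inverse coercion: YAML maps back to named numeric vectors, and numeric
## scalars that YAML surfaced as strings (e.g. "3.0e14") back to numbers
coerce_numeric_field <- function(v) {
  u <- unlist(v)
  out <- suppressWarnings(as.numeric(u))
  if (any(is.na(out) & !is.na(u)))
    stop("non-numeric value where a number was expected", call. = FALSE)
  names(out) <- names(u)
  out
}

#' @rdname params_to_yaml
#' @param text YAML text (ignored when `path` given).
#' @export
params_from_yaml <- function(path = NULL, text = NULL) {
  raw <- if (!is.null(path)) yaml::read_yaml(path) else yaml::yaml.load(text)
  p <- unclass(load_defaults())
  for (k in names(raw)) {
    v <- raw[[k]]
    if (k == "blocked_agonists") v <- as.character(unlist(v))
    else if (is.numeric(p[[k]])) v <- coerce_numeric_field(v)
    p[[k]] <- v
  }
  class(p) <- "thrombo_params"
  validate_params(p)
  p
}

#' @export
print.thrombo_params <- function(x, ...) {
  cat("<thrombo_params>\n")
  cat("  t_ct =", x$t_ct, "s; t_act =", x$t_act, "s\n")
  cat("  weights:", paste(names(x$w), x$w, sep = "=", collapse = ", "), "\n")
  cat("  k_ra =", x$k_ra, "m/s; k_aa =", x$k_aa, "m/s\n")
  cat("  wall: k_rpd_b =", x$k_rpd_b, "; k_apd_b =", x$k_apd_b,
      "m/s; tau_emb_b =", x$tau_emb_b, "dyne/cm^2\n")
  cat("  tau_emb =", x$tau_emb, "dyne/cm^2; PLT_max =",
      format(x$PLT_max, digits = 4), "PLT/m^3\n")
  if (length(x$blocked_agonists))
    cat("  blocked agonists:", paste(x$blocked_agonists, collapse = ", "), "\n")
  invisible(x)
}

## effective (blocking-aware) kinetic inputs, used by both the R kinetics
## functions and the compiled driver: blocking removes the agonist from the
## activation weight AND zeroes its generation source.
effective_kinetics <- function(params) {
  w <- params$w
  lambda <- params$lambda_j
  s_pj <- params$s_pj
  phi_at <- params$phi_at
  phi_rt <- params$phi_rt
  blk <- params$blocked_agonists
  if ("ADP" %in% blk) { w["ADP"] <- 0; lambda <- 0 }
  if ("TxA2" %in% blk) { w["TxA2"] <- 0; s_pj <- 0 }
  if ("TB" %in% blk) { w["TB"] <- 0; phi_at <- 0; phi_rt <- 0 }
  list(w = w, lambda_j = lambda, s_pj = s_pj,
       phi_at = phi_at, phi_rt = phi_rt)
}
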