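## Boundary-flux kinetics on reactive walls, material-specific embolization,
## and the thrombus-interface propagation rule that converts wall/thrombus
## adjacency into bulk deposition rates.

#' Create a boundary patch
#'
#' A boundary patch carries the three material surface coefficients
#' (resting/activated platelet deposition rates and the characteristic
#' embolization shear stress) plus the deposited surface densities used by
#' the surface-flux kinetics.
#'
#' @param id patch identifier.
#' @param kind one of `"inlet"`, `"outlet"`, `"wall"`, `"injury"`,
#'   `"injection_port"`.
#' @param k_rpd_b,k_apd_b platelet-wall deposition rates, m/s.
#' @param tau_emb_b characteristic embolization shear stress, dyne/cm^2.
#' @param RP_d_s,AP_d_s,AP_s_s deposited surface densities, PLT/m^2.
#' @param PLT_s_max surface capacity used for the density invariant.
#' @return an object of class `boundary_patch`.
#' @export
boundary_patch <- function(id, kind = "wall", k_rpd_b = 0, k_apd_b = 0,
                           tau_emb_b = 30, RP_d_s = 0, AP_d_s = 0,
                           AP_s_s = 0, PLT_s_max = 7e10) {
  kind <- match.arg(kind, c("inlet", "outlet", "wall", "injury",
                            "injection_port"))
  stopifnot(k_rpd_b >= 0, k_apd_b >= 0, tau_emb_b > 0,
            RP_d_s >= 0, AP_d_s >= 0, AP_s_s >= 0)
  if (RP_d_s + AP_d_s + AP_s_s > PLT_s_max * (1 + 1e-12))
    stop("deposited surface densities exceed PLT_s_max", call. = FALSE)
  structure(list(id = id, kind = kind, k_rpd_b = k_rpd_b, k_apd_b = k_apd_b,
                 tau_emb_b = tau_emb_b, RP_d_s = RP_d_s, AP_d_s = AP_d_s,
                 AP_s_s = AP_s_s, PLT_s_max = PLT_s_max),
            class = "boundary_patch")
}

#' Free surface fraction of a boundary patch
#'
#' S = 1 - (RP_d_s + AP_d_s + AP_s_s) / PLT_s_max, clamped to [0, 1]:
#' 1 on a pristine surface, 0 when the surface is saturated with deposited
#' platelets. S scales every platelet-adhesion flux.
#'
#' @param patch a [boundary_patch()].
#' @return dimensionless coverage S.
#' @export
surface_coverage <- function(patch) {
  S <- 1 - (patch$RP_d_s + patch$AP_d_s + patch$AP_s_s) / patch$PLT_s_max
  min(max(S, 0), 1)
}

#' Material-specific boundary embolization rate
#'
#' Same functional form as the bulk [embolization_rate()] with the patch
#' characteristic stress `tau_emb_b` in place of `tau_emb`.
#'
#' @param tau_wall wall shear stress, dyne/cm^2.
#' @param patch a [boundary_patch()].
#' @param params a `thrombo_params` object.
#' @return f_embb in 1/s.
#' @export
boundary_embolization_rate <- function(tau_wall, patch, params) {
  embolization_rate(tau_wall, patch$tau_emb_b, params)
}

#' Surface reaction fluxes and surface-density kinetics
#'
#' Implements the full set of wall boundary conditions: adhesion of free
#' platelets scaled by the free surface fraction S, return of embolized
#' surface platelets to the free stream, ADP release by agonist/shear
#' activation of deposited resting platelets and by contact activation of
#' arriving resting platelets, TxA2 synthesis by deposited activated
#' platelets, thrombin generation from prothrombin on deposited platelet
#' membranes (no ATIII flux), and the surface-density rate equations for the
#' three deposited states. Negative flux = consumption at the wall.
#'
#' @param patch a [boundary_patch()].
#' @param state adjacent-cell [species_state()] (scalars).
#' @param tau_wall wall shear stress, dyne/cm^2.
#' @param params a `thrombo_params` object.
#' @return list with `flux` (per free-stream species, amount/m^2/s) and
#'   `ddt_surface` (RP_d_s, AP_d_s, AP_s_s rates, PLT/m^2/s).
#' @export
boundary_fluxes <- function(patch, state, tau_wall, params) {
  eff <- effective_kinetics(params)
  S <- surface_coverage(patch)
  Om <- agonist_weight(state$a_pr, state$a_ps, state$TB, params)
  k_apa <- chemical_activation_rate(Om, params)
  k_spa <- shear_activation_rate(tau_wall, params)
  f_embb <- boundary_embolization_rate(tau_wall, patch, params)
  th <- params$theta
  adh_RP <- S * patch$k_rpd_b * state$RP   # PLT/m^2/s
  adh_AP <- S * patch$k_apd_b * state$AP
  act_s <- (k_apa + k_spa) * patch$RP_d_s
  gen_TB <- state$PT *
    (eff$phi_at * patch$AP_d_s + eff$phi_rt * patch$RP_d_s)  # U/m^2/s
  flux <- list(
    RP = -adh_RP + f_embb * patch$RP_d_s,
    AP = -adh_AP + f_embb * patch$AP_d_s,
    a_pr = eff$lambda_j * (act_s + th * adh_RP),
    a_ps = eff$s_pj * patch$AP_d_s,
    PT = -params$eps * gen_TB,
    TB = gen_TB,
    AT = 0
  )
  ddt <- list(
    RP_d_s = (1 - th) * adh_RP - act_s - f_embb * patch$RP_d_s,
    AP_d_s = th * adh_RP + adh_AP + act_s -
      (f_embb + params$f_stb) * patch$AP_d_s,
    AP_s_s = params$f_stb * patch$AP_d_s
  )
  list(flux = flux, ddt_surface = ddt, S = S)
}

#' Bulk deposition rates from thrombus-interface propagation
#'
#' When the deposited volume fraction of a cell exceeds the propagation
#' threshold `phi_prop`, deposition propagates to every fluid cell sharing a
#' face with it: the neighbour receives k_rpd = k_ra * A_int / V and
#' k_apd = k_aa * A_int / V, where A_int is the total shared face area and
#' V the neighbour's volume. Rates are zero away from the interface, making
#' thrombus growth strictly local (one cell layer per threshold crossing).
#'
#' @param phi nx-by-ny deposited volume fraction field in [0, 1].
#' @param grid a `thrombo_grid`.
#' @param params a `thrombo_params` object (uses `k_ra`, `k_aa`,
#'   `phi_prop`).
#' @param phi_prop optional threshold override.
#' @return list with nx-by-ny matrices `k_rpd` and `k_apd` (1/s).
#' @export
propagation_rates <- function(phi, grid, params, phi_prop = NULL) {
  if (is.null(phi_prop)) phi_prop <- params$phi_prop
  stopifnot(all(phi >= 0), all(phi <= 1 + 1e-12))
  nx <- grid$nx; ny <- grid$ny
  stopifnot(identical(dim(phi), c(nx, ny)))
  over <- (phi > phi_prop) & !grid$solid
  Ax <- face_area_x(grid)   # (nx+1) x ny
  Ay <- face_area_y(grid)   # nx x (ny+1)
  V <- cell_volumes(grid)
  A_int <- matrix(0, nx, ny)
  if (nx > 1) {
    ## west neighbour over threshold contributes the shared x-face
    A_int[-1, ] <- A_int[-1, ] + over[-nx, ] * Ax[2:nx, ]
    A_int[-nx, ] <- A_int[-nx, ] + over[-1, ] * Ax[2:nx, ]
  }
  if (ny > 1) {
    A_int[, -1] <- A_int[, -1] + over[, -ny] * Ay[, 2:ny]
    A_int[, -ny] <- A_int[, -ny] + over[, -1] * Ay[, 2:ny]
  }
  A_int[grid$solid] <- 0
  k <- A_int / V
  list(k_rpd = params$k_ra * k, k_apd = params$k_aa * k)
}
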