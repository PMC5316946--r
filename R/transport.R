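## Species transport: convection-diffusion of the seven free-stream species
## (deposited species never advect) with shear-enhanced platelet
## diffusivity, plus the thrombus volume-fraction bookkeeping.

MOBILE_SPECIES <- c("RP", "AP", "a_pr", "a_ps", "PT", "TB", "AT")

#' Shear-enhanced platelet diffusivity
#'
#' D = 1.58e-13 + 6.0e-13 gamma (m^2/s) with gamma the shear-rate magnitude
#' in 1/s, applied to free-stream resting and activated platelets; the
#' chemical species use their constant diffusivities from `params$D`.
#'
#' @param gamma shear-rate magnitude, 1/s (vectorized).
#' @param params a `thrombo_params` object.
#' @return diffusivity in m^2/s.
#' @export
platelet_diffusivity <- function(gamma, params = load_defaults()) {
  stopifnot(all(gamma >= 0))
  params$D_plt_base + params$D_plt_slope * gamma
}

#' Advance species transport by one (or more) explicit steps
#'
#' Conservative finite-volume advection (first-order upwind) and diffusion
#' (central) of the mobile species on the staggered flow field. Deposited
#' species are returned unchanged (their dynamics are purely local). When a
#' `rates` bundle is supplied, the volumetric sources of [bulk_sources()]
#' are applied after transport (explicit Euler) — the full coupled
#' deposition/embolization update with wall fluxes lives in
#' [run_simulation()].
#'
#' @param state a [species_state()] whose entries are nx-by-ny matrices.
#' @param flow a `thrombo_flow`.
#' @param grid a `thrombo_grid`.
#' @param params a `thrombo_params` object.
#' @param dt time step, s. Must satisfy the advective/diffusive stability
#'   bound (checked; a violation aborts with the suggested dt).
#' @param nsteps number of identical sub-steps to take.
#' @param inlet named inlet concentrations (defaults: all zero).
#' @param rates optional [rate_bundle()] applied via [bulk_sources()].
#' @return the advanced `species_state`.
#' @export
step_species <- function(state, flow, grid, params, dt, nsteps = 1L,
                         inlet = NULL, rates = NULL) {
  gp <- pack_grid(grid, params)
  nx <- grid$nx; ny <- grid$ny
  dt_stab <- stable_dt(grid, flow, params)
  if (dt > dt_stab)
    stop(sprintf("dt = %.3g exceeds the stability bound; use dt <= %.3g",
                 dt, dt_stab), call. = FALSE)
  cin <- stats::setNames(rep(0, 7), MOBILE_SPECIES)
  if (!is.null(inlet)) cin[names(inlet)] <- unlist(inlet)
  Dplt <- matrix(platelet_diffusivity(as.numeric(flow$gamma), params), nx, ny)
  out <- state
  for (s in MOBILE_SPECIES) {
    Dc <- if (s %in% c("RP", "AP")) Dplt
          else matrix(params$D[[s]], nx, ny)
    out[[s]] <- cpp_advect_diffuse(gp, matrix(out[[s]], nx, ny),
                                   flow$u, flow$v, Dc, dt, as.integer(nsteps),
                                   cin[[s]])
  }
  if (!is.null(rates)) {
    src <- bulk_sources(out, rates, params)
    for (s in SPECIES) out[[s]] <- pmax(out[[s]] + dt * nsteps * src[[s]], 0)
  }
  out
}

## largest stable explicit transport step for the current flow field
stable_dt <- function(grid, flow, params, cfl = 0.9) {
  nx <- grid$nx; ny <- grid$ny
  rw <- radius_weight(grid); rwf <- radius_weight_face(grid)
  V <- cell_volumes(grid)
  Dplt <- matrix(platelet_diffusivity(as.numeric(flow$gamma), params), nx, ny)
  Dmax <- pmax(Dplt, max(params$D))
  Ax <- face_area_x(grid); Ay <- face_area_y(grid)
  Fx <- flow$u * Ax; Fy <- flow$v * Ay
  rate <- matrix(0, nx, ny)
  rate <- rate + pmax(Fx[-1, , drop = FALSE], 0) -
    pmin(Fx[-(nx + 1), , drop = FALSE], 0)
  rate <- rate + pmax(Fy[, -1, drop = FALSE], 0) -
    pmin(Fy[, -(ny + 1), drop = FALSE], 0)
  if (nx > 1) {
    dxc <- diff(grid$xc)
    rate[-1, ] <- rate[-1, ] + Dmax[-1, ] * Ax[2:nx, ] /
      matrix(dxc, nx - 1, ny)
    rate[-nx, ] <- rate[-nx, ] + Dmax[-nx, ] * Ax[2:nx, ] /
      matrix(dxc, nx - 1, ny)
  }
  if (ny > 1) {
    dyc <- diff(grid$yc)
    rate[, -1] <- rate[, -1] + Dmax[, -1] * Ay[, 2:ny] /
      matrix(dyc, nx, ny - 1, byrow = TRUE)
    rate[, -ny] <- rate[, -ny] + Dmax[, -ny] * Ay[, 2:ny] /
      matrix(dyc, nx, ny - 1, byrow = TRUE)
  }
  rate <- rate / V
  rate[grid$solid] <- 0
  cfl / max(rate, 1e-12)
}

#' Thrombus volume fraction from the deposited species
#'
#' phi = (RP_d + AP_d + AP_s) / PLT_max, clamped to \[0, 1\], with the
#' thrombus mask phi > phi_mask.
#'
#' @param state a [species_state()].
#' @param params a `thrombo_params` object.
#' @param phi_mask mask threshold (defaults to `params$phi_prop`).
#' @return list with `phi` and logical `mask` (same shape as the fields).
#' @export
update_thrombus_fraction <- function(state, params, phi_mask = NULL) {
  if (is.null(phi_mask)) phi_mask <- params$phi_prop
  phi <- (state$RP_d + state$AP_d + state$AP_s) / params$PLT_max
  phi <- pmin(pmax(phi, 0), 1)
  list(phi = phi, mask = phi > phi_mask)
}

#' Add an agonist injection source to a state (local, 0D/unit use)
#'
#' Adds `rate * area * dt / volume` of the species to the cell(s) adjacent
#' to an injection-port patch. Scenario-level injection (the fixed
#' pipette-tip concentration exchanged through the port area) is configured
#' by the scenario builders; this helper exposes the same bookkeeping for
#' direct state manipulation.
#'
#' @param state a [species_state()].
#' @param port a [boundary_patch()] of kind `"injection_port"`.
#' @param species one of the mobile species names.
#' @param rate injection flux, amount/m^2/s (>= 0).
#' @param dt time increment, s.
#' @param area port area, m^2.
#' @param volume receiving volume, m^3.
#' @return the updated state.
#' @export
inject_species <- function(state, port, species, rate, dt = 1,
                           area = 1, volume = 1) {
  if (!species %in% MOBILE_SPECIES)
    stop("unknown species: ", species, call. = FALSE)
  stopifnot(rate >= 0, dt >= 0, area > 0, volume > 0)
  state[[species]] <- state[[species]] + rate * area * dt / volume
  state
}
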