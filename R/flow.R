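## Hemodynamics: incompressible flow on the staggered grid with the
## thrombus resistance sink, plus scalar shear-rate/stress fields. The
## numerical kernels live in compiled code; these wrappers define the
## user-facing surface and the grid/parameter packing shared with the
## coupled driver.

#' Hindrance function of the deposited-platelet fraction
#'
#' f(phi) = phi (1 + 6.5 phi): the dimensionless factor by which the
#' deposited platelet fraction scales the resistance force of the thrombus
#' on the fluid. Zero at phi = 0 and strictly increasing.
#'
#' @param phi deposited volume fraction in \[0, 1\] (vectorized).
#' @return dimensionless hindrance value.
#' @export
hindrance <- function(phi) {
  if (any(phi < 0 | phi > 1)) stop("phi must lie in [0, 1]", call. = FALSE)
  phi * (1 + 6.5 * phi)
}

#' Thrombus resistance force on the fluid
#'
#' Returns -C2 f(phi) (v_f - v_T) with the thrombus phase at rest
#' (v_T = 0): the Darcy-like momentum sink that brings the fluid to rest
#' inside dense deposits.
#'
#' @param phi deposited volume fraction.
#' @param v_f fluid velocity, m/s (same shape as `phi`).
#' @param params a `thrombo_params` object (uses `C2`).
#' @return force density, N/m^3.
#' @export
resistance_force <- function(phi, v_f, params) {
  -params$C2 * hindrance(phi) * v_f
}

## ---------------------------------------------------------------------------
## packing helpers (R -> compiled core)
## ---------------------------------------------------------------------------

bc_code <- function(bc) {
  switch(bc$type, wall = 0L, inlet = 1L, pressure = 2L, symmetry = 3L,
         axis = 4L,
         stop("unknown boundary type: ", bc$type, call. = FALSE))
}

## Enumerate every wall face bounding the fluid region: outer sides of type
## "wall" plus any face separating a fluid cell from a solid cell. Returns
## (i, j, side, patch) with side 1=W, 2=E, 3=S, 4=N, patch defaulting to 1.
enumerate_wall_faces <- function(grid) {
  nx <- grid$nx; ny <- grid$ny
  sol <- grid$solid
  out <- list()
  add <- function(i, j, side) out[[length(out) + 1L]] <<- c(i, j, side)
  for (j in seq_len(ny)) {
    for (i in seq_len(nx)) {
      if (sol[i, j]) next
      if ((i == 1 && grid$side_bc$west$type == "wall") ||
          (i > 1 && sol[i - 1, j])) add(i, j, 1L)
      if ((i == nx && grid$side_bc$east$type == "wall") ||
          (i < nx && sol[i + 1, j])) add(i, j, 2L)
      if ((j == 1 && grid$side_bc$south$type == "wall") ||
          (j > 1 && sol[i, j - 1])) add(i, j, 3L)
      if ((j == ny && grid$side_bc$north$type == "wall") ||
          (j < ny && sol[i, j + 1])) add(i, j, 4L)
    }
  }
  if (!length(out))
    return(data.frame(i = integer(0), j = integer(0), side = integer(0),
                      patch = integer(0)))
  m <- do.call(rbind, out)
  data.frame(i = m[, 1], j = m[, 2], side = m[, 3], patch = 1L)
}

## area of a wall face identified by (fluid cell i, j, side)
wall_face_area <- function(grid, i, j, side) {
  rw <- radius_weight(grid)
  rwf <- radius_weight_face(grid)
  ifelse(side <= 2, grid$dy[j] * rw[j],
         ifelse(side == 3, grid$dx[i] * rwf[j], grid$dx[i] * rwf[j + 1]))
}

## Flatten grid + boundary data into the list consumed by the compiled core.
pack_grid <- function(grid, params) {
  nx <- grid$nx; ny <- grid$ny
  sb <- grid$side_bc
  w_uprof <- rep(0, ny)
  if (sb$west$type == "inlet") {
    u <- sb$west$u
    w_uprof <- if (length(u) == 1L) rep(u, ny) else rep(u, length.out = ny)
  }
  wf <- grid$wall_faces
  if (nrow(wf) == 0L) wf <- enumerate_wall_faces(grid)
  pt <- grid$patches
  V <- cell_volumes(grid)
  adh_rpdb <- adh_apdb <- wall_area <- port_kex <- matrix(0, nx, ny)
  tau_char <- matrix(params$tau_emb, nx, ny)
  port_conc <- 0
  if (nrow(wf)) {
    A <- wall_face_area(grid, wf$i, wf$j, wf$side)
    for (r in seq_len(nrow(wf))) {
      i <- wf$i[r]; j <- wf$j[r]
      pr <- pt[match(wf$patch[r], pt$patch), ]
      wall_area[i, j] <- wall_area[i, j] + A[r]
      adh_rpdb[i, j] <- adh_rpdb[i, j] + pr$k_rpd_b * A[r] / V[i, j]
      adh_apdb[i, j] <- adh_apdb[i, j] + pr$k_apd_b * A[r] / V[i, j]
      if (pr$k_rpd_b + pr$k_apd_b > 0)
        tau_char[i, j] <- min(tau_char[i, j], pr$tau_emb_b)
      if (pr$port_area > 0 && pr$port_conc > 0) {
        dist <- if (wf$side[r] <= 2) grid$dx[i] / 2 else grid$dy[j] / 2
        port_kex[i, j] <- port_kex[i, j] +
          params$D[["a_pr"]] * pr$port_area / (dist * V[i, j])
        port_conc <- pr$port_conc
      }
    }
  }
  list(nx = nx, ny = ny, axisym = as.integer(grid$mode == "axisymmetric"),
       xf = grid$xf, yf = grid$yf, xc = grid$xc, yc = grid$yc,
       dx = grid$dx, dy = grid$dy,
       rc = radius_weight(grid), rf = radius_weight_face(grid),
       solid = as.integer(grid$solid),
       wbc = bc_code(sb$west), ebc = bc_code(sb$east),
       sbc = bc_code(sb$south), nbc = bc_code(sb$north),
       w_p = if (!is.null(sb$west$p)) sb$west$p else 0,
       e_p = if (!is.null(sb$east$p)) sb$east$p else 0,
       w_uprof = w_uprof,
       w_conc_dirichlet = as.integer(sb$west$type %in% c("inlet", "pressure")),
       adh_rpdb = as.numeric(adh_rpdb), adh_apdb = as.numeric(adh_apdb),
       wall_area = as.numeric(wall_area), tau_char = as.numeric(tau_char),
       port_kex = as.numeric(port_kex), port_conc = port_conc)
}

## parameter list for the compiled core, with agonist blocking folded in
pack_params <- function(params) {
  eff <- effective_kinetics(params)
  p <- unclass(params)
  p$w <- eff$w
  p$lambda_j <- eff$lambda_j
  p$s_pj <- eff$s_pj
  p$phi_at <- eff$phi_at
  p$phi_rt <- eff$phi_rt
  p
}

## ---------------------------------------------------------------------------
## flow solves
## ---------------------------------------------------------------------------

#' Solve the flow field around a thrombus
#'
#' Computes the incompressible velocity/pressure field on the staggered grid
#' with the Brinkman-type resistance sink C2 f(phi) v treated implicitly
#' (stable for arbitrarily dense deposits). `dt <= 0` solves to steady
#' state; `dt > 0` advances one transient step of size `dt` from `init`
#' (iterated to the divergence tolerance), which is the quasi-steady
#' stepping mode used by the coupled driver.
#'
#' @param grid a `thrombo_grid`.
#' @param phi deposited volume fraction matrix (defaults to zero).
#' @param params a `thrombo_params` object.
#' @param init optional previous `thrombo_flow` to warm-start from.
#' @param dt transient step in seconds, or `<= 0` for steady state.
#' @param max_outer,tol,p_sweeps solver controls: outer iteration cap,
#'   normalized mass-residual target, pressure sweeps per outer iteration.
#' @return a `thrombo_flow` list: face velocities `u` ((nx+1) x ny) and `v`
#'   (nx x (ny+1)), cell pressure `p`, shear-rate `gamma` (1/s), shear
#'   stress `tau` (Pa) and `tau_dyne` (dyne/cm^2), inlet flow rate `Q_in`,
#'   and convergence diagnostics.
#' @export
solve_flow <- function(grid, phi = NULL, params = load_defaults(),
                       init = NULL, dt = -1, max_outer = 4000, tol = 1e-8,
                       du_tol = 1e-6, p_sweeps = 40, m_sweeps = 3) {
  if (is.null(phi)) phi <- matrix(0, grid$nx, grid$ny)
  stopifnot(identical(dim(phi), c(grid$nx, grid$ny)))
  gp <- pack_grid(grid, params)
  ini <- if (is.null(init)) NULL else init[c("u", "v", "p")]
  r <- cpp_solve_flow(gp, phi, pack_params(params), ini, dt, max_outer,
                      tol, du_tol, 0.7, 0.3, p_sweeps, m_sweeps)
  if (!r$converged && dt <= 0)
    warning("flow solver reached max_outer with residual ",
            format(r$residual, digits = 3))
  gamma <- cpp_shear(gp, r$u, r$v)
  structure(list(u = r$u, v = r$v, p = r$p, gamma = gamma,
                 tau = params$mu_f * gamma,
                 tau_dyne = pa_to_dyne(params$mu_f * gamma),
                 Q_in = r$Q_in, residual = r$residual, iters = r$iters,
                 converged = r$converged),
            class = "thrombo_flow")
}

#' One transient flow step
#'
#' Advances the momentum/pressure system by `dt` with the resistance sink
#' implicit; a thin wrapper over [solve_flow()] in transient mode.
#'
#' @inheritParams solve_flow
#' @param flow current `thrombo_flow` state.
#' @export
step_flow <- function(flow, phi, grid, params, dt, max_outer = 60,
                      tol = 1e-8) {
  solve_flow(grid, phi, params, init = flow, dt = dt,
             max_outer = max_outer, tol = tol)
}

#' Shear-rate and shear-stress fields
#'
#' gamma is the magnitude of the symmetric velocity-gradient tensor,
#' sqrt(2 D:D), evaluated at cell centres with one-sided differences at
#' walls; tau = mu_f gamma.
#'
#' @param flow a `thrombo_flow` (or list with `u`, `v`).
#' @param grid a `thrombo_grid`.
#' @param params a `thrombo_params` object.
#' @return list with `gamma` (1/s), `tau` (Pa), `tau_dyne` (dyne/cm^2).
#' @export
shear_fields <- function(flow, grid, params = load_defaults()) {
  gp <- pack_grid(grid, params)
  gamma <- cpp_shear(gp, flow$u, flow$v)
  list(gamma = gamma, tau = params$mu_f * gamma,
       tau_dyne = pa_to_dyne(params$mu_f * gamma))
}
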