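## Benchmark scenario builders, the top-level coupled driver, thrombus
## morphometrics, occlusion detection and agonist-blocking experiments.

#' Injured-vessel benchmark scenario
#'
#' Axisymmetric model of thrombus growth in a small blood vessel
#' (diameter 0.06 mm, length 0.5 mm) perfused at a mean velocity of
#' 800 um/s by a prescribed pressure difference. The wall is healthy
#' endothelium (zero deposition rates) except for a 30 um injured segment
#' centred mid-vessel with elevated adhesion (k_rpd_b = 4.0e-5 m/s,
#' k_apd_b = 4.0e-4 m/s, tau_emb_b = 1.0 dyne/cm^2) surrounding a 3 um ADP
#' injection port. Inlet platelet counts are rodent values
#' (RP = 6e14, AP = 6e12 PLT/m^3).
#'
#' @param overrides named list of parameter overrides (e.g.
#'   `blocked_agonists`), applied via [apply_scenario_overrides()].
#' @param mesh_scale fraction of the base 40 x 160 (radial x axial) mesh.
#' @param inject_adp if `TRUE`, the injection port carries a fixed ADP
#'   concentration of `port_conc` at the pipette tip.
#' @param port_conc ADP concentration at the port, nmol/m^3 (1 mM).
#' @param diameter,length vessel dimensions, m.
#' @param mean_velocity target mean inlet velocity at phi = 0, m/s.
#' @param injury_k_rpd_b,injury_k_apd_b,injury_tau_emb_b injured-site
#'   material coefficients.
#' @param injury_length injured segment length, m.
#' @param t_end default simulation horizon, s.
#' @return a `thrombo_scenario` list with `grid`, `params` and `config`.
#' @export
build_vessel_scenario <- function(overrides = list(), mesh_scale = 0.25,
                                  inject_adp = TRUE, port_conc = 1e9,
                                  diameter = 0.06e-3, length = 0.5e-3,
                                  mean_velocity = 800e-6,
                                  injury_k_rpd_b = 4.0e-5,
                                  injury_k_apd_b = 4.0e-4,
                                  injury_tau_emb_b = 1.0,
                                  injury_length = 30e-6,
                                  t_end = 1200) {
  stopifnot(mesh_scale > 0, mesh_scale <= 1, diameter > 0, length > 0)
  params <- load_defaults(utils::modifyList(list(H = 0.1e6), overrides))
  R <- diameter / 2
  nr <- max(6L, round(40 * mesh_scale))
  nz <- max(12L, round(160 * mesh_scale))
  dp <- 8 * params$mu_f * length * mean_velocity / R^2
  grid <- make_grid(xf = seq(0, length, length.out = nz + 1),
                    yf = seq(0, R, length.out = nr + 1),
                    mode = "axisymmetric",
                    side_bc = list(west = list(type = "pressure", p = dp),
                                   east = list(type = "pressure", p = 0),
                                   south = list(type = "axis"),
                                   north = list(type = "wall")))
  z0 <- length / 2
  patches <- data.frame(
    patch = c(1L, 2L, 3L),
    kind = c("wall", "injury", "injection_port"),
    k_rpd_b = c(0, injury_k_rpd_b, injury_k_rpd_b),
    k_apd_b = c(0, injury_k_apd_b, injury_k_apd_b),
    tau_emb_b = c(params$tau_emb, injury_tau_emb_b, injury_tau_emb_b),
    port_conc = c(0, 0, if (inject_adp) port_conc else 0),
    port_area = c(0, 0, pi * (1.5e-6)^2))
  wf <- enumerate_wall_faces(grid)
  injured <- wf$side == 4L & abs(grid$xc[wf$i] - z0) <= injury_length / 2
  wf$patch[injured] <- 2L
  ## the injection port is the injured wall face closest to the site centre
  if (any(injured)) {
    cand <- which(injured)
    wf$patch[cand[which.min(abs(grid$xc[wf$i[cand]] - z0))]] <- 3L
  }
  grid$patches <- patches
  grid$wall_faces <- wf
  cin <- c(RP = 6e14, AP = 6e12, a_pr = 0, a_ps = 0, PT = 1.1e6,
           TB = 0, AT = 2.844e6)
  config <- list(scenario = "vessel", cin = cin, t_end = t_end,
                 out_dt = 1, field_dt = 0, flow_dt = 2,
                 dphi_trigger = 0.02, dt_max = 0.02, cfl = 0.8,
                 stop_at_occlusion = TRUE, flow_max_outer = 4000,
                 flow_tol = 1e-6, wall_y = R, wall_north = TRUE,
                 mesh_scale = mesh_scale, inject_adp = inject_adp,
                 mean_velocity = mean_velocity, pressure_drop = dp)
  structure(list(grid = grid, params = params, config = config),
            class = "thrombo_scenario")
}

#' Micro-crevice benchmark scenario
#'
#' Planar 2D model of platelet deposition in a rectangular flow channel
#' (half-height 1.5 mm, symmetry plane on top) with a rectangular crevice
#' of height 0.125 mm and length `L_c` sunk into the floor, perfused at a
#' mean inlet velocity of 0.0173 m/s. All wetted walls are titanium alloy
#' (k_rpd_b = 1.0e-20 m/s — no resting-platelet deposition,
#' k_apd_b = 1.0e-5 m/s, tau_emb_b = 0.1 dyne/cm^2). Inlet platelet counts
#' are human values (RP = 2.5e14, AP = 1e13 PLT/m^3); heparin is present
#' (in vitro, [H] = 0.1e6 nmol/m^3). The modelled window spans 0.9 mm of
#' the channel length with the crevice 0.3 mm from the inlet.
#'
#' @param L_c crevice length, m (0.075e-3 or 0.137e-3 in the benchmarks).
#' @param overrides named list of parameter overrides.
#' @param mesh_scale fraction of the base near-wall resolution (3.125 um
#'   spacing at scale 1).
#' @param half_height,depth_crevice,window_length,x_crevice geometry, m.
#' @param inlet_velocity mean inlet velocity, m/s.
#' @param t_end default simulation horizon, s.
#' @return a `thrombo_scenario` list with `grid`, `params` and `config`.
#' @export
build_crevice_scenario <- function(L_c = 0.075e-3, overrides = list(),
                                   mesh_scale = 0.25,
                                   half_height = 1.5e-3,
                                   depth_crevice = 0.125e-3,
                                   window_length = 0.9e-3,
                                   x_crevice = 0.3e-3,
                                   inlet_velocity = 0.0173,
                                   t_end = 600) {
  stopifnot(L_c > 0, mesh_scale > 0, mesh_scale <= 1)
  params <- load_defaults(utils::modifyList(list(H = 0.1e6), overrides))
  hf <- 3.125e-6 / mesh_scale          # near-wall spacing
  ## y: uniform through the crevice depth, graded up to the symmetry plane
  ncrev <- max(3L, round(depth_crevice / hf))
  yf <- c(seq(-depth_crevice, 0, length.out = ncrev + 1)[-(ncrev + 1)],
          graded_faces(0, half_height, h0 = hf, ratio = 1.35))
  ## x: fine across the crevice span, graded toward inlet and outlet
  x1 <- x_crevice - 4 * hf
  x2 <- x_crevice + L_c + 4 * hf
  xf_mid <- seq(x1, x2, length.out = max(4L, round((x2 - x1) / hf)) + 1L)
  xf_w <- graded_faces(0, x1, h0 = hf, ratio = 1.35, from = "end")
  xf_e <- graded_faces(x2, window_length, h0 = hf, ratio = 1.35)
  xf <- sort(unique(c(xf_w, xf_mid, xf_e)))
  ny <- length(yf) - 1L; nx <- length(xf) - 1L
  xc <- 0.5 * (xf[-1] + xf[-(nx + 1)]); yc <- 0.5 * (yf[-1] + yf[-(ny + 1)])
  solid <- outer(xc, yc, function(x, y)
    y < 0 & (x < x_crevice | x > x_crevice + L_c))
  uprof <- 1.5 * inlet_velocity * (1 - (1 - pmax(yc, 0) / half_height)^2)
  uprof[yc < 0] <- 0
  grid <- make_grid(xf = xf, yf = yf, mode = "planar", solid = solid,
                    side_bc = list(west = list(type = "inlet", u = uprof),
                                   east = list(type = "pressure", p = 0),
                                   south = list(type = "wall"),
                                   north = list(type = "symmetry")))
  grid$patches <- data.frame(patch = 1L, kind = "wall",
                             k_rpd_b = 1.0e-20, k_apd_b = 1.0e-5,
                             tau_emb_b = 0.1, port_conc = 0, port_area = 0)
  grid$wall_faces <- enumerate_wall_faces(grid)
  cin <- c(RP = 2.5e14, AP = 1e13, a_pr = 0, a_ps = 0, PT = 1.1e6,
           TB = 0, AT = 2.844e6)
  config <- list(scenario = "crevice", cin = cin, t_end = t_end,
                 out_dt = 1, field_dt = 0, flow_dt = 2,
                 dphi_trigger = 0.02, dt_max = 0.02, cfl = 0.8,
                 stop_at_occlusion = FALSE, flow_max_outer = 4000,
                 flow_tol = 1e-6, wall_y = 0, wall_north = FALSE,
                 mesh_scale = mesh_scale, L_c = L_c,
                 x_crevice = x_crevice, inlet_velocity = inlet_velocity)
  structure(list(grid = grid, params = params, config = config),
            class = "thrombo_scenario")
}

#' Run a coupled thrombus-growth simulation
#'
#' Advances the fully coupled system — quasi-steady flow with the thrombus
#' resistance sink, shear fields, species transport, activation /
#' deposition / propagation / embolization / inhibition kinetics and the
#' thrombus fraction — from `t0` to `t_end` (or geometric occlusion). The
#' model is deterministic: identical inputs give identical trajectories.
#'
#' @param scenario a `thrombo_scenario` from [build_vessel_scenario()] or
#'   [build_crevice_scenario()].
#' @param t_end optional horizon override, s.
#' @param out_dt morphometrics/totals output cadence, s.
#' @param field_dt phi-field snapshot cadence, s (0 = none).
#' @param init optional initial state for restarts: list with `C` (list of
#'   10 species matrices in the order RP, AP, a_pr, a_ps, PT, TB, AT, RP_d,
#'   AP_d, AP_s) and optionally `u`, `v`, `p`.
#' @param t0 start time (for restarts), s.
#' @param stop_at_occlusion stop as soon as a thrombus column spans the
#'   lumen.
#' @return a `thrombo_result` list: `morphometrics` data frame (time,
#'   height, length, volume, aspect, Q), `totals` per-species integrals,
#'   occlusion times (geometric primary, flow-based secondary), final
#'   fields, flow and phi, and solver diagnostics.
#' @export
run_simulation <- function(scenario, t_end = NULL, out_dt = NULL,
                           field_dt = NULL, init = NULL, t0 = 0,
                           stop_at_occlusion = NULL) {
  stopifnot(inherits(scenario, "thrombo_scenario"))
  grid <- scenario$grid; params <- scenario$params
  cfg <- scenario$config
  if (!is.null(t_end)) cfg$t_end <- t_end
  if (!is.null(out_dt)) cfg$out_dt <- out_dt
  if (!is.null(field_dt)) cfg$field_dt <- field_dt
  if (!is.null(stop_at_occlusion))
    cfg$stop_at_occlusion <- stop_at_occlusion
  gp <- pack_grid(grid, params)
  ccfg <- list(cin = as.numeric(cfg$cin), t0 = t0, t_end = cfg$t_end,
               out_dt = cfg$out_dt, field_dt = cfg$field_dt,
               flow_dt = cfg$flow_dt, dphi_trigger = cfg$dphi_trigger,
               morpho_thresh = params$phi_occ, phi_occ = params$phi_occ,
               wall_y = cfg$wall_y, wall_north = as.integer(cfg$wall_north),
               dt_max = cfg$dt_max, cfl = cfg$cfl,
               stop_at_occlusion = as.integer(cfg$stop_at_occlusion),
               flow_max_outer = cfg$flow_max_outer,
               flow_tol = cfg$flow_tol, init = init)
  if (cfg$t_end <= t0) {
    ## degenerate horizon: return the initial state unchanged
    nx <- grid$nx; ny <- grid$ny
    C0 <- if (!is.null(init)) init$C else {
      z <- matrix(0, nx, ny)
      cini <- lapply(seq_len(10), function(s) {
        if (s <= 7) {
          m <- matrix(cfg$cin[[s]], nx, ny); m[grid$solid] <- 0; m
        } else z
      })
      cini
    }
    state <- stats::setNames(C0, SPECIES)
    phi <- (state$RP_d + state$AP_d + state$AP_s) / params$PLT_max
    return(structure(list(
      morphometrics = data.frame(time = t0, height = 0, length = 0,
                                 volume = sum(phi * cell_volumes(grid)),
                                 aspect = NA_real_, Q = NA_real_),
      totals = NULL, occlusion_time = NA_real_,
      occlusion_time_flow = NA_real_, occluded = FALSE,
      state = state, phi = pmin(phi, 1), flow = NULL,
      grid = grid, params = params, config = cfg,
      events = list(clamp_events = 0, flow_solves = 0), t_final = t0),
      class = "thrombo_result"))
  }
  r <- cpp_run_coupled(gp, pack_params(params), ccfg)
  morpho <- data.frame(time = r$time, height = r$height, length = r$length,
                       volume = r$volume,
                       aspect = ifelse(r$height > 0, r$length / r$height,
                                       NA_real_),
                       Q = r$Q)
  totals <- as.data.frame(stats::setNames(r$totals, SPECIES))
  totals <- cbind(time = r$time, totals)
  state <- stats::setNames(r$C, SPECIES)
  occ <- r$occlusion_time_geometric
  structure(list(
    morphometrics = morpho, totals = totals,
    occlusion_time = if (occ >= 0) occ else NA_real_,
    occlusion_time_flow = if (r$occlusion_time_flow >= 0)
      r$occlusion_time_flow else NA_real_,
    occluded = occ >= 0,
    state = state, phi = r$phi,
    flow = structure(list(u = r$u, v = r$v, p = r$p, gamma = r$gamma,
                          tau = params$mu_f * r$gamma,
                          Q_in = utils::tail(r$Q, 1)),
                     class = "thrombo_flow"),
    phi_history = if (length(r$phi_times))
      list(time = r$phi_times, phi = r$phi_history) else NULL,
    grid = grid, params = params, config = cfg,
    events = list(clamp_events = r$clamp_events,
                  flow_solves = r$flow_solves, dt_last = r$dt_last,
                  Q0 = r$Q0),
    t_final = r$t_final),
    class = "thrombo_result")
}

#' @export
print.thrombo_result <- function(x, ...) {
  cat("<thrombo_result> ", x$config$scenario, " scenario, t = ",
      x$t_final, " s\n", sep = "")
  if (isTRUE(x$occluded))
    cat("  occluded at t =", x$occlusion_time, "s (geometric)\n")
  m <- utils::tail(x$morphometrics, 1)
  cat(sprintf("  thrombus: height %.1f um, length %.1f um, volume %.3g m^3\n",
              m$height * 1e6, m$length * 1e6, m$volume))
  invisible(x)
}

#' Thrombus morphometrics
#'
#' Height is the maximal wall-normal extent of the phi >= threshold region
#' (measured from the reactive wall), length the maximal streamwise extent,
#' and volume the phi-weighted cell volume integral (including the 2*pi
#' factor for axisymmetric grids).
#'
#' @param phi nx-by-ny deposited volume fraction.
#' @param grid a `thrombo_grid`.
#' @param threshold mask threshold in (0, 1).
#' @param wall_y wall coordinate (m); defaults to the outer radius
#'   (axisymmetric) or the channel floor y = 0 (planar).
#' @param wall_north whether the reference wall is the north boundary.
#' @return list with `height`, `length`, `volume`, `aspect` and `time`
#'   fields (time is `NA` here; the driver fills it in histories).
#' @export
morphometrics <- function(phi, grid, threshold = 0.2, wall_y = NULL,
                          wall_north = NULL) {
  stopifnot(threshold > 0, threshold < 1)
  if (is.null(wall_north)) wall_north <- grid$mode == "axisymmetric"
  if (is.null(wall_y)) wall_y <- if (wall_north) max(grid$yf) else 0
  mask <- (phi >= threshold) & !grid$solid
  vol_w <- if (grid$mode == "axisymmetric") 2 * pi else 1
  vol <- sum(phi[!grid$solid] * cell_volumes(grid)[!grid$solid]) * vol_w
  if (!any(mask))
    return(list(height = 0, length = 0, volume = vol, aspect = NA_real_,
                time = NA_real_))
  ij <- which(mask, arr.ind = TRUE)
  ext <- if (wall_north) wall_y - grid$yf[ij[, 2]]
         else grid$yf[ij[, 2] + 1L] - wall_y
  height <- max(0, ext)
  length_ <- max(grid$xf[ij[, 1] + 1L]) - min(grid$xf[ij[, 1]])
  list(height = height, length = length_, volume = vol,
       aspect = if (height > 0) length_ / height else NA_real_,
       time = NA_real_)
}

#' Detect lumen occlusion
#'
#' Primary (geometric) criterion: a connected region with
#' phi >= phi_occ spans the full cross-section of some streamwise station.
#' Secondary (hydraulic) criterion: the flow rate at fixed driving pressure
#' has fallen below 1% of its initial value. Both are computed; the
#' geometric one is authoritative.
#'
#' @param phi nx-by-ny deposited volume fraction.
#' @param flow optional `thrombo_flow` for the hydraulic criterion.
#' @param grid a `thrombo_grid`.
#' @param phi_occ occlusive threshold.
#' @param Q0 reference (initial) flow rate for the hydraulic criterion.
#' @return list with `occluded` (geometric), `occluded_flow` (hydraulic or
#'   `NA`).
#' @export
detect_occlusion <- function(phi, flow = NULL, grid, phi_occ = 0.2,
                             Q0 = NULL) {
  open_cell <- !grid$solid
  blocked <- (phi >= phi_occ) | grid$solid
  spans <- vapply(seq_len(grid$nx), function(i)
    any(open_cell[i, ]) && all(blocked[i, ]), logical(1))
  occ_flow <- NA
  if (!is.null(flow) && !is.null(Q0) && Q0 > 0)
    occ_flow <- abs(flow$Q_in) < 0.01 * Q0
  list(occluded = any(spans), occluded_flow = occ_flow)
}

#' Agonist-blocking experiment
#'
#' Runs the supplied scenario once per blocking case up to occlusion or
#' `t_max`, and tabulates the occlusion times. Cases are character vectors
#' of agonists to block (subsets of `c("ADP", "TxA2", "TB")`).
#'
#' @param base a `thrombo_scenario` (typically the vessel benchmark without
#'   ADP injection).
#' @param cases named list of blocked-agonist sets.
#' @param t_max reporting horizon, s.
#' @return data.frame with case, blocked agonists, occlusion time (`NA` if
#'   none within `t_max`) and thrombus volume at the end of each run.
#' @export
blocking_experiment <- function(base,
                                cases = list(none = character(0),
                                             ADP = "ADP", TB = "TB",
                                             TxA2 = "TxA2",
                                             all = c("ADP", "TxA2", "TB")),
                                t_max = 1200) {
  stopifnot(inherits(base, "thrombo_scenario"))
  rows <- lapply(names(cases), function(nm) {
    sc <- base
    sc$params <- apply_scenario_overrides(
      sc$params, list(blocked_agonists = cases[[nm]]))
    res <- run_simulation(sc, t_end = t_max)
    data.frame(case = nm,
               blocked = paste(cases[[nm]], collapse = "+"),
               occlusion_time = res$occlusion_time,
               volume_final = utils::tail(res$morphometrics$volume, 1),
               t_final = res$t_final)
  })
  do.call(rbind, rows)
}
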