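## Configuration parsing (YAML), VTK/CSV output, checkpoint/restart and the
## synthetic fixtures used by the test suite.

CONFIG_KEYS <- c("scenario", "mesh_scale", "t_end", "out_dt", "field_dt",
                 "flow_dt", "dphi_trigger", "dt_max", "cfl",
                 "stop_at_occlusion", "inject_adp", "port_conc", "L_c",
                 "blocked_agonists", "params", "inlet")

#' Read a scenario configuration file
#'
#' YAML with a `scenario` key (`vessel` or `crevice`) plus optional
#' geometry/numerics overrides, a `params` block of model-parameter
#' overrides, a `blocked_agonists` list and an `inlet` block of inlet
#' concentrations. Unknown keys are rejected with their key path. An empty
#' file yields the default vessel scenario.
#'
#' @param path YAML file path (or `text =` YAML string).
#' @param text YAML text, used when `path` is `NULL`.
#' @return a fully built `thrombo_scenario`.
#' @export
read_config <- function(path = NULL, text = NULL) {
  raw <- if (!is.null(path)) yaml::read_yaml(path) else yaml::yaml.load(text)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), CONFIG_KEYS)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  scen <- if (is.null(raw$scenario)) "vessel" else raw$scenario
  if (!scen %in% c("vessel", "crevice"))
    stop("scenario: must be 'vessel' or 'crevice'", call. = FALSE)
  po <- if (is.null(raw$params)) list() else raw$params
  defaults <- unclass(load_defaults())
  for (k in names(po))
    if (is.numeric(defaults[[k]])) po[[k]] <- coerce_numeric_field(po[[k]])
  if (!is.null(raw$blocked_agonists))
    po$blocked_agonists <- as.character(unlist(raw$blocked_agonists))
  args <- list(overrides = po)
  if (!is.null(raw$mesh_scale)) args$mesh_scale <- as.numeric(raw$mesh_scale)
  if (!is.null(raw$t_end)) args$t_end <- as.numeric(raw$t_end)
  sc <- if (scen == "vessel") {
    if (!is.null(raw$inject_adp)) args$inject_adp <- isTRUE(raw$inject_adp)
    if (!is.null(raw$port_conc))
      args$port_conc <- as.numeric(raw$port_conc)
    do.call(build_vessel_scenario, args)
  } else {
    if (!is.null(raw$L_c)) args$L_c <- as.numeric(raw$L_c)
    do.call(build_crevice_scenario, args)
  }
  for (k in c("out_dt", "field_dt", "flow_dt", "dphi_trigger", "dt_max",
              "cfl"))
    if (!is.null(raw[[k]])) sc$config[[k]] <- as.numeric(raw[[k]])
  if (!is.null(raw$stop_at_occlusion))
    sc$config$stop_at_occlusion <- isTRUE(raw$stop_at_occlusion)
  if (!is.null(raw$inlet)) {
    bad <- setdiff(names(raw$inlet), names(sc$config$cin))
    if (length(bad))
      stop("inlet: unknown species ", paste(bad, collapse = ", "),
           call. = FALSE)
    vin <- coerce_numeric_field(raw$inlet)
    sc$config$cin[names(vin)] <- vin
  }
  validate_params(sc$params)
  if (any(unlist(sc$config[c("out_dt", "flow_dt", "dt_max", "cfl")]) <= 0))
    stop("out_dt, flow_dt, dt_max and cfl must be positive", call. = FALSE)
  sc
}

#' Write the fully resolved configuration of a scenario
#'
#' Records scenario identity, geometry/numerics and the complete parameter
#' set, sufficient to reproduce the run.
#'
#' @param scenario a `thrombo_scenario`.
#' @param path output YAML path.
#' @export
write_config <- function(scenario, path) {
  stopifnot(inherits(scenario, "thrombo_scenario"))
  cfg <- scenario$config
  out <- list(scenario = cfg$scenario, mesh_scale = cfg$mesh_scale,
              t_end = cfg$t_end, out_dt = cfg$out_dt,
              field_dt = cfg$field_dt, flow_dt = cfg$flow_dt,
              dphi_trigger = cfg$dphi_trigger, dt_max = cfg$dt_max,
              cfl = cfg$cfl, stop_at_occlusion = cfg$stop_at_occlusion,
              inlet = as.list(cfg$cin),
              params = params_serializable(scenario$params))
  if (cfg$scenario == "vessel") {
    out$inject_adp <- cfg$inject_adp
  } else {
    out$L_c <- cfg$L_c
  }
  writeLines(yaml::as.yaml(out, precision = 17), path)
  invisible(path)
}

## ---------------------------------------------------------------------------
## VTK output (legacy ASCII rectilinear grid, cell data), ParaView-readable
## ---------------------------------------------------------------------------

fmt17 <- function(x) formatC(x, format = "g", digits = 17)

#' Write fields to a legacy VTK rectilinear-grid file
#'
#' One file per checkpoint, holding phi, pressure, shear rate, the cell
#' centred velocity vector and all ten species as CELL_DATA on the grid's
#' face coordinates. Values are written at full double precision so that a
#' written checkpoint restores bit-exactly.
#'
#' @param state a [species_state()] of nx-by-ny matrices.
#' @param flow a `thrombo_flow` (or `NULL`).
#' @param phi deposited-fraction matrix (or `NULL` to derive from state).
#' @param grid a `thrombo_grid`.
#' @param t time stamp encoded in the file name.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return the file path, invisibly.
#' @export
write_fields <- function(state, flow, phi, grid, t, dir, prefix = "fields") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  params_tmp <- NULL
  if (is.null(phi))
    phi <- (state$RP_d + state$AP_d + state$AP_s) / (7e10 / 2.78e-6)
  path <- file.path(dir, sprintf("%s_t%012.6f.vtk", prefix, t))
  nx <- grid$nx; ny <- grid$ny
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wl("# vtk DataFile Version 3.0")
  wl(sprintf("thrombosim fields t=%s", fmt17(t)))
  wl("ASCII")
  wl("DATASET RECTILINEAR_GRID")
  wl(sprintf("DIMENSIONS %d %d 1", nx + 1L, ny + 1L))
  wl(sprintf("X_COORDINATES %d double", nx + 1L))
  wl(paste(fmt17(grid$xf), collapse = " "))
  wl(sprintf("Y_COORDINATES %d double", ny + 1L))
  wl(paste(fmt17(grid$yf), collapse = " "))
  wl("Z_COORDINATES 1 double")
  wl("0")
  wl(sprintf("CELL_DATA %d", nx * ny))
  scalar <- function(name, m) {
    wl(sprintf("SCALARS %s double 1", name))
    wl("LOOKUP_TABLE default")
    wl(paste(fmt17(as.numeric(m)), collapse = " "))
  }
  scalar("phi", phi)
  if (!is.null(flow)) {
    scalar("p", flow$p)
    scalar("gamma", flow$gamma)
    ucc <- 0.5 * (flow$u[-1, , drop = FALSE] +
                    flow$u[-(nx + 1), , drop = FALSE])
    vcc <- 0.5 * (flow$v[, -1, drop = FALSE] +
                    flow$v[, -(ny + 1), drop = FALSE])
    wl("VECTORS velocity double")
    wl(paste(fmt17(as.numeric(rbind(as.numeric(ucc), as.numeric(vcc), 0))),
             collapse = " "))
  }
  for (s in SPECIES) scalar(s, state[[s]])
  invisible(path)
}

#' Read back cell data written by [write_fields()]
#'
#' A minimal parser for this package's own legacy-VTK output, used for
#' checkpoint/restart and round-trip verification.
#'
#' @param path a file produced by [write_fields()].
#' @return list with `xf`, `yf`, and one nx-by-ny matrix per scalar field.
#' @export
read_vtk_fields <- function(path) {
  ln <- readLines(path)
  grab_after <- function(pat) {
    i <- grep(pat, ln)[1]
    as.numeric(strsplit(trimws(ln[i + 1L]), "\\s+")[[1]])
  }
  nxy <- as.integer(strsplit(ln[grep("^DIMENSIONS", ln)], " ")[[1]][2:3]) - 1L
  nx <- nxy[1]; ny <- nxy[2]
  xf <- grab_after("^X_COORDINATES")
  yf <- grab_after("^Y_COORDINATES")
  out <- list(xf = xf, yf = yf)
  for (i in grep("^SCALARS", ln)) {
    nm <- strsplit(ln[i], " ")[[1]][2]
    vals <- as.numeric(strsplit(trimws(ln[i + 2L]), "\\s+")[[1]])
    out[[nm]] <- matrix(vals, nx, ny)
  }
  out
}

#' Write a restartable checkpoint
#'
#' Plain-text, full-precision snapshot of the ten species fields and the
#' flow state; [read_checkpoint()] restores a list directly usable as the
#' `init` argument of [run_simulation()], reproducing the uninterrupted
#' trajectory.
#'
#' @param result a `thrombo_result` (or list with `state` and `flow`).
#' @param path output file path.
#' @export
write_checkpoint <- function(result, path) {
  con <- file(path, "w")
  on.exit(close(con))
  emit <- function(name, m) {
    writeLines(sprintf("# %s %d %d", name, nrow(m), ncol(m)), con)
    writeLines(paste(fmt17(as.numeric(m)), collapse = " "), con)
  }
  for (s in SPECIES) emit(s, result$state[[s]])
  emit("u", result$flow$u); emit("v", result$flow$v)
  emit("p", result$flow$p)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  ln <- readLines(path)
  heads <- grep("^# ", ln)
  out <- list()
  for (h in heads) {
    parts <- strsplit(ln[h], " ")[[1]]
    nm <- parts[2]
    out[[nm]] <- matrix(as.numeric(strsplit(trimws(ln[h + 1L]),
                                            "\\s+")[[1]]),
                        as.integer(parts[3]), as.integer(parts[4]))
  }
  list(C = unname(out[SPECIES]), u = out$u, v = out$v, p = out$p)
}

#' Write a morphometrics time series to CSV
#'
#' @param result a `thrombo_result`.
#' @param path output CSV path.
#' @export
write_morphometrics <- function(result, path) {
  utils::write.csv(result$morphometrics, path, row.names = FALSE)
  invisible(path)
}

## ---------------------------------------------------------------------------
## synthetic fixtures with closed-form references (test support)
## ---------------------------------------------------------------------------

#' Synthetic fields and analytic references for verification
#'
#' Generates small self-contained verification cases: `poiseuille` (tube or
#' plates geometry plus the exact profile), `advect1d` (top-hat in a
#' uniform stream), `diffuse1d` (point release with Gaussian reference),
#' `phi_plug` (rectangular deposit of known morphometrics),
#' `phi_spanning_disc` (an occlusive plug) and `wellmixed0d` (a closed 0D
#' species state). Deterministic: no randomness is used.
#'
#' @param kind fixture name.
#' @param ... kind-specific settings (documented in the source; all have
#'   defaults).
#' @return list with the synthetic inputs and the analytic `reference`.
#' @export
make_fixture <- function(kind = c("poiseuille", "advect1d", "diffuse1d",
                                  "phi_plug", "phi_spanning_disc",
                                  "wellmixed0d"), ...) {
  kind <- match.arg(kind)
  args <- list(...)
  `%||%` <- function(a, b) if (is.null(a)) b else a
  switch(kind,
    poiseuille = {
      geometry <- args$geometry %||% "tube"
      R <- args$R %||% 30e-6
      U <- args$U %||% 800e-6
      L <- args$L %||% 10 * R
      n <- args$n %||% 64L
      nzc <- args$nz %||% 24L
      mu <- args$mu %||% 3.5e-3
      if (geometry == "tube") {
        dp <- 8 * mu * L * U / R^2
        grid <- make_grid(seq(0, L, length.out = nzc + 1),
                          seq(0, R, length.out = n + 1),
                          mode = "axisymmetric",
                          side_bc = list(west = list(type = "pressure",
                                                     p = dp),
                                         east = list(type = "pressure",
                                                     p = 0),
                                         south = list(type = "axis"),
                                         north = list(type = "wall")))
        uref <- function(r) 2 * U * (1 - (r / R)^2)
        list(grid = grid, reference = uref, U_mean = U, ratio_max = 2,
             wall_shear_rate = 4 * U / R, dp = dp)
      } else {
        H <- 2 * R    # full gap between the plates
        dp <- 12 * mu * L * U / H^2
        grid <- make_grid(seq(0, L, length.out = nzc + 1),
                          seq(0, H, length.out = n + 1),
                          mode = "planar",
                          side_bc = list(west = list(type = "pressure",
                                                     p = dp),
                                         east = list(type = "pressure",
                                                     p = 0),
                                         south = list(type = "wall"),
                                         north = list(type = "wall")))
        uref <- function(y) 6 * U * (y / H) * (1 - y / H)
        list(grid = grid, reference = uref, U_mean = U, ratio_max = 1.5,
             dp = dp)
      }
    },
    advect1d = {
      L <- args$L %||% 1e-3
      n <- args$n %||% 200L
      v <- args$v %||% 1e-3
      grid <- make_grid(seq(0, L, length.out = n + 1),
                        c(0, 1e-5),
                        mode = "planar",
                        side_bc = list(west = list(type = "inlet", u = v),
                                       east = list(type = "pressure", p = 0),
                                       south = list(type = "symmetry"),
                                       north = list(type = "symmetry")))
      xc <- grid$xc
      C0 <- matrix(as.numeric(xc > 0.2 * L & xc < 0.3 * L), n, 1)
      list(grid = grid, C0 = C0, v = v,
           com0 = sum(xc * C0) / sum(C0))
    },
    diffuse1d = {
      L <- args$L %||% 2e-3
      n <- args$n %||% 400L
      D <- args$D %||% 2.57e-10
      grid <- make_grid(seq(0, L, length.out = n + 1),
                        c(0, 1e-5),
                        mode = "planar",
                        side_bc = list(west = list(type = "wall"),
                                       east = list(type = "wall"),
                                       south = list(type = "symmetry"),
                                       north = list(type = "symmetry")))
      C0 <- matrix(0, n, 1)
      C0[n %/% 2, 1] <- 1 / grid$dx[n %/% 2]   # unit-mass point release
      list(grid = grid, C0 = C0, D = D,
           variance = function(t) 2 * D * t,
           reference = function(x, t)
             stats::dnorm(x, mean = grid$xc[n %/% 2], sd = sqrt(2 * D * t)))
    },
    phi_plug = {
      h <- args$h %||% 10e-6
      l <- args$l %||% 25e-6
      R <- args$R %||% 30e-6
      L <- args$L %||% 100e-6
      n <- args$n %||% 24L
      nzc <- args$nz %||% 40L
      grid <- make_grid(seq(0, L, length.out = nzc + 1),
                        seq(0, R, length.out = n + 1),
                        mode = "axisymmetric",
                        side_bc = list(west = list(type = "pressure", p = 1),
                                       east = list(type = "pressure", p = 0),
                                       south = list(type = "axis"),
                                       north = list(type = "wall")))
      phi <- outer(grid$xc, grid$yc, function(x, y)
        as.numeric(x >= 0.4 * L & x < 0.4 * L + l & y > R - h))
      list(grid = grid, phi = phi, height = h, length = l)
    },
    phi_spanning_disc = {
      R <- args$R %||% 30e-6
      L <- args$L %||% 100e-6
      n <- args$n %||% 16L
      nzc <- args$nz %||% 32L
      grid <- make_grid(seq(0, L, length.out = nzc + 1),
                        seq(0, R, length.out = n + 1),
                        mode = "axisymmetric",
                        side_bc = list(west = list(type = "pressure", p = 1),
                                       east = list(type = "pressure", p = 0),
                                       south = list(type = "axis"),
                                       north = list(type = "wall")))
      phi <- outer(grid$xc, grid$yc, function(x, y)
        0.9 * (x >= 0.3 * L & x <= 0.7 * L))
      list(grid = grid, phi = phi)
    },
    wellmixed0d = {
      rp <- args$RP %||% 6e14
      list(state = species_state(RP = rp, AP = 0.01 * rp, PT = 1.1e6,
                                 AT = 2.844e6))
    })
}
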