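## Structured 2D finite-volume grids: planar x-y or axisymmetric z-r
## (streamwise coordinate first, wall-normal/radial second). Spacings may be
## non-uniform per axis; blocked ("solid") cells carve non-rectangular
## domains such as a wall crevice. Axisymmetric volumes and face areas carry
## the radius weight (the common 2*pi factor is kept out of the internal
## metric and applied only where integrated volumes are reported).

#' Build a structured 2D grid
#'
#' @param xf strictly increasing streamwise face coordinates (m), length nx+1.
#' @param yf strictly increasing wall-normal (planar) or radial
#'   (axisymmetric) face coordinates (m), length ny+1; axisymmetric grids
#'   must start at the axis, `yf[1] == 0`.
#' @param mode `"planar"` or `"axisymmetric"`.
#' @param solid logical nx-by-ny matrix of blocked cells (default none).
#' @param side_bc list with entries `west`, `east`, `south`, `north`; each a
#'   list with `type` in `"wall"`, `"inlet"` (prescribed velocity; give
#'   `u` as scalar mean or per-row profile), `"pressure"` (give `p`),
#'   `"symmetry"`, or `"axis"`.
#' @param patches data.frame of boundary materials with columns `patch`
#'   (integer id), `kind`, `k_rpd_b`, `k_apd_b`, `tau_emb_b`, `port_conc`,
#'   `port_area`. Patch 1 is the default inert wall.
#' @param wall_faces data.frame assigning wall faces to patches, columns
#'   `i`, `j` (fluid cell), `side` (1=west, 2=east, 3=south, 4=north) and
#'   `patch`. Faces not listed default to patch 1.
#' @return an object of class `thrombo_grid`.
#' @export
make_grid <- function(xf, yf, mode = c("planar", "axisymmetric"),
                      solid = NULL, side_bc = NULL,
                      patches = NULL, wall_faces = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(xf) >= 3, length(yf) >= 2,
            all(diff(xf) > 0), all(diff(yf) > 0))
  if (mode == "axisymmetric" && abs(yf[1]) > 1e-15)
    stop("axisymmetric grids must start at the axis (yf[1] = 0)",
         call. = FALSE)
  nx <- length(xf) - 1L
  ny <- length(yf) - 1L
  if (is.null(solid)) solid <- matrix(FALSE, nx, ny)
  stopifnot(identical(dim(solid), c(nx, ny)))
  if (is.null(side_bc))
    side_bc <- list(west = list(type = "wall"), east = list(type = "wall"),
                    south = list(type = "wall"), north = list(type = "wall"))
  if (mode == "axisymmetric") side_bc$south <- list(type = "axis")
  if (is.null(patches))
    patches <- data.frame(patch = 1L, kind = "wall", k_rpd_b = 0,
                          k_apd_b = 0, tau_emb_b = 30, port_conc = 0,
                          port_area = 0)
  if (is.null(wall_faces))
    wall_faces <- data.frame(i = integer(0), j = integer(0),
                             side = integer(0), patch = integer(0))
  g <- list(mode = mode, nx = nx, ny = ny, xf = xf, yf = yf,
            xc = 0.5 * (xf[-1] + xf[-(nx + 1)]),
            yc = 0.5 * (yf[-1] + yf[-(ny + 1)]),
            dx = diff(xf), dy = diff(yf),
            solid = solid, side_bc = side_bc,
            patches = patches, wall_faces = wall_faces)
  class(g) <- "thrombo_grid"
  g
}

## radius weight at cell centers (1 for planar)
radius_weight <- function(grid) {
  if (grid$mode == "axisymmetric") grid$yc else rep(1, grid$ny)
}

## radius weight at y faces (1 for planar)
radius_weight_face <- function(grid) {
  if (grid$mode == "axisymmetric") grid$yf else rep(1, grid$ny + 1L)
}

#' Cell volumes and face areas of a grid
#'
#' Axisymmetric metrics include the radius factor; the 2*pi factor is
#' omitted (applied only in reported integrated volumes).
#'
#' @param grid a `thrombo_grid`.
#' @return `cell_volumes`: nx-by-ny matrix of cell volumes (solid cells
#'   included). `face_area_x`: (nx+1)-by-ny matrix of streamwise-face
#'   areas. `face_area_y`: nx-by-(ny+1) matrix of wall-normal-face areas.
#' @export
cell_volumes <- function(grid) {
  outer(grid$dx, grid$dy * radius_weight(grid))
}

#' @rdname cell_volumes
#' @export
face_area_x <- function(grid) {
  matrix(rep(grid$dy * radius_weight(grid), each = grid$nx + 1L),
         grid$nx + 1L, grid$ny)
}

#' @rdname cell_volumes
#' @export
face_area_y <- function(grid) {
  outer(grid$dx, radius_weight_face(grid))
}

#' @export
print.thrombo_grid <- function(x, ...) {
  cat("<thrombo_grid> ", x$mode, ", ", x$nx, " x ", x$ny, " cells, ",
      sum(x$solid), " solid\n", sep = "")
  cat("  x: [", min(x$xf) * 1e3, ",", max(x$xf) * 1e3, "] mm;  y: [",
      min(x$yf) * 1e3, ",", max(x$yf) * 1e3, "] mm\n")
  invisible(x)
}

## Graded 1D spacing: n cells from a to b with spacing growing geometrically
## from h0 at the `from` end by ratio r (capped so the interval is filled
## exactly; used for boundary-layer style grids).
graded_faces <- function(a, b, h0, ratio = 1.0, from = c("start", "end")) {
  from <- match.arg(from)
  L <- b - a
  stopifnot(L > 0, h0 > 0, ratio >= 1)
  h <- numeric(0)
  s <- 0
  hc <- h0
  while (s + hc < L - 1e-12) {
    h <- c(h, hc)
    s <- s + hc
    hc <- hc * ratio
  }
  h <- c(h, L - s)
  ## merge a trailing sliver into the last full cell
  n <- length(h)
  if (n > 1 && h[n] < 0.4 * h[n - 1]) {
    h[n - 1] <- h[n - 1] + h[n]
    h <- h[-n]
  }
  if (from == "end") h <- rev(h)
  a + cumsum(c(0, h))
}
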