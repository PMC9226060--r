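#' Construct a posterior-pole superpixel grid
#'
#' Builds the square lattice of thickness-averaging cells overlaid on the
#' central 24 x 24 degrees of the macula, centred on the fovea. The
#' conventional scheme (`"CMA"`) uses 8 x 8 superpixels of 3 x 3 degrees,
#' as in the posterior pole analysis of commercial OCT software; the localized
#' scheme (`"LMA"`) uses 12 x 12 superpixels of 2 x 2 degrees, whose cell
#' centres coincide with the 10-2 stimulus locations.
#'
#' Superpixel ids S1..S(n^2) run row-major from the superior corner of the
#' grid: the first row is the most superior (largest `y`), columns increase
#' with `x`. Coordinates are right-eye degrees with the retinal correspondence
#' given by the vertical flip of the visual field (see [flip_vertical()]).
#'
#' @param scheme `"CMA"` (8 x 8, 3 degree cells) or `"LMA"` (12 x 12, 2 degree
#'   cells).
#' @return An object of class `superpixel_grid`: a list with elements
#'   `scheme`, `n`, `cell_size`, `center`, `rotation` (degrees), `excluded`
#'   (integer superpixel ids).
#' @export
#' @examples
#' g <- superpixel_grid("CMA")
#' g$n^2  # 64 superpixels
superpixel_grid <- function(scheme = c("CMA", "LMA")) {
  scheme <- match.arg(scheme)
  n <- if (scheme == "CMA") 8L else 12L
  structure(
    list(scheme = scheme, n = n, cell_size = 24 / n,
         center = c(0, 0), rotation = 0, excluded = integer(0)),
    class = "superpixel_grid")
}

#' Rotate a superpixel grid about the fovea
#'
#' The grid is rotated by the fovea-to-Bruch's-membrane-opening-centre (FoBMO)
#' angle so that thickness averaging follows the anatomical axis of each eye
#' while the analysis grid stays horizontal. Cell membership tests
#' counter-rotate query coordinates about the fovea; distances between
#' superpixel centres are unchanged by rotation.
#'
#' @param grid A `superpixel_grid`.
#' @param angle_deg Rotation in degrees, positive counter-clockwise.
#' @return The rotated grid.
#' @export
rotate_grid <- function(grid, angle_deg) {
  stopifnot(is.finite(angle_deg))
  grid$rotation <- grid$rotation + angle_deg
  grid
}

# 2-column rotation about the grid centre (degrees, counter-clockwise)
rotate_xy <- function(xy, angle_deg, center = c(0, 0)) {
  th <- angle_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
  sweep(sweep(xy, 2L, center) %*% t(R), 2L, center, `+`)
}

# 0-based cell index along one axis with the peripheral-side tie-break:
# a coordinate lying exactly on an interior cell boundary joins the cell
# farther from fixation. Returns NA outside [-half, half].
cell_index_1d <- function(v, cell, half = 12) {
  idx <- floor((v + half) / cell)
  res <- (v + half) - idx * cell
  on_boundary <- (res < 1e-9 | cell - res < 1e-9)
  idx[on_boundary & v < 0] <- idx[on_boundary & v < 0] - 1L
  n <- as.integer(round(2 * half / cell))
  idx[on_boundary & abs(v - half) < 1e-9] <- n - 1L  # outer edge stays inside
  idx[v < -half - 1e-9 | v > half + 1e-9] <- NA_integer_
  as.integer(idx)
}

#' Locate the superpixel containing a point
#'
#' Query coordinates are counter-rotated by the grid rotation about the fovea
#' and assigned to cells with half-open intervals whose closed edge lies on the
#' peripheral side: a point exactly on a cell boundary joins the cell farther
#' from fixation.
#'
#' @param grid A `superpixel_grid`.
#' @param x,y Coordinates in degrees (vectors allowed).
#' @return Integer superpixel ids (row-major from the superior corner).
#' @export
locate_superpixel <- function(grid, x, y) {
  xy <- rotate_xy(cbind(x, y), -grid$rotation, grid$center)
  half <- grid$n * grid$cell_size / 2
  col <- cell_index_1d(xy[, 1L] - grid$center[1L], grid$cell_size, half)
  iy <- cell_index_1d(xy[, 2L] - grid$center[2L], grid$cell_size, half)
  if (anyNA(col) || anyNA(iy)) {
    stop("location outside the superpixel grid extent", call. = FALSE)
  }
  row <- grid$n - 1L - iy  # row 1 is the most superior
  as.integer(row * grid$n + col + 1L)
}

#' Superpixel centres and distances
#'
#' `superpixel_centers()` returns the centres of all cells in the analysis
#' frame (rotation applied about the fovea); `superpixel_center()` the centre
#' of one cell; `superpixel_distance()` the Euclidean distance in degrees
#' between two cell centres, which is the length scale of correlation vectors.
#'
#' @param grid A `superpixel_grid`.
#' @return `superpixel_centers()`: data frame with `id`, `x`, `y`.
#' @export
superpixel_centers <- function(grid) {
  n <- grid$n; cs <- grid$cell_size
  half <- n * cs / 2
  col <- (seq_len(n * n) - 1L) %% n
  row <- (seq_len(n * n) - 1L) %/% n
  xy <- cbind(x = grid$center[1L] - half + (col + 0.5) * cs,
              y = grid$center[2L] + half - (row + 0.5) * cs)
  xy <- rotate_xy(xy, grid$rotation, grid$center)
  data.frame(id = seq_len(n * n), x = xy[, 1L], y = xy[, 2L])
}

#' @rdname superpixel_centers
#' @param id,id_a,id_b Superpixel ids in `1..n^2`.
#' @export
superpixel_center <- function(grid, id) {
  ctr <- superpixel_centers(grid)
  if (any(!id %in% ctr$id)) stop("invalid superpixel id", call. = FALSE)
  as.matrix(ctr[match(id, ctr$id), c("x", "y"), drop = FALSE])
}

#' @rdname superpixel_centers
#' @export
superpixel_distance <- function(grid, id_a, id_b) {
  a <- superpixel_center(grid, id_a)
  b <- superpixel_center(grid, id_b)
  unname(sqrt(rowSums((a - b)^2)))
}

#' Exclude superpixels overlying the optic nerve head
#'
#' Superpixels whose centre falls within the optic disc circle are flagged as
#' excluded: their thickness carries no ganglion cell information and they are
#' masked from correlation atlases and vector targets. With the default
#' anatomical disc position (about 15.5 degrees nasal, just below the
#' horizontal) the disc lies outside the 24-degree grid and nothing is
#' excluded.
#'
#' @param grid A `superpixel_grid`.
#' @param disc_center Numeric length 2, disc centre in degrees (right-eye
#'   retinal coordinates).
#' @param disc_radius Disc radius in degrees.
#' @return The grid with its `excluded` set updated.
#' @export
apply_onh_exclusion <- function(grid, disc_center = c(15.5, -1.5),
                                disc_radius = 2.0) {
  ctr <- superpixel_centers(grid)
  d2 <- (ctr$x - disc_center[1L])^2 + (ctr$y - disc_center[2L])^2
  grid$excluded <- sort(unique(c(grid$excluded, ctr$id[d2 <= disc_radius^2])))
  grid
}

#' @export
print.superpixel_grid <- function(x, ...) {
  cat(sprintf("%s superpixel grid: %d x %d cells of %g deg, rotation %g deg",
              x$scheme, x$n, x$n, x$cell_size, x$rotation))
  if (length(x$excluded)) {
    cat(sprintf(", %d excluded", length(x$excluded)))
  }
  cat("\n")
  invisible(x)
}
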