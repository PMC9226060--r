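#' Generate the 10-2 perimetric test pattern
#'
#' Constructs the 68-location central test pattern used by standard automated
#' perimetry and fundus-tracking perimetry within the central 10 degrees of the
#' visual field. Locations lie on the odd-integer lattice (2 degrees apart in
#' both directions) and satisfy `x^2 + y^2 <= 82`, which yields exactly 68
#' locations, 17 per quadrant, with none on the horizontal or vertical axis.
#'
#' Coordinates follow the right-eye visual-field convention: positive `x` is
#' the temporal field, positive `y` the superior field, in degrees of visual
#' angle. Location ids are assigned row-wise from the superior-most row,
#' left to right, matching the usual perimetric printout order.
#'
#' @return A data frame of class `vf_pattern` with columns `id`, `x`, `y`
#'   and attribute `spacing` (degrees between neighbouring locations).
#' @seealso [read_vf_pattern()] to substitute a device-exact coordinate table.
#' @export
#' @examples
#' p <- vf_pattern_10_2()
#' nrow(p)  # 68
vf_pattern_10_2 <- function() {
  v <- seq(-9L, 9L, 2L)
  pts <- expand.grid(x = v, y = v, KEEP.OUT.ATTRS = FALSE)
  pts <- pts[pts$x^2 + pts$y^2 <= 82L, , drop = FALSE]
  pts <- pts[order(-pts$y, pts$x), , drop = FALSE]
  new_vf_pattern(data.frame(id = seq_len(nrow(pts)), x = pts$x, y = pts$y))
}

new_vf_pattern <- function(df, spacing = 2) {
  rownames(df) <- NULL
  structure(df, spacing = spacing, class = c("vf_pattern", "data.frame"))
}

validate_vf_pattern <- function(p) {
  stopifnot(is.data.frame(p), all(c("id", "x", "y") %in% names(p)))
  if (anyDuplicated(p[, c("x", "y")])) {
    stop("duplicate locations in visual field pattern", call. = FALSE)
  }
  invisible(p)
}

#' Read or write a visual field pattern coordinate table
#'
#' A pattern file is a CSV with columns `id`, `x`, `y` (degrees, right-eye
#' visual-field convention). This allows a device-exact coordinate table to be
#' substituted for the generated pattern.
#'
#' @param path File path.
#' @return `read_vf_pattern()` returns a `vf_pattern`; `write_vf_pattern()`
#'   returns `path` invisibly.
#' @export
read_vf_pattern <- function(path) {
  df <- utils::read.csv(path)
  validate_vf_pattern(df)
  new_vf_pattern(df[, c("id", "x", "y")])
}

#' @rdname read_vf_pattern
#' @param pattern A `vf_pattern`.
#' @export
write_vf_pattern <- function(pattern, path) {
  utils::write.csv(as.data.frame(pattern)[, c("id", "x", "y")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Flip a pattern across the horizontal midline
#'
#' Visual-field locations are flipped along the horizontal midline (`y` is
#' negated) so that they correspond to the retinal hemifield imaged by OCT:
#' a stimulus in the superior field is seen by the inferior retina.
#' Location ids are preserved; the operation is an involution.
#'
#' @param pattern A `vf_pattern` (or any data frame with a `y` column).
#' @return The flipped pattern, same class and ids.
#' @export
flip_vertical <- function(pattern) {
  pattern$y <- -pattern$y
  pattern
}

#' Convert coordinates to right-eye format
#'
#' Left-eye data are mirrored horizontally (`x` negated) so that all eyes share
#' the right-eye convention; right-eye data are returned unchanged. Applying
#' the conversion twice to a left eye restores the original coordinates.
#'
#' @param coords A data frame with columns `x` and `y` (a `vf_pattern` works).
#' @param laterality `"right"` or `"left"`.
#' @return `coords` with `x` mirrored for left eyes.
#' @export
to_right_eye_format <- function(coords, laterality) {
  laterality <- match.arg(laterality, c("right", "left"))
  if (laterality == "left") coords$x <- -coords$x
  coords
}

#' @export
print.vf_pattern <- function(x, ...) {
  cat(sprintf("Visual field test pattern: %d locations, %g deg spacing\n",
              nrow(x), attr(x, "spacing")))
  print(utils::head(as.data.frame(x), 4L))
  if (nrow(x) > 4L) cat(sprintf("... and %d more locations\n", nrow(x) - 4L))
  invisible(x)
}
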