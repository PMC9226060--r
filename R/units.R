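#' Assign visual field locations to superpixels, forming VF units
#'
#' Overlays a (vertically flipped) 10-2 pattern on a superpixel grid and builds
#' the unit map used for structure-function correlation.
#'
#' Under the conventional scheme (`"CMA"`) each location joins the superpixel
#' containing it (boundary ties broken toward the peripheral cell, away from
#' fixation); every non-empty superpixel becomes one visual field unit whose
#' member sensitivities are later averaged. On the standard 8 x 8 / 3-degree
#' grid this produces 40 units of 1 to 4 locations. Under the localized scheme
#' (`"LMA"`) every location is its own unit and its mapped superpixel is the
#' 2 x 2 degree cell centred on it, so all 68 units are singletons.
#'
#' @param pattern A `vf_pattern`, already flipped to retinal orientation
#'   (see [flip_vertical()]) and in right-eye format.
#' @param grid A `superpixel_grid`; its rotation is honoured when locating
#'   cells.
#' @param scheme Mapping scheme; defaults to the grid's scheme.
#' @return A data frame of class `vf_unit_map` with one row per location:
#'   columns `unit_id` (C1..C40 or L1..L68), `scheme`, `location_id`, `x_deg`,
#'   `y_deg`, `superpixel_id`; attributes `grid`, `scheme` and `units`
#'   (one row per unit: `unit_id`, `superpixel_id`, `n_members`).
#' @export
#' @examples
#' p <- flip_vertical(vf_pattern_10_2())
#' um <- assign_units(p, superpixel_grid("CMA"))
#' nrow(attr(um, "units"))  # 40
assign_units <- function(pattern, grid, scheme = grid$scheme) {
  scheme <- match.arg(scheme, c("CMA", "LMA"))
  validate_vf_pattern(pattern)
  sp <- locate_superpixel(grid, pattern$x, pattern$y)

  if (scheme == "LMA") {
    ord <- order(pattern$id)
    df <- data.frame(unit_id = paste0("L", seq_along(ord)),
                     scheme = scheme,
                     location_id = pattern$id[ord],
                     x_deg = pattern$x[ord], y_deg = pattern$y[ord],
                     superpixel_id = sp[ord])
  } else {
    # order units by grid position (row-major), i.e. by superpixel id
    usp <- sort(unique(sp))
    unit_of_sp <- stats::setNames(paste0("C", seq_along(usp)), usp)
    df <- data.frame(unit_id = unname(unit_of_sp[as.character(sp)]),
                     scheme = scheme,
                     location_id = pattern$id,
                     x_deg = pattern$x, y_deg = pattern$y,
                     superpixel_id = sp)
    df <- df[order(df$superpixel_id, df$location_id), ]
  }
  rownames(df) <- NULL
  units <- unique(df[, c("unit_id", "superpixel_id")])
  units$n_members <- as.integer(table(df$unit_id)[units$unit_id])
  rownames(units) <- NULL
  structure(df, grid = grid, scheme = scheme, units = units,
            class = c("vf_unit_map", "data.frame"))
}

#' Units of a unit map
#'
#' @param unit_map A `vf_unit_map`.
#' @return Data frame with `unit_id`, `superpixel_id`, `n_members`.
#' @export
unit_table <- function(unit_map) attr(unit_map, "units")

#' Export a unit map
#'
#' Writes the per-location table (`unit_id`, `scheme`, `location_id`, `x_deg`,
#' `y_deg`, `superpixel_id`) as CSV or JSON.
#'
#' @param unit_map A `vf_unit_map`.
#' @param path Output file; format chosen by extension (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_unit_map <- function(unit_map, path) {
  df <- as.data.frame(unit_map)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(df, path, dataframe = "rows", digits = NA)
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' @export
print.vf_unit_map <- function(x, ...) {
  u <- attr(x, "units")
  cat(sprintf("%s unit map: %d units over %d locations (sizes %s)\n",
              attr(x, "scheme"), nrow(u), nrow(x),
              paste(sort(unique(u$n_members)), collapse = "/")))
  invisible(x)
}
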