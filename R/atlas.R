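#' Decibel / linear sensitivity conversion
#'
#' Perimetric sensitivity in dB is `10 * log10(1/L)` of the threshold stimulus
#' luminance `L` (in relative units), so the linear (reciprocal-luminance)
#' sensitivity is `10^(dB/10)`: 0 dB maps to 1, each 10 dB is a tenfold gain.
#'
#' @param db,linear Values to convert (vectors allowed).
#' @return The converted values.
#' @export
db_to_linear <- function(db) 10^(db / 10)

#' @rdname db_to_linear
#' @export
linear_to_db <- function(linear) 10 * log10(linear)

#' Average sensitivity within visual field units
#'
#' Sensitivities are converted to the linear scale and averaged arithmetically
#' over the member locations of each unit (set `average_scale = "db"` to
#' average in dB before conversion instead).
#'
#' @param exam An exam data frame (`location_id`, `sensitivity_db`).
#' @param unit_map A `vf_unit_map`.
#' @param average_scale `"linear"` (default) or `"db"`.
#' @return Named vector of per-unit mean linear sensitivities.
#' @export
unit_sensitivity <- function(exam, unit_map, average_scale = "linear") {
  i <- match(unit_map$location_id, exam$location_id)
  if (anyNA(i)) stop("exam is missing locations of the unit map", call. = FALSE)
  db <- exam$sensitivity_db[i]
  u <- factor(unit_map$unit_id, levels = unique(unit_map$unit_id))
  if (identical(average_scale, "linear")) {
    v <- tapply(db_to_linear(db), u, mean)
  } else {
    v <- db_to_linear(tapply(db, u, mean))
  }
  stats::setNames(as.numeric(v), levels(u))
}

# subjects x units matrix of linearized unit sensitivities
unit_sensitivity_matrix <- function(sens_db, unit_map,
                                    average_scale = "linear") {
  loc <- unit_map$location_id
  u <- factor(unit_map$unit_id, levels = unique(unit_map$unit_id))
  agg <- t(sapply(levels(u), function(uu) {
    cols <- loc[u == uu]
    if (identical(average_scale, "linear")) {
      rowMeans(db_to_linear(sens_db[, cols, drop = FALSE]))
    } else {
      db_to_linear(rowMeans(sens_db[, cols, drop = FALSE]))
    }
  }))
  t(agg)
}

#' Exhaustive correlation atlas between VF units and OCT superpixels
#'
#' For every visual field unit of the mapping scheme, computes the Pearson
#' correlation (across all subjects, patients and healthy pooled) between
#' the unit's mean linear sensitivity and the layer thickness in every
#' superpixel of the grid - not only the mapped one. The result is a
#' units-by-superpixels matrix whose rows are the per-unit correlation
#' heatmaps.
#'
#' Pairs in which either side has zero variance across subjects are undefined
#' and stored as `NA`; superpixels excluded for the optic nerve head are
#' masked the same way. A cohort in which every pair is undefined (e.g.
#' healthy subjects with no noise) is degenerate and raises an error rather
#' than returning a silent atlas.
#'
#' @param cohort An `sf_cohort` with at least 3 subjects.
#' @param unit_map A `vf_unit_map` built on the flipped pattern.
#' @param layer `"GCL"` or `"IPL"`.
#' @param modality `"standard"` or `"tracked"` perimetry.
#' @param average_scale Passed to [unit_sensitivity()].
#' @return A matrix of class `sf_atlas` (rows: units, columns: superpixels)
#'   with attributes `scheme`, `layer`, `modality`, `n_subjects`, `unit_map`,
#'   `grid`, `n_undefined`.
#' @export
correlation_atlas <- function(cohort, unit_map,
                              layer = c("GCL", "IPL"),
                              modality = c("standard", "tracked"),
                              average_scale = "linear") {
  layer <- match.arg(layer)
  modality <- match.arg(modality)
  grid <- attr(unit_map, "grid")
  scheme <- attr(unit_map, "scheme")
  if (length(cohort$subjects) < 3L) {
    stop("correlation atlas requires at least 3 subjects", call. = FALSE)
  }
  Th <- cohort_thickness(cohort, scheme, layer)
  Se <- cohort_sensitivity(cohort, modality)
  U <- unit_sensitivity_matrix(Se, unit_map, average_scale)
  r <- suppressWarnings(stats::cor(U, Th))
  r[, grid$excluded] <- NA_real_
  if (all(is.na(r))) {
    stop("degenerate cohort: no between-subject variance anywhere; ",
         "correlation atlas is undefined", call. = FALSE)
  }
  dimnames(r) <- list(unit_table(unit_map)$unit_id,
                      paste0("S", seq_len(ncol(Th))))
  structure(r, scheme = scheme, layer = layer, modality = modality,
            n_subjects = nrow(Th), unit_map = unit_map, grid = grid,
            n_undefined = sum(is.na(r)) - nrow(r) * length(grid$excluded),
            class = c("sf_atlas", "matrix", "array"))
}

#' @export
print.sf_atlas <- function(x, ...) {
  cat(sprintf("Correlation atlas (%s, %s, %s perimetry): %d units x %d superpixels, n = %d subjects\n",
              attr(x, "scheme"), attr(x, "layer"), attr(x, "modality"),
              nrow(x), ncol(x), attr(x, "n_subjects")))
  fin <- x[is.finite(x)]
  if (length(fin)) {
    cat(sprintf("  r range: [%.2f, %.2f]; undefined entries: %d\n",
                min(fin), max(fin), sum(is.na(x))))
  }
  invisible(x)
}

#' Long-format view of an atlas
#'
#' @param x An `sf_atlas`.
#' @param ... Unused.
#' @return Data frame with `unit_id`, `superpixel_id`, `layer`, `r`.
#' @export
as.data.frame.sf_atlas <- function(x, ...) {
  data.frame(unit_id = rep(rownames(x), times = ncol(x)),
             superpixel_id = rep(seq_len(ncol(x)), each = nrow(x)),
             layer = attr(x, "layer"),
             r = as.vector(unclass(x)))
}
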