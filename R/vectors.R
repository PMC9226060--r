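#' Maximum-correlation vector map
#'
#' For each visual field unit, finds the superpixel whose thickness is
#' maximally correlated with the unit's sensitivity and draws a vector from
#' the unit's mapped superpixel to that target. Masked (optic nerve head) and
#' undefined entries never participate in the argmax. Correlations within
#' `tie_tol` of the maximum are treated as tied; ties are broken first by the
#' smallest centre distance to the mapped superpixel (conservative toward a
#' "hit") and then by the lowest superpixel id. Vector length is the Euclidean
#' distance between superpixel centres, in degrees; a unit whose atlas row is
#' entirely undefined yields an `NA` row.
#'
#' @param atlas An `sf_atlas`.
#' @param tie_tol Absolute tolerance for declaring tied correlations.
#' @return A data frame of class `sf_vector_map` with one row per unit:
#'   `unit_id`, `mapped_superpixel`, `target_superpixel`, `r_max`,
#'   `length_deg`, `hit` (length zero), `crosses_midline` (mapped and target
#'   centres on opposite sides of the horizontal midline).
#' @export
vector_map <- function(atlas, tie_tol = 1e-9) {
  unit_map <- attr(atlas, "unit_map")
  grid <- attr(atlas, "grid")
  units <- unit_table(unit_map)
  ctr <- superpixel_centers(grid)

  rows <- lapply(seq_len(nrow(units)), function(i) {
    r <- unclass(atlas)[i, ]
    mapped <- units$superpixel_id[i]
    ok <- which(is.finite(r))
    if (length(ok) == 0L) {
      return(data.frame(unit_id = units$unit_id[i],
                        mapped_superpixel = mapped,
                        target_superpixel = NA_integer_, r_max = NA_real_,
                        length_deg = NA_real_, hit = NA,
                        crosses_midline = NA))
    }
    rmax <- max(r[ok])
    tied <- ok[r[ok] >= rmax - tie_tol]
    d_mapped <- superpixel_distance(grid, tied, rep(mapped, length(tied)))
    tied <- tied[order(d_mapped, tied)]
    target <- tied[1L]
    len <- superpixel_distance(grid, target, mapped)
    data.frame(unit_id = units$unit_id[i],
               mapped_superpixel = mapped,
               target_superpixel = as.integer(target),
               r_max = unname(r[target]),
               length_deg = unname(len),
               hit = unname(len) < 1e-9,
               crosses_midline = ctr$y[ctr$id == mapped] *
                 ctr$y[ctr$id == target] < 0)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, scheme = attr(atlas, "scheme"), layer = attr(atlas, "layer"),
            modality = attr(atlas, "modality"), grid = grid,
            unit_map = unit_map,
            class = c("sf_vector_map", "data.frame"))
}

#' Summarize a vector map
#'
#' @param vmap An `sf_vector_map`.
#' @return A list: `n_units`, `n_defined` (units with a defined vector),
#'   `hit_count`, `hit_rate` (fraction of defined vectors with zero length),
#'   `median_nonzero_length` (degrees, `NA` when every vector is a hit),
#'   `crossings` (vectors crossing the horizontal midline).
#' @export
summarize_vectors <- function(vmap) {
  def <- vmap[!is.na(vmap$hit), ]
  nz <- def$length_deg[def$length_deg > 0]
  list(n_units = nrow(vmap),
       n_defined = nrow(def),
       hit_count = sum(def$hit),
       hit_rate = if (nrow(def)) sum(def$hit) / nrow(def) else NA_real_,
       median_nonzero_length = if (length(nz)) stats::median(nz) else NA_real_,
       crossings = sum(def$crosses_midline))
}

#' Split per-unit maximum correlations by hemimacula
#'
#' Groups the maximum correlation of each unit by the retinal hemifield
#' (superior/inferior) of its mapped superpixel centre.
#'
#' @param x An `sf_vector_map`, or an `sf_atlas` (converted internally with
#'   [vector_map()]).
#' @return A list with numeric vectors `superior` and `inferior`.
#' @export
hemimacula_split <- function(x) {
  if (inherits(x, "sf_atlas")) x <- vector_map(x)
  grid <- attr(x, "grid")
  ctr <- superpixel_centers(grid)
  y <- ctr$y[match(x$mapped_superpixel, ctr$id)]
  list(superior = x$r_max[y > 0], inferior = x$r_max[y < 0])
}

#' @export
print.sf_vector_map <- function(x, ...) {
  s <- summarize_vectors(x)
  cat(sprintf("Vector map (%s, %s, %s perimetry): %d units, %d hits (%.0f%%), median nonzero length %s deg\n",
              attr(x, "scheme"), attr(x, "layer"), attr(x, "modality"),
              s$n_units, s$hit_count, 100 * s$hit_rate,
              format(round(s$median_nonzero_length, 2))))
  invisible(x)
}
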