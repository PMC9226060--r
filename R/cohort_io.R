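#' Export and import a cohort
#'
#' A cohort directory contains `thickness.csv` (subject_id, scheme, layer,
#' superpixel_id, thickness), `sensitivity.csv` (subject_id, modality,
#' location_id, sensitivity_db) and `manifest.json` with the seed, simulation
#' parameters and per-subject ground truth (diagnosis, laterality, FoBMO
#' angle, damage patterns, severity metrics). Re-exporting the same cohort is
#' byte-identical; `read_cohort()` reconstructs a working `sf_cohort`.
#'
#' @param cohort An `sf_cohort`.
#' @param dir Directory to write into (created if needed).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` an
#'   `sf_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  thick <- do.call(rbind, lapply(cohort$subjects, function(s) {
    cbind(subject_id = s$spec$id, s$thickness)
  }))
  utils::write.csv(thick[, c("subject_id", "scheme", "layer",
                             "superpixel_id", "thickness")],
                   file.path(dir, "thickness.csv"), row.names = FALSE)
  sens <- do.call(rbind, lapply(cohort$subjects, function(s) {
    do.call(rbind, lapply(names(s$exams), function(m) {
      data.frame(subject_id = s$spec$id, modality = m,
                 location_id = s$exams[[m]]$location_id,
                 sensitivity_db = s$exams[[m]]$sensitivity_db)
    }))
  }))
  utils::write.csv(sens, file.path(dir, "sensitivity.csv"), row.names = FALSE)

  manifest <- list(
    package = "macumap",
    seed = cohort$seed,
    params = serialize_params(cohort$params),
    subjects = lapply(cohort$subjects, function(s) {
      list(id = s$spec$id, diagnosis = s$spec$diagnosis,
           laterality = s$spec$laterality,
           fobmo_angle = s$spec$fobmo_angle,
           thickness_scale = s$spec$thickness_scale,
           sens_offset = s$spec$sens_offset,
           damage = lapply(s$spec$damage, unclass),
           metrics = if (!is.null(s$metrics)) as.list(s$metrics) else NULL)
    }))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

serialize_params <- function(p) {
  out <- unclass(p)
  out$profiles <- lapply(out$profiles, unclass)
  out
}

deserialize_params <- function(lst) {
  prof <- lapply(lst$profiles, function(pr) {
    normative_profile(pr$layer, pr$peak_thickness, pr$peak_eccentricity,
                      pr$foveal_thickness, pr$peripheral_floor,
                      pr$decay_scale, pr$shape)
  })
  lst$profiles <- NULL
  do.call(sim_params, c(lst, list(profiles = prof)))
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  thick <- utils::read.csv(file.path(dir, "thickness.csv"))
  sens <- utils::read.csv(file.path(dir, "sensitivity.csv"))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = FALSE)
  params <- deserialize_params(man$params)
  subjects <- lapply(man$subjects, function(s) {
    spec <- subject_spec(
      diagnosis = if (is.null(s$diagnosis) || is.na(s$diagnosis)) "healthy"
                  else s$diagnosis,
      laterality = s$laterality, fobmo_angle = s$fobmo_angle,
      damage = lapply(s$damage, function(d) {
        damage_pattern(d$hemiretina, d$angular_extent,
                       unlist(d$eccentricity_band), d$depth,
                       d$edge_softness, d$center_angle)
      }),
      thickness_scale = s$thickness_scale, sens_offset = s$sens_offset,
      id = s$id)
    spec
  })
  cohort <- sf_cohort_from_tables(thick, sens, params, subjects)
  cohort$seed <- man$seed
  for (i in seq_along(cohort$subjects)) {
    m <- man$subjects[[i]]$metrics
    if (!is.null(m)) cohort$subjects[[i]]$metrics <- as.data.frame(m)
  }
  cohort
}
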