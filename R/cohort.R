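#' Simulation parameters for synthetic cohorts
#'
#' Bundles every tunable of the cohort simulator with defaults chosen to
#' emulate a clinical glaucoma structure-function study: test-retest noise on
#' thickness and sensitivity, fixation jitter for non-tracked perimetry,
#' between-subject heterogeneity, ganglion cell displacement, the monotone
#' thickness-to-sensitivity link, and per-eye anatomical (FoBMO) rotation.
#'
#' @param thickness_noise_sd Measurement noise per superpixel, micrometres.
#' @param sens_noise_sd Sensitivity test-retest noise, dB.
#' @param jitter_sd Fixation jitter per stimulus presentation for standard
#'   (non-tracked) perimetry, degrees; tracked perimetry presents at the
#'   intended retinal location.
#' @param subject_scale_sd SD of the per-subject multiplicative thickness
#'   scale (normative anatomical variation).
#' @param subject_sens_sd SD of the per-subject additive sensitivity offset,
#'   dB.
#' @param dmax,tau Ganglion cell displacement parameters, degrees
#'   (see [displace_to_rgc()]); set `dmax = 0` to disable displacement.
#' @param max_loss Sensitivity loss at full damage, dB.
#' @param ceiling_db Upper clamp for simulated sensitivities, dB.
#' @param base_db,ecc_slope Healthy sensitivity profile
#'   (see [healthy_sensitivity()]).
#' @param fobmo_mean,fobmo_sd Per-subject FoBMO angle distribution, degrees.
#' @param n_quad Side of the fixed sample-point lattice used to average
#'   fields within each superpixel (deterministic quadrature).
#' @param profiles Named list of [normative_profile()]s for `GCL` and `IPL`.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(thickness_noise_sd = 2,
                       sens_noise_sd = 1.5,
                       jitter_sd = 1.5,
                       subject_scale_sd = 0.06,
                       subject_sens_sd = 0.8,
                       dmax = 2, tau = 3,
                       max_loss = 35,
                       ceiling_db = 35,
                       base_db = 33, ecc_slope = 0.1,
                       fobmo_mean = -7, fobmo_sd = 2.5,
                       n_quad = 5,
                       profiles = list(GCL = normative_profile("GCL"),
                                       IPL = normative_profile("IPL"))) {
  structure(as.list(environment()), class = "sim_params")
}

#' Specify one synthetic subject
#'
#' @param diagnosis `"glaucoma"` or `"healthy"`; healthy subjects must carry no
#'   damage.
#' @param laterality Eye tested, `"right"` or `"left"` (one eye per subject;
#'   all analysis is done in right-eye format).
#' @param fobmo_angle FoBMO angle of this eye, degrees.
#' @param damage List of [damage_pattern()]s (empty for healthy subjects).
#' @param thickness_scale Multiplicative thickness factor for this subject.
#' @param sens_offset Additive sensitivity offset, dB.
#' @param id Subject identifier.
#' @return A list of class `subject_spec`.
#' @export
subject_spec <- function(diagnosis = c("glaucoma", "healthy"),
                         laterality = "right",
                         fobmo_angle = -7,
                         damage = list(),
                         thickness_scale = 1,
                         sens_offset = 0,
                         id = NULL) {
  diagnosis <- match.arg(diagnosis)
  if (inherits(damage, "damage_pattern")) damage <- list(damage)
  if (diagnosis == "healthy" && length(damage) > 0L) {
    stop("healthy subjects must have an empty damage list", call. = FALSE)
  }
  structure(list(id = id, diagnosis = diagnosis, laterality = laterality,
                 fobmo_angle = fobmo_angle, damage = damage,
                 thickness_scale = thickness_scale, sens_offset = sens_offset),
            class = "subject_spec")
}

# fixed interior sample-point lattice for one grid (grid frame), plus cell ids
cell_quadrature <- function(grid, n_quad) {
  cs <- grid$cell_size
  off <- ((seq_len(n_quad) - 0.5) / n_quad - 0.5) * cs
  ctr <- superpixel_centers(superpixel_grid(grid$scheme))  # unrotated centres
  pts <- expand.grid(dx = off, dy = off, KEEP.OUT.ATTRS = FALSE)
  list(x = rep(ctr$x, each = nrow(pts)) + rep(pts$dx, times = nrow(ctr)),
       y = rep(ctr$y, each = nrow(pts)) + rep(pts$dy, times = nrow(ctr)),
       id = rep(ctr$id, each = nrow(pts)))
}

#' Sample superpixel thickness for one subject
#'
#' Averages `normative * thickness_scale * (1 - damage)` over a fixed interior
#' lattice of sample points per superpixel (after rotating the grid by its
#' rotation angle about the fovea, e.g. the subject's FoBMO angle) and adds
#' independent Gaussian measurement noise per superpixel, truncated at zero.
#' Uses the current RNG stream; seed it for reproducibility.
#'
#' @param subject A [subject_spec()].
#' @param grid A `superpixel_grid`, typically `rotate_grid(g, fobmo_angle)`.
#' @param params A [sim_params()].
#' @param layers Layers to sample.
#' @return Data frame with `layer`, `superpixel_id`, `thickness` (um).
#' @export
sample_thickness <- function(subject, grid, params = sim_params(),
                             layers = c("GCL", "IPL")) {
  q <- cell_quadrature(grid, params$n_quad)
  xy <- rotate_xy(cbind(q$x, q$y), grid$rotation, grid$center)
  dmg <- damage_fraction(subject$damage, xy[, 1L], xy[, 2L])
  out <- lapply(layers, function(ly) {
    base <- normative_thickness(params$profiles[[ly]], xy[, 1L], xy[, 2L])
    cell_mean <- as.numeric(
      tapply(subject$thickness_scale * base * (1 - dmg), q$id, mean))
    # averaging noise scales inversely with cell side (fewer A-scans per
    # cell); thickness_noise_sd is referenced to the standard 3-degree cell
    sd_cell <- params$thickness_noise_sd * 3 / grid$cell_size
    noise <- stats::rnorm(length(cell_mean), 0, sd_cell)
    data.frame(layer = ly, superpixel_id = sort(unique(q$id)),
               thickness = pmax(cell_mean + noise, 0))
  })
  do.call(rbind, out)
}

#' Simulate one visual field examination
#'
#' For each stimulus location (retinal orientation), the stimulus is projected
#' at the intended location plus a per-presentation fixation offset (standard
#' perimetry) or exactly at the intended location (fundus-tracking perimetry).
#' Damage is read at the ganglion cell position of the projected point
#' ([displace_to_rgc()]) and sensitivity follows the linear-in-damage link
#' `healthy - max_loss * damage + noise`, clamped to `[0, ceiling_db]`.
#' Uses the current RNG stream.
#'
#' @param subject A [subject_spec()].
#' @param pattern A `vf_pattern` flipped to retinal orientation.
#' @param modality `"standard"` or `"tracked"`.
#' @param params A [sim_params()].
#' @return Data frame with `location_id`, `sensitivity_db`; attributes
#'   `modality` and `fixation_offsets` (68 x 2 matrix, zero when tracked).
#' @export
simulate_exam <- function(subject, pattern,
                          modality = c("standard", "tracked"),
                          params = sim_params()) {
  modality <- match.arg(modality)
  n <- nrow(pattern)
  off <- if (modality == "standard" && params$jitter_sd > 0) {
    matrix(stats::rnorm(2L * n, 0, params$jitter_sd), n, 2L)
  } else {
    matrix(0, n, 2L)
  }
  px <- pattern$x + off[, 1L]
  py <- pattern$y + off[, 2L]
  rgc <- displace_to_rgc(px, py, params$dmax, params$tau)
  dmg <- damage_fraction(subject$damage, rgc[, 1L], rgc[, 2L])
  healthy <- healthy_sensitivity(sqrt(px^2 + py^2),
                                 params$base_db, params$ecc_slope)
  mu <- healthy + subject$sens_offset - params$max_loss * dmg
  # response variability grows as sensitivity falls (classic perimetric
  # frequency-of-seeing behaviour); sens_noise_sd is the sd at the healthy
  # baseline and the exponential rise is capped at 6 dB
  noise <- if (params$sens_noise_sd > 0) {
    rel <- pmin(exp(-0.081 * pmax(mu, 0) + 3.27), 6) /
      exp(-0.081 * params$base_db + 3.27)
    stats::rnorm(n, 0, params$sens_noise_sd * rel)
  } else 0
  sens <- mu + noise
  structure(
    data.frame(location_id = pattern$id,
               sensitivity_db = pmin(pmax(sens, 0), params$ceiling_db)),
    modality = modality, fixation_offsets = off)
}

#' Mean deviation of an examination
#'
#' Unweighted mean of (measured - healthy) sensitivity in dB over the test
#' locations, with the healthy reference taken from the eccentricity profile of
#' [healthy_sensitivity()]. Device mean deviation weights locations by normal
#' variance; the unweighted mean is used here as the reference surface is
#' exactly known.
#'
#' @param exam An exam data frame (`location_id`, `sensitivity_db`).
#' @param pattern The `vf_pattern` the exam was collected on.
#' @param params A [sim_params()] providing the healthy profile.
#' @return Mean deviation in dB (0 for a healthy noiseless exam).
#' @export
mean_deviation <- function(exam, pattern, params = sim_params()) {
  i <- match(exam$location_id, pattern$id)
  if (anyNA(i)) stop("exam contains unknown location ids", call. = FALSE)
  ecc <- sqrt(pattern$x[i]^2 + pattern$y[i]^2)
  mean(exam$sensitivity_db -
         healthy_sensitivity(ecc, params$base_db, params$ecc_slope))
}

#' Classify disease severity into tertiles
#'
#' Tertile bounds follow the cohort stratification used for localized
#' structure-function testing: mean GCL thickness <= 23 um with mean deviation
#' (MD) <= -10 dB for the most severe tertile; 24-27 um with -10 to -4 dB for
#' the middle; >= 28 um with >= -4 dB for the mildest. Mean GCL is rounded to
#' the nearest micrometre before banding; the MD bands are half-open at -10
#' and closed at -4. The consensus `tertile` is `NA` when the two metrics
#' disagree.
#'
#' @param mean_gcl Mean GCL thickness over the posterior-pole grid, um.
#' @param md 10-2 mean deviation, dB.
#' @return Data frame with `gcl_tertile`, `md_tertile`, `tertile`.
#' @export
classify_tertile <- function(mean_gcl, md) {
  g <- round(mean_gcl)
  gt <- ifelse(g <= 23, 1L, ifelse(g <= 27, 2L, 3L))
  mt <- ifelse(md <= -10, 1L, ifelse(md < -4, 2L, 3L))
  data.frame(gcl_tertile = gt, md_tertile = mt,
             tertile = ifelse(gt == mt, gt, NA_integer_))
}

# severity-dependent damage draws (uses current RNG stream)
draw_damage <- function(severity) {
  rng <- switch(severity,
    `1` = list(depth = c(0.75, 0.95), extent = c(130, 180),
               inner = c(0.5, 2), outer = c(9, 11.5), second = 0.6),
    `2` = list(depth = c(0.50, 0.80), extent = c(90, 140),
               inner = c(1, 3), outer = c(8, 10), second = 0.25),
    `3` = list(depth = c(0.25, 0.55), extent = c(50, 100),
               inner = c(2, 4), outer = c(7, 9), second = 0.1))
  hemi <- if (stats::runif(1) < 0.6) "inferior" else "superior"
  ctr <- function(h) if (h == "superior") stats::runif(1, 40, 140)
                     else stats::runif(1, 220, 320)
  pats <- list(damage_pattern(
    hemiretina = hemi,
    angular_extent = stats::runif(1, rng$extent[1], rng$extent[2]),
    eccentricity_band = c(stats::runif(1, rng$inner[1], rng$inner[2]),
                          stats::runif(1, rng$outer[1], rng$outer[2])),
    depth = stats::runif(1, rng$depth[1], rng$depth[2]),
    edge_softness = stats::runif(1, 1, 2),
    center_angle = ctr(hemi)))
  if (stats::runif(1) < rng$second) {
    other <- if (hemi == "superior") "inferior" else "superior"
    pats <- c(pats, list(damage_pattern(
      hemiretina = other,
      angular_extent = stats::runif(1, 40, 90),
      eccentricity_band = pats[[1L]]$eccentricity_band,
      depth = pats[[1L]]$depth * stats::runif(1, 0.3, 0.7),
      edge_softness = stats::runif(1, 1, 2),
      center_angle = ctr(other))))
  }
  pats
}

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# generate thickness tables and exams for one subject spec
generate_subject_data <- function(spec, pattern_retinal, grids, params,
                                  modalities = c("standard", "tracked")) {
  thick <- do.call(rbind, lapply(names(grids), function(sc) {
    g <- rotate_grid(grids[[sc]], spec$fobmo_angle)
    cbind(scheme = sc, sample_thickness(spec, g, params))
  }))
  exams <- lapply(modalities, function(m) {
    simulate_exam(spec, pattern_retinal, m, params)
  })
  names(exams) <- modalities
  list(spec = spec, thickness = thick, exams = exams)
}

new_sf_cohort <- function(subjects, pattern, params, seed = NA_integer_) {
  structure(list(subjects = subjects,
                 pattern = pattern,
                 pattern_retinal = flip_vertical(pattern),
                 grids = list(CMA = superpixel_grid("CMA"),
                              LMA = superpixel_grid("LMA")),
                 params = params, seed = seed),
            class = "sf_cohort")
}

#' Generate cohort data for an explicit list of subjects
#'
#' Lower-level companion to [simulate_cohort()]: takes fully specified
#' [subject_spec()]s (no severity stratification or rejection sampling) and
#' generates their thickness tables and examinations reproducibly from `seed`.
#' Useful for controlled experiments, e.g. a shared damage template with
#' varying depth or noise-free data.
#'
#' @param subjects List of [subject_spec()]s.
#' @param params A [sim_params()].
#' @param seed Integer seed.
#' @param modalities Perimetry modalities to simulate for every subject.
#' @return An object of class `sf_cohort`.
#' @export
build_cohort <- function(subjects, params = sim_params(), seed = 1L,
                         modalities = c("standard", "tracked")) {
  pattern <- vf_pattern_10_2()
  pat_ret <- flip_vertical(pattern)
  grids <- list(CMA = superpixel_grid("CMA"), LMA = superpixel_grid("LMA"))
  subjects <- with_local_seed(seed, {
    lapply(seq_along(subjects), function(i) {
      sp <- subjects[[i]]
      if (is.null(sp$id)) sp$id <- sprintf("S%02d", i)
      generate_subject_data(sp, pat_ret, grids, params, modalities)
    })
  })
  cohort <- new_sf_cohort(subjects, pattern, params, seed)
  cohort <- annotate_metrics(cohort)
  cohort
}

# attach mean GCL / MD / tertile metrics to each subject
annotate_metrics <- function(cohort) {
  for (i in seq_along(cohort$subjects)) {
    s <- cohort$subjects[[i]]
    th <- s$thickness
    mg <- mean(th$thickness[th$scheme == "CMA" & th$layer == "GCL"])
    exam <- s$exams[[1L]]
    md <- mean_deviation(exam, cohort$pattern_retinal, cohort$params)
    cohort$subjects[[i]]$metrics <-
      cbind(data.frame(mean_gcl = mg, md = md), classify_tertile(mg, md))
  }
  cohort
}

#' Simulate a tertile-stratified glaucoma cohort
#'
#' Draws glaucoma subjects with severity-dependent arcuate damage until each
#' severity tertile quota is met, plus healthy controls. A candidate subject
#' is retained only if the mean GCL thickness and mean deviation computed from
#' its own simulated data agree on the targeted tertile
#' (see [classify_tertile()]); otherwise it is redrawn. The whole cohort is
#' reproducible from `seed`.
#'
#' @param n_glaucoma,n_healthy Subject counts (defaults give the 48-subject
#'   study configuration: 38 glaucoma, 10 healthy).
#' @param severity_mix Proportions of glaucoma subjects targeted at tertiles
#'   1 (severe), 2, 3 (mild); normalized internally.
#' @param seed Integer seed.
#' @param params A [sim_params()].
#' @param max_attempts Redraw budget per required subject.
#' @return An object of class `sf_cohort`.
#' @export
#' @examples
#' \donttest{
#' coh <- simulate_cohort(n_glaucoma = 6, n_healthy = 2, seed = 1)
#' }
simulate_cohort <- function(n_glaucoma = 38, n_healthy = 10,
                            severity_mix = c(1, 1, 1) / 3,
                            seed = 1L,
                            params = sim_params(),
                            max_attempts = 80L) {
  stopifnot(n_glaucoma >= 0, n_healthy >= 0, length(severity_mix) == 3L,
            all(severity_mix >= 0))
  if (sum(severity_mix) <= 0) {
    if (n_glaucoma > 0) {
      stop("impossible severity mix: glaucoma subjects requested but all ",
           "tertile targets are zero", call. = FALSE)
    }
    severity_mix <- c(1, 1, 1)
  }
  severity_mix <- severity_mix / sum(severity_mix)
  quota <- diff(c(0L, round(cumsum(severity_mix * n_glaucoma))))
  pattern <- vf_pattern_10_2()
  pat_ret <- flip_vertical(pattern)
  grids <- list(CMA = superpixel_grid("CMA"), LMA = superpixel_grid("LMA"))

  subjects <- with_local_seed(seed, {
    draw_subject <- function(diagnosis, severity = NULL) {
      spec <- subject_spec(
        diagnosis = diagnosis,
        laterality = sample(c("right", "left"), 1L),
        fobmo_angle = stats::rnorm(1, params$fobmo_mean, params$fobmo_sd),
        damage = if (identical(diagnosis, "glaucoma")) draw_damage(severity)
                 else list(),
        thickness_scale = max(stats::rnorm(1, 1, params$subject_scale_sd), 0.5),
        sens_offset = stats::rnorm(1, 0, params$subject_sens_sd))
      generate_subject_data(spec, pat_ret, grids, params)
    }
    metrics_of <- function(sdat) {
      th <- sdat$thickness
      mg <- mean(th$thickness[th$scheme == "CMA" & th$layer == "GCL"])
      md <- mean_deviation(sdat$exams[[1L]], pat_ret, params)
      cbind(data.frame(mean_gcl = mg, md = md), classify_tertile(mg, md))
    }
    out <- list()
    gi <- 0L
    for (sev in 1:3) {
      need <- quota[sev]
      while (need > 0L) {
        ok <- FALSE
        for (att in seq_len(max_attempts)) {
          cand <- draw_subject("glaucoma", as.character(sev))
          m <- metrics_of(cand)
          if (!is.na(m$tertile) && m$tertile == sev) { ok <- TRUE; break }
        }
        if (!ok) {
          stop(sprintf("could not realize a tertile-%d glaucoma subject in %d attempts",
                       sev, max_attempts), call. = FALSE)
        }
        gi <- gi + 1L
        cand$spec$id <- sprintf("G%02d", gi)
        cand$metrics <- m
        out[[length(out) + 1L]] <- cand
        need <- need - 1L
      }
    }
    for (h in seq_len(n_healthy)) {
      cand <- draw_subject("healthy")
      cand$spec$id <- sprintf("H%02d", h)
      cand$metrics <- metrics_of(cand)
      out[[length(out) + 1L]] <- cand
    }
    out
  })
  new_sf_cohort(subjects, pattern, params, seed)
}

#' Cohort accessors
#'
#' `cohort_thickness()` returns a subjects-by-superpixels thickness matrix for
#' one scheme and layer; `cohort_sensitivity()` a subjects-by-locations dB
#' matrix for one modality; `cohort_summary()` per-subject metadata and
#' severity metrics.
#'
#' @param cohort An `sf_cohort`.
#' @param scheme `"CMA"` or `"LMA"`.
#' @param layer `"GCL"` or `"IPL"`.
#' @return A numeric matrix with subject ids as row names.
#' @export
cohort_thickness <- function(cohort, scheme = c("CMA", "LMA"),
                             layer = c("GCL", "IPL")) {
  scheme <- match.arg(scheme); layer <- match.arg(layer)
  rows <- lapply(cohort$subjects, function(s) {
    th <- s$thickness
    th <- th[th$scheme == scheme & th$layer == layer, ]
    if (nrow(th) == 0L) {
      stop(sprintf("cohort has no %s/%s thickness data", scheme, layer),
           call. = FALSE)
    }
    th$thickness[order(th$superpixel_id)]
  })
  m <- do.call(rbind, rows)
  rownames(m) <- vapply(cohort$subjects, function(s) s$spec$id, "")
  colnames(m) <- paste0("S", seq_len(ncol(m)))
  m
}

#' @rdname cohort_thickness
#' @param modality `"standard"` or `"tracked"`.
#' @export
cohort_sensitivity <- function(cohort, modality = c("standard", "tracked")) {
  modality <- match.arg(modality)
  rows <- lapply(cohort$subjects, function(s) {
    ex <- s$exams[[modality]]
    if (is.null(ex)) {
      stop(sprintf("cohort has no %s perimetry data", modality), call. = FALSE)
    }
    ex$sensitivity_db[order(ex$location_id)]
  })
  m <- do.call(rbind, rows)
  rownames(m) <- vapply(cohort$subjects, function(s) s$spec$id, "")
  colnames(m) <- paste0("loc", seq_len(ncol(m)))
  m
}

#' @rdname cohort_thickness
#' @export
cohort_summary <- function(cohort) {
  do.call(rbind, lapply(cohort$subjects, function(s) {
    cbind(data.frame(subject_id = s$spec$id,
                     diagnosis = s$spec$diagnosis,
                     laterality = s$spec$laterality,
                     fobmo_angle = s$spec$fobmo_angle,
                     n_damage_patterns = length(s$spec$damage)),
          if (!is.null(s$metrics)) s$metrics else
            data.frame(mean_gcl = NA_real_, md = NA_real_,
                       gcl_tertile = NA_integer_, md_tertile = NA_integer_,
                       tertile = NA_integer_))
  }))
}

#' Ground-truth damage exposure per superpixel
#'
#' Averages each subject's true damage fraction over the same within-cell
#' sample lattice used for thickness generation (honouring the subject's FoBMO
#' rotation). Rows are subjects, columns superpixels; useful to identify which
#' superpixels and units a simulated lesion actually touches.
#'
#' @param cohort An `sf_cohort` with known subject specifications.
#' @param grid A `superpixel_grid` (unrotated base grid).
#' @return Subjects-by-superpixels matrix of mean damage fractions.
#' @export
damage_exposure <- function(cohort, grid) {
  m <- do.call(rbind, lapply(cohort$subjects, function(s) {
    g <- rotate_grid(grid, s$spec$fobmo_angle)
    q <- cell_quadrature(g, cohort$params$n_quad)
    xy <- rotate_xy(cbind(q$x, q$y), g$rotation, g$center)
    d <- damage_fraction(s$spec$damage, xy[, 1L], xy[, 2L])
    as.numeric(tapply(d, q$id, mean))
  }))
  rownames(m) <- vapply(cohort$subjects, function(s) s$spec$id, "")
  colnames(m) <- paste0("S", seq_len(ncol(m)))
  m
}

#' Assemble a cohort from tabular data
#'
#' Entry point for external (or re-imported) data: one long thickness table
#' and one long sensitivity table, already in right-eye format.
#'
#' @param thickness Data frame with columns `subject_id`, `scheme`, `layer`,
#'   `superpixel_id`, `thickness`.
#' @param sensitivity Data frame with columns `subject_id`, `modality`,
#'   `location_id`, `sensitivity_db`.
#' @param params A [sim_params()] (used only for pattern/profile metadata).
#' @param subjects Optional list of [subject_spec()]s carrying ground truth.
#' @return An `sf_cohort`.
#' @export
sf_cohort_from_tables <- function(thickness, sensitivity,
                                  params = sim_params(), subjects = NULL) {
  need_t <- c("subject_id", "scheme", "layer", "superpixel_id", "thickness")
  need_s <- c("subject_id", "modality", "location_id", "sensitivity_db")
  stopifnot(all(need_t %in% names(thickness)),
            all(need_s %in% names(sensitivity)))
  ids <- unique(c(thickness$subject_id, sensitivity$subject_id))
  subj <- lapply(ids, function(id) {
    sp <- NULL
    if (!is.null(subjects)) {
      hit <- Filter(function(s) identical(s$id, id), subjects)
      if (length(hit)) sp <- hit[[1L]]
    }
    if (is.null(sp)) {
      sp <- subject_spec("healthy", id = id)
      sp$diagnosis <- NA_character_
    }
    th <- thickness[thickness$subject_id == id,
                    c("scheme", "layer", "superpixel_id", "thickness")]
    se <- sensitivity[sensitivity$subject_id == id, ]
    exams <- lapply(split(se, se$modality), function(e) {
      structure(data.frame(location_id = e$location_id,
                           sensitivity_db = e$sensitivity_db),
                modality = e$modality[1L])
    })
    list(spec = sp, thickness = th, exams = exams)
  })
  new_sf_cohort(subj, vf_pattern_10_2(), params)
}

#' @export
print.sf_cohort <- function(x, ...) {
  dg <- vapply(x$subjects, function(s) s$spec$diagnosis, "")
  cat(sprintf("Synthetic structure-function cohort: %d subjects (%d glaucoma, %d healthy), seed %s\n",
              length(x$subjects), sum(dg == "glaucoma", na.rm = TRUE),
              sum(dg == "healthy", na.rm = TRUE), format(x$seed)))
  invisible(x)
}
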