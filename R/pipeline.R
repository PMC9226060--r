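#' Configuration for a reproducible pipeline run
#'
#' A run is fully determined by its configuration: cohort sizes, simulation
#' parameters, the scheme/modality/layer combinations to analyze, and the
#' output directory. The configuration is serializable to JSON
#' ([write_run_config()]) and a run started from the same configuration
#' produces identical outputs.
#'
#' @param seed Integer seed for the simulation stage (analysis stages are
#'   deterministic given the cohort).
#' @param n_glaucoma,n_healthy Cohort sizes.
#' @param severity_mix Tertile mix passed to [simulate_cohort()].
#' @param params A [sim_params()].
#' @param schemes,modalities,layers Combinations to analyze (all crossings are
#'   run, which includes the conventional-aggregation-on-tracked and
#'   localized-aggregation-on-standard cross analyses).
#' @param out_dir Output directory.
#' @param figures Whether analysis and comparison figures are written.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_glaucoma = 38L, n_healthy = 10L,
                       severity_mix = c(1, 1, 1) / 3,
                       params = sim_params(),
                       schemes = c("CMA", "LMA"),
                       modalities = c("standard", "tracked"),
                       layers = c("GCL", "IPL"),
                       out_dir = "macumap-run",
                       figures = TRUE) {
  structure(as.list(environment()), class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  out <- unclass(config)
  out$params <- serialize_params(out$params)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  lst$params <- deserialize_params(lst$params)
  do.call(run_config, lst)
}

#' Pipeline stage: simulate and export a cohort
#'
#' @param config A [run_config()].
#' @return The simulated `sf_cohort`, invisibly; files are written under
#'   `file.path(config$out_dir, "cohort")`.
#' @export
cmd_simulate <- function(config) {
  t0 <- Sys.time()
  cohort <- simulate_cohort(config$n_glaucoma, config$n_healthy,
                            config$severity_mix, config$seed, config$params)
  dir <- file.path(config$out_dir, "cohort")
  write_cohort(cohort, dir)
  message(sprintf("[simulate] seed %d: %d subjects -> %s (%.1f s)",
                  config$seed, length(cohort$subjects), dir,
                  as.numeric(Sys.time() - t0, units = "secs")))
  invisible(cohort)
}

#' Pipeline stage: correlation atlas and vector map for one configuration
#'
#' Builds the unit map for the requested scheme, computes the correlation
#' atlas and the maximum-correlation vector map, and (optionally) writes their
#' CSV tables and figures. Every figure has a machine-readable CSV twin.
#'
#' @param cohort An `sf_cohort`.
#' @param scheme,modality,layer Analysis configuration.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param figures Write heatmap and vector-map figures (PNG).
#' @param onh_disc Optional list with `center` and `radius` to exclude optic
#'   nerve head superpixels before analysis.
#' @return A list of class `sf_analysis`: `atlas`, `vmap`, `summary`,
#'   `scheme`, `modality`, `layer`.
#' @export
cmd_analyze <- function(cohort, scheme = "CMA", modality = "standard",
                        layer = "GCL", out_dir = NULL, figures = FALSE,
                        onh_disc = NULL) {
  grid <- superpixel_grid(scheme)
  if (!is.null(onh_disc)) {
    grid <- apply_onh_exclusion(grid, onh_disc$center, onh_disc$radius)
  }
  um <- assign_units(flip_vertical(cohort$pattern), grid)
  atlas <- correlation_atlas(cohort, um, layer, modality)
  vmap <- vector_map(atlas)
  res <- structure(list(atlas = atlas, vmap = vmap,
                        summary = summarize_vectors(vmap),
                        scheme = scheme, modality = modality, layer = layer),
                   class = "sf_analysis")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    tag <- sprintf("%s_%s_%s", tolower(scheme), modality, tolower(layer))
    utils::write.csv(as.data.frame(atlas),
                     file.path(out_dir, paste0("atlas_", tag, ".csv")),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(vmap),
                     file.path(out_dir, paste0("vectors_", tag, ".csv")),
                     row.names = FALSE)
    if (figures) {
      ggplot2::ggsave(file.path(out_dir, paste0("heatmap_", tag, ".png")),
                      plot_atlas(atlas), width = 10, height = 9, dpi = 150)
      ggplot2::ggsave(file.path(out_dir, paste0("vectormap_", tag, ".png")),
                      plot_vector_map(vmap), width = 7, height = 7, dpi = 150)
    }
  }
  invisible(res)
}

#' Pipeline stage: compare correlation distributions across analyses
#'
#' Runs the Fisher z / Wilcoxon signed-rank comparison for every pair of the
#' supplied analyses. Analyses sharing a mapping scheme are paired unit by
#' unit; a conventional-vs-localized pair is paired with [pair_units()].
#'
#' @param analyses Named list of `sf_analysis` objects (at least 2).
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param figures Write the box-plot figure.
#' @return Data frame with one row per comparison: names, layer/modality
#'   tags, medians, ranges, `n_pairs`, `p_value`.
#' @export
cmd_compare <- function(analyses, out_dir = NULL, figures = FALSE) {
  stopifnot(length(analyses) >= 2L)
  if (is.null(names(analyses)) || any(names(analyses) == "")) {
    names(analyses) <- vapply(analyses, function(a) {
      sprintf("%s_%s_%s", a$scheme, a$modality, a$layer)
    }, "")
  }
  combos <- utils::combn(length(analyses), 2L)
  rows <- lapply(seq_len(ncol(combos)), function(k) {
    a <- analyses[[combos[1L, k]]]; b <- analyses[[combos[2L, k]]]
    if (identical(a$scheme, b$scheme)) {
      i <- match(a$vmap$unit_id, b$vmap$unit_id)
      keep <- !is.na(a$vmap$r_max) & !is.na(b$vmap$r_max[i])
      cmp <- compare_paired(a$vmap$r_max[keep], b$vmap$r_max[i][keep],
                            pairing_rule = "same_units")
    } else {
      if (identical(a$scheme, "CMA")) {
        pr <- pair_units(a$vmap, b$vmap)
        cmp <- compare_paired(pr$z_cma, pr$z_lma, values = "z",
                              pairing_rule = attr(pr, "pairing_rule"))
      } else {
        pr <- pair_units(b$vmap, a$vmap)
        cmp <- compare_paired(pr$z_lma, pr$z_cma, values = "z",
                              pairing_rule = attr(pr, "pairing_rule"))
      }
    }
    data.frame(comparison = paste(names(analyses)[combos[, k]],
                                  collapse = " vs "),
               a = names(analyses)[combos[1L, k]],
               b = names(analyses)[combos[2L, k]],
               layer_a = a$layer, layer_b = b$layer,
               median_a = cmp$median_a, median_b = cmp$median_b,
               min_a = cmp$range_a[1L], max_a = cmp$range_a[2L],
               min_b = cmp$range_b[1L], max_b = cmp$range_b[2L],
               n_pairs = cmp$n_pairs, p_value = cmp$p_value,
               pairing_rule = cmp$pairing_rule)
  })
  tab <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(tab, file.path(out_dir, "comparisons.csv"),
                     row.names = FALSE)
    vals <- do.call(rbind, lapply(names(analyses), function(nm) {
      a <- analyses[[nm]]
      data.frame(analysis = nm, unit_id = a$vmap$unit_id,
                 r_max = a$vmap$r_max)
    }))
    utils::write.csv(vals, file.path(out_dir, "rmax_distributions.csv"),
                     row.names = FALSE)
    if (figures) {
      ggplot2::ggsave(file.path(out_dir, "comparison_boxplot.png"),
                      plot_comparison(analyses), width = 8, height = 5,
                      dpi = 150)
    }
  }
  tab
}

#' Run the full pipeline: simulate, analyze, compare, report
#'
#' Simulates the cohort, runs every scheme x modality x layer analysis in the
#' configuration (including the cross analyses: conventional aggregation on
#' tracked perimetry and localized aggregation on standard perimetry), runs
#' all pairwise comparisons, and writes tables, figures and a JSON summary
#' under `config$out_dir`.
#'
#' @param config A [run_config()].
#' @return A list with `cohort`, `analyses`, `comparisons`, invisibly.
#' @export
cmd_report <- function(config) {
  t0 <- Sys.time()
  cohort <- cmd_simulate(config)
  adir <- file.path(config$out_dir, "analysis")
  analyses <- list()
  for (sc in config$schemes) for (mo in config$modalities)
    for (ly in config$layers) {
      nm <- sprintf("%s_%s_%s", sc, mo, ly)
      analyses[[nm]] <- cmd_analyze(cohort, sc, mo, ly, out_dir = adir,
                                    figures = config$figures)
      message(sprintf("[analyze] %s: hit rate %.2f, median r_max %.2f",
                      nm, analyses[[nm]]$summary$hit_rate,
                      stats::median(analyses[[nm]]$vmap$r_max, na.rm = TRUE)))
    }
  comparisons <- cmd_compare(analyses, file.path(config$out_dir, "compare"),
                             figures = config$figures)
  write_run_config(config, file.path(config$out_dir, "config.json"))
  summary <- list(
    package_version = as.character(utils::packageVersion("macumap")),
    seed = config$seed,
    n_subjects = length(cohort$subjects),
    analyses = lapply(analyses, function(a) a$summary),
    elapsed_s = as.numeric(Sys.time() - t0, units = "secs"))
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message(sprintf("[report] complete in %.1f s -> %s",
                  summary$elapsed_s, config$out_dir))
  invisible(list(cohort = cohort, analyses = analyses,
                 comparisons = comparisons))
}

#' Plot a correlation atlas as a heatmap panel
#'
#' One sub-panel per visual field unit, each showing the unit's correlation
#' with every superpixel of the grid, arranged in grid position.
#'
#' @param atlas An `sf_atlas`.
#' @return A ggplot object.
#' @export
plot_atlas <- function(atlas) {
  grid <- attr(atlas, "grid")
  df <- as.data.frame(atlas)
  df$col <- (df$superpixel_id - 1L) %% grid$n
  df$row <- (df$superpixel_id - 1L) %/% grid$n
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~unit_id) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = c(-1, 1), na.value = "grey80") +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::theme(strip.text = ggplot2::element_text(size = 6)) +
    ggplot2::labs(fill = "r",
                  title = sprintf("Correlation atlas: %s, %s, %s perimetry",
                                  attr(atlas, "scheme"), attr(atlas, "layer"),
                                  attr(atlas, "modality")))
}

#' Plot a maximum-correlation vector map
#'
#' Vectors join each unit's mapped superpixel centre to the centre of its
#' maximum-correlation superpixel; grey level encodes correlation strength and
#' the bold line marks the horizontal midline (raphe).
#'
#' @param vmap An `sf_vector_map`.
#' @return A ggplot object.
#' @export
plot_vector_map <- function(vmap) {
  grid <- attr(vmap, "grid")
  ctr <- superpixel_centers(grid)
  df <- vmap[!is.na(vmap$target_superpixel), ]
  df$x0 <- ctr$x[match(df$mapped_superpixel, ctr$id)]
  df$y0 <- ctr$y[match(df$mapped_superpixel, ctr$id)]
  df$x1 <- ctr$x[match(df$target_superpixel, ctr$id)]
  df$y1 <- ctr$y[match(df$target_superpixel, ctr$id)]
  half <- grid$n * grid$cell_size / 2
  lines <- seq(-half, half, grid$cell_size)
  ggplot2::ggplot(df) +
    ggplot2::geom_hline(yintercept = lines, colour = "grey85",
                        linewidth = 0.25) +
    ggplot2::geom_vline(xintercept = lines, colour = "grey85",
                        linewidth = 0.25) +
    ggplot2::geom_hline(yintercept = 0, colour = "black", linewidth = 1) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1,
                   yend = .data$y1, colour = .data$r_max),
      arrow = ggplot2::arrow(length = ggplot2::unit(4, "pt")),
      linewidth = 0.6) +
    ggplot2::geom_point(data = df[df$hit, ],
                        ggplot2::aes(x = .data$x0, y = .data$y0,
                                     colour = .data$r_max), size = 1.5) +
    ggplot2::scale_colour_gradient(low = "grey80", high = "black",
                                   limits = c(NA, 1)) +
    ggplot2::coord_equal(xlim = c(-half, half), ylim = c(-half, half)) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "temporal field (deg)", y = "superior retina (deg)",
                  colour = "max r",
                  title = sprintf("Vector map: %s, %s, %s perimetry",
                                  attr(vmap, "scheme"), attr(vmap, "layer"),
                                  attr(vmap, "modality")))
}

#' Box plot of per-unit maximum correlations across analyses
#'
#' @param analyses Named list of `sf_analysis` objects.
#' @return A ggplot object.
#' @export
plot_comparison <- function(analyses) {
  if (is.null(names(analyses)) || any(names(analyses) == "")) {
    names(analyses) <- vapply(analyses, function(a) {
      sprintf("%s_%s_%s", a$scheme, a$modality, a$layer)
    }, "")
  }
  df <- do.call(rbind, lapply(names(analyses), function(nm) {
    data.frame(analysis = nm, r_max = analyses[[nm]]$vmap$r_max)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$analysis, y = .data$r_max)) +
    ggplot2::geom_boxplot(fill = "grey90") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1)) +
    ggplot2::labs(x = NULL, y = "maximum correlation per unit")
}
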