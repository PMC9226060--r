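# Independent oracles and fixture builders used across the suite.

# Pearson correlation from the definitional sum formula (no cor()).
pearson_bruteforce <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# Exact two-sided signed-rank p-value by enumeration over all 2^n sign
# assignments of the nonzero differences (tie-free data assumed).
wilcoxon_enum_p <- function(a, b) {
  d <- (a - b)[a != b]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- as.vector(signs %*% r)
  min(1, 2 * min(mean(Ws <= W), mean(Ws >= W)))
}

# Noise-free simulation parameters (all stochastic terms and displacement
# off); individual terms can be switched back on through ...
zero_noise_params <- function(...) {
  args <- list(thickness_noise_sd = 0, sens_noise_sd = 0, jitter_sd = 0,
               subject_scale_sd = 0, subject_sens_sd = 0, dmax = 0)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_params, args)
}

# Cohort sharing a single damage template across glaucoma subjects, with
# depth ramped across subjects; healthy controls appended.
template_cohort <- function(template, n_glaucoma = 12, n_healthy = 4,
                            depth_range = c(0.15, 0.95),
                            params = zero_noise_params(),
                            fobmo = -7, seed = 5) {
  depths <- seq(depth_range[1], depth_range[2], length.out = n_glaucoma)
  subs <- c(
    lapply(depths, function(dp) {
      d <- template
      d$depth <- dp
      subject_spec("glaucoma", fobmo_angle = fobmo, damage = list(d),
                   thickness_scale = 1, sens_offset = 0)
    }),
    lapply(seq_len(n_healthy), function(i) {
      subject_spec("healthy", fobmo_angle = fobmo,
                   thickness_scale = 1, sens_offset = 0)
    }))
  build_cohort(subs, params, seed = seed)
}

# Heterogeneous noisy cohort with hand-built arcuate damage (no severity
# stratification), for mechanism tests that need realistic variation.
varied_cohort <- function(n_glaucoma = 14, n_healthy = 4,
                          params = sim_params(), seed = 3,
                          modalities = c("standard", "tracked")) {
  set.seed(190 + seed)
  subs <- c(
    lapply(seq_len(n_glaucoma), function(i) {
      hemi <- if (runif(1) < 0.5) "inferior" else "superior"
      ctr <- if (hemi == "superior") runif(1, 40, 140) else runif(1, 220, 320)
      subject_spec(
        "glaucoma", fobmo_angle = rnorm(1, -7, 2.5),
        damage = list(damage_pattern(
          hemi, angular_extent = runif(1, 60, 160),
          eccentricity_band = c(runif(1, 1, 3), runif(1, 7, 10.5)),
          depth = runif(1, 0.3, 0.95), edge_softness = runif(1, 1, 2),
          center_angle = ctr)),
        thickness_scale = max(rnorm(1, 1, 0.06), 0.5),
        sens_offset = rnorm(1, 0, 0.8))
    }),
    lapply(seq_len(n_healthy), function(i) {
      subject_spec("healthy", fobmo_angle = rnorm(1, -7, 2.5),
                   thickness_scale = max(rnorm(1, 1, 0.06), 0.5),
                   sens_offset = rnorm(1, 0, 0.8))
    }))
  build_cohort(subs, params, seed = seed, modalities = modalities)
}

# Cohort whose sensitivities equal the thickness of the mapped superpixel on
# the linear scale (identity structure-function link, no noise).
identity_link_cohort <- function(scheme = "LMA", n_subjects = 6, seed = 11) {
  set.seed(seed)
  grid <- superpixel_grid(scheme)
  um <- assign_units(flip_vertical(vf_pattern_10_2()), grid)
  n_sp <- grid$n^2
  thick <- do.call(rbind, lapply(seq_len(n_subjects), function(s) {
    data.frame(subject_id = sprintf("S%02d", s), scheme = scheme,
               layer = "GCL", superpixel_id = seq_len(n_sp),
               thickness = runif(n_sp, 20, 60))
  }))
  sens <- do.call(rbind, lapply(seq_len(n_subjects), function(s) {
    th <- thick$thickness[thick$subject_id == sprintf("S%02d", s)]
    data.frame(subject_id = sprintf("S%02d", s), modality = "standard",
               location_id = um$location_id,
               sensitivity_db = linear_to_db(th[um$superpixel_id]))
  }))
  list(cohort = sf_cohort_from_tables(thick, sens), unit_map = um)
}
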