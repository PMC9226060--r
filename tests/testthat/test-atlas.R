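test_that("decibel-linear conversion follows 10^(dB/10)", {
  expect_equal(db_to_linear(0), 1)
  expect_equal(db_to_linear(10), 10)
  expect_equal(db_to_linear(30), 1000)
  expect_equal(linear_to_db(db_to_linear(c(0, 7, 21.5))), c(0, 7, 21.5))
})

test_that("unit sensitivity averages on the linear scale", {
  flipped <- flip_vertical(vf_pattern_10_2())
  um <- assign_units(flipped, superpixel_grid("CMA"))
  exam <- data.frame(location_id = 1:68, sensitivity_db = 20)
  u <- unit_sensitivity(exam, um)
  expect_length(u, 40L)
  expect_equal(unname(u), rep(100, 40))
  # a 0 dB / 20 dB pair averages to (1 + 100) / 2
  four <- um$location_id[um$unit_id == um$unit_id[um$x_deg == 3 & um$y_deg == 3]]
  exam$sensitivity_db <- 20
  exam$sensitivity_db[four[1:2]] <- c(0, 20)
  pair_unit <- um$unit_id[um$location_id == four[1]]
  two <- unit_sensitivity(data.frame(location_id = four[1:2],
                                     sensitivity_db = c(0, 20)),
                          um[um$location_id %in% four[1:2], ])
  expect_equal(unname(two[pair_unit]), 50.5)
  # singleton units return their own linearized value
  lum <- assign_units(flipped, superpixel_grid("LMA"))
  ex1 <- data.frame(location_id = 1:68, sensitivity_db = seq(0, 33.5, 0.5))
  expect_equal(unname(unit_sensitivity(ex1, lum)),
               db_to_linear(seq(0, 33.5, 0.5)))
})

test_that("identity structure-function link puts 1 on the atlas diagonal", {
  for (scheme in c("LMA", "CMA")) {
    fix <- identity_link_cohort(scheme)
    at <- correlation_atlas(fix$cohort, fix$unit_map, "GCL", "standard")
    units <- unit_table(fix$unit_map)
    diagonal <- unclass(at)[cbind(seq_len(nrow(units)), units$superpixel_id)]
    expect_equal(diagonal, rep(1, nrow(units)), tolerance = 1e-12)
  }
})

test_that("atlas agrees with the definitional Pearson formula", {
  # printed 5-subject toy table
  toy_thick <- c(31.2, 24.8, 41.0, 18.9, 28.4)
  toy_sens <- c(310.5, 120.2, 1120.8, 35.7, 260.1)
  expect_equal(pearson_bruteforce(toy_sens, toy_thick),
               cor(toy_sens, toy_thick), tolerance = 1e-12)
  # exhaustive sweep over small cohorts: atlas vs brute force
  fix <- identity_link_cohort("LMA", n_subjects = 10, seed = 3)
  coh <- fix$cohort
  # perturb sensitivities so the link is noisy, not exact
  set.seed(14)
  for (i in seq_along(coh$subjects)) {
    coh$subjects[[i]]$exams$standard$sensitivity_db <-
      coh$subjects[[i]]$exams$standard$sensitivity_db + rnorm(68, 0, 2)
  }
  for (n_sub in c(4, 7, 10)) {
    small <- coh
    small$subjects <- coh$subjects[seq_len(n_sub)]
    at <- correlation_atlas(small, fix$unit_map, "GCL", "standard")
    U <- macumap:::unit_sensitivity_matrix(cohort_sensitivity(small, "standard"),
                                           fix$unit_map)
    Th <- cohort_thickness(small, "LMA", "GCL")
    for (u in seq(1, 68, 9)) for (s in seq(1, 144, 12)) {
      expect_lt(abs(unclass(at)[u, s] - pearson_bruteforce(U[, u], Th[, s])),
                1e-9)
    }
  }
})

test_that("atlas is invariant under affine rescaling of thickness", {
  fix <- identity_link_cohort("LMA", n_subjects = 6, seed = 9)
  at1 <- correlation_atlas(fix$cohort, fix$unit_map, "GCL", "standard")
  mm <- fix$cohort
  for (i in seq_along(mm$subjects)) {
    mm$subjects[[i]]$thickness$thickness <-
      mm$subjects[[i]]$thickness$thickness * 0.001  # micrometres -> mm
  }
  at2 <- correlation_atlas(mm, fix$unit_map, "GCL", "standard")
  expect_equal(unclass(at2), unclass(at1), tolerance = 1e-9)
})

test_that("atlas refuses degenerate cohorts and tiny samples", {
  fix <- identity_link_cohort("LMA", n_subjects = 2)
  expect_error(correlation_atlas(fix$cohort, fix$unit_map, "GCL", "standard"),
               "at least 3")
  # healthy-only, noise-free: no between-subject variance anywhere
  subs <- lapply(1:4, function(i) {
    subject_spec("healthy", fobmo_angle = -7, thickness_scale = 1)
  })
  coh <- build_cohort(subs, zero_noise_params(), seed = 1)
  um <- assign_units(flip_vertical(coh$pattern), superpixel_grid("CMA"))
  expect_error(correlation_atlas(coh, um, "GCL", "standard"), "degenerate")
})

test_that("zero-variance pairs are undefined, not zero", {
  fix <- identity_link_cohort("LMA", n_subjects = 5, seed = 21)
  coh <- fix$cohort
  # make superpixel 10 constant across subjects
  for (i in seq_along(coh$subjects)) {
    th <- coh$subjects[[i]]$thickness
    th$thickness[th$superpixel_id == 10] <- 40
    coh$subjects[[i]]$thickness <- th
  }
  at <- correlation_atlas(coh, fix$unit_map, "GCL", "standard")
  expect_true(all(is.na(unclass(at)[, 10])))
  expect_true(all(is.finite(unclass(at)[, -10])))
})
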