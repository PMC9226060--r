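test_that("noise-free healthy thickness equals the cell-averaged normative field", {
  p0 <- zero_noise_params()
  sub <- subject_spec("healthy", thickness_scale = 1)
  g <- superpixel_grid("CMA")
  set.seed(1)
  th <- sample_thickness(sub, g, p0)
  # independent quadrature: recompute the 5x5 cell average directly
  pr <- p0$profiles$GCL
  ctr <- superpixel_centers(g)
  for (id in c(1, 28, 37, 64)) {
    off <- ((seq_len(5) - 0.5) / 5 - 0.5) * g$cell_size
    pts <- expand.grid(x = ctr$x[id] + off, y = ctr$y[id] + off)
    want <- mean(normative_thickness(pr, pts$x, pts$y))
    got <- th$thickness[th$layer == "GCL" & th$superpixel_id == id]
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("thickness sampling is seed-reproducible and noise has the stated scale", {
  params <- sim_params(thickness_noise_sd = 3)
  sub <- subject_spec("healthy")
  g <- superpixel_grid("CMA")
  set.seed(7); a <- sample_thickness(sub, g, params)
  set.seed(7); b <- sample_thickness(sub, g, params)
  expect_identical(a, b)
  # 200 replicates: per-superpixel sd close to 3 um
  set.seed(42)
  reps <- replicate(200, sample_thickness(sub, g, params,
                                          layers = "GCL")$thickness)
  sds <- apply(reps, 1, sd)
  expect_true(all(sds > 2.4 & sds < 3.6))
})

test_that("healthy noise-free exams reproduce the normal sensitivity surface", {
  p0 <- zero_noise_params()
  pat <- flip_vertical(vf_pattern_10_2())
  ex <- simulate_exam(subject_spec("healthy"), pat, "tracked", p0)
  ecc <- sqrt(pat$x^2 + pat$y^2)
  expect_equal(ex$sensitivity_db, healthy_sensitivity(ecc))
  expect_equal(mean_deviation(ex, pat, p0), 0)
  expect_true(all(attr(ex, "fixation_offsets") == 0))
})

test_that("full damage with a saturating link floors sensitivity at 0 dB", {
  p0 <- zero_noise_params(max_loss = 40)
  pat <- flip_vertical(vf_pattern_10_2())
  pan <- list(damage_pattern("inferior", 360, c(0, 12), 1, 0, 270),
              damage_pattern("superior", 360, c(0, 12), 1, 0, 90))
  sub <- subject_spec("glaucoma", damage = pan)
  ex <- simulate_exam(sub, pat, "tracked", p0)
  expect_true(all(ex$sensitivity_db == 0))
})

test_that("mean deviation follows its arithmetic definition", {
  p0 <- zero_noise_params()
  pat <- flip_vertical(vf_pattern_10_2())
  ex <- simulate_exam(subject_spec("healthy"), pat, "tracked", p0)
  # uniform 5 dB depression
  ex5 <- ex; ex5$sensitivity_db <- ex$sensitivity_db - 5
  expect_equal(mean_deviation(ex5, pat, p0), -5)
  # 4-location toy with losses 0/2/4/6
  toy_pat <- pat[1:4, ]
  toy <- ex[1:4, ]
  toy$sensitivity_db <- toy$sensitivity_db - c(0, 2, 4, 6)
  expect_equal(mean_deviation(toy, toy_pat, p0), -3)
})

test_that("fixation jitter inflates variance at damage edges", {
  params <- sim_params(sens_noise_sd = 0, jitter_sd = 1.5, dmax = 0)
  pat <- flip_vertical(vf_pattern_10_2())
  sub <- subject_spec("glaucoma", damage = list(
    damage_pattern("inferior", 120, c(2, 9), 1, 0.5, 270)))
  set.seed(31)
  sens <- replicate(100, simulate_exam(sub, pat, "standard",
                                       params)$sensitivity_db)
  v <- apply(sens, 1, var)
  edge <- which(pat$x == -1 & pat$y == -9)    # outer band edge
  plateau <- which(pat$x == -1 & pat$y == -5) # mid-band plateau
  flat <- which(pat$x == 1 & pat$y == 1)      # undamaged centre
  expect_gt(v[edge], v[plateau])
  expect_gt(v[edge], v[flat])
})

test_that("severity tertiles follow the printed thickness and MD bounds", {
  t <- classify_tertile(c(21, 25, 30, 25), c(-14, -6, -1, -15))
  expect_equal(t$gcl_tertile, c(1L, 2L, 3L, 2L))
  expect_equal(t$md_tertile, c(1L, 2L, 3L, 1L))
  expect_equal(t$tertile, c(1L, 2L, 3L, NA))
  # band edges: -10 belongs to the severe tertile, -4 to the mild one
  expect_equal(classify_tertile(23, -10)$tertile, 1L)
  expect_equal(classify_tertile(28, -4)$tertile, 3L)
})

test_that("simulated cohorts meet size, stratification, and reproducibility", {
  coh <- simulate_cohort(n_glaucoma = 9, n_healthy = 3, seed = 2)
  expect_equal(length(coh$subjects), 12L)
  s <- cohort_summary(coh)
  expect_equal(unname(table(s$tertile[s$diagnosis == "glaucoma"])),
               c(3L, 3L, 3L), ignore_attr = TRUE)
  expect_true(all(s$mean_gcl[s$tertile == 1 & s$diagnosis == "glaucoma"] <= 23.5))
  expect_true(all(s$md[s$tertile == 1 & s$diagnosis == "glaucoma"] <= -10))
  # byte-identical re-export under the same seed
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(coh, d1)
  write_cohort(simulate_cohort(9, 3, seed = 2), d2)
  for (f in c("thickness.csv", "sensitivity.csv", "manifest.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("cohorts survive an export/import round trip", {
  coh <- varied_cohort(n_glaucoma = 5, n_healthy = 3, seed = 4)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(cohort_thickness(back, "CMA", "GCL"),
               cohort_thickness(coh, "CMA", "GCL"))
  expect_equal(cohort_sensitivity(back, "tracked"),
               cohort_sensitivity(coh, "tracked"))
  # ground truth (damage patterns) preserved
  expect_equal(back$subjects[[1]]$spec$damage, coh$subjects[[1]]$spec$damage)
})

test_that("all simulated sensitivities and thicknesses respect their bounds", {
  coh <- varied_cohort(n_glaucoma = 6, n_healthy = 2, seed = 8)
  for (m in c("standard", "tracked")) {
    s <- cohort_sensitivity(coh, m)
    expect_true(all(s >= 0 & s <= coh$params$ceiling_db))
  }
  expect_true(all(cohort_thickness(coh, "LMA", "IPL") >= 0))
})
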