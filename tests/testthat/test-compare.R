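test_that("fisher z is the odd, increasing atanh with domain checks", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.549306, tolerance = 1e-6)
  r <- seq(-0.95, 0.95, 0.05)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_true(all(diff(fisher_z(r)) > 0))
  expect_error(fisher_z(1))
  expect_error(fisher_z(c(0.2, -1.2)))
})

test_that("identical paired vectors carry no effect (p = 1)", {
  v <- c(0.2, 0.4, 0.5, 0.6, 0.7, 0.8)
  cmp <- compare_paired(v, v)
  expect_equal(cmp$p_value, 1)
  expect_equal(cmp$median_a, cmp$median_b)
  expect_error(compare_paired(v[1:3], v[1:3]), "at least 5")
})

test_that("signed-rank p matches exhaustive sign enumeration", {
  # n = 6 toy pair
  a <- c(0.71, 0.64, 0.80, 0.55, 0.60, 0.75)
  b <- c(0.62, 0.66, 0.70, 0.50, 0.48, 0.69)
  cmp <- compare_paired(a, b)
  expect_equal(cmp$p_value, wilcoxon_enum_p(fisher_z(a), fisher_z(b)),
               tolerance = 1e-12)
  expect_equal(cmp$method, "exact")
  # exhaustive property: every n from 5 to 10, random tie-free draws
  set.seed(77)
  for (n in 5:10) {
    for (rep in 1:3) {
      x <- round(runif(n, -0.9, 0.9), 3)
      y <- round(runif(n, -0.9, 0.9), 3)
      zx <- fisher_z(x); zy <- fisher_z(y)
      if (any(zx == zy) || anyDuplicated(abs(zx - zy))) next
      expect_equal(compare_paired(x, y)$p_value, wilcoxon_enum_p(zx, zy),
                   tolerance = 1e-12)
    }
  }
})

test_that("large or tied samples fall back to the normal approximation", {
  set.seed(5)
  a <- runif(40, 0.3, 0.9)
  b <- a + rnorm(40, 0.05, 0.05)
  b <- pmin(b, 0.99)
  cmp <- compare_paired(a, b)
  expect_equal(cmp$method, "normal approximation")
  expect_true(cmp$p_value > 0 && cmp$p_value <= 1)
  wt <- suppressWarnings(stats::wilcox.test(fisher_z(a), fisher_z(b),
                                            paired = TRUE, exact = FALSE,
                                            correct = TRUE))
  expect_equal(cmp$p_value, wt$p.value)
})

test_that("scheme averaging is detected as stochastic dominance", {
  # matched cohorts where arm A is arm B averaged over 4 replicates:
  # A has less noise, hence systematically higher correlation with truth
  set.seed(123)
  n <- 40
  r_a <- r_b <- numeric(n)
  for (i in seq_len(n)) {
    truth <- rnorm(25)
    noisy1 <- truth + rnorm(25, 0, 1.5)
    avg <- truth + rnorm(25, 0, 1.5 / 2)   # averaging four i.i.d. exams
    r_b[i] <- cor(truth, noisy1)
    r_a[i] <- cor(truth, avg)
  }
  cmp <- compare_paired(r_a, r_b)
  expect_gt(cmp$median_a, cmp$median_b)
  expect_lt(cmp$p_value, 0.05)
})

test_that("unit pairing rules yield 40 pairs with the documented averaging", {
  coh <- varied_cohort(n_glaucoma = 8, n_healthy = 3, seed = 26)
  um_c <- assign_units(flip_vertical(coh$pattern), superpixel_grid("CMA"))
  um_l <- assign_units(flip_vertical(coh$pattern), superpixel_grid("LMA"))
  vc <- vector_map(correlation_atlas(coh, um_c, "GCL", "standard"))
  vl <- vector_map(correlation_atlas(coh, um_l, "GCL", "standard"))
  pr <- pair_units(vc, vl)
  expect_equal(nrow(pr), 40L)
  # hand-check one multi-member unit: mean of member Fisher-z values
  units <- unit_table(um_c)
  u4 <- units$unit_id[units$n_members == 4][1]
  members <- um_c$location_id[um_c$unit_id == u4]
  lma_units <- um_l$unit_id[match(members, um_l$location_id)]
  want <- mean(fisher_z(vl$r_max[match(lma_units, vl$unit_id)]))
  expect_equal(pr$z_lma[pr$unit_id == u4], want)
  # singleton units pair with their single localized value
  u1 <- units$unit_id[units$n_members == 1][1]
  m1 <- um_c$location_id[um_c$unit_id == u1]
  l1 <- um_l$unit_id[um_l$location_id == m1]
  expect_equal(pr$z_lma[pr$unit_id == u1],
               fisher_z(vl$r_max[vl$unit_id == l1]))
  # the spatial rule also yields 40 pairs
  pr2 <- pair_units(vc, vl, "spatial_nearest")
  expect_equal(nrow(pr2), 40L)
})

test_that("distribution summaries use interpolated quartiles", {
  s <- distribution_summary(0.5)
  expect_equal(unlist(s), c(median = 0.5, q1 = 0.5, q3 = 0.5,
                            min = 0.5, max = 0.5))
  s2 <- distribution_summary(seq(0.1, 1.0, 0.1))
  expect_equal(s2$median, 0.55)
  expect_equal(s2$min, 0.1)
  expect_equal(s2$max, 1.0)
  set.seed(1)
  v <- runif(31)
  expect_equal(distribution_summary(sample(v)), distribution_summary(v))
  expect_error(distribution_summary(numeric(0)), "non-empty")
})
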