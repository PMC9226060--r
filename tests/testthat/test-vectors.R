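test_that("identity link makes every unit a hit", {
  for (scheme in c("LMA", "CMA")) {
    fix <- identity_link_cohort(scheme)
    at <- correlation_atlas(fix$cohort, fix$unit_map, "GCL", "standard")
    vm <- vector_map(at)
    expect_true(all(vm$hit))
    expect_true(all(vm$length_deg == 0))
    s <- summarize_vectors(vm)
    expect_equal(s$hit_rate, 1)
    expect_true(is.na(s$median_nonzero_length))
  }
})

test_that("vector geometry follows superpixel centre distances", {
  fix <- identity_link_cohort("CMA")
  at <- correlation_atlas(fix$cohort, fix$unit_map, "GCL", "standard")
  # force the argmax of unit 1 to a cell 2 columns and 1 row away
  units <- unit_table(fix$unit_map)
  mapped <- units$superpixel_id[1]
  target <- mapped + 2L + 8L  # two columns temporal, one row down
  atm <- unclass(at)
  atm[1, ] <- pmin(atm[1, ], 0.5)
  atm[1, target] <- 0.99
  at2 <- at; at2[] <- atm
  vm <- vector_map(at2)
  expect_equal(vm$target_superpixel[1], target)
  expect_equal(vm$length_deg[1], sqrt(6^2 + 3^2), tolerance = 1e-12)
  expect_equal(round(vm$length_deg[1], 1), 6.7)
  expect_false(vm$hit[1])
})

test_that("ties are broken toward the mapped superpixel, then lowest id", {
  fix <- identity_link_cohort("CMA")
  at <- correlation_atlas(fix$cohort, fix$unit_map, "GCL", "standard")
  units <- unit_table(fix$unit_map)
  mapped <- units$superpixel_id[1]
  atm <- matrix(0.2, nrow(at), ncol(at))
  # exact tie between the mapped superpixel and a distant one: mapped wins
  atm[1, c(mapped, 64L)] <- 0.9
  at2 <- at; at2[] <- atm
  expect_true(vector_map(at2)$hit[1])
  # tie between two equally distant neighbours: lowest id wins
  atm <- matrix(0.2, nrow(at), ncol(at))
  atm[1, c(mapped - 1L, mapped + 1L)] <- 0.9
  at2[] <- atm
  expect_equal(vector_map(at2)$target_superpixel[1], mapped - 1L)
})

test_that("excluded superpixels never become vector targets", {
  set.seed(20)
  coh <- varied_cohort(n_glaucoma = 8, n_healthy = 3, seed = 6)
  grid <- superpixel_grid("CMA")
  um0 <- assign_units(flip_vertical(coh$pattern), grid)
  vm0 <- vector_map(correlation_atlas(coh, um0, "GCL", "standard"))
  # exclude every observed target, rerun: none may reappear
  banned <- unique(vm0$target_superpixel[seq_len(5)])
  gx <- grid
  gx$excluded <- banned
  umx <- assign_units(flip_vertical(coh$pattern), gx)
  vmx <- vector_map(correlation_atlas(coh, umx, "GCL", "standard"))
  expect_false(any(vmx$target_superpixel %in% banned))
})

test_that("vector maps are invariant to subject order", {
  coh <- varied_cohort(n_glaucoma = 7, n_healthy = 3, seed = 12)
  um <- assign_units(flip_vertical(coh$pattern), superpixel_grid("LMA"))
  vm1 <- vector_map(correlation_atlas(coh, um, "IPL", "tracked"))
  perm <- coh
  set.seed(2)
  perm$subjects <- perm$subjects[sample(seq_along(perm$subjects))]
  vm2 <- vector_map(correlation_atlas(perm, um, "IPL", "tracked"))
  expect_equal(vm2$target_superpixel, vm1$target_superpixel)
  expect_equal(vm2$r_max, vm1$r_max)
})

test_that("summaries count hits, lengths and crossings as defined", {
  vm <- structure(
    data.frame(unit_id = paste0("C", 1:5),
               mapped_superpixel = 1:5, target_superpixel = c(1:2, 10, 20, 30),
               r_max = c(0.9, 0.8, 0.7, 0.6, 0.5),
               length_deg = c(0, 0, 3, 6, 9),
               hit = c(TRUE, TRUE, FALSE, FALSE, FALSE),
               crosses_midline = c(FALSE, FALSE, FALSE, TRUE, TRUE)),
    class = c("sf_vector_map", "data.frame"))
  s <- summarize_vectors(vm)
  expect_equal(s$hit_count, 2L)
  expect_equal(s$hit_rate, 2 / 5)
  expect_equal(s$median_nonzero_length, 6)
  expect_equal(s$crossings, 2L)
  # hit-rate arithmetic: 8 hits of 40 is 20%
  expect_equal(8 / 40, 0.20)
})

test_that("hemimacula split groups units by mapped-centre hemifield", {
  coh <- varied_cohort(n_glaucoma = 8, n_healthy = 3, seed = 16)
  um <- assign_units(flip_vertical(coh$pattern), superpixel_grid("CMA"))
  vm <- vector_map(correlation_atlas(coh, um, "GCL", "standard"))
  hs <- hemimacula_split(vm)
  expect_equal(length(hs$superior) + length(hs$inferior), nrow(vm))
  ctr <- superpixel_centers(superpixel_grid("CMA"))
  sup_units <- ctr$y[match(vm$mapped_superpixel, ctr$id)] > 0
  expect_equal(length(hs$superior), sum(sup_units))
  expect_equal(hs$superior, vm$r_max[sup_units])
})
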