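test_that("mean_image averages present values voxelwise", {
  grid <- tiny_grid()
  one <- const_volume(1, grid)
  three <- const_volume(3, grid)
  expect_identical(mean_image(list(one))$values, one$values)
  expect_equal(mean_image(list(one, three))$values,
               array(2, dim = grid$shape))

  # voxel missing in 1 of 3 inputs: mean of the present values
  a <- const_volume(2, grid); b <- const_volume(NaN, grid)
  c3 <- const_volume(4, grid)
  b$values[2:9, , ] <- 3
  m <- mean_image(list(a, b, c3))
  expect_equal(m$values[1, 1, 1], 3)        # (2 + 4) / 2
  expect_equal(m$values[2, 1, 1], 3)        # (2 + 3 + 4) / 3
  allna <- mean_image(list(const_volume(NaN, grid), const_volume(NaN, grid)))
  expect_true(all(!is.finite(allna$values)))
})

test_that("difference_image subtracts CU mean from AD mean", {
  grid <- tiny_grid()
  expect_equal(difference_image(const_volume(2.5, grid),
                                const_volume(1.0, grid))$values,
               array(1.5, dim = grid$shape))
  same <- const_volume(1.7, grid)
  expect_equal(difference_image(same, same)$values,
               array(0, dim = grid$shape))
})

test_that("tracer_mask thresholds at a fraction of the anchor mean", {
  grid <- tiny_grid()
  it <- coord_mask(grid, function(x, y, z) abs(x) <= 2 & y == 0 & z == 0)

  # constant difference 0.9: threshold 0.3, every voxel kept
  d <- const_volume(0.9, grid)
  m <- suppressMessages(tracer_mask(d, it))
  expect_equal(attr(m, "threshold"), 0.3)
  expect_equal(mask_size(m), prod(grid$shape))

  # 0.9 inside the anchor, 0.1 outside: mask recovers the anchor exactly
  d2 <- const_volume(0.1, grid)
  d2$values[it$membership] <- 0.9
  m2 <- suppressMessages(tracer_mask(d2, it))
  expect_identical(m2$membership, it$membership)

  # no AD>CU contrast in the anchor
  expect_error(suppressMessages(tracer_mask(const_volume(-0.2, grid), it)),
               "no AD>CU contrast")
  expect_error(suppressMessages(tracer_mask(d, it, fraction = 1.5)),
               "fraction")
})

test_that("tracer_mask is antitone in the threshold fraction", {
  grid <- tiny_grid()
  it <- coord_mask(grid, function(x, y, z) z == 0)
  set.seed(7)
  d <- volume_image(array(runif(prod(grid$shape), -0.2, 1),
                          dim = grid$shape), grid)
  fractions <- c(0.1, 0.25, 0.5, 0.75, 0.9)
  masks <- lapply(fractions, function(f)
    suppressMessages(tracer_mask(d, it, fraction = f)))
  for (i in seq_along(fractions)[-1])
    expect_true(all(masks[[i]]$membership <= masks[[i - 1]]$membership))
})

test_that("universal_mask intersects, restricts to GM, then symmetrizes", {
  grid <- tiny_grid()
  core <- coord_mask(grid, function(x, y, z) abs(x) <= 4 & abs(y) <= 2 & z > 0)
  wide <- coord_mask(grid, function(x, y, z) abs(x) <= 6 & abs(y) <= 4 & z > -2)
  gm_all <- coord_mask(grid, function(x, y, z) x > -Inf)

  # identical symmetric tracer masks, GM everywhere -> that mask
  u <- universal_mask(list(core, core), gm_all)
  expect_identical(u$membership, core$membership)

  # six masks sharing a symmetric core
  u6 <- universal_mask(rep(list(wide, core), 3), gm_all)
  expect_identical(u6$membership, core$membership)
  expect_equal(dice(u6, reflect_lr(u6)), 1.0)

  # GM restriction applies before symmetrization
  gm_half <- coord_mask(grid, function(x, y, z) abs(y) <= 0)
  uh <- universal_mask(list(core, wide), gm_half)
  expect_true(all(uh$membership <= gm_half$membership))

  disjoint <- coord_mask(grid, function(x, y, z) z < 0)
  expect_error(universal_mask(list(core, disjoint), gm_all), "empty")
})

test_that("subregions are carved within the universal mask", {
  grid <- tiny_grid()
  universal <- coord_mask(grid, function(x, y, z) abs(x) <= 4 & z >= 0)
  anat_sup <- coord_mask(grid, function(x, y, z) x > -Inf)
  expect_identical(subregion_mask(universal, anat_sup)$membership,
                   universal$membership)

  half <- coord_mask(grid, function(x, y, z) abs(x) <= 4 & z >= 0 & y > 0)
  sub <- subregion_mask(universal, half)
  expect_equal(mask_size(sub), mask_size(universal) * 4 / 9)
  expect_true(all(sub$membership <= universal$membership))

  outside <- coord_mask(grid, function(x, y, z) z < 0)
  expect_error(subregion_mask(universal, outside, name = "frontal"),
               "frontal")
})

test_that("noiseless phantom pipeline recovers the seeded region exactly", {
  spec <- phantom_spec(noise_sd = 0, cu_suvr_sd = 0)
  set.seed(5)
  cu <- lapply(1:3, function(i) simulate_subject(spec, "CU"))
  ad <- lapply(1:3, function(i) simulate_subject(spec, "AD"))
  cu_mean <- mean_image(lapply(cu, `[[`, "image"))
  ad_mean <- mean_image(lapply(ad, `[[`, "image"))
  d <- difference_image(ad_mean, cu_mean)
  tm <- suppressMessages(tracer_mask(d, spec$layout$inferior_temporal))
  u <- universal_mask(list(tm, tm), spec$layout$gray_matter)
  truth <- mask_union(spec$layout[c("mesial_temporal", "meta_temporal",
                                    "temporo_parietal", "frontal")])
  expect_identical(u$membership, truth$membership)
})

test_that("noisy phantom pipeline recovers the seeded region with high Dice", {
  truth <- NULL
  dices <- vapply(1:10, function(s) {
    spec <- phantom_spec(noise_sd = 0.2, cu_suvr_sd = 0)  # CNR ~ 5
    set.seed(100 + s)
    cu <- lapply(1:8, function(i) simulate_subject(spec, "CU"))
    ad <- lapply(1:8, function(i) simulate_subject(spec, "AD"))
    cu_mean <- mean_image(lapply(cu, `[[`, "image"))
    ad_mean <- mean_image(lapply(ad, `[[`, "image"))
    d <- difference_image(ad_mean, cu_mean)
    tm <- suppressMessages(tracer_mask(d, spec$layout$inferior_temporal))
    u <- universal_mask(list(tm, tm), spec$layout$gray_matter)
    truth <<- mask_union(spec$layout[c("mesial_temporal", "meta_temporal",
                                       "temporo_parietal", "frontal")])
    dice(u, truth)
  }, numeric(1))
  expect_true(all(dices >= 0.9))
})
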