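test_that("noiseless texture-free phantom has exact tissue-class plateaus", {
  cfg <- phantom_config(n_slices = 6, n_rows = 32, n_cols = 32, shells = 0,
                        texture_amplitude = 0, noise_sd = 0,
                        soft_value = 1064, air_value = 24, seed = 3)
  vol <- generate_phantom_volume(cfg)
  # interior plateau is exactly the soft value; far background exactly air
  expect_true(any(vol$voxels == 1064))
  expect_identical(vol$voxels[1, 1, 1], 24)
  expect_identical(vol$voxels[1, 16, 16], 1064)
  # class plateaus dominate: edge antialiasing touches few voxels
  frac_plateau <- mean(vol$voxels %in% c(24, 1064))
  expect_gt(frac_plateau, 0.8)
})

test_that("identical config and seed give bit-identical volumes", {
  cfg <- phantom_config(n_slices = 5, n_rows = 24, n_cols = 24, seed = 11)
  expect_identical(generate_phantom_volume(cfg)$voxels,
                   generate_phantom_volume(cfg)$voxels)
})

test_that("background noise matches the configured standard deviation", {
  cfg0 <- phantom_config(n_slices = 40, n_rows = 64, n_cols = 64,
                         air_value = 500, noise_sd = 0,
                         texture_amplitude = 0, seed = 9)
  cfg <- phantom_config(n_slices = 40, n_rows = 64, n_cols = 64,
                        air_value = 500, noise_sd = 20,
                        texture_amplitude = 0, seed = 9)
  clean <- generate_phantom_volume(cfg0)$voxels
  noisy <- generate_phantom_volume(cfg)$voxels
  bg <- clean == 500                      # pure-air voxels, far from any edge
  expect_gt(sum(bg), 1e5)
  s <- sd(noisy[bg])
  expect_gt(s, 19); expect_lt(s, 21)
})

test_that("phantom rejects degenerate configurations", {
  expect_error(phantom_config(n_slices = 0), "positive")
  expect_error(phantom_config(texture_corr_length = 64), "correlation length")
  expect_error(phantom_config(soft_value = 5000), "4095")
})

test_that("degrade_to_thick averages groups of k slices with the floor rule", {
  arr <- array(0L, c(3, 4, 4))
  arr[1, , ] <- 100L; arr[2, , ] <- 200L; arr[3, , ] <- 300L
  thin <- ct_volume(arr, 1)
  thick <- degrade_to_thick(thin, 3)
  expect_equal(dim(thick$voxels)[1], 1L)
  expect_true(all(thick$voxels == 200))
  expect_equal(thick$thickness, 3); expect_equal(thick$interval, 3)

  thin10 <- ct_volume(array(7L, c(10, 4, 4)), 1)
  expect_equal(dim(degrade_to_thick(thin10, 3)$voxels)[1], 3L)
})

test_that("degrade_to_thick equals the brute-force voxelwise mean", {
  set.seed(21)
  arr <- array(sample.int(4096, 9 * 8 * 8, replace = TRUE) - 1L, c(9, 8, 8))
  thin <- ct_volume(arr, 1)
  thick <- degrade_to_thick(thin, 3)
  for (j in 1:3) {
    ref <- (arr[3 * j - 2, , ] + arr[3 * j - 1, , ] + arr[3 * j, , ]) / 3
    expect_lte(max(abs(thick$voxels[j, , ] - ref)), 0.5)
  }
})

test_that("degradation is mean-preserving and shift-equivariant", {
  set.seed(22)
  arr <- array(sample.int(3000, 10 * 8 * 8, replace = TRUE) - 1L, c(10, 8, 8))
  thin <- ct_volume(arr, 1)
  thick <- degrade_to_thick(thin, 3)
  expect_lt(abs(mean(thick$voxels) - mean(arr[1:9, , ])), 0.5)
  shifted <- degrade_to_thick(ct_volume(arr + 50L, 1), 3)
  expect_lte(max(abs((shifted$voxels - 50L) - thick$voxels)), 1)
})

test_that("degrade_to_thick enforces its preconditions", {
  thin <- ct_volume(array(0L, c(4, 4, 4)), 1)
  expect_error(degrade_to_thick(thin, 1), "k must be")
  expect_error(degrade_to_thick(ct_volume(array(0L, c(2, 4, 4)), 1), 3),
               "at least k")
})

test_that("paired cases bundle consistent thin/thick volumes and mapping", {
  case <- tiny_case(seed = 2, n_slices = 30, size = 16)
  expect_equal(dim(case$thick$voxels)[1], 10L)
  expect_equal(nrow(case$mapping), 10L)

  case9 <- tiny_case(seed = 2, n_slices = 9, size = 16)
  expect_equal(case9$mapping$thick_index, 0:2)

  case31 <- tiny_case(seed = 2, n_slices = 31, size = 16)
  expect_equal(dim(case31$thick$voxels)[1], 10L)
  expect_false(30 %in% case31$mapping$pos_C)   # dropped trailing slice
})

test_that("fracture plane carves soft-tissue values through the shell", {
  base <- phantom_config(n_slices = 12, n_rows = 48, n_cols = 48,
                         texture_amplitude = 0, noise_sd = 0, seed = 4)
  frac <- phantom_config(n_slices = 12, n_rows = 48, n_cols = 48,
                         texture_amplitude = 0, noise_sd = 0, seed = 4,
                         fracture = TRUE)
  a <- generate_phantom_volume(base)$voxels
  b <- generate_phantom_volume(frac)$voxels
  changed <- which(a != b)
  expect_gt(length(changed), 0)
  expect_true(all(b[changed] <= a[changed]))  # bone replaced by softer value
})
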