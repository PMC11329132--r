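test_that("zero-residual and identity generators reproduce the input slice", {
  sl <- rand_slice(16)
  m2 <- stub_enhancer(list(), method = 2)      # all-zero residual stubs
  out2 <- enhance_slice(m2, sl)
  for (pos in position_labels()) expect_identical(out2[[pos]], sl)
  m1 <- stub_enhancer(list(), method = 1)      # identity stubs
  out1 <- enhance_slice(m1, sl)
  for (pos in position_labels()) expect_identical(out1[[pos]], sl)
})

test_that("a constant residual shifts stored values by the expected amount", {
  sl <- matrix(819L, 8, 8)                     # unit value 0.2
  enh <- stub_enhancer(stats::setNames(
    lapply(position_labels(), function(p) function(x) x * 0 + 0.1),
    position_labels()), method = 2)
  out <- enhance_slice(enh, sl, "C")
  expect_true(all(out$C == 1229L))  # round(0.3 * 4095), half away from zero
})

test_that("missing position models are reported", {
  enh <- copy_baseline_enhancer(3, 1)
  enh$models$`2P` <- NULL
  expect_error(enhance_slice(enh, rand_slice(8), "2P"), "lacks position")
})

test_that("enhance_volume covers exactly the union of mapping rows", {
  thick <- ct_volume(array(1000L, c(3, 16, 16)), 3)
  enh <- copy_baseline_enhancer(3, 1)
  out <- enhance_volume(enh, thick)
  # rows: j0 -> 0..3, j1 -> 2..6, j2 -> 5..8; union 0..8
  expect_equal(n_slices(out$volume), 9L)
  expect_equal(out$offset, 0L)
  expect_equal(out$volume$thickness, 1)
  expect_equal(out$volume$interval, 1)
})

test_that("overlapping predictions blend by rounded mean with provenance", {
  thick <- ct_volume(array(1000L, c(2, 8, 8)), 3)
  # every position predicts a constant keyed to its offset
  consts <- c("2P" = 100, "1P" = 120, "C" = 140, "1N" = 160, "2N" = 200)
  fns <- lapply(consts, function(v) function(x) x * 0 + v / 2047.5 - 1)  # method 1
  enh <- stub_enhancer(fns, method = 1)
  out <- enhance_volume(enh, thick)
  # thin index 3 gets 2N of row 0 (200) and 1P of row 1 (120) -> mean 160
  i <- 3 - out$offset + 1
  expect_true(all(out$volume$voxels[i, , ] == 160))
  expect_equal(nrow(out$provenance[[i]]), 2L)
  expect_setequal(out$provenance[[i]]$position, c("2N", "1P"))
  # interior slices are covered by one or two sources, never more
  expect_true(all(vapply(out$provenance, nrow, integer(1)) <= 2L))
})

test_that("nearest-position overlap rule prefers the smaller offset", {
  thick <- ct_volume(array(1000L, c(2, 8, 8)), 3)
  consts <- c("2P" = 100, "1P" = 120, "C" = 140, "1N" = 160, "2N" = 200)
  fns <- lapply(consts, function(v) function(x) x * 0 + v / 2047.5 - 1)
  enh <- stub_enhancer(fns, method = 1)
  out <- enhance_volume(enh, thick, overlap = "nearest")
  i <- 3 - out$offset + 1
  expect_true(all(out$volume$voxels[i, , ] == 120))   # 1P beats 2N
  expect_equal(nrow(out$provenance[[i]]), 1L)
  expect_identical(out$provenance[[i]]$position, "1P")
})

test_that("oracle generators reconstruct the thin phantom within rounding", {
  case <- tiny_case(seed = 31, n_slices = 18, size = 32,
                    texture_amplitude = 120)
  oracle_fns <- lapply(position_labels(), function(pos) {
    col <- case$mapping[[paste0("pos_", pos)]]
    function(x) {
      # identify the thick slice by exact match, replay its true residual
      for (r in seq_len(nrow(case$mapping))) {
        j <- case$mapping$thick_index[r]
        xs <- ctthinslice:::norm_values(to_signed_unit(get_slice(case$thick, j + 1)))
        if (isTRUE(all.equal(xs, x, tolerance = 1e-12))) {
          ti <- col[r]
          if (is.na(ti)) return(x * 0)
          return(ctthinslice:::norm_values(to_unit(get_slice(case$thin, ti + 1))) -
                 ctthinslice:::norm_values(to_unit(get_slice(case$thick, j + 1))))
        }
      }
      stop("input not recognised")
    }
  })
  enh <- stub_enhancer(stats::setNames(oracle_fns, position_labels()),
                       method = 2)
  out <- enhance_volume(enh, case$thick)
  idx <- out$offset + seq_len(n_slices(out$volume))
  for (i in seq_along(idx)) {
    expect_lte(max(abs(get_slice(out$volume, i) -
                       get_slice(case$thin, idx[i]))), 1)
  }
})

test_that("predict() on a fitted enhancer runs the inference pipeline", {
  case <- tiny_case(seed = 32, n_slices = 9)
  fit <- train_enhancer(list(case), 2, tiny_train_config())
  out <- predict(fit, case$thick)
  expect_s3_class(out, "enhanced_volume")
  expect_equal(n_slices(out$volume), 9L)
  expect_true(all(out$volume$voxels >= 0 & out$volume$voxels <= 4095))
})
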