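test_that("MSE and PSNR follow the unit-scale peak-1 convention", {
  a <- matrix(0L, 8, 8); b <- matrix(4095L, 8, 8)
  expect_equal(mse(a, a), 0)
  expect_equal(mse(a, b), 1)
  expect_identical(psnr(a, a), Inf)
  # psnr is the closed form of mse: MSE 1e-4 <-> 40 dB exactly
  x <- matrix(0.01 * 4095, 1, 1)
  expect_equal(psnr(matrix(0, 1, 1), x), 40)
  expect_error(mse(a, matrix(0L, 4, 4)), "shapes")
})

test_that("metrics match brute-force implementations on random slice pairs", {
  set.seed(99)
  gw <- ctthinslice:::gaussian_window(11, 1.5)
  for (rep in 1:100) {
    a <- rand_slice(16); b <- rand_slice(16)
    # longhand MSE / PSNR
    ref_mse <- sum((a / 4095 - b / 4095)^2) / 256
    expect_lt(abs(mse(a, b) - ref_mse), 1e-12)
    expect_lt(abs(psnr(a, b) - 10 * log10(1 / ref_mse)), 1e-9)
    if (rep <= 10) {
      # longhand windowed SSIM: explicit loop over window positions
      au <- a / 4095; bu <- b / 4095
      vals <- c()
      for (i in 1:6) for (j in 1:6) {
        wa <- au[i:(i + 10), j:(j + 10)]; wb <- bu[i:(i + 10), j:(j + 10)]
        mua <- sum(gw * wa); mub <- sum(gw * wb)
        saa <- sum(gw * wa * wa) - mua^2
        sbb <- sum(gw * wb * wb) - mub^2
        sab <- sum(gw * wa * wb) - mua * mub
        C1 <- 1e-4; C2 <- 9e-4
        vals <- c(vals, (2 * mua * mub + C1) * (2 * sab + C2) /
                          ((mua^2 + mub^2 + C1) * (saa + sbb + C2)))
      }
      expect_lt(abs(ssim(a, b) - mean(vals)), 1e-6)
    }
  }
})

test_that("SSIM is 1 for identical images and negative for inverted contrast", {
  a <- rand_slice(16)
  expect_equal(ssim(a, a), 1)
  chk <- matrix(0L, 16, 16); chk[(row(chk) + col(chk)) %% 2 == 0] <- 4095L
  inv <- 4095L - chk
  expect_lt(ssim(chk, inv), 0)
  expect_error(ssim(matrix(0L, 8, 8), matrix(0L, 8, 8)), "window")
})

test_that("SSIM is symmetric in its arguments", {
  set.seed(12)
  for (rep in 1:5) {
    a <- rand_slice(16); b <- rand_slice(16)
    expect_equal(ssim(a, b), ssim(b, a), tolerance = 1e-12)
  }
})

test_that("winner counts merge PSNR and MSE into one family and track ties", {
  t1 <- data.frame(psnr = c(30, 20, 25), mse = c(1e-3, 1e-2, 10^-2.5),
                   ssim = c(0.9, 0.8, 0.85))
  t2 <- data.frame(psnr = c(28, 22, 25), mse = c(10^-2.8, 10^-2.2, 10^-2.5),
                   ssim = c(0.9, 0.85, 0.8))
  w <- winner_counts(t1, t2)
  expect_equal(unname(w$psnr_mse), c(1, 1, 1))   # one win each + one tie
  expect_equal(unname(w$ssim), c(1, 1, 1))
  expect_error(winner_counts(t1, t2[1:2, ]), "length")
})

test_that("PSNR winners always equal MSE winners", {
  set.seed(4)
  mse1 <- 10^runif(50, -6, -1); mse2 <- 10^runif(50, -6, -1)
  t1 <- data.frame(psnr = 10 * log10(1 / mse1), mse = mse1, ssim = runif(50))
  t2 <- data.frame(psnr = 10 * log10(1 / mse2), mse = mse2, ssim = runif(50))
  expect_identical(t1$mse < t2$mse, t1$psnr > t2$psnr)
  w <- winner_counts(t1, t2)
  expect_equal(sum(w$psnr_mse), 50)
})

test_that("difference images are antisymmetric with red/blue channel swap", {
  a <- rand_slice(8); b <- rand_slice(8)
  d1 <- difference_image(a, b); d2 <- difference_image(b, a)
  expect_identical(d1$map, -d2$map)
  expect_equal(d1$render[, , 1], d2$render[, , 3])
  expect_equal(d1$render[, , 3], d2$render[, , 1])
  expect_true(all(d1$render[, , 2] == 0))
  same <- difference_image(a, a)
  expect_true(all(same$map == 0) && all(same$render == 0))
  up <- difference_image(b + 100, b)
  expect_true(all(up$render[, , 1] == 1) && all(up$render[, , 3] == 0))
})

test_that("Cohen's kappa matches longhand contingency arithmetic", {
  expect_equal(cohen_kappa(c(1, 2, 3, 1), c(1, 2, 3, 1)), 1)
  expect_equal(cohen_kappa(c("A", "A", "B", "B"), c("A", "B", "A", "B")), 0)
  # 2x2 table {AA: 20, AB: 5, BA: 10, BB: 15}
  r1 <- c(rep("A", 25), rep("B", 25))
  r2 <- c(rep("A", 20), rep("B", 5), rep("A", 10), rep("B", 15))
  po <- 35 / 50; pe <- (25 * 30 + 25 * 20) / 50^2
  expect_equal(cohen_kappa(r1, r2), (po - pe) / (1 - pe), tolerance = 1e-12)
  expect_error(cohen_kappa(1:3, 1:4), "length")
  expect_equal(cohen_kappa(c("A", "A"), c("A", "A")), 1)
  expect_error(cohen_kappa(c("A", "A"), c("A", "B")), NA)  # two categories: fine
})

test_that("kappa agrees with an independent implementation on random tables", {
  skip_if_not_installed("e1071")
  set.seed(31)
  for (rep in 1:20) {
    r1 <- sample(1:4, 60, replace = TRUE)
    r2 <- ifelse(runif(60) < 0.5, r1, sample(1:4, 60, replace = TRUE))
    ref <- e1071::classAgreement(table(factor(r1, 1:4), factor(r2, 1:4)))$kappa
    expect_equal(cohen_kappa(r1, r2), ref, tolerance = 1e-12)
  }
})

test_that("kappa is invariant under relabeling of categories", {
  set.seed(32)
  r1 <- sample(c("w", "x", "y"), 40, replace = TRUE)
  r2 <- sample(c("w", "x", "y"), 40, replace = TRUE)
  relab <- c(w = "P", x = "Q", y = "R")
  expect_equal(cohen_kappa(r1, r2), cohen_kappa(relab[r1], relab[r2]),
               tolerance = 1e-12)
})

test_that("metric reports aggregate both ways and round trip through JSON", {
  set.seed(44)
  mk <- function(n, off = 0) data.frame(slice = seq_len(n) - 1,
                                        psnr = 30 + runif(n) + off,
                                        mse = 10^-(3 + runif(n)),
                                        ssim = 0.9 + runif(n) / 20)
  res <- list(method1 = list(caseA = mk(4), caseB = mk(6)),
              method2 = list(caseA = mk(4, 1), caseB = mk(6, 1)))
  rep <- metric_report(res)
  expect_equal(nrow(rep$per_slice), 20L)
  expect_equal(nrow(rep$per_case), 4L)
  sl <- rep$per_slice[rep$per_slice$method == "method1", ]
  g <- rep$grand[rep$grand$method == "method1", ]
  expect_equal(g$psnr[g$aggregation == "over_slices"], mean(sl$psnr))
  pc <- rep$per_case[rep$per_case$method == "method1", ]
  expect_equal(g$psnr[g$aggregation == "over_case_means"], mean(pc$psnr))
  expect_false(is.null(rep$winners))
  expect_equal(sum(rep$winners$psnr_mse), 10)
  dir <- file.path(tempdir(), "report_rt")
  write_metric_report(rep, dir)
  back <- read_metric_report(dir)
  expect_equal(back$per_slice$psnr, rep$per_slice$psnr, tolerance = 1e-12)
  expect_equal(back$grand$mse, rep$grand$mse, tolerance = 1e-12)
  expect_equal(unname(back$winners$psnr_mse), unname(rep$winners$psnr_mse))
})

test_that("single-slice reports carry that slice's triple as every mean", {
  tab <- data.frame(slice = 0, psnr = 33.3, mse = 4.7e-4, ssim = 0.97)
  rep <- metric_report(list(m = list(c1 = tab)))
  expect_equal(rep$grand$psnr, c(33.3, 33.3))
  expect_equal(rep$per_case$mse, 4.7e-4)
})

test_that("infinite PSNR is excluded from means and counted", {
  tab <- data.frame(slice = 0:1, psnr = c(Inf, 40), mse = c(0, 1e-4),
                    ssim = c(1, 0.99))
  rep <- metric_report(list(m = list(c1 = tab)))
  expect_equal(rep$n_infinite_psnr, 1L)
  expect_equal(rep$grand$psnr[1], 40)
})
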