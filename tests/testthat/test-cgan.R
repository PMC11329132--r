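test_that("generator preserves spatial shape and bounds its output", {
  G <- build_generator(generator_spec(depth = 6, base_width = 2), seed = 1)
  x <- matrix(runif(64 * 64, -1, 1), 64)
  y <- predict_generator(G, x)
  expect_equal(dim(y), c(64L, 64L))
  expect_true(all(y >= -1 & y <= 1))
})

test_that("two generator builds with one seed have identical parameters", {
  spec <- generator_spec(depth = 3, base_width = 4)
  expect_identical(build_generator(spec, seed = 42)$par,
                   build_generator(spec, seed = 42)$par)
  expect_false(identical(build_generator(spec, seed = 42)$par,
                         build_generator(spec, seed = 43)$par))
})

test_that("input sizes not divisible by 2^depth are rejected", {
  G <- build_generator(generator_spec(depth = 6, base_width = 2), seed = 1)
  expect_error(predict_generator(G, matrix(0, 96, 96)), "divisible")
})

test_that("discriminator emits the classic 30x30 patch grid for 256 px input", {
  D <- build_discriminator(discriminator_spec(n_blocks = 3, base_width = 2),
                           seed = 2)
  x <- matrix(runif(256^2, -1, 1), 256)
  fw <- ctthinslice:::disc_forward(D, x, x)
  expect_equal(dim(fw$logits), c(30L, 30L))
  expect_true(all(is.finite(fw$logits)))
})

test_that("patch-grid shape depends on the condition, not the candidate", {
  D <- build_discriminator(discriminator_spec(3, 4), seed = 3)
  x <- matrix(runif(64 * 64, -1, 1), 64)
  y1 <- matrix(runif(64 * 64, -1, 1), 64)
  y2 <- -y1
  f1 <- ctthinslice:::disc_forward(D, x, y1)
  f2 <- ctthinslice:::disc_forward(D, x, y2)
  expect_equal(dim(f1$logits), dim(f2$logits))
  expect_false(identical(f1$logits, f2$logits))
})

test_that("cGAN losses match a longhand evaluation on toy grids", {
  d_real <- matrix(c(0.3, -0.2, 1.1, 0.4), 2)
  d_fake <- matrix(c(-0.5, 0.2, 0.0, -1.3), 2)
  y <- matrix(c(0.1, -0.4, 0.7, 0.0), 2)
  g <- matrix(c(0.2, -0.1, 0.6, -0.2), 2)
  w <- loss_weights(adversarial = 1, l1 = 100)
  out <- cgan_losses(d_real, d_fake, y, g, w)
  bce <- function(d, t) mean(log(1 + exp(-abs(d))) + pmax(d, 0) - t * d)
  expect_equal(out$discriminator, 0.5 * (bce(d_real, 1) + bce(d_fake, 0)),
               tolerance = 1e-9)
  expect_equal(out$l1, mean(abs(y - g)), tolerance = 1e-12)
  expect_equal(out$generator, bce(d_fake, 1) + 100 * mean(abs(y - g)),
               tolerance = 1e-9)
})

test_that("L1 term is zero iff the images coincide, and lambda = 0 drops it", {
  d <- matrix(0.1, 2, 2)
  y <- matrix(runif(16), 4)
  same <- cgan_losses(d, d, y, y, loss_weights())
  expect_equal(same$l1, 0)
  off <- cgan_losses(d, d, y, y + 0.1, loss_weights(l1 = 0))
  expect_equal(off$generator, off$adversarial)
  expect_gt(mean(abs(y - (y + 0.1))), 0)
})

test_that("backpropagation matches finite differences", {
  set.seed(42)
  G <- build_generator(generator_spec(depth = 2, base_width = 4), seed = 7)
  x <- matrix(runif(16 * 16, -1, 1), 16)
  fw <- ctthinslice:::gen_forward(G, x)
  R <- array(rnorm(length(fw$y)), dim(fw$y))
  gr <- ctthinslice:::gen_backward(G, fw, R)
  loss <- function(Gm) sum(ctthinslice:::gen_forward(Gm, x)$y * R)
  for (nm in c("enc1.W", "enc2.W", "enc2.g", "dec2.W", "out.W")) {
    i <- 3L; e <- 1e-6
    Gp <- G; Gm <- G
    Gp$par[[nm]][i] <- Gp$par[[nm]][i] + e
    Gm$par[[nm]][i] <- Gm$par[[nm]][i] - e
    fd <- (loss(Gp) - loss(Gm)) / (2 * e)
    expect_lt(abs(gr[[nm]][i] - fd), 1e-4 * max(1, abs(fd)))
  }
  D <- build_discriminator(discriminator_spec(2, 4), seed = 8)
  y <- matrix(runif(16 * 16, -1, 1), 16)
  fwd <- ctthinslice:::disc_forward(D, x, y)
  R2 <- matrix(rnorm(length(fwd$logits)), nrow(fwd$logits))
  gd <- ctthinslice:::disc_backward(D, fwd, R2)
  dloss <- function(Dm) sum(ctthinslice:::disc_forward(Dm, x, y)$logits * R2)
  for (nm in c("c1.W", "c2.W", "c2.g", "c4.W")) {
    i <- 2L; e <- 1e-6
    Dp <- D; Dm <- D
    Dp$par[[nm]][i] <- Dp$par[[nm]][i] + e
    Dm$par[[nm]][i] <- Dm$par[[nm]][i] - e
    fd <- (dloss(Dp) - dloss(Dm)) / (2 * e)
    expect_lt(abs(gd[[nm]][i] - fd), 1e-4 * max(1, abs(fd)))
  }
})

test_that("baseline initializations start at the trivial solution exactly", {
  spec <- generator_spec(depth = 3, base_width = 8)
  x <- matrix(runif(32 * 32, -1, 1), 32)
  Gz <- build_generator(spec, seed = 1, out_init = "zero")
  expect_true(all(predict_generator(Gz, x) == 0))
  Gp <- build_generator(spec, seed = 1, out_init = "passthrough")
  expect_lt(max(abs(predict_generator(Gp, x) - x)), 1e-12)
})

test_that("one small optimisation step decreases the generator L1 term", {
  # single repeated example with a dense residual target: the L1 landscape
  # is smooth there and a small step must descend
  set.seed(10)
  x <- matrix(runif(16 * 16, -0.9, 0.9), 16)
  target <- matrix(0.3, 16, 16)
  ex <- list(input = x, target = target, position = "C", method = 2)
  cfg <- tiny_train_config(lr = 1e-4)
  G <- build_generator(cfg$generator, seed = 3, out_init = "zero")
  D <- build_discriminator(cfg$discriminator, seed = 4)
  gs <- ctthinslice:::adam_init(G$par); ds <- ctthinslice:::adam_init(D$par)
  l1_0 <- mean(abs(predict_generator(G, x) - target))
  st <- ctthinslice:::train_step(G, D, gs, ds, ex, cfg)
  l1_1 <- mean(abs(predict_generator(st$G, x) - target))
  expect_lt(l1_1, l1_0)
})
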