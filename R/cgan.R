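#' Generator and discriminator architecture specifications
#'
#' `generator_spec()` describes the U-Net generator: a 1-channel
#' encoder-decoder with `depth` 2x downsamplings (4x4 stride-2 convolutions
#' with leaky-ReLU), mirrored nearest-neighbour-upsample + 3x3 convolution
#' decoder levels with skip concatenations, a full-resolution skip of the
#' raw input into the output convolution, and a bounded odd output
#' activation (hard-tanh) onto `[-1, 1]`. Output spatial shape always equals
#' input spatial shape; inputs must be divisible by `2^depth`.
#'
#' `discriminator_spec()` describes the conditional PatchGAN discriminator:
#' the condition and the candidate image are channel-concatenated and pushed
#' through `n_blocks` 4x4 stride-2 convolutions, one 4x4 stride-1
#' convolution, and a 1-channel 4x4 stride-1 head, yielding a 2-D grid of
#' patch logits (for a 256 px input with 3 strided blocks this is the
#' classic 30 x 30 grid with a ~70 px receptive field).
#'
#' @param depth number of 2x downsamplings in the generator (default 6,
#'   suitable for 64-256 px inputs).
#' @param base_width feature width of the first level (default 64); widths
#'   double per level, capped at `8 * base_width`.
#' @param n_blocks number of strided discriminator blocks (default 3).
#' @return a `generator_spec` / `discriminator_spec` list.
#' @export
generator_spec <- function(depth = 6, base_width = 64) {
  stopifnot(depth >= 1, base_width >= 1)
  structure(list(depth = as.integer(depth), base_width = as.integer(base_width)),
            class = "generator_spec")
}

#' @rdname generator_spec
#' @export
discriminator_spec <- function(n_blocks = 3, base_width = 64) {
  stopifnot(n_blocks >= 1, base_width >= 1)
  structure(list(n_blocks = as.integer(n_blocks),
                 base_width = as.integer(base_width)),
            class = "discriminator_spec")
}

#' Loss weights for the conditional-GAN objective
#'
#' The generator objective is `adversarial * BCE(D(x, G(x)), real) +
#' l1 * mean|y - G(x)|`; the discriminator objective is the mean of the
#' real-pair and fake-pair binary cross-entropies. Defaults follow the
#' published pix2pix values (adversarial weight 1, L1 weight 100, labels
#' real = 1 / fake = 0).
#'
#' @param adversarial adversarial weight (>= 0).
#' @param l1 reconstruction (L1) weight lambda (>= 0).
#' @param real_label,fake_label target labels for the discriminator.
#' @export
loss_weights <- function(adversarial = 1, l1 = 100, real_label = 1,
                         fake_label = 0) {
  if (l1 < 0 || adversarial < 0) stopf("loss weights must be non-negative")
  structure(list(adversarial = adversarial, l1 = l1,
                 real_label = real_label, fake_label = fake_label),
            class = "loss_weights")
}

# He (fan-in) initialization: keeps activation scale stable through a
# normalisation-free network
he_init <- function(fan_in, cout)
  matrix(stats::rnorm(fan_in * cout, 0, sqrt(2 / fan_in)), fan_in, cout)

gen_widths <- function(spec)
  pmin(spec$base_width * 2^(seq_len(spec$depth) - 1L), 8L * spec$base_width)

# row index into a conv weight matrix for kernel offset (di, dj) and input
# channel c (all 1-based), matching the im2col column layout
conv_w_row <- function(k, cin, di, dj, c) ((dj - 1L) * k + di - 1L) * cin + c

#' Build a generator / discriminator
#'
#' Parameters are initialized from zero-mean Gaussians with He (fan-in)
#' scaling — the appropriate scheme for a normalisation-free network —
#' under the given seed, so two builds with the same seed are identical.
#' The generator's output convolution supports three initialization modes:
#' `"default"` (random), `"zero"` (initial output is the zero image — the
#' natural start for residual learning, Method 2), and `"passthrough"`
#' (the output convolution initially copies the raw-input skip channel, so
#' the generator starts as the identity map — the natural start for raw
#' learning, Method 1). Both non-default modes make training start exactly
#' at the copy-thick-input baseline.
#'
#' @param spec a [generator_spec] / [discriminator_spec].
#' @param seed integer seed for parameter initialization.
#' @param out_init output-layer initialization mode (generator only).
#' @return an object of class `cgan_generator` / `cgan_discriminator`.
#' @export
build_generator <- function(spec, seed = 1,
                            out_init = c("default", "zero", "passthrough")) {
  stopifnot(inherits(spec, "generator_spec"))
  out_init <- match.arg(out_init)
  set.seed(seed)
  w <- gen_widths(spec)
  par <- list()
  cin <- 1L
  for (i in seq_len(spec$depth)) {
    par[[sprintf("enc%d.W", i)]] <- he_init(16L * cin, w[i])
    par[[sprintf("enc%d.b", i)]] <- numeric(w[i])
    if (i > 1L) {                      # instance norm (first layer unnormalized)
      par[[sprintf("enc%d.g", i)]] <- rep(1, w[i])
      par[[sprintf("enc%d.gb", i)]] <- numeric(w[i])
    }
    cin <- w[i]
  }
  for (i in seq.int(spec$depth, 2L)) {
    ci <- w[i] + w[i - 1L]
    par[[sprintf("dec%d.W", i)]] <- he_init(9L * ci, w[i - 1L])
    par[[sprintf("dec%d.b", i)]] <- numeric(w[i - 1L])
    par[[sprintf("dec%d.g", i)]] <- rep(1, w[i - 1L])
    par[[sprintf("dec%d.gb", i)]] <- numeric(w[i - 1L])
  }
  ci <- w[1] + 1L
  Wout <- switch(out_init,
    default = he_init(9L * ci, 1L),
    zero = matrix(0, 9L * ci, 1L),
    passthrough = {
      m <- matrix(0, 9L * ci, 1L)
      m[conv_w_row(3L, ci, 2L, 2L, ci), 1L] <- 1   # center tap of the input skip
      m
    })
  par[["out.W"]] <- Wout
  par[["out.b"]] <- numeric(1L)
  structure(list(spec = spec, par = par, seed = seed, out_init = out_init),
            class = "cgan_generator")
}

gen_check_size <- function(gen, d) {
  f <- 2^gen$spec$depth
  if (d[1] %% f != 0L || d[2] %% f != 0L)
    stopf("input size %dx%d is not divisible by 2^depth = %d", d[1], d[2], f)
}

gen_forward <- function(gen, x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  gen_check_size(gen, dim(x))
  depth <- gen$spec$depth
  enc_out <- vector("list", depth)
  enc_cache <- vector("list", depth)
  enc_neg <- vector("list", depth)
  enc_in <- vector("list", depth)
  h <- x
  for (i in seq_len(depth)) {
    cf <- conv_fwd(h, gen$par[[sprintf("enc%d.W", i)]],
                   gen$par[[sprintf("enc%d.b", i)]], 4L, 2L, 1L)
    z <- cf$y
    if (i > 1L) {
      nf <- inorm_fwd(z, gen$par[[sprintf("enc%d.g", i)]],
                      gen$par[[sprintf("enc%d.gb", i)]])
      enc_in[[i]] <- nf; z <- nf$y
    }
    a <- lrelu(z)
    enc_cache[[i]] <- cf$cache; enc_neg[[i]] <- a$neg
    enc_out[[i]] <- a$y
    h <- a$y
  }
  dec_cache <- vector("list", depth); dec_neg <- vector("list", depth)
  dec_in <- vector("list", depth)
  if (depth >= 2L) for (i in seq.int(depth, 2L)) {
    up <- upsample2(h)
    cat_in <- ccat(up, enc_out[[i - 1L]])
    cf <- conv_fwd(cat_in, gen$par[[sprintf("dec%d.W", i)]],
                   gen$par[[sprintf("dec%d.b", i)]], 3L, 1L, 1L)
    nf <- inorm_fwd(cf$y, gen$par[[sprintf("dec%d.g", i)]],
                    gen$par[[sprintf("dec%d.gb", i)]])
    dec_in[[i]] <- nf
    a <- lrelu(nf$y, 0)                    # plain ReLU in the decoder
    dec_cache[[i]] <- cf$cache; dec_neg[[i]] <- a$neg
    h <- a$y
  }
  up <- upsample2(h)
  cat_in <- ccat(up, x)
  cf <- conv_fwd(cat_in, gen$par[["out.W"]], gen$par[["out.b"]], 3L, 1L, 1L)
  act <- hardtanh(cf$y)
  list(y = act$y, x = x, enc_cache = enc_cache, enc_neg = enc_neg,
       enc_in = enc_in, dec_in = dec_in,
       dec_cache = dec_cache, dec_neg = dec_neg, out_cache = cf$cache,
       out_mask = act$mask)
}

gen_backward <- function(gen, fw, gy) {
  depth <- gen$spec$depth
  w <- gen_widths(gen$spec)
  grads <- list()
  g <- gy * fw$out_mask
  cb <- conv_bwd(g, fw$out_cache, gen$par[["out.W"]])
  grads[["out.W"]] <- cb$gW; grads[["out.b"]] <- cb$gb
  g_enc <- vector("list", depth)
  gh <- upsample2_bwd(cb$gx[, , seq_len(w[1]), drop = FALSE])
  # gh is the gradient flowing into the activated output of the level the
  # decoder read from (level 1's mirror = deepest when depth == 1)
  if (depth >= 2L) {
    # walk the decoder in reverse execution order: shallow (i = 2) to deep
    for (i in seq.int(2L, depth)) {
      g_act <- lrelu_bwd(gh, fw$dec_neg[[i]], 0)
      nb <- inorm_bwd(g_act, fw$dec_in[[i]], gen$par[[sprintf("dec%d.g", i)]])
      grads[[sprintf("dec%d.g", i)]] <- nb$gg
      grads[[sprintf("dec%d.gb", i)]] <- nb$gb
      cb <- conv_bwd(nb$gx, fw$dec_cache[[i]], gen$par[[sprintf("dec%d.W", i)]])
      grads[[sprintf("dec%d.W", i)]] <- cb$gW
      grads[[sprintf("dec%d.b", i)]] <- cb$gb
      gskip <- cb$gx[, , w[i] + seq_len(w[i - 1L]), drop = FALSE]
      g_enc[[i - 1L]] <- if (is.null(g_enc[[i - 1L]])) gskip else g_enc[[i - 1L]] + gskip
      gh <- upsample2_bwd(cb$gx[, , seq_len(w[i]), drop = FALSE])
    }
  }
  g_enc[[depth]] <- if (is.null(g_enc[[depth]])) gh else g_enc[[depth]] + gh
  for (i in seq.int(depth, 1L)) {
    g_pre <- lrelu_bwd(g_enc[[i]], fw$enc_neg[[i]])
    if (i > 1L) {
      nb <- inorm_bwd(g_pre, fw$enc_in[[i]], gen$par[[sprintf("enc%d.g", i)]])
      grads[[sprintf("enc%d.g", i)]] <- nb$gg
      grads[[sprintf("enc%d.gb", i)]] <- nb$gb
      g_pre <- nb$gx
    }
    cb <- conv_bwd(g_pre, fw$enc_cache[[i]], gen$par[[sprintf("enc%d.W", i)]])
    grads[[sprintf("enc%d.W", i)]] <- cb$gW
    grads[[sprintf("enc%d.b", i)]] <- cb$gb
    if (i > 1L)
      g_enc[[i - 1L]] <- if (is.null(g_enc[[i - 1L]])) cb$gx else g_enc[[i - 1L]] + cb$gx
  }
  grads
}

#' @rdname build_generator
#' @export
build_discriminator <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "discriminator_spec"))
  set.seed(seed)
  wmax <- 8L * spec$base_width
  widths <- pmin(spec$base_width * 2^(seq_len(spec$n_blocks) - 1L), wmax)
  layers <- list()
  cin <- 2L
  for (i in seq_len(spec$n_blocks)) {
    layers[[i]] <- list(cout = widths[i], stride = 2L, act = TRUE)
    cin <- widths[i]
  }
  layers[[spec$n_blocks + 1L]] <-
    list(cout = min(wmax, 2L * cin), stride = 1L, act = TRUE)
  layers[[spec$n_blocks + 2L]] <- list(cout = 1L, stride = 1L, act = FALSE)
  par <- list()
  cin <- 2L
  for (i in seq_along(layers)) {
    co <- layers[[i]]$cout
    par[[sprintf("c%d.W", i)]] <- he_init(16L * cin, co)
    par[[sprintf("c%d.b", i)]] <- numeric(co)
    if (layers[[i]]$act && i > 1L) {
      par[[sprintf("c%d.g", i)]] <- rep(1, co)
      par[[sprintf("c%d.gb", i)]] <- numeric(co)
    }
    cin <- co
  }
  structure(list(spec = spec, layers = layers, par = par, seed = seed),
            class = "cgan_discriminator")
}

disc_forward <- function(disc, x, y) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  if (is.matrix(y)) dim(y) <- c(dim(y), 1L)
  h <- ccat(x, y)
  caches <- vector("list", length(disc$layers))
  negs <- vector("list", length(disc$layers))
  ins <- vector("list", length(disc$layers))
  for (i in seq_along(disc$layers)) {
    L <- disc$layers[[i]]
    d <- dim(h)
    if (d[1] < 2L || d[2] < 2L)
      stopf("discriminator input too small at layer %d", i)
    cf <- conv_fwd(h, disc$par[[sprintf("c%d.W", i)]],
                   disc$par[[sprintf("c%d.b", i)]], 4L, L$stride, 1L)
    caches[[i]] <- cf$cache
    z <- cf$y
    if (L$act) {
      if (i > 1L) {
        nf <- inorm_fwd(z, disc$par[[sprintf("c%d.g", i)]],
                        disc$par[[sprintf("c%d.gb", i)]])
        ins[[i]] <- nf; z <- nf$y
      }
      a <- lrelu(z); negs[[i]] <- a$neg; h <- a$y
    } else h <- z
  }
  list(logits = h[, , 1L], caches = caches, negs = negs, ins = ins)
}

disc_backward <- function(disc, fw, glogits) {
  g <- glogits
  dim(g) <- c(dim(glogits), 1L)
  grads <- list()
  for (i in rev(seq_along(disc$layers))) {
    if (disc$layers[[i]]$act) {
      g <- lrelu_bwd(g, fw$negs[[i]])
      if (i > 1L) {
        nb <- inorm_bwd(g, fw$ins[[i]], disc$par[[sprintf("c%d.g", i)]])
        grads[[sprintf("c%d.g", i)]] <- nb$gg
        grads[[sprintf("c%d.gb", i)]] <- nb$gb
        g <- nb$gx
      }
    }
    cb <- conv_bwd(g, fw$caches[[i]], disc$par[[sprintf("c%d.W", i)]])
    grads[[sprintf("c%d.W", i)]] <- cb$gW
    grads[[sprintf("c%d.b", i)]] <- cb$gb
    g <- cb$gx
  }
  grads$gx <- g
  grads
}

#' Conditional-GAN losses
#'
#' Computes the pix2pix-style objective from discriminator patch grids and
#' images. The discriminator loss is the mean of the two binary
#' cross-entropies (real pair toward the real label, fake pair toward the
#' fake label); the generator loss is the non-saturating adversarial term
#' (fake pair toward the real label) plus `l1 * mean|y - g_out|`.
#'
#' @param d_real,d_fake patch logit grids from the discriminator on the
#'   (condition, truth) and (condition, generated) pairs.
#' @param y target image; `g_out` generated image (same shape).
#' @param g_out generator output.
#' @param weights a [loss_weights].
#' @return list with elements `generator`, `discriminator`, `adversarial`,
#'   `l1`.
#' @export
cgan_losses <- function(d_real, d_fake, y, g_out, weights = loss_weights()) {
  if (!all(dim(d_real) == dim(d_fake))) stopf("patch grid shapes differ")
  if (!all(dim(as.matrix(y)) == dim(as.matrix(g_out))))
    stopf("image shapes differ")
  bce <- function(d, t) mean(softplus(d) - t * d)
  d_loss <- 0.5 * (bce(d_real, weights$real_label) +
                   bce(d_fake, weights$fake_label))
  l1 <- mean(abs(unclass(as.matrix(y)) - unclass(as.matrix(g_out))))
  adv <- bce(d_fake, weights$real_label)
  list(generator = weights$adversarial * adv + weights$l1 * l1,
       discriminator = d_loss, adversarial = adv, l1 = l1)
}

#' Run a generator on one normalized slice
#'
#' Dispatches on the generator class: trained `cgan_generator`s run the
#' U-Net forward pass; `stub_generator`s (fixed functions, used for
#' baselines and closure checks) call their function.
#'
#' @param gen a generator.
#' @param x numeric matrix on the signed `[-1, 1]` scale.
#' @return numeric matrix, same shape, values in `[-1, 1]`.
#' @export
predict_generator <- function(gen, x) UseMethod("predict_generator")

#' @export
predict_generator.cgan_generator <- function(gen, x) {
  x <- unclass(as.matrix(x))
  gen_forward(gen, x)$y[, , 1L]
}

#' @export
predict_generator.stub_generator <- function(gen, x) {
  gen$fn(unclass(as.matrix(x)))
}

#' Create a stub generator from a fixed function
#'
#' Stub generators stand in for trained models where a fixed map is wanted:
#' the identity stub is the copy-thick-input baseline under Method 1, the
#' zero stub is the same baseline under Method 2, and oracle stubs replaying
#' ground-truth targets verify the inference pipeline end to end.
#'
#' @param fn function taking and returning a numeric matrix.
#' @export
stub_generator <- function(fn) structure(list(fn = fn),
                                         class = c("stub_generator", "generator"))
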