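#' Phantom configuration
#'
#' Describes a procedurally generated wrist-like CT phantom: an air
#' background, a soft-tissue ellipse whose outline drifts smoothly along the
#' slice axis, a configurable number of closed cortical-bone shells with
#' band-limited trabecular texture inside, an optional oblique fracture
#' plane through the first shell, and additive Gaussian acquisition noise.
#' All values are 12-bit stored values in `[0, 4095]` (HU relate through the
#' metadata rescale intercept of -1024; e.g. air ~ 24, soft tissue ~ 1064).
#'
#' Defaults emulate a thin-slice (1 mm) wrist acquisition at desk scale:
#' 36 slices of 64 x 64 voxels, two bone shells, trabecular texture of
#' amplitude 150 stored values with a 3-voxel correlation length, and noise
#' with a standard deviation of 10 stored values.
#'
#' @param n_slices,n_rows,n_cols grid shape (positive integers).
#' @param voxel_size length-3 numeric, (slice, row, col) size in mm.
#' @param shells number of cortical bone shells (>= 0).
#' @param cortical_value,soft_value,air_value,trabecular_value stored values
#'   of the tissue classes, each in `[0, 4095]`.
#' @param texture_amplitude trabecular texture amplitude in stored values.
#' @param texture_corr_length texture correlation length in voxels; must be
#'   smaller than every grid extent.
#' @param fracture logical; render a 1-voxel-thick oblique fracture plane
#'   through the first shell.
#' @param fracture_normal length-3 numeric; normal of the fracture plane in
#'   (slice, row, col) voxel coordinates.
#' @param noise_sd acquisition noise standard deviation in stored values.
#' @param seed RNG seed; the same config (including seed) always yields a
#'   bit-identical volume.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(n_slices = 36, n_rows = 64, n_cols = 64,
                           voxel_size = c(1, 0.5, 0.5), shells = 2,
                           cortical_value = 2600, soft_value = 1064,
                           air_value = 24, trabecular_value = 1400,
                           texture_amplitude = 150, texture_corr_length = 3,
                           fracture = FALSE, fracture_normal = c(0.45, 1, 0.35),
                           noise_sd = 10, seed = 1) {
  if (any(c(n_slices, n_rows, n_cols) < 1)) stopf("grid dimensions must be positive")
  vals <- c(cortical_value, soft_value, air_value, trabecular_value)
  if (any(vals < 0 | vals > 4095)) stopf("tissue stored values must lie in [0, 4095]")
  if (texture_corr_length >= min(n_slices, n_rows, n_cols))
    stopf("texture correlation length (%g) must be below the smallest grid extent",
          texture_corr_length)
  if (shells < 0 || noise_sd < 0 || texture_amplitude < 0)
    stopf("shells, noise_sd and texture_amplitude must be non-negative")
  structure(list(n_slices = as.integer(n_slices), n_rows = as.integer(n_rows),
                 n_cols = as.integer(n_cols), voxel_size = voxel_size,
                 shells = as.integer(shells), cortical_value = cortical_value,
                 soft_value = soft_value, air_value = air_value,
                 trabecular_value = trabecular_value,
                 texture_amplitude = texture_amplitude,
                 texture_corr_length = texture_corr_length,
                 fracture = isTRUE(fracture), fracture_normal = fracture_normal,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_config")
}

# Separable Gaussian smoothing along each axis of a 3-D array (reflecting
# borders), used to give the trabecular texture its correlation length.
smooth3d <- function(a, sigma) {
  r <- max(1L, ceiling(2.5 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2)); k <- k / sum(k)
  sm_axis <- function(x, axis) {
    n <- dim(x)[axis]
    idx <- outer(seq_len(n), seq(-r, r), "+")
    idx <- abs(idx - 1L) %% (2L * n - 2L); idx <- pmin(idx, 2L * n - 2L - idx) + 1L
    out <- array(0, dim(x))
    for (j in seq_along(k)) {
      sel <- idx[, j]
      out <- out + k[j] * switch(axis, x[sel, , , drop = FALSE],
                                 x[, sel, , drop = FALSE],
                                 x[, , sel, drop = FALSE])
    }
    out
  }
  sm_axis(sm_axis(sm_axis(a, 1L), 2L), 3L)
}

#' Generate a thin-slice phantom volume
#'
#' Builds the synthetic volume described by a [phantom_config]: tissue-class
#' labels are painted deterministically from the config geometry, texture and
#' noise are drawn from the config seed, then values are clipped to
#' `[0, 4095]` and rounded to integer stored values.
#'
#' @param config a [phantom_config].
#' @return a [ct_volume] with `thickness = interval = voxel_size[1]`.
#' @export
generate_phantom_volume <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(config$seed)
  ns <- config$n_slices; nr <- config$n_rows; nc <- config$n_cols
  t_z <- if (ns > 1) (seq_len(ns) - 1) / (ns - 1) else rep(0.5, ns)
  row_g <- matrix(seq_len(nr), nr, nc)
  col_g <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  soft_mask <- array(FALSE, dim = c(ns, nr, nc))
  interior_mask <- array(FALSE, dim = c(ns, nr, nc))
  shell_mask <- array(FALSE, dim = c(ns, nr, nc))

  # Structures are rendered with partial-volume (anti-aliased) edges: a
  # boundary voxel's value reflects its fractional occupancy, as the
  # scanner's point-spread and slice averaging produce in real CT. Hard
  # binary edges would turn the smooth structural drift along z into
  # aliased single-pixel flips that carry no learnable signal.
  ew <- 1.2                               # edge transition width, voxels
  ramp <- function(d) clip(0.5 - d / ew, 0, 1)   # d = signed distance (out > 0)
  vol <- array(config$air_value, dim = c(ns, nr, nc))

  # shell geometry parameters are drawn once (seeded) so shells drift
  # smoothly and reproducibly along z
  sh <- NULL
  if (config$shells > 0) {
    ang <- stats::runif(config$shells, 0, 2 * pi)
    sh <- list(
      dr = 0.16 * nr * cos(ang), dc = 0.16 * nc * sin(ang),
      rad = 0.10 * min(nr, nc) * stats::runif(config$shells, 0.8, 1.3),
      wob = stats::runif(config$shells, 0.5, 1.5))
  }

  # The body and shells taper monotonically along z (as a distal limb
  # does), with a gentle superimposed wobble: a consistent through-plane
  # progression is what position-specific models exploit on real anatomy.
  for (z in seq_len(ns)) {
    tz <- t_z[z]
    a <- 0.36 * nr * (1.05 - 0.35 * tz + 0.012 * sin(2.4 * pi * tz))
    b <- 0.40 * nc * (1.02 - 0.30 * tz + 0.010 * cos(1.9 * pi * tz))
    e <- ((row_g - (nr + 1) / 2) / a)^2 + ((col_g - (nc + 1) / 2) / b)^2
    d_soft <- (sqrt(e) - 1) * min(a, b)   # approx. signed distance, voxels
    alpha_soft <- ramp(d_soft)
    v <- config$air_value + alpha_soft * (config$soft_value - config$air_value)
    soft_mask[z, , ] <- alpha_soft >= 1
    if (config$shells > 0) {
      for (s in seq_len(config$shells)) {
        cr <- (nr + 1) / 2 + sh$dr[s] * (0.97 + 0.03 * sin(2 * pi * sh$wob[s] * tz))
        cc <- (nc + 1) / 2 + sh$dc[s] * (0.97 + 0.03 * cos(2 * pi * sh$wob[s] * tz))
        rad <- sh$rad[s] * (1.15 - 0.4 * tz + 0.015 * sin(2.2 * pi * tz + s))
        d <- sqrt((row_g - cr)^2 + (col_g - cc)^2) - rad  # 0 at outer edge
        alpha_in <- ramp(d + 2.2) * alpha_soft            # inside inner wall
        alpha_ring <- ramp(abs(d + 1.1) - 1.1) * alpha_soft
        v <- v + alpha_in * (config$trabecular_value - v)
        v <- v + alpha_ring * (config$cortical_value - v)
        interior_mask[z, , ] <- interior_mask[z, , ] | (alpha_in >= 1)
        shell_mask[z, , ] <- shell_mask[z, , ] | (alpha_ring >= 1)
      }
    }
    vol[z, , ] <- v
  }

  if (config$texture_amplitude > 0 && any(interior_mask)) {
    tex <- array(stats::rnorm(ns * nr * nc), dim = c(ns, nr, nc))
    tex <- smooth3d(tex, config$texture_corr_length / 2)
    tex <- tex / stats::sd(tex)
    vol[interior_mask] <- vol[interior_mask] +
      config$texture_amplitude * tex[interior_mask]
  }

  if (config$fracture && any(shell_mask | interior_mask)) {
    nvec <- config$fracture_normal / sqrt(sum(config$fracture_normal^2))
    zi <- slice.index(vol, 1); ri <- slice.index(vol, 2); ci <- slice.index(vol, 3)
    d0 <- nvec[1] * (ns + 1) / 2 + nvec[2] * (nr + 1) / 2 + nvec[3] * (nc + 1) / 2
    plane <- abs(nvec[1] * zi + nvec[2] * ri + nvec[3] * ci - d0) <= 0.5
    brk <- plane & (shell_mask | interior_mask)
    vol[brk] <- config$soft_value
  }

  if (config$noise_sd > 0)
    vol <- vol + stats::rnorm(length(vol), sd = config$noise_sd)
  vol <- round_half_away(clip(vol, 0, 4095))
  ct_volume(vol, thickness = config$voxel_size[1],
            interval = config$voxel_size[1],
            pixel_spacing = config$voxel_size[2:3],
            source = sprintf("phantom(seed=%d)", config$seed))
}

#' Virtually thicken a thin-slice volume
#'
#' Simulates a thick-slice acquisition from a thin-slice volume by the
#' standard partial-volume model: thick slice j is the unweighted arithmetic
#' mean of thin slices `(k(j-1)+1) .. kj`, rounded half away from zero.
#' Trailing thin slices that do not fill a complete group are dropped, so
#' the output has `floor(n/k)` slices with thickness = interval = k times
#' the thin thickness.
#'
#' @param thin a [ct_volume].
#' @param k integer thickness ratio, >= 2.
#' @return a [ct_volume] of thick slices.
#' @export
degrade_to_thick <- function(thin, k) {
  stopifnot(inherits(thin, "ct_volume"))
  k <- as.integer(k)
  if (is.na(k) || k < 2L) stopf("thickness ratio k must be an integer >= 2")
  n <- n_slices(thin)
  if (n < k) stopf("need at least k = %d thin slices, have %d", k, n)
  m <- n %/% k
  d <- dim(thin$voxels)
  a <- thin$voxels[seq_len(m * k), , , drop = FALSE]
  dim(a) <- c(k, m, d[2], d[3])
  means <- colMeans(a)                    # over the k grouped thin slices
  vox <- round_half_away(means)
  ct_volume(vox, thickness = k * thin$thickness, interval = k * thin$interval,
            pixel_spacing = thin$pixel_spacing, intercept = thin$intercept,
            source = sprintf("%s|thick(k=%d)", thin$source, k))
}

#' Build a paired thin/thick training case
#'
#' Generates a thin-slice phantom, derives its virtual thick-slice volume
#' with [degrade_to_thick()], and attaches the thick-to-thin slice-location
#' mapping from [build_mapping()].
#'
#' @param config a [phantom_config].
#' @param k thickness ratio (odd integer >= 3 for the five-position scheme).
#' @param id case identifier string.
#' @return an object of class `paired_case` with elements `thin`, `thick`,
#'   `mapping` and `id`.
#' @export
make_paired_case <- function(config, k = 3, id = sprintf("case%d", config$seed)) {
  thin <- generate_phantom_volume(config)
  thick <- degrade_to_thick(thin, k)
  structure(list(thin = thin, thick = thick,
                 mapping = build_mapping(n_slices(thin), k),
                 id = as.character(id)),
            class = "paired_case")
}

#' Desk-scale phantom evaluation suite
#'
#' The paired-case family used by the package's own end-to-end experiments:
#' 64 x 64 in-plane, 60 thin slices per case, two tapering bone shells, no
#' trabecular texture and near-noiseless acquisition (sd 2 stored values).
#' The family is deliberately easy — its through-plane progression is
#' smooth and consistent — so that learning-signal checks measure the
#' method, not phantom difficulty. Case geometry varies through per-case
#' seeds derived from one suite seed.
#'
#' @param n_cases number of paired cases.
#' @param seed suite seed; per-case seeds are derived from it.
#' @param k thickness ratio.
#' @param ... overrides forwarded to [phantom_config()].
#' @return list of `paired_case`s.
#' @export
phantom_suite <- function(n_cases = 4, seed = 1, k = 3, ...) {
  base <- list(n_slices = 60, n_rows = 64, n_cols = 64,
               noise_sd = 2, texture_amplitude = 0)
  args <- utils::modifyList(base, list(...))
  lapply(seq_len(n_cases), function(i) {
    args$seed <- derive_seed(seed, paste0("suite-case-", i))
    make_paired_case(do.call(phantom_config, args), k,
                     id = sprintf("case%d", i))
  })
}

#' @exportS3Method base::print
print.paired_case <- function(x, ...) {
  cat(sprintf("<paired_case> %s: %d thin / %d thick slices (k = %d)\n",
              x$id, n_slices(x$thin), n_slices(x$thick), attr(x$mapping, "k")))
  invisible(x)
}
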