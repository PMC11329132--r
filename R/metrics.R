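#' Image-quality metrics on the unit scale
#'
#' All three metrics are computed on `[0, 1]`-scaled images (stored value /
#' 4095) with peak 1. `mse()` is the mean of squared per-pixel differences;
#' `psnr()` is `10 * log10(1 / MSE)` in decibels and is `+Inf` (never
#' capped) for identical images; `ssim()` is the mean local structural
#' similarity with an 11 x 11 Gaussian window (sigma 1.5) and stabilizers
#' `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2` with dynamic range `L = 1` — the
#' original SSIM defaults.
#'
#' @param a,b numeric matrices of stored values in `[0, 4095]`, equal shape.
#' @param window odd window side length for `ssim`.
#' @param sigma Gaussian window standard deviation.
#' @param K1,K2 stabilizer constants.
#' @return a scalar.
#' @examples
#' a <- matrix(0, 8, 8); b <- matrix(4095, 8, 8)
#' mse(a, b)    # 1
#' psnr(a, a)   # Inf
#' @export
mse <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stopf("slice shapes differ")
  mean((a / 4095 - b / 4095)^2)
}

#' @rdname mse
#' @export
psnr <- function(a, b) {
  m <- mse(a, b)
  if (m == 0) Inf else 10 * log10(1 / m)
}

# 'valid'-mode 2-D correlation with a small kernel, via shifted adds
filter2_valid <- function(x, w) {
  k <- nrow(w)
  oh <- nrow(x) - k + 1L; ow <- ncol(x) - k + 1L
  out <- matrix(0, oh, ow)
  for (dj in seq_len(k)) for (di in seq_len(k))
    out <- out + w[di, dj] * x[di:(di + oh - 1L), dj:(dj + ow - 1L)]
  out
}

gaussian_window <- function(n, sigma) {
  r <- (n - 1) / 2
  g <- exp(-((-r):r)^2 / (2 * sigma^2))
  w <- outer(g, g)
  w / sum(w)
}

#' @rdname mse
#' @export
ssim <- function(a, b, window = 11, sigma = 1.5, K1 = 0.01, K2 = 0.03) {
  a <- as.matrix(a) / 4095; b <- as.matrix(b) / 4095
  if (!all(dim(a) == dim(b))) stopf("slice shapes differ")
  if (nrow(a) < window || ncol(a) < window)
    stopf("image (%dx%d) smaller than the %dx%d SSIM window",
          nrow(a), ncol(a), window, window)
  w <- gaussian_window(window, sigma)
  C1 <- K1^2; C2 <- K2^2                    # L = 1 on unit-scaled images
  mu_a <- filter2_valid(a, w); mu_b <- filter2_valid(b, w)
  s_aa <- filter2_valid(a * a, w) - mu_a^2
  s_bb <- filter2_valid(b * b, w) - mu_b^2
  s_ab <- filter2_valid(a * b, w) - mu_a * mu_b
  num <- (2 * mu_a * mu_b + C1) * (2 * s_ab + C2)
  den <- (mu_a^2 + mu_b^2 + C1) * (s_aa + s_bb + C2)
  mean(num / den)
}

#' Per-slice method-winner counts
#'
#' For each slice, the PSNR/MSE family winner is the method with the lower
#' MSE (equivalently the higher PSNR — the relation is strictly monotone, so
#' the two metrics always name the same winner and are counted once, as in
#' the merged "PSNR, MSE" column of per-slice comparisons); the SSIM winner
#' is the method with the higher SSIM. Strict ties are excluded from both
#' tallies and reported separately.
#'
#' @param triples1,triples2 data frames with columns `psnr`, `mse`, `ssim`,
#'   one row per slice, equal row counts (methods 1 and 2).
#' @return list of two named count vectors, `psnr_mse` and `ssim`, each with
#'   entries `method1`, `method2`, `ties`.
#' @export
winner_counts <- function(triples1, triples2) {
  if (nrow(triples1) != nrow(triples2)) stopf("per-slice lists differ in length")
  tally <- function(better1, better2) c(
    method1 = sum(better1), method2 = sum(better2),
    ties = sum(!better1 & !better2))
  list(psnr_mse = tally(triples1$mse < triples2$mse,
                        triples2$mse < triples1$mse),
       ssim = tally(triples1$ssim > triples2$ssim,
                    triples2$ssim > triples1$ssim))
}

#' Signed difference image
#'
#' `a - b` in stored-value units plus an RGB render mapping positive
#' differences to red intensity, negative to blue and zero to black, with
#' symmetric scaling by the maximum absolute difference.
#'
#' @param a,b stored-value matrices of equal shape.
#' @return list with `map` (signed matrix) and `render` (H x W x 3 array in
#'   `[0, 1]`).
#' @export
difference_image <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stopf("slice shapes differ")
  m <- a - b
  render <- array(0, c(nrow(m), ncol(m), 3))
  s <- max(abs(m))
  if (s > 0) {
    render[, , 1] <- pmax(m, 0) / s
    render[, , 3] <- pmax(-m, 0) / s
  }
  list(map = m, render = render)
}

#' @rdname difference_image
#' @param path output PNG path.
#' @export
write_difference_png <- function(a, b, path) {
  png::writePNG(difference_image(a, b)$render, path)
  invisible(path)
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)`, with
#' observed agreement `p_o` and chance agreement `p_e` from the marginal
#' products of the contingency table. Used for inter-rater agreement on
#' ordinal image-quality grades and on binary method preferences. If the
#' raters use a single category (`p_e = 1`), kappa is defined as 1 for
#' perfect agreement and is an error otherwise.
#'
#' @param ratings1,ratings2 equal-length vectors of categorical ratings.
#' @return kappa in `[-1, 1]`.
#' @examples
#' cohen_kappa(c("A", "A", "B", "B"), c("A", "B", "A", "B"))  # 0
#' @export
cohen_kappa <- function(ratings1, ratings2) {
  if (length(ratings1) != length(ratings2)) stopf("rating lists differ in length")
  if (length(ratings1) == 0) stopf("empty ratings")
  lev <- sort(unique(c(ratings1, ratings2)))
  tab <- table(factor(ratings1, lev), factor(ratings2, lev))
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (pe >= 1 - 1e-15) {
    if (po >= 1 - 1e-15) return(1)
    stopf("kappa undefined: chance agreement is 1 but observed agreement is not")
  }
  (po - pe) / (1 - pe)
}

#' Aggregate per-slice metrics into a report
#'
#' Collects per-slice metric tables per method and per case into one
#' report: per-case means, grand means (both as the mean over all slices
#' and as the mean of per-case means — the two differ by case-size
#' weighting and both are kept, labelled), and, when exactly two methods
#' are present, per-slice winner counts per metric family. Slices with
#' infinite PSNR are excluded from PSNR means and their count is recorded.
#'
#' @param results named list (one entry per method) of named lists (one
#'   entry per case) of per-slice data frames with columns `slice`, `psnr`,
#'   `mse`, `ssim`.
#' @return an object of class `metric_report` with fields `per_slice`,
#'   `per_case`, `grand`, `winners` (or `NULL`), `n_infinite_psnr`.
#' @export
metric_report <- function(results) {
  if (length(results) == 0) stopf("no results to report")
  per_slice <- do.call(rbind, unlist(lapply(names(results), function(m) {
    lapply(names(results[[m]]), function(cs)
      cbind(method = m, case = cs, results[[m]][[cs]],
            stringsAsFactors = FALSE))
  }), recursive = FALSE))
  rownames(per_slice) <- NULL
  fin_mean <- function(x) mean(x[is.finite(x)])
  agg <- function(df) data.frame(psnr = fin_mean(df$psnr), mse = mean(df$mse),
                                 ssim = mean(df$ssim), n_slices = nrow(df))
  keys <- unique(per_slice[c("method", "case")])
  per_case <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    sel <- per_slice$method == keys$method[i] & per_slice$case == keys$case[i]
    cbind(keys[i, ], agg(per_slice[sel, ]), row.names = NULL)
  }))
  grand <- do.call(rbind, lapply(unique(per_slice$method), function(m) {
    sl <- per_slice[per_slice$method == m, ]
    pc <- per_case[per_case$method == m, ]
    rbind(cbind(method = m, aggregation = "over_slices", agg(sl)),
          cbind(method = m, aggregation = "over_case_means",
                data.frame(psnr = mean(pc$psnr), mse = mean(pc$mse),
                           ssim = mean(pc$ssim), n_slices = sum(pc$n_slices))))
  }))
  winners <- NULL
  if (length(results) == 2L) {
    ms <- names(results)
    s1 <- per_slice[per_slice$method == ms[1], ]
    s2 <- per_slice[per_slice$method == ms[2], ]
    if (nrow(s1) == nrow(s2)) winners <- winner_counts(s1, s2)
  }
  structure(list(per_slice = per_slice, per_case = per_case, grand = grand,
                 winners = winners,
                 n_infinite_psnr = sum(!is.finite(per_slice$psnr))),
            class = "metric_report")
}

#' @exportS3Method base::print
print.metric_report <- function(x, ...) {
  cat("<metric_report>\n")
  cat("Per-case means:\n")
  print(x$per_case, row.names = FALSE, digits = 6)
  cat("Grand means:\n")
  print(x$grand, row.names = FALSE, digits = 6)
  if (!is.null(x$winners)) {
    cat("Winner counts (PSNR/MSE family):",
        paste(names(x$winners$psnr_mse), x$winners$psnr_mse, collapse = ", "), "\n")
    cat("Winner counts (SSIM):",
        paste(names(x$winners$ssim), x$winners$ssim, collapse = ", "), "\n")
  }
  if (x$n_infinite_psnr > 0)
    cat(sprintf("(%d slice(s) with infinite PSNR excluded from PSNR means)\n",
                x$n_infinite_psnr))
  invisible(x)
}

#' Serialize / restore a metric report
#'
#' `write_metric_report()` writes `per_slice.csv`, `per_case.csv` and
#' `report.json` (full-precision JSON of the whole report) under `dir`;
#' `read_metric_report()` restores the report from the JSON exactly.
#'
#' @param report a [metric_report].
#' @param dir output directory.
#' @export
write_metric_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(report$per_slice, file.path(dir, "per_slice.csv"),
                   row.names = FALSE)
  utils::write.csv(report$per_case, file.path(dir, "per_case.csv"),
                   row.names = FALSE)
  jsonlite::write_json(unclass(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns",
                       na = "string")
  invisible(dir)
}

#' @rdname write_metric_report
#' @export
read_metric_report <- function(dir) {
  obj <- jsonlite::read_json(file.path(dir, "report.json"), simplifyVector = TRUE)
  fix_df <- function(x) { df <- as.data.frame(x); df$psnr <- as.numeric(df$psnr); df }
  out <- list(per_slice = fix_df(obj$per_slice), per_case = fix_df(obj$per_case),
              grand = fix_df(obj$grand),
              winners = if (is.null(obj$winners)) NULL else
                lapply(obj$winners, function(w) unlist(w)),
              n_infinite_psnr = obj$n_infinite_psnr)
  class(out) <- "metric_report"
  out
}
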