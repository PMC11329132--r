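#' Generate the five thin slices for one thick slice
#'
#' Runs the position-specific generators on a single thick slice. Under
#' Method 1 (raw learning) the generator output on the signed `[-1, 1]`
#' scale is mapped straight back to stored values. Under Method 2 (residual
#' learning) the generator output is interpreted as a residual on the
#' `[0, 1]` scale: it is added to the unit-scaled input, clipped to
#' `[0, 1]`, and rescaled to `[0, 4095]`.
#'
#' @param enhancer a `ct_enhancer` (trained, stub or baseline).
#' @param slice numeric matrix of stored values in `[0, 4095]`.
#' @param positions subset of [position_labels()] to generate.
#' @return named list of stored-value matrices, one per requested position.
#' @export
enhance_slice <- function(enhancer, slice, positions = position_labels()) {
  stopifnot(inherits(enhancer, "ct_enhancer"))
  positions <- match.arg(positions, position_labels(), several.ok = TRUE)
  missing <- setdiff(positions, names(enhancer$models))
  if (length(missing))
    stopf("enhancer lacks position model(s): %s", paste(missing, collapse = ", "))
  x_signed <- norm_values(to_signed_unit(slice))
  out <- lapply(positions, function(pos) {
    g <- predict_generator(enhancer$models[[pos]], x_signed)
    if (enhancer$method == 1L) {
      from_signed_unit(g)
    } else {
      y_unit <- clip(norm_values(to_unit(slice)) + g, 0, 1)
      m <- round_half_away(y_unit * 4095)
      storage.mode(m) <- "integer"
      m
    }
  })
  stats::setNames(out, positions)
}

#' Enhance a thick-slice volume into a thin-slice volume
#'
#' The full inference pipeline: each thick slice is run through the five
#' position generators, and the per-position predictions are assembled into
#' a thin-slice volume using the slice-location mapping for the enhancer's
#' thickness ratio `k`. Where predictions from adjacent thick slices target
#' the same thin index, they are reconciled by the chosen overlap rule:
#' `"mean"` (rounded unweighted mean of contributors, the default) or
#' `"nearest"` (the contributor whose position offset is smallest in
#' magnitude wins). Thin indices near the volume boundary that no mapping
#' row covers are omitted; the result records its index offset so outputs
#' remain alignable with ground truth.
#'
#' @param enhancer a `ct_enhancer`.
#' @param thick a thick-slice [ct_volume].
#' @param overlap `"mean"` or `"nearest"`.
#' @return an object of class `enhanced_volume`: `volume` (thin
#'   [ct_volume]), `offset` (0-based thin index of the first output slice),
#'   `provenance` (per-slice list of contributing (thick index, position)
#'   pairs and whether the slice was blended), `method`.
#' @export
enhance_volume <- function(enhancer, thick, overlap = c("mean", "nearest")) {
  stopifnot(inherits(enhancer, "ct_enhancer"), inherits(thick, "ct_volume"))
  overlap <- match.arg(overlap)
  N <- n_slices(thick)
  if (N < 1) stopf("thick volume is empty")
  k <- enhancer$k
  mapping <- build_mapping(N * k, k)
  d <- dim(thick$voxels)
  n_thin <- N * k
  acc <- array(0, c(n_thin, d[2], d[3]))
  cnt <- integer(n_thin)
  best_off <- rep(NA_integer_, n_thin)
  prov <- vector("list", n_thin)
  for (r in seq_len(nrow(mapping))) {
    j <- mapping$thick_index[r]
    preds <- enhance_slice(enhancer, get_slice(thick, j + 1L))
    for (pos in position_labels()) {
      ti <- mapping[[paste0("pos_", pos)]][r]
      if (is.na(ti)) next
      i <- ti + 1L
      off <- abs(position_offsets[[pos]])
      if (overlap == "mean") {
        acc[i, , ] <- acc[i, , ] + preds[[pos]]
        cnt[i] <- cnt[i] + 1L
        prov[[i]] <- rbind(prov[[i]],
                           data.frame(thick_index = j, position = pos))
      } else if (is.na(best_off[i]) || off < best_off[i]) {
        acc[i, , ] <- preds[[pos]]
        cnt[i] <- 1L
        best_off[i] <- off
        prov[[i]] <- data.frame(thick_index = j, position = pos)
      }
    }
  }
  covered <- which(cnt > 0L)
  if (length(covered) == 0) stopf("no thin slice is covered by any mapping row")
  span <- min(covered):max(covered)
  if (any(cnt[span] == 0L))
    stopf("internal gap in thin-slice coverage at index %d",
          span[which(cnt[span] == 0L)[1]] - 1L)
  vox <- array(0, c(length(span), d[2], d[3]))
  for (ii in seq_along(span))
    vox[ii, , ] <- round_half_away(acc[span[ii], , ] / cnt[span[ii]])
  vol <- ct_volume(vox, thickness = thick$thickness / k,
                   interval = thick$interval / k,
                   pixel_spacing = thick$pixel_spacing,
                   intercept = thick$intercept,
                   source = sprintf("%s|enhanced(m%d)", thick$source,
                                    enhancer$method))
  structure(list(volume = vol, offset = min(covered) - 1L,
                 provenance = prov[span], method = enhancer$method),
            class = "enhanced_volume")
}

#' @exportS3Method base::print
print.enhanced_volume <- function(x, ...) {
  blended <- sum(vapply(x$provenance, nrow, integer(1)) > 1L)
  cat(sprintf("<enhanced_volume> method %d: %d thin slices (offset %d), %d blended\n",
              x$method, n_slices(x$volume), x$offset, blended))
  invisible(x)
}
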