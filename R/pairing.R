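#' Position labels for the five-model slice-generation scheme
#'
#' Each thick slice is paired with five thin slices: the corresponding thin
#' slice `C` at its geometric center and the adjacent thin slices two before
#' (`2P`), one before (`1P`), one after (`1N`) and two after (`2N`). One
#' generator is trained per position. Offsets relative to the center index
#' are -2, -1, 0, +1, +2.
#'
#' @export
position_labels <- function() c("2P", "1P", "C", "1N", "2N")

position_offsets <- c("2P" = -2L, "1P" = -1L, "C" = 0L, "1N" = 1L, "2N" = 2L)

#' Offset of a position label relative to the center thin slice
#' @param position one of `"2P"`, `"1P"`, `"C"`, `"1N"`, `"2N"`.
#' @export
position_offset <- function(position) {
  position <- match.arg(position, position_labels())
  position_offsets[[position]]
}

#' Build the thick-to-thin slice-location mapping table
#'
#' For thickness ratio `k` (odd, >= 3), thick slice `j` (0-based) covers thin
#' slices `kj .. kj+k-1`; its center thin index is `C = kj + (k-1)/2` and the
#' five positions sit at `C + {-2,-1,0,+1,+2}`. Indices falling outside
#' `[0, n_thin)` are absent (`NA`): boundary rows are short rather than
#' padded. Rows exist for `j` in `[0, floor(n_thin/k))`.
#'
#' @param n_thin number of thin slices (>= k).
#' @param k odd integer thickness ratio >= 3.
#' @return a `mapping_table`: a data frame with columns `thick_index`,
#'   `pos_2P`, `pos_1P`, `pos_C`, `pos_1N`, `pos_2N` (0-based thin indices,
#'   `NA` = absent) and attributes `k`, `n_thin`.
#' @examples
#' build_mapping(9, 3)
#' @export
build_mapping <- function(n_thin, k = 3) {
  n_thin <- as.integer(n_thin); k <- as.integer(k)
  if (is.na(k) || k < 3L || k %% 2L == 0L)
    stopf("k must be an odd integer >= 3 (the center thin slice is undefined for even k)")
  if (is.na(n_thin) || n_thin < k) stopf("need n_thin >= k")
  j <- seq_len(n_thin %/% k) - 1L
  centers <- k * j + (k - 1L) %/% 2L
  tab <- data.frame(thick_index = j)
  for (pos in position_labels()) {
    idx <- centers + position_offsets[[pos]]
    idx[idx < 0L | idx >= n_thin] <- NA_integer_
    tab[[paste0("pos_", pos)]] <- idx
  }
  structure(tab, k = k, n_thin = n_thin,
            class = c("mapping_table", "data.frame"))
}

#' Serialize a mapping table to CSV
#'
#' Absent positions are written as empty cells.
#' @param mapping a `mapping_table` from [build_mapping()].
#' @param path output CSV path.
#' @export
write_mapping_csv <- function(mapping, path) {
  utils::write.csv(as.data.frame(mapping), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_mapping_csv
#' @param k,n_thin values of the table attributes (not stored in the CSV).
#' @export
read_mapping_csv <- function(path, k = 3, n_thin = NA) {
  tab <- utils::read.csv(path)
  if (is.na(n_thin)) n_thin <- max(unlist(tab[-1]), na.rm = TRUE) + 1L
  structure(tab, k = as.integer(k), n_thin = as.integer(n_thin),
            class = c("mapping_table", "data.frame"))
}

#' Materialize training examples for one position model
#'
#' For every mapping row in which the requested position is present, builds
#' one (input, target) pair. The input is always the thick slice on the
#' signed `[-1, 1]` scale. Under Method 1 (raw learning) the target is the
#' thin slice on the same signed scale; under Method 2 (residual/difference
#' learning) the target is `to_unit(thin) - to_unit(thick)`, which lies in
#' `[-1, 1]` by construction and is added back to the `[0, 1]`-scaled input
#' at inference.
#'
#' @param case a `paired_case` from [make_paired_case()].
#' @param position a position label, see [position_labels()].
#' @param method 1 (raw) or 2 (residual).
#' @return a list of `training_example`s, each with elements `input`,
#'   `target`, `position`, `method`, `case_id`, `thick_index`, `thin_index`.
#' @export
make_training_examples <- function(case, position, method = c(1, 2)) {
  stopifnot(inherits(case, "paired_case"))
  method <- as.integer(method[1])
  if (!method %in% c(1L, 2L)) stopf("method must be 1 or 2")
  position <- match.arg(position, position_labels())
  col <- case$mapping[[paste0("pos_", position)]]
  rows <- which(!is.na(col))
  if (length(rows) == 0)
    stopf("no mapping row provides position %s for case %s", position, case$id)
  lapply(rows, function(r) {
    j <- case$mapping$thick_index[r]
    ti <- col[r]
    thick_sl <- get_slice(case$thick, j + 1L)
    thin_sl <- get_slice(case$thin, ti + 1L)
    target <- if (method == 1L) norm_values(to_signed_unit(thin_sl))
              else norm_values(to_unit(thin_sl)) - norm_values(to_unit(thick_sl))
    structure(list(input = norm_values(to_signed_unit(thick_sl)), target = target,
                   position = position, method = method, case_id = case$id,
                   thick_index = j, thin_index = ti),
              class = "training_example")
  })
}
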