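#' Design a set of sample barcodes with a minimum Hamming distance
#'
#' Greedy construction over a seeded shuffle of all `4^length` codes: a
#' candidate is kept iff its Hamming distance to every kept code is at least
#' `min_distance`. With 6-nt codes and distance 3 at least 64 codes are
#' always reachable, comfortably above the multiplexing needs of a single
#' run.
#'
#' @param k Number of barcodes required.
#' @param length Barcode length in nt (default 6).
#' @param min_distance Minimum pairwise Hamming distance (default 3).
#' @param seed Integer seed for the candidate shuffle.
#' @return Object of class `barcode_set`: list with `barcodes`, `length`,
#'   `min_distance`.
#' @export
design_barcodes <- function(k, length = 6, min_distance = 3, seed = 1) {
  if (k < 1L) stop("k must be >= 1")
  if (min_distance > length) stop("min_distance cannot exceed barcode length")
  grids <- do.call(expand.grid, rep(list(DNA_BASES), length))
  all_codes <- do.call(paste0, grids)
  kept <- character(0)
  kept_mat <- NULL
  with_seed(seed, {
    order <- sample.int(length(all_codes))
    for (i in order) {
      cand <- strsplit(all_codes[i], "")[[1]]
      if (is.null(kept_mat) ||
          all(colSums(kept_mat != cand) >= min_distance)) {
        kept <- c(kept, all_codes[i])
        kept_mat <- cbind(kept_mat, cand)
        if (length(kept) == k) break
      }
    }
  })
  if (length(kept) < k)
    stop(sprintf("only %d codes of length %d at distance >= %d are reachable",
                 length(kept), length, min_distance))
  structure(list(barcodes = kept, length = length, min_distance = min_distance),
            class = "barcode_set")
}

#' Minimum pairwise Hamming distance of a barcode set
#'
#' Exhaustive over all pairs.
#'
#' @param bs A `barcode_set` or character vector of equal-length codes.
#' @return Integer minimum distance (`Inf` for fewer than two codes).
#' @export
min_pairwise_hamming <- function(bs) {
  codes <- if (inherits(bs, "barcode_set")) bs$barcodes else bs
  if (length(codes) < 2L) return(Inf)
  best <- Inf
  for (i in seq_len(length(codes) - 1L))
    for (j in (i + 1L):length(codes))
      best <- min(best, hamming(codes[i], codes[j]))
  best
}

#' @export
print.barcode_set <- function(x, ...) {
  cat(sprintf("barcode_set: %d codes of length %d, design distance >= %d\n",
              length(x$barcodes), x$length, x$min_distance))
  invisible(x)
}
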