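# Independent oracles, written before (and kept independent of) the
# implementation paths they check.

# Plain-R affine-gap local alignment oracle (Gotoh recurrences written out
# directly over dense matrices, no shared code with the package kernel).
# Same conventions: gap of length L costs open + (L-1)*ext; tie-break
# smallest query_start, then ref_start, then query_end, then ref_end.
sw_oracle <- function(query, ref, match = 2, mismatch = -2,
                      gap_open = -5, gap_ext = -1) {
  q <- strsplit(query, "")[[1]]; r <- strsplit(ref, "")[[1]]
  n <- length(q); m <- length(r)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)   # horizontal: gap in query
  F <- matrix(-Inf, n + 1, m + 1)   # vertical: gap in ref
  for (i in 1:n) for (j in 1:m) {
    E[i + 1, j + 1] <- max(H[i + 1, j] + gap_open, E[i + 1, j] + gap_ext)
    F[i + 1, j + 1] <- max(H[i, j + 1] + gap_open, F[i, j + 1] + gap_ext)
    sub <- if (q[i] == r[j]) match else mismatch
    H[i + 1, j + 1] <- max(0, H[i, j] + sub, E[i + 1, j + 1], F[i + 1, j + 1])
  }
  best <- max(H)
  if (best == 0)
    return(list(score = 0, query_start = NA, query_end = NA,
                ref_start = NA, ref_end = NA))
  ends <- which(H == best, arr.ind = TRUE)
  cands <- lapply(seq_len(nrow(ends)), function(k) {
    i <- unname(ends[k, 1]) - 1L; j <- unname(ends[k, 2]) - 1L
    qe <- i; re <- j
    state <- "H"
    repeat {
      if (state == "H") {
        if (H[i + 1, j + 1] == 0) break
        sub <- if (q[i] == r[j]) match else mismatch
        if (i >= 1 && j >= 1 && H[i + 1, j + 1] == H[i, j] + sub) {
          i <- i - 1L; j <- j - 1L
        } else if (H[i + 1, j + 1] == F[i + 1, j + 1]) state <- "F"
        else state <- "E"
      } else if (state == "F") {
        if (i > 1 && F[i + 1, j + 1] == F[i, j + 1] + gap_ext) i <- i - 1L
        else { i <- i - 1L; state <- "H" }
      } else {
        if (j > 1 && E[i + 1, j + 1] == E[i + 1, j] + gap_ext) j <- j - 1L
        else { j <- j - 1L; state <- "H" }
      }
    }
    c(qs = i + 1L, rs = j + 1L, qe = qe, re = re)
  })
  key <- vapply(cands, function(cc) cc[["qs"]] * 1e9 + cc[["rs"]] * 1e6 +
                  cc[["qe"]] * 1e3 + cc[["re"]], numeric(1))
  bestc <- cands[[which.min(key)]]
  list(score = best, query_start = bestc[["qs"]], query_end = bestc[["qe"]],
       ref_start = bestc[["rs"]], ref_end = bestc[["re"]])
}

# Brute-force Poisson upper tail via explicit partial sums.
poisson_tail_oracle <- function(n, N, mu) {
  lam <- N * mu
  ks <- seq_len(n) - 1L
  1 - sum(exp(-lam) * lam^ks / factorial(ks))
}
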