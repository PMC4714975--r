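# Shared fixtures, built in code. The reference and any simulated data are
# deterministic under fixed seeds.

test_ref <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_reference(seed = 1)
    cache
  }
})

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# Minimal clonotype table straight from field vectors; unspecified columns
# get neutral defaults.
make_table <- function(cdr3_nt, copies, v_call = "V1-1", j_call = "J1",
                       d_call = "D1", cdr3_aa = NULL, isotype = "IgM",
                       n_total = 0L, mutation_count = 0L,
                       mutation_window_len = 129L, sample_id = "S1") {
  n <- length(cdr3_nt)
  if (n == 0L)
    return(ighrep:::as_clonotype_table(ighrep:::empty_clonotype_table(),
                                       sample_id))
  if (is.null(cdr3_aa)) cdr3_aa <- paste0("P", seq_len(n))
  df <- data.frame(
    sequence = paste0(cdr3_nt, seq_len(n)), copies = as.integer(copies),
    sample_id = sample_id,
    v_call = rep_len(v_call, n), d_call = rep_len(d_call, n),
    j_call = rep_len(j_call, n), isotype = rep_len(isotype, n),
    cdr2_start = 46L, cdr3_start = 175L,
    cdr3_end = 175L + nchar(cdr3_nt) - 1L,
    cdr3_nt = cdr3_nt, cdr3_aa = rep_len(cdr3_aa, n),
    productive = TRUE, v_del = 0L, d5_del = 0L, d3_del = 0L, j_del = 0L,
    p2 = "", n2_len = 0L, n1_len = 0L, p1 = "",
    n_total = rep_len(as.integer(n_total), n),
    mutation_count = rep_len(as.integer(mutation_count), n),
    mutation_window_len = rep_len(as.integer(mutation_window_len), n),
    stringsAsFactors = FALSE)
  ighrep:::as_clonotype_table(df, sample_id)
}

# Hand-built two-V "reference" for relatedness threshold fixtures; bypasses
# the generator so aligned length and mismatch count are exact by
# construction.
make_v_pair_ref <- function(len, n_mismatch, seed = 42) {
  set.seed(seed)
  a <- rand_dna(len)
  b <- a
  if (n_mismatch > 0) {
    pos <- seq(5L, len - 5L, length.out = n_mismatch)
    chars <- strsplit(b, "")[[1]]
    for (p in round(pos)) chars[p] <- setdiff(c("A", "C", "G", "T"), chars[p])[1]
    b <- paste(chars, collapse = "")
  }
  structure(list(segments = data.frame(
    id = c("Va", "Vb"), kind = "V", family = c("Va", "Vb"),
    sequence = c(a, b), chromosomal_order = 1:2,
    cdr1_start = 10L, cdr2_start = 20L, cdr3_start = len - 8L,
    cdr3_end = NA_integer_, stringsAsFactors = FALSE)),
    class = "germline_reference")
}
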