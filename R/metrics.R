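# Repertoire statistics: D50 diversity, pairwise CDR3 peptide sharing,
# normalized VH usage, N-insertion profiles, convergent-recombination
# entropy, mutation summaries and isotype-by-mutation cross-tabulations.

#' D50 repertoire diversity
#'
#' With CDR3 nucleotide abundances ranked r1 >= r2 >= ... >= rS summing to
#' J reads, C is the minimum number of distinct CDR3s whose cumulative
#' abundance reaches at least half of J; D50 = C / S * 100. Low values
#' indicate a repertoire dominated by few clones; uniform repertoires give
#' exactly 50 (even S). Rank ties are broken lexicographically on the
#' CDR3 for determinism.
#'
#' @param table A `clonotype_table`.
#' @return D50 percentage in (0, 100].
#' @export
d50 <- function(table) {
  if (nrow(table) == 0L) stop("empty clonotype table")
  ab <- tapply(table$copies, table$cdr3_nt, sum)
  ab <- ab[order(-ab, names(ab))]
  J <- sum(ab); S <- length(ab)
  C <- unname(which(cumsum(ab) >= J / 2)[1])
  100 * C / S
}

#' Pairwise CDR3 peptide sharing between two samples
#'
#' pA->B is the percentage of distinct CDR3 peptides of A also found in
#' B; pB->A symmetrically. Computed on distinct peptides, unweighted by
#' copies. A nucleotide-level variant is available via `level`.
#'
#' @param a,b `clonotype_table`s.
#' @param level "peptide" (default) or "nucleotide".
#' @return Named numeric vector `c(pAB, pBA)` in percent.
#' @export
pairwise_sharing <- function(a, b, level = c("peptide", "nucleotide")) {
  level <- match.arg(level)
  col <- if (level == "peptide") "cdr3_aa" else "cdr3_nt"
  pa <- unique(a[[col]][nzchar(a[[col]])])
  pb <- unique(b[[col]][nzchar(b[[col]])])
  if (!length(pa) || !length(pb)) stop("empty table")
  c(pAB = 100 * length(intersect(pa, pb)) / length(pa),
    pBA = 100 * length(intersect(pb, pa)) / length(pb))
}

#' VH gene usage, normalized or copy-weighted
#'
#' In normalized mode each distinct CDR3 nucleotide sequence counts once
#' under its V call, no matter how often it was read; in raw mode counts
#' are copy-weighted. Output is ordered 5' to 3' by chromosomal rank when
#' a reference is supplied (unused V genes appear with 0).
#'
#' @param table A `clonotype_table`.
#' @param normalized Count unique sequences (TRUE, default) or reads.
#' @param ref Optional `germline_reference` for chromosomal ordering.
#' @return data.frame (v_call, pct) with percentages summing to 100.
#' @export
vh_usage <- function(table, normalized = TRUE, ref = NULL) {
  if (nrow(table) == 0L) stop("empty clonotype table")
  if (normalized) {
    u <- table[!duplicated(table$cdr3_nt), c("v_call", "cdr3_nt")]
    counts <- base::table(u$v_call)
  } else {
    counts <- tapply(table$copies, table$v_call, sum)
  }
  if (!is.null(ref)) {
    vs <- segments_of(ref, "V")
    vs <- vs[order(vs$chromosomal_order), ]
    full <- setNames(numeric(nrow(vs)), vs$id)
    full[names(counts)] <- counts
    counts <- full
  }
  data.frame(v_call = names(counts),
             pct = 100 * as.numeric(counts) / sum(counts),
             stringsAsFactors = FALSE)
}

#' Default N-insertion length bins
#' @export
N_INSERTION_BINS <- list("0" = c(0, 0), "1-2" = c(1, 2), "3-4" = c(3, 4),
                         "5-7" = c(5, 7), ">=8" = c(8, Inf))

#' N-insertion profile over unique sequences
#'
#' Total nontemplated bases per junction (V-DJ plus D-J) binned over
#' distinct sequences: each distinct sequence counts once regardless of
#' its copy number.
#'
#' @param table A `clonotype_table` (needs `n_total`).
#' @param bins Named list of `c(lo, hi)` inclusive ranges.
#' @return data.frame (bin, pct); percentages sum to 100.
#' @export
n_insertion_profile <- function(table, bins = N_INSERTION_BINS) {
  if (nrow(table) == 0L) stop("empty clonotype table")
  n <- table$n_total
  pct <- vapply(bins, function(r) 100 * mean(n >= r[1] & n <= r[2]), numeric(1))
  data.frame(bin = names(bins), pct = as.numeric(pct), stringsAsFactors = FALSE)
}

#' Convergent-recombination entropy per CDR3 peptide
#'
#' A peptide produced by n distinct V(D)J nucleotide recombinations with
#' frequencies P1..Pn gets Shannon entropy E = -sum Pi log2 Pi; E is 0
#' when a single recombination encodes the peptide and log2(n) when all
#' are equally frequent. Recombination identity is the distinct
#' (v_call, d_call, j_call, cdr3_nt) tuple. Frequencies are copy-weighted
#' by default ("reads"); "unique" weights each recombination equally.
#' Entropies are binned into [0,0.5), [0.5,1.5), [1.5,2.5), [2.5,Inf);
#' bin fractions are reported over distinct peptides and, separately,
#' weighted by reads.
#'
#' @param table A `clonotype_table`.
#' @param weighting "reads" (default) or "unique".
#' @return List of class `convergence_result`: `peptides` data.frame
#'   (cdr3_aa, n_recombinations, entropy, copies) and `bins` data.frame
#'   (bin, fraction_peptides, fraction_reads); fractions sum to 1.
#' @export
convergence_entropy <- function(table, weighting = c("reads", "unique")) {
  weighting <- match.arg(weighting)
  tab <- table[nzchar(table$cdr3_aa), , drop = FALSE]
  if (nrow(tab) == 0L) stop("no productive CDR3 peptides")
  key <- paste(tab$v_call, tab$d_call, tab$j_call, tab$cdr3_nt, sep = "|")
  agg <- tapply(tab$copies, list(tab$cdr3_aa, key), sum)
  peps <- unique(tab$cdr3_aa)
  ent <- numeric(length(peps)); nrec <- integer(length(peps)); cop <- numeric(length(peps))
  for (i in seq_along(peps)) {
    cc <- agg[peps[i], ]
    cc <- cc[!is.na(cc)]
    w <- if (weighting == "reads") cc else rep(1, length(cc))
    p <- w / sum(w)
    ent[i] <- -sum(p * log2(p))
    nrec[i] <- length(cc); cop[i] <- sum(cc)
  }
  brk <- c(0, 0.5, 1.5, 2.5, Inf)
  lab <- c("[0,0.5)", "[0.5,1.5)", "[1.5,2.5)", "[2.5,Inf)")
  bin <- cut(ent, brk, right = FALSE, labels = lab)
  bins <- data.frame(
    bin = lab,
    fraction_peptides = as.numeric(base::table(bin)[lab]) / length(ent),
    fraction_reads = vapply(lab, function(b) sum(cop[bin == b]) / sum(cop),
                            numeric(1)),
    stringsAsFactors = FALSE)
  structure(list(peptides = data.frame(cdr3_aa = peps, n_recombinations = nrec,
                                       entropy = ent, copies = cop,
                                       stringsAsFactors = FALSE),
                 bins = bins),
            class = "convergence_result")
}

#' Mutation summary over eligible unique sequences
#'
#' Only records with `copies >= min_copies` and an evaluated mutation
#' count enter. For each threshold t the percentage of eligible unique
#' sequences with at least t mutations is reported, plus the mutation
#' rate per 10^4 bp of analysis window.
#'
#' @param table A `clonotype_table`.
#' @param thresholds Integer thresholds (default 1, 2, 4).
#' @param min_copies Copy floor (default 5).
#' @return List with `pct` (named by ">=t"), `rate_per_1e4`, `n_eligible`;
#'   all NA when no record is eligible.
#' @export
mutation_summary <- function(table, thresholds = c(1, 2, 4), min_copies = 5) {
  el <- table[!is.na(table$mutation_count) & table$copies >= min_copies, ,
              drop = FALSE]
  if (nrow(el) == 0L)
    return(list(pct = setNames(rep(NA_real_, length(thresholds)),
                               paste0(">=", thresholds)),
                rate_per_1e4 = NA_real_, n_eligible = 0L))
  pct <- vapply(thresholds, function(t) 100 * mean(el$mutation_count >= t),
                numeric(1))
  list(pct = setNames(pct, paste0(">=", thresholds)),
       rate_per_1e4 = 1e4 * sum(el$mutation_count) / sum(el$mutation_window_len),
       n_eligible = nrow(el))
}

#' Isotype usage stratified by mutation load
#'
#' Unique sequences with evaluated mutation counts are divided into
#' strata 0, 1, 2, 3, 4, >=5 mutations; per-stratum isotype fractions sum
#' to 100. Class-switched means isotype is neither IgM nor IgD. Also
#' reports isotype fractions within mutated (>= 1) versus non-mutated
#' sequences.
#'
#' @param table A `clonotype_table`.
#' @param min_copies Copy floor for mutation evaluation (default 5).
#' @return List with `by_stratum` (data.frame: stratum, isotype, pct),
#'   `switched_pct` (per-stratum class-switched percentage) and
#'   `mutated_vs_not` (isotype pct within mutated / non-mutated).
#' @export
isotype_by_mutation <- function(table, min_copies = 5) {
  el <- table[!is.na(table$mutation_count) & table$copies >= min_copies &
                !is.na(table$isotype), , drop = FALSE]
  if (nrow(el) == 0L) stop("no eligible records")
  strat <- ifelse(el$mutation_count >= 5, ">=5", as.character(el$mutation_count))
  lv <- c("0", "1", "2", "3", "4", ">=5")
  strat <- factor(strat, levels = lv)
  rows <- list(); sw <- list()
  for (s in levels(strat)) {
    sub <- el[strat == s, , drop = FALSE]
    if (nrow(sub) == 0L) next
    tt <- base::table(sub$isotype)
    rows[[s]] <- data.frame(stratum = s, isotype = names(tt),
                            pct = 100 * as.numeric(tt) / nrow(sub),
                            stringsAsFactors = FALSE)
    sw[[s]] <- data.frame(stratum = s,
                          pct_switched = 100 * mean(!sub$isotype %in% c("IgM", "IgD")),
                          n = nrow(sub), stringsAsFactors = FALSE)
  }
  grp <- ifelse(el$mutation_count >= 1, "mutated", "non_mutated")
  mv <- lapply(unique(grp), function(g) {
    sub <- el[grp == g, , drop = FALSE]
    tt <- base::table(sub$isotype)
    data.frame(group = g, isotype = names(tt),
               pct = 100 * as.numeric(tt) / nrow(sub),
               pct_switched = 100 * mean(!sub$isotype %in% c("IgM", "IgD")),
               stringsAsFactors = FALSE)
  })
  list(by_stratum = do.call(rbind, rows), switched_pct = do.call(rbind, sw),
       mutated_vs_not = do.call(rbind, mv))
}

#' Tidy long-format export of a sample's metrics
#'
#' @param table A `clonotype_table`.
#' @param ref Optional reference for VH ordering.
#' @return data.frame (sample_id, metric, stratum, value).
#' @export
metrics_tidy <- function(table, ref = NULL) {
  sid <- attr(table, "sample_id") %||% "S"
  rows <- list(data.frame(sample_id = sid, metric = "d50", stratum = "",
                          value = d50(table), stringsAsFactors = FALSE))
  vu <- vh_usage(table, TRUE, ref)
  rows[[length(rows) + 1L]] <- data.frame(sample_id = sid, metric = "vh_usage",
                                          stratum = vu$v_call, value = vu$pct)
  np <- n_insertion_profile(table)
  rows[[length(rows) + 1L]] <- data.frame(sample_id = sid, metric = "n_insertion",
                                          stratum = np$bin, value = np$pct)
  ce <- try(convergence_entropy(table), silent = TRUE)
  if (!inherits(ce, "try-error"))
    rows[[length(rows) + 1L]] <- data.frame(sample_id = sid, metric = "entropy_bin",
                                            stratum = ce$bins$bin,
                                            value = ce$bins$fraction_peptides)
  ms <- mutation_summary(table)
  rows[[length(rows) + 1L]] <- data.frame(sample_id = sid, metric = "pct_mutated",
                                          stratum = names(ms$pct),
                                          value = as.numeric(ms$pct))
  rows[[length(rows) + 1L]] <- data.frame(sample_id = sid, metric = "mutation_rate_per_1e4",
                                          stratum = "", value = ms$rate_per_1e4)
  do.call(rbind, rows)
}
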