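# Artifact removal: VH relatedness, related-read collapsing, singleton
# removal, and the Poisson model of barcode cross-contamination. The
# filter order is fixed: collapse_related_reads -> remove_singletons ->
# filter_cross_contamination; total counts are non-increasing at every
# stage.

#' Pairwise VH relatedness graph
#'
#' All unordered pairs of germline V segments are locally aligned; a pair
#' is related iff the aligned region has more than 200 matched bases and
#' fewer than 6 mismatches (both thresholds strict).
#'
#' @param ref A `germline_reference`.
#' @param scoring A [sw_scoring()] list.
#' @param min_match,max_mismatch Relatedness thresholds (matched bases
#'   must exceed `min_match`; mismatches must stay below `max_mismatch`).
#' @return Object of class `relatedness_graph`: list with `nodes` and an
#'   `edges` data.frame (v1, v2, aligned_match_len, n_mismatch).
#' @export
build_vh_relatedness <- function(ref, scoring = sw_scoring(),
                                 min_match = 200, max_mismatch = 6) {
  vs <- segments_of(ref, "V")
  if (nrow(vs) < 2L) stop("need >= 2 V segments")
  e1 <- character(0); e2 <- character(0); ml <- integer(0); mm <- integer(0)
  for (i in seq_len(nrow(vs) - 1L)) {
    for (j in (i + 1L):nrow(vs)) {
      h <- .sw_align_cpp(vs$sequence[i], vs$sequence[j], scoring$match,
                         scoring$mismatch, scoring$gap_open, scoring$gap_ext)
      if (h$n_match > min_match && h$n_mismatch < max_mismatch) {
        e1 <- c(e1, vs$id[i]); e2 <- c(e2, vs$id[j])
        ml <- c(ml, h$n_match); mm <- c(mm, h$n_mismatch)
      }
    }
  }
  structure(list(nodes = vs$id,
                 edges = data.frame(v1 = e1, v2 = e2, aligned_match_len = ml,
                                    n_mismatch = mm, stringsAsFactors = FALSE)),
            class = "relatedness_graph")
}

#' Are two V calls related?
#'
#' Identical calls are trivially related; otherwise the relatedness graph
#' decides.
#'
#' @param graph A `relatedness_graph`.
#' @param a,b V segment ids.
#' @return Logical.
#' @export
are_related <- function(graph, a, b) {
  if (is.na(a) || is.na(b)) return(FALSE)
  if (a == b) return(TRUE)
  e <- graph$edges
  any((e$v1 == a & e$v2 == b) | (e$v1 == b & e$v2 == a))
}

#' Collapse related minor reads into oblivion
#'
#' Two records are related if their V calls are related and their CDR3
#' nucleotide sequences have the same length and at most
#' `cdr3_max_mismatch` mismatches. Records are processed in descending
#' copy order (ties by CDR3 for determinism); a minor record whose count
#' is below `minor_fraction` of a related major is removed — not merged:
#' its copies vanish from the table, matching the removal semantics of
#' the filter this implements.
#'
#' @param table A `clonotype_table`.
#' @param graph A `relatedness_graph`.
#' @param cdr3_max_mismatch Maximum CDR3 mismatches for read relatedness
#'   (default 1; the intent is to absorb sequencing-error variants).
#' @param minor_fraction Removal threshold (default 0.05): minors strictly
#'   below this fraction of the major are removed.
#' @return Filtered `clonotype_table`.
#' @export
collapse_related_reads <- function(table, graph, cdr3_max_mismatch = 1,
                                   minor_fraction = 0.05) {
  if (nrow(table) < 2L) return(table)
  ord <- order(-table$copies, table$cdr3_nt)
  tab <- table[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(tab))
  len <- nchar(tab$cdr3_nt)
  for (i in seq_len(nrow(tab) - 1L)) {
    if (!keep[i]) next
    for (j in (i + 1L):nrow(tab)) {
      if (!keep[j] || len[j] != len[i]) next
      if (tab$copies[j] >= minor_fraction * tab$copies[i]) next
      if (!are_related(graph, tab$v_call[i], tab$v_call[j])) next
      if (hamming(tab$cdr3_nt[i], tab$cdr3_nt[j]) <= cdr3_max_mismatch)
        keep[j] <- FALSE
    }
  }
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  as_clonotype_table(out, attr(table, "sample_id"), attr(table, "log"))
}

#' Remove single-copy CDR3s
#'
#' Every CDR3 nucleotide sequence whose total copy count across the table
#' is 1 is removed from further consideration.
#'
#' @param table A `clonotype_table`.
#' @return Filtered `clonotype_table`.
#' @export
remove_singletons <- function(table) {
  if (nrow(table) == 0L) return(table)
  tot <- tapply(table$copies, table$cdr3_nt, sum)
  keep <- tot[table$cdr3_nt] > 1L
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  as_clonotype_table(out, attr(table, "sample_id"), attr(table, "log"))
}

#' Poisson upper-tail probability of a cross-contamination count
#'
#' Probability that a CDR3 occurs `n` or more times in a recipient sample
#' if all its copies were barcode cross-contamination from a source with
#' `N` reads at rate `mu`: the Poisson survival function at `lambda = N *
#' mu`, `P(X >= n) = 1 - sum_{k=0}^{n-1} e^{-lambda} lambda^k / k!`. The
#' `printed_formula` variant starts the sum at k = 1 (which makes
#' P(X >= 1) identically 1) and is kept only for comparison.
#'
#' @param n Observed recipient count (>= 1).
#' @param N Source sample count (>= 0).
#' @param mu Cross-contamination rate in (0, 1); the preset 1/8000 is the
#'   chance that a 6-nt barcode with three differing positions is
#'   converted into another at ~5% per-position synthesis error
#'   (0.05^3 = 1/8000).
#' @param printed_formula Use the k>=1 sum variant (default FALSE).
#' @return Probability in [0, 1].
#' @export
contamination_p <- function(n, N, mu = 1 / 8000, printed_formula = FALSE) {
  if (any(n < 1) || any(N < 0) || mu <= 0 || mu >= 1)
    stop("require n >= 1, N >= 0, 0 < mu < 1")
  lam <- N * mu
  p <- if (printed_formula) {
    vapply(seq_along(lam), function(i) {
      ks <- seq_len(n[i] - 1L)
      1 - sum(dpois(ks, lam[i]))
    }, numeric(1))
  } else ppois(n - 1, lam, lower.tail = FALSE)
  pmin(pmax(p, 0), 1)
}

#' Filter shared CDR3s that look like cross-contamination
#'
#' For each CDR3 nucleotide sequence present in two or more samples of a
#' run, each recipient's count `n` is tested against the largest
#' co-occurring count `N` in any other sample (the most conservative
#' single-source model). The CDR3 is retained in a sample iff
#' P(X >= n | lambda = N mu) < alpha, i.e. the count is too high to be
#' contamination; otherwise its records are removed from that sample.
#'
#' @param samples Named list of `clonotype_table`s from one run.
#' @param mu Cross-contamination rate (default 1/8000).
#' @param alpha Significance level (default 0.001).
#' @return List with `samples` (filtered tables) and `report` (one row
#'   per test: cdr3_nt, sample, n, N, lambda, P, verdict).
#' @export
filter_cross_contamination <- function(samples, mu = 1 / 8000, alpha = 0.001) {
  counts <- lapply(samples, function(t) tapply(t$copies, t$cdr3_nt, sum))
  all_cdr3 <- unlist(lapply(counts, names), use.names = FALSE)
  shared <- unique(all_cdr3[duplicated(all_cdr3)])
  report <- list()
  removed <- lapply(samples, function(t) character(0))
  for (cdr3 in shared) {
    occ <- vapply(counts, function(cc) if (cdr3 %in% names(cc)) cc[[cdr3]] else 0L,
                  numeric(1))
    present <- which(occ > 0)
    for (s in present) {
      N <- max(occ[-s])
      if (N == 0) next
      n <- occ[s]
      P <- contamination_p(n, N, mu)
      verdict <- if (P < alpha) "RETAIN" else "REMOVE"
      report[[length(report) + 1L]] <- data.frame(
        cdr3_nt = cdr3, sample_id = names(samples)[s], n = n, N = N,
        lambda = N * mu, P = P, verdict = verdict, stringsAsFactors = FALSE)
      if (verdict == "REMOVE")
        removed[[s]] <- c(removed[[s]], cdr3)
    }
  }
  out <- samples
  for (s in seq_along(samples)) {
    if (length(removed[[s]])) {
      t <- samples[[s]]
      keep <- !(t$cdr3_nt %in% removed[[s]])
      t2 <- t[keep, , drop = FALSE]
      rownames(t2) <- NULL
      out[[s]] <- as_clonotype_table(t2, attr(t, "sample_id"), attr(t, "log"))
    }
  }
  list(samples = out,
       report = if (length(report)) do.call(rbind, report)
       else data.frame(cdr3_nt = character(0), sample_id = character(0),
                       n = numeric(0), N = numeric(0), lambda = numeric(0),
                       P = numeric(0), verdict = character(0)))
}

#' Run the full artifact-removal stack in its fixed order
#'
#' @param samples Named list of `clonotype_table`s.
#' @param graph A `relatedness_graph`.
#' @param cdr3_max_mismatch,minor_fraction See [collapse_related_reads()].
#' @param mu,alpha See [filter_cross_contamination()].
#' @return List with filtered `samples`, the contamination `report`, and a
#'   per-stage count `log`.
#' @export
apply_artifact_filters <- function(samples, graph, cdr3_max_mismatch = 1,
                                   minor_fraction = 0.05, mu = 1 / 8000,
                                   alpha = 0.001) {
  stage_counts <- function(ss) vapply(ss, cnt, numeric(1))
  log <- list(input = stage_counts(samples))
  samples <- lapply(samples, collapse_related_reads, graph = graph,
                    cdr3_max_mismatch = cdr3_max_mismatch,
                    minor_fraction = minor_fraction)
  log$after_collapse <- stage_counts(samples)
  samples <- lapply(samples, remove_singletons)
  log$after_singletons <- stage_counts(samples)
  fc <- filter_cross_contamination(samples, mu, alpha)
  log$after_contamination <- stage_counts(fc$samples)
  list(samples = fc$samples, report = fc$report,
       log = do.call(rbind, log))
}
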