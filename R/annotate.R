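# V(D)J annotation: local alignment against the germline catalog, CDR3
# boundary migration from reference marks onto reads, canonical junction
# decomposition, and somatic-mutation calling.

#' Scoring scheme for nucleotide local alignment
#'
#' @param match,mismatch,gap_open,gap_ext Integer scores; a gap of length L
#'   costs `gap_open + (L-1) * gap_ext`.
#' @return List of scores.
#' @export
sw_scoring <- function(match = 2, mismatch = -2, gap_open = -5, gap_ext = -1) {
  list(match = as.integer(match), mismatch = as.integer(mismatch),
       gap_open = as.integer(gap_open), gap_ext = as.integer(gap_ext))
}

#' Smith-Waterman local alignment
#'
#' Affine-gap local alignment returning the maximal-scoring alignment with
#' deterministic tie-breaking (earliest query start, then reference start,
#' then query end, then reference end). Coordinates are 1-based inclusive;
#' the edit string is one character per aligned column (M match, X
#' mismatch, I query-only base, D reference-only base).
#'
#' @param query,ref Nucleotide strings.
#' @param scoring A [sw_scoring()] list.
#' @param segment_id Optional label carried into the hit.
#' @return List of class `alignment_hit`.
#' @export
smith_waterman <- function(query, ref, scoring = sw_scoring(), segment_id = NA_character_) {
  if (nchar(query) == 0L || nchar(ref) == 0L) stop("empty sequence")
  hit <- .sw_align_cpp(query, ref, scoring$match, scoring$mismatch,
                       scoring$gap_open, scoring$gap_ext)
  hit$segment_id <- segment_id
  class(hit) <- "alignment_hit"
  hit
}

# Map a reference position to the query through an alignment, linearly
# extrapolating outside the aligned block. NA when the hit is empty.
project_ref_pos <- function(hit, ref_pos) {
  if (is.na(hit$query_start)) return(NA_integer_)
  if (ref_pos < hit$ref_start)
    return(hit$query_start - (hit$ref_start - ref_pos))
  if (ref_pos > hit$ref_end)
    return(hit$query_end + (ref_pos - hit$ref_end))
  q <- hit$query_start - 1L; r <- hit$ref_start - 1L
  for (op in strsplit(hit$edit, "")[[1]]) {
    if (op == "M" || op == "X") { q <- q + 1L; r <- r + 1L }
    else if (op == "I") q <- q + 1L
    else r <- r + 1L
    if (r == ref_pos) return(q)
  }
  NA_integer_
}

best_hit <- function(query, segs, scoring, offset = 0L) {
  best <- NULL
  for (i in seq_len(nrow(segs))) {
    h <- .sw_align_cpp(query, segs$sequence[i], scoring$match, scoring$mismatch,
                       scoring$gap_open, scoring$gap_ext)
    if (is.null(best) || h$score > best$score) { best <- h; best$segment_id <- segs$id[i] }
  }
  if (!is.null(best) && !is.na(best$query_start)) {
    best$query_start <- best$query_start + offset
    best$query_end <- best$query_end + offset
  }
  class(best) <- "alignment_hit"
  best
}

#' Assign germline V/J/C (and later D) segments to a merged read
#'
#' The V call is the best-scoring local hit over all V segments; the J call
#' is the best hit in the read downstream of the V alignment; the constant
#' region/isotype is the best C hit downstream of J. Reads whose V or J
#' score falls below the floor are unmappable and return `NULL`.
#'
#' @param seq Merged read sequence.
#' @param ref A `germline_reference`.
#' @param scoring A [sw_scoring()] list.
#' @param min_v_score,min_j_score,min_c_score Reporting floors.
#' @return List with `v_call`, `j_call`, `c_call` and their
#'   `alignment_hit`s, or `NULL` for an unmappable read.
#' @export
assign_segments <- function(seq, ref, scoring = sw_scoring(),
                            min_v_score = 60, min_j_score = 30, min_c_score = 30) {
  vh <- best_hit(seq, segments_of(ref, "V"), scoring)
  if (is.na(vh$query_start) || vh$score < min_v_score)
    return(NULL)  # UNMAPPED
  down <- substr(seq, vh$query_end + 1L, nchar(seq))
  if (nchar(down) == 0L) return(NULL)  # UNMAPPED
  jh <- best_hit(down, segments_of(ref, "J"), scoring, offset = vh$query_end)
  if (is.na(jh$query_start) || jh$score < min_j_score)
    return(NULL)  # UNMAPPED
  cdown <- substr(seq, jh$query_end + 1L, nchar(seq))
  ch <- NULL
  if (nchar(cdown) > 0L) {
    ch <- best_hit(cdown, segments_of(ref, "C"), scoring, offset = jh$query_end)
    if (is.na(ch$query_start) || ch$score < min_c_score) ch <- NULL
  }
  list(v_call = vh$segment_id, v_hit = vh,
       j_call = jh$segment_id, j_hit = jh,
       c_call = if (is.null(ch)) NA_character_ else ch$segment_id,
       c_hit = ch)
}

#' Migrate CDR3 (and CDR2) boundaries from the reference onto a read
#'
#' The CDR3 start is the read position aligned to (or projected from) the
#' V segment's CDR3 mark; the end comes from the J segment's CDR3-end
#' mark. Translation uses the standard code in the V reading frame;
#' out-of-frame or stop-containing CDR3s are flagged non-productive.
#'
#' @param seq Read sequence.
#' @param calls Result of [assign_segments()].
#' @param ref A `germline_reference`.
#' @return List with `cdr2_start`, `cdr3_start`, `cdr3_end`, `cdr3_nt`,
#'   `cdr3_aa`, `productive`, or `NULL` when a boundary projects outside
#'   the read (failed migration; counted separately in annotation logs).
#' @export
migrate_cdr3 <- function(seq, calls, ref) {
  v <- segment_row(ref, calls$v_call)
  j <- segment_row(ref, calls$j_call)
  s <- project_ref_pos(calls$v_hit, v$cdr3_start)
  e <- project_ref_pos(calls$j_hit, j$cdr3_end)
  c2 <- project_ref_pos(calls$v_hit, v$cdr2_start)
  L <- nchar(seq)
  if (is.na(s) || is.na(e) || s < 1L || e > L || s > e || is.na(c2) || c2 < 1L)
    return(NULL)  # FAILED_MIGRATION
  cdr3_nt <- substr(seq, s, e)
  aa <- translate_nt(cdr3_nt)
  productive <- !is.na(aa) && !grepl("*", aa, fixed = TRUE)
  list(cdr2_start = c2, cdr3_start = s, cdr3_end = e, cdr3_nt = cdr3_nt,
       cdr3_aa = if (productive) aa else "", productive = productive)
}

#' Canonical junction decomposition of a rearranged sequence
#'
#' Given the V and J calls and CDR3 boundaries, derives the
#' template-maximal decomposition: V and J templates are extended by exact
#' germline matching from the CDR3 anchors, the D segment is placed at the
#' longest exact substring shared with any germline D (requiring at least
#' `d_min_match` nt, else no D is called), palindromic P additions of up to
#' 2 nt are recognized at untrimmed segment ends, and remaining junction
#' bases are counted as nontemplated N (n2 at the V-DJ join, n1 at the D-J
#' join; with no D call the whole stretch is reported as n1). Ambiguous
#' bases that could be template or N are assigned to template, which
#' biases N counts low by construction; the same convention defines the
#' simulator's ground truth, where the decomposition is equally
#' unidentifiable from sequence alone.
#'
#' @param seq Full rearranged sequence (read or simulated amplicon).
#' @param v_id,j_id Germline V and J calls.
#' @param cdr3_start,cdr3_end 1-based CDR3 boundaries on `seq`.
#' @param ref A `germline_reference`.
#' @param d_min_match Minimum exact D match run to call a D (default 5).
#' @return List with `v_del`, `d5_del`, `d3_del`, `j_del`, `d_call`, `p2`,
#'   `n2`, `n1`, `p1`, `n_total`.
#' @export
decompose_junction <- function(seq, v_id, j_id, cdr3_start, cdr3_end, ref,
                               d_min_match = 5) {
  v <- segment_row(ref, v_id); j <- segment_row(ref, j_id)
  v_seq <- v$sequence; j_seq <- j$sequence
  v_len <- nchar(v_seq); v_mark <- v$cdr3_start
  j_mark <- j$cdr3_end
  L <- nchar(seq)

  t <- 0L
  while (cdr3_start + t <= L && v_mark + t <= v_len &&
         substr(seq, cdr3_start + t, cdr3_start + t) ==
         substr(v_seq, v_mark + t, v_mark + t)) t <- t + 1L
  v_end_read <- cdr3_start + t - 1L
  v_del <- v_len - (v_mark + t - 1L)

  s <- 0L
  while (cdr3_end - s >= 1L && j_mark - s >= 1L &&
         substr(seq, cdr3_end - s, cdr3_end - s) ==
         substr(j_seq, j_mark - s, j_mark - s)) s <- s + 1L
  j_start_read <- cdr3_end - s + 1L
  if (j_start_read <= v_end_read) {        # overlapping claims: V wins
    j_start_read <- v_end_read + 1L
    s <- cdr3_end - j_start_read + 1L
  }
  j_del <- j_mark - s

  region <- if (v_end_read + 1L <= j_start_read - 1L)
    substr(seq, v_end_read + 1L, j_start_read - 1L) else ""

  d_call <- NA_character_; d5_del <- NA_integer_; d3_del <- NA_integer_
  region2 <- region; region1 <- ""
  if (nchar(region) > 0L) {
    ds <- segments_of(ref, "D")
    best <- NULL
    for (i in seq_len(nrow(ds))) {
      lcs <- .lcs_substring_cpp(region, ds$sequence[i])
      if (is.null(best) || lcs$length > best$length) { best <- lcs; best$id <- ds$id[i] }
    }
    if (!is.null(best) && best$length >= d_min_match) {
      d_call <- best$id
      d_len <- nchar(ds$sequence[match(best$id, ds$id)])
      d5_del <- best$b_start - 1L
      d3_del <- d_len - (best$b_start + best$length - 1L)
      region2 <- substr(region, 1L, best$a_start - 1L)
      region1 <- substr(region, best$a_start + best$length, nchar(region))
    } else {
      region2 <- ""; region1 <- region
    }
  }

  p2 <- ""
  if (v_del == 0L && nchar(region2) > 0L) {
    cand <- revcomp(substr(v_seq, v_len - 1L, v_len))
    if (nchar(region2) >= 2L && substr(region2, 1L, 2L) == cand) p2 <- cand
    else if (substr(region2, 1L, 1L) == substr(cand, 1L, 1L))
      p2 <- substr(cand, 1L, 1L)
    region2 <- substr(region2, nchar(p2) + 1L, nchar(region2))
  }
  p1 <- ""
  if (j_del == 0L && nchar(region1) > 0L) {
    cand <- revcomp(substr(j_seq, 1L, 2L))
    nr <- nchar(region1)
    if (nr >= 2L && substr(region1, nr - 1L, nr) == cand) p1 <- cand
    else if (substr(region1, nr, nr) == substr(cand, 2L, 2L))
      p1 <- substr(cand, 2L, 2L)
    region1 <- substr(region1, 1L, nr - nchar(p1))
  }
  if (is.na(d_call)) { n1 <- region1; n2 <- region2 }  # region2 is "" here
  else { n2 <- region2; n1 <- region1 }
  list(v_del = v_del, d5_del = d5_del, d3_del = d3_del, j_del = j_del,
       d_call = d_call, p2 = p2, n2 = n2, n1 = n1, p1 = p1,
       n_total = nchar(n1) + nchar(n2))
}

#' Call somatic mutations in the CDR2-to-CDR3 window
#'
#' Mismatches between the read and the best-aligned germline V inside
#' `[cdr2_start, cdr3_start)` are reported, each annotated with the
#' germline hotspot context (DGYW/WRCH/none). Reads observed in 4 or fewer
#' copies are excluded from mutation statistics (`evaluated = FALSE`), so
#' isolated sequencing errors do not masquerade as hypermutation.
#'
#' @param seq Read sequence.
#' @param calls Result of [assign_segments()].
#' @param boundaries Result of [migrate_cdr3()].
#' @param ref A `germline_reference`.
#' @param copies Copy count of the (deduplicated) sequence.
#' @param min_copies Minimum copies for evaluation (default 5).
#' @return List with `evaluated`, `mutations` (data.frame: seq_pos,
#'   ref_base, read_base, hotspot_class), `count`, `window_len`.
#' @export
call_mutations <- function(seq, calls, boundaries, ref, copies, min_copies = 5) {
  window_len <- boundaries$cdr3_start - boundaries$cdr2_start
  if (window_len <= 0L)
    return(list(evaluated = FALSE, mutations = NULL, count = NA_integer_,
                window_len = 0L))
  if (is.na(copies) || copies < min_copies)
    return(list(evaluated = FALSE, mutations = NULL, count = NA_integer_,
                window_len = window_len))
  v_seq <- segment_row(ref, calls$v_call)$sequence
  hit <- calls$v_hit
  q <- hit$query_start - 1L; r <- hit$ref_start - 1L
  pos <- integer(0); rpos <- integer(0); rb <- character(0); qb <- character(0)
  for (op in strsplit(hit$edit, "")[[1]]) {
    if (op == "M" || op == "X") {
      q <- q + 1L; r <- r + 1L
      if (op == "X" && q >= boundaries$cdr2_start && q < boundaries$cdr3_start) {
        pos <- c(pos, q); rpos <- c(rpos, r)
        rb <- c(rb, substr(v_seq, r, r))
        qb <- c(qb, substr(seq, q, q))
      }
    } else if (op == "I") q <- q + 1L
    else r <- r + 1L
  }
  muts <- if (length(pos))
    data.frame(seq_pos = pos, ref_base = rb, read_base = qb,
               hotspot_class = hotspot_class(v_seq, rpos),
               stringsAsFactors = FALSE)
  else data.frame(seq_pos = integer(0), ref_base = character(0),
                  read_base = character(0), hotspot_class = character(0),
                  stringsAsFactors = FALSE)
  list(evaluated = TRUE, mutations = muts, count = length(pos),
       window_len = window_len)
}

#' Annotate a set of sequences into a clonotype table
#'
#' Deduplicates identical sequences (copies = read count), then per unique
#' sequence assigns segments, migrates CDR3 boundaries, decomposes the
#' junction and calls mutations. Unmappable sequences and failed boundary
#' migrations are dropped and counted in the attached log.
#'
#' @param seqs Character vector of merged-read sequences (one per read) or
#'   unique sequences when `copies` is supplied.
#' @param ref A `germline_reference`.
#' @param sample_id Sample label carried into the table.
#' @param copies Optional integer vector of per-sequence copy counts; when
#'   missing, identical elements of `seqs` are tallied.
#' @param scoring A [sw_scoring()] list.
#' @param min_copies Copy threshold for mutation evaluation.
#' @param d_min_match Minimum D match run.
#' @param ... Floors passed to [assign_segments()].
#' @return A `clonotype_table` (data.frame, one row per unique sequence)
#'   with attributes `sample_id` and `log`.
#' @export
annotate_sequences <- function(seqs, ref, sample_id = "S1", copies = NULL,
                               scoring = sw_scoring(), min_copies = 5,
                               d_min_match = 5, ...) {
  if (is.null(copies)) {
    tab <- table(seqs)
    uniq <- names(tab)
    copies <- as.integer(tab)
  } else {
    uniq <- seqs
    copies <- as.integer(copies)
  }
  n_unmapped <- 0L; n_failed <- 0L
  rows <- vector("list", length(uniq))
  for (i in seq_along(uniq)) {
    s <- uniq[i]
    calls <- assign_segments(s, ref, scoring, ...)
    if (is.null(calls)) { n_unmapped <- n_unmapped + 1L; next }
    bounds <- migrate_cdr3(s, calls, ref)
    if (is.null(bounds)) { n_failed <- n_failed + 1L; next }
    junc <- decompose_junction(s, calls$v_call, calls$j_call,
                               bounds$cdr3_start, bounds$cdr3_end, ref,
                               d_min_match = d_min_match)
    mut <- call_mutations(s, calls, bounds, ref, copies[i], min_copies)
    rows[[i]] <- data.frame(
      sequence = s, copies = copies[i], sample_id = sample_id,
      v_call = calls$v_call, d_call = junc$d_call, j_call = calls$j_call,
      isotype = calls$c_call,
      cdr2_start = bounds$cdr2_start, cdr3_start = bounds$cdr3_start,
      cdr3_end = bounds$cdr3_end, cdr3_nt = bounds$cdr3_nt,
      cdr3_aa = bounds$cdr3_aa, productive = bounds$productive,
      v_del = junc$v_del, d5_del = junc$d5_del, d3_del = junc$d3_del,
      j_del = junc$j_del, p2 = junc$p2, n2_len = nchar(junc$n2),
      n1_len = nchar(junc$n1), p1 = junc$p1, n_total = junc$n_total,
      mutation_count = if (mut$evaluated) mut$count else NA_integer_,
      mutation_window_len = mut$window_len,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- empty_clonotype_table()
  rownames(out) <- NULL
  as_clonotype_table(out, sample_id,
                     log = data.frame(unique_in = length(uniq),
                                      unmapped = n_unmapped,
                                      failed_migration = n_failed,
                                      annotated = nrow(out)))
}
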