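# Demultiplexing, quality trimming and perfect-overlap merging of
# paired-end amplicon reads.

#' Demultiplex read pairs by exact barcode match
#'
#' A pair is assigned iff the constant-region (reverse) mate begins with an
#' exact barcode; the barcode is stripped before downstream processing.
#' There is no 1-mismatch rescue: misassignment is modelled downstream as
#' full barcode conversion by the Poisson cross-contamination filter, and
#' error-correcting demultiplexing would change its rate.
#'
#' @param fwd,rev Read sets ([read_fastq()] lists) with matching order.
#' @param barcodes A `barcode_set`; element i is sample i's code. Named
#'   elements (or `sample_ids`) label the output.
#' @param sample_ids Optional sample names, one per barcode in use.
#' @return List with `samples` (per-sample list of `fwd`/`rev` read sets,
#'   barcode removed) and `unassigned` count.
#' @export
demultiplex <- function(fwd, rev, barcodes, sample_ids = NULL) {
  codes <- barcodes$barcodes
  if (length(codes) == 0L) stop("empty barcode set")
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_along(codes))
  if (length(sample_ids) > length(codes))
    stop("more sample ids than barcodes")
  codes <- codes[seq_along(sample_ids)]   # barcodes in use, one per sample
  prefix <- substr(rev$seq, 1L, barcodes$length)
  assign <- match(prefix, codes)
  out <- list()
  for (k in seq_along(codes)) {
    idx <- which(assign == k)
    rv <- subset_reads(rev, idx)
    rv$seq <- substr(rv$seq, barcodes$length + 1L, nchar(rv$seq))
    rv$qual <- lapply(rv$qual, function(q) q[-seq_len(barcodes$length)])
    out[[sample_ids[k]]] <- list(fwd = subset_reads(fwd, idx), rev = rv)
  }
  list(samples = out, unassigned = sum(is.na(assign)))
}

#' Quality-trim a read with a 2-base sliding window
#'
#' Windows `(i, i+1)` are scanned left to right; at the first window whose
#' minimum quality falls below `threshold` the read is truncated before
#' the window, i.e. everything from the window to the 3' end is removed.
#' Reads shorter than the window are returned unchanged.
#'
#' @param seq Nucleotide string.
#' @param qual Integer Phred vector, same length.
#' @param window Window size in nt (default 2).
#' @param threshold Phred floor (default 20).
#' @return List with trimmed `seq` and `qual`.
#' @export
quality_trim <- function(seq, qual, window = 2, threshold = 20) {
  L <- nchar(seq)
  if (L != length(qual)) stop("sequence and quality lengths differ")
  if (L < window) return(list(seq = seq, qual = qual))
  bad <- qual < threshold
  # first window (length `window`) containing any failing base
  fail <- which(bad)
  if (!length(fail)) return(list(seq = seq, qual = qual))
  first_win <- max(1L, min(fail) - window + 1L)
  keep <- first_win - 1L
  list(seq = substr(seq, 1L, keep), qual = qual[seq_len(keep)])
}

#' Merge a trimmed read pair by perfect end-overlap
#'
#' The reverse mate is reverse-complemented, every relative shift is
#' scored as matches minus mismatches (gap-free), and the maximal-scoring
#' overlap is accepted only if it is mismatch-free and at least
#' `min_overlap` nt; otherwise the pair is rejected with a reason code
#' (`NO_OVERLAP`, `MISMATCH`, `TOO_SHORT`).
#'
#' @param fwd_seq Forward read (5' of amplicon).
#' @param rev_seq Reverse read in sequencing orientation (barcode already
#'   stripped).
#' @param min_overlap Minimum acceptable overlap, nt (default 15).
#' @return List with `status` ("MERGED" or "REJECTED"), `seq`,
#'   `overlap_len`, `reason`.
#' @export
merge_pair <- function(fwd_seq, rev_seq, min_overlap = 15) {
  if (nchar(fwd_seq) == 0L || nchar(rev_seq) == 0L)
    return(list(status = "REJECTED", seq = NA_character_,
                overlap_len = 0L, reason = "TOO_SHORT"))
  rc <- revcomp(rev_seq)
  sc <- .overlap_scan_cpp(fwd_seq, rc)
  if (sc$score <= 0L)
    return(list(status = "REJECTED", seq = NA_character_,
                overlap_len = 0L, reason = "NO_OVERLAP"))
  if (sc$n_mismatch > 0L)
    return(list(status = "REJECTED", seq = NA_character_,
                overlap_len = sc$overlap, reason = "MISMATCH"))
  if (sc$overlap < min_overlap)
    return(list(status = "REJECTED", seq = NA_character_,
                overlap_len = sc$overlap, reason = "TOO_SHORT"))
  s <- sc$shift
  nf <- nchar(fwd_seq); nr <- nchar(rc)
  merged <- if (s >= 0L) {
    if (s + nr >= nf) paste0(substr(fwd_seq, 1L, s), rc)   # rc reaches past fwd
    else fwd_seq                                           # rc inside fwd
  } else {
    if (nr + s <= nf) paste0(substr(rc, 1L, -s), fwd_seq)  # fwd reaches past rc
    else rc                                                # fwd inside rc
  }
  list(status = "MERGED", seq = merged, overlap_len = sc$overlap,
       reason = NA_character_)
}

#' Demultiplex, trim and merge a whole paired-end run
#'
#' @param fwd,rev Read sets from [read_fastq()].
#' @param barcodes A `barcode_set`.
#' @param sample_ids Optional sample names.
#' @param window,threshold Trimming parameters.
#' @param min_length Reads shorter than this after trimming are dropped
#'   (default 100 nt).
#' @param min_overlap Merging overlap floor.
#' @return List with per-sample `merged` (data.frame id/seq/overlap_len)
#'   and a `log` data.frame of per-sample assigned / length-filtered /
#'   rejection counts plus the unassigned count.
#' @export
preprocess_run <- function(fwd, rev, barcodes, sample_ids = NULL,
                           window = 2, threshold = 20, min_length = 100,
                           min_overlap = 15) {
  dm <- demultiplex(fwd, rev, barcodes, sample_ids)
  out <- list(); logs <- list()
  for (sname in names(dm$samples)) {
    s <- dm$samples[[sname]]
    n_in <- length(s$fwd$id)
    ids <- character(0); seqs <- character(0); ovl <- integer(0)
    n_short <- 0L
    rej <- c(NO_OVERLAP = 0L, MISMATCH = 0L, TOO_SHORT = 0L)
    for (i in seq_len(n_in)) {
      f <- quality_trim(s$fwd$seq[i], s$fwd$qual[[i]], window, threshold)
      r <- quality_trim(s$rev$seq[i], s$rev$qual[[i]], window, threshold)
      if (nchar(f$seq) < min_length || nchar(r$seq) < min_length) {
        n_short <- n_short + 1L
        next
      }
      m <- merge_pair(f$seq, r$seq, min_overlap)
      if (m$status == "MERGED") {
        ids <- c(ids, s$fwd$id[i]); seqs <- c(seqs, m$seq)
        ovl <- c(ovl, m$overlap_len)
      } else rej[m$reason] <- rej[m$reason] + 1L
    }
    out[[sname]] <- data.frame(id = ids, seq = seqs, overlap_len = ovl,
                               stringsAsFactors = FALSE)
    logs[[sname]] <- data.frame(sample_id = sname, assigned = n_in,
                                too_short_after_trim = n_short,
                                rej_no_overlap = rej[["NO_OVERLAP"]],
                                rej_mismatch = rej[["MISMATCH"]],
                                rej_too_short = rej[["TOO_SHORT"]],
                                merged = length(ids),
                                stringsAsFactors = FALSE)
  }
  list(merged = out, log = do.call(rbind, logs), unassigned = dm$unassigned)
}
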