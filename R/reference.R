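# Synthetic germline segment catalog.
#
# Geometry is fixed so that every stage downstream has something to grab:
# V segments are 288 nt with CDR1/CDR2/CDR3 start marks at 76/151/280 (all
# codon boundaries in the V reading frame; the CDR3 mark opens a conserved
# TGT Cys codon), J segments are 45 nt contributing their first 21 nt to the
# CDR3 (the mark is the CDR3's last base on J), D segments are 14-24 nt and
# constant-region stubs 90 nt, one per isotype. V families share a common
# ancestor sequence: member k differs from member 1 at 3*(k-1) positions
# inside 120..270, so every family of >= 2 contains a pair related under the
# artifact-filter rule (>200 matched, <6 mismatches) and families of >= 3
# also contain unrelated within-family pairs.

V_LEN <- 288L
V_CDR1_START <- 76L
V_CDR2_START <- 151L
V_CDR3_START <- 280L
J_LEN <- 45L
J_CDR3_END <- 21L
C_LEN <- 90L

DEFAULT_ISOTYPES <- c("IgM", "IgD", "IgG1", "IgG3", "IgG2b", "IgG2c", "IgE", "IgA")

#' Generate a synthetic germline V/D/J/C segment catalog
#'
#' Stands in for an IMGT-style download: every V carries CDR1/CDR2/CDR3
#' start coordinates, every J the CDR3 end coordinate, and segments carry a
#' chromosomal rank used to order usage plots 5' to 3'. V segments are
#' organised in families whose members diverge by 3 substitutions per step,
#' which guarantees both related and unrelated pairs under the V
#' relatedness rule used by the artifact filter.
#'
#' @param n_v Named integer vector of V counts per family (names become
#'   family labels), or a single total split into families of two.
#' @param n_d,n_j Number of D and J segments.
#' @param isotypes Character vector of constant-region names.
#' @param seed Integer seed; the catalog is deterministic given the seed.
#' @return An object of class `germline_reference`: a list with element
#'   `segments`, a data.frame with one row per segment.
#' @export
generate_reference <- function(n_v = c(V1 = 2, V3 = 2, V5 = 1, V6 = 1, V11 = 2, V12 = 2),
                               n_d = 4, n_j = 4,
                               isotypes = DEFAULT_ISOTYPES, seed = 1) {
  if (is.null(names(n_v))) {
    total <- sum(n_v)
    fams <- rep(2L, total %/% 2L)
    if (total %% 2L) fams <- c(fams, 1L)
    n_v <- setNames(fams, paste0("V", seq_along(fams)))
  }
  if (sum(n_v) < 2L) stop("need at least 2 V segments to exercise relatedness")
  if (n_d < 1L || n_j < 1L || length(isotypes) < 1L) stop("counts must be >= 1")

  with_seed(seed, {
    rows <- list()
    ord <- 0L
    for (fam in names(n_v)) {
      base <- strsplit(random_dna(V_LEN), "")[[1]]
      base[V_CDR3_START:(V_CDR3_START + 2L)] <- c("T", "G", "T")
      for (k in seq_len(n_v[[fam]])) {
        chars <- base
        if (k > 1L) {
          pos <- sample(120:270, 3L * (k - 1L))
          for (p in pos) chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
        }
        ord <- ord + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          id = paste0(fam, "-", k), kind = "V", family = fam,
          sequence = paste(chars, collapse = ""), chromosomal_order = ord,
          cdr1_start = V_CDR1_START, cdr2_start = V_CDR2_START,
          cdr3_start = V_CDR3_START, cdr3_end = NA_integer_,
          stringsAsFactors = FALSE)
      }
    }
    for (k in seq_len(n_d)) {
      rows[[length(rows) + 1L]] <- data.frame(
        id = paste0("D", k), kind = "D", family = paste0("D", k),
        sequence = random_dna(sample(14:24, 1L)), chromosomal_order = k,
        cdr1_start = NA_integer_, cdr2_start = NA_integer_,
        cdr3_start = NA_integer_, cdr3_end = NA_integer_,
        stringsAsFactors = FALSE)
    }
    for (k in seq_len(n_j)) {
      chars <- strsplit(random_dna(J_LEN), "")[[1]]
      chars[(J_CDR3_END - 2L):J_CDR3_END] <- c("T", "G", "G")  # conserved Trp
      rows[[length(rows) + 1L]] <- data.frame(
        id = paste0("J", k), kind = "J", family = paste0("J", k),
        sequence = paste(chars, collapse = ""), chromosomal_order = k,
        cdr1_start = NA_integer_, cdr2_start = NA_integer_,
        cdr3_start = NA_integer_, cdr3_end = J_CDR3_END,
        stringsAsFactors = FALSE)
    }
    for (k in seq_along(isotypes)) {
      rows[[length(rows) + 1L]] <- data.frame(
        id = isotypes[k], kind = "C", family = isotypes[k],
        sequence = random_dna(C_LEN), chromosomal_order = k,
        cdr1_start = NA_integer_, cdr2_start = NA_integer_,
        cdr3_start = NA_integer_, cdr3_end = NA_integer_,
        stringsAsFactors = FALSE)
    }
    ref <- structure(list(segments = do.call(rbind, rows)),
                     class = "germline_reference")
    validate_reference(ref)
    ref
  })
}

#' Validate a germline reference against its structural invariants
#'
#' @param ref A `germline_reference`.
#' @return Invisibly `TRUE`; errors on violation.
#' @export
validate_reference <- function(ref) {
  seg <- ref$segments
  if (any(nchar(seg$sequence) == 0L)) stop("empty segment sequence")
  if (any(duplicated(seg$id))) stop("duplicate segment ids")
  v <- seg[seg$kind == "V", ]
  if (any(nchar(v$sequence) < 200L)) stop("V segments must be >= 200 nt")
  ok <- with(v, cdr1_start < cdr2_start & cdr2_start < cdr3_start &
               cdr3_start <= nchar(sequence))
  if (!all(ok)) stop("V CDR marks must be increasing and in bounds")
  d <- seg[seg$kind == "D", ]
  if (any(nchar(d$sequence) < 10L | nchar(d$sequence) > 25L))
    stop("D segments must be 10-25 nt")
  j <- seg[seg$kind == "J", ]
  if (any(nchar(j$sequence) < 30L | nchar(j$sequence) > 60L))
    stop("J segments must be 30-60 nt")
  if (any(is.na(j$cdr3_end) | j$cdr3_end > nchar(j$sequence)))
    stop("J CDR3 end mark out of bounds")
  invisible(TRUE)
}

#' Extract segments of one kind from a reference
#'
#' @param ref A `germline_reference`.
#' @param kind One of "V", "D", "J", "C".
#' @return data.frame of matching segment rows.
#' @export
segments_of <- function(ref, kind) {
  ref$segments[ref$segments$kind == kind, , drop = FALSE]
}

segment_row <- function(ref, id) {
  i <- match(id, ref$segments$id)
  if (is.na(i)) stop("unknown segment id: ", id)
  ref$segments[i, , drop = FALSE]
}

#' Write a reference as FASTA plus a TSV sidecar of coordinates
#'
#' @param ref A `germline_reference`.
#' @param fasta,sidecar Output paths.
#' @return Invisibly the two paths.
#' @export
write_reference <- function(ref, fasta, sidecar) {
  seqs <- Biostrings::DNAStringSet(ref$segments$sequence)
  names(seqs) <- ref$segments$id
  Biostrings::writeXStringSet(seqs, fasta)
  write.table(ref$segments[, setdiff(names(ref$segments), "sequence")],
              sidecar, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta, sidecar))
}

#' Read a reference written by [write_reference()]
#'
#' @param fasta,sidecar Paths written by [write_reference()].
#' @return A `germline_reference`.
#' @export
read_reference <- function(fasta, sidecar) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  meta <- read.delim(sidecar, stringsAsFactors = FALSE)
  meta$sequence <- as.character(seqs[meta$id])
  ref <- structure(list(segments = meta), class = "germline_reference")
  validate_reference(ref)
  ref
}

#' @export
print.germline_reference <- function(x, ...) {
  tab <- table(x$segments$kind)
  cat("germline_reference:",
      paste(sprintf("%d %s", tab, names(tab)), collapse = ", "), "\n")
  invisible(x)
}
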