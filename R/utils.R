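#' @noRd
DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement a nucleotide string
#'
#' @param x Character vector of sequences over A/C/G/T (N allowed).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 1L) {
    # scalar fast path; Biostrings object construction dominates otherwise
    chars <- strsplit(chartr("ACGTacgt", "TGCAtgca", x), "")[[1]]
    return(paste(rev(chars), collapse = ""))
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Hamming distance between two equal-length strings
#'
#' @param a,b Strings of equal length.
#' @return Integer count of differing positions.
#' @export
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("hamming() requires equal-length strings")
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Translate a nucleotide sequence to amino acids
#'
#' Standard nuclear code; sequences whose length is not a multiple of three
#' return `NA`.
#'
#' @param nt Nucleotide string.
#' @return Amino-acid string, or `NA_character_` if out of frame.
#' @export
translate_nt <- function(nt) {
  if (is.na(nt) || nchar(nt) == 0L || nchar(nt) %% 3L != 0L) return(NA_character_)
  starts <- seq(1L, nchar(nt), by = 3L)
  codons <- substring(nt, starts, starts + 2L)
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. All package-level randomness goes through this
# so that seeds never leak between stages.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")

#' Classify the germline context of a position as an AID hotspot
#'
#' A position is classed `DGYW` if any germline 4-mer window covering it
#' matches D-G-Y-W (IUPAC D = A/G/T, Y = C/T, W = A/T), else `WRCH` if any
#' window matches W-R-C-H (R = A/G, H = A/C/T), else `none`. DGYW takes
#' precedence where both match.
#'
#' @param seq Germline nucleotide string.
#' @param pos 1-based position(s) within `seq`.
#' @return Character vector in `c("DGYW", "WRCH", "none")`.
#' @export
hotspot_class <- function(seq, pos) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  iupac <- list(D = c("A", "G", "T"), Y = c("C", "T"), W = c("A", "T"),
                R = c("A", "G"), H = c("A", "C", "T"), G = "G", C = "C")
  match4 <- function(start, motif) {
    if (start < 1L || start + 3L > n) return(FALSE)
    all(vapply(1:4, function(k) chars[start + k - 1L] %in% iupac[[substr(motif, k, k)]],
               logical(1)))
  }
  vapply(pos, function(p) {
    starts <- (p - 3L):p
    if (any(vapply(starts, match4, logical(1), motif = "DGYW"))) return("DGYW")
    if (any(vapply(starts, match4, logical(1), motif = "WRCH"))) return("WRCH")
    "none"
  }, character(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
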