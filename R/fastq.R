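# Thin FASTQ adapters around Biostrings. Reads are carried through the
# pipeline as a plain list: ids (chr), seq (chr), qual (list of integer
# Phred vectors), which keeps per-read trimming cheap.

#' Read a FASTQ file into the pipeline's read-set representation
#'
#' @param path FASTQ path (optionally gzipped).
#' @return List with `id`, `seq`, `qual` (integer Phred vectors).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  qual_chr <- as.character(S4Vectors::mcols(x)$qualities)
  list(id = sub(" .*$", "", names(x)),
       seq = as.character(x),
       qual = lapply(qual_chr, function(q) utf8ToInt(q) - 33L))
}

#' Write a read set to FASTQ
#'
#' @param reads List with `id`, `seq`, `qual` as produced by [read_fastq()].
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_fastq <- function(reads, path) {
  seqs <- Biostrings::DNAStringSet(reads$seq)
  names(seqs) <- reads$id
  quals <- Biostrings::BStringSet(vapply(reads$qual,
                                         function(q) intToUtf8(q + 33L),
                                         character(1)))
  Biostrings::writeXStringSet(seqs, path, format = "fastq", qualities = quals)
  invisible(path)
}

subset_reads <- function(reads, idx) {
  list(id = reads$id[idx], seq = reads$seq[idx], qual = reads$qual[idx])
}
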