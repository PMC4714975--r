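# Per-sample clonotype table: one row per unique nucleotide sequence with
# its copy count and annotations. The three bookkeeping roles used for
# repertoire accounting are: CNT (total clean reads, sum of copies), CNU
# (unique clean nucleotide sequences, number of rows / distinct CDR3 nt),
# CPU (unique clean peptides).

empty_clonotype_table <- function() {
  data.frame(sequence = character(0), copies = integer(0),
             sample_id = character(0), v_call = character(0),
             d_call = character(0), j_call = character(0),
             isotype = character(0), cdr2_start = integer(0),
             cdr3_start = integer(0), cdr3_end = integer(0),
             cdr3_nt = character(0), cdr3_aa = character(0),
             productive = logical(0), v_del = integer(0),
             d5_del = integer(0), d3_del = integer(0), j_del = integer(0),
             p2 = character(0), n2_len = integer(0), n1_len = integer(0),
             p1 = character(0), n_total = integer(0),
             mutation_count = integer(0), mutation_window_len = integer(0),
             stringsAsFactors = FALSE)
}

as_clonotype_table <- function(df, sample_id, log = NULL) {
  structure(df, class = c("clonotype_table", "data.frame"),
            sample_id = sample_id, log = log)
}

#' Total clean reads (CNT) of a clonotype table
#' @param table A `clonotype_table`.
#' @return Integer sum of copies.
#' @export
cnt <- function(table) sum(table$copies)

#' Unique clean nucleotide sequences (CNU)
#' @param table A `clonotype_table`.
#' @return Number of distinct CDR3 nucleotide sequences.
#' @export
cnu <- function(table) length(unique(table$cdr3_nt))

#' Unique clean peptide sequences (CPU)
#' @param table A `clonotype_table`.
#' @return Number of distinct non-empty CDR3 peptides.
#' @export
cpu <- function(table) length(unique(table$cdr3_aa[nzchar(table$cdr3_aa)]))

#' @export
print.clonotype_table <- function(x, ...) {
  cat(sprintf("clonotype_table [%s]: %d unique sequences, %d reads, %d CDR3nt, %d CDR3aa\n",
              attr(x, "sample_id") %||% "?", nrow(x), cnt(x), cnu(x), cpu(x)))
  invisible(x)
}

#' Read a clonotype table written by [write_clonotype_table()]
#' @param path TSV path.
#' @param sample_id Sample label; defaults to the table's own column.
#' @return A `clonotype_table`.
#' @export
read_clonotype_table <- function(path, sample_id = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   na.strings = c("NA"), colClasses = NA)
  for (col in c("p1", "p2", "cdr3_aa"))
    if (col %in% names(df)) df[[col]][is.na(df[[col]])] <- ""
  if (is.null(sample_id))
    sample_id <- if (nrow(df)) df$sample_id[1] else "S"
  as_clonotype_table(df, sample_id)
}

#' Write a clonotype table as AIRR-style TSV
#' @param table A `clonotype_table`.
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_clonotype_table <- function(table, path) {
  df <- as.data.frame(table)
  df$sequence_id <- sprintf("%s_%06d", attr(table, "sample_id") %||% "S", seq_len(nrow(df)))
  df$duplicate_count <- df$copies
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
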