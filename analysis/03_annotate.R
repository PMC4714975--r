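#!/usr/bin/env Rscript
# Stage 3 — V(D)J annotation.
#
# Deduplicates merged reads per sample and, for each unique sequence,
# assigns V/D/J/C segments by Smith-Waterman alignment, migrates the
# CDR3 boundaries from the reference marks, reconstructs the junction
# (deletions, P and N additions) and calls somatic mutations in the
# CDR2-to-CDR3 window for sequences with at least 5 copies.

suppressPackageStartupMessages(library(ighrep))

out <- "results/annotate"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
ref <- read_reference("results/sim/reference.fasta",
                      "results/sim/reference_marks.tsv")
samples <- c("neo1", "neo2", "adu1", "adu2")

for (s in samples) {
  m <- read.delim(file.path("results/preprocess", paste0("merged_", s, ".tsv")))
  tab <- annotate_sequences(m$seq, ref, sample_id = s)
  write_clonotype_table(tab, file.path(out, paste0("annotated_", s, ".tsv")))
  lg <- attr(tab, "log")
  cat(sprintf("%s: %d reads -> %d unique, %d annotated (%d unmapped, %d failed migration)\n",
              s, nrow(m), lg$unique_in, lg$annotated, lg$unmapped,
              lg$failed_migration))
}
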