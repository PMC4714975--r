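#!/usr/bin/env Rscript
# Stage 1 — simulate the study material.
#
# Builds a germline V/D/J/C reference, designs sample barcodes, and
# simulates two barcoded MiSeq-style runs that caricature the study's
# contrast: a "neonatal" group with Tdt-negative junctions (no N
# additions, no hypermutation, flat clone sizes) and an "adult" group
# with full N additions, hotspot-biased hypermutation, class switching
# and strong clonal expansion. Everything downstream reads only the
# files written here.

suppressPackageStartupMessages(library(ighrep))

out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
set.seed(20260923)

ref <- generate_reference(seed = 1)
write_reference(ref, file.path(out, "reference.fasta"),
                file.path(out, "reference_marks.tsv"))
bs <- design_barcodes(k = 8, length = 6, min_distance = 3, seed = 2)
writeLines(bs$barcodes, file.path(out, "barcodes.txt"))

neonatal <- simulation_params(n_clonotypes = 250, abundance_law = 0.6,
                              n_insertion_rate = 0, shm_rate = 0,
                              switch_prob = 0.02, seq_error_rate = 0.002,
                              reads_per_sample = 2500, seed = 11)
adult <- simulation_params(n_clonotypes = 250, abundance_law = 1.4,
                           n_insertion_rate = 2.5, shm_rate = 1e-3,
                           hotspot_bias = 5, switch_prob = 0.15,
                           seq_error_rate = 0.002,
                           reads_per_sample = 2500, seed = 12)

reps <- list(neo1 = simulate_repertoire(neonatal, ref, seed = 101),
             neo2 = simulate_repertoire(neonatal, ref, seed = 102),
             adu1 = simulate_repertoire(adult, ref, seed = 103),
             adu2 = simulate_repertoire(adult, ref, seed = 104))
run <- emit_run(reps, bs, adult, file.path(out, "run1"), seed = 7)

cat("Simulated", length(reps), "samples,",
    sum(vapply(reps, function(r) sum(r$abundance), 0)), "read pairs\n")
cat("Mean true N insertions — neonatal:",
    round(mean(c(reps$neo1$n_total, reps$neo2$n_total)), 2),
    "| adult:", round(mean(c(reps$adu1$n_total, reps$adu2$n_total)), 2), "\n")
cat("FASTQ:", run$fwd, "and", run$rev, "\n")
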