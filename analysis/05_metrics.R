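#!/usr/bin/env Rscript
# Stage 5 — repertoire statistics.
#
# Computes, per sample: D50 diversity, normalized VH usage, the
# N-insertion profile, convergent-recombination entropy bins, mutation
# summaries and the isotype-by-mutation cross-tabulation; plus pairwise
# CDR3 peptide sharing within and between the neonatal-like and
# adult-like groups.

suppressPackageStartupMessages(library(ighrep))

out <- "results/metrics"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
ref <- read_reference("results/sim/reference.fasta",
                      "results/sim/reference_marks.tsv")
samples <- c("neo1", "neo2", "adu1", "adu2")
tabs <- lapply(setNames(samples, samples), function(s)
  read_clonotype_table(file.path("results/filter",
                                 paste0("clonotypes_", s, ".tsv"))))

tidy <- do.call(rbind, lapply(tabs, metrics_tidy, ref = ref))
write.table(tidy, file.path(out, "metrics_tidy.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("D50 (low = dominated by few clones):\n")
for (s in samples) cat(sprintf("  %s: %.1f\n", s, d50(tabs[[s]])))

pairs <- t(combn(samples, 2))
share <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
  p <- pairwise_sharing(tabs[[pairs[i, 1]]], tabs[[pairs[i, 2]]])
  data.frame(a = pairs[i, 1], b = pairs[i, 2],
             pAB = p[["pAB"]], pBA = p[["pBA"]])
}))
write.table(share, file.path(out, "sharing.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nCDR3 peptide sharing (% of A's peptides found in B):\n")
print(share, row.names = FALSE)

cat("\nN-insertion profile (% of unique sequences):\n")
np <- sapply(tabs, function(t) n_insertion_profile(t)$pct)
rownames(np) <- n_insertion_profile(tabs[[1]])$bin
print(round(np, 1))

cat("\nMutation load (eligible = >4 copies):\n")
for (s in samples) {
  ms <- mutation_summary(tabs[[s]])
  cat(sprintf("  %s: >=1 %.1f%%, >=2 %.1f%%, rate %.1f per 10^4 bp (n=%d)\n",
              s, ms$pct[1], ms$pct[2], ms$rate_per_1e4, ms$n_eligible))
}

cat("\nConvergent-recombination entropy bins (fraction of peptides):\n")
ce <- sapply(tabs, function(t) convergence_entropy(t)$bins$fraction_peptides)
rownames(ce) <- convergence_entropy(tabs[[1]])$bins$bin
print(round(ce, 3))

iso <- isotype_by_mutation(tabs$adu1)
write.table(iso$by_stratum, file.path(out, "isotype_by_mutation_adu1.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("\nClass-switched % by mutation stratum (adu1):\n")
print(iso$switched_pct, row.names = FALSE)
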