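#!/usr/bin/env Rscript
# Stage 6 — CDR3 treemaps.
#
# One nested treemap per sample (V -> V-J -> V-J-CDR3, leaf area
# proportional to read frequency, largest rectangles at the bottom
# right). Clonally expanded repertoires show as a few large contiguous
# rectangles; diverse ones as many small tiles.

suppressPackageStartupMessages(library(ighrep))

out <- "results/treemaps"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
samples <- c("neo1", "neo2", "adu1", "adu2")

for (s in samples) {
  tab <- read_clonotype_table(file.path("results/filter",
                                        paste0("clonotypes_", s, ".tsv")))
  lay <- layout_treemap(tab, canvas = c(1000, 600), seed = match(s, samples))
  render_svg(lay, corner_radius = 3, path = file.path(out, paste0(s, ".svg")))
  lf <- lay$rectangles[lay$rectangles$level == "VJCDR3", ]
  cat(sprintf("%s: %d leaves, largest leaf %.1f%% of canvas\n", s, nrow(lf),
              100 * max(lf$w * lf$h) / (1000 * 600)))
  write.table(lay$rectangles, file.path(out, paste0(s, "_layout.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
cat("Treemaps written under", out, "\n")
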