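#!/usr/bin/env Rscript

# Step 5: Ka/Ks per ortholog pair (Yang-Nielsen-style approximate method)
# and classification into selection bands: Ka/Ks > 1 (candidate positive
# selection), 0.5-1 (relaxed constraint), < 0.5 (strong constraint).
# Pairs with no synonymous change have an undefined ratio and drop out of
# the banding, mirroring how sparse short alignments behave in real data.

suppressPackageStartupMessages(library(orthodiv))

fx <- read_fixture("results/analysis/fixture")
pairs <- read.delim("results/analysis/ortholog_pairs.tsv",
                    stringsAsFactors = FALSE)
ann <- annotate_pairs(pairs, fx$species_a, fx$species_b, fx$proteins,
                      align_params())

kk <- kaks_table(ann, method = "yn")
sel <- classify_selection(kk)

def <- sel$results[!is.na(sel$results$ka_ks), ]
message(sprintf("Ka and Ks both defined for %d / %d pairs",
                nrow(def), nrow(kk)))
message(sprintf("mean Ka %.4f, mean Ks %.4f, mean Ka/Ks %.3f",
                mean(def$Ka), mean(def$Ks), mean(def$ka_ks)))
message(sprintf("selection bands: %d positive (>1), %d relaxed (0.5-1), %d constrained (<0.5)",
                sel$bands[["positive"]], sel$bands[["relaxed"]],
                sel$bands[["constrained"]]))
if (sel$bands[["positive"]] > 0) {
  message("top pairs by Ka/Ks:")
  top <- head(def[, c("pair_id", "S_sub", "N_sub", "Ka", "Ks", "ka_ks")], 5)
  for (r in seq_len(nrow(top))) {
    message(sprintf("  %-24s Ka %.4f Ks %.4f Ka/Ks %.3f",
                    top$pair_id[r], top$Ka[r], top$Ks[r], top$ka_ks[r]))
  }
}

write.table(sel$results, "results/analysis/kaks_table.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(sel$scatter, "results/analysis/scatter.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("wrote results/analysis/kaks_table.tsv and scatter.tsv")
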