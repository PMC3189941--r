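#!/usr/bin/env Rscript

# Step 3: delineate CDS and UTRs on each ortholog pair using the shared
# reference protein (six-frame alignment, in-frame ATG / stop search
# within +/-30 bp) and apply the quality filters: no indels, CDS >= 150 bp,
# no internal stop, high-stringency UTR alignments only.

suppressPackageStartupMessages(library(orthodiv))

fx <- read_fixture("results/analysis/fixture")
pairs <- read.delim("results/analysis/ortholog_pairs.tsv",
                    stringsAsFactors = FALSE)
params <- align_params()

ann <- annotate_pairs(pairs, fx$species_a, fx$species_b, fx$proteins, params)
ok <- !vapply(ann, function(x) isTRUE(x$rejected), logical(1))
message(sprintf("accepted %d / %d pairs", sum(ok), length(ann)))
if (any(!ok)) {
  message("rejections: ", paste(vapply(ann[!ok], `[[`, "", "reason"),
                                collapse = ", "))
}
message(sprintf("pairs with aligned 5'UTR: %d; with aligned 3'UTR: %d",
                sum(vapply(ann[ok], `[[`, logical(1), "has_utr5")),
                sum(vapply(ann[ok], `[[`, logical(1), "has_utr3"))))

summary <- do.call(rbind, lapply(ann, function(a) {
  data.frame(id_a = a$id_a, id_b = a$id_b,
             accepted = !isTRUE(a$rejected),
             reason = if (isTRUE(a$rejected)) a$reason else "",
             cds_start_a = if (isTRUE(a$rejected)) NA else a$cds_a[1],
             cds_end_a = if (isTRUE(a$rejected)) NA else a$cds_a[2],
             cds_len = if (isTRUE(a$rejected)) NA else diff(a$cds_a),
             utr5 = isTRUE(a$has_utr5), utr3 = isTRUE(a$has_utr3),
             stringsAsFactors = FALSE)
}))
write.table(summary, "results/analysis/annotated_pairs.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("wrote results/analysis/annotated_pairs.tsv")
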