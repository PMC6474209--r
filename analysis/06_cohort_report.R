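#!/usr/bin/env Rscript
# Stage 6: cohort summary - laminar assignment, area comparison, report tables.

suppressPackageStartupMessages(library(spikedecoder))

out <- "results/analysis/report"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

tab <- read.table("results/analysis/decoding/single_neuron_performance.tsv",
                  sep = "\t", header = TRUE)
tab$layer <- assign_layer(tab$depth)
rep_ <- build_report(tab)

write.table(rep_$by_area, file.path(out, "by_area.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
write.table(rep_$by_area_layer, file.path(out, "by_area_layer.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
write.table(rep_$layer_tests, file.path(out, "layer_tests.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)

if (length(unique(tab$area_tag)) == 2 && min(table(tab$area_tag)) >= 2) {
  cmp <- group_compare(tab$performance, tab$area_tag, "rank-sum")
  message(sprintf("area comparison (rank-sum): W = %.1f, p = %.3f",
                  cmp$statistic, cmp$p_value))
}
message(paste(capture.output(print(rep_$by_area)), collapse = "\n"))
message("report tables in ", out)
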