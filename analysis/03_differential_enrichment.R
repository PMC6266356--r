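#!/usr/bin/env Rscript
# Stage 3: differential enrichment between exposed and control IP.
#
# Fragments are counted per peak and condition (centre-in-region rule) and
# compared with the exact conditional binomial test; BH correction and an
# FDR < 0.05 cut split the peaks into up- and down-regulated lists.

suppressPackageStartupMessages(library(hrescreen))

ds <- read_dataset("results/data")
frags <- extend_reads(ds$reads, 250, ds$genome)
ip <- frags[frags$sample == "IP", ]
peaks <- read.delim("results/peaks.tsv", stringsAsFactors = FALSE)

by_cond <- split(ip, ip$condition)
cnt <- count_in_regions(peaks, by_cond)
ratio <- cnt$lib_sizes[["exposed"]] / cnt$lib_sizes[["control"]]
dt <- test_differential(cnt$raw[, "control"], cnt$raw[, "exposed"], ratio)

diff <- peaks
names(diff)[names(diff) == "pvalue"] <- "peak_pvalue"
diff$count_control <- cnt$raw[, "control"]
diff$count_exposed <- cnt$raw[, "exposed"]
diff$signed_fold <- dt$signed_fold
diff$pvalue <- dt$pvalue
diff$fdr <- adjust_fdr(dt$pvalue)
write.table(diff, "results/differential.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

deps <- select_deps(diff, fdr_cut = 0.05)
message(sprintf("%d/%d peaks differential at FDR<0.05 (%d up, %d down)",
                nrow(deps$up) + nrow(deps$down), nrow(diff),
                nrow(deps$up), nrow(deps$down)))
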