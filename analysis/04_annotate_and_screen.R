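#!/usr/bin/env Rscript
# Stage 4: annotate peaks and screen down-regulated promoter DEPs for the
# HRE motif.
#
# Peaks are classified by summit into promoter / upstream / exon / intron
# / intergenic (promoter = TSS +/- 2 kb). Down-regulated promoter DEPs are
# scanned for (A/G)CGTG on both strands; genes with a hit become candidate
# targets, which are then compared against the planted truth.

suppressPackageStartupMessages(library(hrescreen))

ds <- read_dataset("results/data")
diff <- read.delim("results/differential.tsv", stringsAsFactors = FALSE)
index <- build_feature_index(ds$genes, chrom_lengths(ds$genome))

ann <- classify_regions(diff, index)
write.table(ann, "results/annotated_peaks.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cs <- category_summary(ann)
write.table(cs, "results/category_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("peak categories: ",
        paste(sprintf("%s %.1f%%", cs$category, cs$percent),
              collapse = ", "))

deps <- select_deps(diff, fdr_cut = 0.05)
pd <- promoter_deps(deps$down, index)
screened <- screen_candidates(pd, ds$genome)
write.table(screened$candidates, "results/candidates.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(screened$rejected, "results/screen_rejected.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

truth_genes <- ds$truth$gene_id[as.logical(ds$truth$has_hre)]
m <- evaluate_against_truth(screened$candidates$gene_id, truth_genes)
message(sprintf(paste0("%d down promoter DEPs -> %d HRE-positive ",
                       "candidates; sensitivity %.2f, precision %.2f"),
                nrow(pd), nrow(screened$candidates), m$sensitivity,
                m$precision))
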