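#!/usr/bin/env Rscript
# Stage 2: extend reads to fragments, build coverage, call peaks.
#
# Reads are extended to 250 bp (the analysis-side fragment assumption) and
# IP coverage pooled over both conditions is tested against the pooled
# input with the Poisson local-lambda model (p < 1e-4). Writes the peak
# table, a BED6+ track, and the peak-geometry summaries (length histogram,
# per-chromosome counts).

suppressPackageStartupMessages(library(hrescreen))

ds <- read_dataset("results/data")
frags <- extend_reads(ds$reads, 250, ds$genome)
ip <- frags[frags$sample == "IP", ]
input <- frags[frags$sample == "input", ]

peaks <- call_peaks(compute_coverage(ip, ds$genome),
                    compute_coverage(input, ds$genome))
write.table(peaks, "results/peaks.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write_peaks_bed(peaks, "results/peaks.bed")

s <- summarize_peaks(peaks)
write.table(s$length_hist, "results/peak_length_hist.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(s$per_chrom, "results/peaks_per_chromosome.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message(sprintf("called %d peaks (median width %d bp); per chromosome: %s",
                s$n_peaks, as.integer(median(peaks$end - peaks$start)),
                paste(s$per_chrom$chrom, s$per_chrom$n, collapse = ", ")))
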