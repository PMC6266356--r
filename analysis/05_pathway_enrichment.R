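#!/usr/bin/env Rscript
# Stage 5: pathway overlap and hypergeometric enrichment.
#
# Applies the packaged curated-function filter to the packaged screened
# gene list (synthetic stand-ins for the study's screen), counts pathway
# overlaps ("Hits") against the packaged pathway collection, and computes
# upper-tail hypergeometric enrichment with BH correction.

suppressPackageStartupMessages(library(hrescreen))

fixture <- function(name) system.file("extdata", name,
                                      package = "hrescreen",
                                      mustWork = TRUE)

screened <- read.delim(fixture("screened_genes_synthetic.tsv"),
                       stringsAsFactors = FALSE)
kept <- apply_function_filter(screened,
                              fixture("function_annotation_synthetic.tsv"))
message(sprintf("function filter: %d of %d screened genes kept",
                nrow(kept), nrow(screened)))

gmt <- read_gmt(fixture("pathways_kegg_synthetic.gmt"))
uni <- read.delim(fixture("gene_universe_synthetic.txt"),
                  stringsAsFactors = FALSE)$gene_id
res <- enrich_all(screened$gene_id, gmt, uni)
write.table(res, "results/pathway_enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

for (i in seq_len(nrow(res)))
  message(sprintf("  %-45s total %3d hits %d  p=%.2e", res$name[i],
                  res$total[i], res$hits[i], res$pvalue[i]))
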