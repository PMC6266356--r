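#!/usr/bin/env Rscript
# Stage 1: build the reference synthetic ChIP-Seq dataset.
#
# A 2 Mb, two-chromosome genome carries 200 genes; 30 of them are bound by
# the factor, each with an HRE 5-mer planted in its promoter, and binding
# drops 4-fold (300 -> 75 expected fragments) in the exposed condition.
# Every other promoter is scrubbed of spurious HREs so downstream recovery
# can be judged against unambiguous truth. Files land in results/data/.

suppressPackageStartupMessages(library(hrescreen))

cfg <- sim_config(seed = 20181112)
print(cfg)

genome <- generate_genome(cfg)
genes <- generate_genes(genome, cfg)
planted <- plant_hre(genome, genes, cfg)
reads <- simulate_reads(planted$genome, genes, planted$truth, cfg)

files <- write_dataset(planted$genome, genes, reads, planted$truth,
                       "results/data")
message(sprintf("wrote %d files: %d genes, %d bound (all with HRE), %s reads",
                length(files), nrow(genes), nrow(planted$truth),
                format(nrow(reads), big.mark = ",")))
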