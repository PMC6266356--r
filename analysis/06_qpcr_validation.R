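#!/usr/bin/env Rscript
# Stage 6: qPCR validation arm.
#
# (a) Counts validated genes (fold < 1 with a significance star) in the
# transcribed validation table. (b) Demonstrates the 2^-ddCt machinery on
# simulated Ct data with known true folds: relative expression, one-way
# ANOVA over dCt, LSD post-hoc p-values and star tiers.

suppressPackageStartupMessages(library(hrescreen))

fixture <- function(name) system.file("extdata", name,
                                      package = "hrescreen",
                                      mustWork = TRUE)

wide <- read.delim(fixture("qpcr_validation_table.tsv"),
                   stringsAsFactors = FALSE)
long <- rbind(
  data.frame(gene_id = wide$gene_id, group = "LB",
             mean_fold = wide$fold_LB, stars = wide$stars_LB),
  data.frame(gene_id = wide$gene_id, group = "HB",
             mean_fold = wide$fold_HB, stars = wide$stars_HB))
message(sprintf("validated genes in the transcribed table: %d of %d",
                count_validated(long), nrow(wide)))

# simulated Ct data: two genes truly repressed, one flat
set.seed(20181112)
rec <- rbind(
  simulate_ct_data(c(LB = 0.12, HB = 0.08), n = 6, ct_sd = 0.1,
                   seed = 11, gene_id = "Ptp4a3_sim"),
  simulate_ct_data(c(LB = 0.40, HB = 0.30), n = 6, ct_sd = 0.1,
                   seed = 12, gene_id = "Gzmb_sim"),
  simulate_ct_data(c(LB = 1.0, HB = 1.0), n = 6, ct_sd = 0.1,
                   seed = 13, gene_id = "Flat_sim"))
tab <- relative_expression(rec)
write.table(tab, "results/qpcr_simulated_validation.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
for (i in seq_len(nrow(tab)))
  message(sprintf("  %-10s %s fold %.3f +/- %.3f  LSD p=%.2e %s",
                  tab$gene_id[i], tab$group[i], tab$mean_fold[i],
                  tab$sd_fold[i], tab$p_vs_control[i], tab$stars[i]))
message(sprintf("validated in simulation: %d of %d genes",
                count_validated(tab), length(unique(tab$gene_id))))
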