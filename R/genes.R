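#' Lay out non-overlapping gene models on a genome
#'
#' Genes are placed sequentially along each chromosome with inter-gene gaps
#' of at least 4,200 bp, so that TSS +/- 2 kb promoter windows are pairwise
#' disjoint and never overlap a neighbouring gene body. Strand is random;
#' each gene carries 1-5 non-overlapping exons whose first and last exon
#' touch the span boundaries. The TSS is the span start on the + strand and
#' `end - 1` on the - strand. All coordinates 0-based half-open.
#'
#' @param genome a `genome_model`.
#' @param config a [sim_config()].
#' @return data.frame with columns `gene_id`, `chrom`, `strand`, `start`,
#'   `end`, `tss` and a list-column `exons` (two-column matrices of
#'   half-open intervals).
#' @export
generate_genes <- function(genome, config) {
  stopifnot(inherits(genome, "genome_model"), inherits(config, "sim_config"))
  set.seed(config$seed + 202)
  n_genes <- config$n_genes
  lens <- chrom_lengths(genome)
  if (n_genes == 0) {
    return(data.frame(gene_id = character(), chrom = character(),
                      strand = character(), start = numeric(),
                      end = numeric(), tss = numeric(),
                      exons = I(list())))
  }
  # round-robin allocation of genes to chromosomes
  chrom_of <- rep(names(lens), length.out = n_genes)
  per_chrom <- table(factor(chrom_of, levels = names(lens)))

  span_min <- 1000; span_max <- 4000
  gap_min <- 4200; gap_max <- 5800
  rows <- vector("list", n_genes)
  k <- 0
  for (chrom in names(lens)) {
    nc <- per_chrom[[chrom]]
    if (nc == 0) next
    pos <- 2000 + sample(0:1000, 1)  # keep the first promoter on-chromosome
    for (i in seq_len(nc)) {
      span <- sample(span_min:span_max, 1)
      start <- pos
      end <- start + span
      if (end + 2000 > lens[[chrom]])
        stop("genome too small: ", chrom, " (", lens[[chrom]],
             " bp) cannot hold ", nc, " genes with disjoint promoter ",
             "windows", call. = FALSE)
      strand <- sample(c("+", "-"), 1)
      tss <- if (strand == "+") start else end - 1
      n_ex <- sample(1:5, 1)
      if (n_ex == 1) {
        exons <- matrix(c(start, end), ncol = 2)
      } else {
        cuts <- sort(sample((start + 1):(end - 1), 2 * n_ex - 2))
        bounds <- c(start, cuts, end)
        idx <- seq(1, length(bounds) - 1, by = 2)
        exons <- cbind(bounds[idx], bounds[idx + 1])
      }
      colnames(exons) <- c("start", "end")
      k <- k + 1
      rows[[k]] <- list(gene_id = sprintf("G%04d", k), chrom = chrom,
                        strand = strand, start = start, end = end,
                        tss = tss, exons = exons)
      pos <- end + sample(gap_min:gap_max, 1)
    }
  }
  data.frame(
    gene_id = vapply(rows, `[[`, "", "gene_id"),
    chrom = vapply(rows, `[[`, "", "chrom"),
    strand = vapply(rows, `[[`, "", "strand"),
    start = vapply(rows, `[[`, 0, "start"),
    end = vapply(rows, `[[`, 0, "end"),
    tss = vapply(rows, `[[`, 0, "tss"),
    exons = I(lapply(rows, `[[`, "exons")),
    stringsAsFactors = FALSE
  )
}
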