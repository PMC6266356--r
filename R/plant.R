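#' Plant HRE motifs in bound promoters and scrub them elsewhere
#'
#' Selects the bound genes, writes an HRE 5-mer (ACGTG or GCGTG, random
#' choice and strand; a minus-strand plant writes the reverse complement
#' CACGT/CACGC) at a random offset within each selected promoter window
#' \[TSS-2000, TSS+2000), and -- unless disabled -- scrubs spurious HRE
#' 5-mers from all non-target promoter windows (plus a 150 bp margin, so a
#' called peak slightly overhanging the window cannot pick up a stray
#' motif) by point substitution of the middle base. The result is a genome
#' whose promoter-level HRE truth is unambiguous.
#'
#' @param genome a `genome_model`.
#' @param genes data.frame from [generate_genes()].
#' @param config a [sim_config()].
#' @return list with `genome` (modified) and `truth`, a data.frame with one
#'   row per bound gene: `gene_id`, `motif_offset` (bp relative to TSS, on
#'   the genomic axis), `motif_strand`, `bind_rate_control`,
#'   `bind_rate_exposed`, plus bookkeeping columns `chrom`, `tss`,
#'   `motif_pos` (genomic 0-based start of the 5-mer), `motif_kmer` and
#'   `has_hre`.
#' @export
plant_hre <- function(genome, genes, config) {
  stopifnot(inherits(genome, "genome_model"), inherits(config, "sim_config"))
  set.seed(config$seed + 303)
  n_bound <- round(config$frac_bound * config$n_genes)
  n_hre <- round(config$frac_bound_with_hre * config$n_genes)
  if (n_bound > nrow(genes))
    stop("plant_hre: fewer genes than bound targets requested", call. = FALSE)
  hw <- 2000
  lens <- chrom_lengths(genome)

  bound_ids <- if (n_bound > 0) sort(sample(genes$gene_id, n_bound)) else
    character()
  hre_ids <- if (n_hre > 0) sort(sample(bound_ids, n_hre)) else character()

  # scrub every promoter window that is not an HRE target
  if (config$scrub_promoters) {
    margin <- 150
    non_targets <- genes[!genes$gene_id %in% hre_ids, , drop = FALSE]
    for (i in seq_len(nrow(non_targets))) {
      g <- non_targets[i, ]
      s <- max(g$tss - hw - margin, 0)
      e <- min(g$tss + hw + margin, lens[[g$chrom]])
      genome$seq[[g$chrom]] <- .scrub_window(genome$seq[[g$chrom]], s, e)
    }
  }

  # plant one motif per HRE target; record binding geometry for all bound
  truth <- genes[match(bound_ids, genes$gene_id), c("gene_id", "chrom",
                                                    "strand", "tss")]
  nb <- nrow(truth)
  truth$motif_offset <- if (nb) sample(seq(-hw, hw - 6), nb, replace = TRUE)
    else numeric()
  truth$motif_strand <- if (nb) sample(c("+", "-"), nb, replace = TRUE)
    else character()
  truth$motif_kmer <- if (nb) sample(.hre_forward, nb, replace = TRUE)
    else character()
  truth$has_hre <- truth$gene_id %in% hre_ids
  truth$motif_pos <- truth$tss + truth$motif_offset
  truth$bind_rate_control <- rep(config$bind_rate_control, nb)
  truth$bind_rate_exposed <- rep(config$bind_rate_exposed, nb)

  for (i in seq_len(nb)) {
    if (!truth$has_hre[i]) next
    pos <- truth$motif_pos[i]
    len <- lens[[truth$chrom[i]]]
    if (pos < 0 || pos + 5 > len)
      stop("plant_hre: planting position ", pos, " outside chromosome ",
           truth$chrom[i], call. = FALSE)
    kmer <- truth$motif_kmer[i]
    written <- if (truth$motif_strand[i] == "+") kmer else revcomp(kmer)
    substr(genome$seq[[truth$chrom[i]]], pos + 1, pos + 5) <- written
  }
  truth <- truth[, c("gene_id", "motif_offset", "motif_strand",
                     "bind_rate_control", "bind_rate_exposed", "chrom",
                     "tss", "motif_pos", "motif_kmer", "has_hre")]
  rownames(truth) <- NULL
  list(genome = genome, truth = truth)
}

# remove all HRE 5-mers (both strands) from seq[s, e) by flipping the
# middle base; iterates because a substitution can create a new 5-mer
.scrub_window <- function(chrom_seq, s, e) {
  win <- substr(chrom_seq, s + 1, e)
  for (iter in 1:25) {
    hits <- scan_hre(win)
    if (nrow(hits) == 0) {
      substr(chrom_seq, s + 1, e) <- win
      return(chrom_seq)
    }
    ch <- strsplit(win, "", fixed = TRUE)[[1]]
    at <- unique(hits$position) + 3  # 1-based middle base of each 5-mer
    ch[at] <- ifelse(ch[at] == "T", "A", "T")
    win <- paste(ch, collapse = "")
  }
  stop("promoter scrubbing did not converge", call. = FALSE)
}
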