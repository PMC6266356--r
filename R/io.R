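#' Write a synthetic dataset to standard genomics formats
#'
#' Emits `genome.fa` (FASTA, 60-column wrap), `genes.gff3` (1-based closed
#' coordinates, gene + exon features), one BED6 file per
#' sample/condition/replicate named `{condition}-{sample}{replicate}.bed`
#' (0-based half-open; name column = replicate, score 0), and `truth.tsv`.
#' [read_dataset()] round-trips the files back to the in-memory objects.
#'
#' @param genome a `genome_model`.
#' @param genes gene table from [generate_genes()].
#' @param reads read placements from [simulate_reads()].
#' @param truth truth table from [plant_hre()] (may be NULL).
#' @param out_dir output directory (created if needed).
#' @return invisibly, the named vector of file paths written.
#' @export
write_dataset <- function(genome, genes, reads, truth, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop("write_dataset: cannot create output directory ", out_dir,
         call. = FALSE)
  files <- c(genome = file.path(out_dir, "genome.fa"),
             genes = file.path(out_dir, "genes.gff3"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome$seq),
                              filepath = files[["genome"]], width = 60)

  gr_genes <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1, end = genes$end),
    strand = genes$strand, type = "gene", ID = genes$gene_id)
  ex <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    m <- genes$exons[[i]]
    data.frame(chrom = genes$chrom[i], start = m[, 1], end = m[, 2],
               strand = genes$strand[i], parent = genes$gene_id[i],
               stringsAsFactors = FALSE)
  }))
  if (!is.null(ex) && nrow(ex)) {
    gr_ex <- GenomicRanges::GRanges(
      seqnames = ex$chrom,
      ranges = IRanges::IRanges(start = ex$start + 1, end = ex$end),
      strand = ex$strand, type = "exon",
      ID = paste0(ex$parent, ".e", stats::ave(seq_len(nrow(ex)), ex$parent,
                                              FUN = seq_along)))
    gr_ex$Parent <- ex$parent
    gr_genes$Parent <- NA_character_
    gr <- c(gr_genes, gr_ex)
  } else gr <- gr_genes
  rtracklayer::export(gr, files[["genes"]], format = "gff3")

  key <- paste0(reads$condition, "-", reads$sample, reads$replicate)
  for (k in sort(unique(key))) {
    r <- reads[key == k, , drop = FALSE]
    path <- file.path(out_dir, paste0(k, ".bed"))
    files[[k]] <- path
    writeLines(paste(r$chrom, format(r$start, scientific = FALSE,
                                     trim = TRUE),
                     format(r$end, scientific = FALSE, trim = TRUE),
                     r$replicate, 0, r$strand, sep = "\t"), path)
  }
  if (!is.null(truth)) {
    files[["truth"]] <- file.path(out_dir, "truth.tsv")
    utils::write.table(truth, files[["truth"]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(files)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir directory containing `genome.fa`, `genes.gff3`, `*.bed` and
#'   optionally `truth.tsv`.
#' @return list with `genome`, `genes`, `reads`, `truth` (NULL if absent).
#' @export
read_dataset <- function(dir) {
  fa <- file.path(dir, "genome.fa")
  if (!file.exists(fa)) stop("read_dataset: missing ", fa, call. = FALSE)
  ss <- Biostrings::readDNAStringSet(fa)
  genome <- structure(list(seq = stats::setNames(as.character(ss),
                                                 names(ss))),
                      class = "genome_model")

  gff <- rtracklayer::import(file.path(dir, "genes.gff3"), format = "gff3")
  gdf <- as.data.frame(gff)
  gene_rows <- gdf[gdf$type == "gene", , drop = FALSE]
  exon_rows <- gdf[gdf$type == "exon", , drop = FALSE]
  exon_parent <- vapply(exon_rows$Parent, function(p) as.character(p)[1],
                        character(1))
  genes <- data.frame(
    gene_id = as.character(gene_rows$ID),
    chrom = as.character(gene_rows$seqnames),
    strand = as.character(gene_rows$strand),
    start = gene_rows$start - 1,
    end = as.numeric(gene_rows$end),
    stringsAsFactors = FALSE)
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  genes$exons <- I(lapply(genes$gene_id, function(id) {
    e <- exon_rows[exon_parent == id, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    m <- cbind(start = e$start - 1, end = as.numeric(e$end))
    m
  }))
  genes <- genes[order(genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL

  beds <- sort(list.files(dir, pattern = "\\.bed$", full.names = TRUE))
  reads <- do.call(rbind, lapply(beds, function(path) {
    stem <- sub("\\.bed$", "", basename(path))
    cond <- sub("-.*$", "", stem)
    samp <- sub("[0-9]+$", "", sub("^[^-]*-", "", stem))
    repl <- as.numeric(sub("^.*?([0-9]+)$", "\\1", stem))
    gr <- rtracklayer::import(path, format = "BED")
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr) - 1,
               end = as.numeric(GenomicRanges::end(gr)),
               strand = as.character(GenomicRanges::strand(gr)),
               sample = samp, condition = cond, replicate = repl,
               stringsAsFactors = FALSE)
  }))
  truth_path <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truth_path))
    utils::read.delim(truth_path, stringsAsFactors = FALSE) else NULL
  list(genome = genome, genes = genes, reads = reads, truth = truth)
}
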