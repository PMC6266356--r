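#' Build a feature index over gene models
#'
#' Precomputes, per gene, the promoter window
#' `[tss - promoter_halfwidth, tss + promoter_halfwidth)` (on the genomic
#' axis, clipped to chromosome bounds), the strand-oriented upstream window
#' beyond it (out to `upstream_extent` bp from the TSS), and the exon set.
#'
#' @param genes gene table from [generate_genes()] (or [read_dataset()]).
#' @param chrom_lengths named vector of chromosome lengths (optional; used
#'   to clip windows at the right-hand end).
#' @param promoter_halfwidth promoter half-width in bp (default 2000).
#' @param upstream_extent upstream extent in bp from the TSS (default
#'   10000).
#' @return a `feature_index` list.
#' @export
build_feature_index <- function(genes, chrom_lengths = NULL,
                                promoter_halfwidth = 2000,
                                upstream_extent = 10000) {
  if (anyDuplicated(genes$gene_id))
    stop("build_feature_index: duplicate gene_id", call. = FALSE)
  hw <- promoter_halfwidth
  up <- upstream_extent
  len_of <- function(chrom) {
    if (is.null(chrom_lengths)) Inf else chrom_lengths[[chrom]]
  }
  g <- genes
  g$prom_start <- pmax(g$tss - hw, 0)
  g$prom_end <- pmin(g$tss + hw,
                     vapply(g$chrom, len_of, 0))
  plus <- g$strand == "+"
  g$up_start <- ifelse(plus, pmax(g$tss - up, 0), g$tss + hw)
  g$up_end <- ifelse(plus, pmax(g$tss - hw, 0),
                     pmin(g$tss + up, vapply(g$chrom, len_of, 0)))
  exons <- do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
    m <- g$exons[[i]]
    if (is.null(m) || nrow(m) == 0) return(NULL)
    data.frame(gene_id = g$gene_id[i], chrom = g$chrom[i],
               start = m[, 1], end = m[, 2], stringsAsFactors = FALSE)
  }))
  if (is.null(exons))
    exons <- data.frame(gene_id = character(), chrom = character(),
                        start = numeric(), end = numeric())
  structure(list(genes = g, exons = exons,
                 promoter_halfwidth = hw, upstream_extent = up),
            class = "feature_index")
}

#' Classify regions into the five genomic categories
#'
#' Each region is classified by its summit with priority
#' promoter > exon > intron > upstream > intergenic. Gene assignment is
#' the matching gene; ties across genes are broken by smallest
#' `|distance_to_tss|`, then lexicographic gene id. `distance_to_tss` is
#' strand-oriented (`summit - tss` on +, `tss - summit` on -).
#'
#' @param regions data.frame with `chrom` and `summit` (0-based).
#' @param index a `feature_index`.
#' @return `regions` with added `category`, `gene_id` (NA for
#'   intergenic) and `distance_to_tss`.
#' @export
classify_regions <- function(regions, index) {
  stopifnot(inherits(index, "feature_index"))
  g <- index$genes
  ex <- index$exons
  n <- nrow(regions)
  category <- rep("intergenic", n)
  gene_id <- rep(NA_character_, n)
  dist <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    s <- regions$summit[i]
    chrom <- regions$chrom[i]
    gc <- g[g$chrom == chrom, , drop = FALSE]
    if (nrow(gc) == 0) next
    d <- ifelse(gc$strand == "+", s - gc$tss, gc$tss - s)
    pick <- function(sel) {
      if (!any(sel)) return(NULL)
      cand <- which(sel)
      cand[order(abs(d[cand]), gc$gene_id[cand])][1]
    }
    in_prom <- s >= gc$prom_start & s < gc$prom_end
    in_span <- s >= gc$start & s < gc$end
    in_up <- s >= gc$up_start & s < gc$up_end
    in_exon <- rep(FALSE, nrow(gc))
    if (any(in_span)) {
      exc <- ex[ex$chrom == chrom, , drop = FALSE]
      hit_ex <- unique(exc$gene_id[s >= exc$start & s < exc$end])
      in_exon <- gc$gene_id %in% hit_ex
    }
    j <- NULL
    if (!is.null(j <- pick(in_prom))) category[i] <- "promoter"
    else if (!is.null(j <- pick(in_exon))) category[i] <- "exon"
    else if (!is.null(j <- pick(in_span & !in_exon))) category[i] <- "intron"
    else if (!is.null(j <- pick(in_up))) category[i] <- "upstream"
    if (!is.null(j)) {
      gene_id[i] <- gc$gene_id[j]
      dist[i] <- d[j]
    }
  }
  regions$category <- category
  regions$gene_id <- gene_id
  regions$distance_to_tss <- dist
  regions
}

#' Classify a single region
#' @param region one-row data.frame (or list) with `chrom` and `summit`.
#' @param index a `feature_index`.
#' @return one-row data.frame from [classify_regions()].
#' @export
classify_region <- function(region, index) {
  df <- as.data.frame(region, stringsAsFactors = FALSE)
  if (df$summit[1] < 0)
    stop("classify_region: summit off chromosome", call. = FALSE)
  classify_regions(df[1, , drop = FALSE], index)
}

#' Category percentage summary of an annotated region set
#' @param annotated output of [classify_regions()].
#' @return data.frame of counts and percentages per category (all five
#'   categories always present; percentages sum to 100 for a non-empty
#'   set).
#' @export
category_summary <- function(annotated) {
  lv <- c("promoter", "upstream", "exon", "intron", "intergenic")
  tab <- table(factor(annotated$category, levels = lv))
  n <- sum(tab)
  data.frame(category = lv, count = as.numeric(tab),
             percent = if (n > 0) 100 * as.numeric(tab) / n else
               rep(0, length(lv)),
             stringsAsFactors = FALSE)
}

#' Promoter-located differential peaks, one row per gene
#'
#' Keeps only regions classified as promoter, joins the gene assignment,
#' and for genes with several promoter DEPs keeps the smallest-FDR row.
#'
#' @param deps differential region table (needs `chrom`, `start`, `end`,
#'   `summit`, `fdr`, `direction`).
#' @param index a `feature_index`.
#' @return data.frame keyed by `gene_id`, with `tss` joined in.
#' @export
promoter_deps <- function(deps, index) {
  if (nrow(deps) == 0) {
    out <- cbind(deps, category = character(), gene_id = character(),
                 distance_to_tss = numeric(), tss = numeric())
    return(out)
  }
  ann <- classify_regions(deps, index)
  ann <- ann[ann$category == "promoter", , drop = FALSE]
  if (nrow(ann) == 0) { rownames(ann) <- NULL; return(ann) }
  ann$tss <- index$genes$tss[match(ann$gene_id, index$genes$gene_id)]
  ann <- ann[order(ann$gene_id, ann$fdr, ann$chrom, ann$start), ,
             drop = FALSE]
  ann <- ann[!duplicated(ann$gene_id), , drop = FALSE]
  ann <- ann[order(ann$chrom, ann$start), , drop = FALSE]
  rownames(ann) <- NULL
  ann
}
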