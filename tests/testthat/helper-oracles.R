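# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (local complement tables, per-base loops, enumeration)
# so that tests compare two independent routes to the same quantity.

# both-strand HRE 5-mer scan by direct enumeration of every position
bf_scan_hre <- function(seq, strands = "both") {
  seq <- toupper(seq)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rc5 <- function(k) {
    paste(rev(comp[strsplit(k, "")[[1]]]), collapse = "")
  }
  fwd_set <- c("ACGTG", "GCGTG")
  out <- list()
  n <- nchar(seq)
  if (n >= 5) for (i in 1:(n - 4)) {
    k <- substr(seq, i, i + 4)
    if (k %in% fwd_set)
      out[[length(out) + 1]] <- data.frame(position = i - 1, strand = "+",
                                           matched_kmer = k)
    if (strands == "both" && rc5(k) %in% fwd_set)
      out[[length(out) + 1]] <- data.frame(position = i - 1, strand = "-",
                                           matched_kmer = rc5(k))
  }
  if (!length(out))
    return(data.frame(position = numeric(), strand = character(),
                      matched_kmer = character()))
  df <- do.call(rbind, out)
  df <- df[order(df$position, match(df$strand, c("+", "-"))), ]
  rownames(df) <- NULL
  df
}

# per-base membership count
bf_coverage <- function(starts, ends, len) {
  vapply(0:(len - 1), function(p) sum(starts <= p & p < ends), 0)
}

# priority classification of one summit against a gene table
bf_classify <- function(summit, chrom, genes, hw = 2000, up = 10000,
                        lens = NULL) {
  cand <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (g$chrom != chrom) next
    len <- if (is.null(lens)) Inf else lens[[g$chrom]]
    d <- if (g$strand == "+") summit - g$tss else g$tss - summit
    cat_g <- NULL
    in_prom <- summit >= max(g$tss - hw, 0) && summit < min(g$tss + hw, len)
    ex <- g$exons[[1]]
    in_exon <- any(summit >= ex[, 1] & summit < ex[, 2])
    in_span <- summit >= g$start && summit < g$end
    if (g$strand == "+") {
      in_up <- summit >= max(g$tss - up, 0) && summit < max(g$tss - hw, 0)
    } else {
      in_up <- summit >= g$tss + hw && summit < min(g$tss + up, len)
    }
    cat_g <- if (in_prom) "promoter" else if (in_exon) "exon" else
      if (in_span) "intron" else if (in_up) "upstream" else NULL
    if (!is.null(cat_g))
      cand[[length(cand) + 1]] <- list(category = cat_g,
                                       gene_id = g$gene_id, d = d)
  }
  if (!length(cand))
    return(list(category = "intergenic", gene_id = NA_character_,
                d = NA_real_))
  pri <- c(promoter = 1, exon = 2, intron = 3, upstream = 4)
  ord <- order(pri[vapply(cand, `[[`, "", "category")],
               abs(vapply(cand, `[[`, 0, "d")),
               vapply(cand, `[[`, "", "gene_id"))
  cand[[ord[1]]]
}

# exhaustive hypergeometric upper tail: universe of size N whose first K
# elements are pathway members; draw q; P(overlap >= h)
bf_hyper <- function(h, q, K, N) {
  if (q == 0) return(as.numeric(h <= 0))
  draws <- utils::combn(N, q)
  mean(apply(draws, 2, function(d) sum(d <= K) >= h))
}

# Benjamini-Hochberg step-up by hand
bf_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# two-sided exact binomial p by enumeration (likelihood-based rejection
# region, the classical definition)
bf_binom_two_sided <- function(x, n, p0 = 0.5) {
  d <- dbinom(0:n, n, p0)
  sum(d[d <= d[x + 1] * (1 + 1e-07)])
}

# small, fast simulation design used across tests
tiny_cfg <- function(seed, ...) {
  args <- list(seed = seed, n_chroms = 1, chrom_length = 150000,
               n_genes = 12, frac_bound = 0.25, frac_bound_with_hre = 0.25,
               reads_per_sample = 15000)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

fixture <- function(name) {
  system.file("extdata", name, package = "hrescreen", mustWork = TRUE)
}

# long-format view of the transcribed qPCR validation fixture
load_validation_fixture <- function() {
  wide <- read.delim(fixture("qpcr_validation_table.tsv"),
                     stringsAsFactors = FALSE)
  rbind(
    data.frame(gene_id = wide$gene_id, group = "LB",
               mean_fold = wide$fold_LB, stars = wide$stars_LB),
    data.frame(gene_id = wide$gene_id, group = "HB",
               mean_fold = wide$fold_HB, stars = wide$stars_HB))
}
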