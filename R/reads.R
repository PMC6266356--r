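#' Simulate IP and input read placements for two conditions
#'
#' Input samples receive `Poisson(background_rate x chrom length)` fragments
#' with uniform 5' starts. IP samples receive the same background plus, for
#' each bound gene, `Poisson(bind_rate_condition)` fragments whose centres
#' are normal around the planted motif position (sd 100 bp, truncated to
#' the chromosome). Fragment length is uniform on the shear range; the
#' emitted read is the first `read_length` bp of the fragment (minus-strand
#' reads come from the fragment 3' end). Fragments shorter than the read
#' yield truncated reads.
#'
#' @param genome a `genome_model`.
#' @param genes data.frame from [generate_genes()].
#' @param truth truth table from [plant_hre()] (bound genes + rates).
#' @param config a [sim_config()].
#' @return data.frame of read placements: `chrom`, `start`, `end`
#'   (0-based half-open), `strand`, `sample` (`IP`/`input`), `condition`
#'   (`control`/`exposed`), `replicate`.
#' @export
simulate_reads <- function(genome, genes, truth, config) {
  stopifnot(inherits(genome, "genome_model"), inherits(config, "sim_config"))
  if (config$frac_bound > 0 && nrow(genes) == 0)
    stop("simulate_reads: frac_bound > 0 but the gene list is empty",
         call. = FALSE)
  lens <- chrom_lengths(genome)
  fr <- config$fragment_length_range
  rl <- config$read_length

  samples <- expand.grid(replicate = seq_len(config$replicates),
                         sample = c("IP", "input"),
                         condition = c("control", "exposed"),
                         stringsAsFactors = FALSE)
  samples <- samples[!(samples$sample == "input" & samples$replicate > 1), ,
                     drop = FALSE]
  samples <- samples[order(samples$condition, samples$sample,
                           samples$replicate), , drop = FALSE]

  reads_from_fragments <- function(chrom, fs, fe) {
    n <- length(fs)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    start <- ifelse(strand == "+", fs, pmax(fe - rl, fs))
    end <- ifelse(strand == "+", pmin(fs + rl, fe), fe)
    data.frame(chrom = rep(chrom, n), start = start, end = end,
               strand = strand, stringsAsFactors = FALSE)
  }

  out <- vector("list", 0)
  for (si in seq_len(nrow(samples))) {
    smp <- samples[si, ]
    set.seed(config$seed + 1000 + si)
    for (chrom in names(lens)) {
      len <- lens[[chrom]]
      # background fragments (both sample types)
      n_bg <- stats::rpois(1, config$background_rate * len)
      if (n_bg > 0) {
        fs <- floor(stats::runif(n_bg, 0, len))
        fl <- sample(fr[1]:fr[2], n_bg, replace = TRUE)
        fe <- pmin(fs + fl, len)
        r <- reads_from_fragments(chrom, fs, fe)
        r$sample <- smp$sample; r$condition <- smp$condition
        r$replicate <- smp$replicate
        out[[length(out) + 1]] <- r
      }
      # binding fragments (IP only)
      if (smp$sample == "IP" && nrow(truth) > 0) {
        tt <- truth[truth$chrom == chrom, , drop = FALSE]
        for (i in seq_len(nrow(tt))) {
          rate <- if (smp$condition == "control") tt$bind_rate_control[i]
            else tt$bind_rate_exposed[i]
          n_sig <- stats::rpois(1, rate)
          if (n_sig == 0) next
          centre <- round(stats::rnorm(n_sig, tt$motif_pos[i] + 2, 100))
          centre <- pmin(pmax(centre, 0), len - 1)
          fl <- sample(fr[1]:fr[2], n_sig, replace = TRUE)
          fs <- pmax(centre - floor(fl / 2), 0)
          fe <- pmin(fs + fl, len)
          r <- reads_from_fragments(chrom, fs, fe)
          r$sample <- smp$sample; r$condition <- smp$condition
          r$replicate <- smp$replicate
          out[[length(out) + 1]] <- r
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), strand = character(),
                      sample = character(), condition = character(),
                      replicate = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
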