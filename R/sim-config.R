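#' Simulation configuration for the synthetic ChIP-Seq dataset
#'
#' Bundles every knob of the synthetic-data generator. The defaults describe
#' the reference design used throughout the package: a 2 Mb two-chromosome
#' genome carrying 200 genes, 30 of which are "bound" promoters with a
#' planted HRE motif, sequenced to ~200,000 single-end 150 bp reads per
#' sample from fragments sheared to 150-900 bp. Binding drops 4-fold in the
#' exposed condition (300 -> 75 expected fragments per bound promoter),
#' which places bound-promoter summits at roughly 4-5x the local background
#' coverage -- the enrichment regime of a sharp transcription-factor ChIP.
#'
#' @param seed integer seed; mandatory, drives every random draw.
#' @param n_chroms number of chromosomes.
#' @param chrom_length length of each chromosome in bp (>= 10,000).
#' @param n_genes total number of genes laid out on the genome.
#' @param frac_bound fraction of genes whose promoter is bound by the factor.
#' @param frac_bound_with_hre fraction of genes that are bound *and* carry a
#'   planted HRE 5-mer in their promoter; must not exceed `frac_bound`.
#' @param reads_per_sample expected background fragments per sample; the
#'   per-bp background rate is `reads_per_sample / genome length` unless
#'   `background_rate` is given explicitly.
#' @param fragment_length_range sonication shear range in bp, uniform.
#' @param read_length sequenced read length in bp.
#' @param background_rate background fragments per bp (overrides
#'   `reads_per_sample` when non-NULL).
#' @param bind_rate_control,bind_rate_exposed expected IP fragments per
#'   bound promoter per sample in each condition.
#' @param replicates IP replicates per condition (inputs always have one).
#' @param scrub_promoters if TRUE (default), spurious HRE 5-mers are removed
#'   from non-target promoter windows so planted truth is unambiguous.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed,
                       n_chroms = 2,
                       chrom_length = 1e6,
                       n_genes = 200,
                       frac_bound = 0.15,
                       frac_bound_with_hre = 0.15,
                       reads_per_sample = 2e5,
                       fragment_length_range = c(150, 900),
                       read_length = 150,
                       background_rate = NULL,
                       bind_rate_control = 300,
                       bind_rate_exposed = 75,
                       replicates = 1,
                       scrub_promoters = TRUE) {
  if (missing(seed) || is.null(seed) || !is.finite(seed))
    stop("sim_config: 'seed' is mandatory", call. = FALSE)
  if (n_chroms < 1 || chrom_length < 10000)
    stop("sim_config: need >= 1 chromosome of >= 10,000 bp", call. = FALSE)
  if (frac_bound < 0 || frac_bound > 1 ||
      frac_bound_with_hre < 0 || frac_bound_with_hre > 1)
    stop("sim_config: fractions must lie in [0, 1]", call. = FALSE)
  if (frac_bound_with_hre > frac_bound)
    stop("sim_config: frac_bound_with_hre must not exceed frac_bound",
         call. = FALSE)
  if (length(fragment_length_range) != 2 ||
      fragment_length_range[1] > fragment_length_range[2] ||
      fragment_length_range[1] <= 0)
    stop("sim_config: bad fragment_length_range", call. = FALSE)
  if (read_length <= 0) stop("sim_config: read_length must be > 0",
                             call. = FALSE)
  if (is.null(background_rate))
    background_rate <- reads_per_sample / (n_chroms * chrom_length)
  if (background_rate < 0) stop("sim_config: negative background_rate",
                                call. = FALSE)
  if (bind_rate_exposed > bind_rate_control)
    warning("sim_config: bind_rate_exposed exceeds bind_rate_control; ",
            "planted truth will not be down-regulated")
  structure(list(
    seed = as.numeric(seed),
    n_chroms = as.numeric(n_chroms),
    chrom_length = as.numeric(chrom_length),
    n_genes = as.numeric(n_genes),
    frac_bound = as.numeric(frac_bound),
    frac_bound_with_hre = as.numeric(frac_bound_with_hre),
    reads_per_sample = as.numeric(reads_per_sample),
    fragment_length_range = as.numeric(fragment_length_range),
    read_length = as.numeric(read_length),
    background_rate = as.numeric(background_rate),
    bind_rate_control = as.numeric(bind_rate_control),
    bind_rate_exposed = as.numeric(bind_rate_exposed),
    replicates = as.numeric(replicates),
    scrub_promoters = isTRUE(scrub_promoters)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_chroms, "chrom x", x$chrom_length, "bp,",
      x$n_genes, "genes,", round(x$frac_bound * x$n_genes), "bound (",
      round(x$frac_bound_with_hre * x$n_genes), "with HRE ),",
      x$reads_per_sample, "reads/sample, bind", x$bind_rate_control, "->",
      x$bind_rate_exposed, ", seed", x$seed, "\n")
  invisible(x)
}
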