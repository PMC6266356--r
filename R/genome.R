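#' Generate a random toy genome
#'
#' Draws i.i.d. uniform A/C/G/T bases for each chromosome from the seeded
#' generator. The result stands in for a reference assembly as the
#' coordinate system of every downstream stage; all internal coordinates
#' are 0-based half-open.
#'
#' @param config a [sim_config()].
#' @return a `genome_model`: a list with element `seq`, a named character
#'   vector of uppercase chromosome sequences (`chr1`, `chr2`, ...).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 101)
  n <- config$n_chroms
  len <- config$chrom_length
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
  names(seqs) <- paste0("chr", seq_len(n))
  structure(list(seq = seqs), class = "genome_model")
}

#' Chromosome lengths of a genome model
#' @param genome a `genome_model`.
#' @return named integer vector of lengths in bp.
#' @export
chrom_lengths <- function(genome) {
  stopifnot(inherits(genome, "genome_model"))
  nchar(genome$seq)
}

#' @export
print.genome_model <- function(x, ...) {
  len <- chrom_lengths(x)
  cat("genome_model:", length(len), "chromosome(s),",
      format(sum(len), big.mark = ","), "bp total\n")
  for (nm in names(len)) cat("  ", nm, len[[nm]], "bp\n")
  invisible(x)
}

#' Extract the sequence of a genomic region
#'
#' Returns the substring `[start, end)` (0-based half-open) of a
#' chromosome.
#'
#' @param genome a `genome_model`.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open interval.
#' @return character scalar; `""` for an empty region.
#' @export
extract_region_sequence <- function(genome, chrom, start, end) {
  stopifnot(inherits(genome, "genome_model"))
  if (!chrom %in% names(genome$seq))
    stop("unknown chromosome: ", chrom, call. = FALSE)
  len <- nchar(genome$seq[[chrom]])
  if (start < 0 || end > len || start > end)
    stop("region [", start, ",", end, ") out of bounds for ", chrom,
         " (length ", len, ")", call. = FALSE)
  if (start == end) return("")
  substr(genome$seq[[chrom]], start + 1, end)
}
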