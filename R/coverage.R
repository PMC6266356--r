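#' Extend reads to model fragments
#'
#' Each read is extended to `ext_len` bp in its 3' direction (the standard
#' single-end fragment model): a + strand read `[s, e)` becomes
#' `[s, min(s + ext_len, chrom length))`, a - strand read becomes
#' `[max(e - ext_len, 0), e)`. Input order is preserved.
#'
#' @param reads read placements (`chrom`, `start`, `end`, `strand`; extra
#'   columns are carried through).
#' @param ext_len extension length in bp; default 250, the midpoint of the
#'   200-300 bp fragment-size assumption used on the analysis side.
#' @param genome a `genome_model` (for chromosome bounds).
#' @return data.frame of fragment intervals with the same columns.
#' @export
extend_reads <- function(reads, ext_len = 250, genome) {
  stopifnot(ext_len > 0, inherits(genome, "genome_model"))
  lens <- chrom_lengths(genome)
  unknown <- setdiff(unique(reads$chrom), names(lens))
  if (length(unknown))
    stop("extend_reads: unknown chromosome(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  len_of <- lens[reads$chrom]
  frag <- reads
  frag$start <- ifelse(reads$strand == "+", reads$start,
                       pmax(reads$end - ext_len, 0))
  frag$end <- ifelse(reads$strand == "+",
                     pmin(reads$start + ext_len, len_of), reads$end)
  frag
}

#' Per-base fragment coverage
#'
#' `depth[i]` is the number of fragments containing base `i - 1` (0-based).
#' The total depth over a chromosome equals the summed length of its
#' (already clipped) fragments.
#'
#' @param fragments fragment intervals (`chrom`, `start`, `end`).
#' @param genome a `genome_model`.
#' @return a `coverage_set`: per-chromosome list with `depth` (integer
#'   vector of chromosome length) and `centers` (sorted fragment midpoints,
#'   used for interval counting); attribute `total_fragments`.
#' @export
compute_coverage <- function(fragments, genome) {
  stopifnot(inherits(genome, "genome_model"))
  lens <- chrom_lengths(genome)
  unknown <- setdiff(unique(fragments$chrom), names(lens))
  if (length(unknown))
    stop("compute_coverage: unknown chromosome(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  out <- lapply(names(lens), function(chrom) {
    f <- fragments[fragments$chrom == chrom, , drop = FALSE]
    if (nrow(f) == 0) {
      return(list(depth = integer(lens[[chrom]]), centers = numeric()))
    }
    cov <- IRanges::coverage(IRanges::IRanges(start = f$start + 1,
                                              end = f$end),
                             width = lens[[chrom]])
    list(depth = as.integer(cov), centers = sort((f$start + f$end) / 2))
  })
  names(out) <- names(lens)
  structure(out, total_fragments = nrow(fragments), class = "coverage_set")
}

# sliding window mean with edge-aware window sizes (window = +/- halfwidth)
.sliding_mean <- function(x, halfwidth) {
  n <- length(x)
  cs <- c(0, cumsum(as.numeric(x)))
  i <- seq_len(n)
  lo <- pmax(i - halfwidth, 1)
  hi <- pmin(i + halfwidth, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# number of centers falling in [start, end) per interval (centers sorted)
.count_centers <- function(centers, start, end) {
  if (length(centers) == 0) return(rep(0, length(start)))
  findInterval(end - 1e-9, centers) - findInterval(start - 1e-9, centers)
}
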