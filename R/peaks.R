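#' Call IP-vs-input enriched peaks with a Poisson local-lambda test
#'
#' Bases are candidates when the one-sided Poisson upper-tail p-value of
#' the IP depth is below `p_threshold`, against a local rate
#' `lambda = max(scaled input mean over +/- local_halfwidth bp,
#' scaled genome-wide input mean, pseudocount)`. Input is scaled to the IP
#' library by the total-fragment ratio. Candidate bases closer than
#' `merge_gap` bp are merged; merged intervals whose maximum IP depth is
#' below `min_depth` are dropped, so raising `min_depth` can only remove
#' whole peaks (monotone peak count). Per-peak fragment counts, summit
#' (leftmost coverage maximum) and an interval-level Poisson p-value are
#' recomputed on the merged interval.
#'
#' @param ip,input `coverage_set`s on the same chromosomes.
#' @param min_depth minimum summit depth for a reported peak.
#' @param p_threshold per-base Poisson p-value cutoff (default 1e-4).
#' @param merge_gap merge candidates within this many bp.
#' @param local_halfwidth half-width of the local background window (bp).
#' @param pseudocount floor for lambda and the enrichment denominator.
#' @return data.frame of peaks: `name`, `chrom`, `start`, `end`, `summit`,
#'   `ip_count`, `input_count` (library-scaled), `enrichment`, `pvalue`.
#' @export
call_peaks <- function(ip, input, min_depth = 5, p_threshold = 1e-4,
                       merge_gap = 100, local_halfwidth = 5000,
                       pseudocount = 0.25) {
  stopifnot(inherits(ip, "coverage_set"), inherits(input, "coverage_set"))
  if (!identical(names(ip), names(input)))
    stop("call_peaks: IP and input cover different chromosomes",
         call. = FALSE)
  if (length(ip) == 0 || attr(ip, "total_fragments") == 0)
    stop("call_peaks: empty IP track", call. = FALSE)
  total_ip <- attr(ip, "total_fragments")
  total_input <- attr(input, "total_fragments")
  ratio <- if (total_input > 0) total_ip / total_input else 1
  genome_len <- sum(vapply(input, function(t) length(t$depth), 0))
  global_depth <- ratio *
    sum(vapply(input, function(t) sum(as.numeric(t$depth)), 0)) / genome_len
  global_center_rate <- ratio * total_input / genome_len

  peaks <- lapply(names(ip), function(chrom) {
    d <- ip[[chrom]]$depth
    lambda <- pmax(.sliding_mean(input[[chrom]]$depth, local_halfwidth) *
                     ratio, global_depth, pseudocount)
    cand <- which(stats::ppois(d - 1, lambda, lower.tail = FALSE) <
                    p_threshold)
    if (length(cand) == 0) return(NULL)
    # merge candidate bases within merge_gap
    brk <- which(diff(cand) > merge_gap + 1)
    s_idx <- cand[c(1, brk + 1)]
    e_idx <- cand[c(brk, length(cand))]
    start <- s_idx - 1
    end <- e_idx  # half-open
    summit <- vapply(seq_along(s_idx), function(i) {
      s_idx[i] - 1 + which.max(d[s_idx[i]:e_idx[i]]) - 1
    }, 0)
    max_depth <- d[summit + 1]
    keep <- max_depth >= min_depth
    if (!any(keep)) return(NULL)
    start <- start[keep]; end <- end[keep]; summit <- summit[keep]
    ip_count <- .count_centers(ip[[chrom]]$centers, start, end)
    input_count <- .count_centers(input[[chrom]]$centers, start, end) * ratio
    lambda_peak <- pmax(input_count, (end - start) * global_center_rate,
                        pseudocount)
    data.frame(chrom = chrom, start = start, end = end, summit = summit,
               ip_count = ip_count, input_count = input_count,
               enrichment = ip_count / (input_count + pseudocount),
               pvalue = stats::ppois(ip_count - 1, lambda_peak,
                                     lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  peaks <- do.call(rbind, peaks)
  if (is.null(peaks)) {
    peaks <- data.frame(chrom = character(), start = numeric(),
                        end = numeric(), summit = numeric(),
                        ip_count = numeric(), input_count = numeric(),
                        enrichment = numeric(), pvalue = numeric(),
                        stringsAsFactors = FALSE)
  }
  peaks <- peaks[order(peaks$chrom, peaks$start), , drop = FALSE]
  rownames(peaks) <- NULL
  if (nrow(peaks))
    peaks <- cbind(name = paste0("peak_", seq_len(nrow(peaks))), peaks,
                   stringsAsFactors = FALSE)
  else peaks <- cbind(name = character(), peaks)
  peaks
}

#' Summarize peak geometry
#'
#' @param peaks peak table from [call_peaks()].
#' @return list with `length_hist` (100 bp bins of peak widths),
#'   `per_chrom` (peak counts per chromosome) and `n_peaks`.
#' @export
summarize_peaks <- function(peaks) {
  if (nrow(peaks) == 0) {
    return(list(length_hist = data.frame(bin_start = numeric(),
                                         bin_end = numeric(),
                                         count = numeric()),
                per_chrom = data.frame(chrom = character(),
                                       n = numeric()),
                n_peaks = 0))
  }
  w <- peaks$end - peaks$start
  bin <- floor(w / 100) * 100
  tab <- table(bin)
  length_hist <- data.frame(bin_start = as.numeric(names(tab)),
                            bin_end = as.numeric(names(tab)) + 100,
                            count = as.numeric(tab))
  pc <- table(peaks$chrom)
  per_chrom <- data.frame(chrom = names(pc), n = as.numeric(pc),
                          stringsAsFactors = FALSE)
  list(length_hist = length_hist, per_chrom = per_chrom,
       n_peaks = nrow(peaks))
}

#' Write peaks as BED6+ with score = -10 log10(p), capped at 1000
#'
#' @param peaks peak table from [call_peaks()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_peaks_bed <- function(peaks, path) {
  score <- pmin(round(-10 * log10(pmax(peaks$pvalue, 1e-300))), 1000)
  bed <- data.frame(peaks$chrom, peaks$start, peaks$end, peaks$name,
                    score, ".", peaks$ip_count,
                    round(peaks$input_count, 3),
                    round(peaks$enrichment, 4),
                    signif(peaks$pvalue, 6))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
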