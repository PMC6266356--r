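#' Count fragments per region and condition
#'
#' A fragment is counted in a region iff its centre lies in the half-open
#' interval `[start, end)`; each fragment is counted at most once per
#' condition. Library-scaled counts rescale every condition to the mean
#' library size.
#'
#' @param regions data.frame with `chrom`, `start`, `end`.
#' @param fragments_by_condition named list of fragment data.frames.
#' @return list with `raw` and `scaled` (regions x conditions matrices)
#'   and `lib_sizes`.
#' @export
count_in_regions <- function(regions, fragments_by_condition) {
  conds <- names(fragments_by_condition)
  stopifnot(!is.null(conds))
  lib <- vapply(fragments_by_condition, nrow, 0)
  if (all(lib == 0))
    warning("count_in_regions: no fragments; all counts are zero")
  raw <- matrix(0, nrow = nrow(regions), ncol = length(conds),
                dimnames = list(NULL, conds))
  for (cn in conds) {
    f <- fragments_by_condition[[cn]]
    if (nrow(f) == 0) next
    centre <- (f$start + f$end) / 2
    for (chrom in unique(regions$chrom)) {
      idx <- which(regions$chrom == chrom)
      cc <- sort(centre[f$chrom == chrom])
      raw[idx, cn] <- .count_centers(cc, regions$start[idx],
                                     regions$end[idx])
    }
  }
  scale_to <- mean(lib[lib > 0])
  if (!is.finite(scale_to)) scale_to <- 1
  scaled <- sweep(raw, 2, ifelse(lib > 0, scale_to / lib, 1), `*`)
  list(raw = raw, scaled = scaled, lib_sizes = lib)
}

#' Exact-binomial differential enrichment test
#'
#' Conditional Poisson comparison for an unreplicated two-condition design:
#' given the total `count_control + count_exposed`, the exposed count is
#' binomial with success probability `scale_ratio / (1 + scale_ratio)`
#' under the null of equal rates, where `scale_ratio` is the
#' exposed/control library-size ratio. The two-sided exact binomial
#' p-value is reported together with a signed linear fold change
#' `+/- max(r, 1/r)`, `r = (count_exposed + 0.5) /
#' (scale_ratio * count_control + 0.5)`, negative when exposed < control.
#'
#' @param count_control,count_exposed non-negative count vectors.
#' @param scale_ratio exposed/control library-size ratio (default 1).
#' @return data.frame with `signed_fold` and `pvalue`.
#' @export
test_differential <- function(count_control, count_exposed,
                              scale_ratio = 1) {
  stopifnot(length(count_control) == length(count_exposed),
            all(count_control >= 0), all(count_exposed >= 0),
            scale_ratio > 0)
  p0 <- scale_ratio / (1 + scale_ratio)
  n <- count_control + count_exposed
  pvalue <- vapply(seq_along(n), function(i) {
    if (n[i] == 0) return(1)
    stats::binom.test(count_exposed[i], n[i], p = p0)$p.value
  }, 0)
  r <- (count_exposed + 0.5) / (scale_ratio * count_control + 0.5)
  signed_fold <- ifelse(r >= 1, r, -1 / r)
  signed_fold[n == 0] <- 1
  data.frame(signed_fold = signed_fold, pvalue = pvalue)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' @param pvalues vector of p-values in \[0, 1\].
#' @return step-up FDR values.
#' @export
adjust_fdr <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric())
  stopifnot(all(pvalues >= 0 & pvalues <= 1))
  stats::p.adjust(pvalues, method = "BH")
}

#' Split differential regions into up- and down-regulated lists
#'
#' @param regions data.frame with `chrom`, `start`, `signed_fold`, `fdr`.
#' @param fdr_cut FDR cutoff (strict `<`).
#' @return list with `up` and `down` data.frames, each ordered by
#'   (chrom, start) and carrying a `direction` column.
#' @export
select_deps <- function(regions, fdr_cut = 0.05) {
  regions$direction <- ifelse(regions$signed_fold < 0, "down", "up")
  pass <- regions[regions$fdr < fdr_cut, , drop = FALSE]
  pass <- pass[order(pass$chrom, pass$start), , drop = FALSE]
  up <- pass[pass$direction == "up", , drop = FALSE]
  down <- pass[pass$direction == "down", , drop = FALSE]
  rownames(up) <- NULL; rownames(down) <- NULL
  list(up = up, down = down)
}
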