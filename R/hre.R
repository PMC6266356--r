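#' Reverse complement of a DNA string
#'
#' Strict alphabet \{A, C, G, T, N\}; an involution
#' (`revcomp(revcomp(s)) == s`).
#'
#' @param x character vector of uppercase DNA strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (any(grepl("[^ACGTN]", x)))
    stop("revcomp: sequence contains characters outside {A,C,G,T,N}",
         call. = FALSE)
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# the HRE 5-mers: (A/G)CGTG read 5'->3', and their reverse complements as
# they appear on the forward genomic strand
.hre_forward <- c("ACGTG", "GCGTG")
.hre_reverse <- c("CACGT", "CACGC")

#' Scan a sequence for HRE motif hits
#'
#' Finds every occurrence of the hypoxia response element (A/G)CGTG. By
#' default both strands are scanned (a minus-strand hit is a position whose
#' forward-strand 5-mer is the reverse complement CACGT/CACGC);
#' `strands = "forward"` restricts to the literal single-strand reading.
#' Overlapping hits are all reported. Lowercase input is folded to upper
#' case; N never matches.
#'
#' @param sequence a single DNA string.
#' @param strands `"both"` (default) or `"forward"`.
#' @return data.frame with columns `position` (0-based start of the 5-mer
#'   on the forward strand), `strand`, and `matched_kmer` (the motif as
#'   read 5'->3' on the hit strand), sorted by position then strand
#'   (`+` before `-`).
#' @export
scan_hre <- function(sequence, strands = c("both", "forward")) {
  strands <- match.arg(strands)
  stopifnot(length(sequence) == 1)
  s <- toupper(sequence)
  empty <- data.frame(position = numeric(), strand = character(),
                      matched_kmer = character(), stringsAsFactors = FALSE)
  n <- nchar(s)
  if (n < 5) return(empty)
  starts <- seq_len(n - 4)
  kmers <- substring(s, starts, starts + 4)
  fwd <- which(kmers %in% .hre_forward)
  hits <- data.frame(position = starts[fwd] - 1, strand = rep("+", length(fwd)),
                     matched_kmer = kmers[fwd], stringsAsFactors = FALSE)
  if (strands == "both") {
    rev <- which(kmers %in% .hre_reverse)
    if (length(rev)) {
      hits <- rbind(hits, data.frame(
        position = starts[rev] - 1, strand = rep("-", length(rev)),
        matched_kmer = revcomp(kmers[rev]), stringsAsFactors = FALSE))
    }
  }
  hits <- hits[order(hits$position, match(hits$strand, c("+", "-"))), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Screen promoter DEP regions for HRE motifs and emit candidate genes
#'
#' The core screening step: each down-regulated promoter DEP region is
#' scanned for the HRE; genes whose region contains at least one hit become
#' candidate target genes. By default the scan window is the differentially
#' enriched region itself; `window = "promoter"` widens it to the full
#' TSS +/- `promoter_halfwidth` window.
#'
#' @param promoter_deps data.frame from [promoter_deps()] (one row per
#'   gene with `gene_id`, `chrom`, `start`, `end`, `tss`, `direction`).
#' @param genome a `genome_model`.
#' @param strands passed to [scan_hre()].
#' @param window `"region"` (default) or `"promoter"`.
#' @param promoter_halfwidth promoter half-width in bp (used when
#'   `window = "promoter"`).
#' @return list with `candidates` (rows with >= 1 hit, sorted by gene_id)
#'   and `rejected` (audit table of HRE-free regions). Both carry
#'   `n_hits`, comma-separated genomic `hit_positions`, `hit_strands`,
#'   `hit_kmers` and the logical `passes_hre`.
#' @export
screen_candidates <- function(promoter_deps, genome,
                              strands = c("both", "forward"),
                              window = c("region", "promoter"),
                              promoter_halfwidth = 2000) {
  strands <- match.arg(strands)
  window <- match.arg(window)
  stopifnot(inherits(genome, "genome_model"))
  cols <- c("gene_id", "chrom", "start", "end")
  if (!all(cols %in% names(promoter_deps)))
    stop("screen_candidates: promoter_deps must have columns ",
         paste(cols, collapse = ", "), call. = FALSE)
  keep <- !is.na(promoter_deps$gene_id)
  if (any(!keep))
    warning("screen_candidates: skipping ", sum(!keep),
            " region(s) without a gene assignment")
  pd <- promoter_deps[keep, , drop = FALSE]
  out <- pd
  out$n_hits <- numeric(nrow(pd))
  out$hit_positions <- character(nrow(pd))
  out$hit_strands <- character(nrow(pd))
  out$hit_kmers <- character(nrow(pd))
  lens <- chrom_lengths(genome)
  for (i in seq_len(nrow(pd))) {
    if (window == "promoter") {
      if (!"tss" %in% names(pd))
        stop("screen_candidates: window='promoter' needs a 'tss' column",
             call. = FALSE)
      s <- max(pd$tss[i] - promoter_halfwidth, 0)
      e <- min(pd$tss[i] + promoter_halfwidth, lens[[pd$chrom[i]]])
    } else {
      s <- pd$start[i]; e <- pd$end[i]
    }
    hits <- scan_hre(extract_region_sequence(genome, pd$chrom[i], s, e),
                     strands = strands)
    out$n_hits[i] <- nrow(hits)
    if (nrow(hits)) {
      out$hit_positions[i] <- paste(hits$position + s, collapse = ",")
      out$hit_strands[i] <- paste(hits$strand, collapse = ",")
      out$hit_kmers[i] <- paste(hits$matched_kmer, collapse = ",")
    }
  }
  out$passes_hre <- out$n_hits > 0
  cand <- out[out$passes_hre, , drop = FALSE]
  cand <- cand[order(cand$gene_id), , drop = FALSE]
  rownames(cand) <- NULL
  rej <- out[!out$passes_hre, , drop = FALSE]
  rownames(rej) <- NULL
  list(candidates = cand, rejected = rej)
}

#' Filter candidate genes by a curated function annotation
#'
#' Stand-in for manual literature curation: a user-supplied table marks
#' which candidate genes have a clear biological function. Genes absent
#' from the table default to `keep = FALSE`.
#'
#' @param candidates candidate data.frame (needs `gene_id`).
#' @param function_table data.frame or TSV path with columns `gene_id`,
#'   `keep` (logical or 0/1) and optionally `function` free text.
#' @return the kept candidate rows, with `function_keep` set.
#' @export
apply_function_filter <- function(candidates, function_table) {
  if (is.character(function_table) && length(function_table) == 1) {
    function_table <- utils::read.delim(function_table,
                                        stringsAsFactors = FALSE)
  }
  if (!all(c("gene_id", "keep") %in% names(function_table)))
    stop("apply_function_filter: table needs columns gene_id, keep",
         call. = FALSE)
  keep <- function_table$keep
  if (!is.logical(keep)) {
    kc <- toupper(trimws(as.character(keep)))
    bad <- which(!kc %in% c("0", "1", "TRUE", "FALSE"))
    if (length(bad))
      stop("apply_function_filter: unparseable keep flag at line ", bad[1],
           call. = FALSE)
    keep <- kc %in% c("1", "TRUE")
  }
  flag <- keep[match(candidates$gene_id, function_table$gene_id)]
  flag[is.na(flag)] <- FALSE
  candidates$function_keep <- flag
  candidates[flag, , drop = FALSE]
}
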