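#' Read a GMT gene-set file
#'
#' Standard tab-separated GMT: set name, description, then member genes.
#' A `total=N` token in the description declares the full pathway size
#' (which may exceed the members listed); otherwise the member count is
#' used. (A dedicated reader is used because the description column, which
#' carries the declared total, must be preserved.)
#'
#' @param path GMT file.
#' @return data.frame with `name`, `description`, `total` and list-column
#'   `members` (upper-cased).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 0) < 3)
  if (length(bad))
    stop("read_gmt: line ", bad[1], " has fewer than 3 fields",
         call. = FALSE)
  name <- vapply(parts, `[[`, "", 1)
  if (anyDuplicated(name))
    stop("read_gmt: duplicate pathway name", call. = FALSE)
  desc <- vapply(parts, `[[`, "", 2)
  members <- lapply(parts, function(p) unique(toupper(p[-(1:2)])))
  total <- vapply(seq_along(parts), function(i) {
    hit <- regmatches(desc[i], regexpr("total=[0-9]+", desc[i]))
    if (length(hit)) as.numeric(sub("total=", "", hit))
    else length(members[[i]])
  }, 0)
  data.frame(name = name, description = desc, total = total,
             members = I(members), stringsAsFactors = FALSE)
}

#' Overlap of a query gene set with a pathway
#'
#' Case-normalized (upper-cased) set intersection.
#'
#' @param query_genes character vector of query gene ids.
#' @param members character vector of pathway member ids.
#' @return list with `hits` (count) and `hit_genes` (sorted).
#' @export
overlap_genes <- function(query_genes, members) {
  hit_genes <- sort(intersect(unique(toupper(query_genes)),
                              unique(toupper(members))))
  list(hits = length(hit_genes), hit_genes = hit_genes)
}

#' Upper-tail hypergeometric enrichment p-value
#'
#' P(X >= hits) where X counts pathway genes in a draw of `query_size`
#' genes from a universe of `universe_size` containing `pathway_total`
#' pathway genes.
#'
#' @param hits observed overlap.
#' @param query_size number of query genes.
#' @param pathway_total pathway size in the universe.
#' @param universe_size background size.
#' @return the p-value.
#' @export
hypergeom_test <- function(hits, query_size, pathway_total, universe_size) {
  if (pathway_total > universe_size || query_size > universe_size ||
      hits > min(query_size, pathway_total) || hits < 0)
    stop("hypergeom_test: inconsistent counts", call. = FALSE)
  stats::phyper(hits - 1, pathway_total, universe_size - pathway_total,
                query_size, lower.tail = FALSE)
}

#' Enrichment of a query set over a pathway collection
#'
#' One hypergeometric test per pathway with BH correction across the
#' collection; results are sorted by p-value, name as tie-break. The
#' declared pathway `total` is used as the pathway size.
#'
#' @param query_genes character vector (must be contained in the
#'   universe after case-folding).
#' @param pathways data.frame from [read_gmt()] (or with the same
#'   columns).
#' @param universe character vector of background gene ids.
#' @return data.frame with `name`, `total`, `hits`, `hit_genes`
#'   (comma-separated), `pvalue`, `adjusted_p`.
#' @export
enrich_all <- function(query_genes, pathways, universe) {
  if (nrow(pathways) == 0)
    return(data.frame(name = character(), total = numeric(),
                      hits = numeric(), hit_genes = character(),
                      pvalue = numeric(), adjusted_p = numeric(),
                      stringsAsFactors = FALSE))
  query <- unique(toupper(query_genes))
  uni <- unique(toupper(universe))
  missing <- setdiff(query, uni)
  if (length(missing))
    stop("enrich_all: query gene(s) not in universe: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  res <- lapply(seq_len(nrow(pathways)), function(i) {
    ov <- overlap_genes(query, pathways$members[[i]])
    p <- hypergeom_test(ov$hits, length(query),
                        min(pathways$total[i], length(uni)), length(uni))
    data.frame(name = pathways$name[i], total = pathways$total[i],
               hits = ov$hits,
               hit_genes = paste(ov$hit_genes, collapse = ","),
               pvalue = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$adjusted_p <- adjust_fdr(res$pvalue)
  res <- res[order(res$pvalue, res$name), , drop = FALSE]
  rownames(res) <- NULL
  res
}
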