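#' Configuration for a full screening run
#'
#' Every analysis parameter defaults to the value documented in its stage's
#' help page; the simulation block defaults to the reference design of
#' [sim_config()].
#'
#' @param seed run seed (also the simulation seed when `sim` is NULL).
#' @param out_dir output directory for all stage files.
#' @param sim a [sim_config()], or NULL to build one from `seed`.
#' @param input_dir read an existing dataset (FASTA/GFF3/BED/truth) instead
#'   of simulating; truth is optional there.
#' @param ext_len read extension length (bp).
#' @param min_depth,p_threshold,merge_gap,local_halfwidth,pseudocount peak
#'   caller settings, see [call_peaks()].
#' @param fdr_cut DEP FDR cutoff.
#' @param promoter_halfwidth,upstream_extent annotation windows (bp).
#' @param scan_strands,scan_window HRE screen settings, see
#'   [screen_candidates()].
#' @param function_table optional path to a gene-function keep table.
#' @param gmt optional path to a GMT pathway collection.
#' @param universe `"annotation"` (all genes in the run's annotation) or a
#'   path to a one-column gene list.
#' @return a `run_config` list.
#' @export
run_config <- function(seed, out_dir, sim = NULL, input_dir = NULL,
                       ext_len = 250, min_depth = 5, p_threshold = 1e-4,
                       merge_gap = 100, local_halfwidth = 5000,
                       pseudocount = 0.25, fdr_cut = 0.05,
                       promoter_halfwidth = 2000, upstream_extent = 10000,
                       scan_strands = "both", scan_window = "region",
                       function_table = NULL, gmt = NULL,
                       universe = "annotation") {
  if (is.null(sim) && is.null(input_dir)) sim <- sim_config(seed = seed)
  cfg <- list(seed = as.numeric(seed), out_dir = out_dir, sim = sim,
              input_dir = input_dir, ext_len = as.numeric(ext_len),
              min_depth = as.numeric(min_depth),
              p_threshold = as.numeric(p_threshold),
              merge_gap = as.numeric(merge_gap),
              local_halfwidth = as.numeric(local_halfwidth),
              pseudocount = as.numeric(pseudocount),
              fdr_cut = as.numeric(fdr_cut),
              promoter_halfwidth = as.numeric(promoter_halfwidth),
              upstream_extent = as.numeric(upstream_extent),
              scan_strands = scan_strands, scan_window = scan_window,
              function_table = function_table, gmt = gmt,
              universe = universe)
  class(cfg) <- "run_config"
  cfg
}

#' Serialize / restore a run configuration
#'
#' JSON round trip: `read_run_config(write_run_config(cfg, path))` is
#' identical to `cfg`.
#'
#' @param config a `run_config`.
#' @param path JSON file path.
#' @return `path` (write) / the restored `run_config` (read).
#' @export
write_run_config <- function(config, path) {
  raw <- unclass(config)
  if (!is.null(raw$sim)) raw$sim <- unclass(raw$sim)
  jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim <- NULL
  if (!is.null(raw$sim)) {
    sim_args <- raw$sim
    sim_args$background_rate <- NULL  # re-derived by sim_config
    sim <- do.call(sim_config, sim_args)
    sim$background_rate <- raw$sim$background_rate
  }
  args <- raw
  args$sim <- sim
  do.call(run_config, args)
}

# deterministic digest of a config; excludes the output location so that
# identical analyses into different directories share a hash
.config_hash <- function(config) {
  x <- unclass(config)
  x$out_dir <- NULL
  if (!is.null(x$sim)) x$sim <- unclass(x$sim)
  tf <- tempfile(fileext = ".txt")
  on.exit(unlink(tf))
  dput(x, file = tf,
       control = c("keepNA", "keepInteger", "showAttributes", "hexNumeric"))
  unname(tools::md5sum(tf))
}

#' Run the whole screening pipeline
#'
#' simulate (or load) -> extend/coverage -> peak calling on the pooled IP
#' coverage -> per-condition counting and exact-binomial differential test
#' -> BH correction and DEP selection -> five-way annotation -> HRE screen
#' of down-regulated promoter DEPs -> optional function filter and pathway
#' enrichment. All stage outputs are written under `config$out_dir`; a
#' machine-readable summary (JSON) is written and returned. Reruns with an
#' identical configuration are byte-identical.
#'
#' @param config a [run_config()].
#' @return a `run_summary` list: stage `counts`, truth `metrics` (when
#'   planted truth is available), `files` manifest, `config_hash`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  files <- character()

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- data ---------------------------------------------------------
  if (!is.null(config$input_dir)) {
    ds <- stage("load", read_dataset(config$input_dir))
    genome <- ds$genome; genes <- ds$genes; reads <- ds$reads
    truth <- ds$truth
  } else {
    genome <- stage("genome", generate_genome(config$sim))
    genes <- stage("genes", generate_genes(genome, config$sim))
    planted <- stage("plant", plant_hre(genome, genes, config$sim))
    genome <- planted$genome; truth <- planted$truth
    reads <- stage("reads", simulate_reads(genome, genes, truth,
                                           config$sim))
    files <- c(files, stage("write",
                            write_dataset(genome, genes, reads, truth,
                                          file.path(out, "data"))))
  }

  # --- coverage and peaks ------------------------------------------
  frags <- stage("extend", extend_reads(reads, config$ext_len, genome))
  ip <- frags[frags$sample == "IP", , drop = FALSE]
  inp <- frags[frags$sample == "input", , drop = FALSE]
  cov_ip <- stage("coverage", compute_coverage(ip, genome))
  cov_in <- stage("coverage", compute_coverage(inp, genome))
  peaks <- stage("peaks", call_peaks(
    cov_ip, cov_in, min_depth = config$min_depth,
    p_threshold = config$p_threshold, merge_gap = config$merge_gap,
    local_halfwidth = config$local_halfwidth,
    pseudocount = config$pseudocount))
  files["peaks_bed"] <- file.path(out, "peaks.bed")
  write_peaks_bed(peaks, files[["peaks_bed"]])
  files["peaks_tsv"] <- .write_tsv(peaks, file.path(out, "peaks.tsv"))

  # --- differential -------------------------------------------------
  by_cond <- list(control = ip[ip$condition == "control", , drop = FALSE],
                  exposed = ip[ip$condition == "exposed", , drop = FALSE])
  counts <- stage("counts", count_in_regions(peaks, by_cond))
  scale_ratio <- if (counts$lib_sizes[["control"]] > 0)
    counts$lib_sizes[["exposed"]] / counts$lib_sizes[["control"]] else 1
  dt <- stage("difftest", test_differential(counts$raw[, "control"],
                                            counts$raw[, "exposed"],
                                            scale_ratio))
  diff <- peaks
  names(diff)[names(diff) == "pvalue"] <- "peak_pvalue"
  diff$count_control <- counts$raw[, "control"]
  diff$count_exposed <- counts$raw[, "exposed"]
  diff$signed_fold <- dt$signed_fold
  diff$pvalue <- dt$pvalue
  diff$fdr <- adjust_fdr(dt$pvalue)
  deps <- select_deps(diff, config$fdr_cut)
  files["differential"] <- .write_tsv(diff, file.path(out,
                                                      "differential.tsv"))

  # --- annotation ---------------------------------------------------
  index <- stage("annotate", build_feature_index(
    genes, chrom_lengths(genome),
    promoter_halfwidth = config$promoter_halfwidth,
    upstream_extent = config$upstream_extent))
  annotated <- stage("annotate", classify_regions(diff, index))
  files["annotated"] <- .write_tsv(annotated,
                                   file.path(out, "annotated_peaks.tsv"))
  files["categories"] <- .write_tsv(category_summary(annotated),
                                    file.path(out, "category_summary.tsv"))
  prom_down <- stage("promoter_deps", promoter_deps(deps$down, index))
  prom_up <- stage("promoter_deps", promoter_deps(deps$up, index))
  files["promoter_deps"] <- .write_tsv(
    rbind(prom_down, prom_up), file.path(out, "promoter_deps.tsv"))

  # --- HRE screen ---------------------------------------------------
  screened <- stage("screen", screen_candidates(
    prom_down, genome, strands = config$scan_strands,
    window = config$scan_window,
    promoter_halfwidth = config$promoter_halfwidth))
  candidates <- screened$candidates
  files["candidates"] <- .write_tsv(candidates,
                                    file.path(out, "candidates.tsv"))
  files["rejected"] <- .write_tsv(screened$rejected,
                                  file.path(out, "screen_rejected.tsv"))
  kept <- candidates
  if (!is.null(config$function_table)) {
    kept <- stage("function_filter",
                  apply_function_filter(candidates, config$function_table))
    files["function_kept"] <- .write_tsv(kept,
                                         file.path(out,
                                                   "function_kept.tsv"))
  }

  # --- enrichment (optional) ---------------------------------------
  enr <- NULL
  if (!is.null(config$gmt)) {
    pathways <- stage("enrich", read_gmt(config$gmt))
    uni <- if (identical(config$universe, "annotation")) genes$gene_id
      else utils::read.delim(config$universe,
                             stringsAsFactors = FALSE)$gene_id
    enr <- stage("enrich", enrich_all(kept$gene_id, pathways, uni))
    files["enrichment"] <- .write_tsv(enr,
                                      file.path(out, "enrichment.tsv"))
  }

  # --- summary ------------------------------------------------------
  metrics <- NULL
  if (!is.null(truth)) {
    truth_genes <- truth$gene_id[if ("has_hre" %in% names(truth))
      as.logical(truth$has_hre) else rep(TRUE, nrow(truth))]
    metrics <- evaluate_against_truth(candidates$gene_id, truth_genes)
  }
  # manifest paths relative to the output directory
  files <- sub(paste0(normalizePath(out, winslash = "/"), "/"), "",
               vapply(files, function(f)
                 normalizePath(f, winslash = "/", mustWork = FALSE), ""),
               fixed = TRUE)
  summary <- list(
    counts = list(
      n_reads = nrow(reads), n_peaks = nrow(peaks),
      dep_up = nrow(deps$up), dep_down = nrow(deps$down),
      promoter_dep_up = nrow(prom_up), promoter_dep_down = nrow(prom_down),
      hre_positive = nrow(candidates), function_kept = nrow(kept),
      enriched_pathways = if (is.null(enr)) 0
        else sum(enr$adjusted_p < 0.05)),
    metrics = metrics,
    files = as.list(files),
    config_hash = .config_hash(config),
    seed = config$seed)
  class(summary) <- "run_summary"
  jsonlite::write_json(unclass(summary), file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  summary
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Compare a candidate gene list against planted truth
#'
#' @param candidate_genes reported candidate gene ids.
#' @param truth_genes planted target gene ids.
#' @return list with `sensitivity` (recovered / planted) and `precision`
#'   (recovered / reported; `NaN` when nothing was reported).
#' @export
evaluate_against_truth <- function(candidate_genes, truth_genes) {
  cand <- unique(candidate_genes)
  tr <- unique(truth_genes)
  recovered <- length(intersect(cand, tr))
  list(sensitivity = if (length(tr)) recovered / length(tr) else NaN,
       precision = if (length(cand)) recovered / length(cand) else NaN,
       n_candidates = length(cand), n_truth = length(tr),
       n_recovered = recovered)
}

#' @export
print.run_summary <- function(x, ...) {
  c1 <- x$counts
  cat("run_summary: ", c1$n_peaks, " peaks; DEPs up/down ", c1$dep_up,
      "/", c1$dep_down, "; promoter down ", c1$promoter_dep_down,
      "; HRE-positive ", c1$hre_positive, "; kept ", c1$function_kept,
      "\n", sep = "")
  if (!is.null(x$metrics))
    cat("  vs truth: sensitivity ", round(x$metrics$sensitivity, 3),
        ", precision ", round(x$metrics$precision, 3), "\n", sep = "")
  invisible(x)
}
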