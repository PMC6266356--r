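#' Relative expression by the 2^-ddCt (Livak) method
#'
#' Per replicate, `dCt = ct_target - ct_reference`; `ddCt` anchors each
#' replicate of the test group to the *mean* control-group dCt; the
#' per-replicate folds `2^-ddCt` are then averaged.
#'
#' @param records Ct table with columns `gene_id`, `group`, `replicate`,
#'   `ct_target`, `ct_reference`.
#' @param gene gene to evaluate.
#' @param group test group.
#' @param control_group reference group (default `"C"`).
#' @return list with `gene_id`, `group`, `mean_fold`, `sd_fold`, `n`.
#' @export
delta_delta_ct <- function(records, gene, group, control_group = "C") {
  r <- records[records$gene_id == gene, , drop = FALSE]
  ctrl <- r[r$group == control_group, , drop = FALSE]
  if (nrow(ctrl) == 0)
    stop("delta_delta_ct: no control-group records for ", gene,
         call. = FALSE)
  tst <- r[r$group == group, , drop = FALSE]
  if (nrow(tst) == 0)
    stop("delta_delta_ct: no records for gene ", gene, " group ", group,
         call. = FALSE)
  dct_ctrl <- ctrl$ct_target - ctrl$ct_reference
  dct <- tst$ct_target - tst$ct_reference
  ddct <- dct - mean(dct_ctrl)
  folds <- 2^(-ddct)
  list(gene_id = gene, group = group, mean_fold = mean(folds),
       sd_fold = stats::sd(folds), n = length(folds))
}

#' One-way ANOVA over groups of dCt values
#'
#' Standard between/within sum-of-squares decomposition via
#' [stats::aov()].
#'
#' @param groups named list of numeric vectors (>= 2 groups, each >= 2
#'   values).
#' @return list with `F`, `p`, `mse` (pooled within-group mean square),
#'   `df_within`, `means`, `n`, and `degenerate` (TRUE when the
#'   within-group variance is zero everywhere).
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2 || any(vapply(groups, length, 0) < 2))
    stop("one_way_anova: need >= 2 groups with >= 2 values each",
         call. = FALSE)
  df <- data.frame(value = unlist(groups, use.names = FALSE),
                   grp = factor(rep(names(groups),
                                    vapply(groups, length, 0))))
  # a zero-residual fit makes anova() warn; the degenerate flag below
  # reports that case explicitly
  an <- suppressWarnings(stats::anova(stats::aov(value ~ grp, data = df)))
  mse <- an[["Mean Sq"]][2]
  degenerate <- mse <= .Machine$double.eps * max(abs(df$value), 1)
  Fv <- an[["F value"]][1]
  p <- an[["Pr(>F)"]][1]
  if (degenerate) {
    between <- an[["Mean Sq"]][1]
    if (between > 0) { Fv <- Inf; p <- 0 } else { Fv <- 0; p <- 1 }
  }
  list(F = Fv, p = p, mse = mse, df_within = an[["Df"]][2],
       means = vapply(groups, mean, 0),
       n = vapply(groups, length, 0), degenerate = degenerate)
}

#' LSD (least significant difference) post-hoc test against control
#'
#' Two-sided t-test of each non-control group mean against the control
#' mean, using the pooled within-group mean square error and its degrees
#' of freedom from the one-way ANOVA.
#'
#' @param groups named list of numeric vectors including the control.
#' @param control_group name of the control group.
#' @return named vector of p-values, one per non-control group.
#' @export
lsd_posthoc <- function(groups, control_group = "C") {
  if (!control_group %in% names(groups))
    stop("lsd_posthoc: control group absent", call. = FALSE)
  a <- one_way_anova(groups)
  others <- setdiff(names(groups), control_group)
  m_c <- a$means[[control_group]]
  n_c <- a$n[[control_group]]
  p <- vapply(others, function(gname) {
    if (a$degenerate) {
      return(if (a$means[[gname]] == m_c) 1 else 0)
    }
    tval <- (a$means[[gname]] - m_c) /
      sqrt(a$mse * (1 / a$n[[gname]] + 1 / n_c))
    2 * stats::pt(-abs(tval), a$df_within)
  }, 0)
  stats::setNames(p, others)
}

#' Star tier for a p-value
#'
#' `***` below 0.001, `**` below 0.01, `*` below 0.05, otherwise empty --
#' all strict inequalities.
#'
#' @param p vector of p-values.
#' @return character vector of star tiers.
#' @export
assign_stars <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*",
                                                         "")))
}

#' Full relative-expression validation table
#'
#' For every gene: 2^-ddCt fold per non-control group, one-way ANOVA over
#' all group dCt values, LSD p-value versus control and its star tier.
#'
#' @param records Ct table (see [delta_delta_ct()]).
#' @param control_group control group name.
#' @return data.frame with one row per (gene, non-control group):
#'   `gene_id`, `group`, `mean_fold`, `sd_fold`, `n`, `anova_p`,
#'   `p_vs_control`, `stars`.
#' @export
relative_expression <- function(records, control_group = "C") {
  rows <- list()
  for (gene in unique(records$gene_id)) {
    r <- records[records$gene_id == gene, , drop = FALSE]
    dct <- r$ct_target - r$ct_reference
    groups <- split(dct, r$group)
    a <- one_way_anova(groups)
    lsd <- lsd_posthoc(groups, control_group)
    for (gname in setdiff(names(groups), control_group)) {
      f <- delta_delta_ct(records, gene, gname, control_group)
      rows[[length(rows) + 1]] <- data.frame(
        gene_id = gene, group = gname, mean_fold = f$mean_fold,
        sd_fold = f$sd_fold, n = f$n, anova_p = a$p,
        p_vs_control = lsd[[gname]],
        stars = assign_stars(lsd[[gname]]), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Count validated genes in a relative-expression table
#'
#' A gene is validated when, in at least one dose group, its mean fold is
#' below 1 *and* the significance tier is non-empty.
#'
#' @param validation_table long-format table with `gene_id`, `mean_fold`,
#'   `stars`.
#' @return integer count of validated genes.
#' @export
count_validated <- function(validation_table) {
  hit <- validation_table$mean_fold < 1 &
    validation_table$stars != ""
  length(unique(validation_table$gene_id[hit]))
}

#' Simulate qPCR Ct records with known true folds
#'
#' The control group has a baseline dCt; each test group's true dCt is
#' shifted by `-log2(fold)` so that the expected 2^-ddCt equals `fold`.
#' Gaussian noise of `ct_sd` cycles is added independently to target and
#' reference Ct values.
#'
#' @param true_folds named vector of true folds per test group.
#' @param n replicates per group.
#' @param ct_sd Ct noise, in cycles.
#' @param seed RNG seed.
#' @param gene_id gene label.
#' @param control_group control group name.
#' @param base_ct_target,base_ct_reference baseline Ct values.
#' @return a Ct record data.frame (see [delta_delta_ct()]).
#' @export
simulate_ct_data <- function(true_folds, n = 6, ct_sd = 0.1, seed = 1,
                             gene_id = "GENE", control_group = "C",
                             base_ct_target = 26, base_ct_reference = 17) {
  set.seed(seed)
  groups <- c(stats::setNames(0, control_group), -log2(true_folds))
  rows <- lapply(names(groups), function(gname) {
    data.frame(gene_id = gene_id, group = gname, replicate = seq_len(n),
               ct_target = base_ct_target + groups[[gname]] +
                 stats::rnorm(n, 0, ct_sd),
               ct_reference = base_ct_reference + stats::rnorm(n, 0, ct_sd),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
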