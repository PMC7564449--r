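# Filtering / normalization chain.
#
# Fixed stage order (re-running on filtered output is a no-op):
#   mRNA-side counts: outliers -> normalize -> quantile -> dominance
#   miRNA RPM:        rpm floor (-> log2(RPM+1)) -> dominance

filter_report <- function(stage, ids_in, ids_out, axis = c("genes", "samples")) {
  axis <- match.arg(axis)
  removed <- setdiff(ids_in, ids_out)
  tibble::tibble(stage = stage, axis = axis,
                 n_in = length(ids_in), n_out = length(ids_out),
                 removed_ids = list(removed))
}

#' Remove outlier samples by mean inter-sample correlation
#'
#' A sample is dropped when its mean Spearman correlation with all other
#' samples, computed on `log2(count + 1)`, falls strictly below `cor_cut`.
#'
#' @param expr A [cw_expr()] with unit `raw_count` or `normalized_count`.
#' @param cor_cut Correlation threshold (default 0.6).
#' @return A list with elements `expr` and `report` (a one-row tibble).
#' @export
remove_outlier_samples <- function(expr, cor_cut = 0.6) {
  stopifnot(inherits(expr, "cw_expr"))
  if (ncol(expr$values) < 3) stop("need at least 3 samples", call. = FALSE)
  if (is_log_unit(expr$unit)) stop("expected a count-scale unit", call. = FALSE)
  lv <- log2(expr$values + 1)
  cm <- suppressWarnings(stats::cor(lv, method = "spearman"))
  diag(cm) <- NA
  mean_cor <- rowMeans(cm, na.rm = TRUE)
  keep <- sample_ids(expr)[!(mean_cor < cor_cut) | is.na(mean_cor)]
  if (length(keep) == 0) {
    stop("degenerate cohort: every sample falls below cor_cut", call. = FALSE)
  }
  out <- expr_subset(expr, samples = keep)
  rep <- filter_report("outlier_samples", sample_ids(expr), keep, "samples")
  cw_log("outlier_samples", in_ = ncol(expr$values), out = length(keep))
  list(expr = out, report = rep)
}

#' Two-step count normalization
#'
#' Each sample is first scaled so its library equals the median input
#' library; a residual median-of-ratios correction (computed over genes
#' expressed in every sample, against their per-gene geometric means) then
#' absorbs composition differences that library totals miss. The second
#' step is composition-robust: a handful of strongly shifted genes cannot
#' drag the factor, which matters on the few-hundred-gene panels this
#' pipeline typically works with. Unit becomes `normalized_count`; zero
#' rows survive; proportional samples come out identical.
#'
#' @param expr A [cw_expr()] with unit `raw_count`.
#' @return A [cw_expr()] with unit `normalized_count`.
#' @export
normalize_counts <- function(expr) {
  stopifnot(inherits(expr, "cw_expr"))
  if (expr$unit != "raw_count") stop("expected raw counts", call. = FALSE)
  libs <- colSums(expr$values)
  zero <- names(libs)[libs == 0]
  if (length(zero) > 0) {
    stop("sample(s) with all-zero counts: ", paste(zero, collapse = ", "),
         call. = FALSE)
  }
  v <- sweep(expr$values, 2, stats::median(libs) / libs, `*`)
  pos <- rowSums(v > 0) == ncol(v)
  if (sum(pos) >= 10 && ncol(v) > 1) {
    logv <- log(v[pos, , drop = FALSE])
    ratio <- logv - rowMeans(logv)
    f <- exp(apply(ratio, 2, stats::median))
    f <- f / exp(mean(log(f)))          # factors multiply to one
    v <- sweep(v, 2, f, `/`)
  }
  cw_expr(v, "normalized_count", expr$biotype)
}

#' Filter lowly expressed miRNAs and move to log2(RPM + 1)
#'
#' miRNAs whose overall mean RPM is strictly below `rpm_floor` are removed
#' ("less than" the floor; a mean exactly at the floor is retained), then
#' surviving values are transformed `x -> log2(x + 1)`.
#'
#' @param expr A [cw_expr()] with unit `rpm`.
#' @param rpm_floor Mean-RPM floor (default 3).
#' @return A list with elements `expr` (unit `log2_rpm_plus1`) and `report`.
#' @export
filter_low_mirna <- function(expr, rpm_floor = 3) {
  stopifnot(inherits(expr, "cw_expr"))
  if (expr$unit != "rpm") stop("expected RPM unit", call. = FALSE)
  keep <- gene_ids(expr)[!(rowMeans(expr$values) < rpm_floor)]
  out <- expr_subset(expr, genes = keep)
  out <- cw_expr(log2(out$values + 1), "log2_rpm_plus1", out$biotype)
  rep <- filter_report("rpm_floor", gene_ids(expr), keep, "genes")
  cw_log("rpm_floor", in_ = nrow(expr$values), out = length(keep))
  list(expr = out, report = rep)
}

#' One-third dominance exclusion
#'
#' Removes genes for which a single patient's expression exceeds one third
#' of that gene's total across patients (`mode = "per_gene"`, the reading
#' implemented by default). `mode = "grand_total"` instead compares against
#' one third of the whole matrix total, the alternative reading of the same
#' rule; neither is asserted as the original authors' intent.
#'
#' @param expr A [cw_expr()] of any unit.
#' @param mode `"per_gene"` or `"grand_total"`.
#' @return A list with elements `expr` and `report`.
#' @export
apply_dominance_filter <- function(expr, mode = c("per_gene", "grand_total")) {
  stopifnot(inherits(expr, "cw_expr"))
  mode <- match.arg(mode)
  mx <- apply(expr$values, 1, max)
  lim <- if (mode == "per_gene") rowSums(expr$values) / 3
         else sum(expr$values) / 3
  keep <- gene_ids(expr)[!(mx > lim)]
  out <- expr_subset(expr, genes = keep)
  rep <- filter_report("dominance", gene_ids(expr), keep, "genes")
  cw_log("dominance", in_ = nrow(expr$values), out = length(keep))
  list(expr = out, report = rep)
}

#' Quantile filter on gene means
#'
#' Removes the genes sitting below the `q`-th quantile of gene means,
#' under the empirical-rank convention: the `floor(q * n_genes)`
#' lowest-mean genes are dropped (so `q -> 0` removes nothing and ties at
#' the cut shift the count by at most one).
#'
#' @param expr A [cw_expr()].
#' @param q Quantile in (0,1); default 0.25.
#' @return A list with elements `expr` and `report`.
#' @export
filter_quantile <- function(expr, q = 0.25) {
  stopifnot(inherits(expr, "cw_expr"), q > 0, q < 1)
  means <- rowMeans(expr$values)
  n_drop <- floor(q * length(means))
  drop <- utils::head(gene_ids(expr)[order(means, gene_ids(expr))], n_drop)
  keep <- setdiff(gene_ids(expr), drop)
  out <- expr_subset(expr, genes = keep)
  rep <- filter_report("quantile", gene_ids(expr), keep, "genes")
  cw_log("quantile", in_ = nrow(expr$values), out = length(keep))
  list(expr = out, report = rep)
}

#' Full preprocessing chains
#'
#' `preprocess_mrna()` runs outlier removal, normalization, the quantile
#' filter and the dominance rule on a raw count matrix;
#' `preprocess_mirna()` runs the mean-RPM floor (with log2 transform) and
#' the dominance rule on a miRNA RPM matrix.
#'
#' @param expr A [cw_expr()] (`raw_count` for mRNA-side, `rpm` for miRNA).
#' @param config A [cerna_config()].
#' @return A list with elements `expr` and `reports` (tibble of all stages).
#' @export
preprocess_mrna <- function(expr, config = cerna_config()) {
  s1 <- remove_outlier_samples(expr, config$cor_cut)
  e2 <- normalize_counts(s1$expr)
  s3 <- filter_quantile(e2, config$quantile_cut)
  s4 <- apply_dominance_filter(s3$expr, config$dominance_mode)
  list(expr = s4$expr,
       reports = dplyr::bind_rows(s1$report, s3$report, s4$report))
}

#' @rdname preprocess_mrna
#' @export
preprocess_mirna <- function(expr, config = cerna_config()) {
  s1 <- filter_low_mirna(expr, config$rpm_floor)
  s2 <- apply_dominance_filter(s1$expr, config$dominance_mode)
  list(expr = s2$expr, reports = dplyr::bind_rows(s1$report, s2$report))
}
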