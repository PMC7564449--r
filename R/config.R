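#' Pipeline run configuration
#'
#' Collects every tunable of the pipeline with its default. Defaults follow
#' the published analysis settings: sample-correlation outlier cut 0.6,
#' miRNA mean-RPM floor 3, |log2FC| > 1 and FDR < 0.05 for differential
#' calls, soft-threshold power 4, minimum module size 15, eigengene merge
#' cutoff 0.3, ARI retention threshold 0.6 (strict), ceRNA-miRNA Pearson
#' ceiling -0.3 (strict), and k = 2 clusters for the oligodendroglioma-style
#' two-subgroup cohort (k = 3 for a three-subgroup lower-grade-glioma-style
#' cohort).
#'
#' @param cor_cut Mean inter-sample Spearman correlation below which a
#'   sample is dropped as an outlier.
#' @param rpm_floor miRNAs with overall mean RPM strictly below this are
#'   removed before the log2(RPM+1) transform.
#' @param quantile_cut Quantile of gene means below which genes are
#'   filtered (toolchain default 0.25).
#' @param lfc_threshold,fdr_threshold Differential-expression call
#'   thresholds (strict `>` / strict `<`).
#' @param beta Soft-threshold power for the signed adjacency, or `"auto"`
#'   to pick the smallest power with scale-free fit R^2 >= 0.8.
#' @param min_module_size Minimum dynamic-tree-cut module size.
#' @param merge_cut Eigengene dissimilarity (1 - cor) below which modules
#'   are merged.
#' @param ari_threshold Networks with ARI strictly above this are retained.
#' @param k_clusters Number of Ward clusters used for ARI evaluation.
#' @param cerna_corr_max Pearson correlation ceiling (strict `<`) for
#'   miRNA-ceRNA survival candidate pairs.
#' @param interaction_rule How multiple interaction tables are combined:
#'   `"union"` (default), `"intersection"`, or `"min_sources"`.
#' @param min_sources Minimum distinct source databases when
#'   `interaction_rule = "min_sources"`.
#' @param dominance_mode `"per_gene"` (default): a gene is removed when one
#'   sample exceeds one third of that gene's cross-sample total;
#'   `"grand_total"`: the alternative reading against the cohort-wide total.
#' @param scale_before_ward Z-score genes before Ward clustering.
#' @param include_ncrna_in_ari Include ncRNA members when clustering for
#'   ARI (default `FALSE`: coding genes only).
#' @param rng_seed Integer seed from which all pipeline randomness flows.
#'
#' @return A list of class `cw_config`.
#' @export
cerna_config <- function(cor_cut = 0.6,
                         rpm_floor = 3,
                         quantile_cut = 0.25,
                         lfc_threshold = 1,
                         fdr_threshold = 0.05,
                         beta = 4,
                         min_module_size = 15,
                         merge_cut = 0.3,
                         ari_threshold = 0.6,
                         k_clusters = 2,
                         cerna_corr_max = -0.3,
                         interaction_rule = c("union", "intersection",
                                              "min_sources"),
                         min_sources = 2,
                         dominance_mode = c("per_gene", "grand_total"),
                         scale_before_ward = TRUE,
                         include_ncrna_in_ari = FALSE,
                         rng_seed = 1L) {
  cfg <- list(
    cor_cut = cor_cut, rpm_floor = rpm_floor, quantile_cut = quantile_cut,
    lfc_threshold = lfc_threshold, fdr_threshold = fdr_threshold,
    beta = beta, min_module_size = min_module_size, merge_cut = merge_cut,
    ari_threshold = ari_threshold, k_clusters = k_clusters,
    cerna_corr_max = cerna_corr_max,
    interaction_rule = match.arg(interaction_rule),
    min_sources = min_sources,
    dominance_mode = match.arg(dominance_mode),
    scale_before_ward = isTRUE(scale_before_ward),
    include_ncrna_in_ari = isTRUE(include_ncrna_in_ari),
    rng_seed = as.integer(rng_seed))
  class(cfg) <- "cw_config"
  validate_config(cfg)
}

#' @rdname cerna_config
#' @param cfg A `cw_config` object.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "cw_config"))
  chk <- function(ok, what) if (!ok) stop("invalid config: ", what, call. = FALSE)
  chk(cfg$cor_cut >= 0 && cfg$cor_cut <= 1, "cor_cut must be in [0,1]")
  chk(cfg$rpm_floor >= 0, "rpm_floor must be >= 0")
  chk(cfg$quantile_cut > 0 && cfg$quantile_cut < 1,
      "quantile_cut must be in (0,1)")
  chk(cfg$lfc_threshold >= 0, "lfc_threshold must be >= 0")
  chk(cfg$fdr_threshold > 0 && cfg$fdr_threshold <= 1,
      "fdr_threshold must be in (0,1]")
  chk(identical(cfg$beta, "auto") ||
        (is.numeric(cfg$beta) && cfg$beta >= 1 && cfg$beta <= 30),
      "beta must be 'auto' or a power in [1,30]")
  chk(cfg$min_module_size >= 2, "min_module_size must be >= 2")
  chk(cfg$merge_cut >= 0 && cfg$merge_cut <= 1, "merge_cut must be in [0,1]")
  chk(cfg$k_clusters >= 2, "k_clusters must be >= 2")
  chk(cfg$cerna_corr_max <= 0, "cerna_corr_max must be <= 0")
  chk(cfg$min_sources >= 1, "min_sources must be >= 1")
  chk(is.finite(cfg$rng_seed), "rng_seed must be an integer")
  invisible(cfg)
}

#' Write / read a run configuration as YAML
#'
#' @param cfg A `cw_config` object.
#' @param path File path.
#' @return `write_config()` returns `path` invisibly; `read_config()`
#'   returns a validated `cw_config`.
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(cerna_config, raw)
}

#' @export
print.cw_config <- function(x, ...) {
  cat("<cw_config>\n")
  for (k in names(x)) cat("  ", k, ": ", as.character(x[[k]]), "\n", sep = "")
  invisible(x)
}
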