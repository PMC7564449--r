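#' Per-gene log2 fold change between two groups
#'
#' On count scales the fold change is `log2((meanA + c) / (meanB + c))`
#' with pseudocount `c = 1`; on log scales it is the plain mean difference
#' (already log2 units).
#'
#' @param expr A [cw_expr()].
#' @param groups Factor or character vector with levels/values `A`-like and
#'   `B`-like, named by sample id (or in column order). The first level is
#'   the numerator group.
#' @param pseudocount Count-scale pseudocount.
#' @return A named numeric vector of log2 fold changes (group A over B).
#' @export
compute_log2fc <- function(expr, groups, pseudocount = 1) {
  stopifnot(inherits(expr, "cw_expr"))
  groups <- align_groups(expr, groups)
  lv <- split(seq_along(groups), groups)
  if (length(lv) != 2 || any(lengths(lv) == 0)) {
    stop("need exactly two non-empty groups", call. = FALSE)
  }
  a <- rowMeans(expr$values[, lv[[1]], drop = FALSE])
  b <- rowMeans(expr$values[, lv[[2]], drop = FALSE])
  if (is_log_unit(expr$unit)) a - b
  else log2((a + pseudocount) / (b + pseudocount))
}

align_groups <- function(expr, groups) {
  sid <- sample_ids(expr)
  if (!is.null(names(groups))) {
    miss <- setdiff(sid, names(groups))
    if (length(miss) > 0) {
      stop("groups missing for sample(s): ",
           paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
    }
    groups <- groups[sid]
  } else if (length(groups) != length(sid)) {
    stop("groups must be named by sample id or match the sample count",
         call. = FALSE)
  }
  # a factor's level order defines the numerator group; otherwise first
  # occurrence wins
  if (is.factor(groups)) factor(groups, levels = levels(groups))
  else factor(groups, levels = unique(as.character(groups)))
}

#' Two-group differential expression test
#'
#' Distribution-free two-sided Wilcoxon rank-sum p-values per gene, with
#' Benjamini-Hochberg adjustment *within each biotype class* (coding,
#' lncRNA, pseudogene, miRNA are corrected separately, mirroring separate
#' analysis runs per data type). Constant genes get `p = 1` by convention.
#' Direction calls use strict thresholds: `up` iff
#' `log2fc > lfc_threshold` and `fdr < fdr_threshold`; `down` symmetric;
#' otherwise `ns`.
#'
#' @inheritParams compute_log2fc
#' @param lfc_threshold,fdr_threshold Call thresholds (strict).
#' @return A tibble with columns `gene_id`, `biotype`, `log2fc`, `p_value`,
#'   `fdr`, `direction`, of class `cw_dea`.
#' @export
differential_test <- function(expr, groups, lfc_threshold = 1,
                              fdr_threshold = 0.05) {
  stopifnot(inherits(expr, "cw_expr"))
  groups <- align_groups(expr, groups)
  lv <- split(seq_along(groups), groups)
  if (length(lv) != 2 || any(lengths(lv) < 2)) {
    stop("need two groups with >= 2 samples each", call. = FALSE)
  }
  v <- expr$values
  ia <- lv[[1]]; ib <- lv[[2]]
  pvals <- vapply(seq_len(nrow(v)), function(i) {
    x <- v[i, ia]; y <- v[i, ib]
    if (stats::var(c(x, y)) == 0) return(1)
    # exact null for small untied samples, normal approximation otherwise
    suppressWarnings(stats::wilcox.test(x, y)$p.value)
  }, numeric(1))
  res <- tibble::tibble(
    gene_id = gene_ids(expr),
    biotype = unname(expr$biotype),
    log2fc = unname(compute_log2fc(expr, groups)),
    p_value = pvals) |>
    dplyr::group_by(.data$biotype) |>
    dplyr::mutate(fdr = stats::p.adjust(.data$p_value, method = "BH")) |>
    dplyr::ungroup() |>
    dplyr::mutate(direction = dplyr::case_when(
      .data$log2fc > lfc_threshold & .data$fdr < fdr_threshold ~ "up",
      .data$log2fc < -lfc_threshold & .data$fdr < fdr_threshold ~ "down",
      TRUE ~ "ns"))
  class(res) <- c("cw_dea", class(res))
  attr(res, "thresholds") <- c(lfc = lfc_threshold, fdr = fdr_threshold)
  res
}

#' Split differential results into up/down gene sets
#'
#' @param results A `cw_dea` tibble from [differential_test()], or any
#'   data frame with `gene_id`, `log2fc`, `fdr` columns.
#' @param lfc_threshold,fdr_threshold Strict call thresholds.
#' @return A list with character vectors `up` and `down`.
#' @export
select_degs <- function(results, lfc_threshold = 1, fdr_threshold = 0.05) {
  stopifnot(is.data.frame(results))
  if (nrow(results) == 0) return(list(up = character(0), down = character(0)))
  up <- results$gene_id[results$log2fc > lfc_threshold &
                          results$fdr < fdr_threshold]
  down <- results$gene_id[results$log2fc < -lfc_threshold &
                            results$fdr < fdr_threshold]
  cw_log("select_degs", up = length(up), down = length(down),
         tested = nrow(results))
  list(up = up, down = down)
}

#' @export
glance.cw_dea <- function(x, ...) {
  tibble::tibble(n_genes = nrow(x),
                 n_up = sum(x$direction == "up"),
                 n_down = sum(x$direction == "down"),
                 n_ns = sum(x$direction == "ns"))
}

#' Volcano plot of a differential-expression result
#'
#' @param object A `cw_dea` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cw_dea <- function(object, ...) {
  thr <- attr(object, "thresholds")
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$log2fc,
                               y = -log10(pmax(.data$fdr, 1e-300)),
                               colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(up = "#c0392b", down = "#27ae60",
                                            ns = "grey60")) +
    ggplot2::geom_vline(xintercept = c(-thr[["lfc"]], thr[["lfc"]]),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "log2 fold change", y = "-log10 FDR",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
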