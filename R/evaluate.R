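#' Ward clustering of samples on a gene subset
#'
#' Agglomerative clustering (Ward linkage, `ward.D2`) of sample profiles on
#' Euclidean distances, cut at `k` clusters. Genes are z-scored first by
#' default so high-expression genes do not dominate the distances.
#'
#' @param expr A [cw_expr()] or genes x samples matrix (log2 scale is used
#'   for count units).
#' @param k Number of clusters.
#' @param scale Z-score each gene before clustering.
#' @return Integer cluster labels named by sample id.
#' @export
ward_cluster <- function(expr, k, scale = TRUE) {
  v <- if (inherits(expr, "cw_expr")) expr_log2(expr) else expr
  stopifnot(is.matrix(v))
  if (nrow(v) < 2) stop("need at least 2 genes to cluster samples",
                        call. = FALSE)
  if (ncol(v) < k) stop("fewer samples than clusters", call. = FALSE)
  if (scale) {
    sds <- apply(v, 1, stats::sd)
    v <- v[sds > 0, , drop = FALSE]
    if (nrow(v) < 2) stop("fewer than 2 non-constant genes", call. = FALSE)
    v <- t(scale(t(v)))
  }
  hc <- stats::hclust(stats::dist(t(v)), method = "ward.D2")
  stats::cutree(hc, k = k)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement computed from the contingency table:
#' `ARI = (sum_ij C(n_ij,2) - E) / (0.5 * (sum_i C(a_i,2) + sum_j C(b_j,2)) - E)`
#' with `E = sum_i C(a_i,2) * sum_j C(b_j,2) / C(n,2)`. Identical
#' partitions give 1; independent partitions give values near 0. When both
#' partitions are single clusters the denominator vanishes and 1 is
#' returned by convention (perfect, if degenerate, agreement).
#'
#' @param p1,p2 Cluster label vectors over the same samples (named vectors
#'   are aligned by name).
#' @return The ARI, a scalar in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(p1, p2) {
  if (!is.null(names(p1)) && !is.null(names(p2))) {
    if (!setequal(names(p1), names(p2))) {
      stop("partitions cover different sample sets", call. = FALSE)
    }
    p2 <- p2[names(p1)]
  } else if (length(p1) != length(p2)) {
    stop("partitions have different lengths", call. = FALSE)
  }
  n <- length(p1)
  tab <- table(p1, p2)
  sum_ij <- sum(choose(tab, 2))
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  e <- a * b / choose(n, 2)
  den <- (a + b) / 2 - e
  if (den == 0) return(1)
  (sum_ij - e) / den
}

#' Evaluate ceRNA networks by clustering concordance
#'
#' For each network, Ward-clusters the samples on the network's coding
#' targets (optionally including ncRNA targets) and scores the agreement
#' with the clinical subgroup labels by ARI. Supports several `k` at once
#' (one ARI column per `k`); retention uses the first `k` and is strict:
#' `ari > ari_threshold`.
#'
#' @param networks A `cw_networks` tibble.
#' @param expr A [cw_expr()] holding the coding/ncRNA expression.
#' @param clinical Clinical tibble with `sample_id` and `subgroup`.
#' @param k Integer vector of cluster counts (first entry drives
#'   retention).
#' @param ari_threshold Strict retention threshold (default 0.6).
#' @param scale,include_ncrna Passed to the clustering step.
#' @return A tibble of class `cw_evaluation`, one row per network, sorted
#'   by ARI descending: `network_id`, `mirna_id`, `n_coding`, `n_nc`,
#'   `ari_k<k>` columns, `ari`, `retained`.
#' @export
evaluate_networks <- function(networks, expr, clinical, k = 2,
                              ari_threshold = 0.6, scale = TRUE,
                              include_ncrna = FALSE) {
  stopifnot(is.data.frame(networks), inherits(expr, "cw_expr"))
  validate_clinical(clinical)
  truth <- stats::setNames(clinical$subgroup, clinical$sample_id)
  miss <- setdiff(sample_ids(expr), names(truth))
  if (length(miss) > 0) {
    stop("clinical subgroup missing for sample(s): ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  }
  truth <- truth[sample_ids(expr)]
  res <- purrr::pmap_dfr(networks, function(network_id, mirna_id,
                                            coding_targets, nc_targets,
                                            n_coding, n_nc, ...) {
    genes <- if (include_ncrna) c(coding_targets, nc_targets)
             else coding_targets
    genes <- intersect(genes, gene_ids(expr))
    row <- tibble::tibble(network_id = network_id, mirna_id = mirna_id,
                          n_coding = n_coding, n_nc = n_nc)
    for (kk in k) {
      ari <- if (length(genes) < 2) NA_real_ else {
        part <- ward_cluster(expr_subset(expr, genes = genes), kk,
                             scale = scale)
        adjusted_rand_index(part, truth)
      }
      row[[paste0("ari_k", kk)]] <- ari
    }
    row
  })
  res$ari <- res[[paste0("ari_k", k[1])]]
  res$retained <- !is.na(res$ari) & res$ari > ari_threshold
  res <- dplyr::arrange(res, dplyr::desc(.data$ari))
  class(res) <- c("cw_evaluation", class(res))
  attr(res, "ari_threshold") <- ari_threshold
  cw_log("evaluate", networks = nrow(res), retained = sum(res$retained))
  res
}

#' @export
glance.cw_evaluation <- function(x, ...) {
  tibble::tibble(n_networks = nrow(x), n_retained = sum(x$retained),
                 best_ari = if (nrow(x) > 0) max(x$ari, na.rm = TRUE) else
                   NA_real_)
}

#' ARI-per-network plot
#'
#' @param object A `cw_evaluation` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cw_evaluation <- function(object, ...) {
  thr <- attr(object, "ari_threshold")
  ggplot2::ggplot(object,
                  ggplot2::aes(x = stats::reorder(.data$network_id, .data$ari),
                               y = .data$ari, fill = .data$retained)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "adjusted Rand index", fill = "retained") +
    ggplot2::theme_minimal()
}
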