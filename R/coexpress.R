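# Signed weighted co-expression: soft-thresholded adjacency, topological
# overlap, average-linkage dendrogram with a tree-variant dynamic cut,
# module eigengenes, eigengene merging, module-trait correlation.

#' Signed soft-thresholded adjacency
#'
#' Pairwise Pearson correlation of gene profiles mapped through
#' `a_ij = (0.5 * (1 + cor(i, j)))^beta`, so perfectly anti-correlated
#' genes get weight 0, uncorrelated genes 0.5^beta, and perfectly
#' correlated genes 1. Constant genes are dropped with a warning.
#'
#' @param expr A [cw_expr()] (correlations are computed on the log2 scale
#'   for count units) or a plain genes x samples matrix.
#' @param beta Soft-threshold power.
#' @return A list of class `cw_adjacency` with elements `values`
#'   (symmetric matrix in `[0,1]`, unit diagonal) and `beta`.
#' @export
signed_adjacency <- function(expr, beta = 4) {
  v <- if (inherits(expr, "cw_expr")) expr_log2(expr) else expr
  stopifnot(is.matrix(v), is.numeric(beta), beta >= 1)
  if (ncol(v) < 3) stop("need at least 3 samples", call. = FALSE)
  sds <- apply(v, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant gene(s) dropped", call. = FALSE)
    v <- v[sds > 0, , drop = FALSE]
  }
  s <- stats::cor(t(v))
  a <- (0.5 * (1 + s))^beta
  # clamp tiny numeric overshoot; exact 1 on the diagonal
  a[a > 1] <- 1
  diag(a) <- 1
  structure(list(values = a, beta = beta), class = "cw_adjacency")
}

#' Scale-free topology fit of a connectivity vector
#'
#' Bins the connectivities into `n_bins` equal-width bins, then regresses
#' `log10(frequency)` on `log10(mean connectivity in bin)` over the
#' non-empty bins and returns the R-squared.
#'
#' @param k Numeric vector of per-gene connectivities.
#' @param n_bins Number of bins (>= 10 recommended).
#' @return R-squared of the log-log regression.
#' @export
scale_free_fit <- function(k, n_bins = 10) {
  stopifnot(length(k) >= n_bins, all(k >= 0))
  br <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks = br, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  mk <- tapply(k, bin, mean)
  ok <- !is.na(freq) & freq > 0 & !is.na(mk) & mk > 0
  if (sum(ok) < 3) return(NA_real_)
  fit <- stats::lm(log10(freq[ok]) ~ log10(mk[ok]))
  suppressWarnings(summary(fit)$r.squared)   # exact fits are legitimate
}

#' Soft-threshold scan
#'
#' For each candidate power, computes per-gene connectivity
#' `k_i = sum_{j != i} a_ij`, the scale-free fit R-squared (via
#' [scale_free_fit()]) and the mean connectivity. Mean connectivity is
#' monotonically non-increasing in the power.
#'
#' @inheritParams signed_adjacency
#' @param betas Candidate powers (default 1:20).
#' @param n_bins Connectivity histogram bins.
#' @return A tibble of class `cw_softscan` with columns `beta`, `fit_r2`,
#'   `mean_connectivity`.
#' @export
scan_soft_threshold <- function(expr, betas = 1:20, n_bins = 10) {
  v <- if (inherits(expr, "cw_expr")) expr_log2(expr) else expr
  if (nrow(v) < 30) stop("too few genes to bin connectivities (< 30)",
                         call. = FALSE)
  sds <- apply(v, 1, stats::sd)
  v <- v[sds > 0, , drop = FALSE]
  s01 <- 0.5 * (1 + stats::cor(t(v)))
  diag(s01) <- 0      # k excludes the self-edge
  res <- purrr::map_dfr(betas, function(b) {
    k <- rowSums(s01^b)
    tibble::tibble(beta = b, fit_r2 = scale_free_fit(k, n_bins),
                   mean_connectivity = mean(k))
  })
  class(res) <- c("cw_softscan", class(res))
  res
}

#' Pick a soft-threshold power from a scan
#'
#' Conventional rule: the smallest power whose scale-free fit R-squared
#' reaches `r2_cut`; if none does, the power with the best fit, with a
#' warning.
#'
#' @param scan A `cw_softscan` tibble.
#' @param r2_cut Fit threshold (default 0.8).
#' @return A single power.
#' @export
pick_beta <- function(scan, r2_cut = 0.8) {
  ok <- which(!is.na(scan$fit_r2) & scan$fit_r2 >= r2_cut)
  if (length(ok) > 0) return(scan$beta[min(ok)])
  warning("no power reaches fit R^2 >= ", r2_cut,
          "; using the best-fitting power", call. = FALSE)
  scan$beta[which.max(scan$fit_r2)]
}

#' Topological overlap matrix
#'
#' Standard unsigned TOM:
#' `tom_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for
#' `i != j`, with connectivity `k` excluding the diagonal, and
#' `tom_ii = 1`. `diss = 1 - tom`.
#'
#' @param adj A `cw_adjacency` from [signed_adjacency()].
#' @return A list of class `cw_tom` with elements `tom` and `diss`.
#' @export
topological_overlap <- function(adj) {
  stopifnot(inherits(adj, "cw_adjacency"))
  a <- adj$values
  diag(a) <- 0
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  tom[tom > 1] <- 1
  structure(list(tom = tom, diss = 1 - tom), class = "cw_tom")
}

#' Dendrogram modules via a tree-variant dynamic cut
#'
#' Average-linkage hierarchical clustering of the TOM dissimilarity,
#' statically cut at the 0.99 quantile of merge heights; branches of at
#' least `min_module_size` genes become modules (labelled `M1`, `M2`, ...
#' in decreasing size order), all remaining genes are `"unassigned"`.
#'
#' @param tom A `cw_tom` from [topological_overlap()], or a dissimilarity
#'   matrix.
#' @param min_module_size Minimum genes per module (default 15).
#' @param cut_quantile Quantile of merge heights for the static cut.
#' @return Named character vector: gene id -> module label, with the
#'   dendrogram attached as attribute `"hclust"`.
#' @export
cluster_and_cut <- function(tom, min_module_size = 15, cut_quantile = 0.99) {
  diss <- if (inherits(tom, "cw_tom")) tom$diss else tom
  stopifnot(is.matrix(diss))
  if (nrow(diss) < 2 * min_module_size) {
    stop("need at least 2 * min_module_size genes", call. = FALSE)
  }
  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  h <- stats::quantile(hc$height, cut_quantile, names = FALSE)
  branch <- stats::cutree(hc, h = h)
  if (length(unique(branch)) == 1) {
    warning("all genes fall in a single branch; returning one module",
            call. = FALSE)
  }
  sizes <- sort(table(branch), decreasing = TRUE)
  keep <- names(sizes)[sizes >= min_module_size]
  labels <- rep("unassigned", length(branch))
  names(labels) <- rownames(diss)
  for (i in seq_along(keep)) {
    labels[branch == as.integer(keep[i])] <- paste0("M", i)
  }
  if (all(labels == "unassigned") && length(unique(branch)) == 1) {
    labels[] <- "M1"
  }
  attr(labels, "hclust") <- hc
  labels
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of the
#' per-gene z-scored module submatrix across samples, scaled to unit norm,
#' with its sign fixed so that it correlates positively with the module's
#' mean expression profile. A single-gene module's eigengene is that
#' gene's z-scored profile (unit-normalized).
#'
#' @param expr A [cw_expr()] or genes x samples matrix (log2 scale is used
#'   for count units).
#' @param module_of Named module labels from [cluster_and_cut()];
#'   `"unassigned"` genes are skipped.
#' @return A samples x modules numeric matrix of eigengene scores.
#' @export
module_eigengene <- function(expr, module_of) {
  v <- if (inherits(expr, "cw_expr")) expr_log2(expr) else expr
  mods <- setdiff(unique(module_of), "unassigned")
  if (length(mods) == 0) stop("no modules to summarize", call. = FALSE)
  me <- vapply(mods, function(m) {
    genes <- names(module_of)[module_of == m]
    x <- v[genes, , drop = FALSE]
    sds <- apply(x, 1, stats::sd)
    x <- x[sds > 0, , drop = FALSE]
    if (nrow(x) == 0) return(rep(0, ncol(v)))
    z <- t(scale(t(x)))
    pc <- if (nrow(z) == 1) as.numeric(z) else svd(z, nu = 0, nv = 1)$v[, 1]
    pc <- pc / sqrt(sum(pc^2))
    ref <- colMeans(z)
    s <- sum(pc * ref)
    if (s < 0) pc <- -pc
    pc
  }, numeric(ncol(v)))
  rownames(me) <- colnames(v)
  me
}

#' Merge modules with similar eigengenes
#'
#' Iteratively merges the module pair with the smallest eigengene
#' dissimilarity `1 - cor(ME_a, ME_b)` while it is below `merge_cut`,
#' recomputing eigengenes after every merge, until a fixed point.
#'
#' @inheritParams module_eigengene
#' @param merge_cut Dissimilarity cutoff (default 0.3, i.e. merge pairs
#'   with eigengene correlation above 0.7).
#' @return A list with `module_of` (relabelled `M1`, `M2`, ... by size),
#'   `merged_from` (final label -> original labels) and `eigengenes`.
#' @export
merge_close_modules <- function(expr, module_of, merge_cut = 0.3) {
  v <- if (inherits(expr, "cw_expr")) expr_log2(expr) else expr
  labels <- module_of
  prov <- stats::setNames(as.list(setdiff(unique(labels), "unassigned")),
                          setdiff(unique(labels), "unassigned"))
  repeat {
    mods <- setdiff(unique(labels), "unassigned")
    if (length(mods) < 2) break
    me <- module_eigengene(v, labels)
    cm <- stats::cor(me)
    diag(cm) <- -Inf
    best <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    if (1 - max(cm) >= merge_cut) break
    a <- colnames(cm)[best[["col"]]]
    b <- rownames(cm)[best[["row"]]]
    labels[labels == b] <- a
    prov[[a]] <- c(prov[[a]], prov[[b]])
    prov[[b]] <- NULL
  }
  # canonical relabel by decreasing size
  mods <- setdiff(unique(labels), "unassigned")
  sizes <- vapply(mods, function(m) sum(labels == m), integer(1))
  new_names <- stats::setNames(paste0("M", seq_along(mods)),
                               mods[order(-sizes)])
  out <- labels
  for (m in mods) out[labels == m] <- new_names[[m]]
  merged_from <- stats::setNames(prov[names(new_names)],
                                 unname(new_names))
  list(module_of = out, merged_from = merged_from,
       eigengenes = module_eigengene(v, out))
}

#' Module-trait correlation
#'
#' Pearson correlation between each module eigengene and a numeric trait
#' vector (binary traits coded 0/1), with the standard t-based two-sided
#' p-value. The module with the largest r is flagged the positive key
#' module, the smallest the negative key module.
#'
#' @param eigengenes Samples x modules matrix from [module_eigengene()].
#' @param trait Numeric (or two-level) vector named by sample id, or a
#'   clinical tibble plus `trait_col`.
#' @param trait_col Column of `trait` to use when a data frame is given
#'   (two-level columns are coded 0/1 on sorted levels).
#' @return A tibble with columns `module`, `cor`, `p_value`, `key`
#'   (`"positive"`, `"negative"` or `NA`).
#' @export
module_trait_relationship <- function(eigengenes, trait,
                                      trait_col = "subgroup") {
  if (is.data.frame(trait)) {
    tv <- trait[[trait_col]]
    if (!is.numeric(tv)) {
      lev <- sort(unique(as.character(tv)))
      if (length(lev) < 2) stop("constant trait", call. = FALSE)
      tv <- as.numeric(as.character(tv) == lev[1])
    }
    trait <- stats::setNames(tv, trait$sample_id)
  }
  trait <- trait[rownames(eigengenes)]
  if (anyNA(trait)) stop("trait missing for some samples", call. = FALSE)
  if (stats::sd(trait) == 0) stop("constant trait", call. = FALSE)
  n <- length(trait)
  res <- purrr::map_dfr(colnames(eigengenes), function(m) {
    r <- stats::cor(eigengenes[, m], trait)
    tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
    tibble::tibble(module = m, cor = r,
                   p_value = 2 * stats::pt(-abs(tstat), df = n - 2))
  })
  res$key <- NA_character_
  imax <- which.max(res$cor); imin <- which.min(res$cor)
  if (imax == imin) {
    res$key[imax] <- if (res$cor[imax] >= 0) "positive" else "negative"
  } else {
    res$key[imax] <- "positive"
    res$key[imin] <- "negative"
  }
  res
}

#' Full co-expression module decomposition
#'
#' Runs [signed_adjacency()] (choosing the power by [scan_soft_threshold()]
#' when `beta = "auto"`), [topological_overlap()], [cluster_and_cut()],
#' [merge_close_modules()] and, when a clinical table is supplied,
#' [module_trait_relationship()].
#'
#' @param expr A [cw_expr()] or genes x samples matrix.
#' @param beta Soft power or `"auto"`.
#' @param min_module_size,merge_cut See the component functions.
#' @param clinical Optional clinical tibble for trait correlations.
#' @param trait_col Trait column in `clinical`.
#' @return A list of class `cw_modules`: `module_of`, `eigengenes`,
#'   `merged_from`, `trait_cor` (tibble or `NULL`), `beta`, `scan`.
#' @export
wgcna_modules <- function(expr, beta = 4, min_module_size = 15,
                          merge_cut = 0.3, clinical = NULL,
                          trait_col = "subgroup") {
  scan <- NULL
  if (identical(beta, "auto")) {
    scan <- scan_soft_threshold(expr)
    beta <- pick_beta(scan)
    cw_log("wgcna", beta_auto = beta)
  }
  adj <- signed_adjacency(expr, beta)
  tom <- topological_overlap(adj)
  labels <- cluster_and_cut(tom, min_module_size)
  merged <- merge_close_modules(expr, labels, merge_cut)
  trait_cor <- NULL
  if (!is.null(clinical)) {
    trait_cor <- module_trait_relationship(merged$eigengenes, clinical,
                                           trait_col)
  }
  cw_log("wgcna", genes = length(merged$module_of),
         modules = length(unique(setdiff(merged$module_of, "unassigned"))),
         unassigned = sum(merged$module_of == "unassigned"))
  structure(list(module_of = merged$module_of,
                 eigengenes = merged$eigengenes,
                 merged_from = merged$merged_from,
                 trait_cor = trait_cor, beta = beta, scan = scan),
            class = "cw_modules")
}

#' @export
print.cw_modules <- function(x, ...) {
  mods <- setdiff(unique(x$module_of), "unassigned")
  cat("<cw_modules> beta=", x$beta, ", ", length(mods), " module(s), ",
      sum(x$module_of == "unassigned"), " unassigned of ",
      length(x$module_of), " genes\n", sep = "")
  invisible(x)
}

#' @export
tidy.cw_modules <- function(x, ...) {
  tb <- tibble::tibble(gene_id = names(x$module_of),
                       module = unname(x$module_of))
  if (!is.null(x$trait_cor)) {
    tb <- dplyr::left_join(tb, x$trait_cor, by = "module")
  }
  tb
}

#' @export
glance.cw_modules <- function(x, ...) {
  mods <- setdiff(unique(x$module_of), "unassigned")
  tibble::tibble(
    n_genes = length(x$module_of), n_modules = length(mods),
    n_unassigned = sum(x$module_of == "unassigned"), beta = x$beta,
    max_trait_cor = if (is.null(x$trait_cor)) NA_real_ else
      max(x$trait_cor$cor),
    min_trait_cor = if (is.null(x$trait_cor)) NA_real_ else
      min(x$trait_cor$cor))
}

#' Module-trait relationship plot
#'
#' @param object A `cw_modules` object carrying trait correlations.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cw_modules <- function(object, ...) {
  if (is.null(object$trait_cor)) stop("no trait correlations to plot",
                                      call. = FALSE)
  ggplot2::ggplot(object$trait_cor,
                  ggplot2::aes(x = .data$module, y = .data$cor,
                               fill = .data$cor)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = "eigengene-trait Pearson r") +
    ggplot2::theme_minimal()
}

#' Soft-threshold scan plot
#'
#' @param object A `cw_softscan` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cw_softscan <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("fit_r2", "mean_connectivity"),
                              names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$beta, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "soft-threshold power", y = NULL) +
    ggplot2::theme_minimal()
}
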