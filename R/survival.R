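#' Candidate (miRNA, ceRNA) pairs by negative correlation
#'
#' Within each network, pairs the hub miRNA with each of its non-coding
#' targets and keeps the pairs whose Pearson correlation (log2 scales) is
#' strictly below `cerna_corr_max` (default -0.3). Pairs with a constant
#' expression vector are skipped with a warning.
#'
#' @param networks A `cw_networks` tibble (usually the retained ones).
#' @param expr_nc A [cw_expr()] with the ncRNA expression.
#' @param expr_mirna A [cw_expr()] with the miRNA expression.
#' @param cerna_corr_max Correlation ceiling (strict `<`).
#' @return A tibble: `network_id`, `mirna_id`, `cerna_id`, `pearson_r`.
#' @export
filter_cerna_pairs <- function(networks, expr_nc, expr_mirna,
                               cerna_corr_max = -0.3) {
  stopifnot(is.data.frame(networks))
  common <- intersect(sample_ids(expr_nc), sample_ids(expr_mirna))
  vn <- expr_log2(expr_subset(expr_nc, samples = common))
  vm <- expr_log2(expr_subset(expr_mirna, samples = common))
  out <- purrr::pmap_dfr(networks, function(network_id, mirna_id,
                                            nc_targets, ...) {
    if (!mirna_id %in% rownames(vm)) return(NULL)
    m <- vm[mirna_id, ]
    if (stats::sd(m) == 0) {
      warning("constant miRNA profile: ", mirna_id, "; skipped",
              call. = FALSE)
      return(NULL)
    }
    purrr::map_dfr(intersect(nc_targets, rownames(vn)), function(g) {
      x <- vn[g, ]
      if (stats::sd(x) == 0) {
        warning("constant ceRNA profile: ", g, "; skipped", call. = FALSE)
        return(NULL)
      }
      tibble::tibble(network_id = network_id, mirna_id = mirna_id,
                     cerna_id = g, pearson_r = stats::cor(m, x))
    })
  })
  if (nrow(out) == 0) return(out)
  out <- dplyr::filter(out, .data$pearson_r < cerna_corr_max)
  cw_log("cerna_pairs", kept = nrow(out))
  out
}

#' Deterministic 1-D 2-means split into high/low expression
#'
#' Exact two-cluster k-means on one gene's per-sample expression. In one
#' dimension the optimal 2-means solution is a threshold split, so the
#' global within-cluster sum-of-squares optimum is found directly by
#' scanning all n - 1 cut points between sorted values (prefix sums make
#' this O(n log n)). Deterministic: no random initialization, no restarts.
#' The cluster with the larger centroid is labelled `"high"`.
#'
#' @param values Numeric vector (named by sample id) with >= 2 distinct
#'   values.
#' @return Character vector of `"high"` / `"low"` labels, named like
#'   `values`.
#' @export
kmeans_split <- function(values) {
  stopifnot(is.numeric(values))
  if (length(unique(values)) < 2) {
    stop("all values identical; cannot split", call. = FALSE)
  }
  ord <- order(values)
  xs <- values[ord]
  n <- length(xs)
  cs <- cumsum(xs); cs2 <- cumsum(xs^2)
  tot <- cs[n]; tot2 <- cs2[n]
  i <- seq_len(n - 1)
  wss <- (cs2[i] - cs[i]^2 / i) +
    ((tot2 - cs2[i]) - (tot - cs[i])^2 / (n - i))
  valid <- xs[i] < xs[i + 1]          # a cut inside a tie is meaningless
  wss[!valid] <- Inf
  best <- which.min(wss)
  cut <- (xs[best] + xs[best + 1]) / 2
  out <- ifelse(values > cut, "high", "low")
  names(out) <- names(values)
  out
}

#' Kaplan-Meier estimate per group
#'
#' Product-limit curves with Greenwood-variance confidence intervals on
#' the log-log scale (the convention that yields one-sided "x to NA"
#' intervals when the upper limit is never reached). The median is the
#' earliest time at which the survival estimate drops to 0.5 or below
#' (`NA` when never reached).
#'
#' @param time,event Follow-up times (days, >= 0) and event indicators.
#' @param group Group labels (a single group is fine).
#' @return A list of class `cw_km`: `curves` (tibble of step functions)
#'   and `table` (per-group n, events, median, 95% CI).
#' @export
kaplan_meier <- function(time, event, group = rep("all", length(time))) {
  stopifnot(length(time) == length(event), length(time) == length(group),
            all(time >= 0))
  group <- as.character(group)
  if (any(table(factor(group, levels = unique(group))) == 0)) {
    stop("empty group", call. = FALSE)
  }
  df <- data.frame(time = time, event = as.integer(event), group = group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df,
                           conf.type = "log-log")
  sm <- summary(fit, censored = TRUE)
  strata <- if (is.null(sm$strata)) rep(unique(group), length(sm$time))
            else sub("^group=", "", as.character(sm$strata))
  curves <- tibble::tibble(group = strata, time = sm$time, surv = sm$surv,
                           lower = sm$lower, upper = sm$upper)
  tab <- summary(fit)$table
  if (is.null(dim(tab))) tab <- matrix(tab, nrow = 1,
                                       dimnames = list(unique(group),
                                                       names(tab)))
  table <- tibble::tibble(
    group = sub("^group=", "", rownames(tab)),
    n = unname(tab[, "records"]),
    events = unname(tab[, "events"]),
    median = unname(tab[, "median"]),
    ci_lower = unname(tab[, "0.95LCL"]),
    ci_upper = unname(tab[, "0.95UCL"]))
  structure(list(curves = curves, table = table), class = "cw_km")
}

#' @export
print.cw_km <- function(x, ...) {
  cat("<cw_km> Kaplan-Meier estimate\n")
  print(x$table)
  invisible(x)
}

#' Two-group log-rank test
#'
#' @param time,event,group As in [kaplan_meier()]; exactly two groups.
#' @return Two-sided chi-square p-value. Degenerate inputs (no events, or
#'   no risk-set overlap) return `p = 1` by convention.
#' @export
logrank_test <- function(time, event, group) {
  stopifnot(length(unique(group)) == 2)
  if (sum(event) == 0) return(1)
  df <- data.frame(time = time, event = as.integer(event),
                   group = as.character(group))
  sd_ <- tryCatch(
    survival::survdiff(survival::Surv(time, event) ~ group, data = df),
    error = function(e) NULL)
  if (is.null(sd_)) return(1)
  unname(stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE))
}

#' Survival stratification of miRNA-ceRNA pairs
#'
#' For every candidate pair, splits the cohort into high/low ceRNA
#' expression via [kmeans_split()], fits per-group Kaplan-Meier curves,
#' tests the split by log-rank, and applies Benjamini-Hochberg correction
#' across all pairs in the batch (one cohort = one batch).
#'
#' @param pairs Tibble from [filter_cerna_pairs()].
#' @param expr_nc [cw_expr()] with ncRNA expression.
#' @param clinical Clinical tibble with `sample_id`, `os_time`, `os_event`.
#' @return A tibble of class `cw_survival`, one row per pair with the
#'   per-group medians, 95% CIs, counts, `logrank_p` and `fdr`, sorted by
#'   p-value; KM curves are attached as attribute `"km"` for plotting.
#' @export
survival_stratification <- function(pairs, expr_nc, clinical) {
  validate_clinical(clinical)
  if (!all(c("os_time", "os_event") %in% names(clinical))) {
    stop("clinical table lacks os_time/os_event; survival stage unavailable",
         call. = FALSE)
  }
  cl <- dplyr::filter(clinical, !is.na(.data$os_time), !is.na(.data$os_event))
  common <- intersect(sample_ids(expr_nc), cl$sample_id)
  cl <- cl[match(common, cl$sample_id), ]
  vn <- expr_log2(expr_subset(expr_nc, samples = common))
  km_store <- list()
  res <- purrr::pmap_dfr(pairs, function(network_id, mirna_id, cerna_id,
                                         pearson_r, ...) {
    split <- kmeans_split(vn[cerna_id, ])
    km <- kaplan_meier(cl$os_time, cl$os_event, split[cl$sample_id])
    km_store[[paste(mirna_id, cerna_id, sep = "|")]] <<- km
    tb <- km$table
    hi <- tb[tb$group == "high", ]; lo <- tb[tb$group == "low", ]
    tibble::tibble(
      network_id = network_id, mirna_id = mirna_id, cerna_id = cerna_id,
      pearson_r = pearson_r,
      median_high = hi$median, ci_lower_high = hi$ci_lower,
      ci_upper_high = hi$ci_upper, n_high = hi$n,
      median_low = lo$median, ci_lower_low = lo$ci_lower,
      ci_upper_low = lo$ci_upper, n_low = lo$n,
      logrank_p = logrank_test(cl$os_time, cl$os_event,
                               split[cl$sample_id]))
  })
  if (nrow(res) == 0) {
    class(res) <- c("cw_survival", class(res))
    return(res)
  }
  res$fdr <- stats::p.adjust(res$logrank_p, method = "BH")
  res <- dplyr::arrange(res, .data$logrank_p)
  class(res) <- c("cw_survival", class(res))
  attr(res, "km") <- km_store
  cw_log("survival", pairs = nrow(res),
         significant = sum(res$fdr < 0.05))
  res
}

#' @export
glance.cw_survival <- function(x, ...) {
  tibble::tibble(n_pairs = nrow(x),
                 n_significant = sum(x$fdr < 0.05),
                 min_fdr = if (nrow(x) > 0) min(x$fdr) else NA_real_)
}

#' Kaplan-Meier curves for one stratified pair
#'
#' @param object A `cw_survival` tibble.
#' @param pair Row index or `"miRNA|ceRNA"` key of the pair to plot
#'   (default: the most significant pair).
#' @param ... Unused.
#' @return A ggplot object with per-group step curves.
#' @export
autoplot.cw_survival <- function(object, pair = 1, ...) {
  km_store <- attr(object, "km")
  key <- if (is.numeric(pair))
    paste(object$mirna_id[pair], object$cerna_id[pair], sep = "|") else pair
  km <- km_store[[key]]
  if (is.null(km)) stop("no stored curves for pair ", key, call. = FALSE)
  start <- dplyr::distinct(km$curves, .data$group) |>
    dplyr::mutate(time = 0, surv = 1, lower = 1, upper = 1)
  curves <- dplyr::bind_rows(start, km$curves)
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$time, y = .data$surv,
                                       colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::labs(title = key, x = "time (days)",
                  y = "survival probability", colour = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
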