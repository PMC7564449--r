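test_that("negative-correlation pair filter keeps sponges, drops independents", {
  sim <- simulate_cohort(simulation_config(rng_seed = 41))
  tr <- sim$truth$triplets
  nets <- tibble::tibble(
    network_id = "Network01",
    mirna_id = tr$miRNA[1],
    mirna_direction = "down", source_module = "up_key",
    coding_targets = list(unique(tr$mRNA[tr$miRNA == tr$miRNA[1]])),
    nc_targets = list(unique(tr$lncRNA[tr$miRNA == tr$miRNA[1]])),
    n_coding = 2L, n_nc = 2L)
  nc_genes <- rownames(sim$expr$values)[
    sim$expr$biotype %in% c("lncRNA", "pseudogene")]
  expr_nc <- expr_subset(sim$expr, genes = nc_genes)
  pairs <- suppressMessages(
    filter_cerna_pairs(nets, expr_nc, sim$mirna, -0.3))
  expect_setequal(pairs$cerna_id, unique(tr$lncRNA[tr$miRNA == tr$miRNA[1]]))
  expect_true(all(pairs$pearson_r < -0.3))
  # an independent (non-planted) ncRNA in the same network is dropped
  indep <- setdiff(nc_genes, c(names(sim$truth$module_of),
                               sim$truth$de_genes_up,
                               sim$truth$de_genes_down))[1]
  nets$nc_targets <- list(c(nets$nc_targets[[1]], indep))
  pairs2 <- suppressMessages(
    filter_cerna_pairs(nets, expr_nc, sim$mirna, -0.3))
  expect_false(indep %in% pairs2$cerna_id)
})

test_that("the correlation ceiling is strict around -0.3", {
  # ncRNA profiles engineered to correlate with the miRNA at -0.31
  # (kept) and at -0.3 + 1e-6 (dropped); built on log2 scales directly
  set.seed(30)
  n <- 50
  m <- rnorm(n)
  u <- (m - mean(m)) / sqrt(sum((m - mean(m))^2))
  e <- residuals(lm(rnorm(n) ~ m))
  e <- e / sqrt(sum(e^2))
  mk <- function(r) r * u + sqrt(1 - r^2) * e
  sample_id <- sprintf("s%02d", seq_len(n))
  vn <- rbind(lnc_keep = mk(-0.31), lnc_drop = mk(-0.3 + 1e-6))
  colnames(vn) <- sample_id
  expr_nc <- cw_expr(vn, "log2_rpm_plus1",
                     setNames(rep("lncRNA", 2), rownames(vn)))
  vm <- matrix(m, 1, dimnames = list("miR-x", sample_id))
  expr_m <- cw_expr(vm, "log2_rpm_plus1", c(`miR-x` = "miRNA"))
  nets <- tibble::tibble(network_id = "Network01", mirna_id = "miR-x",
                         mirna_direction = "down", source_module = "up_key",
                         coding_targets = list(character(0)),
                         nc_targets = list(c("lnc_keep", "lnc_drop")),
                         n_coding = 0L, n_nc = 2L)
  pairs <- suppressMessages(filter_cerna_pairs(nets, expr_nc, expr_m, -0.3))
  expect_identical(pairs$cerna_id, "lnc_keep")
  expect_equal(pairs$pearson_r, -0.31, tolerance = 1e-10)
})

test_that("1-D k-means equals the exhaustive optimal threshold split", {
  vals <- setNames(c(0, 0, 0, 10, 10, 10), sprintf("s%d", 1:6))
  split <- kmeans_split(vals)
  expect_setequal(names(split[split == "low"]), c("s1", "s2", "s3"))
  set.seed(23)
  for (i in 1:100) {
    x <- switch(1 + i %% 3,
                rnorm(30),
                c(rnorm(15, 0), rnorm(15, 3)),
                rexp(25))
    x <- x + rnorm(length(x), 0, 1e-9)   # break exact ties
    km <- kmeans_split(x)
    oracle <- kmeans1d_bruteforce(x)
    expect_equal(unname(km), unname(oracle))
  }
  # order invariance
  x <- c(rnorm(10), rnorm(10, 4))
  names(x) <- sprintf("s%02d", 1:20)
  perm <- sample(names(x))
  expect_equal(kmeans_split(x)[perm], kmeans_split(x[perm]))
  expect_error(kmeans_split(rep(2, 5)), "identical")
})

test_that("product-limit estimate matches hand and brute-force computation", {
  km <- kaplan_meier(c(5, 8, 12), c(TRUE, TRUE, TRUE))
  expect_equal(km$curves$surv[km$curves$time == 5], 2 / 3)
  expect_equal(km$curves$surv[km$curves$time == 8], 1 / 3)
  expect_equal(km$curves$surv[km$curves$time == 12], 0)
  expect_equal(km$table$median, 8)
  # no events: flat curve, undefined median
  km0 <- kaplan_meier(c(3, 6, 9), c(FALSE, FALSE, FALSE))
  expect_true(all(km0$curves$surv == 1))
  expect_true(is.na(km0$table$median))
  # scale equivariance
  set.seed(24)
  t1 <- rexp(40, 1 / 100); ev <- runif(40) < 0.7
  k1 <- kaplan_meier(t1, ev); k2 <- kaplan_meier(2 * t1, ev)
  expect_equal(k2$table$median, 2 * k1$table$median)
  expect_equal(k2$curves$surv, k1$curves$surv)
  # brute-force risk-set oracle on random small datasets
  for (i in 1:20) {
    n <- sample(5:25, 1)
    tt <- sample(1:40, n, replace = TRUE)
    evt <- runif(n) < 0.6
    if (!any(evt)) evt[1] <- TRUE
    km <- kaplan_meier(tt, evt)
    bf <- km_bruteforce(tt, evt)
    got <- km$curves[km$curves$time %in% bf$time & km$curves$surv >= 0, ]
    got <- got[match(bf$time, got$time), ]
    expect_equal(got$surv, bf$surv, tolerance = 1e-12)
  }
})

test_that("log-rank p is label-symmetric with sane degenerate conventions", {
  set.seed(25)
  tt <- c(rexp(30, 1 / 100), rexp(30, 1 / 50))
  ev <- runif(60) < 0.8
  g <- rep(c("A", "B"), each = 30)
  p1 <- logrank_test(tt, ev, g)
  expect_equal(p1, logrank_test(tt, ev, ifelse(g == "A", "B", "A")))
  expect_equal(logrank_test(tt, rep(FALSE, 60), g), 1)
})

test_that("planted survival effects are detected in most cohorts", {
  # HR 2 planted on the trait signal, n = 168, ~30% censoring; a ceRNA-based
  # high/low split attenuates the effect through assignment noise, so the
  # bar is detection (any pair at FDR < 0.05) in >= 80% of cohorts
  hits <- 0
  for (s in 1:10) {
    sim <- simulate_cohort(simulation_config(rng_seed = s))
    norm <- normalize_counts(sim$expr)
    tr <- sim$truth$triplets
    nets <- tibble::tibble(
      network_id = sprintf("N%02d", seq_along(unique(tr$miRNA))),
      mirna_id = unique(tr$miRNA), mirna_direction = "down",
      source_module = "up_key",
      coding_targets = purrr::map(unique(tr$miRNA),
                                  ~ unique(tr$mRNA[tr$miRNA == .x])),
      nc_targets = purrr::map(unique(tr$miRNA),
                              ~ unique(tr$lncRNA[tr$miRNA == .x])),
      n_coding = 2L, n_nc = 2L)
    nc_genes <- rownames(norm$values)[
      norm$biotype %in% c("lncRNA", "pseudogene")]
    expr_nc <- expr_subset(norm, genes = nc_genes)
    pairs <- suppressMessages(suppressWarnings(
      filter_cerna_pairs(nets, expr_nc, sim$mirna)))
    surv <- suppressMessages(
      survival_stratification(pairs, expr_nc, sim$clinical))
    if (nrow(surv) > 0 && any(surv$fdr < 0.05)) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("survival stratification produces Table-2-shaped output with BH control", {
  sim <- simulate_cohort(simulation_config(rng_seed = 42))
  tr <- sim$truth$triplets
  nets <- tibble::tibble(
    network_id = sprintf("Network%02d", seq_along(unique(tr$miRNA))),
    mirna_id = unique(tr$miRNA), mirna_direction = "down",
    source_module = "up_key",
    coding_targets = purrr::map(unique(tr$miRNA),
                                ~ unique(tr$mRNA[tr$miRNA == .x])),
    nc_targets = purrr::map(unique(tr$miRNA),
                            ~ unique(tr$lncRNA[tr$miRNA == .x])),
    n_coding = 2L, n_nc = 2L)
  nc_genes <- rownames(sim$expr$values)[
    sim$expr$biotype %in% c("lncRNA", "pseudogene")]
  expr_nc <- expr_subset(sim$expr, genes = nc_genes)
  pairs <- suppressMessages(filter_cerna_pairs(nets, expr_nc, sim$mirna))
  surv <- suppressMessages(
    survival_stratification(pairs, expr_nc, sim$clinical))
  expect_true(all(c("median_high", "ci_lower_high", "ci_upper_high",
                    "n_high", "median_low", "logrank_p", "fdr") %in%
                    names(surv)))
  expect_equal(surv$fdr, p.adjust(surv$logrank_p, "BH"))
  expect_true(all(surv$fdr >= surv$logrank_p))
  expect_true(all(surv$pearson_r < -0.3))
  # planted protective effect: high-expression group outlives low
  expect_gt(stats::median(surv$median_high - surv$median_low, na.rm = TRUE), 0)
})
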