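test_that("the generator is a pure function of its configuration", {
  cfg <- module_simcfg(seed = 7)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$expr$values, b$expr$values)
  expect_identical(a$mirna$values, b$mirna$values)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$interactions, b$interactions)
  c2 <- simulate_cohort(module_simcfg(seed = 8))
  expect_false(identical(a$expr$values, c2$expr$values))
})

test_that("factor-model calibration yields the target within-module correlation", {
  # analytic calibration: v_f = r * w / (1 - r), w = trigamma(1/phi) + 1/mu;
  # checked by Monte Carlo on a non-trait module at n = 100 samples
  cfg <- module_simcfg(seed = 11, n_per_group = 50)
  sim <- simulate_cohort(cfg)
  m2 <- names(sim$truth$module_of)[sim$truth$module_of == "M2"]
  cm <- cor(t(log2(sim$expr$values[m2, ] + 1)))
  expect_equal(mean(cm[upper.tri(cm)]), 0.7, tolerance = 0.1 / 0.7)
})

test_that("sponge coupling is negative at defaults and vanishes at strength 0", {
  cfg <- module_simcfg(seed = 3, n_per_group = 100)
  sim <- simulate_cohort(cfg)
  tr <- sim$truth$triplets
  r <- mapply(function(l, mi) {
    cor(log2(sim$expr$values[l, ] + 1), log2(sim$mirna$values[mi, ] + 1))
  }, tr$lncRNA, tr$miRNA)
  expect_lt(mean(r), -0.35)
  cfg0 <- module_simcfg(seed = 3, n_per_group = 100)
  cfg0$sponge_strength <- 0
  sim0 <- simulate_cohort(cfg0)
  tr0 <- sim0$truth$triplets
  r0 <- mapply(function(l, mi) {
    cor(log2(sim0$expr$values[l, ] + 1), log2(sim0$mirna$values[mi, ] + 1))
  }, tr0$lncRNA, tr0$miRNA)
  expect_lt(abs(mean(r0)), 0.1)
})

test_that("planted fold changes converge to the configured effect", {
  cfg <- simulation_config(
    n_samples = c(codel = 200, noncodel = 200),
    n_genes = c(coding = 400, lncRNA = 20, pseudogene = 10, miRNA = 20),
    n_modules = 1, module_size = 20, nc_per_module = 4, psg_per_module = 2,
    n_de_up = 60, n_de_down = 60, n_de_nc = 2, n_sponge_mirnas = 2,
    targets_per_mirna = 5, nc_targets_per_mirna = 2, n_dominated = 0,
    rng_seed = 5)
  sim <- simulate_cohort(cfg)
  z <- sim$truth$subgroup_of[colnames(sim$expr$values)] == "codel"
  lfc <- function(g) {
    log2((rowMeans(sim$expr$values[g, z, drop = FALSE]) + 1) /
           (rowMeans(sim$expr$values[g, !z, drop = FALSE]) + 1))
  }
  up_free <- setdiff(sim$truth$de_genes_up, names(sim$truth$module_of))
  down_free <- setdiff(sim$truth$de_genes_down, names(sim$truth$module_of))
  expect_equal(mean(lfc(up_free)), 1.5, tolerance = 0.2 / 1.5)
  expect_equal(mean(lfc(down_free)), -1.5, tolerance = 0.2 / 1.5)
})

test_that("null genes reject at the nominal rate under a two-group test", {
  cfg <- simulation_config(
    n_samples = c(codel = 60, noncodel = 60),
    n_genes = c(coding = 1200, lncRNA = 10, pseudogene = 5, miRNA = 10),
    n_modules = 1, module_size = 15, nc_per_module = 2, psg_per_module = 2,
    n_de_up = 10, n_de_down = 10, n_de_nc = 1, n_sponge_mirnas = 1,
    targets_per_mirna = 3, nc_targets_per_mirna = 1, n_dominated = 0,
    rng_seed = 13)
  sim <- simulate_cohort(cfg)
  planted <- unique(c(sim$truth$de_genes_up, sim$truth$de_genes_down,
                      names(sim$truth$module_of)))
  nulls <- setdiff(rownames(sim$expr$values), c(planted, sim$truth$dominated))
  nulls <- nulls[sim$expr$biotype[nulls] == "coding"]
  expect_gte(length(nulls), 1000)
  z <- sim$truth$subgroup_of[colnames(sim$expr$values)] == "codel"
  # normalize first: library-size variation would otherwise couple genes
  norm <- normalize_counts(sim$expr)
  p <- apply(norm$values[nulls, ], 1, function(x) {
    suppressWarnings(stats::wilcox.test(x[z], x[!z])$p.value)
  })
  rate <- mean(p < 0.05)
  se <- sqrt(0.05 * 0.95 / length(p))
  expect_lt(abs(rate - 0.05), 2 * se + 1e-9)
})

test_that("planted triplets are recoverable in principle", {
  sim <- simulate_cohort(simulation_config(rng_seed = 21))
  tr <- sim$truth$triplets
  # every triplet edge exists in the interaction table
  has_edge <- function(mi, tg) {
    any(sim$interactions$mirna_id == mi & sim$interactions$target_id == tg)
  }
  expect_true(all(mapply(has_edge, tr$miRNA, tr$lncRNA)))
  expect_true(all(mapply(has_edge, tr$miRNA, tr$mRNA)))
  # members survive the default filters
  pre <- suppressMessages(preprocess_mrna(sim$expr))
  pmi <- suppressMessages(preprocess_mirna(sim$mirna))
  expect_true(all(tr$lncRNA %in% rownames(pre$expr$values)))
  expect_true(all(tr$mRNA %in% rownames(pre$expr$values)))
  expect_true(all(tr$miRNA %in% rownames(pmi$expr$values)))
})

test_that("describe_truth counts match the configuration", {
  cfg <- module_simcfg(seed = 2)
  sim <- simulate_cohort(cfg)
  d <- describe_truth(sim$truth)
  expect_equal(d$count[d$category == "modules"], 3L)
  expect_equal(d$count[d$category == "triplets"],
               2L * cfg$n_sponge_mirnas)
  expect_equal(d$count[d$category == "samples"], sum(cfg$n_samples))
  expect_equal(d$count[d$category == "de_genes_down"], 0L)
})

test_that("infeasible configurations are rejected", {
  expect_error(
    simulation_config(n_genes = c(coding = 50, lncRNA = 10, pseudogene = 5,
                                  miRNA = 10),
                      n_modules = 3, module_size = 40),
    "infeasible")
})
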