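test_that("signed adjacency follows the soft-threshold mapping exactly", {
  # three analytic correlation cases: +1, -1, 0 at beta = 4
  s <- seq(1, 10)
  m <- rbind(a = s, b = s * 2 + 3, c = rev(s))
  colnames(m) <- sprintf("s%02d", 1:10)
  adj <- signed_adjacency(make_expr(m, unit = "log_normalized"), beta = 4)
  expect_equal(unname(adj$values["a", "b"]), 1)          # cor = 1
  expect_equal(unname(adj$values["a", "c"]), 0)          # cor = -1
  set.seed(2)
  x <- rnorm(2000); y <- rnorm(2000)
  m2 <- rbind(a = x, b = y)
  colnames(m2) <- sprintf("s%04d", 1:2000)
  adj2 <- signed_adjacency(make_expr(m2, unit = "log_normalized"), beta = 4)
  r <- cor(x, y)
  expect_equal(unname(adj2$values["a", "b"]), (0.5 * (1 + r))^4)
  expect_lt(abs(unname(adj2$values["a", "b"]) - 0.5^4), 0.01)
  # self-adjacency is exactly 1; map is monotone in cor
  expect_true(all(diag(adj$values) == 1))
  cors <- seq(-1, 1, by = 0.1)
  expect_true(all(diff((0.5 * (1 + cors))^4) > 0))
})

test_that("TOM equals a naive triple-loop oracle and handles edge cases", {
  set.seed(3)
  for (rep in 1:20) {
    r <- matrix(runif(100), 10)
    a <- (r + t(r)) / 2
    diag(a) <- 1
    dimnames(a) <- list(sprintf("g%d", 1:10), sprintf("g%d", 1:10))
    tom <- topological_overlap(structure(list(values = a, beta = 4),
                                         class = "cw_adjacency"))
    oracle <- tom_bruteforce(a)
    diag(oracle) <- 1
    expect_lt(max(abs(tom$tom - oracle)), 1e-12)
    expect_equal(tom$diss, 1 - tom$tom)
    expect_equal(tom$tom, t(tom$tom))
  }
  # identity adjacency: empty neighborhoods
  idn <- diag(3)
  dimnames(idn) <- list(letters[1:3], letters[1:3])
  t0 <- topological_overlap(structure(list(values = idn, beta = 1),
                                      class = "cw_adjacency"))
  expect_true(all(t0$tom[upper.tri(t0$tom)] == 0))
  # complete graph: full overlap
  ones <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  t1 <- topological_overlap(structure(list(values = ones, beta = 1),
                                      class = "cw_adjacency"))
  expect_true(all(t1$tom == 1))
})

test_that("scale-free fit is exact on an exact power-law degree sequence", {
  # counts proportional to k^-2 at k in {1,2,4,5,8,10}: log-log linear
  vals <- c(1, 2, 4, 5, 8, 10)
  k <- rep(vals, times = 1600 / vals^2)
  expect_equal(scale_free_fit(k, n_bins = 10), 1, tolerance = 1e-10)
})

test_that("soft-threshold scan has non-increasing mean connectivity", {
  sim <- simulate_cohort(module_simcfg(seed = 5))
  genes <- names(sim$truth$module_of)[1:200]
  e <- expr_subset(sim$expr, genes = genes)
  scan <- scan_soft_threshold(e, betas = 1:10)
  expect_true(all(diff(scan$mean_connectivity) <= 1e-9))
  # brute-force recomputation of the fit for one power
  lv <- log2(e$values + 1)
  s01 <- 0.5 * (1 + cor(t(lv)))
  diag(s01) <- 0
  k <- rowSums(s01^6)
  expect_equal(scan$fit_r2[scan$beta == 6], scale_free_fit(k, 10))
  expect_error(scan_soft_threshold(expr_subset(e, genes = genes[1:20])),
               "too few")
})

test_that("dynamic tree cut recovers planted blocks and respects size gates", {
  set.seed(8)
  n <- 60
  f1 <- rnorm(n); f2 <- rnorm(n)
  block <- function(f, k) t(sapply(seq_len(k), function(i) {
    sqrt(0.8) * f + sqrt(0.2) * rnorm(n)
  }))
  m <- rbind(block(f1, 50), block(f2, 50))
  dimnames(m) <- list(sprintf("g%03d", 1:100), sprintf("s%02d", 1:n))
  truth <- rep(c("A", "B"), each = 50)
  adj <- signed_adjacency(make_expr(m, unit = "log_normalized"), 4)
  tom <- topological_overlap(adj)
  labels <- cluster_and_cut(tom, min_module_size = 15)
  mods <- setdiff(unique(labels), "unassigned")
  expect_equal(length(mods), 2L)
  expect_gte(adjusted_rand_index(labels, setNames(truth, names(labels))), 0.95)
  # pigeonhole: a minimum above half the gene count leaves no room
  expect_error(cluster_and_cut(tom, min_module_size = 51), "min_module_size")
  labels2 <- cluster_and_cut(tom, min_module_size = 50)
  expect_lte(length(setdiff(unique(labels2), "unassigned")), 2L)
  # gene order does not change the partition (up to names)
  rev_tom <- structure(list(tom = tom$tom[100:1, 100:1],
                            diss = tom$diss[100:1, 100:1]), class = "cw_tom")
  labels3 <- cluster_and_cut(rev_tom, min_module_size = 15)
  expect_equal(adjusted_rand_index(labels3[names(labels)], labels), 1)
})

test_that("module eigengene is the unit-norm first PC with fixed sign", {
  set.seed(12)
  z <- matrix(rnorm(50), 5, 10,
              dimnames = list(sprintf("g%d", 1:5), sprintf("s%02d", 1:10)))
  module_of <- setNames(rep("M1", 5), rownames(z))
  me <- module_eigengene(z, module_of)
  # independent oracle: prcomp on the per-gene z-scored submatrix
  zz <- t(scale(t(z)))
  pc <- prcomp(t(zz), center = FALSE)$x[, 1]
  pc <- pc / sqrt(sum(pc^2))
  if (sum(pc * colMeans(zz)) < 0) pc <- -pc
  expect_equal(unname(me[, "M1"]), unname(pc), tolerance = 1e-10)
  expect_equal(sum(me[, "M1"]^2), 1)
  # identical genes: eigengene tracks the shared profile exactly
  shared <- rnorm(10)
  m_id <- matrix(rep(shared, each = 4), 4, 10,
                 dimnames = list(sprintf("g%d", 1:4), sprintf("s%02d", 1:10)))
  me2 <- module_eigengene(m_id, setNames(rep("M1", 4), rownames(m_id)))
  expect_equal(abs(cor(me2[, "M1"], shared)), 1)
  expect_gt(cor(me2[, "M1"], colMeans(t(scale(t(m_id))))), 0.99)
  # PC1 captures at least as much squared projection as any direction
  v1 <- sum((zz %*% me[, "M1"])^2)
  for (i in 1:20) {
    d <- rnorm(10); d <- d / sqrt(sum(d^2))
    expect_gte(v1 + 1e-12, sum((zz %*% d)^2))
  }
})

test_that("module merging reaches the same fixed point in any order", {
  set.seed(14)
  n <- 40
  shared <- rnorm(n)
  mk <- function(k, f) t(sapply(seq_len(k), function(i) {
    sqrt(0.9) * f + sqrt(0.1) * rnorm(n)
  }))
  m <- rbind(mk(10, shared), mk(10, shared), mk(10, shared),
             mk(10, rnorm(n)))
  dimnames(m) <- list(sprintf("g%03d", 1:40), sprintf("s%02d", 1:n))
  base_labels <- setNames(rep(c("A", "B", "C", "D"), each = 10),
                          rownames(m))
  for (perm in list(c("A", "B", "C"), c("B", "C", "A"), c("C", "A", "B"))) {
    relabel <- setNames(c(perm, "D"), c("A", "B", "C", "D"))
    labels <- setNames(relabel[base_labels], names(base_labels))
    merged <- merge_close_modules(m, labels, merge_cut = 0.3)
    mods <- setdiff(unique(merged$module_of), "unassigned")
    expect_equal(length(mods), 2L)
    # the three similar modules always collapse into the same big module
    big <- names(which.max(table(merged$module_of)))
    expect_equal(sum(merged$module_of == big), 30L)
  }
  # dissimilar modules stay put
  m2 <- rbind(mk(10, rnorm(n)), mk(10, rnorm(n)))
  dimnames(m2) <- list(sprintf("h%02d", 1:20), sprintf("s%02d", 1:n))
  lab2 <- setNames(rep(c("A", "B"), each = 10), rownames(m2))
  merged2 <- merge_close_modules(m2, lab2, merge_cut = 0.3)
  expect_equal(length(setdiff(unique(merged2$module_of), "unassigned")), 2L)
})

test_that("module-trait correlation flags the trait-coupled module", {
  set.seed(15)
  n <- 40
  trait <- rep(c(1, 0), each = n / 2)
  me <- cbind(M1 = trait + rnorm(n, 0, 0.2), M2 = rnorm(n))
  me <- apply(me, 2, function(x) x / sqrt(sum(x^2)))
  rownames(me) <- sprintf("s%02d", 1:n)
  tc <- module_trait_relationship(me, setNames(trait, rownames(me)))
  expect_equal(tc$key[tc$module == "M1"], "positive")
  expect_gt(tc$cor[tc$module == "M1"], 0.9)
  # perfect alignment: r = 1, vanishing p
  me2 <- cbind(M1 = (trait - mean(trait)))
  me2 <- me2 / sqrt(sum(me2^2))
  rownames(me2) <- rownames(me)
  tc2 <- module_trait_relationship(me2, setNames(trait, rownames(me)))
  expect_equal(tc2$cor, 1, tolerance = 1e-12)
  expect_lt(tc2$p_value, 1e-10)
  expect_error(
    module_trait_relationship(me, setNames(rep(1, n), rownames(me))),
    "constant")
})
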