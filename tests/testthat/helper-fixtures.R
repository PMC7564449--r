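# Shared fixtures, built in code at test time.

# tiny expression container
make_expr <- function(values, unit = "raw_count", biotype = NULL) {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  }
  if (is.null(biotype)) {
    biotype <- stats::setNames(rep("coding", nrow(values)), rownames(values))
  }
  cw_expr(values, unit, biotype)
}

# small simulation settings for module-structure tests:
# 3 modules x 100 genes, balanced 60/60 samples
module_simcfg <- function(seed = 1, n_per_group = 60) {
  simulation_config(
    n_samples = c(codel = n_per_group, noncodel = n_per_group),
    n_genes = c(coding = 300, lncRNA = 30, pseudogene = 10, miRNA = 20),
    n_modules = 3, module_size = 100, nc_per_module = 6, psg_per_module = 2,
    n_de_up = 0, n_de_down = 0, n_de_nc = 0,
    n_sponge_mirnas = 2, targets_per_mirna = 8, nc_targets_per_mirna = 2,
    n_free_de_mirnas_up = 0, n_free_de_mirnas_down = 0,
    n_dominated = 0, rng_seed = seed)
}

# independent brute-force TOM (naive O(n^3) triple loop)
tom_bruteforce <- function(a) {
  diag(a) <- 0
  n <- nrow(a)
  k <- rowSums(a)
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) l <- l + a[i, u] * a[u, j]
    tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  dimnames(tom) <- dimnames(a)
  tom
}

# independent brute-force ARI: count concordant co-assignments over pairs
ari_bruteforce <- function(p1, p2) {
  n <- length(p1)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    same1 <- p1[i] == p1[j]
    same2 <- p2[i] == p2[j]
    if (same1 && same2) n11 <- n11 + 1
    else if (!same1 && !same2) n00 <- n00 + 1
    else if (same1) n10 <- n10 + 1
    else n01 <- n01 + 1
  }
  tot <- choose(n, 2)
  exp_idx <- (n11 + n10) * (n11 + n01) / tot
  max_idx <- ((n11 + n10) + (n11 + n01)) / 2
  if (max_idx == exp_idx) return(1)
  (n11 - exp_idx) / (max_idx - exp_idx)
}

# brute-force product-limit estimator over the risk set
km_bruteforce <- function(time, event) {
  ts <- sort(unique(time[event]))
  s <- 1
  out <- numeric(0)
  for (t in ts) {
    at_risk <- sum(time >= t)
    d <- sum(time == t & event)
    s <- s * (1 - d / at_risk)
    out <- c(out, s)
  }
  data.frame(time = ts, surv = out)
}

# optimal 1-D two-cluster split by exhaustive threshold search
kmeans1d_bruteforce <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  best_wss <- Inf
  best_cut <- NA
  for (i in seq_len(n - 1)) {
    lo <- xs[1:i]; hi <- xs[(i + 1):n]
    wss <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (wss < best_wss) {
      best_wss <- wss
      best_cut <- (xs[i] + xs[i + 1]) / 2
    }
  }
  ifelse(x > best_cut, "high", "low")
}
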