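# Synthetic cohorts with planted ground truth.
#
# Counts are negative-binomial around log-scale gene means; co-expression
# modules arise from shared latent factors. The trait module models a
# discrete genomic state (a codeletion): its genes carry a direct subgroup
# mean shift plus a small shared factor, so codel/noncodel expression
# states are nearly bimodal as in real cohorts. Sponge miRNAs load
# negatively on the module's standardized trait signal; survival hazard is
# tied to the same signal. Calibration is analytic:
#   var(log NB(mu, phi)) ~ trigamma(1/phi) + 1/mu =: w  (gamma-Poisson),
#   within-module r = shared / (shared + w) => shared = r * w / (1 - r);
# for non-trait modules shared = v_f (pure factor); for the trait module
# shared = var(direct shift) + v_t, with v_t the residual factor variance.

#' Configuration for the synthetic-cohort generator
#'
#' Defaults emulate the study cohort this pipeline was designed around:
#' 168 IDH-mutant oligodendrogliomas of which 127 carry the 1p/19q
#' codeletion, negative-binomial RNA-seq counts (dispersion 0.2), three
#' co-expression modules of which the first carries the codeletion
#' expression signature (a direct log2 shift of 2 between subgroups plus a
#' shared residual factor — the deletion is a discrete genomic state, so
#' its signature is nearly bimodal), planted differential genes at log2FC
#' 1.5, sponge miRNAs whose loading on the trait signal (0.7, with miRNA
#' residual log-SD 0.94) yields miRNA-target Pearson correlations near
#' -0.5, and exponential survival with hazard ratio 2 between trait-signal
#' halves under roughly 30% censoring.
#'
#' @param n_samples Named integer vector of samples per subgroup; the first
#'   name is the trait-positive subgroup. A subgroup named `"wildtype"`
#'   receives an extra negative shift on the trait-module genes so that
#'   three-group cohorts remain separable at k = 3.
#' @param n_genes Named vector with entries `coding`, `lncRNA`,
#'   `pseudogene`, `miRNA`.
#' @param n_modules Number of planted co-expression modules (module 1 is
#'   the trait module).
#' @param module_size Genes per module (coding plus non-coding members).
#' @param nc_per_module,psg_per_module lncRNAs / pseudogenes per module.
#' @param n_de_up,n_de_down Free (non-module) planted DE coding genes.
#' @param n_de_nc Free planted DE lncRNAs per direction.
#' @param n_sponge_mirnas miRNAs negatively coupled to the trait factor.
#' @param targets_per_mirna Coding targets per sponge miRNA.
#' @param nc_targets_per_mirna lncRNA targets per sponge miRNA.
#' @param n_free_de_mirnas_up,n_free_de_mirnas_down Planted DE miRNAs with
#'   a plain subgroup shift and no sponge coupling.
#' @param decoy_factor Decoy interaction edges per planted edge; decoys
#'   pair miRNAs with genes outside the planted modules.
#' @param within_module_cor Target pairwise Pearson r of log expression
#'   inside a module.
#' @param de_log2fc Planted log2 fold change for free DE genes/miRNAs.
#' @param nb_dispersion Negative-binomial dispersion phi
#'   (`var = mu + phi mu^2`).
#' @param sponge_strength Loading of sponge miRNAs on the standardized
#'   trait-module signal; 0 removes the coupling entirely.
#' @param trait_effect Direct log2 expression shift of trait-module genes
#'   between the trait-positive subgroup and the rest (the discrete
#'   codeletion signature).
#' @param wildtype_shift Extra negative log2 shift of trait-module genes
#'   in a wildtype subgroup.
#' @param mirna_sd Residual log-SD of miRNA RPM; the default pairs with
#'   `sponge_strength` to put sponge correlations near -0.5.
#' @param planted_logmean,null_logmean,planted_logsd,null_logsd Baseline
#'   natural-log mean distributions for planted vs background genes.
#' @param libsize_logsd Log-SD of per-sample library size factors.
#' @param baseline_hazard Hazard (per day) of the low-trait-factor half.
#' @param hazard_ratio Hazard ratio between low and high trait-factor
#'   halves (values > 1 mean high expression is protective).
#' @param censor_range Uniform censoring window in days (gives ~30%
#'   censoring at the default hazard).
#' @param n_dominated Spike-in genes violating the one-third dominance rule
#'   (exercise the filter; recorded in the truth as removable).
#' @param rng_seed Integer seed; the whole cohort is a pure function of the
#'   configuration.
#'
#' @return A list of class `cw_simcfg`.
#' @export
simulation_config <- function(n_samples = c(codel = 127, noncodel = 41),
                              n_genes = c(coding = 600, lncRNA = 60,
                                          pseudogene = 20, miRNA = 120),
                              n_modules = 3,
                              module_size = 70,
                              nc_per_module = 6,
                              psg_per_module = 2,
                              n_de_up = 60,
                              n_de_down = 80,
                              n_de_nc = 4,
                              n_sponge_mirnas = 8,
                              targets_per_mirna = 12,
                              nc_targets_per_mirna = 2,
                              n_free_de_mirnas_up = 2,
                              n_free_de_mirnas_down = 3,
                              decoy_factor = 5,
                              within_module_cor = 0.7,
                              de_log2fc = 1.5,
                              nb_dispersion = 0.2,
                              sponge_strength = 0.7,
                              trait_effect = 2.0,
                              wildtype_shift = 1.0,
                              mirna_sd = 0.94,
                              planted_logmean = log(600),
                              planted_logsd = 0.3,
                              null_logmean = log(150),
                              null_logsd = 2.0,
                              libsize_logsd = 0.15,
                              baseline_hazard = log(2) / 3000,
                              hazard_ratio = 2.0,
                              censor_range = c(2000, 20000),
                              n_dominated = 2,
                              rng_seed = 1L) {
  cfg <- as.list(environment())
  cfg$n_samples <- as.integer(n_samples)
  names(cfg$n_samples) <- names(n_samples)
  class(cfg) <- "cw_simcfg"
  stopifnot(all(cfg$n_samples > 0), !is.null(names(cfg$n_samples)),
            all(n_genes > 0), n_modules >= 1,
            within_module_cor > 0, within_module_cor < 1,
            nb_dispersion > 0, hazard_ratio > 0, baseline_hazard > 0,
            de_log2fc >= 0, decoy_factor >= 0)
  n_mod_coding <- module_size - nc_per_module - psg_per_module
  if (n_mod_coding < 2) stop("module_size too small for its nc/psg members",
                             call. = FALSE)
  if (n_modules * n_mod_coding + n_de_up + n_de_down +
        targets_per_mirna > n_genes[["coding"]]) {
    stop("infeasible config: planted coding genes exceed n_genes['coding']",
         call. = FALSE)
  }
  if (n_modules * nc_per_module + 2 * n_de_nc > n_genes[["lncRNA"]]) {
    stop("infeasible config: planted lncRNAs exceed n_genes['lncRNA']",
         call. = FALSE)
  }
  if (n_modules * psg_per_module > n_genes[["pseudogene"]]) {
    stop("infeasible config: planted pseudogenes exceed n_genes['pseudogene']",
         call. = FALSE)
  }
  if (n_sponge_mirnas + n_free_de_mirnas_up + n_free_de_mirnas_down >
        n_genes[["miRNA"]]) {
    stop("infeasible config: planted miRNAs exceed n_genes['miRNA']",
         call. = FALSE)
  }
  if (targets_per_mirna > n_mod_coding || nc_targets_per_mirna > nc_per_module) {
    stop("infeasible config: per-miRNA targets exceed trait-module members",
         call. = FALSE)
  }
  cfg
}

# Run code under a seed without disturbing the caller's RNG stream.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Factor variance hitting a target within-module log-scale correlation.
factor_variance <- function(rho, phi, mu_ref) {
  w <- trigamma(1 / phi) + 1 / mu_ref
  rho * w / (1 - rho)
}

#' Simulate a cohort with planted ceRNA structure
#'
#' Generates a coding/ncRNA count matrix, a miRNA RPM matrix, a clinical
#' table with survival, a miRNA-target interaction table (planted sponge
#' edges plus decoys), and a ground-truth record. See
#' [simulation_config()] for the generating model.
#'
#' @param cfg A [simulation_config()] object.
#' @return A list with elements `expr` ([cw_expr()], raw counts), `mirna`
#'   ([cw_expr()], RPM), `clinical` (tibble), `interactions` (tibble) and
#'   `truth` (class `cw_truth`).
#' @export
simulate_cohort <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "cw_simcfg"))
  with_local_seed(cfg$rng_seed, {
    subgroups <- names(cfg$n_samples)
    n <- sum(cfg$n_samples)
    sample_id <- sprintf("S%03d", seq_len(n))
    subgroup <- rep(subgroups, cfg$n_samples)
    trait_pos <- subgroups[1]
    z <- as.numeric(subgroup == trait_pos)
    w <- as.numeric(subgroup == "wildtype")
    pz <- mean(z); pw <- mean(w)

    # trait-module signal: direct subgroup shift (discrete deletion
    # signature) plus a small residual shared factor, calibrated so total
    # shared variance hits the within-module correlation target
    w_noise <- trigamma(1 / cfg$nb_dispersion) + 1 / exp(cfg$planted_logmean)
    shared_target <- cfg$within_module_cor * w_noise /
      (1 - cfg$within_module_cor)
    d_trait <- cfg$trait_effect * log(2)
    d_wt <- cfg$wildtype_shift * log(2)
    t_det <- d_trait * (z - pz) - d_wt * (w - pw)
    var_det <- d_trait^2 * pz * (1 - pz) + d_wt^2 * pw * (1 - pw) +
      2 * d_trait * d_wt * pz * pw
    # cap the residual factor: the deletion signature is a discrete state,
    # so within-group co-fluctuation stays small relative to the shift
    v_t <- min(max(shared_target - var_det, 0.02), 0.05)
    f1 <- stats::rnorm(n)
    trait_signal_raw <- t_det + sqrt(v_t) * f1
    trait_signal <- trait_signal_raw / sqrt(var_det + v_t)
    other_factors <- if (cfg$n_modules > 1)
      matrix(stats::rnorm(n * (cfg$n_modules - 1)), nrow = cfg$n_modules - 1)
    else matrix(numeric(0), nrow = 0, ncol = n)
    rownames(other_factors) <- paste0("M", seq_len(cfg$n_modules))[-1]

    # gene id pools
    ids <- list(
      coding = sprintf("GENE%04d", seq_len(cfg$n_genes[["coding"]])),
      lncRNA = sprintf("LNC%03d", seq_len(cfg$n_genes[["lncRNA"]])),
      pseudogene = sprintf("PSG%03d", seq_len(cfg$n_genes[["pseudogene"]])),
      miRNA = sprintf("hsa-sim-miR-%03d", seq_len(cfg$n_genes[["miRNA"]])))

    n_mod_coding <- cfg$module_size - cfg$nc_per_module - cfg$psg_per_module
    take <- function(pool, k, used) setdiff(pool, used)[seq_len(k)]

    used_c <- character(0); used_l <- character(0); used_p <- character(0)
    module_of <- character(0)
    for (m in seq_len(cfg$n_modules)) {
      mc <- take(ids$coding, n_mod_coding, used_c); used_c <- c(used_c, mc)
      ml <- take(ids$lncRNA, cfg$nc_per_module, used_l); used_l <- c(used_l, ml)
      mp <- take(ids$pseudogene, cfg$psg_per_module, used_p)
      used_p <- c(used_p, mp)
      module_of[c(mc, ml, mp)] <- paste0("M", m)
    }
    de_up_free <- take(ids$coding, cfg$n_de_up, used_c)
    used_c <- c(used_c, de_up_free)
    de_down_free <- take(ids$coding, cfg$n_de_down, used_c)
    used_c <- c(used_c, de_down_free)
    de_nc_up <- take(ids$lncRNA, cfg$n_de_nc, used_l)
    used_l <- c(used_l, de_nc_up)
    de_nc_down <- take(ids$lncRNA, cfg$n_de_nc, used_l)
    used_l <- c(used_l, de_nc_down)

    gene_id <- c(ids$coding, ids$lncRNA, ids$pseudogene)
    biotype <- c(rep("coding", length(ids$coding)),
                 rep("lncRNA", length(ids$lncRNA)),
                 rep("pseudogene", length(ids$pseudogene)))
    names(biotype) <- gene_id
    planted <- unique(c(names(module_of), de_up_free, de_down_free,
                        de_nc_up, de_nc_down))

    # baselines: planted genes sit comfortably above the quantile filter
    b <- stats::rnorm(length(gene_id), cfg$null_logmean, cfg$null_logsd)
    names(b) <- gene_id
    b[planted] <- stats::rnorm(length(planted), cfg$planted_logmean,
                               cfg$planted_logsd)

    v_f <- factor_variance(cfg$within_module_cor, cfg$nb_dispersion,
                           exp(cfg$planted_logmean))
    d_ln <- cfg$de_log2fc * log(2)
    log_sf <- stats::rnorm(n, 0, cfg$libsize_logsd)

    log_mu <- matrix(rep(b, n), nrow = length(gene_id),
                     dimnames = list(gene_id, sample_id))
    log_mu <- sweep(log_mu, 2, log_sf, `+`)
    m1 <- names(module_of)[module_of == "M1"]
    log_mu[m1, ] <- log_mu[m1, ] + rep(trait_signal_raw, each = length(m1))
    for (m in rownames(other_factors)) {
      members <- names(module_of)[module_of == m]
      log_mu[members, ] <- log_mu[members, ] +
        sqrt(v_f) * rep(other_factors[m, ], each = length(members))
    }
    up_ids <- c(de_up_free, de_nc_up)
    down_ids <- c(de_down_free, de_nc_down)
    log_mu[up_ids, ] <- log_mu[up_ids, ] +
      d_ln * rep(z - pz, each = length(up_ids))
    log_mu[down_ids, ] <- log_mu[down_ids, ] -
      d_ln * rep(z - pz, each = length(down_ids))

    counts <- matrix(
      stats::rnbinom(length(log_mu), size = 1 / cfg$nb_dispersion,
                     mu = exp(log_mu)),
      nrow = nrow(log_mu), dimnames = dimnames(log_mu))

    # dominance spike-ins: one huge sample, removable by the 1/3 rule
    dominated <- character(0)
    if (cfg$n_dominated > 0) {
      dominated <- sprintf("SPIKE%02d", seq_len(cfg$n_dominated))
      spike <- matrix(stats::rpois(cfg$n_dominated * n, 100),
                      nrow = cfg$n_dominated,
                      dimnames = list(dominated, sample_id))
      for (i in seq_len(cfg$n_dominated)) {
        spike[i, sample.int(n, 1)] <- 3e5
      }
      counts <- rbind(counts, spike)
      biotype[dominated] <- "coding"
    }

    # miRNA RPM (continuous, lognormal residuals)
    mir_id <- ids$miRNA
    sponge <- mir_id[seq_len(cfg$n_sponge_mirnas)]
    free_up <- mir_id[cfg$n_sponge_mirnas + seq_len(cfg$n_free_de_mirnas_up)]
    free_down <- mir_id[cfg$n_sponge_mirnas + cfg$n_free_de_mirnas_up +
                          seq_len(cfg$n_free_de_mirnas_down)]
    n_planted_mir <- length(sponge) + length(free_up) + length(free_down)
    n_null_mir <- length(mir_id) - n_planted_mir
    # background miRNAs: a mixture with a low-RPM tail for the floor filter
    null_bm <- ifelse(stats::runif(n_null_mir) < 0.7,
                      stats::rnorm(n_null_mir, log(20), 1.0),
                      stats::rnorm(n_null_mir, log(0.8), 0.7))
    bm <- c(stats::rnorm(n_planted_mir, log(50), 0.4), null_bm)
    names(bm) <- mir_id
    log_rpm <- matrix(rep(bm, n), nrow = length(mir_id),
                      dimnames = list(mir_id, sample_id))
    log_rpm[sponge, ] <- log_rpm[sponge, ] -
      cfg$sponge_strength * rep(trait_signal, each = length(sponge))
    log_rpm[free_up, ] <- log_rpm[free_up, ] +
      d_ln * rep(z - pz, each = length(free_up))
    log_rpm[free_down, ] <- log_rpm[free_down, ] -
      d_ln * rep(z - pz, each = length(free_down))
    rpm <- exp(log_rpm + matrix(stats::rnorm(length(log_rpm), 0, cfg$mirna_sd),
                                nrow = nrow(log_rpm)))

    # interaction table: planted sponge edges plus out-of-module decoys
    trait_members <- names(module_of)[module_of == "M1"]
    trait_coding <- trait_members[biotype[trait_members] == "coding"]
    trait_lnc <- trait_members[biotype[trait_members] == "lncRNA"]
    dbs <- c("RNAInter", "ENCORI", "mirDIP", "TarBase", "LncBase", "miRWalk")
    planted_edges <- purrr::map_dfr(sponge, function(mi) {
      tc <- sample(trait_coding, cfg$targets_per_mirna)
      tl <- sample(trait_lnc, cfg$nc_targets_per_mirna)
      tibble::tibble(
        mirna_id = mi, target_id = c(tc, tl),
        target_class = c(rep("coding", length(tc)), rep("ncRNA", length(tl))),
        source_db = sample(dbs, length(tc) + length(tl), replace = TRUE),
        evidence = sample(c("predicted", "validated"),
                          length(tc) + length(tl), replace = TRUE,
                          prob = c(0.7, 0.3)))
    })
    triplets <- planted_edges |>
      dplyr::group_by(.data$mirna_id) |>
      dplyr::summarise(
        lncRNA = list(.data$target_id[.data$target_class == "ncRNA"][1:2]),
        mRNA = list(.data$target_id[.data$target_class == "coding"][1:2]),
        .groups = "drop") |>
      tidyr::unnest(c("lncRNA", "mRNA")) |>
      dplyr::transmute(lncRNA = .data$lncRNA, miRNA = .data$mirna_id,
                       mRNA = .data$mRNA)

    n_decoy <- round(cfg$decoy_factor * nrow(planted_edges))
    nonmodule <- setdiff(gene_id, names(module_of))
    decoys <- tibble::tibble(
      mirna_id = sample(mir_id, n_decoy, replace = TRUE),
      target_id = sample(nonmodule, n_decoy, replace = TRUE),
      source_db = sample(dbs, n_decoy, replace = TRUE),
      evidence = sample(c("predicted", "validated"), n_decoy,
                        replace = TRUE, prob = c(0.9, 0.1))) |>
      dplyr::mutate(target_class = ifelse(biotype[.data$target_id] == "coding",
                                          "coding", "ncRNA"),
                    .after = "target_id")
    interactions <- dplyr::bind_rows(planted_edges, decoys) |>
      dplyr::distinct(.data$mirna_id, .data$target_id, .data$source_db,
                      .keep_all = TRUE)

    # survival: hazard switches at the trait signal's natural high/low
    # boundary (optimal 1-D split), the same boundary an expression-based
    # high/low classification recovers; the high state is protective
    high <- as.numeric(kmeans_split(trait_signal) == "high")
    lambda <- cfg$baseline_hazard * cfg$hazard_ratio^(-high)
    t_event <- stats::rexp(n, rate = lambda)
    t_cens <- stats::runif(n, cfg$censor_range[1], cfg$censor_range[2])
    clinical <- tibble::tibble(
      sample_id = sample_id, subgroup = subgroup, idh_mutant = TRUE,
      os_time = pmin(t_event, t_cens), os_event = t_event <= t_cens)

    survival_effect <- stats::setNames(
      rep(cfg$hazard_ratio, length(trait_lnc)), trait_lnc)

    truth <- structure(list(
      de_genes_up = c(de_up_free, de_nc_up,
                      if (cfg$trait_effect > 0) names(module_of)[module_of == "M1"]),
      de_genes_down = c(de_down_free, de_nc_down),
      de_mirnas_up = free_up,
      de_mirnas_down = c(if (cfg$sponge_strength > 0 && cfg$trait_effect > 0) sponge,
                         free_down),
      sponge_mirnas = sponge,
      module_of = module_of,
      trait_module = "M1",
      triplets = triplets,
      survival_effect = survival_effect,
      subgroup_of = stats::setNames(subgroup, sample_id),
      trait_factor = stats::setNames(trait_signal, sample_id),
      dominated = dominated), class = "cw_truth")

    list(expr = cw_expr(counts, "raw_count", biotype),
         mirna = cw_expr(rpm, "rpm",
                         stats::setNames(rep("miRNA", length(mir_id)), mir_id)),
         clinical = clinical,
         interactions = interactions,
         truth = truth)
  })
}

#' Summarize a simulation ground-truth record
#'
#' @param truth A `cw_truth` object from [simulate_cohort()].
#' @return A tibble of planted-object counts per category.
#' @export
describe_truth <- function(truth) {
  stopifnot(inherits(truth, "cw_truth"))
  tibble::tibble(
    category = c("de_genes_up", "de_genes_down", "de_mirnas_up",
                 "de_mirnas_down", "sponge_mirnas", "modules", "triplets",
                 "survival_effects", "samples"),
    count = c(length(truth$de_genes_up), length(truth$de_genes_down),
              length(truth$de_mirnas_up), length(truth$de_mirnas_down),
              length(truth$sponge_mirnas),
              length(unique(truth$module_of)),
              nrow(truth$triplets),
              length(truth$survival_effect),
              length(truth$subgroup_of)))
}

#' Simulate a two-arm survival dataset
#'
#' Exponential event times with a specified hazard ratio between groups and
#' uniform censoring; the building block behind the cohort generator's
#' survival arm, exposed for calibration studies.
#'
#' @param n_per_group Subjects per group.
#' @param hazard_ratio Hazard of group B relative to group A.
#' @param baseline_hazard Group-A hazard per day.
#' @param censor_range Uniform censoring window (days).
#' @return A tibble with columns `time`, `event`, `group`.
#' @export
simulate_survival <- function(n_per_group, hazard_ratio = 2,
                              baseline_hazard = log(2) / 3000,
                              censor_range = c(1000, 12000)) {
  n <- 2 * n_per_group
  group <- rep(c("A", "B"), each = n_per_group)
  lambda <- baseline_hazard * ifelse(group == "B", hazard_ratio, 1)
  t_event <- stats::rexp(n, rate = lambda)
  t_cens <- stats::runif(n, censor_range[1], censor_range[2])
  tibble::tibble(time = pmin(t_event, t_cens), event = t_event <= t_cens,
                 group = group)
}
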