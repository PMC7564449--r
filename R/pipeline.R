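# End-to-end orchestration: preprocess -> DEA -> co-expression ->
# key-module selection -> ceRNA assembly -> ARI evaluation -> survival.

run_stage <- function(name, code) {
  tryCatch(force(code), error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full ceRNA discovery pipeline
#'
#' Composes every stage under one configuration and writes all artifacts
#' plus a hash manifest under `output_dir`. Inputs come either from
#' `input_dir` (TSVs: `expression.tsv`, `mirna.tsv`, `clinical.tsv`,
#' `interactions.tsv`, `annotation.tsv`) or from the synthetic generator
#' when `simulate` is given. The key module per direction network is the
#' module with the largest absolute trait correlation; only DE miRNAs of
#' the opposite direction seed networks from it.
#'
#' @param config A [cerna_config()]. All randomness flows from
#'   `config$rng_seed`.
#' @param input_dir Directory of input TSVs (ignored when `simulate` is
#'   given).
#' @param output_dir Output directory (created if missing).
#' @param simulate `NULL`, `TRUE` (default generator settings) or a
#'   [simulation_config()]; its seed is overridden by `config$rng_seed`.
#' @param cohort `"od"` (two subgroups, k = 2) or `"lgg"` (three
#'   subgroups, k = 3); overrides `config$k_clusters`.
#' @return A list of class `cw_pipeline`: `config`, `reports`, `dea`,
#'   `mirna_dea`, `deg_counts`, `modules_up`, `modules_down`, `networks`,
#'   `evaluation`, `pairs`, `survival`, `truth` (when simulated) and
#'   `manifest`.
#' @export
run_cerna_pipeline <- function(config = cerna_config(), input_dir = NULL,
                               output_dir = tempfile("cerna_run_"),
                               simulate = NULL,
                               cohort = c("od", "lgg")) {
  validate_config(config)
  cohort <- match.arg(cohort)
  if (cohort == "lgg") config$k_clusters <- 3L
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)

  truth <- NULL
  if (!is.null(simulate)) {
    sim_cfg <- if (inherits(simulate, "cw_simcfg")) simulate
               else simulation_config()
    sim_cfg$rng_seed <- config$rng_seed
    if (cohort == "lgg" && length(sim_cfg$n_samples) < 3) {
      sim_cfg$n_samples <- c(sim_cfg$n_samples, wildtype = 60L)
    }
    sim <- run_stage("simulate", simulate_cohort(sim_cfg))
    expr_raw <- sim$expr; mirna_raw <- sim$mirna
    clinical <- sim$clinical; interactions <- sim$interactions
    truth <- sim$truth
  } else {
    if (is.null(input_dir)) stop("need input_dir or simulate", call. = FALSE)
    ann <- file.path(input_dir, "annotation.tsv")
    expr_raw <- run_stage("read", read_expression(
      file.path(input_dir, "expression.tsv"), "raw_count", ann))
    mirna_raw <- run_stage("read", read_expression(
      file.path(input_dir, "mirna.tsv"), "rpm", ann))
    clinical <- run_stage("read", read_clinical(
      file.path(input_dir, "clinical.tsv")))
    interactions <- run_stage("read", read_interactions(
      file.path(input_dir, "interactions.tsv")))
  }

  pre_m <- run_stage("preprocess", preprocess_mrna(expr_raw, config))
  pre_mi <- run_stage("preprocess", preprocess_mirna(mirna_raw, config))
  expr <- pre_m$expr
  mirna <- expr_subset(pre_mi$expr,
                       samples = intersect(sample_ids(pre_mi$expr),
                                           sample_ids(expr)))
  clinical <- dplyr::filter(clinical, .data$sample_id %in% sample_ids(expr))

  trait_level <- if ("codel" %in% clinical$subgroup) "codel"
                 else clinical$subgroup[1]
  groups <- factor(ifelse(clinical$subgroup == trait_level, "trait", "rest"),
                   levels = c("trait", "rest"))
  names(groups) <- clinical$sample_id

  dea <- run_stage("dea", differential_test(
    expr, groups, config$lfc_threshold, config$fdr_threshold))
  mirna_dea <- run_stage("dea", differential_test(
    mirna, groups[sample_ids(mirna)], config$lfc_threshold,
    config$fdr_threshold))
  deg_counts <- dplyr::count(dea, .data$biotype, .data$direction) |>
    dplyr::bind_rows(dplyr::count(mirna_dea, .data$biotype, .data$direction))

  degs <- select_degs(dea, config$lfc_threshold, config$fdr_threshold)
  run_wgcna_side <- function(genes) {
    if (length(genes) < 2 * config$min_module_size) return(NULL)
    wgcna_modules(expr_subset(expr, genes = genes), beta = config$beta,
                  min_module_size = config$min_module_size,
                  merge_cut = config$merge_cut, clinical = clinical,
                  trait_col = "subgroup")
  }
  modules_up <- run_stage("wgcna", run_wgcna_side(degs$up))
  modules_down <- run_stage("wgcna", run_wgcna_side(degs$down))

  combined <- run_stage("cerna", combine_interactions(
    split(interactions, interactions$source_db),
    rule = config$interaction_rule, min_sources = config$min_sources))

  key_module_genes <- function(mod) {
    if (is.null(mod) || is.null(mod$trait_cor) ||
          nrow(mod$trait_cor) == 0) return(character(0))
    key <- mod$trait_cor$module[which.max(abs(mod$trait_cor$cor))]
    names(mod$module_of)[mod$module_of == key]
  }
  networks <- run_stage("cerna", {
    up_nets <- build_cerna_networks(
      key_module_genes(modules_up), "up", mirna_dea, combined,
      expr$biotype, source_module = "up_key")
    down_nets <- build_cerna_networks(
      key_module_genes(modules_down), "down", mirna_dea, combined,
      expr$biotype, source_module = "down_key")
    nets <- dplyr::bind_rows(up_nets, down_nets)
    if (nrow(nets) > 0) {
      nets$network_id <- sprintf("Network%02d", seq_len(nrow(nets)))
    }
    class(nets) <- unique(c("cw_networks", class(nets)))
    nets
  })

  evaluation <- run_stage("evaluate", if (nrow(networks) > 0) {
    evaluate_networks(networks, expr, clinical, k = config$k_clusters,
                      ari_threshold = config$ari_threshold,
                      scale = config$scale_before_ward,
                      include_ncrna = config$include_ncrna_in_ari)
  } else NULL)
  retained <- if (is.null(evaluation)) networks[0, ] else
    dplyr::semi_join(networks,
                     dplyr::filter(evaluation, .data$retained),
                     by = "network_id")

  nc_genes <- gene_ids(expr)[expr$biotype %in% c("lncRNA", "pseudogene")]
  pairs <- surv <- NULL
  if (nrow(retained) > 0 && length(nc_genes) > 0) {
    expr_nc <- expr_subset(expr, genes = nc_genes)
    pairs <- run_stage("survival", filter_cerna_pairs(
      retained, expr_nc, mirna, config$cerna_corr_max))
    if (!is.null(pairs) && nrow(pairs) > 0 &&
          all(c("os_time", "os_event") %in% names(clinical))) {
      surv <- run_stage("survival", survival_stratification(
        pairs, expr_nc, clinical))
    }
  }

  # write artifacts + manifest
  out <- function(name) file.path(output_dir, name)
  readr::write_tsv(dea, out("dea_genes.tsv"), progress = FALSE)
  readr::write_tsv(mirna_dea, out("dea_mirna.tsv"), progress = FALSE)
  reports <- dplyr::bind_rows(mrna = pre_m$reports, mirna = pre_mi$reports,
                              .id = "matrix") |>
    dplyr::mutate(removed_ids = purrr::map_chr(
      .data$removed_ids, paste, collapse = ","))
  readr::write_tsv(reports, out("filter_reports.tsv"), progress = FALSE)
  for (side in c("up", "down")) {
    mod <- if (side == "up") modules_up else modules_down
    if (!is.null(mod)) {
      readr::write_tsv(tidy(mod), out(paste0("modules_", side, ".tsv")),
                       progress = FALSE)
      readr::write_tsv(tibble::as_tibble(mod$eigengenes,
                                         rownames = "sample_id"),
                       out(paste0("eigengenes_", side, ".tsv")),
                       progress = FALSE)
    }
  }
  if (nrow(networks) > 0) {
    readr::write_tsv(dplyr::select(networks, -"coding_targets", -"nc_targets"),
                     out("networks_summary.tsv"), progress = FALSE)
    write_network_sif(networks, out("networks.sif"), expr$biotype)
  }
  if (!is.null(evaluation)) {
    readr::write_tsv(evaluation, out("network_evaluation.tsv"),
                     progress = FALSE)
  }
  if (!is.null(surv)) {
    readr::write_tsv(tibble::as_tibble(surv), out("survival_pairs.tsv"),
                     progress = FALSE)
  }
  write_config(config, out("config.yaml"))
  files <- sort(setdiff(list.files(output_dir), "manifest.tsv"))
  manifest <- tibble::tibble(
    file = files,
    md5 = unname(tools::md5sum(file.path(output_dir, files))))
  readr::write_tsv(manifest, out("manifest.tsv"), progress = FALSE)

  structure(list(config = config, reports = reports, dea = dea,
                 mirna_dea = mirna_dea, deg_counts = deg_counts,
                 modules_up = modules_up, modules_down = modules_down,
                 networks = networks, evaluation = evaluation,
                 pairs = pairs, survival = surv, truth = truth,
                 output_dir = output_dir, manifest = manifest),
            class = "cw_pipeline")
}

#' @export
print.cw_pipeline <- function(x, ...) {
  cat("<cw_pipeline> run at", x$output_dir, "\n")
  cat("  DEGs:", sum(x$dea$direction != "ns"), "genes,",
      sum(x$mirna_dea$direction != "ns"), "miRNAs\n")
  cat("  networks built:", nrow(x$networks), "| retained:",
      if (is.null(x$evaluation)) 0 else sum(x$evaluation$retained), "\n")
  if (!is.null(x$survival)) {
    cat("  survival pairs:", nrow(x$survival), "| FDR<0.05:",
        sum(x$survival$fdr < 0.05), "\n")
  }
  invisible(x)
}

#' @export
glance.cw_pipeline <- function(x, ...) {
  tibble::tibble(
    n_degs = sum(x$dea$direction != "ns"),
    n_de_mirnas = sum(x$mirna_dea$direction != "ns"),
    n_networks = nrow(x$networks),
    n_retained = if (is.null(x$evaluation)) 0L else
      sum(x$evaluation$retained),
    n_survival_pairs = if (is.null(x$survival)) 0L else nrow(x$survival),
    seed = x$config$rng_seed)
}
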