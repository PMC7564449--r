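#' Combine miRNA-target interaction tables
#'
#' Multiple interaction resources are combined into one deduplicated edge
#' set. `"union"` (default) keeps any edge seen in any resource,
#' `"intersection"` keeps edges present in every table supplied, and
#' `"min_sources"` keeps edges backed by at least `min_sources` distinct
#' source databases.
#'
#' @param tables A list of interaction tibbles (see [read_interactions()]),
#'   or a single tibble.
#' @param rule Combination rule.
#' @param min_sources Minimum distinct `source_db` count for
#'   `"min_sources"`.
#' @return A deduplicated interaction tibble; `n_sources` records the
#'   number of distinct supporting databases per edge.
#' @export
combine_interactions <- function(tables,
                                 rule = c("union", "intersection",
                                          "min_sources"),
                                 min_sources = 2) {
  rule <- match.arg(rule)
  if (is.data.frame(tables)) tables <- list(tables)
  stopifnot(length(tables) >= 1)
  all_edges <- dplyr::bind_rows(tables, .id = ".table")
  support <- all_edges |>
    dplyr::group_by(.data$mirna_id, .data$target_id) |>
    dplyr::summarise(n_sources = dplyr::n_distinct(.data$source_db),
                     n_tables = dplyr::n_distinct(.data$.table),
                     .groups = "drop")
  combined <- all_edges |>
    dplyr::distinct(.data$mirna_id, .data$target_id, .keep_all = TRUE) |>
    dplyr::select(-".table") |>
    dplyr::left_join(support, by = c("mirna_id", "target_id"))
  out <- switch(rule,
    union = combined,
    intersection = dplyr::filter(combined, .data$n_tables == length(tables)),
    min_sources = dplyr::filter(combined, .data$n_sources >= min_sources))
  dplyr::select(out, -"n_tables")
}

#' Assemble candidate ceRNA networks
#'
#' One network per differentially expressed miRNA whose direction is
#' opposite to the key module's direction: its targets are the module
#' members supported by the interaction table. Networks without a coding
#' target are dropped, and a network must contain at least one non-coding
#' target (the sponge arm) to qualify as a ceRNA network.
#'
#' @param module_genes Character vector of key-module gene ids.
#' @param module_direction `"up"` or `"down"`: the DE direction of the
#'   module's genes.
#' @param de_mirnas A `cw_dea` tibble (or any tibble with `gene_id` and
#'   `direction`) for the miRNAs.
#' @param interactions Combined interaction tibble
#'   (see [combine_interactions()]).
#' @param annotation Named biotype vector covering the targets; targets
#'   with no annotation are skipped with a warning.
#' @param source_module Module label recorded on each network.
#' @return A tibble of class `cw_networks`: one row per network with
#'   `network_id`, `mirna_id`, `mirna_direction`, `source_module`,
#'   list-columns `coding_targets` / `nc_targets`, and counts.
#' @export
build_cerna_networks <- function(module_genes, module_direction,
                                 de_mirnas, interactions, annotation,
                                 source_module = NA_character_) {
  stopifnot(module_direction %in% c("up", "down"))
  opposite <- if (module_direction == "up") "down" else "up"
  hubs <- de_mirnas$gene_id[de_mirnas$direction == opposite]
  empty <- tibble::tibble(network_id = character(), mirna_id = character(),
                          mirna_direction = character(),
                          source_module = character(),
                          coding_targets = list(), nc_targets = list(),
                          n_coding = integer(), n_nc = integer())
  class(empty) <- c("cw_networks", class(empty))
  if (length(hubs) == 0 || nrow(interactions) == 0) return(empty)

  unknown <- setdiff(unique(interactions$target_id), names(annotation))
  if (length(unknown) > 0) {
    warning(length(unknown), " interaction target(s) missing annotation; skipped",
            call. = FALSE)
  }
  rows <- purrr::map_dfr(sort(hubs), function(mi) {
    tg <- interactions$target_id[interactions$mirna_id == mi]
    tg <- intersect(tg, module_genes)
    tg <- tg[tg %in% names(annotation)]
    bt <- annotation[tg]
    coding <- sort(tg[bt == "coding"])
    nc <- sort(tg[bt %in% c("lncRNA", "pseudogene")])
    if (length(coding) == 0 || length(nc) == 0) return(NULL)
    tibble::tibble(mirna_id = mi, mirna_direction = opposite,
                   source_module = source_module,
                   coding_targets = list(coding), nc_targets = list(nc),
                   n_coding = length(coding), n_nc = length(nc))
  })
  if (nrow(rows) == 0) return(empty)
  rows <- dplyr::mutate(rows,
                        network_id = sprintf("Network%02d", dplyr::row_number()),
                        .before = 1)
  class(rows) <- c("cw_networks", class(rows))
  cw_log("cerna", hubs = length(hubs), networks = nrow(rows))
  rows
}

#' @export
tidy.cw_networks <- function(x, ...) network_edges(x)

#' @export
glance.cw_networks <- function(x, ...) {
  tibble::tibble(n_networks = nrow(x),
                 n_mirnas = dplyr::n_distinct(x$mirna_id),
                 n_coding_targets = length(unique(unlist(x$coding_targets))),
                 n_nc_targets = length(unique(unlist(x$nc_targets))))
}
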