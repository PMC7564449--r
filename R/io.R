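#' Read an expression TSV
#'
#' Expects a tab-separated file with a header row of sample ids and gene ids
#' in the first column (genes-in-rows, the dominant TCGA dialect); set
#' `genes_in_rows = FALSE` to transpose on read. An optional annotation TSV
#' (columns `gene_id`, `biotype`, optionally `chromosome`) supplies biotypes;
#' unannotated genes fall back to `"coding"` with a warning.
#'
#' @param path Path to the expression TSV.
#' @param unit Measurement unit tag, see [cw_expr()].
#' @param annotation Optional path to an annotation TSV, or a data frame.
#' @param genes_in_rows Logical; transpose on read when `FALSE`.
#' @return A [cw_expr()] object.
#' @export
read_expression <- function(path, unit, annotation = NULL,
                            genes_in_rows = TRUE) {
  raw <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  id_col <- names(raw)[1]
  ids <- as.character(raw[[id_col]])
  if (anyDuplicated(ids)) {
    stop("duplicate ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  vals <- raw[-1]
  non_num <- !vapply(vals, is.numeric, logical(1))
  if (any(non_num)) {
    bad <- names(vals)[non_num][1]
    row <- which(is.na(suppressWarnings(as.numeric(vals[[bad]]))))[1]
    stop("non-numeric cell in ", path, " (column '", bad, "', data row ",
         ifelse(is.na(row), "?", row), ")", call. = FALSE)
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (!genes_in_rows) m <- t(m)
  bt <- NULL
  if (!is.null(annotation)) {
    ann <- if (is.data.frame(annotation)) annotation else
      readr::read_tsv(annotation, col_types = readr::cols(), progress = FALSE)
    bt <- stats::setNames(as.character(ann$biotype), as.character(ann$gene_id))
  }
  cw_expr(m, unit = unit, biotype = bt)
}

#' Write an expression container to TSV (genes in rows)
#'
#' @param expr A [cw_expr()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  stopifnot(inherits(expr, "cw_expr"))
  tibble::as_tibble(expr$values, rownames = "gene_id") |>
    readr::write_tsv(path, progress = FALSE)
  invisible(path)
}

#' Read a clinical table
#'
#' One row per sample with columns `sample_id`, `subgroup` (e.g. codel /
#' noncodel / wildtype), `idh_mutant`, and optionally `os_time` (days) and
#' `os_event`. Missing survival columns only block the survival stage.
#'
#' @param path Path to a TSV.
#' @return A tibble.
#' @export
read_clinical <- function(path) {
  cl <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  validate_clinical(cl)
  cl
}

validate_clinical <- function(cl) {
  need <- c("sample_id", "subgroup")
  miss <- setdiff(need, names(cl))
  if (length(miss) > 0) {
    stop("clinical table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(cl$sample_id)) {
    stop("clinical table has duplicated sample ids", call. = FALSE)
  }
  if ("os_time" %in% names(cl) && any(stats::na.omit(cl$os_time) < 0)) {
    stop("negative survival times in clinical table", call. = FALSE)
  }
  invisible(cl)
}

#' Read a miRNA-target interaction table
#'
#' Tab-separated edge list with columns `mirna_id`, `target_id`,
#' `target_class` (`coding` or `ncRNA`), `source_db`, `evidence`
#' (`predicted` or `validated`). Stands in for lookups against resources
#' such as RNAInter, ENCORI, mirDIP, TarBase, LncBase and miRWalk.
#'
#' @param path Path to a TSV.
#' @return A tibble, deduplicated on (mirna_id, target_id, source_db).
#' @export
read_interactions <- function(path) {
  tb <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  need <- c("mirna_id", "target_id", "target_class", "source_db", "evidence")
  miss <- setdiff(need, names(tb))
  if (length(miss) > 0) {
    stop("interaction table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  dplyr::distinct(tb, .data$mirna_id, .data$target_id, .data$source_db,
                  .keep_all = TRUE)
}

#' Export ceRNA networks as Cytoscape SIF plus node attributes
#'
#' Writes one line per miRNA-target edge with relation `targets`, and a
#' companion `<path>.nodes.tsv` with node id, biotype and regulation
#' direction.
#'
#' @param networks A `cw_networks` tibble from [build_cerna_networks()], or
#'   any tibble with `mirna_id`, `coding_targets`, `nc_targets` list-columns.
#' @param path Output SIF path.
#' @param annotation Optional named biotype vector for the attribute file.
#' @return `path`, invisibly.
#' @export
write_network_sif <- function(networks, path, annotation = NULL) {
  edges <- network_edges(networks)
  if (nrow(edges) == 0) stop("cannot export an empty network", call. = FALSE)
  readr::write_tsv(
    tibble::tibble(source = edges$mirna_id, relation = "targets",
                   target = edges$target_id),
    path, col_names = FALSE, progress = FALSE)
  nodes <- tibble::tibble(
    node_id = c(unique(edges$mirna_id), unique(edges$target_id)),
    role = c(rep("miRNA_hub", length(unique(edges$mirna_id))),
             rep("target", length(unique(edges$target_id)))))
  nodes$biotype <- if (is.null(annotation)) NA_character_ else
    unname(annotation[nodes$node_id])
  dirs <- c(stats::setNames(edges$mirna_direction, edges$mirna_id),
            stats::setNames(edges$target_direction, edges$target_id))
  nodes$direction <- unname(dirs[nodes$node_id])
  readr::write_tsv(nodes, paste0(path, ".nodes.tsv"), progress = FALSE)
  invisible(path)
}

#' Read a SIF edge list back into a tibble
#'
#' @param path Path to a SIF written by [write_network_sif()].
#' @return A tibble with columns `source`, `relation`, `target`.
#' @export
read_network_sif <- function(path) {
  readr::read_tsv(path, col_names = c("source", "relation", "target"),
                  col_types = "ccc", progress = FALSE)
}

# Flatten a networks tibble into one row per (miRNA, target) edge.
network_edges <- function(networks) {
  stopifnot(is.data.frame(networks))
  if (nrow(networks) == 0) {
    return(tibble::tibble(mirna_id = character(), mirna_direction = character(),
                          target_id = character(), target_class = character(),
                          target_direction = character()))
  }
  purrr::pmap_dfr(networks, function(mirna_id, mirna_direction,
                                     coding_targets, nc_targets, ...) {
    tdir <- if (identical(mirna_direction, "down")) "up" else "down"
    tibble::tibble(
      mirna_id = mirna_id,
      mirna_direction = mirna_direction,
      target_id = c(coding_targets, nc_targets),
      target_class = c(rep("coding", length(coding_targets)),
                       rep("ncRNA", length(nc_targets))),
      target_direction = tdir)
  })
}

# One structured log line per stage so filter attrition is auditable.
cw_log <- function(stage, ...) {
  kv <- c(...)
  msg <- paste0("[", stage, "] ",
                paste(names(kv), unname(kv), sep = "=", collapse = " "))
  message(msg)
  invisible(msg)
}
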