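#' Expression matrix container
#'
#' `cw_expr()` wraps a dense genes x samples numeric matrix together with the
#' measurement unit and a per-gene biotype annotation. Every pipeline stage
#' consumes and returns this container; tabular views are available through
#' [tidy()] / [as_tibble()].
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param unit One of `"raw_count"`, `"normalized_count"`, `"rpm"`,
#'   `"log2_rpm_plus1"`, `"log_normalized"`.
#' @param biotype Named character vector mapping every gene id to one of
#'   `"coding"`, `"lncRNA"`, `"pseudogene"`, `"miRNA"`. Genes missing from
#'   the map are assigned `"coding"` with a warning.
#'
#' @return An object of class `cw_expr`: a list with elements `values`,
#'   `unit` and `biotype`.
#' @export
#' @examples
#' m <- matrix(rpois(6, 10), 3, 2,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:2)))
#' e <- cw_expr(m, "raw_count", setNames(rep("coding", 3), rownames(m)))
#' dim(e)
cw_expr <- function(values,
                    unit = c("raw_count", "normalized_count", "rpm",
                             "log2_rpm_plus1", "log_normalized"),
                    biotype = NULL) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must carry gene rownames and sample colnames", call. = FALSE)
  }
  gid <- rownames(values)
  sid <- colnames(values)
  if (anyDuplicated(gid)) {
    stop("duplicate gene ids: ",
         paste(unique(gid[duplicated(gid)]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(sid)) {
    stop("duplicate sample ids: ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "), call. = FALSE)
  }
  if (anyNA(values)) stop("expression values contain NA", call. = FALSE)
  if (!unit %in% c("log2_rpm_plus1", "log_normalized") && any(values < 0)) {
    stop("negative values are not allowed for unit '", unit, "'", call. = FALSE)
  }
  if (is.null(biotype)) biotype <- character(0)
  missing_bt <- setdiff(gid, names(biotype))
  if (length(missing_bt) > 0) {
    warning(length(missing_bt),
            " gene(s) missing from annotation; assigned biotype 'coding'",
            call. = FALSE)
    biotype[missing_bt] <- "coding"
  }
  biotype <- biotype[gid]
  bad_bt <- setdiff(unique(biotype), c("coding", "lncRNA", "pseudogene", "miRNA"))
  if (length(bad_bt) > 0) {
    stop("unknown biotype(s): ", paste(bad_bt, collapse = ", "), call. = FALSE)
  }
  structure(list(values = values, unit = unit, biotype = biotype),
            class = "cw_expr")
}

#' @export
dim.cw_expr <- function(x) dim(x$values)

#' @export
print.cw_expr <- function(x, ...) {
  cat("<cw_expr> ", nrow(x$values), " genes x ", ncol(x$values),
      " samples [", x$unit, "]\n", sep = "")
  bt <- table(x$biotype)
  cat("  biotypes:", paste(names(bt), bt, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

gene_ids <- function(expr) rownames(expr$values)
sample_ids <- function(expr) colnames(expr$values)

is_log_unit <- function(unit) unit %in% c("log2_rpm_plus1", "log_normalized")

#' Subset an expression container
#'
#' @param expr A [cw_expr()] object.
#' @param genes,samples Character vectors of ids to keep (`NULL` keeps all).
#' @return A `cw_expr` restricted to the requested genes/samples, in the
#'   requested order.
#' @export
expr_subset <- function(expr, genes = NULL, samples = NULL) {
  stopifnot(inherits(expr, "cw_expr"))
  if (is.null(genes)) genes <- gene_ids(expr)
  if (is.null(samples)) samples <- sample_ids(expr)
  missing_g <- setdiff(genes, gene_ids(expr))
  if (length(missing_g) > 0) {
    stop("unknown gene id(s): ", paste(utils::head(missing_g, 5), collapse = ", "),
         call. = FALSE)
  }
  missing_s <- setdiff(samples, sample_ids(expr))
  if (length(missing_s) > 0) {
    stop("unknown sample id(s): ", paste(utils::head(missing_s, 5), collapse = ", "),
         call. = FALSE)
  }
  cw_expr(expr$values[genes, samples, drop = FALSE], expr$unit,
          expr$biotype[genes])
}

#' Expression values on a log2 scale
#'
#' Count-scale units are transformed as `log2(x + 1)`; log-scale units are
#' returned as-is. Used everywhere a correlation or a clustering needs a
#' variance-stabilized scale.
#'
#' @param expr A [cw_expr()] object.
#' @return A numeric genes x samples matrix.
#' @export
expr_log2 <- function(expr) {
  stopifnot(inherits(expr, "cw_expr"))
  if (is_log_unit(expr$unit)) expr$values else log2(expr$values + 1)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an expression container into a long tibble
#'
#' @param x A [cw_expr()] object.
#' @param ... Unused.
#' @return A tibble with columns `gene_id`, `biotype`, `sample_id`, `value`.
#' @export
tidy.cw_expr <- function(x, ...) {
  tibble::as_tibble(x$values, rownames = "gene_id") |>
    dplyr::mutate(biotype = unname(x$biotype), .after = "gene_id") |>
    tidyr::pivot_longer(cols = -c("gene_id", "biotype"),
                        names_to = "sample_id", values_to = "value")
}

#' @export
glance.cw_expr <- function(x, ...) {
  tibble::tibble(n_genes = nrow(x$values), n_samples = ncol(x$values),
                 unit = x$unit,
                 n_coding = sum(x$biotype == "coding"),
                 n_lncRNA = sum(x$biotype == "lncRNA"),
                 n_pseudogene = sum(x$biotype == "pseudogene"),
                 n_miRNA = sum(x$biotype == "miRNA"))
}
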