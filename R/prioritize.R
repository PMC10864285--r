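#' Is a gene symbol an uncharacterized "CG + number" name?
#'
#' Genes whose only name is a systematic CG number are treated as not well
#' studied and therefore worth screening. Multi-gene probe-set symbols joined
#' by `"///"` are split, and the record counts as uncharacterized if any
#' component is a bare CG number. The match is case-sensitive and exact:
#' `"CG4951"` qualifies, `"CG"` and `"CG4951-RA"` do not.
#'
#' @param symbol Character vector of gene symbols.
#' @return Logical vector.
#' @examples
#' is_uncharacterized(c("CG4951", "Dtwd2", "CG18787 /// CG18789"))
#' @export
is_uncharacterized <- function(symbol) {
  vapply(as.character(symbol), function(s) {
    parts <- trimws(strsplit(s, "///", fixed = TRUE)[[1]])
    any(grepl("^CG[0-9]+$", parts))
  }, logical(1), USE.NAMES = FALSE)
}

#' Keep only candidates with an available RNAi stock
#'
#' @param genes Data frame of candidates with a `gene_id` column.
#' @param stock_table Data frame mapping `gene_id` to `stock_id` (one row per
#'   stock).
#' @return List with `kept` and `removed` tibbles; `kept` gains a
#'   `has_rnai_stock` column (always `TRUE`) and a `stock_ids` list-column.
#' @export
filter_by_stock <- function(genes, stock_table) {
  stopifnot(is.data.frame(genes), "gene_id" %in% names(genes),
            is.data.frame(stock_table),
            all(c("gene_id", "stock_id") %in% names(stock_table)))
  stocks <- split(as.character(stock_table$stock_id),
                  as.character(stock_table$gene_id))
  has <- genes$gene_id %in% names(stocks)
  kept <- tibble::as_tibble(genes[has, , drop = FALSE])
  kept$has_rnai_stock <- TRUE
  kept$stock_ids <- unname(stocks[kept$gene_id])
  list(kept = kept, removed = tibble::as_tibble(genes[!has, , drop = FALSE]))
}

#' Annotate candidates with orthologs
#'
#' Pure table join; the sentinel `"notfound"` is used for genes without an
#' ortholog entry (never an empty string).
#'
#' @param genes Data frame with `gene_id`.
#' @param ortholog_table Data frame with `gene_id`, `human`, `mouse`.
#' @return `genes` with `human_ortholog` and `mouse_ortholog` columns added.
#' @export
annotate_orthologs <- function(genes, ortholog_table) {
  stopifnot(all(c("gene_id", "human", "mouse") %in% names(ortholog_table)))
  i <- match(genes$gene_id, ortholog_table$gene_id)
  fill <- function(x) {
    x <- as.character(x)
    x[is.na(x) | x == ""] <- "notfound"
    x
  }
  genes$human_ortholog <- fill(ortholog_table$human[i])
  genes$mouse_ortholog <- fill(ortholog_table$mouse[i])
  tibble::as_tibble(genes)
}

#' Collapse stage-level single-cell expression to cluster medians
#'
#' Each ovary cell cluster (germ cells, germarium soma, follicle cells) is
#' summarized as the median of the stage-level expression values assigned to
#' it; even stage counts use the midpoint of the two central values (the
#' ordinary sample median).
#'
#' @param stage_values Named numeric vector, stage -> expression value.
#' @param stage_to_cluster Named character vector, stage -> cluster label.
#'   Every stage in `stage_values` must be mapped.
#' @return Tibble with `cluster`, `median`, `n_stages`. Clusters present in
#'   the map but with no stage values get `median = NA` and are flagged via
#'   `n_stages = 0`.
#' @examples
#' cluster_median(c(a = 2, b = 4, c = 10), c(a = "gc", b = "gc", c = "gc"))
#' @export
cluster_median <- function(stage_values, stage_to_cluster) {
  stages <- names(stage_values)
  unmapped <- setdiff(stages, names(stage_to_cluster))
  if (length(unmapped)) {
    stop("stages with no cluster assignment: ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  }
  clusters <- unique(unname(stage_to_cluster))
  med <- vapply(clusters, function(cl) {
    v <- stage_values[stages[stage_to_cluster[stages] == cl]]
    if (length(v) == 0) NA_real_ else stats::median(v)
  }, numeric(1))
  n <- vapply(clusters, function(cl) {
    sum(stage_to_cluster[stages] == cl)
  }, integer(1))
  tibble::tibble(cluster = clusters, median = unname(med), n_stages = unname(n))
}

#' Is a gene germline-biased in the single-cell data?
#'
#' `TRUE` when the germ-cell (GC) cluster value strictly exceeds both the
#' germarium-soma and follicle-cell values; a tie is not "higher".
#'
#' @param gc,soma,fc Cluster median expression values (vectors recycle).
#' @return Logical vector.
#' @examples
#' germline_bias(5, 1, 2)
#' germline_bias(2, 2, 1)
#' @export
germline_bias <- function(gc, soma, fc) {
  if (any(is.na(gc) | is.na(soma) | is.na(fc))) {
    stop("undefined cluster value: gc/soma/fc must all be defined", call. = FALSE)
  }
  gc > soma & gc > fc
}

#' Prioritize selected candidates for experimental validation
#'
#' From a candidate table, keeps uncharacterized (CG-number) genes that have
#' at least one RNAi stock, annotates orthologs, and optionally applies an
#' explicit include/exclude list standing in for manual review.
#'
#' @param candidates Tibble with `gene_id`, `gene_symbol` (as produced by
#'   [run_selection_funnel()]).
#' @param stock_table Data frame `gene_id`, `stock_id`.
#' @param ortholog_table Optional data frame `gene_id`, `human`, `mouse`.
#' @param include,exclude Optional character vectors of gene ids forced in /
#'   out after the automatic filters.
#' @return Tibble of prioritized candidates with `uncharacterized`,
#'   `has_rnai_stock`, `stock_ids` and ortholog columns.
#' @export
prioritize_candidates <- function(candidates, stock_table,
                                  ortholog_table = NULL,
                                  include = character(), exclude = character()) {
  out <- tibble::as_tibble(candidates)
  out$uncharacterized <- is_uncharacterized(out$gene_symbol)
  out <- out[out$uncharacterized | out$gene_id %in% include, , drop = FALSE]
  out <- filter_by_stock(out, stock_table)$kept
  if (!is.null(ortholog_table)) out <- annotate_orthologs(out, ortholog_table)
  out[!out$gene_id %in% exclude, , drop = FALSE]
}
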