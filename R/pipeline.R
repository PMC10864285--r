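#' Write a run manifest
#'
#' Records everything needed to reproduce a run: the package and R versions,
#' the seed, the full threshold configuration, and MD5 digests of every input
#' and output file.
#'
#' @param dir Output directory.
#' @param thresholds The [screen_thresholds()] used.
#' @param inputs Named character vector of input file paths.
#' @param outputs Named character vector of output file paths.
#' @param seed Integer seed used for any randomness (or `NULL`).
#' @param extra Optional named list merged into the manifest.
#' @return Invisibly, the manifest path.
#' @export
write_run_manifest <- function(dir, thresholds, inputs = character(),
                               outputs = character(), seed = NULL,
                               extra = list()) {
  digest_files <- function(paths) {
    if (length(paths) == 0) return(list())
    existing <- paths[file.exists(paths)]
    as.list(tools::md5sum(existing))
  }
  manifest <- c(list(
    package = "ovascreen",
    version = as.character(utils::packageVersion("ovascreen")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    thresholds = unclass(as_thresholds(thresholds)),
    input_digests = digest_files(inputs),
    output_digests = digest_files(outputs)
  ), extra)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Run the screen pipeline end to end
#'
#' Executes whichever stages the configuration provides inputs for, in
#' order: candidate selection from an expression matrix, prioritization
#' against a stock table, screen-table scoring, and overrepresentation /
#' PPI-network analysis of the positive genes. Each stage's tables are
#' written to `out` and a manifest records the configuration and file
#' digests.
#'
#' @param config Either a YAML file path or a named list. Recognised
#'   entries: `matrix` (expression TSV path), `whole_body`,
#'   `exclude_tissues`, `stocks` (TSV `gene_id`/`stock_id`), `orthologs`
#'   (TSV `gene_id`/`human`/`mouse`), `screen_table` (TSV in the screen cell
#'   dialect), `gmt`, `edges` (TSV `gene_a`/`gene_b`/`combined_score`),
#'   `thresholds` (list of [screen_thresholds()] overrides), `seed`.
#' @param out Output directory.
#' @return Invisibly, a list of the in-memory stage results plus
#'   `manifest` (path).
#' @export
run_pipeline <- function(config, out) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  th <- as_thresholds(config$thresholds)
  if (!is.null(config$seed)) set.seed(as.integer(config$seed))
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write_tsv <- function(df, name) {
    df <- as.data.frame(df)
    for (j in seq_along(df)) {
      if (is.list(df[[j]])) {
        df[[j]] <- vapply(df[[j]], paste, character(1), collapse = ",")
      }
    }
    path <- file.path(out, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  results <- list()
  outputs <- character()
  inputs <- unlist(config[intersect(names(config),
                                    c("matrix", "stocks", "orthologs",
                                      "screen_table", "gmt", "edges"))])

  if (!is.null(config$matrix)) {
    profiles <- read_expression_matrix(
      config$matrix,
      whole_body = config$whole_body %||% "whole_body",
      exclude_tissues = config$exclude_tissues %||% character())
    sel <- run_selection_funnel(profiles, thresholds = th,
                                whole_body = config$whole_body %||% "whole_body")
    results$selection <- sel
    outputs["candidates"] <- write_tsv(sel$candidates, "candidates.tsv")
    outputs["funnel"] <- write_tsv(sel$report, "funnel_report.tsv")
    if (!is.null(config$stocks)) {
      stocks <- utils::read.table(config$stocks, header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE)
      orth <- if (!is.null(config$orthologs)) {
        utils::read.table(config$orthologs, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
      }
      pri <- prioritize_candidates(sel$candidates, stocks, orth)
      results$prioritized <- pri
      outputs["prioritized"] <- write_tsv(pri, "prioritized.tsv")
    }
  }

  positives <- NULL
  if (!is.null(config$screen_table)) {
    sc <- score_screen(config$screen_table, thresholds = th)
    results$screen <- sc
    positives <- sc$gene_calls$gene_symbol[sc$gene_calls$positive]
    outputs["line_calls"] <- write_tsv(sc$line_calls, "line_calls.tsv")
    outputs["gene_calls"] <- write_tsv(sc$gene_calls, "gene_calls.tsv")
    outputs["venn"] <- write_tsv(sc$venn, "venn_summary.tsv")
  }

  if (!is.null(config$gmt) && !is.null(positives)) {
    terms <- read_gmt(config$gmt)
    results$overrepresentation <- overrepresentation(
      intersect(positives, unique(unlist(terms$members))),
      terms, thresholds = th)
    outputs["overrepresentation"] <-
      write_tsv(results$overrepresentation, "overrepresentation.tsv")
  }
  if (!is.null(config$edges) && !is.null(positives)) {
    edges <- utils::read.table(config$edges, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
    net <- ppi_subnetwork(edges, positives, thresholds = th)
    results$network <- net
    outputs["components"] <- write_tsv(net$membership, "ppi_membership.tsv")
  }

  results$manifest <- write_run_manifest(out, th, inputs = inputs,
                                         outputs = outputs,
                                         seed = config$seed)
  invisible(results)
}
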