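#' Upper-tail hypergeometric overrepresentation p-value
#'
#' Probability of drawing at least `k` members of a `K`-gene term when `n`
#' genes are sampled without replacement from a background of `N`, i.e.
#' P(X >= k) for X ~ Hypergeometric(N, K, n). This is the standard
#' overrepresentation direction.
#'
#' @param k Observed overlap between the input set and the term.
#' @param K Term size within the background.
#' @param n Input-set size within the background.
#' @param N Background size.
#' @return P(X >= k). Vectorized over its arguments.
#' @examples
#' hypergeom_p(0, 5, 10, 50) # P(X >= 0) = 1
#' @export
hypergeom_p <- function(k, K, n, N) {
  bad <- is.na(k) | is.na(K) | is.na(n) | is.na(N) |
    k < 0 | k > pmin(K, n) | K > N | n > N
  if (any(bad)) {
    stop("need 0 <= k <= min(K, n) and K, n <= N", call. = FALSE)
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment; elementwise `q >= p`,
#' order-preserving, idempotent.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values, same order as the input.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03))
#' @export
bh_fdr <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Read a GMT gene-set file
#'
#' One term per line: term id, description, then tab-separated member genes.
#'
#' @param path GMT file path.
#' @return Tibble with `term_id`, `term_name` and a `members` list-column of
#'   unique gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad)) {
    stop("GMT line ", bad[1], " has fewer than 3 fields", call. = FALSE)
  }
  tibble::tibble(
    term_id = vapply(parts, `[[`, character(1), 1),
    term_name = vapply(parts, `[[`, character(1), 2),
    members = lapply(parts, function(p) unique(p[-(1:2)]))
  )
}

#' Gene-set overrepresentation analysis
#'
#' For each term, counts the overlap with the input set, drops terms whose
#' overlap is below `min_term_overlap` (default: at least two input genes)
#' before any testing, computes the upper-tail hypergeometric p-value, and
#' adjusts across the retained terms with Benjamini-Hochberg FDR.
#'
#' @param input_genes Character vector of query genes; must be contained in
#'   the background.
#' @param terms Tibble as from [read_gmt()] (or any data frame with
#'   `term_id`, `term_name`, `members`).
#' @param background Character vector of background genes. Defaults to the
#'   union of all term members, since database-internal backgrounds are
#'   rarely published; supply the true assay universe when known.
#' @param thresholds [screen_thresholds()] or overrides (uses
#'   `min_term_overlap`).
#' @return Tibble sorted by p-value with `term_id`, `term_name`, `k`, `K`,
#'   `n`, `N`, `p_value`, `q_value` and an `overlap` list-column.
#' @export
overrepresentation <- function(input_genes, terms, background = NULL,
                               thresholds = screen_thresholds()) {
  th <- as_thresholds(thresholds)
  stopifnot(all(c("term_id", "members") %in% names(terms)))
  if (is.null(background)) background <- unique(unlist(terms$members))
  background <- unique(as.character(background))
  if (length(background) == 0) stop("empty background set", call. = FALSE)
  input_genes <- unique(as.character(input_genes))
  outside <- setdiff(input_genes, background)
  if (length(outside)) {
    stop("input genes missing from the background: ",
         paste(utils::head(outside, 5), collapse = ", "),
         if (length(outside) > 5) ", ..." else "", call. = FALSE)
  }
  members <- lapply(terms$members, function(m) intersect(unique(m), background))
  overlap <- lapply(members, intersect, x = input_genes)
  k <- lengths(overlap)
  keep <- k >= th$min_term_overlap
  res <- tibble::tibble(
    term_id = terms$term_id[keep],
    term_name = if ("term_name" %in% names(terms)) terms$term_name[keep]
                else terms$term_id[keep],
    k = k[keep],
    K = lengths(members)[keep],
    n = length(input_genes),
    N = length(background),
    overlap = overlap[keep]
  )
  res$p_value <- if (nrow(res)) hypergeom_p(res$k, res$K, res$n, res$N) else numeric(0)
  res$q_value <- bh_fdr(res$p_value)
  res[order(res$p_value, res$term_id), , drop = FALSE]
}

#' Confidence-filtered protein-protein interaction subnetwork
#'
#' Keeps edges with combined confidence score at or above `min_ppi_score`
#' (default 0.4, "medium confidence"), de-duplicates repeated pairs keeping
#' the maximum score, drops self-loops, induces the subgraph on the query
#' gene set and reports connected components sorted by size.
#'
#' @param edges Data frame with `gene_a`, `gene_b`, `combined_score` (scores
#'   in \[0, 1\]); interactions are undirected.
#' @param genes Character vector of genes to induce on. Genes with no
#'   surviving edge appear as isolated vertices.
#' @param thresholds [screen_thresholds()] or overrides (uses
#'   `min_ppi_score`).
#' @return List with `graph` (an igraph object), `components` (tibble:
#'   `component`, `size`), and `membership` (tibble: `gene`, `component`).
#' @export
ppi_subnetwork <- function(edges, genes, thresholds = screen_thresholds()) {
  th <- as_thresholds(thresholds)
  stopifnot(all(c("gene_a", "gene_b", "combined_score") %in% names(edges)))
  if (any(edges$combined_score < 0 | edges$combined_score > 1, na.rm = TRUE)) {
    stop("combined scores must lie in [0, 1]", call. = FALSE)
  }
  genes <- unique(as.character(genes))
  e <- edges[!is.na(edges$combined_score) &
               edges$combined_score >= th$min_ppi_score, , drop = FALSE]
  a <- as.character(e$gene_a); b <- as.character(e$gene_b)
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(genes), name = genes)
  if (nrow(e) > 0) {
    key <- paste(a, b, sep = "\r")
    best <- tapply(e$combined_score, key, max)
    pairs <- do.call(rbind, strsplit(names(best), "\r", fixed = TRUE))
    sel <- pairs[, 1] != pairs[, 2] & pairs[, 1] %in% genes & pairs[, 2] %in% genes
    pairs <- pairs[sel, , drop = FALSE]
    best <- best[sel]
    if (nrow(pairs) > 0) {
      g <- igraph::add_edges(g, as.vector(t(pairs)),
                             combined_score = as.numeric(best))
    }
  }
  comp <- igraph::components(g)
  ord <- order(-comp$csize, seq_along(comp$csize))
  relabel <- match(seq_along(comp$csize), ord)
  membership <- tibble::tibble(gene = igraph::V(g)$name,
                               component = relabel[comp$membership])
  components <- tibble::tibble(component = seq_along(ord),
                               size = comp$csize[ord])
  list(graph = g, components = components, membership = membership)
}
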