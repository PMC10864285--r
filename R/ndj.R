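#' X-chromosome nondisjunction frequency from a raw progeny tally
#'
#' In the standard X-nondisjunction test cross (females over `y w / Y, B^S`
#' males) four progeny classes are scored: normal X/X females, Bar X/B^S Y
#' males, exceptional X/O males (from nullo-X ova) and exceptional X/X/B^S Y
#' females (from diplo-X ova). The reciprocal exceptional zygotes (XXX and
#' YO) die, so each surviving exceptional fly represents two nondisjunction
#' ova; the estimator therefore doubles the exceptional count in both
#' numerator and denominator:
#'
#'   NDJ = 2(XO + XXY) / (2(XO + XXY) + XX + XY)
#'
#' @param xx_females Count of normal X/X females.
#' @param bs_males Count of normal X/B^S Y (Bar) males.
#' @param xo_males Count of exceptional X/O males.
#' @param xxy_females Count of exceptional X/X/B^S Y females.
#' @return The nondisjunction frequency, a fraction in \[0, 1\]. Vectorized.
#' @examples
#' ndj_frequency(100, 90, 3, 2) # 10 / 200 = 0.05
#' @export
ndj_frequency <- function(xx_females, bs_males, xo_males, xxy_females) {
  counts <- cbind(xx_females, bs_males, xo_males, xxy_females)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("progeny counts must be non-negative integers", call. = FALSE)
  }
  exc2 <- 2 * (xo_males + xxy_females)
  denom <- exc2 + xx_females + bs_males
  if (any(denom == 0)) {
    stop("no progeny: nondisjunction frequency undefined", call. = FALSE)
  }
  exc2 / denom
}

#' Nondisjunction frequency from a summary (adjusted total, events) pair
#'
#' Screen tables report crosses as "`<adjusted total>, <k> NDJ`", where the
#' adjusted total is the estimator's denominator 2(XO + XXY) + XX + XY and
#' `k = XO + XXY` is the number of surviving exceptional progeny. The
#' frequency is then `2 k / adjusted_total`, identical to [ndj_frequency()]
#' on any raw tally consistent with the summary.
#'
#' @param adjusted_total Adjusted progeny total (must be >= `2 * ndj_events`
#'   and positive).
#' @param ndj_events Count of exceptional (XO + XXY) progeny.
#' @return Fraction in \[0, 1\]. Vectorized.
#' @examples
#' ndj_from_summary(226, 18) # 0.1593..., prints as 15.9%
#' @export
ndj_from_summary <- function(adjusted_total, ndj_events) {
  if (any(is.na(adjusted_total)) || any(is.na(ndj_events)) ||
      any(adjusted_total <= 0) || any(ndj_events < 0) ||
      any(adjusted_total < 2 * ndj_events)) {
    stop("need adjusted_total > 0 and adjusted_total >= 2 * ndj_events",
         call. = FALSE)
  }
  2 * ndj_events / adjusted_total
}

# Parse one screen-table cell: "STERILE", "ND", "" (not tested), or
# "<adjusted total>, <k> NDJ". Returns list(status, adjusted_total, ndj_events).
parse_screen_cell <- function(cell, where = "cell") {
  cell <- trimws(ifelse(is.na(cell), "", cell))
  if (cell == "") {
    return(list(status = "missing", adjusted_total = NA_integer_,
                ndj_events = NA_integer_))
  }
  if (toupper(cell) == "STERILE") {
    return(list(status = "STERILE", adjusted_total = NA_integer_,
                ndj_events = NA_integer_))
  }
  if (toupper(cell) == "ND") {
    return(list(status = "ND", adjusted_total = NA_integer_,
                ndj_events = NA_integer_))
  }
  m <- regmatches(cell, regexec("^([0-9]+),\\s*([0-9]+)\\s*NDJ$", cell))[[1]]
  if (length(m) != 3) {
    stop(sprintf("%s: malformed screen cell '%s'", where, cell), call. = FALSE)
  }
  total <- as.integer(m[2]); k <- as.integer(m[3])
  if (total <= 0 || total < 2 * k) {
    stop(sprintf("%s: inconsistent cell '%s' (need total >= 2 * NDJ events)",
                 where, cell), call. = FALSE)
  }
  list(status = "counts", adjusted_total = total, ndj_events = k)
}

#' Parse a screen-results table into per-cross records
#'
#' Reads the per-gene x shRNA-line x driver results of a nondisjunction /
#' sterility screen. The expected columns are `gene_symbol`, `stock_id`,
#' the driver cells `mvd1` and `mata` in the cell dialect
#' `"STERILE"` / `"ND"` / `"<total>, <k> NDJ"` / empty, and optionally
#' `gene_number`, `human_ortholog`, `mouse_ortholog`, `no_stage14`,
#' `tub_gal4`. The `no_stage14` and `tub_gal4` columns are carried through as
#' annotation only; they never contribute to positivity.
#'
#' @param table A file path (TSV/CSV) or a data frame.
#' @param sep Field separator when `table` is a path.
#' @return A long tibble with one row per gene x line x driver:
#'   `gene_symbol`, `stock_id`, `driver` (`"MVD1"`/`"mata"`), `status`
#'   (`"counts"`, `"STERILE"`, `"ND"`, `"missing"`), `adjusted_total`,
#'   `ndj_events`, plus any annotation columns. Malformed cells raise an
#'   error naming the row.
#' @export
parse_screen_table <- function(table, sep = "\t") {
  if (is.character(table) && length(table) == 1) {
    table <- utils::read.table(table, header = TRUE, sep = sep, quote = "",
                               stringsAsFactors = FALSE, comment.char = "",
                               na.strings = NULL, colClasses = "character")
  }
  stopifnot(is.data.frame(table))
  need <- c("gene_symbol", "stock_id", "mvd1", "mata")
  missing <- setdiff(need, names(table))
  if (length(missing)) {
    stop("screen table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ann_cols <- intersect(c("gene_number", "human_ortholog", "mouse_ortholog",
                          "no_stage14", "tub_gal4"), names(table))
  rows <- lapply(seq_len(nrow(table)), function(i) {
    out <- lapply(c(MVD1 = "mvd1", mata = "mata"), function(col) {
      parse_screen_cell(table[[col]][i], where = sprintf("row %d (%s)", i, col))
    })
    df <- tibble::tibble(
      gene_symbol = table$gene_symbol[i],
      stock_id = table$stock_id[i],
      driver = names(out),
      status = unname(vapply(out, `[[`, character(1), "status")),
      adjusted_total = unname(vapply(out, `[[`, integer(1), "adjusted_total")),
      ndj_events = unname(vapply(out, `[[`, integer(1), "ndj_events"))
    )
    for (col in ann_cols) df[[col]] <- table[[col]][i]
    df
  })
  do.call(rbind, rows)
}

#' Path to the packaged screen-results fixture
#'
#' A plain-text transcription of the published table of 110 positive RNAi
#' lines (94 genes) with their MVD1 and mat-alpha cross outcomes, TRiP stock
#' ids, orthologs and somatic-cross annotations.
#'
#' @return File path of the TSV inside the installed package.
#' @export
screen_table_fixture <- function() {
  system.file("extdata", "table1.tsv", package = "ovascreen", mustWork = TRUE)
}

# Category set for a single parsed cross (one driver). Returns character().
cross_categories <- function(status, adjusted_total, ndj_events, th) {
  if (status %in% c("missing", "ND")) return(character(0))
  if (status == "STERILE") return("Sterile")
  cats <- character(0)
  pct <- 100 * ndj_from_summary(adjusted_total, ndj_events)
  if (!is.null(th$ndj_rounding_decimals)) {
    pct <- round(pct, th$ndj_rounding_decimals)
  }
  if (pct >= th$ndj_min_pct) cats <- c(cats, "NDJ")
  small <- if (th$brood_inclusive) adjusted_total <= th$brood_max
           else adjusted_total < th$brood_max
  if (small) cats <- c(cats, "Small_brood")
  cats
}

CATEGORY_ORDER <- c("Sterile", "NDJ", "Small_brood")

venn_label <- function(categories) {
  if (length(categories) == 0) return("")
  paste(CATEGORY_ORDER[CATEGORY_ORDER %in% categories], collapse = "+")
}

#' Call one RNAi line positive or negative
#'
#' A line is positive when, in either germline driver, the cross was sterile,
#' showed a nondisjunction frequency at or above the threshold, or produced a
#' small brood. The evidence categories are the union over the two drivers.
#' Sterile crosses are not additionally counted as small broods. A line whose
#' only entries are `ND`/missing is "untested", not negative.
#'
#' @param results Tibble of parsed cross records (rows of
#'   [parse_screen_table()]) for one gene x shRNA line; only `MVD1` and
#'   `mata` driver rows are evidence.
#' @param thresholds [screen_thresholds()] or overrides.
#' @return One-row tibble: `gene_symbol`, `stock_id`, `call`
#'   (`"positive"`/`"negative"`/`"untested"`), `positive`, `categories`
#'   (list-column) and `venn_region`.
#' @export
call_line <- function(results, thresholds = screen_thresholds()) {
  th <- as_thresholds(thresholds)
  stopifnot(nrow(results) >= 1)
  ev <- results[results$driver %in% c("MVD1", "mata"), , drop = FALSE]
  cats <- character(0)
  tested <- FALSE
  for (i in seq_len(nrow(ev))) {
    if (!ev$status[i] %in% c("missing", "ND")) tested <- TRUE
    cats <- union(cats, cross_categories(ev$status[i], ev$adjusted_total[i],
                                         ev$ndj_events[i], th))
  }
  cats <- CATEGORY_ORDER[CATEGORY_ORDER %in% cats]
  call <- if (!tested) "untested" else if (length(cats)) "positive" else "negative"
  tibble::tibble(gene_symbol = results$gene_symbol[1],
                 stock_id = results$stock_id[1],
                 call = call,
                 positive = call == "positive",
                 categories = list(cats),
                 venn_region = venn_label(cats))
}

#' Aggregate line calls into a gene call
#'
#' A gene is positive if at least one of its shRNA lines is positive; its
#' category set is the union over the positive lines and its Venn region is
#' that exact subset. Untested lines are ignored.
#'
#' @param line_calls Tibble of [call_line()] rows for one gene.
#' @return One-row tibble: `gene_symbol`, `positive`, `n_lines`,
#'   `n_positive_lines`, `categories` (list-column), `venn_region`.
#' @export
call_gene <- function(line_calls) {
  stopifnot(nrow(line_calls) >= 1)
  cats <- sort(unique(unlist(line_calls$categories[line_calls$positive])))
  cats <- CATEGORY_ORDER[CATEGORY_ORDER %in% cats]
  tibble::tibble(gene_symbol = line_calls$gene_symbol[1],
                 positive = any(line_calls$positive),
                 n_lines = nrow(line_calls),
                 n_positive_lines = sum(line_calls$positive),
                 categories = list(cats),
                 venn_region = venn_label(cats))
}

#' Count genes per exact Venn category subset
#'
#' @param gene_calls Tibble of [call_gene()] rows.
#' @return Tibble with `venn_region`, `n_categories`, `n_genes`, covering
#'   every non-empty region observed; region counts sum to the number of
#'   positive genes.
#' @export
venn_summary <- function(gene_calls) {
  pos <- gene_calls[gene_calls$positive, , drop = FALSE]
  regions <- c("Sterile", "NDJ", "Small_brood", "Sterile+NDJ",
               "Sterile+Small_brood", "NDJ+Small_brood",
               "Sterile+NDJ+Small_brood")
  n <- vapply(regions, function(r) sum(pos$venn_region == r), integer(1))
  tibble::tibble(venn_region = regions,
                 n_categories = lengths(strsplit(regions, "+", fixed = TRUE)),
                 n_genes = unname(n))
}

#' Score a whole screen table
#'
#' Convenience wrapper: parse (if needed), call every line, aggregate to
#' genes, and summarize the Venn regions.
#'
#' @param table Path, data frame, or already-parsed long tibble (output of
#'   [parse_screen_table()]).
#' @param thresholds [screen_thresholds()] or overrides.
#' @return List with `crosses` (parsed records), `line_calls`, `gene_calls`
#'   and `venn` tibbles.
#' @examples
#' res <- score_screen(screen_table_fixture())
#' sum(res$gene_calls$positive)
#' @export
score_screen <- function(table, thresholds = screen_thresholds()) {
  th <- as_thresholds(thresholds)
  crosses <- if (is.data.frame(table) && "driver" %in% names(table)) {
    table
  } else {
    parse_screen_table(table)
  }
  key <- paste(crosses$gene_symbol, crosses$stock_id,
               stats::ave(seq_len(nrow(crosses)),
                   paste(crosses$gene_symbol, crosses$stock_id, crosses$driver),
                   FUN = seq_along),
               sep = "\r")
  line_calls <- do.call(rbind, lapply(split(seq_len(nrow(crosses)), key),
                                      function(ix) {
    call_line(crosses[ix, , drop = FALSE], th)
  }))
  line_calls <- line_calls[order(line_calls$gene_symbol, line_calls$stock_id), ]
  gene_calls <- do.call(rbind, lapply(
    split(seq_len(nrow(line_calls)), line_calls$gene_symbol),
    function(ix) call_gene(line_calls[ix, , drop = FALSE])
  ))
  list(crosses = crosses, line_calls = line_calls, gene_calls = gene_calls,
       venn = venn_summary(gene_calls))
}
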