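#' Screen-wide decision thresholds
#'
#' Collects every tunable cutoff used by the selection funnel, the cross
#' scoring rules and the enrichment/network filters into a single validated
#' object, so that one configuration travels with a run and is recorded in its
#' manifest.
#'
#' @param p_max Maximum t-test p-value for an "up"/"down" expression call
#'   (inclusive). Default 0.05.
#' @param enrich_up_min Enrichment value that "up" must strictly exceed
#'   (tissue mean over whole-body mean). Default 1.
#' @param ndj_min_pct Minimum nondisjunction frequency, in percent, for the
#'   NDJ positivity criterion. Default 1.7.
#' @param brood_max Brood-size cutoff (adjusted progeny total) for the
#'   small-brood criterion. Default 100.
#' @param brood_inclusive If `TRUE` (default) a brood equal to `brood_max`
#'   counts as small ("<= 100 progeny"); if `FALSE` the comparison is strict
#'   ("< 100").
#' @param min_term_overlap Minimum number of input genes a gene-set term must
#'   contain to be tested for overrepresentation. Default 2.
#' @param min_ppi_score Minimum combined confidence score for a
#'   protein-protein interaction edge to be kept. Default 0.4 (the usual
#'   "medium confidence" cutoff).
#' @param ndj_rounding_decimals Number of decimals the NDJ percentage is
#'   rounded to before comparison against `ndj_min_pct`, or `NULL` for no
#'   rounding. Default 1, matching how screen tables print frequencies
#'   (2/119 = 1.68 percent prints, and is judged, as 1.7 percent).
#' @param var_equal Use the pooled-variance Student's t test (`TRUE`, default)
#'   or Welch's unequal-variance variant.
#'
#' @return An object of class `screen_thresholds` (a named list).
#' @examples
#' th <- screen_thresholds()
#' th$ndj_min_pct
#' @export
screen_thresholds <- function(p_max = 0.05,
                              enrich_up_min = 1,
                              ndj_min_pct = 1.7,
                              brood_max = 100,
                              brood_inclusive = TRUE,
                              min_term_overlap = 2,
                              min_ppi_score = 0.4,
                              ndj_rounding_decimals = 1,
                              var_equal = TRUE) {
  num_pos <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
      stop(sprintf("`%s` must be a single positive number", name), call. = FALSE)
    }
  }
  num_pos(p_max, "p_max")
  num_pos(enrich_up_min, "enrich_up_min")
  num_pos(ndj_min_pct, "ndj_min_pct")
  num_pos(brood_max, "brood_max")
  num_pos(min_term_overlap, "min_term_overlap")
  num_pos(min_ppi_score, "min_ppi_score")
  if (!is.null(ndj_rounding_decimals)) {
    if (!is.numeric(ndj_rounding_decimals) || length(ndj_rounding_decimals) != 1L ||
        is.na(ndj_rounding_decimals) || ndj_rounding_decimals < 0) {
      stop("`ndj_rounding_decimals` must be NULL or a single non-negative number",
           call. = FALSE)
    }
  }
  stopifnot(is.logical(brood_inclusive), length(brood_inclusive) == 1L,
            is.logical(var_equal), length(var_equal) == 1L)
  structure(
    list(
      p_max = p_max,
      enrich_up_min = enrich_up_min,
      ndj_min_pct = ndj_min_pct,
      brood_max = brood_max,
      brood_inclusive = brood_inclusive,
      min_term_overlap = min_term_overlap,
      min_ppi_score = min_ppi_score,
      ndj_rounding_decimals = ndj_rounding_decimals,
      var_equal = var_equal
    ),
    class = "screen_thresholds"
  )
}

#' @export
print.screen_thresholds <- function(x, ...) {
  cat("Screen thresholds:\n")
  for (nm in names(x)) {
    val <- x[[nm]]
    cat(sprintf("  %-22s %s\n", nm, if (is.null(val)) "none" else format(val)))
  }
  invisible(x)
}

as_thresholds <- function(x) {
  if (inherits(x, "screen_thresholds")) return(x)
  if (is.null(x)) return(screen_thresholds())
  if (is.list(x)) return(do.call(screen_thresholds, x))
  stop("`thresholds` must be NULL, a list, or a screen_thresholds object",
       call. = FALSE)
}
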