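#' Construct a probe-set expression profile
#'
#' The unit record of the selection funnel: one microarray probe set with its
#' replicate intensities and per-replicate detection ("present") flags across
#' tissues.
#'
#' @param probe_id Probe-set identifier.
#' @param gene_id Stable gene identifier the probe set maps to.
#' @param gene_symbol Gene symbol (may be a multi-gene "a /// b" symbol).
#' @param intensities Named list, tissue -> numeric vector of replicate
#'   intensities (linear scale, at least one replicate per reported tissue).
#' @param present Named list, tissue -> logical vector of detection flags,
#'   aligned 1:1 with `intensities`. MAS5-style letters are accepted and
#'   mapped P -> `TRUE`, M/A -> `FALSE`.
#' @param whole_body Name of the whole-body reference tissue; must be present
#'   in `intensities`.
#'
#' @return A `probe_profile` object.
#' @examples
#' p <- probe_profile("p1_at", "g1", "sym1",
#'   intensities = list(ovary = c(10, 12), whole_body = c(3, 4)),
#'   present = list(ovary = c(TRUE, TRUE), whole_body = c(TRUE, TRUE)))
#' p$gene_id
#' @export
probe_profile <- function(probe_id, gene_id, gene_symbol, intensities, present,
                          whole_body = "whole_body") {
  stopifnot(is.list(intensities), length(intensities) > 0)
  if (!whole_body %in% names(intensities)) {
    stop(sprintf("probe %s: whole-body tissue '%s' missing from intensities",
                 probe_id, whole_body), call. = FALSE)
  }
  present <- lapply(present, parse_present_flags)
  for (tis in names(intensities)) {
    x <- intensities[[tis]]
    if (!is.numeric(x) || length(x) == 0) {
      stop(sprintf("probe %s: tissue '%s' has no replicate intensities",
                   probe_id, tis), call. = FALSE)
    }
    if (!is.null(present[[tis]]) && length(present[[tis]]) != length(x)) {
      stop(sprintf("probe %s: present flags for '%s' do not align with intensities",
                   probe_id, tis), call. = FALSE)
    }
  }
  structure(
    list(probe_id = as.character(probe_id),
         gene_id = as.character(gene_id),
         gene_symbol = as.character(gene_symbol),
         intensities = intensities,
         present = present,
         whole_body = whole_body),
    class = "probe_profile"
  )
}

# Accepts logicals, 0/1, or MAS5 detection letters (P present, M marginal,
# A absent); marginal counts as not detected.
parse_present_flags <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x != 0)
  x <- toupper(trimws(as.character(x)))
  if (all(x %in% c("P", "M", "A"))) return(x == "P")
  if (all(x %in% c("TRUE", "FALSE", "T", "F", "1", "0"))) {
    return(x %in% c("TRUE", "T", "1"))
  }
  stop("present flags must be logical, 0/1, or P/M/A letters", call. = FALSE)
}

#' Read a wide replicate expression matrix into probe profiles
#'
#' Expects a tab- (or comma-) separated file with columns `probe_id`,
#' `gene_id`, `gene_symbol` followed by replicate column groups named
#' `<tissue>.rep<k>` and, optionally, `<tissue>.present<k>`.
#'
#' @param path File path.
#' @param whole_body Tissue name of the whole-body reference column group.
#' @param exclude_tissues Tissue column groups to drop before analysis (for
#'   example cultured-cell samples that are not part of the tissue panel).
#' @param sep Field separator; `"\t"` by default, `","` accepted.
#' @return A list of [probe_profile()] objects.
#' @export
read_expression_matrix <- function(path, whole_body = "whole_body",
                                   exclude_tissues = character(), sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  required <- c("probe_id", "gene_id", "gene_symbol")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("expression matrix is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  rep_cols <- grep("^(.+)\\.rep[0-9]+$", names(df), value = TRUE)
  pres_cols <- grep("^(.+)\\.present[0-9]+$", names(df), value = TRUE)
  tissues <- unique(sub("\\.rep[0-9]+$", "", rep_cols))
  tissues <- setdiff(tissues, exclude_tissues)
  if (!whole_body %in% tissues) {
    stop(sprintf("no '%s.rep<k>' columns found for the whole-body reference",
                 whole_body), call. = FALSE)
  }
  lapply(seq_len(nrow(df)), function(i) {
    ints <- list()
    pres <- list()
    for (tis in tissues) {
      rc <- rep_cols[startsWith(rep_cols, paste0(tis, ".rep"))]
      vals <- as.numeric(df[i, rc])
      keep <- !is.na(vals)
      if (!any(keep)) next
      ints[[tis]] <- vals[keep]
      pc <- pres_cols[startsWith(pres_cols, paste0(tis, ".present"))]
      if (length(pc)) {
        flags <- parse_present_flags(unlist(df[i, pc], use.names = FALSE))
        pres[[tis]] <- flags[keep]
      }
    }
    probe_profile(df$probe_id[i], df$gene_id[i], df$gene_symbol[i],
                  ints, pres, whole_body = whole_body)
  })
}
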