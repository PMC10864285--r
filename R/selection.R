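#' Per-tissue enrichment call for one probe set
#'
#' Computes the enrichment value (tissue mean over whole-body mean), a
#' two-tailed two-sample t-test p-value between the tissue and whole-body
#' replicates, and the resulting direction: `"up"` when enrichment exceeds
#' `enrich_up_min` (strictly) and p <= `p_max`, `"down"` when enrichment < 1
#' and p <= `p_max`, `"others"` otherwise.
#'
#' With fewer than two replicates on either side no t-test is possible: the
#' call is forced to `"others"` with an undefined p-value and `flagged = TRUE`.
#' When both samples have zero variance the t statistic is degenerate; the
#' p-value is taken as its limit (1 for equal means, 0 for unequal means).
#'
#' @param profile A [probe_profile()].
#' @param tissue Tissue to test.
#' @param whole_body Whole-body reference tissue name (defaults to the one
#'   recorded in the profile).
#' @param thresholds A [screen_thresholds()] object (or list of overrides).
#' @return One-row tibble: `probe_id`, `gene_id`, `tissue`, `enrichment`,
#'   `p_value`, `direction`, `flagged`.
#' @examples
#' p <- probe_profile("p1", "g1", "s1",
#'   intensities = list(ovary = c(10, 12, 9, 11), whole_body = c(2, 3, 2, 3)),
#'   present = list())
#' compute_tissue_call(p, "ovary")
#' @export
compute_tissue_call <- function(profile, tissue, whole_body = NULL,
                                thresholds = screen_thresholds()) {
  th <- as_thresholds(thresholds)
  if (is.null(whole_body)) whole_body <- profile$whole_body
  x <- profile$intensities[[tissue]]
  y <- profile$intensities[[whole_body]]
  if (is.null(x)) {
    stop(sprintf("probe %s: no intensities for tissue '%s'",
                 profile$probe_id, tissue), call. = FALSE)
  }
  if (is.null(y) || mean(y) <= 0) {
    stop(sprintf("probe %s: whole-body mean must be positive", profile$probe_id),
         call. = FALSE)
  }
  enrichment <- mean(x) / mean(y)
  if (length(x) < 2 || length(y) < 2) {
    p <- NA_real_
    direction <- "others"
    flagged <- TRUE
  } else {
    p <- two_sample_p(x, y, var_equal = th$var_equal)
    direction <- call_direction(enrichment, p, th)
    flagged <- FALSE
  }
  tibble::tibble(probe_id = profile$probe_id, gene_id = profile$gene_id,
                 tissue = tissue, enrichment = enrichment, p_value = p,
                 direction = direction, flagged = flagged)
}

call_direction <- function(enrichment, p, th) {
  if (is.na(p)) return("others")
  if (enrichment > th$enrich_up_min && p <= th$p_max) return("up")
  if (enrichment < 1 && p <= th$p_max) return("down")
  "others"
}

# Two-tailed two-sample t-test p-value with explicit handling of the
# zero-variance limit (both samples constant).
two_sample_p <- function(x, y, var_equal = TRUE) {
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    return(if (mean(x) == mean(y)) 1 else 0)
  }
  stats::t.test(x, y, var.equal = var_equal, alternative = "two.sided")$p.value
}

#' Drop genes whose symbols mark them as outside the screen's scope
#'
#' Removes unknown genes (symbols containing `"---"`), annotated
#' non-protein-coding genes (`CR` followed by digits), RNA genes (symbols
#' containing `"rna"`, case-insensitive, covering the `snRNA:`/`tRNA:`/`rRNA`
#' dialects) and ribosomal proteins (`RpS`/`RpL` prefixes).
#'
#' @param symbols Data frame with a `gene_symbol` column.
#' @return List with `kept` (tibble of surviving rows) and `report` (tibble of
#'   dropped counts by reason). A row matching several patterns is counted
#'   under the first one, in the order unknown, noncoding_cr, rna_gene,
#'   ribosomal.
#' @examples
#' filter_unwanted_genes(data.frame(gene_symbol = c("c(3)G", "CR43242", "RpL3")))
#' @export
filter_unwanted_genes <- function(symbols) {
  stopifnot(is.data.frame(symbols), "gene_symbol" %in% names(symbols))
  sym <- as.character(symbols$gene_symbol)
  reason <- rep(NA_character_, length(sym))
  rules <- list(
    unknown = function(s) grepl("---", s, fixed = TRUE),
    noncoding_cr = function(s) grepl("^CR[0-9]", s),
    rna_gene = function(s) grepl("rna", s, ignore.case = TRUE),
    ribosomal = function(s) grepl("^rp[sl]", s, ignore.case = TRUE)
  )
  for (nm in names(rules)) {
    hit <- is.na(reason) & rules[[nm]](sym)
    reason[hit] <- nm
  }
  counts <- vapply(names(rules), function(nm) sum(reason == nm, na.rm = TRUE),
                   integer(1))
  report <- tibble::tibble(reason = names(rules), n_dropped = unname(counts))
  list(kept = tibble::as_tibble(symbols[is.na(reason), , drop = FALSE]),
       report = report)
}

#' Remove probe sets with no detection in any germline-relevant tissue
#'
#' A probe set survives only if at least one replicate carries a "present"
#' call in at least one of the required tissues (by default ovary, testis and
#' larval CNS). Probe sets undetected in all replicates of all three are
#' removed.
#'
#' @param profiles List of [probe_profile()] objects.
#' @param tissues Character vector of tissues in which detection is required.
#' @param missing_flags What to do when a profile has no present flags for a
#'   required tissue: `"absent"` (default) treats them as all-absent,
#'   `"error"` stops.
#' @return List with `kept` and `removed` profile lists.
#' @export
filter_absent_probesets <- function(profiles,
                                    tissues = c("ovary", "testis", "cns"),
                                    missing_flags = c("absent", "error")) {
  missing_flags <- match.arg(missing_flags)
  keep <- vapply(profiles, function(p) {
    any(vapply(tissues, function(tis) {
      flags <- p$present[[tis]]
      if (is.null(flags)) {
        if (missing_flags == "error") {
          stop(sprintf("probe %s: no present flags for required tissue '%s'",
                       p$probe_id, tis), call. = FALSE)
        }
        return(FALSE)
      }
      any(flags)
    }, logical(1)))
  }, logical(1))
  list(kept = profiles[keep], removed = profiles[!keep])
}

#' Choose one representative probe set per gene
#'
#' Ranks a gene's candidate probe sets by (1) the number of replicate
#' present calls across the focal tissues and (2) the number of those tissues
#' called "up", both descending. Exact ties are broken by lexicographically
#' smallest probe id, so the choice is deterministic.
#'
#' @param gene_id Gene the candidates belong to (consistency check only).
#' @param candidate_profiles List of [probe_profile()] objects for the gene.
#' @param calls Tibble of tissue calls (as from [compute_tissue_call()]) for
#'   those probes; only rows for `tissues` are consulted.
#' @param tissues Focal tissues for both ranking keys.
#' @return The winning probe id (character scalar).
#' @export
select_representative_probe <- function(gene_id, candidate_profiles, calls,
                                        tissues = c("ovary", "testis", "cns")) {
  stopifnot(length(candidate_profiles) >= 1)
  ids <- vapply(candidate_profiles, `[[`, character(1), "probe_id")
  n_present <- vapply(candidate_profiles, function(p) {
    sum(vapply(tissues, function(tis) sum(p$present[[tis]] %||% logical(0)),
               numeric(1)))
  }, numeric(1))
  n_up <- vapply(ids, function(pid) {
    sub <- calls[calls$probe_id == pid & calls$tissue %in% tissues, , drop = FALSE]
    sum(sub$direction == "up")
  }, numeric(1))
  ord <- order(-n_present, -n_up, ids)
  ids[ord[1]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify a gene's tissue-direction pattern into a selection group
#'
#' Ovary up-regulation is mandatory for selection. Given that, membership of
#' testis and larval CNS among the "up" tissues defines the four selected
#' groups; an "up" call in any other panel tissue disqualifies the gene.
#'
#' @param directions Named character vector, tissue -> direction
#'   (`"up"`/`"down"`/`"others"`), covering the full tissue panel (whole body
#'   excluded).
#' @param ovary,testis,cns Names of the three special tissues within the panel.
#' @return One of `"ovary_only"`, `"ovary_cns"`, `"ovary_testis"`,
#'   `"ovary_cns_testis"`, `"not_selected"`.
#' @examples
#' classify_tissue_group(c(ovary = "up", testis = "others", cns = "up",
#'                         midgut = "others"))
#' @export
classify_tissue_group <- function(directions, ovary = "ovary", testis = "testis",
                                  cns = "cns") {
  if (!ovary %in% names(directions)) {
    stop("ovary call missing from the direction map", call. = FALSE)
  }
  if (directions[[ovary]] != "up") return("not_selected")
  other <- setdiff(names(directions), c(ovary, testis, cns))
  if (any(directions[other] == "up", na.rm = TRUE)) return("not_selected")
  testis_up <- isTRUE(directions[[testis]] == "up")
  cns_up <- isTRUE(directions[[cns]] == "up")
  if (testis_up && cns_up) "ovary_cns_testis"
  else if (cns_up) "ovary_cns"
  else if (testis_up) "ovary_testis"
  else "ovary_only"
}

#' Run the candidate-selection funnel
#'
#' Applies, in order: symbol-based removal of out-of-scope genes, removal of
#' probe sets with no present call in ovary/testis/CNS, per-tissue enrichment
#' calls, per-gene representative-probe selection, and tissue-group
#' classification. Genes classified into any ovary group are the selected
#' candidates.
#'
#' @param profiles List of [probe_profile()] objects.
#' @param thresholds [screen_thresholds()] or overrides.
#' @param ovary,testis,cns Names of the special tissues.
#' @param whole_body Whole-body reference tissue (defaults to the profiles').
#' @return List with `candidates` (tibble: gene_id, gene_symbol, probe_id,
#'   group), `calls` (tissue calls for the representative probes),
#'   `groups` (per-gene group incl. `not_selected`) and `report` (per-stage
#'   funnel counts; at every stage `n_out + n_dropped == n_in`).
#' @export
run_selection_funnel <- function(profiles, thresholds = screen_thresholds(),
                                 ovary = "ovary", testis = "testis", cns = "cns",
                                 whole_body = NULL) {
  th <- as_thresholds(thresholds)
  special <- c(ovary, testis, cns)
  stage <- function(name, n_in, n_out, reason) {
    tibble::tibble(stage = name, n_in = n_in, n_out = n_out,
                   n_dropped = n_in - n_out, reason = reason)
  }
  report <- list()

  if (length(profiles) == 0) {
    empty <- tibble::tibble(gene_id = character(), gene_symbol = character(),
                            probe_id = character(), group = character())
    return(list(candidates = empty, calls = NULL, groups = empty,
                report = stage("input", 0L, 0L, "input probe sets")))
  }
  if (is.null(whole_body)) whole_body <- profiles[[1]]$whole_body

  n0 <- length(profiles)
  report$input <- stage("input", n0, n0, "input probe sets")

  # 1. symbol filter
  symtab <- tibble::tibble(
    idx = seq_along(profiles),
    gene_symbol = vapply(profiles, `[[`, character(1), "gene_symbol")
  )
  fw <- filter_unwanted_genes(symtab)
  profiles <- profiles[fw$kept$idx]
  report$symbols <- stage("symbol_filter", n0, length(profiles),
                          "unknown/CR/rna/ribosomal symbols removed")

  # 2. present-call filter
  n1 <- length(profiles)
  fa <- filter_absent_probesets(profiles, tissues = special)
  profiles <- fa$kept
  report$present <- stage("present_filter", n1, length(profiles),
                          "no present call in ovary/testis/CNS")

  if (length(profiles) == 0) {
    empty <- tibble::tibble(gene_id = character(), gene_symbol = character(),
                            probe_id = character(), group = character())
    return(list(candidates = empty, calls = NULL, groups = empty,
                report = do.call(rbind, report)))
  }

  # 3. per-tissue calls for all surviving probes
  panel <- setdiff(unique(unlist(lapply(profiles, function(p) names(p$intensities)))),
                   whole_body)
  calls <- do.call(rbind, lapply(profiles, function(p) {
    do.call(rbind, lapply(intersect(panel, names(p$intensities)), function(tis) {
      compute_tissue_call(p, tis, whole_body = whole_body, thresholds = th)
    }))
  }))

  # 4. representative probe per gene
  gene_ids <- vapply(profiles, `[[`, character(1), "gene_id")
  n_genes_in <- length(unique(gene_ids))
  rep_probe <- vapply(split(seq_along(profiles), gene_ids), function(ix) {
    select_representative_probe(gene_ids[ix[1]], profiles[ix], calls,
                                tissues = special)
  }, character(1))
  report$collapse <- stage("collapse_probes", length(profiles), n_genes_in,
                           "one representative probe per gene")

  # 5. classify each gene from its representative probe's calls
  by_id <- stats::setNames(profiles, vapply(profiles, `[[`, character(1), "probe_id"))
  groups <- do.call(rbind, lapply(names(rep_probe), function(gid) {
    pid <- rep_probe[[gid]]
    sub <- calls[calls$probe_id == pid, , drop = FALSE]
    dirs <- stats::setNames(sub$direction, sub$tissue)
    tibble::tibble(gene_id = gid,
                   gene_symbol = by_id[[pid]]$gene_symbol,
                   probe_id = pid,
                   group = classify_tissue_group(dirs, ovary = ovary,
                                                 testis = testis, cns = cns))
  }))
  candidates <- groups[groups$group != "not_selected", , drop = FALSE]
  report$select <- stage("group_selection", n_genes_in, nrow(candidates),
                         "ovary up-regulation required; no other tissue up")

  calls_rep <- calls[calls$probe_id %in% rep_probe, , drop = FALSE]
  list(candidates = candidates, calls = calls_rep, groups = groups,
       report = do.call(rbind, report))
}
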