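#' Configuration for the synthetic screen generator
#'
#' Builds a fully serializable configuration with planted ground truth for
#' every input the pipeline consumes: a replicate expression matrix with
#' present calls, a screen-results table, and a stage-level single-cell
#' table. The same config and seed always reproduce identical outputs.
#'
#' Defaults describe the study conditions the generator emulates: five panel
#' tissues plus a whole-body reference, four biological replicates per
#' tissue, lognormal intensities with sd 0.25 on the log scale around a base
#' mean of 100, planted 4-fold tissue effects, a detection floor equal to the
#' base mean, and broods averaging 300 eggs.
#'
#' @param seed Integer seed governing all randomness downstream.
#' @param n_genes Number of genes (one probe set each).
#' @param tissues Panel tissues (the first three are ovary, testis, CNS).
#' @param whole_body Name of the whole-body reference sample group.
#' @param n_replicates Biological replicates per tissue.
#' @param base_mean Baseline intensity (linear scale); intensities are
#'   lognormal around `log(base_mean)`.
#' @param log_sd Replicate noise sd on the log scale.
#' @param detection_floor Intensity above which a replicate is called
#'   "present".
#' @param fold_change Planted enrichment fold for up-regulated genes.
#' @param n_planted Number of genes with planted tissue effects; they are
#'   assigned to the four ovary groups roughly in the observed proportions
#'   (half ovary-only).
#' @param n_sterile,n_ndj,n_small Planted positive genes in the screen truth:
#'   sterile in both drivers, elevated nondisjunction, and small brood.
#' @param d_positive True nondisjunction egg fraction for planted NDJ genes.
#' @param d_background Baseline nondisjunction egg fraction for all other
#'   crosses.
#' @param brood_mean Mean egg count per cross for normal broods.
#' @param brood_small Mean egg count for planted small-brood genes.
#' @return A `sim_config` object (list) with planted truth tables
#'   `expression_truth`, `screen_truth` and `sc_truth`.
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 50, n_planted = 5)
#' table(cfg$expression_truth$true_group)
#' @export
sim_config <- function(seed,
                       n_genes = 200,
                       tissues = c("ovary", "testis", "cns", "midgut", "hindgut"),
                       whole_body = "whole_body",
                       n_replicates = 4,
                       base_mean = 100,
                       log_sd = 0.25,
                       detection_floor = base_mean,
                       fold_change = 4,
                       n_planted = 20,
                       n_sterile = 6,
                       n_ndj = 8,
                       n_small = 6,
                       d_positive = 0.10,
                       d_background = 0.004,
                       brood_mean = 300,
                       brood_small = 60) {
  stopifnot(length(tissues) >= 3, n_genes >= n_planted,
            n_genes >= n_sterile + n_ndj + n_small,
            d_positive >= 0, d_positive < 1, d_background >= 0, d_background < 1)
  seed <- as.integer(seed)
  gene_id <- sprintf("FBgn%07d", seq_len(n_genes))
  gene_symbol <- sprintf("CG%05d", 10000 + seq_len(n_genes))
  probe_id <- sprintf("sim%05d_at", seq_len(n_genes))

  # planted tissue groups: half ovary-only, the rest split across the
  # ovary+cns / ovary+testis / ovary+cns+testis groups
  groups <- rep("not_selected", n_genes)
  if (n_planted > 0) {
    quota <- c(ovary_only = ceiling(n_planted / 2),
               ovary_cns = ceiling(n_planted / 5),
               ovary_testis = ceiling(n_planted / 5))
    quota <- pmin(quota, n_planted)
    lab <- rep(names(quota), quota)[seq_len(min(n_planted, sum(quota)))]
    if (length(lab) < n_planted) {
      lab <- c(lab, rep("ovary_cns_testis", n_planted - length(lab)))
    }
    groups[seq_len(n_planted)] <- lab
  }
  group_tissues <- list(
    ovary_only = "ovary", ovary_cns = c("ovary", "cns"),
    ovary_testis = c("ovary", "testis"),
    ovary_cns_testis = c("ovary", "cns", "testis"),
    not_selected = character(0)
  )
  expression_truth <- tibble::tibble(
    gene_id = gene_id, gene_symbol = gene_symbol, probe_id = probe_id,
    true_group = groups,
    up_tissues = unname(group_tissues[groups])
  )

  # screen truth: planted positives first, everything else background
  n_pos <- n_sterile + n_ndj + n_small
  phen <- rep("negative", n_genes)
  phen[seq_len(n_sterile)] <- "sterile"
  phen[n_sterile + seq_len(n_ndj)] <- "ndj"
  phen[n_sterile + n_ndj + seq_len(n_small)] <- "small_brood"
  screen_truth <- tibble::tibble(
    gene_symbol = gene_symbol,
    stock_id = sprintf("SIM%05d", seq_len(n_genes)),
    phenotype = phen,
    sterile_mvd1 = phen == "sterile",
    sterile_mata = phen == "sterile",
    d = ifelse(phen == "ndj", d_positive, d_background),
    brood_mean = ifelse(phen == "small_brood", brood_small, brood_mean),
    true_categories = lapply(phen, function(p) {
      switch(p, sterile = "Sterile", ndj = "NDJ", small_brood = "Small_brood",
             character(0))
    })
  )

  # single-cell truth: planted expression genes are germline biased
  biased <- groups != "not_selected"
  sc_truth <- tibble::tibble(
    gene_id = gene_id,
    gc_mean = ifelse(biased, 4 * base_mean, base_mean),
    soma_mean = base_mean,
    fc_mean = base_mean,
    germline_biased = biased
  )

  structure(
    list(seed = seed, n_genes = n_genes, tissues = tissues,
         whole_body = whole_body, n_replicates = n_replicates,
         base_mean = base_mean, log_sd = log_sd,
         detection_floor = detection_floor, fold_change = fold_change,
         expression_truth = expression_truth, screen_truth = screen_truth,
         sc_truth = sc_truth, n_planted = n_planted, n_positive = n_pos),
    class = "sim_config"
  )
}

#' Simulate a replicate expression matrix with planted tissue effects
#'
#' Per gene x tissue x replicate, draws a lognormal intensity around the base
#' mean, multiplied by the planted fold-change in that gene's up-regulated
#' tissues; a replicate is "present" when its intensity exceeds the detection
#' floor. Whole-body replicates are always at baseline.
#'
#' @param cfg A [sim_config()].
#' @return List with `profiles` (list of [probe_profile()]), `matrix` (wide
#'   tibble in the on-disk layout: `<tissue>.rep<k>` / `<tissue>.present<k>`
#'   columns) and `truth` (the planted tissue groups).
#' @export
simulate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  all_tissues <- c(cfg$tissues, cfg$whole_body)
  nrep <- cfg$n_replicates
  tr <- cfg$expression_truth
  profiles <- vector("list", cfg$n_genes)
  wide <- vector("list", cfg$n_genes)
  for (i in seq_len(cfg$n_genes)) {
    up <- tr$up_tissues[[i]]
    ints <- list(); pres <- list(); row <- list()
    for (tis in all_tissues) {
      mu <- log(cfg$base_mean) + if (tis %in% up) log(cfg$fold_change) else 0
      x <- exp(stats::rnorm(nrep, mean = mu, sd = cfg$log_sd))
      ints[[tis]] <- x
      pres[[tis]] <- x > cfg$detection_floor
      row[paste0(tis, ".rep", seq_len(nrep))] <- as.list(x)
      row[paste0(tis, ".present", seq_len(nrep))] <- as.list(x > cfg$detection_floor)
    }
    profiles[[i]] <- probe_profile(tr$probe_id[i], tr$gene_id[i],
                                   tr$gene_symbol[i], ints, pres,
                                   whole_body = cfg$whole_body)
    wide[[i]] <- tibble::as_tibble(c(list(probe_id = tr$probe_id[i],
                                          gene_id = tr$gene_id[i],
                                          gene_symbol = tr$gene_symbol[i]), row))
  }
  list(profiles = profiles, matrix = do.call(rbind, wide),
       truth = tr[, c("gene_id", "gene_symbol", "probe_id", "true_group")])
}

#' Simulate one nondisjunction test cross at the egg level
#'
#' Generative model: the brood starts as `N_eggs ~ Poisson(brood_mean)` eggs;
#' each egg derives from a nondisjunction meiosis with probability `d`.
#' Nondisjunction ova are diplo-X or nullo-X with equal probability, and
#' every egg receives an X or a B^S Y sperm with equal probability. The XXX
#' and YO zygote classes are inviable and removed; survivors are tallied into
#' the four scored classes. Under this mechanism the doubled-count estimator
#' [ndj_frequency()] is a consistent estimator of `d`, and the expected
#' surviving fraction of eggs is `1 - d/2`.
#'
#' @param d True nondisjunction egg fraction, in \[0, 1).
#' @param brood_mean Mean egg count.
#' @param seed Optional integer seed for this draw.
#' @return List with the scored tally (`xx_females`, `bs_males`, `xo_males`,
#'   `xxy_females`), the hidden counts (`n_eggs`, `n_inviable`), and the
#'   summary pair (`adjusted_total`, `ndj_events`).
#' @examples
#' simulate_cross(0.05, brood_mean = 300, seed = 1)
#' @export
simulate_cross <- function(d, brood_mean, seed = NULL) {
  stopifnot(d >= 0, d < 1, brood_mean > 0)
  if (!is.null(seed)) set.seed(seed)
  n_eggs <- stats::rpois(1, brood_mean)
  n_ndj <- stats::rbinom(1, n_eggs, d)
  n_normal <- n_eggs - n_ndj
  n_diplo <- stats::rbinom(1, n_ndj, 0.5)   # X/X ova
  n_nullo <- n_ndj - n_diplo                # O ova
  xx <- stats::rbinom(1, n_normal, 0.5)     # X ovum + X sperm
  xy <- n_normal - xx                       # X ovum + B^S Y sperm
  xxy <- stats::rbinom(1, n_diplo, 0.5)     # X/X ovum + B^S Y sperm
  xxx <- n_diplo - xxy                      # inviable
  xo <- stats::rbinom(1, n_nullo, 0.5)      # O ovum + X sperm
  yo <- n_nullo - xo                        # inviable
  list(xx_females = xx, bs_males = xy, xo_males = xo, xxy_females = xxy,
       n_eggs = n_eggs, n_inviable = xxx + yo,
       adjusted_total = 2 * (xo + xxy) + xx + xy,
       ndj_events = xo + xxy)
}

#' Simulate a screen-results table with planted phenotypes
#'
#' Per gene x line x driver: emits `"STERILE"` when the truth marks that
#' driver sterile, otherwise simulates a cross at the gene's true
#' nondisjunction egg fraction and brood mean and serializes it as
#' `"<adjusted total>, <k> NDJ"`.
#'
#' @param cfg A [sim_config()].
#' @return List with `table` (wide tibble in the screen-table dialect:
#'   `gene_symbol`, `stock_id`, `mvd1`, `mata`) and `truth` (planted
#'   phenotypes and intended categories).
#' @export
simulate_screen <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  tr <- cfg$screen_truth
  cell <- function(sterile, d, brood) {
    if (sterile) return("STERILE")
    cr <- simulate_cross(d, brood)
    sprintf("%d, %d NDJ", cr$adjusted_total, cr$ndj_events)
  }
  mvd1 <- character(nrow(tr)); mata <- character(nrow(tr))
  for (i in seq_len(nrow(tr))) {
    mvd1[i] <- cell(tr$sterile_mvd1[i], tr$d[i], tr$brood_mean[i])
    mata[i] <- cell(tr$sterile_mata[i], tr$d[i], tr$brood_mean[i])
  }
  list(table = tibble::tibble(gene_symbol = tr$gene_symbol,
                              stock_id = tr$stock_id,
                              mvd1 = mvd1, mata = mata),
       truth = tr)
}

#' Simulate a stage-level single-cell expression table
#'
#' Draws lognormal stage-level expression values around each gene's true
#' cluster means for a default stage map of three germ-cell stages, two
#' germarium-soma stages and three follicle-cell stages.
#'
#' @param cfg A [sim_config()].
#' @return List with `table` (tibble: `gene_id`, `stage`, `value`),
#'   `stage_map` (named character vector stage -> cluster) and `truth`.
#' @export
simulate_single_cell <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  stage_map <- c(germline_1 = "gc", germline_2 = "gc", germline_3 = "gc",
                 soma_1 = "soma", soma_2 = "soma",
                 fc_1 = "fc", fc_2 = "fc", fc_3 = "fc")
  tr <- cfg$sc_truth
  rows <- lapply(seq_len(nrow(tr)), function(i) {
    mu <- c(gc = tr$gc_mean[i], soma = tr$soma_mean[i], fc = tr$fc_mean[i])
    tibble::tibble(
      gene_id = tr$gene_id[i],
      stage = names(stage_map),
      value = exp(stats::rnorm(length(stage_map),
                               mean = log(mu[stage_map]), sd = cfg$log_sd))
    )
  })
  list(table = do.call(rbind, rows), stage_map = stage_map, truth = tr)
}

#' Write a complete simulated dataset to disk
#'
#' Generates the expression matrix, screen table and single-cell table for a
#' config and writes them, with the stage map, planted truth and the config
#' snapshot, into a directory. Identical config and seed produce
#' byte-identical files.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written file paths.
#' @export
simulate_dataset <- function(cfg, dir) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  expr <- simulate_expression(cfg)
  scr <- simulate_screen(cfg)
  sc <- simulate_single_cell(cfg)
  paths <- c(matrix = file.path(dir, "matrix.tsv"),
             screen = file.path(dir, "screen.tsv"),
             single_cell = file.path(dir, "single_cell.tsv"),
             stage_map = file.path(dir, "stage_map.yaml"),
             truth = file.path(dir, "truth.json"),
             config = file.path(dir, "sim_config.json"))
  write_tsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_tsv(expr$matrix, paths["matrix"])
  write_tsv(scr$table, paths["screen"])
  write_tsv(sc$table, paths["single_cell"])
  yaml::write_yaml(as.list(sc$stage_map), paths["stage_map"])
  jsonlite::write_json(
    list(expression = expr$truth,
         screen = scr$truth[, c("gene_symbol", "stock_id", "phenotype", "d",
                                "brood_mean")],
         single_cell = sc$truth),
    paths["truth"], dataframe = "rows", auto_unbox = TRUE, digits = NA)
  cfg_out <- cfg[c("seed", "n_genes", "tissues", "whole_body", "n_replicates",
                   "base_mean", "log_sd", "detection_floor", "fold_change")]
  jsonlite::write_json(cfg_out, paths["config"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
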