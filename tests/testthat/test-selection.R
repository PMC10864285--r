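test_that("tissue calls combine the enrichment ratio and the t-test", {
  p <- make_profile(ovary = c(10, 12, 9, 11), whole_body = c(2, 3, 2, 3))
  call <- compute_tissue_call(p, "ovary")
  expect_equal(call$enrichment, 4.2)
  expect_equal(call$p_value, oracle_t_p(c(10, 12, 9, 11), c(2, 3, 2, 3)),
               tolerance = 1e-12)
  expect_identical(call$direction, "up")

  # identical samples: enrichment exactly 1, never "up" (strict inequality)
  p2 <- make_profile(ovary = c(2, 3, 2, 3), whole_body = c(2, 3, 2, 3))
  call2 <- compute_tissue_call(p2, "ovary")
  expect_equal(call2$enrichment, 1)
  expect_identical(call2$direction, "others")

  # mirrored samples give the symmetric "down" call at the same p
  p3 <- make_profile(ovary = c(2, 3, 2, 3), whole_body = c(10, 12, 9, 11))
  call3 <- compute_tissue_call(p3, "ovary")
  expect_lt(call3$enrichment, 1)
  expect_equal(call3$p_value, call$p_value, tolerance = 1e-12)
  expect_identical(call3$direction, "down")
})

test_that("degenerate replicate layouts are handled, never fatal", {
  # one replicate on a side: no t-test, forced "others" and flagged
  p <- make_profile(ovary = 10, whole_body = c(2, 3))
  call <- compute_tissue_call(p, "ovary")
  expect_identical(call$direction, "others")
  expect_true(is.na(call$p_value))
  expect_true(call$flagged)

  # zero variance on both sides: p is the degenerate t limit
  same <- make_profile(ovary = c(5, 5), whole_body = c(5, 5))
  expect_equal(compute_tissue_call(same, "ovary")$p_value, 1)
  diff <- make_profile(ovary = c(9, 9), whole_body = c(3, 3))
  dcall <- compute_tissue_call(diff, "ovary")
  expect_equal(dcall$p_value, 0)
  expect_identical(dcall$direction, "up")

  # zero whole-body mean is a hard error
  z <- make_profile(ovary = c(1, 2), whole_body = c(0, 0))
  expect_error(compute_tissue_call(z, "ovary"), "whole-body mean")
})

test_that("direction is a partition: exactly one of up/down/others", {
  set.seed(11)
  for (i in 1:100) {
    x <- exp(rnorm(4, sd = 1))
    y <- exp(rnorm(4, sd = 1))
    p <- make_profile(ovary = x, whole_body = y)
    call <- compute_tissue_call(p, "ovary")
    up <- call$enrichment > 1 && call$p_value <= 0.05
    down <- call$enrichment < 1 && call$p_value <= 0.05
    expected <- if (up) "up" else if (down) "down" else "others"
    expect_identical(call$direction, expected)
  }
})

test_that("enrichment is monotone in a common tissue scaling", {
  set.seed(12)
  for (i in 1:20) {
    x <- exp(rnorm(4)); y <- exp(rnorm(4)); c_scale <- runif(1, 1, 5)
    e1 <- compute_tissue_call(make_profile(ovary = x, whole_body = y),
                              "ovary")$enrichment
    e2 <- compute_tissue_call(make_profile(ovary = c_scale * x, whole_body = y),
                              "ovary")$enrichment
    expect_gte(e2, e1)
  }
})

test_that("unwanted symbols are dropped with a per-reason report", {
  tab <- data.frame(gene_symbol = c("CR43242", "c(3)G", "---", "snRNA:U1",
                                    "RpL32", "RpS3", "CG4951", "ord"))
  res <- filter_unwanted_genes(tab)
  expect_setequal(res$kept$gene_symbol, c("c(3)G", "CG4951", "ord"))
  rep <- setNames(res$report$n_dropped, res$report$reason)
  expect_equal(rep[["unknown"]], 1)
  expect_equal(rep[["noncoding_cr"]], 1)
  expect_equal(rep[["rna_gene"]], 1)
  expect_equal(rep[["ribosomal"]], 2)
  # empty in, empty out
  empty <- filter_unwanted_genes(data.frame(gene_symbol = character()))
  expect_equal(nrow(empty$kept), 0)
})

test_that("probe sets absent from all germline tissues are removed", {
  absent <- make_profile("pA", present = list(
    ovary = c(FALSE, FALSE), testis = c(FALSE, FALSE), cns = c(FALSE, FALSE),
    gut = c(TRUE, TRUE), whole_body = c(TRUE, TRUE)),
    ovary = c(1, 1), testis = c(1, 1), cns = c(1, 1), gut = c(9, 9),
    whole_body = c(1, 1))
  witness <- make_profile("pB", present = list(
    ovary = c(TRUE, FALSE), testis = c(FALSE, FALSE), cns = c(FALSE, FALSE),
    whole_body = c(TRUE, TRUE)),
    ovary = c(5, 1), testis = c(1, 1), cns = c(1, 1), whole_body = c(1, 1))
  all_on <- make_profile("pC", ovary = c(5, 5), testis = c(5, 5),
                         cns = c(5, 5), whole_body = c(5, 5))
  res <- filter_absent_probesets(list(absent, witness, all_on))
  expect_setequal(vapply(res$kept, `[[`, "", "probe_id"), c("pB", "pC"))
  expect_equal(vapply(res$removed, `[[`, "", "probe_id"), "pA")
  # kept + removed partition the input
  expect_equal(length(res$kept) + length(res$removed), 3)
  # missing flags: default treats as absent, strict mode errors
  noflags <- make_profile("pD", ovary = c(5, 5), whole_body = c(1, 1),
                          present = list())
  expect_equal(length(filter_absent_probesets(list(noflags))$kept), 0)
  expect_error(filter_absent_probesets(list(noflags), missing_flags = "error"),
               "present flags")
})

test_that("representative probe ranks by present calls then up calls", {
  a <- make_profile("pA", "g", present = list(
    ovary = rep(TRUE, 4), testis = rep(TRUE, 4), cns = rep(TRUE, 4),
    whole_body = rep(TRUE, 4)),
    ovary = c(10, 11, 10, 11), testis = c(2, 2, 2, 2), cns = c(2, 2, 2, 2),
    whole_body = c(2, 2.1, 2, 2.1))
  b <- make_profile("pB", "g", present = list(
    ovary = rep(TRUE, 4), testis = c(TRUE, TRUE, FALSE, FALSE),
    cns = rep(FALSE, 4), whole_body = rep(TRUE, 4)),
    ovary = c(10, 11, 10, 11), testis = c(2, 2, 2, 2), cns = c(2, 2, 2, 2),
    whole_body = c(2, 2.1, 2, 2.1))
  calls <- rbind(compute_tissue_call(a, "ovary"), compute_tissue_call(b, "ovary"))
  expect_identical(select_representative_probe("g", list(a, b), calls), "pA")
  # single candidate wins trivially
  expect_identical(select_representative_probe("g", list(b), calls), "pB")
  # exact tie on both keys: lexicographically smallest id
  b2 <- a; b2$probe_id <- "pZ"
  calls2 <- rbind(compute_tissue_call(a, "ovary"), compute_tissue_call(b2, "ovary"))
  expect_identical(select_representative_probe("g", list(b2, a), calls2), "pA")
})

test_that("tissue-group classification requires ovary and tolerates only testis/CNS", {
  expect_identical(
    classify_tissue_group(c(ovary = "up", testis = "others", cns = "others",
                            midgut = "others")), "ovary_only")
  expect_identical(
    classify_tissue_group(c(ovary = "up", testis = "up", cns = "up",
                            midgut = "down")), "ovary_cns_testis")
  expect_identical(
    classify_tissue_group(c(ovary = "up", testis = "others", cns = "up")),
    "ovary_cns")
  expect_identical(
    classify_tissue_group(c(ovary = "up", testis = "up", cns = "others")),
    "ovary_testis")
  # any other tissue up disqualifies
  expect_identical(
    classify_tissue_group(c(ovary = "up", testis = "others", cns = "others",
                            midgut = "up")), "not_selected")
  expect_identical(
    classify_tissue_group(c(ovary = "others", testis = "up", cns = "up")),
    "not_selected")
  expect_error(classify_tissue_group(c(testis = "up")), "ovary")
})

test_that("the funnel recovers planted genes and conserves counts", {
  cfg <- sim_config(seed = 301, n_genes = 100, n_planted = 10)
  sim <- simulate_expression(cfg)
  res <- run_selection_funnel(sim$profiles)
  planted <- sim$truth$gene_id[sim$truth$true_group != "not_selected"]
  expect_length(planted, 10)
  # a planted gene can be lost to a spurious "up" call in a bystander tissue,
  # so require the design sensitivity (>= 0.9), not perfection
  expect_gte(sum(planted %in% res$candidates$gene_id), 9)
  expect_lte(sum(setdiff(sim$truth$gene_id, planted) %in% res$candidates$gene_id),
             0.1 * 90)
  # per-stage conservation
  expect_true(all(res$report$n_out + res$report$n_dropped == res$report$n_in))
  # empty input gives an empty, zeroed funnel
  empty <- run_selection_funnel(list())
  expect_equal(nrow(empty$candidates), 0)
  expect_equal(empty$report$n_in, 0)
})
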