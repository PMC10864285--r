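test_that("the doubled-count estimator evaluates the printed formula", {
  expect_equal(ndj_frequency(100, 90, 3, 2), 0.05)  # 10 / 200
  expect_equal(ndj_frequency(50, 60, 0, 0), 0)
  expect_equal(ndj_frequency(0, 0, 3, 1), 1)        # all-NDJ limit
  expect_error(ndj_frequency(0, 0, 0, 0), "no progeny")
  expect_error(ndj_frequency(-1, 0, 0, 0), "non-negative")
})

test_that("summary-cell frequencies agree with raw-tally frequencies", {
  expect_equal(round(100 * ndj_from_summary(226, 18), 1), 15.9)
  expect_equal(ndj_from_summary(505, 0), 0)
  expect_error(ndj_from_summary(3, 2), "2 \\* ndj_events")
  expect_error(ndj_from_summary(0, 0))

  # equivalence: any raw tally and its summary give the same frequency
  set.seed(31)
  for (i in 1:1000) {
    xx <- rpois(1, 50); xy <- rpois(1, 50)
    xo <- rpois(1, 2); xxy <- rpois(1, 2)
    if (xx + xy + xo + xxy == 0) next
    f_raw <- ndj_frequency(xx, xy, xo, xxy)
    f_sum <- ndj_from_summary(2 * (xo + xxy) + xx + xy, xo + xxy)
    expect_identical(f_sum, f_raw)
    expect_gte(f_raw, 0); expect_lte(f_raw, 1)
    # exchanging the two exceptional classes changes nothing
    expect_identical(ndj_frequency(xx, xy, xxy, xo), f_raw)
  }
})

test_that("the estimator is strictly increasing in exceptional progeny", {
  for (k in 0:20) {
    expect_lt(ndj_frequency(40, 40, k, k), ndj_frequency(40, 40, k + 1, k))
  }
})

test_that("screen cells parse to cross records and malformed cells fail loudly", {
  tab <- data.frame(gene_symbol = c("CG3430", "CG11133"),
                    stock_id = c("HMC06551", "HMJ23886"),
                    mvd1 = c("586, 2 NDJ", "STERILE"),
                    mata = c("226, 18 NDJ", "ND"),
                    tub_gal4 = c("Lethal", ""))
  res <- parse_screen_table(tab)
  expect_equal(nrow(res), 4)
  r <- res[res$gene_symbol == "CG3430" & res$driver == "mata", ]
  expect_identical(r$status, "counts")
  expect_identical(r$adjusted_total, 226L)
  expect_identical(r$ndj_events, 18L)
  expect_identical(res$status[res$gene_symbol == "CG11133"], c("STERILE", "ND"))
  expect_identical(unique(res$tub_gal4[res$gene_symbol == "CG3430"]), "Lethal")

  # "7, 2 NDJ" satisfies total >= 2k; "3, 2 NDJ" cannot come from any tally
  ok <- tab; ok$mvd1[1] <- "7, 2 NDJ"
  expect_silent(parse_screen_table(ok))
  bad <- tab; bad$mvd1[1] <- "3, 2 NDJ"
  expect_error(parse_screen_table(bad), "row 1.*inconsistent")
  garbled <- tab; garbled$mata[2] <- "maybe"
  expect_error(parse_screen_table(garbled), "row 2.*malformed")
})

test_that("line calls implement the three positivity criteria per driver", {
  th <- screen_thresholds()
  mk <- function(mvd1, mata) {
    parse_screen_table(data.frame(gene_symbol = "g", stock_id = "s",
                                  mvd1 = mvd1, mata = mata))
  }
  # sterile in one driver, tiny brood in the other
  lc <- call_line(mk("STERILE", "6, 0 NDJ"), th)
  expect_true(lc$positive)
  expect_setequal(lc$categories[[1]], c("Sterile", "Small_brood"))

  # 2/119 = 1.68% rounds to 1.7% at one decimal and meets the cutoff
  lc2 <- call_line(mk("505, 0 NDJ", "119, 1 NDJ"), th)
  expect_setequal(lc2$categories[[1]], "NDJ")
  # without rounding the same line is negative
  lc2r <- call_line(mk("505, 0 NDJ", "119, 1 NDJ"),
                    screen_thresholds(ndj_rounding_decimals = NULL))
  expect_false(lc2r$positive)

  # brood exactly at the cutoff: inclusive by default, strict when configured
  lc3 <- call_line(mk("100, 0 NDJ", "ND"), th)
  expect_setequal(lc3$categories[[1]], "Small_brood")
  lc3s <- call_line(mk("100, 0 NDJ", "ND"),
                    screen_thresholds(brood_inclusive = FALSE))
  expect_false(lc3s$positive)

  # a sterile cross is not also a small brood
  lc4 <- call_line(mk("STERILE", "STERILE"), th)
  expect_setequal(lc4$categories[[1]], "Sterile")

  # one cell can meet both NDJ and small-brood criteria
  lc5 <- call_line(mk("ND", "26, 1 NDJ"), th)
  expect_setequal(lc5$categories[[1]], c("NDJ", "Small_brood"))

  # only ND entries: untested, not negative
  lc6 <- call_line(mk("ND", "ND"), th)
  expect_identical(lc6$call, "untested")
  expect_false(lc6$positive)
})

test_that("gene calls are the union over positive lines", {
  mk_line <- function(stock, mvd1, mata) {
    call_line(parse_screen_table(data.frame(gene_symbol = "g", stock_id = stock,
                                            mvd1 = mvd1, mata = mata)))
  }
  lines <- rbind(mk_line("s1", "STERILE", "ND"),
                 mk_line("s2", "500, 0 NDJ", "40, 0 NDJ"),
                 mk_line("s3", "ND", "ND"))
  g <- call_gene(lines)
  expect_true(g$positive)
  expect_setequal(g$categories[[1]], c("Sterile", "Small_brood"))
  expect_identical(g$venn_region, "Sterile+Small_brood")
  expect_equal(g$n_positive_lines, 2)

  single <- call_gene(mk_line("s1", "300, 10 NDJ", "ND"))
  expect_identical(single$venn_region, "NDJ")

  neg <- call_gene(mk_line("s1", "500, 0 NDJ", "400, 1 NDJ"))
  expect_false(neg$positive)
  expect_length(neg$categories[[1]], 0)
})

test_that("the Venn summary partitions the positive genes", {
  tab <- data.frame(
    gene_symbol = c("gA", "gB", "gC", "gD"),
    stock_id = c("s1", "s2", "s3", "s4"),
    mvd1 = c("STERILE", "300, 10 NDJ", "50, 0 NDJ", "600, 0 NDJ"),
    mata = c("ND", "400, 0 NDJ", "STERILE", "500, 1 NDJ"))
  res <- score_screen(tab)
  venn <- setNames(res$venn$n_genes, res$venn$venn_region)
  expect_equal(venn[["Sterile"]], 1)                 # gA
  expect_equal(venn[["NDJ"]], 1)                     # gB
  expect_equal(venn[["Sterile+Small_brood"]], 1)     # gC
  expect_equal(sum(res$venn$n_genes), sum(res$gene_calls$positive))

  # all-negative input: every region zero
  none <- score_screen(data.frame(gene_symbol = "g", stock_id = "s",
                                  mvd1 = "900, 0 NDJ", mata = "800, 0 NDJ"))
  expect_equal(sum(none$venn$n_genes), 0)
})
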