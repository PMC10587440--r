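test_that("tau index hits its limits and the hand-computed value", {
  expect_equal(tau_index(c(5, 5, 5, 5)), 0)
  expect_equal(tau_index(c(9, 0, 0, 0)), 1)
  expect_equal(tau_index(c(8, 4, 0, 0)), 5 / 6)  # (0 + 0.5 + 1 + 1)/3
  expect_true(is.na(tau_index(c(0, 0, 0))))
  expect_error(tau_index(c(-1, 2)), "negative")
})

test_that("tau is bounded and scale-invariant", {
  withr::with_seed(37, {
    m <- matrix(rlnorm(200 * 6), 200, 6)
    taus <- tau_index(m)
    expect_true(all(taus >= 0 & taus <= 1))
    expect_equal(tau_index(m * 17.3), taus)
  })
})

test_that("SE-gene association matches an exhaustive distance check", {
  ses <- GRanges("chr1", IRanges(c(10000, 100000), c(20000, 130000)),
                 se_id = c("SE_1", "SE_2"))
  genes <- GRanges("chr1", IRanges(c(15000, 80000), width = 2000),
                   strand = "+", gene_id = c("gIn", "gFar"))
  a0 <- associate_ses_to_genes(ses, genes, window = 0, anchor = "tss")
  expect_true(a0$has_se[["gIn"]])
  expect_false(a0$has_se[["gFar"]])     # 18 kb from SE_2, window 0
  a10 <- associate_ses_to_genes(ses, genes, window = 10000)
  expect_false(a10$has_se[["gFar"]])    # still 18 kb away
  expect_equal(a0$se_to_genes$SE_1, "gIn")

  withr::with_seed(41, {
    rs <- sort(sample.int(9e5, 15))
    rse <- GRanges("chr1", IRanges(rs, rs + 5000))
    gs <- sample.int(9e5, 200)
    rg <- GRanges("chr1", IRanges(gs, gs + 1000), gene_id = as.character(1:200))
    win <- 7500
    got <- associate_ses_to_genes(rse, rg, window = win)$has_se
    want <- vapply(seq_along(rg), function(i) {
      any(pmax(start(rse) - end(rg)[i], start(rg)[i] - end(rse), 0) <= win)
    }, logical(1))
    expect_equal(unname(got), want)
  })
})

test_that("size quintiles split evenly with the remainder rule and keep order", {
  mk <- function(widths) GRanges("chr1", IRanges(seq(1, by = 1e6,
                                                     length.out = length(widths)),
                                                 width = widths))
  g10 <- size_quintiles(mk(sample(1000:2000, 10)))
  expect_equal(as.vector(table(g10)), rep(2L, 5))
  g12 <- size_quintiles(mk(sample(1000:2000, 12)))
  expect_equal(as.vector(table(g12)), c(3L, 3L, 2L, 2L, 2L))
  expect_error(size_quintiles(mk(c(100, 200))), "at least 5")

  withr::with_seed(43, {
    for (rep in 1:5) {
      ses <- mk(sample(500:50000, sample(23:87, 1), replace = TRUE))
      q <- size_quintiles(ses)
      expect_lte(max(width(ses)[q == "G1"]), min(width(ses)[q == "G5"]))
      # concatenating groups in order reproduces the ascending-size sort
      w_sorted <- unlist(lapply(paste0("G", 1:5), function(l) {
        sort(width(ses)[q == l])
      }))
      expect_equal(w_sorted, sort(width(ses)))
      expect_lte(diff(range(table(q))), 1)
    }
  })
})

test_that("distance groups partition with T3 = overlap and median splits", {
  d <- c(-100, -10, 0, 10, 100)
  g <- distance_groups(d)
  expect_equal(as.character(g), c("T1", "T2", "T3", "T4", "T5"))
  expect_equal(as.character(distance_groups(c(0, 0, 0))), rep("T3", 3))
  withr::with_seed(47, {
    d2 <- sample(-5e4:5e4, 500)
    g2 <- distance_groups(d2)
    expect_false(anyNA(g2))                    # partition
    expect_true(all(d2[g2 == "T3"] == 0))
    expect_true(max(abs(d2[g2 == "T2"])) <= min(abs(d2[g2 == "T1"])))
    expect_true(max(abs(d2[g2 == "T4"])) <= min(abs(d2[g2 == "T5"])))
  })
})

test_that("group comparisons are rank-based, directional, and BH-adjusted", {
  withr::with_seed(53, {
    same <- compare_groups(c(rep(1, 50), rep(1, 50)),
                           rep(c("A", "B"), each = 50), reference = "B")
    expect_equal(same$p_value, 1)
    expect_equal(same$direction, 0)

    shifted <- c(rlnorm(200), rlnorm(200) * 2)
    grp2 <- rep(c("ref", "hi"), each = 200)
    res <- compare_groups(shifted, grp2, reference = "ref")
    expect_lt(res$p_adjusted, 0.01)
    expect_equal(res$direction, 1)
    # swapping roles flips direction, preserves the p-value
    res_sw <- compare_groups(shifted, factor(grp2, levels = c("hi", "ref")),
                             reference = "hi")
    expect_equal(res_sw$p_value, res$p_value, tolerance = 1e-12)
    expect_equal(res_sw$direction, -res$direction)
  })
  expect_error(compare_groups(1:10, rep("A", 10), "B"), "not present")
})

test_that("signed SE-TSS distances follow the strand convention", {
  ses <- GRanges("chr1", IRanges(10000, 20000))
  genes <- GRanges("chr1", IRanges(c(12000, 25000, 25000), width = 100),
                   strand = c("+", "+", "-"),
                   gene_id = c("inside", "plus_right", "minus_right"))
  d <- se_gene_distances(ses, genes)
  expect_equal(d$distance[d$gene_id == "inside"], 0)
  # + strand gene at 25000: SE ends 5000 bp before the TSS => upstream => +
  expect_equal(d$distance[d$gene_id == "plus_right"], 5000)
  # same geometry on - strand (TSS at 25099): SE is downstream => negative
  expect_equal(d$distance[d$gene_id == "minus_right"], -5099)
})

test_that("body-map summaries report sizes, gaps, and genome coverage", {
  cons <- GRanges("chr1", IRanges(c(1, 1201), c(600, 1900)))
  se <- GRanges("chr1", IRanges(1, 50000))
  mcols(se)$n_constituents <- 2L
  mcols(se)$constituents <- GRangesList(cons)
  mcols(se)$total_signal <- 1e5
  res <- summarize_bodymap(list(liver = se), genome = c(chr1 = 1e6))
  liver <- res[res$tissue == "liver", ]
  expect_equal(liver$genome_coverage_pct, 5.0)
  expect_equal(liver$mean_constituent_size, 650)
  expect_equal(liver$mean_constituent_gap, 600)
  expect_equal(liver$median_constituents, 2)
  expect_equal(liver$mean_signal_density, 2)
  expect_equal(res$tissue, c("liver", "pooled"))
})
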