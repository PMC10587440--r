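gr1 <- function(s, e) GRanges("chr1", IRanges(s, e))

test_that("within-tissue consensus keeps regions supported by all samples", {
  one <- gr1(c(1, 100000), c(50000, 140000))
  expect_identical(tissue_consensus(list(one)), one)
  # overlap then union: (0,50k) and (40k,90k) -> (0,90k)
  cons <- tissue_consensus(list(gr1(1, 50000), gr1(40001, 90000)))
  expect_equal(c(start(cons), end(cons)), c(1L, 90000L))
  # disjoint samples -> empty consensus
  expect_length(tissue_consensus(list(gr1(1, 1000), gr1(5000, 6000))), 0L)
  # m-of-n relaxation
  three <- list(gr1(1, 1000), gr1(500, 1500), gr1(9000, 9500))
  expect_length(tissue_consensus(three), 0L)
  expect_length(tissue_consensus(three, min_samples = 2), 1L)
})

test_that("cross-tissue merging is inclusive at exactly the 10 kb threshold", {
  # overlap exactly 10,000 bp -> one SE spanning the union
  a <- gr1(1, 60000); b <- gr1(50001, 120000)
  res <- merge_across_tissues(list(A = a, B = b))
  expect_length(res$ses, 1L)
  expect_equal(c(start(res$ses), end(res$ses)), c(1L, 120000L))
  expect_true(all(res$presence[1, c("A", "B")]))
  # overlap 9,999 bp -> two distinct SEs
  res2 <- merge_across_tissues(list(A = a, B = gr1(50002, 120000)))
  expect_length(res2$ses, 2L)
})

test_that("cross-tissue merging equals the transitive-closure oracle", {
  withr::with_seed(13, {
    tissue_sets <- lapply(1:14, function(i) {
      s <- sort(sample.int(3e6, 8)) * 1L
      gr1(s, s + sample(c(8000L, 15000L, 30000L), 8, replace = TRUE))
    })
    names(tissue_sets) <- paste0("t", 1:14)
    # reduce within tissue first (a tissue's call set is non-overlapping)
    tissue_sets <- lapply(tissue_sets, reduce)
    got <- merge_across_tissues(tissue_sets, min_overlap = 10000)
    want <- oracle_merge_tissues(tissue_sets, min_overlap = 10000)
    expect_equal(start(got$ses), want$start)
    expect_equal(end(got$ses), want$end)
    got_tissues <- apply(got$presence, 1, function(r) {
      paste(sort(colnames(got$presence)[r]), collapse = ",")
    })
    expect_equal(unname(got_tissues), want$tissues)

    # order invariance: permuting tissues yields the same set and presence
    perm <- sample(14)
    got_p <- merge_across_tissues(tissue_sets[perm], min_overlap = 10000)
    expect_equal(granges(got_p$ses), granges(got$ses))
    expect_equal(got_p$presence[, colnames(got$presence), drop = FALSE],
                 got$presence)

    # idempotence: merging the merged set changes nothing
    again <- merge_across_tissues(list(all = granges(got$ses)),
                                  min_overlap = 10000)
    expect_equal(granges(again$ses), granges(got$ses))
  })
})

test_that("activity is mean signal density and matches a per-base oracle", {
  ses <- gr1(c(1, 20001), c(10000, 30000))
  mcols(ses)$se_id <- c("SE_1", "SE_2")
  tr_a <- GRanges("chr1", IRanges(1, 10000), score = 3.0)
  tr_b <- GRanges("chr1", IRanges(25001, 26000), score = 5.0)
  am <- build_activity_matrix(ses, list(a = tr_a, b = tr_b))
  expect_equal(am$activity["SE_1", "a"], 3.0)
  expect_equal(am$activity["SE_1", "b"], 0)
  expect_equal(am$activity["SE_2", "b"], 5.0 * 1000 / 10000)
  expect_true(all(am$activity >= 0))

  withr::with_seed(17, {
    ses5 <- gr1(seq(1, 90000, by = 20000), seq(5000, 94000, by = 20000))
    s <- sort(sample.int(95000, 60))
    track <- GRanges("chr1", IRanges(s, s + 500), score = runif(60, 0, 4))
    got <- build_activity_matrix(ses5, list(x = track))$activity[, "x"]
    per_base <- numeric(1e5)
    for (i in seq_along(track)) {
      idx <- start(track)[i]:end(track)[i]
      per_base[idx] <- per_base[idx] + track$score[i]
    }
    want <- vapply(seq_along(ses5), function(i) {
      mean(per_base[start(ses5)[i]:end(ses5)[i]])
    }, numeric(1))
    expect_equal(unname(got), want)
  })
  expect_error(
    build_activity_matrix(ses, list(a = tr_a),
                          presence = matrix(TRUE, 2, 2,
                                            dimnames = list(NULL, c("a", "b")))),
    "missing signal track")
})

test_that("tissue-specific SEs are those present in exactly one tissue", {
  pres <- rbind(rep(TRUE, 14),
                c(TRUE, rep(FALSE, 13)),
                c(rep(FALSE, 12), TRUE, TRUE))
  colnames(pres) <- paste0("t", 1:14)
  rownames(pres) <- paste0("SE_", 1:3)
  ts <- tissue_specific_ses(pres)
  expect_equal(unname(ts$tissue_count), c(14, 1, 2))
  expect_equal(ts$specific$t1, "SE_2")
  expect_equal(ts$frac_single, 1 / 3)
  expect_equal(ts$frac_all, 1 / 3)
})

test_that("clustering recovers separable blocks and is deterministic", {
  skip_if_not_installed("mclust")
  bm <- simulate_block_matrix(n_se = 120, n_tissues = 8, k = 2, snr = 8,
                              seed = 31)
  fit <- cluster_ses(bm$activity, k = 2, seed = 1)
  expect_equal(mclust::adjustedRandIndex(fit$cluster, bm$labels), 1)
  fit2 <- cluster_ses(bm$activity, k = 2, seed = 1)
  expect_identical(fit$cluster, fit2$cluster)
  expect_error(cluster_ses(bm$activity, k = 500), "exceeds")
})
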