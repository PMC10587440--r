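test_that("BED and GFF coordinate conventions converge to the same interval", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200", bed)
  gb <- read_intervals(bed, "bed")
  expect_equal(start(gb), 101L)
  expect_equal(end(gb), 200L)
  expect_equal(width(gb), 100L)

  gff <- withr::local_tempfile(fileext = ".gff")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tenhancer\t101\t200\t.\t+\t.\tID=e1;state=EnhA"),
             gff)
  gg <- read_intervals(gff, "gff")
  expect_equal(c(start(gg), end(gg)), c(101L, 200L))
  expect_equal(as.character(gg$state), "EnhA")

  # GFF -> BED -> GFF round trip preserves coordinates exactly
  bed2 <- withr::local_tempfile(fileext = ".bed")
  write_bed(granges(gg), bed2)   # stranded record -> BED6
  expect_equal(readLines(bed2), "chr1\t100\t200\t.\t0\t+")
  back <- read_intervals(bed2, "bed")
  expect_identical(ranges(back), ranges(gb))
})

test_that("canonical BED3/BED6 round-trips are byte-identical", {
  for (content in list("chr1\t100\t200",
                       c("chr1\t0\t50", "chr2\t999\t12345"),
                       c("chr1\t100\t200\tpeakA\t5\t+",
                         "chr1\t300\t400\tpeakB\t7\t-"))) {
    f <- withr::local_tempfile(fileext = ".bed")
    writeLines(content, f)
    g <- read_intervals(f, "bed")
    f2 <- withr::local_tempfile(fileext = ".bed")
    write_bed(g, f2)
    expect_identical(readLines(f2), content)
  }
})

test_that("RepeatMasker .out parsing converts coordinates and keeps classes", {
  f <- withr::local_tempfile(fileext = ".out")
  writeLines(c("header line 1", "header line 2", "",
               " 463 10.8 0.0 0.0 chr1 501 600 (100) + MIR3 SINE/MIR 1 100 (0) 1",
               " 463 10.8 0.0 0.0 chr2 700 900 (100) C L1_Ssc LINE/L1 1 200 (0) 2"),
             f)
  g <- read_intervals(f, "repeatmasker")
  expect_equal(start(g), c(501L, 700L))
  expect_equal(end(g), c(600L, 900L))
  expect_equal(as.character(g$repeat_class), c("SINE/MIR", "LINE/L1"))
  expect_equal(as.character(g$repeat_family), c("SINE", "LINE"))
  expect_equal(as.character(strand(g)), c("+", "-"))

  bad <- withr::local_tempfile(fileext = ".out")
  writeLines(c("h", "h", "", "only four fields here x"), bad)
  expect_error(read_intervals(bad, "repeatmasker"), "line 4")
})

test_that("merge_intervals bridges gaps at most min_gap and is idempotent", {
  # 0-based (0,10),(15,20) <=> 1-based [1,10],[16,20]: gap 5 bridges at min_gap 5
  g <- GRanges("chr1", IRanges(c(1, 16), c(10, 20)))
  m <- merge_intervals(g, min_gap = 5)
  expect_equal(c(start(m), end(m)), c(1L, 20L))
  # gap 6 does not
  g2 <- GRanges("chr1", IRanges(c(1, 17), c(10, 20)))
  m2 <- merge_intervals(g2, min_gap = 5)
  expect_length(m2, 2L)
  expect_length(merge_intervals(GRanges()), 0L)

  withr::with_seed(42, {
    for (rep in 1:3) {
      gr <- random_gr(120, max_pos = 2e5)
      min_gap <- sample(c(0, 10, 1000), 1)
      got <- merge_intervals(gr, min_gap)
      want <- oracle_merge(gr, min_gap)
      expect_equal(as.character(seqnames(got)), as.character(seqnames(want)))
      expect_equal(start(got), start(want))
      expect_equal(end(got), end(want))
      expect_identical(merge_intervals(got, min_gap), got)  # idempotent
    }
  })
})

test_that("overlap_size matches a per-base mask oracle and is symmetric", {
  a <- GRanges("chr1", IRanges(1, 100))
  b <- GRanges("chr1", IRanges(51, 150))
  expect_equal(overlap_size(a, b), 50)
  expect_equal(overlap_size(a, GRanges("chr1", IRanges(500, 600))), 0)

  withr::with_seed(7, {
    A <- random_gr(200, max_pos = 9e4, max_width = 800)
    B <- random_gr(200, max_pos = 9e4, max_width = 800)
    expect_equal(overlap_size(A, B),
                 oracle_overlap_bp(A, B, c("chr1", "chr2"), 1e5))
    expect_equal(overlap_size(A, B), overlap_size(B, A))
    expect_equal(overlap_size(A, A), total_width(A))
  })
})

test_that("closest_tss finds the nearest TSS with the declared sign convention", {
  genes <- GRanges("chr1", IRanges(c(1500, 1000), width = 1),
                   strand = c("+", "+"), gene_id = c("gA", "gB"))
  # TSS inside the query => distance 0
  r <- closest_tss(GRanges("chr1", IRanges(1000, 2000)), genes[1])
  expect_equal(r$distance, 0)
  # + strand, query past the TSS => downstream => negative
  r2 <- closest_tss(GRanges("chr1", IRanges(2000, 2100)), genes[2])
  expect_equal(r2$distance, -1000)
  # - strand mirrors the sign
  gneg <- GRanges("chr1", IRanges(900, 1000), strand = "-", gene_id = "gC")
  r3 <- closest_tss(GRanges("chr1", IRanges(2000, 2100)), gneg)
  expect_equal(r3$distance, 1000)
  # equidistant tie -> lower reference index
  ties <- GRanges("chr1", IRanges(c(900, 1100), width = 1), strand = "+",
                  gene_id = c("g1", "g2"))
  expect_equal(closest_tss(GRanges("chr1", IRanges(1000, 1000)), ties)$gene_index, 1L)
  expect_error(closest_tss(GRanges("chr1", IRanges(1, 2)), GRanges()), "empty")

  # exhaustive-scan oracle on random layouts
  withr::with_seed(11, {
    refs <- GRanges("chr1", IRanges(sort(sample.int(1e5, 30)), width = 1),
                    strand = sample(c("+", "-"), 30, replace = TRUE))
    tssp <- tss_position(refs)
    qs <- random_gr(50, chroms = "chr1", max_pos = 1e5, max_width = 2000)
    res <- closest_tss(qs, refs)
    for (i in seq_len(50)) {
      d_all <- pmax(start(qs)[i] - tssp, tssp - end(qs)[i], 0)
      expect_equal(abs(res$distance[i]), min(d_all))
    }
  })
})

test_that("shuffle_intervals preserves widths and chromosomes", {
  g <- GRanges(c("chr1", "chr2"), IRanges(c(10, 500), width = c(100, 250)))
  genome <- c(chr1 = 1e4, chr2 = 1e4)
  s <- withr::with_seed(1, shuffle_intervals(g, genome))
  expect_equal(width(s), width(g))
  expect_equal(as.character(seqnames(s)), as.character(seqnames(g)))
  expect_true(all(start(s) >= 1 & end(s) <= 1e4))
  expect_error(shuffle_intervals(GRanges("chr1", IRanges(1, 2e4)), genome),
               "longer")
})
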