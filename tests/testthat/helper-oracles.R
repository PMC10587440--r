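suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

# random intervals on a small toy genome
random_gr <- function(n, chroms = c("chr1", "chr2"), max_pos = 1e6,
                      max_width = 5000) {
  chrom <- sample(chroms, n, replace = TRUE)
  s <- sample.int(max_pos - max_width, n, replace = TRUE)
  w <- sample.int(max_width, n, replace = TRUE)
  GRanges(chrom, IRanges(s, width = w))
}

# brute-force merge oracle: repeated pairwise union until fixpoint
oracle_merge <- function(gr, min_gap = 0) {
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr), end = end(gr))
  repeat {
    changed <- FALSE
    i <- 1
    while (i <= nrow(df)) {
      j <- i + 1
      while (j <= nrow(df)) {
        same <- df$chrom[i] == df$chrom[j]
        gap_ij <- max(df$start[j] - df$end[i] - 1, df$start[i] - df$end[j] - 1, 0)
        touches <- df$start[j] <= df$end[i] && df$start[i] <= df$end[j]
        if (same && (touches || gap_ij <= min_gap)) {
          df$start[i] <- min(df$start[i], df$start[j])
          df$end[i] <- max(df$end[i], df$end[j])
          df <- df[-j, , drop = FALSE]
          changed <- TRUE
        } else j <- j + 1
      }
      i <- i + 1
    }
    if (!changed) break
  }
  df <- df[order(df$chrom, df$start), ]
  GRanges(df$chrom, IRanges(df$start, df$end))
}

# per-base boolean-mask overlap oracle on a toy genome
oracle_overlap_bp <- function(a, b, chroms, chrom_len) {
  total <- 0
  for (ch in chroms) {
    ma <- logical(chrom_len); mb <- logical(chrom_len)
    for (i in which(as.character(seqnames(a)) == ch)) {
      ma[start(a)[i]:end(a)[i]] <- TRUE
    }
    for (i in which(as.character(seqnames(b)) == ch)) {
      mb[start(b)[i]:end(b)[i]] <- TRUE
    }
    total <- total + sum(ma & mb)
  }
  total
}

# independent tangent-rule oracle: explicit loop over every rank, counting
# points on/below the unit-slope line through that rank's point
oracle_tangent_nsuper <- function(scores) {
  n <- length(scores)
  y <- sort(scores)
  xs <- (seq_len(n) - 1) / (n - 1)
  ys <- (y - min(y)) / (max(y) - min(y))
  best_count <- Inf; best_i <- NA
  for (i in seq_len(n)) {
    b <- ys[i] - xs[i]
    count <- 0
    for (j in seq_len(n)) if (ys[j] <= xs[j] + b + 1e-12) count <- count + 1
    if (count <= best_count) { best_count <- count; best_i <- i }
  }
  sum(scores > y[best_i])
}

# brute-force transitive-closure oracle for cross-tissue SE merging:
# repeatedly unite any two records overlapping >= min_overlap until fixpoint
oracle_merge_tissues <- function(tissue_ses, min_overlap) {
  recs <- do.call(rbind, lapply(names(tissue_ses), function(t) {
    g <- tissue_ses[[t]]
    if (length(g) == 0) return(NULL)
    data.frame(chrom = as.character(seqnames(g)), start = start(g),
               end = end(g), tissues = t)
  }))
  repeat {
    changed <- FALSE
    i <- 1
    while (i <= nrow(recs)) {
      j <- i + 1
      while (j <= nrow(recs)) {
        ov <- min(recs$end[i], recs$end[j]) - max(recs$start[i], recs$start[j]) + 1
        if (recs$chrom[i] == recs$chrom[j] && ov >= min_overlap) {
          recs$start[i] <- min(recs$start[i], recs$start[j])
          recs$end[i] <- max(recs$end[i], recs$end[j])
          recs$tissues[i] <- paste(sort(unique(c(
            strsplit(recs$tissues[i], ",")[[1]],
            strsplit(recs$tissues[j], ",")[[1]]))), collapse = ",")
          recs <- recs[-j, , drop = FALSE]
          changed <- TRUE
        } else j <- j + 1
      }
      i <- i + 1
    }
    if (!changed) break
  }
  recs[order(recs$chrom, recs$start), ]
}

# small, fast simulation configurations for tests
fast_config <- function(seed = 1, ...) {
  args <- list(...)
  defaults <- list(seed = seed, n_tissues = 3, n_genes = 60,
                   se_constituent_count_mean = 8,
                   background_peak_density = 2)
  do.call(sim_config, utils::modifyList(defaults, args))
}
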