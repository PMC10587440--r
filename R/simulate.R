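PIG_TISSUES <- c("adipose", "cecum", "cerebellum", "colon", "cortex",
                 "duodenum", "hypothalamus", "ileum", "jejunum", "liver",
                 "lung", "muscle", "spleen", "stomach")

ENHANCER_STATES <- c("EnhA", "EnhAMe", "EnhAWk", "EnhAHet", "EnhPois")

#' Configuration for the synthetic body-map generator
#'
#' Defaults emulate the study conditions the pipeline is designed for:
#' 14 tissues, ~20 planted super-enhancer loci active per tissue built from
#' constituent enhancer peaks of mean size 682 bp separated by mean gaps of
#' 625 bp (Poisson constituent counts, mean 43, min 2), ~2000 sparse
#' low-signal background peaks against a 50x signal contrast, five enhancer
#' state classes with separate mixing proportions inside and outside SEs,
#' X-chromosome placement depletion (rate factor 0.2), repeat classes with a
#' planted 5x SINE overlap bias, and a tissue x gene TPM matrix in which
#' genes near an SE locus have elevated, tissue-concordant expression.
#'
#' @param seed RNG seed (integer).
#' @param n_chroms Number of chromosomes; the last is named `chrX`.
#' @param chrom_length Length of every chromosome, bp.
#' @param n_tissues Number of tissues (up to 14 named pig tissues).
#' @param n_planted_se_per_tissue Expected planted SEs active per tissue.
#' @param se_constituent_count_mean Poisson mean constituent peaks per SE
#'   (min 2).
#' @param se_constituent_size_mean Mean constituent size, bp (sd 20%).
#' @param se_gap_mean Mean exponential gap between constituents, bp.
#' @param background_peak_density Background peaks per Mb of genome.
#' @param signal_fold_se_vs_background Signal ratio of SE constituents to
#'   background peaks.
#' @param state_mix,state_mix_se State-class proportions for background /
#'   SE-constituent peaks (named, sum to 1).
#' @param x_depletion_factor Per-bp SE placement rate on `chrX` relative to
#'   autosomes, in `[0, 1]`.
#' @param repeat_fraction Named genome fractions per repeat class.
#' @param repeat_se_fold Named target fold enrichment of each repeat class
#'   in the planted SE footprint.
#' @param repeat_piece_size Size of an individual repeat element, bp.
#' @param mir_frac_in_se,mir_frac_out Share of SINE elements labelled
#'   `SINE/MIR` inside / outside the SE footprint.
#' @param frac_single_tissue Fraction of SE loci active in exactly one
#'   tissue.
#' @param tissue_share_prob For multi-tissue loci, each further tissue is
#'   recruited with this probability.
#' @param se_expression_fold TPM multiplier for SE-target genes in tissues
#'   where their locus is active (at distance 0; decays linearly to 1 at
#'   the window edge when `proximity_decay`).
#' @param se_gene_window Window (bp) around a locus within which target
#'   gene TSS are planted.
#' @param proximity_decay Whether the expression boost decays with TSS-SE
#'   distance.
#' @param n_genes Number of genes.
#' @param frac_genes_near_se Fraction of genes planted as SE targets.
#' @param tpm_noise_cv Coefficient of variation of multiplicative TPM noise.
#' @param tpm_base_meanlog,tpm_base_sdlog Lognormal baseline expression.
#' @param cons_mean_se,cons_mean_other,cons_concentration Beta-distributed
#'   conservation identity (%) for SE-target / other genes.
#' @param tau_damping_se Exponent in (0, 1] applied to the per-tissue
#'   expression noise of SE-target genes (mean-corrected); values below 1
#'   make SE genes more uniformly expressed across tissues (lower tau), the
#'   behaviour expected of broadly active SE-driven genes. 1 disables it.
#' @param signal_noise_sdlog Lognormal sd of peak signal noise.
#' @param locus_min_separation Minimum bp between planted loci (keeps
#'   planted units distinct under default stitching).
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1,
                       n_chroms = 10,
                       chrom_length = 15e6,
                       n_tissues = 14,
                       n_planted_se_per_tissue = 20,
                       se_constituent_count_mean = 43,
                       se_constituent_size_mean = 682,
                       se_gap_mean = 625,
                       background_peak_density = 2000 / 150,
                       signal_fold_se_vs_background = 50,
                       state_mix = c(EnhA = 0.30, EnhAMe = 0.15, EnhAWk = 0.30,
                                     EnhAHet = 0.10, EnhPois = 0.15),
                       state_mix_se = c(EnhA = 0.45, EnhAMe = 0.15, EnhAWk = 0.20,
                                        EnhAHet = 0.15, EnhPois = 0.05),
                       x_depletion_factor = 0.2,
                       repeat_fraction = c(SINE = 0.10, LINE = 0.15,
                                           LTR = 0.05, DNA = 0.03),
                       repeat_se_fold = c(SINE = 5, LINE = 1, LTR = 1, DNA = 1),
                       repeat_piece_size = 250,
                       mir_frac_in_se = 0.6,
                       mir_frac_out = 0.3,
                       frac_single_tissue = 0.3,
                       tissue_share_prob = 0.35,
                       se_expression_fold = 2,
                       se_gene_window = 50000,
                       proximity_decay = TRUE,
                       n_genes = 1000,
                       frac_genes_near_se = 0.5,
                       tpm_noise_cv = 0.3,
                       tpm_base_meanlog = log(10),
                       tpm_base_sdlog = 1,
                       cons_mean_se = 86,
                       cons_mean_other = 80,
                       cons_concentration = 25,
                       tau_damping_se = 0.5,
                       signal_noise_sdlog = 0.25,
                       locus_min_separation = 40000) {
  cfg <- as.list(environment())
  counts <- c(cfg$n_chroms, cfg$chrom_length, cfg$n_tissues,
              cfg$n_planted_se_per_tissue, cfg$se_constituent_count_mean,
              cfg$se_constituent_size_mean, cfg$se_gap_mean, cfg$n_genes)
  if (any(counts <= 0)) stop("all counts and sizes must be positive")
  for (mix in list(cfg$state_mix, cfg$state_mix_se)) {
    if (!setequal(names(mix), ENHANCER_STATES)) {
      stop("state mix must name exactly: ", paste(ENHANCER_STATES, collapse = ", "))
    }
    if (abs(sum(mix) - 1) > 1e-9) stop("state mix must sum to 1")
  }
  if (cfg$x_depletion_factor < 0 || cfg$x_depletion_factor > 1) {
    stop("x_depletion_factor must be in [0, 1]")
  }
  if (cfg$n_tissues > length(PIG_TISSUES)) {
    stop("at most ", length(PIG_TISSUES), " tissues supported")
  }
  structure(cfg, class = "sim_config")
}

# place n non-overlapping pieces of width `size` uniformly within the
# (merged) interval set `regions`, in concatenated-coordinate space
place_pieces <- function(regions, n, size) {
  if (n == 0L) return(GRanges())
  w <- width(regions)
  W <- sum(as.numeric(w))
  if (n * size > W) stop("infeasible packing: ", n, " pieces of ", size,
                         " bp exceed ", W, " bp of space")
  offs <- sort(runif(n, 0, W - n * size)) + (seq_len(n) - 1) * size
  cum <- cumsum(c(0, as.numeric(w)))
  idx <- findInterval(offs, cum, rightmost.closed = FALSE)
  s <- start(regions)[idx] + (offs - cum[idx])
  e <- pmin(floor(s) + size - 1, end(regions)[idx])  # truncate at boundaries
  GRanges(seqnames(regions)[idx], IRanges(floor(s), e))
}

# place k variable-length blocks on one chromosome with minimum separation
place_blocks <- function(lengths, chrom_length, sep, margin = 1000) {
  k <- length(lengths)
  if (k == 0L) return(integer())
  slack <- chrom_length - 2 * margin - sum(lengths) - (k - 1) * sep
  if (slack < 0) {
    stop("infeasible packing: requested loci exceed chromosome capacity")
  }
  offs <- sort(runif(k, 0, slack))
  margin + floor(offs) + c(0, cumsum(lengths[-k] + sep))
}

#' Simulate a complete synthetic super-enhancer body map
#'
#' Generates a genome, per-tissue enhancer peaks with state classes and
#' H3K27ac-like signal, per-tissue signal tracks, repeat annotations with a
#' planted SE overlap bias, gene models, a tissue x gene TPM matrix and a
#' conservation column -- together with the ground truth of every planted
#' structure. Deterministic for a fixed seed; per-tissue draws use fixed
#' seed offsets so individual tissues reproduce when `n_tissues` changes.
#'
#' SE loci are shared structures with a cross-tissue activity pattern
#' (a configurable fraction is single-tissue); per tissue, the planted SEs
#' are the loci active in that tissue. Genes planted near a locus receive a
#' TPM boost in every tissue where the locus is active.
#'
#' @param config A [sim_config()].
#' @return A list of class `"se_simulation"`: `genome` (named lengths),
#'   `tissues`, `peaks` (named list of `GRanges` with `state`, `signal`,
#'   `planted`, `locus_id`; these double as the per-tissue signal tracks),
#'   `repeats` (`GRanges`), `genes` (`GRanges`), `tpm` (genes x tissues),
#'   `conservation` (named %), `truth` (planted loci, per-tissue SE
#'   intervals, presence matrix, target genes, planted enrichment), and
#'   `config`.
#' @export
simulate_bodymap <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  chroms <- c(paste0("chr", seq_len(cfg$n_chroms - 1)), "chrX")
  genome <- setNames(rep(cfg$chrom_length, cfg$n_chroms), chroms)
  tissues <- PIG_TISSUES[seq_len(cfg$n_tissues)]

  shared <- withr::with_seed(cfg$seed, simulate_shared(cfg, genome, tissues))

  peaks <- vector("list", cfg$n_tissues)
  names(peaks) <- tissues
  tpm_noise <- matrix(NA_real_, nrow = cfg$n_genes, ncol = cfg$n_tissues)
  sdlog_n <- sqrt(log(1 + cfg$tpm_noise_cv^2))
  for (i in seq_len(cfg$n_tissues)) {
    sub <- withr::with_seed((cfg$seed + 1000 + i) %% .Machine$integer.max, {
      bg <- simulate_background(cfg, genome, shared$loci)
      active <- which(shared$presence[, i])
      planted <- shared$constituents[shared$cons_locus %in% active]
      pl_locus <- shared$cons_locus[shared$cons_locus %in% active]
      n_pl <- length(planted)
      sig <- cfg$signal_fold_se_vs_background *
        rlnorm(n_pl, -cfg$signal_noise_sdlog^2 / 2, cfg$signal_noise_sdlog)
      mcols(planted) <- NULL
      mcols(planted)$state <- shared$cons_state[shared$cons_locus %in% active]
      mcols(planted)$signal <- sig
      mcols(planted)$planted <- TRUE
      mcols(planted)$locus_id <- pl_locus
      all_peaks <- sort(c(planted, bg), ignore.strand = TRUE)
      noise <- rlnorm(cfg$n_genes, -sdlog_n^2 / 2, sdlog_n)
      list(peaks = all_peaks, noise = noise)
    })
    peaks[[i]] <- sub$peaks
    tpm_noise[, i] <- sub$noise
  }

  # SE-target genes get damped cross-tissue noise (lower tau), corrected
  # to keep the noise mean at 1 so the expression null is undisturbed
  a <- cfg$tau_damping_se
  if (a < 1) {
    target <- !is.na(mcols(shared$genes)$locus_id)
    corr <- exp(sdlog_n^2 * a * (a - 1) / 2)
    tpm_noise[target, ] <- tpm_noise[target, , drop = FALSE]^a / corr
  }
  # TPM: lognormal baseline x planted boost x per-tissue noise, columns
  # renormalised to sum to 1e6 (TPM definition)
  tpm <- shared$tpm_base * shared$boost[, seq_len(cfg$n_tissues), drop = FALSE] *
    tpm_noise
  tpm <- sweep(tpm, 2, colSums(tpm), "/") * 1e6
  dimnames(tpm) <- list(mcols(shared$genes)$gene_id, tissues)

  truth <- shared$truth
  truth$planted_se <- lapply(seq_len(cfg$n_tissues), function(i) {
    sort(shared$locus_spans[shared$presence[, i]])
  })
  names(truth$planted_se) <- tissues
  truth$target_genes <- lapply(seq_len(cfg$n_tissues), function(i) {
    active <- which(shared$presence[, i])
    mcols(shared$genes)$gene_id[!is.na(mcols(shared$genes)$locus_id) &
                                  mcols(shared$genes)$locus_id %in% active]
  })
  names(truth$target_genes) <- tissues

  structure(list(genome = genome, tissues = tissues, peaks = peaks,
                 repeats = shared$repeats, genes = shared$genes, tpm = tpm,
                 conservation = setNames(shared$conservation,
                                         mcols(shared$genes)$gene_id),
                 truth = truth, config = cfg),
            class = "se_simulation")
}

# everything drawn from the primary seed stream: loci, constituents,
# repeats, genes, baseline expression, conservation
simulate_shared <- function(cfg, genome, tissues) {
  nt <- cfg$n_tissues
  # cross-tissue activity pattern per locus
  mean_active <- if (nt == 1L) 1 else {
    cfg$frac_single_tissue +
      (1 - cfg$frac_single_tissue) * (2 + (nt - 2) * cfg$tissue_share_prob)
  }
  n_loci <- max(1L, round(cfg$n_planted_se_per_tissue * nt / mean_active))
  n_active <- if (nt == 1L) rep(1L, n_loci) else {
    single <- runif(n_loci) < cfg$frac_single_tissue
    ifelse(single, 1L, 2L + rbinom(n_loci, nt - 2L, cfg$tissue_share_prob))
  }
  presence <- matrix(FALSE, n_loci, nt)
  for (l in seq_len(n_loci)) {
    presence[l, sample.int(nt, n_active[l])] <- TRUE
  }

  # constituent templates (shared across the tissues where a locus is active)
  n_cons <- pmax(2L, rpois(n_loci, cfg$se_constituent_count_mean))
  templates <- lapply(n_cons, function(k) {
    sizes <- pmax(100L, round(rnorm(k, cfg$se_constituent_size_mean,
                                    0.2 * cfg$se_constituent_size_mean)))
    gaps <- pmax(1L, round(rexp(k - 1L, 1 / cfg$se_gap_mean)))
    list(sizes = sizes, gaps = gaps,
         len = sum(sizes) + sum(gaps))
  })
  locus_len <- vapply(templates, `[[`, numeric(1), "len")

  # chromosome assignment: per-bp rate on chrX depleted by x_depletion_factor
  w <- as.numeric(genome)
  w[names(genome) == "chrX"] <- w[names(genome) == "chrX"] * cfg$x_depletion_factor
  locus_chrom <- sample(names(genome), n_loci, replace = TRUE, prob = w / sum(w))

  locus_start <- integer(n_loci)
  for (ch in unique(locus_chrom)) {
    on <- which(locus_chrom == ch)
    starts <- place_blocks(locus_len[on], genome[[ch]],
                           cfg$locus_min_separation)
    # starts are ascending and align with the `on` order the lengths were
    # passed in
    locus_start[on] <- starts
  }
  locus_spans <- GRanges(factor(locus_chrom, levels = names(genome)),
                         IRanges(locus_start, locus_start + locus_len - 1L))
  mcols(locus_spans)$locus_id <- seq_len(n_loci)
  mcols(locus_spans)$n_constituents <- n_cons

  # absolute constituent peaks + states
  cons_list <- lapply(seq_len(n_loci), function(l) {
    tpl <- templates[[l]]
    s <- locus_start[l] + c(0, cumsum(tpl$sizes[-length(tpl$sizes)] + tpl$gaps))
    GRanges(factor(locus_chrom[l], levels = names(genome)),
            IRanges(as.integer(s), width = tpl$sizes))
  })
  constituents <- do.call(c, cons_list)
  cons_locus <- rep(seq_len(n_loci), n_cons)
  cons_state <- sample(names(cfg$state_mix_se), length(constituents),
                       replace = TRUE, prob = cfg$state_mix_se)

  # repeats: planted to achieve the configured fold enrichment in the
  # pooled SE footprint
  footprint <- reduce(locus_spans, ignore.strand = TRUE)
  rep_out <- simulate_repeats(cfg, genome, footprint)

  # genes
  genes <- simulate_genes(cfg, genome, locus_spans)
  tpm_base <- rlnorm(cfg$n_genes, cfg$tpm_base_meanlog, cfg$tpm_base_sdlog)
  gl <- mcols(genes)$locus_id
  gd <- mcols(genes)$se_distance
  decay <- ifelse(is.na(gd), 0,
                  if (cfg$proximity_decay) pmax(0, 1 - gd / cfg$se_gene_window)
                  else 1)
  # full boost in tissues where the gene's locus is active, half boost
  # (on the fold-1 scale) elsewhere: SE-target genes are elevated overall
  # and concordantly stronger in their SE's tissues
  mult_active <- 1 + (cfg$se_expression_fold - 1) * decay
  mult_other <- 1 + 0.5 * (cfg$se_expression_fold - 1) * decay
  boost <- matrix(1, cfg$n_genes, nt)
  tg <- which(!is.na(gl))
  for (g in tg) {
    on <- presence[gl[g], ]
    boost[g, on] <- mult_active[g]
    boost[g, !on] <- mult_other[g]
  }

  is_target <- !is.na(gl)
  cons_mean <- ifelse(is_target, cfg$cons_mean_se, cfg$cons_mean_other) / 100
  conservation <- 100 * rbeta(cfg$n_genes,
                              cons_mean * cfg$cons_concentration,
                              (1 - cons_mean) * cfg$cons_concentration)

  lx <- sum(as.numeric(genome[names(genome) == "chrX"]))
  la <- sum(as.numeric(genome)) - lx
  truth <- list(
    loci = locus_spans,
    presence = presence,
    planted_enrichment = c(rep_out$planted_folds, list(
      x_depletion_factor = cfg$x_depletion_factor,
      x_fold_implied = cfg$x_depletion_factor * sum(as.numeric(genome)) /
        (cfg$x_depletion_factor * lx + la))),
    n_loci = n_loci,
    frac_single_planted = mean(rowSums(presence) == 1L)
  )
  list(loci = locus_spans, locus_spans = locus_spans, presence = presence,
       constituents = constituents, cons_locus = cons_locus,
       cons_state = cons_state, repeats = rep_out$repeats, genes = genes,
       tpm_base = tpm_base, boost = boost, conservation = conservation,
       truth = truth)
}

simulate_repeats <- function(cfg, genome, footprint) {
  D <- sum(as.numeric(genome))
  A <- sum(as.numeric(width(footprint)))
  genome_gr <- GRanges(names(genome), IRanges(1, as.integer(genome)))
  outside <- GenomicRanges::setdiff(genome_gr, footprint, ignore.strand = TRUE)
  size <- cfg$repeat_piece_size
  subfam <- c(SINE = "SINE/tRNA", LINE = "LINE/L1", LTR = "LTR/ERVL",
              DNA = "DNA/hAT")
  pieces <- list()
  planted <- list()
  for (cl in names(cfg$repeat_fraction)) {
    B <- cfg$repeat_fraction[[cl]] * D
    f <- cfg$repeat_se_fold[[cl]]
    C <- f * B * A / D
    if (C > 0.95 * A || C > B) {
      stop("infeasible repeat planting for class ", cl,
           ": requested in-SE coverage exceeds the SE footprint")
    }
    gin <- place_pieces(footprint, round(C / size), size)
    gout <- place_pieces(outside, round((B - C) / size), size)
    lab_in <- if (cl == "SINE") {
      ifelse(runif(length(gin)) < cfg$mir_frac_in_se, "SINE/MIR", subfam[[cl]])
    } else rep(subfam[[cl]], length(gin))
    lab_out <- if (cl == "SINE") {
      ifelse(runif(length(gout)) < cfg$mir_frac_out, "SINE/MIR", subfam[[cl]])
    } else rep(subfam[[cl]], length(gout))
    g <- c(gin, gout)
    mcols(g)$repeat_class <- c(lab_in, lab_out)
    mcols(g)$repeat_family <- cl
    pieces[[cl]] <- g
    planted[[paste0("fold_", cl)]] <- f
    if (cl == "SINE") {
      c_mir <- cfg$mir_frac_in_se * C
      b_mir <- c_mir + cfg$mir_frac_out * (B - C)
      planted[["fold_SINE_MIR"]] <- (c_mir / A) / (b_mir / D)
    }
  }
  repeats <- sort(do.call(c, unname(pieces)), ignore.strand = TRUE)
  mcols(repeats)$repeat_name <- sub("^[^/]*/", "", mcols(repeats)$repeat_class)
  list(repeats = repeats, planted_folds = planted)
}

simulate_genes <- function(cfg, genome, locus_spans) {
  n_near <- round(cfg$frac_genes_near_se * cfg$n_genes)
  n_far <- cfg$n_genes - n_near
  win <- cfg$se_gene_window
  # target genes: TSS uniform within locus span +/- window
  locus_of <- sample.int(length(locus_spans), n_near, replace = TRUE)
  lo <- pmax(1, start(locus_spans)[locus_of] - win)
  hi <- pmin(genome[as.character(seqnames(locus_spans))[locus_of]],
             end(locus_spans)[locus_of] + win)
  tss_near <- floor(runif(n_near, lo, hi + 1))
  d_near <- pmax(start(locus_spans)[locus_of] - tss_near,
                 tss_near - end(locus_spans)[locus_of], 0)
  chrom_near <- as.character(seqnames(locus_spans))[locus_of]

  # background genes: kept clear of every locus by window + 10 kb
  avoid <- suppressWarnings(reduce(resize(locus_spans,
                                          width(locus_spans) + 2 * (win + 10000),
                                          fix = "center"),
                                   ignore.strand = TRUE))
  avoid <- restrict(avoid, start = 1)
  chrom_far <- character(0); tss_far <- numeric(0)
  while (length(tss_far) < n_far) {
    need <- n_far - length(tss_far)
    cand_chrom <- sample(names(genome), 2L * need + 10L, replace = TRUE,
                         prob = as.numeric(genome) / sum(as.numeric(genome)))
    cand_pos <- floor(runif(length(cand_chrom), 1, genome[cand_chrom] + 1))
    cand <- GRanges(factor(cand_chrom, levels = names(genome)),
                    IRanges(cand_pos, cand_pos))
    ok <- !overlapsAny(cand, avoid, ignore.strand = TRUE)
    chrom_far <- c(chrom_far, cand_chrom[ok])
    tss_far <- c(tss_far, cand_pos[ok])
  }
  chrom_far <- chrom_far[seq_len(n_far)]
  tss_far <- tss_far[seq_len(n_far)]

  chrom <- c(chrom_near, chrom_far)
  tss <- as.integer(c(tss_near, tss_far))
  strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  body_len <- pmax(500L, round(rlnorm(cfg$n_genes, log(8000), 0.6)))
  s <- ifelse(strand == "+", tss, pmax(1L, tss - body_len + 1L))
  e <- ifelse(strand == "+",
              pmin(genome[chrom], tss + body_len - 1L), tss)
  genes <- GRanges(factor(chrom, levels = names(genome)),
                   IRanges(as.integer(s), as.integer(e)), strand = strand)
  mcols(genes)$locus_id <- c(locus_of, rep(NA_integer_, n_far))
  mcols(genes)$se_distance <- c(d_near, rep(NA_real_, n_far))
  ord <- order(as.factor(seqnames(genes)), start(genes))
  genes <- genes[ord]
  mcols(genes)$gene_id <- sprintf("gene%05d", seq_len(cfg$n_genes))
  genes
}

simulate_background <- function(cfg, genome, loci) {
  n_bg <- round(cfg$background_peak_density * sum(as.numeric(genome)) / 1e6)
  chrom <- sample(names(genome), n_bg, replace = TRUE,
                  prob = as.numeric(genome) / sum(as.numeric(genome)))
  sizes <- pmax(100L, round(rnorm(n_bg, cfg$se_constituent_size_mean,
                                  0.2 * cfg$se_constituent_size_mean)))
  starts <- floor(runif(n_bg, 1, genome[chrom] - sizes + 1))
  bg <- GRanges(factor(chrom, levels = names(genome)),
                IRanges(as.integer(starts), width = sizes))
  bg <- bg[!overlapsAny(bg, loci, ignore.strand = TRUE)]
  mcols(bg)$state <- sample(names(cfg$state_mix), length(bg),
                            replace = TRUE, prob = cfg$state_mix)
  mcols(bg)$signal <- rlnorm(length(bg), -cfg$signal_noise_sdlog^2 / 2,
                             cfg$signal_noise_sdlog)
  mcols(bg)$planted <- FALSE
  mcols(bg)$locus_id <- NA_integer_
  bg
}

#' @export
print.se_simulation <- function(x, ...) {
  cat(sprintf(paste0("synthetic SE body map: %d chroms (%.0f Mb), %d tissues, ",
                     "%d planted loci, %d genes\n"),
              length(x$genome), sum(x$genome) / 1e6, length(x$tissues),
              x$truth$n_loci, length(x$genes)))
  invisible(x)
}

#' Write a simulation to disk in the pipeline's input formats
#'
#' Emits `enhancers_<tissue>.gff`, `signal_<tissue>.bedgraph`, `genes.bed`,
#' `tpm.tsv`, `conservation.tsv`, `repeats.out`, `genome.chrom.sizes` and
#' `truth.json`. Output is deterministic (byte-identical for identical
#' simulations).
#'
#' @param sim An `"se_simulation"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(dir, ...)
  write_chrom_sizes(sim$genome, fp("genome.chrom.sizes"))
  for (t in sim$tissues) {
    write_gff(sim$peaks[[t]], fp(paste0("enhancers_", t, ".gff")),
              type = "enhancer", attr_cols = c("state", "signal"))
    write_bedgraph(sim$peaks[[t]], fp(paste0("signal_", t, ".bedgraph")))
  }
  genes <- sim$genes
  mcols(genes)$name <- mcols(genes)$gene_id
  write_bed(genes, fp("genes.bed"))
  tpm <- data.frame(gene_id = rownames(sim$tpm),
                    round(sim$tpm, 4), check.names = FALSE)
  write.table(tpm, fp("tpm.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  cons <- data.frame(gene_id = names(sim$conservation),
                     identity_pct = round(sim$conservation, 4))
  write.table(cons, fp("conservation.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_repeatmasker(sim$repeats, fp("repeats.out"))
  truth <- list(
    n_loci = sim$truth$n_loci,
    frac_single_planted = sim$truth$frac_single_planted,
    planted_enrichment = sim$truth$planted_enrichment,
    loci = data.frame(chrom = as.character(seqnames(sim$truth$loci)),
                      start = start(sim$truth$loci),
                      end = end(sim$truth$loci),
                      locus_id = mcols(sim$truth$loci)$locus_id),
    planted_se = lapply(sim$truth$planted_se, function(g) {
      data.frame(chrom = as.character(seqnames(g)),
                 start = start(g), end = end(g))
    }),
    target_genes = sim$truth$target_genes
  )
  jsonlite::write_json(truth, fp("truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Simulate a block-structured SE activity matrix
#'
#' Builds an SE x tissue activity matrix with `k` planted clusters: each
#' cluster is active (at `snr` x the noise sd above baseline) in its own
#' small set of tissues, with Gaussian noise on top, floored at 0 so the
#' matrix is a valid activity matrix. Used to exercise and validate
#' [cluster_ses()].
#'
#' @param n_se Number of SEs (rows).
#' @param n_tissues Number of tissues (columns).
#' @param k Number of planted clusters.
#' @param snr Block signal-to-noise ratio.
#' @param noise_sd Noise standard deviation.
#' @param seed RNG seed.
#' @return A list: `activity` (matrix), `labels` (planted cluster per row).
#' @export
simulate_block_matrix <- function(n_se = 500, n_tissues = 14, k = 10,
                                  snr = 5, noise_sd = 1, seed = 1) {
  stopifnot(k <= n_tissues || k <= 2^n_tissues, n_se >= k)
  withr::with_seed(seed, {
    profiles <- matrix(0, k, n_tissues)
    for (c in seq_len(k)) {
      active <- ((c - 1L) + 0:2) %% n_tissues + 1L
      profiles[c, active] <- snr * noise_sd
    }
    labels <- sample(rep_len(seq_len(k), n_se))
    activity <- profiles[labels, , drop = FALSE] +
      matrix(rnorm(n_se * n_tissues, 0, noise_sd), n_se, n_tissues)
    activity <- pmax(activity + 3 * noise_sd, 0)
    colnames(activity) <- paste0("tissue", seq_len(n_tissues))
    list(activity = activity, labels = labels)
  })
}
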