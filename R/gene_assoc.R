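#' Tau tissue-specificity index
#'
#' The standard index `tau = sum_i(1 - x_i/max(x)) / (n - 1)`: 0 for
#' perfectly uniform expression across tissues, 1 for expression confined to
#' a single tissue. Invariant to rescaling the expression vector by a
#' positive constant. An all-zero vector has no defined specificity and
#' returns `NA`.
#'
#' @param tpm Nonnegative expression vector (one value per tissue), or a
#'   matrix with genes in rows.
#' @return Tau in `[0, 1]` (per gene for a matrix input), `NA` where all
#'   values are zero.
#' @export
tau_index <- function(tpm) {
  if (is.matrix(tpm)) return(apply(tpm, 1, tau_index))
  if (length(tpm) < 2L) stop("tau needs at least 2 tissues")
  if (any(tpm < 0)) stop("negative expression value")
  m <- max(tpm)
  if (m == 0) return(NA_real_)
  sum(1 - tpm / m) / (length(tpm) - 1)
}

#' Associate super-enhancers with genes
#'
#' A gene is SE-associated when its body (default) or TSS lies within
#' `window` bp of any SE; `window = 0` is a direct intersection. Both
#' directions of the mapping are returned.
#'
#' @param ses `GRanges` of non-redundant SEs (ids from `mcols(ses)$se_id`
#'   when present).
#' @param genes `GRanges` of gene models with `gene_id` metadata.
#' @param window Association window in bp (default 0).
#' @param anchor `"body"` (whole gene span) or `"tss"` (single-bp TSS).
#' @return A list: `has_se` (named logical per gene), `gene_to_ses` and
#'   `se_to_genes` (named lists of ids).
#' @export
associate_ses_to_genes <- function(ses, genes, window = 0,
                                   anchor = c("body", "tss")) {
  anchor <- match.arg(anchor)
  stopifnot(window >= 0)
  gene_ids <- if (!is.null(mcols(genes)$gene_id)) as.character(mcols(genes)$gene_id)
              else as.character(seq_along(genes))
  se_ids <- if (!is.null(mcols(ses)$se_id)) as.character(mcols(ses)$se_id)
            else paste0("SE_", seq_along(ses))
  gq <- if (anchor == "tss") {
    p <- tss_position(genes)
    GRanges(seqnames(genes), IRanges(p, p))
  } else {
    granges(genes)
  }
  hits <- findOverlaps(gq, ses, maxgap = window, ignore.strand = TRUE)
  has_se <- setNames(logical(length(genes)), gene_ids)
  has_se[unique(queryHits(hits))] <- TRUE
  gene_to_ses <- split(se_ids[subjectHits(hits)], gene_ids[queryHits(hits)])
  se_to_genes <- split(gene_ids[queryHits(hits)], se_ids[subjectHits(hits)])
  list(has_se = has_se, gene_to_ses = gene_to_ses, se_to_genes = se_to_genes)
}

#' Size quintiles of super-enhancers (G1-G5)
#'
#' SEs sorted ascending by length (ties stable by chromosome and start) and
#' split into five contiguous groups whose sizes differ by at most 1; a
#' remainder of r gives one extra member to each of the first r groups.
#'
#' @param ses `GRanges` of SEs (position-sorted input recommended).
#' @param n_groups Number of groups (default 5).
#' @return Factor `G1..G5` parallel to `ses`, ordered levels; attribute
#'   `"order"` holds the ascending-size permutation.
#' @export
size_quintiles <- function(ses, n_groups = 5) {
  n <- length(ses)
  if (n < n_groups) stop("need at least ", n_groups, " SEs")
  ord <- order(width(ses))  # stable: ties keep positional input order
  base <- n %/% n_groups
  r <- n %% n_groups
  sizes <- rep(base, n_groups) + c(rep(1L, r), rep(0L, n_groups - r))
  lab_sorted <- rep(paste0("G", seq_len(n_groups)), times = sizes)
  labels <- character(n)
  labels[ord] <- lab_sorted
  out <- factor(labels, levels = paste0("G", seq_len(n_groups)), ordered = TRUE)
  attr(out, "order") <- ord
  out
}

#' Distance groups T1-T5 around the TSS
#'
#' `T3` is exactly the records at signed distance 0 (gene overlapping an
#' SE). Negative (downstream) distances are split at their median absolute
#' distance into far `T1` and near `T2`; positive (upstream) distances into
#' near `T4` and far `T5`. Group order follows ascending signed distance.
#'
#' @param distance Signed distances in bp (e.g. from [closest_tss()]).
#' @param breaks Optional explicit `c(downstream, upstream)` absolute-bp
#'   split points overriding the median rule.
#' @return Ordered factor `T1..T5` parallel to `distance`; empty groups are
#'   permitted.
#' @export
distance_groups <- function(distance, breaks = NULL) {
  lab <- rep(NA_character_, length(distance))
  lab[!is.na(distance) & distance == 0] <- "T3"
  neg <- !is.na(distance) & distance < 0
  pos <- !is.na(distance) & distance > 0
  if (any(neg)) {
    split_dn <- if (is.null(breaks)) median(abs(distance[neg])) else breaks[1]
    lab[neg] <- ifelse(abs(distance[neg]) > split_dn, "T1", "T2")
  }
  if (any(pos)) {
    split_up <- if (is.null(breaks)) median(abs(distance[pos])) else breaks[2]
    lab[pos] <- ifelse(abs(distance[pos]) > split_up, "T5", "T4")
  }
  factor(lab, levels = paste0("T", 1:5), ordered = TRUE)
}

#' Rank-sum comparisons of groups against a reference
#'
#' Two-sided Mann-Whitney test of each group versus the reference group,
#' with Benjamini-Hochberg adjustment across the comparisons of one
#' invocation. Degenerate comparisons (all values identical in both groups)
#' report p = 1.
#'
#' @param values Numeric vector (e.g. mean TPM, tau, conservation).
#' @param groups Factor parallel to `values`.
#' @param reference Reference group label (e.g. `"T3"`).
#' @return data.frame: per non-reference group, `n`, `median`,
#'   `median_ref`, `direction` (sign of the median difference), `statistic`
#'   (Mann-Whitney W), `p_value`, `p_adjusted`.
#' @export
compare_groups <- function(values, groups, reference) {
  groups <- as.factor(groups)
  if (!reference %in% levels(groups)) stop("reference group not present")
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- droplevels(groups[keep])
  ref_vals <- values[groups == reference]
  if (length(ref_vals) < 2L) stop("reference group has fewer than 2 members")
  others <- setdiff(levels(groups), reference)
  res <- do.call(rbind, lapply(others, function(g) {
    v <- values[groups == g]
    if (length(v) < 2L) stop("group ", g, " has fewer than 2 members")
    if (diff(range(c(v, ref_vals))) == 0) {
      w <- list(statistic = length(v) * length(ref_vals) / 2, p.value = 1)
    } else {
      w <- wilcox.test(v, ref_vals, alternative = "two.sided", exact = FALSE)
    }
    data.frame(group = g, reference = reference,
               n = length(v), n_ref = length(ref_vals),
               median = median(v), median_ref = median(ref_vals),
               direction = sign(median(v) - median(ref_vals)),
               statistic = unname(w$statistic), p_value = w$p.value)
  }))
  res$p_adjusted <- p.adjust(res$p_value, method = "BH")
  rownames(res) <- NULL
  res
}

#' Signed SE-TSS distance for every gene
#'
#' For each gene, the signed distance from its TSS to the nearest SE edge
#' (0 when the TSS falls inside an SE; sign by the gene's strand, negative
#' when the SE lies downstream of the TSS).
#'
#' @param ses `GRanges` of SEs.
#' @param genes `GRanges` of gene models.
#' @return data.frame: `gene_id`, `se_index`, signed `distance` (bp).
#' @export
se_gene_distances <- function(ses, genes) {
  if (length(ses) == 0L) stop("empty SE set")
  gene_ids <- if (!is.null(mcols(genes)$gene_id)) as.character(mcols(genes)$gene_id)
              else as.character(seq_along(genes))
  p <- tss_position(genes)
  tss_gr <- GRanges(seqnames(genes), IRanges(p, p), strand = strand(genes),
                    gene_id = gene_ids)
  # reuse closest_tss with roles swapped: query = TSS points, refs = SEs
  # (anchor the SE at whichever edge is nearer the TSS)
  schrom <- as.character(seqnames(ses))
  out <- data.frame(gene_id = gene_ids, se_index = NA_integer_,
                    distance = NA_real_)
  for (i in seq_along(tss_gr)) {
    on_chrom <- which(schrom == as.character(seqnames(tss_gr)[i]))
    if (!length(on_chrom)) next
    d <- pmax(start(ses)[on_chrom] - p[i], p[i] - end(ses)[on_chrom], 0L)
    j <- on_chrom[which.min(d)]
    dist <- max(start(ses)[j] - p[i], p[i] - end(ses)[j], 0L)
    if (dist > 0) {
      se_after_tss <- start(ses)[j] > p[i]
      downstream <- if (as.character(strand(tss_gr)[i]) == "-") !se_after_tss
                    else se_after_tss
      if (downstream) dist <- -dist
    }
    out$se_index[i] <- j
    out$distance[i] <- dist
  }
  out
}

#' Summary statistics of a super-enhancer body map
#'
#' Per tissue and pooled: SE count, mean/median SE size, mean signal
#' density, genome coverage (merged SE bp as a percentage of genome size),
#' median constituents per SE, mean constituent size, and mean
#' inter-constituent gap.
#'
#' @param calls Named list, one element per tissue: either an `"se_call"`
#'   (its `super` slot is used) or a `GRanges` of SE regions carrying
#'   `constituents` (and optionally `total_signal`) metadata.
#' @param genome Named numeric vector of chromosome lengths.
#' @return data.frame, one row per tissue plus a `"pooled"` row.
#' @export
summarize_bodymap <- function(calls, genome) {
  D <- sum(as.numeric(genome))
  get_regions <- function(x) if (inherits(x, "se_call")) x$super else x
  one <- function(regions, label) {
    cons <- mcols(regions)$constituents
    cons_w <- if (!is.null(cons)) unlist(lapply(cons, width)) else numeric()
    gaps <- if (!is.null(cons)) unlist(lapply(cons, function(g) {
      if (length(g) < 2L) return(numeric())
      start(g)[-1] - end(g)[-length(g)] - 1L
    })) else numeric()
    signal <- mcols(regions)$total_signal
    data.frame(
      tissue = label,
      n_se = length(regions),
      mean_size = mean(width(regions)),
      median_size = median(width(regions)),
      mean_signal_density = if (!is.null(signal)) mean(signal / width(regions)) else NA_real_,
      genome_coverage_pct = 100 * total_width(regions) / D,
      median_constituents = if (length(cons_w)) median(lengths(cons)) else NA_real_,
      mean_constituent_size = if (length(cons_w)) mean(cons_w) else NA_real_,
      mean_constituent_gap = if (length(gaps)) mean(gaps) else NA_real_
    )
  }
  regions_list <- lapply(calls, get_regions)
  labels <- names(calls)
  if (is.null(labels)) labels <- paste0("tissue", seq_along(calls))
  per <- do.call(rbind, Map(one, regions_list, labels))
  pooled_regions <- do.call(c, unname(regions_list))
  pooled <- one(pooled_regions, "pooled")
  out <- rbind(per, pooled)
  rownames(out) <- NULL
  out
}
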