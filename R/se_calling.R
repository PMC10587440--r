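#' Stitch enhancer peaks into candidate regions
#'
#' Joins peaks whose inter-peak gap is at most `stitch_distance` bp into one
#' stitched region, the first stage of rank-based super-enhancer calling.
#' Optionally removes peaks falling entirely inside TSS +/- `tss_exclusion`
#' before stitching (off by default, matching the default parameterisation
#' of the stitched-ranking algorithm).
#'
#' @param peaks `GRanges` of enhancer peaks; metadata columns (e.g. `state`,
#'   `signal`) travel with the constituents.
#' @param stitch_distance Maximum gap bridged, bp (default 12500).
#' @param tss Optional `GRanges` of gene models supplying TSS positions.
#' @param tss_exclusion Half-width (bp) of the promoter exclusion zone
#'   around each TSS; `0` disables exclusion.
#' @return A `GRanges` of stitched regions with metadata columns
#'   `n_constituents` and `constituents` (a `GRangesList` of the member
#'   peaks, sorted by start).
#' @export
stitch_peaks <- function(peaks, stitch_distance = 12500, tss = NULL,
                         tss_exclusion = 0) {
  stopifnot(is(peaks, "GRanges"), stitch_distance >= 0)
  peaks <- sort(peaks, ignore.strand = TRUE)
  if (!is.null(tss) && tss_exclusion > 0) {
    p <- tss_position(tss)
    zone <- GRanges(seqnames(tss),
                    IRanges(pmax(1L, p - as.integer(tss_exclusion)),
                            p + as.integer(tss_exclusion)))
    inside <- overlapsAny(peaks, zone, type = "within", ignore.strand = TRUE)
    peaks <- peaks[!inside]
  }
  if (length(peaks) == 0L) {
    regions <- GRanges()
    mcols(regions)$n_constituents <- integer()
    mcols(regions)$constituents <- GRangesList()
    return(regions)
  }
  regions <- reduce(peaks, min.gapwidth = stitch_distance + 1L,
                    ignore.strand = TRUE, with.revmap = TRUE)
  revmap <- mcols(regions)$revmap
  mcols(regions)$revmap <- NULL
  mcols(regions)$n_constituents <- lengths(revmap)
  mcols(regions)$constituents <- relist(peaks[unlist(revmap)], revmap)
  sort(regions, ignore.strand = TRUE)
}

#' Total signal of regions under a bedGraph track
#'
#' `sum(signal value x overlapped bp)` over all track intervals overlapping
#' each region; bases not covered by the track contribute 0.
#'
#' @param regions `GRanges` of regions to score.
#' @param track `GRanges` signal track with a numeric `score` (or `signal`)
#'   column, e.g. from `read_intervals(format = "bedgraph")`.
#' @return Numeric vector of total signal (signal units x bp), one per region.
#' @export
score_regions <- function(regions, track) {
  val <- mcols(track)$score
  if (is.null(val)) val <- mcols(track)$signal
  if (is.null(val)) stop("signal track has no 'score' or 'signal' column")
  if (any(val < 0)) stop("negative signal value in track")
  hits <- findOverlaps(regions, track, ignore.strand = TRUE)
  ov <- width(pintersect(regions[queryHits(hits)], track[subjectHits(hits)],
                         ignore.strand = TRUE))
  contrib <- as.numeric(ov) * val[subjectHits(hits)]
  out <- numeric(length(regions))
  if (length(hits)) {
    agg <- rowsum(contrib, group = queryHits(hits))
    out[as.integer(rownames(agg))] <- agg[, 1]
  }
  out
}

#' Tangent-line cutoff on the scaled rank-signal curve
#'
#' Sorts scores ascending, scales ranks and scores to `[0, 1]`, and slides a
#' line of slope 1 along the curve: the cutoff is placed at the rank
#' minimising the number of points on or below the line (the tangent point
#' of the hockey-stick curve); ties go to the largest rank. Regions scoring
#' strictly above the cutoff signal are super-enhancers. The partition is
#' invariant to rescaling all scores by a positive constant.
#'
#' @param scores Numeric vector of region total signals.
#' @return A list of class `"se_cutoff"`: `cutoff_signal` (unscaled),
#'   `cutoff_rank` (ascending-signal rank), `n_super`, `n_regions`, and
#'   `is_super` (logical, in the input order of `scores`).
#' @export
tangent_cutoff <- function(scores) {
  n <- length(scores)
  if (n < 3L) stop("need at least 3 regions to place a cutoff")
  if (diff(range(scores)) == 0) stop("degenerate signal distribution: all scores identical")
  ord <- order(scores)           # stable in R: ties keep input order
  y <- scores[ord]
  xs <- (seq_len(n) - 1) / (n - 1)
  ys <- (y - y[1]) / (y[n] - y[1])
  # count of points on/below the slope-1 line through (xs[i], ys[i]):
  # ys[j] <= xs[j] + (ys[i] - xs[i])
  resid <- ys - xs
  counts <- vapply(seq_len(n), function(i) sum(resid <= resid[i]), integer(1))
  i_star <- max(which(counts == min(counts)))
  cutoff_signal <- y[i_star]
  is_super <- scores > cutoff_signal
  structure(list(cutoff_signal = cutoff_signal,
                 cutoff_rank = i_star,
                 n_super = sum(is_super),
                 n_regions = n,
                 is_super = is_super),
            class = "se_cutoff")
}

#' @export
print.se_cutoff <- function(x, ...) {
  cat(sprintf("SE cutoff: signal %.4g at rank %d/%d; %d super-enhancers\n",
              x$cutoff_signal, x$cutoff_rank, x$n_regions, x$n_super))
  invisible(x)
}

#' Call super-enhancers for one sample
#'
#' Full composition: stitch the pooled enhancer peaks, score each stitched
#' region against the H3K27ac signal track, rank, and apply the tangent-line
#' cutoff. Ranks are assigned by ascending total signal with ties broken by
#' genomic position (chromosome, start), so the call is deterministic.
#'
#' @inheritParams stitch_peaks
#' @param track H3K27ac signal track (`GRanges` with `score`/`signal`).
#' @param control Optional input-control track; when supplied its region
#'   signal is subtracted and floored at 0 before ranking.
#' @return A list of class `"se_call"`: `regions` (all stitched regions with
#'   `total_signal`, `rank`, `is_super`, `n_constituents`, `constituents`),
#'   `super`, `typical` (the two partitions), and `cutoff` (`se_cutoff`).
#' @export
call_superenhancers <- function(peaks, track, stitch_distance = 12500,
                                tss = NULL, tss_exclusion = 0,
                                control = NULL) {
  regions <- stitch_peaks(peaks, stitch_distance = stitch_distance,
                          tss = tss, tss_exclusion = tss_exclusion)
  total <- score_regions(regions, track)
  if (!is.null(control)) {
    total <- pmax(total - score_regions(regions, control), 0)
  }
  # deterministic rank: ascending signal, ties by (chrom, start);
  # regions are already position-sorted so a stable order() suffices
  ord <- order(total)
  rank <- integer(length(total))
  rank[ord] <- seq_along(total)
  mcols(regions)$total_signal <- total
  mcols(regions)$rank <- rank
  cutoff <- tangent_cutoff(total)
  mcols(regions)$is_super <- cutoff$is_super
  structure(list(regions = regions,
                 super = regions[mcols(regions)$is_super],
                 typical = regions[!mcols(regions)$is_super],
                 cutoff = cutoff),
            class = "se_call")
}

#' @export
print.se_call <- function(x, ...) {
  cat(sprintf("SE call: %d stitched regions, %d super / %d typical\n",
              length(x$regions), length(x$super), length(x$typical)))
  print(x$cutoff)
  invisible(x)
}

#' Precision/recall of called SEs against a truth set
#'
#' A called region matches a truth region when their overlap covers at least
#' `min_frac` of both (reciprocal overlap).
#'
#' @param called,truth `GRanges`.
#' @param min_frac Reciprocal overlap fraction required (default 0.5).
#' @return A list with `precision`, `recall`, `n_called`, `n_truth`.
#' @export
se_recovery_stats <- function(called, truth, min_frac = 0.5) {
  if (length(called) == 0L || length(truth) == 0L) {
    return(list(precision = NA_real_, recall = NA_real_,
                n_called = length(called), n_truth = length(truth)))
  }
  hits <- findOverlaps(called, truth, ignore.strand = TRUE)
  ov <- width(pintersect(called[queryHits(hits)], truth[subjectHits(hits)],
                         ignore.strand = TRUE))
  good <- ov >= min_frac * width(called)[queryHits(hits)] &
          ov >= min_frac * width(truth)[subjectHits(hits)]
  list(precision = length(unique(queryHits(hits)[good])) / length(called),
       recall = length(unique(subjectHits(hits)[good])) / length(truth),
       n_called = length(called), n_truth = length(truth))
}
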