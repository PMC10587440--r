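#' @import GenomicRanges
#' @import IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits metadata metadata<-
#' @importFrom GenomeInfoDb seqnames seqlevels seqlevels<- seqlevelsInUse
#'   sortSeqlevels
#' @importFrom stats rnorm rlnorm rexp rpois runif rbeta rbinom kmeans
#'   wilcox.test p.adjust setNames
#' @importFrom utils read.table write.table head tail
NULL

#' Merge genomic intervals, bridging small gaps
#'
#' Unites intervals on the same chromosome whose gap is at most `min_gap`
#' base pairs. Strand is ignored; the result is sorted and its pairwise gaps
#' all exceed `min_gap`.
#'
#' @param x A `GRanges`.
#' @param min_gap Maximum gap (bp) that is bridged; `0` merges only
#'   touching/overlapping intervals.
#' @return A sorted, strand-free `GRanges` with pairwise gaps `> min_gap`.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 16), c(10, 20)))
#' merge_intervals(gr, min_gap = 5)
#' @export
merge_intervals <- function(x, min_gap = 0) {
  stopifnot(is(x, "GRanges"), min_gap >= 0)
  gr <- x
  strand(gr) <- "*"
  sort(reduce(gr, min.gapwidth = min_gap + 1L, ignore.strand = TRUE))
}

#' Total covered base pairs of an interval set
#'
#' Self-overlaps are collapsed before summing, so every base is counted once.
#'
#' @param x A `GRanges`.
#' @return Total merged width in bp.
#' @export
total_width <- function(x) {
  sum(as.numeric(width(reduce(x, ignore.strand = TRUE))))
}

#' Base pairs covered by both of two interval sets
#'
#' The per-base intersection size (what `bedtools intersect` totals).
#' Symmetric in its arguments.
#'
#' @param a,b `GRanges` objects.
#' @return Total overlapping bp (numeric, to avoid integer overflow on
#'   genome-scale inputs).
#' @export
overlap_size <- function(a, b) {
  ia <- reduce(granges(a), ignore.strand = TRUE)
  ib <- reduce(granges(b), ignore.strand = TRUE)
  lev <- union(seqlevels(ia), seqlevels(ib))
  seqlevels(ia) <- lev
  seqlevels(ib) <- lev
  sum(as.numeric(width(GenomicRanges::intersect(ia, ib, ignore.strand = TRUE))))
}

#' Per-pair overlaps between two interval sets
#'
#' @param a,b `GRanges` objects.
#' @return A data.frame with one row per overlapping pair: indices into `a`
#'   and `b` and the overlap width in bp.
#' @export
overlap_pairs <- function(a, b) {
  hits <- findOverlaps(a, b, ignore.strand = TRUE)
  ov <- pintersect(a[queryHits(hits)], b[subjectHits(hits)],
                   ignore.strand = TRUE)
  data.frame(query = queryHits(hits), subject = subjectHits(hits),
             overlap_bp = width(ov))
}

#' Signed distance from intervals to their nearest TSS
#'
#' For each query interval, finds the reference transcription start site
#' (strand-aware single-bp anchor) minimising the unsigned distance from the
#' anchor to the nearest edge of the query; the distance is 0 when the anchor
#' falls inside the query. The sign follows the reference strand: positive
#' when the query lies upstream of the TSS, negative when downstream
#' (mirroring a reference-strand distance convention). Ties are broken by the
#' smaller reference index.
#'
#' @param query A `GRanges` of intervals (e.g. super-enhancers).
#' @param genes A `GRanges` of gene models; the TSS is the start for `+`/`*`
#'   strand genes and the end for `-` strand genes.
#' @return A data.frame with `gene_index`, `gene_id` (from
#'   `mcols(genes)$gene_id` if present, else the index), and signed
#'   `distance` in bp, one row per query.
#' @export
closest_tss <- function(query, genes) {
  if (length(genes) == 0L) stop("reference gene set is empty")
  tss <- tss_position(genes)
  gchrom <- as.character(seqnames(genes))
  gstrand <- as.character(strand(genes))
  ids <- if (!is.null(mcols(genes)$gene_id)) {
    as.character(mcols(genes)$gene_id)
  } else {
    as.character(seq_along(genes))
  }

  qchrom <- as.character(seqnames(query))
  n <- length(query)
  out_idx <- integer(n)
  out_dist <- numeric(n)
  for (i in seq_len(n)) {
    on_chrom <- which(gchrom == qchrom[i])
    if (length(on_chrom) == 0L) on_chrom <- seq_along(genes)  # cross-chrom fallback
    p <- tss[on_chrom]
    d <- pmax(start(query)[i] - p, p - end(query)[i], 0L)
    # penalise cross-chromosome candidates when a same-chrom one exists
    if (!all(gchrom[on_chrom] == qchrom[i])) {
      d <- ifelse(gchrom[on_chrom] == qchrom[i], d, Inf)
    }
    j <- on_chrom[which.min(d)]          # which.min takes the first = lowest index
    dist <- max(start(query)[i] - tss[j], tss[j] - end(query)[i], 0L)
    if (dist > 0) {
      # downstream of the TSS w.r.t. reference strand => negative
      after_tss <- start(query)[i] > tss[j]
      downstream <- if (gstrand[j] == "-") !after_tss else after_tss
      if (downstream) dist <- -dist
    }
    out_idx[i] <- j
    out_dist[i] <- dist
  }
  data.frame(gene_index = out_idx, gene_id = ids[out_idx], distance = out_dist)
}

#' Strand-aware TSS coordinates of gene models
#'
#' @param genes A `GRanges`.
#' @return Integer vector of 1-based TSS positions.
#' @export
tss_position <- function(genes) {
  ifelse(as.character(strand(genes)) == "-", end(genes), start(genes))
}

#' Shuffle intervals uniformly, preserving lengths and chromosome
#'
#' Each interval is re-placed uniformly at random on its own chromosome.
#' Used to build permutation nulls for fold-enrichment statistics. Draws from
#' the current RNG stream; seed outside.
#'
#' @param x A `GRanges`.
#' @param genome Named vector of chromosome lengths (bp).
#' @return A `GRanges` with the same widths and chromosomes.
#' @export
shuffle_intervals <- function(x, genome) {
  chrom <- as.character(seqnames(x))
  w <- width(x)
  maxstart <- genome[chrom] - w + 1
  if (any(is.na(maxstart)) || any(maxstart < 1)) {
    stop("interval longer than its chromosome or chromosome missing from genome")
  }
  newstart <- floor(runif(length(x), min = 1, max = maxstart + 1))
  GRanges(chrom, IRanges(start = as.integer(newstart), width = w))
}
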