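#' Within-tissue consensus of per-sample SE calls
#'
#' Keeps the SE regions supported by at least 1 bp of overlap in every
#' sample of the tissue; the consensus interval is the union of the
#' overlapping sample SEs. With a single sample this is the identity.
#'
#' @param sample_ses List of `GRanges`, one per sample.
#' @param min_samples Support required; default `length(sample_ses)`
#'   (intersection semantics), relaxable to m-of-n.
#' @return A `GRanges` of consensus SEs.
#' @export
tissue_consensus <- function(sample_ses, min_samples = length(sample_ses)) {
  stopifnot(length(sample_ses) >= 1L)
  if (length(sample_ses) == 1L) return(sample_ses[[1]])
  pooled <- reduce(do.call(c, unname(lapply(sample_ses, granges))),
                   ignore.strand = TRUE)
  support <- Reduce(`+`, lapply(sample_ses, function(s) {
    as.integer(overlapsAny(pooled, s, ignore.strand = TRUE))
  }))
  sort(pooled[support >= min_samples])
}

#' Merge SE calls across tissues into a non-redundant set
#'
#' SEs from different tissues whose pairwise overlap is at least
#' `min_overlap` bp (inclusive) are united transitively into one
#' non-redundant SE spanning their union; calls overlapping by less remain
#' distinct records. The result does not depend on tissue input order.
#'
#' @param tissue_ses Named list of `GRanges`, one per tissue.
#' @param min_overlap Minimum absolute overlap in bp (default 10000).
#' @return A list with `ses` (`GRanges`, ids `SE_1..SE_n` in positional
#'   order) and `presence` (logical matrix, SEs x tissues: the tissues that
#'   contributed a call to each non-redundant SE).
#' @export
merge_across_tissues <- function(tissue_ses, min_overlap = 10000) {
  stopifnot(min_overlap > 0)
  tissues <- names(tissue_ses)
  if (is.null(tissues)) tissues <- paste0("tissue", seq_along(tissue_ses))
  pooled <- do.call(c, unname(lapply(tissue_ses, granges)))
  tissue_of <- rep(tissues, lengths(tissue_ses))
  n <- length(pooled)
  if (n == 0L) {
    return(list(ses = GRanges(),
                presence = matrix(FALSE, 0, length(tissues),
                                  dimnames = list(NULL, tissues))))
  }
  hits <- findOverlaps(pooled, pooled, minoverlap = min_overlap,
                       ignore.strand = TRUE)
  # union-find over the (>= min_overlap)-overlap graph: transitive closure
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  qh <- queryHits(hits); sh <- subjectHits(hits)
  for (k in seq_along(qh)) {
    a <- find(qh[k]); b <- find(sh[k])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  comp <- vapply(seq_len(n), find, integer(1))
  comp <- match(comp, unique(comp))
  merged <- unlist(range(split(pooled, comp)), use.names = FALSE)
  presence <- matrix(FALSE, nrow = length(merged), ncol = length(tissues),
                     dimnames = list(NULL, tissues))
  presence[cbind(comp, match(tissue_of, tissues))] <- TRUE
  ord <- order(as.factor(seqnames(merged)), start(merged))
  merged <- merged[ord]
  presence <- presence[ord, , drop = FALSE]
  mcols(merged)$se_id <- paste0("SE_", seq_along(merged))
  rownames(presence) <- mcols(merged)$se_id
  list(ses = merged, presence = presence)
}

#' SE x tissue activity matrix
#'
#' Activity is mean H3K27ac signal density over the SE: region total signal
#' divided by SE length (signal units per bp); 0 where the tissue's track
#' has no signal over the SE.
#'
#' @param ses Non-redundant SE `GRanges` (from [merge_across_tissues()]).
#' @param tracks Named list of signal-track `GRanges`, one per tissue.
#' @param presence Optional logical presence matrix to carry along.
#' @return A list of class `"se_activity"`: `activity` (numeric matrix,
#'   SEs x tissues), `presence` (or NULL), `ses`.
#' @export
build_activity_matrix <- function(ses, tracks, presence = NULL) {
  if (!is.null(presence)) {
    missing <- setdiff(colnames(presence), names(tracks))
    if (length(missing)) stop("missing signal track for tissue: ",
                              paste(missing, collapse = ", "))
    tracks <- tracks[colnames(presence)]
  }
  activity <- vapply(tracks, function(tr) {
    score_regions(ses, tr) / width(ses)
  }, numeric(length(ses)))
  if (length(ses) == 1L) activity <- matrix(activity, nrow = 1,
                                            dimnames = list(NULL, names(tracks)))
  rownames(activity) <- if (!is.null(mcols(ses)$se_id)) mcols(ses)$se_id else NULL
  structure(list(activity = activity, presence = presence, ses = ses),
            class = "se_activity")
}

#' Tissue-specificity of non-redundant SEs
#'
#' Counts, per SE, the number of tissues in which it was called; an SE is
#' tissue-specific when that count is exactly 1.
#'
#' @param presence Logical matrix SEs x tissues.
#' @return A list: `tissue_count` (per SE), `histogram` (table of counts),
#'   `specific` (named list: per tissue, the row names of its specific SEs),
#'   `frac_single` and `frac_all` (fractions of SEs called in exactly one /
#'   in all tissues).
#' @export
tissue_specific_ses <- function(presence) {
  counts <- rowSums(presence)
  specific <- lapply(colnames(presence), function(t) {
    rownames(presence)[presence[, t] & counts == 1L]
  })
  names(specific) <- colnames(presence)
  list(tissue_count = counts,
       histogram = table(factor(counts, levels = seq_len(ncol(presence)))),
       specific = specific,
       frac_single = mean(counts == 1L),
       frac_all = mean(counts == ncol(presence)))
}

#' Cluster SEs by cross-tissue activity profile
#'
#' Rows are z-scored across tissues (constant rows map to 0), then k-means
#' with a fixed seed and multiple restarts; deterministic for a fixed seed.
#'
#' @param activity Numeric matrix SEs x tissues (or an `"se_activity"`).
#' @param k Number of clusters (default 10).
#' @param seed RNG seed for the k-means restarts.
#' @param nstart Number of random restarts (default 25).
#' @return A list: `cluster` (integer labels per SE), `centers` (k x tissues
#'   mean scaled profiles), `scaled` (the z-scored matrix).
#' @export
cluster_ses <- function(activity, k = 10, seed = 1, nstart = 25) {
  if (inherits(activity, "se_activity")) activity <- activity$activity
  if (k > nrow(activity)) stop("k exceeds the number of SEs")
  if (ncol(activity) < 2L) stop("need at least 2 tissues to cluster")
  mu <- rowMeans(activity)
  sdev <- apply(activity, 1, sd)
  scaled <- (activity - mu) / ifelse(sdev > 0, sdev, 1)
  scaled[sdev == 0, ] <- 0
  fit <- withr::with_seed(seed,
    kmeans(scaled, centers = k, nstart = nstart, iter.max = 100))
  list(cluster = fit$cluster, centers = fit$centers, scaled = scaled)
}
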