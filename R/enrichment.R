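#' Fold enrichment of a state in a genomic feature
#'
#' The fold-enrichment statistic `(C/A)/(B/D)`, where `A` is the merged size
#' of the state's segments (bp), `B` the merged size of the feature's
#' segments, `C` the size of their overlap, and `D` the size of the entire
#' genome. A value of 1 is the random expectation; all four components are
#' returned for auditability.
#'
#' @param state `GRanges` of the state's segments (e.g. super-enhancers).
#' @param feature `GRanges` of the genomic feature (e.g. a repeat class).
#' @param genome Named numeric vector of chromosome lengths (bp).
#' @param state_name,feature_name Labels carried into the result.
#' @return One-row data.frame: `state`, `feature`, `A`, `B`, `C`, `D`,
#'   `fold`.
#' @export
fold_enrichment <- function(state, feature, genome,
                            state_name = "state", feature_name = "feature") {
  A <- total_width(state)
  B <- total_width(feature)
  D <- sum(as.numeric(genome))
  if (A == 0) stop("empty state: A = 0")
  if (B == 0) stop("empty feature: B = 0")
  C <- overlap_size(state, feature)
  data.frame(state = state_name, feature = feature_name,
             A = A, B = B, C = C, D = D,
             fold = (C / A) / (B / D))
}

#' Permutation null for fold enrichment
#'
#' Re-places the state's intervals uniformly at random (lengths and
#' chromosomes preserved) `n_perm` times and recomputes the fold statistic,
#' giving an empirical null alongside the observed value.
#'
#' @inheritParams fold_enrichment
#' @param n_perm Number of shuffles (default 200).
#' @param seed RNG seed.
#' @return One-row data.frame: observed components and fold plus
#'   `perm_mean`, `perm_sd`, and `p_perm` (two-sided empirical p, with the
#'   +1 correction).
#' @export
fold_enrichment_null <- function(state, feature, genome, n_perm = 200,
                                 seed = 1, state_name = "state",
                                 feature_name = "feature") {
  obs <- fold_enrichment(state, feature, genome, state_name, feature_name)
  perms <- withr::with_seed(seed, vapply(seq_len(n_perm), function(i) {
    fold_enrichment(shuffle_intervals(state, genome), feature, genome)$fold
  }, numeric(1)))
  dev <- abs(perms - mean(perms))
  obs$perm_mean <- mean(perms)
  obs$perm_sd <- sd(perms)
  obs$p_perm <- (sum(dev >= abs(obs$fold - mean(perms))) + 1) / (n_perm + 1)
  obs
}

#' Chromatin-state composition of super vs normal enhancers
#'
#' For each of the five enhancer state classes, the share of constituent
#' peaks (and of bp) lying inside super-enhancers versus outside, plus the
#' overall fraction of enhancer peaks absorbed into SEs.
#'
#' @param peaks `GRanges` of enhancer peaks with a `state` metadata column.
#' @param super `GRanges` of super-enhancer regions.
#' @return A list: `by_state` (data.frame with per-class counts, bp and
#'   percentages in SE / NE) and `frac_peaks_in_se` (overall fraction).
#' @export
state_composition <- function(peaks, super) {
  state <- mcols(peaks)$state
  if (is.null(state) || anyNA(state) || any(state == "")) {
    bad <- if (is.null(state)) 1L else which(is.na(state) | state == "")[1]
    stop("peak without a state label at record ", bad)
  }
  in_se <- overlapsAny(peaks, super, ignore.strand = TRUE)
  w <- as.numeric(width(peaks))
  by_state <- do.call(rbind, lapply(sort(unique(state)), function(s) {
    sel <- state == s
    data.frame(state = s,
               n_se = sum(sel & in_se), n_ne = sum(sel & !in_se),
               bp_se = sum(w[sel & in_se]), bp_ne = sum(w[sel & !in_se]),
               pct_peaks_in_se = 100 * sum(sel & in_se) / sum(sel),
               pct_bp_in_se = 100 * sum(w[sel & in_se]) / sum(w[sel]))
  }))
  rownames(by_state) <- NULL
  list(by_state = by_state, frac_peaks_in_se = mean(in_se))
}

#' Fold enrichment of SEs on autosomes and the X chromosome
#'
#' Applies [fold_enrichment()] with the feature set to the full span of the
#' X chromosome and of the pooled autosomes.
#'
#' @param ses `GRanges` of SEs.
#' @param genome Named numeric vector of chromosome lengths.
#' @param x_aliases Chromosome names recognised as X (default
#'   `c("X", "chrX")`).
#' @return data.frame with one row per group (`autosomes`, `X`).
#' @export
chromosome_enrichment <- function(ses, genome, x_aliases = c("X", "chrX")) {
  is_x <- names(genome) %in% x_aliases
  chrom_span <- GRanges(names(genome), IRanges(1, as.integer(genome)))
  res <- fold_enrichment(ses, chrom_span[!is_x], genome,
                         state_name = "SE", feature_name = "autosomes")
  if (!any(is_x)) {
    warning("no chromosome matches the X alias set; autosomes only")
    return(res)
  }
  rbind(res, fold_enrichment(ses, chrom_span[is_x], genome,
                             state_name = "SE", feature_name = "X"))
}

#' Fold enrichment of SEs in repeat classes
#'
#' Computes the `(C/A)/(B/D)` statistic against each repeat class (SINE,
#' LINE, LTR, DNA, ...) and optionally each class/subfamily label (e.g.
#' `SINE/MIR`).
#'
#' @param ses `GRanges` of SEs.
#' @param repeats `GRanges` with `repeat_family` and `repeat_class` columns
#'   (from `read_intervals(format = "repeatmasker")`).
#' @param genome Named numeric vector of chromosome lengths.
#' @param level `"family"` (SINE, LINE, ...) or `"subfamily"`
#'   (`SINE/MIR`, ...).
#' @return data.frame, one row per repeat label.
#' @export
repeat_enrichment <- function(ses, repeats, genome,
                              level = c("family", "subfamily")) {
  level <- match.arg(level)
  lab <- if (level == "family") mcols(repeats)$repeat_family
         else mcols(repeats)$repeat_class
  do.call(rbind, lapply(sort(unique(lab)), function(cl) {
    fold_enrichment(ses, repeats[lab == cl], genome,
                    state_name = "SE", feature_name = cl)
  }))
}
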