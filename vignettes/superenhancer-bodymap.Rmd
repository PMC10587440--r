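---
title: "Building super-enhancer body maps from H3K27ac signal"
author: "sebodymap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building super-enhancer body maps from H3K27ac signal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sebodymap)
```

## The problem

Super-enhancers (SEs) are large clusters of enhancers carrying exceptionally
high transcriptional-coactivator signal — in practice, H3K27ac ChIP-seq
signal — that drive genes central to cell identity. Given per-tissue
enhancer annotations (five chromatin-state classes: EnhA, EnhAMe, EnhAWk,
EnhAHet, EnhPois) and per-tissue H3K27ac signal, this package

1. calls SEs per sample by the stitched-ranking procedure (`stitch_peaks()`,
   `score_regions()`, `tangent_cutoff()`, `call_superenhancers()`),
2. assembles a cross-tissue **body map**: within-tissue consensus, a
   non-redundant SE set merged across tissues, an SE × tissue activity
   matrix, tissue-specificity counts, and k-means activity clusters,
3. quantifies enrichment of SEs in genomic features (chromosomes, repeat
   classes) with the fold statistic $(C/A)/(B/D)$, and
4. relates SEs to genes: expression (TPM), the tau tissue-specificity
   index, conservation, SE size quintiles (G1–G5) and TSS-distance groups
   (T1–T5).

A synthetic-data generator (`simulate_bodymap()`) produces every input with
known ground truth, so each stage is verifiable end to end without any
external download.

## Super-enhancer calling

**Stitching.** Enhancer peaks (all five state classes pooled) whose
inter-peak gap is at most the stitch distance (default **12,500 bp**, the
standard default of rank-based SE callers) are joined into one candidate
region. An optional promoter exclusion removes peaks fully inside
TSS ± `tss_exclusion` before stitching; it is **off by default**, matching
the default parameterisation.

**Scoring.** A region's score is $\sum_i v_i \cdot o_i$ over signal-track
intervals $i$ overlapping it, where $v_i$ is the track value and $o_i$ the
overlapped width — i.e. total signal in units of signal × bp. Bases without
track coverage contribute 0. An optional input-control track is subtracted
and floored at 0; none is used by default (recorded in the call object).

**Cutoff.** Scores are sorted ascending and both rank and score are scaled
to $[0,1]$. A line of slope 1 is slid along the curve; the cutoff sits at
the rank minimising the number of points on or below the line — the tangent
point of the hockey-stick curve. Regions scoring strictly above the cutoff
score are super-enhancers. Properties that matter:

* *Scale invariance*: multiplying all scores by $c>0$ leaves the partition
  unchanged (both axes are normalised).
* *Determinism*: ranks use a stable sort with genomic position
  (chromosome, start) as the final key; ties in the tangent criterion go to
  the largest rank, so repeated runs are identical.
* *Degenerate input*: fewer than 3 regions, or all scores identical, is an
  error rather than an arbitrary split.

We deliberately evaluate the tangent condition by the points-below-line
count at every rank rather than by thresholding a windowed discrete slope.
A windowed slope estimate crosses 1 up to half a window *before* the curve's
hinge, which systematically drags the cutoff into the background and flags
of order $n/100$ typical regions as super; the points-below-line form has no
such bias, needs no smoothing parameter, and an independent brute-force
implementation of the same condition pins its behaviour in the test suite.

## The body map

* **Within-tissue consensus** (`tissue_consensus()`): a region is kept when
  every sample of the tissue supports it with ≥ 1 bp of overlap
  (intersection semantics, relaxable to m-of-n); the consensus interval is
  the union of the overlapping sample SEs. A single sample passes through
  unchanged.
* **Cross-tissue merge** (`merge_across_tissues()`): SEs from different
  tissues overlapping by at least **10,000 bp** — read as absolute overlap,
  inclusive at the boundary — are united transitively (union–find over the
  overlap graph) into one non-redundant SE spanning their union. Calls
  overlapping by less remain distinct. The result is invariant to tissue
  input order and idempotent, and a brute-force closure oracle verifies it.
* **Activity** (`build_activity_matrix()`): mean signal density
  (score / length, signal units per bp) of each non-redundant SE in each
  tissue; presence records which tissues contributed a call. Both the
  continuous matrix and the boolean presence are kept, since either reading
  of "activity" may be wanted downstream.
* **Tissue specificity** (`tissue_specific_ses()`): an SE is
  tissue-specific when it was called in exactly one tissue. This is a
  declared interpretation — "detected by the same approach" is otherwise
  underspecified — and the presence matrix is returned so other definitions
  can be applied.
* **Clustering** (`cluster_ses()`): rows are z-scored across tissues
  (constant rows map to 0), then `stats::kmeans` with k = 10 by default, a
  fixed seed and 25 restarts. Row z-scoring is the heatmap-clustering
  convention; the restart count makes the partition reproducible in
  practice on block-structured matrices.

## Fold enrichment

For a state (e.g. the SE set) and a genomic feature (a repeat class, the X
chromosome), with $A$ = merged bp of the state, $B$ = merged bp of the
feature, $C$ = bp of their intersection and $D$ = genome size:

$$\text{fold} = \frac{C/A}{B/D},$$

1 being the random expectation. All sizes are merged before the formula so
self-overlapping annotations are not double-counted, and all four components
are returned for audit. Two structural identities are tested: features that
tile the genome satisfy $\sum_f (B_f/D)\,\text{fold}_f = 1$, and the fold
depends only on covered bases, not on how intervals are split.

`chromosome_enrichment()` pools all autosomes into a single feature (one
fold for "autosomes", one for X) rather than averaging per-chromosome folds;
`repeat_enrichment()` reports both the class level (SINE, LINE, LTR, DNA)
and the class/subfamily level (e.g. SINE/MIR). Because the point estimate
carries no uncertainty, `fold_enrichment_null()` re-places the state
uniformly at random (lengths and chromosomes preserved, seeded) and returns
the permutation mean, sd and a two-sided empirical p.

## Genes, expression, tau

* **Association** (`associate_ses_to_genes()`): a gene is SE-associated
  when its body (default) or TSS lies within `window` bp of a non-redundant
  SE; the default window is 0 (direct intersection). The windowed-overlap
  reading is configurable because the underlying tooling convention is
  ambiguous; both directions of the mapping are emitted.
* **Tau** (`tau_index()`): the standard index
  $\tau = \sum_i (1-\hat{x}_i)/(n-1)$ with $\hat{x}_i = x_i/\max_j x_j$;
  0 for uniform expression, 1 for single-tissue expression, undefined (NA)
  for all-zero vectors, invariant to rescaling. The source analysis names
  tau without defining it; this is the field-standard formula.
* **Size groups** (`size_quintiles()`): SEs sorted ascending by length and
  cut into five contiguous groups G1–G5 whose sizes differ by at most one
  (remainder r goes to the first r groups); ties keep positional order.
* **Distance groups** (`distance_groups()`): signed TSS distances
  (`se_gene_distances()`, sign by gene strand: negative = SE downstream of
  the TSS, 0 = TSS inside an SE). T3 is exactly the distance-0 records;
  each side is split at its **median absolute distance** into far/near
  halves (T1/T2 downstream, T4/T5 upstream). The original analysis printed
  only the group sizes, not the split points, so the median rule is the
  closest reproducible reading; explicit breakpoints can be supplied.
* **Comparisons** (`compare_groups()`): two-sided Mann–Whitney tests of
  each group against a stated reference (T3 for distance groups), BH
  adjustment across the comparisons of one call, medians and direction
  reported, degenerate comparisons given p = 1. The rank test is the
  non-parametric default for skewed TPM; expression enters as the raw mean
  TPM across tissues (a log-scale transform can be applied upstream).

## The synthetic generator

`simulate_bodymap(sim_config(...))` emulates the structure of a multi-tissue
H3K27ac body-map study on a desk-scale genome. Key parameters (units,
default, rationale):

| parameter | default | what it encodes |
|---|---|---|
| `n_chroms`, `chrom_length` | 10 × 15 Mb | 9 autosomes + chrX; large enough that planted SEs stay sparse |
| `n_tissues` | 14 | the tissue panel of the emulated design |
| `n_planted_se_per_tissue` | 20 | expected SE loci active per tissue |
| `se_constituent_count_mean` | 43 | Poisson mean constituents per SE (min 2) |
| `se_constituent_size_mean` | 682 bp | mean constituent enhancer size (sd 20%) |
| `se_gap_mean` | 625 bp | exponential inter-constituent gap; with the above, a planted SE spans ≈ 56 kb |
| `background_peak_density` | 13.3 / Mb | ≈ 2,000 sparse background peaks genome-wide |
| `signal_fold_se_vs_background` | 50 | signal contrast of SE constituents |
| `state_mix`, `state_mix_se` | see `?sim_config` | five-class composition outside/inside SEs (EnhA and EnhAHet enriched, EnhPois depleted inside) |
| `x_depletion_factor` | 0.2 | per-bp SE placement rate on chrX relative to autosomes |
| `repeat_fraction`, `repeat_se_fold` | SINE 10% at 5×, others at 1× | repeat classes planted to hit a target fold in the SE footprint exactly in expectation |
| `frac_single_tissue`, `tissue_share_prob` | 0.30, 0.35 | cross-tissue activity patterns of SE loci (≈ 30% single-tissue) |
| `se_expression_fold`, `se_gene_window` | 2, 50 kb | expression boost of genes planted near a locus |
| `tpm_noise_cv`, `tpm_base_sdlog` | 0.3, 1.0 | per-tissue noise and between-gene spread of lognormal baseline TPM |
| `tau_damping_se` | 0.5 | SE-target genes drawn with damped cross-tissue noise, so they come out broadly expressed (lower tau) |

Design points worth spelling out:

* **SE loci are shared structures.** Each locus carries a tissue-activity
  pattern (single-tissue with probability `frac_single_tissue`, otherwise
  2 + Binomial further tissues); per tissue, the planted SEs are the loci
  active there. Most real SEs are active in several tissues, and this
  sharing is what makes an SE-associated gene's *mean* TPM across tissues
  respond to the planted effect.
* **Expression effect.** A gene planted within 50 kb of a locus is
  multiplied by `se_expression_fold` in every tissue where the locus is
  active and by half the effect (on the fold − 1 scale) elsewhere —
  elevated overall, concordantly stronger in the SE's tissues — and the
  multiplier decays linearly to 1 at the window edge, giving the proximity
  gradient the distance-group analysis measures. With fold = 1 every
  multiplier is exactly 1 (a clean null). The noise damping for target
  genes is mean-corrected so it does not shift the null.
* **Repeat planting.** For a class with target fold $f$ and genome fraction
  $b$, $C = f \cdot bD \cdot A/D$ bp of elements are placed uniformly and
  non-overlapping *inside* the pooled SE footprint and the remainder
  strictly outside, so the planted fold is exact in expectation; SINE/MIR
  is over-represented among in-footprint SINEs, giving a subfamily fold
  above the class fold.
* **Determinism.** One seed drives everything; per-tissue draws use fixed
  seed offsets so tissue k's data do not change when `n_tissues` changes.
  Written output is byte-identical across runs of the same configuration.
* **TPM columns** are renormalised to sum to $10^6$ after effects are
  applied, per the definition of the unit.
* **Conservation** is Beta-distributed identity (%) with a higher mean for
  SE-target genes (86 vs 80 at concentration 25), so the conservation
  contrast is testable.

What the generator does **not** emulate: read-level noise and mappability,
input-control tracks, replicate structure within tissues (one sample per
tissue is emitted; consensus is exercised with constructed inputs),
realistic chromosome size spectra, nucleotide sequence, and correlated
gene–gene expression. Passing the test suite therefore demonstrates the
pipeline's correctness and calibration on cleanly planted structure, not
robustness to alignment artefacts or replicate discordance in real data.

## Numerical and degenerate-input choices

* Intervals are `GRanges` (1-based, closed) throughout; BED's 0-based
  half-open and GFF/RepeatMasker's 1-based inclusive conventions are
  converted only at the I/O boundary (`read_intervals()`, `write_bed()`,
  ...), eliminating off-by-one drift inside the pipeline.
* Chromosome matching is exact string match; X is recognised through an
  alias set (`c("X", "chrX")` by default).
* Empty inputs: merging and consensus of empty sets return empty sets;
  an empty reference set for nearest-TSS queries, an empty state or feature
  in the fold formula, fewer than 5 SEs for quintiles, and degenerate score
  distributions are errors with explicit messages.
* All randomised procedures (generator, permutation null, k-means restarts)
  take explicit seeds; tests and the acceptance script derive every seed
  from one input seed.

## Problem sizes used in the checks

The shipped tests run the full pipeline at the generator's default scale
(150 Mb genome, 14 tissues, ≈ 2,900 peaks/tissue) for calling-recovery and
summary checks, and use reduced panels (4 tissues, 3 constituents per SE,
1,000–4,000 genes, 50 null replicates) for the expression power, type-I and
distance-gradient checks, pooling genes over 3 seeds for group medians.
The X-depletion recovery uses 200 planted SEs per tissue pooled over 10
seeds so the density-ratio estimator's sampling error (≈ 9%) sits well
inside the 25% recovery band. These sizes are the package's chosen
trade-off between statistical resolution and an interactive test cycle.

## Known limitations

* The tangent cutoff assumes a convex "hockey-stick" rank–signal curve; on
  multimodal score distributions the single tangent point may split modes
  unnaturally (the full ranked table is returned so other cutoffs can be
  applied).
* Within-tissue consensus with intersection semantics is conservative: a
  true SE missed in one replicate is dropped from the tissue.
* `merge_across_tissues()` can chain transitively: two SEs that never
  overlap each other may merge through an intermediary, producing long
  non-redundant records; this is inherent to the 10 kb absolute-overlap
  definition.
* Tissue-specific SE detection (presence in exactly one tissue) ignores
  activity magnitude; a borderline sub-threshold call in a second tissue
  makes an SE "specific".
* The conservation column is consumed, not computed; orthology and
  alignment are out of scope.

## A minimal run

```{r example, eval = FALSE}
library(sebodymap)

sim <- simulate_bodymap(sim_config(seed = 1))

# per-tissue calling
calls <- lapply(sim$peaks, function(p) call_superenhancers(p, p))

# non-redundant body map
merged <- merge_across_tissues(lapply(calls, function(x) x$super))
am <- build_activity_matrix(merged$ses, sim$peaks, merged$presence)
tissue_specific_ses(merged$presence)$frac_single

# enrichment and gene association
chromosome_enrichment(merged$ses, sim$genome)
repeat_enrichment(merged$ses, sim$repeats, sim$genome)
assoc <- associate_ses_to_genes(merged$ses, sim$genes,
                                window = 50000, anchor = "tss")
compare_groups(rowMeans(sim$tpm),
               factor(ifelse(assoc$has_se, "SE", "nonSE")),
               reference = "nonSE")
```
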