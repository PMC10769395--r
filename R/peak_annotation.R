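#' Strand-aware promoter intervals for gene models
#'
#' The promoter covers positions whose signed distance `d` to the TSS
#' satisfies `-3000 <= d < +1000`, with `d = p - t` on the plus strand and
#' `d = t - p` on the minus strand; the TSS `t` is `start` for plus-strand
#' genes and `end - 1` for minus-strand genes. Each interval is 4 kb before
#' chromosome-end clamping and always contains the TSS.
#'
#' @param genes Gene-model data frame from [read_gene_models()].
#' @param upstream,downstream Distances in bp defining `-upstream <= d <
#'   +downstream` (defaults 3000 and 1000).
#' @return `data.frame` with `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open), `tss`, `strand`.
#' @export
promoter_intervals <- function(genes, upstream = 3000L, downstream = 1000L) {
  plus <- genes$strand == "+"
  tss <- ifelse(plus, genes$start, genes$end - 1L)
  # plus: p in [t - upstream, t + downstream)
  # minus: -upstream <= t - p < downstream  =>  p in [t - downstream + 1, t + upstream + 1)
  start <- ifelse(plus, tss - upstream, tss - downstream + 1L)
  end <- ifelse(plus, tss + downstream, tss + upstream + 1L)
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             start = pmax(0L, as.integer(start)), end = as.integer(end),
             tss = as.integer(tss), strand = genes$strand,
             stringsAsFactors = FALSE)
}

#' Classify peaks as promoter or distal
#'
#' A peak is `promoter` iff its summit lies inside any gene's promoter
#' interval (distal regions are everything outside promoters). With
#' `by_summit = FALSE` any overlap of the peak interval with a promoter
#' counts instead.
#'
#' @param peaks Peak data frame.
#' @param genes Gene-model data frame.
#' @param upstream,downstream Promoter extent, see [promoter_intervals()].
#' @param by_summit Test summit membership (default) or any-overlap.
#' @return Character vector `"promoter"`/`"distal"`, one per peak.
#' @export
classify_peak <- function(peaks, genes, upstream = 3000L, downstream = 1000L,
                          by_summit = TRUE) {
  if (nrow(genes) == 0L) return(rep("distal", nrow(peaks)))
  prom <- promoter_intervals(genes, upstream, downstream)
  pr <- GenomicRanges::GRanges(prom$chrom, IRanges::IRanges(prom$start + 1L, prom$end))
  if (by_summit) {
    s <- peak_summit(peaks)
    q <- GenomicRanges::GRanges(peaks$chrom, IRanges::IRanges(s + 1L, s + 1L))
  } else {
    q <- .as_granges(peaks)
  }
  # peaks on chromosomes without genes are legitimately distal; silence the
  # disjoint-seqlevels warning that case triggers
  hits <- suppressWarnings(GenomicRanges::countOverlaps(q, pr)) > 0L
  ifelse(hits, "promoter", "distal")
}

#' Percentage of peaks classified as promoter
#'
#' @inheritParams classify_peak
#' @return Percentage in \[0, 100\].
#' @export
promoter_fraction <- function(peaks, genes, upstream = 3000L, downstream = 1000L,
                              by_summit = TRUE) {
  if (is.null(peaks) || nrow(peaks) == 0L) stop("empty peak list")
  100 * mean(classify_peak(peaks, genes, upstream, downstream, by_summit) == "promoter")
}

#' Assign peaks to genes by flank-extended overlap
#'
#' A peak is assigned to every gene whose span, extended by `flank` bp on both
#' sides (clamped at 0) it intersects under the half-open convention. A gene
#' is "bound" iff its peak list is non-empty.
#'
#' @param peaks Peak data frame.
#' @param genes Gene-model data frame.
#' @param flank Extension in bp (default 5000, a declared proxy for binding
#'   "in the proximity of the gene body").
#' @return Named list mapping `gene_id` to an integer vector of peak row
#'   indices (empty for unbound genes).
#' @export
assign_peaks_to_genes <- function(peaks, genes, flank = 5000L) {
  stopifnot(flank >= 0L)
  out <- stats::setNames(vector("list", nrow(genes)), genes$gene_id)
  ext_start <- pmax(0L, genes$start - as.integer(flank))
  ext_end <- genes$end + as.integer(flank)
  gr_genes <- GenomicRanges::GRanges(genes$chrom,
                                     IRanges::IRanges(ext_start + 1L, ext_end))
  gr_peaks <- .as_granges(peaks)
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gr_genes, gr_peaks))
  for (i in seq_len(nrow(genes))) out[[i]] <- integer()
  sp <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))
  for (q in names(sp)) out[[as.integer(q)]] <- as.integer(sp[[q]])
  out
}

#' Gene ids bound by at least one peak
#' @inheritParams assign_peaks_to_genes
#' @return Character vector of bound gene ids.
#' @export
bound_genes <- function(peaks, genes, flank = 5000L) {
  asg <- assign_peaks_to_genes(peaks, genes, flank)
  names(asg)[lengths(asg) > 0L]
}

# bp gap between half-open intervals [a,b) and [c,d); overlap or adjacency -> 0
.interval_gap <- function(a, b, c, d) {
  pmax(0L, pmax(c - b, a - d))
}

.min_mark_distance <- function(gene, marks) {
  m <- marks[marks$chrom == gene$chrom, , drop = FALSE]
  if (nrow(m) == 0L) return(NA_integer_)
  min(.interval_gap(gene$start, gene$end, m$start, m$end))
}

#' Repressive-mark category of a gene locus
#'
#' Computes the bp gap from the gene span to the nearest H3K9me3 and H3K27me3
#' peak (0 when overlapping or adjacent). A mark is "present" iff its distance
#' is `<= window`; the category is derived from the presence pair, and
#' `closest_mark` is the present mark with the smaller distance (exact ties
#' are reported as `"both_tied"`).
#'
#' @param gene Single-row gene-model data frame.
#' @param k9_peaks,k27_peaks Peak data frames for H3K9me3 / H3K27me3 broad
#'   peaks (may have zero rows).
#' @param window Proximity window in bp (default 10000; a declared choice —
#'   the adjacency notion it quantifies is qualitative in the source data).
#' @return One-row `data.frame`: `gene_id`, `category` in
#'   \{`H3K9me3_only`, `H3K27me3_only`, `both`, `none`\}, `closest_mark`,
#'   `distance_k9`, `distance_k27` (NA when no peak on the chromosome).
#' @export
mark_category <- function(gene, k9_peaks, k27_peaks, window = 10000L) {
  stopifnot(nrow(gene) == 1L)
  d9 <- .min_mark_distance(gene, k9_peaks)
  d27 <- .min_mark_distance(gene, k27_peaks)
  p9 <- !is.na(d9) && d9 <= window
  p27 <- !is.na(d27) && d27 <= window
  category <- if (p9 && p27) "both" else if (p9) "H3K9me3_only" else
    if (p27) "H3K27me3_only" else "none"
  closest <- if (!p9 && !p27) "none" else if (p9 && !p27) "H3K9me3" else
    if (p27 && !p9) "H3K27me3" else if (d9 < d27) "H3K9me3" else
    if (d27 < d9) "H3K27me3" else "both_tied"
  data.frame(gene_id = gene$gene_id, category = category,
             closest_mark = closest, distance_k9 = d9, distance_k27 = d27,
             stringsAsFactors = FALSE)
}

#' Mark categories for a set of gene loci
#' @param genes Gene-model data frame.
#' @inheritParams mark_category
#' @return Row-bound [mark_category()] results, one row per gene.
#' @export
mark_categories <- function(genes, k9_peaks, k27_peaks, window = 10000L) {
  do.call(rbind, lapply(seq_len(nrow(genes)), function(i)
    mark_category(genes[i, , drop = FALSE], k9_peaks, k27_peaks, window)))
}

#' Summarize mark categories as counts and percentages
#'
#' @param categories Data frame with a `category` column
#'   ([mark_categories()] output).
#' @return `data.frame` with `category`, `count`, `pct` (exact) and
#'   `pct_rounded` (nearest integer); counts partition the gene list.
#' @export
summarize_mark_categories <- function(categories) {
  if (is.null(categories) || nrow(categories) == 0L) stop("empty category list")
  lev <- c("H3K9me3_only", "H3K27me3_only", "both", "none")
  counts <- table(factor(categories$category, levels = lev))
  pct <- 100 * as.integer(counts) / nrow(categories)
  data.frame(category = lev, count = as.integer(counts), pct = pct,
             pct_rounded = as.integer(round(pct)), stringsAsFactors = FALSE)
}
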