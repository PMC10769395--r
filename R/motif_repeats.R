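#' Summit of a peak
#'
#' `start + summit_offset` when a summit was called, otherwise the interval
#' midpoint `floor((start + end) / 2)`.
#'
#' @param peaks Peak data frame.
#' @return Integer vector of 0-based summit positions.
#' @export
peak_summit <- function(peaks) {
  mid <- as.integer((peaks$start + peaks$end) %/% 2L)
  so <- peaks$summit_offset
  ifelse(is.na(so), mid, peaks$start + as.integer(so))
}

#' Extract the sequence window around a peak summit
#'
#' Returns the genome slice `[summit - width/2, summit + width/2)`, clamped at
#' chromosome ends. The paper-style default profiles a total of 500 bp around
#' the summit (summit +/- 250).
#'
#' @param peak Single-row peak data frame.
#' @param genome `DNAStringSet` from [read_genome()].
#' @param width Total window width in bp (even, >= 4).
#' @return Character string with attribute `truncated` (logical) set when the
#'   window was clamped at a chromosome end.
#' @export
extract_summit_window <- function(peak, genome, width = 500L) {
  stopifnot(nrow(peak) == 1L)
  if (width < 4L || width %% 2L != 0L) stop("width must be even and >= 4")
  if (!peak$chrom %in% names(genome))
    stop("chromosome not in genome: ", peak$chrom)
  len <- length(genome[[peak$chrom]])
  s <- peak_summit(peak)
  lo <- s - width %/% 2L
  hi <- s + width %/% 2L
  if (hi <= 0L || lo >= len)
    stop(sprintf("window [%d,%d) entirely off chromosome %s", lo, hi, peak$chrom))
  clo <- max(0L, lo); chi <- min(len, hi)
  out <- genome_slice(genome, peak$chrom, clo, chi)
  attr(out, "truncated") <- (clo != lo || chi != hi)
  attr(out, "window_start") <- clo
  out
}

#' Find maximal runs of consecutive gapless motif copies
#'
#' Scans left to right: a run begins at the first motif occurrence not already
#' consumed and extends greedily while the next 4 bases repeat the motif. Each
#' maximal run is reported once with its copy number `n`; `N` bases never
#' match. GGAA and TTCC have no self-overlap, so the greedy scan is
#' unambiguous.
#'
#' @param sequence Uppercase DNA string.
#' @param motif 4-base motif (`"GGAA"` or `"TTCC"` in practice).
#' @return `data.frame` with `window_offset` (0-based run start), `motif`,
#'   `n` (copies in the run); zero rows when the motif is absent.
#' @export
find_motif_runs <- function(sequence, motif) {
  if (nchar(motif) != 4L) stop("motif length must be 4")
  empty <- data.frame(window_offset = integer(), motif = character(),
                      n = integer(), stringsAsFactors = FALSE)
  L <- nchar(sequence)
  if (L < 4L) return(empty)
  # all occurrence start positions (1-based), then chain occurrences 4 apart
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  mc <- strsplit(motif, "", fixed = TRUE)[[1L]]
  pos <- seq_len(L - 3L)
  hit <- chars[pos] == mc[1L] & chars[pos + 1L] == mc[2L] &
         chars[pos + 2L] == mc[3L] & chars[pos + 3L] == mc[4L]
  occ <- pos[hit]
  if (!length(occ)) return(empty)
  is_start <- !(occ - 4L) %in% occ
  starts <- occ[is_start]
  n <- vapply(starts, function(s) {
    k <- 1L
    while ((s + 4L * k) %in% occ) k <- k + 1L
    k
  }, integer(1L))
  data.frame(window_offset = starts - 1L, motif = motif, n = n,
             stringsAsFactors = FALSE)
}

.RUN_BINS <- c("1", "2", "3", "4", ">4")

.bin_runs <- function(n) {
  cut(n, breaks = c(0.5, 1.5, 2.5, 3.5, 4.5, Inf), labels = .RUN_BINS)
}

#' Profile consecutive GGAA/TTCC runs across a peak set
#'
#' For each peak, extracts the summit window, pools maximal GGAA runs and
#' maximal TTCC runs (a plus-strand GGAA microsatellite and its minus-strand
#' TTCC complement are the same element, so pooling counts each element once
#' while scanning only the forward strand), and bins runs by copy number into
#' \{1, 2, 3, 4, >4\}.
#'
#' @param peaks Peak data frame (non-empty).
#' @param genome `DNAStringSet`.
#' @param width Total window width in bp (default 500).
#' @param separate When `TRUE`, profile GGAA and TTCC separately instead of
#'   pooling.
#' @return A `repeat_profile`: data frame with one row per bin and columns
#'   `bin`, `n_peaks`, `peaks_with_at_least_one`, `pct_peaks`, `total_runs`,
#'   `mean_runs_per_peak` (plus `motif` when `separate = TRUE`).
#' @export
profile_peaks <- function(peaks, genome, width = 500L, separate = FALSE) {
  if (is.null(peaks) || nrow(peaks) == 0L) stop("empty peak list")
  runs_by_peak <- lapply(seq_len(nrow(peaks)), function(i) {
    win <- extract_summit_window(peaks[i, , drop = FALSE], genome, width)
    rbind(find_motif_runs(win, "GGAA"), find_motif_runs(win, "TTCC"))
  })
  motifs <- if (separate) c("GGAA", "TTCC") else "pooled"
  out <- do.call(rbind, lapply(motifs, function(m) {
    sel <- lapply(runs_by_peak, function(r)
      if (m == "pooled") r else r[r$motif == m, , drop = FALSE])
    per_bin <- lapply(sel, function(r) table(.bin_runs(r$n)))
    total_runs <- Reduce(`+`, per_bin)
    with_one <- Reduce(`+`, lapply(per_bin, function(tb) as.integer(tb > 0L)))
    np <- nrow(peaks)
    data.frame(motif = m, bin = .RUN_BINS, n_peaks = np,
               peaks_with_at_least_one = as.integer(with_one),
               pct_peaks = 100 * as.integer(with_one) / np,
               total_runs = as.integer(total_runs),
               mean_runs_per_peak = as.integer(total_runs) / np,
               stringsAsFactors = FALSE)
  }))
  if (!separate) out$motif <- NULL
  rownames(out) <- NULL
  class(out) <- c("repeat_profile", "data.frame")
  out
}

#' @export
print.repeat_profile <- function(x, ...) {
  cat("Consecutive GGAA/TTCC run profile over", x$n_peaks[1L], "peaks\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
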