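test_that("promoter membership follows the signed-distance definition on both strands", {
  gplus <- make_genes("chr1", 10000, 12000, "+")     # TSS t = 10000
  # d = p - t: promoter iff -3000 <= d < 1000
  summit_at <- function(pos) make_peaks("chr1", pos, pos + 2L, summit_offset = 0L)
  expect_equal(classify_peak(summit_at(9500), gplus), "promoter")    # d = -500
  expect_equal(classify_peak(summit_at(7000), gplus), "promoter")    # d = -3000
  expect_equal(classify_peak(summit_at(6999), gplus), "distal")
  expect_equal(classify_peak(summit_at(10999), gplus), "promoter")   # d = 999
  expect_equal(classify_peak(summit_at(11000), gplus), "distal")     # d = 1000
  gminus <- make_genes("chr1", 16000, 20000, "-")    # TSS t = 19999
  expect_equal(classify_peak(summit_at(20500), gminus), "promoter")  # d = -501
  expect_equal(classify_peak(summit_at(22999), gminus), "promoter")  # d = -3000
  expect_equal(classify_peak(summit_at(23000), gminus), "distal")
  expect_equal(classify_peak(summit_at(19000), gminus), "promoter")  # d = 999
  expect_equal(classify_peak(summit_at(18999), gminus), "distal")    # d = 1000
  # no genes on the chromosome -> distal
  expect_equal(classify_peak(summit_at(5), make_genes("chr2", 1, 10, "+")),
               "distal")
})

test_that("classify_peak agrees with exhaustive signed-distance evaluation", {
  genes <- rbind(make_genes("chrT", 20000, 24000, "+", "gp"),
                 make_genes("chrT", 30000, 36000, "-", "gm"))
  pos <- seq(15000L, 42000L, by = 7L)
  peaks <- make_peaks("chrT", pos, pos + 2L, summit_offset = 0L,
                      name = sprintf("s%d", seq_along(pos)))
  got <- classify_peak(peaks, genes)
  # oracle: evaluate d at every summit for every gene, by definition
  oracle <- vapply(pos, function(p) {
    inside <- vapply(seq_len(nrow(genes)), function(i) {
      t <- if (genes$strand[i] == "+") genes$start[i] else genes$end[i] - 1L
      d <- if (genes$strand[i] == "+") p - t else t - p
      d >= -3000 && d < 1000
    }, logical(1L))
    if (any(inside)) "promoter" else "distal"
  }, character(1L))
  expect_identical(got, oracle)
})

test_that("promoter/distal calls are invariant under coordinate reflection", {
  set.seed(9)
  L <- 50000L
  genes <- make_genes("chrT", c(8000, 30000), c(12000, 33000), c("+", "-"))
  pos <- sort(sample(3000:47000, 400))
  peaks <- make_peaks("chrT", pos, pos + 2L, summit_offset = 0L,
                      name = sprintf("s%d", seq_along(pos)))
  fwd <- classify_peak(peaks, genes)
  # reflect: p' = L - 1 - p, swap start/end, flip strand
  rgenes <- genes
  rgenes$start <- L - genes$end; rgenes$end <- L - genes$start
  rgenes$strand <- ifelse(genes$strand == "+", "-", "+")
  rpos <- L - 1L - pos
  rpeaks <- make_peaks("chrT", rpos, rpos + 2L, summit_offset = 0L,
                       name = peaks$name)
  expect_identical(classify_peak(rpeaks, rgenes), fwd)
})

test_that("promoter_fraction counts planted promoter summits", {
  genes <- make_genes("chr1", seq(10000, 10000 + 99 * 8000, by = 8000),
                      seq(12000, 12000 + 99 * 8000, by = 8000),
                      rep("+", 100), sprintf("g%03d", 1:100))
  tss <- genes$start
  # 84 summits inside promoters, 16 between promoters (d = +1500 is distal
  # for the own gene and far upstream of the -3000 bound of the next)
  pos <- c(tss[1:84] + 100L, tss[85:100] + 1500L)
  peaks <- make_peaks("chr1", pos, pos + 2L, summit_offset = 0L,
                      name = sprintf("s%d", seq_along(pos)))
  expect_equal(promoter_fraction(peaks, genes), 84)
  expect_equal(promoter_fraction(peaks, genes[0, ]), 0)
  expect_error(promoter_fraction(peaks[0, ], genes), "empty")
})

test_that("assign_peaks_to_genes matches a brute-force overlap oracle and is monotone in flank", {
  set.seed(21)
  genes <- make_genes("chr1", gs <- sort(sample.int(2e5, 50)) , gs + 3000L,
                      sample(c("+", "-"), 50, TRUE), sprintf("g%02d", 1:50))
  ps <- sample.int(2e5, 200)
  peaks <- make_peaks("chr1", ps, ps + sample(100:1000, 200, TRUE),
                      name = sprintf("p%03d", 1:200))
  for (flank in c(0L, 5000L)) {
    got <- assign_peaks_to_genes(peaks, genes, flank)
    for (i in seq_len(50)) {
      es <- max(0L, genes$start[i] - flank); ee <- genes$end[i] + flank
      exp_idx <- which(peaks$start < ee & es < peaks$end)
      expect_equal(sort(got[[genes$gene_id[i]]]), exp_idx)
    }
  }
  a0 <- assign_peaks_to_genes(peaks, genes, 0L)
  a1 <- assign_peaks_to_genes(peaks, genes, 2000L)
  for (g in names(a0)) expect_true(all(a0[[g]] %in% a1[[g]]))
  # boundary: half-open extended span excludes a peak ending exactly at its start
  g1 <- make_genes("chr9", 5100, 6000, "+")
  p1 <- make_peaks("chr9", 0, 100)
  expect_length(assign_peaks_to_genes(p1, g1, 5000L)$g1, 0L)
  expect_length(assign_peaks_to_genes(p1, g1, 5001L)$g1, 1L)
})

test_that("mark_category derives presence, category and closest mark from bp gaps", {
  gene <- make_genes("chr1", 100000, 110000, "+")
  k27 <- make_peaks("chr1", 105000, 106000)   # overlaps -> distance 0
  k9 <- make_peaks("chr1", 160000, 161000)    # 50 kb away
  mc <- mark_category(gene, k9, k27, window = 10000L)
  expect_equal(mc$category, "H3K27me3_only")
  expect_equal(mc$closest_mark, "H3K27me3")
  expect_equal(mc$distance_k27, 0L)
  expect_equal(mc$distance_k9, 50000L)
  # both overlapping -> both; equal distances -> both_tied
  mc2 <- mark_category(gene, make_peaks("chr1", 99000, 100500), k27, 10000L)
  expect_equal(mc2$category, "both")
  expect_equal(mc2$closest_mark, "both_tied")  # both overlap: gap 0 each
  mc3 <- mark_category(gene, make_peaks("chr1", 112000, 113000),
                       make_peaks("chr1", 96000, 98000), 10000L)
  expect_equal(mc3$category, "both")
  expect_equal(mc3$closest_mark, "both_tied")  # both gaps 2000
  # adjacency is distance 0 (bp-gap convention)
  mc4 <- mark_category(gene, make_peaks("chr1", 110000, 111000),
                       make_peaks("chr2", 0, 10), 10000L)
  expect_equal(mc4$distance_k9, 0L)
  expect_equal(mc4$category, "H3K9me3_only")
  expect_true(is.na(mc4$distance_k27))         # no k27 peak on the chromosome
})

test_that("mark categories summarize and partition; planted 23/9/7/21 gives 38/15/12/35", {
  # plant 60 gene loci with mark-peak geometry producing the category split
  n <- c(H3K9me3_only = 23L, H3K27me3_only = 9L, both = 7L, none = 21L)
  genes <- make_genes("chr1", s <- seq(0, by = 100000L, length.out = 60L),
                      s + 10000L, rep("+", 60), sprintf("tf%02d", 1:60))
  cat_of <- rep(names(n), n)
  k9 <- k27 <- list()
  for (i in seq_len(60)) {
    near <- genes$start[i] + 2000L
    if (cat_of[i] %in% c("H3K9me3_only", "both"))
      k9[[length(k9) + 1L]] <- make_peaks("chr1", near, near + 500L,
                                          name = sprintf("k9_%d", i))
    if (cat_of[i] %in% c("H3K27me3_only", "both"))
      k27[[length(k27) + 1L]] <- make_peaks("chr1", near + 100L, near + 600L,
                                            name = sprintf("k27_%d", i))
  }
  cats <- mark_categories(genes, do.call(rbind, k9), do.call(rbind, k27),
                          window = 10000L)
  sm <- summarize_mark_categories(cats)
  expect_equal(stats::setNames(sm$count, sm$category), n)
  expect_equal(sm$pct_rounded[match(c("H3K9me3_only", "H3K27me3_only", "both", "none"),
                                    sm$category)],
               c(38L, 15L, 12L, 35L))
  expect_equal(sum(sm$count), 60L)
  # random categories still partition and percentages sum to 100
  set.seed(2)
  rc <- data.frame(category = sample(names(n), 200, TRUE))
  sr <- summarize_mark_categories(rc)
  expect_equal(sum(sr$count), 200L)
  expect_equal(sum(sr$pct), 100)
  expect_error(summarize_mark_categories(rc[0, , drop = FALSE]), "empty")
})
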