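#' Simulation configuration
#'
#' One structured configuration drives every generator. Defaults state the
#' conditions the pipeline is meant to emulate: a 79-tumor / 42-cell-line
#' expression cohort, an 85-sample survival cohort with a hazard ratio of 3
#' at the median-expression split, nucleus tracks imaged every 2 h over a
#' 96 h horizon (49 frames), and peak sets with planted consecutive
#' GGAA/TTCC runs spanning the five run-length bins.
#'
#' @param seed Integer seed; every generator derives its stream from it.
#' @param genome_length Total genome length in bp, split evenly across
#'   chromosomes.
#' @param n_chromosomes Number of chromosomes.
#' @param planted_runs Data frame with `motif` (`"GGAA"`/`"TTCC"`), `n`
#'   (copies per run), `count` (runs to plant); total count must not exceed
#'   `n_peaks` (at most one planted run per peak). Default: per run-length
#'   bin `n` = 1..5, 10% of peaks carry a GGAA run and 5% a TTCC run.
#' @param n_peaks,peak_width Peak count and width in bp.
#' @param n_genes Gene-model count.
#' @param de_fraction_up,de_fraction_down Fractions of genes planted as
#'   up-/down-regulated (sum <= 1).
#' @param de_effect_log2 Planted |log2 fold-change| for true DEGs.
#' @param cohort_n_tumors,cohort_n_celllines Cohort sample sizes.
#' @param cohort_n_genes Genes in the simulated cohort matrices.
#' @param n_shifted Genes with a planted tumor-vs-cell-line location shift.
#' @param shift_delta Planted shift on the log scale (0 = null cohort).
#' @param n_correlated Target genes correlated with the planted regulator.
#' @param planted_rho Planted regulator-target correlation, |rho| < 1.
#' @param survival_n Survival-cohort size.
#' @param hazard_ratio Hazard ratio of the high-expression group.
#' @param baseline_hazard Exponential baseline hazard (events per time unit).
#' @param censor_max Upper bound of the uniform censoring time.
#' @param n_tracks Number of simulated nucleus tracks.
#' @param n_frames Frames per track (49 = 96 h at 2 h intervals).
#' @param frame_interval Hours between frames.
#' @param speed Directed-track speed in px/frame.
#' @param jitter Confined-track jitter SD in px.
#' @param quality_mean Mean detection quality (SD fixed at 10).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 200000L, n_chromosomes = 2L,
                       planted_runs = NULL,
                       n_peaks = 200L, peak_width = 400L,
                       n_genes = 100L,
                       de_fraction_up = 0.1, de_fraction_down = 0.1,
                       de_effect_log2 = 1.0,
                       cohort_n_tumors = 79L, cohort_n_celllines = 42L,
                       cohort_n_genes = 1000L, n_shifted = 10L,
                       shift_delta = 2.0,
                       n_correlated = 1L, planted_rho = 0.9,
                       survival_n = 85L, hazard_ratio = 3.0,
                       baseline_hazard = 0.05, censor_max = 60,
                       n_tracks = 20L, n_frames = 49L, frame_interval = 2,
                       speed = 5, jitter = 1, quality_mean = 150) {
  cfg <- as.list(environment())
  if (is.null(cfg$planted_runs))
    # default: 10% of peaks per GGAA bin, 5% per TTCC bin, bins n = 1..>4
    cfg$planted_runs <- data.frame(
      motif = rep(c("GGAA", "TTCC"), each = 5L),
      n = rep(c(1L, 2L, 3L, 4L, 5L), 2L),
      count = rep(c(n_peaks %/% 10L, n_peaks %/% 20L), each = 5L))
  stopifnot(cfg$n_peaks >= 0, cfg$n_genes >= 1, cfg$peak_width >= 8,
            abs(cfg$planted_rho) < 1, cfg$n_frames >= 2,
            all(cfg$planted_runs$n >= 1), all(cfg$planted_runs$count >= 0))
  if (cfg$de_fraction_up + cfg$de_fraction_down > 1)
    stop("de fractions sum above 1")
  if (sum(cfg$planted_runs$count) > cfg$n_peaks)
    stop("more planted runs than peaks (one run per peak)")
  class(cfg) <- "sim_config"
  cfg
}

# per-stage substream so inserting a stage never perturbs another stage's draws
.stage_seed <- function(cfg, stage) {
  offs <- c(genome = 101L, de = 211L, cohort = 307L, survival = 401L,
            tracks = 503L)
  (as.integer(cfg$seed) + offs[[stage]]) %% .Machine$integer.max
}

# maximal (motif)+ runs via regex; the generator/oracle-side scan, kept
# independent of find_motif_runs()
.regex_runs <- function(sequence, motif) {
  m <- gregexpr(paste0("(?:", motif, ")+"), sequence, perl = TRUE)[[1L]]
  if (m[1L] == -1L)
    return(data.frame(start = integer(), n = integer()))
  data.frame(start = as.integer(m) - 1L,
             n = as.integer(attr(m, "match.length")) %/% 4L)
}

.OTHER_BASE <- c(G = "C", A = "C", T = "G", C = "G")

# mutate one base inside every unwanted n>=2 run until only the planted
# (exact start/length) runs remain; accidental singletons are left alone
.break_unwanted_runs <- function(chars, planted) {
  for (iter in 1:100) {
    seqstr <- paste(chars, collapse = "")
    dirty <- FALSE
    for (motif in c("GGAA", "TTCC")) {
      runs <- .regex_runs(seqstr, motif)
      ok <- planted[planted$motif == motif, , drop = FALSE]
      for (i in seq_len(nrow(runs))) {
        if (runs$n[i] < 2L) next
        if (any(ok$pos == runs$start[i] & ok$n == runs$n[i])) next
        # mutate the first base of the copy just past any planted footprint
        s <- runs$start[i]; cand <- s + 4L
        while (.in_footprint(cand, planted)) cand <- cand + 4L
        if (cand >= s + 4L * runs$n[i]) cand <- s   # run is a planted suffix
        chars[cand + 1L] <- .OTHER_BASE[[chars[cand + 1L]]]
        dirty <- TRUE
      }
    }
    if (!dirty) return(chars)
  }
  stop("could not sanitize accidental motif runs")
}

.in_footprint <- function(pos0, planted) {
  nrow(planted) > 0L &&
    any(pos0 >= planted$pos & pos0 < planted$pos + 4L * planted$n)
}

#' Simulate a genome and summit-bearing peak set with planted GGAA/TTCC runs
#'
#' Background sequence is uniform over \{A,C,G,T\}; accidental consecutive
#' runs of two or more motif copies are broken by base substitution (isolated
#' accidental singletons may remain). Peaks are non-overlapping with summits
#' at their centers; each planted run is placed at a drawn offset within the
#' profiling window around one peak's summit, with flanking bases substituted
#' so the run cannot extend. The truth table comes from an independent
#' post-generation regex scan of every profiling window, so it records
#' exactly what a maximal-run profiler must find (planted runs flagged).
#'
#' @param config A [sim_config()].
#' @param dir Optional directory; when given, writes `genome.fa`,
#'   `peaks.narrowPeak` and `truth_runs.tsv`.
#' @param window Profiling window width the planted offsets respect
#'   (default 500).
#' @return List with `genome` (`DNAStringSet`), `peaks` (peak data frame),
#'   and `truth` (data frame: `peak_name`, `chrom`, `pos`,
#'   `offset_from_summit`, `motif`, `n`, `planted`).
#' @export
simulate_genome_and_peaks <- function(config, dir = NULL, window = 500L) {
  set.seed(.stage_seed(config, "genome"))
  n_chr <- config$n_chromosomes
  chr_len <- config$genome_length %/% n_chr
  per_chr <- diff(round(seq(0, config$n_peaks, length.out = n_chr + 1L)))
  slot <- if (config$n_peaks > 0) chr_len %/% max(per_chr) else chr_len
  if (config$n_peaks > 0 && slot < max(config$peak_width, window) + 20L)
    stop("infeasible packing: too many peaks for genome length")

  half <- window %/% 2L
  runs_todo <- config$planted_runs[rep(seq_len(nrow(config$planted_runs)),
                                       config$planted_runs$count),
                                   c("motif", "n"), drop = FALSE]
  run_i <- 1L; pk <- 0L
  chrom_names <- paste0("chr", seq_len(n_chr))
  chrom_seqs <- character(n_chr)
  peaks <- vector("list", config$n_peaks)
  for (ci in seq_len(n_chr)) {
    chars <- sample(c("A", "C", "G", "T"), chr_len, replace = TRUE)
    planted <- data.frame(pos = integer(), motif = character(), n = integer())
    for (pi in seq_len(per_chr[ci])) {
      pk <- pk + 1L
      start <- (pi - 1L) * slot +
        sample.int(max(1L, slot - config$peak_width - 1L), 1L) - 1L
      summit_off <- config$peak_width %/% 2L
      summit <- start + summit_off
      peaks[[pk]] <- data.frame(
        chrom = chrom_names[ci], start = start, end = start + config$peak_width,
        name = sprintf("peak_%04d", pk),
        score = round(stats::runif(1, 100, 1000)), strand = ".",
        signal = round(stats::runif(1, 2, 20), 3),
        pvalue_neglog10 = round(stats::runif(1, 3, 30), 3),
        qvalue_neglog10 = round(stats::runif(1, 2, 25), 3),
        summit_offset = summit_off, stringsAsFactors = FALSE)
      if (run_i <= nrow(runs_todo)) {
        motif <- runs_todo$motif[run_i]; nrep <- runs_todo$n[run_i]
        run_i <- run_i + 1L
        foot <- 4L * nrep
        lo <- max(summit - half + 1L, 1L)
        hi <- min(summit + half - foot - 1L, chr_len - foot - 2L)
        if (hi < lo) stop("planted run footprint does not fit in the window")
        pos <- if (hi == lo) lo else sample(lo:hi, 1L)   # 0-based run start
        mc <- strsplit(motif, "")[[1L]]
        chars[(pos + 1L):(pos + foot)] <- rep(mc, nrep)
        # flanking breakers: a previous copy needs its last base at pos-1,
        # a next copy needs its first base at pos+foot
        if (chars[pos] == mc[4L]) chars[pos] <- .OTHER_BASE[[mc[4L]]]
        if (chars[pos + foot + 1L] == mc[1L])
          chars[pos + foot + 1L] <- .OTHER_BASE[[mc[1L]]]
        planted <- rbind(planted,
                         data.frame(pos = pos, motif = motif, n = nrep))
      }
    }
    chars <- .break_unwanted_runs(chars, planted)
    chrom_seqs[ci] <- paste(chars, collapse = "")
    attr(chrom_seqs, paste0("planted_", ci)) <- planted
  }
  names(chrom_seqs) <- chrom_names
  peaks <- do.call(rbind, peaks)

  truth <- do.call(rbind, lapply(seq_len(NROW(peaks)), function(i) {
    p <- peaks[i, ]
    ci <- match(p$chrom, chrom_names)
    planted <- attr(chrom_seqs, paste0("planted_", ci))
    summit <- p$start + p$summit_offset
    wlo <- max(0L, summit - half); whi <- min(chr_len, summit + half)
    win <- substr(chrom_seqs[[ci]], wlo + 1L, whi)
    do.call(rbind, lapply(c("GGAA", "TTCC"), function(m) {
      r <- .regex_runs(win, m)
      if (!nrow(r)) return(NULL)
      pos <- wlo + r$start
      ok <- planted[planted$motif == m, , drop = FALSE]
      mi <- match(pos, ok$pos)
      data.frame(peak_name = p$name, chrom = p$chrom, pos = pos,
                 offset_from_summit = pos - summit, motif = m, n = r$n,
                 planted = !is.na(mi) & ok$n[mi] == r$n,
                 stringsAsFactors = FALSE)
    }))
  }))
  if (is.null(truth))
    truth <- data.frame(peak_name = character(), chrom = character(),
                        pos = integer(), offset_from_summit = integer(),
                        motif = character(), n = integer(), planted = logical())
  rownames(truth) <- NULL
  out <- list(genome = Biostrings::DNAStringSet(chrom_seqs),
              peaks = peaks, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_genome(out$genome, file.path(dir, "genome.fa"))
    write_intervals(peaks, file.path(dir, "peaks.narrowPeak"), "narrowPeak")
    write_table(truth, file.path(dir, "truth_runs.tsv"),
                params = list(seed = config$seed, window = window))
  }
  out
}

#' Simulate gene models and a differential-expression table with planted DEGs
#'
#' Genes are non-overlapping spans with random strands. A planted fraction of
#' genes is up-regulated at `+de_effect_log2` and a fraction down-regulated at
#' `-de_effect_log2`, both with FDR drawn uniformly below 0.05; null genes
#' have `log2fc ~ N(0, 0.1)` and `fdr ~ U(0.05, 1)`, so a threshold filter at
#' FDR < 0.05 recovers the planted labels exactly.
#'
#' @param config A [sim_config()].
#' @param dir Optional directory; writes `genes.bed`, `de.tsv`,
#'   `truth_de.tsv`.
#' @return List with `genes` (gene-model data frame), `de` (DE data frame),
#'   `truth` (`gene_id`, `label` in up/down/null).
#' @export
simulate_gene_models_and_de <- function(config, dir = NULL) {
  set.seed(.stage_seed(config, "de"))
  ng <- config$n_genes
  n_chr <- config$n_chromosomes
  chr_len <- config$genome_length %/% n_chr
  per_chr <- diff(round(seq(0, ng, length.out = n_chr + 1L)))
  slot <- chr_len %/% max(per_chr)
  gene_len <- max(200L, min(2000L, slot %/% 2L))
  if (slot < gene_len + 2L) stop("infeasible packing: too many genes")
  rows <- list(); gi <- 0L
  for (ci in seq_len(n_chr)) {
    for (pi in seq_len(per_chr[ci])) {
      gi <- gi + 1L
      start <- (pi - 1L) * slot + sample.int(slot - gene_len - 1L, 1L) - 1L
      rows[[gi]] <- data.frame(
        chrom = paste0("chr", ci), start = start, end = start + gene_len,
        gene_id = sprintf("GENE%04d", gi), score = 0,
        strand = sample(c("+", "-"), 1L), stringsAsFactors = FALSE)
    }
  }
  genes <- do.call(rbind, rows)
  n_up <- round(config$de_fraction_up * ng)
  n_down <- round(config$de_fraction_down * ng)
  label <- rep("null", ng)
  idx <- sample.int(ng, n_up + n_down)
  label[idx[seq_len(n_up)]] <- "up"
  label[idx[n_up + seq_len(n_down)]] <- "down"
  log2fc <- stats::rnorm(ng, 0, 0.1)
  fdr <- stats::runif(ng, 0.05, 1)
  log2fc[label == "up"] <- config$de_effect_log2
  log2fc[label == "down"] <- -config$de_effect_log2
  fdr[label != "null"] <- stats::runif(n_up + n_down, 0, 0.05 - 1e-9)
  de <- data.frame(gene_id = genes$gene_id, log2fc = log2fc, fdr = fdr,
                   stringsAsFactors = FALSE)
  truth <- data.frame(gene_id = genes$gene_id, label = label,
                      stringsAsFactors = FALSE)
  out <- list(genes = genes, de = de, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    b <- genes; b$name <- b$gene_id
    write_intervals(b[, c("chrom", "start", "end", "name", "score", "strand")],
                    file.path(dir, "genes.bed"), "bed6")
    write_table(de, file.path(dir, "de.tsv"),
                params = list(seed = config$seed))
    write_table(truth, file.path(dir, "truth_de.tsv"))
  }
  out
}

#' Simulate a tumor / cell-line expression cohort
#'
#' Log-normal expression (exponentiated Gaussian draws, mimicking RPKM-like
#' skew). Planted "shifted" genes have tumor draws with Gaussian mean raised
#' by `shift_delta` relative to cell lines; a planted regulator gene and
#' `n_correlated` target genes are drawn (within each cohort) from a
#' bivariate normal with correlation `planted_rho` before exponentiation;
#' all other genes are independent null genes.
#'
#' @param config A [sim_config()].
#' @param dir Optional directory; writes `tumors.tsv`, `celllines.tsv`,
#'   `truth_cohort.tsv`.
#' @return List with `tumors`, `celllines` (numeric matrices, shared gene
#'   rownames `REGULATOR`, `GENE....`), `truth` (`gene_id`, `role` in
#'   regulator/correlated/shifted/null, `rho`, `shift`).
#' @export
simulate_cohort <- function(config, dir = NULL) {
  set.seed(.stage_seed(config, "cohort"))
  nt <- config$cohort_n_tumors; nc <- config$cohort_n_celllines
  stopifnot(nt >= 3, nc >= 3)
  ng <- config$cohort_n_genes
  rho <- config$planted_rho
  n_corr <- config$n_correlated
  n_shift <- config$n_shifted
  if (1L + n_corr + n_shift > ng) stop("planted genes exceed cohort_n_genes")
  gene_ids <- c("REGULATOR", sprintf("GENE%04d", seq_len(ng - 1L)))
  role <- c("regulator",
            rep("correlated", n_corr),
            rep("shifted", n_shift),
            rep("null", ng - 1L - n_corr - n_shift))
  mu <- 1; sigma <- 1
  draw <- function(ns) {
    z_reg <- stats::rnorm(ns)
    z <- matrix(stats::rnorm(ng * ns), nrow = ng)
    z[1L, ] <- z_reg
    corr_rows <- which(role == "correlated")
    for (i in corr_rows)
      z[i, ] <- rho * z_reg + sqrt(1 - rho^2) * stats::rnorm(ns)
    z
  }
  zt <- draw(nt); zc <- draw(nc)
  zt[role == "shifted", ] <- zt[role == "shifted", , drop = FALSE] +
    config$shift_delta
  tumors <- exp(mu + sigma * zt)
  celllines <- exp(mu + sigma * zc)
  dimnames(tumors) <- list(gene_ids, sprintf("tumor%03d", seq_len(nt)))
  dimnames(celllines) <- list(gene_ids, sprintf("cellline%03d", seq_len(nc)))
  truth <- data.frame(gene_id = gene_ids, role = role,
                      rho = ifelse(role == "correlated", rho, 0),
                      shift = ifelse(role == "shifted", config$shift_delta, 0),
                      stringsAsFactors = FALSE)
  out <- list(tumors = tumors, celllines = celllines, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_table(tumors, file.path(dir, "tumors.tsv"))
    write_table(celllines, file.path(dir, "celllines.tsv"))
    write_table(truth, file.path(dir, "truth_cohort.tsv"),
                params = list(seed = config$seed))
  }
  out
}

#' Simulate a survival cohort with a planted hazard difference
#'
#' Expression is standard normal; the high-expression half (above the median)
#' has exponential event times at `baseline_hazard * hazard_ratio`, the low
#' half at `baseline_hazard`; censoring is uniform on `(0, censor_max)`.
#'
#' @param config A [sim_config()].
#' @param dir Optional directory; writes `survival.tsv`.
#' @return Data frame with `sample_id`, `time`, `event`, `expression`, and
#'   truth column `true_group` (high/low).
#' @export
simulate_survival <- function(config, dir = NULL) {
  set.seed(.stage_seed(config, "survival"))
  n <- config$survival_n
  expr <- stats::rnorm(n)
  high <- expr > stats::median(expr)
  rate <- config$baseline_hazard * ifelse(high, config$hazard_ratio, 1)
  t_event <- stats::rexp(n, rate)
  t_cens <- stats::runif(n, 0, config$censor_max)
  rec <- data.frame(
    sample_id = sprintf("s%03d", seq_len(n)),
    time = pmin(t_event, t_cens),
    event = as.integer(t_event <= t_cens),
    expression = expr,
    true_group = ifelse(high, "high", "low"),
    stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_table(rec, file.path(dir, "survival.tsv"),
                params = list(seed = config$seed,
                              hazard_ratio = config$hazard_ratio))
  }
  rec
}

#' Simulate nucleus-detection tracks with known path lengths
#'
#' Alternating directed (constant velocity at `speed` px/frame, random
#' heading) and confined (zero-mean Gaussian jitter, SD `jitter`) tracks on a
#' grid of well-separated start positions, with per-frame quality
#' `N(quality_mean, 10)`. The truth path length is the exact sum of step
#' distances of the emitted coordinates.
#'
#' @param config A [sim_config()].
#' @param dir Optional directory; writes `detections.tsv`,
#'   `truth_tracks.tsv`.
#' @return List with `detections` (data frame `track_id`, `frame`, `x`, `y`,
#'   `quality`) and `truth` (`track_id`, `type`, `n_points`, `path_length`,
#'   `mean_quality`).
#' @export
simulate_tracks <- function(config, dir = NULL) {
  set.seed(.stage_seed(config, "tracks"))
  nt <- config$n_tracks; nf <- config$n_frames
  stopifnot(nt >= 1)
  grid <- ceiling(sqrt(nt))
  spacing <- 800 / grid
  rows <- vector("list", nt); truth <- vector("list", nt)
  for (i in seq_len(nt)) {
    type <- if (i %% 2L == 1L) "directed" else "confined"
    x0 <- ((i - 1L) %% grid + 0.5) * spacing
    y0 <- ((i - 1L) %/% grid + 0.5) * spacing
    if (type == "directed") {
      th <- stats::runif(1, 0, 2 * pi)
      # reflect heading toward the field center so tracks stay in frame
      steps_x <- rep(cos(th) * config$speed, nf - 1L)
      steps_y <- rep(sin(th) * config$speed, nf - 1L)
      reach <- config$speed * (nf - 1L)
      if (x0 + sum(steps_x) < 0 || x0 + sum(steps_x) > 800) steps_x <- -steps_x
      if (y0 + sum(steps_y) < 0 || y0 + sum(steps_y) > 800) steps_y <- -steps_y
    } else {
      steps_x <- stats::rnorm(nf - 1L, 0, config$jitter)
      steps_y <- stats::rnorm(nf - 1L, 0, config$jitter)
    }
    x <- x0 + c(0, cumsum(steps_x))
    y <- y0 + c(0, cumsum(steps_y))
    q <- stats::rnorm(nf, config$quality_mean, 10)
    id <- sprintf("track_%03d", i)
    rows[[i]] <- data.frame(track_id = id, frame = seq_len(nf) - 1L,
                            x = x, y = y, quality = q,
                            stringsAsFactors = FALSE)
    truth[[i]] <- data.frame(
      track_id = id, type = type, n_points = nf,
      path_length = sum(sqrt(diff(x)^2 + diff(y)^2)),
      mean_quality = mean(q), stringsAsFactors = FALSE)
  }
  out <- list(detections = do.call(rbind, rows),
              truth = do.call(rbind, truth))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_table(out$detections, file.path(dir, "detections.tsv"),
                params = list(seed = config$seed))
    write_table(out$truth, file.path(dir, "truth_tracks.tsv"))
  }
  out
}
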