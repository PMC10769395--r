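test_that("sim_config validates fractions, rho and packing", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(de_fraction_up = 0.7, de_fraction_down = 0.5), "sum")
  expect_error(sim_config(planted_rho = 1), "planted_rho")
  expect_error(sim_config(n_peaks = 5,
                          planted_runs = data.frame(motif = "GGAA", n = 2,
                                                    count = 6)),
               "more planted runs")
  expect_error(simulate_genome_and_peaks(
    sim_config(genome_length = 10000, n_peaks = 500)), "infeasible packing")
})

test_that("planted runs appear verbatim at their truth coordinates", {
  cfg <- sim_config(seed = 41, n_peaks = 30, genome_length = 60000,
                    n_chromosomes = 1,
                    planted_runs = data.frame(motif = c("GGAA", "TTCC"),
                                              n = c(3L, 5L), count = c(4L, 3L)))
  sim <- simulate_genome_and_peaks(cfg)
  tr <- sim$truth[sim$truth$planted, ]
  expect_equal(nrow(tr), 7L)
  seqs <- as.character(sim$genome)
  for (i in seq_len(nrow(tr))) {
    s <- substr(seqs[[tr$chrom[i]]], tr$pos[i] + 1L, tr$pos[i] + 4L * tr$n[i])
    expect_equal(s, strrep(tr$motif[i], tr$n[i]))
    # flanks do not extend the run
    before <- substr(seqs[[tr$chrom[i]]], tr$pos[i] - 3L, tr$pos[i])
    after <- substr(seqs[[tr$chrom[i]]], tr$pos[i] + 4L * tr$n[i] + 1L,
                    tr$pos[i] + 4L * tr$n[i] + 4L)
    expect_false(before == tr$motif[i])
    expect_false(after == tr$motif[i])
  }
  # every planted run lies within +/-250 bp of its peak summit
  expect_true(all(tr$offset_from_summit >= -250 &
                  tr$offset_from_summit + 4 * tr$n <= 250))
})

test_that("with no planted runs, windows contain no n >= 2 accidental runs", {
  cfg <- sim_config(seed = 42, n_peaks = 10, genome_length = 20000,
                    n_chromosomes = 1,
                    planted_runs = data.frame(motif = character(),
                                              n = integer(), count = integer()))
  sim <- simulate_genome_and_peaks(cfg)
  expect_true(all(sim$truth$n == 1L))       # singletons may occur by chance
  expect_true(all(!sim$truth$planted))
  # truth equals an independent regex scan of each emitted window
  for (i in seq_len(nrow(sim$peaks))) {
    p <- sim$peaks[i, ]
    w <- extract_summit_window(p, sim$genome, 500)
    found <- sum(nrow(oracle_runs(w, "GGAA")), nrow(oracle_runs(w, "TTCC")))
    expect_equal(sum(sim$truth$peak_name == p$name), found)
  }
})

test_that("generators are deterministic: same config, byte-identical outputs", {
  cfg <- sim_config(seed = 43, n_peaks = 20, genome_length = 40000,
                    n_genes = 20, cohort_n_genes = 30, n_tracks = 4)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  for (d in c(d1, d2)) {
    simulate_genome_and_peaks(cfg, dir = d)
    simulate_gene_models_and_de(cfg, dir = d)
    simulate_cohort(cfg, dir = d)
    simulate_survival(cfg, dir = d)
    simulate_tracks(cfg, dir = d)
  }
  f1 <- list.files(d1); f2 <- list.files(d2)
  expect_identical(f1, f2)
  for (f in f1)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
})

test_that("DE generator plants exact up/down counts recoverable at the thresholds", {
  cfg <- sim_config(seed = 44, n_genes = 100)
  gd <- simulate_gene_models_and_de(cfg)
  expect_equal(sum(gd$truth$label == "up"), 10L)
  expect_equal(sum(gd$truth$label == "down"), 10L)
  expect_true(all(gd$genes$strand %in% c("+", "-")))
  # gene spans non-overlapping per chromosome
  for (ch in unique(gd$genes$chrom)) {
    g <- gd$genes[gd$genes$chrom == ch, ]
    g <- g[order(g$start), ]
    expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
  }
})

test_that("cohort generator plants recoverable correlation and shift structure", {
  cfg <- sim_config(seed = 45)
  co <- simulate_cohort(cfg)
  expect_equal(dim(co$tumors), c(1000L, 79L))
  expect_equal(dim(co$celllines), c(1000L, 42L))
  expect_true(all(co$tumors >= 0))
  pair <- co$truth$gene_id[co$truth$role == "correlated"][1]
  r <- cor(log(co$tumors["REGULATOR", ]), log(co$tumors[pair, ]))
  expect_lt(abs(r - 0.9), 0.15)
})

test_that("survival generator plants the stated group hazard structure", {
  cfg <- sim_config(seed = 46)
  sv <- simulate_survival(cfg)
  expect_equal(nrow(sv), 85L)
  expect_setequal(unique(sv$event), c(0L, 1L))
  expect_equal(sum(sv$true_group == "high"), 42L)   # above-median half of 85
  expect_identical(sv$true_group, ifelse(sv$expression > median(sv$expression),
                                         "high", "low"))
})

test_that("directed tracks have exact arithmetic truth lengths", {
  cfg <- sim_config(seed = 47, n_tracks = 2, speed = 5, jitter = 0)
  sim <- simulate_tracks(cfg)
  dir <- sim$truth[sim$truth$type == "directed", ]
  expect_equal(dir$path_length, 5 * 48)
  conf <- sim$truth[sim$truth$type == "confined", ]
  expect_equal(conf$path_length, 0)               # jitter 0 -> no movement
})
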