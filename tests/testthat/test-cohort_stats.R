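test_that("welch_t matches t.test and honors degenerate conventions", {
  set.seed(14)
  for (i in 1:25) {
    a <- rnorm(sample(3:40, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(3:40, 1), mean = runif(1, -1, 1))
    got <- welch_t(a, b)
    ref <- t.test(a, b)                      # Welch is t.test's default
    expect_equal(got$statistic, unname(ref$statistic))
    expect_equal(got$df, unname(ref$parameter))
    expect_equal(got$p, ref$p.value)
  }
  x <- c(1, 2, 3)
  same <- welch_t(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  sw <- welch_t(c(0, 1), c(5, 6))
  expect_equal(welch_t(c(5, 6), c(0, 1))$statistic, -sw$statistic)
  expect_equal(welch_t(c(5, 6), c(0, 1))$p, sw$p)
  expect_equal(welch_t(c(2, 2), c(2, 2))$p, 1)   # zero variance, equal means
  expect_error(welch_t(1, c(1, 2)), ">= 2")
})

test_that("welch detects a 1-SD shift at n = 42 vs 79 almost always", {
  set.seed(15)
  hits <- replicate(200, welch_t(rnorm(79, 1), rnorm(42, 0))$p < 0.01)
  expect_gte(mean(hits), 0.99)
})

test_that("bh_fdr implements the step-up rule and matches p.adjust", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0,1\\]")
  set.seed(16)
  for (i in 1:20) {
    p <- runif(sample(1:200, 1))^sample(1:3, 1)
    q <- bh_fdr(p)
    expect_equal(q, p.adjust(p, "BH"))
    expect_true(all(q >= p))
    o <- sample(length(p))
    expect_equal(bh_fdr(p[o]), q[o])         # permutation equivariance
  }
})

test_that("range_screen recovers planted shifts and returns empty on identical matrices", {
  cfg <- sim_config(seed = 17)
  co <- simulate_cohort(cfg)
  rs <- range_screen(co$tumors, co$celllines)
  shifted <- co$truth$gene_id[co$truth$role == "shifted"]
  expect_true(all(shifted %in% rs$pass))
  expect_equal(range_screen(co$tumors, co$tumors)$pass, character())
  miss <- range_screen(co$tumors, co$celllines, genes = c("NOPE", shifted[1]))
  expect_equal(miss$skipped, "NOPE")
})

test_that("correlation_screen finds a perfect and planted correlate, flags constants", {
  cfg <- sim_config(seed = 18)
  co <- simulate_cohort(cfg)
  m <- co$tumors
  m <- rbind(m, SELF = m["REGULATOR", ], FLAT = rep(3, ncol(m)))
  cs <- correlation_screen(m, "REGULATOR", c("SELF", "FLAT", "GENE0001"))
  expect_equal(cs$r[cs$gene_id == "SELF"], 1)
  expect_true(cs$degenerate[cs$gene_id == "FLAT"])
  expect_false(cs$pass[cs$gene_id == "FLAT"])
  expect_true(cs$pass[cs$gene_id == "GENE0001"])   # planted rho = 0.9
  expect_true(all(cs$q >= cs$p, na.rm = TRUE))
})

test_that("spearman screen is invariant to monotone transforms", {
  cfg <- sim_config(seed = 19, cohort_n_genes = 50, n_correlated = 5)
  co <- simulate_cohort(cfg)
  cands <- co$truth$gene_id[-1]
  a <- correlation_screen(co$tumors, "REGULATOR", cands, method = "spearman")
  b <- correlation_screen(co$tumors^3, "REGULATOR", cands, method = "spearman")
  expect_equal(a$r, b$r)
  expect_equal(a$q, b$q)
})

test_that("quartile_concordance takes ceil(N/4) top samples and an inclusive median rule", {
  cfg <- sim_config(seed = 20)
  co <- simulate_cohort(cfg)
  qc <- quartile_concordance(co$tumors, "REGULATOR", "GENE0001")
  expect_equal(qc$n, 20L)                    # ceil(79/4)
  # perfectly rank-correlated target
  m <- co$tumors
  m <- rbind(m, TWIN = 2 * m["REGULATOR", ])
  expect_equal(quartile_concordance(m, "REGULATOR", "TWIN")$k, 20L)
  # invariance under strictly increasing transform of the target
  m2 <- m; m2["GENE0001", ] <- exp(m2["GENE0001", ])
  expect_equal(quartile_concordance(m2, "REGULATOR", "GENE0001")$k, qc$k)
  # independent target: k/n near 1/2 on average
  set.seed(20)
  ks <- replicate(400, {
    mm <- matrix(rexp(2 * 79), 2, dimnames = list(c("r", "t"), NULL))
    quartile_concordance(mm, "r", "t")$k
  })
  expect_lt(abs(mean(ks / 20) - 0.5), 3 * sd(ks / 20) / sqrt(400) + 0.03)
})

test_that("km_logrank produces valid curves and sane degenerate behavior", {
  cfg <- sim_config(seed = 22)
  sv <- simulate_survival(cfg)
  km <- km_logrank(sv)
  expect_true(all(diff(km$high$survival) <= 1e-12))
  expect_true(all(km$high$survival >= 0 & km$high$survival <= 1))
  expect_equal(km$n_high + km$n_low, nrow(sv))
  # no events at all -> flat curves, chi2 = 0, p = 1
  none <- data.frame(time = 1:10, event = 0, expression = rep(c(0, 1), 5))
  km0 <- km_logrank(none, split = 0.5)
  expect_equal(km0$chi2, 0)
  expect_equal(km0$p, 1)
  expect_true(all(km0$high$survival == 1))
  # identical groups duplicated -> chi2 exactly 0
  half <- data.frame(time = c(1, 2, 3, 4), event = c(1, 1, 0, 1))
  dup <- rbind(cbind(half, expression = 0), cbind(half, expression = 1))
  expect_equal(km_logrank(dup, split = 0.5)$chi2, 0)
  expect_error(km_logrank(data.frame(time = 1:3, event = 1,
                                     expression = c(1, 1, 0)), split = 0.5),
               "< 2 records")
})

test_that("KM estimator equals the empirical survival function without censoring", {
  set.seed(23)
  tm <- rexp(60)
  rec <- data.frame(time = tm, event = 1, expression = rep(c(0, 1), 30))
  km <- km_logrank(rec, split = 0.5)
  hi <- rec$time[rec$expression > 0.5]
  ecdf_surv <- vapply(km$high$time, function(t) mean(hi > t), 0)
  expect_equal(km$high$survival, ecdf_surv)
})

test_that("ddct fold change follows 2^-ddCt", {
  expect_equal(ddct_fold_change(c(25, 20), c(27, 20)), 4)
  expect_equal(ddct_fold_change(c(25, 20), c(25, 20)), 1)
  expect_equal(ddct_fold_change(list(ct_target = 30, ct_reference = 22),
                                list(ct_target = 28, ct_reference = 21)), 0.5)
  set.seed(24)
  for (i in 1:20) {
    ct <- runif(4, 15, 35)
    expect_equal(ddct_fold_change(ct[1:2], ct[3:4]),
                 2^-((ct[1] - ct[2]) - (ct[3] - ct[4])))
  }
  expect_error(ddct_fold_change(c(NA, 20), c(27, 20)), "finite")
})
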