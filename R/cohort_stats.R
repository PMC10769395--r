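#' Welch's unpaired two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value. Implemented directly so degenerate inputs have the
#' documented conventions: when both variances are zero and the means are
#' equal, `t = 0` and `p = 1`.
#'
#' @param group_a,group_b Numeric vectors, each with at least 2 finite values.
#' @return List with `statistic` (sign of `mean(a) - mean(b)`), `df`, `p`
#'   (two-sided), `p_greater` (one-sided, A greater), and `direction`.
#' @export
welch_t <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2L || nb < 2L) stop("each group needs >= 2 values")
  ma <- mean(group_a); mb <- mean(group_b)
  va <- stats::var(group_a); vb <- stats::var(group_b)
  se2 <- va / na + vb / nb
  if (se2 == 0) {
    t <- if (ma == mb) 0 else sign(ma - mb) * Inf
    df <- na + nb - 2
  } else {
    t <- (ma - mb) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  p <- if (is.infinite(t)) 0 else 2 * stats::pt(-abs(t), df)
  p_greater <- if (is.infinite(t)) (if (t > 0) 0 else 1) else
    stats::pt(t, df, lower.tail = FALSE)
  list(statistic = t, df = df, p = min(1, p), p_greater = p_greater,
       direction = sign(ma - mb))
}

#' Screen for genes expressed higher in tumors than cell lines
#'
#' One-directional Welch screen: a gene passes when its tumor mean exceeds the
#' cell-line mean and the one-sided Welch p-value (tumors greater) is below
#' `p_cut`. By default values are log2(x + 1)-transformed first — RPKM-like
#' values are strongly right-skewed and the t-test only calibrates near its
#' nominal level on the log scale (the same transform the correlation screen
#' applies before Pearson). Genes missing from either matrix are skipped and
#' reported.
#'
#' @param tumors,celllines Numeric expression matrices (genes x samples, gene
#'   rownames).
#' @param genes Character vector of gene ids to screen (default: genes shared
#'   by both matrices).
#' @param p_cut One-sided p cutoff (default 0.01).
#' @param log_transform Apply log2(x + 1) before testing (default `TRUE`).
#' @return List with `pass` (gene ids), `table` (per-gene statistic, df, p),
#'   and `skipped` (genes absent from either matrix).
#' @export
range_screen <- function(tumors, celllines, genes = NULL, p_cut = 0.01,
                         log_transform = TRUE) {
  if (log_transform) {
    tumors <- log2(tumors + 1)
    celllines <- log2(celllines + 1)
  }
  if (is.null(genes))
    genes <- intersect(rownames(tumors), rownames(celllines))
  present <- genes %in% rownames(tumors) & genes %in% rownames(celllines)
  skipped <- genes[!present]
  genes <- genes[present]
  res <- lapply(genes, function(g)
    welch_t(tumors[g, ], celllines[g, ]))
  tab <- data.frame(
    gene_id = genes,
    statistic = vapply(res, `[[`, 0, "statistic"),
    df = vapply(res, `[[`, 0, "df"),
    p = vapply(res, `[[`, 0, "p_greater"),
    stringsAsFactors = FALSE)
  list(pass = tab$gene_id[tab$p < p_cut & tab$statistic > 0],
       table = tab, skipped = skipped)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' `q_i = min_(j >= i) p_(j) * m / j`, clipped to 1, returned in input order.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0,1]")
  m <- length(pvalues)
  if (m == 0L) return(numeric())
  o <- order(pvalues)
  q_sorted <- pmin(1, rev(cummin(rev(pvalues[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  # guard the q >= p identity against float round-off in p * m / j at j = m
  pmax(q, pvalues)
}

#' Correlation screen of candidate genes against a regulator
#'
#' Correlates each candidate's expression with the regulator's across samples
#' and controls the FDR over the candidate set with [bh_fdr()]. For Pearson,
#' values are log2(x + 1)-transformed first (RPKM-like inputs are heavily
#' right-skewed); Spearman works on ranks and needs no transform.
#' Zero-variance candidates have undefined correlation and are flagged,
#' never passed.
#'
#' @param matrix Numeric expression matrix (genes x samples).
#' @param regulator Regulator gene id (row of `matrix`).
#' @param candidates Character vector of candidate gene ids.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param q_cut FDR cutoff defining the pass set (default 0.01).
#' @return `data.frame` with `gene_id`, `r`, `p`, `q`, `pass`, `degenerate`.
#' @export
correlation_screen <- function(matrix, regulator, candidates,
                               method = c("pearson", "spearman"),
                               q_cut = 0.01) {
  method <- match.arg(method)
  if (!regulator %in% rownames(matrix)) stop("regulator not in matrix: ", regulator)
  if (ncol(matrix) < 3L) stop("need >= 3 samples")
  x <- matrix[regulator, ]
  if (method == "pearson") x <- log2(x + 1)
  res <- lapply(candidates, function(g) {
    y <- matrix[g, ]
    if (method == "pearson") y <- log2(y + 1)
    if (stats::sd(y) == 0 || stats::sd(x) == 0)
      return(c(r = NA_real_, p = NA_real_, degenerate = 1))
    ct <- stats::cor.test(x, y, method = method, exact = FALSE)
    c(r = unname(ct$estimate), p = ct$p.value, degenerate = 0)
  })
  out <- data.frame(
    gene_id = candidates,
    r = vapply(res, `[[`, 0, "r"),
    p = vapply(res, `[[`, 0, "p"),
    degenerate = vapply(res, `[[`, 0, "degenerate") == 1,
    stringsAsFactors = FALSE)
  q <- rep(NA_real_, nrow(out))
  ok <- !out$degenerate
  q[ok] <- bh_fdr(out$p[ok])
  out$q <- q
  out$pass <- !out$degenerate & out$q < q_cut
  out[, c("gene_id", "r", "p", "q", "pass", "degenerate")]
}

#' Top-quartile / median concordance between regulator and target
#'
#' Takes the `ceil(N/4)` samples with the highest regulator expression (ties
#' broken by sample order) and counts how many of them express the target at
#' or above the cohort-wide median of the target. Reproduces the "16 of the
#' 20 top-quartile tumors" construction at N = 79.
#'
#' @param matrix Numeric expression matrix (genes x samples).
#' @param regulator,target Gene ids (rows of `matrix`).
#' @return List with `k` (concordant count), `n` (top-quartile size), and
#'   `top_samples`.
#' @export
quartile_concordance <- function(matrix, regulator, target) {
  stopifnot(regulator %in% rownames(matrix), target %in% rownames(matrix))
  N <- ncol(matrix)
  if (N < 4L) stop("need >= 4 samples")
  n <- as.integer(ceiling(N / 4))
  reg <- matrix[regulator, ]
  top <- order(-reg)[seq_len(n)]   # stable: ties keep sample order
  tgt <- matrix[target, ]
  med <- stats::median(tgt)
  k <- sum(tgt[top] >= med)
  list(k = as.integer(k), n = n,
       top_samples = colnames(matrix)[top])
}

#' Kaplan-Meier curves and log-rank test at an expression split
#'
#' Splits samples into high/low expression groups at the median (or a given
#' value), fits product-limit survival curves per group, and tests the
#' difference with the two-group log-rank chi-square (1 df). With no events in
#' either group the curves are identically 1 and `chi2 = 0`, `p = 1`.
#'
#' @param records Data frame with `time`, `event` (0/1), `expression`.
#' @param split `"median"` or a numeric cutoff value; high group is
#'   `expression > cutoff`.
#' @return List with `high` and `low` (each a `data.frame` of `time`,
#'   `n_risk`, `survival`), `chi2`, `p`, `cutoff`, `n_high`, `n_low`.
#' @export
km_logrank <- function(records, split = "median") {
  stopifnot(all(records$time >= 0), all(records$event %in% c(0, 1)))
  cutoff <- if (identical(split, "median")) stats::median(records$expression)
            else as.numeric(split)
  high <- records$expression > cutoff
  if (sum(high) < 2L || sum(!high) < 2L)
    stop("a group has < 2 records after split at ", format(cutoff))
  grp <- factor(ifelse(high, "high", "low"), levels = c("low", "high"))
  curve <- function(sel) {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                             data = records[sel, , drop = FALSE])
    data.frame(time = fit$time, n_risk = fit$n.risk, survival = fit$surv)
  }
  if (sum(records$event) == 0) {
    chi2 <- 0; p <- 1
  } else {
    sd <- survival::survdiff(survival::Surv(time, event) ~ grp, data =
                               data.frame(records, grp = grp))
    chi2 <- sd$chisq
    p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  }
  list(high = curve(high), low = curve(!high), chi2 = chi2, p = p,
       cutoff = cutoff, n_high = sum(high), n_low = sum(!high))
}

#' Relative qPCR fold change by the delta-delta-Ct method
#'
#' `2^-ddCt` with `ddCt = (Ct_target - Ct_reference)_treated -
#' (Ct_target - Ct_reference)_control`; Ct values are normalized to a
#' reference transcript (e.g. NACA).
#'
#' @param treated,control Numeric vectors `c(ct_target, ct_reference)` or
#'   lists with `ct_target`/`ct_reference` elements.
#' @return Linear fold change (treated relative to control).
#' @export
ddct_fold_change <- function(treated, control) {
  get <- function(x, i, nm) if (is.list(x)) x[[nm]] else x[[i]]
  dct_t <- get(treated, 1L, "ct_target") - get(treated, 2L, "ct_reference")
  dct_c <- get(control, 1L, "ct_target") - get(control, 2L, "ct_reference")
  if (!all(is.finite(c(dct_t, dct_c)))) stop("Ct values must be finite")
  2^(-(dct_t - dct_c))
}
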