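#' Threshold-filter a differential-expression table
#'
#' Splits genes into up- and down-regulated sets at a linear fold-change
#' threshold (boundary inclusive) and an FDR threshold (boundary exclusive),
#' the "+/-1.5-fold change; FDR < 0.05"-style rule. Fold changes are accepted
#' on the linear scale and compared on log2 internally, so down-regulation is
#' symmetric (`2^log2fc <= 1/fc_threshold`).
#'
#' @param records DE data frame with `gene_id`, `log2fc`, `fdr`
#'   ([read_table()] schema `"de"`).
#' @param fc_threshold Linear fold-change threshold `>= 1` (default 1.5).
#' @param fdr_threshold FDR cutoff in (0, 1\] (default 0.05).
#' @param experiment_id Label carried on the result.
#' @return A `deg_set`: list with `experiment_id`, `up`, `down` (character
#'   vectors of gene ids), `fc_threshold`, `fdr_threshold`.
#' @export
filter_degs <- function(records, fc_threshold = 1.5, fdr_threshold = 0.05,
                        experiment_id = "experiment") {
  stopifnot(fc_threshold >= 1, fdr_threshold > 0, fdr_threshold <= 1)
  if (anyDuplicated(records$gene_id))
    stop("duplicate gene_id: ",
         records$gene_id[duplicated(records$gene_id)][1L])
  sig <- records$fdr < fdr_threshold
  lfc <- log2(fc_threshold)
  up <- records$gene_id[sig & records$log2fc >= lfc]
  down <- records$gene_id[sig & records$log2fc <= -lfc]
  structure(list(experiment_id = experiment_id, up = up, down = down,
                 fc_threshold = fc_threshold, fdr_threshold = fdr_threshold),
            class = "deg_set")
}

#' @export
print.deg_set <- function(x, ...) {
  cat(sprintf("DEG set '%s': %d up, %d down (|FC| >= %g, FDR < %g)\n",
              x$experiment_id, length(x$up), length(x$down),
              x$fc_threshold, x$fdr_threshold))
  invisible(x)
}

#' Intersect DEG sets across experiments
#'
#' Keeps genes up in every experiment and genes down in every experiment;
#' any gene with conflicting signs across experiments is excluded from both
#' directions.
#'
#' @param sets List of two or more `deg_set` objects.
#' @return A `deg_set` with the shared thresholds and a combined
#'   `experiment_id`.
#' @export
intersect_experiments <- function(sets) {
  stopifnot(length(sets) >= 2L)
  up <- Reduce(intersect, lapply(sets, `[[`, "up"))
  down <- Reduce(intersect, lapply(sets, `[[`, "down"))
  any_up <- Reduce(union, lapply(sets, `[[`, "up"))
  any_down <- Reduce(union, lapply(sets, `[[`, "down"))
  conflicted <- intersect(any_up, any_down)
  structure(list(
    experiment_id = paste(vapply(sets, `[[`, "", "experiment_id"),
                          collapse = "&"),
    up = setdiff(up, conflicted), down = setdiff(down, conflicted),
    fc_threshold = sets[[1L]]$fc_threshold,
    fdr_threshold = sets[[1L]]$fdr_threshold), class = "deg_set")
}

#' Restrict a DEG set to a curated gene list
#'
#' Used to focus deregulated genes on, e.g., a curated catalogue of bona-fide
#' DNA-binding transcription factors.
#'
#' @param deg_set A `deg_set`.
#' @param curated_list Non-empty character vector of gene ids.
#' @return A `deg_set` restricted to the list.
#' @export
filter_by_gene_list <- function(deg_set, curated_list) {
  if (!length(curated_list)) stop("curated list is empty")
  deg_set$up <- intersect(deg_set$up, curated_list)
  deg_set$down <- intersect(deg_set$down, curated_list)
  deg_set
}

#' Call direct targets from binding and differential expression
#'
#' A direct target is a gene both bound by the factor and deregulated on its
#' perturbation: `positive = bound` intersected with the up set, `negative =
#' bound` intersected with the down set.
#'
#' @param bound_genes Character vector of bound gene ids ([bound_genes()]).
#' @param deg_set A `deg_set`.
#' @return A `direct_target_set`: list with `bound`, `positive`, `negative`
#'   and `counts`.
#' @export
call_direct_targets <- function(bound_genes, deg_set) {
  positive <- intersect(bound_genes, deg_set$up)
  negative <- intersect(bound_genes, deg_set$down)
  structure(list(bound = bound_genes, positive = positive, negative = negative,
                 counts = c(bound = length(bound_genes),
                            positive = length(positive),
                            negative = length(negative),
                            total = length(positive) + length(negative))),
            class = "direct_target_set")
}

#' @export
print.direct_target_set <- function(x, ...) {
  cat(sprintf("Direct targets: %d of %d bound genes deregulated (%d up, %d down)\n",
              x$counts[["total"]], x$counts[["bound"]],
              x$counts[["positive"]], x$counts[["negative"]]))
  invisible(x)
}

#' Overlap statistics between two gene sets
#'
#' @param set_a,set_b Character vectors of gene ids.
#' @return List with `overlap` (size of the intersection), `n_a`, `n_b`,
#'   `jaccard`, and `members` (the intersection itself).
#' @export
overlap_classes <- function(set_a, set_b) {
  a <- unique(set_a); b <- unique(set_b)
  both <- intersect(a, b)
  u <- length(union(a, b))
  list(overlap = length(both), n_a = length(a), n_b = length(b),
       jaccard = if (u == 0L) NA_real_ else length(both) / u,
       members = both)
}
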