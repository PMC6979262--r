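#' Draw disjoint train/validation cell splits
#'
#' For each replicate, samples without replacement within each group first a
#' training set and then a validation set of `n_per_set_per_group` cells,
#' so the two sets are always disjoint and balanced across groups.
#'
#' @param m a [count_matrix()] with two group labels.
#' @param n_per_set_per_group cells per group in each of the two sets;
#'   requires `2 * n_per_set_per_group <= min(group sizes)`.
#' @param n_replicates number of independent splits (default 50).
#' @return a list of length `n_replicates`; each element has `replicate`,
#'   `train` and `validation` (character cell-id vectors).
#' @export
make_splits <- function(m, n_per_set_per_group, n_replicates = 50) {
  g <- two_groups(m, min_cells = 1)
  sizes <- c(length(g$g1), length(g$g2))
  if (2 * n_per_set_per_group > min(sizes))
    stop("infeasible split: need 2 x ", n_per_set_per_group,
         " cells per group but smallest group has ", min(sizes))
  lapply(seq_len(n_replicates), function(r) {
    pick <- function(idx) sample(idx, 2 * n_per_set_per_group)
    s1 <- pick(g$g1); s2 <- pick(g$g2)
    k <- n_per_set_per_group
    list(replicate = r,
         train = m$cell_ids[c(s1[seq_len(k)], s2[seq_len(k)])],
         validation = m$cell_ids[c(s1[k + seq_len(k)], s2[k + seq_len(k)])])
  })
}

result_p <- function(result, ids) {
  result$pvalue[match(ids, result$isoform_id)]
}

#' False positive rate at a significance threshold
#'
#' Fraction of the subset's isoforms with a non-missing p-value below
#' `alpha`; missing p-values count as not significant (the denominator is
#' the full subset).
#'
#' @param result a `de_result`.
#' @param alpha significance threshold (default 0.05).
#' @param subset isoform ids to evaluate over; defaults to all tested.
#' @return proportion in `[0, 1]`.
#' @export
fpr <- function(result, alpha = 0.05, subset = result$isoform_id) {
  if (length(subset) == 0) stop("empty subset")
  p <- result_p(result, subset)
  mean(!is.na(p) & p < alpha)
}

#' Top-ranked isoforms by p-value
#'
#' Returns the `ceil(fraction * |subset|)` isoforms with the smallest
#' p-values. Ordering is fully deterministic: by p-value, then by absolute
#' statistic (descending), then by isoform id; missing p-values rank last.
#'
#' @param result a `de_result`.
#' @param fraction proportion in `(0, 1]` of the subset to keep.
#' @param subset isoform ids to rank within; defaults to all tested.
#' @return ordered character vector of isoform ids.
#' @export
top_k <- function(result, fraction, subset = result$isoform_id) {
  stopifnot(fraction > 0, fraction <= 1)
  idx <- match(subset, result$isoform_id)
  if (anyNA(idx)) stop("subset contains untested isoforms")
  p <- result$pvalue[idx]
  s <- abs(result$statistic[idx])
  s[is.na(s)] <- -Inf
  ord <- order(ifelse(is.na(p), 2, p), -s, subset)
  k <- ceiling(fraction * length(subset))
  subset[ord][seq_len(k)]
}

#' Rediscovery rate
#'
#' The proportion of the training set's top-ranked isoforms that reach
#' significance (`p < alpha`) in the validation result. Under a global null
#' with a calibrated test the expected RDR equals `alpha`.
#'
#' @param train,validation `de_result`s from disjoint cell sets.
#' @param fraction top fraction of the subset ranked in the training
#'   result (default 1, i.e. all isoforms).
#' @param alpha validation significance threshold (default 0.05).
#' @param subset isoform ids to evaluate over.
#' @return proportion in `[0, 1]`.
#' @export
rdr <- function(train, validation, fraction = 1, alpha = 0.05,
                subset = train$isoform_id) {
  top <- top_k(train, fraction, subset)
  if (length(top) == 0) stop("empty top set")
  pv <- result_p(validation, top)
  mean(!is.na(pv) & pv < alpha)
}

#' True rediscovery rate
#'
#' The proportion of the training set's top-ranked isoforms that are both
#' significant in the validation result and truly differentially expressed
#' according to the simulation ground truth: the intersection of
#' rediscovered and true DE isoforms, over the size of the top set. Always
#' bounded above by [rdr()] on the same inputs.
#'
#' @inheritParams rdr
#' @param truth data.frame with columns `isoform_id` and `de_flag`.
#' @return proportion in `[0, 1]`.
#' @export
true_rdr <- function(train, validation, truth, fraction = 1, alpha = 0.05,
                     subset = train$isoform_id) {
  top <- top_k(train, fraction, subset)
  if (length(top) == 0) stop("empty top set")
  pv <- result_p(validation, top)
  flag <- truth$de_flag[match(top, truth$isoform_id)]
  flag[is.na(flag)] <- FALSE
  mean(!is.na(pv) & pv < alpha & flag)
}

#' Ratio of true to observed rediscovery rate
#'
#' A specificity summary of the rediscoveries: 1 means every rediscovered
#' isoform is truly DE. Missing when the observed RDR is 0.
#'
#' @param true_rdr_value,rdr_value proportions in `[0, 1]`.
#' @return ratio in `[0, 1]`, or `NA` when `rdr_value` is 0.
#' @export
rdr_ratio <- function(true_rdr_value, rdr_value) {
  stopifnot(true_rdr_value >= 0, true_rdr_value <= 1,
            rdr_value >= 0, rdr_value <= 1)
  if (rdr_value == 0) return(NA_real_)
  true_rdr_value / rdr_value
}

#' Area under the ROC curve on top-ranked isoforms
#'
#' Restricts to the top `fraction` of the subset (ranked by the result's
#' p-values), scores each isoform by `-log10(p)` and computes the AUC
#' against the ground-truth DE flags as the tie-corrected Mann-Whitney
#' statistic: the probability that a random true-DE isoform outscores a
#' random non-DE one, ties counting one half. Missing p-values score
#' lowest. Returns `NA` (with a warning) when the restriction leaves a
#' single truth class.
#'
#' @param result a `de_result`.
#' @param truth data.frame with `isoform_id` and `de_flag`.
#' @param fraction top fraction of the subset to restrict to (default 1).
#' @param subset isoform ids to evaluate over.
#' @return AUC in `[0, 1]`, or `NA`.
#' @export
roc_auc <- function(result, truth, fraction = 1, subset = result$isoform_id) {
  top <- top_k(result, fraction, subset)
  p <- result_p(result, top)
  score <- -log10(pmax(p, 1e-300))
  score[is.na(p)] <- -Inf
  flag <- truth$de_flag[match(top, truth$isoform_id)]
  flag[is.na(flag)] <- FALSE
  n1 <- sum(flag); n0 <- sum(!flag)
  if (n1 == 0 || n0 == 0) {
    warning("single truth class after top-k restriction; AUC undefined")
    return(NA_real_)
  }
  r <- rank(score) # midranks handle ties
  (sum(r[flag]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
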