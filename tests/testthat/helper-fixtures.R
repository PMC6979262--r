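# Shared fixtures, all built in code.

# A tiny deterministic matrix whose log2(CPM + 1) values equal `logvals`
# when library sizes are 1e6 (CPM == raw value at that library size).
matrix_with_logcpm <- function(logvals, group_labels) {
  vals <- 2^logvals - 1
  count_matrix(vals, group_labels = group_labels,
               library_sizes = rep(1e6, ncol(vals)))
}

# Small simulated two-group data set shared across DE-test checks.
small_sim <- function(n_isoforms = 300, n_cells = 30, seed = 42, ...) {
  simulate_dataset(sim_config(n_isoforms = n_isoforms,
                              n_cells_per_group = n_cells,
                              seed = seed, ...))
}

# Swap the two group labels of a count matrix.
swap_labels <- function(m) {
  labs <- sort(unique(m$group_labels))
  m$group_labels <- ifelse(m$group_labels == labs[1], labs[2], labs[1])
  m
}

# Exhaustive-enumeration oracle for the two-sided Mann-Whitney p-value
# (no ties): doubles the smaller tail of the exact U distribution.
wilcox_enum_p <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  pooled <- c(x1, x2)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  lo <- mean(us <= u_obs); hi <- mean(us >= u_obs)
  min(1, 2 * min(lo, hi))
}

# Brute-force AUC oracle: concordant-pair counting with ties worth 1/2.
auc_pairs <- function(score, label) {
  pos <- score[label]; neg <- score[!label]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}
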