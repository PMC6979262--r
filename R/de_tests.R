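#' @name de_tests
#' @title Two-group differential expression tests
#'
#' @description
#' Seven natively implemented two-group DE tests behind one interface,
#' covering the main model families used for single-cell expression data:
#' normal theory ([ttest_log_cpm()]), nonparametric ([wilcoxon_test()]),
#' empirical-Bayes normal with a mean-variance trend ([moderated_t_trend()]),
#' negative binomial ([nb_wald()]), zero-inflated negative binomial
#' ([zinb_lrt()]), two-part hurdle ([hurdle_lrt()]) and beta-Poisson GLM
#' ([bp4_glm_test()]).
#'
#' All tests take a [count_matrix()] with exactly two group labels and
#' return a `de_result`: a data.frame with one row per isoform and columns
#' `isoform_id`, `statistic`, `effect` (log2 scale where defined), `pvalue`
#' and `note`, plus a `method` attribute. Shared degenerate rules: an
#' isoform with zero variance in both groups and equal means gets `p = 1`;
#' isoforms a test cannot handle get a missing p-value with the reason in
#' `note` and rank last in all downstream top-k orderings.
NULL

de_result <- function(method, isoform_ids, statistic, effect, pvalue,
                      note = "") {
  stopifnot(all(is.na(pvalue) | (pvalue >= 0 & pvalue <= 1)))
  out <- data.frame(isoform_id = isoform_ids,
                    statistic = as.numeric(statistic),
                    effect = as.numeric(effect),
                    pvalue = as.numeric(pvalue),
                    note = if (length(note) == 1) rep(note, length(isoform_ids)) else note,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "method") <- method
  class(out) <- c("de_result", "data.frame")
  out
}

# Resolve the two groups; `min_cells` guards each test's sample-size
# precondition. Groups are taken in sorted label order; `effect` is always
# group2 minus group1 on the relevant scale.
two_groups <- function(m, min_cells = 1) {
  validate_count_matrix(m)
  labs <- sort(unique(m$group_labels))
  if (length(labs) != 2)
    stop("exactly two group labels required, found: ",
         paste(labs, collapse = ", "))
  g1 <- which(m$group_labels == labs[1])
  g2 <- which(m$group_labels == labs[2])
  if (length(g1) < min_cells || length(g2) < min_cells)
    stop("each group needs at least ", min_cells, " cells (have ",
         length(g1), " and ", length(g2), ")")
  list(labels = labs, g1 = g1, g2 = g2)
}

#' Run one DE test by name
#'
#' Dispatcher over the seven implemented tests; the method names match the
#' command-line interface.
#'
#' @param m a [count_matrix()] with two group labels.
#' @param method one of `"ttest"`, `"wilcoxon"`, `"limmatrend"`, `"nbwald"`,
#'   `"zinb"`, `"hurdle"`, `"bp4"`.
#' @return a `de_result` data.frame.
#' @export
run_de_test <- function(m, method = c("ttest", "wilcoxon", "limmatrend",
                                      "nbwald", "zinb", "hurdle", "bp4")) {
  method <- match.arg(method)
  switch(method,
         ttest = ttest_log_cpm(m),
         wilcoxon = wilcoxon_test(m),
         limmatrend = moderated_t_trend(m),
         nbwald = nb_wald(m),
         zinb = zinb_lrt(m),
         hurdle = hurdle_lrt(m),
         bp4 = bp4_glm_test(m))
}

#' All implemented DE method names
#' @return character vector.
#' @export
de_methods <- function() c("ttest", "wilcoxon", "limmatrend", "nbwald",
                           "zinb", "hurdle", "bp4")

row_group_stats <- function(x, idx) {
  n <- length(idx)
  xm <- x[, idx, drop = FALSE]
  mu <- rowMeans(xm)
  v <- if (n > 1) rowSums((xm - mu)^2) / (n - 1) else rep(NA_real_, nrow(x))
  list(mean = mu, var = v, n = n)
}

#' Welch t-test on log2(CPM + 1)
#'
#' Per-isoform two-sided Welch (unequal-variance) t-test with
#' Satterthwaite degrees of freedom, computed on the log2(CPM + 1) scale.
#' Degenerate rules: both groups constant with equal means gives `p = 1`;
#' both constant with different means gives `p = 0` (infinite evidence
#' against equality under the normal model).
#'
#' @param m a [count_matrix()]; each group needs >= 2 cells.
#' @return a `de_result`; `effect` is the difference of group means on the
#'   log2(CPM + 1) scale (group2 - group1 in sorted label order).
#' @export
ttest_log_cpm <- function(m) {
  g <- two_groups(m, min_cells = 2)
  x <- log_cpm(m)
  s1 <- row_group_stats(x, g$g1)
  s2 <- row_group_stats(x, g$g2)
  diff <- s2$mean - s1$mean
  se2 <- s1$var / s1$n + s2$var / s2$n
  tt <- diff / sqrt(se2)
  df <- se2^2 / ((s1$var / s1$n)^2 / (s1$n - 1) + (s2$var / s2$n)^2 / (s2$n - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  note <- rep("", nrow(x))
  zero_se <- se2 == 0
  if (any(zero_se)) {
    eq <- zero_se & diff == 0
    ne <- zero_se & diff != 0
    p[eq] <- 1; tt[eq] <- 0
    p[ne] <- 0; tt[ne] <- Inf * sign(diff[ne])
    note[zero_se] <- "zero variance in both groups"
  }
  de_result("ttest", m$isoform_ids, tt, diff, pmin(p, 1), note)
}

#' Wilcoxon rank-sum (Mann-Whitney) test on log2(CPM + 1)
#'
#' Per-isoform two-sided rank-sum test. When both groups have at most
#' `exact_max` cells and the row has no ties, the exact null distribution of
#' the Mann-Whitney U statistic is used; otherwise the tie-corrected normal
#' approximation with continuity correction. A completely tied row (all
#' values equal) gets `p = 1`. Being rank-based the p-value is invariant to
#' any monotone transform of the expression scale.
#'
#' @param m a [count_matrix()]; each group needs >= 1 cell.
#' @param exact_max largest per-group size for the exact path (default 25).
#' @return a `de_result`; `statistic` is the Mann-Whitney U of group1 and
#'   `effect` the difference of group means of log2(CPM + 1).
#' @export
wilcoxon_test <- function(m, exact_max = 25L) {
  g <- two_groups(m, min_cells = 1)
  x <- log_cpm(m)
  n1 <- length(g$g1); n2 <- length(g$g2); N <- n1 + n2
  use_exact_base <- n1 <= exact_max && n2 <= exact_max
  res <- apply(x, 1, function(v) {
    counts <- tabulate(match(v, v))
    counts <- counts[counts > 0]
    if (length(counts) == 1) return(c(n1 * n2 / 2, 1)) # all tied
    r <- rank(v)
    U <- sum(r[g$g1]) - n1 * (n1 + 1) / 2
    tie_term <- sum(counts^3 - counts)
    if (tie_term == 0 && use_exact_base) {
      p <- if (U > n1 * n2 / 2)
        2 * stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE)
      else
        2 * stats::pwilcox(U, n1, n2)
      return(c(U, min(1, p)))
    }
    sigma <- sqrt(n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1))))
    z <- U - n1 * n2 / 2
    z <- (z - sign(z) * 0.5) / sigma
    c(U, min(1, 2 * stats::pnorm(-abs(z))))
  })
  eff <- rowMeans(x[, g$g2, drop = FALSE]) - rowMeans(x[, g$g1, drop = FALSE])
  de_result("wilcoxon", m$isoform_ids, res[1, ], eff, res[2, ])
}

# Invert the trigamma function by Newton iteration (monotone decreasing).
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  x <- 0.5 + 1 / y
  for (i in 1:60) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (x <= 0) x <- 1e-8
    if (abs(dif) < 1e-10 * x) break
  }
  x
}

#' Moderated t-test with a mean-variance trend
#'
#' Per-isoform linear model on log2(CPM + 1) (two-group design, so the fit
#' is the pair of group means), followed by empirical-Bayes moderation of
#' the residual variances toward a smooth trend of variance against average
#' log expression. The log residual variances are modelled as a scaled F
#' draw around the trend: the prior degrees of freedom `d0` are estimated
#' by matching the excess variance of `log(s^2)` over the chi-square
#' sampling variance (`trigamma` moments), and the trend level is
#' bias-corrected by the corresponding digamma terms. The posterior
#' variance is the convex combination `(d*s^2 + d0*s0^2) / (d + d0)` and
#' the moderated t has `d + d0` degrees of freedom.
#'
#' @param m a [count_matrix()]; >= 2 cells per group and >= 50 isoforms
#'   (the trend is estimated across isoforms). For fewer isoforms use
#'   [ttest_log_cpm()].
#' @param trend_span lowess span for the variance trend.
#' @return a `de_result`; `effect` is the group-mean difference of
#'   log2(CPM + 1).
#' @export
moderated_t_trend <- function(m, trend_span = 0.5) {
  g <- two_groups(m, min_cells = 2)
  if (nrow(m$values) < 50)
    stop("moderated t with trend needs >= 50 isoforms; ",
         "use ttest_log_cpm() for small panels")
  x <- log_cpm(m)
  n1 <- length(g$g1); n2 <- length(g$g2)
  d <- n1 + n2 - 2
  m1 <- rowMeans(x[, g$g1, drop = FALSE])
  m2 <- rowMeans(x[, g$g2, drop = FALSE])
  rss <- rowSums((x[, g$g1, drop = FALSE] - m1)^2) +
    rowSums((x[, g$g2, drop = FALSE] - m2)^2)
  s2 <- rss / d
  amean <- rowMeans(x)
  ok <- s2 > 0
  if (sum(ok) < 10) stop("too few isoforms with positive variance for a trend")
  z <- log(s2[ok])
  lo <- stats::lowess(amean[ok], z, f = trend_span)
  trend_at <- stats::approx(lo$x, lo$y, xout = amean, rule = 2, ties = mean)$y
  e <- z - stats::approx(lo$x, lo$y, xout = amean[ok], rule = 2, ties = mean)$y
  excess <- stats::var(e) - trigamma(d / 2)
  if (is.finite(excess) && excess > 1e-8) {
    d0 <- 2 * trigamma_inverse(excess)
    s0_2 <- exp(trend_at - digamma(d / 2) + log(d / 2) +
                  digamma(d0 / 2) - log(d0 / 2))
    post <- (d * s2 + d0 * s0_2) / (d + d0)
    df_total <- d + d0
  } else {
    # variances consistent with pure sampling noise around the trend:
    # infinite prior df, posterior variance equals the (bias-corrected) trend
    d0 <- Inf
    s0_2 <- exp(trend_at - digamma(d / 2) + log(d / 2))
    post <- s0_2
    df_total <- Inf
  }
  se <- sqrt(post * (1 / n1 + 1 / n2))
  diff <- m2 - m1
  tt <- diff / se
  p <- 2 * stats::pt(-abs(tt), df_total)
  note <- rep("", nrow(x))
  degen <- se == 0
  if (any(degen)) {
    p[degen] <- ifelse(diff[degen] == 0, 1, 0)
    tt[degen] <- ifelse(diff[degen] == 0, 0, Inf * sign(diff[degen]))
    note[degen] <- "zero posterior variance"
  }
  out <- de_result("limmatrend", m$isoform_ids, tt, diff, pmin(p, 1), note)
  attr(out, "prior_df") <- d0
  attr(out, "trend_var") <- s0_2
  attr(out, "posterior_var") <- post
  out
}
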