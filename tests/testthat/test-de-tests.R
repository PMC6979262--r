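# Shared small data set for the cross-cutting properties.
sim_small <- small_sim()

test_that("every test returns valid, label-swap- and row-order-invariant results", {
  m <- sim_small$matrix
  perm <- sample(seq_along(m$isoform_ids))
  m_perm <- count_matrix(m$values[perm, ], isoform_ids = m$isoform_ids[perm],
                         cell_ids = m$cell_ids, group_labels = m$group_labels,
                         library_sizes = m$library_sizes)
  for (meth in de_methods()) {
    r <- run_de_test(m, meth)
    expect_s3_class(r, "de_result")
    expect_equal(nrow(r), nrow(m$values))
    expect_true(all(is.na(r$pvalue) | (r$pvalue >= 0 & r$pvalue <= 1)),
                label = paste(meth, "p in [0,1]"))
    r_swap <- run_de_test(swap_labels(m), meth)
    expect_equal(r_swap$pvalue, r$pvalue, tolerance = 1e-6,
                 label = paste(meth, "label-swap p"))
    expect_equal(r_swap$effect, -r$effect, tolerance = 1e-5,
                 label = paste(meth, "label-swap effect sign"))
    r_perm <- run_de_test(m_perm, meth)
    expect_equal(r_perm$pvalue[match(m$isoform_ids, r_perm$isoform_id)],
                 r$pvalue, tolerance = 1e-10,
                 label = paste(meth, "row-order invariance"))
  }
})

test_that("identical groups give null results for every test", {
  half <- sim_small$matrix$values[1:100, 1:15]
  dup <- count_matrix(cbind(half, half),
                      cell_ids = paste0("c", 1:30),
                      group_labels = rep(c("a", "b"), each = 15),
                      library_sizes = rep(colSums(half), 2))
  for (meth in de_methods()) {
    r <- run_de_test(dup, meth)
    expect_true(all(r$pvalue > 0.99, na.rm = TRUE),
                label = paste(meth, "duplicated groups p ~ 1"))
    expect_true(all(abs(r$effect) < 1e-6, na.rm = TRUE),
                label = paste(meth, "duplicated groups effect 0"))
  }
})

test_that("Welch t matches the closed-form oracle on toy vectors", {
  lv <- rbind(c(10, 11, 12, 20, 21, 22))
  m <- matrix_with_logcpm(lv, rep(c("a", "b"), each = 3))
  r <- ttest_log_cpm(m)
  # hand evaluation of the Welch formulas
  m1 <- 11; m2 <- 21; v1 <- 1; v2 <- 1; n <- 3
  se2 <- v1 / n + v2 / n
  t_oracle <- (m2 - m1) / sqrt(se2)
  df_oracle <- se2^2 / ((v1 / n)^2 / (n - 1) + (v2 / n)^2 / (n - 1))
  p_oracle <- 2 * pt(-abs(t_oracle), df_oracle)
  expect_equal(r$statistic, t_oracle)
  expect_equal(r$pvalue, p_oracle)
  expect_equal(r$effect, 10)
})

test_that("t-test degenerate rules and affine invariance hold", {
  m <- matrix_with_logcpm(rbind(c(3, 3, 3, 3, 3, 3), c(1, 1, 1, 5, 5, 5)),
                          rep(c("a", "b"), each = 3))
  r <- ttest_log_cpm(m)
  expect_equal(r$pvalue, c(1, 0))
  # common affine transform of the log values leaves t unchanged
  lv <- matrix(rnorm(60, 8), 10, 6)
  t1 <- ttest_log_cpm(matrix_with_logcpm(lv, rep(c("a", "b"), 3)))$statistic
  t2 <- ttest_log_cpm(matrix_with_logcpm(2 * lv + 1, rep(c("a", "b"), 3)))$statistic
  expect_equal(t1, t2, tolerance = 1e-9)
})

test_that("Wilcoxon matches exhaustive enumeration on small samples", {
  m <- matrix_with_logcpm(rbind(c(1, 2, 3, 4, 5, 6)),
                          c("a", "a", "a", "b", "b", "b"))
  r <- wilcoxon_test(m)
  expect_equal(r$pvalue, 0.1) # 2 of the 20 rank assignments are as extreme
  expect_equal(r$pvalue, wilcox_enum_p(c(1, 2, 3), c(4, 5, 6)))
  set.seed(31)
  for (i in 1:10) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    v <- sample(100, n1 + n2) # distinct values, no ties
    mm <- matrix_with_logcpm(rbind(log2(v + 1)),
                             rep(c("a", "b"), c(n1, n2)))
    expect_equal(wilcoxon_test(mm)$pvalue,
                 wilcox_enum_p(v[seq_len(n1)], v[n1 + seq_len(n2)]),
                 tolerance = 1e-12, label = paste("enumeration case", i))
  }
})

test_that("Wilcoxon ties and transforms behave as a rank test should", {
  m <- matrix_with_logcpm(rbind(rep(2, 8)), rep(c("a", "b"), 4))
  expect_equal(wilcoxon_test(m)$pvalue, 1)
  # invariance under a monotone transform of the normalised expression
  set.seed(9)
  vals <- matrix(rpois(80 * 24, 3), 80, 24)
  libs <- rep(1e6, 24)
  m1 <- count_matrix(vals, group_labels = rep(c("a", "b"), 12),
                     library_sizes = libs)
  m2 <- count_matrix(vals^2, group_labels = rep(c("a", "b"), 12),
                     library_sizes = libs)
  expect_equal(wilcoxon_test(m2)$pvalue, wilcoxon_test(m1)$pvalue)
})

test_that("moderated t agrees with an independent trend implementation", {
  sim <- small_sim(400, 25, seed = 77)
  m <- sim$matrix
  mine <- moderated_t_trend(m)
  # independent route: limma's linear model + trended empirical Bayes
  library(limma)
  x <- log_cpm(m)
  design <- stats::model.matrix(~ factor(m$group_labels,
                                         levels = sort(unique(m$group_labels))))
  fit <- limma::eBayes(limma::lmFit(x, design), trend = TRUE)
  expect_gt(cor(mine$pvalue, fit$p.value[, 2], method = "spearman"), 0.999)
  expect_lt(median(abs(mine$pvalue - fit$p.value[, 2])), 0.01)
  # prior df of the same order as limma's moment estimate
  expect_lt(abs(log(attr(mine, "prior_df") / fit$df.prior)), log(2))
})

test_that("moderated variances are convex combinations of observed and trend", {
  sim <- small_sim(200, 20, seed = 15)
  m <- sim$matrix
  r <- moderated_t_trend(m)
  x <- log_cpm(m)
  g <- split(seq_along(m$group_labels), m$group_labels)
  rss <- rowSums((x[, g[[1]]] - rowMeans(x[, g[[1]]]))^2) +
    rowSums((x[, g[[2]]] - rowMeans(x[, g[[2]]]))^2)
  s2 <- rss / (ncol(x) - 2)
  post <- attr(r, "posterior_var")
  s0 <- attr(r, "trend_var")
  expect_true(all(post >= pmin(s2, s0) - 1e-12))
  expect_true(all(post <= pmax(s2, s0) + 1e-12))
  one_vs_two <- subset_cells(m, c(1, 21, 22)) # 1 control, 2 treated cells
  expect_error(moderated_t_trend(one_vs_two), "at least 2")
  small <- count_matrix(m$values[1:10, ], group_labels = m$group_labels,
                        library_sizes = m$library_sizes)
  expect_error(moderated_t_trend(small), ">= 50 isoforms")
})

test_that("NB Wald with zero dispersion matches a Poisson GLM oracle", {
  set.seed(41)
  y <- matrix(rpois(40, 8), 2, 20)
  lib <- runif(20, 0.5e6, 2e6)
  m <- count_matrix(y, group_labels = rep(c("a", "b"), 10),
                    library_sizes = lib)
  r <- nb_wald(m, dispersion = 0)
  off <- log(lib) - mean(log(lib))
  grp <- factor(rep(c("a", "b"), 10))
  for (i in 1:2) {
    fit <- glm(y[i, ] ~ grp + offset(off), family = poisson())
    z <- coef(summary(fit))[2, 3]
    expect_equal(r$statistic[i], z, tolerance = 1e-6)
  }
})

test_that("NB Wald is calibrated on NB null data at 80 cells per group", {
  set.seed(43)
  mu <- exp(runif(2000, log(2), log(50)))
  y <- t(vapply(mu, function(m) rnbinom(160, size = 2, mu = m),
                numeric(160)))
  m <- count_matrix(y, group_labels = rep(c("a", "b"), each = 80),
                    library_sizes = rep(1e6, 160))
  r <- nb_wald(m)
  f <- fpr(r, 0.05)
  expect_gt(f, 0.03); expect_lt(f, 0.07)
})

test_that("ZINB maximum likelihood recovers generating parameters", {
  set.seed(99)
  y <- ifelse(runif(1e4) < 0.3, 0, rnbinom(1e4, size = 2, mu = 8))
  f <- fit_zinb(y)
  expect_lt(abs(f$pi0 - 0.3), 0.03)
  expect_lt(abs(f$mu - 8) / 8, 0.05)
  expect_lt(abs(f$size - 2) / 2, 0.15)
})

test_that("ZINB LRT p-values are near-uniform under a true ZINB null", {
  set.seed(7)
  y <- t(vapply(1:300, function(i) {
    mu <- exp(runif(1, 0.5, 3))
    ifelse(runif(160) < 0.25, 0, rnbinom(160, size = 1.5, mu = mu))
  }, numeric(160)))
  m <- count_matrix(y, group_labels = rep(c("a", "b"), each = 80),
                    library_sizes = rep(1e6, 160))
  r <- zinb_lrt(m)
  ks <- suppressWarnings(ks.test(r$pvalue, "punif"))
  expect_lt(unname(ks$statistic), 0.10)
  expect_error(zinb_lrt(subset_cells(m, c(1:3, 81:83))), "at least 5")
})

test_that("hurdle splits detection and expression evidence correctly", {
  # groups differing only in detection rate; positives share one value set
  vals <- rbind(c(5, 6, 7, 8, rep(0, 16), 5, 6, 7, 8, rep(0, 4),
                  rep(5, 6), 6, 7, 8, 5, 6, 7))
  stopifnot(ncol(vals) == 40)
  m <- count_matrix(vals, group_labels = rep(c("a", "b"), each = 20),
                    library_sizes = rep(1e6, 40))
  r <- hurdle_lrt(m)
  # oracle: logistic LRT via glm + Gaussian LRT via the RSS ratio
  d <- as.integer(vals[1, ] > 0)
  grp <- factor(rep(c("a", "b"), each = 20))
  g_fit <- glm(d ~ grp, family = binomial())
  g_null <- glm(d ~ 1, family = binomial())
  chi_detect <- as.numeric(deviance(g_null) - deviance(g_fit))
  x <- log_cpm(m)[1, vals[1, ] > 0]
  gg <- grp[vals[1, ] > 0]
  rss1 <- sum(tapply(x, gg, function(v) sum((v - mean(v))^2)))
  chi_cont <- length(x) * log(sum((x - mean(x))^2) / rss1)
  expect_equal(r$statistic, chi_detect + chi_cont, tolerance = 1e-8)
  expect_equal(attr(r, "df"), 2L)
  expect_equal(r$pvalue, pchisq(chi_detect + chi_cont, 2, lower.tail = FALSE))
})

test_that("hurdle skips isoforms with under two expressing cells", {
  vals <- rbind(c(3, rep(0, 19)), rep(0, 20))
  m <- count_matrix(vals, group_labels = rep(c("a", "b"), each = 10),
                    library_sizes = rep(1e6, 20))
  r <- hurdle_lrt(m)
  expect_true(all(is.na(r$pvalue)))
  expect_match(r$note[1], "fewer than 2")
})

test_that("BP4 GLM recovers an injected lambda1 fold change", {
  set.seed(21)
  eff <- replicate(30, {
    x1 <- bp4_rvs(bp4_params(2, 4, 40, 1), 160)
    x2 <- bp4_rvs(bp4_params(2, 4, 80, 1), 160)
    m <- count_matrix(matrix(c(x1, x2), nrow = 1),
                      group_labels = rep(c("a", "b"), each = 160),
                      library_sizes = rep(1e6, 320))
    bp4_glm_test(m)$effect
  })
  expect_lt(abs(mean(eff) - 1), 0.15) # log2 scale: true effect is 1
})

test_that("BP4 GLM power grows with the number of cells", {
  power_at <- function(nc) {
    set.seed(3)
    mean(replicate(150, {
      x1 <- bp4_rvs(bp4_params(2, 4, 40, 1), nc)
      x2 <- bp4_rvs(bp4_params(2, 4, 80, 1), nc)
      m <- count_matrix(matrix(c(x1, x2), nrow = 1),
                        group_labels = rep(c("a", "b"), each = nc),
                        library_sizes = rep(1e6, 2 * nc))
      bp4_glm_test(m)$pvalue < 1e-3
    }), na.rm = TRUE)
  }
  expect_gt(power_at(80), power_at(20))
})
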