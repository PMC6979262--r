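# A small deterministic result table used by the ranking tests.
mk_result <- function(p, stat = NULL, ids = sprintf("g%02d", seq_along(p))) {
  if (is.null(stat)) stat <- ifelse(is.na(p), NA, 1)
  rdrbench:::de_result("toy", ids, stat, 0, p)
}

test_that("splits are balanced, disjoint and feasibility-checked", {
  m <- count_matrix(matrix(rpois(400, 4), 4, 100),
                    group_labels = rep(c("a", "b"), each = 50))
  set.seed(1)
  sp <- make_splits(m, 20, n_replicates = 50)
  expect_length(sp, 50)
  for (s in sp[c(1, 25, 50)]) {
    expect_length(intersect(s$train, s$validation), 0)
    for (set in list(s$train, s$validation)) {
      labs <- m$group_labels[match(set, m$cell_ids)]
      expect_equal(unname(table(labs)), c(20L, 20L), ignore_attr = TRUE)
    }
  }
  expect_error(make_splits(m, 26), "infeasible")
  # the documented boundary: 80-cell groups cannot give 41 + 41
  m80 <- count_matrix(matrix(1, 1, 160),
                      group_labels = rep(c("a", "b"), each = 80))
  expect_error(make_splits(m80, 41), "infeasible")
  expect_length(make_splits(m80, 40, 2), 2)
})

test_that("fpr counts strictly sub-alpha p-values over the subset", {
  expect_equal(fpr(mk_result(rep(1, 5))), 0)
  expect_equal(fpr(mk_result(c(0.01, 0.5))), 0.5)
  expect_equal(fpr(mk_result(c(0.01, NA, 0.5, 0.02))), 0.5) # NA not significant
  # exact uniform grid k/1000: 49 values strictly below 0.05
  grid <- mk_result((1:1000) / 1000, ids = sprintf("g%04d", 1:1000))
  expect_equal(fpr(grid), 0.049)
  expect_error(fpr(mk_result(0.5), subset = character(0)), "empty")
})

test_that("top_k ranks by p, breaks ties deterministically, NA last", {
  r <- mk_result(c(0.5, 0.1, NA, 0.1, 0.9),
                 stat = c(1, 2, NA, 5, 1),
                 ids = c("e", "d", "c", "b", "a"))
  expect_equal(top_k(r, 1), c("b", "d", "e", "a", "c"))
  expect_equal(top_k(r, 0.4), c("b", "d"))
  # ceil arithmetic: 5% of 10,000 is 500
  expect_length(top_k(mk_result(runif(10000), ids = sprintf("i%05d", 1:10000)),
                      0.05), 500)
  # identical call, identical ordering under total ties
  tied <- mk_result(rep(0.2, 6), stat = rep(1, 6))
  expect_identical(top_k(tied, 1), top_k(tied, 1))
  expect_equal(top_k(tied, 0.5), sort(tied$isoform_id)[1:3])
})

test_that("rdr counts validation rediscoveries among training top-k", {
  tr <- mk_result(c(0.001, 0.002, 0.003, 0.004))
  va <- mk_result(c(0.01, 0.2, 0.03, 0.8))
  expect_equal(rdr(tr, va, fraction = 1), 0.5) # 2 of 4 validate
  expect_equal(rdr(tr, mk_result(rep(1, 4)), 1), 0)
  # alpha-strictness monotonicity
  expect_lte(rdr(tr, va, 1, alpha = 0.01), rdr(tr, va, 1, alpha = 0.05))
})

test_that("true_rdr intersects rediscoveries with ground truth", {
  tr <- mk_result(c(0.001, 0.002, 0.003, 0.004))
  va <- mk_result(c(0.01, 0.2, 0.03, 0.8))
  truth <- data.frame(isoform_id = sprintf("g%02d", 1:4),
                      de_flag = c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(true_rdr(tr, va, truth, 1), 0.25) # only g01 is true and validates
  none <- data.frame(isoform_id = sprintf("g%02d", 1:4), de_flag = FALSE)
  expect_equal(true_rdr(tr, va, none, 1), 0)
  # true_rdr <= rdr across random configurations
  set.seed(2)
  for (i in 1:20) {
    p1 <- mk_result(runif(30), ids = sprintf("x%02d", 1:30))
    p2 <- mk_result(runif(30), ids = sprintf("x%02d", 1:30))
    tt <- data.frame(isoform_id = sprintf("x%02d", 1:30),
                     de_flag = runif(30) < 0.3)
    f <- sample(c(0.1, 0.5, 1), 1)
    expect_lte(true_rdr(p1, p2, tt, f), rdr(p1, p2, f))
  }
})

test_that("rdr_ratio guards division by zero", {
  expect_equal(rdr_ratio(0.25, 0.5), 0.5)
  expect_equal(rdr_ratio(0, 0.3), 0)
  expect_true(is.na(rdr_ratio(0.2, 0)))
  expect_error(rdr_ratio(-0.1, 0.5))
})

test_that("roc_auc equals brute-force pair counting on all small sets", {
  # perfect separation and complete ties
  truth6 <- data.frame(isoform_id = sprintf("g%02d", 1:6),
                       de_flag = rep(c(TRUE, FALSE), each = 3))
  perfect <- mk_result(c(0.001, 0.002, 0.003, 0.5, 0.6, 0.7))
  expect_equal(roc_auc(perfect, truth6), 1)
  flat <- mk_result(rep(0.5, 6))
  expect_equal(roc_auc(flat, truth6), 0.5)
  # randomised small sets, sizes 2..8, with ties
  set.seed(4)
  for (i in 1:30) {
    n <- sample(2:8, 1)
    p <- sample(c(0.01, 0.05, 0.2, 0.5, 0.9), n, replace = TRUE)
    flag <- runif(n) < 0.5
    if (all(flag) || !any(flag)) next
    ids <- sprintf("s%02d", seq_len(n))
    r <- mk_result(p, ids = ids)
    tt <- data.frame(isoform_id = ids, de_flag = flag)
    expect_equal(roc_auc(r, tt),
                 auc_pairs(-log10(p), flag),
                 label = paste("pair-counting case", i))
  }
  # single class is undefined
  allpos <- data.frame(isoform_id = sprintf("g%02d", 1:6), de_flag = TRUE)
  expect_warning(a <- roc_auc(perfect, allpos), "single truth class")
  expect_true(is.na(a))
})
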