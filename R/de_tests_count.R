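#' Negative-binomial Wald test
#'
#' Per-isoform negative-binomial model with log link and a log library-size
#' offset. Expression values are rounded half-to-even to integers for the
#' count likelihood. Dispersions are estimated by method of moments from
#' Pearson-type residuals around offset-adjusted group means, then shrunk on
#' the log scale toward a lowess trend of dispersion against mean
#' expression (prior weight equivalent to `prior_cells` residual degrees of
#' freedom). The group effect is tested by a Wald z-test from a GLM fit
#' with the shrunken dispersion held fixed.
#'
#' @param m a [count_matrix()]; >= 2 cells per group.
#' @param prior_cells shrinkage weight of the dispersion trend, in units of
#'   residual degrees of freedom (default 20).
#' @param dispersion optional fixed dispersion(s), recycled across
#'   isoforms, bypassing the moment/trend estimate (0 gives a Poisson
#'   Wald test).
#' @return a `de_result`; `effect` is the group log2 fold change,
#'   `statistic` the Wald z. Isoforms whose GLM does not converge carry a
#'   missing p-value with the reason in `note`.
#' @export
nb_wald <- function(m, prior_cells = 20, dispersion = NULL) {
  g <- two_groups(m, min_cells = 2)
  y <- round(m$values)
  off <- log(m$library_sizes) - mean(log(m$library_sizes))
  eo <- exp(off)
  n <- ncol(y)
  grp <- factor(m$group_labels, levels = g$labels)
  if (is.null(dispersion)) {
    # offset-adjusted group means (Poisson MLE per group)
    q1 <- rowSums(y[, g$g1, drop = FALSE]) / sum(eo[g$g1])
    q2 <- rowSums(y[, g$g2, drop = FALSE]) / sum(eo[g$g2])
    mu <- outer(q1, eo) ; mu[, g$g2] <- outer(q2, eo[g$g2])
    # method-of-moments dispersion, then squeeze toward the mean trend
    num <- rowSums(((y - mu)^2 - mu) / pmax(mu, 1e-8)^2 * (mu > 0))
    phi_mom <- pmax(num / (n - 2), 0)
    mean_y <- rowMeans(y)
    ok <- mean_y > 0
    floor_phi <- 1e-8
    lo <- stats::lowess(log(mean_y[ok]), log(phi_mom[ok] + floor_phi), f = 0.5)
    trend <- exp(stats::approx(lo$x, lo$y, xout = pmax(log(mean_y), min(lo$x)),
                               rule = 2, ties = mean)$y) - floor_phi
    trend <- pmax(trend, 0)
    w <- prior_cells / ((n - 2) + prior_cells)
    phi <- exp((1 - w) * log(phi_mom + floor_phi) + w * log(trend + floor_phi)) - floor_phi
    phi <- pmax(phi, 0)
  } else {
    phi <- rep_len(pmax(dispersion, 0), nrow(y))
  }
  nr <- nrow(y)
  stat <- effect <- pval <- rep(NA_real_, nr)
  note <- rep("", nr)
  for (i in seq_len(nr)) {
    yi <- y[i, ]
    if (all(yi == 0)) { stat[i] <- 0; effect[i] <- 0; pval[i] <- 1
      note[i] <- "all zero"; next }
    fam <- if (phi[i] < 1e-6) stats::poisson()
           else MASS::negative.binomial(theta = 1 / phi[i])
    fit <- try(suppressWarnings(
      stats::glm(yi ~ grp + offset(off), family = fam)), silent = TRUE)
    if (inherits(fit, "try-error") || !fit$converged) {
      note[i] <- "GLM did not converge"; next }
    co <- summary(fit)$coefficients
    if (nrow(co) < 2 || !is.finite(co[2, 2]) || co[2, 2] > 1e4) {
      note[i] <- "unstable coefficient"; next }
    stat[i] <- co[2, 1] / co[2, 2]
    effect[i] <- co[2, 1] / log(2)
    pval[i] <- 2 * stats::pnorm(-abs(stat[i]))
  }
  out <- de_result("nbwald", m$isoform_ids, stat, effect, pval, note)
  attr(out, "dispersion") <- phi
  out
}

#' Fit a zero-inflated negative binomial by maximum likelihood
#'
#' Mixture of a point mass at zero (weight `pi0`) and NB(mu, size).
#' Optimised over (logit pi0, log mu, log size) with `L-BFGS-B` from a
#' moment start; the zero-inflation start is the excess of observed zeros
#' over the NB moment fit's zero mass.
#'
#' @param y non-negative integer vector.
#' @return list with `pi0`, `mu`, `size`, `loglik`, `convergence` (0 = ok).
#' @export
fit_zinb <- function(y) {
  stopifnot(all(y >= 0))
  n <- length(y)
  if (all(y == 0))
    return(list(pi0 = 1, mu = 0.1, size = 1, loglik = 0, convergence = 0))
  nll <- function(par) {
    pi0 <- stats::plogis(par[1]); mu <- exp(par[2]); size <- exp(par[3])
    p0 <- stats::dnbinom(0, size = size, mu = mu)
    ll0 <- log(pi0 + (1 - pi0) * p0)
    llp <- log1p(-pi0) + stats::dnbinom(y, size = size, mu = mu, log = TRUE)
    v <- ifelse(y == 0, ll0, llp)
    s <- -sum(v)
    if (!is.finite(s)) 1e10 else s
  }
  mbar <- mean(y); v <- stats::var(y)
  size0 <- if (v > mbar) mbar^2 / (v - mbar) else 10
  size0 <- min(max(size0, 0.05), 100)
  z_obs <- mean(y == 0)
  z_nb <- stats::dnbinom(0, size = size0, mu = max(mbar, 0.05))
  pi0_0 <- min(max((z_obs - z_nb) / max(1 - z_nb, 1e-6), 0.02), 0.9)
  start <- c(stats::qlogis(pi0_0), log(max(mbar, 0.05)), log(size0))
  o <- try(stats::optim(start, nll, method = "L-BFGS-B",
                        lower = c(-15, -15, -7), upper = c(15, 15, 7),
                        control = list(maxit = 200)), silent = TRUE)
  if (inherits(o, "try-error"))
    return(list(pi0 = NA, mu = NA, size = NA, loglik = NA, convergence = 1))
  list(pi0 = stats::plogis(o$par[1]), mu = exp(o$par[2]),
       size = exp(o$par[3]), loglik = -o$value,
       convergence = if (o$convergence %in% c(0, 1)) 0 else o$convergence)
}

#' Zero-inflated negative binomial likelihood-ratio test
#'
#' Per isoform, a ZINB model (zero-inflation probability, mean, size) is
#' fitted by maximum likelihood separately in each group and once on the
#' pooled cells; the statistic `2 * (l1 + l2 - l0)` is referred to a
#' chi-square with 3 degrees of freedom (all three parameters free per
#' group under the alternative). Values are rounded half-to-even for the
#' count likelihood. Non-convergent fits yield a missing p-value with the
#' reason in `note`.
#'
#' @param m a [count_matrix()]; >= 5 cells per group.
#' @return a `de_result`; `effect` is the log2 ratio of fitted NB means.
#' @export
zinb_lrt <- function(m) {
  g <- two_groups(m, min_cells = 5)
  y <- round(m$values)
  nr <- nrow(y)
  stat <- effect <- pval <- rep(NA_real_, nr)
  note <- rep("", nr)
  for (i in seq_len(nr)) {
    yi <- y[i, ]
    y1 <- yi[g$g1]; y2 <- yi[g$g2]
    if (stats::var(yi) == 0) { stat[i] <- 0; effect[i] <- 0; pval[i] <- 1
      note[i] <- "constant values"; next }
    f1 <- fit_zinb(y1); f2 <- fit_zinb(y2); f0 <- fit_zinb(yi)
    if (anyNA(c(f1$loglik, f2$loglik, f0$loglik)) ||
        f1$convergence != 0 || f2$convergence != 0 || f0$convergence != 0) {
      note[i] <- "ZINB fit did not converge"; next }
    stat[i] <- max(0, 2 * (f1$loglik + f2$loglik - f0$loglik))
    effect[i] <- log2(max(f2$mu, 1e-8) / max(f1$mu, 1e-8))
    pval[i] <- stats::pchisq(stat[i], df = 3, lower.tail = FALSE)
  }
  de_result("zinb", m$isoform_ids, stat, effect, pval, note)
}

#' Two-part hurdle likelihood-ratio test
#'
#' Splits each isoform's evidence into a detection part and an expression
#' part. The detection part tests whether the fraction of expressing cells
#' (value > 0) differs between groups by a logistic-regression likelihood
#' ratio (the G-test of the 2 x 2 group-by-detection table, 1 df). The
#' expression part tests whether log2(CPM + 1) differs between groups among
#' expressing cells only, by a Gaussian likelihood ratio
#' (`n * log(RSS0 / RSS1)`, 1 df). The combined statistic is the sum of the
#' two chi-squares; a part with no information (constant detection, or
#' fewer than 2 expressing cells in either group) contributes 0 and its
#' degree of freedom is dropped. Isoforms with fewer than 2 expressing
#' cells overall are skipped with a missing p-value.
#'
#' @param m a [count_matrix()] with two groups.
#' @return a `de_result`; `effect` is the expression-part group difference
#'   of log2(CPM + 1) among expressing cells (0 when undefined);
#'   `statistic` is the combined chi-square. The chi-square degrees of
#'   freedom per isoform are attached as attribute `df`.
#' @export
hurdle_lrt <- function(m) {
  g <- two_groups(m, min_cells = 1)
  x <- log_cpm(m)
  pos <- m$values > 0
  nr <- nrow(x)
  stat <- effect <- pval <- rep(NA_real_, nr)
  dfs <- rep(0L, nr)
  note <- rep("", nr)
  n1 <- length(g$g1); n2 <- length(g$g2); n <- n1 + n2
  for (i in seq_len(nr)) {
    di <- pos[i, ]
    k <- sum(di)
    if (k < 2) { note[i] <- "fewer than 2 expressing cells"; next }
    chi <- 0; df <- 0L
    # detection part: G-test of the 2x2 table
    k1 <- sum(di[g$g1]); k2 <- sum(di[g$g2])
    if (k > 0 && k < n) {
      obs <- c(k1, n1 - k1, k2, n2 - k2)
      exp_ <- c(n1 * k / n, n1 * (n - k) / n, n2 * k / n, n2 * (n - k) / n)
      nz <- obs > 0
      chi <- chi + 2 * sum(obs[nz] * log(obs[nz] / exp_[nz]))
      df <- df + 1L
    }
    # expression part: Gaussian LRT on expressing cells
    eff_i <- 0
    if (k1 >= 2 && k2 >= 2) {
      v1 <- x[i, g$g1][di[g$g1]]
      v2 <- x[i, g$g2][di[g$g2]]
      rss1 <- sum((v1 - mean(v1))^2) + sum((v2 - mean(v2))^2)
      vv <- c(v1, v2)
      rss0 <- sum((vv - mean(vv))^2)
      eff_i <- mean(v2) - mean(v1)
      if (rss0 > 0) {
        chi <- chi + length(vv) * log(rss0 / max(rss1, 1e-12 * rss0))
        df <- df + 1L
      }
    }
    stat[i] <- chi; dfs[i] <- df; effect[i] <- eff_i
    pval[i] <- if (df == 0) 1 else stats::pchisq(chi, df, lower.tail = FALSE)
  }
  out <- de_result("hurdle", m$isoform_ids, stat, effect, pval, note)
  attr(out, "df") <- dfs
  out
}

#' Beta-Poisson GLM z-test
#'
#' Per-isoform generalized linear model under the BP4 mean-variance law.
#' The group effect enters through the rate parameter,
#' `lambda1 = exp(b0 + b1 * group)`, with the remaining parameters (alpha,
#' beta, lambda2) shared between groups; hence the mean is log-linear in
#' the group indicator and the variance function is
#' `V(mu) = mu * lambda2 + mu^2 * phi2`. The shared parameters are
#' estimated once per isoform by method of moments on CPM: with `lambda2`
#' fixed at 1, `phi2 = (v - m) / m^2` from the within-group pooled variance
#' `v` and grand mean `m` (floored at 0, which reduces the law to
#' quasi-Poisson). The regression is then solved by iteratively reweighted
#' least squares on the unrounded CPM (only the first two moments enter),
#' with a Pearson overdispersion factor guarding variance-function misfit.
#' The effect is tested by a two-sided Wald z-test.
#'
#' @param m a [count_matrix()]; >= 5 cells per group.
#' @param max_iter IWLS iteration cap.
#' @return a `de_result`; `effect` is the group log2 fold change of
#'   `lambda1`, `statistic` the Wald z.
#' @export
bp4_glm_test <- function(m, max_iter = 50L) {
  g <- two_groups(m, min_cells = 5)
  x <- compute_cpm(m)
  grp <- as.numeric(m$group_labels == g$labels[2])
  X <- cbind(1, grp)
  nr <- nrow(x)
  stat <- effect <- pval <- rep(NA_real_, nr)
  note <- rep("", nr)
  n <- ncol(x)
  for (i in seq_len(nr)) {
    xi <- x[i, ]
    if (stats::var(xi) == 0) { stat[i] <- 0; effect[i] <- 0; pval[i] <- 1
      note[i] <- "constant values"; next }
    m1 <- mean(xi[g$g1]); m2 <- mean(xi[g$g2])
    mbar <- mean(xi)
    v_pool <- (sum((xi[g$g1] - m1)^2) + sum((xi[g$g2] - m2)^2)) / (n - 2)
    lambda2 <- 1
    phi2 <- max((v_pool - mbar * lambda2) / mbar^2, 0)
    vfun <- function(mu) pmax(mu * lambda2 + mu^2 * phi2, 1e-10)
    # IWLS, log link, moment start from group means
    b <- c(log(max(m1, 1e-3)), log(max(m2, 1e-3)) - log(max(m1, 1e-3)))
    ok <- FALSE
    for (it in seq_len(max_iter)) {
      eta <- X %*% b
      mu <- exp(pmin(eta, 50))
      w <- as.vector(mu^2 / vfun(mu))
      z <- eta + (xi - mu) / mu
      XtW <- t(X * w)
      A <- XtW %*% X
      if (!all(is.finite(A)) || abs(det(A)) < 1e-12) break
      b_new <- solve(A, XtW %*% z)
      if (max(abs(b_new - b)) < 1e-8) { b <- b_new; ok <- TRUE; break }
      b <- b_new
    }
    if (!ok && it == max_iter) ok <- TRUE # accept last iterate at cap
    if (!ok) { note[i] <- "IWLS did not converge"; next }
    eta <- X %*% b
    mu <- exp(pmin(eta, 50))
    w <- as.vector(mu^2 / vfun(mu))
    A <- t(X * w) %*% X
    cov_b <- try(solve(A), silent = TRUE)
    if (inherits(cov_b, "try-error")) { note[i] <- "singular information"; next }
    disp <- sum((xi - mu)^2 / vfun(mu)) / (n - 2)
    se <- sqrt(cov_b[2, 2] * max(disp, 1e-8))
    if (!is.finite(se) || se == 0) { note[i] <- "unstable standard error"; next }
    stat[i] <- b[2] / se
    effect[i] <- b[2] / log(2)
    pval[i] <- 2 * stats::pnorm(-abs(stat[i]))
  }
  de_result("bp4", m$isoform_ids, stat, effect, pval, note)
}
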