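#' Default parameter priors for the simulated isoform population
#'
#' Per-isoform BP4 parameters are drawn independently from these priors:
#' `alpha ~ Gamma(shape = 2, scale = 1)`, `beta ~ Gamma(shape = 2, scale = 2)`,
#' `lambda1 ~ LogNormal(meanlog = 3, sdlog = 1.5)`, `lambda2` fixed at 1.
#' The resulting population has a right-skewed mean distribution, strong
#' per-isoform overdispersion and a substantial zero fraction, the hallmarks
#' of single-cell expression matrices. Users with a real matrix can instead
#' fit per-isoform parameters via [fit_bp4()] and pass the fitted population
#' to [simulate_dataset()] directly.
#'
#' @return a list of prior settings accepted by [sample_param_population()].
#' @export
bp4_prior_defaults <- function() {
  list(alpha_shape = 2, alpha_scale = 1,
       beta_shape = 2, beta_scale = 2,
       lambda1_meanlog = 3, lambda1_sdlog = 1.5,
       lambda2 = 1)
}

#' Draw a heterogeneous BP4 parameter population
#'
#' @param n_isoforms number of isoforms.
#' @param prior prior settings, see [bp4_prior_defaults()].
#' @return a `bp4_params` object with vector fields of length `n_isoforms`.
#' @export
sample_param_population <- function(n_isoforms, prior = bp4_prior_defaults()) {
  stopifnot(n_isoforms >= 1)
  defaults <- bp4_prior_defaults()
  unknown <- setdiff(names(prior), names(defaults))
  if (length(unknown)) stop("unknown prior settings: ", paste(unknown, collapse = ", "))
  prior <- utils::modifyList(defaults, prior)
  bad <- names(prior)[!vapply(prior, function(v) is.numeric(v) && length(v) == 1 && is.finite(v) && v > 0, logical(1))]
  if (length(bad)) stop("prior settings must be positive scalars: ", paste(bad, collapse = ", "))
  bp4_params(
    alpha = stats::rgamma(n_isoforms, shape = prior$alpha_shape, scale = prior$alpha_scale),
    beta = stats::rgamma(n_isoforms, shape = prior$beta_shape, scale = prior$beta_scale),
    lambda1 = stats::rlnorm(n_isoforms, meanlog = prior$lambda1_meanlog, sdlog = prior$lambda1_sdlog),
    lambda2 = rep(prior$lambda2, n_isoforms))
}

#' Inject differential expression into a parameter population
#'
#' Flags `round(de_fraction * n)` isoforms as truly differentially expressed
#' and multiplies their `lambda1` (which controls the mean) by `2^(+lfc)` or
#' `2^(-lfc)` in the treated population, each direction with probability 1/2
#' independently per isoform. All other parameters, and all non-flagged
#' isoforms, are untouched, so the two groups share the same distribution
#' except for the injected mean shifts.
#'
#' @param params control-group `bp4_params` (vector fields).
#' @param de_fraction fraction of isoforms to flag (default 0.05).
#' @param lfc log2 fold-change magnitude applied to `lambda1` (default 1).
#' @return a list with `treated` (modified `bp4_params`) and `truth`, a
#'   data.frame with columns `de_flag`, `direction` (`"up"`/`"down"`/`NA`)
#'   and `lfc` (signed log2 fold change; 0 where unflagged).
#' @export
inject_de <- function(params, de_fraction = 0.05, lfc = 1) {
  stopifnot(inherits(params, "bp4_params"),
            de_fraction >= 0, de_fraction <= 1, lfc >= 0)
  n <- length(params$lambda1)
  n_de <- round(de_fraction * n)
  flagged <- sort(sample.int(n, n_de))
  sign <- ifelse(stats::runif(n_de) < 0.5, 1, -1)
  treated <- params
  treated$lambda1[flagged] <- params$lambda1[flagged] * 2^(sign * lfc)
  truth <- data.frame(de_flag = rep(FALSE, n),
                      direction = rep(NA_character_, n),
                      lfc = rep(0, n), stringsAsFactors = FALSE)
  truth$de_flag[flagged] <- TRUE
  truth$direction[flagged] <- ifelse(sign > 0, "up", "down")
  truth$lfc[flagged] <- sign * lfc
  list(treated = treated, truth = truth)
}

#' Simulation configuration
#'
#' Bundles every knob of the two-group simulation. Defaults describe the
#' reference scenario: 10,000 isoforms, 80 cells per group, 5% true DE at
#' log2 fold change 1, per-cell library sizes uniform on 1-3 million.
#'
#' @param n_isoforms number of isoforms before the all-zero filter.
#' @param n_cells_per_group cells in each of the two groups.
#' @param de_fraction fraction of isoforms truly DE (0 gives a null data set).
#' @param lfc log2 fold-change magnitude of the injected effects.
#' @param library_size_range length-2 numeric, uniform sampling range of
#'   per-cell library sizes.
#' @param seed integer seed; the whole simulation is a deterministic
#'   function of the config including this seed.
#' @param prior parameter-prior settings, see [bp4_prior_defaults()].
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_isoforms = 10000, n_cells_per_group = 80,
                       de_fraction = 0.05, lfc = 1,
                       library_size_range = c(1e6, 3e6),
                       seed = 1, prior = bp4_prior_defaults()) {
  stopifnot(n_isoforms >= 1, n_cells_per_group >= 1,
            de_fraction >= 0, de_fraction <= 1, lfc >= 0,
            length(library_size_range) == 2,
            library_size_range[1] > 0,
            library_size_range[1] <= library_size_range[2])
  structure(list(n_isoforms = as.integer(n_isoforms),
                 n_cells_per_group = as.integer(n_cells_per_group),
                 de_fraction = de_fraction, lfc = lfc,
                 library_size_range = as.numeric(library_size_range),
                 seed = as.integer(seed), prior = prior),
            class = "sim_config")
}

#' Simulate a two-group single-cell expression data set
#'
#' Draws a heterogeneous BP4 parameter population, injects DE into the
#' treated copy, and generates per-cell expression. Library-size variation
#' enters multiplicatively through the scale parameter: each cell `j` gets
#' `lambda2_ij = lambda2_i * L_j / T`, where `L_j` is the cell's library
#' size drawn uniformly from `library_size_range` and `T` is the expected
#' total expression of an unscaled cell, so that `E(colsum_j) = L_j`.
#' Values are therefore non-negative but generally non-integer, like
#' abundance estimates from real quantifiers. Isoforms with zero expression
#' across all cells are removed from the matrix and the truth table
#' together, keeping them aligned.
#'
#' @param cfg a [sim_config()].
#' @return a list with `matrix` (a [count_matrix()] whose `library_sizes`
#'   are the generative ones and whose groups are `"control"`/`"treated"`),
#'   `truth` (data.frame: `isoform_id`, `de_flag`, `direction`, `lfc`,
#'   aligned with the matrix rows) and `params` (the control population).
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_isoforms
  nc <- cfg$n_cells_per_group
  ctrl <- sample_param_population(n, cfg$prior)
  inj <- inject_de(ctrl, cfg$de_fraction, cfg$lfc)
  lib <- stats::runif(2 * nc, cfg$library_size_range[1], cfg$library_size_range[2])
  # expected unscaled cell total, from the control population
  T0 <- sum(bp4_moments(ctrl)$mean)
  s <- lib / T0
  draw_group <- function(p, cols) {
    b <- matrix(stats::rbeta(n * length(cols), p$alpha, p$beta), n, length(cols))
    k <- matrix(stats::rpois(n * length(cols), p$lambda1 * b), n, length(cols))
    sweep(k * p$lambda2, 2, s[cols], `*`)
  }
  x <- cbind(draw_group(ctrl, seq_len(nc)),
             draw_group(inj$treated, nc + seq_len(nc)))
  iso <- sprintf("iso%05d", seq_len(n))
  keep <- rowSums(x) > 0
  m <- count_matrix(x[keep, , drop = FALSE],
                    isoform_ids = iso[keep],
                    cell_ids = sprintf("cell%03d", seq_len(2 * nc)),
                    group_labels = rep(c("control", "treated"), each = nc),
                    library_sizes = lib)
  truth <- cbind(data.frame(isoform_id = iso, stringsAsFactors = FALSE),
                 inj$truth)[keep, , drop = FALSE]
  rownames(truth) <- NULL
  list(matrix = m, truth = truth, params = ctrl)
}

#' Build a null data set by resampling cells ignoring group labels
#'
#' Samples `2 * n_per_group` cells without replacement from the pooled cell
#' set of `m` (labels discarded) and assigns them to two pseudo-groups. By
#' construction the pseudo-groups share one distribution, so any DE call on
#' the result is a false positive. This is the null construction applied to
#' user-supplied real matrices; for simulated data, regenerating with
#' `de_fraction = 0` is the preferred null (both routes are available).
#'
#' @param m a [count_matrix()].
#' @param n_per_group cells per pseudo-group.
#' @return a [count_matrix()] with group labels `"null1"`/`"null2"`.
#' @export
make_null_dataset <- function(m, n_per_group) {
  validate_count_matrix(m)
  total <- length(m$cell_ids)
  if (2 * n_per_group > total)
    stop("cannot draw 2 x ", n_per_group, " cells from ", total)
  idx <- sample.int(total, 2 * n_per_group)
  subset_cells(m, idx,
               group_labels = rep(c("null1", "null2"), each = n_per_group))
}
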