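#' Benchmark configuration
#'
#' Everything needed to regenerate a full evaluation sweep: the simulation
#' settings, the scenario, which methods to run, the split sizes and the
#' evaluation grid. All randomness flows from `seed`, which is expanded
#' into independent per-replicate simulation and split seeds so that adding
#' a method never perturbs the simulated data.
#'
#' @param methods character vector of method names, see [de_methods()].
#' @param scenario `"alternative"` (DE injected per `de_fraction`) or
#'   `"null"` (data regenerated with `de_fraction = 0`).
#' @param n_replicates independent simulate/split replicates (default 50).
#' @param n_per_set_per_group cells per group in each of the training and
#'   validation sets; default half the simulated group size.
#' @param alpha significance threshold for FPR and rediscovery (default 0.05).
#' @param fractions top-fraction grid (default `c(0.05, 0.1, 0.2, 1)`).
#' @param stratum_threshold,stratum_cell_fraction expression-stratification
#'   rule, see [stratify_by_expression()].
#' @param sim a [sim_config()] providing the generator settings; its
#'   `de_fraction` is forced to 0 under the null scenario and its seed is
#'   superseded by `seed`.
#' @param seed master seed of the sweep.
#' @return a list of class `benchmark_config`.
#' @export
benchmark_config <- function(methods = c("ttest", "wilcoxon"),
                             scenario = c("alternative", "null"),
                             n_replicates = 50,
                             n_per_set_per_group = NULL,
                             alpha = 0.05,
                             fractions = c(0.05, 0.1, 0.2, 1),
                             stratum_threshold = 1,
                             stratum_cell_fraction = 0.25,
                             sim = sim_config(),
                             seed = 1) {
  scenario <- match.arg(scenario)
  stopifnot(all(methods %in% de_methods()), n_replicates >= 1,
            alpha > 0, alpha < 1, all(fractions > 0), all(fractions <= 1))
  if (is.null(n_per_set_per_group))
    n_per_set_per_group <- sim$n_cells_per_group %/% 2
  if (2 * n_per_set_per_group > sim$n_cells_per_group)
    stop("n_per_set_per_group too large for the simulated group size")
  structure(list(methods = methods, scenario = scenario,
                 n_replicates = as.integer(n_replicates),
                 n_per_set_per_group = as.integer(n_per_set_per_group),
                 alpha = alpha, fractions = fractions,
                 stratum_threshold = stratum_threshold,
                 stratum_cell_fraction = stratum_cell_fraction,
                 sim = sim, seed = as.integer(seed)),
            class = "benchmark_config")
}

#' Run a full benchmark sweep
#'
#' For each replicate: simulate a fresh two-group data set (with no DE
#' injected under the null scenario), draw one disjoint train/validation
#' split, run every requested method on both subsets, and record FPR, RDR,
#' TrueRDR, RDR ratio and AUC per expression stratum and top fraction.
#' Strata are computed once on the training subset and reused for the
#' paired validation metrics. A failure in one (method, replicate) is
#' logged and the sweep continues.
#'
#' @param cfg a [benchmark_config()].
#' @param progress print one line per replicate.
#' @return a list with `table` (long-format data.frame: `method`,
#'   `replicate`, `stratum`, `top_fraction`, `metric`, `value`), `failures`
#'   (data.frame of logged errors) and `config`.
#' @export
run_benchmark <- function(cfg, progress = FALSE) {
  stopifnot(inherits(cfg, "benchmark_config"))
  set.seed(cfg$seed)
  sim_seeds <- sample.int(.Machine$integer.max - 1, cfg$n_replicates)
  split_seeds <- sample.int(.Machine$integer.max - 1, cfg$n_replicates)
  rows <- list()
  fails <- list()
  for (r in seq_len(cfg$n_replicates)) {
    if (progress) message("replicate ", r, "/", cfg$n_replicates)
    scfg <- cfg$sim
    scfg$seed <- sim_seeds[r]
    if (cfg$scenario == "null") scfg$de_fraction <- 0
    sim <- simulate_dataset(scfg)
    set.seed(split_seeds[r])
    sp <- make_splits(sim$matrix, cfg$n_per_set_per_group, 1)[[1]]
    m_train <- subset_cells(sim$matrix, sp$train)
    m_valid <- subset_cells(sim$matrix, sp$validation)
    strata <- stratify_by_expression(m_train, cfg$stratum_threshold,
                                     cfg$stratum_cell_fraction)
    strata$all <- m_train$isoform_ids
    for (method in cfg$methods) {
      res <- try({
        tr <- run_de_test(m_train, method)
        va <- run_de_test(m_valid, method)
        for (st in names(strata)) {
          ids <- strata[[st]]
          if (length(ids) == 0) next
          for (f in cfg$fractions) {
            rv <- rdr(tr, va, f, cfg$alpha, ids)
            tv <- true_rdr(tr, va, sim$truth, f, cfg$alpha, ids)
            av <- suppressWarnings(roc_auc(tr, sim$truth, f, ids))
            rows[[length(rows) + 1]] <- data.frame(
              method = method, replicate = r, stratum = st,
              top_fraction = f,
              metric = c("FPR", "RDR", "TrueRDR", "RDR_ratio", "AUC"),
              value = c(fpr(tr, cfg$alpha, ids), rv, tv,
                        rdr_ratio(tv, rv), av),
              stringsAsFactors = FALSE)
          }
        }
        NULL
      }, silent = TRUE)
      if (inherits(res, "try-error"))
        fails[[length(fails) + 1]] <- data.frame(
          method = method, replicate = r,
          error = conditionMessage(attr(res, "condition")),
          stringsAsFactors = FALSE)
    }
  }
  table <- if (length(rows)) do.call(rbind, rows) else
    data.frame(method = character(), replicate = integer(),
               stratum = character(), top_fraction = numeric(),
               metric = character(), value = numeric())
  failures <- if (length(fails)) do.call(rbind, fails) else
    data.frame(method = character(), replicate = integer(),
               error = character())
  list(table = table, failures = failures, config = cfg)
}

#' Summarise a benchmark table
#'
#' Median and quartiles of each metric per method, stratum and top
#' fraction over replicates -- the numeric content of the usual box-plot
#' panels.
#'
#' @param table the `table` element of [run_benchmark()]'s result (or a
#'   compatible long-format data.frame).
#' @return a data.frame with columns `method`, `stratum`, `top_fraction`,
#'   `metric`, `n`, `q25`, `median`, `q75`.
#' @export
summarize_benchmark <- function(table) {
  stopifnot(all(c("method", "stratum", "top_fraction", "metric", "value")
                %in% names(table)))
  key <- interaction(table$method, table$stratum, table$top_fraction,
                     table$metric, drop = TRUE, lex.order = TRUE)
  pieces <- lapply(split(seq_len(nrow(table)), key), function(idx) {
    v <- table$value[idx]
    v <- v[!is.na(v)]
    data.frame(method = table$method[idx[1]],
               stratum = table$stratum[idx[1]],
               top_fraction = table$top_fraction[idx[1]],
               metric = table$metric[idx[1]],
               n = length(v),
               q25 = if (length(v)) unname(stats::quantile(v, 0.25)) else NA_real_,
               median = if (length(v)) stats::median(v) else NA_real_,
               q75 = if (length(v)) unname(stats::quantile(v, 0.75)) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$method, out$stratum, out$top_fraction, out$metric), ]
  rownames(out) <- NULL
  out
}
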