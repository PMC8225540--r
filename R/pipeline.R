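#' Run one benchmark scenario end to end
#'
#' For each replicate: simulate a population, fit the base model, compute
#' clearance EBEs. Hyper-parameters are tuned once per scenario (5-fold CV
#' on up to `tune_datasets` replicates) and reused across replicates; each
#' ML method then produces one importance ranking per replicate. Selections
#' are evaluated with all requested approaches (top-M with M = number of
#' true covariates; order-of-importance and minimum-of-importance at the
#' accuracy-maximizing threshold), and the pooled ROC/AUROC is built from
#' the order-of-importance sweep. The SCM comparator ("scm" in `methods`)
#' reuses the cached base-model fits.
#'
#' @param spec a [scenario_spec()].
#' @param methods subset of `c("rf", "svr_linear", "svr_rbf", "nn", "scm")`.
#' @param approaches subset of `c("top_m", "order", "min")` (ML methods
#'   only).
#' @param pop a [pop_params()].
#' @param n_replicates overrides `spec$n_replicates`.
#' @param master_seed master seed; all stage seeds derive from it.
#' @param n_shuffles permutation-importance shuffles.
#' @param tune_datasets replicates used for hyper-parameter tuning.
#' @param control optimizer control for [fit_population()].
#' @return object of class `scenario_result`: per-method metrics (mean/SD
#'   F1 per approach, AUROC), shrinkage summary, per-replicate artifacts.
#' @export
run_scenario <- function(spec, methods = "rf",
                         approaches = c("top_m", "order", "min"),
                         pop = pop_params(),
                         n_replicates = spec$n_replicates,
                         master_seed = spec$seed, n_shuffles = 100L,
                         tune_datasets = 3L, control = list()) {
  methods <- match.arg(methods, c("rf", "svr_linear", "svr_rbf", "nn", "scm"),
                       several.ok = TRUE)
  approaches <- match.arg(approaches, c("top_m", "order", "min"),
                          several.ok = TRUE)
  struct <- build_covariate_structure(spec,
                                      rng_seed = derive_seed(master_seed, spec$name, 0L))
  truth <- struct$truth_labels
  n_true <- sum(truth)
  ml_methods <- setdiff(methods, "scm")
  datasets <- vector("list", n_replicates)
  ebes <- vector("list", n_replicates)
  fits <- vector("list", n_replicates)
  shrink <- matrix(NA_real_, n_replicates, 3,
                   dimnames = list(NULL, c("V", "CL", "ka")))
  for (k in seq_len(n_replicates)) {
    ds <- simulate_dataset(spec, struct, pop,
                           replicate_seed = derive_seed(master_seed, spec$name, k))
    fit <- fit_population(ds, control = control)
    datasets[[k]] <- ds
    fits[[k]] <- fit
    if (fit$converged) {
      eb <- compute_ebes(ds, fit)
      ebes[[k]] <- eb
      shrink[k, ] <- attr(eb, "shrinkage")
    }
  }
  ok <- !vapply(ebes, is.null, logical(1))
  results <- list()
  for (m in ml_methods) {
    tune_ix <- which(ok)[seq_len(min(tune_datasets, sum(ok)))]
    xy <- lapply(tune_ix, function(k) {
      covs <- datasets[[k]]$covariates
      list(x = covs[, setdiff(names(covs), "ID"), drop = FALSE],
           y = ebes[[k]]$CL_EBE[match(covs$ID, ebes[[k]]$ID)])
    })
    hp <- grid_search_hyperparams(xy, m,
                                  seed = derive_seed(master_seed, paste0(spec$name, ".tune.", m), 0L))
    scores <- vector("list", n_replicates)
    for (k in which(ok)) {
      scores[[k]] <- screen_covariates(
        datasets[[k]], ebes[[k]], hp,
        seed = derive_seed(master_seed, paste0(spec$name, ".", m), k),
        n_shuffles = n_shuffles)
    }
    scores <- scores[ok]
    roc <- roc_curve(scores, truth)
    f1 <- list()
    sel_meta <- list()
    for (ap in approaches) {
      if (ap == "top_m") {
        sels <- lapply(scores, select_top_m, m = n_true)
        sel_meta[[ap]] <- list(m = n_true)
      } else {
        opt <- optimize_threshold(scores, truth, approach = ap)
        sels <- if (ap == "order") {
          lapply(scores, select_order_of_importance, threshold = opt$threshold)
        } else {
          lapply(scores, select_min_importance, threshold = opt$threshold)
        }
        sel_meta[[ap]] <- list(threshold = opt$threshold,
                               accuracy = opt$accuracy)
      }
      f1[[ap]] <- vapply(sels, function(s)
        f1_score(confusion_counts(s, truth)), numeric(1))
    }
    results[[m]] <- list(hyperparams = hp, scores = scores, roc = roc,
                         auroc = roc$auroc, f1 = f1, selection = sel_meta)
  }
  if ("scm" %in% methods) {
    f1_scm <- f1_scm_tr <- rep(NA_real_, n_replicates)
    scm_sels <- vector("list", n_replicates)
    for (k in which(vapply(fits, function(f) isTRUE(f$converged), logical(1)))) {
      sel <- tryCatch(
        scm_search(datasets[[k]], base_fit = fits[[k]], control = control),
        error = function(e) NULL)
      if (is.null(sel)) next
      scm_sels[[k]] <- sel
      f1_scm[k] <- f1_score(confusion_counts(sel, truth))
      f1_scm_tr[k] <- f1_score(
        confusion_counts(sel, truth, "selected_with_true_relationship"))
    }
    results[["scm"]] <- list(
      selections = scm_sels,
      f1 = list(scm = f1_scm[!is.na(f1_scm)],
                scm_tr = f1_scm_tr[!is.na(f1_scm_tr)])
    )
  }
  structure(list(
    scenario = spec$name, spec = spec, structure = struct, truth = truth,
    n_replicates = n_replicates, converged = ok,
    shrinkage = shrink, results = results,
    master_seed = master_seed
  ), class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result %s> %d replicates (%d converged)\n",
              x$scenario, x$n_replicates, sum(x$converged)))
  cat(sprintf("  mean CL shrinkage: %.1f%%\n",
              mean(x$shrinkage[, "CL"], na.rm = TRUE)))
  for (m in names(x$results)) {
    r <- x$results[[m]]
    if (!is.null(r$auroc))
      cat(sprintf("  %-10s AUROC %.3f; mean F1 %s\n", m, r$auroc,
                  paste(sprintf("%s=%.2f", names(r$f1),
                                vapply(r$f1, mean, numeric(1))),
                        collapse = " ")))
    else
      cat(sprintf("  %-10s mean F1 %s\n", m,
                  paste(sprintf("%s=%.2f", names(r$f1),
                                vapply(r$f1, mean, numeric(1))),
                        collapse = " ")))
  }
  invisible(x)
}

#' Read a benchmark configuration file
#'
#' YAML with keys `scenarios` (list of labels or `"all"`), `n_subjects`,
#' `n_replicates`, `master_seed`, `shrinkage_scenarios`,
#' `extreme_scenario`, `methods`, `approaches`, `preset`.
#'
#' @param path YAML file path.
#' @return named list (config).
#' @export
read_benchmark_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$preset)) cfg$n_replicates <- preset_replicates(cfg$preset)
  cfg
}

#' Replicate counts of the benchmark presets
#'
#' `"smoke"` (3 replicates) for plumbing checks, `"desk"` (10) for
#' desk-scale runs, `"full"` (100) for the complete benchmark.
#'
#' @param preset preset name.
#' @return integer replicate count.
#' @export
preset_replicates <- function(preset = c("desk", "smoke", "full")) {
  preset <- match.arg(preset)
  c(smoke = 3L, desk = 10L, full = 100L)[[preset]]
}

#' Run the full benchmark over a scenario grid
#'
#' Iterates [run_scenario()] over the grid and aggregates a summary table:
#' per method and selection approach, the mean (SD) F1 across scenarios,
#' the number of scenarios with perfect selection (F1 = 1 on every
#' replicate), and the mean AUROC for ML methods.
#'
#' @param config benchmark config list (see [read_benchmark_config()]).
#' @param out_dir optional directory for per-scenario CSV/JSON artifacts.
#' @return object of class `benchmark_result`: `scenarios` (list of
#'   `scenario_result`), `summary` (data.frame), `per_scenario`
#'   (data.frame).
#' @export
run_benchmark <- function(config = list(), out_dir = NULL) {
  grid <- build_scenario_grid(config)
  if (!length(grid)) stop("empty scenario grid")
  methods <- config$methods %||% "rf"
  approaches <- config$approaches %||% c("top_m", "order", "min")
  n_shuffles <- config$n_shuffles %||% 100L
  tune_datasets <- config$tune_datasets %||% 3L
  master_seed <- config$master_seed %||% 1L
  res <- lapply(grid, function(sp)
    run_scenario(sp, methods = methods, approaches = approaches,
                 n_replicates = config$n_replicates %||% sp$n_replicates,
                 master_seed = derive_seed(master_seed, sp$name, 0L),
                 n_shuffles = n_shuffles, tune_datasets = tune_datasets))
  names(res) <- vapply(grid, `[[`, "", "name")
  rows <- list()
  for (sr in res) {
    for (m in names(sr$results)) {
      f1l <- sr$results[[m]]$f1
      for (ap in names(f1l)) {
        f1 <- f1l[[ap]]
        rows[[length(rows) + 1]] <- data.frame(
          scenario = sr$scenario, method = m, approach = ap,
          mean_f1 = mean(f1), sd_f1 = stats::sd(f1),
          perfect = all(f1 == 1),
          auroc = sr$results[[m]]$auroc %||% NA_real_,
          mean_cl_shrinkage = mean(sr$shrinkage[, "CL"], na.rm = TRUE)
        )
      }
    }
  }
  per_scenario <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(
    split(per_scenario, list(per_scenario$method, per_scenario$approach),
          drop = TRUE),
    function(d) data.frame(
      method = d$method[1], approach = d$approach[1],
      n_perfect_scenarios = sum(d$perfect),
      mean_f1 = mean(d$mean_f1), sd_f1 = stats::sd(d$mean_f1),
      mean_auroc = if (all(is.na(d$auroc))) NA_real_ else mean(d$auroc)
    )))
  rownames(agg) <- NULL
  out <- structure(list(scenarios = res, summary = agg,
                        per_scenario = per_scenario, config = config),
                   class = "benchmark_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(per_scenario, file.path(out_dir, "per_scenario.csv"),
                     row.names = FALSE)
    utils::write.csv(agg, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
  }
  out
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("<benchmark_result> %d scenarios\n", length(x$scenarios)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
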