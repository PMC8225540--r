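#' Covariate selection from importance scores
#'
#' Three rules turn a normalized importance ranking into a covariate set:
#' top-M keeps the M highest-scoring covariates; order-of-importance walks
#' down the ranking until the cumulative score reaches a threshold;
#' minimum-of-importance keeps every covariate whose score strictly exceeds
#' a floor. Ties in score are broken by covariate name for determinism.
#'
#' @name selection
NULL

.ranked_scores <- function(scores) {
  df <- as.data.frame(scores)
  df[order(-df$score, df$covariate), c("covariate", "score")]
}

.selection_result <- function(selected, approach, threshold_or_m,
                              relationships = NULL) {
  structure(list(selected = selected, approach = approach,
                 threshold_or_m = threshold_or_m,
                 relationships = relationships),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection:%s> %s\n", x$approach,
              if (length(x$selected)) paste(x$selected, collapse = ", ")
              else "(empty)"))
  invisible(x)
}

#' @rdname selection
#' @param scores an `importance_result` (or data.frame with `covariate`,
#'   `score`).
#' @param m number of covariates to keep (top-M rule). In benchmark mode M
#'   is set to the number of true covariates of the scenario.
#' @export
select_top_m <- function(scores, m) {
  rk <- .ranked_scores(scores)
  if (m < 1 || m > nrow(rk)) stop("M out of range [1, ", nrow(rk), "]")
  .selection_result(rk$covariate[seq_len(m)], "top_m", m)
}

#' @rdname selection
#' @param threshold cumulative-score threshold in [0, 1]
#'   (order-of-importance) or strict score floor (minimum-of-importance).
#' @export
select_order_of_importance <- function(scores, threshold) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  rk <- .ranked_scores(scores)
  if (threshold == 0) return(.selection_result(character(0), "order", 0))
  cum <- cumsum(rk$score)
  k <- match(TRUE, cum >= threshold - 1e-12, nomatch = nrow(rk))
  .selection_result(rk$covariate[seq_len(k)], "order", threshold)
}

#' @rdname selection
#' @export
select_min_importance <- function(scores, threshold) {
  if (threshold < 0) stop("threshold must be >= 0")
  rk <- .ranked_scores(scores)
  .selection_result(rk$covariate[rk$score > threshold], "min", threshold)
}

#' Accuracy-maximizing threshold for a selection rule
#'
#' Sweeps thresholds over a fixed grid (0 to 1, step `step`); for each
#' candidate, applies the rule to every replicate's scores, pools the
#' confusion counts against the truth labels, and computes the selection
#' accuracy `(TP + TN) / (TP + TN + FP + FN)`. Returns the
#' accuracy-maximizing threshold, ties broken toward the smaller value.
#' Requires truth labels, so this mirrors the benchmark calibration and is
#' unavailable for real data.
#'
#' @param scores_list list of `importance_result`s (replicates of one
#'   scenario and method).
#' @param truth named logical vector: `TRUE` for true covariates.
#' @param approach `"order"` or `"min"`.
#' @param step grid step (default 0.01).
#' @return list with `threshold`, `accuracy`, and the swept `grid`.
#' @export
optimize_threshold <- function(scores_list, truth,
                               approach = c("order", "min"), step = 0.01) {
  approach <- match.arg(approach)
  if (length(scores_list) < 1) stop("no replicates supplied")
  grid <- seq(0, 1, by = step)
  select_fn <- if (approach == "order") select_order_of_importance
               else select_min_importance
  acc <- vapply(grid, function(th) {
    tp <- tn <- fp <- fn <- 0
    for (sc in scores_list) {
      sel <- select_fn(sc, th)$selected
      cc <- confusion_counts(.selection_result(sel, approach, th), truth)
      tp <- tp + cc$tp; tn <- tn + cc$tn; fp <- fp + cc$fp; fn <- fn + cc$fn
    }
    (tp + tn) / (tp + tn + fp + fn)
  }, numeric(1))
  best <- which.max(acc) # which.max takes the first (smallest) maximizer
  list(threshold = grid[best], accuracy = acc[best],
       grid = data.frame(threshold = grid, accuracy = acc))
}

# candidate relationship forms per covariate class; categorical covariates
# only admit the linear form
.scm_candidate_forms <- function(covariate) {
  if (grepl("^CA", covariate)) "linear_cat"
  else c("linear", "power", "exponential", "piecewise")
}

#' Stepwise covariate modeling (forward inclusion / backward elimination)
#'
#' Forward step: every candidate (covariate, form) pair not yet in the
#' model is added to the current model on clearance, the extended model is
#' refit, and the likelihood-ratio p-value against the current model is
#' computed (1 df for linear/power/exponential, 2 df for the piecewise
#' hockey-stick). The single best relationship is added while its p-value
#' is below `p_forward`; once a covariate is included, its other forms are
#' no longer tested. Backward step: each included relationship is removed
#' in turn and dropped (largest p first) while its re-inclusion p-value
#' exceeds `p_backward`. Non-convergent candidate fits are skipped with a
#' warning, never aborting the search.
#'
#' @param dataset a `pop_pk_dataset`.
#' @param candidates covariate names to test (default: all covariate
#'   columns).
#' @param p_forward,p_backward inclusion/elimination p-value cutoffs
#'   (defaults 0.05 and 0.01).
#' @param base_fit optional pre-computed base-model fit (cached by the
#'   pipeline).
#' @param control optimizer control passed to [fit_population()].
#' @return a `selection_result` with `relationships` (final forms and
#'   coefficients), plus attributes `trace` (fit log) and `final_fit`.
#' @export
scm_search <- function(dataset, candidates = NULL, p_forward = 0.05,
                       p_backward = 0.01, base_fit = NULL, control = list()) {
  if (is.null(candidates))
    candidates <- setdiff(names(dataset$covariates), "ID")
  # candidate fits need OFV differences reliable to ~0.1, not fully polished
  # optima; a looser stopping rule keeps the search tractable
  control <- utils::modifyList(list(factr = 1e9, polish = FALSE), control)
  if (is.null(base_fit)) base_fit <- fit_population(dataset, control = control)
  if (!base_fit$converged) stop("base model fit did not converge")
  meds <- vapply(candidates, function(v) {
    if (grepl("^CO", v)) stats::median(dataset$covariates[[v]]) else 0
  }, numeric(1))
  current <- list(fit = base_fit, rels = list())
  trace <- list()
  refit <- function(rels, warm_from) {
    # warm start: current estimates carried over, new betas at 0
    nb <- sum(vapply(rels, function(r) .rel_df(r$form), 1L))
    start <- c(warm_from$theta_raw[1:7], rep(0, nb))
    b <- 8L
    for (r in rels) {
      k <- .rel_df(r$form)
      if (!is.null(r$coef)) start[b:(b + k - 1)] <- r$coef
      b <- b + k
    }
    fit_population(dataset, relationships = rels, start = start,
                   method = base_fit$method,
                   nq = if (is.na(base_fit$nq)) 11L else base_fit$nq,
                   control = control)
  }
  # profile screen: optimize only the candidate's coefficient(s) with the
  # parent model frozen; a cheap lower bound on the full OFV drop used to
  # rank candidates
  profile_dofv <- function(rel, parent) {
    rels <- c(parent$rels, list(rel))
    fd <- .fit_data(dataset, rels)
    dose <- dataset$records$AMT[dataset$records$EVID == 1][1]
    eta_cache <- cbind(matrix(0, length(fd$ids), 3),
                       matrix(NA_real_, length(fd$ids), 3))
    k <- .rel_df(rel$form)
    fixed <- c(parent$fit$theta_raw)
    obj_b <- function(b) {
      cpp_marginal_neg2ll(c(fixed, b), fd$times, fd$logdv, fd$obs_start,
                          fd$obs_len, dose, fd$xrel, fd$rel_type, fd$rel_med,
                          eta_cache)
    }
    lim <- if (rel$form %in% c("power", "exponential")) 30 else 20
    o <- tryCatch(
      stats::optim(rep(0, k), obj_b, method = "L-BFGS-B", lower = -lim,
                   upper = lim,
                   control = list(maxit = 25L, factr = 1e10,
                                  ndeps = rep(1e-6, k))),
      error = function(e) NULL)
    if (is.null(o) || !is.finite(o$value)) return(NA_real_)
    parent$fit$minus2ll - o$value
  }
  # ---- forward inclusion: every candidate is first scored by the profile
  # drop; only the leaders (within `slack` OFV units of the best screened
  # drop) are refit to completion, and the inclusion test uses the
  # completed fits
  slack <- 3
  repeat {
    in_model <- vapply(current$rels, `[[`, "", "covariate")
    cand <- setdiff(candidates, in_model)
    if (!length(cand)) break
    screened <- list()
    for (v in cand) {
      for (form in .scm_candidate_forms(v)) {
        rel <- list(covariate = v, form = form, median = meds[[v]])
        dofv <- profile_dofv(rel, current)
        if (is.na(dofv)) next
        screened[[length(screened) + 1]] <- list(rel = rel, dofv = dofv)
      }
    }
    if (!length(screened)) break
    dofvs <- vapply(screened, `[[`, 0, "dofv")
    keep <- which(dofvs > max(dofvs) - slack & dofvs > 1e-8)
    if (!length(keep)) break
    best <- NULL
    for (ix in keep) {
      rel <- screened[[ix]]$rel
      v <- rel$covariate
      fit <- tryCatch(refit(c(current$rels, list(rel)), current$fit),
                      error = function(e) NULL)
      if (is.null(fit) || !fit$converged) {
        warning("skipping non-convergent candidate ", v, ":", rel$form)
        next
      }
      df <- .rel_df(rel$form)
      p <- lrt_pvalue(current$fit$minus2ll, fit$minus2ll, df)
      dofv <- current$fit$minus2ll - fit$minus2ll
      trace[[length(trace) + 1]] <- list(step = "forward", covariate = v,
                                         form = rel$form, p = p, dofv = dofv)
      better <- is.null(best) || p < best$p - 1e-12 ||
        (abs(p - best$p) <= 1e-12 && dofv > best$dofv + 1e-9) ||
        (abs(p - best$p) <= 1e-12 && abs(dofv - best$dofv) <= 1e-9 &&
           v < best$rel$covariate)
      if (better) best <- list(rel = rel, fit = fit, p = p, dofv = dofv)
    }
    if (is.null(best) || best$p >= p_forward) break
    rel <- best$rel
    nb <- length(best$fit$betas)
    k <- .rel_df(rel$form)
    rel$coef <- best$fit$betas[(nb - k + 1):nb]
    current <- list(fit = best$fit, rels = c(current$rels, list(rel)))
  }
  # refresh stored coefficients from the accepted fit
  .sync_coefs <- function(rels, fit) {
    b <- 1L
    for (i in seq_along(rels)) {
      k <- .rel_df(rels[[i]]$form)
      rels[[i]]$coef <- fit$betas[b:(b + k - 1)]
      b <- b + k
    }
    rels
  }
  if (length(current$rels))
    current$rels <- .sync_coefs(current$rels, current$fit)
  # ---- backward elimination
  repeat {
    if (!length(current$rels)) break
    worst <- NULL
    for (i in seq_along(current$rels)) {
      reduced <- current$rels[-i]
      fit <- tryCatch(refit(reduced, current$fit), error = function(e) NULL)
      if (is.null(fit) || !fit$converged) {
        warning("skipping non-convergent reduced model without ",
                current$rels[[i]]$covariate)
        next
      }
      df <- .rel_df(current$rels[[i]]$form)
      p <- lrt_pvalue(fit$minus2ll, current$fit$minus2ll, df)
      trace[[length(trace) + 1]] <- list(step = "backward",
                                         covariate = current$rels[[i]]$covariate,
                                         form = current$rels[[i]]$form, p = p,
                                         dofv = fit$minus2ll - current$fit$minus2ll)
      if (is.null(worst) || p > worst$p ||
          (p == worst$p && current$rels[[i]]$covariate < worst$covariate)) {
        worst <- list(i = i, p = p, fit = fit,
                      covariate = current$rels[[i]]$covariate)
      }
    }
    if (is.null(worst) || worst$p <= p_backward) break
    current <- list(fit = worst$fit, rels = current$rels[-worst$i])
    if (length(current$rels))
      current$rels <- .sync_coefs(current$rels, current$fit)
  }
  selected <- vapply(current$rels, `[[`, "", "covariate")
  rels <- current$rels
  names(rels) <- selected
  out <- .selection_result(selected, "scm",
                           c(p_forward = p_forward, p_backward = p_backward),
                           relationships = rels)
  attr(out, "trace") <- trace
  attr(out, "final_fit") <- current$fit
  out
}
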