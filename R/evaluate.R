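#' Confusion counts of a covariate selection
#'
#' Under the `"selected"` definition a true positive is any true covariate
#' in the selection. Under `"selected_with_true_relationship"` (the
#' SCM_TR-style scoring) a selected true continuous covariate counts as a
#' true positive only if its fitted form is `"power"`, and a categorical one
#' only if its form is the (categorical) linear form - the generating forms
#' of the true model. A true covariate selected with the wrong form is
#' counted as a missed true positive (FN), not as an extra FP, since the
#' covariate itself is true.
#'
#' @param selection a `selection_result`.
#' @param truth named logical vector over all scenario covariates (`TRUE`
#'   for true covariates).
#' @param tp_definition `"selected"` (default) or
#'   `"selected_with_true_relationship"`.
#' @return object of class `confusion_counts`: list `tp`, `fp`, `tn`, `fn`,
#'   `tp_definition`.
#' @export
confusion_counts <- function(selection, truth,
                             tp_definition = c("selected",
                                               "selected_with_true_relationship")) {
  tp_definition <- match.arg(tp_definition)
  sel <- selection$selected
  unknown <- setdiff(sel, names(truth))
  if (length(unknown))
    stop("selection contains unknown covariate(s): ",
         paste(unknown, collapse = ", "))
  true_cov <- names(truth)[truth]
  false_cov <- names(truth)[!truth]
  sel_true <- intersect(sel, true_cov)
  if (tp_definition == "selected_with_true_relationship") {
    ok_form <- vapply(sel_true, function(v) {
      rel <- selection$relationships[[v]]
      if (is.null(rel)) return(TRUE) # score-based selections carry no form
      if (grepl("^CA", v)) rel$form == "linear_cat" else rel$form == "power"
    }, logical(1))
    sel_true <- sel_true[ok_form]
  }
  tp <- length(sel_true)
  fp <- length(intersect(sel, false_cov))
  structure(list(tp = tp, fp = fp,
                 tn = length(false_cov) - fp,
                 fn = length(true_cov) - tp,
                 tp_definition = tp_definition),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion> TP=%d FP=%d TN=%d FN=%d (%s)\n",
              x$tp, x$fp, x$tn, x$fn, x$tp_definition))
  invisible(x)
}

#' F1 score
#'
#' Harmonic mean of recall `TP/(TP+FN)` and precision `TP/(TP+FP)`;
#' returns 0 when either is 0 or undefined.
#'
#' @param counts a [confusion_counts()].
#' @return value in [0, 1].
#' @export
f1_score <- function(counts) {
  tp <- counts$tp
  if (tp == 0) return(0)
  recall <- tp / (tp + counts$fn)
  precision <- tp / (tp + counts$fp)
  2 * recall * precision / (recall + precision)
}

#' Selection accuracy
#'
#' `(TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param counts a [confusion_counts()].
#' @return value in [0, 1].
#' @export
accuracy <- function(counts) {
  n <- counts$tp + counts$fp + counts$tn + counts$fn
  if (n == 0) stop("no predictions")
  (counts$tp + counts$tn) / n
}

#' ROC curve and AUROC of an importance ranking
#'
#' The order-of-importance threshold is swept from 0 to 1 (step `step`);
#' at each threshold the per-replicate selections are pooled into one
#' confusion table from which (FPR, TPR) is computed. Covariates with tied
#' scores receive fractional (mid-rank) credit, the standard ROC tie
#' convention, so that uninformative uniform scores trace the diagonal
#' instead of an order determined by covariate names. The curve is anchored
#' at (0,0) and (1,1) and the AUROC obtained by trapezoidal integration
#' over the monotone FPR sequence.
#'
#' @param scores_list list of `importance_result`s (replicates).
#' @param truth named logical truth vector; the scenario must contain at
#'   least one false covariate (otherwise FPR is undefined).
#' @param step threshold grid step (default 0.005).
#' @return object of class `roc_curve`: `points` (data.frame `threshold`,
#'   `fpr`, `tpr`) and `auroc`.
#' @export
roc_curve <- function(scores_list, truth, step = 0.005) {
  if (length(scores_list) < 1) stop("no replicates supplied")
  if (!any(!truth)) stop("FPR undefined: scenario has no false covariate")
  if (!any(truth)) stop("TPR undefined: scenario has no true covariate")
  thresholds <- seq(0, 1, by = step)
  n_true <- sum(truth); n_false <- sum(!truth)
  ranked <- lapply(scores_list, .ranked_scores)
  tpr <- fpr <- numeric(length(thresholds))
  for (i in seq_along(thresholds)) {
    th <- thresholds[i]
    tp <- fp <- 0
    for (rk in ranked) {
      if (th == 0) next
      cum <- cumsum(rk$score)
      k <- match(TRUE, cum >= th - 1e-12, nomatch = nrow(rk))
      # fractional credit within the tie group containing position k
      tie <- which(abs(rk$score - rk$score[k]) < 1e-12)
      n_above <- tie[1] - 1
      frac <- (k - n_above) / length(tie)
      full <- rk$covariate[seq_len(n_above)]
      tp <- tp + sum(truth[full]) + frac * sum(truth[rk$covariate[tie]])
      fp <- fp + sum(!truth[full]) + frac * sum(!truth[rk$covariate[tie]])
    }
    tpr[i] <- tp / (n_true * length(ranked))
    fpr[i] <- fp / (n_false * length(ranked))
  }
  pts <- data.frame(threshold = c(NA, thresholds, NA),
                    fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  ord <- order(pts$fpr, pts$tpr)
  pts <- pts[ord, ]
  auroc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                  utils::tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auroc = auroc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> AUROC = %.4f (%s)\n", x$auroc,
              classify_auroc(x$auroc)))
  invisible(x)
}

#' Qualitative AUROC category
#'
#' Maps an AUROC to the conventional qualitative bands: excellent
#' [0.9, 1], good [0.8, 0.9), fair [0.7, 0.8), poor [0.6, 0.7), failed
#' [0.5, 0.6); values below 0.5 are labeled `"worse than random"`.
#' Boundary values belong to the upper band.
#'
#' @param auroc value in [0, 1].
#' @return character label.
#' @export
classify_auroc <- function(auroc) {
  if (is.na(auroc) || auroc < 0 || auroc > 1)
    stop("AUROC must be in [0, 1]")
  if (auroc >= 0.9) "excellent"
  else if (auroc >= 0.8) "good"
  else if (auroc >= 0.7) "fair"
  else if (auroc >= 0.6) "poor"
  else if (auroc >= 0.5) "failed"
  else "worse than random"
}
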