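#' Hyper-parameters for the ML regressors
#'
#' @param method `"rf"`, `"svr_linear"`, `"svr_rbf"` or `"nn"`.
#' @param rf_n_trees random-forest tree count (fixed at 500 in the
#'   benchmark).
#' @param rf_min_leaf minimum observations per leaf (1-50).
#' @param rf_feature_ratio fraction of covariates sampled per split
#'   (0.3-0.7).
#' @param svr_C regularization constant (1e-5 to 1).
#' @param svr_epsilon epsilon-insensitive tube width (1e-4 to 1).
#' @param nn_layers widths of the two hidden layers.
#' @param nn_dropout dropout probability during training.
#' @param nn_epochs maximum training epochs (early stopping, patience 25).
#' @param seed training seed.
#' @return object of class `hyper_params`.
#' @export
hyper_params <- function(method = c("rf", "svr_linear", "svr_rbf", "nn"),
                         rf_n_trees = 500L, rf_min_leaf = 5L,
                         rf_feature_ratio = 0.5, svr_C = 1, svr_epsilon = 0.1,
                         nn_layers = c(500L, 500L), nn_dropout = 0.3,
                         nn_epochs = 500L, seed = 1L) {
  method <- match.arg(method)
  stopifnot(rf_min_leaf >= 1, rf_min_leaf <= 50,
            rf_feature_ratio >= 0.3, rf_feature_ratio <= 0.7,
            svr_C >= 1e-5, svr_C <= 1, svr_epsilon >= 1e-4, svr_epsilon <= 1,
            nn_dropout >= 0, nn_dropout < 1)
  structure(list(method = method, rf_n_trees = as.integer(rf_n_trees),
                 rf_min_leaf = as.integer(rf_min_leaf),
                 rf_feature_ratio = rf_feature_ratio, svr_C = svr_C,
                 svr_epsilon = svr_epsilon, nn_layers = as.integer(nn_layers),
                 nn_dropout = nn_dropout, nn_epochs = as.integer(nn_epochs),
                 seed = as.integer(seed)),
            class = "hyper_params")
}

#' Split subjects into training and validation features/targets
#'
#' Features are all covariate columns (true and false alike; no truth
#' leakage); the target is the clearance EBE. Subjects are split 80/20 at
#' random by ID. For the random forest the validation role is played by the
#' out-of-bag subjects instead, so its training set is the full population
#' (see [screen_covariates()]).
#'
#' @param dataset a `pop_pk_dataset`.
#' @param ebes an `ebe_set` from [compute_ebes()].
#' @param split_seed integer seed.
#' @param train_frac training fraction (default 0.8).
#' @return list with `train` and `val`, each `list(x, y, ids)`, plus `all`.
#' @export
prepare_features_targets <- function(dataset, ebes, split_seed = 1L,
                                     train_frac = 0.8) {
  covs <- dataset$covariates
  ids <- covs$ID
  if (length(ids) < 10) stop("need at least 10 subjects to split")
  y <- ebes$CL_EBE[match(ids, ebes$ID)]
  if (any(is.na(y))) stop("every subject needs a clearance EBE")
  x <- covs[, setdiff(names(covs), "ID"), drop = FALSE]
  set.seed(split_seed)
  n_train <- round(train_frac * length(ids))
  tr_ids <- sort(sample(ids, n_train))
  tr <- ids %in% tr_ids
  list(
    train = list(x = x[tr, , drop = FALSE], y = y[tr], ids = ids[tr]),
    val = list(x = x[!tr, , drop = FALSE], y = y[!tr], ids = ids[!tr]),
    all = list(x = x, y = y, ids = ids)
  )
}

#' Grid search for method hyper-parameters
#'
#' For the random forest the grid is `min_leaf` in {1, 2, 5, 10, 20, 50}
#' crossed with `feature_ratio` in {0.3, 0.4, 0.5, 0.6, 0.7} (500 trees
#' fixed). For SVR the grid is 6 log-spaced values of `C` in [1e-5, 1]
#' crossed with 5 log-spaced values of `epsilon` in [1e-4, 1]. Selection is
#' by 5-fold cross-validated mean squared error averaged over up to
#' `max_datasets` of the supplied feature/target tables; the neural network
#' uses a fixed architecture and is returned unchanged. One `hyper_params`
#' per scenario is reused for all replicates.
#'
#' @param xy_list list of `list(x, y)` feature/target tables (one per
#'   tuning dataset).
#' @param method as in [hyper_params()].
#' @param seed integer seed (fold assignment and forest seeds).
#' @param max_datasets cap on tuning datasets used (default 3).
#' @return a [hyper_params()] with attribute `cv_mse` (the grid with its
#'   scores) for the searched methods.
#' @export
grid_search_hyperparams <- function(xy_list, method, seed = 1L,
                                    max_datasets = 3L) {
  method <- match.arg(method, c("rf", "svr_linear", "svr_rbf", "nn"))
  if (method == "nn") return(hyper_params("nn", seed = seed))
  if (length(xy_list) < 1) stop("need at least one tuning dataset")
  xy_list <- xy_list[seq_len(min(length(xy_list), max_datasets))]
  grid <- if (method == "rf") {
    expand.grid(min_leaf = c(1L, 2L, 5L, 10L, 20L, 50L),
                feature_ratio = c(0.3, 0.4, 0.5, 0.6, 0.7))
  } else {
    expand.grid(C = 10^seq(-5, 0, length.out = 6),
                epsilon = 10^seq(-4, 0, length.out = 5))
  }
  grid$cv_mse <- NA_real_
  for (g in seq_len(nrow(grid))) {
    mses <- vapply(seq_along(xy_list), function(d) {
      x <- as.matrix(xy_list[[d]]$x)
      y <- xy_list[[d]]$y
      set.seed(derive_seed(seed, "folds", d))
      folds <- sample(rep_len(1:5, length(y)))
      fold_mse <- vapply(1:5, function(f) {
        tr <- folds != f
        hp <- if (method == "rf") {
          hyper_params("rf", rf_min_leaf = grid$min_leaf[g],
                       rf_feature_ratio = grid$feature_ratio[g],
                       seed = derive_seed(seed, "cv", g * 10 + f))
        } else {
          hyper_params(method, svr_C = grid$C[g],
                       svr_epsilon = grid$epsilon[g],
                       seed = derive_seed(seed, "cv", g * 10 + f))
        }
        fit <- train_model(hp, x[tr, , drop = FALSE], y[tr])
        mean((predict(fit, x[!tr, , drop = FALSE]) - y[!tr])^2)
      }, numeric(1))
      mean(fold_mse)
    }, numeric(1))
    grid$cv_mse[g] <- mean(mses)
  }
  if (all(!is.finite(grid$cv_mse))) stop("all grid fits failed")
  best <- which.min(grid$cv_mse)
  hp <- if (method == "rf") {
    hyper_params("rf", rf_min_leaf = grid$min_leaf[best],
                 rf_feature_ratio = grid$feature_ratio[best], seed = seed)
  } else {
    hyper_params(method, svr_C = grid$C[best], svr_epsilon = grid$epsilon[best],
                 seed = seed)
  }
  attr(hp, "cv_mse") <- grid
  hp
}

#' Train one ML regressor
#'
#' Random forest: 500 bagged trees with per-split feature subsampling
#' (ranger). SVR: epsilon-insensitive support-vector regression with linear
#' or radial kernel (e1071). NN: two-hidden-layer ReLU network with dropout
#' and full-batch ADAM, trained on the mean squared error.
#'
#' @param hparams a [hyper_params()].
#' @param x feature matrix/data.frame (covariates only).
#' @param y numeric target (clearance EBEs).
#' @return object of class `cov_model`; use `predict()` on new covariate
#'   tables.
#' @export
train_model <- function(hparams, x, y) {
  x <- as.data.frame(x)
  p <- ncol(x)
  fit <- switch(hparams$method,
    rf = {
      df <- cbind(.y = y, x)
      ranger::ranger(
        dependent.variable.name = ".y", data = df,
        num.trees = hparams$rf_n_trees,
        mtry = max(1L, round(hparams$rf_feature_ratio * p)),
        min.node.size = hparams$rf_min_leaf,
        keep.inbag = TRUE, importance = "permutation",
        seed = hparams$seed, num.threads = 1L
      )
    },
    svr_linear = ,
    svr_rbf = {
      kern <- if (hparams$method == "svr_linear") "linear" else "radial"
      if (stats::sd(y) < 1e-12) {
        # degenerate constant target: svm cannot scale y; store the constant
        structure(list(constant = y[1]), class = "constant_model")
      } else {
        e1071::svm(as.matrix(x), y, type = "eps-regression", kernel = kern,
                   cost = hparams$svr_C, epsilon = hparams$svr_epsilon,
                   scale = TRUE)
      }
    },
    nn = .nn_train(x, y, hidden = hparams$nn_layers,
                   dropout = hparams$nn_dropout, epochs = hparams$nn_epochs,
                   seed = hparams$seed),
    stop("unknown method: ", hparams$method)
  )
  structure(list(method = hparams$method, fit = fit, hparams = hparams,
                 feature_names = colnames(x), n_train = nrow(x)),
            class = "cov_model")
}

#' @export
predict.cov_model <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)[, object$feature_names, drop = FALSE]
  switch(object$method,
    rf = stats::predict(object$fit, data = newdata,
                        num.threads = 1L)$predictions,
    svr_linear = ,
    svr_rbf = {
      if (inherits(object$fit, "constant_model")) {
        rep(object$fit$constant, nrow(newdata))
      } else {
        as.numeric(stats::predict(object$fit, as.matrix(newdata)))
      }
    },
    nn = .nn_predict(object$fit, newdata)
  )
}

#' Permutation importance of each covariate
#'
#' For each covariate, its validation-set column is shuffled `n_shuffles`
#' times; the mean increase of the validation MSE over the unshuffled
#' baseline is the raw importance. Negative differences are clipped to 0
#' and scores are rescaled to sum to 1. For the random forest the
#' "validation" predictions are out-of-bag: each permuted row is predicted
#' only by trees that did not see that subject during training. If no
#' covariate increases the error, uniform scores are returned with a
#' warning (degenerate model).
#'
#' @param model a `cov_model` from [train_model()].
#' @param x_val,y_val validation features and targets. For `method = "rf"`
#'   pass the training table itself; out-of-bag masking handles validation.
#' @param n_shuffles shuffles per covariate (default 100).
#' @param seed integer seed.
#' @return object of class `importance_result`: data.frame `covariate`,
#'   `raw_diff`, `score` with attributes `method`, `n_shuffles`,
#'   `baseline_mse`.
#' @details For the random forest the raw differences are the classic
#'   out-of-bag permutation importances computed tree-wise during training
#'   (each tree permutes the covariate within its own out-of-bag subjects);
#'   this is the importance measure shipped with random-forest
#'   implementations, and the explicit shuffle loop is used for the other
#'   methods to mimic it on their held-out validation sets.
#' @export
permutation_importance <- function(model, x_val, y_val, n_shuffles = 100L,
                                   seed = 1L) {
  x_val <- as.data.frame(x_val)[, model$feature_names, drop = FALSE]
  n <- nrow(x_val)
  if (n < 1) stop("empty validation set")
  p <- ncol(x_val)
  if (model$method == "rf" &&
      !is.null(model$fit$variable.importance)) {
    raw <- as.numeric(model$fit$variable.importance[model$feature_names])
    baseline <- model$fit$prediction.error
  } else {
    predict_batch <- function(xbig) predict(model, xbig)
    base_pred <- predict_batch(x_val)
    baseline <- mean((base_pred - y_val)^2, na.rm = TRUE)
    set.seed(seed)
    raw <- numeric(p)
    for (j in seq_len(p)) {
      # stack the shuffled copies so each covariate needs one predict call
      perms <- replicate(n_shuffles, sample.int(n))
      xbig <- x_val[rep(seq_len(n), n_shuffles), , drop = FALSE]
      xbig[[j]] <- x_val[[j]][as.vector(perms)]
      pred <- predict_batch(xbig)
      sq <- (pred - rep(y_val, n_shuffles))^2
      mse_s <- tapply(sq, rep(seq_len(n_shuffles), each = n), mean,
                      na.rm = TRUE)
      raw[j] <- mean(mse_s) - baseline
    }
  }
  clipped <- pmax(raw, 0)
  if (sum(clipped) <= 0) {
    warning("degenerate model: shuffling never increased the error; ",
            "returning uniform scores")
    scores <- rep(1 / p, p)
  } else {
    scores <- clipped / sum(clipped)
  }
  out <- data.frame(covariate = model$feature_names, raw_diff = raw,
                    score = scores, stringsAsFactors = FALSE)
  structure(out, class = c("importance_result", "data.frame"),
            method = model$method, n_shuffles = as.integer(n_shuffles),
            baseline_mse = baseline)
}

#' Screen covariates of one dataset with one ML method
#'
#' Convenience wrapper running the full screening stage: split, train,
#' permutation importance. The random forest trains on all subjects and
#' validates out-of-bag; the other methods train on the 80% split and
#' validate on the held-out 20%.
#'
#' @param dataset a `pop_pk_dataset`.
#' @param ebes an `ebe_set`.
#' @param hparams a [hyper_params()].
#' @param seed integer seed for split, training and shuffling.
#' @param n_shuffles shuffles per covariate.
#' @return an `importance_result`.
#' @export
screen_covariates <- function(dataset, ebes, hparams, seed = 1L,
                              n_shuffles = 100L) {
  split <- prepare_features_targets(dataset, ebes,
                                    split_seed = derive_seed(seed, "split", 0L))
  hparams$seed <- derive_seed(seed, "train", 0L)
  if (hparams$method == "rf") {
    model <- train_model(hparams, split$all$x, split$all$y)
    permutation_importance(model, split$all$x, split$all$y,
                           n_shuffles = n_shuffles,
                           seed = derive_seed(seed, "perm", 0L))
  } else {
    model <- train_model(hparams, split$train$x, split$train$y)
    permutation_importance(model, split$val$x, split$val$y,
                           n_shuffles = n_shuffles,
                           seed = derive_seed(seed, "perm", 0L))
  }
}
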