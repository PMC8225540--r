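# small synthetic regression fixture: one strong predictor among noise
make_xy <- function(n = 100, p = 5, beta = 2, sd = 0.05, seed = 1) {
  set.seed(seed)
  x <- as.data.frame(matrix(rnorm(n * p), n, p))
  names(x) <- paste0("COV", seq_len(p))
  y <- beta * x$COV1 + rnorm(n, 0, sd)
  list(x = x, y = y)
}

test_that("feature/target split partitions subjects reproducibly", {
  ds <- fix_dataset_2b()
  eb <- fix_ebes_2b()
  sp <- prepare_features_targets(ds, eb, split_seed = 3)
  expect_length(sp$train$ids, 80)
  expect_length(sp$val$ids, 20)
  expect_length(intersect(sp$train$ids, sp$val$ids), 0)
  expect_setequal(c(sp$train$ids, sp$val$ids), ds$covariates$ID)
  expect_false("ID" %in% names(sp$train$x))
  # same seed, same split
  sp2 <- prepare_features_targets(ds, eb, split_seed = 3)
  expect_identical(sp$train$ids, sp2$train$ids)
  # split membership does not depend on covariate column order
  ds2 <- ds
  ds2$covariates <- ds$covariates[, c("ID", "COF1", "CAT1", "COT1", "CAF1")]
  sp3 <- prepare_features_targets(ds2, eb, split_seed = 3)
  expect_identical(sp$train$ids, sp3$train$ids)
})

test_that("hyper-parameter grids have the documented shape and optimum", {
  xy <- make_xy(n = 60, seed = 4)
  hp <- grid_search_hyperparams(list(xy), "rf", seed = 2)
  grid <- attr(hp, "cv_mse")
  expect_equal(nrow(grid), 30) # 6 leaf sizes x 5 feature ratios
  expect_setequal(unique(grid$min_leaf), c(1, 2, 5, 10, 20, 50))
  # returned combo attains the grid minimum (brute-force re-check)
  best <- grid[which.min(grid$cv_mse), ]
  expect_equal(hp$rf_min_leaf, best$min_leaf)
  expect_equal(hp$rf_feature_ratio, best$feature_ratio)
  # nn: fixed architecture, no search
  hpn <- grid_search_hyperparams(list(xy), "nn", seed = 2)
  expect_equal(hpn$nn_layers, c(500L, 500L))
  expect_equal(hpn$nn_dropout, 0.3)
  svr <- grid_search_hyperparams(list(xy), "svr_linear", seed = 2)
  gs <- attr(svr, "cv_mse")
  expect_equal(nrow(gs), 30) # 6 C values x 5 epsilon values
  expect_true(all(gs$C >= 1e-5 & gs$C <= 1))
})

test_that("svr recovers a clean linear signal", {
  xy <- make_xy(n = 120, sd = 0.01, seed = 6)
  hp <- hyper_params("svr_linear", svr_C = 1, svr_epsilon = 0.001, seed = 1)
  fit <- train_model(hp, xy$x[1:90, ], xy$y[1:90])
  pred <- predict(fit, xy$x[91:120, ])
  r2 <- 1 - var(pred - xy$y[91:120]) / var(xy$y[91:120])
  expect_gt(r2, 0.99)
})

test_that("rf training is seeded and handles degenerate targets", {
  xy <- make_xy(n = 60, seed = 7)
  hp <- hyper_params("rf", seed = 99)
  f1 <- train_model(hp, xy$x, xy$y)
  f2 <- train_model(hp, xy$x, xy$y)
  expect_identical(predict(f1, xy$x), predict(f2, xy$x))
  # constant target: constant predictions, zero training MSE
  yc <- rep(2.5, 60)
  fc <- train_model(hp, xy$x, yc)
  expect_equal(unique(predict(fc, xy$x)), 2.5)
})

test_that("the nn trainer fits a smooth signal", {
  xy <- make_xy(n = 150, p = 3, beta = 1.5, sd = 0.05, seed = 8)
  hp <- hyper_params("nn", nn_layers = c(32L, 32L), nn_dropout = 0.1,
                     nn_epochs = 400L, seed = 3)
  fit <- train_model(hp, xy$x[1:120, ], xy$y[1:120])
  pred <- predict(fit, xy$x[121:150, ])
  r2 <- 1 - var(pred - xy$y[121:150]) / var(xy$y[121:150])
  expect_gt(r2, 0.8)
})

test_that("importance scores are a distribution over covariates", {
  xy <- make_xy(n = 100, seed = 9)
  for (m in c("rf", "svr_rbf")) {
    hp <- hyper_params(m, seed = 5)
    fit <- train_model(hp, xy$x[1:80, ], xy$y[1:80])
    imp <- permutation_importance(fit, xy$x[81:100, ], xy$y[81:100],
                                  n_shuffles = 50, seed = 2)
    expect_equal(sum(imp$score), 1, tolerance = 1e-9)
    expect_true(all(imp$score >= 0))
  }
})

test_that("a constant predictor yields uniform scores with a warning", {
  xy <- make_xy(n = 60, seed = 10)
  hp <- hyper_params("svr_linear", seed = 1)
  fit <- train_model(hp, xy$x, rep(1, 60))
  expect_warning(
    imp <- permutation_importance(fit, xy$x, rep(1, 60), n_shuffles = 10,
                                  seed = 1),
    "degenerate")
  expect_equal(imp$score, rep(0.2, 5))
})

test_that("the informative covariate dominates the importance ranking", {
  hits_rf <- hits_svr <- 0
  for (s in 1:10) {
    xy <- make_xy(n = 100, p = 5, beta = 2, sd = 0.05, seed = 100 + s)
    hp <- hyper_params("rf", rf_min_leaf = 2, seed = s)
    fit <- train_model(hp, xy$x, xy$y)
    imp <- permutation_importance(fit, xy$x, xy$y, seed = s)
    if (imp$score[imp$covariate == "COV1"] > 0.9 &&
        all(imp$score[imp$covariate != "COV1"] < 0.05)) hits_rf <- hits_rf + 1
    hps <- hyper_params("svr_linear", svr_C = 1, svr_epsilon = 0.01, seed = s)
    fits <- train_model(hps, xy$x[1:80, ], xy$y[1:80])
    imps <- permutation_importance(fits, xy$x[81:100, ], xy$y[81:100],
                                   n_shuffles = 50, seed = s)
    if (imps$score[imps$covariate == "COV1"] > 0.9) hits_svr <- hits_svr + 1
  }
  expect_gte(hits_rf, 9)
  expect_gte(hits_svr, 9)
})

test_that("scores follow covariate columns, not positions", {
  xy <- make_xy(n = 100, p = 4, seed = 12)
  perm <- c(3, 1, 4, 2)
  for (m in c("rf", "svr_linear")) {
    hp <- hyper_params(m, seed = 4)
    f1 <- train_model(hp, xy$x, xy$y)
    i1 <- permutation_importance(f1, xy$x, xy$y, n_shuffles = 30, seed = 6)
    f2 <- train_model(hp, xy$x[, perm], xy$y)
    i2 <- permutation_importance(f2, xy$x[, perm], xy$y, n_shuffles = 30,
                                 seed = 6)
    s1 <- setNames(i1$score, i1$covariate)
    s2 <- setNames(i2$score, i2$covariate)
    # the dominant covariate is identified regardless of storage order
    expect_equal(names(which.max(s1)), names(which.max(s2)))
    expect_equal(s1[order(names(s1))], s2[order(names(s2))],
                 tolerance = 0.06)
  }
})

test_that("more shuffles stabilize but do not change the scores", {
  xy <- make_xy(n = 100, p = 4, beta = 1, sd = 0.2, seed = 13)
  hp <- hyper_params("svr_rbf", svr_C = 1, svr_epsilon = 0.01, seed = 2)
  fit <- train_model(hp, xy$x[1:80, ], xy$y[1:80])
  i100 <- permutation_importance(fit, xy$x[81:100, ], xy$y[81:100],
                                 n_shuffles = 100, seed = 3)
  i1000 <- permutation_importance(fit, xy$x[81:100, ], xy$y[81:100],
                                  n_shuffles = 1000, seed = 3)
  expect_true(all(abs(i100$score - i1000$score) < 0.02))
})

test_that("screen_covariates runs the full stage reproducibly", {
  ds <- fix_dataset_2b()
  eb <- fix_ebes_2b()
  hp <- hyper_params("rf", rf_min_leaf = 5, rf_feature_ratio = 0.5)
  i1 <- screen_covariates(ds, eb, hp, seed = 31)
  i2 <- screen_covariates(ds, eb, hp, seed = 31)
  expect_identical(i1$score, i2$score)
  expect_setequal(i1$covariate, c("CAT1", "COT1", "CAF1", "COF1"))
  # the true continuous covariate (high effect) dominates
  expect_gt(sum(i1$score[i1$covariate %in% c("CAT1", "COT1")]), 0.8)
})
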