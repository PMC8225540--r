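test_that("scenario grid enumerates the benchmark", {
  g <- build_scenario_grid()
  expect_length(g, 36)
  expect_equal(vapply(g[1:6], `[[`, "", "name"),
               c("1a", "1b", "1c", "1d", "1e", "1f"))
  g38 <- build_scenario_grid(list(shrinkage_scenarios = TRUE))
  expect_length(g38, 38)
  expect_equal(g38[[37]]$name, "7a")
  expect_equal(g38[[37]]$design, "7a")
  # 7a/7b reuse the 6e covariate structure
  expect_equal(g38[[37]]$n_cot_false, g38[[35]]$n_cot_false)
  g2 <- build_scenario_grid(list(scenarios = "scenario 2"))
  expect_length(g2, 6)
  expect_equal(vapply(g2, `[[`, "", "name"),
               paste0("2", c("a", "b", "c", "d", "e", "f")))
  expect_error(build_scenario_grid(list(scenarios = "9z")), "unknown")
})

test_that("scenario letters encode effect and correlation bands", {
  g <- build_scenario_grid()
  names(g) <- vapply(g, `[[`, "", "name")
  expect_equal(g[["2e"]]$effect_band, "small")
  expect_equal(g[["2e"]]$correlation_band, "high")
  expect_equal(g[["2b"]]$effect_band, "high")
  expect_equal(g[["2b"]]$correlation_band, "small")
  expect_equal(g[["3d"]]$correlation_band, "medium")
})

test_that("the grid is a pure function of its config", {
  cfg <- list(n_subjects = 50, master_seed = 9)
  expect_identical(build_scenario_grid(cfg), build_scenario_grid(cfg))
})

test_that("correlation matrices honour bands and positive definiteness", {
  g <- build_scenario_grid()
  names(g) <- vapply(g, `[[`, "", "name")
  # single continuous covariate: trivial matrix
  sp1 <- scenario_spec("x", 1, 1, 1, 0, "high", "high")
  expect_equal(sample_correlation_matrix(sp1, 1), matrix(1, 1, 1))
  # 2e: one designated pair, high band
  R <- sample_correlation_matrix(g[["2e"]], rng_seed = 3)
  expect_equal(dim(R), c(2, 2))
  expect_gt(abs(R[1, 2]), 0.6)
  # 6a: 12 continuous covariates, small band, many seeds
  for (s in 1:100) {
    R <- sample_correlation_matrix(g[["6a"]], rng_seed = s)
    expect_true(all(abs(R[upper.tri(R)]) < 0.3))
    expect_gt(min(eigen(R, symmetric = TRUE, only.values = TRUE)$values),
              1e-10)
  }
  # high band stays feasible at the largest dimension
  R <- sample_correlation_matrix(g[["6e"]], rng_seed = 11)
  expect_gt(min(eigen(R, symmetric = TRUE, only.values = TRUE)$values), 1e-10)
  expect_gt(R[1, 2], 0.6)       # true-true pair
  expect_gt(R[1, 3], 0.6)       # COT1-COF1 designated pair
})

test_that("effect sizes fall strictly inside the declared bands", {
  for (band in c("small", "high")) {
    lim <- if (band == "small") c(0.05, 0.20) else c(0.40, 1.00)
    sp <- scenario_spec("x", 2, 2, 0, 0, effect_band = band)
    for (s in 1:250) {
      eff <- sample_effect_sizes(sp, rng_seed = s)
      expect_true(all(eff$effect_sizes > lim[1] & eff$effect_sizes < lim[2]))
      expect_true(all(eff$beta_cat > lim[1] & eff$beta_cat < lim[2]))
    }
  }
})

test_that("continuous beta solves the q90-vs-median effect equation", {
  sp <- scenario_spec("x", 0, 1, 0, 0, effect_band = "high")
  # q90/q50 = 2 and E = 0.40 has the closed-form solution log(1.4)/log(2)
  eff <- sample_effect_sizes(sp, covariate_quantiles = list(q50 = 1, q90 = 2),
                             rng_seed = 1)
  e <- eff$effect_sizes[1]
  expect_equal(eff$beta_cot[[1]], log(1 + e) / log(2))
  # numerical inversion oracle: (q90/q50)^beta = 1 + E
  f <- function(b) 2^b - (1 + e)
  root <- uniroot(f, c(0, 5), tol = 1e-12)$root
  expect_equal(eff$beta_cot[[1]], root, tolerance = 1e-8)
  # reference value of the calibration
  eff40 <- list(beta = log(1.4) / log(2))
  expect_equal(eff40$beta, 0.4854, tolerance = 1e-3)
  # plugging beta back in: CL change at q90 stays inside the small band
  sps <- scenario_spec("x", 0, 3, 0, 0, effect_band = "small")
  marg <- continuous_marginal()
  for (s in 1:50) {
    eff <- sample_effect_sizes(sps, marg, rng_seed = s)
    change <- (marg$q90 / marg$q50)^eff$beta_cot - 1
    expect_true(all(change < 0.20 & change > 0))
  }
  expect_error(sample_effect_sizes(sp, list(q50 = 1, q90 = 0.9)),
               "degenerate")
})

test_that("generated covariates match their marginal specification", {
  sp <- scenario_spec("x", 1, 2, 1, 0, effect_band = "high",
                      correlation_band = "high", n_subjects = 10000L)
  struct <- build_covariate_structure(sp, rng_seed = 5)
  gen <- generate_covariates(sp, struct, n_subjects = 10000L, rng_seed = 6)
  covs <- gen$covariates
  expect_equal(names(covs)[1], "ID")
  # categorical prevalence near 0.5
  expect_equal(mean(covs$CAT1), 0.5, tolerance = 0.02)
  expect_equal(mean(covs$CAF1), 0.5, tolerance = 0.02)
  # rank correlation of the designated pair near its target
  target <- struct$correlation_matrix["COT1", "COT2"]
  expect_equal(cor(covs$COT1, covs$COT2, method = "spearman"), target,
               tolerance = 0.03)
  # log-normal margins: median near 1, CV near 0.3
  expect_equal(median(covs$COT1), 1, tolerance = 0.02)
  expect_equal(sd(covs$COT2) / mean(covs$COT2), 0.3, tolerance = 0.02)
  # seeded reproducibility
  gen2 <- generate_covariates(sp, struct, n_subjects = 10000L, rng_seed = 6)
  expect_identical(gen$covariates, gen2$covariates)
})

test_that("covariate structure separates true and false covariates", {
  spec <- fix_spec_2b()
  struct <- build_covariate_structure(spec, rng_seed = 42L)
  expect_setequal(names(struct$truth_labels),
                  c("CAT1", "CAF1", "COT1", "COF1"))
  expect_true(struct$truth_labels[["CAT1"]])
  expect_false(struct$truth_labels[["COF1"]])
  # false covariates carry no beta
  expect_named(struct$beta_cat, "CAT1")
  expect_named(struct$beta_cot, "COT1")
  expect_length(struct$effect_sizes, 2)
})
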