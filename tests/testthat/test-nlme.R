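test_that("individual -2LL matches a direct recomputation", {
  pop <- pop_params()
  times <- c(1, 2, 4, 8, 24)
  eta <- c(0.1, -0.2, 0.3)
  V <- pop$V_pop * exp(eta[1]); CL <- pop$CL_pop * exp(eta[2])
  ka <- pop$ka_pop * exp(eta[3])
  cp <- conc_profile(times, V, CL, ka, pop$dose)
  set.seed(2)
  logdv <- log(cp) + rnorm(5, 0, 0.3)
  # independent recomputation from raw formulas
  manual <- sum((logdv - log(cp))^2 / pop$sigma2 +
                  log(2 * pi * pop$sigma2))
  expect_equal(individual_neg2ll(eta, times, logdv, pop), manual,
               tolerance = 1e-10)
  # zero residuals leave only the normalizing constant
  expect_equal(individual_neg2ll(eta, times, log(cp), pop),
               5 * log(2 * pi * pop$sigma2), tolerance = 1e-10)
  # one observation with a one-sigma log-residual
  one <- individual_neg2ll(eta, times[1], log(cp[1]) + sqrt(pop$sigma2), pop)
  expect_equal(one, 1 + log(2 * pi * pop$sigma2), tolerance = 1e-10)
})

test_that("Laplace marginal agrees with adaptive quadrature on small instances", {
  pop <- pop_params(omega2_V = 0.1, omega2_CL = 0.1, omega2_ka = 0.1,
                    sigma2 = 0.05)
  ds <- make_dataset(5, times = seq(0.5, 44, length.out = 16), pop = pop,
                     seed = 11)
  theta <- c(log(10), log(1), log(1), log(c(0.1, 0.1, 0.1)), log(0.05))
  lap <- marginal_minus2ll(ds, theta, method = "laplace")
  agq <- agq_minus2ll(ds, theta)
  expect_equal(lap, agq, tolerance = 0.1 / abs(agq))
  # at perturbed parameters too
  theta2 <- theta + c(0.1, -0.1, 0.05, 0.2, -0.2, 0.1, 0.1)
  expect_lt(abs(marginal_minus2ll(ds, theta2, method = "laplace") -
                  agq_minus2ll(ds, theta2)), 0.15)
})

test_that("population parameters are recovered on a rich design", {
  pop <- pop_params()
  ds <- make_dataset(500, times = c(0.5, 1, 2, 4, 8, 12, 24, 36, 48),
                     pop = pop, seed = 21)
  fit <- fit_population(ds)
  expect_true(fit$converged)
  expect_equal(unname(fit$theta[["V"]]), 10, tolerance = 0.15)
  expect_equal(unname(fit$theta[["CL"]]), 1, tolerance = 0.15)
  expect_equal(unname(fit$theta[["ka"]]), 1, tolerance = 0.15)
  expect_equal(unname(fit$omega2[["CL"]]), 0.2, tolerance = 0.15)
  expect_equal(unname(fit$sigma2), 0.15, tolerance = 0.15)
})

test_that("noise-free data pin the fixed effects", {
  pop <- pop_params(omega2_V = 0, omega2_CL = 0, omega2_ka = 0,
                    sigma2 = 1e-6)
  ds <- make_dataset(20, times = c(0.5, 1, 2, 4, 8, 16, 24), pop = pop,
                     seed = 5)
  fit <- fit_population(ds)
  expect_equal(unname(fit$theta[["V"]]), 10, tolerance = 0.01)
  expect_equal(unname(fit$theta[["CL"]]), 1, tolerance = 0.01)
  expect_equal(unname(fit$theta[["ka"]]), 1, tolerance = 0.01)
})

test_that("refitting is deterministic", {
  fit1 <- fit_population(fix_dataset_2b())
  fit2 <- fit_population(fix_dataset_2b())
  expect_identical(fit1$minus2ll, fit2$minus2ll)
  expect_identical(fit1$theta_raw, fit2$theta_raw)
})

test_that("EBEs shrink to zero as Omega shrinks", {
  ds <- fix_dataset_2b()
  fit <- fix_fit_2b()
  small <- fit
  small$theta_raw[4:6] <- log(1e-8)
  small$omega2[] <- 1e-8
  eb <- compute_ebes(ds, small)
  expect_lt(max(abs(eb$ETA_CL)), 1e-3)
  expect_equal(eb$CL_EBE, rep(fit$theta[["CL"]], nrow(eb)), tolerance = 1e-3)
})

test_that("EBEs recover the generating etas with rich individual data", {
  pop <- pop_params(sigma2 = 0.001)
  ds <- make_dataset(30, times = seq(0.5, 40, length.out = 20), pop = pop,
                     seed = 8)
  # evaluate at the generating parameters to isolate the EBE step
  theta <- c(log(10), log(1), log(1), log(c(0.2, 0.2, 0.3)), log(0.001))
  fit <- fit_population(ds)
  fit$theta_raw <- theta
  fit$theta[] <- c(10, 1, 1)
  eb <- compute_ebes(ds, fit)
  expect_equal(eb$ETA_CL, ds$truth$etas[, 2], tolerance = 0.02)
})

test_that("MAP estimates beat eta = 0 for every subject", {
  ds <- fix_dataset_2b()
  fit <- fix_fit_2b()
  eb <- compute_ebes(ds, fit)
  pop_hat <- pop_params(fit$theta[["V"]], fit$theta[["CL"]],
                        fit$theta[["ka"]], fit$omega2[["V"]],
                        fit$omega2[["CL"]], fit$omega2[["ka"]], fit$sigma2)
  obs <- ds$records[ds$records$EVID == 0, ]
  map_obj <- function(eta, o) {
    individual_neg2ll(eta, o$TIME, log(o$DV), pop_hat) +
      sum(eta^2 / fit$omega2)
  }
  for (i in seq_len(nrow(eb))) {
    o <- obs[obs$ID == eb$ID[i], ]
    eta_hat <- as.numeric(eb[i, c("ETA_V", "ETA_CL", "ETA_KA")])
    expect_lte(map_obj(eta_hat, o), map_obj(c(0, 0, 0), o) + 1e-6)
  }
})

test_that("eta-shrinkage has the right fixed points", {
  eb <- data.frame(ETA_V = rep(0, 10), ETA_CL = rep(0, 10),
                   ETA_KA = rep(0, 10))
  s <- eta_shrinkage(eb, c(V = 0.2, CL = 0.2, ka = 0.3))
  expect_equal(unname(s), rep(100, 3))
  set.seed(3)
  draws <- rnorm(5000)
  eb2 <- data.frame(ETA_V = draws * sqrt(0.2), ETA_CL = draws * sqrt(0.2),
                    ETA_KA = draws * sqrt(0.3))
  s2 <- eta_shrinkage(eb2, c(V = var(draws) * 0.2, CL = var(draws) * 0.2,
                             ka = var(draws) * 0.3))
  expect_equal(unname(s2), rep(0, 3), tolerance = 1e-8)
  s3 <- eta_shrinkage(eb2, c(V = 0, CL = 0.2, ka = 0.3))
  expect_true(is.na(s3[["V"]]))
  # variance-based variant relates to the SD-based one
  s4 <- eta_shrinkage(eb, c(V = 0.2, CL = 0.2, ka = 0.3), type = "var")
  expect_equal(unname(s4), rep(100, 3))
})

test_that("likelihood-ratio p-values match the chi-square distribution", {
  expect_equal(lrt_pvalue(100, 100 - 3.841, 1), 0.05, tolerance = 1e-3)
  expect_equal(lrt_pvalue(100, 100, 1), 1)
  expect_equal(lrt_pvalue(50, 50 - 6.635, 1), 0.01, tolerance = 1e-3)
  expect_equal(lrt_pvalue(50, 50 - 5.991, 2), 0.05, tolerance = 1e-3)
  expect_warning(p <- lrt_pvalue(100, 101, 1), "clipped")
  expect_equal(p, 1)
  expect_error(lrt_pvalue(1, 0, 0), "df")
})

test_that("adding a covariate relationship never worsens the fit", {
  spec <- fix_spec_2b(n_subjects = 60L)
  for (s in 1:8) {
    struct <- build_covariate_structure(spec, rng_seed = s)
    ds <- simulate_dataset(spec, struct, replicate_seed = 100 + s)
    base <- fit_population(ds, control = list(factr = 1e9, polish = FALSE))
    rel <- list(list(covariate = "COF1", form = "power",
                     median = median(ds$covariates$COF1)))
    ext <- fit_population(ds, relationships = rel,
                          start = c(base$theta_raw, 0),
                          control = list(factr = 1e9, polish = FALSE))
    expect_lte(ext$minus2ll, base$minus2ll + 1e-6)
  }
})
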