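ode_conc <- function(t, V, CL, ka, dose) {
  # independent oracle: integrate the two-compartment ODE system
  rhs <- function(t, y, p) {
    list(c(-p$ka * y[1], p$ka * y[1] - p$CL / p$V * y[2]))
  }
  out <- deSolve::lsoda(c(gut = dose, cen = 0), c(0, t[t > 0]), rhs,
                        list(ka = ka, CL = CL, V = V),
                        rtol = 1e-13, atol = 1e-25, maxsteps = 50000)
  conc <- out[-1, "cen"] / V
  res <- numeric(length(t))
  res[t > 0] <- conc
  res
}

test_that("closed-form concentration matches an ODE oracle", {
  skip_if_not_installed("deSolve")
  expect_equal(conc_profile(0, 10, 1, 1, 100), 0)
  # reference point of the benchmark model
  expect_equal(conc_profile(24, 10, 1, 1, 100), ode_conc(24, 10, 1, 1, 100),
               tolerance = 1e-8)
  set.seed(1)
  for (i in 1:100) {
    V <- runif(1, 2, 50); CL <- runif(1, 0.2, 5)
    ka <- runif(1, 0.2, 4); t <- runif(1, 0.1, 48)
    expect_equal(conc_profile(t, V, CL, ka, 100),
                 ode_conc(t, V, CL, ka, 100), tolerance = 1e-8)
  }
})

test_that("flip-flop limit is handled analytically", {
  skip_if_not_installed("deSolve")
  # ka exactly CL/V
  expect_equal(conc_profile(6, 10, 2, 0.2, 100),
               ode_conc(6, 10, 2, 0.2, 100), tolerance = 1e-6)
  # approaching the limit from both sides is continuous
  near <- conc_profile(6, 10, 2, 0.2 + 1e-9, 100)
  at <- conc_profile(6, 10, 2, 0.2, 100)
  expect_equal(near, at, tolerance = 1e-6)
  expect_error(conc_profile(-1, 10, 1, 1, 100), "negative")
})

test_that("individual parameters follow the clearance covariate model", {
  pop <- pop_params()
  # identity case
  expect_equal(unname(individual_parameters(pop, c(0, 0, 0))),
               c(10, 1, 1))
  struct <- list(beta_cat = c(CAT1 = 0.5), beta_cot = c(COT1 = 1),
                 medians = c(COT1 = 1))
  ip <- individual_parameters(pop, c(0, 0, 0), list(CAT1 = 1, COT1 = 1),
                              struct)
  expect_equal(unname(ip["CL"]), 1.5)
  ip2 <- individual_parameters(pop, c(0, 0, 0), list(CAT1 = 0, COT1 = 2),
                               struct)
  expect_equal(unname(ip2["CL"]), 2)
  # etas act log-normally
  ip3 <- individual_parameters(pop, c(log(2), log(3), log(4)),
                               list(CAT1 = 0, COT1 = 1), struct)
  expect_equal(unname(ip3), c(20, 3, 4))
  bad <- list(beta_cat = c(CAT1 = -1.5), beta_cot = numeric(0),
              medians = numeric(0))
  expect_error(individual_parameters(pop, c(0, 0, 0), list(CAT1 = 1), bad),
               "invalid")
})

test_that("simulated datasets have the right structure", {
  ds <- fix_dataset_2b()
  rec <- ds$records
  expect_equal(sum(rec$EVID == 1), 100)
  expect_equal(sum(rec$EVID == 0), 400) # 4 post-zero times per subject
  expect_true(all(rec$TIME[rec$EVID == 1] == 0))
  expect_true(all(rec$AMT[rec$EVID == 1] == 100))
  expect_true(all(rec$DV[rec$EVID == 0] > 0))
  # odd subjects on grid 1, even on grid 2
  des <- sampling_design("standard")
  expect_equal(rec$TIME[rec$ID == 1 & rec$EVID == 0], des$grid1[-1])
  expect_equal(rec$TIME[rec$ID == 2 & rec$EVID == 0], des$grid2[-1])
  # reproducibility
  spec <- fix_spec_2b()
  struct <- build_covariate_structure(spec, rng_seed = 42L)
  ds2 <- simulate_dataset(spec, struct, replicate_seed = 7L)
  expect_identical(ds$records, ds2$records)
  expect_identical(ds$covariates, ds2$covariates)
})

test_that("degenerate noise reproduces the deterministic profile", {
  spec <- fix_spec_2b(n_subjects = 10L)
  struct <- build_covariate_structure(spec, rng_seed = 1L)
  struct$beta_cat[] <- 0
  struct$beta_cot[] <- 0
  pop <- pop_params(omega2_V = 0, omega2_CL = 0, omega2_ka = 0, sigma2 = 0)
  ds <- simulate_dataset(spec, struct, pop, replicate_seed = 3L)
  obs <- ds$records[ds$records$EVID == 0, ]
  expect_equal(obs$DV, conc_profile(obs$TIME, 10, 1, 1, 100))
})

test_that("log-residuals match the residual-error model", {
  spec <- scenario_spec("big", 0, 1, 0, 0, effect_band = "small",
                        n_subjects = 2500L)
  struct <- build_covariate_structure(spec, rng_seed = 2L)
  struct$beta_cot[] <- 0
  ds <- simulate_dataset(spec, struct, replicate_seed = 4L)
  obs <- ds$records[ds$records$EVID == 0, ]
  ip <- ds$truth$individual_params
  pred <- vapply(seq_len(nrow(obs)), function(r) {
    i <- obs$ID[r]
    conc_profile(obs$TIME[r], ip[i, "V"], ip[i, "CL"], ip[i, "ka"], 100)
  }, numeric(1))
  res <- log(obs$DV) - log(pred)
  expect_lt(abs(mean(res)), 0.01)
  expect_lt(abs(var(res) - 0.15), 0.01)
})

test_that("datasets round-trip through NONMEM-style CSV", {
  ds <- fix_dataset_2b()
  path <- tempfile(fileext = ".csv")
  write_dataset(ds, path)
  back <- read_dataset(path)
  expect_equal(back$records$DV[ds$records$EVID == 0],
               ds$records$DV[ds$records$EVID == 0], tolerance = 1e-12)
  expect_equal(back$records[, c("ID", "TIME", "AMT", "EVID", "MDV")],
               ds$records[, c("ID", "TIME", "AMT", "EVID", "MDV")],
               ignore_attr = TRUE)
  expect_equal(back$covariates$COT1, ds$covariates$COT1, tolerance = 1e-12)
  expect_equal(back$structure$truth_labels, ds$structure$truth_labels)
  # dose rows written as MDV=1 with "." DV
  lines <- readLines(path)
  dose_row <- strsplit(lines[2], ",")[[1]]
  expect_equal(dose_row[6], ".")
  unlink(c(path, paste0(path, ".json")))
})

test_that("the reader validates its input", {
  # hand-written 3-row fixture: dose row with '.' DV is accepted
  path <- tempfile(fileext = ".csv")
  writeLines(c(
    "ID,TIME,AMT,EVID,MDV,DV,COT1",
    "1,0,100,1,1,.,1.2",
    "1,1,0,0,0,5.5,1.2",
    "1,8,0,0,0,2.2,1.2"
  ), path)
  ds <- read_dataset(path)
  expect_equal(nrow(ds$records), 3)
  expect_true(is.na(ds$records$DV[1]))
  expect_equal(ds$covariates$COT1, 1.2)
  # missing EVID column
  writeLines(c("ID,TIME,AMT,MDV,DV", "1,0,100,1,."), path)
  expect_error(read_dataset(path), "EVID")
  # non-numeric DV on an observation row, named by row
  writeLines(c(
    "ID,TIME,AMT,EVID,MDV,DV",
    "1,0,100,1,1,.",
    "1,1,0,0,0,oops"
  ), path)
  expect_error(read_dataset(path), "row 2")
  unlink(path)
})
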