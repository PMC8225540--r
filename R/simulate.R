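#' Population PK parameters of the true model
#'
#' One-compartment oral model with first-order absorption, linear
#' elimination, bioavailability 1, log-normal inter-individual variability
#' on V, CL and ka, and exponential residual error on concentrations.
#'
#' @param V_pop central volume (L). @param CL_pop clearance (L/h).
#' @param ka_pop absorption rate constant (1/h).
#' @param omega2_V,omega2_CL,omega2_ka variances of the log-normal random
#'   effects on V, CL, ka.
#' @param sigma2 variance of the exponential residual error.
#' @param dose oral dose amount (single dose at time 0).
#' @return object of class `pop_params`.
#' @export
pop_params <- function(V_pop = 10, CL_pop = 1, ka_pop = 1,
                       omega2_V = 0.2, omega2_CL = 0.2, omega2_ka = 0.3,
                       sigma2 = 0.15, dose = 100) {
  stopifnot(V_pop > 0, CL_pop > 0, ka_pop > 0, dose > 0,
            omega2_V >= 0, omega2_CL >= 0, omega2_ka >= 0, sigma2 >= 0)
  structure(list(V_pop = V_pop, CL_pop = CL_pop, ka_pop = ka_pop,
                 omega2 = c(V = omega2_V, CL = omega2_CL, ka = omega2_ka),
                 sigma2 = sigma2, dose = dose),
            class = "pop_params")
}

#' Observation-time grids of a sampling design
#'
#' Each design has two time grids (hours) assigned to alternating halves of
#' the population. The standard design has 5 nominal times per subject
#' including time 0; the sparse designs `"7a"` and `"7b"` reduce the number
#' of observations per subject and thereby raise eta-shrinkage. Time 0 is a
#' dose record only (predicted concentration is 0 under single oral dosing),
#' so observations are taken at the post-zero times.
#'
#' @param design `"standard"`, `"7a"` or `"7b"`.
#' @return list with two numeric vectors `grid1`, `grid2` (full grids
#'   including time 0).
#' @export
sampling_design <- function(design = c("standard", "7a", "7b")) {
  design <- match.arg(design)
  switch(design,
    standard = list(grid1 = c(0, 1, 8, 12, 24), grid2 = c(0, 2, 4, 20, 48)),
    "7a" = list(grid1 = c(0, 1, 8), grid2 = c(0, 2, 4, 20)),
    "7b" = list(grid1 = c(0, 1, 8), grid2 = c(0, 2, 4))
  )
}

#' One-compartment oral concentration profile
#'
#' Closed-form solution
#' `C(t) = D*ka / (V*ka - CL) * (exp(-CL*t/V) - exp(-ka*t))`, with the
#' analytic flip-flop limit `D*ka*t/V * exp(-ka*t)` when `ka` is numerically
#' equal to `CL/V`.
#'
#' @param t time(s) in hours, non-negative.
#' @param V,CL,ka individual volume, clearance, absorption rate.
#' @param dose dose amount at time 0.
#' @return concentration(s), non-negative.
#' @export
conc_profile <- function(t, V, CL, ka, dose) {
  if (any(t < 0)) stop("negative time")
  cpp_conc(as.numeric(t), V, CL, ka, dose)
}

#' Individual PK parameters from random effects and covariates
#'
#' `V_i = V_pop*exp(eta1)`, `ka_i = ka_pop*exp(eta3)` and
#' `CL_i = CL_pop * exp(eta2) * prod(1 + CAT*beta1) * prod((COT/med)^beta2)`
#' over the true covariates; false covariates never enter.
#'
#' @param pop a [pop_params()].
#' @param etas numeric length-3 vector `(eta_V, eta_CL, eta_ka)`.
#' @param covariates named list/row of covariate values (may be missing
#'   entries for covariate-free models).
#' @param structure a `covariate_structure` (or `NULL` for no covariates).
#' @return named numeric vector `(V, CL, ka)`.
#' @export
individual_parameters <- function(pop, etas, covariates = NULL,
                                  structure = NULL) {
  mult <- 1
  if (!is.null(structure)) {
    for (v in names(structure$beta_cat)) {
      term <- 1 + covariates[[v]] * structure$beta_cat[[v]]
      if (term <= 0) stop("invalid categorical effect: 1 + CAT*beta <= 0")
      mult <- mult * term
    }
    for (v in names(structure$beta_cot)) {
      mult <- mult * (covariates[[v]] / structure$medians[[v]])^structure$beta_cot[[v]]
    }
  }
  c(V = pop$V_pop * exp(etas[1]),
    CL = pop$CL_pop * exp(etas[2]) * mult,
    ka = pop$ka_pop * exp(etas[3]))
}

#' Simulate one virtual population
#'
#' Draws covariates, independent normal random effects with the stated
#' variances, computes individual parameters and true concentrations at each
#' post-zero grid time, and applies exponential residual error
#' `DV = C * exp(eps)`, `eps ~ N(0, sigma2)`. Grid 1 is assigned to
#' odd-indexed subjects and grid 2 to even-indexed subjects. Time 0 is
#' emitted as the dose record only.
#'
#' @param spec a [scenario_spec()].
#' @param struct a `covariate_structure` from [build_covariate_structure()].
#' @param pop a [pop_params()].
#' @param replicate_seed integer seed for this population.
#' @return object of class `pop_pk_dataset` with elements `records`
#'   (data.frame ID, TIME, AMT, EVID, MDV, DV), `covariates`, `structure`
#'   (with sample medians), and `truth` (etas, individual parameters).
#' @export
simulate_dataset <- function(spec, struct, pop = pop_params(),
                             replicate_seed = spec$seed) {
  gen <- generate_covariates(spec, struct, spec$n_subjects,
                             rng_seed = derive_seed(replicate_seed, "cov", 0L))
  covs <- gen$covariates
  struct <- gen$structure
  n <- spec$n_subjects
  des <- sampling_design(spec$design)
  set.seed(derive_seed(replicate_seed, "pk", 0L))
  om <- pop$omega2
  etas <- cbind(
    V = stats::rnorm(n, 0, sqrt(om[["V"]])),
    CL = stats::rnorm(n, 0, sqrt(om[["CL"]])),
    ka = stats::rnorm(n, 0, sqrt(om[["ka"]]))
  )
  ipars <- matrix(0, n, 3, dimnames = list(NULL, c("V", "CL", "ka")))
  rec <- vector("list", n)
  for (i in seq_len(n)) {
    ipars[i, ] <- individual_parameters(pop, etas[i, ], covs[i, ], struct)
    grid <- if (i %% 2 == 1) des$grid1 else des$grid2
    tobs <- grid[grid > 0]
    cpred <- conc_profile(tobs, ipars[i, "V"], ipars[i, "CL"], ipars[i, "ka"],
                          pop$dose)
    dv <- cpred * exp(stats::rnorm(length(tobs), 0, sqrt(pop$sigma2)))
    rec[[i]] <- data.frame(
      ID = i,
      TIME = c(0, tobs),
      AMT = c(pop$dose, rep(0, length(tobs))),
      EVID = c(1L, rep(0L, length(tobs))),
      MDV = c(1L, rep(0L, length(tobs))),
      DV = c(NA_real_, dv)
    )
  }
  structure(list(
    records = do.call(rbind, rec),
    covariates = covs,
    structure = struct,
    pop = pop,
    truth = list(etas = etas, individual_params = ipars,
                 beta_cat = struct$beta_cat, beta_cot = struct$beta_cot,
                 seed = replicate_seed),
    design = spec$design,
    scenario = spec$name
  ), class = "pop_pk_dataset")
}

#' @export
print.pop_pk_dataset <- function(x, ...) {
  nobs <- sum(x$records$EVID == 0)
  cat(sprintf("<pop_pk_dataset> scenario %s: %d subjects, %d observations, %d covariates\n",
              x$scenario, length(unique(x$records$ID)), nobs,
              ncol(x$covariates) - 1L))
  invisible(x)
}

#' Write / read a NONMEM-style dataset
#'
#' The rectangular CSV has header `ID,TIME,AMT,EVID,MDV,DV` followed by the
#' covariate columns; missing DV (dose rows) is written as `"."`. Simulation
#' truth (labels, betas, etas, seed) goes to a sidecar JSON manifest at
#' `<path>.json`, never into the CSV.
#'
#' @param dataset a `pop_pk_dataset`.
#' @param path CSV file path.
#' @return `write_dataset`: `path`, invisibly. `read_dataset`: a
#'   `pop_pk_dataset` (truth restored from the manifest when present).
#' @export
write_dataset <- function(dataset, path) {
  rec <- dataset$records
  covs <- dataset$covariates
  m <- merge(rec, covs, by = "ID", sort = FALSE)
  m <- m[order(m$ID, m$TIME, -m$EVID), ]
  m$DV <- ifelse(is.na(m$DV), ".", format(m$DV, digits = 15, trim = TRUE))
  utils::write.csv(m, path, row.names = FALSE, quote = FALSE)
  manifest <- list(
    scenario = dataset$scenario,
    design = dataset$design,
    truth_labels = as.list(dataset$structure$truth_labels),
    beta_cat = as.list(dataset$truth$beta_cat),
    beta_cot = as.list(dataset$truth$beta_cot),
    medians = as.list(dataset$structure$medians),
    etas = dataset$truth$etas,
    seed = dataset$truth$seed,
    pop = unclass(dataset$pop)
  )
  jsonlite::write_json(manifest, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  req <- c("ID", "TIME", "AMT", "EVID", "MDV", "DV")
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols))
    stop("malformed header: missing column(s) ", paste(missing_cols, collapse = ", "))
  num <- function(x, col) {
    y <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(y) & !(x %in% c(".", "", "NA")))
    if (length(bad))
      stop("non-numeric ", col, " on row ", bad[1])
    y
  }
  rec <- data.frame(
    ID = num(raw$ID, "ID"), TIME = num(raw$TIME, "TIME"),
    AMT = num(raw$AMT, "AMT"), EVID = as.integer(num(raw$EVID, "EVID")),
    MDV = as.integer(num(raw$MDV, "MDV"))
  )
  dv <- raw$DV
  dv[dv %in% c(".", "")] <- NA
  bad <- which(is.na(suppressWarnings(as.numeric(dv))) & !is.na(dv))
  if (length(bad)) stop("non-numeric DV on row ", bad[1])
  rec$DV <- as.numeric(dv)
  if (any(rec$EVID == 0 & rec$MDV == 0 & is.na(rec$DV))) {
    bad <- which(rec$EVID == 0 & rec$MDV == 0 & is.na(rec$DV))[1]
    stop("non-numeric DV on observation row ", bad)
  }
  covnames <- setdiff(names(raw), req)
  covs <- unique(data.frame(
    ID = rec$ID,
    lapply(stats::setNames(covnames, covnames), function(v) num(raw[[v]], v))
  ))
  rownames(covs) <- NULL
  manifest_path <- paste0(path, ".json")
  truth <- NULL
  struct <- NULL
  scenario <- NA_character_
  design <- "standard"
  pop <- NULL
  if (file.exists(manifest_path)) {
    man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
    scenario <- man$scenario
    design <- man$design
    struct <- structure(list(
      truth_labels = unlist(man$truth_labels),
      beta_cat = unlist(man$beta_cat) %||% stats::setNames(numeric(0), character(0)),
      beta_cot = unlist(man$beta_cot) %||% stats::setNames(numeric(0), character(0)),
      medians = unlist(man$medians),
      categorical_names = grep("^CA", covnames, value = TRUE),
      continuous_names = grep("^CO", covnames, value = TRUE)
    ), class = "covariate_structure")
    truth <- list(etas = man$etas, beta_cat = struct$beta_cat,
                  beta_cot = struct$beta_cot, seed = man$seed)
    if (!is.null(man$pop)) {
      pp <- man$pop
      pop <- pop_params(pp$V_pop, pp$CL_pop, pp$ka_pop, pp$omega2[1],
                        pp$omega2[2], pp$omega2[3], pp$sigma2, pp$dose)
    }
  }
  structure(list(records = rec, covariates = covs, structure = struct,
                 pop = pop, truth = truth, design = design,
                 scenario = scenario),
            class = "pop_pk_dataset")
}
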