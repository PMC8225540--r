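#' Benchmark scenario grid
#'
#' The benchmark crosses six covariate configurations (rows 1-6) with six
#' effect-size/correlation combinations (letters a-f) for 36 scenarios.
#' Letters encode: a = small effect/small correlation, c = small/medium,
#' e = small/high, b = high/small, d = high/medium, f = high/high.
#' Two optional sparse-sampling scenarios (7a, 7b) reuse the row-6 covariate
#' structure of scenario 6e with reduced observation grids and are used to
#' study the effect of high eta-shrinkage on screening performance.
#'
#' @name scenarios
NULL

.scenario_rows <- function() {
  data.frame(
    row = 1:6,
    n_cat_true = c(0L, 1L, 1L, 1L, 1L, 2L),
    n_cot_true = c(1L, 1L, 1L, 2L, 3L, 2L),
    n_cat_false = c(1L, 1L, 3L, 3L, 5L, 5L),
    n_cot_false = c(1L, 1L, 5L, 5L, 10L, 10L)
  )
}

.band_letters <- function() {
  data.frame(
    letter = c("a", "b", "c", "d", "e", "f"),
    effect_band = c("small", "high", "small", "high", "small", "high"),
    correlation_band = c("small", "small", "medium", "medium", "high", "high"),
    stringsAsFactors = FALSE
  )
}

#' Construct one scenario specification
#'
#' @param name scenario label, e.g. `"2e"`.
#' @param n_cat_true,n_cot_true number of true categorical / continuous
#'   covariates (those with an effect on clearance).
#' @param n_cat_false,n_cot_false number of false covariates (no effect).
#' @param effect_band `"small"` (effect sizes < 20%) or `"high"` (> 40%).
#' @param correlation_band `"small"` (< 0.3), `"medium"` (0.3-0.6) or
#'   `"high"` (> 0.6) for the designated continuous-covariate pairs.
#' @param design sampling-design label: `"standard"`, `"7a"` or `"7b"`.
#' @param n_replicates number of simulated populations.
#' @param n_subjects subjects per population.
#' @param seed scenario-level seed.
#' @return an object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, n_cat_true, n_cot_true, n_cat_false,
                          n_cot_false, effect_band = c("small", "high"),
                          correlation_band = c("small", "medium", "high"),
                          design = "standard", n_replicates = 100L,
                          n_subjects = 100L, seed = 1L) {
  effect_band <- match.arg(effect_band)
  correlation_band <- match.arg(correlation_band)
  counts <- c(n_cat_true, n_cot_true, n_cat_false, n_cot_false)
  if (any(counts < 0)) stop("covariate counts must be non-negative")
  if (n_cat_true + n_cot_true < 1)
    stop("scenarios with covariate effects need at least one true covariate")
  if (!design %in% c("standard", "7a", "7b")) stop("unknown design: ", design)
  structure(list(
    name = name, n_cat_true = as.integer(n_cat_true),
    n_cot_true = as.integer(n_cot_true),
    n_cat_false = as.integer(n_cat_false),
    n_cot_false = as.integer(n_cot_false),
    effect_band = effect_band, correlation_band = correlation_band,
    design = design, n_replicates = as.integer(n_replicates),
    n_subjects = as.integer(n_subjects), seed = as.integer(seed)
  ), class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf(
    "<scenario %s> CAT %d/%d COT %d/%d (true/false), effect %s, corr %s, design %s\n",
    x$name, x$n_cat_true, x$n_cat_false, x$n_cot_true, x$n_cot_false,
    x$effect_band, x$correlation_band, x$design
  ))
  invisible(x)
}

#' Enumerate the benchmark scenario grid
#'
#' Returns the cross product of the six covariate-configuration rows and the
#' six effect/correlation combinations (36 scenarios, ordered 1a, 1b, ...,
#' 6f), optionally followed by the sparse-sampling scenarios 7a and 7b and an
#' extreme scenario with 95 false and 5 true covariates.
#'
#' @param config list with any of: `scenarios` (`"all"` or labels like
#'   `"2e"`, or row labels like `"scenario 2"`), `n_subjects`,
#'   `n_replicates`, `master_seed`, `shrinkage_scenarios` (logical),
#'   `extreme_scenario` (logical).
#' @return list of [scenario_spec()] objects.
#' @export
build_scenario_grid <- function(config = list()) {
  n_subjects <- config$n_subjects %||% 100L
  n_replicates <- config$n_replicates %||% 100L
  master_seed <- config$master_seed %||% 1L
  rows <- .scenario_rows()
  bands <- .band_letters()
  letters_ord <- c("a", "b", "c", "d", "e", "f")
  grid <- list()
  for (r in rows$row) {
    for (le in letters_ord) {
      b <- bands[bands$letter == le, ]
      nm <- paste0(r, le)
      grid[[nm]] <- scenario_spec(
        name = nm,
        n_cat_true = rows$n_cat_true[r], n_cot_true = rows$n_cot_true[r],
        n_cat_false = rows$n_cat_false[r], n_cot_false = rows$n_cot_false[r],
        effect_band = b$effect_band, correlation_band = b$correlation_band,
        design = "standard", n_replicates = n_replicates,
        n_subjects = n_subjects,
        seed = derive_seed(master_seed, nm, 0L)
      )
    }
  }
  if (isTRUE(config$shrinkage_scenarios)) {
    for (nm in c("7a", "7b")) {
      base6e <- grid[["6e"]]
      grid[[nm]] <- scenario_spec(
        name = nm,
        n_cat_true = base6e$n_cat_true, n_cot_true = base6e$n_cot_true,
        n_cat_false = base6e$n_cat_false, n_cot_false = base6e$n_cot_false,
        effect_band = base6e$effect_band,
        correlation_band = base6e$correlation_band,
        design = nm, n_replicates = n_replicates, n_subjects = n_subjects,
        seed = derive_seed(master_seed, nm, 0L)
      )
    }
  }
  if (isTRUE(config$extreme_scenario)) {
    # 5 true / 95 false covariates; effect sizes reuse the high band
    grid[["X"]] <- scenario_spec(
      name = "X", n_cat_true = 2L, n_cot_true = 3L,
      n_cat_false = 45L, n_cot_false = 50L,
      effect_band = "high", correlation_band = "small",
      design = "standard", n_replicates = n_replicates,
      n_subjects = n_subjects, seed = derive_seed(master_seed, "X", 0L)
    )
  }
  sel <- config$scenarios %||% "all"
  if (!identical(sel, "all")) {
    keep <- unlist(lapply(sel, function(s) {
      if (grepl("^scenario [0-9]$", s)) {
        r <- sub("^scenario ", "", s)
        grep(paste0("^", r, "[a-f]$"), names(grid), value = TRUE)
      } else s
    }))
    unknown <- setdiff(keep, names(grid))
    if (length(unknown))
      stop("unknown scenario label(s): ", paste(unknown, collapse = ", "))
    grid <- grid[keep]
  }
  unname(grid)
}

.band_limits <- function(band) {
  switch(band,
    small = c(0.0, 0.3),
    medium = c(0.3, 0.6),
    high = c(0.6, 0.9),
    stop("unknown correlation band: ", band)
  )
}

.effect_limits <- function(band) {
  switch(band,
    small = c(0.05, 0.20),
    high = c(0.40, 1.00),
    stop("unknown effect band: ", band)
  )
}

#' Draw a correlation matrix for the continuous covariates of a scenario
#'
#' The designated pairs - every true-true pair, plus one false partner per
#' true continuous covariate - are drawn inside the scenario's correlation
#' band; all remaining pairs are drawn from the small band. (Requiring every
#' true-false pair to sit in the high band is infeasible beyond a few
#' dimensions: two covariates each correlated 0.8 with the same hub must
#' correlate at least 0.28 with each other.) The matrix is repaired to the
#' nearest positive definite matrix by eigenvalue clipping; the draw is
#' repeated (up to `max_redraws` times) if the repair pushes a designated
#' entry out of its band.
#'
#' @param spec a [scenario_spec()].
#' @param rng_seed integer seed.
#' @param max_redraws redraw budget before giving up.
#' @return correlation matrix over `n_cot_true + n_cot_false` covariates,
#'   ordered true continuous covariates first.
#' @export
sample_correlation_matrix <- function(spec, rng_seed = spec$seed,
                                      max_redraws = 100L) {
  p_true <- spec$n_cot_true
  p <- p_true + spec$n_cot_false
  if (p < 1) stop("scenario has no continuous covariate")
  if (p == 1) return(matrix(1, 1, 1))
  lim <- .band_limits(spec$correlation_band)
  lim_small <- .band_limits("small")
  set.seed(rng_seed)
  banded <- matrix(FALSE, p, p)
  if (p_true > 1) banded[seq_len(p_true), seq_len(p_true)] <- TRUE
  for (i in seq_len(min(p_true, p - p_true))) {
    banded[i, p_true + i] <- banded[p_true + i, i] <- TRUE
  }
  banded <- banded & upper.tri(banded)
  for (trial in seq_len(max_redraws)) {
    R <- diag(p)
    up <- upper.tri(R)
    vals <- ifelse(banded[up],
      stats::runif(sum(up), lim[1], lim[2]),
      stats::runif(sum(up), lim_small[1], lim_small[2])
    )
    R[up] <- vals
    R <- R + t(R) - diag(diag(R))
    Rf <- .nearest_pd(R)
    bu <- banded[up]
    vb <- Rf[up][bu]
    vo <- Rf[up][!bu]
    ok <- all(vb > lim[1] & vb < lim[2]) &&
      all(abs(vo) < lim_small[2]) &&
      min(eigen(Rf, symmetric = TRUE, only.values = TRUE)$values) > 1e-10
    if (ok) return(Rf)
  }
  stop("correlation band '", spec$correlation_band,
       "' infeasible for dimension ", p, " after ", max_redraws, " redraws")
}

# eigenvalue clipping to the nearest positive-definite correlation matrix
.nearest_pd <- function(R, floor = 1e-7) {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) > floor) return(R)
  vals <- pmax(e$values, floor)
  A <- e$vectors %*% diag(vals, length(vals)) %*% t(e$vectors)
  d <- sqrt(diag(A))
  A <- A / tcrossprod(d)
  diag(A) <- 1
  (A + t(A)) / 2
}

#' Marginal distribution of the continuous covariates
#'
#' Continuous covariates are log-normal with median 1 and coefficient of
#' variation `cv`. Returns the log-scale standard deviation and the
#' theoretical median and 90th percentile.
#' @param cv coefficient of variation (default 0.3).
#' @return list with `sdlog`, `q50`, `q90`.
#' @export
continuous_marginal <- function(cv = 0.3) {
  sdlog <- sqrt(log(1 + cv^2))
  list(sdlog = sdlog, q50 = 1, q90 = exp(stats::qnorm(0.9) * sdlog))
}

#' Draw effect sizes and covariate coefficients for the true covariates
#'
#' Effect sizes `E` are uniform inside the scenario band: (0.05, 0.20) for
#' the small band, (0.40, 1.00) for the high band. A true categorical
#' covariate gets `beta1 = E` (its carriers' clearance is scaled by 1 + E).
#' A true continuous covariate gets `beta2 = log(1 + E) / log(q90/q50)`, so
#' that a subject at the marginal 90th percentile has clearance changed by
#' exactly `E` relative to the median subject.
#'
#' @param spec a [scenario_spec()].
#' @param covariate_quantiles list with `q50` and `q90` of the continuous
#'   marginal (default: theoretical values from [continuous_marginal()]).
#' @param rng_seed integer seed.
#' @return list with `effect_sizes`, `beta_cat`, `beta_cot`.
#' @export
sample_effect_sizes <- function(spec, covariate_quantiles = continuous_marginal(),
                                rng_seed = spec$seed) {
  q50 <- covariate_quantiles$q50
  q90 <- covariate_quantiles$q90
  if (q90 <= q50) stop("degenerate covariate: q90 must exceed q50")
  lim <- .effect_limits(spec$effect_band)
  set.seed(rng_seed)
  e_cat <- stats::runif(spec$n_cat_true, lim[1], lim[2])
  e_cot <- stats::runif(spec$n_cot_true, lim[1], lim[2])
  list(
    effect_sizes = c(e_cat, e_cot),
    beta_cat = e_cat,
    beta_cot = log(1 + e_cot) / log(q90 / q50)
  )
}

#' Build the full covariate structure of a scenario
#'
#' Combines the correlation matrix and effect-size draws into one object
#' describing how covariates are generated and how the true ones act on
#' clearance. Covariates are named `CAT1..` (true categorical), `COT1..`
#' (true continuous), `CAF1..` (false categorical), `COF1..` (false
#' continuous).
#'
#' @inheritParams sample_correlation_matrix
#' @param cv coefficient of variation of the continuous marginals.
#' @return an object of class `covariate_structure`.
#' @export
build_covariate_structure <- function(spec, rng_seed = spec$seed, cv = 0.3) {
  marg <- continuous_marginal(cv)
  cot <- if (spec$n_cot_true + spec$n_cot_false > 0) {
    sample_correlation_matrix(spec, rng_seed = derive_seed(rng_seed, "corr", 0L))
  } else matrix(numeric(0), 0, 0)
  eff <- sample_effect_sizes(spec, marg,
                             rng_seed = derive_seed(rng_seed, "effects", 0L))
  nm <- function(pref, k) if (k > 0) paste0(pref, seq_len(k)) else character(0)
  categorical <- c(nm("CAT", spec$n_cat_true), nm("CAF", spec$n_cat_false))
  continuous <- c(nm("COT", spec$n_cot_true), nm("COF", spec$n_cot_false))
  truth <- c(
    stats::setNames(rep(TRUE, spec$n_cat_true), nm("CAT", spec$n_cat_true)),
    stats::setNames(rep(FALSE, spec$n_cat_false), nm("CAF", spec$n_cat_false)),
    stats::setNames(rep(TRUE, spec$n_cot_true), nm("COT", spec$n_cot_true)),
    stats::setNames(rep(FALSE, spec$n_cot_false), nm("COF", spec$n_cot_false))
  )
  dimnames(cot) <- list(continuous, continuous)
  structure(list(
    spec_name = spec$name,
    categorical_names = categorical,
    continuous_names = continuous,
    truth_labels = truth,
    correlation_matrix = cot,
    effect_sizes = eff$effect_sizes,
    beta_cat = stats::setNames(eff$beta_cat, nm("CAT", spec$n_cat_true)),
    beta_cot = stats::setNames(eff$beta_cot, nm("COT", spec$n_cot_true)),
    sdlog = marg$sdlog,
    medians = stats::setNames(rep(1, length(continuous)), continuous)
  ), class = "covariate_structure")
}

#' Generate a covariate table for one population
#'
#' Continuous covariates are drawn through a Gaussian copula: a multivariate
#' normal draw with the scenario correlation matrix is transformed margin by
#' margin to log-normal with median 1 and CV `cv`. Categorical covariates
#' are independent Bernoulli(0.5), coded 0/1. Sample medians of the
#' continuous covariates are recorded into the returned structure.
#'
#' @param spec a [scenario_spec()].
#' @param struct a [build_covariate_structure()] result.
#' @param n_subjects number of subjects.
#' @param rng_seed integer seed.
#' @return list with `covariates` (data.frame, `ID` first) and `structure`
#'   (with per-population sample medians filled in).
#' @export
generate_covariates <- function(spec, struct, n_subjects = spec$n_subjects,
                                rng_seed = spec$seed) {
  if (n_subjects < 2) stop("need at least 2 subjects")
  set.seed(rng_seed)
  p_cont <- length(struct$continuous_names)
  out <- data.frame(ID = seq_len(n_subjects))
  for (v in struct$categorical_names)
    out[[v]] <- stats::rbinom(n_subjects, 1L, 0.5)
  if (p_cont > 0) {
    R <- struct$correlation_matrix
    ev <- eigen(R, symmetric = TRUE)
    if (min(ev$values) <= 0) stop("correlation matrix is not positive definite")
    L <- ev$vectors %*% diag(sqrt(ev$values), p_cont)
    Z <- matrix(stats::rnorm(n_subjects * p_cont), n_subjects, p_cont) %*% t(L)
    X <- exp(struct$sdlog * Z) # meanlog 0 => median 1
    colnames(X) <- struct$continuous_names
    for (v in struct$continuous_names) out[[v]] <- X[, v]
    struct$medians <- apply(X, 2, stats::median)
  }
  # keep conventional column order: CAT, COT, CAF, COF
  ord <- c("ID", grep("^CAT", names(out), value = TRUE),
           grep("^COT", names(out), value = TRUE),
           grep("^CAF", names(out), value = TRUE),
           grep("^COF", names(out), value = TRUE))
  list(covariates = out[, ord, drop = FALSE], structure = struct)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
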