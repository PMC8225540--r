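# Shared fixtures: built once per test run, in code.

# scenario 2b: 1 true categorical, 1 true continuous, 1 false each,
# high effect, small correlation - the workhorse small scenario
fix_spec_2b <- function(n_subjects = 100L) {
  scenario_spec("2b", n_cat_true = 1, n_cot_true = 1, n_cat_false = 1,
                n_cot_false = 1, effect_band = "high",
                correlation_band = "small", n_subjects = n_subjects,
                seed = 42L)
}

fix_dataset_2b <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- fix_spec_2b()
      struct <- build_covariate_structure(spec, rng_seed = 42L)
      cache <<- simulate_dataset(spec, struct, replicate_seed = 7L)
    }
    cache
  }
})

fix_fit_2b <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- fit_population(fix_dataset_2b())
    cache
  }
})

fix_ebes_2b <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- compute_ebes(fix_dataset_2b(), fix_fit_2b())
    cache
  }
})

# quick importance_result stub from named scores
fix_scores <- function(...) {
  v <- c(...)
  structure(data.frame(covariate = names(v), raw_diff = v, score = v,
                       stringsAsFactors = FALSE),
            class = c("importance_result", "data.frame"))
}

# Build a dataset with an arbitrary observation grid directly from the
# model equations (no scenario machinery), for estimation tests.
make_dataset <- function(n, times, pop = pop_params(), seed = 1) {
  set.seed(seed)
  etas <- cbind(rnorm(n, 0, sqrt(pop$omega2[["V"]])),
                rnorm(n, 0, sqrt(pop$omega2[["CL"]])),
                rnorm(n, 0, sqrt(pop$omega2[["ka"]])))
  rec <- lapply(seq_len(n), function(i) {
    V <- pop$V_pop * exp(etas[i, 1])
    CL <- pop$CL_pop * exp(etas[i, 2])
    ka <- pop$ka_pop * exp(etas[i, 3])
    cp <- conc_profile(times, V, CL, ka, pop$dose)
    dv <- cp * exp(rnorm(length(times), 0, sqrt(pop$sigma2)))
    data.frame(ID = i, TIME = c(0, times), AMT = c(pop$dose, 0 * times),
               EVID = c(1L, rep(0L, length(times))),
               MDV = c(1L, rep(0L, length(times))),
               DV = c(NA, dv))
  })
  structure(list(records = do.call(rbind, rec),
                 covariates = data.frame(ID = seq_len(n)),
                 structure = NULL, pop = pop,
                 truth = list(etas = etas), design = "custom",
                 scenario = "test"),
            class = "pop_pk_dataset")
}

# Adaptive Gauss-Hermite quadrature oracle (21 nodes per dimension),
# written directly from the integral definition.
agq_minus2ll <- function(dataset, theta_raw, nq = 21) {
  J <- matrix(0, nq, nq)
  for (i in seq_len(nq - 1)) J[i, i + 1] <- J[i + 1, i] <- sqrt(i)
  e <- eigen(J, symmetric = TRUE)
  nodes <- e$values
  logw <- 2 * log(abs(e$vectors[1, ]))
  Vp <- exp(theta_raw[1]); CLp <- exp(theta_raw[2]); kap <- exp(theta_raw[3])
  w2 <- exp(theta_raw[4:6]); s2 <- exp(theta_raw[7])
  obs <- dataset$records[dataset$records$EVID == 0, ]
  Z <- as.matrix(expand.grid(nodes, nodes, nodes))
  LW <- rowSums(as.matrix(expand.grid(logw, logw, logw)))
  total <- 0
  for (i in unique(obs$ID)) {
    o <- obs[obs$ID == i, ]
    h <- function(eta) {
      cp <- conc_profile(o$TIME, Vp * exp(eta[1]), CLp * exp(eta[2]),
                         kap * exp(eta[3]), dataset$pop$dose)
      if (any(!is.finite(cp)) || any(cp <= 0)) return(1e10)
      0.5 * (sum((log(o$DV) - log(cp))^2 / s2 + log(2 * pi * s2)) +
               sum(eta^2 / w2 + log(2 * pi * w2)))
    }
    opt <- optim(c(0, 0, 0), h, method = "BFGS")
    H <- numDeriv_hessian(h, opt$par)
    A <- solve(chol(H)) # upper-tri inverse: eta = mode + t(A) %*% z ... use A
    lvals <- vapply(seq_len(nrow(Z)), function(r) {
      z <- Z[r, ]
      eta <- opt$par + drop(A %*% z)
      -h(eta) + 0.5 * sum(z^2) + LW[r]
    }, numeric(1))
    m <- max(lvals)
    log_int <- m + log(sum(exp(lvals - m))) - 0.5 * determinant_logdet(H) +
      1.5 * log(2 * pi)
    total <- total - 2 * log_int
  }
  total
}

numDeriv_hessian <- function(f, x, h = 1e-4) {
  n <- length(x)
  H <- matrix(0, n, n)
  f0 <- f(x)
  for (k in seq_len(n)) {
    ek <- replace(numeric(n), k, h)
    H[k, k] <- (f(x + ek) + f(x - ek) - 2 * f0) / h^2
    for (l in seq_len(n)) {
      if (l <= k) next
      el <- replace(numeric(n), l, h)
      H[k, l] <- H[l, k] <-
        (f(x + ek + el) - f(x + ek - el) - f(x - ek + el) + f(x - ek - el)) /
        (4 * h^2)
    }
  }
  H
}

determinant_logdet <- function(H) as.numeric(determinant(H)$modulus)

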