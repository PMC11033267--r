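#' MCMC configuration
#'
#' @param chains number of chains (default 3).
#' @param iter iterations per chain, including warmup.
#' @param warmup warmup (adaptation) iterations per chain.
#' @param seed integer seed; chains are seeded deterministically from it.
#' @param target_accept dual-averaging target acceptance statistic.
#' @param max_treedepth NUTS doubling cap.
#' @return an object of class `mcmc_config`.
#' @export
mcmc_config <- function(chains = 3, iter = 10000, warmup = 5000, seed = 1L,
                        target_accept = 0.9, max_treedepth = 10) {
  stopifnot(chains >= 1, warmup < iter, warmup >= 0,
            target_accept > 0, target_accept < 1)
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 warmup = as.integer(warmup), seed = as.integer(seed),
                 target_accept = target_accept,
                 max_treedepth = as.integer(max_treedepth)),
            class = "mcmc_config")
}

#' Named MCMC profiles
#'
#' `"full"` is the full-scale profile for real field datasets
#' (3 chains, 10000 iterations, 5000 warmup); `"desk"` is a reduced profile
#' for simulation studies and tests (3 chains, 1500 iterations, half
#' warmup).
#'
#' @param profile `"full"` or `"desk"`.
#' @param seed seed passed through to [mcmc_config()].
#' @return an `mcmc_config`.
#' @export
mcmc_profile <- function(profile = c("desk", "full"), seed = 1L) {
  profile <- match.arg(profile)
  if (profile == "full") {
    mcmc_config(chains = 3, iter = 10000, warmup = 5000, seed = seed)
  } else {
    mcmc_config(chains = 3, iter = 1500, warmup = 750, seed = seed)
  }
}

model_list_for_cpp <- function(spec, data, prior_only = FALSE) {
  pr <- spec$priors
  Xi <- data$X_I[, spec$covariates, drop = FALSE]
  Xr <- data$X_R[, spec$covariates, drop = FALSE]
  list(y = as.integer(data$y), K = spec$K, I = data$I,
       H = if (spec$has_h) data$H else 0L, m = spec$m,
       has_F = spec$has_F, has_h = spec$has_h,
       i_idx = as.integer(data$i_idx), j_idx = as.integer(data$j_idx),
       hi_idx = as.integer(data$hi_idx), hj_idx = as.integer(data$hj_idx),
       X_I = Xi, X_R = Xr, x_H = as.numeric(data$x_H),
       intercept_sd = pr$intercept_sd, beta_sd = pr$beta_sd,
       lkj_shape = pr$lkj_shape, scale_sd = pr$scale_prior$sd,
       lik_weight = if (prior_only) 0 else 1)
}

init_theta <- function(spec, data) {
  lay <- param_layout(spec, data)
  theta <- numeric(attr(lay, "total"))
  for (b in names(lay)) {
    idx <- lay[[b]]
    theta[idx] <- if (grepl("^z_", b)) {
      stats::runif(length(idx), -0.1, 0.1)
    } else if (grepl("^y_", b)) {
      stats::runif(length(idx), -0.2, 0.2)
    } else if (grepl("^lsigma", b)) {
      stats::runif(length(idx), -1.5, -0.5)
    } else {
      stats::runif(length(idx), -1, 1)
    }
  }
  theta
}

#' Fit a model by NUTS Hamiltonian Monte Carlo
#'
#' Samples the posterior of a [model_spec()] given a `dyad_data` object with
#' the package's built-in No-U-Turn sampler (dual-averaging step-size
#' adaptation, diagonal mass-matrix estimation during warmup). Chains run
#' sequentially and are seeded deterministically from `mcmc$seed`, so a fit
#' is exactly reproducible. The per-draw, per-event log-likelihood matrix
#' needed for WAIC is evaluated at every retained draw.
#'
#' @param spec a [model_spec()].
#' @param data a `dyad_data` from [build_design()].
#' @param mcmc an [mcmc_config()].
#' @param prior_only if `TRUE` the likelihood is switched off and the
#'   sampler explores the prior (for prior predictive and calibration
#'   checks).
#' @return An object of class `dyad_fit`: per-chain draw matrices on the
#'   unconstrained scale, the pointwise log-likelihood matrix, sampler
#'   diagnostics and all metadata (spec, config, scaler) needed by the
#'   reporting functions.
#' @export
fit_model <- function(spec, data, mcmc = mcmc_profile("desk"),
                      prior_only = FALSE) {
  if (spec$K != data$K) stop("spec and data disagree on K", call. = FALSE)
  ml <- model_list_for_cpp(spec, data, prior_only)
  chains <- vector("list", mcmc$chains)
  stepsizes <- numeric(mcmc$chains)
  divergences <- integer(mcmc$chains)
  accept <- numeric(mcmc$chains)
  treedepth <- numeric(mcmc$chains)
  logp <- vector("list", mcmc$chains)
  for (c in seq_len(mcmc$chains)) {
    set.seed(mcmc$seed + 1009L * c)
    theta0 <- init_theta(spec, data)
    res <- mnl_nuts(ml, theta0, mcmc$iter, mcmc$warmup,
                    mcmc$target_accept, mcmc$max_treedepth)
    chains[[c]] <- res$draws
    stepsizes[c] <- res$stepsize
    divergences[c] <- res$divergences
    keep <- (mcmc$warmup + 1):mcmc$iter
    accept[c] <- mean(res$accept_stat[keep])
    treedepth[c] <- mean(res$treedepth[keep])
    logp[[c]] <- res$logp
  }
  draws <- do.call(rbind, chains)
  colnames(draws) <- param_names(spec, data)
  pointwise <- mnl_pointwise_loglik(draws, ml)
  n_keep <- mcmc$iter - mcmc$warmup
  fit <- structure(list(
    spec = spec, data = data, mcmc = mcmc, prior_only = prior_only,
    chains = chains, draws = draws, logp = logp,
    n_chains = mcmc$chains, n_keep = n_keep,
    pointwise_loglik = pointwise,
    stepsize = stepsizes, divergences = divergences,
    accept_stat = accept, mean_treedepth = treedepth,
    param_names = colnames(draws)
  ), class = "dyad_fit")
  dr <- sum(divergences) / (mcmc$chains * n_keep)
  if (dr > 0.1) {
    warning(sprintf("divergence rate %.1f%% exceeds 10%%; treat results %s",
                    100 * dr, "with caution"), call. = FALSE)
    fit$divergence_warning <- TRUE
  }
  fit
}

#' @export
print.dyad_fit <- function(x, ...) {
  cat("dyad_fit: variant", x$spec$variant, "|", x$n_chains, "chains x",
      x$n_keep, "retained draws |", ncol(x$draws), "parameters\n")
  cat("  divergences:", sum(x$divergences),
      "| mean accept:", round(mean(x$accept_stat), 3), "\n")
  invisible(x)
}

#' Extract posterior draws of a parameter block on the natural scale
#'
#' @param fit a `dyad_fit`.
#' @param block one of `alpha`, `beta_I`, `beta_R`, `beta_H`, `sigma_I`,
#'   `sigma_R`, `sigma_hI`, `sigma_hR`, `y_I`, `y_R`, `y_hI`, `y_hR`,
#'   `z_I`, `z_R`, `z_hI`, `z_hR`, `lp`.
#' @return matrix of draws (rows = draws), columns named.
#' @export
extract_par <- function(fit, block) {
  if (block == "lp") return(matrix(unlist(fit$logp), ncol = 1,
                                   dimnames = list(NULL, "lp")))
  lay <- param_layout(fit$spec, fit$data)
  if (grepl("^sigma", block)) {
    src <- sub("^sigma", "lsigma", block)
    if (is.null(lay[[src]])) stop("block ", block, " absent from variant ",
                                  fit$spec$variant, call. = FALSE)
    out <- exp(fit$draws[, lay[[src]], drop = FALSE])
    colnames(out) <- sub("lsigma", "sigma", colnames(out))
    return(out)
  }
  if (is.null(lay[[block]])) {
    stop("block ", block, " absent from variant ", fit$spec$variant,
         call. = FALSE)
  }
  fit$draws[, lay[[block]], drop = FALSE]
}

## ---- convergence diagnostics ---------------------------------------------

split_chain_matrix <- function(fit, idx) {
  # list of per-chain draw vectors for one parameter, each split in half
  out <- list()
  for (ch in fit$chains) {
    x <- ch[, idx]
    n <- length(x)
    h <- n %/% 2
    out <- c(out, list(x[1:h], x[(n - h + 1):n]))
  }
  out
}

rank_normalize <- function(chains_list) {
  x <- unlist(chains_list)
  z <- stats::qnorm((rank(x, ties.method = "average") - 3 / 8) /
                      (length(x) + 1 / 4))
  lens <- vapply(chains_list, length, 1L)
  split(z, rep(seq_along(chains_list), lens))
}

rhat_from_chains <- function(chains_list) {
  m <- length(chains_list)
  n <- length(chains_list[[1]])
  means <- vapply(chains_list, mean, 0)
  vars <- vapply(chains_list, stats::var, 0)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(1)
  sqrt((n - 1) / n + B / (n * W))
}

#' Split rank-normalized R-hat for one or all parameters
#'
#' Chains are split in half, draws are rank-normalized across chains, and
#' the classic Gelman-Rubin potential scale reduction factor is computed on
#' the transformed draws.
#'
#' @param fit a `dyad_fit` with at least 2 chains.
#' @param pars parameter indices or names; default all.
#' @return named numeric vector of R-hat values.
#' @export
rhat <- function(fit, pars = NULL) {
  if (fit$n_chains < 2) stop("R-hat needs at least 2 chains", call. = FALSE)
  if (is.null(pars)) pars <- seq_len(ncol(fit$draws))
  if (is.character(pars)) pars <- match(pars, fit$param_names)
  out <- vapply(pars, function(idx) {
    rhat_from_chains(rank_normalize(split_chain_matrix(fit, idx)))
  }, 0)
  names(out) <- fit$param_names[pars]
  out
}

ess_from_chains <- function(chains_list, max_lag = 300L) {
  m <- length(chains_list)
  n <- length(chains_list[[1]])
  max_lag <- min(max_lag, n - 2L)
  vars <- vapply(chains_list, stats::var, 0)
  means <- vapply(chains_list, mean, 0)
  W <- mean(vars)
  var_plus <- W * (n - 1) / n + stats::var(means)
  if (var_plus == 0) return(m * n)
  acov <- sapply(chains_list, function(x) {
    stats::acf(x, lag.max = max_lag, type = "covariance",
               plot = FALSE, demean = TRUE)$acf[, 1, 1]
  })
  rho <- 1 - (W - rowMeans(acov[-1, , drop = FALSE])) / var_plus
  # Geyer initial monotone positive sequence
  tau <- 1
  t <- 1
  prev <- Inf
  while (t + 1 <= length(rho)) {
    pair <- rho[t] + rho[t + 1]
    if (pair < 0) break
    pair <- min(pair, prev)
    prev <- pair
    tau <- tau + 2 * pair
    t <- t + 2
  }
  max(m * n / tau, 1)
}

#' Convergence diagnostics
#'
#' Split rank-normalized R-hat and bulk effective sample size per scalar
#' parameter, plus divergence counts per chain.
#'
#' @param fit a `dyad_fit`.
#' @param pars parameters (indices or names); default all.
#' @param ess also compute effective sample sizes (slower).
#' @return An object of class `dyad_diagnostics`: data.frame with columns
#'   `param`, `rhat` (and `ess`), plus attributes `divergences` and
#'   `stepsize`.
#' @export
diagnose <- function(fit, pars = NULL, ess = FALSE) {
  if (fit$n_chains < 2) {
    stop("diagnostics require >= 2 chains (R-hat unavailable)",
         call. = FALSE)
  }
  if (is.null(pars)) pars <- seq_len(ncol(fit$draws))
  if (is.character(pars)) pars <- match(pars, fit$param_names)
  df <- data.frame(param = fit$param_names[pars],
                   rhat = unname(rhat(fit, pars)),
                   stringsAsFactors = FALSE)
  if (ess) {
    df$ess <- vapply(pars, function(idx) {
      ess_from_chains(rank_normalize(split_chain_matrix(fit, idx)))
    }, 0)
  }
  structure(df, class = c("dyad_diagnostics", "data.frame"),
            divergences = fit$divergences, stepsize = fit$stepsize)
}

#' @export
print.dyad_diagnostics <- function(x, ...) {
  cat("Diagnostics over", nrow(x), "parameters\n")
  cat("  max R-hat:", round(max(x$rhat), 4), "\n")
  if (!is.null(x$ess)) cat("  min ESS:", round(min(x$ess), 1), "\n")
  cat("  divergences per chain:",
      paste(attr(x, "divergences"), collapse = ", "), "\n")
  invisible(x)
}

#' Posterior summary: mean, SD and percentile interval
#'
#' Interval endpoints are empirical percentiles of the posterior draws
#' (2.5% and 97.5% at the default level).
#'
#' @param x a draws matrix (rows = draws) or a `dyad_fit` (summarizes the
#'   interpretable blocks: intercepts, fixed effects, random-effect SDs).
#' @param level credible level (default 0.95).
#' @return data.frame with columns `param`, `mean`, `sd`, `lower`, `upper`.
#' @export
posterior_summary <- function(x, level = 0.95) {
  if (inherits(x, "dyad_fit")) {
    blocks <- c("alpha",
                if (x$spec$has_F) c("beta_I", "beta_R", "beta_H"),
                "sigma_I", "sigma_R",
                if (x$spec$has_h) c("sigma_hI", "sigma_hR"))
    mats <- lapply(blocks, function(b) extract_par(x, b))
    x <- do.call(cbind, mats)
  }
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  if (nrow(x) == 0) stop("no draws to summarize", call. = FALSE)
  a <- (1 - level) / 2
  qs <- apply(x, 2, stats::quantile, probs = c(a, 1 - a), names = FALSE)
  data.frame(param = colnames(x) %||% paste0("V", seq_len(ncol(x))),
             mean = colMeans(x),
             sd = apply(x, 2, stats::sd),
             lower = qs[1, ], upper = qs[2, ],
             row.names = NULL, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
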