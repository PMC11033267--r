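#' Prior configuration
#'
#' Priors follow the model statement: standard normal on intercepts and fixed
#' effects, LKJ-Cholesky (shape 2) on each random-effect correlation matrix,
#' and independent standard normals on the non-centered innovations. The
#' prior on the random-effect scales is not pinned down by the model
#' statement; the default is half-normal with SD 1, and it is recorded in all
#' outputs so a sensitivity analysis is a single configuration change.
#'
#' @param intercept_sd SD of the normal prior on intercepts (default 1).
#' @param beta_sd SD of the normal prior on fixed effects (default 1).
#' @param lkj_shape LKJ shape for correlation Cholesky factors (default 2).
#' @param scale_prior named list: `family` (only `"half_normal"` is
#'   implemented) and `sd` (default 1).
#' @return An object of class `prior_config`.
#' @export
prior_config <- function(intercept_sd = 1, beta_sd = 1, lkj_shape = 2,
                         scale_prior = list(family = "half_normal", sd = 1)) {
  stopifnot(intercept_sd > 0, beta_sd > 0, lkj_shape > 0,
            identical(scale_prior$family, "half_normal"),
            scale_prior$sd > 0)
  structure(list(intercept_sd = intercept_sd, beta_sd = beta_sd,
                 lkj_shape = lkj_shape, scale_prior = scale_prior),
            class = "prior_config")
}

#' Model specification
#'
#' The four variants differ in which terms enter the linear predictor for the
#' log-odds of each category against the reference:
#' \describe{
#'   \item{`i`}{intercepts + correlated individual-level initiator and
#'     recipient random effects.}
#'   \item{`ih`}{`i` + correlated household-level random effects for both
#'     roles, nested (each child belongs to exactly one household).}
#'   \item{`iF`}{`i` + fixed effects: initiator block (age, sex, age x sex),
#'     recipient block, and the same-household indicator.}
#'   \item{`ihF`}{all of the above.}
#' }
#'
#' @param variant one of `"i"`, `"ih"`, `"iF"`, `"ihF"`.
#' @param taxonomy a [behavior_taxonomy()].
#' @param covariates per-role covariate names; must be columns of the design
#'   blocks built by [build_design()].
#' @param priors a [prior_config()].
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(variant = c("ihF", "i", "ih", "iF"),
                       taxonomy = behavior_taxonomy(),
                       covariates = c("age", "sex", "age_sex"),
                       priors = prior_config()) {
  variant <- match.arg(variant)
  has_F <- grepl("F", variant, fixed = TRUE)
  has_h <- grepl("h", variant, fixed = TRUE)
  if (has_F && length(covariates) == 0) {
    stop("variants with fixed effects need a non-empty covariate set",
         call. = FALSE)
  }
  structure(list(variant = variant, taxonomy = taxonomy, K = taxonomy$K,
                 has_F = has_F, has_h = has_h,
                 covariates = if (has_F) covariates else character(0),
                 m = if (has_F) length(covariates) else 0L,
                 priors = priors),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Multilevel multinomial model, variant", x$variant, "\n")
  cat("  categories:", x$K, "(reference:",
      x$taxonomy$labels[x$taxonomy$reference_index], ")\n")
  cat("  fixed effects:",
      if (x$has_F) paste(x$covariates, collapse = ", ") else "none", "\n")
  cat("  household random effects:", if (x$has_h) "yes" else "no", "\n")
  invisible(x)
}

## ---- correlation Cholesky transforms -------------------------------------

#' Build a correlation Cholesky factor from unconstrained parameters
#'
#' The unconstrained vector `y` (length `d*(d-1)/2`, row-major over the
#' strict lower triangle) is mapped through `tanh` to canonical partial
#' correlations and assembled row by row into a lower-triangular matrix with
#' unit-norm rows, i.e. a valid Cholesky factor of a correlation matrix.
#'
#' @param y unconstrained numeric vector.
#' @param d matrix dimension.
#' @return d x d lower-triangular matrix `L` with `L %*% t(L)` a correlation
#'   matrix.
#' @export
corr_chol_from_y <- function(y, d) {
  stopifnot(length(y) == d * (d - 1) / 2)
  L <- diag(d)
  p <- 1L
  if (d >= 2) {
    for (i in 2:d) {
      s <- 1
      for (j in 1:(i - 1)) {
        w <- tanh(y[p]); p <- p + 1L
        L[i, j] <- w * s
        s <- s * sqrt(1 - w^2)
      }
      L[i, i] <- s
    }
  }
  L
}

#' Unconstrain a correlation Cholesky factor
#'
#' Inverse of [corr_chol_from_y()].
#'
#' @param L lower-triangular correlation Cholesky factor.
#' @return unconstrained numeric vector.
#' @export
y_from_corr_chol <- function(L) {
  d <- nrow(L)
  y <- numeric(d * (d - 1) / 2)
  p <- 1L
  if (d >= 2) {
    for (i in 2:d) {
      s <- 1
      for (j in 1:(i - 1)) {
        w <- L[i, j] / s
        y[p] <- atanh(w); p <- p + 1L
        s <- s * sqrt(1 - w^2)
      }
    }
  }
  y
}

#' Cholesky factor of a correlation matrix
#'
#' @param R symmetric positive-definite correlation matrix.
#' @return lower-triangular factor `L` with `L %*% t(L) = R`.
#' @export
corr_to_chol <- function(R) {
  if (any(abs(diag(R) - 1) > 1e-8)) {
    stop("not a correlation matrix: diagonal != 1", call. = FALSE)
  }
  t(chol(R))
}

#' LKJ-Cholesky log density
#'
#' Log density of a correlation Cholesky factor under the LKJ prior with the
#' given shape, including the normalizing constant (computed via the
#' canonical-partial-correlation Beta factorization).
#'
#' @param L lower-triangular correlation Cholesky factor.
#' @param shape LKJ shape parameter (shape 1 is uniform over correlation
#'   matrices; larger shapes concentrate mass near the identity).
#' @return log density (scalar).
#' @export
lkj_chol_lpdf <- function(L, shape = 2) {
  d <- nrow(L)
  if (d < 2) return(0)
  lp <- 0
  for (k in 2:d) {
    lp <- lp + (d - k + 2 * shape - 2) * log(L[k, k])
  }
  # normalizing constant: column j (0-based) has (d-1-j) partial correlations
  # each with density Beta(b_j, b_j) rescaled to (-1, 1), b_j = shape + (d-2-j)/2
  for (j in 0:(d - 2)) {
    b <- shape + (d - 2 - j) / 2
    lp <- lp - (d - 1 - j) * ((2 * b - 1) * log(2) + lbeta(b, b))
  }
  lp
}

#' Sample a correlation Cholesky factor from the LKJ prior
#'
#' @param d dimension.
#' @param shape LKJ shape.
#' @return lower-triangular d x d factor.
#' @export
rlkj_chol <- function(d, shape = 2) {
  if (d < 2) return(diag(d))
  y <- numeric(d * (d - 1) / 2)
  p <- 1L
  for (i in 2:d) {
    for (j in 1:(i - 1)) {
      b <- shape + (d - 1 - j) / 2      # column j (1-based): b = shape+(d-2-(j-1))/2
      w <- 2 * stats::rbeta(1, b, b) - 1
      y[p] <- atanh(w); p <- p + 1L
    }
  }
  corr_chol_from_y(y, d)
}

## ---- probabilities and likelihood ----------------------------------------

#' Category probabilities from contrast-scale linear predictors
#'
#' Maps the K-1 log-odds contrasts against the reference category (whose
#' contrast is pinned at zero) to the K-simplex, using log-sum-exp for
#' numerical stability.
#'
#' @param eta numeric vector of length K-1, or a matrix with K-1 columns
#'   (one row per event).
#' @return probability vector of length K (or matrix with K columns); the
#'   reference category is the last element.
#' @export
category_probabilities <- function(eta) {
  if (is.matrix(eta)) {
    eta0 <- cbind(eta, 0)
    mx <- apply(eta0, 1, max)
    ex <- exp(eta0 - mx)
    return(ex / rowSums(ex))
  }
  if (any(!is.finite(eta))) stop("non-finite linear predictor", call. = FALSE)
  eta0 <- c(eta, 0)
  mx <- max(eta0)
  ex <- exp(eta0 - mx)
  ex / sum(ex)
}

#' Linear predictor contrasts for each event
#'
#' Sums, per event and non-reference category, the terms included by the
#' model variant: intercept, initiator and recipient individual effects,
#' optionally household effects, and optionally the fixed-effect blocks.
#'
#' @param params a parameter list (see [params_from_truth()] or
#'   [params_zero()]): `alpha` (length K-1), optional `beta_I`, `beta_R`
#'   ((K-1) x m), `beta_H` (K-1), and random effects either as realized
#'   matrices `nu_I`, `nu_R` ((K-1) x I), `h_I`, `h_R` ((K-1) x H) or in
#'   non-centered form (`sigma_*`, `L_*`, `z_*`).
#' @param data a `dyad_data` object.
#' @param event optional single event index; default all events.
#' @return matrix of contrasts (events x (K-1)), or a vector for one event.
#' @export
linear_predictor <- function(params, data, event = NULL) {
  K1 <- data$K - 1L
  nu_I <- realized_effects(params, "nu_I", "sigma_I", "L_I", "z_I")
  nu_R <- realized_effects(params, "nu_R", "sigma_R", "L_R", "z_R")
  n <- data$n_events
  idx <- if (is.null(event)) seq_len(n) else as.integer(event)
  eta <- matrix(params$alpha, nrow = length(idx), ncol = K1, byrow = TRUE)
  eta <- eta + t(nu_I[, data$i_idx[idx], drop = FALSE]) +
    t(nu_R[, data$j_idx[idx], drop = FALSE])
  if (!is.null(params$beta_I)) {
    eta <- eta + data$X_I[idx, , drop = FALSE] %*% t(params$beta_I) +
      data$X_R[idx, , drop = FALSE] %*% t(params$beta_R) +
      outer(data$x_H[idx], params$beta_H)
  }
  h_I <- realized_effects(params, "h_I", "sigma_hI", "L_hI", "z_hI",
                          optional = TRUE)
  if (!is.null(h_I)) {
    h_R <- realized_effects(params, "h_R", "sigma_hR", "L_hR", "z_hR")
    eta <- eta + t(h_I[, data$hi_idx[idx], drop = FALSE]) +
      t(h_R[, data$hj_idx[idx], drop = FALSE])
  }
  if (!is.null(event) && length(idx) == 1L) drop(eta) else eta
}

realized_effects <- function(params, nm, s_nm, l_nm, z_nm, optional = FALSE) {
  if (!is.null(params[[nm]])) return(params[[nm]])
  if (is.null(params[[z_nm]])) {
    if (optional) return(NULL)
    stop("parameters contain neither ", nm, " nor its non-centered parts",
         call. = FALSE)
  }
  diag(params[[s_nm]], nrow = length(params[[s_nm]])) %*%
    params[[l_nm]] %*% params[[z_nm]]
}

#' Pointwise log-likelihood
#'
#' Log probability of each observed event's category under the model, i.e.
#' the categorical log-pmf at the softmax of the event's linear predictor.
#'
#' @inheritParams linear_predictor
#' @return numeric vector of length `n_events`.
#' @export
log_likelihood_pointwise <- function(params, data) {
  eta <- linear_predictor(params, data)
  eta0 <- cbind(eta, 0)
  mx <- apply(eta0, 1, max)
  lse <- mx + log(rowSums(exp(eta0 - mx)))
  eta0[cbind(seq_len(nrow(eta0)), data$y)] - lse
}

#' Joint log prior
#'
#' Sum of the log prior densities of all parameters under a model spec:
#' normal on intercepts and fixed effects, standard normal on non-centered
#' innovations, LKJ-Cholesky on each correlation factor and the configured
#' scale prior (half-normal) on each SD vector. Includes all normalizing
#' constants.
#'
#' @param params parameter list in non-centered form (`alpha`, optional
#'   betas, `z_*`, `L_*`, `sigma_*`).
#' @param spec a [model_spec()].
#' @return scalar log prior density.
#' @export
log_prior <- function(params, spec) {
  pr <- spec$priors
  lp <- sum(stats::dnorm(params$alpha, 0, pr$intercept_sd, log = TRUE))
  if (spec$has_F) {
    lp <- lp + sum(stats::dnorm(c(params$beta_I, params$beta_R,
                                  params$beta_H), 0, pr$beta_sd, log = TRUE))
  }
  roles <- c("I", "R")
  if (spec$has_h) roles <- c(roles, "hI", "hR")
  for (r in roles) {
    z <- params[[paste0("z_", r)]]
    L <- params[[paste0("L_", r)]]
    sig <- params[[paste0("sigma_", r)]]
    lp <- lp + sum(stats::dnorm(z, log = TRUE))
    lp <- lp + lkj_chol_lpdf(L, pr$lkj_shape)
    if (any(sig < 0)) return(-Inf)
    lp <- lp + sum(log(2) + stats::dnorm(sig, 0, pr$scale_prior$sd,
                                         log = TRUE))
  }
  lp
}

#' All-zero parameters for a spec and data
#'
#' Intercepts, fixed effects and innovations at zero, scales at zero and
#' correlation factors at the identity: the linear predictor is identically
#' zero and every category has probability 1/K.
#'
#' @param spec a [model_spec()].
#' @param data a `dyad_data`.
#' @return parameter list.
#' @export
params_zero <- function(spec, data) {
  K1 <- spec$K - 1L
  p <- list(alpha = numeric(K1),
            sigma_I = numeric(K1), sigma_R = numeric(K1),
            L_I = diag(K1), L_R = diag(K1),
            z_I = matrix(0, K1, data$I), z_R = matrix(0, K1, data$I))
  if (spec$has_F) {
    p$beta_I <- matrix(0, K1, spec$m)
    p$beta_R <- matrix(0, K1, spec$m)
    p$beta_H <- numeric(K1)
  }
  if (spec$has_h) {
    p$sigma_hI <- numeric(K1); p$sigma_hR <- numeric(K1)
    p$L_hI <- diag(K1); p$L_hR <- diag(K1)
    p$z_hI <- matrix(0, K1, data$H); p$z_hR <- matrix(0, K1, data$H)
  }
  p
}

## ---- packing between parameter lists and the sampler's flat vector -------

param_dims <- function(spec, data) {
  K1 <- spec$K - 1L
  list(K1 = K1, m = spec$m, I = data$I, H = data$H,
       P = as.integer(K1 * (K1 - 1) / 2))
}

param_layout <- function(spec, data) {
  d <- param_dims(spec, data)
  blocks <- list(alpha = d$K1)
  if (spec$has_F) {
    blocks$beta_I <- d$K1 * d$m
    blocks$beta_R <- d$K1 * d$m
    blocks$beta_H <- d$K1
  }
  blocks$z_I <- d$K1 * d$I
  blocks$z_R <- d$K1 * d$I
  blocks$y_I <- d$P
  blocks$y_R <- d$P
  blocks$lsigma_I <- d$K1
  blocks$lsigma_R <- d$K1
  if (spec$has_h) {
    blocks$z_hI <- d$K1 * d$H
    blocks$z_hR <- d$K1 * d$H
    blocks$y_hI <- d$P
    blocks$y_hR <- d$P
    blocks$lsigma_hI <- d$K1
    blocks$lsigma_hR <- d$K1
  }
  ends <- cumsum(unlist(blocks))
  starts <- ends - unlist(blocks) + 1L
  layout <- Map(function(s, e) if (e >= s) s:e else integer(0),
                starts, ends)
  attr(layout, "total") <- unname(ends[length(ends)])
  attr(layout, "dims") <- d
  layout
}

unpack_theta <- function(theta, spec, data) {
  lay <- param_layout(spec, data)
  d <- attr(lay, "dims")
  get <- function(nm) theta[lay[[nm]]]
  p <- list(alpha = get("alpha"))
  if (spec$has_F) {
    p$beta_I <- matrix(get("beta_I"), d$K1, d$m)
    p$beta_R <- matrix(get("beta_R"), d$K1, d$m)
    p$beta_H <- get("beta_H")
  }
  p$z_I <- matrix(get("z_I"), d$K1, d$I)
  p$z_R <- matrix(get("z_R"), d$K1, d$I)
  p$L_I <- corr_chol_from_y(get("y_I"), d$K1)
  p$L_R <- corr_chol_from_y(get("y_R"), d$K1)
  p$sigma_I <- exp(get("lsigma_I"))
  p$sigma_R <- exp(get("lsigma_R"))
  if (spec$has_h) {
    p$z_hI <- matrix(get("z_hI"), d$K1, d$H)
    p$z_hR <- matrix(get("z_hR"), d$K1, d$H)
    p$L_hI <- corr_chol_from_y(get("y_hI"), d$K1)
    p$L_hR <- corr_chol_from_y(get("y_hR"), d$K1)
    p$sigma_hI <- exp(get("lsigma_hI"))
    p$sigma_hR <- exp(get("lsigma_hR"))
  }
  p
}

param_names <- function(spec, data) {
  lay <- param_layout(spec, data)
  d <- attr(lay, "dims")
  nm <- character(attr(lay, "total"))
  lab <- function(base, rows, cols = NULL) {
    if (is.null(cols)) sprintf("%s[%d]", base, rows)
    else sprintf("%s[%d,%d]", base, rep(rows, times = length(cols)),
                 rep(cols, each = length(rows)))
  }
  for (b in names(lay)) {
    n <- length(lay[[b]])
    if (n == 0) next
    nm[lay[[b]]] <- if (n == d$K1) lab(b, 1:d$K1)
    else if (b %in% c("y_I", "y_R", "y_hI", "y_hR")) lab(b, 1:n)
    else if (grepl("^beta", b)) lab(b, 1:d$K1, 1:d$m)
    else if (grepl("^z_h", b)) lab(b, 1:d$K1, 1:d$H)
    else lab(b, 1:d$K1, 1:d$I)
  }
  nm
}
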