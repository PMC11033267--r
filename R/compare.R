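#' Widely Applicable Information Criterion
#'
#' Computes, from a draws x events pointwise log-likelihood matrix, the log
#' pointwise predictive density `lppd = sum_n log mean_s exp(ll_sn)` (via
#' log-sum-exp), the effective parameter count `p_waic = sum_n var_s(ll_sn)`
#' and `waic = -2 (lppd - p_waic)`, with a standard error from the
#' event-level dispersion of the pointwise contributions.
#'
#' @param x a draws x events matrix of pointwise log-likelihoods, or a
#'   `dyad_fit` (its stored matrix is used).
#' @return An object of class `waic_result` with elements `lppd`, `p_waic`,
#'   `waic`, `se_waic`, `n_events` and the pointwise `-2(lppd_n - p_waic_n)`
#'   contributions.
#' @export
waic <- function(x) {
  if (inherits(x, "dyad_fit")) x <- x$pointwise_loglik
  if (!is.matrix(x)) stop("need a draws x events matrix", call. = FALSE)
  S <- nrow(x)
  if (S < 2) stop("WAIC needs at least 2 draws (variance undefined)",
                  call. = FALSE)
  mx <- apply(x, 2, max)
  lppd_n <- mx + log(colMeans(exp(sweep(x, 2, mx)))) # log mean exp per event
  p_n <- apply(x, 2, stats::var)
  pointwise <- -2 * (lppd_n - p_n)
  res <- list(lppd = sum(lppd_n), p_waic = sum(p_n),
              waic = -2 * (sum(lppd_n) - sum(p_n)),
              se_waic = sqrt(ncol(x) * stats::var(pointwise)),
              n_events = ncol(x), pointwise = pointwise)
  class(res) <- "waic_result"
  res
}

#' @export
print.waic_result <- function(x, ...) {
  cat(sprintf("WAIC %.2f (SE %.2f): lppd %.2f, p_waic %.2f, n = %d\n",
              x$waic, x$se_waic, x$lppd, x$p_waic, x$n_events))
  invisible(x)
}

#' Compare models by WAIC and Akaike-style weights
#'
#' Deltas are reported against the minimum-WAIC model and weights are
#' `exp(-delta/2)` normalized over the candidate set, interpreted as the
#' probability that each model makes the best predictions on new data
#' relative to the others. When pointwise contributions are available the
#' standard error of each pairwise delta against the best model is also
#' reported.
#'
#' @param ... named models: `dyad_fit` objects, `waic_result` objects or
#'   bare WAIC values; or a single named list of such.
#' @return An object of class `comparison_table`: a data.frame sorted by
#'   WAIC with columns `model`, `waic`, `se_waic`, `delta`, `se_delta`,
#'   `weight`.
#' @export
compare_models <- function(...) {
  models <- list(...)
  if (length(models) == 1 && is.list(models[[1]]) &&
      !inherits(models[[1]], c("dyad_fit", "waic_result"))) {
    models <- models[[1]]
  }
  if (length(models) == 0) stop("no models to compare", call. = FALSE)
  if (is.null(names(models)) || any(!nzchar(names(models)))) {
    names(models) <- paste0("model", seq_along(models))
  }
  wr <- lapply(models, function(m) {
    if (inherits(m, "dyad_fit")) waic(m)
    else if (inherits(m, "waic_result")) m
    else if (is.numeric(m) && length(m) == 1) {
      list(waic = as.numeric(m), se_waic = NA_real_, pointwise = NULL)
    } else stop("cannot interpret a model entry", call. = FALSE)
  })
  w <- vapply(wr, function(r) r$waic, 0)
  delta <- w - min(w)
  weight <- exp(-delta / 2)
  weight <- weight / sum(weight)
  best <- which.min(w)
  se_delta <- vapply(seq_along(wr), function(i) {
    pi <- wr[[i]]$pointwise
    pb <- wr[[best]]$pointwise
    if (i == best || is.null(pi) || is.null(pb) ||
        length(pi) != length(pb)) return(NA_real_)
    sqrt(length(pi) * stats::var(pi - pb))
  }, 0)
  tab <- data.frame(model = names(models), waic = w,
                    se_waic = vapply(wr, function(r) r$se_waic, 0),
                    delta = delta, se_delta = se_delta, weight = weight,
                    row.names = NULL, stringsAsFactors = FALSE)
  tab <- tab[order(tab$waic), ]
  rownames(tab) <- NULL
  class(tab) <- c("comparison_table", "data.frame")
  tab
}

#' @export
print.comparison_table <- function(x, ...) {
  y <- x
  y$waic <- round(y$waic, 2)
  y$delta <- round(y$delta, 2)
  y$weight <- round(y$weight, 3)
  y$se_waic <- round(y$se_waic, 2)
  y$se_delta <- round(y$se_delta, 2)
  print.data.frame(y)
  invisible(x)
}
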