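role_suffix <- function(fit, role) {
  suffix <- switch(role,
                   initiator = "I", recipient = "R",
                   household_initiator = "hI", household_recipient = "hR",
                   stop("unknown role: ", role, call. = FALSE))
  if (grepl("^h", suffix) && !fit$spec$has_h) {
    stop("variant ", fit$spec$variant, " has no household random effects",
         call. = FALSE)
  }
  suffix
}

#' Recompose random-effect correlations across behaviors
#'
#' For every retained draw, rebuilds the correlation matrix of the chosen
#' role's random effects from its sampled Cholesky factor (`L %*% t(L)`) and
#' summarizes each unordered category pair: posterior mean, percentile
#' interval, and a significance flag (interval excludes zero). Because no
#' multiplicity correction is applied in the primary analysis, a
#' Bonferroni-adjusted flag over all pairs is also reported.
#'
#' @param fit a `dyad_fit`.
#' @param role `"initiator"`, `"recipient"`, `"household_initiator"` or
#'   `"household_recipient"` (household roles only for `ih`/`ihF`).
#' @param level credible level (default 0.95).
#' @return data.frame with one row per pair `(k, l)`, `k > l`: posterior
#'   `mean`, `lower`, `upper`, `significant`, `significant_bonferroni`;
#'   attribute `mean_matrix` holds the posterior-mean correlation matrix.
#' @export
recompose_correlations <- function(fit, role = "initiator", level = 0.95) {
  suffix <- role_suffix(fit, role)
  ydraws <- extract_par(fit, paste0("y_", suffix))
  K1 <- fit$spec$K - 1L
  P <- K1 * (K1 - 1) / 2
  lowtri <- which(lower.tri(matrix(0, K1, K1)))
  rho <- t(apply(ydraws, 1, function(y) {
    tcrossprod(corr_chol_from_y(y, K1))[lowtri]
  }))
  if (P == 1) rho <- matrix(rho, ncol = 1)
  idx <- which(lower.tri(matrix(0, K1, K1)), arr.ind = TRUE)
  a <- (1 - level) / 2
  ab <- 0.05 / P / 2
  qs <- apply(rho, 2, stats::quantile, probs = c(a, 1 - a, ab, 1 - ab),
              names = FALSE)
  labels <- fit$spec$taxonomy$labels
  out <- data.frame(
    k = idx[, 1], l = idx[, 2],
    behavior_k = labels[idx[, 1]], behavior_l = labels[idx[, 2]],
    mean = colMeans(rho), lower = qs[1, ], upper = qs[2, ],
    stringsAsFactors = FALSE)
  out$significant <- out$lower > 0 | out$upper < 0
  out$significant_bonferroni <- qs[3, ] > 0 | qs[4, ] < 0
  Rm <- diag(K1)
  Rm[lowtri] <- out$mean
  Rm[upper.tri(Rm)] <- t(Rm)[upper.tri(Rm)]
  attr(out, "mean_matrix") <- Rm
  attr(out, "role") <- role
  out
}

#' Posterior summaries of random-effect standard deviations
#'
#' @param fit a `dyad_fit`.
#' @param role as in [recompose_correlations()].
#' @return data.frame per non-reference category: posterior `mean`, `sd`
#'   and percentile interval of the random-effect SD.
#' @export
random_effect_sds <- function(fit, role = "initiator", level = 0.95) {
  suffix <- role_suffix(fit, role)
  s <- extract_par(fit, paste0("sigma_", suffix))
  out <- posterior_summary(s, level)
  out$category <- seq_len(nrow(out))
  out$behavior <- fit$spec$taxonomy$labels[out$category]
  out$role <- role
  out[, c("category", "behavior", "role", "mean", "sd", "lower", "upper")]
}

#' Define a prediction scenario
#'
#' A scenario fixes the demographic covariates on their natural scale
#' (years, sex labels, household status) and optionally lets one covariate
#' vary over a grid. Continuous covariates default to the event-level sample
#' mean (the standardization base), sexes to female and household status to
#' different-household; random effects are set to zero, so predictions
#' describe behavior between an "average" initiator and an "average"
#' recipient.
#'
#' @param varying name of the varying covariate (`"initiator_age"`,
#'   `"recipient_age"`, `"initiator_sex"`, `"recipient_sex"`,
#'   `"same_household"`) or `NULL` for a point scenario.
#' @param grid grid of values for the varying covariate (ages in years,
#'   sexes as `"female"`/`"male"`, household status as logical).
#' @param initiator_age,recipient_age fixed ages in years (default: sample
#'   mean).
#' @param initiator_sex,recipient_sex fixed sexes.
#' @param same_household fixed household status.
#' @return an object of class `prediction_scenario`.
#' @export
prediction_scenario <- function(varying = NULL, grid = NULL,
                                initiator_age = NULL, recipient_age = NULL,
                                initiator_sex = "female",
                                recipient_sex = "female",
                                same_household = FALSE) {
  if (!is.null(varying)) {
    varying <- match.arg(varying, c("initiator_age", "recipient_age",
                                    "initiator_sex", "recipient_sex",
                                    "same_household"))
    if (is.null(grid)) stop("a varying scenario needs a grid", call. = FALSE)
  }
  structure(list(varying = varying, grid = grid,
                 initiator_age = initiator_age,
                 recipient_age = recipient_age,
                 initiator_sex = match.arg(initiator_sex,
                                           c("female", "male")),
                 recipient_sex = match.arg(recipient_sex,
                                           c("female", "male")),
                 same_household = isTRUE(same_household)),
            class = "prediction_scenario")
}

# per-draw probability simplexes for each grid point of a scenario
scenario_prob_draws <- function(fit, scenario) {
  spec <- fit$spec
  scaler <- fit$data$scaler
  K1 <- spec$K - 1L
  alpha <- extract_par(fit, "alpha")
  S <- nrow(alpha)
  fixed <- list(
    initiator_age = scenario$initiator_age %||% scaler$age_I$mean,
    recipient_age = scenario$recipient_age %||% scaler$age_R$mean,
    initiator_sex = scenario$initiator_sex,
    recipient_sex = scenario$recipient_sex,
    same_household = scenario$same_household)
  grid <- if (is.null(scenario$varying)) list(NULL) else
    as.list(scenario$grid)
  if (!is.null(scenario$varying) &&
      scenario$varying %in% c("initiator_age", "recipient_age")) {
    rng <- if (scenario$varying == "initiator_age") scaler$age_I$range
    else scaler$age_R$range
    if (!is.null(rng) &&
        (min(unlist(grid)) < rng[1] - 1e-9 ||
         max(unlist(grid)) > rng[2] + 1e-9)) {
      warning("age grid extends beyond the observed age range",
              call. = FALSE)
    }
  }
  if (spec$has_F) {
    bI <- extract_par(fit, "beta_I")
    bR <- extract_par(fit, "beta_R")
    bH <- extract_par(fit, "beta_H")
  }
  lapply(grid, function(gv) {
    cov <- fixed
    if (!is.null(scenario$varying)) cov[[scenario$varying]] <- gv
    eta <- alpha
    if (spec$has_F) {
      zi <- standardize_age(cov$initiator_age, scaler, "initiator")
      zj <- standardize_age(cov$recipient_age, scaler, "recipient")
      si <- as.numeric(identical(cov$initiator_sex, "male") ||
                         isTRUE(cov$initiator_sex == "male"))
      sj <- as.numeric(identical(cov$recipient_sex, "male") ||
                         isTRUE(cov$recipient_sex == "male"))
      xi <- c(age = zi, sex = si, age_sex = zi * si)[spec$covariates]
      xj <- c(age = zj, sex = sj, age_sex = zj * sj)[spec$covariates]
      xh <- as.numeric(isTRUE(cov$same_household))
      for (m in seq_len(spec$m)) {
        cols <- (m - 1) * K1 + seq_len(K1)
        eta <- eta + xi[m] * bI[, cols] + xj[m] * bR[, cols]
      }
      eta <- eta + xh * bH
    }
    category_probabilities(eta)   # S x K matrix of per-draw simplexes
  })
}

#' Predicted behavior probabilities over a covariate grid
#'
#' For every retained posterior draw and grid point, computes the K-simplex
#' of behavior probabilities at zero random effects, then summarizes each
#' category by its posterior mean and percentile band.
#'
#' @param fit a `dyad_fit`.
#' @param scenario a [prediction_scenario()].
#' @param level credible level for the band.
#' @return data.frame of class `prediction_curve`: columns `value` (grid
#'   value; `NA` for a point scenario), `category`, `behavior`, `mean`,
#'   `lower`, `upper`; attribute `varying` names the varying covariate.
#' @export
predict_probabilities <- function(fit, scenario = prediction_scenario(),
                                  level = 0.95) {
  probs <- scenario_prob_draws(fit, scenario)
  K <- fit$spec$K
  a <- (1 - level) / 2
  grid_vals <- if (is.null(scenario$varying)) NA else scenario$grid
  rows <- Map(function(p, gv) {
    qs <- apply(p, 2, stats::quantile, probs = c(a, 1 - a), names = FALSE)
    data.frame(value = rep(gv, K), category = seq_len(K),
               behavior = fit$spec$taxonomy$labels,
               mean = colMeans(p), lower = qs[1, ], upper = qs[2, ],
               stringsAsFactors = FALSE)
  }, probs, as.list(grid_vals))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "varying") <- scenario$varying
  attr(out, "level") <- level
  class(out) <- c("prediction_curve", "data.frame")
  out
}

#' Contrast predicted probabilities between two scenarios
#'
#' Computes, per draw and category, the difference of predicted
#' probabilities between two scenarios that differ in the contrasted factor
#' only, and flags categories whose percentile interval excludes zero.
#'
#' @param fit a `dyad_fit`.
#' @param scenario_a,scenario_b [prediction_scenario()]s with matching
#'   grids.
#' @param level credible level.
#' @return data.frame: per category (and grid value), mean difference
#'   (a minus b), interval and `significant` flag.
#' @export
contrast_scenarios <- function(fit, scenario_a, scenario_b, level = 0.95) {
  if (!identical(scenario_a$varying, scenario_b$varying) ||
      !identical(scenario_a$grid, scenario_b$grid)) {
    stop("scenario grids do not match", call. = FALSE)
  }
  pa <- scenario_prob_draws(fit, scenario_a)
  pb <- scenario_prob_draws(fit, scenario_b)
  K <- fit$spec$K
  a <- (1 - level) / 2
  grid_vals <- if (is.null(scenario_a$varying)) NA else scenario_a$grid
  rows <- Map(function(p1, p2, gv) {
    d <- p1 - p2
    qs <- apply(d, 2, stats::quantile, probs = c(a, 1 - a), names = FALSE)
    data.frame(value = rep(gv, K), category = seq_len(K),
               behavior = fit$spec$taxonomy$labels,
               mean = colMeans(d), lower = qs[1, ], upper = qs[2, ],
               significant = qs[1, ] > 0 | qs[2, ] < 0,
               stringsAsFactors = FALSE)
  }, pa, pb, as.list(grid_vals))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Label the age trend of each behavior's prediction curve
#'
#' A category is `increasing` (`decreasing`) if its posterior-mean curve is
#' monotone over the age grid within tolerance; otherwise it is `peaked`
#' and the grid cell of the maximum is reported as a yearly interval
#' `[floor(peak), floor(peak) + 1)`.
#'
#' @param curve a `prediction_curve` over an age grid.
#' @param tol monotonicity tolerance on probability differences.
#' @return data.frame: `category`, `behavior`, `trend`, `peak_age`,
#'   `peak_lower`, `peak_upper`.
#' @export
label_age_trend <- function(curve, tol = 1e-6) {
  varying <- attr(curve, "varying")
  if (is.null(varying) || !grepl("age$", varying)) {
    stop("trend labelling needs a curve over an age grid", call. = FALSE)
  }
  out <- do.call(rbind, lapply(split(curve, curve$category), function(cc) {
    cc <- cc[order(cc$value), ]
    d <- diff(cc$mean)
    trend <- if (all(d >= -tol)) "increasing"
    else if (all(d <= tol)) "decreasing"
    else "peaked"
    peak <- if (trend == "peaked") cc$value[which.max(cc$mean)] else NA_real_
    data.frame(category = cc$category[1], behavior = cc$behavior[1],
               trend = trend, peak_age = peak,
               peak_lower = if (is.na(peak)) NA_real_ else floor(peak),
               peak_upper = if (is.na(peak)) NA_real_ else floor(peak) + 1,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Dyad-level descriptive statistics
#'
#' Tallies, for every behavior crossed with household status (same or
#' different) and sex composition (same or different), the total number of
#' observations, the number of unique directed dyads exhibiting the
#' behavior and the average per dyad; plus per-child and per-household
#' participation totals (each event counts once for the initiator and once
#' for the recipient).
#'
#' @param events a `dyad_events` data.frame.
#' @param roster the matching `child_roster`.
#' @return a list of class `dyad_descriptives`: `by_group` (per behavior x
#'   grouping), `per_child`, `per_household`, and summary means/SDs.
#' @export
dyad_descriptives <- function(events, roster) {
  sex <- stats::setNames(roster$sex, roster$child_id)
  hh <- stats::setNames(roster$household_id, roster$child_id)
  same_h <- hh[events$initiator_id] == hh[events$recipient_id]
  same_s <- sex[events$initiator_id] == sex[events$recipient_id]
  grp <- data.frame(behavior_code = events$behavior_code,
                    same_household = unname(same_h),
                    same_sex = unname(same_s),
                    dyad = paste(events$initiator_id, events$recipient_id,
                                 sep = "->"),
                    stringsAsFactors = FALSE)
  agg <- do.call(rbind, lapply(
    split(grp, grp[c("behavior_code", "same_household", "same_sex")],
          drop = TRUE),
    function(g) data.frame(behavior_code = g$behavior_code[1],
                           same_household = g$same_household[1],
                           same_sex = g$same_sex[1],
                           total = nrow(g),
                           dyads = length(unique(g$dyad)),
                           stringsAsFactors = FALSE)))
  agg$avg_per_dyad <- agg$total / agg$dyads
  rownames(agg) <- NULL

  part <- c(events$initiator_id, events$recipient_id)
  per_child <- as.data.frame(table(factor(part, levels = roster$child_id)),
                             stringsAsFactors = FALSE)
  names(per_child) <- c("child_id", "n")
  hpart <- hh[part]
  per_house <- as.data.frame(
    table(factor(hpart, levels = sort(unique(roster$household_id)))),
    stringsAsFactors = FALSE)
  names(per_house) <- c("household_id", "n")

  structure(list(by_group = agg, per_child = per_child,
                 per_household = per_house,
                 child_mean = mean(per_child$n),
                 child_sd = stats::sd(per_child$n),
                 household_mean = mean(per_house$n),
                 household_sd = stats::sd(per_house$n),
                 n_events = nrow(events)),
            class = "dyad_descriptives")
}

#' @export
print.dyad_descriptives <- function(x, ...) {
  cat("Descriptives over", x$n_events, "events:\n")
  cat(sprintf("  per child: mean %.2f (SD %.2f); per household: %s %.2f %s\n",
              x$child_mean, x$child_sd, "mean", x$household_mean,
              sprintf("(SD %.2f)", x$household_sd)))
  invisible(x)
}
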