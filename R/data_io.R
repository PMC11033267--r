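#' Read a child roster
#'
#' The roster is a UTF-8 comma-delimited file with a header row and columns
#' `child_id`, `sex`, `household_id`, `age_at_study_start`. Sex must be coded
#' `female` or `male`. `age_at_study_start` may be negative only for children
#' born during the fieldwork window (entry age 0 at birth).
#'
#' @param path path to the roster CSV.
#' @return A data.frame of class `child_roster` with one validated row per
#'   child.
#' @export
load_roster <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("child_id", "sex", "household_id", "age_at_study_start")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("roster is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  dup <- df$child_id[duplicated(df$child_id)]
  if (length(dup)) {
    stop("duplicated child_id in roster: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  bad_sex <- which(!df$sex %in% c("female", "male"))
  if (length(bad_sex)) {
    stop(sprintf("unknown sex token %s in roster row %d",
                 sQuote(df$sex[bad_sex[1]]), bad_sex[1]), call. = FALSE)
  }
  if (any(!nzchar(df$household_id))) {
    stop("empty household_id in roster", call. = FALSE)
  }
  df$age_at_study_start <- as.numeric(df$age_at_study_start)
  if (anyNA(df$age_at_study_start)) {
    stop("non-numeric age_at_study_start in roster", call. = FALSE)
  }
  class(df) <- c("child_roster", "data.frame")
  df
}

#' Write a child roster
#'
#' @param roster a `child_roster` data.frame.
#' @param path output CSV path.
#' @export
write_roster <- function(roster, path) {
  utils::write.csv(
    roster[, c("child_id", "sex", "household_id", "age_at_study_start")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read directed dyadic observation events
#'
#' Events are one per row in a UTF-8 CSV with header columns `event_id`,
#' `episode_id`, `date` (ISO-8601, may be empty), `initiator_id`,
#' `recipient_id`, `behavior_code`, `initiator_age`, `recipient_age`.
#' Every event is validated against the roster (both children known, no
#' self-directed events) and the taxonomy (codes in 1..K, ages in [0, 13)).
#'
#' @param path path to the observations CSV.
#' @param taxonomy a [behavior_taxonomy()].
#' @param roster a roster from [load_roster()].
#' @return A data.frame of class `dyad_events`.
#' @export
load_observations <- function(path, taxonomy, roster) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("event_id", "episode_id", "date", "initiator_id",
                "recipient_id", "behavior_code", "initiator_age",
                "recipient_age")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("observations file is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df$event_id <- as.integer(df$event_id)
  df$episode_id <- as.integer(df$episode_id)
  df$behavior_code <- as.integer(df$behavior_code)
  df$initiator_age <- as.numeric(df$initiator_age)
  df$recipient_age <- as.numeric(df$recipient_age)
  validate_events(df, taxonomy, roster)
  class(df) <- c("dyad_events", "data.frame")
  df
}

validate_events <- function(df, taxonomy, roster) {
  selfdir <- which(df$initiator_id == df$recipient_id)
  if (length(selfdir)) {
    stop(sprintf("self-directed event (initiator == recipient) at row %d",
                 selfdir[1]), call. = FALSE)
  }
  known <- roster$child_id
  unknown <- setdiff(c(df$initiator_id, df$recipient_id), known)
  if (length(unknown)) {
    stop("event references unknown child id(s): ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  bad <- which(df$behavior_code < 1L | df$behavior_code > taxonomy$K |
                 is.na(df$behavior_code))
  if (length(bad)) {
    stop(sprintf("behavior_code out of range 1..%d at row %d",
                 taxonomy$K, bad[1]), call. = FALSE)
  }
  ages <- c(df$initiator_age, df$recipient_age)
  if (any(is.na(ages)) || any(ages < 0) || any(ages >= 13)) {
    stop("ages at observation must lie in [0, 13)", call. = FALSE)
  }
  invisible(df)
}

#' Write observation events
#'
#' Inverse of [load_observations()]: writes the same CSV dialect so that a
#' load/write cycle reproduces the file field-for-field.
#'
#' @param events a `dyad_events` data.frame.
#' @param path output CSV path.
#' @export
write_observations <- function(events, path) {
  cols <- c("event_id", "episode_id", "date", "initiator_id", "recipient_id",
            "behavior_code", "initiator_age", "recipient_age")
  utils::write.csv(events[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build model-ready design structures from events and a roster
#'
#' Index-codes children and households, standardizes the continuous
#' covariates and assembles the covariate blocks consumed by the likelihood.
#' The default covariate set per role is (standardized age, sex, their
#' product) for initiator and recipient, plus the same-household indicator.
#' Sex is coded female = 0, male = 1 and ages are standardized per role by
#' their own event-level mean and SD, so that the intercepts are the
#' female/female, different-household, mean-age baseline.
#'
#' @param events validated `dyad_events`.
#' @param roster validated `child_roster`.
#' @param taxonomy a [behavior_taxonomy()].
#' @param scaler optional scaler (as stored in a previous design) to reuse
#'   instead of recomputing column means/SDs; used to keep standardization
#'   idempotent across datasets.
#' @return An object of class `dyad_data`: outcome vector `y`, index vectors
#'   (`i_idx`, `j_idx`, `hi_idx`, `hj_idx`), covariate blocks `X_I`, `X_R`,
#'   indicator `x_H`, the `scaler`, and bookkeeping (ids, sizes, taxonomy).
#' @export
build_design <- function(events, roster, taxonomy, scaler = NULL) {
  validate_events(events, taxonomy, roster)
  child_ids <- roster$child_id
  household_ids <- sort(unique(roster$household_id))
  i_idx <- match(events$initiator_id, child_ids)
  j_idx <- match(events$recipient_id, child_ids)
  child_house <- match(roster$household_id, household_ids)
  hi_idx <- child_house[i_idx]
  hj_idx <- child_house[j_idx]

  sex_code <- ifelse(roster$sex == "male", 1, 0)
  sex_i <- sex_code[i_idx]
  sex_j <- sex_code[j_idx]

  if (is.null(scaler)) {
    scaler <- list(
      age_I = list(mean = mean(events$initiator_age),
                   sd = stats::sd(events$initiator_age),
                   range = range(events$initiator_age)),
      age_R = list(mean = mean(events$recipient_age),
                   sd = stats::sd(events$recipient_age),
                   range = range(events$recipient_age)))
  }
  if (!is.finite(scaler$age_I$sd) || scaler$age_I$sd == 0 ||
      !is.finite(scaler$age_R$sd) || scaler$age_R$sd == 0) {
    stop("zero age variance: cannot standardize", call. = FALSE)
  }
  zage_i <- (events$initiator_age - scaler$age_I$mean) / scaler$age_I$sd
  zage_j <- (events$recipient_age - scaler$age_R$mean) / scaler$age_R$sd

  X_I <- cbind(age = zage_i, sex = sex_i, age_sex = zage_i * sex_i)
  X_R <- cbind(age = zage_j, sex = sex_j, age_sex = zage_j * sex_j)
  x_H <- as.numeric(roster$household_id[i_idx] ==
                      roster$household_id[j_idx])

  structure(list(
    y = events$behavior_code,
    K = taxonomy$K,
    taxonomy = taxonomy,
    i_idx = i_idx, j_idx = j_idx,
    hi_idx = hi_idx, hj_idx = hj_idx,
    X_I = X_I, X_R = X_R, x_H = x_H,
    scaler = scaler,
    child_ids = child_ids,
    household_ids = household_ids,
    child_household = child_house,
    n_events = nrow(events),
    I = length(child_ids),
    H = length(household_ids)
  ), class = "dyad_data")
}

#' @export
print.dyad_data <- function(x, ...) {
  cat("dyad_data:", x$n_events, "events,", x$I, "children,", x$H,
      "households,", x$K, "behavior categories\n")
  invisible(x)
}

#' Standardize an age on the natural scale using a stored scaler
#'
#' @param age age in years.
#' @param scaler the `scaler` element of a `dyad_data` object.
#' @param role `"initiator"` or `"recipient"`.
#' @return standardized age.
#' @export
standardize_age <- function(age, scaler, role = c("initiator", "recipient")) {
  role <- match.arg(role)
  s <- if (role == "initiator") scaler$age_I else scaler$age_R
  (age - s$mean) / s$sd
}
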