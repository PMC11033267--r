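# Fixtures are built in code: tiny hand-written tables, plus cached
# desk-scale simulations/fits shared across test files.

toy_roster_df <- function() {
  data.frame(
    child_id = c("a1", "a2", "b1", "b2"),
    sex = c("female", "male", "female", "male"),
    household_id = c("hA", "hA", "hB", "hB"),
    age_at_study_start = c(3.5, 6.0, 2.0, 9.0),
    stringsAsFactors = FALSE)
}

toy_roster_file <- function(df = toy_roster_df()) {
  f <- tempfile(fileext = ".csv")
  utils::write.csv(df, f, row.names = FALSE, quote = FALSE)
  f
}

toy_events_df <- function() {
  data.frame(
    event_id = 1:6,
    episode_id = c(1L, 1L, 2L, 2L, 3L, 3L),
    date = rep("1959-06-01", 6),
    initiator_id = c("a1", "a2", "a1", "b1", "b2", "a2"),
    recipient_id = c("a2", "a1", "b1", "b2", "a1", "b2"),
    behavior_code = c(1L, 2L, 3L, 1L, 2L, 4L),
    initiator_age = c(3.5, 6.0, 3.5, 2.0, 9.0, 6.0),
    recipient_age = c(6.0, 3.5, 2.0, 9.0, 3.5, 9.0),
    stringsAsFactors = FALSE)
}

toy_events_file <- function(df = toy_events_df()) {
  f <- tempfile(fileext = ".csv")
  utils::write.csv(df, f, row.names = FALSE, quote = FALSE)
  f
}

toy_taxonomy <- function(K = 4) {
  behavior_taxonomy(sprintf("behavior_%02d", seq_len(K)))
}

toy_design <- function() {
  roster <- load_roster(toy_roster_file())
  events <- load_observations(toy_events_file(), toy_taxonomy(), roster)
  build_design(events, roster, toy_taxonomy())
}

# build a dyad_fit shell around externally supplied draws, for testing
# post-processing functions without running MCMC
fake_fit <- function(spec, data, draws_by_chain) {
  draws <- do.call(rbind, draws_by_chain)
  colnames(draws) <- dyadmnl:::param_names(spec, data)
  structure(list(spec = spec, data = data,
                 chains = draws_by_chain, draws = draws,
                 n_chains = length(draws_by_chain),
                 n_keep = nrow(draws_by_chain[[1]]),
                 param_names = colnames(draws),
                 divergences = rep(0L, length(draws_by_chain)),
                 stepsize = rep(NA_real_, length(draws_by_chain)),
                 logp = lapply(draws_by_chain,
                               function(m) numeric(nrow(m)))),
            class = "dyad_fit")
}

# shared small simulation + fits (computed once per test run)
.cache <- new.env(parent = emptyenv())

small_sim <- function() {
  if (is.null(.cache$sim)) {
    K1 <- 3
    truth <- make_truth(
      4, "iF",
      alpha = c(0.4, 0.1, -0.2),
      # strong age effects on categories 1-2 and a strong initiator-sex
      # effect on category 1, so that covariates absorb initiator variance
      beta_I = cbind(age = c(1.2, -1.0, 0), sex = c(1.2, 0, 0),
                     age_sex = c(0, 0, 0)),
      beta_R = cbind(age = c(-0.8, 0.6, 0), sex = c(0, 0, 0),
                     age_sex = c(0, 0, 0)),
      beta_H = c(0.3, -0.2, 0),
      corr_I = diag(K1), corr_R = diag(K1),
      scale_I = c(0.3, 0.3, 0.3), scale_R = c(0.25, 0.25, 0.25))
    cfg <- sim_config(n_children = 40, n_households = 16, K = 4,
                      n_events = 1500, household_size_mean = 2.5,
                      variant = "iF", seed = 31)
    .cache$sim <- simulate_dataset(cfg, truth)
    .cache$sim_truth <- truth
  }
  .cache$sim
}

small_truth <- function() {
  small_sim()
  .cache$sim_truth
}

small_fit <- function(variant = "iF") {
  key <- paste0("fit_", variant)
  if (is.null(.cache[[key]])) {
    sim <- small_sim()
    .cache[[key]] <- fit_model(
      model_spec(variant, sim$taxonomy), sim$data,
      mcmc_config(chains = 2, iter = 700, warmup = 350, seed = 99))
  }
  .cache[[key]]
}
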