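# shared fixtures, built once per test run and memoised

.fixture_env <- new.env(parent = emptyenv())

# nominal simulation reused by the model tests
nominal_run <- function() {
  if (is.null(.fixture_env$nominal)) {
    .fixture_env$nominal <- simulate_cvs(cvs_parameters())
  }
  .fixture_env$nominal
}

nominal_free_values <- function() {
  pt <- cvs_parameters()
  stats::setNames(pt$value[match(cvs_free_parameters(), pt$name)],
                  cvs_free_parameters())
}

# synthetic patient used across measurement / identifiability tests
fixture_patient <- function() {
  if (is.null(.fixture_env$patient)) {
    .fixture_env$patient <- generate_patient(seed = 42)
  }
  .fixture_env$patient
}

# one full desk-scale pipeline run shared by the acceptance tests: a
# synthetic patient with the default CV table, reduction with default
# thresholds, GA refits, scaled ensemble chains, 100 prediction draws
acceptance_pipeline <- function() {
  if (is.null(.fixture_env$pipeline)) {
    .fixture_env$pipeline <- suppressWarnings(run_pipeline(
      fixture_patient(),
      seed = 1L,
      ga = ga_config(pop_size = 36, generations = 40,
                     stall_generations = 15),
      mcmc = mcmc_config(n_steps = 2500L, burn_in = 1250L)
    ))
  }
  .fixture_env$pipeline
}

# noise-free parameter-recovery run at reduced dimension: four candidate
# parameters free (the others fixed at their true nominal values),
# noise-free measurements carrying the default CV uncertainties
recovery_pipeline <- function() {
  if (is.null(.fixture_env$recovery)) {
    pat <- preset_patients(seed = 50, noise_free = TRUE)$full
    ptab <- cvs_parameters()
    keep_free <- c("q_sbv", "E_LVa", "R_MC_T", "R_TR_T")
    ptab$status[ptab$status == "free" & !ptab$name %in% keep_free] <- "fixed"
    .fixture_env$recovery <- list(
      patient = pat,
      result = suppressWarnings(run_pipeline(
        pat, parameters = ptab, seed = 2L,
        ga = ga_config(pop_size = 24, generations = 20,
                       stall_generations = 10),
        mcmc = mcmc_config(n_steps = 600L, burn_in = 300L),
        n_predictions = 40L
      )))
  }
  .fixture_env$recovery
}
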