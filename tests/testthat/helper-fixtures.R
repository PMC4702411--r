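# Shared fixtures: small generating scenarios and a fast fitting
# configuration for unit tests.  All cohorts are generated in code.

# two well-separated groups (log-level gap ~ 5, sd 0.3)
separated_scenario <- function(n = 60) {
  scenario_config(
    n_subjects = n,
    kinetics = c(k12 = 0.7, k21 = 0.25, k10 = 0.6),
    mu10 = c(1e3, 1.5e5),
    A = c(0, 2000),
    pi = c(0.6, 0.4),
    sigma = 0.3,
    production = "constant", variance = "shared")
}

# moderately separated two-group scenario for the trend sweep
close_scenario <- function(n = 100) {
  scenario_config(
    n_subjects = n,
    kinetics = c(k12 = 0.7, k21 = 0.25, k10 = 0.6),
    mu10 = c(2e4, 1e5),
    A = c(0, 400),
    pi = c(0.55, 0.45),
    sigma = 0.45,
    production = "constant", variance = "shared")
}

fast_config <- function(seed = 1, sem_iterations = 30, ...) {
  fit_config(sem_iterations = sem_iterations, seed = seed, n_restarts = 6,
             n_successful_chains = 1, ...)
}

# long-format csv on disk, returns the path
write_fixture_csv <- function(df, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "cohort.csv")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# a cohort built directly from vectors (bypasses file round-trip)
cohort_from_long <- function(subject, time, hcg, labels = NULL) {
  new_cohort(data.frame(subject_id = subject, time = time, hcg = hcg,
                        log_hcg = log(hcg), stringsAsFactors = FALSE),
             labels = labels)
}
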