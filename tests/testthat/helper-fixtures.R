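# Shared fixtures, built once per test run and cached in an environment so
# several test files (and the acceptance suite) can reuse them.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# A small mixed cohort (2 HF + 2 non-HF subjects, 2 epochs each).
small_cohort <- function() {
  cached("small_cohort", function() make_cohort(2, 2, 2, seed = 11))
}

small_epochs <- function() {
  cached("small_epochs", function() preprocess_cohort(small_cohort()))
}

small_features <- function() {
  cached("small_features", function() extract_feature_table(small_epochs()))
}

# The full-size study cohort: 10 HF + 10 non-HF subjects, 10 epochs each,
# seed 1 - the end-to-end discrimination condition.
full_features <- function() {
  cached("full_features", function() {
    coh <- make_cohort(10, 10, 10, seed = 1)
    ep <- preprocess_cohort(coh)
    extract_feature_table(ep)
  })
}

# One clean separated epoch pair (no artifacts, no degradation).
clean_epoch <- function() {
  cached("clean_epoch", function() {
    p <- class_params(artifact_rate = 0)
    r <- make_recording(p, "S1", 0, duration = 35, fs = 1000, seed = 5)
    res <- extract_respiration(r$recording)
    bcg <- extract_bcg(r$recording, res)
    list(bcg = bcg[1:30000], res = res[1:30000], fs = 1000)
  })
}

# A synthetic feature table with a controlled class difference: subject
# random effects plus one or more informative columns. Used by evaluation
# tests that do not need real signal features.
synth_feature_table <- function(n_subjects = 10, epochs = 5, informative = "t28",
                                effect = 2, subject_sd = 0.5, noise_sd = 1,
                                seed = 1) {
  withr::with_seed(seed, {
    rows <- list()
    for (s in seq_len(n_subjects)) {
      lab <- as.integer(s <= n_subjects / 2)
      subj_eff <- rnorm(33, 0, subject_sd)
      for (e in seq_len(epochs)) {
        v <- rnorm(33, 0, noise_sd) + subj_eff
        names(v) <- sprintf("t%02d", 1:33)
        v[informative] <- v[informative] + effect * lab
        rows[[length(rows) + 1]] <- tibble::as_tibble(as.list(v)) |>
          dplyr::mutate(subject_id = sprintf("S%02d", s), label = lab,
                        epoch_index = e, .before = 1)
      }
    }
    dplyr::bind_rows(rows)
  })
}
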