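# CSV interchange for recordings, cohorts, feature tables and results.
# Every file written carries the pipeline configuration hash as a leading
# "#" comment (CSV) or a JSON field, for provenance.

config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  writeLines(yaml::as.yaml(config), tf)
  unname(tools::md5sum(tf))
}

write_csv_hashed <- function(df, path, hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(hash)) writeLines(sprintf("# bcghf_config_hash: %s", hash), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_csv_hashed <- function(path) {
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read and write force-sensor recordings as CSV
#'
#' The interchange format is a two-column CSV (`time_s`, `counts`) of raw
#' ADC samples. On reading, the sampling rate is inferred from the median
#' time step and checked against `fs` when supplied; a non-monotone time
#' column is an error.
#'
#' @param rec A `bcg_recording`.
#' @param path CSV file path.
#' @param hash Optional configuration hash embedded as a comment line.
#' @return `write_recording()`: the path, invisibly.
#' @export
write_recording <- function(rec, path, hash = NULL) {
  write_csv_hashed(as.data.frame(rec[c("time_s", "counts")]), path, hash)
}

#' @rdname write_recording
#' @param fs Expected sampling rate (Hz); a mismatch beyond 1% is an error.
#' @param subject_id,label Metadata attached to the recording.
#' @return `read_recording()`: a `bcg_recording`.
#' @export
read_recording <- function(path, fs = NULL, subject_id = NA_character_,
                           label = NA_integer_) {
  df <- read_csv_hashed(path)
  if (!all(c("time_s", "counts") %in% names(df))) {
    abort("recording CSV must have columns time_s, counts",
          class = "bcghf_invalid_argument")
  }
  dt <- diff(df$time_s)
  if (any(dt <= 0)) {
    abort("time column must be strictly increasing",
          class = "bcghf_invalid_argument")
  }
  fs_obs <- 1 / median(dt)
  if (!is.null(fs) && abs(fs_obs - fs) / fs > 0.01) {
    abort(sprintf("sampling rate mismatch: file has %.6g Hz, expected %g Hz",
                  fs_obs, fs), class = "bcghf_invalid_argument")
  }
  new_recording(df$time_s, df$counts, fs %||% fs_obs, subject_id, label,
                meta = list(path = path))
}

#' Write and read a cohort of recordings plus manifest
#'
#' Each subject's recording is written as its own CSV and a
#' `manifest.csv` (`subject_id`, `label`, `file`, `seed`) indexes the
#' cohort directory.
#'
#' @param cohort A cohort tibble from [make_cohort()].
#' @param dir Output directory (created if needed).
#' @param hash Optional configuration hash.
#' @return The manifest tibble, invisibly.
#' @export
write_cohort <- function(cohort, dir, hash = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("%s.csv", cohort$subject_id)
  for (i in seq_len(nrow(cohort))) {
    write_recording(cohort$recording[[i]], file.path(dir, files[i]), hash)
  }
  manifest <- tibble(subject_id = cohort$subject_id, label = cohort$label,
                     file = files,
                     seed = cohort$seed %||% NA_integer_)
  write_csv_hashed(as.data.frame(manifest), file.path(dir, "manifest.csv"),
                   hash)
  invisible(manifest)
}

#' @rdname write_cohort
#' @param fs Expected sampling rate passed to [read_recording()].
#' @return `read_cohort()`: a cohort tibble with a `recording` list-column.
#' @export
read_cohort <- function(dir, fs = NULL) {
  manifest <- read_csv_hashed(file.path(dir, "manifest.csv"))
  recs <- purrr::map(seq_len(nrow(manifest)), function(i) {
    read_recording(file.path(dir, manifest$file[i]), fs,
                   manifest$subject_id[i], manifest$label[i])
  })
  out <- as_tibble(manifest)
  out$recording <- recs
  out
}

#' Write and read feature tables as CSV
#'
#' @param features A feature table from [extract_feature_table()].
#' @param path CSV path.
#' @param hash Optional configuration hash.
#' @return The path (write) or the feature tibble (read).
#' @export
write_feature_table <- function(features, path, hash = NULL) {
  write_csv_hashed(as.data.frame(features), path, hash)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  as_tibble(read_csv_hashed(path))
}

#' Serialize evaluation results
#'
#' Writes a metrics CSV (one row per protocol and classifier), pooled ROC
#' points as CSV, and a JSON bundle with metrics, confusion counts and
#' chosen hyperparameters.
#'
#' @param cvs A list of `hf_cv` objects (e.g. LOO and LOSO).
#' @param dir Output directory.
#' @param hash Optional configuration hash.
#' @return The metrics tibble, invisibly.
#' @export
write_results <- function(cvs, dir, hash = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (inherits(cvs, "hf_cv")) cvs <- list(cvs)
  metrics <- dplyr::bind_rows(purrr::map(cvs, tidy))
  write_csv_hashed(as.data.frame(metrics), file.path(dir, "metrics.csv"), hash)
  roc <- dplyr::bind_rows(purrr::map(cvs, function(cv) {
    r <- tidyr::unnest(dplyr::select(cv$results, "classifier", "roc"), "roc")
    r$protocol <- cv$protocol
    r
  }))
  write_csv_hashed(as.data.frame(roc), file.path(dir, "roc.csv"), hash)
  bundle <- purrr::map(cvs, function(cv) {
    list(protocol = cv$protocol, seed = cv$seed, n_epochs = cv$n_epochs,
         n_subjects = cv$n_subjects,
         classifiers = purrr::map(
           split(cv$results, cv$results$classifier), function(row) {
             list(metrics = as.list(dplyr::select(
                    row, "acc", "sen", "spe", "f1", "auc")),
                  confusion = as.list(row$confusion[[1]]),
                  hyper = as.list(row$hyper[[1]][1, ]),
                  importance = if (!is.null(row$importance[[1]])) {
                    as.list(row$importance[[1]])
                  })
           }))
  })
  jsonlite::write_json(list(config_hash = hash, results = bundle),
                       file.path(dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(metrics)
}
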