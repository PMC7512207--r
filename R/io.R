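#' Write a cohort as per-trial CSV matrices plus a manifest
#'
#' One `channels x samples` CSV per trial under `dir/<subject_id>/`, plus
#' `manifest.csv` (subject_id, group, n_trials, fs). Plain-text layout so
#' any stage can be run and inspected in isolation.
#'
#' @param cohort List of `epoched_recording`s.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rec in cohort) {
    sdir <- file.path(dir, rec$subject_id)
    dir.create(sdir, showWarnings = FALSE)
    for (t in seq_len(dim(rec$data)[1])) {
      m <- rec$data[t, , , drop = FALSE]
      dim(m) <- dim(m)[2:3]
      rownames(m) <- rec$channel_names
      write.csv(m, file.path(sdir, sprintf("trial%04d.csv", t)))
    }
  }
  man <- cohort_manifest(cohort)
  man$fs <- vapply(cohort, `[[`, 0, "fs")
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort_csv()]
#'
#' @param dir Directory containing `manifest.csv` and per-subject folders.
#' @return List of `epoched_recording`s (class `"eeg_cohort"`).
#' @export
read_cohort_csv <- function(dir) {
  man <- read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  out <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    sdir <- file.path(dir, man$subject_id[i])
    files <- sort(list.files(sdir, pattern = "^trial[0-9]+\\.csv$",
                             full.names = TRUE))
    mats <- lapply(files, function(f) {
      m <- read.csv(f, row.names = 1, check.names = FALSE)
      as.matrix(m)
    })
    data <- array(0, dim = c(length(mats), nrow(mats[[1]]), ncol(mats[[1]])))
    for (t in seq_along(mats)) data[t, , ] <- mats[[t]]
    out[[i]] <- epoched_recording(man$subject_id[i], man$group[i], man$fs[i],
                                  data, rownames(mats[[1]]))
  }
  structure(out, class = "eeg_cohort")
}

#' Serialize a trained model to JSON
#'
#' Stores the architecture/parameters, standardization statistics and class
#' order, so a model can be reloaded and applied without the training data.
#'
#' @param model An `"eeg_model"`.
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  enc <- unclass(model)
  enc$standardization <- if (!is.null(model$standardization))
    unclass(model$standardization)
  if (!is.null(enc$config)) enc$config <- unclass(enc$config)
  jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' Load a model serialized by [write_model_json()]
#'
#' @param path JSON file path.
#' @return An `"eeg_model"`.
#' @export
read_model_json <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (m$kind %in% c("LDA", "QDA")) {
    m$means <- as.matrix(m$means)
    if (m$kind == "LDA") m$covs <- as.matrix(m$covs)
    else m$covs <- lapply(m$covs, as.matrix)
  } else {
    m$W1 <- as.matrix(m$W1); m$W2 <- as.matrix(m$W2)
    m$b1 <- as.numeric(m$b1); m$b2 <- as.numeric(m$b2)
  }
  if (!is.null(m$standardization)) {
    m$standardization <- structure(
      list(mean = unlist(m$standardization$mean),
           sd = unlist(m$standardization$sd)),
      class = "standardization_stats")
  }
  if (!is.null(m$priors)) m$priors <- unlist(m$priors)
  class(m) <- "eeg_model"
  m
}
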