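#' Extract the 14 channel-averaged features of one trial
#'
#' Computes the nine spectral and five nonlinear features per channel and
#' averages over channels. Channels whose sample entropy is undefined (no
#' template matches) are excluded from the SampEn average with a warning.
#'
#' @param epoch `channels x samples` matrix.
#' @param fs Sampling rate (Hz).
#' @param params A `nonlinear_params`.
#' @param features Optional character subset of [feature_names()] to
#'   compute (others are returned as `NA`); useful to cut run time when
#'   only some features are needed.
#' @param ... Passed to [compute_psdn()].
#' @return Named numeric vector of length 14.
#' @export
extract_epoch_features <- function(epoch, fs, params = nonlinear_params(),
                                   features = NULL, ...) {
  if (is.vector(epoch)) epoch <- matrix(epoch, nrow = 1)
  all_names <- feature_names()
  features <- features %||% all_names
  out <- stats::setNames(rep(NA_real_, length(all_names)), all_names)
  spectral_wanted <- intersect(features, all_names[1:9])
  nonlinear_wanted <- intersect(features, all_names[10:14])
  if (length(spectral_wanted)) {
    sp <- vapply(seq_len(nrow(epoch)),
                 function(ch) spectral_features(epoch[ch, ], fs, ...),
                 numeric(9))
    out[all_names[1:9]] <- rowMeans(sp)
  }
  if (length(nonlinear_wanted)) {
    nl <- nonlinear_features(epoch, fs, params)
    if (anyNA(nl["SampEn", ]))
      warning(sprintf("SampEn undefined on %d channel(s); excluded from the average",
                      sum(is.na(nl["SampEn", ]))))
    out[rownames(nl)] <- rowMeans(nl, na.rm = TRUE)
  }
  out
}

#' Build the trial-by-feature table for a cohort
#'
#' One row per trial with subject ID, group label and the 14 channel-averaged
#' features.
#'
#' @param cohort List of `epoched_recording`s.
#' @param params A `nonlinear_params`.
#' @param features Optional subset of [feature_names()] to compute.
#' @param estimator PSD estimator passed to [compute_psdn()].
#' @param verbose Print per-subject progress.
#' @return `data.frame` with columns `subject_id`, `group`, `trial` and the
#'   14 feature columns.
#' @export
extract_features <- function(cohort, params = nonlinear_params(),
                             features = NULL, estimator = "welch",
                             verbose = FALSE) {
  rows <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    rec <- cohort[[i]]
    nt <- dim(rec$data)[1]
    mat <- matrix(NA_real_, nt, length(feature_names()),
                  dimnames = list(NULL, feature_names()))
    for (t in seq_len(nt)) {
      ep <- rec$data[t, , , drop = FALSE]
      dim(ep) <- dim(ep)[2:3]
      mat[t, ] <- extract_epoch_features(ep, rec$fs, params, features,
                                         estimator = estimator)
    }
    rows[[i]] <- data.frame(subject_id = rec$subject_id, group = rec$group,
                            trial = seq_len(nt), mat,
                            stringsAsFactors = FALSE, row.names = NULL)
    if (verbose) message(sprintf("extracted %s (%d trials)", rec$subject_id, nt))
  }
  out <- do.call(rbind, rows)
  out$group <- factor(out$group, levels = eeg_groups())
  out
}

#' Write / read a feature table as CSV
#'
#' @param table Feature table from [extract_features()].
#' @param path CSV file path.
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` returns the table with `group` releveled.
#' @export
write_feature_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  out$group <- factor(out$group, levels = eeg_groups())
  out
}
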