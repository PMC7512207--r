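#' Stratified subject-level train/test split
#'
#' Samples `n_train_per_group` subjects per group into the training set;
#' the rest form the test set. Splitting is always at subject level so no
#' subject contributes trials to both sides.
#'
#' @param cohort `eeg_cohort` or manifest `data.frame` with `subject_id`
#'   and `group`.
#' @param n_train_per_group Training subjects per group (default 20, vs 17
#'   held out of 37).
#' @param seed Integer seed.
#' @return List with `train` and `test` character ID vectors.
#' @export
split_subjects <- function(cohort, n_train_per_group = 20, seed = 1) {
  man <- if (is.data.frame(cohort)) cohort else cohort_manifest(cohort)
  ids <- withr::with_seed(as.integer(seed), {
    unlist(lapply(eeg_groups(), function(g) {
      pool <- man$subject_id[man$group == g]
      if (length(pool) <= n_train_per_group)
        stopf("group %s has %d subjects; cannot hold out a test set after %d training draws",
              g, length(pool), n_train_per_group)
      sample(pool, n_train_per_group)
    }))
  })
  list(train = ids, test = setdiff(man$subject_id, ids))
}

#' Permutation p-value for a subject-level kappa
#'
#' Permutes the predicted labels against the actual ones and recomputes
#' kappa, giving an exact-style one-sided p-value for kappa > 0.
#'
#' @param actual,predicted Subject-level label vectors.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return List with `kappa` and `p_value`.
#' @export
kappa_permutation_test <- function(actual, predicted, n_perm = 999, seed = 1) {
  obs <- cohens_kappa(confusion_matrix3(actual, predicted))$kappa
  perm <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_perm), function(i) {
      cohens_kappa(confusion_matrix3(actual, sample(predicted)))$kappa
    }, 0)
  })
  list(kappa = obs, p_value = (1 + sum(perm >= obs)) / (n_perm + 1))
}

#' Run the full analysis pipeline on a synthetic or supplied cohort
#'
#' Executes, in order: cohort generation (unless a cohort is supplied),
#' subject-level train/test split, feature extraction, FCBF feature
#' selection on training rows only, training-set standardization, model
#' training (with optional leave-one-subject-out MLP tuning), test-trial
#' prediction, majority-vote subject diagnosis and evaluation. All
#' randomness flows from `seed` via named substreams, so a rerun with the
#' same configuration reproduces the report exactly.
#'
#' @param cohort Optional pre-generated `eeg_cohort`; when `NULL` one is
#'   generated from `config`.
#' @param config A `cohort_config` (used when `cohort` is `NULL`).
#' @param n_train_per_group Training subjects per group.
#' @param params A `nonlinear_params` for feature extraction.
#' @param models Subset of `c("lda", "qda", "mlp")`.
#' @param select Run FCBF (default); otherwise use all 14 features.
#' @param mlp MLP settings: an `mlp_config` for a fixed fit, or a list with
#'   `decay_grid`, `hidden_grid`, `n_restarts` to tune by
#'   leave-one-subject-out CV first.
#' @param seed Root seed for split, MLP and permutation substreams.
#' @param verbose Print stage progress.
#' @return List of class `"eeg_pipeline_report"`: the selection, per-model
#'   evaluations, tuned configurations and a provenance block.
#' @export
run_pipeline <- function(cohort = NULL, config = cohort_config(),
                         n_train_per_group = 20,
                         params = nonlinear_params(),
                         models = c("lda", "qda", "mlp"),
                         select = TRUE, mlp = mlp_config(),
                         seed = 1, verbose = FALSE) {
  models <- match.arg(models, several.ok = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  seeds <- derive_seeds(seed, 3)  # split / mlp / permutation

  if (is.null(cohort)) {
    say("generating cohort (%d subjects/group)", config$n_subjects_per_group)
    cohort <- generate_cohort(config)
  }
  split <- split_subjects(cohort, n_train_per_group, seed = seeds[1])

  say("extracting features from %d recordings", length(cohort))
  feat <- extract_features(cohort, params)
  train <- feat[feat$subject_id %in% split$train, , drop = FALSE]
  test <- feat[feat$subject_id %in% split$test, , drop = FALSE]

  selection <- NULL
  use_features <- feature_names()
  if (select) {
    selection <- fcbf(train)
    use_features <- selection$selected
    say("FCBF selected: %s", paste(use_features, collapse = ", "))
  }

  st <- standardization_stats(train[, use_features, drop = FALSE])
  xtr <- standardize(train[, use_features, drop = FALSE], st)
  xte <- standardize(test[, use_features, drop = FALSE], st)

  results <- list()
  tuned <- NULL
  for (kind in models) {
    model <- switch(kind,
      lda = train_lda(xtr, train$group),
      qda = train_qda(xtr, train$group),
      mlp = {
        cfg <- if (inherits(mlp, "mlp_config")) mlp else {
          say("tuning MLP over %d x %d grid",
              length(mlp$decay_grid), length(mlp$hidden_grid))
          tuned <- tune_mlp(train, use_features,
                             decay_grid = mlp$decay_grid,
                             hidden_grid = mlp$hidden_grid,
                             n_restarts = mlp$n_restarts %||% 30,
                             max_iterations = mlp$max_iterations %||% 300,
                             rng_seed = seeds[2])
          tuned
        }
        cfg$rng_seed <- seeds[2]
        train_mlp(xtr, train$group, cfg)
      })
    model$standardization <- st
    pred <- predict_trials(model, xte)
    trials <- cbind(test[, c("subject_id", "group")], pred)
    ev <- evaluate_predictions(trials)
    perm <- kappa_permutation_test(ev$subjects$group, ev$subjects$label,
                                   seed = seeds[3])
    results[[kind]] <- list(model = model, trials = trials, evaluation = ev,
                            kappa_permutation = perm)
    say("%s: subject kappa %.3f (perm p = %.4f)", toupper(kind),
        perm$kappa, perm$p_value)
  }

  structure(list(split = split, selection = selection,
                 features_used = use_features, mlp_tuned = tuned,
                 feature_table = feat, results = results,
                 provenance = list(seed = seed, substream_seeds = seeds,
                                   n_train_per_group = n_train_per_group,
                                   models = models,
                                   timestamp = format(Sys.time(), tz = "UTC"))),
            class = "eeg_pipeline_report")
}

#' @export
print.eeg_pipeline_report <- function(x, ...) {
  cat("<eeg_pipeline_report>\n")
  cat("  features used:", paste(x$features_used, collapse = ", "), "\n")
  for (kind in names(x$results)) {
    ev <- x$results[[kind]]$evaluation
    cat(sprintf("  %s: subject accuracy %.2f%%, kappa %.4f (perm p = %.4f)\n",
                toupper(kind), ev$accuracy_subject, ev$kappa_subject$kappa,
                x$results[[kind]]$kappa_permutation$p_value))
  }
  invisible(x)
}
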