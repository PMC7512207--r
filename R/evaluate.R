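#' Subject-level diagnosis by majority vote over trials
#'
#' Returns the most frequent trial label. Ties are broken by the highest
#' mean posterior over the tied classes when posteriors are supplied
#' (logged via `message`), otherwise by canonical class order.
#'
#' @param labels Trial labels of one subject.
#' @param posteriors Optional trials x classes posterior matrix/data frame
#'   with class-named columns.
#' @return Single factor label.
#' @export
majority_vote <- function(labels, posteriors = NULL) {
  labels <- factor(as.character(labels), levels = eeg_groups())
  if (!length(labels) || anyNA(labels)) stopf("subject has no valid trial labels")
  counts <- table(labels)
  top <- names(counts)[counts == max(counts)]
  if (length(top) == 1L) return(factor(top, levels = eeg_groups()))
  if (!is.null(posteriors)) {
    mp <- colMeans(as.matrix(posteriors[, top, drop = FALSE]))
    win <- top[which.max(mp)]
    message(sprintf("majority-vote tie (%s) broken by mean posterior -> %s",
                    paste(top, collapse = "/"), win))
  } else {
    win <- top[1]
    message(sprintf("majority-vote tie (%s) broken by class order -> %s",
                    paste(top, collapse = "/"), win))
  }
  factor(win, levels = eeg_groups())
}

#' 3 x 3 confusion matrix in canonical class order
#'
#' @param actual,predicted Equal-length label vectors over HC/MCI/AD.
#' @param level `"trial"` or `"subject"` (bookkeeping attribute).
#' @return Integer matrix (rows = actual, columns = predicted) of class
#'   `"confusion_matrix3"`.
#' @export
confusion_matrix3 <- function(actual, predicted, level = c("subject", "trial")) {
  level <- match.arg(level)
  if (length(actual) != length(predicted)) stopf("label sequences differ in length")
  a <- as.character(actual); p <- as.character(predicted)
  bad <- setdiff(unique(c(a, p)), eeg_groups())
  if (length(bad)) stopf("unknown label(s): %s", paste(bad, collapse = ", "))
  cm <- table(factor(a, levels = eeg_groups()), factor(p, levels = eeg_groups()))
  out <- matrix(as.integer(cm), 3, 3,
                dimnames = list(actual = eeg_groups(), predicted = eeg_groups()))
  structure(out, class = c("confusion_matrix3", "matrix"), level = level)
}

as_cm3 <- function(cm) {
  if (inherits(cm, "confusion_matrix3")) return(unclass(cm))
  cm <- as.matrix(cm)
  if (!all(dim(cm) == c(3, 3)) || any(cm < 0)) stopf("need a non-negative 3x3 matrix")
  dimnames(cm) <- list(actual = eeg_groups(), predicted = eeg_groups())
  cm
}

#' Cohen's kappa of a confusion matrix
#'
#' Chance-corrected agreement: `kappa = (p_o - p_e) / (1 - p_e)` with
#' observed agreement `p_o = trace/total` and chance agreement
#' `p_e = sum(row_i * col_i) / total^2`.
#'
#' @param cm 3 x 3 confusion matrix (actual x predicted).
#' @return List with `kappa`, `p_o`, `p_e` (class `"kappa_score"`).
#' @export
cohens_kappa <- function(cm) {
  cm <- as_cm3(cm)
  total <- sum(cm)
  if (total <= 0) stopf("empty confusion matrix")
  p_o <- sum(diag(cm)) / total
  p_e <- sum(rowSums(cm) * colSums(cm)) / total^2
  if (p_e >= 1) stopf("undefined kappa: chance agreement is 1")
  structure(list(kappa = (p_o - p_e) / (1 - p_e), p_o = p_o, p_e = p_e),
            class = "kappa_score")
}

#' Overall accuracy of a confusion matrix
#'
#' @param cm 3 x 3 confusion matrix.
#' @return Percentage of correctly classified units, in `[0, 100]`.
#' @export
overall_accuracy <- function(cm) {
  cm <- as_cm3(cm)
  100 * sum(diag(cm)) / sum(cm)
}

#' One-vs-all diagnostic metrics from a 3 x 3 confusion matrix
#'
#' Collapses the matrix to 2 x 2 and reports sensitivity, specificity,
#' accuracy, positive and negative predictive values as percentages. For
#' `HC_vs_all` the positive class is *cognitively impaired* (MCI or AD) --
#' the screening question "is this subject not healthy?"; for `AD_vs_all`
#' the positive class is AD. Undefined ratios (zero denominators) are
#' returned as `NA` rather than silently 0.
#'
#' @param cm 3 x 3 confusion matrix (actual x predicted).
#' @param comparison `"HC_vs_all"` or `"AD_vs_all"`.
#' @return List of class `"binary_metrics"`: `se`, `sp`, `acc`, `ppv`,
#'   `npv` (percent), plus `comparison`, `positive` and the collapsed
#'   2 x 2 counts.
#' @export
one_vs_all_metrics <- function(cm, comparison = c("HC_vs_all", "AD_vs_all")) {
  comparison <- match.arg(comparison)
  cm <- as_cm3(cm)
  pos <- if (comparison == "HC_vs_all") c("MCI", "AD") else "AD"
  neg <- setdiff(eeg_groups(), pos)
  tp <- sum(cm[pos, pos]); fn <- sum(cm[pos, neg])
  fp <- sum(cm[neg, pos]); tn <- sum(cm[neg, neg])
  ratio <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  structure(list(se = ratio(tp, tp + fn), sp = ratio(tn, tn + fp),
                 acc = ratio(tp + tn, tp + tn + fp + fn),
                 ppv = ratio(tp, tp + fp), npv = ratio(tn, tn + fn),
                 comparison = comparison, positive = pos,
                 counts = c(tp = tp, fp = fp, fn = fn, tn = tn)),
            class = "binary_metrics")
}

#' Aggregate trial predictions into a full evaluation report
#'
#' Computes subject diagnoses by majority vote, trial- and subject-level
#' confusion matrices, Cohen's kappa, overall accuracy and both one-vs-all
#' metric blocks.
#'
#' @param trials `data.frame` with `subject_id`, `group` (actual),
#'   `label` (predicted trial label) and optional posterior columns named
#'   after the classes.
#' @return List of class `"eeg_evaluation"`.
#' @export
evaluate_predictions <- function(trials) {
  need <- c("subject_id", "group", "label")
  if (!all(need %in% names(trials)))
    stopf("trials must contain columns: %s", paste(need, collapse = ", "))
  post_cols <- intersect(eeg_groups(), names(trials))
  subj <- unique(trials$subject_id)
  svotes <- lapply(subj, function(s) {
    rows <- trials[trials$subject_id == s, , drop = FALSE]
    post <- if (length(post_cols) == 3) rows[, post_cols, drop = FALSE] else NULL
    data.frame(subject_id = s, group = rows$group[1],
               label = majority_vote(rows$label, post),
               stringsAsFactors = FALSE)
  })
  svotes <- do.call(rbind, svotes)
  cm_trial <- confusion_matrix3(trials$group, trials$label, "trial")
  cm_subj <- confusion_matrix3(svotes$group, svotes$label, "subject")
  structure(list(
    subjects = svotes,
    cm_trial = cm_trial, cm_subject = cm_subj,
    kappa_trial = cohens_kappa(cm_trial), kappa_subject = cohens_kappa(cm_subj),
    accuracy_trial = overall_accuracy(cm_trial),
    accuracy_subject = overall_accuracy(cm_subj),
    hc_vs_all = one_vs_all_metrics(cm_subj, "HC_vs_all"),
    ad_vs_all = one_vs_all_metrics(cm_subj, "AD_vs_all")),
    class = "eeg_evaluation")
}

#' @export
print.eeg_evaluation <- function(x, ...) {
  cat("<eeg_evaluation>\n")
  cat(sprintf("  subject accuracy %.2f%%, kappa %.4f\n",
              x$accuracy_subject, x$kappa_subject$kappa))
  cat("  subject confusion matrix (actual x predicted):\n")
  print(unclass(x$cm_subject))
  for (blk in list(x$hc_vs_all, x$ad_vs_all))
    cat(sprintf("  %s: Se %.2f Sp %.2f Acc %.2f PPV %.2f NPV %.2f\n",
                blk$comparison, blk$se, blk$sp, blk$acc, blk$ppv, blk$npv))
  invisible(x)
}
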