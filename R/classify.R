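#' Per-feature standardization statistics
#'
#' @param x Numeric matrix or data frame of training features.
#' @return List with `mean` and `sd` vectors (class `"standardization_stats"`).
#' @export
standardization_stats <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  if (any(s <= 0)) stopf("zero-SD feature(s): %s",
                         paste(colnames(x)[s <= 0], collapse = ", "))
  structure(list(mean = mu, sd = s), class = "standardization_stats")
}

#' Standardize features with stored training statistics
#'
#' @param x Matrix/data frame of features.
#' @param stats A `standardization_stats` (from the training split).
#' @param invert Undo the transform instead.
#' @return Matrix of (de)standardized features.
#' @export
standardize <- function(x, stats, invert = FALSE) {
  x <- as.matrix(x)
  if (!is.null(names(stats$mean)) && !is.null(colnames(x)))
    x <- x[, names(stats$mean), drop = FALSE]
  if (ncol(x) != length(stats$mean)) stopf("feature-set mismatch")
  if (invert) sweep(sweep(x, 2, stats$sd, "*"), 2, stats$mean, "+")
  else sweep(sweep(x, 2, stats$mean, "-"), 2, stats$sd, "/")
}

ridge_if_needed <- function(S) {
  p <- ncol(S)
  if (rcond(S) < 1e-10) S <- S + diag(1e-6 * sum(diag(S)) / p, p)
  if (rcond(S) < 1e-12) stopf("covariance matrix singular even after ridge")
  S
}

new_da_model <- function(kind, means, covs, priors, stats) {
  structure(list(kind = kind, means = means, covs = covs, priors = priors,
                 standardization = stats, classes = eeg_groups()),
            class = "eeg_model")
}

check_xy <- function(x, y) {
  y <- factor(as.character(y), levels = eeg_groups())
  y <- droplevels(y)
  if (nlevels(y) < 2) stopf("need at least two classes to train")
  if (any(table(y) < 2)) stopf("need >= 2 trials per class")
  list(x = as.matrix(x), y = y)
}

#' Train a linear discriminant model
#'
#' Gaussian class-conditional model with a pooled covariance matrix
#' (homoscedastic) and empirical class priors; a small ridge is added if
#' the pooled covariance is near-singular. Prediction assigns the class
#' with the largest posterior probability.
#'
#' @param x Feature matrix (rows = trials); standardize beforehand.
#' @param y Class labels.
#' @param priors Optional named prior vector (default empirical).
#' @return An `"eeg_model"` of kind `"LDA"`.
#' @export
train_lda <- function(x, y, priors = NULL) {
  d <- check_xy(x, y)
  cls <- levels(d$y)
  means <- do.call(rbind, lapply(cls, function(c)
    colMeans(d$x[d$y == c, , drop = FALSE])))
  rownames(means) <- cls
  centered <- d$x - means[as.integer(d$y), , drop = FALSE]
  pooled <- crossprod(centered) / (nrow(d$x) - length(cls))
  pooled <- ridge_if_needed(pooled)
  pr <- priors %||% as.numeric(table(d$y) / length(d$y))
  m <- new_da_model("LDA", means, pooled, stats::setNames(pr, cls), NULL)
  m$classes <- cls
  m
}

#' Train a quadratic discriminant model
#'
#' As [train_lda()] but with one covariance matrix per class, yielding
#' quadratic decision boundaries.
#'
#' @inheritParams train_lda
#' @return An `"eeg_model"` of kind `"QDA"`.
#' @export
train_qda <- function(x, y, priors = NULL) {
  d <- check_xy(x, y)
  cls <- levels(d$y)
  means <- do.call(rbind, lapply(cls, function(c)
    colMeans(d$x[d$y == c, , drop = FALSE])))
  rownames(means) <- cls
  covs <- lapply(cls, function(c) {
    xc <- d$x[d$y == c, , drop = FALSE]
    ridge_if_needed(stats::cov(xc))
  })
  names(covs) <- cls
  pr <- priors %||% as.numeric(table(d$y) / length(d$y))
  m <- new_da_model("QDA", means, covs, stats::setNames(pr, cls), NULL)
  m$classes <- cls
  m
}

da_log_posterior <- function(model, x) {
  cls <- model$classes
  x <- as.matrix(x)
  lp <- matrix(0, nrow(x), length(cls), dimnames = list(NULL, cls))
  for (i in seq_along(cls)) {
    S <- if (model$kind == "LDA") model$covs else model$covs[[cls[i]]]
    ch <- chol(S)
    z <- backsolve(ch, t(x) - model$means[i, ], transpose = TRUE)
    maha <- colSums(z^2)
    lp[, i] <- log(model$priors[i]) - 0.5 * maha - sum(log(diag(ch)))
  }
  lp
}

#' MLP training configuration
#'
#' @param n_hidden Hidden units (>= 1).
#' @param weight_decay Quadratic penalty coefficient on the weights
#'   (biases unpenalized), >= 0.
#' @param n_restarts Random initializations for tuning (default 30).
#' @param max_iterations BFGS iteration cap per fit.
#' @param rng_seed Seed controlling weight initialization.
#' @return An object of class `"mlp_config"`.
#' @export
mlp_config <- function(n_hidden = 11, weight_decay = 45, n_restarts = 30,
                       max_iterations = 300, rng_seed = 1) {
  if (!is_count(n_hidden)) stopf("n_hidden must be >= 1")
  if (weight_decay < 0) stopf("weight_decay must be >= 0")
  if (!is_count(n_restarts)) stopf("n_restarts must be >= 1")
  structure(list(n_hidden = as.integer(n_hidden), weight_decay = weight_decay,
                 n_restarts = as.integer(n_restarts),
                 max_iterations = as.integer(max_iterations),
                 rng_seed = as.integer(rng_seed)),
            class = "mlp_config")
}

#' Train a single-hidden-layer MLP classifier
#'
#' Logistic hidden units, a 3-unit softmax output layer and a
#' cross-entropy error with quadratic weight decay, optimized by BFGS on an
#' analytic gradient. Deterministic given `config$rng_seed`.
#'
#' @param x Standardized feature matrix.
#' @param y Class labels.
#' @param config An [mlp_config()].
#' @return An `"eeg_model"` of kind `"MLP"` holding the weight matrices.
#' @export
train_mlp <- function(x, y, config = mlp_config()) {
  d <- check_xy(x, y)
  cls <- levels(d$y)
  K <- length(cls)
  p <- ncol(d$x)
  h <- config$n_hidden
  Y <- diag(K)[as.integer(d$y), , drop = FALSE]
  npar <- p * h + h + h * K + K
  theta0 <- withr::with_seed(config$rng_seed,
                             rnorm(npar, 0, 1 / sqrt(max(p, 1))))
  fit <- optim(theta0, fn = cpp_mlp_obj, gr = cpp_mlp_grad,
               X = d$x, Y = Y, h = h, decay = config$weight_decay,
               method = "BFGS",
               control = list(maxit = config$max_iterations, reltol = 1e-10))
  if (fit$convergence != 0) {
    gn <- sqrt(sum(cpp_mlp_grad(fit$par, d$x, Y, h, config$weight_decay)^2))
    warning(sprintf("MLP optimizer did not converge (code %d, |grad| = %.3g)",
                    fit$convergence, gn))
  }
  th <- fit$par
  off <- 0
  W1 <- matrix(th[off + seq_len(p * h)], p, h); off <- off + p * h
  b1 <- th[off + seq_len(h)]; off <- off + h
  W2 <- matrix(th[off + seq_len(h * K)], h, K); off <- off + h * K
  b2 <- th[off + seq_len(K)]
  structure(list(kind = "MLP", W1 = W1, b1 = b1, W2 = W2, b2 = b2,
                 config = config, standardization = NULL, classes = cls,
                 value = fit$value, convergence = fit$convergence),
            class = "eeg_model")
}

#' Predict trial labels and class posteriors
#'
#' Gaussian posteriors for LDA/QDA, softmax outputs for the MLP. The label
#' is the posterior argmax; exact ties resolve to the earlier class in
#' canonical (HC, MCI, AD) order.
#'
#' @param model An `"eeg_model"`.
#' @param x Feature matrix on the same scale the model was trained on.
#' @return `data.frame` with `label` and one posterior column per class.
#' @export
predict_trials <- function(model, x) {
  x <- as.matrix(x)
  if (model$kind %in% c("LDA", "QDA")) {
    if (ncol(x) != ncol(model$means)) stopf("feature-set mismatch")
    lp <- da_log_posterior(model, x)
    lp <- lp - apply(lp, 1, max)
    post <- exp(lp) / rowSums(exp(lp))
  } else {
    if (ncol(x) != nrow(model$W1)) stopf("feature-set mismatch")
    post <- cpp_mlp_forward(x, model$W1, model$b1, model$W2, model$b2)
    colnames(post) <- model$classes
  }
  lab <- model$classes[apply(post, 1, which.max)]
  out <- data.frame(label = factor(lab, levels = eeg_groups()), post,
                    check.names = FALSE)
  rownames(out) <- NULL
  out
}

#' Tune MLP hyperparameters by leave-one-subject-out cross-validation
#'
#' For each `(weight_decay, n_hidden)` grid point, every training subject is
#' held out in turn (all of its trials), an MLP is fitted on the remaining
#' subjects' trials, and the pooled held-out trial predictions are scored
#' with Cohen's kappa. The score is averaged over `n_restarts` random
#' initializations; the argmax grid point wins, ties resolving to fewer
#' hidden units and then smaller decay. The reference full-grid optimum
#' (decay 45, 11 hidden units) is the default of [mlp_config()].
#'
#' @param table Training feature table with `subject_id` and `group`.
#' @param features Feature columns to use.
#' @param decay_grid,hidden_grid Grids for the penalty and hidden units.
#' @param n_restarts Random restarts averaged per grid point.
#' @param max_iterations BFGS cap per fit.
#' @param rng_seed Root seed for the restart streams.
#' @return The winning `mlp_config`; the full score table is attached as
#'   attribute `"search"`.
#' @export
tune_mlp <- function(table, features, decay_grid = seq(0, 100, by = 5),
                     hidden_grid = 1:20, n_restarts = 30,
                     max_iterations = 300, rng_seed = 1) {
  if (!length(decay_grid) || !length(hidden_grid)) stopf("empty tuning grid")
  subjects <- unique(table$subject_id)
  x_all <- as.matrix(table[, features, drop = FALSE])
  grid <- expand.grid(weight_decay = decay_grid, n_hidden = hidden_grid)
  seeds <- derive_seeds(rng_seed, n_restarts)
  scores <- numeric(nrow(grid))
  folds <- lapply(subjects, function(s) table$subject_id == s)
  for (gi in seq_len(nrow(grid))) {
    ks <- numeric(n_restarts)
    for (ri in seq_len(n_restarts)) {
      pred <- factor(rep(NA_character_, nrow(table)), levels = eeg_groups())
      for (f in folds) {
        st <- standardization_stats(x_all[!f, , drop = FALSE])
        xtr <- standardize(x_all[!f, , drop = FALSE], st)
        xte <- standardize(x_all[f, , drop = FALSE], st)
        # tuning fits are throwaway: silence max-iteration warnings
        m <- suppressWarnings(
          train_mlp(xtr, table$group[!f],
                    mlp_config(grid$n_hidden[gi], grid$weight_decay[gi],
                               n_restarts = 1,
                               max_iterations = max_iterations,
                               rng_seed = seeds[ri])))
        pred[f] <- predict_trials(m, xte)$label
      }
      ks[ri] <- cohens_kappa(confusion_matrix3(table$group, pred, "trial"))$kappa
    }
    scores[gi] <- mean(ks)
  }
  best <- order(-scores, grid$n_hidden, grid$weight_decay)[1]
  out <- mlp_config(grid$n_hidden[best], grid$weight_decay[best],
                    n_restarts = n_restarts, max_iterations = max_iterations,
                    rng_seed = rng_seed)
  attr(out, "search") <- cbind(grid, kappa = scores)
  out
}
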