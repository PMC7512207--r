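blob_data <- function(n = 60, sep = 6, seed = 1, p = 3) {
  withr::with_seed(seed, {
    y <- factor(rep(eeg_groups(), each = n), levels = eeg_groups())
    centers <- matrix(c(0, sep, 0, 0, 0, sep, rep(0, 3 * (p - 2))), 3, p)
    x <- centers[as.integer(y), ] + matrix(rnorm(3 * n * p), 3 * n, p)
    list(x = x, y = y)
  })
}

xor_data <- function(n = 40, seed = 2) {
  withr::with_seed(seed, {
    y <- factor(rep(eeg_groups(), each = 2 * n), levels = eeg_groups())
    cx <- rbind(c(2, 2), c(-2, -2),    # HC: opposite corners
                c(2, -2), c(-2, 2),    # MCI: the other diagonal
                c(0, 0), c(0, 0))      # AD: centre
    idx <- rep(1:6, each = n)
    x <- cx[idx, ] + matrix(rnorm(6 * n * 2, 0, 0.4), 6 * n, 2)
    list(x = x, y = y)
  })
}

test_that("standardization round-trips and uses training statistics", {
  d <- blob_data()
  st <- standardization_stats(d$x)
  z <- standardize(d$x, st)
  expect_lt(max(abs(colMeans(z))), 1e-9)
  expect_lt(max(abs(apply(z, 2, sd) - 1)), 1e-9)
  back <- standardize(z, st, invert = TRUE)
  expect_equal(back, unname(d$x), ignore_attr = TRUE, tolerance = 1e-9)
  zz <- standardize(z, st)
  expect_false(isTRUE(all.equal(zz, z)))
  expect_error(standardization_stats(cbind(d$x, const = 1)), "zero-SD")
})

test_that("LDA separates well-separated blobs and matches MASS", {
  d <- blob_data(sep = 8)
  m <- train_lda(d$x, d$y)
  pred <- predict_trials(m, d$x)
  expect_gte(mean(pred$label == d$y), 0.95)
  expect_lt(max(abs(rowSums(pred[, eeg_groups()]) - 1)), 1e-9)
  # probe at a fitted class mean, far from the others
  probe <- m$means["AD", , drop = FALSE]
  expect_equal(as.character(predict_trials(m, probe)$label), "AD")
  skip_if_not_installed("MASS")
  d2 <- blob_data(sep = 2.5, seed = 4)
  ours <- predict_trials(train_lda(d2$x, d2$y), d2$x)
  ref <- predict(MASS::lda(d2$x, d2$y), d2$x)
  expect_gte(mean(as.character(ours$label) == as.character(ref$class)), 0.99)
  expect_lt(max(abs(as.matrix(ours[, eeg_groups()]) -
                    ref$posterior[, eeg_groups()])), 1e-6)
})

test_that("QDA exploits unequal covariances and degenerates to LDA", {
  withr::with_seed(5, {
    n <- 150
    y <- factor(rep(eeg_groups(), each = n), levels = eeg_groups())
    x <- rbind(matrix(rnorm(n * 2, 0, 0.5), n, 2),
               matrix(rnorm(n * 2, 0, 2.0), n, 2),
               matrix(rnorm(n * 2, 0, 6.0), n, 2))  # equal means, coded variance
  })
  accq <- mean(predict_trials(train_qda(x, y), x)$label == y)
  accl <- mean(predict_trials(train_lda(x, y), x)$label == y)
  expect_gt(accq, accl)
  skip_if_not_installed("MASS")
  ref <- predict(MASS::qda(x, y), x)
  expect_gte(mean(as.character(predict_trials(train_qda(x, y), x)$label) ==
                  as.character(ref$class)), 0.99)
  # identical per-class sample covariances: QDA and LDA agree on probes
  base <- withr::with_seed(6, matrix(rnorm(80 * 2), 80, 2))
  xs <- rbind(base, sweep(base, 2, c(4, 0), "+"), sweep(base, 2, c(0, 4), "+"))
  ys <- factor(rep(eeg_groups(), each = 80), levels = eeg_groups())
  grid <- as.matrix(expand.grid(seq(-2, 6, 1), seq(-2, 6, 1)))
  expect_equal(predict_trials(train_qda(xs, ys), grid)$label,
               predict_trials(train_lda(xs, ys), grid)$label)
  expect_error(train_qda(base, factor(rep("AD", 80), levels = eeg_groups())),
               "two classes")
})

test_that("the MLP solves an XOR arrangement that defeats LDA", {
  d <- xor_data()
  m <- train_mlp(d$x, d$y, mlp_config(n_hidden = 8, weight_decay = 0.01,
                                      rng_seed = 3))
  pm <- predict_trials(m, d$x)
  expect_gte(mean(pm$label == d$y), 0.95)
  expect_lte(mean(predict_trials(train_lda(d$x, d$y), d$x)$label == d$y), 0.80)
  expect_lt(max(abs(rowSums(pm[, eeg_groups()]) - 1)), 1e-9)
})

test_that("MLP training is seed-deterministic and decay shrinks to priors", {
  d <- blob_data(n = 30, sep = 3)
  cfg <- mlp_config(n_hidden = 4, weight_decay = 1, rng_seed = 11)
  m1 <- train_mlp(d$x, d$y, cfg)
  m2 <- train_mlp(d$x, d$y, cfg)
  expect_identical(m1$W1, m2$W1)
  m3 <- train_mlp(d$x, d$y, mlp_config(4, 1, rng_seed = 12))
  expect_false(identical(m1$W1, m3$W1))
  mbig <- train_mlp(d$x, d$y, mlp_config(4, 1e6, rng_seed = 11))
  post <- as.matrix(predict_trials(mbig, d$x)[, eeg_groups()])
  expect_lt(max(post) - min(post), 0.05)  # near-constant posteriors
})

test_that("models are equivariant under class relabeling", {
  d <- blob_data(n = 40, sep = 3, seed = 7)
  swap <- c(HC = "AD", MCI = "MCI", AD = "HC")
  ys <- factor(unname(swap[as.character(d$y)]), levels = eeg_groups())
  for (fit in list(train_lda, train_qda)) {
    p1 <- as.character(predict_trials(fit(d$x, d$y), d$x)$label)
    p2 <- as.character(predict_trials(fit(d$x, ys), d$x)$label)
    expect_identical(unname(swap[p1]), p2)
  }
  p1 <- as.character(predict_trials(
    train_mlp(d$x, d$y, mlp_config(4, 1, rng_seed = 2)), d$x)$label)
  p2 <- as.character(predict_trials(
    train_mlp(d$x, ys, mlp_config(4, 1, rng_seed = 2)), d$x)$label)
  expect_gte(mean(swap[p1] == p2), 0.95)  # numerical optimum may differ slightly
})

test_that("prediction is order invariant and checks feature dimension", {
  d <- blob_data(n = 20)
  m <- train_lda(d$x, d$y)
  perm <- withr::with_seed(3, sample(nrow(d$x)))
  expect_equal(predict_trials(m, d$x[perm, ])$label,
               predict_trials(m, d$x)$label[perm])
  expect_error(predict_trials(m, d$x[, 1:2]), "mismatch")
})

test_that("tune_mlp returns the single grid point and demands capacity", {
  d <- xor_data(n = 8)
  tab <- data.frame(subject_id = rep(sprintf("s%d", 1:8), each = 6),
                    group = d$y, d$x, check.names = FALSE)
  names(tab)[3:4] <- c("f1", "f2")
  cfg1 <- tune_mlp(tab, c("f1", "f2"), decay_grid = 5, hidden_grid = 7,
                   n_restarts = 1, max_iterations = 100, rng_seed = 1)
  expect_equal(cfg1$n_hidden, 7L)
  expect_equal(cfg1$weight_decay, 5)
  cfg2 <- tune_mlp(tab, c("f1", "f2"), decay_grid = 0.01, hidden_grid = c(1, 8),
                   n_restarts = 2, max_iterations = 150, rng_seed = 1)
  expect_gte(cfg2$n_hidden, 2L)  # XOR geometry needs more than one hidden unit
  expect_error(tune_mlp(tab, c("f1", "f2"), decay_grid = numeric(0),
                        hidden_grid = 1), "empty")
})
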