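#' Nonlinear feature parameters
#'
#' Defaults are the reported optima of the training-set Kruskal-Wallis grid
#' search: CTM radius 0.075 (on z-scored epochs), SampEn m = 1 and
#' r = 0.1 x SD, FuzzyEn m = 1, r = 0.1 x SD, n = 3. AMI uses lags up to
#' 0.5 s with a 16-bin equal-width histogram; its scalar summary is the
#' mean of the normalized profile over positive lags (`"slope"` fits a
#' least-squares line in s^-1 instead).
#'
#' @param ctm_rho CTM radius (first-difference amplitude units).
#' @param ctm_normalize Compute CTM on the z-scored epoch (default `TRUE`),
#'   making one radius comparable across subjects.
#' @param sampen_m,sampen_r SampEn embedding length and tolerance as a
#'   multiple of the epoch SD.
#' @param fuzzyen_m,fuzzyen_r,fuzzyen_n FuzzyEn length, exponential-boundary
#'   width (multiple of SD) and gradient.
#' @param ami_max_lag_s Maximum AMI lag in seconds.
#' @param ami_bins Histogram bins per axis.
#' @param ami_summary `"mean"` or `"slope"`.
#' @return An object of class `"nonlinear_params"`.
#' @export
nonlinear_params <- function(ctm_rho = 0.075, ctm_normalize = TRUE,
                             sampen_m = 1, sampen_r = 0.1,
                             fuzzyen_m = 1, fuzzyen_r = 0.1, fuzzyen_n = 3,
                             ami_max_lag_s = 0.5, ami_bins = 16,
                             ami_summary = c("mean", "slope")) {
  ami_summary <- match.arg(ami_summary)
  if (ctm_rho <= 0) stopf("ctm_rho must be > 0")
  if (!is_count(sampen_m)) stopf("sampen_m must be a positive integer")
  if (sampen_r <= 0) stopf("sampen_r must be > 0")
  if (!is_count(fuzzyen_m) || fuzzyen_n < 1) stopf("invalid FuzzyEn parameters")
  if (fuzzyen_r <= 0) stopf("fuzzyen_r must be > 0")
  if (ami_bins < 2) stopf("ami_bins must be >= 2")
  structure(list(ctm_rho = ctm_rho, ctm_normalize = ctm_normalize,
                 sampen_m = as.integer(sampen_m), sampen_r = sampen_r,
                 fuzzyen_m = as.integer(fuzzyen_m), fuzzyen_r = fuzzyen_r,
                 fuzzyen_n = fuzzyen_n, ami_max_lag_s = ami_max_lag_s,
                 ami_bins = as.integer(ami_bins), ami_summary = ami_summary),
            class = "nonlinear_params")
}

#' Lempel-Ziv complexity
#'
#' Binarizes the series at its median (values `>= median` map to 1), counts
#' new subsequences in a left-to-right scan and normalizes the count by
#' `N / log2(N)`.
#'
#' @param x 1-D numeric series, length >= 4, not constant.
#' @return Normalized complexity (about 1 for random binary sequences).
#' @export
lempel_ziv_complexity <- function(x) {
  if (length(x) < 4) stopf("series too short for LZC (need N >= 4)")
  if (max(x) == min(x)) stopf("degenerate input: constant series has no median split")
  cpp_lzc(as.numeric(x))
}

#' Lempel-Ziv subsequence count of a symbol sequence
#'
#' The raw complexity counter `c(N)` (number of new subsequences in the
#' left-to-right scan, trailing incomplete word included) on an already
#' binarized sequence; [lempel_ziv_complexity()] equals
#' `c(N) / (N / log2(N))` after median binarization.
#'
#' @param bits Integer vector of symbols (0/1).
#' @return Integer count.
#' @export
lz_subsequence_count <- function(bits) {
  if (length(bits) < 2) stopf("sequence too short")
  cpp_lzc_count(as.integer(bits))
}

#' Central tendency measure
#'
#' Fraction of the `N - 2` first-difference scatter points
#' (`x(n+2)-x(n+1)` vs `x(n+1)-x(n)`) falling strictly inside radius `rho`.
#' Higher values mean lower variability.
#'
#' @param x 1-D numeric series, length >= 3.
#' @param rho Radius, > 0, in the series' amplitude units.
#' @return Fraction in `[0, 1]`.
#' @export
central_tendency_measure <- function(x, rho) {
  if (length(x) < 3) stopf("series too short for CTM (need N >= 3)")
  if (rho <= 0) stopf("rho must be > 0")
  cpp_ctm(as.numeric(x), rho)
}

#' Sample entropy
#'
#' Negative natural log of the conditional probability that templates
#' matching for `m` points (Chebyshev distance strictly below `r_abs`,
#' self-matches excluded) still match at length `m + 1`.
#'
#' @param x 1-D numeric series, length > m + 1.
#' @param m Embedding length.
#' @param r_abs Absolute tolerance (already scaled by the series SD upstream
#'   if desired).
#' @return Entropy in nats; `NA` with a warning when no template matches
#'   exist at either length (undefined entropy).
#' @export
sample_entropy <- function(x, m = 1, r_abs = 0.1 * sd(x)) {
  if (length(x) <= m + 1) stopf("series too short for SampEn (need N > m + 1)")
  if (r_abs <= 0) stopf("r_abs must be > 0")
  out <- cpp_sampen(as.numeric(x), as.integer(m), r_abs)
  if (is.na(out)) warning("SampEn undefined: no template matches at length m or m+1")
  out
}

#' Fuzzy entropy
#'
#' Like sample entropy but with mean-centred templates and a soft
#' exponential similarity `exp(-d^n / r)` in place of the hard threshold,
#' so it is defined for every non-degenerate series.
#'
#' @param x 1-D numeric series, length > m + 1.
#' @param m Embedding length.
#' @param r_abs Width of the exponential boundary (absolute units).
#' @param n Gradient of the exponential boundary.
#' @return Entropy in nats.
#' @export
fuzzy_entropy <- function(x, m = 1, r_abs = 0.1 * sd(x), n = 3) {
  if (length(x) <= m + 1) stopf("series too short for FuzzyEn (need N > m + 1)")
  if (r_abs <= 0 || n < 1) stopf("invalid FuzzyEn parameters")
  cpp_fuzzyen(as.numeric(x), as.integer(m), r_abs, n)
}

#' Auto-mutual information profile
#'
#' Mutual information (base-2) between the series and its lagged copy for
#' lags 0 .. `max_lag_s * fs`, estimated with an equal-width 2-D histogram,
#' then normalized so the zero-lag value is 1.
#'
#' @param x 1-D numeric series.
#' @param fs Sampling rate (Hz).
#' @param max_lag_s Maximum lag in seconds; `max_lag_s * fs` must be an
#'   integer below `length(x)`.
#' @param bins Histogram bins per axis (>= 2).
#' @param summary `"mean"` (mean normalized AMI over lags >= 1) or
#'   `"slope"` (regression slope of the normalized profile vs lag, s^-1).
#' @return List with `lags` (samples), `profile` (normalized, profile\[1\]
#'   is lag 0 and equals 1) and `summary` (scalar).
#' @export
auto_mutual_information <- function(x, fs, max_lag_s = 0.5, bins = 16,
                                    summary = c("mean", "slope")) {
  summary <- match.arg(summary)
  max_lag <- max_lag_s * fs
  if (abs(max_lag - round(max_lag)) > 1e-9)
    stopf("max_lag_s * fs must be an integer number of lags")
  max_lag <- as.integer(round(max_lag))
  if (length(x) <= max_lag) stopf("series shorter than the maximum lag")
  if (bins < 2) stopf("bins must be >= 2")
  prof <- cpp_ami_profile(as.numeric(x), max_lag, as.integer(bins))
  if (is.na(prof[1]) || prof[1] <= 0)
    stopf("degenerate input: AMI(0) is zero, normalization impossible")
  nprof <- prof / prof[1]
  s <- if (summary == "mean") {
    mean(nprof[-1])
  } else {
    t <- (0:max_lag) / fs
    stats::coef(stats::lm.fit(cbind(1, t), nprof))[2]
  }
  list(lags = 0:max_lag, profile = nprof, summary = unname(s))
}

#' All five nonlinear features of one epoch, per channel
#'
#' @param epoch `channels x samples` matrix (or 1-D series).
#' @param fs Sampling rate (Hz).
#' @param params A `nonlinear_params` object.
#' @return `5 x channels` matrix (rows LZC, CTM, SampEn, FuzzyEn, AMI);
#'   undefined SampEn entries are `NA`.
#' @export
nonlinear_features <- function(epoch, fs, params = nonlinear_params()) {
  if (is.vector(epoch)) epoch <- matrix(epoch, nrow = 1)
  max_lag <- as.integer(round(params$ami_max_lag_s * fs))
  cpp_nonlinear_channels(t(epoch), params$ctm_rho, params$ctm_normalize,
                         params$sampen_m, params$sampen_r,
                         params$fuzzyen_m, params$fuzzyen_r, params$fuzzyen_n,
                         max_lag, params$ami_bins,
                         if (params$ami_summary == "mean") 0L else 1L, 1 / fs)
}

#' Select nonlinear feature parameters by Kruskal-Wallis grid search
#'
#' For each tunable feature, computes the channel-averaged trial values over
#' the training cohort at every grid point and keeps the grid point whose
#' three-group Kruskal-Wallis p-value is smallest. Ties (including an
#' uninformative null) are broken lexicographically toward smaller
#' parameter values, so the result is always unique and deterministic.
#'
#' @param cohort Training recordings (list of `epoched_recording`s).
#' @param ctm_rho_grid Candidate CTM radii (default the reported
#'   0.01--0.5 step 0.005 grid).
#' @param sampen_grid Data frame with columns `m`, `r` (r as SD multiples).
#' @param fuzzyen_grid Data frame with columns `m`, `r`, `n`.
#' @param base_params Non-tuned parameters (AMI settings etc.).
#' @return A `nonlinear_params` with the selected values; the per-grid-point
#'   p-value tables are attached as attribute `"search"`.
#' @export
select_nonlinear_params <- function(cohort,
                                    ctm_rho_grid = seq(0.01, 0.5, by = 0.005),
                                    sampen_grid = expand.grid(m = 1:2, r = seq(0.1, 0.25, by = 0.05)),
                                    fuzzyen_grid = expand.grid(m = 1:2, r = seq(0.1, 0.25, by = 0.05), n = 1:3),
                                    base_params = nonlinear_params()) {
  groups <- vapply(cohort, `[[`, "", "group")
  if (length(unique(groups)) < 3) stopf("all three groups must be present")
  fs <- cohort[[1]]$fs

  trial_values <- function(fun) {
    vals <- list(); glab <- list()
    for (rec in cohort) {
      nt <- dim(rec$data)[1]
      v <- vapply(seq_len(nt), function(t) fun(rec$data[t, , , drop = FALSE][1, , ]), 0)
      vals[[length(vals) + 1L]] <- v
      glab[[length(glab) + 1L]] <- rep(rec$group, nt)
    }
    list(v = unlist(vals), g = factor(unlist(glab), levels = eeg_groups()))
  }
  kw_p <- function(tv) kruskal.test(tv$v, tv$g)$p.value

  chan_apply <- function(epoch, f) {
    if (is.vector(epoch)) epoch <- matrix(epoch, nrow = 1)
    mean(apply(epoch, 1, f), na.rm = TRUE)
  }

  # CTM over rho grid (z-scored epochs when base_params says so)
  ctm_p <- vapply(ctm_rho_grid, function(rho) {
    kw_p(trial_values(function(ep) chan_apply(ep, function(x) {
      if (base_params$ctm_normalize) x <- (x - mean(x)) / sd(x)
      cpp_ctm(x, rho)
    })))
  }, 0)
  ctm_best <- ctm_rho_grid[order(ctm_p, ctm_rho_grid)[1]]

  se_p <- vapply(seq_len(nrow(sampen_grid)), function(i) {
    m <- sampen_grid$m[i]; r <- sampen_grid$r[i]
    kw_p(trial_values(function(ep) chan_apply(ep, function(x)
      cpp_sampen(x, as.integer(m), r * sd(x)))))
  }, 0)
  se_ord <- order(se_p, sampen_grid$m, sampen_grid$r)
  se_best <- sampen_grid[se_ord[1], ]

  fe_p <- vapply(seq_len(nrow(fuzzyen_grid)), function(i) {
    m <- fuzzyen_grid$m[i]; r <- fuzzyen_grid$r[i]; n <- fuzzyen_grid$n[i]
    kw_p(trial_values(function(ep) chan_apply(ep, function(x)
      cpp_fuzzyen(x, as.integer(m), r * sd(x), n))))
  }, 0)
  fe_ord <- order(fe_p, fuzzyen_grid$m, fuzzyen_grid$r, fuzzyen_grid$n)
  fe_best <- fuzzyen_grid[fe_ord[1], ]

  out <- nonlinear_params(ctm_rho = ctm_best,
                          ctm_normalize = base_params$ctm_normalize,
                          sampen_m = se_best$m, sampen_r = se_best$r,
                          fuzzyen_m = fe_best$m, fuzzyen_r = fe_best$r,
                          fuzzyen_n = fe_best$n,
                          ami_max_lag_s = base_params$ami_max_lag_s,
                          ami_bins = base_params$ami_bins,
                          ami_summary = base_params$ami_summary)
  attr(out, "search") <- list(
    ctm = data.frame(rho = ctm_rho_grid, p = ctm_p),
    sampen = cbind(sampen_grid, p = se_p),
    fuzzyen = cbind(fuzzyen_grid, p = fe_p))
  out
}
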