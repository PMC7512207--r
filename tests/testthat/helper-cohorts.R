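# Shared synthetic-cohort constructions for tests. Sizes are scaled down
# (fewer channels/trials than the 19-channel, 46-trial default) purely for
# run time; group-profile structure is what each test states.

quick_config <- function(n_subjects = 4, trials = 4, channels = 2, seed = 1,
                         profiles = eegdx::default_profiles(), ...) {
  eegdx::cohort_config(n_subjects_per_group = n_subjects,
                       trials_per_subject_mean = trials,
                       trials_per_subject_sd = 0, n_channels = channels,
                       rng_seed = seed, profiles = profiles, ...)
}

# Cohort whose group signal lives only in the alpha-peak frequency, the
# delta band weight and the noise fraction; all other structure is shared.
planted_profiles <- function(peaks = c(HC = 11.0, MCI = 9.7, AD = 8.4),
                             deltas = c(HC = 0.40, MCI = 0.22, AD = 0.06),
                             nfs = c(HC = 0.85, MCI = 0.55, AD = 0.25)) {
  bands <- names(eegdx::eeg_bands())
  rest <- c(theta = 0.08, alpha = 0.55, beta1 = 0.15, beta2 = 0.12, gamma = 0.10)
  out <- lapply(eegdx::eeg_groups(), function(g) {
    w <- c(delta = deltas[[g]], rest / sum(rest) * (1 - deltas[[g]]))
    eegdx::group_profile(g, peaks[[g]], w[bands], nfs[[g]],
                         alpha_bandwidth_hz = 1.2)
  })
  names(out) <- eegdx::eeg_groups()
  out
}

# Single-oscillator profile: a pure alpha tone at `peak` Hz, no noise.
tone_profile <- function(peak = 10, group = "HC", bw = 0.2) {
  bands <- names(eegdx::eeg_bands())
  w <- stats::setNames(c(0, 0, 1, 0, 0, 0), bands)
  eegdx::group_profile(group, peak, w, noise_fraction = 0,
                       alpha_bandwidth_hz = bw)
}

# Small feature table with known structure for selection/classification
# tests: three informative independent features plus pure-noise columns,
# padded to the 14 standard names.
toy_feature_table <- function(n_per_class = 60, seed = 1, sd_noise = 0.6) {
  withr::with_seed(seed, {
    y <- factor(rep(eegdx::eeg_groups(), each = n_per_class),
                levels = eegdx::eeg_groups())
    shift <- as.integer(y) - 2L
    n <- length(y)
    tab <- data.frame(subject_id = paste0("s", seq_len(n)), group = y,
                      trial = 1L)
    for (f in eegdx::feature_names()) tab[[f]] <- rnorm(n, 0, 1)
    tab$IAF <- 9.5 - 0.6 * shift + rnorm(n, 0, sd_noise)
    tab$RP_delta <- 0.2 + 0.05 * shift + rnorm(n, 0, sd_noise * 0.05)
    tab$SampEn <- 1.4 - 0.1 * shift + rnorm(n, 0, sd_noise * 0.1)
    tab
  })
}
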