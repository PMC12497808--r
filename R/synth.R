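#' Configuration for the synthetic motor-imagery EEG generator
#'
#' The generator emulates the class-conditional signature that motor-imagery
#' decoders exploit: event-related desynchronization (ERD), i.e. attenuation
#' of the ongoing mu-band (~10 Hz) rhythm over sensorimotor channels during
#' imagery. Each trial is 1/f-shaped background noise on every channel, plus
#' a random-phase mu-band sinusoid on the designated ERD channels; for trials
#' of class `k`, the sinusoid amplitude on `erd_channels[[k + 1]]` is
#' multiplied by `1 - erd_depth` inside `erd_window`.
#'
#' Defaults describe a small but realistic two-class scenario: 4-s trials at
#' 250 Hz, mu rhythm at 10 Hz with amplitude twice the background noise SD,
#' ERD over 1-3 s after cue (the canonical imagery window), 80% attenuation,
#' one ERD channel per class.
#'
#' @param n_trials_per_class trials generated per class.
#' @param n_channels,n_samples,fs recording geometry (channels, samples per
#'   trial, sampling rate in Hz).
#' @param n_classes number of classes K.
#' @param erd_channels list of length K; element k holds the 1-based channel
#'   indices whose mu rhythm is attenuated for class `k - 1`.
#' @param erd_depth fractional amplitude attenuation in `[0, 1]`.
#' @param mu_freq mu-rhythm frequency in Hz.
#' @param mu_amp mu-rhythm amplitude (same units as `noise_sd`).
#' @param erd_window integer range of 1-based samples forming the attenuation
#'   window.
#' @param noise_sd standard deviation of the 1/f background noise.
#' @param seed RNG seed; generation is fully deterministic given the config.
#' @return a validated `synth_config` list.
#' @export
synth_config <- function(n_trials_per_class = 100, n_channels = 8,
                         n_samples = 1000, fs = 250, n_classes = 2,
                         erd_channels = as.list(seq_len(n_classes)),
                         erd_depth = 0.8, mu_freq = 10, mu_amp = 2,
                         erd_window = 251:750, noise_sd = 1, seed = 0) {
  cfg <- list(n_trials_per_class = n_trials_per_class,
              n_channels = n_channels, n_samples = n_samples, fs = fs,
              n_classes = n_classes, erd_channels = erd_channels,
              erd_depth = erd_depth, mu_freq = mu_freq, mu_amp = mu_amp,
              erd_window = as.integer(erd_window), noise_sd = noise_sd,
              seed = seed)
  if (cfg$erd_depth < 0 || cfg$erd_depth > 1)
    stop("erd_depth must lie in [0, 1]")
  if (length(cfg$erd_channels) < cfg$n_classes)
    stop("erd_channels must provide an entry per class")
  if (min(cfg$erd_window) < 1 || max(cfg$erd_window) > cfg$n_samples)
    stop("erd_window must lie within 1..n_samples")
  if (any(unlist(cfg$erd_channels) < 1) ||
      any(unlist(cfg$erd_channels) > cfg$n_channels))
    stop("erd_channels indices must lie in 1..n_channels")
  class(cfg) <- "synth_config"
  cfg
}

# 1/f-shaped noise: spectrally shape white noise with power exponent 1
# (amplitude ~ f^-0.5), then rescale to the requested SD.
pink_noise <- function(n, sd) {
  w <- stats::rnorm(n)
  spec <- stats::fft(w)
  f <- c(1, seq_len(n - 1))                     # guard DC bin
  f <- pmin(f, n - f + 1)                       # two-sided frequency index
  spec <- spec * f^(-0.5)
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  sd * x / stats::sd(x)
}

#' Generate a synthetic motor-imagery epoch set
#'
#' Deterministic for a fixed config (including its seed). Labels are balanced
#' and trials are shuffled so classes interleave.
#'
#' @param config a [synth_config()].
#' @param id_prefix prefix for the generated trial ids; give each simulated
#'   "subject" its own prefix to keep provenance ids globally unique.
#' @return a validated [eeg_epochs()] with `n_trials_per_class * n_classes`
#'   trials.
#' @export
synth_epochs <- function(config, id_prefix = "synth") {
  stopifnot(inherits(config, "synth_config"))
  c(n_samples, n_channels, n_classes) %<-% config[c("n_samples", "n_channels", "n_classes")]
  n <- config$n_trials_per_class * n_classes
  labels <- rep(0:(n_classes - 1L), each = config$n_trials_per_class)

  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old), add = TRUE)
  set.seed(config$seed)

  t_idx <- seq_len(n_samples)
  env <- rep(1, n_samples)
  data <- array(0, c(n, n_channels, n_samples))
  mu_channels <- sort(unique(unlist(config$erd_channels[seq_len(n_classes)])))
  for (i in seq_len(n)) {
    trial <- matrix(0, n_channels, n_samples)
    for (ch in seq_len(n_channels))
      trial[ch, ] <- pink_noise(n_samples, config$noise_sd)
    for (ch in mu_channels) {
      phase <- stats::runif(1, 0, 2 * pi)
      osc <- config$mu_amp *
        sin(2 * pi * config$mu_freq * (t_idx - 1) / config$fs + phase)
      amp <- env
      if (ch %in% config$erd_channels[[labels[i] + 1L]])
        amp[config$erd_window] <- 1 - config$erd_depth
      trial[ch, ] <- trial[ch, ] + amp * osc
    }
    data[i, , ] <- trial
  }
  perm <- sample.int(n)
  eeg_epochs(data[perm, , , drop = FALSE], labels[perm], config$fs,
             trial_ids = paste0(id_prefix, "_", perm))
}

# small destructuring helper used above
`%<-%` <- function(lhs, rhs) {
  nms <- as.character(substitute(lhs))[-1L]
  for (i in seq_along(nms))
    assign(nms[i], rhs[[i]], envir = parent.frame())
  invisible(NULL)
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Mu-band power of an epoch set in a time window
#'
#' Periodogram-based band power per trial and channel; used as the oracle
#' that ERD actually attenuates 8-12 Hz power where the generator claims.
#'
#' @param epochs an `eeg_epochs`.
#' @param channel 1-based channel index.
#' @param window integer sample range (1-based); defaults to all samples.
#' @param band numeric length-2 frequency band in Hz.
#' @return numeric vector of per-trial band power.
#' @export
band_power <- function(epochs, channel, window = NULL,
                       band = c(8, 12)) {
  if (is.null(window)) window <- seq_len(dim(epochs$data)[3L])
  n <- length(window)
  freqs <- (seq_len(n %/% 2 + 1) - 1) * epochs$fs / n
  sel <- freqs >= band[1] & freqs <= band[2]
  vapply(seq_len(n_trials(epochs)), function(i) {
    x <- epochs$data[i, channel, window]
    x <- x - mean(x)
    p <- Mod(stats::fft(x))^2 / n
    sum(p[seq_len(n %/% 2 + 1)][sel])
  }, 0)
}
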