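#' Continuous wavelet transform settings
#'
#' Analytic (generalized) Morse wavelet with shape parameter `gamma` and
#' time-bandwidth product `P^2 = gamma * beta`; the defaults
#' `gamma = 3, beta = 20` (time-bandwidth 60) match the common default of
#' wavelet toolboxes. The frequency grid is logarithmic with
#' `voices_per_octave` voices, spanning `[f_min, f_max]` inclusive, and the
#' transform uses L1 normalization so equal-amplitude sinusoids at different
#' frequencies have equal peak magnitude.
#'
#' @param f_min,f_max Frequency limits in Hz (defaults 5 and 100).
#' @param gamma,beta Morse shape parameters.
#' @param voices_per_octave Frequency resolution (default 12).
#' @return A `cwt_config` object.
#' @export
cwt_config <- function(f_min = 5, f_max = 100, gamma = 3, beta = 20,
                       voices_per_octave = 12) {
  assert_that(f_min > 0 && f_max > f_min, "need 0 < f_min < f_max")
  assert_that(gamma > 0 && beta > 0, "Morse parameters must be positive")
  assert_that(is_count(voices_per_octave) && voices_per_octave >= 1,
              "`voices_per_octave` must be a positive integer")
  structure(list(f_min = f_min, f_max = f_max, gamma = gamma, beta = beta,
                 voices_per_octave = voices_per_octave),
            class = "cwt_config")
}

# Log-spaced frequency grid including both endpoints.
cwt_freq_grid <- function(config) {
  octaves <- log2(config$f_max / config$f_min)
  nf <- ceiling(octaves * config$voices_per_octave) + 1
  2^seq(log2(config$f_min), log2(config$f_max), length.out = nf)
}

# Time spread (std of the squared envelope) of the unit-scale Morse
# wavelet, from the frequency-domain derivative via Parseval:
# sigma_t^2 = int |psi'(w)|^2 dw / int |psi(w)|^2 dw. Scales linearly with
# the CWT scale.
morse_sigma_t <- function(gamma, beta) {
  I <- function(p) gamma((p + 1) / gamma) * 2^(-(p + 1) / gamma) / gamma
  sqrt((beta^2 * I(2 * beta - 2) - 2 * beta * gamma * I(2 * beta + gamma - 2) +
          gamma^2 * I(2 * beta + 2 * gamma - 2)) / I(2 * beta))
}

# Analytic Morse wavelet in the frequency domain, peak value 2 at
# omega_peak = (beta/gamma)^(1/gamma).
morse_filter <- function(omega, gamma, beta) {
  a <- 2 * exp(beta / gamma * (1 + log(gamma / beta)))   # 2 (e gamma / beta)^(beta/gamma)
  out <- numeric(length(omega))
  pos <- omega > 0
  w <- omega[pos]
  out[pos] <- a * exp(beta * log(w) - w^gamma)
  out
}

#' Morse-wavelet scalogram of a single-channel signal
#'
#' FFT-based continuous wavelet transform with the analytic Morse wavelet
#' and L1 normalization. Returns complex coefficients on a log frequency
#' grid; a unit-amplitude sinusoid at a grid frequency has ridge magnitude
#' ~1 at any frequency (the L1 contract). The cone of influence (bins whose
#' wavelet support crosses a signal edge, e-folding convention) is flagged
#' in `coi`.
#'
#' @param signal Numeric vector (a layer-representative CSD trace).
#' @param sampling_rate Hz.
#' @param config A [cwt_config()]; `f_max` must be below Nyquist.
#' @param time_ms Optional sample times (default `0, 1/fs, ...` in ms).
#' @return A `lam_scalogram`: list with complex `coeffs`
#'   `[frequency, time]`, `freqs` (Hz, ascending), `time_ms`, logical `coi`
#'   matrix, `kind = "complex"`, `n_trials = 1`.
#' @export
#' @examples
#' fs <- 500
#' x <- sin(2 * pi * 40 * seq(0, 2, by = 1 / fs))
#' sc <- cwt_scalogram(x, fs)
#' sc$freqs[which.max(rowMeans(Mod(sc$coeffs)))]  # ~40
cwt_scalogram <- function(signal, sampling_rate, config = cwt_config(),
                          time_ms = NULL) {
  assert_that(is.numeric(signal) && length(signal) >= 4, "`signal` too short")
  assert_that(config$f_max < sampling_rate / 2,
              "`f_max` must be below the Nyquist frequency")
  n <- length(signal)
  if (n < 2 * sampling_rate / config$f_min) {
    warn("signal shorter than 2 cycles of f_min; scalogram is edge-dominated")
  }
  freqs <- cwt_freq_grid(config)
  m <- stats::nextn(2 * n, 2)
  X <- fft(c(signal, numeric(m - n)))
  omega <- 2 * pi * (0:(m - 1)) / m            # radians per sample
  omega[omega > pi] <- omega[omega > pi] - 2 * pi
  w_peak <- (config$beta / config$gamma)^(1 / config$gamma)
  sig1 <- morse_sigma_t(config$gamma, config$beta)
  coeffs <- matrix(0i, length(freqs), n)
  coi <- matrix(FALSE, length(freqs), n)
  for (k in seq_along(freqs)) {
    s <- w_peak / (2 * pi * freqs[k] / sampling_rate)   # scale in samples
    psi <- morse_filter(s * omega, config$gamma, config$beta)
    row <- fft(X * psi, inverse = TRUE) / m
    coeffs[k, ] <- row[seq_len(n)]
    # e-folding edge region: amplitude down to 1/e at sqrt(2) sigma_t
    halfwidth <- ceiling(sqrt(2) * sig1 * s)
    edge <- min(n, halfwidth)
    coi[k, c(seq_len(edge), n - seq_len(edge) + 1)] <- TRUE
  }
  if (is.null(time_ms)) time_ms <- (seq_len(n) - 1) / sampling_rate * 1000
  new_scalogram(coeffs, freqs, time_ms, kind = "complex", n_trials = 1L,
                coi = coi, sampling_rate = sampling_rate)
}

new_scalogram <- function(coeffs, freqs, time_ms, kind, n_trials,
                          coi = NULL, sampling_rate = NA_real_,
                          layer = NA_character_, condition = NA_character_) {
  structure(
    list(coeffs = coeffs, freqs = freqs, time_ms = time_ms, kind = kind,
         n_trials = as.integer(n_trials), coi = coi,
         sampling_rate = sampling_rate, layer = layer, condition = condition),
    class = "lam_scalogram"
  )
}

#' @export
print.lam_scalogram <- function(x, ...) {
  cat(sprintf("<lam_scalogram:%s> %d freqs (%.3g-%.3g Hz) x %d samples, %d trial(s)\n",
              x$kind, length(x$freqs), min(x$freqs), max(x$freqs),
              length(x$time_ms), x$n_trials))
  invisible(x)
}

#' Average scalograms across trials
#'
#' Two conventions: `complex_then_magnitude` (default) averages the complex
#' coefficients across trials before taking the magnitude, emphasising
#' phase-locked (evoked) activity -- opposite-phase components cancel;
#' `magnitude_then_average` averages per-trial magnitudes (total power,
#' phase-insensitive).
#'
#' @param scalograms List of complex `lam_scalogram`s on one grid.
#' @param mode Averaging convention.
#' @return A magnitude `lam_scalogram` with `n_trials` recorded.
#' @export
trial_average <- function(scalograms,
                          mode = c("complex_then_magnitude",
                                   "magnitude_then_average")) {
  mode <- match.arg(mode)
  assert_that(length(scalograms) >= 1, "need at least one scalogram")
  ref <- scalograms[[1]]
  for (s in scalograms) {
    assert_that(isTRUE(all.equal(s$freqs, ref$freqs)) &&
                  isTRUE(all.equal(s$time_ms, ref$time_ms)),
                "scalograms must share one frequency/time grid")
  }
  acc <- if (mode == "complex_then_magnitude") {
    Mod(Reduce(`+`, lapply(scalograms, function(s) s$coeffs)) /
          length(scalograms))
  } else {
    Reduce(`+`, lapply(scalograms, function(s) Mod(s$coeffs))) /
      length(scalograms)
  }
  out <- new_scalogram(acc, ref$freqs, ref$time_ms, kind = "magnitude",
                       n_trials = length(scalograms), coi = ref$coi,
                       sampling_rate = ref$sampling_rate,
                       layer = ref$layer, condition = ref$condition)
  out$mode <- mode
  out
}

#' Power map of a scalogram
#'
#' Power is the elementwise square of the magnitude `|a + bi|^2`.
#'
#' @param scalogram A complex or magnitude `lam_scalogram`.
#' @return The scalogram with `coeffs` replaced by real power values and
#'   `kind = "power"`.
#' @export
power_map <- function(scalogram) {
  assert_that(inherits(scalogram, "lam_scalogram"),
              "`scalogram` must be a lam_scalogram")
  scalogram$coeffs <- Mod(scalogram$coeffs)^2
  scalogram$kind <- "power"
  scalogram
}

#' The six frequency bands
#'
#' Inclusive band limits: theta 4-7, alpha 8-12, low beta 13-18, high beta
#' 19-30, low gamma 31-60, high gamma 61-100 Hz.
#'
#' @return Tibble with columns `band`, `f_lo`, `f_hi`.
#' @export
band_table <- function() {
  tibble::tibble(
    band = c("theta", "alpha", "low_beta", "high_beta", "low_gamma",
             "high_gamma"),
    f_lo = c(4, 8, 13, 19, 31, 61),
    f_hi = c(7, 12, 18, 30, 60, 100)
  )
}

#' Label frequencies with their band
#'
#' Each frequency maps to at most one band (inclusive limits); frequencies
#' in the gaps between bands (e.g. 7.5 Hz) map to `NA`.
#'
#' @param freqs Numeric frequencies in Hz (within \[1, 200\]).
#' @param bands A band table (default [band_table()]).
#' @return Character vector of band labels (`NA` outside every band).
#' @export
annotate_bands <- function(freqs, bands = band_table()) {
  assert_that(all(freqs >= 1 & freqs <= 200), "`freqs` must lie in [1, 200] Hz")
  out <- rep(NA_character_, length(freqs))
  for (i in seq_len(nrow(bands))) {
    hit <- freqs >= bands$f_lo[i] & freqs <= bands$f_hi[i]
    out[hit] <- bands$band[i]
  }
  out
}

#' Reduce a scalogram's time resolution
#'
#' Block-averages power (or magnitude) over consecutive groups of `factor`
#' time samples; used to put cluster statistics on a coarser, faster grid.
#' A downsampled bin is inside the cone of influence if any member sample
#' was.
#'
#' @param scalogram A power or magnitude `lam_scalogram`.
#' @param factor Positive integer decimation factor.
#' @return The downsampled scalogram.
#' @export
decimate_time <- function(scalogram, factor) {
  assert_that(inherits(scalogram, "lam_scalogram"),
              "`scalogram` must be a lam_scalogram")
  assert_that(scalogram$kind != "complex",
              "decimate power or magnitude scalograms, not complex ones")
  assert_that(is_count(factor) && factor >= 1, "`factor` must be >= 1")
  if (factor == 1) return(scalogram)
  n <- length(scalogram$time_ms)
  nb <- n %/% factor
  assert_that(nb >= 1, "`factor` larger than the time axis")
  idx <- rep(seq_len(nb), each = factor)
  keep <- seq_len(nb * factor)
  grp <- function(m, f) {
    out <- t(apply(m[, keep, drop = FALSE], 1,
                   function(v) tapply(v, idx, f)))
    dimnames(out) <- NULL
    out
  }
  scalogram$coeffs <- grp(scalogram$coeffs, mean)
  if (!is.null(scalogram$coi)) {
    scalogram$coi <- grp(scalogram$coi * 1, max) > 0
  }
  scalogram$time_ms <- as.numeric(tapply(scalogram$time_ms[keep], idx, mean))
  scalogram
}

#' Per-trial layer power scalograms
#'
#' Convenience bridge from a `csd_profile` to the cluster-statistics stage:
#' extracts the layer-representative trace (depth mean of the layer's valid
#' channels) of each requested trial over a time window, computes the
#' Morse CWT, squares to power and optionally decimates the time axis.
#'
#' @param csd A `csd_profile` with a layer map.
#' @param layer Layer label.
#' @param trial_ids Trials to transform.
#' @param window_ms Length-2 window relative to trial start (default the
#'   whole trial).
#' @param config A [cwt_config()].
#' @param time_downsample Decimation factor for the power maps.
#' @return List: `power` 3-D array `[trial, frequency, time]`, `freqs`,
#'   `time_ms`, `coi` (logical matrix), `trial_ids`.
#' @export
layer_power_set <- function(csd, layer, trial_ids, window_ms = NULL,
                            config = cwt_config(), time_downsample = 10) {
  assert_that(inherits(csd, "csd_profile"), "`csd` must be a csd_profile")
  lm <- csd$layer_map
  assert_that(!is.null(lm) && layer %in% names(lm),
              paste0("unknown layer: ", layer))
  ix <- which(csd$valid_channels %in% lm[[layer]])
  assert_that(length(ix) > 0, "layer has no valid CSD channels")
  keep <- if (is.null(window_ms)) seq_along(csd$time_ms) else
    which(csd$time_ms >= window_ms[1] & csd$time_ms < window_ms[2])
  # layer-representative traces, samples x trials
  sig <- apply(csd$csd[ix, keep, trial_ids, drop = FALSE], c(2, 3), mean)
  if (length(trial_ids) == 1) sig <- matrix(sig, ncol = 1)
  bat <- cwt_power_batch(sig, csd$sampling_rate, config, time_downsample)
  list(power = bat$power, freqs = bat$freqs,
       time_ms = decimate_axis(csd$time_ms[keep], time_downsample),
       coi = bat$coi, trial_ids = trial_ids)
}

decimate_axis <- function(time_ms, factor) {
  if (factor == 1) return(time_ms)
  nb <- length(time_ms) %/% factor
  idx <- rep(seq_len(nb), each = factor)
  as.numeric(tapply(time_ms[seq_len(nb * factor)], idx, mean))
}

# Batched FFT CWT -> decimated power for a samples x trials matrix.
# Same wavelet as cwt_scalogram; returns [trial, freq, time_bin].
cwt_power_batch <- function(sigmat, sampling_rate, config = cwt_config(),
                            time_downsample = 1) {
  n <- nrow(sigmat); k <- ncol(sigmat)
  assert_that(config$f_max < sampling_rate / 2,
              "`f_max` must be below the Nyquist frequency")
  freqs <- cwt_freq_grid(config)
  m <- stats::nextn(2 * n, 2)
  X <- mvfft(rbind(sigmat, matrix(0, m - n, k)))
  omega <- 2 * pi * (0:(m - 1)) / m
  omega[omega > pi] <- omega[omega > pi] - 2 * pi
  w_peak <- (config$beta / config$gamma)^(1 / config$gamma)
  nb <- if (time_downsample > 1) n %/% time_downsample else n
  # block-average operator (samples x bins)
  D <- matrix(0, n, nb)
  if (time_downsample > 1) {
    for (b in seq_len(nb)) {
      D[(b - 1) * time_downsample + seq_len(time_downsample), b] <-
        1 / time_downsample
    }
  } else {
    diag(D) <- 1
  }
  sig1 <- morse_sigma_t(config$gamma, config$beta)
  pow <- array(0, dim = c(k, length(freqs), nb))
  coi <- matrix(FALSE, length(freqs), nb)
  for (f in seq_along(freqs)) {
    s <- w_peak / (2 * pi * freqs[f] / sampling_rate)
    psi <- morse_filter(s * omega, config$gamma, config$beta)
    Wm <- mvfft(X * psi, inverse = TRUE) / m
    P <- Mod(Wm[seq_len(n), , drop = FALSE])^2      # samples x trials
    pow[, f, ] <- crossprod(P, D)                   # trials x bins
    halfwidth <- ceiling(sqrt(2) * sig1 * s)
    edge <- pmin(n, halfwidth)
    coi_s <- logical(n)
    coi_s[c(seq_len(edge), n - seq_len(edge) + 1)] <- TRUE
    coi[f, ] <- (coi_s %*% D) > 0
  }
  list(power = pow, freqs = freqs, coi = coi)
}
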