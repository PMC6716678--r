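#' Zero-lag phase synchrony between two signals
#'
#' Pearson correlation of two excitatory traces at lag zero: +1 indicates
#' complete synchronization, -1 complete desynchronization (anti-phase).
#'
#' @param sig_a,sig_b Equal-length numeric signals.
#' @return Correlation in \[-1, 1\]; `NA` if either signal is constant.
#' @export
zero_lag_synchrony <- function(sig_a, sig_b) {
  stopifnot(length(sig_a) == length(sig_b), length(sig_a) > 1)
  if (stats::sd(sig_a) == 0 || stats::sd(sig_b) == 0) return(NA_real_)
  stats::cor(sig_a, sig_b)
}

#' Per-trial synchrony between the input layer and each task module
#'
#' For every trial, computes the mean zero-lag correlation between the
#' excitatory traces of each input-layer node and each node of a module,
#' averaged over all such pairs.
#'
#' @param sim A `sync_sim` run with `record_traces = TRUE`.
#' @return A tibble `trial`, `module`, `synchrony`.
#' @export
trial_synchrony <- function(sim) {
  stopifnot(inherits(sim, "sync_sim"), !is.null(sim$traces))
  ctx <- trial_context(sim$spec)
  n_trials <- dim(sim$traces$E)[3]
  purrr::map_dfr(seq_len(n_trials), function(tr) {
    Em <- sim$traces$E[, , tr]
    purrr::map_dfr(seq_len(sim$spec$n_modules), function(m) {
      nodes <- ctx$idx2[ctx$module_of_l2 == m]
      cors <- outer(ctx$idx1, nodes,
                    Vectorize(function(i, j) zero_lag_synchrony(Em[, i], Em[, j])))
      tibble::tibble(trial = tr, module = m, synchrony = mean(cors))
    })
  })
}

#' Mean gamma amplitude of the Processing unit
#'
#' `a_t = (1/I) sum_i |E_i(t)|` over all Processing-unit nodes: the
#' population-level gamma envelope used as the amplitude signal for
#' phase-amplitude coupling.
#'
#' @param E Matrix of excitatory traces (time steps x nodes) or a vector for
#'   a single node.
#' @return Numeric amplitude per time step.
#' @export
gamma_amplitude <- function(E) {
  if (is.null(dim(E))) return(abs(E))
  rowMeans(abs(E))
}

#' Analytic phase via the Hilbert transform
#'
#' Builds the analytic signal by zeroing the negative-frequency half of the
#' FFT (doubling the positive half) and returns its argument. On a pure
#' sinusoid the phase advances uniformly at `2 pi f dt` per step.
#'
#' @param x Real signal.
#' @return Instantaneous phase in radians, same length as `x`.
#' @export
hilbert_phase <- function(x) {
  n <- length(x)
  stopifnot(n > 2, all(is.finite(x)))
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Arg(stats::fft(stats::fft(x) * h, inverse = TRUE) / n)
}

#' Debiased phase-amplitude coupling (dPAC)
#'
#' \deqn{dPAC = | (1/h) \sum_t a_t (e^{i\phi_t} - \bar\Phi) |, \qquad
#'       \bar\Phi = (1/h) \sum_t e^{i\phi_t}}
#' The subtraction of the mean phase vector removes the bias that
#' non-uniform phase coverage would otherwise induce; a constant amplitude
#' gives exactly zero.
#'
#' @param amplitude Amplitude time series `a_t`.
#' @param phase Phase time series `phi_t` in radians, same length.
#' @return Non-negative coupling strength.
#' @export
dpac <- function(amplitude, phase) {
  h <- length(amplitude)
  stopifnot(h > 0, length(phase) == h, all(is.finite(amplitude)),
            all(is.finite(phase)))
  z <- exp(1i * phase)
  Mod(mean(amplitude * (z - mean(z))))
}

#' Per-trial theta-gamma phase-amplitude coupling
#'
#' For every trial: theta phase from the Hilbert transform of the pMFC
#' excitatory trace, gamma amplitude from [gamma_amplitude()] over all
#' Processing-unit nodes, combined by [dpac()] over the trial's 500 samples.
#'
#' @param sim A `sync_sim` run with `record_traces = TRUE`.
#' @return A tibble `trial`, `dpac`.
#' @export
dpac_by_trial <- function(sim) {
  stopifnot(inherits(sim, "sync_sim"), !is.null(sim$traces))
  n_trials <- dim(sim$traces$E)[3]
  vals <- vapply(seq_len(n_trials), function(tr) {
    dpac(gamma_amplitude(sim$traces$E[, , tr]),
         hilbert_phase(sim$traces$pmfc[, tr]))
  }, numeric(1))
  tibble::tibble(trial = seq_len(n_trials), dpac = vals)
}

#' Morlet wavelet time-frequency power
#'
#' Convolves the signal with complex Morlet wavelets
#' \eqn{e^{i 2\pi f t} e^{-t^2 / (2\sigma^2)}} with width
#' \eqn{\sigma = 4 / (2\pi f)}, over 10 linearly spaced frequencies from 1 to
#' 10 Hz by default, and returns the squared magnitude of the complex
#' convolution. The signal is reflect-padded by each wavelet's half-support
#' (3 sigma) so the returned power covers the full input, with edge effects
#' confined to the reflected margins.
#'
#' @param x Real signal sampled at `dt`.
#' @param freqs Frequencies in Hz.
#' @param dt Sampling step in seconds.
#' @return An object of class `sync_tfr`: list with `power` (frequencies x
#'   time), `freqs`, `dt`.
#' @export
morlet_tfr <- function(x, freqs = seq(1, 10, length.out = 10), dt = 0.002) {
  n <- length(x)
  stopifnot(all(freqs > 0), all(is.finite(x)))
  power <- matrix(NA_real_, length(freqs), n)
  for (k in seq_along(freqs)) {
    f <- freqs[k]
    sigma <- 4 / (2 * pi * f)
    half <- ceiling(3 * sigma / dt)
    if (n <= half) {
      stop("morlet_tfr(): signal shorter than the wavelet half-support (",
           half, " samples) at ", f, " Hz", call. = FALSE)
    }
    tw <- seq(-half, half) * dt
    w <- exp(1i * 2 * pi * f * tw) * exp(-tw^2 / (2 * sigma^2))
    xp <- c(rev(x[seq_len(half) + 1]), x, rev(x[n - seq_len(half)]))
    conv <- fft_convolve(xp, w)
    power[k, ] <- Mod(conv[half + seq_len(n)])^2
  }
  structure(list(power = power, freqs = freqs, dt = dt), class = "sync_tfr")
}

# Centered linear convolution via FFT: returns a vector aligned with x
# (element t is sum_s x[t+s] * conj-free w[s] with w centered on t).
fft_convolve <- function(x, w) {
  n <- length(x); m <- length(w)
  half <- (m - 1) / 2
  N <- stats::nextn(n + m - 1, 2)
  X <- stats::fft(c(x, rep(0, N - n)))
  W <- stats::fft(c(w, rep(0, N - m)))
  full <- stats::fft(X * W, inverse = TRUE) / N
  full[half + seq_len(n)]
}

#' Tidy a time-frequency object
#' @param x A `sync_tfr`.
#' @param ... Unused.
#' @return Tibble `time`, `freq`, `power`.
#' @export
tidy.sync_tfr <- function(x, ...) {
  tidyr::expand_grid(freq = x$freqs,
                     time = seq_len(ncol(x$power)) * x$dt) |>
    dplyr::arrange(.data$time, .data$freq) |>
    dplyr::mutate(power = as.vector(x$power))
}

#' Error-minus-correct feedback power contrast
#'
#' Slices a session-long time-frequency decomposition into the inter-trial
#' intervals of trials 2..n (the window in which feedback of the previous
#' trial arrives), classifies each ITI by the previous trial's accuracy, and
#' returns mean power after errors minus mean power after correct feedback.
#'
#' @param tfr A `sync_tfr` of the concatenated session signal (e.g. the pMFC
#'   excitatory trace), `n_trials * n_steps` samples.
#' @param correct 0/1 accuracy per trial.
#' @param n_steps,iti_steps Trial timing in samples.
#' @return An object of class `sync_contrast`: `contrast` (frequencies x ITI
#'   samples), `freqs`, `dt`, and the class counts.
#' @export
feedback_power_contrast <- function(tfr, correct, n_steps = 500, iti_steps = 250) {
  stopifnot(inherits(tfr, "sync_tfr"))
  n_trials <- length(correct)
  stopifnot(ncol(tfr$power) == n_trials * n_steps)
  prev <- correct[-n_trials]
  if (!any(prev == 0) || !any(prev == 1)) {
    stop("feedback_power_contrast(): need at least one error and one correct feedback",
         call. = FALSE)
  }
  iti_power <- function(tr) {
    tfr$power[, (tr - 1) * n_steps + seq_len(iti_steps), drop = FALSE]
  }
  acc <- function(trs) {
    Reduce(`+`, lapply(trs, iti_power)) / length(trs)
  }
  after_error <- acc(which(prev == 0) + 1)
  after_correct <- acc(which(prev == 1) + 1)
  structure(list(contrast = after_error - after_correct,
                 freqs = tfr$freqs, dt = tfr$dt,
                 n_error = sum(prev == 0), n_correct = sum(prev == 1)),
            class = "sync_contrast")
}

#' @rdname feedback_power_contrast
#' @param x A `sync_contrast`.
#' @param ... Unused.
#' @export
tidy.sync_contrast <- function(x, ...) {
  tidyr::expand_grid(freq = x$freqs,
                     time = seq_len(ncol(x$contrast)) * x$dt) |>
    dplyr::arrange(.data$time, .data$freq) |>
    dplyr::mutate(contrast = as.vector(x$contrast))
}
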