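#' Oscillator parameters for a neuronal triplet
#'
#' Each network node is a triplet: a coupled excitatory/inhibitory phase-code
#' pair `(E, I)` that oscillates, plus one rate-code neuron `x` whose
#' excitability is gated by `E` (binding-by-synchrony). The phase pair follows
#' the discrete updates
#' \deqn{\Delta E = -C I - Damp \, J(r > r_{min}) E + B(t)}
#' \deqn{\Delta I = +C E - Damp \, J(r > r_{min}) I}
#' where `r = sqrt(E^2 + I^2)`, `J` is the indicator that the radius exceeds
#' `r_min`, and `B(t)` is an external burst applied to `E`.
#'
#' The coupling `C` sets the oscillation frequency. Processing-unit nodes
#' oscillate in the gamma band (40 Hz, `Damp = 0.3`, `r_min = 1`); the
#' medial-frontal controller node oscillates at theta (5 Hz, `Damp = 0.003`,
#' `r_min = 0.05`) so that its amplitude decays slowly toward a small floor
#' between error bursts.
#'
#' @param freq Target oscillation frequency in Hz. Ignored if `C` is given.
#' @param C E-I coupling strength (radians per time step). By default it is
#'   calibrated with [coupling_for_frequency()] so the realized discrete-map
#'   frequency equals `freq`.
#' @param damp Damping coefficient per step, applied only while `r > r_min`.
#' @param r_min Attractor radius of the oscillation.
#' @param dt Time step in seconds; fixed at 2 ms throughout.
#' @return A list of class `osc_params`.
#' @examples
#' osc_params()                          # gamma-band processing node
#' osc_params(freq = 5, damp = 0.003, r_min = 0.05)  # theta controller node
#' @export
osc_params <- function(freq = 40, C = NULL, damp = 0.3, r_min = 1, dt = 0.002) {
  stopifnot(is.numeric(freq), freq > 0, damp >= 0, r_min > 0, dt > 0)
  if (is.null(C)) C <- coupling_for_frequency(freq, damp = damp, r_min = r_min, dt = dt)
  stopifnot(C > 0)
  structure(list(freq = freq, C = C, damp = damp, r_min = r_min, dt = dt),
            class = "osc_params")
}

#' Calibrate the E-I coupling for a target frequency
#'
#' The continuous-time reading of the phase dynamics gives frequency
#' `C / (2 pi)` per unit time, i.e. `C = 2 pi f dt`. Under forward-Euler
#' updates at `dt` = 2 ms the per-step rotation is `atan(C / (1 - damp J))`,
#' not `C`, and the damping indicator toggles as the radius breathes around
#' `r_min`; for the gamma-band parameters this inflates the realized frequency
#' by ~6%. We therefore calibrate: the coupling is found by root-finding so
#' that the realized (phase-advance) frequency of a burst-free triplet equals
#' the target. For weak damping (theta) the correction is negligible.
#'
#' @param freq Target frequency in Hz.
#' @param damp,r_min,dt As in [osc_params()].
#' @param n_steps Number of steps used to measure the realized frequency.
#' @return The calibrated coupling `C` (radians per step).
#' @export
coupling_for_frequency <- function(freq, damp, r_min, dt = 0.002, n_steps = 2000) {
  c0 <- 2 * pi * freq * dt
  measured <- function(C) {
    phase_advance_frequency(C, damp = damp, r_min = r_min, dt = dt,
                            n_steps = n_steps) - freq
  }
  stats::uniroot(measured, interval = c(0.5 * c0, 1.5 * c0), tol = 1e-12)$root
}

# Mean per-step phase advance (in Hz) of a burst-free triplet started at
# (r_min, 0). Continuous in C, so usable for root finding (zero-crossing
# counts are step functions of C).
phase_advance_frequency <- function(C, damp, r_min, dt, n_steps) {
  E <- r_min; I <- 0; total <- 0
  cap2 <- (10 * r_min)^2
  for (t in seq_len(n_steps)) {
    J <- as.numeric(E * E + I * I > r_min * r_min)
    E2 <- E - C * I - damp * J * E
    I2 <- I + C * E - damp * J * I
    d <- atan2(I2, E2) - atan2(I, E)
    total <- total + (d + pi) %% (2 * pi) - pi
    E <- E2; I <- I2
    # when damping cannot contain the Euler growth the radius diverges; the
    # per-step rotation depends only on whether r > r_min, so rescaling far
    # above the attractor is exact and avoids overflow
    r2 <- E * E + I * I
    if (r2 > cap2) {
      s <- 10 * r_min / sqrt(r2)
      E <- E * s; I <- I * s
    }
  }
  total / (2 * pi) / (n_steps * dt)
}

#' Advance the phase-code pair of a triplet by one time step
#'
#' @param state A list (or one-row tibble) with numeric `E` and `I` (and
#'   optionally `x`, which is untouched).
#' @param params An [osc_params()] object.
#' @param burst Burst amplitude added to `E` this step (0 when silent).
#' @return The state with updated `E` and `I`.
#' @examples
#' step_phase(list(E = 1, I = 0), osc_params(C = 0.1, damp = 0.3, r_min = 1))
#' @export
step_phase <- function(state, params, burst = 0) {
  stopifnot(inherits(params, "osc_params"))
  E <- state$E; I <- state$I
  if (!all(is.finite(c(E, I, burst)))) {
    stop("step_phase(): non-finite phase state or burst", call. = FALSE)
  }
  J <- as.numeric(E * E + I * I > params$r_min^2)
  state$E <- E + (-params$C * I - params$damp * J * E + burst)
  state$I <- I + (params$C * E - params$damp * J * I)
  state
}

#' Oscillatory gate on a rate-code neuron
#'
#' Communication gain as a function of the node's excitatory phase activation:
#' `G(E) = 1 / (1 + exp(-5 (E - 0.6)))`. The gate is effectively open only
#' near the peak of the excitation cycle, so information flows between nodes
#' whose oscillations are synchronized and is blocked between anti-phase
#' nodes.
#'
#' @param E Excitatory phase activation (vectorized).
#' @return Gain in (0, 1), strictly increasing in `E`.
#' @examples
#' gate(0.6)  # 0.5
#' @export
gate <- function(E) {
  stopifnot(all(is.finite(E)))
  1 / (1 + exp(-5 * (E - 0.6)))
}

#' Advance a rate-code neuron by one time step
#'
#' `dx = -x + f(net - bias) * gain`. With the sigmoid activation
#' (`activation = "sigmoid"`, bias 5, used by the backpropagation network)
#' `f` is the logistic function; with the linear activation (Rescorla-Wagner
#' network) `f(net - bias) = net` and the bias is absent. The leak `-x` makes
#' activation track the gated drive within a couple of steps.
#'
#' @param x Current rate activation.
#' @param net Summed weighted input.
#' @param gain Gate output, see [gate()].
#' @param activation `"sigmoid"` or `"linear"`.
#' @param bias Bias of the sigmoid nodes (default 5).
#' @return Updated rate activation (vectorized over `x`/`net`/`gain`).
#' @export
step_rate <- function(x, net, gain, activation = c("sigmoid", "linear"), bias = 5) {
  activation <- match.arg(activation)
  stopifnot(all(is.finite(c(x, net, gain))))
  drive <- switch(activation,
                  sigmoid = 1 / (1 + exp(-(net - bias))),
                  linear = net)
  x + (-x + drive * gain)
}

#' Simulate one burst-free triplet
#'
#' Iterates the phase updates from initial condition `(E, I) = (r_min, 0)`
#' (or a supplied phase angle) with zero bursts; used to verify oscillation
#' frequency and radius attraction.
#'
#' @param params An [osc_params()] object.
#' @param n_steps Number of 2-ms steps to simulate.
#' @param phase0 Initial phase angle in radians.
#' @param r0 Initial radius (defaults to `r_min`).
#' @return A tibble with columns `step`, `time`, `E`, `I`, `r`.
#' @examples
#' tr <- simulate_triplet(osc_params(), n_steps = 1000)
#' estimate_frequency(tr$E)
#' @export
simulate_triplet <- function(params, n_steps = 1000, phase0 = 0, r0 = NULL) {
  stopifnot(inherits(params, "osc_params"), n_steps >= 1)
  if (is.null(r0)) r0 <- params$r_min
  E <- r0 * cos(phase0); I <- r0 * sin(phase0)
  out_E <- numeric(n_steps); out_I <- numeric(n_steps)
  st <- list(E = E, I = I)
  for (t in seq_len(n_steps)) {
    st <- step_phase(st, params)
    out_E[t] <- st$E; out_I[t] <- st$I
  }
  tibble::tibble(step = seq_len(n_steps),
                 time = seq_len(n_steps) * params$dt,
                 E = out_E, I = out_I,
                 r = sqrt(out_E^2 + out_I^2))
}

#' Estimate oscillation frequency from zero crossings
#'
#' A sinusoid crosses zero twice per cycle, so the frequency estimate is
#' (number of sign changes) / 2 / duration.
#'
#' @param x Numeric signal sampled at `dt`.
#' @param dt Sampling step in seconds.
#' @return Frequency in Hz.
#' @export
estimate_frequency <- function(x, dt = 0.002) {
  stopifnot(length(x) > 2, all(is.finite(x)))
  s <- sign(x)
  s <- s[s != 0]
  crossings <- sum(diff(s) != 0)
  crossings / 2 / (length(x) * dt)
}
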