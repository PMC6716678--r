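#' Advance the full network through one trial
#'
#' Runs the coupled phase/rate dynamics of the Processing unit (and, for the
#' full models, the pMFC controller) for one trial: 250 steps of inter-trial
#' interval without external input, then 250 steps of stimulation. Bursts
#' from the pMFC flow to the Processing unit throughout the trial; the
#' Gaussian-windowed feedback bursts carrying the previous trial's negative
#' prediction error reach the pMFC during the ITI only.
#'
#' Two engines implement the identical per-step contract (including RNG draw
#' order): `"compiled"` (Rcpp, the default) and `"r"` (a pure-R reference
#' used for cross-validation in the test suite).
#'
#' @param net A `network_state` from [init_weights()].
#' @param lfc An [lfc_state()], or `NULL` for the no-synchrony models.
#' @param pmfc List with `E`, `I`: the pMFC phase pair. Ignored when
#'   `lfc` is `NULL`.
#' @param input Layer-1 external input vector (see [encode_stimulus()]).
#' @param delta_min_prev Negative prediction error pending from the previous
#'   trial (drives the feedback bursts).
#' @param config A [run_config()].
#' @param record Logical; record per-step excitatory traces.
#' @param engine `"compiled"` or `"r"`.
#' @return The updated `net` (with trial maxima `X` filled and, if
#'   requested, `trace_E` / `trace_pmfc`), plus updated `pmfc` in field
#'   `pmfc`.
#' @export
forward_trial <- function(net, lfc, pmfc, input, delta_min_prev, config,
                          record = FALSE, engine = c("compiled", "r")) {
  engine <- match.arg(engine)
  spec <- net$spec
  if (length(input) != spec$n_inputs) {
    stop("forward_trial(): input length ", length(input),
         " does not match n_inputs = ", spec$n_inputs, call. = FALSE)
  }
  gating_on <- !is.null(lfc)
  lay <- node_layout(spec)
  signs <- if (gating_on) {
    ifelse(is.na(lay$module), lfc$layer_pointer, lfc$module_pointers[lay$module])
  } else rep(1, nrow(lay))
  W2 <- if (spec$algorithm == "BP") net$W[[2]] else matrix(0, 0, 0)
  if (!gating_on) pmfc <- list(E = 0, I = 0)
  args <- list(net$E, net$I, net$x, pmfc$E, pmfc$I,
               net$W[[1]], W2, as.numeric(signs),
               config$input_magnitude * input, delta_min_prev,
               config$C_proc, config$damp_proc, config$rmin_proc,
               config$C_ctrl, config$damp_ctrl, config$rmin_ctrl,
               spec$algorithm == "BP", spec$bias, gating_on,
               as.integer(config$n_steps), as.integer(config$iti_steps),
               config$dt * 1000, record)
  res <- if (engine == "compiled") do.call(trial_dynamics_cpp, args)
         else do.call(trial_dynamics_r, args)
  net$E <- res$E; net$I <- res$I; net$x <- res$x; net$X <- res$X
  net$pmfc <- list(E = res$E_pmfc, I = res$I_pmfc)
  if (record) {
    net$trace_E <- res$trace_E
    net$trace_pmfc <- res$trace_pmfc
  }
  net
}

# Pure-R reference implementation of the per-trial dynamics. Keep in exact
# lockstep with src/trial_dynamics.cpp (same update order, same RNG draws).
trial_dynamics_r <- function(E, I, x, E_pmfc, I_pmfc, W1, W2, lfc_sign, input,
                             delta_min_prev, C_proc, damp_proc, rmin_proc,
                             C_ctrl, damp_ctrl, rmin_ctrl, sigmoid_act, bias,
                             gating_on, n_steps, iti_steps, dt_ms, record) {
  n1 <- length(input); n2 <- ncol(W1); n3 <- if (nrow(W2) > 0) ncol(W2) else 0L
  n <- n1 + n2 + n3
  gains <- rep(1, n); X <- numeric(n)
  trace_E <- if (record) matrix(0, n_steps, n)
  trace_p <- if (record) numeric(n_steps)
  for (t in seq_len(n_steps)) {
    if (gating_on) {
      fb <- 0
      if (t <= iti_steps && delta_min_prev > 0) {
        tms <- t * dt_ms
        P <- exp(-(tms - 200)^2 / (2 * 25^2))
        if (stats::runif(1) < P) fb <- delta_min_prev
      }
      p <- 1 / (1 + exp(-10 * (E_pmfc - 1)))
      pm_out <- as.numeric(stats::runif(1) < p)
      U <- stats::rnorm(1)
      Jm <- as.numeric(E_pmfc^2 + I_pmfc^2 > rmin_ctrl^2)
      Ep <- E_pmfc + (-C_ctrl * I_pmfc - damp_ctrl * Jm * E_pmfc + fb)
      Ip <- I_pmfc + (C_ctrl * E_pmfc - damp_ctrl * Jm * I_pmfc)
      E_pmfc <- Ep; I_pmfc <- Ip
      J <- as.numeric(E^2 + I^2 > rmin_proc^2)
      B <- lfc_sign * pm_out * U
      Enew <- E + (-C_proc * I - damp_proc * J * E + B)
      Inew <- I + (C_proc * E - damp_proc * J * I)
      E <- Enew; I <- Inew
      gains <- 1 / (1 + exp(-5 * (E - 0.6)))
    }
    # within-step feedforward cascade (zero-lag communication); see the
    # matching comment in src/trial_dynamics.cpp
    stim <- t > iti_steps
    net1 <- if (stim) input else numeric(n1)
    xnew <- numeric(n)
    xnew[seq_len(n1)] <- net1 * gains[seq_len(n1)]
    net2 <- drop(crossprod(W1, xnew[seq_len(n1)]))
    drive2 <- if (sigmoid_act) 1 / (1 + exp(-(net2 - bias))) else net2
    xnew[n1 + seq_len(n2)] <- drive2 * gains[n1 + seq_len(n2)]
    if (n3 > 0) {
      net3 <- drop(crossprod(W2, xnew[n1 + seq_len(n2)]))
      drive3 <- if (sigmoid_act) 1 / (1 + exp(-(net3 - bias))) else net3
      xnew[n1 + n2 + seq_len(n3)] <- drive3 * gains[n1 + n2 + seq_len(n3)]
    }
    x <- xnew
    X <- pmax(X, x)
    if (record) {
      trace_E[t, ] <- E
      trace_p[t] <- E_pmfc
    }
  }
  out <- list(E = E, I = I, x = x, X = X, E_pmfc = E_pmfc, I_pmfc = I_pmfc)
  if (record) {
    out$trace_E <- trace_E
    out$trace_pmfc <- trace_p
  }
  out
}
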