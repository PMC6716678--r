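#' Reward-value prediction (RVPM) state
#'
#' The RL unit assigns a value `Q_i` to each task module, predicts the reward
#' `V` of the currently pointed module, compares it with the received reward
#' to form unsigned prediction errors `delta_plus` / `delta_minus`, and
#' accumulates negative prediction errors in a leaky switch neuron `S`. When
#' `S` crosses the threshold 0.5 the model switches modules via a softmax over
#' `Q + Inh`, where `Inh` transiently inhibits the just-abandoned module.
#'
#' @param n_modules Number of task modules.
#' @param q0 Initial module value. The value update is multiplicative in `V`,
#'   so `Q = 0` would be absorbing; a positive prior (0.5, i.e. "reward
#'   unknown") is required.
#' @param alpha Value learning rate: 0.1 for the RW model, 0.01 for the
#'   multi-layer (BP) models.
#' @param sigma Switch-neuron leak: 0.5 for RW, 0.8 for the multi-layer
#'   models.
#' @param threshold Switch threshold (0.5).
#' @param inh_magnitude Inhibition applied to the abandoned module (2).
#' @param inh_decay Multiplicative inhibition decay per trial (0.9).
#' @return A list of class `rl_state`.
#' @export
rl_state <- function(n_modules = 3, q0 = 0.5, alpha = 0.1, sigma = 0.5,
                     threshold = 0.5, inh_magnitude = 2, inh_decay = 0.9) {
  stopifnot(q0 >= 0, alpha > 0, alpha <= 1, sigma > 0, sigma < 1)
  structure(list(Q = rep(q0, n_modules), S = 0, Inh = rep(0, n_modules),
                 alpha = alpha, sigma = sigma, threshold = threshold,
                 inh_magnitude = inh_magnitude, inh_decay = inh_decay),
            class = "rl_state")
}

#' Expected reward of the pointed module
#'
#' `V = Q' (LFC + 1) / 2`: the pointer vector is normalized from \{-1, +1\}
#' to \{0, 1\}, so `V` is simply the value of the currently synchronized
#' module.
#'
#' @param Q Module value vector (or an `rl_state`).
#' @param lfc An [lfc_state()].
#' @return Scalar value estimate `V`.
#' @export
value_estimate <- function(Q, lfc) {
  if (inherits(Q, "rl_state")) Q <- Q$Q
  sum(Q * (lfc$module_pointers + 1) / 2)
}

#' Signed-to-unsigned prediction errors
#'
#' `delta_plus = max(R - V, 0)`, `delta_minus = max(V - R, 0)`; at most one is
#' nonzero.
#'
#' @param reward Received reward in \{0, 1\}.
#' @param V Value estimate.
#' @return Named list `delta_plus`, `delta_minus`.
#' @export
prediction_errors <- function(reward, V) {
  stopifnot(is.finite(V), reward %in% c(0, 1))
  list(delta_plus = max(reward - V, 0), delta_minus = max(V - reward, 0))
}

#' Reinforcement-modulated Hebbian value update
#'
#' `dQ_i = alpha * V * (LFC_i + 1)/2 * (delta_plus - delta_minus)`: only the
#' pointed module's value moves, up after positive and down after negative
#' prediction errors, scaled by the current value itself.
#'
#' @param rl An [rl_state()].
#' @param V Value estimate of the current trial.
#' @param lfc An [lfc_state()].
#' @param delta_plus,delta_minus Unsigned prediction errors.
#' @return The updated `rl_state`.
#' @export
update_values <- function(rl, V, lfc, delta_plus, delta_minus) {
  rl$Q <- rl$Q + rl$alpha * V * (lfc$module_pointers + 1) / 2 *
    (delta_plus - delta_minus)
  rl
}

#' Leaky accumulation of negative prediction errors
#'
#' `S' = sigma S + (1 - sigma) delta_minus`; when `S'` reaches the threshold
#' the switch fires and `S` resets to exactly 0.
#'
#' @param rl An [rl_state()].
#' @param delta_minus Negative prediction error of the current trial.
#' @return The updated `rl_state`, with logical field `switched` set.
#' @export
update_switch <- function(rl, delta_minus) {
  stopifnot(delta_minus >= 0)
  S <- rl$sigma * rl$S + (1 - rl$sigma) * delta_minus
  rl$switched <- S >= rl$threshold
  rl$S <- if (rl$switched) 0 else S
  rl
}

#' Softmax module choice with transient inhibition
#'
#' Called when the switch neuron fires. The currently pointed module is
#' inhibited (`Inh = -2`) before sampling from
#' `P(i) = exp(Q_i + Inh_i) / sum_j exp(Q_j + Inh_j)`, so the model explores
#' other modules rather than bouncing back immediately. The inhibition decays
#' by 10% at the end of every subsequent trial (see [decay_inhibition()]).
#'
#' @param rl An [rl_state()].
#' @param current Index of the currently pointed module.
#' @return List with the sampled `module` and the updated `rl` state.
#' @export
choose_module <- function(rl, current) {
  stopifnot(current %in% seq_along(rl$Q))
  rl$Inh[current] <- -rl$inh_magnitude
  p <- module_choice_probabilities(rl$Q, rl$Inh)
  list(module = sample.int(length(p), 1, prob = p), rl = rl)
}

#' @rdname choose_module
#' @param Q,Inh Value and inhibition vectors.
#' @return `module_choice_probabilities()` returns the softmax probabilities.
#' @export
module_choice_probabilities <- function(Q, Inh = 0 * Q) {
  z <- exp(Q + Inh - max(Q + Inh))
  z / sum(z)
}

#' Decay the module inhibition at trial end
#' @param rl An [rl_state()].
#' @return The updated `rl_state` (`Inh` shrunk by `inh_decay`).
#' @export
decay_inhibition <- function(rl) {
  rl$Inh <- rl$inh_decay * rl$Inh
  rl
}
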