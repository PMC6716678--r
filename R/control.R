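#' Lateral-frontal (LFC) task pointers
#'
#' The LFC holds one pointer per layer-2 task module, +1 for the module that
#' should be synchronized with the input (and output) layer and -1 for modules
#' that should be desynchronized. A fourth, constant +1 pointer covers the
#' non-modular layers.
#'
#' @param n_modules Number of task modules.
#' @param chosen Index of the initially pointed module (1-based). If `NULL`,
#'   a uniform-random choice is drawn (the state of the running RNG is used).
#' @return A list of class `lfc_state` with fields `module_pointers`
#'   (numeric, one +1 and the rest -1) and `layer_pointer` (constant 1).
#' @export
lfc_state <- function(n_modules = 3, chosen = NULL) {
  stopifnot(n_modules >= 1)
  if (is.null(chosen)) chosen <- sample.int(n_modules, 1)
  set_pointer(structure(list(module_pointers = rep(-1, n_modules),
                             layer_pointer = 1), class = "lfc_state"),
              chosen)
}

#' Point the LFC at a task module
#'
#' @param lfc An [lfc_state()].
#' @param chosen Module index in `1..n_modules`.
#' @return The updated `lfc_state`: the chosen pointer is +1, all other
#'   module pointers -1, the layer pointer unchanged.
#' @export
set_pointer <- function(lfc, chosen) {
  n <- length(lfc$module_pointers)
  if (!(is.numeric(chosen) && length(chosen) == 1 && chosen %in% seq_len(n))) {
    stop("set_pointer(): module index must be in 1..", n, call. = FALSE)
  }
  lfc$module_pointers <- rep(-1, n)
  lfc$module_pointers[chosen] <- 1
  lfc
}

#' Which module is currently pointed at
#' @param lfc An [lfc_state()].
#' @return Integer module index.
#' @export
pointed_module <- function(lfc) which(lfc$module_pointers == 1)[1]

#' Bernoulli burst output of the pMFC rate neuron
#'
#' The posterior medial-frontal node emits a burst with probability
#' `p = 1 / (1 + exp(-10 (E_pMFC - 1)))`: bursts are phase-locked to the top
#' of the theta oscillation and require sufficient amplitude (E near 1).
#'
#' @param E_pmfc Excitatory phase activation of the pMFC triplet.
#' @return 0 or 1 (vectorized over `E_pmfc`).
#' @export
sample_pmfc_output <- function(E_pmfc) {
  stopifnot(all(is.finite(E_pmfc)))
  p <- pmfc_burst_probability(E_pmfc)
  as.numeric(stats::runif(length(p)) < p)
}

#' @rdname sample_pmfc_output
#' @return `pmfc_burst_probability()` returns the burst probability itself.
#' @export
pmfc_burst_probability <- function(E_pmfc) 1 / (1 + exp(-10 * (E_pmfc - 1)))

#' Compose the synchronizing bursts sent to the Processing unit
#'
#' One standardized-Gaussian draw `U(t)` is shared by every node at a given
#' time step: `B_i(t) = LFC_i * pMFC(t) * U(t)`. The sharing is what makes
#' same-sign nodes receive perfectly correlated bursts (driving them into
#' phase) and opposite-sign nodes perfectly anticorrelated bursts (driving
#' them apart).
#'
#' @param lfc An [lfc_state()].
#' @param pmfc_out Bernoulli output of the pMFC rate neuron (0/1).
#' @param node_module Integer per node: its module index for layer-2 nodes,
#'   `NA` for nodes covered by the constant layer pointer.
#' @param U The shared standard-normal draw; drawn from the running RNG if
#'   missing.
#' @return Numeric vector of burst amplitudes, one per node.
#' @export
compose_processing_bursts <- function(lfc, pmfc_out, node_module, U = NULL) {
  stopifnot(pmfc_out %in% c(0, 1))
  if (is.null(U)) U <- stats::rnorm(1)
  signs <- ifelse(is.na(node_module), lfc$layer_pointer,
                  lfc$module_pointers[node_module])
  signs * pmfc_out * U
}

#' Timing profile of the feedback bursts to the pMFC
#'
#' After an error, the negative prediction error of trial `n - 1` is sent to
#' the pMFC excitatory neuron during the inter-trial interval of trial `n` as
#' per-step Bernoulli bursts of size `delta_min` whose success probability is
#' Gaussian-shaped in time, peaking 200 ms after feedback with a 25-ms
#' standard deviation (the empirical latency of feedback-related midfrontal
#' activity; the window represents the communication delay of the error
#' signal). One error thus pumps the pMFC theta amplitude sharply (the sum of
#' the window over the 2-ms ITI grid is about 31 expected kicks), after which
#' the amplitude decays back toward its floor across error-free trials.
#'
#' @param t_ms Time since feedback (= since trial onset of the next trial),
#'   in ms.
#' @return Success probability (vectorized).
#' @export
feedback_burst_probability <- function(t_ms) {
  exp(-(t_ms - 200)^2 / (2 * 25^2))
}

#' Sample the feedback-burst amplitude at one time step
#'
#' @param delta_min Negative prediction error of the previous trial (>= 0).
#' @param t_ms Time since feedback in ms.
#' @return `delta_min` if the Bernoulli fires, else 0.
#' @export
feedback_burst <- function(delta_min, t_ms) {
  stopifnot(delta_min >= 0, is.finite(t_ms))
  if (delta_min == 0) return(0)
  as.numeric(stats::runif(1) < feedback_burst_probability(t_ms)) * delta_min
}
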