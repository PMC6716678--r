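#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a simulation: the per-trial records
#'
#' @param x A `sync_sim`.
#' @param ... Unused.
#' @return The trial-record tibble: task columns plus `response`, `reward`,
#'   `accuracy`, and for the full models `module`, `V`, `delta_plus`,
#'   `delta_minus`, `S`, `switched`.
#' @export
tidy.sync_sim <- function(x, ...) x$trials

#' One-row summary of a simulation
#'
#' @param x A `sync_sim`.
#' @param n_bins Bins used for the plasticity/stability scores.
#' @param ... Unused.
#' @return Tibble with `model`, `beta`, `seed`, `n_trials`, overall
#'   `accuracy`, `plasticity`, `stability`, and `n_switches`.
#' @export
glance.sync_sim <- function(x, n_bins = 120, ...) {
  scores <- score_stability_plasticity(x, n_bins = n_bins)
  tibble::tibble(model = x$model, beta = x$beta, seed = x$seed,
                 n_trials = nrow(x$trials),
                 accuracy = mean(x$trials$accuracy),
                 plasticity = scores$plasticity,
                 stability = scores$stability,
                 n_switches = sum(x$trials$switched, na.rm = TRUE))
}
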