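#' Specification of the task-learning network
#'
#' The Processing unit is a layered rate/phase network. Layer 1 holds the
#' externally driven feature nodes. Layer 2 is divided into task modules; for
#' the Rescorla-Wagner (RW) network the module nodes ARE the three response
#' options (2 layers in total), while for the backpropagation (BP) network
#' they are hidden nodes feeding a shared 3-node response layer. The
#' no-synchrony variants have the same wiring but no phase-code neurons (every
#' gate is fixed open at 1); the no-synchrony RW network is a single 3x3
#' input-to-response map, realized here as one module.
#'
#' @param n_inputs Number of layer-1 feature nodes.
#' @param algorithm `"RW"` or `"BP"`.
#' @param synchrony Logical; `FALSE` builds the no-synchrony variant.
#' @param n_modules Number of layer-2 task modules.
#' @param nodes_per_module Layer-2 nodes per module. Defaults: 3 for RW (the
#'   response options); 8 hidden nodes for BP, enough conjunctive capacity
#'   for the 9 cue-by-feature conjunctions each module must represent in the
#'   3-dimensional cued task.
#' @param n_responses Number of response options.
#' @return A list of class `network_spec`.
#' @export
network_spec <- function(n_inputs, algorithm = c("RW", "BP"), synchrony = TRUE,
                         n_modules = if (synchrony) 3 else if (algorithm == "RW") 1 else 3,
                         nodes_per_module = if (algorithm == "RW") 3 else 8,
                         n_responses = 3) {
  algorithm <- match.arg(algorithm)
  if (algorithm == "RW" && nodes_per_module != n_responses) {
    stop("RW module nodes are the response options; nodes_per_module must equal n_responses",
         call. = FALSE)
  }
  structure(list(n_inputs = n_inputs, algorithm = algorithm,
                 synchrony = synchrony, n_modules = n_modules,
                 nodes_per_module = nodes_per_module,
                 n_responses = n_responses,
                 n_layer2 = n_modules * nodes_per_module,
                 n_outputs = if (algorithm == "BP") n_responses else 0L,
                 bias = 5),
            class = "network_spec")
}

#' Initialize network weights
#'
#' Every weight is drawn from `uniform(0, 1)` scaled by half the bias value
#' (2.5) for the BP network and by 1 for the RW network, matching the scale at
#' which `net - bias` of a sigmoid node is centred near zero at task onset.
#'
#' @param spec A [network_spec()].
#' @param seed Optional integer seed (uses the running RNG if `NULL`).
#' @return A list of class `network_state`: weight matrices `W` (rows =
#'   presynaptic), triplet phase state `E`, `I`, rate state `x`, and the
#'   per-trial maxima `X` (filled by the trial dynamics).
#' @export
init_weights <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "network_spec"))
  if (!is.null(seed)) set.seed(seed)
  scale <- if (spec$algorithm == "BP") spec$bias / 2 else 1
  W <- list(matrix(stats::runif(spec$n_inputs * spec$n_layer2) * scale,
                   spec$n_inputs, spec$n_layer2))
  if (spec$algorithm == "BP") {
    W[[2]] <- matrix(stats::runif(spec$n_layer2 * spec$n_outputs) * scale,
                     spec$n_layer2, spec$n_outputs)
  }
  n_nodes <- spec$n_inputs + spec$n_layer2 + spec$n_outputs
  # triplets start at radius r_min with independent random phases so that any
  # later synchronization is attributable to the bursts
  theta <- stats::runif(n_nodes, 0, 2 * pi)
  structure(list(spec = spec, W = W,
                 E = cos(theta), I = sin(theta),
                 x = numeric(n_nodes), X = numeric(n_nodes)),
            class = "network_state")
}

#' Per-node layer and module membership
#'
#' Nodes are ordered layer 1, then layer 2 module by module, then layer 3.
#'
#' @param spec A [network_spec()].
#' @return A tibble with columns `node`, `layer`, `module` (NA outside
#'   layer 2), and `response` (the response option coded by the node, NA for
#'   non-response nodes).
#' @export
node_layout <- function(spec) {
  l1 <- tibble::tibble(layer = 1L, module = NA_integer_,
                       response = NA_integer_, .rows = spec$n_inputs)
  l2 <- tibble::tibble(layer = 2L,
                       module = rep(seq_len(spec$n_modules), each = spec$nodes_per_module),
                       response = if (spec$algorithm == "RW") {
                         rep(seq_len(spec$n_responses), times = spec$n_modules)
                       } else NA_integer_)
  out <- dplyr::bind_rows(l1, l2)
  if (spec$n_outputs > 0) {
    out <- dplyr::bind_rows(out, tibble::tibble(layer = 3L, module = NA_integer_,
                                                response = seq_len(spec$n_outputs)))
  }
  dplyr::mutate(out, node = dplyr::row_number(), .before = 1)
}

#' Read out the response from trial maxima
#'
#' Argmax over the response-coding nodes' trial maxima `X`: layer 3 for BP,
#' layer 2 for RW, pooling same-response nodes across modules by max so that
#' a gated-out module cannot vote. Ties break toward the lowest index.
#'
#' @param state A `network_state` with `X` filled by the trial dynamics.
#' @return Response index in `1..n_responses`.
#' @export
readout_response <- function(state) {
  spec <- state$spec
  lay <- node_layout(spec)
  if (spec$algorithm == "BP") {
    scores <- state$X[lay$node[lay$layer == 3L]]
  } else {
    l2 <- lay[lay$layer == 2L, ]
    scores <- vapply(seq_len(spec$n_responses), function(r) {
      max(state$X[l2$node[l2$response == r]])
    }, numeric(1))
  }
  which.max(scores)  # which.max breaks ties at the lowest index
}

#' Modified Rescorla-Wagner rule (full model)
#'
#' `dW_io = beta (Target_o - X_o) X_i X_o`. The extra `X_o` factor makes only
#' co-activated neurons eligible for learning, so weights into gated-out
#' (silent) modules are protected. Used only by the full (synchrony) RW model.
#'
#' @param W Input-to-layer-2 weight matrix (inputs x layer-2 nodes).
#' @param X_in Trial maxima of the input nodes.
#' @param X_out Trial maxima of the layer-2 nodes.
#' @param target Target value per layer-2 node (the one-hot correct response,
#'   replicated across modules).
#' @param beta Learning rate in \[0, 1\].
#' @return The updated weight matrix.
#' @export
learn_rw_modified <- function(W, X_in, X_out, target, beta) {
  stopifnot(beta >= 0, beta <= 1,
            nrow(W) == length(X_in), ncol(W) == length(X_out),
            length(target) == length(X_out))
  W + beta * outer(X_in, (target - X_out) * X_out)
}

#' Classic Rescorla-Wagner delta rule (no-synchrony model)
#'
#' `dW_io = beta (Target_o - X_o) X_i`; differs from [learn_rw_modified()]
#' exactly by the co-activation factor `X_o`.
#'
#' @inheritParams learn_rw_modified
#' @return The updated weight matrix.
#' @export
learn_rw_classic <- function(W, X_in, X_out, target, beta) {
  stopifnot(beta >= 0, beta <= 1,
            nrow(W) == length(X_in), ncol(W) == length(X_out),
            length(target) == length(X_out))
  W + beta * outer(X_in, target - X_out)
}

#' One backpropagation step on the trial-level activations
#'
#' Standard backpropagation on the trial maxima `X`, one step per trial, with
#' a cross-entropy readout: output deltas `Target_o - X_o` (the exact
#' gradient of the cross-entropy loss through a logistic output), hidden
#' deltas by the back-propagated weighted sum times the logistic derivative
#' `X (1 - X)`, and `dW = beta * presynaptic X * delta`. The cross-entropy
#' readout keeps the output gradient alive when the logistic outputs start
#' saturated (as they do at the uniform(0, 2.5) weight initialization), which
#' a squared-error delta `(Target_o - X_o) X_o (1 - X_o)` does not.
#'
#' @param W List of the two weight matrices (input->hidden, hidden->output).
#' @param X_in,X_hidden,X_out Trial maxima per layer.
#' @param target One-hot target over the response options.
#' @param beta Learning rate.
#' @return The updated list of weight matrices.
#' @export
learn_bp <- function(W, X_in, X_hidden, X_out, target, beta) {
  stopifnot(length(W) == 2, beta >= 0, beta <= 1,
            length(target) == length(X_out))
  delta_out <- target - X_out
  delta_hid <- drop(W[[2]] %*% delta_out) * X_hidden * (1 - X_hidden)
  W[[2]] <- W[[2]] + beta * outer(X_hidden, delta_out)
  W[[1]] <- W[[1]] + beta * outer(X_in, delta_hid)
  W
}

#' Restricted Boltzmann machine step (extension hook)
#'
#' The framework also applies to modules trained by contrastive divergence on
#' a restricted Boltzmann machine (5 bidirectional iterations of 250 steps
#' each with stochastic binarization of the trial maxima). That variant is
#' declared here as an extension hook only and is not implemented.
#'
#' @param ... Ignored.
#' @export
learn_rbm_step <- function(...) {
  stop("The RBM learning variant is an extension hook and is not implemented.",
       call. = FALSE)
}
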