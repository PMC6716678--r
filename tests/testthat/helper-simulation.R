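# Shared helpers: tiny networks and simulations used across test files.

tiny_rw_states <- function(seed = 1, synchrony = TRUE, q0 = 0.5) {
  streams <- rng_streams(seed)
  spec <- network_spec(n_inputs = 3, algorithm = "RW", synchrony = synchrony)
  net <- with_stream(streams, "weights", init_weights(spec))
  states <- list(net = net, pending_dmin = 0)
  if (synchrony) {
    states$lfc <- with_stream(streams, "rl", lfc_state(spec$n_modules))
    states$rl <- rl_state(spec$n_modules, q0 = q0, alpha = 0.1, sigma = 0.5)
    th <- with_stream(streams, "bursts", stats::runif(1, 0, 2 * pi))
    states$pmfc <- list(E = cos(th), I = sin(th))
  }
  list(states = states, streams = streams, spec = spec)
}

# static BP forward map used as an independent oracle for the gradient check
bp_forward_static <- function(W, input, bias = 5) {
  x1 <- input
  x2 <- 1 / (1 + exp(-(drop(crossprod(W[[1]], x1)) - bias)))
  x3 <- 1 / (1 + exp(-(drop(crossprod(W[[2]], x2)) - bias)))
  list(x1 = x1, x2 = x2, x3 = x3)
}

cross_entropy_loss <- function(W, input, target, bias = 5) {
  out <- bp_forward_static(W, input, bias)$x3
  -sum(target * log(out) + (1 - target) * log(1 - out))
}
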