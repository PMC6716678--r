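#' @importFrom rlang %||%
NULL

# Precomputed per-simulation indices: node ranges per layer, response-node
# lookup, and the layer-2 module assignment used for readout, learning
# targets and per-module weight-change bookkeeping.
trial_context <- function(spec) {
  lay <- node_layout(spec)
  idx2 <- lay$node[lay$layer == 2L]
  list(idx1 = lay$node[lay$layer == 1L],
       idx2 = idx2,
       idx3 = lay$node[lay$layer == 3L],
       module_of_l2 = lay$module[lay$layer == 2L],
       response_of_l2 = lay$response[lay$layer == 2L])
}

readout_from_X <- function(X, ctx, spec) {
  if (spec$algorithm == "BP") {
    scores <- X[ctx$idx3]
  } else {
    x2 <- X[ctx$idx2]
    scores <- vapply(seq_len(spec$n_responses),
                     function(r) max(x2[ctx$response_of_l2 == r]), numeric(1))
  }
  which.max(scores)
}

#' Run one trial of the full per-trial loop
#'
#' Ordered phases: (1) trial dynamics via [forward_trial()] — ITI with
#' feedback bursts to the pMFC, then stimulation; (2) response readout from
#' the trial maxima and reward; (3) RL updates (value estimate, prediction
#' errors, value learning, switch accumulation; on a switch, softmax module
#' choice and pointer update for the next trial); (4) one synaptic learning
#' step. The no-synchrony models skip phase (3) entirely.
#'
#' @param states List with fields `net` (a `network_state`), and for the full
#'   models `lfc`, `pmfc`, `rl`, `pending_dmin`. A field `ctx` (internal
#'   index cache) is added on first use.
#' @param input Layer-1 input vector for this trial.
#' @param target_response Correct response index.
#' @param config A [run_config()].
#' @param streams An [rng_streams()] object (`bursts` and `rl` streams used).
#' @param engine Dynamics engine, see [forward_trial()].
#' @param record Record excitatory traces for this trial.
#' @return List with the updated `states`, a one-row list `record` of trial
#'   observables, `dW_module` (summed `|dW|` into each module's layer-2
#'   nodes), and optional `trace_E` / `trace_pmfc`.
#' @export
run_trial <- function(states, input, target_response, config, streams,
                      engine = "compiled", record = FALSE) {
  net <- states$net
  spec <- net$spec
  sync <- spec$synchrony
  ctx <- states$ctx %||% trial_context(spec)
  states$ctx <- ctx

  net <- with_stream(streams, "bursts",
                     forward_trial(net, if (sync) states$lfc else NULL,
                                   states$pmfc, input,
                                   states$pending_dmin %||% 0,
                                   config, record = record, engine = engine))
  states$pmfc <- net$pmfc
  response <- readout_from_X(net$X, ctx, spec)
  reward <- as.numeric(response == target_response)

  rec <- list(response = response, reward = reward, accuracy = reward,
              module = NA_integer_, V = NA_real_, delta_plus = NA_real_,
              delta_minus = NA_real_, S = NA_real_, switched = NA)

  if (sync) {
    lfc <- states$lfc
    rl <- states$rl
    mod <- pointed_module(lfc)
    V <- value_estimate(rl$Q, lfc)
    pe <- prediction_errors(reward, V)
    rl <- update_values(rl, V, lfc, pe$delta_plus, pe$delta_minus)
    rl <- update_switch(rl, pe$delta_minus)
    if (rl$switched) {
      ch <- with_stream(streams, "rl", choose_module(rl, mod))
      rl <- ch$rl
      lfc <- set_pointer(lfc, ch$module)
    }
    rl <- decay_inhibition(rl)
    rec[c("module", "V", "delta_plus", "delta_minus", "S", "switched")] <-
      list(mod, V, pe$delta_plus, pe$delta_minus, rl$S, rl$switched)
    states$pending_dmin <- pe$delta_minus
    states$lfc <- lfc
    states$rl <- rl
  }

  # synaptic learning step at trial end
  W1_old <- net$W[[1]]
  onehot <- as.numeric(seq_len(spec$n_responses) == target_response)
  if (spec$algorithm == "RW") {
    target2 <- onehot[ctx$response_of_l2]
    net$W[[1]] <- if (sync) {
      learn_rw_modified(net$W[[1]], net$X[ctx$idx1], net$X[ctx$idx2],
                        target2, config$beta)
    } else {
      learn_rw_classic(net$W[[1]], net$X[ctx$idx1], net$X[ctx$idx2],
                       target2, config$beta)
    }
  } else {
    net$W <- learn_bp(net$W, net$X[ctx$idx1], net$X[ctx$idx2],
                      net$X[ctx$idx3], onehot, config$beta)
  }
  dW <- abs(net$W[[1]] - W1_old)
  dW_module <- vapply(seq_len(spec$n_modules), function(m) {
    sum(dW[, ctx$module_of_l2 == m])
  }, numeric(1))

  out <- list(states = states, record = rec, dW_module = dW_module)
  if (record) {
    out$trace_E <- net$trace_E
    out$trace_pmfc <- net$trace_pmfc
    net$trace_E <- NULL
    net$trace_pmfc <- NULL
  }
  states$net <- net
  out$states <- states
  out
}

#' Simulate a model over a full task
#'
#' Runs the complete per-trial loop of one of the four model variants over a
#' reversal-learning task. Reproducible from `seed`: four independent RNG
#' streams (weights, task, bursts, RL choices) are derived from it.
#'
#' @param task A `sync_task` tibble from [make_one_dim_task()] or
#'   [make_multi_dim_task()].
#' @param model `"rw-full"`, `"rw-nosync"`, `"bp-full"` or `"bp-nosync"`.
#' @param beta Synaptic learning rate.
#' @param seed Master seed.
#' @param config Optional [run_config()]; built from `model` and `beta` when
#'   `NULL`. Its `model`/`beta` fields must agree with the arguments.
#' @param record_traces Record per-step excitatory traces of every node and
#'   of the pMFC (needed for synchrony / PAC / time-frequency analyses).
#' @param engine `"compiled"` (default) or `"r"` (reference implementation).
#' @return An object of class `sync_sim`: trial records as a tibble (field
#'   `trials`), final weights, per-trial per-module summed `|dW|` (field
#'   `dW`), the configuration and stream seeds, and optional trace arrays
#'   `traces$E` (steps x nodes x trials) and `traces$pmfc` (steps x trials).
#' @examples
#' task <- make_one_dim_task(seed = 1, n_trials = 36)
#' sim <- run_simulation(task, "rw-nosync", beta = 0.5, seed = 1)
#' glance(sim)
#' @export
run_simulation <- function(task, model = c("rw-full", "rw-nosync", "bp-full", "bp-nosync"),
                           beta = 0.2, seed = 1L, config = NULL,
                           record_traces = FALSE, engine = c("compiled", "r")) {
  model <- match.arg(model)
  engine <- match.arg(engine)
  stopifnot(inherits(task, "sync_task"))
  if (is.null(config)) config <- run_config(model = model, beta = beta)
  stopifnot(identical(config$model, model), identical(config$beta, beta))

  streams <- rng_streams(seed)
  algorithm <- if (startsWith(model, "rw")) "RW" else "BP"
  sync <- grepl("full", model)
  spec <- network_spec(n_inputs = attr(task, "n_inputs"),
                       algorithm = algorithm, synchrony = sync,
                       nodes_per_module = if (algorithm == "BP") config$nodes_per_module else 3L)
  net <- with_stream(streams, "weights", init_weights(spec))
  states <- list(net = net, ctx = trial_context(spec), pending_dmin = 0)
  if (sync) {
    states$lfc <- with_stream(streams, "rl", lfc_state(spec$n_modules))
    states$rl <- rl_state(spec$n_modules, q0 = config$q0, alpha = config$alpha,
                          sigma = config$sigma, threshold = config$threshold,
                          inh_magnitude = config$inh_magnitude,
                          inh_decay = config$inh_decay)
    theta0 <- with_stream(streams, "bursts", stats::runif(1, 0, 2 * pi))
    states$pmfc <- list(E = config$pmfc_init_radius * cos(theta0),
                        I = config$pmfc_init_radius * sin(theta0))
  }

  n_trials <- nrow(task)
  n_nodes <- length(net$E)
  rec_names <- c("response", "reward", "accuracy", "module", "V",
                 "delta_plus", "delta_minus", "S", "switched")
  recs <- matrix(NA_real_, n_trials, length(rec_names),
                 dimnames = list(NULL, rec_names))
  dW <- matrix(0, n_trials, spec$n_modules)
  if (record_traces) {
    trace_E <- array(0, c(config$n_steps, n_nodes, n_trials))
    trace_pmfc <- matrix(0, config$n_steps, n_trials)
  }

  for (tr in seq_len(n_trials)) {
    input <- encode_stimulus(task, tr)
    step <- run_trial(states, input, task$correct_response[tr], config,
                      streams, engine = engine, record = record_traces)
    states <- step$states
    recs[tr, ] <- unlist(step$record[rec_names])
    dW[tr, ] <- step$dW_module
    if (record_traces) {
      trace_E[, , tr] <- step$trace_E
      trace_pmfc[, tr] <- step$trace_pmfc
    }
  }

  trials <- dplyr::bind_cols(
    tibble::as_tibble(task),
    tibble::as_tibble(recs) |>
      dplyr::mutate(dplyr::across(c("response", "module"), as.integer),
                    switched = .data$switched > 0))
  out <- structure(list(trials = trials, model = model, beta = beta,
                        seed = seed, config = config, spec = spec,
                        W = states$net$W, dW = dW,
                        rl = if (sync) states$rl,
                        seeds = streams$seeds,
                        config_hash = config_hash(config)),
                   class = "sync_sim")
  if (record_traces) out$traces <- list(E = trace_E, pmfc = trace_pmfc)
  out
}

#' @export
print.sync_sim <- function(x, ...) {
  cat("<sync_sim> ", x$model, ", beta = ", x$beta, ", ", nrow(x$trials),
      " trials, accuracy = ", round(mean(x$trials$accuracy), 3), "\n", sep = "")
  invisible(x)
}

#' Bin trial-level accuracy
#'
#' Divides the trial sequence into `n_bins` equal bins (3 trials per bin for
#' the 360-trial RW task, 30 for the 3600-trial BP task) and computes mean
#' accuracy per bin.
#'
#' @param x A `sync_sim` or a tibble with columns `trial`, `block`,
#'   `accuracy`.
#' @param n_bins Number of bins; must divide the trial count.
#' @return A tibble of class `sync_bins`: `bin`, `block`, `bin_in_block`,
#'   `accuracy`.
#' @export
bin_metrics <- function(x, n_bins = 120) {
  trials <- if (inherits(x, "sync_sim")) x$trials else x
  n <- nrow(trials)
  if (n %% n_bins != 0) {
    stop("bin_metrics(): ", n, " trials are not divisible into ", n_bins,
         " bins", call. = FALSE)
  }
  bin_size <- n / n_bins
  out <- trials |>
    dplyr::mutate(bin = (dplyr::row_number() - 1) %/% bin_size + 1) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(block = .data$block[1],
                     accuracy = mean(.data$accuracy), .groups = "drop") |>
    dplyr::group_by(.data$block) |>
    dplyr::mutate(bin_in_block = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::relocate("bin", "block", "bin_in_block")
  class(out) <- c("sync_bins", class(out))
  out
}

#' Plasticity and stability scores
#'
#' Plasticity is the mean accuracy over the first 5 bins of blocks 1-3 (how
#' fast new rules are acquired). Stability is the mean accuracy over the
#' first 5 bins of blocks 4-6 minus the mean over the last 5 bins of blocks
#' 1-3: zero means what was learned was retained perfectly on re-entry;
#' catastrophic forgetting gives a negative score.
#'
#' @param x A `sync_sim`, a `sync_bins` tibble, or a trial tibble.
#' @param n_bins Bin count used if `x` still needs binning.
#' @return A one-row tibble with `plasticity` and `stability`.
#' @export
score_stability_plasticity <- function(x, n_bins = 120) {
  bins <- if (inherits(x, "sync_bins")) x else bin_metrics(x, n_bins)
  per_block <- max(bins$bin_in_block)
  first5 <- bins$bin_in_block <= 5
  last5 <- bins$bin_in_block > per_block - 5
  tibble::tibble(
    plasticity = mean(bins$accuracy[bins$block <= 3 & first5]),
    stability = mean(bins$accuracy[bins$block >= 4 & first5]) -
      mean(bins$accuracy[bins$block <= 3 & last5]))
}

#' Replication confidence-interval half-width
#'
#' `2 * SD / sqrt(Nrep)`, the half-width used for all averaged measures.
#'
#' @param x Numeric vector of per-replication values.
#' @return Scalar half-width (NA for fewer than two replications).
#' @export
ci_halfwidth <- function(x) 2 * stats::sd(x) / sqrt(length(x))

#' Learning-rate sweep
#'
#' Crosses a grid of synaptic learning rates (default 0 to 1 in 11 steps of
#' 0.1) with independent replications; each replication regenerates the task
#' order and reinitializes the model from its own derived seed.
#'
#' @param model Model variant, see [run_simulation()].
#' @param n_dims Task dimensionality (1 uses [make_one_dim_task()], 2-3
#'   [make_multi_dim_task()]).
#' @param betas Learning-rate grid.
#' @param reps Replications per grid point (10 at full scale).
#' @param seed Master seed; per-cell seeds are derived from it.
#' @param n_trials Trials per simulation (360 / 3600 at full scale).
#' @param n_bins Bins used for the per-replication scores; must divide
#'   `n_trials`.
#' @param ... Further arguments to [run_config()].
#' @return A tibble of class `sync_sweep` with one row per (beta, rep):
#'   `beta`, `rep`, `seed`, `accuracy`, `plasticity`, `stability`,
#'   `n_switches`.
#' @export
sweep_learning_rate <- function(model, n_dims = 1, betas = seq(0, 1, by = 0.1),
                                reps = 10, seed = 1L,
                                n_trials = if (n_dims == 1) 360 else 3600,
                                n_bins = 120, ...) {
  grid <- tidyr::expand_grid(beta = betas, rep = seq_len(reps))
  set.seed(seed)
  grid$seed <- sample.int(.Machine$integer.max - 1L, nrow(grid))
  res <- purrr::pmap(grid, function(beta, rep, seed) {
    task <- if (n_dims == 1) make_one_dim_task(seed = seed, n_trials = n_trials)
            else make_multi_dim_task(n_dims, seed = seed, n_trials = n_trials)
    cfg <- run_config(model = model, beta = beta, ...)
    glance(run_simulation(task, model, beta = beta, seed = seed, config = cfg),
           n_bins = n_bins)
  })
  out <- dplyr::bind_cols(grid, dplyr::bind_rows(res)[
    c("accuracy", "plasticity", "stability", "n_switches")])
  class(out) <- c("sync_sweep", class(out))
  out
}

#' Summarize a sweep across replications
#'
#' @param sweep A `sync_sweep` tibble.
#' @return Mean and CI half-width ([ci_halfwidth()]) of accuracy, plasticity
#'   and stability per learning rate (or per grid cell).
#' @export
summarize_sweep <- function(sweep) {
  keys <- intersect(c("freq_ctrl", "freq_proc", "damp_ctrl", "rmin_ctrl", "beta"),
                    names(sweep))
  sweep |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(dplyr::across(dplyr::any_of(c("accuracy", "plasticity", "stability")),
                                   list(mean = mean, ci = ci_halfwidth)),
                     n_rep = dplyr::n(), .groups = "drop")
}

#' Oscillator-parameter sweep
#'
#' Fully crosses controller and processing frequencies with the controller's
#' damping and attractor radius, running the full RW model at `beta = 0.2`
#' with 5 replications per cell, and reports mean whole-task accuracy per
#' cell. Grid resolution is the caller's choice; a full-scale
#' crossing is expensive, so sweeps at reduced grids/trials are typical.
#'
#' @param freq_ctrl,freq_proc Frequency grids in Hz.
#' @param damp_ctrl,rmin_ctrl Controller damping / attractor-radius grids.
#' @param reps Replications per cell.
#' @param beta Learning rate.
#' @param model Model variant.
#' @param n_trials Trials per simulation.
#' @param seed Master seed.
#' @return A tibble of class `sync_sweep`: one row per cell and replication
#'   with mean whole-task `accuracy`.
#' @export
sweep_oscillator_params <- function(freq_ctrl = c(2, 5, 10, 20, 40),
                                    freq_proc = c(20, 30, 40, 50, 60),
                                    damp_ctrl = 0.003, rmin_ctrl = 0.05,
                                    reps = 5, beta = 0.2, model = "rw-full",
                                    n_trials = 360, seed = 1L) {
  grid <- tidyr::expand_grid(freq_ctrl = freq_ctrl, freq_proc = freq_proc,
                             damp_ctrl = damp_ctrl, rmin_ctrl = rmin_ctrl,
                             rep = seq_len(reps))
  set.seed(seed)
  grid$seed <- sample.int(.Machine$integer.max - 1L, nrow(grid))
  acc <- purrr::pmap_dbl(grid, function(freq_ctrl, freq_proc, damp_ctrl,
                                        rmin_ctrl, rep, seed) {
    task <- make_one_dim_task(seed = seed, n_trials = n_trials)
    cfg <- run_config(model = model, beta = beta,
                      freq_ctrl = freq_ctrl, freq_proc = freq_proc,
                      damp_ctrl = damp_ctrl, rmin_ctrl = rmin_ctrl)
    sim <- run_simulation(task, model, beta = beta, seed = seed, config = cfg)
    mean(sim$trials$accuracy)
  })
  out <- dplyr::mutate(grid, accuracy = acc)
  class(out) <- c("sync_sweep", class(out))
  out
}
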