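#' Simulation configuration with model defaults
#'
#' Collects every tunable parameter of the model with its default value:
#' gamma-band Processing-unit oscillators (40 Hz, `damp_proc` 0.3, `rmin_proc`
#' 1), theta-band controller (5 Hz, `damp_ctrl` 0.003, `rmin_ctrl` 0.05),
#' sigmoid bias 5, 500-step trials (2 ms steps) with a 250-step inter-trial
#' interval, and the RL-unit parameters (value learning rate `alpha`, switch
#' leak `sigma`, threshold 0.5, inhibition magnitude 2 decaying by 10% per
#' trial). `alpha` and `sigma` default by model family: 0.1 / 0.5 for RW and
#' 0.01 / 0.8 for the multi-layer (BP) models.
#'
#' @param model One of `"rw-full"`, `"rw-nosync"`, `"bp-full"`, `"bp-nosync"`.
#' @param beta Synaptic learning rate in \[0, 1\].
#' @param freq_proc,freq_ctrl Oscillation frequencies (Hz) of the Processing
#'   unit and the controller; the couplings `C_proc` / `C_ctrl` are calibrated
#'   from them with [coupling_for_frequency()] unless given directly.
#' @param damp_proc,rmin_proc,damp_ctrl,rmin_ctrl Damping and attractor
#'   radius per unit.
#' @param dt Time step in seconds (2 ms).
#' @param n_steps,iti_steps Trial length and inter-trial interval in steps.
#' @param bias Sigmoid bias of the BP rate nodes.
#' @param input_magnitude External input to each active layer-1 node.
#' @param alpha,sigma,threshold,inh_magnitude,inh_decay,q0 RL-unit
#'   parameters, see [rl_state()].
#' @param pmfc_init_radius Initial oscillation radius of the pMFC triplet. A
#'   novel task demands maximal control, so the controller starts engaged at
#'   the amplitude scale of the burst-emission threshold (1); this lets the
#'   first inter-trial interval already organize the module phases before any
#'   learning occurs. The radius then decays toward `rmin_ctrl` across
#'   error-free trials.
#' @param nodes_per_module Layer-2 nodes per module (RW: 3, BP: 8).
#' @param C_proc,C_ctrl Couplings in radians per step; override the
#'   frequency-based calibration when supplied.
#' @return A list of class `run_config`.
#' @export
run_config <- function(model = c("rw-full", "rw-nosync", "bp-full", "bp-nosync"),
                       beta = 0.2,
                       freq_proc = 40, freq_ctrl = 5,
                       damp_proc = 0.3, rmin_proc = 1,
                       damp_ctrl = 0.003, rmin_ctrl = 0.05,
                       dt = 0.002, n_steps = 500, iti_steps = 250,
                       bias = 5, input_magnitude = 1,
                       alpha = NULL, sigma = NULL, threshold = 0.5,
                       inh_magnitude = 2, inh_decay = 0.9, q0 = 0.5,
                       pmfc_init_radius = 1,
                       nodes_per_module = NULL,
                       C_proc = NULL, C_ctrl = NULL) {
  model <- match.arg(model)
  bp <- startsWith(model, "bp")
  if (is.null(alpha)) alpha <- if (bp) 0.01 else 0.1
  if (is.null(sigma)) sigma <- if (bp) 0.8 else 0.5
  if (is.null(nodes_per_module)) nodes_per_module <- if (bp) 8L else 3L
  if (!is.numeric(beta) || beta < 0 || beta > 1) {
    stop("run_config(): beta must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(freq_proc > 0, freq_ctrl > 0, damp_proc >= 0, damp_ctrl >= 0,
            rmin_proc > 0, rmin_ctrl > 0, dt > 0,
            n_steps >= 1, iti_steps >= 0, iti_steps < n_steps,
            alpha > 0, alpha <= 1, sigma > 0, sigma < 1,
            threshold > 0, inh_magnitude >= 0,
            inh_decay >= 0, inh_decay < 1, q0 >= 0, input_magnitude > 0,
            pmfc_init_radius > 0)
  if (is.null(C_proc)) {
    C_proc <- coupling_for_frequency(freq_proc, damp = damp_proc,
                                     r_min = rmin_proc, dt = dt)
  }
  if (is.null(C_ctrl)) {
    C_ctrl <- coupling_for_frequency(freq_ctrl, damp = damp_ctrl,
                                     r_min = rmin_ctrl, dt = dt)
  }
  structure(list(model = model, beta = beta,
                 freq_proc = freq_proc, freq_ctrl = freq_ctrl,
                 C_proc = C_proc, C_ctrl = C_ctrl,
                 damp_proc = damp_proc, rmin_proc = rmin_proc,
                 damp_ctrl = damp_ctrl, rmin_ctrl = rmin_ctrl,
                 dt = dt, n_steps = as.integer(n_steps),
                 iti_steps = as.integer(iti_steps),
                 bias = bias, input_magnitude = input_magnitude,
                 alpha = alpha, sigma = sigma, threshold = threshold,
                 inh_magnitude = inh_magnitude, inh_decay = inh_decay,
                 q0 = q0, pmfc_init_radius = pmfc_init_radius,
                 nodes_per_module = as.integer(nodes_per_module)),
            class = "run_config")
}

#' Load a configuration from YAML or JSON
#'
#' The file may set any subset of [run_config()]'s parameters; the rest take
#' their defaults. Unknown keys are rejected by name.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file. An empty file yields
#'   the all-defaults configuration.
#' @return A validated [run_config()].
#' @export
load_config <- function(path) {
  stopifnot(file.exists(path))
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(vals)) vals <- list()
  allowed <- setdiff(names(formals(run_config)), "...")
  unknown <- setdiff(names(vals), allowed)
  if (length(unknown) > 0) {
    stop("load_config(): unknown configuration keys: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(run_config, vals)
}

#' Save a configuration to YAML or JSON
#'
#' Writes the full parameter set (defaults included), so
#' `load_config(save_config(cfg, path))` reproduces `cfg` exactly.
#'
#' @param config A [run_config()].
#' @param path Destination path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  vals <- unclass(config)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(vals, path, precision = 15)
  }
  invisible(path)
}

#' Stable hash of a configuration
#'
#' Used to stamp output files so that analysis steps can refuse inputs
#' produced under a different configuration.
#'
#' @param config A [run_config()].
#' @return A character hash.
#' @export
config_hash <- function(config) {
  stopifnot(inherits(config, "run_config"))
  rlang::hash(unclass(config))
}

#' Independent, named random-number streams
#'
#' Derives one reproducible RNG stream per component (weight initialization,
#' task shuffling, burst noise, RL choices) from a single master seed, so
#' that components can be varied or tested in isolation without perturbing
#' each other's draws.
#'
#' @param seed Master integer seed.
#' @param names Stream names.
#' @return An object of class `rng_streams`; field `seeds` logs the derived
#'   sub-seed of every stream.
#' @export
rng_streams <- function(seed, names = c("weights", "task", "bursts", "rl")) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  env <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  set.seed(seed)
  subseeds <- sample.int(.Machine$integer.max - 1L, length(names))
  for (i in seq_along(names)) {
    set.seed(subseeds[i])
    env[[names[i]]] <- get(".Random.seed", globalenv())
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  structure(list(env = env, seeds = stats::setNames(subseeds, names)),
            class = "rng_streams")
}

#' Evaluate an expression under a named RNG stream
#'
#' Swaps the stream's saved state into the session RNG, evaluates `code`,
#' saves the advanced state back, and restores the previous session RNG.
#'
#' @param streams An [rng_streams()] object.
#' @param name Stream name.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_stream <- function(streams, name, code) {
  stopifnot(inherits(streams, "rng_streams"), name %in% names(streams$seeds))
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  assign(".Random.seed", streams$env[[name]], envir = globalenv())
  on.exit({
    streams$env[[name]] <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  code
}
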