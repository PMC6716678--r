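#' Task-rule permutations
#'
#' Rule A maps each feature to the same-numbered response, rule B shifts by
#' one (F1->R2, F2->R3, F3->R1), rule C shifts by two (F1->R3, F2->R1,
#' F3->R2). Applying B's shift twice gives C.
#'
#' @param feature Feature index in 1..3 (vectorized).
#' @param rule Rule label `"A"`, `"B"` or `"C"` (vectorized).
#' @return Response index in 1..3.
#' @examples
#' correct_response(1, "B")  # 2
#' @export
correct_response <- function(feature, rule) {
  stopifnot(all(feature %in% 1:3), all(rule %in% c("A", "B", "C")))
  shift <- unname(c(A = 0L, B = 1L, C = 2L)[rule])
  (feature - 1L + shift) %% 3L + 1L
}

rule_order <- function(n_blocks = 6) rep(c("A", "B", "C"), length.out = n_blocks)

# Balanced-then-shuffled block fill: every row of `combos` appears
# floor(n/nrow) times, the remainder sampled without replacement.
balanced_block <- function(combos, n) {
  reps <- floor(n / nrow(combos))
  idx <- rep(seq_len(nrow(combos)), reps)
  extra <- n - length(idx)
  if (extra > 0) idx <- c(idx, sample.int(nrow(combos), extra))
  combos[sample(idx), , drop = FALSE]
}

#' One-dimensional reversal-learning task
#'
#' 360 trials in 6 equal blocks with rule order A B C A B C. On each trial one
#' of three stimulus features is shown; each feature appears equally often per
#' block, in random order. Used with the Rescorla-Wagner network.
#'
#' @param seed Integer seed for the trial shuffling (uses the running RNG if
#'   `NULL`).
#' @param n_trials Total number of trials (divisible by 6 blocks).
#' @return A tibble of class `sync_task` with columns `trial`, `block`,
#'   `rule`, `f1` (the active feature) and `correct_response`, plus
#'   attributes `n_dims = 1` and `n_inputs = 3`.
#' @export
make_one_dim_task <- function(seed = NULL, n_trials = 360) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_trials %% 6 == 0)
  block_len <- n_trials / 6
  rules <- rule_order()
  combos <- data.frame(f1 = 1:3)
  blocks <- purrr::map(1:6, function(b) {
    tibble::tibble(block = b, rule = rules[b],
                   f1 = balanced_block(combos, block_len)$f1)
  })
  out <- dplyr::bind_rows(blocks)
  out$trial <- seq_len(nrow(out))
  out$correct_response <- correct_response(out$f1, out$rule)
  out <- dplyr::relocate(out, "trial")
  structure(out, n_dims = 1L, n_inputs = 3L,
            class = c("sync_task", class(out)))
}

#' Multi-dimensional cued reversal-learning task
#'
#' `n_dims` stimulus dimensions of three features each, plus a cue dimension
#' with `n_dims` features indicating which stimulus dimension is relevant on
#' the current trial. The correct response is the block's rule applied to the
#' relevant dimension's active feature. All cue-by-feature combinations are
#' presented (as near as block length allows) equally often per block, in
#' random order. Used with the backpropagation network.
#'
#' @param n_dims Number of stimulus dimensions (2 or 3).
#' @param seed Integer seed for the shuffling.
#' @param n_trials Total number of trials (divisible by 6).
#' @return A tibble of class `sync_task` with columns `trial`, `block`,
#'   `rule`, `cue` (relevant dimension), `f1..fN` (active feature per
#'   dimension) and `correct_response`; attribute `n_inputs = n_dims + 3
#'   n_dims`.
#' @export
make_multi_dim_task <- function(n_dims = 3, seed = NULL, n_trials = 3600) {
  stopifnot(n_dims %in% 2:3, n_trials %% 6 == 0)
  if (!is.null(seed)) set.seed(seed)
  block_len <- n_trials / 6
  rules <- rule_order()
  combos <- expand.grid(c(list(cue = seq_len(n_dims)),
                          stats::setNames(rep(list(1:3), n_dims),
                                          paste0("f", seq_len(n_dims)))))
  blocks <- purrr::map(1:6, function(b) {
    filled <- balanced_block(combos, block_len)
    dplyr::bind_cols(tibble::tibble(block = b, rule = rules[b]),
                     tibble::as_tibble(filled))
  })
  out <- dplyr::bind_rows(blocks)
  out$trial <- seq_len(nrow(out))
  feat <- as.matrix(out[paste0("f", seq_len(n_dims))])
  relevant <- feat[cbind(seq_len(nrow(out)), out$cue)]
  out$correct_response <- correct_response(relevant, out$rule)
  out <- dplyr::relocate(out, "trial")
  structure(out, n_dims = as.integer(n_dims),
            n_inputs = as.integer(n_dims + 3 * n_dims),
            class = c("sync_task", class(out)))
}

#' Encode a task trial as the layer-1 input vector
#'
#' One-dimensional tasks activate one of 3 feature nodes; multi-dimensional
#' tasks activate one cue node (first `n_dims` positions) and one feature node
#' per stimulus dimension (3 nodes per dimension thereafter). Active nodes
#' receive constant external input of magnitude 1.
#'
#' @param task A `sync_task` tibble.
#' @param trial Trial number (row index).
#' @return Numeric 0/1 vector of length `attr(task, "n_inputs")`.
#' @export
encode_stimulus <- function(task, trial) {
  n_dims <- attr(task, "n_dims")
  n_inputs <- attr(task, "n_inputs")
  row <- task[trial, ]
  input <- numeric(n_inputs)
  if (n_dims == 1L) {
    input[row$f1] <- 1
  } else {
    input[row$cue] <- 1
    for (d in seq_len(n_dims)) {
      input[n_dims + 3 * (d - 1) + row[[paste0("f", d)]]] <- 1
    }
  }
  input
}
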