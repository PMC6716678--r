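test_that("zero-lag synchrony is the Pearson correlation with flagged degenerate input", {
  x <- sin(seq(0, 20, length.out = 500))
  expect_equal(zero_lag_synchrony(x, x), 1)
  expect_equal(zero_lag_synchrony(x, -x), -1)
  expect_true(is.na(zero_lag_synchrony(x, rep(1, 500))))
  set.seed(1)
  r <- replicate(200, zero_lag_synchrony(stats::rnorm(500), stats::rnorm(500)))
  expect_gt(mean(abs(r) < 0.15), 0.99)
})

test_that("dPAC reproduces its closed forms", {
  h <- 500
  phi <- 2 * pi * (0:(h - 1)) / h
  # constant amplitude: the debiasing term cancels exactly
  expect_equal(dpac(rep(3.7, h), phi), 0, tolerance = 1e-12)
  # a_t = 1 + cos(phi) on a uniform full-cycle grid -> exactly 0.5
  expect_equal(dpac(1 + cos(phi), phi), 0.5, tolerance = 1e-12)
  # coupling survives a phase-clustering bias that fools raw PAC
  phi_biased <- phi[c(1:400, seq(401, 500, by = 4))]
  expect_equal(dpac(rep(1, length(phi_biased)), phi_biased), 0, tolerance = 1e-12)
})

test_that("random amplitude-phase pairing gives near-zero dPAC relative to coupling", {
  set.seed(2)
  h <- 2000
  phi <- 2 * pi * (0:(h - 1)) / h
  a <- 1 + cos(phi)
  coupled <- dpac(a, phi)
  shuffled <- replicate(50, dpac(sample(a), phi))
  expect_gt(coupled, stats::quantile(shuffled, 0.99) * 3)
})

test_that("gamma amplitude averages absolute excitation across nodes", {
  E <- cbind(c(1, -2, 0), c(3, 0, -1))
  expect_equal(gamma_amplitude(E), c(2, 1, 0.5))
  expect_equal(gamma_amplitude(rep(0, 10)), rep(0, 10))
  expect_equal(gamma_amplitude(-3 * E), 3 * gamma_amplitude(E))
})

test_that("the Hilbert phase of a sinusoid advances uniformly at 2 pi f dt", {
  dt <- 0.002
  f <- 5
  t <- seq(0, 2, by = dt)
  ph <- hilbert_phase(cos(2 * pi * f * t))
  dph <- diff(ph)
  dph <- (dph + pi) %% (2 * pi) - pi
  interior <- dph[50:(length(dph) - 50)]
  expect_equal(mean(interior), 2 * pi * f * dt, tolerance = 0.01)
})

test_that("Morlet power localizes a sinusoid at its frequency bin", {
  dt <- 0.002
  t <- seq(dt, 8, by = dt)
  x <- sin(2 * pi * 5 * t)
  tfr <- morlet_tfr(x, freqs = seq(1, 10, length.out = 10), dt = dt)
  mid <- round(ncol(tfr$power) / 2)
  expect_equal(tfr$freqs[which.max(tfr$power[, mid])], 5)
  # power scales quadratically with amplitude
  tfr2 <- morlet_tfr(2 * x, freqs = seq(1, 10, length.out = 10), dt = dt)
  expect_equal(tfr2$power[, mid], 4 * tfr$power[, mid], tolerance = 1e-8)
  # zero signal, zero power; too-short signals are refused
  z <- morlet_tfr(rep(0, length(t)), freqs = c(5), dt = dt)
  expect_true(all(z$power == 0))
  expect_error(morlet_tfr(x[1:100], freqs = c(1), dt = dt), "half-support")
})

test_that("the feedback contrast is the error-minus-correct ITI mean and is antisymmetric", {
  set.seed(3)
  n_trials <- 8; n_steps <- 40; iti <- 20
  power <- matrix(stats::rnorm(2 * n_trials * n_steps)^2, 2)
  tfr <- structure(list(power = power, freqs = c(3, 6), dt = 0.002),
                   class = "sync_tfr")
  correct <- c(1, 0, 1, 1, 0, 0, 1, 1)
  fc <- feedback_power_contrast(tfr, correct, n_steps = n_steps, iti_steps = iti)
  # manual oracle
  prev <- correct[-n_trials]
  slice <- function(tr) power[, (tr - 1) * n_steps + seq_len(iti)]
  man <- Reduce(`+`, lapply(which(prev == 0) + 1, slice)) / sum(prev == 0) -
    Reduce(`+`, lapply(which(prev == 1) + 1, slice)) / sum(prev == 1)
  expect_equal(fc$contrast, man)
  flipped <- feedback_power_contrast(tfr, 1 - correct,
                                     n_steps = n_steps, iti_steps = iti)
  expect_equal(flipped$contrast, -fc$contrast)
  expect_error(feedback_power_contrast(tfr, rep(1, n_trials),
                                       n_steps = n_steps, iti_steps = iti),
               "at least one")
})

test_that("tidiers return long tables aligned with the matrices", {
  tfr <- structure(list(power = matrix(1:6, 2), freqs = c(2, 4), dt = 0.5),
                   class = "sync_tfr")
  td <- tidy(tfr)
  expect_equal(nrow(td), 6)
  expect_equal(td$power[td$time == 0.5], c(1, 2))
  expect_equal(td$power[td$freq == 4 & td$time == 1.5], 6)
})
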