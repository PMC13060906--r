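# small constructed population: trials with a known additive motif effect
constructed_population <- function(n_neurons = 12, n_trials = 20,
                                   effect = 1, seed = 5, fs = 20) {
  set.seed(seed)
  water <- 5 + (seq_len(n_trials) - 1) * 10
  nfr_b <- (max(water) + 8) * 500
  labels <- rep(0L, nfr_b)
  bout_rows <- list()
  for (i in seq_len(n_trials)) {
    f0 <- round((water[i] + 0.5) * 500)
    labels[(f0 + 1):(f0 + 250)] <- 5L          # a 0.5 s Retract bout
    bout_rows[[i]] <- data.frame(trial = i, motif = 5L, start_frame = f0,
                                 end_frame = f0 + 250)
  }
  t_ne <- seq(0, (nfr_b - 1) / 500, by = 1 / fs)
  traces <- matrix(rnorm(n_neurons * length(t_ne)), n_neurons)
  lab_ne <- labels[pmin(nfr_b, floor(t_ne * 500) + 1L)]
  on <- as.numeric(lab_ne == 5L)
  # first third excited, second third inhibited, rest null
  k <- floor(n_neurons / 3)
  sign_vec <- c(rep(1, k), rep(-1, k), rep(0, n_neurons - 2 * k))
  traces <- traces + outer(sign_vec * effect, on)
  events <- as_events(data.frame(water_time = water, response_window = 7))
  list(pop = list(traces = traces, t = t_ne, fs = fs,
                  neuron_ids = seq_len(n_neurons)),
       bouts = do.call(rbind, bout_rows), events = events,
       sign = sign_vec)
}

test_that("constructed motif effects are detected with the right sign and size", {
  cp <- constructed_population(effect = 1)
  mod <- motif_modulation(cp$pop, cp$bouts, cp$events, motifs = 5L)
  expect_equal(mod$class[cp$sign == 1], rep("excited", sum(cp$sign == 1)))
  expect_equal(mod$class[cp$sign == -1], rep("inhibited", sum(cp$sign == -1)))
  expect_equal(mean(mod$delta_z[cp$sign == 1]), 1, tolerance = 0.25)
})

test_that("motifs absent from all trials are flagged undefined", {
  cp <- constructed_population()
  mod <- motif_modulation(cp$pop, cp$bouts, cp$events, motifs = c(2L, 5L))
  expect_true(all(mod$class[mod$motif == 2L] == "undefined"))
  expect_true(all(mod$class[mod$motif == 5L] != "undefined"))
})

test_that("modulation sorting is a tie-stable permutation with undefined last", {
  mod <- data.frame(neuron = 1:3, motif = 5L, delta_z = c(0.5, -0.2, 0.9),
                    p = 0, class = "excited", n_trials = 10)
  expect_equal(sort_by_modulation(mod, 5L), c(3L, 1L, 2L))
  mod$delta_z <- c(1, 1, 1)
  expect_equal(sort_by_modulation(mod, 5L), 1:3)   # ties -> by neuron id
  mod$delta_z <- c(0.5, NA, 0.9)
  expect_equal(sort_by_modulation(mod, 5L), c(3L, 1L, 2L))
  expect_setequal(sort_by_modulation(mod, 5L), mod$neuron)
})

test_that("noiseless linear encoding decodes with R^2 ~ 1", {
  set.seed(8)
  n <- 2000
  K <- cbind(x = cumsum(rnorm(n)), y = cumsum(rnorm(n)),
             z = cumsum(rnorm(n)), velocity = abs(rnorm(n)))
  W <- matrix(rnorm(20 * 4), 20, 4)
  pop <- list(traces = t(scale(K) %*% t(W)), t = seq_len(n), fs = 1,
              neuron_ids = 1:20)
  # 20 noiseless traces span only the 4 targets: the design is deliberately
  # rank-deficient, so the ridge fallback fires
  suppressWarnings(dec <- decode_kinematics(pop, K, k = 5))
  expect_true(all(dec$r2$r2 >= 1 - 1e-6))
  expect_true(all(abs(dec$normalized_weights) <= 1 + 1e-12))
})

test_that("pure-noise populations decode at chance", {
  set.seed(9)
  n <- 10000
  K <- cbind(x = cumsum(rnorm(n)), y = cumsum(rnorm(n)),
             z = cumsum(rnorm(n)), velocity = abs(rnorm(n)))
  pop <- list(traces = matrix(rnorm(30 * n), 30), t = seq_len(n), fs = 1,
              neuron_ids = 1:30)
  dec <- decode_kinematics(pop, K, k = 5)
  expect_true(all(dec$r2$r2 <= 0.05))
})

test_that("decoding is invariant to neuron order", {
  set.seed(10)
  n <- 1500
  K <- cbind(x = rnorm(n), y = rnorm(n), z = rnorm(n), velocity = rnorm(n))
  W <- matrix(rnorm(15 * 4), 15, 4)
  tr <- t(K %*% t(W)) + matrix(rnorm(15 * n, 0, 0.5), 15)
  pop1 <- list(traces = tr, t = seq_len(n), fs = 1, neuron_ids = 1:15)
  perm <- sample(15)
  pop2 <- list(traces = tr[perm, ], t = seq_len(n), fs = 1,
               neuron_ids = (1:15)[perm])
  d1 <- decode_kinematics(pop1, K)
  d2 <- decode_kinematics(pop2, K)
  expect_equal(d1$r2$r2, d2$r2$r2, tolerance = 1e-9)
  expect_equal(d2$weights[as.character(1:15), ], d1$weights,
               tolerance = 1e-9)
})

# stationary unit-variance targets: mixtures of incommensurate sinusoids so
# contiguous-block CV sees the same distribution in every fold
stationary_targets <- function(n) {
  tt <- seq_len(n)
  mk <- function(f1, f2) as.numeric(scale(sin(2 * pi * f1 * tt) +
                                            0.7 * cos(2 * pi * f2 * tt)))
  cbind(x = mk(0.0113, 0.0071), y = mk(0.0091, 0.0137),
        z = mk(0.0079, 0.0103), velocity = mk(0.0123, 0.0059))
}

test_that("held-out R^2 matches the analytic readout expectation", {
  set.seed(12)
  n <- 6000; m_per <- 10
  K <- stationary_targets(n)
  sigma <- 1.5
  W <- kronecker(diag(4), matrix(1, m_per, 1))   # 10 unit-weight neurons/target
  tr <- t(K %*% t(W)) + matrix(rnorm(4 * m_per * n, 0, sigma), 4 * m_per)
  pop <- list(traces = tr, t = seq_len(n), fs = 1,
              neuron_ids = seq_len(4 * m_per))
  dec <- decode_kinematics(pop, K, k = 5)
  # optimal readout averages m neurons: effective noise variance sigma^2/m
  expected <- 1 / (1 + sigma^2 / m_per)
  expect_equal(dec$r2$r2, rep(expected, 4), tolerance = 0.05)
})

test_that("low-noise weight recovery matches the optimal readout", {
  set.seed(14)
  n <- 4000; m_per <- 10; sigma <- 0.2
  K <- stationary_targets(n)
  W <- kronecker(diag(4), matrix(1, m_per, 1))
  tr <- t(K %*% t(W)) + matrix(rnorm(4 * m_per * n, 0, sigma), 4 * m_per)
  pop <- list(traces = tr, t = seq_len(n), fs = 1,
              neuron_ids = seq_len(4 * m_per))
  dec <- decode_kinematics(pop, K, k = 5)
  for (j in 1:4) expect_gt(cor(dec$weights[, j], W[, j]), 0.95)
})

test_that("rank-deficient designs fall back to ridge with a warning", {
  set.seed(13)
  n <- 200
  K <- cbind(x = rnorm(n), y = rnorm(n), z = rnorm(n), velocity = rnorm(n))
  tr <- matrix(rnorm(3 * n), 3)
  tr <- rbind(tr, tr[1, ])                       # duplicated neuron
  pop <- list(traces = tr, t = seq_len(n), fs = 1, neuron_ids = 1:4)
  w <- testthat::capture_warnings(dec <- decode_kinematics(pop, K))
  expect_true(any(grepl("rank-deficient", w)))
  expect_true(all(is.finite(dec$r2$r2)))
})

test_that("null neurons are classified modulated at about the nominal rate", {
  cp <- constructed_population(n_neurons = 300, n_trials = 30, effect = 0,
                               seed = 21)
  mod <- motif_modulation(cp$pop, cp$bouts, cp$events, motifs = 5L)
  frac <- mean(mod$class != "unchanged")
  ci <- qbinom(c(0.005, 0.995), 300, 0.05) / 300
  expect_gte(frac, ci[1]); expect_lte(frac, ci[2])
})
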