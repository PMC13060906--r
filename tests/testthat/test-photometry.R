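test_that("a perfectly affine 470 channel yields identically zero dF/F", {
  set.seed(1)
  f410 <- 2 + exp(-seq(0, 10, length.out = 500) / 5) + rnorm(500, 0, 0.01)
  f470 <- 2 * f410 + 1
  d <- isosbestic_dff(f470, f410)
  expect_lt(max(abs(d$dff)), 1e-12)
  expect_equal(unname(d$fit_params), c(2, 1), tolerance = 1e-9)
})

test_that("a multiplicative signal orthogonal to the isosbestic channel is recovered", {
  n <- 2000
  f410 <- 3 + 0.5 * cos(seq(0, 4 * pi, length.out = n))
  s <- sin(seq(0, 40 * pi, length.out = n))      # fast; ~orthogonal to f410
  s <- s - mean(s)
  s <- s - f410 * sum(s * f410) / sum(f410^2)    # enforce orthogonality
  f_fit_true <- 1.5 * f410 + 0.2
  f470 <- f_fit_true * (1 + 0.1 * s)
  d <- isosbestic_dff(f470, f410)
  # recovered dff equals 0.1 * s up to the (small) fit perturbation
  expect_gt(cor(d$dff, 0.1 * s), 0.999)
  expect_lt(mean(abs(d$dff - 0.1 * s)), 1e-3)
})

test_that("isosbestic fit is invariant to rescaling the 410 channel", {
  set.seed(3)
  f410 <- 5 + cumsum(rnorm(300, 0, 0.01))
  f470 <- 1.2 * f410 + 0.3 + rnorm(300, 0, 0.02)
  d1 <- isosbestic_dff(f470, f410)
  d2 <- isosbestic_dff(f470, 10 * f410)
  expect_equal(d1$dff, d2$dff, tolerance = 1e-9)
})

test_that("dF/F error handling covers constant and non-positive baselines", {
  expect_error(isosbestic_dff(1:10, rep(1, 10)), "constant")
  expect_error(isosbestic_dff(1:3, 1:4), "mismatch")
  f410 <- seq(-5, 5, length.out = 100)
  f470 <- f410            # fit crosses zero
  expect_error(isosbestic_dff(f470, f410), "non-positive")
})

test_that("z-scoring is affine-invariant and rejects constants", {
  set.seed(5)
  x <- rnorm(200)
  z <- zscore_trace(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(zscore_trace(3 * x + 7), z, tolerance = 1e-12)
  expect_error(zscore_trace(rep(2, 50)), "variance")
})

test_that("generator photometry is corrected back to the true calcium signal", {
  cfg <- quick_config(20, seed = 71)      # defaults: coupling_gain 0.5
  gen <- generate_session(cfg)
  gn <- attach_neural(gen$session, gen$truth, cfg)
  ph <- process_photometry(gn$session$photometry$left)
  expect_gt(cor(ph$dff, gn$truth$calcium), 0.9)
})

test_that("stratification sizes, ordering, and window checks are exact", {
  cfg <- quick_config(10, seed = 72)
  gen <- generate_session(cfg)
  gn <- attach_neural(gen$session, gen$truth, cfg)
  ph <- process_photometry(gn$session$photometry$left)
  rts <- gn$truth$rts
  al <- align_and_stratify(ph$z, ph$t, gen$session$events, rts,
                           window = c(-1, 3))
  expect_equal(nrow(al$matrix), 10)            # trial count preserved
  n_reach <- sum(is.finite(rts))
  expect_equal(length(al$fast_idx), ceiling(0.3 * n_reach))
  expect_equal(length(al$slow_idx), ceiling(0.3 * n_reach))
  expect_true(max(rts[al$fast_idx]) <= min(rts[al$slow_idx]))
  expect_error(
    align_and_stratify(ph$z, ph$t, gen$session$events, rts,
                       window = c(-1e4, 1e4)),
    "window")
})

test_that("calcium peaks track reaction time in stratified group means", {
  cfg <- quick_config(60, seed = 73)
  gen <- generate_session(cfg)
  gn <- attach_neural(gen$session, gen$truth, cfg)
  ph <- process_photometry(gn$session$photometry$left)
  al <- align_and_stratify(ph$z, ph$t, gen$session$events, gn$truth$rts,
                           window = c(-1, 4))
  expect_lt(al$fast_peak_s, al$slow_peak_s)
})

test_that("monotone activity-kinematics coupling gives rho = 1", {
  act <- data.frame(motif = rep(2L, 10),
                    distance_mm = 1:10, mean_speed = (1:10)^2,
                    peak_speed = sqrt(1:10))
  act$mean_z <- log(act$distance_mm + 1)       # monotone in all features
  act$peak_z <- act$mean_z + 0.5
  kc <- kinematic_correlation(act)
  expect_equal(kc$rho, rep(1, nrow(kc)))
  expect_true(all(!kc$insufficient))
})

test_that("sparse cells are flagged instead of tested", {
  act <- data.frame(motif = rep(3L, 3), distance_mm = 1:3, mean_speed = 1:3,
                    peak_speed = 1:3, mean_z = 1:3, peak_z = 1:3)
  kc <- kinematic_correlation(act, min_n = 5)
  expect_true(all(kc$insufficient))
  expect_true(all(is.na(kc$rho)))
})

test_that("correlation p-values are calibrated under independence", {
  set.seed(99)
  reps <- 400
  p <- numeric(reps)
  for (r in seq_len(reps)) {
    act <- data.frame(motif = 2L, distance_mm = rnorm(30),
                      mean_speed = rnorm(30), peak_speed = rnorm(30),
                      mean_z = rnorm(30), peak_z = rnorm(30))
    kc <- kinematic_correlation(act)
    p[r] <- kc$p[kc$feature == "distance_mm" & kc$measure == "mean_z"]
  }
  frac <- mean(p < 0.05)
  expect_gt(frac, 0.02); expect_lt(frac, 0.09)   # binomial range around 0.05
})

test_that("photometry coupling induces positive speed correlations", {
  cfg <- quick_config(25, seed = 74)
  gen <- generate_session(cfg)
  gn <- attach_neural(gen$session, gen$truth, cfg)
  ph <- process_photometry(gn$session$photometry$left)
  kin <- kin_from_centroid(gn$truth$centroid, 500, cfg$spout_xyz)
  bouts <- segment_bouts(gen$session$labels, kin, 500)
  act <- motif_activity(ph$z, ph$t, bouts, 500)
  kc <- kinematic_correlation(act)
  spd <- kc[kc$feature == "mean_speed" & kc$measure == "mean_z" &
              !kc$insufficient, ]
  expect_gt(mean(spd$rho > 0), 0.8)
})
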