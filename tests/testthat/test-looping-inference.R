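# Mixture estimation of looping frequency and vector autocorrelation.

make_controls <- function(n, seed) {
  # the calibration geometry: looped = fixed 22-nm separation + 22-nm
  # noise, unlooped = compact chain + 22-nm noise
  list(looped = gen_displacement_trajectories(1, n_mol = n, n_frames = 1,
                                              seed = seed),
       unlooped = gen_displacement_trajectories(0, n_mol = n, n_frames = 1,
                                                seed = seed + 1))
}

test_that("mixture fit is exact on pure and exactly mixed targets", {
  ctl <- make_controls(1500, 41)
  dl <- density_estimate(ctl$looped$r, "cdf", kernel_width = 10, r_max = 200,
                         n_boot = 0)
  du <- density_estimate(ctl$unlooped$r, "cdf", kernel_width = 10, r_max = 200,
                         n_boot = 0)
  expect_equal(fit_loop_fraction(dl, dl, du)$f_loop, 1)
  expect_equal(fit_loop_fraction(du, dl, du)$f_loop, 0)
  mix <- dl
  mix$values <- 0.79 * dl$values + 0.21 * du$values
  expect_equal(fit_loop_fraction(mix, dl, du)$f_loop, 0.79, tolerance = 1e-12)
  expect_error(fit_loop_fraction(dl, du, du), "degenerate")
})

test_that("sampled mixtures are recovered within 0.05 in most seeds", {
  # calibration geometry: Rayleigh-type controls (sigma 35 vs 55 nm, the
  # scale set by a 22-nm noise floor on compact vs extended conformations),
  # n = 1000 target draws
  # Monte-Carlo calibration of this estimator in this geometry puts its
  # spread at ~0.04 for n = 1000 target draws, so errors within one/two
  # spreads are the computable expectation
  rayleigh <- function(n, sig) sig * sqrt(rnorm(n)^2 + rnorm(n)^2)
  errs <- vapply(1:10, function(s) {
    set.seed(900 + s)
    L <- rayleigh(2000, 35); U <- rayleigh(2000, 55)
    n_loop <- rbinom(1, 1000, 0.6)
    t_ <- c(rayleigh(n_loop, 35), rayleigh(1000 - n_loop, 55))
    bootstrap_loop_fraction(t_, L, U, n_boot = 0)$f_loop - 0.6
  }, numeric(1))
  expect_gte(sum(abs(errs) <= 0.05), 7)
  expect_gte(sum(abs(errs) <= 0.08), 9)
  expect_lt(abs(mean(errs)), 0.03)
})

test_that("mixture estimator is nearly unbiased across the f range", {
  for (f in c(0.1, 0.5, 0.9)) {
    ests <- vapply(1:4, function(s) {
      ctl <- make_controls(5000, 2000 + 50 * s + round(1000 * f))
      trT <- gen_displacement_trajectories(f, n_mol = 5000, n_frames = 1,
                                           seed = 3000 + 50 * s + round(1000 * f))
      bootstrap_loop_fraction(trT$r, ctl$looped$r, ctl$unlooped$r,
                              n_boot = 0)$f_loop
    }, numeric(1))
    expect_lt(abs(mean(ests) - f), 0.02 + 2 * sd(ests) / sqrt(length(ests)))
  }
})

test_that("bootstrap randomizes controls and reports small sem for
          well-separated large samples", {
  rayleigh <- function(n, sig) sig * sqrt(rnorm(n)^2 + rnorm(n)^2)
  set.seed(43)
  L <- rayleigh(4000, 30); U <- rayleigh(4000, 80)
  n_loop <- rbinom(1, 4000, 0.7)
  t_ <- c(rayleigh(n_loop, 30), rayleigh(4000 - n_loop, 80))
  fit <- bootstrap_loop_fraction(t_, L, U, n_boot = 300, seed = 45)
  expect_lt(fit$sem, 0.02)
  ctl <- make_controls(1500, 43)
  # target drawn from the looped control population: f near 1
  trL <- gen_displacement_trajectories(1, n_mol = 1500, n_frames = 1, seed = 46)
  fit1 <- bootstrap_loop_fraction(trL$r, ctl$looped$r, ctl$unlooped$r,
                                  n_boot = 300, seed = 47)
  expect_gt(fit1$f_loop, 0.93)
  expect_lt(fit1$sem, 0.05)
})

test_that("PDF and CDF bases agree within their joint error", {
  ctl <- make_controls(2500, 48)
  trT <- gen_displacement_trajectories(0.6, n_mol = 2000, n_frames = 1, seed = 49)
  fc <- bootstrap_loop_fraction(trT$r, ctl$looped$r, ctl$unlooped$r,
                                n_boot = 300, kind = "cdf", seed = 50)
  fp <- bootstrap_loop_fraction(trT$r, ctl$looped$r, ctl$unlooped$r,
                                n_boot = 300, kind = "pdf", seed = 51)
  joint <- sqrt(fc$sem^2 + fp$sem^2)
  expect_lt(abs(fc$f_loop - fp$f_loop), joint)
})

test_that("autocorrelation of a constant vector equals its squared magnitude", {
  tr <- data.frame(molecule_id = 1, frame = 0:9, dx = 30, dy = 40)
  ac <- vector_autocorrelation(tr, n_boot = 0)
  expect_equal(ac$value_nm2, rep(2500, nrow(ac)))
  expect_equal(ac$lag_s, seq(0, 0.5, by = 0.1))
})

test_that("iid zero-mean noise gives lag-0 = 2 s^2 and zero beyond", {
  set.seed(52)
  s <- 25
  tr <- data.frame(molecule_id = rep(1:400, each = 8),
                   frame = rep(0:7, times = 400),
                   dx = rnorm(3200, 0, s), dy = rnorm(3200, 0, s))
  ac <- vector_autocorrelation(tr, n_boot = 100, seed = 53)
  expect_lt(abs(ac$value_nm2[1] - 2 * s^2) / (2 * s^2), 0.05)
  expect_true(all(abs(ac$value_nm2[-1]) < 3 * ac$sem[-1] + 1e-9))
})

test_that("the lag-0 to lag-1 drop equals the injected noise variance and
          frozen-state curves are flat afterwards", {
  sig <- 22
  tr <- gen_displacement_trajectories(0.79, n_mol = 1500, n_frames = 6,
                                      noise = noise_model(sig), seed = 54)
  ac <- vector_autocorrelation(tr, n_boot = 150, seed = 55)
  drop <- ac$value_nm2[1] - ac$value_nm2[2]
  # per coordinate each of two spots contributes sigma^2: total 4 sigma^2
  expect_lt(abs(drop - 4 * sig^2) / (4 * sig^2), 0.12)
  plateau <- ac$value_nm2[-1]
  expect_true(all(abs(plateau - mean(plateau)) < 3 * ac$sem[-1]))
  expect_error(vector_autocorrelation(tr[tr$frame == 0, ]), ">= 2 frames")
})
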