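# State enumeration, partition-function bookkeeping, steady states, fits.

test_that("full enumeration of the wild type gives 176 microstates in 122
          unique states", {
  st <- enumerate_states(lambda_strain("WT"), "full")
  expect_equal(attr(st, "n_microstates"), 176L)
  expect_equal(nrow(st), 122L)
  expect_true(all(st$d >= 1))
  expect_equal(sum(st$d), 176L)
})

test_that("strain constraints remove the right states", {
  dol <- enumerate_states(lambda_strain("dOL"), "full")
  expect_true(all(!dol$looped))
  expect_true(all(!dol$L1 & !dol$L2 & !dol$L3))
  or3 <- enumerate_states(lambda_strain("OR3m"), "full")
  expect_true(all(!or3$R3))
  ol3 <- enumerate_states(lambda_strain("OL3m"), "full")
  expect_true(all(!ol3$L3))
  # without O_L3, tetramer-secured loops are impossible but octamer loops remain
  expect_true(all(ol3$tet == 0))
  expect_true(any(ol3$looped))
})

test_that("minimal mode keeps the lysogenic state family", {
  st <- enumerate_states(lambda_strain("WT"), "minimal")
  expect_true(all(st$L1 & st$L2))
  expect_true(all((!st$R1 & !st$R2 & !st$R3) | (st$R1 & st$R2)))
  expect_lt(nrow(st), 30)
})

test_that("probabilities normalize, and a two-state toy matches hand
          computation", {
  p <- thermo_params(dG_oct = 0.3, dG_tet = -3.2, R_unloop = 2, R_loop = 5)
  st <- enumerate_states(lambda_strain("WT"))
  for (ci2 in c(0, 0.5, 5, 50, 5000))
    expect_equal(sum(state_probabilities(st, ci2, p)), 1, tolerance = 1e-12)
  # ci2 = 0: all mass on the empty configuration
  pr0 <- state_probabilities(st, 0, p)
  expect_equal(sum(pr0[st$i == 0]), 1, tolerance = 1e-12)
  # toy: two one-dimer states with dG = 0 and -RT ln 2 -> probabilities 1/3, 2/3
  cfg <- list(binding = list(OL1 = 0, OL2 = -0.593 * log(2), OL3 = 99,
                             OR1 = 99, OR2 = 99, OR3 = 99),
              cooperativity = 0, RT = 0.593, ci_wt_nM = 220,
              nM_per_molecule = 1.47, phi_dimer = 0.1,
              doubling_time_min = 120, R_basal_frac = 0.2)
  ptoy <- thermo_params(config = cfg)
  toy <- enumerate_states(lambda_strain("WT"))
  toy <- toy[toy$i == 1 & (toy$L1 | toy$L2), ]
  pr <- state_probabilities(toy, 10, ptoy)
  expect_equal(unname(pr[order(state_energies(toy, ptoy), decreasing = TRUE)]),
               c(1 / 3, 2 / 3), tolerance = 1e-12)
})

test_that("partition sums agree with an independent brute-force enumeration", {
  p <- thermo_params(dG_oct = 0.4, dG_tet = -3.0, R_unloop = 2, R_loop = 5)
  st <- enumerate_states(lambda_strain("WT"))
  for (ci2 in c(1, 8, 40)) {
    bf <- brute_force_lambda(ci2, p$G, p$coop, p$dG_oct, p$dG_tet)
    expect_equal(loop_probability(st, ci2, p), bf$p_loop, tolerance = 1e-10)
    rates <- c(repressed = 0, basal = p$R_basal_frac * p$R_unloop,
               active_unlooped = p$R_unloop, active_looped = p$R_loop)
    expect_equal(mean_expression_rate(st, ci2, p),
                 sum(bf$class_probs * rates[names(bf$class_probs)]),
                 tolerance = 1e-10)
  }
})

test_that("limiting behaviors of expression and looping", {
  p <- thermo_params(dG_oct = 0.3, dG_tet = -3.2, R_unloop = 2, R_loop = 5)
  st <- enumerate_states(lambda_strain("WT"))
  # saturating CI with O_R3 bindable: repressed states dominate
  expect_lt(mean_expression_rate(st, 1e7, p), 0.01 * p$R_unloop)
  # deep tetramer energy: looped probability -> 1 at saturating CI
  p2 <- thermo_params(dG_oct = 0.3, dG_tet = -30, R_unloop = 2, R_loop = 5)
  expect_gt(loop_probability(st, 1e4, p2), 0.999)
  # O_L deletion never loops
  dol <- enumerate_states(lambda_strain("dOL"))
  for (ci2 in c(0, 10, 1000))
    expect_equal(loop_probability(dol, ci2, p), 0)
  # uniform rates: mean rate is that constant at any concentration
  st_norep <- st[st$rate_class != "repressed", ]
  p3 <- p; p3$R_basal_frac <- 1; p3$R_loop <- p3$R_unloop
  for (ci2 in c(0.1, 10, 1000))
    expect_equal(mean_expression_rate(st_norep, ci2, p3), p3$R_unloop,
                 tolerance = 1e-12)
})

test_that("steady states solve production = degradation", {
  p <- thermo_params(dG_oct = 0.25, dG_tet = -3.3, R_unloop = 2.26, R_loop = 4.55)
  ss <- steady_state_concentration(lambda_strain("WT"), p)
  st <- enumerate_states(lambda_strain("WT"))
  expect_equal(mean_expression_rate(st, ss$ci2_nM, p), p$k_deg * ss$c_nM,
               tolerance = 1e-6)
  # zero production: steady state at zero
  p0 <- thermo_params(dG_oct = 0, dG_tet = 0, R_unloop = 0, R_loop = 0)
  expect_equal(steady_state_concentration(lambda_strain("WT"), p0)$c_nM, 0)
  # constant unrepressed production R: c = R / k_deg
  one <- st[st$i == 0, ]
  pR <- thermo_params(dG_oct = 0, dG_tet = 0, R_unloop = 3, R_loop = 3)
  pR$R_basal_frac <- 1
  ssR <- steady_state_concentration(one, pR)
  expect_equal(ssR$c_nM, 3 / pR$k_deg, tolerance = 1e-6)
})

test_that("predicted observables are sane and continuous in dG_tet", {
  p <- thermo_params(dG_oct = 0.25, dG_tet = -3.3, R_unloop = 2.26, R_loop = 4.55)
  pred <- predict_observables(p)
  expect_true(all(pred$f >= 0 & pred$f <= 1))
  expect_equal(pred$wlu[["WT"]], 1, tolerance = 0.05)
  # re-prediction at identical parameters is identical
  expect_identical(pred$f, predict_observables(p)$f)
  # no jumps along a dG_tet sweep
  tets <- seq(-4, -2, by = 0.1)
  fs <- vapply(tets, function(g) {
    pp <- p; pp$dG_tet <- g
    predict_observables(pp)$f[["WT"]]
  }, numeric(1))
  expect_true(all(abs(diff(fs)) < 0.06))
})

test_that("parameter fitting round-trips model-generated observables", {
  truth <- thermo_params(dG_oct = 0.4, dG_tet = -3.0, R_unloop = 2.0, R_loop = 5.0)
  obs_model <- predict_observables(truth)
  obs <- observable_set(f = obs_model$f, wlu = obs_model$wlu)
  fit <- fit_free_parameters(obs)
  expect_lt(abs(fit$par[["dG_oct"]] - 0.4), 0.1)
  expect_lt(abs(fit$par[["dG_tet"]] + 3.0), 0.1)
  expect_lt(abs(fit$par[["R_unloop"]] - 2.0) / 2.0, 0.05)
  expect_lt(abs(fit$par[["R_loop"]] - 5.0) / 5.0, 0.05)
})

test_that("residual landscape is consistent with the fit optimum", {
  obs <- observable_set()
  fit <- fit_free_parameters(obs)
  g1 <- fit$par[["dG_oct"]] + c(-0.4, 0, 0.4)
  g2 <- fit$par[["dG_tet"]] + c(-0.4, 0, 0.4)
  ls <- residual_landscape(obs, fit, "energies", g1, g2)
  expect_equal(which(ls$log10_min_sse == min(ls$log10_min_sse), arr.ind = TRUE),
               matrix(c(2L, 2L), 1, dimnames = list(NULL, c("row", "col"))))
  expect_equal(10^min(ls$log10_min_sse), fit$sse, tolerance = 0.02)
})

test_that("sensitivity scan containing the default point reproduces the
          default fit", {
  obs <- observable_set()
  fit <- fit_free_parameters(obs)
  scan <- sensitivity_scan(obs, ci_levels = 220 / 1.47, dimer_fractions = 0.1)
  expect_true(scan$ok[1])
  expect_equal(scan$dG_tet[1], fit$par[["dG_tet"]], tolerance = 1e-6)
  expect_equal(scan$activation_ratio[1], fit$activation_ratio, tolerance = 1e-6)
})
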