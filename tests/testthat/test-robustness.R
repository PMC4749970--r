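motif_noise_fixture <- function(noise_rel = 0.05, seed = 8) {
  m <- motif_models()$chain
  u <- step_input()
  truth <- generate_truth(m, u,
                          hidden_input_spec(2L, "pulse", amplitude = 0.5,
                                            onset = 2, offset = 7),
                          seq(0, 10, 0.5), noise_sd = "relative",
                          noise_rel = noise_rel, seed = seed)
  # identity weighting: the motif outputs are commensurate, and precision
  # weights would make chasing the (scaled) noise arbitrarily profitable
  ms <- truth$measurements
  ms$weights <- rep(list(diag(m$n_outputs)), length(ms$sample_times))
  list(model = m, input = u, truth = truth, data = ms,
       cfg = reg_config(0.5, 0.01), grid = test_grid(),
       # distributional studies need many fits; a few hundred iterations
       # resolve the AUC well within the sampling spread
       ctl = list(maxit = 400, factr = 1e9))
}

test_that("measurement perturbations are seeded, unbiased and scale as the level", {
  fx <- motif_noise_fixture()
  data <- fx$truth$measurements
  expect_identical(perturb_measurements(data, 0, 1)$observations,
                   data$observations)
  p1 <- perturb_measurements(data, 1.5, seed = 99)
  p2 <- perturb_measurements(data, 1.5, seed = 99)
  expect_identical(p1$observations, p2$observations)
  expect_false(identical(p1$observations,
                         perturb_measurements(data, 1.5, 100)$observations))
  # law of large numbers: standardised perturbations have mean ~0, var ~level^2
  level <- 0.7
  z <- vapply(seq_len(300), function(i) {
    p <- perturb_measurements(data, level, seed = i)
    (p$observations - data$observations) / data$sds
  }, data$observations)
  expect_lt(abs(mean(z)), 3 * level / sqrt(length(z)))
  expect_equal(stats::var(as.numeric(z)), level^2, tolerance = 0.1)
  nosd <- measurement_set(data$sample_times, data$observations)
  expect_error(perturb_measurements(nosd, 1, 1), "standard deviations")
})

test_that("parameter draws are uniform on the scaled intervals", {
  pt <- c(k1 = 1, k2 = 0.5)
  hw <- c(k1 = 0.2, k2 = 0.1)
  study <- param_study_config(pt, hw, noise_levels = c(0, 1), n_samples = 5)
  expect_identical(unname(perturb_parameters(study, 0, 1)[1:2]), unname(pt))
  d1 <- perturb_parameters(study, 1, seed = 5)
  expect_identical(d1, perturb_parameters(study, 1, seed = 5))
  draws <- t(vapply(seq_len(2000), function(i)
    perturb_parameters(study, 1, seed = i)[1:2], numeric(2)))
  expect_true(all(draws[, 1] >= 0.8 - 1e-12 & draws[, 1] <= 1.2 + 1e-12))
  ks <- stats::ks.test(draws[, 1], "punif", 0.8, 1.2)
  expect_gt(ks$p.value, 0.001)
  # clipping at zero for nonnegative rate constants
  study2 <- param_study_config(c(k = 0.05), c(k = 1), 1, 5)
  many <- vapply(seq_len(200), function(i)
    perturb_parameters(study2, 1, seed = i), numeric(1))
  expect_true(all(many >= 0))
})

test_that("a single-sample study at level zero equals the unperturbed fit", {
  fx <- motif_noise_fixture()
  res <- run_noise_study(fx$model, fx$input, fx$data, fx$cfg,
                         fx$grid, noise_study_config(0, n_samples = 1,
                                                     seed = 3),
                         control = fx$ctl)
  sol <- solve_den(fx$model, fx$input, fx$data, fx$cfg,
                   fx$grid, control = fx$ctl)
  auc <- compute_auc(sol$hidden_input)
  got <- res$summaries$median[order(res$summaries$component)]
  expect_equal(got, unname(auc$per_component), tolerance = 1e-8)
})

test_that("AUC medians are stable across noise while spread grows", {
  fx <- motif_noise_fixture()
  study <- noise_study_config(c(0, 1, 2), n_samples = 8, seed = 11)
  res <- run_noise_study(fx$model, fx$input, fx$data, fx$cfg,
                         fx$grid, study, control = fx$ctl)
  s <- res$summaries
  target <- s[s$component == 2, ]
  target <- target[order(target$level), ]
  # median AUC of the true target stays within 25% across levels
  expect_lt(max(abs(target$median - target$median[1])) / target$median[1],
            0.25)
  # spread at level 0 is exactly zero (deterministic), grows with level
  expect_equal(target$var[1], 0)
  expect_gt(target$var[3], target$var[2])
  # untargeted components stay near zero at moderate noise and clearly
  # below the target everywhere
  spurious <- s[s$component %in% c(1, 3), ]
  expect_lt(max(spurious$median[spurious$level <= 1]), 0.25)
  for (lv in unique(s$level))
    expect_gt(target$median[target$level == lv],
              2 * max(spurious$median[spurious$level == lv]))
})

test_that("parameter uncertainty inflates AUC spread faster than noise", {
  fx <- motif_noise_fixture()
  m <- fx$model
  hw <- 0.15 * m$parameters   # 15% relative confidence half-widths
  pstudy <- param_study_config(m$parameters, hw, noise_levels = c(0, 1),
                               n_samples = 8, seed = 13)
  pres <- run_param_study(m, fx$input, fx$data, fx$cfg,
                          fx$grid, pstudy, control = fx$ctl)
  ps <- pres$summaries
  # level 0 reproduces a single deterministic fit for every component
  expect_equal(max(ps$var[ps$level == 0]), 0)
  # at level 1 the dominant component keeps its rank in most samples
  lv1 <- pres$samples[pres$samples$level == 1, ]
  ranks_ok <- vapply(split(lv1, lv1$sample), function(d)
    d$component[which.max(d$auc)] == 2L, logical(1))
  expect_gte(mean(ranks_ok), 0.9)
  # parameter error inflates the target AUC spread faster than the same
  # level of measurement noise
  nres <- run_noise_study(fx$model, fx$input, fx$data, fx$cfg, fx$grid,
                          noise_study_config(1, n_samples = 8, seed = 13),
                          control = fx$ctl)
  v_param <- ps$var[ps$level == 1 & ps$component == 2]
  v_noise <- nres$summaries$var[nres$summaries$component == 2]
  expect_gt(v_param, v_noise)
})
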