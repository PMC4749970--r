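make_auc <- function(per) {
  # auc_table from raw per-component values via a constant trajectory
  gr <- control_grid(c(0, 1), 4)
  w <- hidden_input_trajectory(gr, matrix(rep(per, each = 5), 5))
  compute_auc(w)
}

test_that("compute_auc matches rectangles and a fine-grid oracle", {
  gr <- control_grid(c(0, 5), 10)
  w <- hidden_input_trajectory(gr, matrix(2, 11, 1))
  expect_equal(unname(compute_auc(w)$per_component), 10)

  w0 <- hidden_input_trajectory(gr, matrix(0, 11, 3))
  a0 <- compute_auc(w0)
  expect_true(a0$all_zero)
  expect_true(all(is.na(a0$fractions)))

  set.seed(9)
  vals <- matrix(rnorm(21 * 2), 21, 2)
  gr2 <- control_grid(c(0, 3), 20)
  w2 <- hidden_input_trajectory(gr2, vals)
  tt <- seq(0, 3, length.out = 100001)
  wt <- eval_hidden_input(w2, tt)
  oracle <- colSums((abs(wt[-1, ]) + abs(wt[-nrow(wt), ])) / 2 * diff(tt))
  expect_equal(unname(compute_auc(w2)$per_component), unname(oracle),
               tolerance = 1e-6)
})

test_that("identify_targets returns the minimal dominating prefix", {
  t1 <- identify_targets(make_auc(c(0.90, 0.06, 0.04)), truth = 1L)
  expect_equal(t1$nodes, 1L)
  expect_true(t1$recovered)
  expect_gte(t1$cumulative_fraction, 0.85)

  t2 <- identify_targets(make_auc(c(0.50, 0.45, 0.05)))
  expect_equal(sort(t2$nodes), c(1L, 2L))
  expect_equal(t2$cumulative_fraction, 0.95, tolerance = 1e-9)

  expect_length(identify_targets(make_auc(c(0, 0, 0)))$nodes, 0L)

  # ties break to the lower index
  t3 <- identify_targets(make_auc(c(0.3, 0.4, 0.3)), criterion = 0.65)
  expect_equal(t3$nodes, c(2L, 1L))
})

test_that("identify_targets minimality agrees with exhaustive search", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(3:6, 1)
    per <- runif(n)
    crit <- runif(1, 0.5, 0.95)
    got <- identify_targets(make_auc(per), criterion = crit)
    frac <- per / sum(per)
    # brute force: smallest cardinality subset reaching the criterion
    best_k <- min(vapply(seq_len(n), function(k) {
      combs <- utils::combn(n, k)
      if (any(colSums(matrix(frac[combs], k)) >= crit - 1e-12)) k else n + 1L
    }, numeric(1)))
    expect_length(got$nodes, best_k)
    expect_gte(sum(frac[got$nodes]), crit - 1e-12)
  }
})

test_that("pair recovery demands exact set equality", {
  a <- make_auc(c(0.05, 0.55, 0.40))
  t_pair <- identify_targets(a, truth = c(2L, 1L))
  expect_equal(sort(t_pair$nodes), c(2L, 3L))
  expect_false(t_pair$recovered)       # one matching node is not enough
  expect_equal(t_pair$truth_fraction, 0.60, tolerance = 1e-9)
})

test_that("thresholding masks small components and does not hurt the fit", {
  m <- motif_models()$chain
  u <- step_input()
  ts <- seq(0, 10, 0.5)
  truth <- generate_truth(m, u, hidden_input_spec(2L, "pulse", 0.5,
                                                  onset = 2, offset = 7),
                          ts, noise_sd = "relative", noise_rel = 0.03,
                          seed = 4)
  cfg <- reg_config(0.05, 0.005)
  gr <- test_grid()
  ctl <- list(maxit = 600, factr = 1e8)
  sol <- solve_den(m, u, truth$measurements, cfg, gr, control = ctl)
  ref <- threshold_and_refit(m, u, truth$measurements, cfg, gr, sol,
                             auc_fraction_cutoff = 0.05, control = ctl)
  auc0 <- compute_auc(sol$hidden_input)
  auc1 <- compute_auc(ref$hidden_input)
  # thresholding never increases the number of nonzero components
  expect_lte(sum(auc1$per_component > 0), sum(auc0$per_component > 0))
  # masked components are exactly zero
  expect_true(all(ref$hidden_input$values[, ref$zero_mask] == 0))
  # the state estimate does not degrade
  sc0 <- score_reconstruction(truth, sol)
  sc1 <- score_reconstruction(truth, ref)
  expect_lte(max(sc1$state_discrepancy), max(sc0$state_discrepancy) * 1.1)
})

test_that("thresholding with no small components changes nothing material", {
  m <- motif_models()$chain
  u <- step_input()
  ts <- seq(0, 10, 0.5)
  data <- noiseless_data(m, u, ts, hidden = function(t) c(0, 0.5, 0))
  cfg <- reg_config(0.02, 0.002)
  gr <- test_grid()
  sol <- solve_den(m, u, data, cfg, gr)
  ref <- threshold_and_refit(m, u, data, cfg, gr, sol,
                             auc_fraction_cutoff = 0.01)
  expect_equal(ref$objective$total, sol$objective$total, tolerance = 1e-4)
})

test_that("excluding the true node of an observable error is not acceptable", {
  m <- motif_models()$chain
  u <- step_input()
  ts <- seq(0, 10, 0.5)
  data <- noiseless_data(m, u, ts,
                         hidden = function(t) c(0, 0.5 * (t > 2 & t < 7), 0))
  cfg <- reg_config(0.02, 0.002)
  gr <- test_grid()
  primary <- solve_den(m, u, data, cfg, gr)
  ptargets <- identify_targets(compute_auc(primary$hidden_input))
  expect_equal(ptargets$nodes, 2L)
  alts <- explore_alternatives(m, u, data, cfg, gr, primary)
  excl_true <- Filter(function(a) identical(a$excluded_nodes, 2L), alts)
  expect_length(excl_true, 1L)
  expect_false(excl_true[[1]]$acceptable)
  expect_gt(excl_true[[1]]$fit_ratio, 1.25)
})

test_that("recovery matrix flags output-invisible nodes and recovers the rest", {
  m <- motif_models()$symmetric
  u <- step_input()
  gen <- function(nodes, seed)
    generate_truth(m, u,
                   hidden_input_spec(nodes, "pulse",
                                     amplitude = 0.5, onset = 2, offset = 7),
                   seq(0, 10, 0.5), noise_sd = rep(0, m$n_outputs),
                   seed = seed)
  # node 2 and 3 are mutually unobservable; 1 and 4 are well determined
  rm <- recovery_matrix(m, u, reg_config(0.02, 0.002), test_grid(),
                        node_sets = list(1L, 4L, 2L),
                        truth_generator = gen, seed = 1)
  tab <- rm$table
  expect_equal(tab$recovered[tab$true_nodes == "1"], TRUE)
  expect_equal(tab$recovered[tab$true_nodes == "4"], TRUE)
  # the symmetric branch splits across both confusable nodes
  expect_false(tab$recovered[tab$true_nodes == "2"])
  expect_equal(tab$predicted_nodes[tab$true_nodes == "2"], "2,3")
})
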