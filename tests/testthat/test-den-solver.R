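test_that("weighted_sse matches a naive double-loop oracle", {
  set.seed(7)
  ts <- seq(0, 4, 1)
  Y <- matrix(rnorm(10), 5, 2)
  W <- lapply(1:5, function(i) {
    M <- matrix(rnorm(4), 2); crossprod(M) + diag(2)
  })
  data <- measurement_set(ts, Y, weights = W)
  fitted <- matrix(rnorm(10), 5, 2)
  oracle <- 0
  for (i in 1:5) for (j in 1:2) for (k in 1:2)
    oracle <- oracle + (Y[i, j] - fitted[i, j]) * W[[i]][j, k] *
      (Y[i, k] - fitted[i, k])
  expect_equal(weighted_sse(data, fitted), oracle, tolerance = 1e-12)
  # trivial cases
  expect_equal(weighted_sse(data, Y), 0)
  d1 <- measurement_set(c(0, 1), rbind(c(3, 4), c(0, 0)))
  expect_equal(weighted_sse(d1, matrix(0, 2, 2)), 25)
})

test_that("penalty quadrature agrees with a fine-grid trapezoid oracle", {
  gr <- control_grid(c(0, 2), 50)
  cfg <- reg_config(lambda1 = 1.5, lambda2 = 0.7)
  set.seed(3)
  vals <- matrix(rnorm(51 * 2), 51, 2)   # sign changes inside intervals too
  w <- hidden_input_trajectory(gr, vals)
  tt <- seq(0, 2, length.out = 100001)
  wt <- eval_hidden_input(w, tt)
  trap <- function(f) sum((f[-1] + f[-length(f)]) / 2 * diff(tt))
  l1_o <- 1.5 * sum(apply(abs(wt), 2, trap))
  l2_o <- 0.7 * sum(apply(wt^2, 2, trap))
  pen <- penalty(w, cfg)
  expect_equal(pen[["l1_term"]], l1_o, tolerance = 1e-7)
  expect_equal(pen[["l2_term"]], l2_o, tolerance = 1e-6)
  # exact simple cases
  w0 <- hidden_input_trajectory(gr, matrix(0, 51, 2))
  expect_equal(unname(penalty(w0, cfg)), c(0, 0))
  wc <- hidden_input_trajectory(control_grid(c(0, 2), 10),
                                matrix(1, 11, 1))
  expect_equal(unname(penalty(wc, reg_config(1, 1))), c(2, 2))
})

test_that("noiseless nominal data yield an essentially zero hidden input", {
  u <- step_input()
  ts <- seq(0, 10, 0.5)
  for (m in motif_models(c("chain", "feedforward"))) {
    data <- noiseless_data(m, u, ts)
    sol <- solve_den(m, u, data, reg_config(0.01, 0.001), test_grid())
    expect_solution_ok(sol)
    auc <- compute_auc(sol$hidden_input)
    yscale <- max(abs(data$observations))
    expect_lt(auc$total, 1e-4 * yscale)
    expect_lt(sol$objective$fit_term, 1e-6)
  }
})

test_that("ridge limit matches an independent quadratic-program oracle", {
  m <- scalar_linear_model()
  ts <- seq(0, 5, 0.1)
  truth <- simulate_model(m, NULL, ts, hidden_input = function(t) 0.5)
  data <- measurement_set(ts, truth$outputs)
  gr <- control_grid(c(0, 5), 50)
  lambda2 <- 1e-3
  cfg <- reg_config(lambda1 = 0, lambda2 = lambda2)
  sol <- solve_den(m, NULL, data, cfg, gr,
                   control = list(factr = 1e2, maxit = 20000, pgtol = 1e-9,
                                  lmm = 40))
  expect_solution_ok(sol)

  # oracle: ridge regression on the discretised linear dynamics.  The map
  # from knot values to outputs is linear; build it column by column with
  # the adaptive integrator (independent of the solver's transcription),
  # with the hat-basis mass matrix as the ridge metric.
  kn <- gr$knots
  nK <- length(kn)
  base <- simulate_model(m, NULL, ts)
  G <- matrix(0, length(ts), nK)
  for (j in seq_len(nK)) {
    e <- numeric(nK); e[j] <- 1
    wj <- hidden_input_trajectory(gr, matrix(e, ncol = 1))
    simj <- simulate_model(m, NULL, ts, hidden_input = wj,
                           initial_state = 0)
    G[, j] <- simj$outputs[, 1]
  }
  h <- diff(kn)
  M <- matrix(0, nK, nK)
  for (j in seq_len(nK - 1)) {
    M[j, j] <- M[j, j] + h[j] / 3
    M[j + 1, j + 1] <- M[j + 1, j + 1] + h[j] / 3
    M[j, j + 1] <- M[j, j + 1] + h[j] / 6
    M[j + 1, j] <- M[j + 1, j] + h[j] / 6
  }
  rhs <- crossprod(G, data$observations[, 1] - base$outputs[, 1])
  w_oracle <- solve(crossprod(G) + lambda2 * M, rhs)
  expect_equal(drop(sol$hidden_input$values), drop(w_oracle),
               tolerance = 1e-4)
  # the interior of the estimate sits within 5% of the true constant input
  interior <- kn > 0.75 & kn < 4.25
  expect_lt(max(abs(sol$hidden_input$values[interior, 1] - 0.5)), 0.025)
})

test_that("a large enough lambda1 forces the hidden input to zero", {
  m <- motif_models()$chain
  u <- step_input()
  ts <- seq(0, 10, 0.5)
  data <- noiseless_data(m, u, ts,
                         hidden = function(t) c(0, 0.3, 0))
  gr <- test_grid()
  sol <- solve_den(m, u, data, reg_config(1e4, 0.001), gr)
  expect_equal(max(abs(sol$hidden_input$values)), 0)
  # the misfit then equals the nominal model's weighted residual
  nom <- simulate_model(m, u, ts)
  expect_equal(sol$objective$fit_term, weighted_sse(data, nom$outputs),
               tolerance = 1e-6)
  # and w = 0 is optimal against random feasible perturbations
  ev0 <- sol$objective$total
  set.seed(5)
  for (i in 1:5) {
    wpert <- hidden_input_trajectory(
      gr, matrix(rnorm(41 * 3, sd = 0.05), 41, 3))
    fitp <- weighted_sse(data, simulate_model(
      m, u, ts, hidden_input = wpert)$outputs)
    penp <- penalty(wpert, reg_config(1e4, 0.001))
    expect_gt(fitp + sum(penp), ev0)
  }
})

test_that("objective breakdown is additive and masked components stay zero", {
  m <- motif_models()$feedback
  u <- step_input()
  ts <- seq(0, 10, 0.5)
  data <- noiseless_data(m, u, ts, hidden = function(t) c(0, 0.4, 0.2))
  sol <- solve_den(m, u, data, reg_config(0.02, 0.002), test_grid(),
                   zero_mask = c(1L, 3L))
  expect_solution_ok(sol)
  expect_equal(max(abs(sol$hidden_input$values[, c(1, 3)])), 0)
  expect_gt(max(abs(sol$hidden_input$values[, 2])), 0)
})

test_that("repeated solves with identical inputs are bit-identical", {
  m <- motif_models()$chain
  u <- step_input()
  ts <- seq(0, 10, 1)
  data <- noiseless_data(m, u, ts, hidden = function(t) c(0, 0.3, 0))
  cfg <- reg_config(0.02, 0.002)
  s1 <- solve_den(m, u, data, cfg, test_grid(), seed = 1)
  s2 <- solve_den(m, u, data, cfg, test_grid(), seed = 1)
  expect_identical(s1$hidden_input$values, s2$hidden_input$values)
  expect_identical(s1$objective$total, s2$objective$total)
})

test_that("the reported observer trajectory reproduces from the estimate", {
  m <- motif_models()$chain
  u <- step_input()
  ts <- seq(0, 10, 0.5)
  data <- noiseless_data(m, u, ts, hidden = function(t) c(0.2, 0, 0))
  sol <- solve_den(m, u, data, reg_config(0.01, 0.001), test_grid())
  re <- simulate_model(m, u, sol$state_estimate$times,
                       hidden_input = sol$hidden_input,
                       initial_state = sol$initial_state)
  expect_equal(re$states, sol$state_estimate$states, tolerance = 1e-8)
  # and the transcription agrees with the adaptive integrator
  expect_lt(sol$diagnostics$transcription_gap, 1e-5)
})

test_that("doubling the control resolution barely moves the AUC", {
  m <- motif_models()$chain
  u <- step_input()
  ts <- seq(0, 10, 0.5)
  data <- noiseless_data(m, u, ts,
                         hidden = function(t)
                           c(0, 0.5 * (t > 2 & t < 7), 0))
  cfg <- reg_config(0.01, 0.001)
  s1 <- solve_den(m, u, data, cfg, control_grid(c(0, 10), 40))
  s2 <- solve_den(m, u, data, cfg, control_grid(c(0, 10), 80))
  a1 <- compute_auc(s1$hidden_input)$per_component
  a2 <- compute_auc(s2$hidden_input)$per_component
  expect_lt(abs(a1[2] - a2[2]) / a2[2], 0.05)
})

test_that("free initial state with a delta0 tolerance recovers a shifted start", {
  m <- motif_models()$chain
  u <- step_input()
  ts <- seq(0, 10, 0.5)
  x0_true <- c(0.3, 0.1, 0.2)
  sim <- simulate_model(m, u, ts, initial_state = x0_true)
  data <- measurement_set(ts, sim$outputs)
  cfg <- reg_config(0.05, 0.005, delta0 = 0.05,
                    initial_state_policy = "free-with-delta0-constraint")
  sol <- solve_den(m, u, data, cfg, test_grid())
  expect_true(sol$objective$solver_status %in% c("optimal", "max-iter"))
  expect_lt(max(abs(sol$initial_state - x0_true)), 0.05)
  r1 <- sol$fitted_outputs[1, ] - data$observations[1, ]
  expect_lte(drop(crossprod(r1, data$weights[[1]] %*% r1)),
             cfg$delta0^2 + 1e-6)
})

test_that("select_lambdas returns single-point grids and monotone paths", {
  m <- scalar_linear_model()
  ts <- seq(0, 5, 0.25)
  truth <- simulate_model(m, NULL, ts, hidden_input = function(t) 0.4)
  data <- measurement_set(ts, truth$outputs)
  gr <- control_grid(c(0, 5), 25)
  one <- select_lambdas(m, NULL, data, gr, 0.3, 0.01)
  expect_equal(one$lambda1, 0.3)
  expect_equal(one$lambda2, 0.01)

  path <- select_lambdas(m, NULL, data, gr,
                         lambda1_grid = 10^seq(-3, 1, length.out = 5),
                         lambda2_grid = 0.01)$path
  path <- path[order(path$lambda1), ]
  expect_true(all(diff(path$fit_term) >= -1e-6))
  expect_true(all(diff(path$l1_norm) <= 1e-6))
})

test_that("discrete-adjoint gradients match finite differences", {
  set.seed(17)
  m <- motif_models()$feedback
  u <- step_input()
  ts <- seq(0, 10, 1)
  data <- noiseless_data(m, u, ts, hidden = function(t) c(0, 0.3, 0.1))
  gr <- control_grid(c(0, 10), 10)
  tr <- dynelnet:::build_transcription(m, u, data, gr, nsub = 2L)
  p <- m$parameters
  nK <- tr$nK
  Wm <- matrix(rnorm(nK * 3, sd = 0.2), nK, 3)
  x0 <- m$initial_state
  fit_of <- function(Wm, x0) {
    fw <- dynelnet:::forward_rk4(m, tr, Wm, x0, p)
    fit <- 0
    for (i in seq_along(data$sample_times)) {
      yh <- m$output_function(0, fw$X[tr$sample_idx[i], ], numeric(0), p)
      r <- yh - data$observations[i, ]
      fit <- fit + sum(r * (data$weights[[i]] %*% r))
    }
    fit
  }
  fw <- dynelnet:::forward_rk4(m, tr, Wm, x0, p)
  meas_grad <- vector("list", tr$S)
  for (i in seq_along(data$sample_times)) {
    gi <- tr$sample_idx[i]
    x <- fw$X[gi, ]
    r <- m$output_function(0, x, numeric(0), p) - data$observations[i, ]
    g <- drop(crossprod(m$output_jacobian(0, x, numeric(0), p),
                        2 * (data$weights[[i]] %*% r)))
    meas_grad[[gi]] <- if (is.null(meas_grad[[gi]])) g else meas_grad[[gi]] + g
  }
  rv <- dynelnet:::reverse_rk4(m, tr, Wm, fw, p, meas_grad)
  eps <- 1e-6
  for (trial in 1:6) {
    j <- sample(nK, 1); k <- sample(3, 1)
    Wp <- Wm; Wp[j, k] <- Wp[j, k] + eps
    Wn <- Wm; Wn[j, k] <- Wn[j, k] - eps
    fd <- (fit_of(Wp, x0) - fit_of(Wn, x0)) / (2 * eps)
    expect_equal(rv$Gw[j, k], fd, tolerance = 1e-6)
  }
  x0p <- x0; x0p[2] <- x0p[2] + eps
  x0n <- x0; x0n[2] <- x0n[2] - eps
  fd0 <- (fit_of(Wm, x0p) - fit_of(Wm, x0n)) / (2 * eps)
  expect_equal(rv$x0bar[2], fd0, tolerance = 1e-6)
})
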