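# Shared fixtures: small models, inputs and data sets built in code.

step_input <- function(t_end = 10, value = 1) {
  constant_input(value, c(0, t_end))
}

# scalar linear benchmark dx/dt = -x + w, y = x
scalar_linear_model <- function() {
  ode_model(
    odes = list(x = quote(-k * x)),
    outputs = list(y = quote(x)),
    parameters = c(k = 1),
    initial_state = 1,
    input_names = character(),
    name = "scalar_linear"
  )
}

# noise-free measurements of a model driven by a known hidden input
noiseless_data <- function(model, input, ts, hidden = NULL) {
  sim <- simulate_model(model, input, ts, hidden_input = hidden)
  measurement_set(ts, sim$outputs, output_labels = model$output_labels)
}

# small solver settings used across tests (41-knot grid, default elsewhere)
test_grid <- function(t_end = 10, n = 40) control_grid(c(0, t_end), n)

expect_solution_ok <- function(sol) {
  expect_s3_class(sol, "den_solution")
  expect_true(sol$objective$solver_status %in% c("optimal", "max-iter"))
  ob <- sol$objective
  expect_equal(ob$total, ob$fit_term + ob$l1_term + ob$l2_term,
               tolerance = 1e-9)
}
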