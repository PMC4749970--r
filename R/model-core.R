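#' Define a nominal ODE model
#'
#' An `ode_model` bundles the right-hand side of a nominal system
#' dx/dt = f(x, u, t; p), an output map y = h(x; p), an initial state and
#' parameter values.  Models are declared symbolically: one R expression per
#' state derivative and per output, written in terms of the state labels, the
#' input names, the parameter names and `t`.  Symbolic declaration lets the
#' package derive exact Jacobians (used by the estimator's adjoint gradients)
#' and export the model to SBML.
#'
#' @param odes named list of R expressions, one per state; names are the state
#'   labels and define the state order.
#' @param outputs named list of R expressions, one per output; names are the
#'   output labels.  Output expressions may reference states and parameters
#'   only.
#' @param parameters named numeric vector of parameter values.
#' @param initial_state numeric vector, one entry per state (recycled scalar
#'   allowed).  Order follows `odes`.
#' @param input_names character vector naming the known external inputs
#'   referenced by the ODE expressions (possibly empty).
#' @param name short model identifier used in reports.
#' @param conserved optional list of R expressions that are conserved along
#'   trajectories (documentation + testing aid).
#' @param nonnegative_params logical; if `TRUE`, parameter perturbation studies
#'   clip sampled parameters at zero (mass-action rate constants must stay
#'   nonnegative).
#' @return an object of class `ode_model`.
#' @export
ode_model <- function(odes, outputs, parameters, initial_state,
                      input_names = character(), name = "model",
                      conserved = NULL, nonnegative_params = TRUE) {
  stopifnot(is.list(odes), length(odes) >= 1L, !is.null(names(odes)),
            is.list(outputs), length(outputs) >= 1L, !is.null(names(outputs)))
  state_labels <- names(odes)
  output_labels <- names(outputs)
  if (anyDuplicated(state_labels) || anyDuplicated(output_labels))
    stop("state and output labels must be unique", call. = FALSE)
  parameters <- unlist(parameters)
  if (length(parameters) && is.null(names(parameters)))
    stop("parameters must be named", call. = FALSE)
  initial_state <- rep_len(as.numeric(initial_state), length(odes))
  names(initial_state) <- state_labels

  n <- length(odes)
  m <- length(outputs)

  rate_function <- compile_model_exprs(odes, state_labels, input_names,
                                       names(parameters))
  output_function <- compile_model_exprs(outputs, state_labels, character(),
                                         names(parameters))
  # exact Jacobians d f / d x and d h / d x, derived symbolically
  jac_exprs <- lapply(odes, function(e)
    lapply(state_labels, function(s) stats::D(e, s)))
  jac_flat <- unlist(jac_exprs, recursive = FALSE)  # row-major: df_i/dx_j
  rate_jacobian <- compile_model_exprs(jac_flat, state_labels, input_names,
                                       names(parameters),
                                       matrix_dims = c(n, n), byrow = TRUE)
  out_jac_flat <- unlist(lapply(outputs, function(e)
    lapply(state_labels, function(s) stats::D(e, s))), recursive = FALSE)
  output_jacobian <- compile_model_exprs(out_jac_flat, state_labels,
                                         character(), names(parameters),
                                         matrix_dims = c(m, n), byrow = TRUE)

  structure(list(
    name = name,
    n_states = n, n_outputs = m,
    odes = odes, output_exprs = outputs,
    rate_function = rate_function,
    output_function = output_function,
    rate_jacobian = rate_jacobian,
    output_jacobian = output_jacobian,
    initial_state = initial_state,
    parameters = parameters,
    state_labels = state_labels,
    output_labels = output_labels,
    input_names = input_names,
    conserved = conserved,
    nonnegative_params = isTRUE(nonnegative_params)
  ), class = "ode_model")
}

# Compile a list of expressions into a fast function(t, x, u, p).
# Generates source text with states/inputs/parameters unpacked into locals,
# then parses it once; much faster than eval()ing expressions in a list env.
compile_model_exprs <- function(exprs, state_labels, input_names, par_names,
                                matrix_dims = NULL, byrow = FALSE) {
  bind <- c(
    sprintf("%s <- x[%dL]", state_labels, seq_along(state_labels)),
    if (length(input_names))
      sprintf("%s <- u[%dL]", input_names, seq_along(input_names)),
    if (length(par_names))
      sprintf("%s <- p[%dL]", par_names, seq_along(par_names))
  )
  body_exprs <- vapply(exprs, function(e) paste(deparse(e), collapse = " "),
                       character(1))
  combine <- paste0("c(", paste(body_exprs, collapse = ", "), ")")
  if (!is.null(matrix_dims)) {
    combine <- sprintf("matrix(%s, nrow = %dL, ncol = %dL, byrow = %s)",
                       combine, matrix_dims[1], matrix_dims[2],
                       if (byrow) "TRUE" else "FALSE")
  }
  src <- paste0("function(t, x, u, p) {\n",
                paste(bind, collapse = "\n"), "\n", combine, "\n}")
  f <- eval(parse(text = src)[[1]], envir = baseenv())
  compiler::cmpfun(f)
}

#' @export
print.ode_model <- function(x, ...) {
  cat(sprintf("<ode_model '%s': %d states, %d outputs, %d parameters>\n",
              x$name, x$n_states, x$n_outputs, length(x$parameters)))
  cat("  states: ", paste(x$state_labels, collapse = ", "), "\n")
  cat("  outputs:", paste(x$output_labels, collapse = ", "), "\n")
  if (length(x$input_names))
    cat("  inputs: ", paste(x$input_names, collapse = ", "), "\n")
  invisible(x)
}

#' Tabulated known external input
#'
#' Represents the known input u(t) of a model as a tabulated time series with
#' an interpolation rule.  Outside the tabulated range the boundary value is
#' held constant.
#'
#' @param times strictly increasing numeric vector.
#' @param values numeric vector or matrix (`length(times)` rows, one column
#'   per input dimension).
#' @param interpolation `"linear"` (default, piecewise-linear) or
#'   `"constant"` (zero-order hold: the value at the most recent knot).
#' @return an object of class `known_input`; evaluate it with
#'   [eval_input()].
#' @export
known_input <- function(times, values, interpolation = c("linear", "constant")) {
  interpolation <- match.arg(interpolation)
  times <- as.numeric(times)
  if (length(times) < 1L || is.unsorted(times, strictly = TRUE))
    stop("input times must be strictly increasing", call. = FALSE)
  values <- as.matrix(values)
  if (nrow(values) != length(times))
    stop("values must have one row per time", call. = FALSE)
  storage.mode(values) <- "double"
  if (!all(is.finite(values))) stop("input values must be finite", call. = FALSE)
  fns <- lapply(seq_len(ncol(values)), function(j) {
    if (length(times) == 1L) {
      v <- values[1L, j]; function(t) rep(v, length(t))
    } else {
      stats::approxfun(times, values[, j],
                       method = if (interpolation == "linear") "linear" else "constant",
                       rule = 2, f = 0)
    }
  })
  structure(list(times = times, values = values,
                 interpolation = interpolation, fns = fns,
                 dim = ncol(values)),
            class = "known_input")
}

#' Constant known input
#'
#' @param value numeric vector of input values (one per input dimension).
#' @param t_range time interval over which the input is tabulated.
#' @export
constant_input <- function(value, t_range = c(0, 1)) {
  known_input(t_range, matrix(rep(value, each = 2), nrow = 2),
              interpolation = "linear")
}

#' Evaluate a known input at given times
#'
#' @param input a [known_input()] object, or `NULL` (interpreted as zero).
#' @param t numeric vector of times.
#' @param dim input dimension used when `input` is `NULL`.
#' @return numeric matrix `length(t)` x input dimension.
#' @export
eval_input <- function(input, t, dim = 1L) {
  if (is.null(input)) return(matrix(0, length(t), dim))
  vapply(input$fns, function(f) f(t), numeric(length(t))) |>
    matrix(nrow = length(t))
}

# scalar-time fast path returning a plain vector
eval_input1 <- function(input, t, dim = 1L) {
  if (is.null(input)) return(numeric(dim))
  vapply(input$fns, function(f) f(t), numeric(1))
}

# Coerce a hidden-input argument into a vectorised function(t) -> n-vector.
# Accepts NULL (zero), a function, or a hidden_input_trajectory.
as_hidden_fn <- function(hidden_input, n_states) {
  if (is.null(hidden_input)) return(NULL)
  if (inherits(hidden_input, "hidden_input_trajectory")) {
    knots <- hidden_input$grid$knots
    vals <- hidden_input$values
    fns <- lapply(seq_len(ncol(vals)), function(k)
      stats::approxfun(knots, vals[, k], rule = 2))
    return(function(t) vapply(fns, function(f) f(t), numeric(1)))
  }
  if (is.function(hidden_input)) return(hidden_input)
  stop("hidden_input must be NULL, a function of t, or a hidden_input_trajectory",
       call. = FALSE)
}

#' Simulate an ODE model
#'
#' Integrates the initial-value problem for a nominal model with known input
#' `u(t)` and, optionally, an additive hidden input `w(t)` on the state
#' derivatives (the "true system" configuration used by the synthetic
#' benchmarks).  Integration uses `deSolve::ode` with adaptive error control.
#'
#' @param model an [ode_model()].
#' @param input a [known_input()] or `NULL` for zero input.
#' @param t_grid increasing numeric vector of report times.
#' @param hidden_input `NULL`, a function `t -> numeric(n_states)`, or a
#'   `hidden_input_trajectory`; added to the right-hand side.
#' @param initial_state optional override of the model's initial state.
#' @param parameters optional override of the model's parameters.
#' @param rtol,atol integrator tolerances.  Tight defaults so that
#'   integration error is negligible against estimated model error.
#' @param method `deSolve` method (default `"lsoda"`, stiff-capable).
#' @param hmax maximum integrator step.  Defaults to the knot spacing of a
#'   tabulated `hidden_input` (adaptive steps would otherwise overstep the
#'   kinks of the interpolated input), otherwise unrestricted.
#' @return a `simulation_result` with elements `times`, `states`
#'   (grid x n_states) and `outputs` (grid x n_outputs).
#' @export
simulate_model <- function(model, input = NULL, t_grid,
                           hidden_input = NULL, initial_state = NULL,
                           parameters = NULL,
                           rtol = 1e-8, atol = 1e-10, method = "lsoda",
                           hmax = NULL) {
  stopifnot(inherits(model, "ode_model"))
  t_grid <- as.numeric(t_grid)
  if (is.unsorted(t_grid, strictly = TRUE))
    stop("t_grid must be strictly increasing", call. = FALSE)
  if (!is.null(input) && !inherits(input, "known_input"))
    stop("input must be a known_input or NULL", call. = FALSE)
  x0 <- if (is.null(initial_state)) model$initial_state else
    rep_len(as.numeric(initial_state), model$n_states)
  p <- resolve_parameters(model, parameters)
  wfn <- as_hidden_fn(hidden_input, model$n_states)
  if (is.null(hmax)) {
    hmax <- if (inherits(hidden_input, "hidden_input_trajectory"))
      min(diff(hidden_input$grid$knots)) else NULL
  }
  nin <- max(1L, length(model$input_names))

  deriv <- function(t, x, parms) {
    u <- eval_input1(input, t, dim = nin)
    dx <- model$rate_function(t, x, u, p)
    if (!is.null(wfn)) dx <- dx + wfn(t)
    list(dx)
  }
  sol <- if (is.null(hmax)) {
    deSolve::ode(y = as.numeric(x0), times = t_grid, func = deriv,
                 parms = NULL, method = method, rtol = rtol, atol = atol)
  } else {
    deSolve::ode(y = as.numeric(x0), times = t_grid, func = deriv,
                 parms = NULL, method = method, rtol = rtol, atol = atol,
                 hmax = hmax)
  }
  if (attr(sol, "istate")[1L] < 0 || nrow(sol) < length(t_grid)) {
    last_t <- sol[nrow(sol), 1L]
    stop(sprintf("integration failed (last reached time %g of %g)",
                 last_t, t_grid[length(t_grid)]), call. = FALSE)
  }
  states <- unname(sol[, -1L, drop = FALSE])
  outputs <- model_outputs(model, states, p)
  structure(list(times = t_grid, states = states, outputs = outputs,
                 state_labels = model$state_labels,
                 output_labels = model$output_labels),
            class = "simulation_result")
}

# apply the output map row-wise
model_outputs <- function(model, states, p = model$parameters) {
  res <- apply(states, 1L, function(x)
    model$output_function(0, x, numeric(0), p))
  if (model$n_outputs == 1L) matrix(res, ncol = 1L) else t(res)
}

resolve_parameters <- function(model, parameters) {
  p <- model$parameters
  if (is.null(parameters)) return(p)
  parameters <- unlist(parameters)
  if (is.null(names(parameters)) && length(parameters) == length(p)) {
    names(parameters) <- names(p)
    return(parameters)
  }
  unknown <- setdiff(names(parameters), names(p))
  if (length(unknown))
    stop("unknown parameters: ", paste(unknown, collapse = ", "), call. = FALSE)
  p[names(parameters)] <- parameters
  p
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result: %d times, %d states, %d outputs on [%g, %g]>\n",
              length(x$times), ncol(x$states), ncol(x$outputs),
              x$times[1], x$times[length(x$times)]))
  invisible(x)
}

#' Time-course measurements of the model outputs
#'
#' Holds output observations at discrete sample times together with the
#' weighting matrices W_i of the weighted square norm used in the misfit term.
#' When per-point standard deviations are supplied the default weighting is
#' diagonal 1/sd^2 (precision weighting); otherwise the identity is used.
#'
#' @param sample_times strictly increasing numeric vector (N >= 2).
#' @param observations numeric matrix N x n_outputs.
#' @param sds optional N x n_outputs matrix (or vector of length n_outputs)
#'   of measurement standard deviations.
#' @param weights optional list of N symmetric positive-semidefinite
#'   n_outputs x n_outputs matrices, overriding the sd-derived default.
#' @param output_labels optional column labels.
#' @return an object of class `measurement_set`.
#' @export
measurement_set <- function(sample_times, observations, sds = NULL,
                            weights = NULL, output_labels = NULL) {
  sample_times <- as.numeric(sample_times)
  observations <- as.matrix(observations)
  storage.mode(observations) <- "double"
  N <- length(sample_times)
  m <- ncol(observations)
  if (N < 2L) stop("need at least two sample times", call. = FALSE)
  if (is.unsorted(sample_times, strictly = TRUE))
    stop("sample times must be strictly increasing", call. = FALSE)
  if (nrow(observations) != N)
    stop("observations must have one row per sample time", call. = FALSE)
  if (!is.null(sds)) {
    if (is.vector(sds) && length(sds) == m)
      sds <- matrix(sds, N, m, byrow = TRUE)
    sds <- as.matrix(sds)
    stopifnot(nrow(sds) == N, ncol(sds) == m)
    if (any(sds < 0)) stop("sds must be nonnegative", call. = FALSE)
  }
  if (is.null(weights)) {
    weights <- if (is.null(sds)) {
      rep(list(diag(m)), N)
    } else {
      lapply(seq_len(N), function(i) {
        s <- sds[i, ]
        s[s <= 0] <- 1  # zero sd means exact point: fall back to unit weight
        diag(1 / s^2, nrow = m)
      })
    }
  } else {
    stopifnot(is.list(weights), length(weights) == N)
    for (W in weights) {
      W <- as.matrix(W)
      if (!isTRUE(all.equal(W, t(W), tolerance = 1e-10)))
        stop("weight matrices must be symmetric", call. = FALSE)
    }
    weights <- lapply(weights, as.matrix)
  }
  if (is.null(output_labels)) {
    output_labels <- colnames(observations)
    if (is.null(output_labels)) output_labels <- paste0("y", seq_len(m))
  }
  colnames(observations) <- output_labels
  structure(list(sample_times = sample_times, observations = observations,
                 weights = weights, sds = sds, n_outputs = m,
                 output_labels = output_labels),
            class = "measurement_set")
}

#' @export
print.measurement_set <- function(x, ...) {
  cat(sprintf("<measurement_set: %d samples x %d outputs on [%g, %g]%s>\n",
              length(x$sample_times), x$n_outputs, x$sample_times[1],
              x$sample_times[length(x$sample_times)],
              if (is.null(x$sds)) ", identity weights" else ", 1/sd^2 weights"))
  invisible(x)
}

#' Linearise a model at a state point
#'
#' Returns the Jacobian pair (A, C) of the rate and output maps, used e.g.
#' for observability rank checks of the built-in motifs.
#'
#' @param model an [ode_model()].
#' @param x state point (defaults to the initial state).
#' @param u input value (defaults to zero).
#' @return list with matrices `A` (n x n) and `C` (m x n).
#' @export
linearise_model <- function(model, x = model$initial_state, u = NULL) {
  nin <- max(1L, length(model$input_names))
  if (is.null(u)) u <- numeric(nin)
  p <- model$parameters
  list(A = model$rate_jacobian(0, x, u, p),
       C = model$output_jacobian(0, x, numeric(0), p))
}
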