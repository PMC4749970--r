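#' Configuration of a measurement-noise robustness study
#'
#' @param noise_levels nonnegative multiples of the empirical measurement
#'   standard deviation (sorted ascending).
#' @param n_samples perturbed data sets per level (reference studies use 500;
#'   desk-scale runs use fewer).
#' @param seed master seed; per-sample seeds are derived deterministically.
#' @export
noise_study_config <- function(noise_levels, n_samples = 500L, seed = 1L) {
  noise_levels <- sort(as.numeric(noise_levels))
  stopifnot(all(noise_levels >= 0), n_samples >= 1L)
  structure(list(noise_levels = noise_levels,
                 n_samples = as.integer(n_samples), seed = as.integer(seed)),
            class = "noise_study_config")
}

#' Configuration of a parameter-uncertainty robustness study
#'
#' Parameters are drawn uniformly from `point +/- level * half-width`, the
#' interval obtained by scaling each parameter's confidence-interval
#' half-width by the noise level.
#'
#' @param param_point named numeric vector of nominal parameter values.
#' @param param_ci_halfwidths named nonnegative numeric vector; every
#'   parameter in `param_point` needs a half-width.
#' @param noise_levels scaling factors applied to the half-widths.
#' @param n_samples draws per level.
#' @param seed master seed.
#' @export
param_study_config <- function(param_point, param_ci_halfwidths,
                               noise_levels, n_samples = 500L, seed = 1L) {
  stopifnot(!is.null(names(param_point)),
            all(names(param_point) %in% names(param_ci_halfwidths)) ||
              all(names(param_ci_halfwidths) %in% names(param_point)))
  hw <- param_ci_halfwidths[names(param_point)]
  if (anyNA(hw)) stop("every parameter needs a confidence half-width", call. = FALSE)
  if (any(hw < 0)) stop("half-widths must be nonnegative", call. = FALSE)
  structure(list(param_point = param_point, param_ci_halfwidths = hw,
                 noise_levels = sort(as.numeric(noise_levels)),
                 n_samples = as.integer(n_samples), seed = as.integer(seed)),
            class = "param_study_config")
}

#' Perturb measurements with scaled Gaussian noise
#'
#' Adds independent Gaussian noise with standard deviation
#' `level * sd_(i,j)` to every data point, where `sd` are the empirical
#' per-point standard deviations stored in the measurement set.  Times and
#' weights are unchanged; the same seed reproduces the same perturbation.
#'
#' @param data a [measurement_set()] with `sds`.
#' @param level nonnegative noise level (multiple of the empirical sd).
#' @param seed integer seed.
#' @return a perturbed [measurement_set()].
#' @export
perturb_measurements <- function(data, level, seed = 1L) {
  stopifnot(inherits(data, "measurement_set"), level >= 0)
  if (is.null(data$sds))
    stop("perturb_measurements needs empirical standard deviations (sds)",
         call. = FALSE)
  if (level == 0) return(data)
  noise <- with_seed(seed, matrix(stats::rnorm(length(data$observations)),
                                  nrow(data$observations)))
  out <- data
  out$observations <- data$observations + level * data$sds * noise
  out
}

#' Draw a perturbed parameter vector
#'
#' @param cfg a [param_study_config()].
#' @param level scaling of the confidence half-widths.
#' @param seed integer seed.
#' @param clip_nonnegative clip draws at zero (used for mass-action rate
#'   constants); clipped draws are flagged in the `"clipped"` attribute.
#' @return named numeric parameter vector.
#' @export
perturb_parameters <- function(cfg, level, seed = 1L, clip_nonnegative = TRUE) {
  stopifnot(inherits(cfg, "param_study_config"), level >= 0)
  p <- cfg$param_point
  if (level == 0) {
    attr(p, "clipped") <- rep(FALSE, length(p))
    return(p)
  }
  hw <- level * cfg$param_ci_halfwidths
  draw <- with_seed(seed, stats::runif(length(p), p - hw, p + hw))
  names(draw) <- names(p)
  clipped <- rep(FALSE, length(p))
  if (clip_nonnegative) {
    clipped <- draw < 0
    draw[clipped] <- 0
  }
  attr(draw, "clipped") <- clipped
  draw
}

# shared machinery of the two robustness studies
run_robustness <- function(model, input, data, cfg, grid, levels, n_samples,
                           seed, make_task, control) {
  records <- list()
  failures <- list()
  for (li in seq_along(levels)) {
    level <- levels[li]
    for (s in seq_len(n_samples)) {
      seed_i <- derive_seed(seed, li * 100000L + s)
      rec <- tryCatch({
        task <- make_task(level, seed_i)
        sol <- solve_den(task$model, input, task$data, cfg, grid,
                         seed = seed_i, control = control)
        auc <- compute_auc(sol$hidden_input)
        data.frame(level = level, sample = s,
                   component = seq_along(auc$per_component),
                   label = names(auc$per_component),
                   auc = unname(auc$per_component))
      }, error = function(e) {
        failures[[length(failures) + 1L]] <<-
          data.frame(level = level, sample = s, error = conditionMessage(e))
        NULL
      })
      if (!is.null(rec)) records[[length(records) + 1L]] <- rec
    }
  }
  long <- do.call(rbind, records)
  summaries <- do.call(rbind, lapply(split(
    long, list(long$level, long$component), drop = TRUE), function(d)
      data.frame(level = d$level[1], component = d$component[1],
                 label = d$label[1], n = nrow(d),
                 median = stats::median(d$auc),
                 q25 = unname(stats::quantile(d$auc, 0.25)),
                 q75 = unname(stats::quantile(d$auc, 0.75)),
                 var = stats::var(d$auc))))
  summaries <- summaries[order(summaries$level, summaries$component), ]
  rownames(summaries) <- NULL
  structure(list(samples = long, summaries = summaries,
                 failures = if (length(failures)) do.call(rbind, failures),
                 seed = seed),
            class = "robustness_result")
}

#' @export
print.robustness_result <- function(x, ...) {
  cat(sprintf("<robustness_result: %d fits over %d levels%s>\n",
              length(unique(paste(x$samples$level, x$samples$sample))),
              length(unique(x$samples$level)),
              if (is.null(x$failures)) "" else
                sprintf(", %d failures", nrow(x$failures))))
  print(x$summaries, digits = 4)
  invisible(x)
}

#' Measurement-noise robustness study
#'
#' For each noise level, generates perturbed copies of the data (Gaussian
#' noise scaled by the empirical standard deviations), fits the dynamic
#' elastic-net to each, and records the per-component AUC of the estimated
#' model error.  Summaries report median and quartiles per component per
#' level; solver failures are recorded and excluded.
#'
#' @inheritParams solve_den
#' @param study a [noise_study_config()].
#' @return a `robustness_result` with `samples` (long format: level, sample,
#'   component, auc) and `summaries`.
#' @export
run_noise_study <- function(model, input, data, cfg, grid, study,
                            control = list()) {
  stopifnot(inherits(study, "noise_study_config"))
  run_robustness(model, input, data, cfg, grid, study$noise_levels,
                 study$n_samples, study$seed,
                 make_task = function(level, seed_i)
                   list(model = model,
                        data = perturb_measurements(data, level, seed_i)),
                 control = control)
}

#' Parameter-uncertainty robustness study
#'
#' Analogue of [run_noise_study()] with the nominal parameters perturbed
#' instead of the data: for each level, parameter vectors are drawn uniformly
#' from the scaled confidence intervals, the perturbed model is taken as the
#' nominal model, and the AUC of the resulting error estimates is recorded.
#'
#' @inheritParams solve_den
#' @param study a [param_study_config()].
#' @return a `robustness_result`.
#' @export
run_param_study <- function(model, input, data, cfg, grid, study,
                            control = list()) {
  stopifnot(inherits(study, "param_study_config"))
  run_robustness(model, input, data, cfg, grid, study$noise_levels,
                 study$n_samples, study$seed,
                 make_task = function(level, seed_i) {
                   p <- perturb_parameters(study, level, seed_i,
                                           clip_nonnegative = model$nonnegative_params)
                   m2 <- model
                   m2$parameters <- resolve_parameters(model, p)
                   list(model = m2, data = data)
                 },
                 control = control)
}
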