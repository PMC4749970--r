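#' Select regularisation parameters along a grid
#'
#' Fits the estimator over the Cartesian grid of candidate `lambda1` and
#' `lambda2` values, records misfit and penalty norms for every point, and
#' returns the knee-point choice: the largest `lambda1` (and, among ties, the
#' largest `lambda2`) whose misfit is within `fit_factor` of the minimum
#' misfit over the whole path.  The rule mirrors the usual practice of
#' picking the sparsest/smoothest estimate that does not visibly degrade the
#' fit.
#'
#' @inheritParams solve_den
#' @param lambda1_grid,lambda2_grid nonnegative numeric vectors.
#' @param fit_factor tolerated misfit inflation over the path minimum
#'   (default 1.1).
#' @return list with `lambda1`, `lambda2`, `config` (a [reg_config()]) and
#'   `path` (data frame: lambda1, lambda2, fit_term, l1_norm, l2_norm,
#'   status, selected).
#' @export
select_lambdas <- function(model, input, data, grid,
                           lambda1_grid, lambda2_grid,
                           fit_factor = 1.1, seed = 1L, control = list()) {
  stopifnot(length(lambda1_grid) >= 1L, length(lambda2_grid) >= 1L,
            all(lambda1_grid >= 0), all(lambda2_grid >= 0))
  lambda1_grid <- sort(unique(as.numeric(lambda1_grid)))
  lambda2_grid <- sort(unique(as.numeric(lambda2_grid)))
  combos <- expand.grid(lambda1 = lambda1_grid, lambda2 = lambda2_grid)
  rows <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    cfg <- reg_config(combos$lambda1[i], combos$lambda2[i])
    rows[[i]] <- tryCatch({
      sol <- solve_den(model, input, data, cfg, grid, seed = seed,
                       control = control)
      w <- sol$hidden_input
      data.frame(lambda1 = cfg$lambda1, lambda2 = cfg$lambda2,
                 fit_term = sol$objective$fit_term,
                 l1_norm = sum(basis_l1_integral(grid, w$values)),
                 l2_norm = sum(basis_l2_integral(grid, w$values)),
                 status = sol$objective$solver_status)
    }, error = function(e)
      data.frame(lambda1 = cfg$lambda1, lambda2 = cfg$lambda2,
                 fit_term = NA_real_, l1_norm = NA_real_, l2_norm = NA_real_,
                 status = paste("failed:", conditionMessage(e))))
  }
  path <- do.call(rbind, rows)
  ok <- !is.na(path$fit_term)
  if (!any(ok)) stop("all fits along the regularisation path failed", call. = FALSE)
  fmin <- min(path$fit_term[ok])
  admissible <- ok & path$fit_term <= fit_factor * max(fmin, .Machine$double.eps)
  cand <- path[admissible, ]
  cand <- cand[order(-cand$lambda1, -cand$lambda2), ]
  sel <- cand[1, ]
  path$selected <- path$lambda1 == sel$lambda1 & path$lambda2 == sel$lambda2
  list(lambda1 = sel$lambda1, lambda2 = sel$lambda2,
       config = reg_config(sel$lambda1, sel$lambda2), path = path)
}
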