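# Selection-policy scoring functions and the regression model predicting
# the distance between the input molecule and the eventual solution.

#' Policy scoring functions
#'
#' `score_ucb1()` is the UCT upper confidence bound: the mean `f1` of the
#' vertex's children plus `c * sqrt(ln(N_v) / n_v)`, where `n_v` counts the
#' vertex's expansions and `N_v` its parent's. An unexpanded vertex
#' (`n_v = 0`) scores `+Inf` so it is expanded at least once. A vertex
#' whose expansions produced no children yet falls back to its own `f1` as
#' the mean.
#'
#' `score_astar()` is the A* objective `d(u,v) + 1 - f1(v)` (minimized):
#' distance travelled from the root plus the familiarity-gap heuristic for
#' the remaining distance.
#'
#' `score_mlr()` is the regression prediction of the root-to-solution
#' distance `d(u,w)` from `d(u,v)` and `f1(v)` (minimized).
#'
#' `score_objective()` multiplies `f1` with a user objective in `[0, 1]`
#' (maximized); multiplication prevents the search from sacrificing one
#' objective for the other.
#'
#' @param v a [vertex_stats] list (fields `f1`, `d_root`,
#'   `children_f1_mean`, `n_v`, `N_v`).
#' @param c exploration coefficient (the benchmark optimum is 0.5).
#' @return A numeric score.
#' @export
score_ucb1 <- function(v, c = 0.5) {
  if (v$n_v == 0L) return(Inf)
  mean_f1 <- if (is.null(v$children_f1_mean) || is.na(v$children_f1_mean))
    v$f1 else v$children_f1_mean
  mean_f1 + c * sqrt(log(v$N_v) / v$n_v)
}

#' @rdname score_ucb1
#' @export
score_astar <- function(v) {
  v$d_root + 1 - v$f1
}

#' @rdname score_ucb1
#' @param m an [mlr_model].
#' @export
score_mlr <- function(v, m = default_mlr_model()) {
  m$coef_d * v$d_root + m$coef_f1 * v$f1 + m$intercept
}

#' @rdname score_ucb1
#' @param o_value objective value in `[0, 1]`.
#' @export
score_objective <- function(v, o_value) {
  if (!is.numeric(o_value) || length(o_value) != 1L || is.na(o_value) ||
      o_value < 0 || o_value > 1)
    stop("objective value must lie in [0, 1]")
  v$f1 * o_value
}

#' Linear model predicting the root-to-solution distance
#'
#' The model predicts `d(u,w)` -- the fingerprint distance between the
#' input molecule `u` and the solution `w` -- as
#' `coef_d * d(u,v) + coef_f1 * f1(v) + intercept` for a tree vertex `v`.
#' The default coefficients `(0.42, -0.91, 1.18)` were fit on
#' breadth-first correction runs of randomly perturbed reference molecules;
#' refit with [collect_training_triples] and [fit_mlr] to adapt the model
#' to another dictionary or radius.
#'
#' @param coef_d coefficient of `d(u,v)`.
#' @param coef_f1 coefficient of `f1(v)`.
#' @param intercept intercept.
#' @param rmse in-sample root-mean-squared error, when known.
#' @return An object of class `mlr_model`.
#' @export
mlr_model <- function(coef_d, coef_f1, intercept, rmse = NA_real_) {
  structure(list(coef_d = as.numeric(coef_d), coef_f1 = as.numeric(coef_f1),
                 intercept = as.numeric(intercept), rmse = as.numeric(rmse)),
            class = "mlr_model")
}

#' @rdname mlr_model
#' @export
default_mlr_model <- function() mlr_model(0.42, -0.91, 1.18)

#' @export
print.mlr_model <- function(x, ...) {
  cat(sprintf("<mlr_model> d(u,w) ~ %.4f * d(u,v) %+.4f * f1(v) %+.4f",
              x$coef_d, x$coef_f1, x$intercept))
  if (!is.na(x$rmse)) cat(sprintf("  (RMSE %.4f)", x$rmse))
  cat("\n")
  invisible(x)
}

#' Collect regression training triples from BFS corrections
#'
#' Corrects each input with the BFS policy (continuing after the first
#' solution until the solution level is complete, so the reported solution
#' is the closest one). For every solved input, each vertex `v` on the
#' root-to-solution chain contributes one triple
#' `(d(u,v), f1(v), d(u,w))` where `u` is the root and `w` the solution; a
#' solution at depth `k` yields `k + 1` triples and an already-correct
#' input yields the single triple `(0, 1, 0)`. Unsolved inputs contribute
#' nothing.
#'
#' @param inputs list of [molgraph]s (typically randomly perturbed
#'   molecules).
#' @param d a [chemical_dictionary].
#' @param max_depth,max_tree_size search budgets per input.
#' @return A data.frame with columns `d_uv`, `f1_v`, `d_uw`.
#' @export
collect_training_triples <- function(inputs, d, max_depth = 25L,
                                     max_tree_size = 25000L) {
  assert_dictionary(d)
  out <- vector("list", length(inputs))
  for (i in seq_along(inputs)) {
    res <- correct_molecule(inputs[[i]], d, policy = "bfs",
                            max_depth = max_depth,
                            max_tree_size = max_tree_size,
                            complete_level = TRUE)
    if (res$status != "solved") next
    ps <- res$path_stats
    out[[i]] <- data.frame(d_uv = ps$d_root, f1_v = ps$f1,
                           d_uw = res$d_root)
  }
  out <- out[!vapply(out, is.null, logical(1L))]
  if (length(out) == 0L)
    return(data.frame(d_uv = numeric(0), f1_v = numeric(0), d_uw = numeric(0)))
  do.call(rbind, out)
}

#' Fit the distance-prediction model by ordinary least squares
#'
#' @param triples a data.frame with columns `d_uv`, `f1_v`, `d_uw` (see
#'   [collect_training_triples]).
#' @return An [mlr_model] with the in-sample RMSE filled in.
#' @export
fit_mlr <- function(triples) {
  if (!all(c("d_uv", "f1_v", "d_uw") %in% names(triples)))
    stop("triples must have columns d_uv, f1_v, d_uw")
  if (nrow(triples) < 3L) stop("need at least 3 training triples")
  fit <- lm(d_uw ~ d_uv + f1_v, data = triples)
  cf <- coef(fit)
  if (any(is.na(cf)))
    stop("rank-deficient training data: triples are collinear")
  rmse <- sqrt(mean(fit$residuals^2))
  mlr_model(cf[["d_uv"]], cf[["f1_v"]], cf[["(Intercept)"]], rmse = rmse)
}
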