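# Stability selection for the Cox model: expected-false-discovery budget,
# truncation of the penalty region, subsampled selection probabilities.

#' Expected number of falsely selected variables (upper bound)
#'
#' The finite-sample bound for stability selection with threshold
#' `pi_thr` and average per-fit selection budget `q_lambda`:
#' E(V) <= q_lambda^2 / ((2 pi_thr - 1) p).
#'
#' @param p number of candidate variables.
#' @param pi_thr selection-probability threshold in (0.5, 1).
#' @param q_lambda average number of variables the base learner may select
#'   per fit.
#' @return The bound, a nonnegative number.
#' @export
error_bound <- function(p, pi_thr, q_lambda) {
  if (pi_thr <= 0.5 || pi_thr >= 1)
    stop("'pi_thr' must lie strictly between 0.5 and 1")
  if (q_lambda < 0) stop("'q_lambda' must be nonnegative")
  q_lambda^2 / ((2 * pi_thr - 1) * p)
}

#' Per-fit selection budget from the error bound
#'
#' Inverts the expected-false-discovery bound: the largest integer budget
#' q_lambda consistent with E(V) <= `ev_budget` at threshold `pi_thr` is
#' ceiling(sqrt((2 pi_thr - 1) * ev_budget * p)).
#'
#' @inheritParams error_bound
#' @param ev_budget target bound on the expected count of false selections.
#' @return Integer budget, capped at `p` (with a warning) when the bound is
#'   looser than the full model.
#' @export
q_from_error_bound <- function(p, pi_thr, ev_budget) {
  if (pi_thr <= 0.5 || pi_thr >= 1)
    stop("'pi_thr' must lie strictly between 0.5 and 1")
  if (ev_budget <= 0) stop("'ev_budget' must be positive")
  q <- as.integer(ceiling(sqrt((2 * pi_thr - 1) * ev_budget * p)))
  if (q > p) {
    warning("selection budget exceeds p; capped at p")
    q <- as.integer(p)
  }
  max(q, 1L)
}

#' Truncate the penalty grid at the budgeted model size
#'
#' Walks the full-data lasso-Cox path from the largest penalty downward
#' for as long as the active set stays within the budget: lambda_min is
#' the smallest grid value at which the full-data lasso still selects at
#' most `q_lambda` variables, i.e. the grid is cut just before the active
#' set first exceeds the budget. Only penalties in
#' [lambda_min, lambda_upper] remain candidates for the ensemble. If the
#' path never reaches `q_lambda` variables the full grid is returned with
#' a warning.
#'
#' @param data a [surv_dataset()].
#' @param grid a [lambda_grid()].
#' @param q_lambda positive integer budget, e.g. from [q_from_error_bound()].
#' @return The truncated `lambda_grid`, with elements `lambda_min` and
#'   `q_lambda` recording the truncation.
#' @export
determine_lambda_min <- function(data, grid, q_lambda) {
  stopifnot(inherits(data, "surv_dataset"), inherits(grid, "lambda_grid"))
  if (length(grid$values) == 0L) stop("empty penalty grid")
  q_lambda <- as.integer(q_lambda)
  if (is.na(q_lambda) || q_lambda < 1L) stop("'q_lambda' must be >= 1")
  path <- coxlasso_path(data, grid)
  out <- grid
  if (max(path$sizes) < q_lambda) {
    warning("full-data path never reaches ", q_lambda,
            " active variables; using the full grid")
    out$lambda_min <- grid$values[length(grid$values)]
  } else {
    over <- which(path$sizes > q_lambda)
    cut <- if (length(over)) max(over[1L] - 1L, 1L) else length(grid$values)
    out$values <- grid$values[seq_len(cut)]
    out$lambda_min <- out$values[length(out$values)]
    out$lambda_lower <- out$lambda_min
  }
  out$q_lambda <- q_lambda
  out
}

#' Stability selection for the Cox proportional-hazards model
#'
#' Ensemble variable selection for right-censored survival data. The
#' penalty region is built once on the full data: [lambda_upper()] gives
#' the entry point of the lasso-Cox path, [lambda_grid()] the geometric
#' candidate set, and [determine_lambda_min()] truncates it so that the
#' base learner selects at most about `q_lambda` variables per fit
#' (alternatively an explicit `lambda_min` can be supplied). Then `B`
#' subsamples of size floor(`subsample_fraction` * n) are drawn without
#' replacement and the lasso-Cox path is refit on each over the truncated
#' grid. The selection budget is enforced in every trial, not just on
#' average: each subsample's path is followed only for as long as its own
#' active set stays within `q_lambda` variables, so that every base fit
#' contributing to the probabilities selects at most `q_lambda` variables.
#' (With an explicit `lambda_min` and no budget, the whole truncated grid
#' counts.) The selection probability of variable j at penalty lambda_k is
#' the fraction of trials in which j has entered the trial's
#' budget-respecting path by lambda_k, i.e. is selected somewhere in
#' [lambda_k, lambda_upper]. A variable's
#' importance is its maximal selection probability over the truncated
#' region; variables with importance at or above `pi_thr` are selected.
#'
#' The threshold, budget and expected number of false selections are tied
#' by the bound E(V) <= q_lambda^2 / ((2 pi_thr - 1) p): fix any two and
#' the third follows (see [q_from_error_bound()], [error_bound()]).
#'
#' @param x covariates: a [surv_dataset()], a numeric matrix, a data frame,
#'   or a model formula with a [survival::Surv()] left-hand side.
#' @param ... passed on to methods.
#' @return An object of class `stabsel`; see [print.stabsel()],
#'   [summary.stabsel()], [plot.stabsel()], [select_variables()].
#' @examples
#' scen <- make_scenario("sim1", censor_rate = 0.2, seed = 7)
#' fit <- stabsel(scen$data, B = 50, pi_thr = 0.6, lambda_min = 0.2, seed = 1)
#' fit
#' @export
stabsel <- function(x, ...) UseMethod("stabsel")

#' @rdname stabsel
#' @param time,status survival times and 0/1 event indicators (default
#'   method, when `x` is a matrix or data frame).
#' @export
stabsel.default <- function(x, time, status, ...) {
  stabsel(surv_dataset(x, time, status), ...)
}

#' @rdname stabsel
#' @param formula a formula `Surv(time, status) ~ covariates`.
#' @param data data frame in which to evaluate `formula`.
#' @export
stabsel.formula <- function(formula, data, ...) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (!survival::is.Surv(y) || attr(y, "type") != "right")
    stop("the response must be a right-censored survival::Surv() object")
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  stabsel(surv_dataset(X, y[, "time"], y[, "status"]), ...)
}

#' @method stabsel surv_dataset
#' @rdname stabsel
#' @param B ensemble size (number of subsamples), default 200.
#' @param pi_thr selection-probability threshold in (0.5, 1), default 0.6.
#' @param ev_budget target bound on the expected number of falsely selected
#'   variables; used to derive `q_lambda` when the latter is not given.
#'   Default 4.
#' @param q_lambda per-fit selection budget; overrides `ev_budget`.
#' @param lambda_min explicit lower end of the penalty region; when given,
#'   the grid is truncated there and no budget-based truncation is done.
#' @param K grid resolution (K+1 penalties before truncation), default 100.
#' @param subsample_fraction fraction of subjects per subsample, default
#'   0.5 (drawn without replacement).
#' @param seed integer seed making the ensemble reproducible.
#' @param keep_paths logical; keep the B per-subsample active-set arrays
#'   (as a logical p x K x B array) for diagnostics.
#' @param strict use strict risk-set inequalities in [lambda_upper()].
#' @param max_redraw maximum redraws of an event-free or failed subsample.
#' @export
stabsel.surv_dataset <- function(x, B = 200L, pi_thr = 0.6, ev_budget = 4,
                                 q_lambda = NULL, lambda_min = NULL,
                                 K = 100L, subsample_fraction = 0.5,
                                 seed = NULL, keep_paths = FALSE,
                                 strict = FALSE, max_redraw = 100L, ...) {
  data <- x
  B <- as.integer(B)
  if (B < 1L) stop("'B' must be at least 1")
  if (pi_thr <= 0.5 || pi_thr >= 1)
    stop("'pi_thr' must lie strictly between 0.5 and 1")
  if (subsample_fraction <= 0 || subsample_fraction > 1)
    stop("'subsample_fraction' must be in (0, 1]")
  if (!is.null(seed)) set.seed(seed)

  lu <- lambda_upper(data, strict = strict)
  full_grid <- lambda_grid(lu, data$n, data$p, K)
  if (!is.null(lambda_min)) {
    grid <- truncate_grid(full_grid, lambda_min)
    if (is.null(q_lambda)) q_lambda <- NA_integer_
    grid$q_lambda <- q_lambda
  } else {
    if (is.null(q_lambda))
      q_lambda <- q_from_error_bound(data$p, pi_thr, ev_budget)
    grid <- determine_lambda_min(data, full_grid, q_lambda)
  }
  L <- length(grid$values)
  m <- max(2L, floor(subsample_fraction * data$n))

  counts <- matrix(0L, data$p, L,
                   dimnames = list(colnames(data$x), signif(grid$values, 6)))
  paths <- if (keep_paths) array(FALSE, c(data$p, L, B)) else NULL
  for (b in seq_len(B)) {
    tries <- 0L
    repeat {
      idx <- sample.int(data$n, m)
      if (sum(data$status[idx]) >= 1L) {
        sub <- surv_dataset(data$x[idx, , drop = FALSE],
                            data$time[idx], data$status[idx])
        beta <- tryCatch(glmnet_cox_path(sub, grid$values),
                         error = function(e) NULL)
        if (!is.null(beta)) break
      }
      tries <- tries + 1L
      if (tries > max_redraw)
        stop("could not draw a fittable subsample after ", max_redraw,
             " attempts")
    }
    act <- abs(beta) > .active_tol
    if (!is.na(q_lambda)) {
      # per-trial budget: follow this subsample's path only while at most
      # q_lambda variables are active at the penalty
      over <- which(colSums(act) > q_lambda)
      if (length(over)) act[, over[1L]:L] <- FALSE
    }
    if (keep_paths) paths[, , b] <- act
    # a trial has selected a variable at lambda_k once it has entered its
    # budget-respecting path anywhere in [lambda_k, lambda_upper]; the
    # trial's selection stands at penalties beyond its own stopping point
    if (L > 1L) for (k in 2:L) act[, k] <- act[, k] | act[, k - 1L]
    counts <- counts + act
  }
  probabilities <- counts / B
  importance <- apply(probabilities, 1L, max)
  selected <- which(importance >= pi_thr)
  bound <- if (is.na(q_lambda)) NA_real_ else
    error_bound(data$p, pi_thr, q_lambda)

  structure(list(probabilities = probabilities, importance = importance,
                 selected = selected, grid = grid,
                 lambda_min = grid$values[L], lambda_upper = lu,
                 q_lambda = q_lambda, pi_thr = pi_thr, B = B,
                 ev_bound = bound, subsample_size = m, seed = seed,
                 n = data$n, p = data$p, paths = paths,
                 call = match.call()),
            class = "stabsel")
}

#' Threshold a selection profile
#'
#' Recomputes the selected set from the stored importance values at a
#' (possibly new) threshold. Variables whose importance ties the threshold
#' are included; raising the threshold never enlarges the set.
#'
#' @param profile a fitted [stabsel()] object.
#' @param pi_thr threshold in (0.5, 1); defaults to the fitted one.
#' @return Named integer vector of selected variable indices.
#' @export
select_variables <- function(profile, pi_thr = profile$pi_thr) {
  stopifnot(inherits(profile, "stabsel"))
  if (pi_thr <= 0.5 || pi_thr >= 1)
    stop("'pi_thr' must lie strictly between 0.5 and 1")
  which(profile$importance >= pi_thr)
}

#' @export
print.stabsel <- function(x, ...) {
  cat("Stability selection for the Cox model\n")
  cat(sprintf("  n = %d, p = %d, B = %d subsamples of size %d\n",
              x$n, x$p, x$B, x$subsample_size))
  cat(sprintf("  penalty region: [%.4g, %.4g] (%d grid values)",
              x$lambda_min, x$lambda_upper, length(x$grid$values)))
  if (!is.na(x$q_lambda))
    cat(sprintf(", q = %d, E(V) bound = %.3g", x$q_lambda, x$ev_bound))
  cat("\n")
  sel <- names(x$importance)[x$selected]
  cat(sprintf("  selected (importance >= %.2f): %s\n", x$pi_thr,
              if (length(sel)) paste(sel, collapse = ", ") else "<none>"))
  invisible(x)
}

#' @export
summary.stabsel <- function(object, ...) {
  ord <- order(object$importance, decreasing = TRUE)
  tab <- data.frame(variable = names(object$importance)[ord],
                    importance = unname(object$importance[ord]),
                    selected = unname(object$importance[ord] >= object$pi_thr))
  structure(list(table = tab, fit = object), class = "summary.stabsel")
}

#' @export
print.summary.stabsel <- function(x, n = 10L, ...) {
  print(x$fit)
  cat("\nTop variables by importance (maximal selection probability):\n")
  print(utils::head(x$table, n), row.names = FALSE)
  invisible(x)
}

#' Plot selection-probability paths
#'
#' One curve per variable: estimated selection probability against the
#' penalty (log scale, decreasing left to right the way paths are walked).
#' Selected variables are drawn in color, the rest in grey; the threshold
#' is a dashed horizontal line.
#'
#' @param x a fitted [stabsel()] object.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.stabsel <- function(x, ...) {
  lam <- x$grid$values
  cols <- rep("grey70", x$p)
  if (length(x$selected))
    cols[x$selected] <- grDevices::hcl.colors(max(length(x$selected), 2L),
                                              "Dark 3")[seq_along(x$selected)]
  graphics::matplot(lam, t(x$probabilities), type = "l", lty = 1,
                    col = cols, log = "x", xlim = rev(range(lam)),
                    xlab = expression(lambda),
                    ylab = "selection probability", ylim = c(0, 1), ...)
  graphics::abline(h = x$pi_thr, lty = 2)
  if (length(x$selected))
    graphics::legend("topleft", legend = names(x$importance)[x$selected],
                     col = cols[x$selected], lty = 1, bty = "n", cex = 0.8)
  invisible(x)
}
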