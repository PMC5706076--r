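# Lasso-penalized Cox partial likelihood: single fits, paths, and the
# cross-validated baseline. The solver is glmnet's cyclical coordinate
# descent on the Breslow partial likelihood; covariates are passed
# unstandardized so that the penalty lives on the same scale as
# lambda_upper() and the null-model KKT condition is exact.

# Numerical zero for active sets: solver coefficients below this are
# treated as zero.
.active_tol <- 1e-10

# Fit glmnet along a user grid, padding very short grids (glmnet prefers
# a sequence) and returning the p x length(lambdas) coefficient matrix at
# exactly the requested penalties. Internal.
glmnet_cox_path <- function(data, lambdas, thresh = 1e-9) {
  lambdas <- as.numeric(lambdas)
  if (any(diff(lambdas) > 0)) stop("penalty sequence must be decreasing")
  pad <- 0L
  fit_lams <- lambdas
  if (length(fit_lams) < 3L) {
    head <- max(fit_lams) * c(1.21, 1.1)
    fit_lams <- c(head, fit_lams)
    pad <- 2L
  }
  y <- survival::Surv(data$time, data$status)
  # deep path entries can hit the iteration cap; the partial path glmnet
  # returns is used and the last converged column recycled below
  fit <- withCallingHandlers(
    glmnet::glmnet(data$x, y, family = "cox", lambda = fit_lams,
                   standardize = FALSE, thresh = thresh),
    warning = function(w) {
      if (grepl("solutions for larger", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  beta <- as.matrix(fit$beta)
  # glmnet may stop the path early; recycle the last fitted column
  got <- ncol(beta)
  want <- length(fit_lams)
  if (got < want)
    beta <- cbind(beta, beta[, rep.int(got, want - got), drop = FALSE])
  beta <- beta[, (pad + 1L):want, drop = FALSE]
  dimnames(beta) <- list(colnames(data$x), signif(lambdas, 6))
  beta
}

#' Fit the lasso-penalized Cox model at one penalty value
#'
#' Minimizes the averaged negative log partial likelihood plus
#' lambda * sum(|beta_j|) by cyclical coordinate descent, warm-starting
#' from the path entry point so the solution is a stationary point of the
#' penalized objective. At `lambda` at or above [lambda_upper()] the
#' solution is the zero vector (verified by the solver, not assumed).
#'
#' @param data a [surv_dataset()].
#' @param lambda nonnegative penalty. `lambda = 0` gives the unpenalized
#'   maximum partial-likelihood fit (requires n reasonably larger than p).
#' @param thresh solver convergence threshold (relative coordinate change).
#' @return Named numeric vector of length p of coefficients on the scale of
#'   the input covariates.
#' @export
fit_coxlasso <- function(data, lambda, thresh = 1e-9) {
  stopifnot(inherits(data, "surv_dataset"))
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0 ||
      !is.finite(lambda))
    stop("'lambda' must be a single nonnegative number")
  lu <- suppressWarnings(lambda_upper(data))
  if (lambda >= lu && lambda > 0) {
    lams <- lambda * c(1.21, 1.1, 1)
  } else {
    top <- max(lu, lambda * 1.01, .Machine$double.eps)
    lams <- top * (max(lambda, 1e-4 * top) / top)^((0:19) / 19)
    if (lambda < lams[length(lams)]) lams <- c(lams, lambda)
  }
  beta <- glmnet_cox_path(data, lams, thresh = thresh)
  out <- beta[, ncol(beta)]
  names(out) <- colnames(data$x)
  out
}

#' Fit the whole lasso-Cox path along a penalty grid
#'
#' Fits sequentially from the largest to the smallest penalty with warm
#' starts and records the active set at each grid value.
#'
#' @param data a [surv_dataset()].
#' @param grid a [lambda_grid()] (possibly truncated).
#' @param thresh solver convergence threshold.
#' @return Object of class `coxlasso_path`: list with `grid`, `beta`
#'   (p x length(grid) coefficient matrix), `active` (list of integer
#'   vectors) and `sizes` (active-set cardinalities).
#' @export
coxlasso_path <- function(data, grid, thresh = 1e-9) {
  stopifnot(inherits(data, "surv_dataset"), inherits(grid, "lambda_grid"))
  beta <- glmnet_cox_path(data, grid$values, thresh = thresh)
  active <- apply(abs(beta) > .active_tol, 2, which, simplify = FALSE)
  structure(list(grid = grid, beta = beta, active = active,
                 sizes = lengths(active)),
            class = "coxlasso_path")
}

#' @export
print.coxlasso_path <- function(x, ...) {
  cat(sprintf("Lasso-Cox path: %d penalties in [%.4g, %.4g]; active-set sizes %d..%d\n",
              length(x$grid$values), min(x$grid$values),
              max(x$grid$values), min(x$sizes), max(x$sizes)))
  invisible(x)
}

#' Export a fitted path as a tidy table
#'
#' One row per (penalty, variable) pair with the fitted coefficient.
#'
#' @param path a [coxlasso_path()].
#' @return data.frame with columns `lambda`, `variable`, `coefficient`.
#' @export
path_to_table <- function(path) {
  stopifnot(inherits(path, "coxlasso_path"))
  p <- nrow(path$beta)
  L <- ncol(path$beta)
  data.frame(lambda = rep(path$grid$values, each = p),
             variable = rep(rownames(path$beta), times = L),
             coefficient = as.vector(path$beta))
}

#' Cross-validated lasso-Cox baseline
#'
#' Selects the penalty minimizing the mean out-of-fold partial-likelihood
#' deviance (the Verweij-Van Houwelingen construction used by
#' `cv.glmnet` for Cox families) over the supplied grid, and returns the
#' active set of a full-data fit at that penalty. Folds are stratified by
#' event status so that every training part contains events.
#'
#' @param data a [surv_dataset()].
#' @param grid a [lambda_grid()]; built from the data when `NULL`.
#' @param nfolds number of folds, default 10.
#' @param seed integer seed controlling the fold assignment.
#' @return List with `lambda_opt`, `selected` (integer indices), `beta`
#'   (coefficients of the full-data fit at `lambda_opt`), `cvm` (mean CV
#'   deviance per grid value) and `foldid`.
#' @export
cv_coxlasso <- function(data, grid = NULL, nfolds = 10L, seed = NULL) {
  stopifnot(inherits(data, "surv_dataset"))
  if (nfolds < 2L) stop("'nfolds' must be at least 2")
  if (is.null(grid))
    grid <- lambda_grid(lambda_upper(data), data$n, data$p)
  if (length(grid$values) == 1L) {
    # nothing to tune: return the full-data fit at the single penalty
    beta <- fit_coxlasso(data, grid$values)
    return(list(lambda_opt = grid$values, beta = beta,
                selected = which(abs(beta) > .active_tol),
                cvm = NA_real_, foldid = NULL))
  }
  if (!is.null(seed)) set.seed(seed)
  foldid <- integer(data$n)
  for (g in c(0L, 1L)) {
    idx <- which(data$status == g)
    if (length(idx))
      foldid[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
  }
  y <- survival::Surv(data$time, data$status)
  cv <- withCallingHandlers(
    glmnet::cv.glmnet(data$x, y, family = "cox", lambda = grid$values,
                      foldid = foldid, standardize = FALSE,
                      grouped = TRUE),
    warning = function(w) {
      if (grepl("solutions for larger", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  k <- match(cv$lambda.min, cv$lambda)
  beta <- as.matrix(cv$glmnet.fit$beta)[, k]
  list(lambda_opt = cv$lambda.min,
       selected = which(abs(beta) > .active_tol),
       beta = beta, cvm = cv$cvm, foldid = foldid)
}
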