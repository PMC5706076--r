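#' Construct a survival dataset
#'
#' Bundles a numeric covariate matrix with survival times and event
#' indicators, after validating the pieces against each other. All
#' model-fitting and selection functions in the package accept this object.
#'
#' @param x numeric matrix (n rows, p columns) of covariates. Column names
#'   are kept if present, otherwise variables are named `x1 ... xp`.
#' @param time positive survival or censoring times, length n.
#' @param status event indicators, length n: 1 = observed failure,
#'   0 = right-censored. At least one event is required, since the partial
#'   likelihood is empty otherwise.
#' @return An object of class `surv_dataset`: a list with elements `x`,
#'   `time`, `status`, `n` and `p`.
#' @seealso [read_surv_csv()] to build one from a CSV file.
#' @examples
#' d <- surv_dataset(matrix(rnorm(20), 10, 2), time = rexp(10),
#'                   status = rep(1, 10))
#' d
#' @export
surv_dataset <- function(x, time, status) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  time <- as.numeric(time)
  status <- as.integer(status)
  if (nrow(x) != length(time) || nrow(x) != length(status))
    stop("'x', 'time' and 'status' must describe the same number of subjects")
  if (anyNA(x) || any(!is.finite(x)))
    stop("covariates must be finite and non-missing")
  if (anyNA(time) || any(time <= 0))
    stop("all times must be strictly positive")
  if (!all(status %in% c(0L, 1L)))
    stop("'status' must be coded 0 (censored) / 1 (event)")
  if (sum(status) < 1L)
    stop("no events in the data: the partial likelihood is undefined ",
         "without at least one observed failure")
  if (is.null(colnames(x)))
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  structure(list(x = x, time = time, status = status,
                 n = nrow(x), p = ncol(x)),
            class = "surv_dataset")
}

#' @export
print.surv_dataset <- function(x, ...) {
  cat(sprintf("Survival dataset: n = %d subjects, p = %d covariates, %d events (%.0f%% censored)\n",
              x$n, x$p, sum(x$status), 100 * mean(x$status == 0)))
  invisible(x)
}

#' Read survival data from CSV
#'
#' Expects a header row with columns `time`, `status` (0/1) and then one
#' column per covariate. Covariate columns keep their header names; unnamed
#' or `V`-style names are replaced by `x1 ... xp`.
#'
#' @param path path to a CSV file.
#' @return A [surv_dataset()].
#' @export
read_surv_csv <- function(path) {
  df <- utils::read.csv(path, header = TRUE)
  need <- c("time", "status")
  if (!all(need %in% names(df)))
    stop("CSV must contain 'time' and 'status' columns")
  covs <- setdiff(names(df), need)
  if (length(covs) == 0L) stop("CSV contains no covariate columns")
  surv_dataset(as.matrix(df[covs]), df$time, df$status)
}

#' Write survival data to CSV
#'
#' Inverse of [read_surv_csv()]: columns `time`, `status`, then covariates.
#'
#' @param data a [surv_dataset()].
#' @param path output file path.
#' @export
write_surv_csv <- function(data, path) {
  stopifnot(inherits(data, "surv_dataset"))
  df <- data.frame(time = data$time, status = data$status, data$x,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Index the unique failure times and their risk sets
#'
#' Computes the ordered unique failure times t_1 < ... < t_m, the indices of
#' the observations failing at each (several in case of ties, handled by
#' Breslow's convention downstream), and the risk sets
#' R_i = \{j : y_j >= t_i\}.
#'
#' @param data a [surv_dataset()].
#' @return A list of class `failure_index` with elements `failure_times`
#'   (length m), `failers` (list of integer vectors), and `risk_sets`
#'   (list of integer vectors). Risk sets are nested:
#'   R_1 contains R_2 contains ... contains R_m.
#' @export
failure_index <- function(data) {
  stopifnot(inherits(data, "surv_dataset"))
  ft <- sort(unique(data$time[data$status == 1L]))
  failers <- lapply(ft, function(t) which(data$status == 1L & data$time == t))
  risk_sets <- lapply(ft, function(t) which(data$time >= t))
  structure(list(failure_times = ft, failers = failers, risk_sets = risk_sets),
            class = "failure_index")
}

#' Negative log partial likelihood of a Cox model
#'
#' Evaluates -log L(beta) for the Breslow partial likelihood
#' at a fixed coefficient vector, using log-sum-exp stabilization over each
#' risk set. At beta = 0 this is sum_i d_i * log |R_i|.
#'
#' @param data a [surv_dataset()].
#' @param beta numeric coefficient vector of length p.
#' @return A single nonnegative number.
#' @export
neg_log_partial_likelihood <- function(data, beta) {
  stopifnot(inherits(data, "surv_dataset"))
  beta <- as.numeric(beta)
  if (length(beta) != data$p) stop("'beta' must have length p = ", data$p)
  if (any(!is.finite(beta))) stop("'beta' must be finite")
  idx <- failure_index(data)
  lp <- drop(data$x %*% beta)
  val <- 0
  for (i in seq_along(idx$failure_times)) {
    r <- lp[idx$risk_sets[[i]]]
    mx <- max(r)
    lse <- mx + log(sum(exp(r - mx)))
    val <- val + length(idx$failers[[i]]) * lse - sum(lp[idx$failers[[i]]])
  }
  val
}

#' Null-model working response for the penalized Cox path
#'
#' At beta = 0 the score of the partial likelihood decomposes into
#' per-subject martingale residuals. For each unique failure time t_i let
#' s_i be the number at risk and for each subject k let C_k be the set of
#' failure times no later than y_k. Then the working score is
#' z*_k = delta_k - sum over C_k of 1/s_i (the product omega_k z_k, stored
#' directly so that subjects with empty C_k are well defined) and the
#' working weight is omega_k = sum over C_k of (s_i - 1)/s_i^2.
#'
#' Two risk-set conventions are offered. The inclusive convention
#' (`strict = FALSE`, the default) counts a subject as at risk at its own
#' failure time (s_i counts y_j >= t_i; C_k = \{i : t_i <= y_k\}); with it
#' the scores sum to zero and [lambda_upper()] is exactly the smallest
#' penalty producing an empty lasso model. `strict = TRUE` uses the strict
#' inequalities instead.
#'
#' @param data a [surv_dataset()].
#' @param strict logical; use strict (>) risk-set inequalities.
#' @return A list of class `cox_working_response` with `risk_counts` (s_i,
#'   length m), `prior_time_sets` (C_k, list of length n), `score`
#'   (delta_k - sum 1/s_i, length n) and `weights` (omega_k, length n).
#' @export
working_response <- function(data, strict = FALSE) {
  stopifnot(inherits(data, "surv_dataset"))
  ft <- sort(unique(data$time[data$status == 1L]))
  s <- if (strict) vapply(ft, function(t) sum(data$time > t), 0)
       else        vapply(ft, function(t) sum(data$time >= t), 0)
  if (strict && any(s < 1)) {
    # the last failer leaves an empty strict risk set; clamp to avoid 1/0
    s <- pmax(s, 1)
  }
  inv_s <- 1 / s
  wgt_s <- (s - 1) / s^2
  score <- numeric(data$n)
  weights <- numeric(data$n)
  prior <- vector("list", data$n)
  for (k in seq_len(data$n)) {
    Ck <- if (strict) which(ft < data$time[k]) else which(ft <= data$time[k])
    prior[[k]] <- Ck
    score[k] <- data$status[k] - sum(inv_s[Ck])
    weights[k] <- sum(wgt_s[Ck])
  }
  structure(list(risk_counts = s, prior_time_sets = prior,
                 score = score, weights = weights),
            class = "cox_working_response")
}

#' Smallest penalty giving the empty lasso-Cox model
#'
#' The entry point of the regularization path:
#' lambda_upper = max_j (1/n) | sum_k x_kj z*_k |, where z*_k is the
#' null-model working score of [working_response()]. Under the inclusive
#' risk-set convention, fitting the lasso-penalized Cox model at any
#' lambda >= lambda_upper returns the empty active set (the Karush-Kuhn-
#' Tucker condition at beta = 0 holds with equality at lambda_upper).
#'
#' The maximum is taken over the absolute inner products: the penalty must
#' be positive and the stationarity condition at zero is two-sided.
#'
#' @inheritParams working_response
#' @return A single nonnegative number. Zero (with a warning) if every
#'   covariate is orthogonal to the null score, in which case no grid can
#'   be built.
#' @export
lambda_upper <- function(data, strict = FALSE) {
  wr <- working_response(data, strict = strict)
  lu <- max(abs(colSums(data$x * wr$score))) / data$n
  if (lu == 0)
    warning("all covariate/score inner products are zero: lambda_upper = 0 ",
            "and the regularization grid is degenerate")
  lu
}

#' Geometric grid of penalty values
#'
#' Builds the K+1 candidate penalties
#' lambda_j = lambda_upper * (lambda_lower/lambda_upper)^(j/K), j = 0..K,
#' with lambda_lower = epsilon * lambda_upper. The ratio epsilon follows the
#' dimensionality rule epsilon = 0.05 when n < p and epsilon = 0.0001 when
#' n >= p.
#'
#' @param lambda_upper positive scalar, usually from [lambda_upper()].
#' @param n,p sample size and number of covariates (used only for the
#'   epsilon rule).
#' @param K number of grid intervals (the grid has K+1 values); default 100.
#' @return An object of class `lambda_grid`: list with `values` (decreasing,
#'   length K+1), `lambda_upper`, `lambda_lower`, `epsilon`, `K`.
#' @export
lambda_grid <- function(lambda_upper, n, p, K = 100L) {
  if (!is.numeric(lambda_upper) || lambda_upper <= 0)
    stop("'lambda_upper' must be a positive number")
  K <- as.integer(K)
  if (is.na(K) || K < 1L) stop("'K' must be a positive integer")
  eps <- if (n < p) 0.05 else 1e-4
  values <- lambda_upper * eps^((0:K) / K)
  structure(list(values = values, lambda_upper = lambda_upper,
                 lambda_lower = lambda_upper * eps, epsilon = eps, K = K),
            class = "lambda_grid")
}

#' @export
print.lambda_grid <- function(x, ...) {
  cat(sprintf("Penalty grid: %d values in [%.4g, %.4g] (epsilon = %g)\n",
              length(x$values), min(x$values), x$lambda_upper, x$epsilon))
  invisible(x)
}

# Truncate a grid at an explicit lower penalty, appending the exact bound
# when it falls between grid points. Internal.
truncate_grid <- function(grid, lambda_min) {
  stopifnot(inherits(grid, "lambda_grid"))
  if (lambda_min > grid$lambda_upper)
    stop("'lambda_min' exceeds lambda_upper: empty penalty region")
  keep <- grid$values >= lambda_min - 1e-12 * grid$lambda_upper
  values <- grid$values[keep]
  if (length(values) == 0L || values[length(values)] > lambda_min * (1 + 1e-10))
    values <- c(values, lambda_min)
  out <- grid
  out$values <- values
  out$lambda_lower <- values[length(values)]
  out$lambda_min <- values[length(values)]
  out
}
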