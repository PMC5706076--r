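# Replication harness and selection-accuracy metrics: selection
# frequencies, exact-recovery (success) rate, TPR/TNR, ranking recovery,
# Harrell's concordance index.

# records: a list of per-replicate run records, each a list with at least
# `selected` (integer indices); stability-selection records also carry
# `importance`, path records `path_active` (list of active sets along the
# penalty grid), and simulation records `true_set`.

check_records <- function(records) {
  if (!is.list(records) || length(records) < 1L)
    stop("need at least one run record")
  if (!all(vapply(records, function(r) is.list(r) && !is.null(r$selected),
                  TRUE)))
    stop("each record must be a list with a 'selected' element")
  invisible(records)
}

#' Selection-frequency summary for a variable group
#'
#' For each variable in `group`, counts the replicates whose selected set
#' contains it, then summarizes those per-variable counts by their minimum,
#' median and maximum. This is the summary usually reported separately for
#' the important (IV) and unimportant (UIV) variables of a simulation.
#' The median of an even number of counts is the mean of the central pair,
#' rounded half-up to an integer.
#'
#' @param records list of run records (see Details in
#'   [replicate_experiment()]).
#' @param group integer indices of the variables to summarize.
#' @return Named numeric vector `c(min, median, max)` of counts.
#' @export
selection_frequency <- function(records, group) {
  check_records(records)
  group <- as.integer(group)
  if (length(group) == 0L) stop("'group' must be non-empty")
  counts <- vapply(group, function(j)
    sum(vapply(records, function(r) j %in% r$selected, TRUE)), 0L)
  med <- floor(stats::median(counts) + 0.5)
  c(min = min(counts), median = med, max = max(counts))
}

#' Exact-recovery (success) rate
#'
#' Fraction of replicates whose selected set equals the true important set
#' exactly; a strict superset or subset counts as a failure.
#'
#' @inheritParams selection_frequency
#' @param true_set integer indices of the truly important variables; when
#'   `NULL`, each record's own `true_set` is used.
#' @return Fraction in [0, 1].
#' @export
success_rate <- function(records, true_set = NULL) {
  check_records(records)
  hit <- vapply(records, function(r) {
    ts <- if (is.null(true_set)) r$true_set else true_set
    setequal(r$selected, ts)
  }, TRUE)
  mean(hit)
}

#' True positive and true negative selection rates
#'
#' TPR is the average, over replicates and truly important variables, of
#' the indicator that the variable is selected; TNR the average, over
#' replicates and unimportant variables, of the indicator that it is not.
#'
#' @inheritParams selection_frequency
#' @param iv,uiv disjoint integer index sets of important and unimportant
#'   variables; when `NULL`, derived per record from its `true_set` and `p`.
#' @return Named numeric vector `c(tpr, tnr)`.
#' @export
tpr_tnr <- function(records, iv = NULL, uiv = NULL) {
  check_records(records)
  if (!is.null(iv) && !is.null(uiv) && length(intersect(iv, uiv)))
    stop("'iv' and 'uiv' must be disjoint")
  per <- vapply(records, function(r) {
    iv_r <- if (is.null(iv)) r$true_set else iv
    uiv_r <- if (is.null(uiv)) setdiff(seq_len(r$p), iv_r) else uiv
    c(if (length(iv_r)) mean(iv_r %in% r$selected) else NA_real_,
      if (length(uiv_r)) mean(!(uiv_r %in% r$selected)) else NA_real_)
  }, c(0, 0))
  c(tpr = mean(per[1, ]), tnr = mean(per[2, ]))
}

#' Probability of recovering the top of the true support
#'
#' For a target fraction `gamma`, a replicate counts as a recovery when
#' ceiling(gamma * s) of the s truly important variables are recovered, in
#' one of two senses. In `"stabsel"` mode, the ceiling(gamma * s)
#' variables of highest importance (ties broken toward the smaller index)
#' must all be truly important. In `"lasso_path"` mode there must exist a
#' penalty on the recorded path at which at least ceiling(gamma * s) true
#' variables are active while no noise variable is.
#'
#' @inheritParams success_rate
#' @param gamma fraction of the support to recover, in (0, 1].
#' @param mode `"stabsel"` (importance ranking) or `"lasso_path"`
#'   (existence of a clean penalty).
#' @return Fraction of replicates in [0, 1].
#' @export
ranking_recovery <- function(records, true_set = NULL, gamma,
                             mode = c("stabsel", "lasso_path")) {
  check_records(records)
  mode <- match.arg(mode)
  if (gamma <= 0 || gamma > 1) stop("'gamma' must be in (0, 1]")
  hit <- vapply(records, function(r) {
    ts <- if (is.null(true_set)) r$true_set else true_set
    k <- ceiling(gamma * length(ts))
    if (mode == "stabsel") {
      if (is.null(r$importance))
        stop("'stabsel' mode needs per-record importance values")
      ord <- order(-r$importance, seq_along(r$importance))
      all(ord[seq_len(k)] %in% ts)
    } else {
      if (is.null(r$path_active))
        stop("'lasso_path' mode needs per-record path active sets")
      any(vapply(r$path_active, function(a)
        sum(a %in% ts) >= k && all(a %in% ts), TRUE))
    }
  }, TRUE)
  mean(hit)
}

#' Harrell's concordance index
#'
#' Among pairs (i, j) with y_i < y_j and subject i an observed failure,
#' the fraction in which the higher risk score belongs to the earlier
#' failure, ties in score counting one half. Computed by
#' [survival::concordance()] with the risk-score orientation.
#'
#' @param time,status survival times and 0/1 event flags.
#' @param risk_scores predicted risks (higher = expected earlier failure),
#'   e.g. a Cox linear predictor.
#' @return Fraction in [0, 1], or `NA` (with a warning) when no pair is
#'   comparable.
#' @export
concordance_index <- function(time, status, risk_scores) {
  stopifnot(length(time) == length(status),
            length(time) == length(risk_scores))
  fit <- survival::concordance(survival::Surv(time, status) ~ risk_scores,
                               reverse = TRUE)
  n_pairs <- sum(fit$count[c("concordant", "discordant", "tied.x")])
  if (n_pairs == 0) {
    warning("no comparable pairs: concordance undefined")
    return(NA_real_)
  }
  unname(fit$concordance)
}

# Run one selection method on one dataset, returning a run record.
# Internal.
run_method <- function(scen, method, seed, B, pi_thr, q_lambda, ev_budget,
                       lambda_min, K, keep_path = FALSE) {
  data <- scen$data
  design <- scen$design
  rec <- list(true_set = design$true_set, p = data$p, seed = seed)
  if (method == "stabsel") {
    fit <- stabsel(data, B = B, pi_thr = pi_thr, q_lambda = q_lambda,
                   ev_budget = ev_budget, lambda_min = lambda_min, K = K,
                   seed = seed)
    rec$selected <- unname(fit$selected)
    rec$importance <- unname(fit$importance)
  } else if (method == "cv_lasso") {
    cv <- cv_coxlasso(data, seed = seed)
    rec$selected <- unname(cv$selected)
  } else if (method == "lasso_path") {
    grid <- lambda_grid(lambda_upper(data), data$n, data$p, K)
    path <- coxlasso_path(data, grid)
    rec$path_active <- unname(path$active)
    # ranking by order of entry into the path: earlier entry = higher rank
    entry <- apply(abs(path$beta) > .active_tol, 1, function(z)
      if (any(z)) which(z)[1] else Inf)
    rec$importance <- -entry
    cv <- cv_coxlasso(data, grid = grid, seed = seed)
    rec$selected <- unname(cv$selected)
  } else if (method == "oracle") {
    # refit restricted to the true support; selection is the support itself
    rec$selected <- design$true_set
  } else stop("unknown method: ", method)
  rec
}

#' Replicate a simulation design and aggregate selection metrics
#'
#' Generates `R` independent datasets from a named design (seeds derived
#' deterministically from the master seed, so any replicate can be redone
#' in isolation), applies the chosen selection method to each, and
#' aggregates: per-group selection-frequency triples, exact-recovery rate,
#' mean selected-model size, TPR/TNR, and per-group average selection
#' rates.
#'
#' Methods: `"stabsel"` (stability selection), `"cv_lasso"`
#' (cross-validated lasso-Cox active set), `"lasso_path"` (full path,
#' selected set from CV, path kept for ranking metrics), `"oracle"` (the
#' true support, the benchmark every selector is compared against).
#'
#' @param scenario design name, passed to [make_scenario()].
#' @param censor_rate target censoring rate.
#' @param method selection method, see above.
#' @param R number of replicates, default 100.
#' @param seed master seed.
#' @param B,pi_thr,q_lambda,ev_budget,lambda_min,K passed to [stabsel()].
#' @param n,p,s design overrides, passed to [make_scenario()].
#' @return Object of class `stabsel_report`: the aggregate metrics plus
#'   the full list of run records.
#' @export
replicate_experiment <- function(scenario, censor_rate = 0,
                                 method = c("stabsel", "cv_lasso",
                                            "lasso_path", "oracle"),
                                 R = 100L, seed = 1L, B = 200L,
                                 pi_thr = 0.6, q_lambda = NULL,
                                 ev_budget = 4, lambda_min = NULL,
                                 K = 100L, n = NULL, p = NULL, s = NULL) {
  method <- match.arg(method)
  R <- as.integer(R)
  if (R < 1L) stop("'R' must be at least 1")
  set.seed(seed)
  data_seeds <- sample.int(.Machine$integer.max - 1L, R)
  method_seeds <- sample.int(.Machine$integer.max - 1L, R)

  records <- vector("list", R)
  failures <- 0L
  for (t in seq_len(R)) {
    scen <- make_scenario(scenario, censor_rate, seed = data_seeds[t],
                          n = n, p = p, s = s)
    rec <- tryCatch(
      run_method(scen, method, method_seeds[t], B, pi_thr, q_lambda,
                 ev_budget, lambda_min, K),
      error = function(e) {
        warning("replicate ", t, " failed: ", conditionMessage(e))
        NULL
      })
    if (is.null(rec)) {
      failures <- failures + 1L
    } else {
      rec$replicate_id <- t
      records[[t]] <- rec
    }
  }
  records <- Filter(Negate(is.null), records)
  if (length(records) == 0L) stop("every replicate failed")

  fixed_support <- scenario %in% c("sim1", "sim3", "null")
  p_used <- records[[1]]$p
  iv <- if (fixed_support) records[[1]]$true_set else NULL
  uiv <- if (fixed_support) setdiff(seq_len(p_used), iv) else NULL

  sizes <- vapply(records, function(r) length(r$selected), 0L)
  rates <- tpr_tnr(records, iv = iv, uiv = uiv)
  rep_n <- length(records)
  out <- list(scenario = scenario, censor_rate = censor_rate,
              method = method, R = R, completed = rep_n,
              failures = failures, p = p_used,
              success_rate = success_rate(records,
                                          if (fixed_support) iv else NULL),
              mean_size = mean(sizes), tpr = rates[["tpr"]],
              tnr = rates[["tnr"]], seed = seed, records = records)
  if (fixed_support) {
    out$iv <- iv
    out$uiv <- uiv
    if (length(iv)) {
      out$freq_iv <- selection_frequency(records, iv)
      out$avg_rate_iv <- mean(vapply(records, function(r)
        mean(iv %in% r$selected), 0))
    }
    if (length(uiv)) {
      out$freq_uiv <- selection_frequency(records, uiv)
      out$avg_rate_uiv <- mean(vapply(records, function(r)
        mean(uiv %in% r$selected), 0))
    }
  }
  class(out) <- "stabsel_report"
  out
}

#' @export
print.stabsel_report <- function(x, ...) {
  cat(sprintf("Replicated experiment: %s, %.0f%% censoring, method = %s\n",
              x$scenario, 100 * x$censor_rate, x$method))
  cat(sprintf("  %d/%d replicates completed\n", x$completed, x$R))
  cat(sprintf("  success rate %.2f | mean size %.2f | TPR %.3f | TNR %.3f\n",
              x$success_rate, x$mean_size, x$tpr, x$tnr))
  if (!is.null(x$freq_iv))
    cat(sprintf("  IV  selections (min/med/max of %d): %d / %d / %d\n",
                x$completed, x$freq_iv[1], x$freq_iv[2], x$freq_iv[3]))
  if (!is.null(x$freq_uiv))
    cat(sprintf("  UIV selections (min/med/max of %d): %d / %d / %d\n",
                x$completed, x$freq_uiv[1], x$freq_uiv[2], x$freq_uiv[3]))
  invisible(x)
}
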