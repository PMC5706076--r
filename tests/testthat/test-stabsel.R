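test_that("error bound and budget inversion reproduce the worked pairings", {
  expect_equal(q_from_error_bound(p = 10, pi_thr = 0.7, ev_budget = 4), 4)
  expect_equal(q_from_error_bound(p = 20, pi_thr = 0.6, ev_budget = 8), 6)
  expect_equal(q_from_error_bound(p = 20, pi_thr = 0.6, ev_budget = 8),
               ceiling(sqrt(1.6 * 20)))
  expect_equal(q_from_error_bound(p = 1000, pi_thr = 0.6, ev_budget = 4), 29)
  expect_equal(q_from_error_bound(p = 1000, pi_thr = 0.6, ev_budget = 4),
               ceiling(sqrt(0.8 * 1000)))

  # round trip: q^2 = 1.6 p at pi_thr = 0.7 gives bound 4 for any p
  for (p in c(10, 100, 1000))
    expect_equal(error_bound(p, 0.7, sqrt(1.6 * p)), 4)
  expect_equal(error_bound(50, 0.8, 0), 0)

  # monotone in q, antitone in pi_thr
  expect_gt(error_bound(50, 0.6, 10), error_bound(50, 0.6, 5))
  expect_gt(error_bound(50, 0.6, 5), error_bound(50, 0.9, 5))

  expect_error(error_bound(10, 0.5, 3), "between 0.5 and 1")
  expect_error(q_from_error_bound(10, 0.4, 2), "between 0.5 and 1")
  expect_warning(q_from_error_bound(4, 0.9, 100), "capped")
})

test_that("lambda_min truncation keeps the path within the budget", {
  d <- random_dataset(60, 6, seed = 31, censor_frac = 0.2)
  grid <- lambda_grid(lambda_upper(d), d$n, d$p, K = 60)
  g3 <- determine_lambda_min(d, grid, q_lambda = 3)
  path <- coxlasso_path(d, g3)
  expect_true(all(path$sizes <= 3))
  expect_lt(length(g3$values), length(grid$values))
  # one grid step further the active set exceeds the budget
  k <- length(g3$values)
  if (k < length(grid$values)) {
    wider <- grid; wider$values <- grid$values[seq_len(k + 1)]
    expect_gt(max(coxlasso_path(d, wider)$sizes), 3)
  }

  # a budget of at least p can never be exceeded: full grid survives
  expect_equal(determine_lambda_min(d, grid, q_lambda = d$p)$values,
               grid$values)
  # unreachable budget warns
  dsmall <- random_dataset(6, 2, seed = 8)
  gsmall <- lambda_grid(lambda_upper(dsmall), 6, 2, K = 5)
  gsmall$values <- gsmall$values[1]
  expect_warning(determine_lambda_min(dsmall, gsmall, 2), "never reaches")
  expect_error(determine_lambda_min(d, grid, q_lambda = 0), ">= 1")
})

test_that("selection probabilities are exact subsample counts", {
  # brute-force counting oracle over the logged per-subsample activity
  d <- random_dataset(30, 5, seed = 77, censor_frac = 0.2)
  fit <- stabsel(d, B = 6, pi_thr = 0.6, q_lambda = 3, seed = 5,
                 keep_paths = TRUE)
  expect_equal(dim(fit$paths), c(5, length(fit$grid$values), 6))
  # brute-force: cumulate each logged trial's activity along the grid and
  # count trials per (variable, penalty) cell
  L <- dim(fit$paths)[2]
  manual <- matrix(0, 5, L)
  for (b in 1:6) {
    A <- fit$paths[, , b]
    if (L > 1) for (k in 2:L) A[, k] <- A[, k] | A[, k - 1]
    manual <- manual + A
  }
  manual <- manual / 6
  expect_equal(unname(fit$probabilities), manual)
  expect_true(all(fit$probabilities * 6 ==
                  round(fit$probabilities * 6)))   # multiples of 1/B
  expect_equal(fit$importance, apply(fit$probabilities, 1, max))
  expect_equal(unname(fit$selected),
               unname(which(fit$importance >= 0.6)))

  # the worked 4-subsample counting example: active sets {1},{1},{1,2},{}
  probs <- c("1" = 3 / 4, "2" = 1 / 4)
  expect_equal(mean(c(1, 1, 1, 0)), probs[["1"]])
  expect_equal(mean(c(0, 0, 1, 0)), probs[["2"]])
})

test_that("stability selection is reproducible and honours its knobs", {
  scen <- make_scenario("sim1", censor_rate = 0.2, seed = 21)
  f1 <- stabsel(scen$data, B = 20, lambda_min = 0.2, seed = 9)
  f2 <- stabsel(scen$data, B = 20, lambda_min = 0.2, seed = 9)
  expect_identical(f1$probabilities, f2$probabilities)
  expect_identical(f1$selected, f2$selected)

  # B = 1: probabilities are 0/1 and the selection is that subsample's
  # active set anywhere on the truncated grid
  f3 <- stabsel(scen$data, B = 1, lambda_min = 0.2, seed = 4)
  expect_true(all(f3$probabilities %in% c(0, 1)))
  expect_equal(unname(f3$selected),
               unname(which(apply(f3$probabilities == 1, 1, any))))

  # explicit lambda_min is honoured exactly
  expect_equal(f1$lambda_min, 0.2)
  expect_true(all(f1$grid$values >= 0.2))

  # thresholding: ties included, raising the threshold shrinks the set
  imp <- f1$importance
  thr <- max(imp)
  expect_true(all(which(imp >= thr) %in% select_variables(f1, min(thr, 0.99))))
  s06 <- select_variables(f1, 0.6)
  s08 <- select_variables(f1, 0.8)
  expect_true(all(s08 %in% s06))
  expect_error(select_variables(f1, 0.4), "between 0.5 and 1")

  # subsample size
  expect_equal(f1$subsample_size, 25)
})

test_that("per-trial budget caps what each subsample may select", {
  d <- random_dataset(40, 8, seed = 55, censor_frac = 0.2)
  fit <- stabsel(d, B = 8, q_lambda = 2, seed = 3, keep_paths = TRUE)
  # each logged trial has at most q variables active at every penalty it
  # is followed to
  per_col <- apply(fit$paths, 3, colSums)
  expect_true(all(per_col <= 2))
  # cumulative counting: probabilities nondecreasing along the grid
  expect_true(all(apply(fit$probabilities, 1, function(r) all(diff(r) >= 0))))
})

test_that("stabsel accepts formula and matrix interfaces", {
  scen <- make_scenario("sim1", censor_rate = 0, seed = 13)
  df <- data.frame(time = scen$data$time, status = scen$data$status,
                   scen$data$x)
  form <- stats::reformulate(colnames(scen$data$x),
                             response = quote(survival::Surv(time, status)))
  f_form <- stabsel(form, data = df, B = 10, lambda_min = 0.3, seed = 2)
  f_mat <- stabsel(scen$data$x, scen$data$time, scen$data$status,
                   B = 10, lambda_min = 0.3, seed = 2)
  expect_equal(unname(f_form$probabilities), unname(f_mat$probabilities))
  expect_error(stabsel(scen$data, pi_thr = 1.2), "between 0.5 and 1")
  expect_error(stabsel(scen$data, B = 0), "at least 1")
})

test_that("print, summary and plot methods run", {
  scen <- make_scenario("sim1", censor_rate = 0, seed = 13)
  fit <- stabsel(scen$data, B = 10, lambda_min = 0.3, seed = 2)
  expect_output(print(fit), "Stability selection")
  expect_output(print(summary(fit)), "importance")
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(fit))
})
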