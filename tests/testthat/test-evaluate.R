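rec <- function(selected, p = 10, true_set = c(1, 2), importance = NULL,
                path_active = NULL) {
  list(selected = selected, p = p, true_set = true_set,
       importance = importance, path_active = path_active)
}

test_that("selection frequencies count replicates per variable", {
  recs <- lapply(1:10, function(i) rec(if (i <= 3) c(1, 2, 3)
                                       else if (i <= 5) c(2, 3)
                                       else if (i <= 9) c(3) else integer(0)))
  # counts: var1 = 3, var2 = 5, var3 = 9
  expect_equal(selection_frequency(recs, c(1, 2, 3)),
               c(min = 3, median = 5, max = 9))
  # all records select the whole group
  all_recs <- lapply(1:7, function(i) rec(1:4))
  expect_equal(selection_frequency(all_recs, 1:4),
               c(min = 7, median = 7, max = 7))
  # nobody selects the group
  expect_equal(selection_frequency(all_recs, c(9, 10)),
               c(min = 0, median = 0, max = 0))
  # even group size: mean of the central pair, rounded half-up
  recs2 <- lapply(1:10, function(i) {
    sel <- c(if (i <= 2) 1, if (i <= 5) 2, if (i <= 6) 3, if (i <= 9) 4)
    rec(if (is.null(sel)) integer(0) else sel)
  })
  expect_equal(selection_frequency(recs2, 1:4)[["median"]], 6)  # (5+6)/2 -> 6
  expect_error(selection_frequency(recs2, integer(0)), "non-empty")
  expect_error(selection_frequency(list(), 1), "at least one")
})

test_that("success rate demands exact recovery", {
  recs <- c(lapply(1:55, function(i) rec(c(1, 2))),
            lapply(1:30, function(i) rec(c(1, 2, 3))),   # superset fails
            lapply(1:15, function(i) rec(1)))            # subset fails
  expect_equal(success_rate(recs, c(1, 2)), 0.55)
  expect_equal(success_rate(lapply(1:4, function(i) rec(c(2, 1)))), 1)
})

test_that("TPR and TNR average the selection indicators", {
  # two records, IV = {1, 2}: selections {1} and {1, 2} give TPR 3/4
  recs <- list(rec(1), rec(c(1, 2)))
  rates <- tpr_tnr(recs, iv = c(1, 2), uiv = 3:10)
  expect_equal(rates[["tpr"]], 3 / 4)
  expect_equal(rates[["tnr"]], 1)
  # an oracle selector is perfect on both axes
  oracle <- lapply(1:5, function(i) rec(c(1, 2)))
  expect_equal(unname(tpr_tnr(oracle, c(1, 2), 3:10)), c(1, 1))
  # select-everything: TPR 1, TNR 0
  eager <- lapply(1:5, function(i) rec(1:10))
  expect_equal(unname(tpr_tnr(eager, c(1, 2), 3:10)), c(1, 0))
  expect_error(tpr_tnr(recs, iv = 1:2, uiv = 2:4), "disjoint")
})

test_that("ranking recovery checks the top of the importance ordering", {
  imp <- c(0.9, 0.8, 0.1, 0.7, 0.2)
  r <- rec(1, p = 5, true_set = c(1, 2, 4), importance = imp)
  # gamma = 0.1, s = 3: top 1 must be true
  expect_equal(ranking_recovery(list(r), gamma = 0.1), 1)
  # gamma = 1: top 3 are {1, 2, 4}, all true
  expect_equal(ranking_recovery(list(r), gamma = 1), 1)
  # noise on top breaks it
  r2 <- rec(1, p = 5, true_set = c(2, 4), importance = c(1, 0.5, 0, 0.4, 0))
  expect_equal(ranking_recovery(list(r2), gamma = 0.1), 0)
  # ties broken toward the smaller index
  r3 <- rec(1, p = 3, true_set = 2, importance = c(0.5, 0.5, 0))
  expect_equal(ranking_recovery(list(r3), gamma = 1), 0)
  # exhaustive cross-check against a brute-force scan of the ordering
  set.seed(40)
  for (i in 1:25) {
    p <- 8
    imp <- round(runif(p), 2)
    ts <- sort(sample(p, 4))
    rr <- rec(1, p = p, true_set = ts, importance = imp)
    for (gamma in c(0.1, 0.3, 0.8)) {
      k <- ceiling(gamma * 4)
      ord <- order(-imp, seq_len(p))
      expect_equal(ranking_recovery(list(rr), gamma = gamma),
                   as.numeric(all(ord[1:k] %in% ts)))
    }
  }
  # path mode: need a clean penalty with >= k true and no noise
  rp <- rec(1, p = 5, true_set = c(1, 2),
            path_active = list(integer(0), 1L, c(1L, 2L), c(1L, 2L, 3L)))
  expect_equal(ranking_recovery(list(rp), gamma = 1, mode = "lasso_path"), 1)
  rp2 <- rec(1, p = 5, true_set = c(1, 2),
             path_active = list(integer(0), c(1L, 3L), c(1L, 2L, 3L)))
  expect_equal(ranking_recovery(list(rp2), gamma = 1, mode = "lasso_path"), 0)
  expect_error(ranking_recovery(list(r), gamma = 0.3, mode = "lasso_path"),
               "path")
  expect_error(ranking_recovery(list(r), gamma = 0), "gamma")
})

test_that("concordance index matches pair enumeration", {
  # hand-worked: times (1,2,3), status (1,1,0), scores (3,1,2) -> 2/3
  expect_equal(concordance_index(c(1, 2, 3), c(1, 1, 0), c(3, 1, 2)), 2 / 3)
  # perfect anti-ordering of scores and times
  expect_equal(concordance_index(1:5, rep(1, 5), 5:1), 1)
  # constant scores: all ties
  expect_equal(concordance_index(1:5, rep(1, 5), rep(2, 5)), 0.5)
  # random data against the brute-force oracle
  for (s in 1:20) {
    set.seed(600 + s)
    n <- 15
    time <- rexp(n); status <- rbinom(n, 1, 0.7); risk <- rnorm(n)
    if (sum(status) == 0) next
    expect_equal(concordance_index(time, status, risk),
                 brute_cindex(time, status, risk), tolerance = 1e-12)
  }
})

test_that("replicated experiments aggregate and reproduce deterministically", {
  r1 <- replicate_experiment("sim3", 0, method = "oracle", R = 5, seed = 3)
  expect_equal(r1$success_rate, 1)
  expect_equal(r1$mean_size, 3)
  expect_equal(r1$tpr, 1)
  expect_equal(r1$tnr, 1)

  r2 <- replicate_experiment("sim1", 0, method = "stabsel", R = 2, seed = 5,
                             B = 10, lambda_min = 0.3)
  r3 <- replicate_experiment("sim1", 0, method = "stabsel", R = 2, seed = 5,
                             B = 10, lambda_min = 0.3)
  expect_equal(r2$records[[1]]$selected, r3$records[[1]]$selected)
  expect_equal(r2$success_rate, r3$success_rate)

  # success never exceeds the weakest important variable's selection rate
  expect_lte(r2$success_rate, min(r2$freq_iv) / r2$completed)

  # independent brute-force pass over the logged records
  sel <- lapply(r2$records, `[[`, "selected")
  expect_equal(r2$mean_size, mean(lengths(sel)))
  expect_equal(r2$tpr,
               mean(sapply(sel, function(s) mean(c(1, 2, 5) %in% s))))
  expect_equal(r2$success_rate,
               mean(sapply(sel, function(s) setequal(s, c(1, 2, 5)))))

  # single replicate equals single-run metrics
  r4 <- replicate_experiment("sim3", 0, method = "oracle", R = 1, seed = 9)
  expect_equal(r4$mean_size, 3)
  expect_equal(r4$completed, 1)
})
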