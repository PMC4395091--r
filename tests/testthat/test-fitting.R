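test_that("the fit error is the unweighted RMSE over populated conditions", {
  # single condition: |1 - 1/(1 + 1*0.5)| = 1/3
  tab <- data.frame(n_A = 1, n_B = 0, R = 4, N_A = 4, fraction = 1)
  expect_equal(rmse_model("M6", c(p = 1, s = 0.5), tab), 1 / 3)
  # exact-model fractions give zero error
  nt <- noiseless_table("M6", c(p = 0.81, s = 0.75))
  expect_equal(rmse_model("M6", c(p = 0.81, s = 0.75), nt), 0)
  # unweighted: duplicating a condition's counts changes nothing
  tab2 <- nt
  tab2$R <- tab2$R * 2L
  expect_equal(rmse_model("M6", c(p = 0.9, s = 0.8), nt),
               rmse_model("M6", c(p = 0.9, s = 0.8), tab2))
  # weighting by R is the count-weighted alternative
  two <- data.frame(n_A = c(1, 0), n_B = c(0, 1), R = c(3, 1),
                    N_A = c(3, 0), fraction = c(1, 0))
  pr <- belief_from_counts(1, 0.5, two$n_A, two$n_B)
  expect_equal(rmse_model("M6", c(p = 1, s = 0.5), two, weight_by_R = TRUE),
               sqrt(sum(two$R * (pr - two$fraction)^2) / 4))
  expect_error(rmse_model("M6", c(p = 1, s = 0.5), nt[0, ]), "empty")
})

test_that("noiseless self-fit recovers every family exactly when the truth is on the grid", {
  settings <- list(
    M1 = list(c(delta = 1.15), c(delta = 1.33), c(delta = 3)),
    M2 = list(c(delta = 3.9, eps = 1.95), c(delta = 1, eps = 1),
              c(delta = 3.66, eps = 1.52)),
    M3 = list(c(delta = 0.63, eps = 0.41), c(delta = 0.5, eps = 0.2),
              c(delta = 0.62, eps = 0.35)),
    M4 = list(c(delta = 0.45, eps = 5.06), c(delta = 0.3, eps = 2),
              c(delta = 0.45, eps = 4.39)),
    M5 = list(c(delta = 8.32, eps = 1.6), c(delta = 12.01, eps = 1.3),
              c(delta = 2, eps = 2)),
    M6 = list(c(p = 0.81, s = 0.75), c(p = 0.82, s = 0.87), c(p = 2, s = 0.5))
  )
  for (fam in names(settings)) {
    base <- default_grid(fam)
    for (truth in settings[[fam]]) {
      # a lattice containing the generating point: exhaustive search must
      # find its zero-error minimum and return it exactly
      grid <- lapply(names(base), function(nm) {
        sort(unique(c(grid_points(base[[nm]]), truth[[nm]])))
      })
      names(grid) <- names(base)
      nt <- noiseless_table(fam, truth, sums = 0:6)
      fit <- grid_fit(nt, fam, grid = grid)
      expect_equal(fit$rmse, 0)
      expect_equal(unname(fit$params), unname(truth), tolerance = 1e-12)
    }
  }
})

test_that("the Bayesian fit lands within one default-grid step of an off-grid truth", {
  grid_step <- function(v, at) {
    v <- sort(v)
    i <- which.min(abs(v - at))
    max(diff(v)[max(1, i - 1):min(length(v) - 1, i)])
  }
  grid <- default_grid("M6")
  for (truth in list(c(p = 0.81, s = 0.75), c(p = 0.82, s = 0.87))) {
    nt <- noiseless_table("M6", truth, sums = 0:9)
    fit <- grid_fit(nt, "M6", grid = grid)
    for (nm in names(truth)) {
      expect_lt(abs(fit$params[[nm]] - truth[[nm]]),
                grid_step(grid_points(grid[[nm]]), truth[[nm]]) + 1e-9)
    }
  }
  # and for M1, the one-parameter nested case
  nt1 <- noiseless_table("M1", c(delta = 1.33), sums = 0:6)
  fit1 <- grid_fit(nt1, "M1")
  step <- grid_step(grid_points(default_grid("M1")$delta), 1.33)
  expect_lt(abs(fit1$params[["delta"]] - 1.33), step + 1e-9)
})

test_that("grid search honours nesting, ties and refinement", {
  # a noiseless M1 table fitted as M6 lands at p = 1, s = 1/delta
  nt <- noiseless_table("M1", c(delta = 1.33), sums = 0:6)
  fit <- grid_fit(nt, "M6",
                  grid = list(p = c(0.5, 1, 2), s = c(0.5, 1 / 1.33, 0.9)))
  expect_equal(unname(fit$params), c(1, 1 / 1.33))
  expect_equal(fit$rmse, 0)
  # all-0.5 symmetric table: symmetry forces p = 1 (and any s fits exactly;
  # the documented tie-break picks the smallest s)
  flat <- data.frame(n_A = c(0, 1, 0, 2, 1, 0), n_B = c(0, 0, 1, 0, 1, 2),
                     R = 2L, N_A = 1L, fraction = 0.5)
  fit <- grid_fit(flat, "M6", grid = list(p = c(0.5, 1, 2), s = c(0.4, 1)))
  expect_equal(unname(fit$params), c(1, 1))  # only s = 1 is flat in n_A - n_B
  # the stored surface attains its minimum at the reported fit
  expect_equal(min(fit$surface$rmse, na.rm = TRUE), fit$rmse)
  # refinement never increases the minimum error
  nt6 <- noiseless_table("M6", c(p = 0.81, s = 0.75), sums = 0:6)
  coarse <- grid_fit(nt6, "M6", grid = coarse_m6_grid())
  fine <- grid_fit(nt6, "M6", grid = coarse_m6_grid(), refine = TRUE)
  expect_lte(fine$rmse, coarse$rmse)
  # a strictly denser grid can only do better
  dense <- grid_fit(nt6, "M6",
                    grid = list(p = grid_spec(0.05, 20, 121, "log"),
                                s = grid_spec(0.02, 1, 99)))
  sparse <- grid_fit(nt6, "M6",
                     grid = list(p = grid_points(grid_spec(0.05, 20, 61, "log")),
                                 s = grid_points(grid_spec(0.02, 1, 50))))
  expect_lte(dense$rmse, sparse$rmse + 1e-12)
  expect_error(grid_fit(nt6, "M3",
                        grid = list(delta = c(2, 3), eps = c(5, 6))),
               "inadmissible")
})

test_that("model comparison keeps the Bayesian model at least as good as M1", {
  set.seed(21)
  for (k in 1:10) {
    tab <- random_table()
    res <- fit_all_models(tab, families = c("M1", "M6"),
                          grids = list(M1 = list(delta = grid_spec(0.05, 20, 61, "log"))))
    expect_lte(res$fits$M6$rmse, res$fits$M1$rmse + 1e-12)
  }
  # full six-family comparison on a noiseless M6 table: M6 wins at ~0 error
  nt <- noiseless_table("M6", c(p = 0.81, s = 0.75), sums = 0:6)
  res <- fit_all_models(nt)
  expect_equal(res$comparison$family[1], "M6")
  # error floor set only by the truth sitting between grid points
  expect_lt(res$fits$M6$rmse, 0.005)
  expect_gt(res$fits$M5$rmse, res$fits$M6$rmse)
  expect_true(!is.unsorted(res$comparison$rmse))
})

test_that("per-question fits recover heterogeneous truths and collapse on z", {
  cfg <- protocol_config("D1", n_questions = 40)
  set.seed(8)
  truths <- question_truth(1:40, exp(runif(40, log(0.3), log(3))),
                           runif(40, 0.5, 0.95))
  sim <- run_experiment(cfg, truths = truths, seed = 12)
  pq <- per_question_fit(sim$records, grid = coarse_m6_grid())
  fits <- merge(pq$fits[pq$fits$fit_ok, ], truths, by = "question_id")
  # log-odds-scale recovery: noisy per question, but centred on the truth
  expect_gt(cor(log(fits$p_q.x), log(fits$p_q.y)), 0.7)
  expect_lt(median(abs(fits$s_q.x - fits$s_q.y)), 0.15)
  # questions with p > 1 imply an initial belief below the coin flip
  worse <- fits[fits$p_q.x > 1, ]
  if (nrow(worse)) expect_true(all(p0_from_p(worse$p_q.x) < 0.5))
  # recovered p and s stay uncorrelated when generated independently
  expect_lt(abs(cor(log(fits$p_q.x), fits$s_q.x)), 0.35)
  # the z-collapse diagnostic: sparse bins (often a single answer) scatter
  # widely, but the logistic in z explains the points far better than a
  # constant, and well-populated bins sit close to 1/(1 + e^z)
  baseline <- sqrt(mean((pq$collapse$fraction - mean(pq$collapse$fraction))^2))
  expect_lt(pq$collapse_rmse, baseline)
  dense <- pq$collapse[pq$collapse$R >= 10, ]
  expect_lt(sqrt(mean((dense$fraction - plogis(-dense$z))^2)), 0.15)
  # a question with too few conditions is flagged unfit, not an error
  tiny <- sim$records[sim$records$question_id == 1 &
                        sim$records$r_condition == 0, ]
  pq_tiny <- per_question_fit(tiny)
  expect_false(pq_tiny$fits$fit_ok[1])
})

test_that("Weber slopes separate scale-free from Bayesian behaviour", {
  # exact line: fraction = 0.2 + 0.6 x at every bin and r
  wt <- expand.grid(r = c(1, 2, 3, 5), x = c(0, 0.5, 1))
  wt$R <- 10L
  wt$fraction <- 0.2 + 0.6 * wt$x
  wt$N_A <- wt$R * wt$fraction
  sl <- weber_slopes(wt)
  expect_equal(sl$slope, rep(0.6, 4), tolerance = 1e-12)
  # two-point group
  sl2 <- weber_slopes(data.frame(r = 1, x = c(0, 1), R = 5L,
                                 N_A = c(0, 5), fraction = c(0, 1)))
  expect_equal(sl2$slope, 1)
  # single-bin groups are omitted with a warning
  expect_warning(
    weber_slopes(data.frame(r = c(1, 1, 2), x = c(0, 1, 0.5), R = 1L,
                            N_A = 1L, fraction = c(0, 1, 1))),
    "single x bin")
  # noiseless Bayesian fractions: slope strictly increases with r
  conds <- expand.grid(r = c(1, 2, 3, 5, 7, 9), k = 0:9)
  conds <- conds[conds$k <= conds$r, ]
  wt6 <- data.frame(r = conds$r, x = conds$k / conds$r, R = 10L, N_A = 0L,
                    fraction = belief_from_counts(0.81, 0.75, conds$k,
                                                  conds$r - conds$k))
  sl6 <- weber_slopes(wt6)
  expect_true(all(diff(sl6$slope) > 0))
})
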