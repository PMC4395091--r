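#' Simulate an experiment and optionally write its files
#'
#' Convenience front end over [run_experiment()]: simulates, and when
#' `out_dir` is given writes `responses.csv`, `truths.csv` and a
#' `manifest.json` recording the seed and configuration so the run can be
#' reproduced exactly.
#'
#' @param config A [protocol_config()].
#' @param truths Optional ground truths; sampled when `NULL`.
#' @param seed Integer seed (default `config$seed`).
#' @param out_dir Optional output directory (created if needed).
#' @return As [run_experiment()], invisibly when writing files.
#' @export
simulate_responses <- function(config, truths = NULL, seed = config$seed,
                               out_dir = NULL) {
  sim <- run_experiment(config, truths = truths, seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_responses(sim$records, file.path(out_dir, "responses.csv"))
    write_truths(sim$truths, file.path(out_dir, "truths.csv"))
    manifest <- list(
      seed = seed,
      config = unclass(config)[c("style", "n_subjects", "n_questions",
                                 "r_schedule", "shuffle_labels",
                                 "nonresponse_prob")],
      n_records = nrow(sim$records),
      n_questions = nrow(sim$truths)
    )
    manifest$config$r_schedule <-
      ifelse(is.infinite(manifest$config$r_schedule), "inf",
             as.character(manifest$config$r_schedule))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    return(invisible(sim))
  }
  sim
}

#' Run the full analysis pipeline on response records
#'
#' Aggregates records into the pooled condition table, fits and compares the
#' six choice models, fits the Bayesian model per question with the
#' z-collapse diagnostic, and computes the Weber's-law slopes. When
#' `out_dir` is given, each product is also written as CSV
#' (`comparison.csv`, `surface_M6.csv`, `per_question_fits.csv`,
#' `weber_table.csv`, `weber_slopes.csv`).
#'
#' @param records Response records (data.frame) or a path to a response CSV.
#' @param families Model families to compare (default all six).
#' @param min_R,include_r0,include_sentinel Passed to
#'   [aggregate_conditions()].
#' @param refine,weight_by_R Passed to the fitting functions.
#' @param per_question Also fit each question separately? Default `TRUE`.
#' @param grids Optional per-family grid overrides.
#' @param out_dir Optional output directory.
#' @return List with `condition_table`, `comparison`, `fits`,
#'   `per_question` (or `NULL`), `weber` (table) and `weber_slopes`.
#' @export
fit_responses <- function(records, families = model_family_names,
                          min_R = 1L, include_r0 = TRUE,
                          include_sentinel = TRUE, refine = FALSE,
                          weight_by_R = FALSE, per_question = TRUE,
                          grids = list(), out_dir = NULL) {
  if (is.character(records)) records <- read_responses(records)
  check_records(records)
  if (nrow(records) == 0) stop("no data: empty response records", call. = FALSE)
  tab <- aggregate_conditions(records, scope = "pooled", min_R = min_R,
                              include_r0 = include_r0,
                              include_sentinel = include_sentinel)
  all_fits <- fit_all_models(tab, families = families, grids = grids,
                             weight_by_R = weight_by_R, refine = refine)
  pq <- if (per_question) {
    per_question_fit(records, min_R = min_R, include_r0 = include_r0,
                     include_sentinel = include_sentinel)
  }
  wt <- weber_table(records)
  ws <- if (nrow(wt)) suppressWarnings(weber_slopes(wt)) else
    data.frame(r = numeric(0), slope = numeric(0), intercept = numeric(0),
               n_points = integer(0))
  out <- list(condition_table = tab, comparison = all_fits$comparison,
              fits = all_fits$fits, per_question = pq, weber = wt,
              weber_slopes = ws)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_condition_table(tab, file.path(out_dir, "condition_table.csv"))
    utils::write.csv(all_fits$comparison, file.path(out_dir, "comparison.csv"),
                     row.names = FALSE)
    if ("M6" %in% names(all_fits$fits)) {
      utils::write.csv(all_fits$fits$M6$surface,
                       file.path(out_dir, "surface_M6.csv"), row.names = FALSE)
    }
    if (!is.null(pq)) {
      utils::write.csv(pq$fits, file.path(out_dir, "per_question_fits.csv"),
                       row.names = FALSE)
    }
    write_condition_table(wt, file.path(out_dir, "weber_table.csv"))
    utils::write.csv(ws, file.path(out_dir, "weber_slopes.csv"),
                     row.names = FALSE)
  }
  out
}

#' Parameter-recovery experiment
#'
#' Simulates `n_replicates` experiments at a fixed ground truth, fits the
#' Bayesian model to each pooled condition table, and summarises how well
#' the generating `(p, s)` are recovered: per-replicate estimates, bias, and
#' the RMSE of the estimates around the truth.
#'
#' @param config A [protocol_config()].
#' @param p,s Ground-truth parameters used for every question.
#' @param n_replicates Number of simulated experiments.
#' @param seed Integer seed; replicate `k` uses `seed + k - 1`.
#' @param grid M6 grid (default [default_grid()]).
#' @return List with `estimates` (data.frame: `replicate`, `p_hat`,
#'   `s_hat`, `rmse`) and `summary` (named vector: `bias_p`, `bias_s`,
#'   `rmse_p`, `rmse_s`).
#' @export
recover_parameters <- function(config, p, s, n_replicates = 10L, seed = 1L,
                               grid = default_grid("M6")) {
  truths <- question_truth(seq_len(config$n_questions),
                           rep(p, config$n_questions),
                           rep(s, config$n_questions))
  rows <- vector("list", n_replicates)
  for (k in seq_len(n_replicates)) {
    sim <- run_experiment(config, truths = truths, seed = seed + k - 1L)
    tab <- aggregate_conditions(sim$records)
    fit <- grid_fit(tab, "M6", grid = grid)
    rows[[k]] <- data.frame(replicate = k, p_hat = fit$params[["p"]],
                            s_hat = fit$params[["s"]], rmse = fit$rmse)
  }
  est <- do.call(rbind, rows)
  summary <- c(bias_p = mean(est$p_hat) - p, bias_s = mean(est$s_hat) - s,
               rmse_p = sqrt(mean((est$p_hat - p)^2)),
               rmse_s = sqrt(mean((est$s_hat - s)^2)))
  list(estimates = est, summary = summary)
}

#' Bootstrap confidence interval for the pooled (p, s) fit
#'
#' Resamples questions with replacement, re-aggregates and refits the
#' Bayesian model, and returns percentile intervals for `p` and `s`.
#'
#' @param records Response records.
#' @param n_boot Number of bootstrap resamples.
#' @param level Interval coverage (default 0.95).
#' @param seed Integer seed for the resampling.
#' @param grid M6 grid.
#' @param ... Passed to [aggregate_conditions()].
#' @return List with `point` (fitted `p`, `s` on the full data), `ci`
#'   (2 x 2 matrix, rows `p` and `s`), and `boot` (data.frame of resampled
#'   estimates).
#' @export
bootstrap_pooled_fit <- function(records, n_boot = 200L, level = 0.95,
                                 seed = 1L, grid = default_grid("M6"), ...) {
  check_records(records)
  set.seed(seed)
  full <- grid_fit(aggregate_conditions(records, ...), "M6", grid = grid)
  # resampling questions only permutes per-question count tables, so
  # aggregate once and re-sum the counts per resample
  per_q <- aggregate_conditions(records, scope = "per_question", ...)
  by_q <- split(per_q, per_q$question_id)
  qids <- names(by_q)
  est <- matrix(NA_real_, n_boot, 2, dimnames = list(NULL, c("p", "s")))
  for (b in seq_len(n_boot)) {
    take <- sample(qids, length(qids), replace = TRUE)
    res <- do.call(rbind, by_q[take])
    key <- paste(res$n_A, res$n_B)
    counts <- rowsum(cbind(res$R, res$N_A), key)
    nn <- matrix(as.numeric(unlist(strsplit(rownames(counts), " "))),
                 ncol = 2, byrow = TRUE)
    tab <- data.frame(n_A = nn[, 1], n_B = nn[, 2], R = counts[, 1],
                      N_A = counts[, 2], fraction = counts[, 2] / counts[, 1])
    fit <- grid_fit(tab, "M6", grid = grid)
    est[b, ] <- fit$params
  }
  alpha <- (1 - level) / 2
  ci <- t(apply(est, 2, stats::quantile, probs = c(alpha, 1 - alpha)))
  list(point = full$params, ci = ci, boot = as.data.frame(est))
}
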