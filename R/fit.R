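#' Specify a one-parameter search grid
#'
#' @param lower,upper Bounds of the grid (inclusive).
#' @param n Number of points, `>= 2`.
#' @param spacing `"linear"` or `"log"` (log requires `lower > 0`).
#' @return A `grid_spec` list; [grid_points()] materialises it.
#' @export
grid_spec <- function(lower, upper, n, spacing = c("linear", "log")) {
  spacing <- match.arg(spacing)
  if (!(upper > lower)) stop("`upper` must exceed `lower`", call. = FALSE)
  if (n < 2) stop("a grid needs at least 2 points", call. = FALSE)
  if (spacing == "log" && lower <= 0) {
    stop("log spacing requires a positive lower bound", call. = FALSE)
  }
  structure(list(lower = lower, upper = upper, n = as.integer(n),
                 spacing = spacing), class = "grid_spec")
}

#' @rdname grid_spec
#' @param spec A `grid_spec`.
#' @export
grid_points <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  if (spec$spacing == "log") {
    exp(seq(log(spec$lower), log(spec$upper), length.out = spec$n))
  } else {
    seq(spec$lower, spec$upper, length.out = spec$n)
  }
}

#' Default search grids per model family
#'
#' Exhaustive-sampling grids chosen so that each interval contains the
#' published fitted values for its family with margin: M6 uses `p`
#' log-spaced over `[0.05, 20]` (241 points, symmetric, so `p = 1` is a grid
#' point) and `s` linear over `[0.005, 1]` (200 points, step 0.005); M1 the
#' same log grid for `delta`; the two-parameter families M2–M5 use 100 x 100
#' grids on intervals inside their admissible domains.
#'
#' @param family One of `"M1"` ... `"M6"`.
#' @return Named list of [grid_spec()]s, one per parameter.
#' @export
default_grid <- function(family) {
  family <- match.arg(family, model_family_names)
  switch(family,
    M1 = list(delta = grid_spec(0.05, 20, 241, "log")),
    M2 = list(delta = grid_spec(0.05, 10, 100), eps = grid_spec(0.1, 5, 100)),
    M3 = list(delta = grid_spec(0, 1, 100), eps = grid_spec(0, 2, 100)),
    M4 = list(delta = grid_spec(0, 1, 100), eps = grid_spec(0, 20, 100)),
    M5 = list(delta = grid_spec(0.1, 50, 100, "log"),
              eps = grid_spec(1.01, 5, 100)),
    M6 = list(p = grid_spec(0.05, 20, 241, "log"),
              s = grid_spec(0.005, 1, 200))
  )
}

#' Root-mean-square error of a model against a condition table
#'
#' The fit error is the RMSE between the model probability and the empirical
#' fraction `N_A / R`, averaged over the populated conditions — unweighted by
#' how many answers each condition received, matching the minimiser of the
#' plain sum of squared distances over available `(n_A, n_B)` pairs.
#' Weighting by `R` is available as an option.
#'
#' @param family,params Model family and named parameter vector as in
#'   [model_probability()].
#' @param table A condition table from [aggregate_conditions()].
#' @param weight_by_R Weight conditions by their answer counts? Default
#'   `FALSE`.
#' @return The RMSE (non-negative scalar).
#' @examples
#' tab <- data.frame(n_A = 1, n_B = 0, R = 4, N_A = 4, fraction = 1)
#' rmse_model("M6", c(p = 1, s = 0.5), tab)  # |1 - 1/1.5| = 1/3
#' @export
rmse_model <- function(family, params, table, weight_by_R = FALSE) {
  check_condition_table(table)
  pr <- model_probability(family, params, table$n_A, table$n_B)
  sq <- (pr - table$fraction)^2
  if (weight_by_R) {
    sqrt(sum(table$R * sq) / sum(table$R))
  } else {
    sqrt(mean(sq))
  }
}

check_condition_table <- function(table) {
  need <- c("n_A", "n_B", "R", "N_A", "fraction")
  missing <- setdiff(need, names(table))
  if (length(missing)) {
    stop("condition table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(table) == 0) stop("condition table is empty", call. = FALSE)
  invisible(table)
}

#' Fit one model family to a condition table by exhaustive grid search
#'
#' Evaluates the RMSE at every point of a parameter lattice, skips points
#' outside the family's admissible domain (including points at which the
#' linear families M3/M4 would leave `[0, 1]` on the table's conditions),
#' and adopts the minimiser. Ties are broken deterministically: smallest
#' second parameter, then smallest first. The full error surface is kept for
#' contour plots and refinement.
#'
#' @inheritParams rmse_model
#' @param family One of `"M1"` ... `"M6"`.
#' @param grid Named list of [grid_spec()]s (default [default_grid()]);
#'   alternatively a named list of numeric vectors of explicit grid values.
#' @param refine Add one refinement pass: a factor-10 finer grid with the
#'   same number of points, centred on the coarse minimum and clipped to the
#'   original bounds. Off by default, keeping the search a single exhaustive
#'   pass.
#' @return An object of class `herd_fit`: list with `family`, `params`
#'   (named best-fit vector), `rmse`, `surface` (data.frame of evaluated
#'   points and their RMSE, `NA` where inadmissible), `n_conditions`.
#' @examples
#' cond <- expand.grid(n_A = 0:5, n_B = 0:5)
#' tab <- data.frame(cond, R = 1L, N_A = 0L,
#'                   fraction = belief_from_counts(0.81, 0.75,
#'                                                 cond$n_A, cond$n_B))
#' fit <- grid_fit(tab, "M6")
#' fit$params
#' @export
grid_fit <- function(table, family, grid = default_grid(family),
                     weight_by_R = FALSE, refine = FALSE) {
  family <- match.arg(family, model_family_names)
  check_condition_table(table)
  values <- lapply(grid, function(g) {
    if (inherits(g, "grid_spec")) grid_points(g) else as.numeric(g)
  })
  pnames <- model_param_names[[family]]
  if (!all(pnames %in% names(values))) {
    stop(sprintf("grid for %s must name parameter(s) %s", family,
                 paste(pnames, collapse = ", ")), call. = FALSE)
  }
  values <- values[pnames]

  best <- grid_eval(table, family, values, weight_by_R)
  if (refine) {
    fine <- lapply(pnames, function(nm) {
      v <- sort(values[[nm]])
      i <- which.min(abs(v - best$params[[nm]]))
      step <- if (length(v) > 1) {
        if (i < length(v)) v[i + 1] - v[i] else v[i] - v[i - 1]
      } else 0
      lo <- max(min(v), v[i] - step)
      hi <- min(max(v), v[i] + step)
      seq(lo, hi, length.out = max(length(v), 20L))
    })
    names(fine) <- pnames
    refined <- grid_eval(table, family, fine, weight_by_R)
    # keep whichever pass found the smaller error; never regress
    if (!is.null(refined) && refined$rmse <= best$rmse) {
      refined$surface <- rbind(best$surface, refined$surface)
      best <- refined
    }
  }
  structure(c(best, list(family = family, n_conditions = nrow(table))),
            class = "herd_fit")
}

# Evaluate the whole lattice at once: G x K probability matrix against the
# K-vector of empirical fractions.
grid_eval <- function(table, family, values, weight_by_R) {
  pars <- as.matrix(expand.grid(values, KEEP.OUT.ATTRS = FALSE))
  P <- model_prob_matrix(family, pars, table$n_A, table$n_B)
  resid2 <- sweep(P, 2, table$fraction)^2
  rmse <- if (weight_by_R) {
    sqrt(as.vector(resid2 %*% table$R) / sum(table$R))
  } else {
    sqrt(rowMeans(resid2))
  }
  if (all(is.na(rmse))) {
    stop(sprintf("every grid point is inadmissible for %s on this table",
                 family), call. = FALSE)
  }
  cand <- which(rmse == min(rmse, na.rm = TRUE))
  if (length(cand) > 1) {
    ord <- if (ncol(pars) > 1) {
      order(pars[cand, 2], pars[cand, 1])
    } else {
      order(pars[cand, 1])
    }
    cand <- cand[ord]
  }
  i <- cand[1]
  surface <- data.frame(pars, rmse = rmse)
  list(params = stats::setNames(as.numeric(pars[i, ]), colnames(pars)),
       rmse = rmse[i], surface = surface)
}

#' @export
print.herd_fit <- function(x, ...) {
  cat(sprintf("<herd_fit %s> %s  RMSE = %.4g on %d conditions\n",
              x$family,
              paste(sprintf("%s = %.4g", names(x$params), x$params),
                    collapse = ", "),
              x$rmse, x$n_conditions))
  invisible(x)
}

#' Fit and compare all six model families
#'
#' Grid-fits every family to the same condition table and tabulates the
#' results sorted by RMSE. Because M1 is the unbiased-prior special case of
#' the Bayesian model M6 (`M1(delta) == M6(p = 1, s = 1/delta)`), M6's grid
#' is augmented with the reciprocal images of M1's grid so that the nesting
#' inequality — best M6 RMSE no worse than best M1 RMSE — holds by
#' construction; it is verified after fitting.
#'
#' @inheritParams grid_fit
#' @param families Families to fit (default all six).
#' @param grids Optional named list overriding [default_grid()] per family.
#' @return List with `comparison` (data.frame: `family`, `param_1`,
#'   `value_1`, `param_2`, `value_2`, `rmse`, sorted by `rmse`) and `fits`
#'   (named list of `herd_fit` objects).
#' @export
fit_all_models <- function(table, families = model_family_names,
                           grids = list(), weight_by_R = FALSE,
                           refine = FALSE) {
  families <- match.arg(families, model_family_names, several.ok = TRUE)
  fits <- list()
  for (fam in families) {
    grid <- grids[[fam]] %||% default_grid(fam)
    if (fam == "M6" && "M1" %in% families && is.null(grids[["M6"]])) {
      m1_grid <- grids[["M1"]] %||% default_grid("M1")
      d <- if (inherits(m1_grid$delta, "grid_spec")) {
        grid_points(m1_grid$delta)
      } else {
        as.numeric(m1_grid$delta)
      }
      s_extra <- 1 / d[d >= 1]
      grid <- list(p = unique(sort(c(grid_points(grid$p), 1))),
                   s = unique(sort(c(grid_points(grid$s), s_extra))))
    }
    fits[[fam]] <- grid_fit(table, fam, grid = grid,
                            weight_by_R = weight_by_R, refine = refine)
  }
  if (all(c("M1", "M6") %in% names(fits)) &&
      fits$M6$rmse > fits$M1$rmse + 1e-12) {
    stop("nesting violated: M6 (which contains M1) fitted worse than M1",
         call. = FALSE)
  }
  comparison <- do.call(rbind, lapply(fits, function(f) {
    data.frame(family = f$family,
               param_1 = names(f$params)[1], value_1 = f$params[[1]],
               param_2 = if (length(f$params) > 1) names(f$params)[2] else NA,
               value_2 = if (length(f$params) > 1) f$params[[2]] else NA,
               rmse = f$rmse)
  }))
  comparison <- comparison[order(comparison$rmse), , drop = FALSE]
  rownames(comparison) <- NULL
  list(comparison = comparison, fits = fits)
}

#' Fit the Bayesian model to each question separately
#'
#' Fits `(p_q, s_q)` per question by grid search on that question's own
#' condition table, then rescales every populated condition by
#' `z = (n_A - n_B) log(s_q) + log(p_q)` with the fitted parameters. If the
#' Bayesian model holds, the `(z, fraction)` points of all questions
#' collapse on the single logistic curve `1/(1 + exp(z))`; the pooled RMSE
#' around that curve is returned as the collapse diagnostic.
#'
#' @param records Response records.
#' @param grid Grid for the M6 fit (default [default_grid()]).
#' @param min_conditions Questions with fewer populated conditions are
#'   flagged unfit (`fit_ok = FALSE`) rather than fitted; default 3.
#' @param ... Passed to [aggregate_conditions()].
#' @return List with `fits` (data.frame: `question_id`, `p_q`, `s_q`,
#'   `rmse`, `n_conditions`, `fit_ok`), `collapse` (data.frame of
#'   `question_id`, `z`, `fraction`, `R`), and `collapse_rmse`.
#' @export
per_question_fit <- function(records, grid = default_grid("M6"),
                             min_conditions = 3L, ...) {
  per_q <- aggregate_conditions(records, scope = "per_question", ...)
  qids <- unique(per_q$question_id)
  rows <- vector("list", length(qids))
  collapse <- vector("list", length(qids))
  for (j in seq_along(qids)) {
    tab <- per_q[per_q$question_id == qids[j], , drop = FALSE]
    if (nrow(tab) < min_conditions) {
      rows[[j]] <- data.frame(question_id = qids[j], p_q = NA_real_,
                              s_q = NA_real_, rmse = NA_real_,
                              n_conditions = nrow(tab), fit_ok = FALSE)
      next
    }
    fit <- grid_fit(tab, "M6", grid = grid)
    rows[[j]] <- data.frame(question_id = qids[j], p_q = fit$params[["p"]],
                            s_q = fit$params[["s"]], rmse = fit$rmse,
                            n_conditions = nrow(tab), fit_ok = TRUE)
    collapse[[j]] <- data.frame(
      question_id = qids[j],
      z = z_transform(fit$params[["p"]], fit$params[["s"]], tab$n_A, tab$n_B),
      fraction = tab$fraction, R = tab$R
    )
  }
  fits <- do.call(rbind, rows)
  collapse <- do.call(rbind, collapse)
  collapse_rmse <- if (is.null(collapse)) NA_real_ else {
    sqrt(mean((collapse$fraction - stats::plogis(-collapse$z))^2))
  }
  list(fits = fits, collapse = collapse, collapse_rmse = collapse_rmse)
}

#' Per-condition regression slopes for the Weber's-law test
#'
#' For each finite information condition `r`, regresses the fraction of
#' correct answers on the fraction `x = n_A/(n_A + n_B)` of correct answers
#' observed, by ordinary least squares across the populated `x` bins
#' (unweighted by default). Under Weber's law the slope would not depend on
#' `r`; under the Bayesian model with `s < 1` it increases with `r`.
#'
#' @param wt A Weber table from [weber_table()].
#' @param weight_by_count Weight bins by their answer counts? Default
#'   `FALSE`.
#' @return A data.frame with columns `r`, `slope`, `intercept`, `n_points`;
#'   groups with fewer than two distinct `x` bins are omitted with a
#'   warning.
#' @export
weber_slopes <- function(wt, weight_by_count = FALSE) {
  need <- c("r", "x", "fraction", "R")
  if (!all(need %in% names(wt))) {
    stop("Weber table must have columns r, x, fraction, R", call. = FALSE)
  }
  out <- lapply(split(wt, wt$r), function(g) {
    if (length(unique(g$x)) < 2) return(NULL)
    fit <- if (weight_by_count) {
      stats::lm(fraction ~ x, data = g, weights = g$R)
    } else {
      stats::lm(fraction ~ x, data = g)
    }
    data.frame(r = g$r[1], slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]), n_points = nrow(g))
  })
  dropped <- names(out)[vapply(out, is.null, logical(1))]
  if (length(dropped)) {
    warning("omitting r group(s) with a single x bin: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    return(data.frame(r = numeric(0), slope = numeric(0),
                      intercept = numeric(0), n_points = integer(0)))
  }
  res <- res[order(res$r), , drop = FALSE]
  rownames(res) <- NULL
  res
}
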