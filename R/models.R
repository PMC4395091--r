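#' @name model_families
#' @title The six competing choice-model families
#'
#' @description Six functional forms for the probability of choosing the
#' correct option A given an observed social-information condition
#' `(n_A, n_B)`:
#'
#' * `M1`: `delta^n_A / (delta^n_A + delta^n_B)` — one parameter
#'   (`delta > 0`); a special case of M6 with unbiased prior (`p = 1`,
#'   `s = 1/delta`).
#' * `M2`: `(delta + n_A)^eps / ((delta + n_A)^eps + (delta + n_B)^eps)`
#'   (`delta > 0`, `eps > 0`).
#' * `M3`: `(delta + eps * n_A) / (1 + eps * (n_A + n_B))`
#'   (`0 <= delta <= 1`, `eps >= 0`; values must land in `[0, 1]` on the
#'   evaluated counts, checked, never clamped).
#' * `M4`: `1/2 + delta * (n_A - n_B) / (n_A + n_B + eps)`
#'   (`delta >= 0`, `eps >= 0`; range-checked like M3).
#' * `M5`: `[1 + (1 + delta * eps^-n_A) / (1 + delta * eps^-n_B)]^-1`
#'   (`delta >= 0`, `eps > 1`).
#' * `M6`: `1 / (1 + p * s^(n_A - n_B))` — the Bayesian model
#'   (`p > 0`, `0 < s <= 1`); see [belief_from_counts()].
#'
#' Parameter vectors are named: `delta` (and `eps`) for M1–M5, `p` and `s`
#' for M6. The parameter bounds above are the smallest domains that contain
#' the published fitted values for these families while guaranteeing outputs
#' in `[0, 1]`; out-of-range evaluations raise an error so that fitting can
#' never silently exploit an invalid region.
NULL

model_family_names <- c("M1", "M2", "M3", "M4", "M5", "M6")

model_param_names <- list(
  M1 = "delta",
  M2 = c("delta", "eps"),
  M3 = c("delta", "eps"),
  M4 = c("delta", "eps"),
  M5 = c("delta", "eps"),
  M6 = c("p", "s")
)

# Static (count-independent) admissibility of a parameter vector.
model_params_admissible <- function(family, params) {
  d <- params[[1]]
  e <- if (length(params) > 1) params[[2]] else NA_real_
  switch(family,
    M1 = d > 0,
    M2 = d > 0 && e > 0,
    M3 = d >= 0 && d <= 1 && e >= 0,
    M4 = d >= 0 && e >= 0,
    M5 = d >= 0 && e > 1,
    M6 = d > 0 && e > 0 && e <= 1
  )
}

#' Evaluate a choice-model family at observed conditions
#'
#' Computes the probability of answering A for one of the six model families
#' (see [model_families]) at the given counts. Parameters outside the
#' family's admissible domain, or parameters for which the linear families
#' M3/M4 would leave `[0, 1]` at any of the evaluated counts, raise a domain
#' error naming the family — results are never clamped.
#'
#' @param family One of `"M1"` ... `"M6"`.
#' @param params Named numeric vector: `delta` (and `eps`) for M1–M5;
#'   `p`, `s` for M6.
#' @param n_A,n_B Non-negative integer counts. Vectorised.
#' @return Probabilities in `[0, 1]`, same length as the counts.
#' @examples
#' model_probability("M6", c(p = 0.81, s = 0.75), n_A = 3, n_B = 1)
#' model_probability("M1", c(delta = 2), n_A = 0:3, n_B = 3:0)
#' @export
model_probability <- function(family, params, n_A, n_B) {
  family <- match.arg(family, model_family_names)
  check_counts(n_A, n_B)
  wanted <- model_param_names[[family]]
  if (!all(wanted %in% names(params))) {
    stop(sprintf("%s requires parameters named %s", family,
                 paste(wanted, collapse = ", ")), call. = FALSE)
  }
  params <- params[wanted]
  if (!model_params_admissible(family, params)) {
    stop(sprintf("parameters outside the admissible domain for %s", family),
         call. = FALSE)
  }
  pr <- drop(model_prob_matrix(family, matrix(unlist(params), nrow = 1),
                               n_A, n_B, screen = FALSE))
  if (anyNA(pr) || any(pr < 0 | pr > 1)) {
    stop(sprintf("%s leaves [0, 1] at some evaluated counts for these parameters",
                 family), call. = FALSE)
  }
  pr
}

# Vectorised evaluation: `pars` is a G x npar matrix of parameter vectors,
# returns a G x K matrix of probabilities (K = length(n_A)). Rows violating
# the family's domain -- including the dynamic [0,1] range check for M3/M4 --
# come back as NA when `screen` is TRUE.
model_prob_matrix <- function(family, pars, n_A, n_B, screen = TRUE) {
  d <- pars[, 1]
  e <- if (ncol(pars) > 1) pars[, 2] else NULL
  diff <- n_A - n_B
  tot <- n_A + n_B
  P <- switch(family,
    M1 = stats::plogis(outer(log(d), diff)),
    M2 = {
      tA <- exp(sweep(log(outer(d, n_A, "+")), 1, e, "*"))
      tB <- exp(sweep(log(outer(d, n_B, "+")), 1, e, "*"))
      tA / (tA + tB)
    },
    M3 = {
      num <- sweep(outer(e, n_A), 1, d, "+")
      num / (1 + outer(e, tot))
    },
    M4 = 0.5 + outer(d, diff) / outer(e, tot, "+"),
    M5 = {
      tA <- 1 + sweep(exp(-outer(log(e), n_A)), 1, d, "*")
      tB <- 1 + sweep(exp(-outer(log(e), n_B)), 1, d, "*")
      1 / (1 + tA / tB)
    },
    M6 = stats::plogis(-sweep(outer(log(e), diff), 1, log(d), "+"))
  )
  if (screen) {
    ok <- vapply(seq_len(nrow(pars)), function(g) {
      model_params_admissible(family, pars[g, ])
    }, logical(1))
    bad_row <- !ok | rowSums(is.na(P) | P < 0 | P > 1) > 0
    P[bad_row, ] <- NA_real_
  }
  P
}

#' Large-group limit of a choice model
#'
#' As the number of observed answers `r = n_A + n_B` grows with the fraction
#' of A answers held at `x`, the six families converge to different limiting
#' response curves, which is what distinguishes them in principle with data
#' at large `r`:
#'
#' * M1, M6: a step function of `sign(x - 1/2)` (value `1/2` at `x = 1/2`);
#' * M2: `x^eps / (x^eps + (1 - x)^eps)` (Weber's law when `eps = 1`);
#' * M3: `x` itself;
#' * M4: `1/2 + delta * (2 x - 1)`;
#' * M5: the constant `1/2`.
#'
#' @param family One of `"M1"` ... `"M6"`.
#' @param params Named parameter vector as in [model_probability()]; only
#'   families whose limit depends on a parameter (M2, M4) consult it.
#' @param x Fraction of A answers among those observed, in `[0, 1]`.
#'   Vectorised.
#' @return The limiting probability of answering A at each `x`.
#' @export
asymptotic_limit <- function(family, params = NULL, x) {
  family <- match.arg(family, model_family_names)
  if (any(x < 0 | x > 1)) stop("`x` must lie in [0, 1]", call. = FALSE)
  switch(family,
    M1 = ,
    M6 = ifelse(x > 0.5, 1, ifelse(x < 0.5, 0, 0.5)),
    M2 = {
      e <- params[["eps"]]
      x^e / (x^e + (1 - x)^e)
    },
    M3 = x,
    M4 = 0.5 + params[["delta"]] * (2 * x - 1),
    M5 = rep(0.5, length(x))
  )
}
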