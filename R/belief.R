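#' Single Bayesian belief update from one observed peer answer
#'
#' Updates an agent's belief that option A is correct after observing one
#' peer's answer, by Bayes' rule with symmetric likelihood: the peer's answer
#' is assumed to match the agent's own hypothesis with probability `c` (the
#' *flexibility*). `c = 1/2` makes the observation uninformative; `c` close to
#' 1 makes each observation strongly persuasive.
#'
#' @param prior Prior belief in A, in `[0, 1]`. Vectorised.
#' @param observed Observed answer, `"A"` or `"B"`.
#' @param c Flexibility, a probability with `1/2 <= c < 1`.
#' @return Posterior belief in A, same length as `prior`.
#' @examples
#' bayes_update(0.5, "A", c = 0.7)   # flat prior: posterior equals c
#' bayes_update(0.8, "B", c = 0.7)
#' @export
bayes_update <- function(prior, observed, c) {
  check_flexibility(c)
  if (any(prior < 0 | prior > 1)) {
    stop("`prior` must lie in [0, 1]", call. = FALSE)
  }
  observed <- match.arg(observed, c("A", "B"))
  if (observed == "A") {
    c * prior / (c * prior + (1 - c) * (1 - prior))
  } else {
    (1 - c) * prior / ((1 - c) * prior + c * (1 - prior))
  }
}

#' Fold a sequence of observed answers through the Bayesian update
#'
#' Applies [bayes_update()] once per observed answer. Because the update is
#' multiplicative in the likelihood ratio, the result depends only on the
#' counts of A and B labels, not on their order, and equals the closed form
#' [belief_from_counts()] with `p = (1 - initial)/initial` and
#' `s = (1 - c)/c`.
#'
#' @param initial Initial belief in A, in `[0, 1]`.
#' @param sequence Character vector of `"A"`/`"B"` labels; may be empty.
#' @param c Flexibility, `1/2 <= c < 1`.
#' @return Final belief in A.
#' @export
iterate_updates <- function(initial, sequence, c) {
  check_flexibility(c)
  if (length(sequence) && !all(sequence %in% c("A", "B"))) {
    stop("`sequence` may contain only \"A\" and \"B\" labels", call. = FALSE)
  }
  belief <- initial
  for (lab in sequence) belief <- bayes_update(belief, lab, c)
  belief
}

#' Closed-form belief after observing (n_A, n_B) peer answers
#'
#' The belief in A after observing `n_A` correct and `n_B` incorrect peer
#' answers is the logistic function
#' \deqn{P[A] = \frac{1}{1 + p\, s^{\,n_A - n_B}},}
#' where `p` is the prior odds against A (initial belief `P0 = 1/(1+p)`) and
#' `s = (1 - c)/c` is the per-observation evidence factor. Computed in
#' log-odds space, so large `|n_A - n_B|` cannot overflow.
#'
#' @param p Prior odds against A, `p > 0`.
#' @param s Response parameter, `0 < s <= 1`.
#' @param n_A,n_B Non-negative counts of observed A and B answers. Vectorised.
#' @return Belief in A, in `[0, 1]`.
#' @examples
#' belief_from_counts(p = 0.81, s = 0.75, n_A = 3, n_B = 1)
#' p0_from_p(0.1)  # initial belief for a question with p = 0.1
#' @export
belief_from_counts <- function(p, s, n_A, n_B) {
  stats::plogis(-z_transform(p, s, n_A, n_B))
}

#' Logistic rescaling z of a social-information condition
#'
#' Maps a condition `(n_A, n_B)` to `z = (n_A - n_B) log(s) + log(p)`, the
#' log-odds against A under the Bayesian model, so that
#' `belief_from_counts(p, s, n_A, n_B) == 1/(1 + exp(z))` exactly. Conditions
#' from questions with different `(p_q, s_q)` collapse on this single logistic
#' curve when each is rescaled with its own parameters.
#'
#' @inheritParams belief_from_counts
#' @return Numeric z values.
#' @export
z_transform <- function(p, s, n_A, n_B) {
  if (any(p <= 0) || any(s <= 0)) {
    stop("`p` and `s` must be strictly positive", call. = FALSE)
  }
  check_counts(n_A, n_B)
  (n_A - n_B) * log(s) + log(p)
}

#' @name parameter_conversions
#' @title Conversions between the model's parameterisations
#'
#' @description The belief model can be written either in terms of the
#' flexibility `c` and initial belief `P0`, or the response parameter
#' `s = (1 - c)/c` and prior odds `p = (1 - P0)/P0`. These helpers convert
#' between the two; each pair is mutually inverse.
#'
#' @param c Flexibility, `1/2 <= c < 1`.
#' @param s Response parameter, `0 < s <= 1`.
#' @param p Prior odds against A, `p > 0`.
#' @param p0 Initial belief in A, `0 < p0 < 1`.
#' @return The converted parameter value.
#' @examples
#' c_from_s(0.4)    # ~0.71: fish-experiment responsiveness in c units
#' p0_from_p(0.1)   # ~0.91: a question the population starts out knowing
NULL

#' @rdname parameter_conversions
#' @export
s_from_c <- function(c) {
  check_flexibility(c)
  (1 - c) / c
}

#' @rdname parameter_conversions
#' @export
c_from_s <- function(s) {
  if (any(s <= 0 | s > 1)) stop("`s` must lie in (0, 1]", call. = FALSE)
  1 / (1 + s)
}

#' @rdname parameter_conversions
#' @export
p_from_p0 <- function(p0) {
  if (any(p0 <= 0 | p0 >= 1)) stop("`p0` must lie in (0, 1)", call. = FALSE)
  (1 - p0) / p0
}

#' @rdname parameter_conversions
#' @export
p0_from_p <- function(p) {
  if (any(p <= 0)) stop("`p` must be strictly positive", call. = FALSE)
  1 / (1 + p)
}

check_flexibility <- function(c) {
  if (any(c < 0.5 | c >= 1)) {
    stop("flexibility `c` must satisfy 1/2 <= c < 1", call. = FALSE)
  }
  invisible(c)
}

check_counts <- function(n_A, n_B) {
  if (any(n_A < 0) || any(n_B < 0)) {
    stop("counts `n_A`, `n_B` must be non-negative", call. = FALSE)
  }
  invisible(NULL)
}
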