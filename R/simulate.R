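#' Configure a sequential answering protocol
#'
#' Builds the configuration of one of the two sequential answering protocols.
#' A population of `n_subjects` labelled agents answers each question over a
#' schedule of rounds with increasing information condition `r`: in the first
#' round (`r = 0`) everyone answers privately; in the round with finite
#' condition `r >= 1` subjects labelled `1..r` have left the question (their
#' last answers stay visible, "quenched") and each remaining subject, in
#' ascending label order, observes the most recent answers of its `r`
#' immediate predecessors before answering; in the final round (`r = Inf`)
#' the remaining subjects observe the most recent answers of *all* preceding
#' subjects.
#'
#' @param style `"D1"` (face-to-face: 31 subjects, 100 questions, rounds
#'   `r = 0, 1, 2, 3, 5, 7, 9, Inf`, labels fixed across questions) or
#'   `"D2"` (web-based: 52 subjects, 120 questions, rounds
#'   `r = 0, 1, 5, 11, 21, Inf`, labels reshuffled at each question).
#'   Defaults below can be overridden.
#' @param n_subjects,n_questions Population and question counts.
#' @param r_schedule Strictly increasing numeric vector of information
#'   conditions, starting at 0, with `Inf` (the all-predecessors round) last
#'   if present; finite entries must be `< n_subjects`.
#' @param shuffle_labels Logical; permute subject labels independently for
#'   each question.
#' @param nonresponse_prob Per-answer probability that a subject fails to
#'   respond in a round (its previous answer then stays visible); default 0,
#'   i.e. full participation.
#' @param seed Integer seed used by [run_experiment()] unless overridden.
#' @return A `protocol_config` list.
#' @examples
#' protocol_config("D1")
#' protocol_config("D2", n_questions = 10)
#' @export
protocol_config <- function(style = c("D1", "D2"),
                            n_subjects = NULL, n_questions = NULL,
                            r_schedule = NULL, shuffle_labels = NULL,
                            nonresponse_prob = 0, seed = 1L) {
  style <- match.arg(style)
  defaults <- if (style == "D1") {
    list(n_subjects = 31L, n_questions = 100L,
         r_schedule = c(0, 1, 2, 3, 5, 7, 9, Inf), shuffle_labels = FALSE)
  } else {
    list(n_subjects = 52L, n_questions = 120L,
         r_schedule = c(0, 1, 5, 11, 21, Inf), shuffle_labels = TRUE)
  }
  cfg <- list(
    style = style,
    n_subjects = as.integer(n_subjects %||% defaults$n_subjects),
    n_questions = as.integer(n_questions %||% defaults$n_questions),
    r_schedule = r_schedule %||% defaults$r_schedule,
    shuffle_labels = shuffle_labels %||% defaults$shuffle_labels,
    nonresponse_prob = nonresponse_prob,
    seed = as.integer(seed)
  )
  rs <- cfg$r_schedule
  if (rs[1] != 0) stop("`r_schedule` must start at r = 0", call. = FALSE)
  if (any(is.infinite(rs)) && !is.infinite(rs[length(rs)])) {
    stop("the all-predecessors round (Inf) must come last", call. = FALSE)
  }
  if (any(diff(rs) <= 0)) {
    stop("`r_schedule` must be strictly increasing", call. = FALSE)
  }
  if (any(rs[is.finite(rs)] >= cfg$n_subjects)) {
    stop("finite `r_schedule` entries must be smaller than `n_subjects`: ",
         "no subject could both leave and answer", call. = FALSE)
  }
  if (cfg$nonresponse_prob < 0 || cfg$nonresponse_prob >= 1) {
    stop("`nonresponse_prob` must lie in [0, 1)", call. = FALSE)
  }
  structure(cfg, class = "protocol_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.protocol_config <- function(x, ...) {
  cat(sprintf("<protocol_config %s> %d subjects, %d questions, rounds r = %s%s\n",
              x$style, x$n_subjects, x$n_questions,
              paste(x$r_schedule, collapse = ", "),
              if (x$shuffle_labels) " (labels shuffled per question)" else ""))
  invisible(x)
}

#' Per-question ground truth of the belief model
#'
#' A question's difficulty and social responsiveness: `p_q` is the prior odds
#' against the correct answer and `s_q` the per-observation evidence factor.
#'
#' @param question_id Identifier(s).
#' @param p_q Prior odds, `> 0`.
#' @param s_q Response parameter, in `(0, 1]`.
#' @return A data.frame with columns `question_id`, `p_q`, `s_q`.
#' @export
question_truth <- function(question_id, p_q, s_q) {
  if (any(p_q <= 0)) stop("`p_q` must be positive", call. = FALSE)
  if (any(s_q <= 0 | s_q > 1)) stop("`s_q` must lie in (0, 1]", call. = FALSE)
  data.frame(question_id = question_id, p_q = p_q, s_q = s_q)
}

#' Sample per-question ground truths
#'
#' Draws question parameters emulating the spread seen across real quiz
#' questions: `log(p_q)` normal with mean `log(0.8)` and sd `0.8`, truncated
#' to `p_q` in `[0.05, 20]` (most questions easier than chance, some harder);
#' `s_q` uniform on `[0.4, 1]`; the two independent.
#'
#' @param n_questions Number of questions.
#' @param p_meanlog,p_sdlog Parameters of the log-normal for `p_q`.
#' @param p_range Truncation range for `p_q`.
#' @param s_range Range of the uniform for `s_q`.
#' @return A ground-truth data.frame as from [question_truth()].
#' @export
sample_question_truths <- function(n_questions,
                                   p_meanlog = log(0.8), p_sdlog = 0.8,
                                   p_range = c(0.05, 20),
                                   s_range = c(0.4, 1)) {
  p <- numeric(0)
  while (length(p) < n_questions) {
    cand <- exp(stats::rnorm(n_questions, p_meanlog, p_sdlog))
    p <- c(p, cand[cand >= p_range[1] & cand <= p_range[2]])
  }
  question_truth(seq_len(n_questions), p[seq_len(n_questions)],
                 stats::runif(n_questions, s_range[1], s_range[2]))
}

#' Tally the most recent answers visible to a subject
#'
#' Counts A and B among the latest answers of the `r` immediate predecessors
#' of `subject` (all predecessors when `r = Inf`). "Latest" means the answer
#' already given in the current round if the predecessor has answered this
#' round, otherwise the last answer on record — which is how a departed
#' subject's quenched answer stays visible.
#'
#' @param latest Character vector of each subject's most recent answer
#'   (`"A"`, `"B"`, or `NA` if none), with in-progress current-round answers
#'   already written in.
#' @param subject Label (1-based) of the observing subject.
#' @param r Information condition: non-negative integer or `Inf`.
#' @return Named vector `c(n_A = ..., n_B = ...)`.
#' @export
most_recent_answers <- function(latest, subject, r) {
  if (r == 0) return(c(n_A = 0L, n_B = 0L))
  first <- max(1, subject - r)
  obs <- latest[seq(first, subject - 1)]
  obs <- obs[!is.na(obs)]
  c(n_A = sum(obs == "A"), n_B = sum(obs == "B"))
}

#' Simulate one question through the full round schedule
#'
#' Runs a single question under the protocol: each answering subject draws
#' answer A with probability `belief_from_counts(p_q, s_q, n_A, n_B)`, where
#' `(n_A, n_B)` are the most recent answers of the predecessors the current
#' round lets it observe (so each round's belief is computed afresh from the
#' displayed counts, not carried over from the subject's earlier rounds).
#'
#' @param config A [protocol_config()].
#' @param p_q,s_q Ground-truth parameters of the question.
#' @param question_id Identifier stored in the records.
#' @param dataset_id Dataset label stored in the records.
#' @return A data.frame of response records with columns `dataset_id`,
#'   `question_id`, `round_index`, `r_condition`, `subject_label`,
#'   `n_A_observed`, `n_B_observed`, `answer`. Uses the current RNG stream.
#' @export
run_question <- function(config, p_q, s_q, question_id = 1L,
                         dataset_id = config$style) {
  stopifnot(inherits(config, "protocol_config"))
  n <- config$n_subjects
  latest <- rep(NA_character_, n)
  departed_upto <- 0L
  nmax <- length(config$r_schedule) * n
  out_label <- integer(nmax); out_round <- integer(nmax)
  out_r <- numeric(nmax); out_nA <- integer(nmax); out_nB <- integer(nmax)
  out_ans <- character(nmax)
  k <- 0L

  for (round_index in seq_along(config$r_schedule)) {
    r <- config$r_schedule[round_index]
    if (is.finite(r) && r >= 1) departed_upto <- max(departed_upto, as.integer(r))
    active <- seq.int(departed_upto + 1L, n)
    for (i in active) {
      if (config$nonresponse_prob > 0 &&
          stats::runif(1) < config$nonresponse_prob) next
      counts <- most_recent_answers(latest, i, r)
      prob_A <- belief_from_counts(p_q, s_q, counts[["n_A"]], counts[["n_B"]])
      ans <- if (stats::runif(1) < prob_A) "A" else "B"
      latest[i] <- ans
      k <- k + 1L
      out_label[k] <- i; out_round[k] <- round_index; out_r[k] <- r
      out_nA[k] <- counts[["n_A"]]; out_nB[k] <- counts[["n_B"]]
      out_ans[k] <- ans
    }
  }
  idx <- seq_len(k)
  data.frame(
    dataset_id = dataset_id, question_id = question_id,
    round_index = out_round[idx], r_condition = out_r[idx],
    subject_label = out_label[idx], n_A_observed = out_nA[idx],
    n_B_observed = out_nB[idx], answer = out_ans[idx]
  )
}

#' Simulate a full experiment
#'
#' Loops [run_question()] over questions, drawing ground truths from a
#' sampler unless supplied, and reshuffling subject labels per question when
#' the protocol asks for it. Deterministic given the seed.
#'
#' @param config A [protocol_config()].
#' @param truths Optional ground-truth data.frame (`question_id`, `p_q`,
#'   `s_q`) with at least `n_questions` rows; sampled with
#'   [sample_question_truths()] when `NULL`.
#' @param seed Integer seed; defaults to `config$seed`.
#' @param dataset_id Dataset label stored in the records.
#' @return List with `records` (all response records) and `truths` (the
#'   generating parameters, for parameter-recovery checks).
#' @examples
#' cfg <- protocol_config("D1", n_questions = 2)
#' sim <- run_experiment(cfg, seed = 7)
#' head(sim$records)
#' @export
run_experiment <- function(config, truths = NULL, seed = config$seed,
                           dataset_id = config$style) {
  stopifnot(inherits(config, "protocol_config"))
  set.seed(seed)
  if (is.null(truths)) {
    truths <- sample_question_truths(config$n_questions)
  }
  if (nrow(truths) < config$n_questions) {
    stop("`truths` must supply one row per question", call. = FALSE)
  }
  per_q <- vector("list", config$n_questions)
  for (q in seq_len(config$n_questions)) {
    if (config$shuffle_labels) {
      # label permutation: irrelevant to exchangeable model agents, but drawn
      # so the RNG stream matches the protocol's actual randomisation steps
      sample.int(config$n_subjects)
    }
    per_q[[q]] <- run_question(config, truths$p_q[q], truths$s_q[q],
                               question_id = truths$question_id[q],
                               dataset_id = dataset_id)
  }
  list(records = do.call(rbind, per_q),
       truths = truths[seq_len(config$n_questions), , drop = FALSE])
}
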