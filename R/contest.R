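#' Early error of an error curve
#'
#' The contest statistic: the mean unsigned error over shots 3 through 7 of a
#' per-shot error curve (averaged across test blocks).  Shots 3-7 are the
#' window in which learners of different orders are most clearly separated —
#' all start a block at the same error and the slower ones catch up late in
#' the block.
#'
#' @param curve Numeric per-shot error curve (1-based shot index, length >= 7).
#' @return Scalar mean of `curve[3:7]`.
#' @examples
#' early_error(c(1, 1, .5, .5, .5, .5, .5, 0, 0, 0, 0, 0, 0, 0, 0))
#' @export
early_error <- function(curve) {
  if (inherits(curve, "vml_curves")) curve <- curve$mean_curve
  if (length(curve) < 7) {
    abort("`curve` must cover at least 7 shots.", class = "vmlearn_invalid_argument")
  }
  mean(curve[3:7])
}

#' Per-repetition early errors of a simulated experiment
#'
#' @param x A `vml_curves` object from [run_experiment()].
#' @return Numeric vector, one early error per repetition.
#' @export
rep_early_errors <- function(x) {
  stopifnot(inherits(x, "vml_curves"))
  colMeans(x$curves[3:7, , drop = FALSE])
}

#' Brute-force Monte-Carlo p-value of a human-vs-doppelganger contest
#'
#' Counts the repetitions in which the simulated learner's early error was as
#' small as the human's (`<=`).  The empirical p-value is `count / n_reps`;
#' when the count is zero the p-value is reported as the upper bound
#' `1/n_reps` with `p_is_bound = TRUE`, never as 0.  This counting approach
#' makes no distributional assumptions.
#'
#' @param human_early The human subject's early error (scalar).
#' @param dopp_samples Per-repetition doppelganger early errors.
#' @return A `vml_contest` object (see [tidy.vml_contest()]).
#' @examples
#' brute_force_p(0.25, c(0.3, 0.28, 0.24, 0.31))
#' @export
brute_force_p <- function(human_early, dopp_samples) {
  if (length(dopp_samples) < 1) {
    abort("`dopp_samples` must be non-empty.", class = "vmlearn_invalid_argument")
  }
  n_reps <- length(dopp_samples)
  count_leq <- sum(dopp_samples <= human_early)
  structure(
    list(
      human_early = human_early,
      n_reps = n_reps,
      count_leq = count_leq,
      p_value = if (count_leq == 0) 1 / n_reps else count_leq / n_reps,
      p_is_bound = count_leq == 0,
      dopp_mean = mean(dopp_samples),
      dopp_sd = sd(dopp_samples),
      dopp_min = min(dopp_samples),
      dopp_max = max(dopp_samples)
    ),
    class = "vml_contest"
  )
}

#' @export
print.vml_contest <- function(x, ...) {
  cat("<vml_contest> human early error ", signif(x$human_early, 4),
    " vs doppelganger mean ", signif(x$dopp_mean, 4),
    " [", signif(x$dopp_min, 4), ", ", signif(x$dopp_max, 4), "]\n",
    "  p ", if (x$p_is_bound) "< " else "= ", signif(x$p_value, 4),
    "  (", x$count_leq, "/", x$n_reps, " repetitions at or below the human)\n",
    sep = ""
  )
  invisible(x)
}

#' Tidy a contest result
#'
#' @param x A `vml_contest`.
#' @param ... Unused.
#' @return `tidy()` gives a one-row tibble with the contest summary;
#'   `glance()` gives the p-value, its bound flag and the repetition count.
#' @export
tidy.vml_contest <- function(x, ...) {
  tibble::tibble(
    human_early = x$human_early, dopp_mean = x$dopp_mean, dopp_sd = x$dopp_sd,
    dopp_min = x$dopp_min, dopp_max = x$dopp_max,
    count_leq = x$count_leq, n_reps = x$n_reps,
    p_value = x$p_value, p_is_bound = x$p_is_bound
  )
}

#' @rdname tidy.vml_contest
#' @export
glance.vml_contest <- function(x, ...) {
  tibble::tibble(
    p_value = x$p_value, p_is_bound = x$p_is_bound,
    count_leq = x$count_leq, n_reps = x$n_reps
  )
}

#' Group-level contest: cohort mean versus doppelganger-cohort mean
#'
#' For each repetition the doppelganger early errors are averaged across
#' subjects and that group mean is compared, by the brute-force count, to the
#' human group mean.
#'
#' @param human_earlies One early error per subject.
#' @param dopp_early_matrix `n_reps x n_subjects` matrix of per-repetition,
#'   per-subject doppelganger early errors (subject order matching
#'   `human_earlies`).
#' @return A `vml_contest`.
#' @export
group_contest <- function(human_earlies, dopp_early_matrix) {
  dopp_early_matrix <- as.matrix(dopp_early_matrix)
  if (ncol(dopp_early_matrix) != length(human_earlies)) {
    abort("subject count mismatch between humans and doppelganger matrix.",
      class = "vmlearn_invalid_argument"
    )
  }
  brute_force_p(mean(human_earlies), rowMeans(dopp_early_matrix))
}

#' Shot-by-shot contests
#'
#' Robustness check on the choice of the early-error window: the brute-force
#' contest is repeated separately at every shot after the first.
#'
#' @param human_curve The human's 15-shot error curve.
#' @param dopp_curves `shots x n_reps` matrix of per-repetition doppelganger
#'   curves (e.g. `x$curves` from [run_experiment()]).
#' @return A tibble with one row per shot 2..15: `shot`, `count_leq`,
#'   `n_reps`, `p_value`, `p_is_bound`.
#' @export
per_shot_contest <- function(human_curve, dopp_curves) {
  n_shots <- length(human_curve)
  stopifnot(nrow(dopp_curves) == n_shots)
  purrr::map_dfr(2:n_shots, function(t) {
    ct <- brute_force_p(human_curve[t], dopp_curves[t, ])
    tibble::tibble(
      shot = t, count_leq = ct$count_leq, n_reps = ct$n_reps,
      p_value = ct$p_value, p_is_bound = ct$p_is_bound
    )
  })
}

#' Re-run a contest with scaled response variability
#'
#' Robustness check on the precision matching: the doppelganger's fitted
#' response-noise SD is multiplied by `scale` (hyperparameters are *not*
#' re-optimized — the scaling perturbs the fitted doppelganger) and both the
#' early-error contest and the shot-by-shot contests are recomputed.
#'
#' @param scale Positive multiplier on `sigma_r` (e.g. 1.35 for +35%).
#' @param order `"first"` or `"second"` (zeroth-order learners have no
#'   response-noise term).
#' @param design,w0,b0,hyper,sigma_r,n_reps,seed As in [run_experiment()].
#' @param human_curve The human's 15-shot error curve.
#' @return A list with `scale`, `early` (a `vml_contest`) and `per_shot`
#'   (tibble from [per_shot_contest()]).
#' @export
variability_scaling_contest <- function(scale, order, design, w0, b0, hyper,
                                        sigma_r, human_curve, n_reps = 1e4,
                                        seed = NULL) {
  if (order == "zeroth") {
    abort("zeroth-order learners have no response-noise term to scale.",
      class = "vmlearn_invalid_argument"
    )
  }
  stopifnot(scale > 0)
  rc <- run_experiment(order, design, w0, b0,
    hyper = hyper,
    sigma_r = scale * sigma_r, n_reps = n_reps, seed = seed
  )
  list(
    scale = scale,
    early = brute_force_p(early_error(human_curve), rep_early_errors(rc)),
    per_shot = per_shot_contest(human_curve, rc$curves)
  )
}

#' Centered running average with symmetric end truncation
#'
#' @param errors Numeric series.
#' @param window Odd window width (default 9, the smoothing used for
#'   long-block error traces).  Near the ends the window shrinks
#'   symmetrically so the average stays centered.
#' @return Smoothed series of the same length.
#' @examples
#' running_average(1:10, window = 3)
#' @export
running_average <- function(errors, window = 9) {
  if (window < 1 || window %% 2 == 0) {
    abort("`window` must be odd and >= 1.", class = "vmlearn_invalid_argument")
  }
  n <- length(errors)
  h <- (window - 1) / 2
  vapply(seq_len(n), function(i) {
    k <- min(h, i - 1, n - i)
    mean(errors[(i - k):(i + k)])
  }, numeric(1))
}

#' Test for meta-learning across blocks
#'
#' Compares each subject's early error in the first six test blocks against
#' the final six by the exact two-sided Wilcoxon signed-rank test.  A
#' significant difference would indicate that subjects improved their
#' learning ability itself (not just within-block performance).
#'
#' @param early_first Early errors in the first six test blocks, one per
#'   subject.
#' @param early_last Early errors in the final six test blocks, paired.
#' @return A list with `p_value`, `statistic` (the signed-rank V), and
#'   `degenerate` (`TRUE` when all paired differences are zero, in which case
#'   `p_value = 1`).
#' @export
meta_learning_check <- function(early_first, early_last) {
  if (length(early_first) != length(early_last)) {
    abort("paired samples must have equal length.", class = "vmlearn_invalid_argument")
  }
  d <- early_last - early_first
  if (all(d == 0)) {
    return(list(p_value = 1, statistic = NA_real_, degenerate = TRUE))
  }
  ht <- suppressWarnings(
    stats::wilcox.test(early_last, early_first,
      paired = TRUE,
      exact = length(d) <= 25, alternative = "two.sided"
    )
  )
  list(
    p_value = unname(ht$p.value),
    statistic = unname(ht$statistic),
    degenerate = FALSE
  )
}
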