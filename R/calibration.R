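#' Long-term accuracy of a 100-shot long block
#'
#' @param long_block_errors The 100 unsigned errors of the long block,
#'   shot-ordered.
#' @return Mean unsigned error over shots 51-100 (1-based, inclusive) — the
#'   late window in which performance has leveled off.
#' @export
long_term_accuracy <- function(long_block_errors) {
  if (length(long_block_errors) != 100) {
    abort("the long block has exactly 100 shots.", class = "vmlearn_invalid_argument")
  }
  mean(long_block_errors[51:100])
}

# Monte-Carlo mean shot-1 unsigned error across the design's test blocks as a
# function of the block-start (w0, b0), under fixed (common) noise draws.
# Shot 1 precedes any update, so only the first target of each block and the
# block's mapping enter.
first_shot_profile <- function(design, sigma, mc_reps, seed) {
  tb <- design_blocks(design, "test")
  x1 <- purrr::map_dbl(tb$targets, 1)
  m <- tb$m
  s <- tb$s
  noise <- withr::with_seed(seed, matrix(rnorm(mc_reps * nrow(tb)), mc_reps))
  function(w0, b0) {
    base <- m * (w0 * x1 + b0) + s - x1 # length n_blocks
    mean(abs(rep(base, each = mc_reps) + sigma * rep(m, each = mc_reps) * as.vector(noise)))
  }
}

#' Fit the block-start parameters matching a target first-shot error
#'
#' Finds a `(w0, b0)` such that a learner that begins every test block at
#' `(w0, b0)` shows the given mean unsigned error on shot 1 across the
#' design's 24 test blocks, in Monte-Carlo expectation over the learner's own
#' action noise.  The constraint is one scalar against two parameters, so the
#' bias is fixed at `b0 = 0` (the center of its range) and `w0` is found by
#' bisection on the simulated error profile, which is V-shaped in `w0`:
#' bisection runs on whichever monotone branch brackets the target (the
#' upper branch is preferred when both do).
#'
#' @param target_first_shot_error The error level to match (mean unsigned
#'   shot-1 error).
#' @param design The subject's `vml_design`.
#' @param sigma Action-noise SD entering shot 1 (the learner's `sigma_g` or
#'   `sigma_r`; 0 for a noise-free geometric match).
#' @param mc_reps Monte-Carlo repetitions for the noise expectation.
#' @param b0 Fixed bias (default 0).
#' @param tol Matching tolerance on the achieved error.
#' @param seed Seed for the common random numbers.
#' @param on_infeasible `"error"` rejects a target outside the achievable
#'   range; `"nearest"` clamps it to the closest achievable error level (a
#'   subject's observed 24-block error is one stochastic realization and can
#'   undercut the Monte-Carlo expectation's minimum).
#' @return A one-row tibble: `w0`, `b0`, `achieved`, `target`.
#' @export
fit_initial_params <- function(target_first_shot_error, design, sigma = 0,
                               mc_reps = 2000, b0 = 0, tol = 1e-3,
                               seed = 1L,
                               on_infeasible = c("error", "nearest")) {
  on_infeasible <- match.arg(on_infeasible)
  f <- first_shot_profile(design, sigma, mc_reps, seed)
  grid <- seq(W_RANGE[1], W_RANGE[2], length.out = 121)
  fg <- vapply(grid, f, numeric(1), b0 = b0)
  i_min <- which.min(fg)
  f_max <- max(fg[1], fg[length(fg)])
  if (target_first_shot_error < fg[i_min] - tol) {
    if (on_infeasible == "error") {
      abort("target first-shot error is below the achievable minimum for this design.",
        class = "vmlearn_infeasible_target"
      )
    }
    warn("target first-shot error below the achievable minimum; matching the minimum.")
    w0 <- grid[i_min]
    return(tibble::tibble(
      w0 = w0, b0 = b0, achieved = fg[i_min],
      target = target_first_shot_error
    ))
  }
  if (target_first_shot_error > f_max + tol) {
    if (on_infeasible == "error") {
      abort("target first-shot error exceeds the maximum over the (w0, b0) clip box.",
        class = "vmlearn_infeasible_target"
      )
    }
    warn("target first-shot error above the achievable maximum; matching the maximum.")
    i_max <- if (fg[1] >= fg[length(fg)]) 1L else length(fg)
    return(tibble::tibble(
      w0 = grid[i_max], b0 = b0, achieved = fg[i_max],
      target = target_first_shot_error
    ))
  }
  target_first_shot_error <- min(max(target_first_shot_error, fg[i_min]), f_max)
  # pick a monotone branch of the V that brackets the target
  use_upper <- fg[length(fg)] >= target_first_shot_error
  lo <- if (use_upper) grid[i_min] else W_RANGE[1]
  hi <- if (use_upper) W_RANGE[2] else grid[i_min]
  root <- uniroot(
    function(w) f(w, b0) - target_first_shot_error,
    lower = lo, upper = hi, extendInt = "no", tol = 1e-9
  )
  w0 <- root$root
  tibble::tibble(
    w0 = w0, b0 = b0, achieved = f(w0, b0),
    target = target_first_shot_error
  )
}

#' Fit the response-noise SD matching a target long-block accuracy
#'
#' Finds `sigma_r` such that the learner's median unsigned error over shots
#' 51-100 of the subject's 100-shot long block (same mapping and targets,
#' learning switched on, Monte-Carlo over noise) matches the target.  The
#' median is monotone in `sigma_r`, so the match is found by root-finding on
#' a common-random-numbers noise surface.
#'
#' @param target_median_error The human's median unsigned error over the
#'   final 50 shots of the long block.
#' @param order `"first"` or `"second"` (zeroth-order learners get no
#'   response noise by design).
#' @param design The subject's `vml_design` (its long block is used).
#' @param w0,b0 Block-start parameters.
#' @param hyper Learner hyperparameters.
#' @param mc_reps Monte-Carlo repetitions of the long block.
#' @param seed Seed for the common random numbers.
#' @param sigma_max Upper bracket for the search.
#' @param rls_variant See [learner_state()].
#' @return A list: `sigma_r`, `achieved`, `target`.
#' @export
fit_sigma_r <- function(target_median_error, order, design, w0, b0,
                        hyper = default_hyper(order), mc_reps = 500,
                        seed = 1L, sigma_max = 1, rls_variant = "printed") {
  if (!order %in% c("first", "second")) {
    abort("response noise is fitted only for first/second-order learners.",
      class = "vmlearn_invalid_argument"
    )
  }
  if (target_median_error < 0) {
    abort("target median error must be >= 0.", class = "vmlearn_invalid_argument")
  }
  if (target_median_error == 0) {
    warn("target median error is 0: returning sigma_r = 0 (converged learner).")
    return(list(sigma_r = 0, achieved = 0, target = 0))
  }
  lb <- design_blocks(design, "long")
  targets <- matrix(lb$targets[[1]], ncol = 1)[, rep(1, mc_reps), drop = FALSE]
  z <- withr::with_seed(seed, matrix(rnorm(length(targets)), nrow(targets)))
  g <- function(sigma) {
    sim <- sim_paths(order, targets,
      w_star = lb$w_star, b_star = lb$b_star,
      w0 = w0, b0 = b0, hyper = hyper, sigma = sigma,
      rls_variant = rls_variant, noise = sigma * z
    )
    median(sim$abs_err[51:100, ])
  }
  if (g(0) >= target_median_error) {
    warn("target median is at or below the learner's noise-free floor; returning sigma_r = 0.")
    return(list(sigma_r = 0, achieved = g(0), target = target_median_error))
  }
  root <- uniroot(function(s) g(s) - target_median_error,
    lower = 0, upper = sigma_max, extendInt = "upX", tol = 1e-7
  )
  list(
    sigma_r = root$root, achieved = g(root$root),
    target = target_median_error
  )
}
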