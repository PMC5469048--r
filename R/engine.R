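# Vectorized simulation engine.
#
# One "unit" is an independent run of a single block: its own mapping, target
# sequence, block-start state and noise stream.  All learner arithmetic is
# vectorized across units, so a million-repetition experiment is a loop over
# shots (tens of iterations), not over repetitions.  The arithmetic is the
# same as the scalar reference in learners.R; tests pin bit-level agreement.

# targets: n_shots x n_units matrix; w_star/b_star/w0/b0/sigma scalar or
# per-unit; noise: optional pre-drawn noise matrix (actual draws, same shape
# as targets).  Returns abs_err (and j, e, c if keep_paths).
sim_paths <- function(order, targets, w_star, b_star, w0, b0,
                      hyper = default_hyper(order), sigma = 0,
                      rls_variant = "printed", noise = NULL,
                      keep_paths = FALSE) {
  n_shots <- nrow(targets)
  n_units <- ncol(targets)
  w_star <- rep_len(w_star, n_units)
  b_star <- rep_len(b_star, n_units)
  m <- 1 / w_star
  s <- -b_star / w_star

  cl <- clip_wb(rep_len(w0, n_units), rep_len(b0, n_units))
  w <- cl$w
  b <- cl$b
  sd_vec <- rep_len(if (order == "zeroth") hyper$sigma_g else sigma, n_units)

  if (order == "zeroth") {
    eta_w <- hyper$eta_w %||% hyper$eta
    eta_b <- hyper$eta_b %||% hyper$eta
    L_prev <- NULL
  } else {
    m_est <- 1 / w
    s_est <- -b / w
    if (order == "second") {
      mu <- hyper$mu
      p11 <- rep(1, n_units)
      p12 <- rep(0, n_units)
      p22 <- rep(1, n_units)
    }
  }

  abs_err <- matrix(NA_real_, n_shots, n_units)
  if (keep_paths) {
    j_mat <- e_mat <- c_mat <- matrix(NA_real_, n_shots, n_units)
  }

  for (t in seq_len(n_shots)) {
    x <- targets[t, ]
    g <- if (is.null(noise)) rnorm(n_units) * sd_vec else noise[t, ]
    j <- w * x + b + g
    cpos <- m * j + s
    e <- cpos - x
    L <- e * e
    abs_err[t, ] <- abs(e)
    if (keep_paths) {
      j_mat[t, ] <- j
      e_mat[t, ] <- e
      c_mat[t, ] <- cpos
    }

    if (order == "zeroth") {
      if (t > 1L) {
        dL <- L - L_prev
        cl <- clip_wb(w - eta_w * dL * g * x, b - eta_b * dL * g)
        w <- cl$w
        b <- cl$b
      }
      L_prev <- L
    } else if (order == "first") {
      m_est <- m_est + hyper$eta_m * e * j
      s_est <- s_est + hyper$eta_s * e
      cl <- clip_wb(1 / m_est, -s_est / m_est)
      w <- cl$w
      b <- cl$b
      m_est <- 1 / w
      s_est <- -b / w
    } else { # second
      v1 <- p11 * j + p12
      v2 <- p12 * j + p22
      denom <- mu + j * v1 + v2
      k1 <- v1 / denom
      k2 <- v2 / denom
      p11 <- p11 - v1 * k1
      p12 <- p12 - v1 * k2
      p22 <- p22 - v2 * k2
      if (rls_variant == "textbook") {
        p11 <- p11 / mu
        p12 <- p12 / mu
        p22 <- p22 / mu
      }
      m_est <- m_est + e * k1
      s_est <- s_est + e * k2
      cl <- clip_wb(1 / m_est, -s_est / m_est)
      w <- cl$w
      b <- cl$b
      m_est <- 1 / w
      s_est <- -b / w
    }
  }

  out <- list(abs_err = abs_err, w = w, b = b)
  if (keep_paths) {
    out$j <- j_mat
    out$e <- e_mat
    out$c <- c_mat
  }
  out
}

#' Repeat a subject's full test-block experiment many times
#'
#' Runs a learner over the 24 test blocks of an experiment design (state reset
#' to `(w0, b0)` at every block start), repeated `n_reps` times with
#' independent noise, and returns the per-repetition error curves: for each
#' repetition, the 15-vector of mean unsigned error per shot averaged across
#' the 24 test blocks.
#'
#' @param order `"zeroth"`, `"first"` or `"second"`.
#' @param design A `vml_design` (the subject's fixed block/target sequence).
#' @param w0,b0 Block-start policy parameters (subject-matched).
#' @param hyper Hyperparameter list for the order (see [learner_state()]).
#' @param sigma_r Response-noise SD (first/second order).
#' @param n_reps Number of repetitions of the whole 24-block experiment.
#' @param seed Optional seed making the run a pure function of its arguments.
#' @param rls_variant See [learner_state()].
#' @param chunk_reps Repetitions simulated per chunk (memory control).
#' @return A `vml_curves` object: list with `curves` (shots x reps matrix),
#'   `mean_curve`, `sd_curve`, `order`, `n_reps`, `n_blocks`.
#' @examples
#' d <- make_design(seed = 1)
#' rc <- run_experiment("second", d, w0 = 0.8, b0 = 0, hyper = list(mu = 1),
#'                      sigma_r = 0.07, n_reps = 50, seed = 2)
#' rc$mean_curve
#' @export
run_experiment <- function(order, design, w0, b0, hyper = default_hyper(order),
                           sigma_r = 0, n_reps = 1e4, seed = NULL,
                           rls_variant = "printed", chunk_reps = 2e4) {
  stopifnot(n_reps >= 1)
  tb <- design_blocks(design, "test")
  n_blocks <- nrow(tb)
  n_shots <- design$shots_per_block
  block_targets <- matrix(unlist(tb$targets), nrow = n_shots) # shots x blocks

  run <- function() {
    done <- 0L
    curves <- matrix(NA_real_, n_shots, n_reps)
    while (done < n_reps) {
      k <- min(chunk_reps, n_reps - done)
      targets <- matrix(rep(block_targets, k), nrow = n_shots)
      sim <- sim_paths(order, targets,
        w_star = rep(tb$w_star, k), b_star = rep(tb$b_star, k),
        w0 = w0, b0 = b0, hyper = hyper, sigma = sigma_r,
        rls_variant = rls_variant
      )
      grp <- rep(seq_len(k), each = n_blocks)
      curves[, done + seq_len(k)] <- t(rowsum(t(sim$abs_err), grp)) / n_blocks
      done <- done + k
    }
    curves
  }
  curves <- if (is.null(seed)) run() else withr::with_seed(seed, run())

  structure(
    list(
      curves = curves,
      mean_curve = rowMeans(curves),
      sd_curve = apply(curves, 1, sd),
      order = order, n_reps = n_reps, n_blocks = n_blocks
    ),
    class = "vml_curves"
  )
}

#' Repeat the experiment with fresh random blocks each repetition
#'
#' Like [run_experiment()], but every repetition draws its own block sequence
#' (mappings and targets) from the task distributions instead of reusing one
#' subject's fixed design.  Use this to compare learning algorithms on the
#' task itself, free of the luck of any single design draw.
#'
#' @inheritParams run_experiment
#' @param blocks_per_rep Blocks simulated per repetition (24, as in a test
#'   session).
#' @param n_shots Shots per block.
#' @return A `vml_curves` object.
#' @export
run_random_experiment <- function(order, w0, b0, hyper = default_hyper(order),
                                  sigma_r = 0, n_reps = 1e4,
                                  blocks_per_rep = 24, n_shots = 15,
                                  seed = NULL, rls_variant = "printed",
                                  chunk_reps = 2e4) {
  stopifnot(n_reps >= 1)
  run <- function() {
    done <- 0L
    curves <- matrix(NA_real_, n_shots, n_reps)
    while (done < n_reps) {
      k <- min(chunk_reps, n_reps - done)
      n_units <- k * blocks_per_rep
      maps <- sample_mappings(n_units)
      targets <- matrix(sample_targets(n_shots * n_units), n_shots)
      sim <- sim_paths(order, targets,
        w_star = maps$w_star, b_star = maps$b_star,
        w0 = w0, b0 = b0, hyper = hyper, sigma = sigma_r,
        rls_variant = rls_variant
      )
      grp <- rep(seq_len(k), each = blocks_per_rep)
      curves[, done + seq_len(k)] <- t(rowsum(t(sim$abs_err), grp)) / blocks_per_rep
      done <- done + k
    }
    curves
  }
  curves <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(
    list(
      curves = curves,
      mean_curve = rowMeans(curves),
      sd_curve = apply(curves, 1, sd),
      order = order, n_reps = n_reps, n_blocks = blocks_per_rep
    ),
    class = "vml_curves"
  )
}

#' @export
print.vml_curves <- function(x, ...) {
  cat("<vml_curves> ", x$order, "-order learner, ", x$n_reps,
    " repetitions of ", x$n_blocks, " blocks\n",
    "mean curve: ", paste(signif(x$mean_curve, 3), collapse = " "), "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
tidy.vml_curves <- function(x, ...) {
  tibble::tibble(
    shot = seq_along(x$mean_curve),
    mean_error = x$mean_curve,
    sd_error = x$sd_curve,
    order = x$order
  )
}
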