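#' Hyperparameter search spaces
#'
#' @param order Learner order.
#' @param three_hyper For zeroth order, use separate learning rates
#'   `eta_w`/`eta_b` instead of a shared `eta`.
#' @return Named list of `c(lower, upper)` bounds; all strictly positive,
#'   `mu <= 1`.
#' @export
hyper_bounds <- function(order, three_hyper = FALSE) {
  switch(order,
    zeroth = {
      eta <- c(1e-2, 1e4)
      if (three_hyper) {
        list(sigma_g = c(1e-3, 0.5), eta_w = eta, eta_b = eta)
      } else {
        list(sigma_g = c(1e-3, 0.5), eta = eta)
      }
    },
    # LMS stability allows eta_m up to ~2/E[j^2] (~30 for the narrow target
    # strip); 10 keeps a safety margin while leaving the optimum interior
    first = list(eta_m = c(1e-3, 10), eta_s = c(1e-3, 10)),
    second = list(mu = c(1e-4, 1))
  )
}

# internal Monte-Carlo objective: mean unsigned error on the last shot of
# mc_blocks fresh random blocks, with common random numbers — the mappings,
# targets and (standard-normal) noise draws are a pure function of `seed`, so
# repeated evaluations differ only through the hyperparameters and the
# surface is deterministic for the simplex search.
mc_objective <- function(order, w0, b0, sigma_r, mc_blocks, seed, n_shots = 15,
                         rls_variant = "printed") {
  draws <- withr::with_seed(seed, {
    list(
      maps = sample_mappings(mc_blocks),
      targets = matrix(sample_targets(n_shots * mc_blocks), n_shots),
      z = matrix(rnorm(n_shots * mc_blocks), n_shots)
    )
  })
  function(hyper) {
    sd0 <- if (order == "zeroth") hyper$sigma_g else sigma_r
    sim <- sim_paths(order, draws$targets,
      w_star = draws$maps$w_star, b_star = draws$maps$b_star,
      w0 = w0, b0 = b0, hyper = hyper, sigma = sigma_r,
      rls_variant = rls_variant, noise = sd0 * draws$z
    )
    mean(sim$abs_err[n_shots, ])
  }
}

#' Monte-Carlo objective for hyperparameter tuning
#'
#' The quantity minimized when optimizing a doppelganger: the mean unsigned
#' error on the final (15th) shot of the block, estimated over `mc_blocks`
#' blocks freshly drawn from the task distributions, with common random
#' numbers across evaluations so the surface is smooth for Nelder-Mead.
#'
#' @param hyper Named hyperparameter list, inside [hyper_bounds()].
#' @param order,w0,b0,sigma_r Learner configuration.
#' @param mc_blocks Number of Monte-Carlo blocks.
#' @param seed Seed of the common random numbers.
#' @param rls_variant See [learner_state()].
#' @return Scalar mean shot-15 unsigned error.
#' @export
hyper_objective <- function(hyper, order, w0, b0, sigma_r = 0,
                            mc_blocks = 2000, seed = 1L,
                            rls_variant = "printed") {
  bounds <- hyper_bounds(order, three_hyper = "eta_w" %in% names(hyper))
  for (nm in names(bounds)) {
    v <- hyper[[nm]]
    if (is.null(v) || v < bounds[[nm]][1] || v > bounds[[nm]][2]) {
      abort(paste0("hyperparameter `", nm, "` missing or outside its bounds."),
        class = "vmlearn_invalid_argument"
      )
    }
  }
  mc_objective(order, w0, b0, sigma_r, mc_blocks, seed,
    rls_variant = rls_variant
  )(hyper)
}

# log for positive rates/SDs, logit for mu: Nelder-Mead is unconstrained, the
# transform enforces the bounds without penalty terms
to_unconstrained <- function(vals, names) {
  ifelse(names == "mu", stats::qlogis(pmin(pmax(vals, 1e-10), 1 - 1e-10)), log(vals))
}
from_unconstrained <- function(vals, names) {
  ifelse(names == "mu", stats::plogis(vals), exp(vals))
}

default_start <- function(order, three_hyper = FALSE) {
  switch(order,
    zeroth = if (three_hyper) {
      list(sigma_g = 0.05, eta_w = 1, eta_b = 1)
    } else {
      list(sigma_g = 0.05, eta = 1)
    },
    first = list(eta_m = 0.1, eta_s = 0.1),
    second = list(mu = 0.9)
  )
}

#' Optimize a doppelganger's hyperparameters by Nelder-Mead
#'
#' Minimizes [hyper_objective()] — the mean end-of-block (shot 15) error on
#' fresh random blocks — in transformed coordinates (log for rates and
#' perturbation SDs, logit for the RLS forgetting factor `mu`), with
#' multi-start: the canonical starting point plus `n_starts - 1` random
#' log-uniform draws inside the bounds.  The best vertex across starts is
#' returned.
#'
#' @param order,w0,b0,sigma_r Learner configuration (the subject-matched
#'   start-of-block accuracy and response variability the learner must live
#'   with).
#' @param mc_blocks Monte-Carlo blocks per objective evaluation.
#' @param n_starts Number of Nelder-Mead starts.
#' @param seed Seed controlling both the common random numbers of the
#'   objective and the random restarts.
#' @param maxit,reltol Passed to [stats::optim()].
#' @param three_hyper Zeroth order only: optimize separate `eta_w`, `eta_b`.
#' @param start Optional named list overriding the canonical first start
#'   (e.g. to warm-start from a previous fit).
#' @param rls_variant See [learner_state()].
#' @return A list: `hyper` (named list of fitted values), `objective`
#'   (achieved mean shot-15 error), `converged` (any start converged),
#'   `starts` (tibble of per-start results).
#' @export
optimize_hyperparams <- function(order, w0, b0, sigma_r = 0, mc_blocks = 2000,
                                 n_starts = 5, seed = 1L, maxit = 200,
                                 reltol = 1e-6, three_hyper = FALSE,
                                 start = NULL, rls_variant = "printed") {
  bounds <- hyper_bounds(order, three_hyper)
  nm <- names(bounds)
  obj <- mc_objective(order, w0, b0, sigma_r, mc_blocks,
    seed = derive_seed(seed, "hyperopt-crn"), rls_variant = rls_variant
  )
  fn <- function(par) obj(as.list(setNames(from_unconstrained(par, nm), nm)))

  starts <- list(unlist(start %||% default_start(order, three_hyper))[nm])
  extra <- withr::with_seed(derive_seed(seed, "hyperopt-starts"), {
    purrr::map(seq_len(max(0, n_starts - 1)), function(i) {
      vapply(bounds, function(bd) exp(runif(1, log(bd[1]), log(bd[2]))), numeric(1))
    })
  })
  starts <- c(starts, extra)

  fits <- purrr::map(starts, function(st) {
    suppressWarnings(optim(to_unconstrained(st, nm), fn,
      method = "Nelder-Mead",
      control = list(maxit = maxit, reltol = reltol)
    ))
  })
  values <- purrr::map_dbl(fits, "value")
  best <- fits[[which.min(values)]]
  raw <- from_unconstrained(best$par, nm)
  # the log transform has no ceiling; pull any runaway vertex back into the box
  clamped <- pmin(pmax(raw, purrr::map_dbl(bounds, 1)), purrr::map_dbl(bounds, 2))
  hyper <- as.list(setNames(clamped, nm))
  best_value <- if (all(clamped == raw)) best$value else obj(hyper)
  start_tbl <- tibble::tibble(
    start = seq_along(starts),
    objective = values,
    converged = purrr::map_int(fits, "convergence") == 0L
  )
  list(
    hyper = hyper, objective = best_value,
    converged = any(start_tbl$converged), starts = start_tbl
  )
}
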