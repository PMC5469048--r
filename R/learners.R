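#' @title Doppelganger learners: node perturbation, LMS, RLS
#'
#' @description
#' All learners share the linear policy `j = w * x + b` with adjustable weight
#' `w` and bias `b`, clipped after every update to the optimal-policy ranges
#' `w in [0.25, 1.75]`, `b in [-0.25, 0.25]` (the learner's prior knowledge of
#' the hypothesis space).  They differ in how feedback drives the update:
#'
#' * **zeroth order** (node perturbation): a Gaussian perturbation `g`
#'   (SD `sigma_g`) is added to the motor output and the *change* in squared
#'   error is correlated with `g`:
#'   `w <- w - eta * (L - L_prev) * g * x`, `b <- b - eta * (L - L_prev) * g`.
#'   The perturbation is the learning signal, so no separate response noise is
#'   added.
#' * **first order** (LMS): runs the delta rule on estimates of the mapping
#'   itself.  Because the action is `j = (x - s_est)/m_est`, the predicted
#'   cursor position `m_est * j + s_est` equals the target `x`, so the signed
#'   shooting error `e = c - x` *is* the prediction residual and the LMS step
#'   is `m_est <- m_est + eta_m * e * j`, `s_est <- s_est + eta_s * e`
#'   (stochastic gradient descent on `e^2` in the estimates), after which
#'   `w = 1/m_est`, `b = -s_est/m_est` are re-derived.  Gaussian response
#'   noise `r` (SD `sigma_r`) is added to the motor output.
#' * **second order** (RLS): recursive least squares on `(m_est, s_est)` with
#'   gain matrix `P` (initialized to the identity) and forgetting
#'   hyperparameter `mu in (0, 1]`; response noise as for first order.
#'
#' After clipping `w` and `b`, first- and second-order learners back-correct
#' their estimates (`m_est = 1/w`, `s_est = -b/w`) so estimates and policy
#' stay consistent.
#'
#' @name learners
NULL

clip_wb <- function(w, b) {
  list(
    w = pmin(pmax(w, W_RANGE[1]), W_RANGE[2]),
    b = pmin(pmax(b, B_RANGE[1]), B_RANGE[2])
  )
}

default_hyper <- function(order) {
  switch(order,
    zeroth = list(sigma_g = 0.05, eta = 1),
    first = list(eta_m = 0.1, eta_s = 0.1),
    second = list(mu = 0.9)
  )
}

#' Create a learner state at the start of a block
#'
#' @param order `"zeroth"`, `"first"` or `"second"`.
#' @param w0,b0 Initial policy weight and bias (the subject-matched starting
#'   hypothesis), inside the clip ranges.
#' @param hyper Named list of hyperparameters: `sigma_g`, `eta` (or `eta_w`,
#'   `eta_b`) for zeroth; `eta_m`, `eta_s` for first; `mu` for second.
#' @param sigma_r Response-noise SD for first/second order (ignored for
#'   zeroth, whose only noise is the perturbation `sigma_g`).
#' @param rls_variant `"printed"` updates `P <- P - v %*% k`; `"textbook"`
#'   additionally divides `P` by `mu` (the classical exponentially-forgetting
#'   RLS).  The two coincide at `mu = 1`.
#' @return A `vml_learner` list.
#' @examples
#' st <- learner_state("first", w0 = 1, b0 = 0, hyper = list(eta_m = .1, eta_s = .1))
#' @export
learner_state <- function(order = c("zeroth", "first", "second"),
                          w0 = 1, b0 = 0, hyper = default_hyper(order),
                          sigma_r = 0, rls_variant = c("printed", "textbook")) {
  order <- match.arg(order)
  rls_variant <- match.arg(rls_variant)
  cl <- clip_wb(w0, b0)
  st <- list(
    order = order, w = cl$w, b = cl$b, hyper = hyper,
    sigma_r = sigma_r, rls_variant = rls_variant
  )
  if (order == "zeroth") {
    st$L_prev <- NA_real_ # set to L1 after shot 1; first update after shot 2
  } else {
    st$m_est <- 1 / cl$w
    st$s_est <- -cl$b / cl$w
    if (order == "second") st$P <- diag(2)
  }
  structure(st, class = "vml_learner")
}

noise_sd <- function(state) {
  if (state$order == "zeroth") state$hyper$sigma_g else state$sigma_r
}

#' Choose a joystick position for a target
#'
#' Applies the current policy plus the learner's Gaussian noise term (the
#' perturbation `g` for zeroth order, response noise `r` otherwise).  The
#' action is *not* clipped to `[-1, 1]`: mappings and targets guarantee the
#' noiseless optimum is inside the physical range and noise excursions are
#' treated as linear extrapolation rather than introducing an unmodeled
#' saturation.
#'
#' @param state A `vml_learner`.
#' @param x Target coordinate.
#' @param noise Optional fixed noise draw (for reproducing a recorded shot);
#'   by default drawn from the current RNG.
#' @return A list with `j` (action) and `noise` (the draw used).
#' @export
act <- function(state, x, noise = NULL) {
  if (is.null(noise)) noise <- rnorm(1, 0, noise_sd(state))
  list(j = state$w * x + state$b + noise, noise = noise)
}

#' Single-shot learning updates
#'
#' Each `update_*()` consumes one shot record and returns the post-shot
#' state.  `record` is a named list carrying the quantities the rule needs:
#' target `x`, action `j`, signed error `e = c - x`, loss `L = e^2`, and for
#' zeroth order the perturbation `g` used on this shot.
#'
#' The zeroth-order rule needs a previous loss; on the first shot of a block
#' it only stores `L_prev = L` (first parameter update after shot 2).
#'
#' @param state A `vml_learner` of the matching order.
#' @param record Named list (`x`, `j`, `e`, `L`, `g` as applicable).
#' @return The updated `vml_learner`.
#' @export
update_zeroth <- function(state, record) {
  stopifnot(state$order == "zeroth")
  L <- record$L
  if (!is.na(state$L_prev)) {
    dL <- L - state$L_prev
    eta_w <- state$hyper$eta_w %||% state$hyper$eta
    eta_b <- state$hyper$eta_b %||% state$hyper$eta
    w <- state$w - eta_w * dL * record$g * record$x
    b <- state$b - eta_b * dL * record$g
    cl <- clip_wb(w, b)
    state$w <- cl$w
    state$b <- cl$b
  }
  state$L_prev <- L
  state
}

#' @rdname update_zeroth
#' @export
update_first <- function(state, record) {
  stopifnot(state$order == "first")
  m_est <- state$m_est + state$hyper$eta_m * record$e * record$j
  s_est <- state$s_est + state$hyper$eta_s * record$e
  rederive_policy(state, m_est, s_est)
}

#' @rdname update_zeroth
#' @export
update_second <- function(state, record) {
  stopifnot(state$order == "second")
  mu <- state$hyper$mu
  j <- record$j
  # P is symmetric and stays so (the update subtracts v v' / denom); the
  # decomposed arithmetic below is shared verbatim with the vectorized engine
  v1 <- state$P[1, 1] * j + state$P[1, 2]
  v2 <- state$P[1, 2] * j + state$P[2, 2]
  denom <- mu + j * v1 + v2
  if (denom <= 0) {
    abort("RLS gain denominator is non-positive (degenerate P/mu).",
      class = "vmlearn_numerical_degeneracy"
    )
  }
  k1 <- v1 / denom
  k2 <- v2 / denom
  p11 <- state$P[1, 1] - v1 * k1
  p12 <- state$P[1, 2] - v1 * k2
  p22 <- state$P[2, 2] - v2 * k2
  if (state$rls_variant == "textbook") {
    p11 <- p11 / mu
    p12 <- p12 / mu
    p22 <- p22 / mu
  }
  state$P <- matrix(c(p11, p12, p12, p22), 2)
  m_est <- state$m_est + record$e * k1
  s_est <- state$s_est + record$e * k2
  rederive_policy(state, m_est, s_est)
}

# derive w,b from estimates, clip, and back-correct the estimates
rederive_policy <- function(state, m_est, s_est) {
  w <- 1 / m_est
  b <- -s_est / m_est
  cl <- clip_wb(w, b)
  state$w <- cl$w
  state$b <- cl$b
  state$m_est <- 1 / cl$w
  state$s_est <- -cl$b / cl$w
  state
}

update_state <- function(state, record) {
  switch(state$order,
    zeroth = update_zeroth(state, record),
    first = update_first(state, record),
    second = update_second(state, record)
  )
}

#' Run one learner through one block, shot by shot
#'
#' Reference (scalar) implementation of the per-shot loop: act, observe the
#' cursor, record the error, update.  The Monte-Carlo engine
#' ([run_experiment()]) vectorizes the identical arithmetic over many
#' repetitions; the two agree bit-for-bit on shared noise draws.
#'
#' @param state A freshly initialized `vml_learner` (block-start `w0`, `b0`).
#' @param mapping A one-row mapping tibble for the block.
#' @param targets Numeric vector of target coordinates.
#' @param noise Optional numeric vector of pre-drawn noise values (length of
#'   `targets`); by default drawn from the current RNG.
#' @return A tibble of shot records: `shot`, `x`, `j`, `c`, `e` (signed
#'   error), `abs_error`, `L`, `noise_draw`, plus the final state as the
#'   `"state"` attribute.
#' @examples
#' set.seed(1)
#' st <- learner_state("second", w0 = 0.8, b0 = 0.1, hyper = list(mu = 1))
#' run_block(st, new_mapping(1.2, -0.1), sample_targets(15))
#' @export
run_block <- function(state, mapping, targets, noise = NULL) {
  n <- length(targets)
  if (is.null(noise)) noise <- rnorm(n, 0, noise_sd(state))
  stopifnot(length(noise) == n)
  j_v <- c_v <- e_v <- numeric(n)
  for (t in seq_len(n)) {
    x <- targets[t]
    a <- act(state, x, noise = noise[t])
    c_pos <- mapping$m * a$j + mapping$s
    e <- c_pos - x
    record <- list(x = x, j = a$j, e = e, L = e^2, g = a$noise)
    state <- update_state(state, record)
    j_v[t] <- a$j
    c_v[t] <- c_pos
    e_v[t] <- e
  }
  out <- tibble::tibble(
    shot = seq_len(n), x = targets, j = j_v, c = c_v, e = e_v,
    abs_error = abs(e_v), L = e_v^2, noise_draw = noise
  )
  attr(out, "state") <- state
  out
}
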