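test_that("actions follow the policy plus Gaussian noise", {
  st <- learner_state("zeroth", w0 = 1, b0 = 0, hyper = list(sigma_g = 0.05, eta = 1))
  expect_equal(act(st, 0.2, noise = 0)$j, 0.2)

  # converged, noiseless first-order learner never misses
  map <- new_mapping(0.8, 0.1)
  st <- learner_state("first",
    w0 = map$w_star, b0 = map$b_star,
    hyper = list(eta_m = 0.1, eta_s = 0.1), sigma_r = 0
  )
  rec <- run_block(st, map, sample_targets(15), noise = rep(0, 15))
  expect_equal(rec$e, rep(0, 15))

  # the action noise has the configured SD
  set.seed(5)
  st <- learner_state("zeroth", hyper = list(sigma_g = 0.08, eta = 1))
  j <- vapply(rep(0.2, 1e5), function(x) act(st, x)$j, numeric(1))
  expect_lt(abs(sd(j) - 0.08) / 0.08, 0.02)
})

test_that("the zeroth-order rule correlates loss change with the perturbation", {
  st <- learner_state("zeroth", w0 = 1, b0 = 0, hyper = list(sigma_g = 0.1, eta = 0.5))
  st$L_prev <- 0.04
  unchanged <- update_zeroth(st, list(x = 0.4, g = 0.1, L = 0.04))
  expect_equal(unchanged$w, 1)
  expect_equal(unchanged$b, 0)

  # hand evaluation: w <- w - eta*(L - L_prev)*g*x, b <- b - eta*(L - L_prev)*g
  st$L_prev <- 0.09
  up <- update_zeroth(st, list(x = 0.4, g = 0.1, L = 0.04))
  expect_equal(up$w, 1 - 0.5 * (0.04 - 0.09) * 0.1 * 0.4, tolerance = 1e-12)
  expect_equal(up$b, 0 - 0.5 * (0.04 - 0.09) * 0.1, tolerance = 1e-12)
  expect_equal(up$L_prev, 0.04)

  # a huge update is clipped back into the hypothesis-space box
  st2 <- learner_state("zeroth", w0 = 1.7, b0 = 0.2, hyper = list(sigma_g = 0.1, eta = 500))
  st2$L_prev <- 1
  up2 <- update_zeroth(st2, list(x = 0.4, g = 0.2, L = 0.04))
  expect_equal(up2$w, 1.75)
  expect_equal(up2$b, 0.25)

  # the rule sees only L = e^2: flipping the sign of e changes nothing
  for (e in c(0.2, -0.2)) {
    upe <- update_zeroth(st, list(x = 0.4, g = 0.1, L = e^2))
    expect_equal(upe$w, up$w)
    expect_equal(upe$b, up$b)
  }

  # before two losses exist there is no update
  fresh <- learner_state("zeroth", w0 = 1.2, b0 = 0.1, hyper = list(sigma_g = 0.1, eta = 10))
  first <- update_zeroth(fresh, list(x = 0.3, g = 0.05, L = 0.2))
  expect_equal(first$w, 1.2)
  expect_equal(first$L_prev, 0.2)
})

test_that("the first-order delta rule updates the mapping estimates", {
  st <- learner_state("first", w0 = 1, b0 = 0, hyper = list(eta_m = 0.1, eta_s = 0.1))
  same <- update_first(st, list(j = 0.5, e = 0))
  expect_equal(same$m_est, 1)
  expect_equal(same$s_est, 0)

  # hand evaluation of the residual-driven step and the policy re-derivation
  up <- update_first(st, list(j = 0.5, e = 0.2))
  m_exp <- 1 + 0.1 * 0.2 * 0.5
  s_exp <- 0 + 0.1 * 0.2
  expect_equal(up$m_est, m_exp, tolerance = 1e-12)
  expect_equal(up$s_est, s_exp, tolerance = 1e-12)
  expect_equal(up$w, 1 / m_exp, tolerance = 1e-12)
  expect_equal(up$b, -s_exp / m_exp, tolerance = 1e-12)

  # clipping back-corrects the estimates so policy and estimates agree
  st2 <- learner_state("first", w0 = 1.7, b0 = 0, hyper = list(eta_m = 5, eta_s = 0))
  up2 <- update_first(st2, list(j = 1, e = 0.5)) # drives m_est up -> w above cap? no: m_est up -> w down
  st3 <- learner_state("first", w0 = 0.3, b0 = 0, hyper = list(eta_m = 5, eta_s = 0))
  up3 <- update_first(st3, list(j = 1, e = -0.57)) # m_est drops -> w blows past the cap
  expect_equal(up3$w, 1.75)
  expect_equal(up3$m_est, 1 / 1.75, tolerance = 1e-12)
  expect_equal(up2$m_est, 1 / up2$w, tolerance = 1e-12)
})

test_that("the RLS update matches its hand-evaluated algebra", {
  st <- learner_state("second", w0 = 1, b0 = 0, hyper = list(mu = 1))
  # e = 0 leaves the estimates alone but still sharpens P
  same <- update_second(st, list(j = 0.5, e = 0))
  expect_equal(same$m_est, 1)
  expect_equal(same$s_est, 0)
  expect_false(identical(same$P, diag(2)))

  # hand evaluation with exact fractions: y=(1/2,1), v=Py, k=v/(mu+y'v)
  up <- update_second(st, list(j = 0.5, e = 0.1))
  denom <- 1 + (0.5^2 + 1)
  k <- c(0.5, 1) / denom
  expect_equal(up$P, diag(2) - outer(c(0.5, 1), k), tolerance = 1e-12)
  expect_equal(up$m_est, 1 + 0.1 * k[1], tolerance = 1e-12)
  expect_equal(up$s_est, 0 + 0.1 * k[2], tolerance = 1e-12)
})

test_that("policy parameters stay inside the clip box after any update", {
  set.seed(21)
  for (order in c("zeroth", "first", "second")) {
    for (rep in 1:50) {
      hyper <- switch(order,
        zeroth = list(sigma_g = runif(1, 0.01, 0.3), eta = runif(1, 0.1, 200)),
        first = list(eta_m = runif(1, 0.01, 2), eta_s = runif(1, 0.01, 2)),
        second = list(mu = runif(1, 0.05, 1))
      )
      st <- learner_state(order,
        w0 = runif(1, 0.25, 1.75), b0 = runif(1, -0.25, 0.25),
        hyper = hyper, sigma_r = 0.1
      )
      if (order == "zeroth") st$L_prev <- runif(1, 0, 2)
      rec <- list(
        x = runif(1, -0.43, 0.43), j = runif(1, -2, 2),
        e = runif(1, -3, 3), g = rnorm(1, 0, 0.2)
      )
      rec$L <- rec$e^2
      st <- switch(order,
        zeroth = update_zeroth(st, rec),
        first = update_first(st, rec),
        second = update_second(st, rec)
      )
      expect_gte(st$w, 0.25)
      expect_lte(st$w, 1.75)
      expect_gte(st$b, -0.25)
      expect_lte(st$b, 0.25)
    }
  }
})

test_that("run_block produces one record per target and a frozen learner at eta 0", {
  set.seed(4)
  map <- sample_mappings(1)
  tg <- sample_targets(15)
  st <- learner_state("zeroth", w0 = 1.2, b0 = 0.1, hyper = list(sigma_g = 0.05, eta = 0))
  rec <- run_block(st, map, tg)
  expect_equal(nrow(rec), 15)
  expect_equal(rec$L, rec$e^2)
  expect_equal(rec$abs_error, abs(rec$e))
  fin <- attr(rec, "state")
  expect_equal(fin$w, 1.2) # learning disabled: policy never moves
  expect_equal(fin$b, 0.1)
})

test_that("the vectorized engine agrees bit-for-bit with the scalar reference", {
  set.seed(99)
  map <- sample_mappings(1)
  tg <- sample_targets(15)
  noise <- rnorm(15, 0, 0.06)
  cases <- list(
    list(order = "zeroth", hyper = list(sigma_g = 0.06, eta = 40), sigma_r = 0),
    list(order = "zeroth", hyper = list(sigma_g = 0.06, eta_w = 40, eta_b = 15), sigma_r = 0),
    list(order = "first", hyper = list(eta_m = 0.4, eta_s = 0.3), sigma_r = 0.06),
    list(order = "second", hyper = list(mu = 0.8), sigma_r = 0.06),
    list(order = "second", hyper = list(mu = 0.8), sigma_r = 0.06, variant = "textbook")
  )
  for (cs in cases) {
    variant <- cs$variant %||% "printed"
    st <- learner_state(cs$order,
      w0 = 0.9, b0 = -0.1, hyper = cs$hyper,
      sigma_r = cs$sigma_r, rls_variant = variant
    )
    rb <- run_block(st, map, tg, noise = noise)
    sim <- vmlearn:::sim_paths(cs$order, matrix(tg), map$w_star, map$b_star,
      w0 = 0.9, b0 = -0.1, hyper = cs$hyper, sigma = cs$sigma_r,
      rls_variant = variant, noise = matrix(noise)
    )
    expect_identical(sim$abs_err[, 1], rb$abs_error)
    expect_identical(sim$w, attr(rb, "state")$w)
    expect_identical(sim$b, attr(rb, "state")$b)
  }
})

test_that("noise-free RLS with tuned forgetting reaches near-perfect accuracy", {
  set.seed(12)
  maps <- sample_mappings(1000)
  targets <- matrix(sample_targets(15 * 1000), 15)
  # small mu discounts the unit prior on P, which otherwise shrinks the
  # weakly-identified magnification estimate all block long
  sim2 <- vmlearn:::sim_paths("second", targets, maps$w_star, maps$b_star,
    w0 = 1, b0 = 0, hyper = list(mu = 0.003), sigma = 0,
    noise = matrix(0, 15, 1000)
  )
  expect_lt(mean(sim2$abs_err[15, ]), 1e-2)

  # curvature beats plain gradients when both are noise-free (paired blocks)
  sim1 <- vmlearn:::sim_paths("first", targets, maps$w_star, maps$b_star,
    w0 = 1, b0 = 0, hyper = list(eta_m = 1.3, eta_s = 1.3), sigma = 0,
    noise = matrix(0, 15, 1000)
  )
  expect_lte(mean(sim2$abs_err[15, ]), mean(sim1$abs_err[15, ]))
})

test_that("repeated experiments are deterministic and well-shaped", {
  d <- fixture_design()
  rc <- run_experiment("first", d,
    w0 = 1.2, b0 = 0,
    hyper = list(eta_m = 0.4, eta_s = 0.4), sigma_r = 0.07,
    n_reps = 60, seed = 5
  )
  expect_equal(dim(rc$curves), c(15L, 60L))
  expect_true(all(rc$curves >= 0))
  rc2 <- run_experiment("first", d,
    w0 = 1.2, b0 = 0,
    hyper = list(eta_m = 0.4, eta_s = 0.4), sigma_r = 0.07,
    n_reps = 60, seed = 5
  )
  expect_identical(rc$curves, rc2$curves)
  # chunking must not change the stream
  rc3 <- run_experiment("first", d,
    w0 = 1.2, b0 = 0,
    hyper = list(eta_m = 0.4, eta_s = 0.4), sigma_r = 0.07,
    n_reps = 60, seed = 5, chunk_reps = 60
  )
  expect_identical(rc$curves, rc3$curves)

  # a noiseless second-order learner's error declines over the block (the
  # per-shot trace wobbles as estimates move, so the decline is assessed on
  # coarse averages of the mean curve)
  rc4 <- run_experiment("second", d,
    w0 = 1.4, b0 = 0.1,
    hyper = list(mu = 0.01), sigma_r = 0, n_reps = 50, seed = 1
  )
  curve <- rc4$mean_curve
  expect_gt(mean(curve[1:5]), mean(curve[6:10]))
  expect_gt(mean(curve[6:10]), mean(curve[11:15]))
  expect_lt(curve[15], 0.5 * curve[1])
})

test_that("RLS equals batch ridge regression on short noise-free blocks", {
  set.seed(31)
  for (i in 1:20) {
    map <- safe_mapping()
    tg <- sample_targets(5)
    w0 <- runif(1, 0.8, 1.2)
    b0 <- runif(1, -0.05, 0.05)
    sim <- vmlearn:::sim_paths("second", matrix(tg), map$w_star, map$b_star,
      w0 = w0, b0 = b0, hyper = list(mu = 1), sigma = 0,
      noise = matrix(0, 5, 1), keep_paths = TRUE
    )
    # no clipping may have occurred for the recursion to equal the batch fit
    expect_gt(sim$w, 0.25)
    expect_lt(sim$w, 1.75)
    Y <- cbind(sim$j[, 1], 1)
    cvec <- sim$c[, 1]
    theta0 <- c(1 / w0, -b0 / w0)
    theta <- theta0 + solve(diag(2) + crossprod(Y), crossprod(Y, cvec - Y %*% theta0))
    expect_equal(1 / sim$w, theta[1], tolerance = 1e-8)
    expect_equal(-sim$b / sim$w, theta[2], tolerance = 1e-8)
  }
})
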