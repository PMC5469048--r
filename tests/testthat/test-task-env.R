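test_that("mappings derive m and s from the optimal policy", {
  id <- new_mapping(1, 0)
  expect_equal(id$m, 1)
  expect_equal(id$s, 0)

  corner <- new_mapping(0.25, -0.25)
  expect_equal(corner$m, 4)
  expect_equal(corner$s, 1)

  set.seed(42)
  maps <- sample_mappings(1e5)
  expect_true(all(maps$w_star >= 0.25 & maps$w_star <= 1.75))
  expect_true(all(maps$b_star >= -0.25 & maps$b_star <= 0.25))
  expect_true(all(maps$m >= 4 / 7 & maps$m <= 4))
  expect_true(all(maps$s >= -1 & maps$s <= 1))
  # consistency identities to numerical tolerance
  expect_equal(maps$m * maps$w_star, rep(1, nrow(maps)))
  expect_equal(maps$m * maps$b_star + maps$s, rep(0, nrow(maps)))
})

test_that("targets are uniform on the always-reachable strip", {
  set.seed(7)
  x <- sample_targets(15)
  expect_length(x, 15)
  expect_true(all(abs(x) <= target_bound()))

  big <- sample_targets(1e5)
  se <- target_bound() / sqrt(3) / sqrt(1e5) # SE of the mean of a uniform
  expect_lt(abs(mean(big)), 3 * se)

  expect_equal(target_bound(exact = TRUE), (1 - 0.25) / 1.75)
  expect_error(sample_targets(0), class = "vmlearn_invalid_argument")
})

test_that("the mapping sends joystick positions to cursor positions", {
  expect_equal(apply_mapping(new_mapping(1, 0), 0.3), 0.3)
  # m = 0.6, s = 0.15  <=>  w* = 1/0.6, b* = -0.25
  shrunk <- new_mapping(1 / 0.6, -0.15 / 0.6)
  expect_equal(apply_mapping(shrunk, 1), 0.75)
  # the most magnified mapping sends the joystick extreme to the screen edge
  expect_equal(apply_mapping(new_mapping(0.25, -0.25), 1), 5)
  expect_error(apply_mapping(new_mapping(1, 0), 1.2),
    class = "vmlearn_invalid_argument"
  )
})

test_that("optimal_action inverts the mapping", {
  expect_equal(optimal_action(new_mapping(1, 0), 0.2), 0.2)
  shrunk <- new_mapping(1 / 0.6, -0.15 / 0.6) # m = 0.6, s = 0.15
  expect_equal(optimal_action(shrunk, 0.15), 0)

  set.seed(3)
  maps <- sample_mappings(1000)
  x <- sample_targets(1000)
  j <- optimal_action(maps, x)
  expect_equal(apply_mapping(maps, j), x)
  expect_equal(j, maps$w_star * x + maps$b_star)
  # every target is reachable within the physical joystick range
  expect_true(all(abs(j) <= 1))
})

test_that("coordinate extremes match the screen geometry", {
  expect_equal(coord_to_cm(0), 0)
  expect_equal(coord_to_cm(10), 53)
  expect_equal(coord_to_cm(2), 10.6)

  # brute-force grid over the corners (the map is monotone in each argument)
  grid <- expand.grid(
    w_star = c(0.25, 1.75), b_star = c(-0.25, 0.25), j = seq(-1, 1, 0.25)
  )
  cpos <- apply_mapping(new_mapping(grid$w_star, grid$b_star), grid$j)
  expect_equal(max(cpos), 5)
  expect_equal(min(cpos), -5)

  # worst-case reachability of the target strip at the box corners
  tg <- expand.grid(
    w_star = c(0.25, 1.75), b_star = c(-0.25, 0.25),
    x = c(-1, 1) * target_bound()
  )
  jj <- optimal_action(new_mapping(tg$w_star, tg$b_star), tg$x)
  # the operative bound is the print-rounded 0.4286, a hair beyond the exact
  # (1 - 0.25)/1.75, so the worst corner overshoots the stick by < 1e-4
  expect_true(all(abs(jj) <= 1 + 1e-4))
  jj_exact <- optimal_action(
    new_mapping(tg$w_star, tg$b_star),
    sign(tg$x) * target_bound(exact = TRUE)
  )
  expect_true(all(abs(jj_exact) <= 1 + 1e-12))
})

test_that("experiment designs have the protocol shape and are reproducible", {
  d <- make_design(seed = 11)
  counts <- table(d$blocks$phase)
  expect_equal(as.vector(counts[c("warmup", "test", "long")]), c(6L, 24L, 1L))
  expect_true(all(lengths(d$blocks$targets[d$blocks$phase == "test"]) == 15))
  expect_equal(lengths(d$blocks$targets[d$blocks$phase == "long"]), 100)
  expect_true(all(abs(unlist(d$blocks$targets)) <= target_bound()))
  # the long block sits right after the 14th test block
  idx_long <- which(d$blocks$phase == "long")
  expect_equal(sum(d$blocks$phase[seq_len(idx_long - 1)] == "test"), 14)

  d2 <- make_design(seed = 11)
  expect_identical(d$blocks, d2$blocks)
  expect_false(identical(d$blocks, make_design(seed = 12)$blocks))
})

test_that("designs round-trip through JSON", {
  d <- make_design(seed = 77)
  path <- withr::local_tempfile(fileext = ".json")
  write_design(d, path)
  d2 <- read_design(path)
  expect_equal(d2$blocks$w_star, d$blocks$w_star)
  expect_equal(d2$blocks$targets, d$blocks$targets)
  expect_equal(d2$long_block_position, d$long_block_position)
})

test_that("derived child seeds are deterministic, distinct and 32-bit safe", {
  expect_identical(derive_seed(1, "a", 2L), derive_seed(1, "a", 2L))
  seeds <- c(
    derive_seed(1, "a", 1L), derive_seed(1, "a", 2L),
    derive_seed(1, "b", 1L), derive_seed(2, "a", 1L)
  )
  expect_equal(length(unique(seeds)), 4L)
  expect_true(all(seeds > 0 & seeds < 2^31))
})
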