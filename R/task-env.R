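#' Screen geometry of the shooting task
#'
#' The task lives in an abstract screen coordinate system: the horizontal
#' screen axis runs from -5 (leftmost edge) to +5 (rightmost edge), chosen so
#' that the most extreme cursor position reachable under any mapping in the
#' task's hypothesis space lands exactly on the screen edge.  The physical
#' display is 53 cm wide and the joystick's full hand travel is 13.6 cm; both
#' are display-side facts only — all dynamics are computed in coordinates.
#'
#' @return A tibble with one row: `coord_min`, `coord_max`, `width_cm`,
#'   `joystick_range_cm`, and the derived `cm_per_unit`.
#' @examples
#' screen_geometry()
#' @export
screen_geometry <- function() {
  tibble::tibble(
    coord_min = -5, coord_max = 5,
    width_cm = 53, joystick_range_cm = 13.6,
    cm_per_unit = 53 / 10
  )
}

#' Convert a coordinate distance to centimetres on the physical screen
#'
#' @param delta_coord Numeric vector of coordinate distances.
#' @param geometry A geometry row as returned by [screen_geometry()].
#' @return Physical distances in cm.
#' @examples
#' coord_to_cm(2) # cursor travel for a full joystick sweep at m = 1
#' @export
coord_to_cm <- function(delta_coord, geometry = screen_geometry()) {
  delta_coord * geometry$width_cm / (geometry$coord_max - geometry$coord_min)
}

#' The half-width of the target region
#'
#' Targets are confined to a central strip so that every target is reachable
#' under every mapping in the hypothesis space.  The operative bound is the
#' rounded value 0.4286 used when running the task; the analytic value
#' \eqn{(1 - 0.25)/1.75} is available for exact coordinate analytics.
#'
#' @param exact If `TRUE`, return the analytic bound instead of the rounded
#'   operative one.
#' @return A positive scalar.
#' @export
target_bound <- function(exact = FALSE) {
  if (exact) (1 - 0.25) / 1.75 else 0.4286
}

# clip box for the adjustable policy parameters == the optimal-policy ranges
W_RANGE <- c(0.25, 1.75)
B_RANGE <- c(-0.25, 0.25)

#' Draw random joystick-to-cursor mappings
#'
#' A block's mapping relates joystick position `j` to cursor position
#' `c = m * j + s`.  Mappings are parameterized through their optimal policy:
#' the optimal weight `w_star = 1/m` is drawn uniformly on `[0.25, 1.75]` and
#' the optimal bias `b_star = -s/m` uniformly on `[-0.25, 0.25]`, from which
#' `m = 1/w_star` and `s = -b_star/w_star`; as a result `m` ranges over
#' `[4/7, 4]` and `s` over `[-1, 1]`.
#'
#' @param n Number of mappings to draw.
#' @return A tibble with columns `w_star`, `b_star`, `m`, `s`.
#' @examples
#' set.seed(1)
#' sample_mappings(3)
#' @export
sample_mappings <- function(n = 1) {
  stopifnot(n >= 1)
  w_star <- runif(n, W_RANGE[1], W_RANGE[2])
  b_star <- runif(n, B_RANGE[1], B_RANGE[2])
  new_mapping(w_star, b_star)
}

#' Build a mapping from its optimal policy parameters
#'
#' @param w_star Optimal weight(s), in `[0.25, 1.75]`.
#' @param b_star Optimal bias(es), in `[-0.25, 0.25]`.
#' @return A tibble with columns `w_star`, `b_star`, `m`, `s`.
#' @export
new_mapping <- function(w_star, b_star) {
  stopifnot(
    all(w_star >= W_RANGE[1] - 1e-12), all(w_star <= W_RANGE[2] + 1e-12),
    all(b_star >= B_RANGE[1] - 1e-12), all(b_star <= B_RANGE[2] + 1e-12)
  )
  tibble::tibble(
    w_star = w_star, b_star = b_star,
    m = 1 / w_star, s = -b_star / w_star
  )
}

#' Draw random target locations
#'
#' Targets are uniform on the central always-reachable strip
#' `[-0.4286, 0.4286]`, the same range in every block so that target
#' positions carry no information about the current mapping.
#'
#' @param n Number of targets (>= 1).
#' @return Numeric vector of length `n`.
#' @export
sample_targets <- function(n) {
  if (length(n) != 1 || is.na(n) || n < 1) {
    abort("`n` must be a single count >= 1.", class = "vmlearn_invalid_argument")
  }
  runif(n, -target_bound(), target_bound())
}

#' Map a joystick position to a cursor position
#'
#' @param mapping A mapping row (from [sample_mappings()] or [new_mapping()]);
#'   recycled against `j`.
#' @param j Joystick coordinate(s) in `[-1, 1]` (the stick is physically
#'   bounded).
#' @return Cursor coordinate(s) `m * j + s`.
#' @examples
#' apply_mapping(new_mapping(1, 0), 0.3)
#' @export
apply_mapping <- function(mapping, j) {
  if (any(j < -1 - 1e-12 | j > 1 + 1e-12)) {
    abort("joystick position `j` must lie in [-1, 1].",
      class = "vmlearn_invalid_argument"
    )
  }
  mapping$m * j + mapping$s
}

#' The optimal joystick position for a target
#'
#' Inverts the mapping: `j = (x - s)/m = w_star * x + b_star`, so that
#' `apply_mapping(mapping, optimal_action(mapping, x)) == x`.
#'
#' @param mapping A mapping row; recycled against `x`.
#' @param x Target coordinate(s).
#' @return Joystick coordinate(s).
#' @export
optimal_action <- function(mapping, x) {
  (x - mapping$s) / mapping$m
}

#' Build the fixed block-and-target sequence of one subject's experiment
#'
#' A subject's session comprises `n_warmup` warmup blocks (excluded from
#' analysis), `n_test_blocks` test blocks of `shots_per_block` shots, and one
#' long block of `long_block_shots` shots inserted after test block
#' `long_block_position`.  Each block gets its own random mapping and target
#' sequence.  The design is shared verbatim by a subject and all of its
#' simulated doppelgangers.
#'
#' @param seed Optional integer seed; if supplied the design is a pure
#'   function of it (the caller's RNG state is untouched).
#' @param n_test_blocks,shots_per_block,n_warmup,long_block_shots,long_block_position
#'   Protocol sizes; defaults follow the study protocol.
#' @return A `vml_design` object: a list with a `blocks` tibble (columns
#'   `phase`, `block`, `w_star`, `b_star`, `m`, `s`, and a `targets` list
#'   column) plus the protocol sizes and the seed.
#' @examples
#' d <- make_design(seed = 1)
#' dplyr::count(d$blocks, phase)
#' @export
make_design <- function(seed = NULL, n_test_blocks = 24, shots_per_block = 15,
                        n_warmup = 6, long_block_shots = 100,
                        long_block_position = 14) {
  build <- function() {
    n_blocks <- n_warmup + n_test_blocks + 1L
    maps <- sample_mappings(n_blocks)
    phase <- c(
      rep("warmup", n_warmup),
      rep("test", long_block_position), "long",
      rep("test", n_test_blocks - long_block_position)
    )
    n_shots <- ifelse(phase == "long", long_block_shots, shots_per_block)
    blocks <- maps |>
      dplyr::mutate(
        phase = phase, block = dplyr::row_number(),
        targets = purrr::map(n_shots, sample_targets),
        .before = 1
      )
    structure(
      list(
        blocks = blocks, n_warmup = n_warmup, n_test_blocks = n_test_blocks,
        shots_per_block = shots_per_block, long_block_shots = long_block_shots,
        long_block_position = long_block_position, seed = seed
      ),
      class = "vml_design"
    )
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' @export
print.vml_design <- function(x, ...) {
  cat(
    "<vml_design> ", x$n_warmup, " warmup + ", x$n_test_blocks, " test blocks x ",
    x$shots_per_block, " shots, long block (", x$long_block_shots,
    " shots) after test block ", x$long_block_position, "\n",
    sep = ""
  )
  invisible(x)
}

#' Extract the analysis blocks of a design
#'
#' @param design A `vml_design`.
#' @param phase One of `"test"`, `"long"`, `"warmup"`.
#' @return The matching rows of `design$blocks`.
#' @export
design_blocks <- function(design, phase = c("test", "long", "warmup")) {
  phase <- match.arg(phase)
  design$blocks[design$blocks$phase == phase, , drop = FALSE]
}

#' Serialize / restore an experiment design as JSON
#'
#' @param design A `vml_design`.
#' @param path File path.
#' @return `write_design()` returns `path` invisibly; `read_design()` returns
#'   a `vml_design` identical to the one written.
#' @export
write_design <- function(design, path) {
  doc <- list(
    n_warmup = design$n_warmup, n_test_blocks = design$n_test_blocks,
    shots_per_block = design$shots_per_block,
    long_block_shots = design$long_block_shots,
    long_block_position = design$long_block_position,
    seed = design$seed,
    blocks = design$blocks |>
      dplyr::mutate(targets = purrr::map(.data$targets, identity))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  blocks <- tibble::as_tibble(doc$blocks)
  blocks$targets <- purrr::map(blocks$targets, as.numeric)
  structure(
    list(
      blocks = blocks, n_warmup = doc$n_warmup,
      n_test_blocks = doc$n_test_blocks,
      shots_per_block = doc$shots_per_block,
      long_block_shots = doc$long_block_shots,
      long_block_position = doc$long_block_position,
      seed = if (is.null(doc$seed)) NULL else as.integer(doc$seed)
    ),
    class = "vml_design"
  )
}
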