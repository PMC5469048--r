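#' Specify the generative model for a synthetic human cohort
#'
#' The raw human shooting data behind the study is not deposited, so the
#' analysis runs on synthetic subjects whose statistical structure matches
#' what is reported about the humans.  The default surrogate is a suboptimal
#' first-order (LMS) learner — human performance sits nearest the first-order
#' doppelgangers — with per-subject learning rates degraded by a factor
#' `eta_scale < 1` from a reference rate and per-subject response noise
#' `sigma_r` drawn from the reported human range.  An alternative
#' `"parametric_curve"` generator assumes no learning mechanism at all: mean
#' unsigned error decays exponentially from a per-subject initial level to a
#' noise-set asymptote.
#'
#' @param generator_kind `"first_order_noisy"` (default) or
#'   `"parametric_curve"`.
#' @param sigma_r_range Per-subject response-noise SD range (default the
#'   reported human range `[0.0481, 0.0942]`, mean 0.0705 by symmetry).
#' @param eta_scale_range Range of the multiplicative degradation of the
#'   surrogate's learning rates relative to `eta_ref` (chosen so surrogates
#'   fall between zeroth- and second-order curves).
#' @param eta_ref Reference LMS rates `(eta_m, eta_s)` the degradation is
#'   applied to; the default is the approximate task-optimal pair (found by
#'   the package's own hyperparameter search at human-level response noise),
#'   so `eta_scale` reads as "fraction of optimal learning speed".  Rates
#'   this fast also mean the surrogate has converged well before the late
#'   window of the long block, so its long-term accuracy reflects its
#'   response noise rather than leftover learning.
#' @param w_init_range,b_init_range Per-subject block-start policy ranges
#'   (the subject's prior guess about the mapping), setting the initial
#'   first-shot error level.
#' @param curve_tau Shot constant of the exponential decay
#'   (`parametric_curve` only).
#' @return A `vml_human_model` list.
#' @export
synthetic_human_model <- function(generator_kind = c("first_order_noisy", "parametric_curve"),
                                  sigma_r_range = c(0.0481, 0.0942),
                                  eta_scale_range = c(0.4, 0.9),
                                  eta_ref = c(eta_m = 2, eta_s = 0.3),
                                  w_init_range = c(0.6, 1.4),
                                  b_init_range = c(-0.15, 0.15),
                                  curve_tau = 2) {
  structure(
    list(
      generator_kind = match.arg(generator_kind),
      sigma_r_range = sigma_r_range, eta_scale_range = eta_scale_range,
      eta_ref = eta_ref, w_init_range = w_init_range,
      b_init_range = b_init_range, curve_tau = curve_tau
    ),
    class = "vml_human_model"
  )
}

simulate_subject_shots <- function(design, params, model) {
  blocks <- design$blocks
  purrr::map_dfr(seq_len(nrow(blocks)), function(i) {
    bl <- blocks[i, ]
    targets <- bl$targets[[1]]
    if (model$generator_kind == "first_order_noisy") {
      st <- learner_state("first",
        w0 = params$w_init, b0 = params$b_init,
        hyper = list(
          eta_m = unname(model$eta_ref["eta_m"]) * params$eta_scale,
          eta_s = unname(model$eta_ref["eta_s"]) * params$eta_scale
        ),
        sigma_r = params$sigma_r
      )
      rec <- run_block(st, bl, targets)
      attr(rec, "state") <- NULL
    } else {
      # no mechanism: |error| decays exponentially to a noise-set asymptote
      n <- length(targets)
      start_err <- abs(bl$m * (params$w_init * targets[1] + params$b_init) +
        bl$s - targets[1])
      asym <- bl$m * params$sigma_r * sqrt(2 / pi)
      lvl <- pmax(asym, asym + (max(start_err, asym) - asym) *
        exp(-(seq_len(n) - 1) / model$curve_tau))
      e <- rnorm(n, 0, lvl / sqrt(2 / pi))
      c_pos <- targets + e
      rec <- tibble::tibble(
        shot = seq_len(n), x = targets, j = (c_pos - bl$s) / bl$m,
        c = c_pos, e = e, abs_error = abs(e), L = e^2, noise_draw = NA_real_
      )
    }
    dplyr::mutate(rec, phase = bl$phase, block = bl$block, .before = 1)
  })
}

summarize_subject <- function(subject_id, shots, params) {
  test <- dplyr::filter(shots, .data$phase == "test")
  long <- dplyr::filter(shots, .data$phase == "long")
  curve <- test |>
    dplyr::group_by(.data$shot) |>
    dplyr::summarise(mean_error = mean(.data$abs_error), .groups = "drop")
  tibble::tibble(
    subject_id = subject_id,
    sigma_r_true = params$sigma_r,
    eta_scale = params$eta_scale,
    w_init = params$w_init,
    b_init = params$b_init,
    mean_first_shot_error = mean(test$abs_error[test$shot == 1]),
    long_term_accuracy = long_term_accuracy(long$abs_error),
    long_term_median = median(long$abs_error[long$shot >= 51]),
    early_error = early_error(curve$mean_error),
    error_curve = list(curve$mean_error)
  )
}

#' Generate a synthetic cohort of subjects
#'
#' Each subject gets its own experiment design (mappings and targets), its
#' own generator parameters drawn from the cohort model, and a full set of
#' simulated shot records (warmup, test, and long blocks), from which the
#' subject's calibration summaries are computed.
#'
#' @param n_subjects Number of subjects (the study cohort is 12).
#' @param model A [synthetic_human_model()].
#' @param seed Root seed; the cohort is a pure function of `(seed, model)`.
#' @return A `vml_cohort`: list with `subjects` (each holding `profile`,
#'   `design`, `shots`), `model`, `seed`.
#' @examples
#' co <- make_cohort(2, seed = 1)
#' cohort_profiles(co)
#' @export
make_cohort <- function(n_subjects = 12, model = synthetic_human_model(),
                        seed = 1L) {
  stopifnot(n_subjects >= 1)
  subjects <- purrr::map(seq_len(n_subjects), function(i) {
    design <- make_design(seed = derive_seed(seed, "design", i))
    params <- withr::with_seed(derive_seed(seed, "subject-params", i), list(
      sigma_r = runif(1, model$sigma_r_range[1], model$sigma_r_range[2]),
      eta_scale = runif(1, model$eta_scale_range[1], model$eta_scale_range[2]),
      w_init = runif(1, model$w_init_range[1], model$w_init_range[2]),
      b_init = runif(1, model$b_init_range[1], model$b_init_range[2])
    ))
    shots <- withr::with_seed(
      derive_seed(seed, "subject-shots", i),
      simulate_subject_shots(design, params, model)
    )
    list(
      profile = summarize_subject(i, shots, params),
      design = design, shots = shots
    )
  })
  structure(list(subjects = subjects, model = model, seed = seed),
    class = "vml_cohort"
  )
}

#' @export
print.vml_cohort <- function(x, ...) {
  cat("<vml_cohort> ", length(x$subjects), " synthetic subjects (",
    x$model$generator_kind, "), seed ", x$seed, "\n",
    sep = ""
  )
  invisible(x)
}

#' Collect the per-subject profile table of a cohort
#'
#' @param cohort A `vml_cohort`.
#' @return Tibble with one row per subject: generator truth (`sigma_r_true`,
#'   `eta_scale`, `w_init`, `b_init`) and the measured summaries
#'   (`mean_first_shot_error`, `long_term_accuracy`, `long_term_median`,
#'   `early_error`, and the 15-shot `error_curve` list column).
#' @export
cohort_profiles <- function(cohort) {
  purrr::map_dfr(cohort$subjects, "profile")
}

#' Write a cohort to disk / read it back
#'
#' Per-subject shot tables go to CSV (`subject, phase, block, shot, x, j, c,
#' error`), designs and the cohort manifest (root seed, model parameters) to
#' JSON.  Re-importing reproduces the profiles and shot records exactly.
#'
#' @param cohort A `vml_cohort`.
#' @param dir Output directory (created if missing).
#' @return `export_cohort()` returns `dir` invisibly; `read_cohort()` the
#'   restored `vml_cohort`.
#' @export
export_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    seed = cohort$seed,
    n_subjects = length(cohort$subjects),
    model = unclass(cohort$model)
  )
  jsonlite::write_json(manifest, file.path(dir, "cohort_manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  for (i in seq_along(cohort$subjects)) {
    su <- cohort$subjects[[i]]
    su$shots |>
      dplyr::transmute(
        subject = i, phase = .data$phase, block = .data$block,
        shot = .data$shot, x = .data$x, j = .data$j, c = .data$c,
        error = .data$e
      ) |>
      # %.17g guarantees the doubles re-import bit-identically
      dplyr::mutate(dplyr::across(
        dplyr::where(is.double),
        \(v) sprintf("%.17g", v)
      )) |>
      readr::write_csv(file.path(dir, sprintf("subject_%02d_shots.csv", i)))
    write_design(su$design, file.path(dir, sprintf("subject_%02d_design.json", i)))
  }
  invisible(dir)
}

#' @rdname export_cohort
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "cohort_manifest.json"),
    simplifyVector = TRUE
  )
  model <- do.call(synthetic_human_model, modifyList(
    manifest$model[c(
      "generator_kind", "sigma_r_range", "eta_scale_range",
      "w_init_range", "b_init_range", "curve_tau"
    )],
    list(eta_ref = unlist(manifest$model$eta_ref))
  ))
  seed <- as.integer(manifest$seed)
  subjects <- purrr::map(seq_len(manifest$n_subjects), function(i) {
    design <- read_design(file.path(dir, sprintf("subject_%02d_design.json", i)))
    # base read.csv: strtod parsing is correctly rounded, so the %.17g
    # export re-imports bit-identically (readr's fast parser is not)
    raw <- tibble::as_tibble(utils::read.csv(
      file.path(dir, sprintf("subject_%02d_shots.csv", i))
    ))
    shots <- raw |>
      dplyr::transmute(
        phase = .data$phase, block = .data$block, shot = .data$shot,
        x = .data$x, j = .data$j, c = .data$c, e = .data$error,
        abs_error = abs(.data$error), L = .data$error^2,
        noise_draw = NA_real_
      )
    params <- withr::with_seed(derive_seed(seed, "subject-params", i), list(
      sigma_r = runif(1, model$sigma_r_range[1], model$sigma_r_range[2]),
      eta_scale = runif(1, model$eta_scale_range[1], model$eta_scale_range[2]),
      w_init = runif(1, model$w_init_range[1], model$w_init_range[2]),
      b_init = runif(1, model$b_init_range[1], model$b_init_range[2])
    ))
    list(
      profile = summarize_subject(i, shots, params),
      design = design, shots = shots
    )
  })
  structure(list(subjects = subjects, model = model, seed = seed),
    class = "vml_cohort"
  )
}
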