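#' Configuration for a full study run
#'
#' Bundles every tunable of the pipeline so a run is a pure function of its
#' config.  The defaults are the study conditions: 12 subjects, contests at
#' 10^4 repetitions (raise `n_reps` toward 10^6 for full fidelity),
#' hyperparameter search over 2000 Monte-Carlo blocks with 5 Nelder-Mead
#' starts, two alternation rounds between hyperparameter optimization and
#' response-noise refitting.
#'
#' @param root_seed Integer root seed; every stage derives its own stream
#'   from it.
#' @param n_subjects Cohort size.
#' @param n_reps Contest repetitions per subject and order.
#' @param orders Learner orders to contest.
#' @param model A [synthetic_human_model()].
#' @param hyperopt List: `mc_blocks`, `n_starts`, `maxit`, `reltol`.
#' @param calibration List: `mc_reps` (first-shot matching),
#'   `sigma_mc_reps` (long-block repetitions for noise matching), `rounds`
#'   (hyperopt/noise alternation rounds).
#' @param variability_scales Optional multipliers for robustness contests
#'   (e.g. `c(1.2, 1.35)`), applied to first/second-order `sigma_r`.
#' @param out_dir Optional output directory; when given, all reports are
#'   written there (CSV/JSON) alongside a run manifest.
#' @return A `vml_config` list.
#' @export
vml_config <- function(root_seed = 1L, n_subjects = 12, n_reps = 1e4,
                       orders = c("zeroth", "first", "second"),
                       model = synthetic_human_model(),
                       hyperopt = list(), calibration = list(),
                       variability_scales = numeric(0), out_dir = NULL) {
  stopifnot(n_subjects >= 1, n_reps >= 1)
  structure(
    list(
      root_seed = as.integer(root_seed), n_subjects = n_subjects,
      n_reps = n_reps, orders = match.arg(orders, several.ok = TRUE),
      model = model,
      hyperopt = modifyList(
        list(mc_blocks = 2000, n_starts = 5, maxit = 200, reltol = 1e-6),
        hyperopt
      ),
      calibration = modifyList(
        list(mc_reps = 2000, sigma_mc_reps = 500, rounds = 2),
        calibration
      ),
      variability_scales = variability_scales,
      out_dir = out_dir
    ),
    class = "vml_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' Any field of [vml_config()] may appear in the file; `model:` takes the
#' arguments of [synthetic_human_model()].
#'
#' @param path YAML file.
#' @param ... Overrides applied on top of the file.
#' @return A `vml_config`.
#' @export
read_run_config <- function(path, ...) {
  doc <- yaml::read_yaml(path)
  if (!is.null(doc$model)) {
    doc$model <- do.call(synthetic_human_model, doc$model)
  }
  do.call(vml_config, modifyList(doc, list(...)))
}

# calibrate one subject for one learner order; returns w0/b0, sigma_r, hyper
calibrate_and_optimize <- function(order, profile, design, cfg) {
  root <- cfg$root_seed
  i <- profile$subject_id
  if (order == "zeroth") {
    ip <- fit_initial_params(profile$mean_first_shot_error, design,
      sigma = 0, mc_reps = cfg$calibration$mc_reps,
      seed = derive_seed(root, "fit-init", i, "zeroth"),
      on_infeasible = "nearest"
    )
    hf <- optimize_hyperparams("zeroth", ip$w0, ip$b0,
      sigma_r = 0,
      mc_blocks = cfg$hyperopt$mc_blocks, n_starts = cfg$hyperopt$n_starts,
      maxit = cfg$hyperopt$maxit, reltol = cfg$hyperopt$reltol,
      seed = derive_seed(root, "hyperopt", i, "zeroth")
    )
    return(list(
      w0 = ip$w0, b0 = ip$b0, sigma_r = 0, hyper = hf$hyper,
      objective = hf$objective, achieved_first_shot = ip$achieved,
      achieved_long_median = NA_real_
    ))
  }
  # first/second: sigma_r and hyperparameters condition on each other;
  # start from the closed-form noise guess and alternate
  sigma <- profile$long_term_median / stats::qnorm(0.75)
  ip <- fit_initial_params(profile$mean_first_shot_error, design,
    sigma = sigma, mc_reps = cfg$calibration$mc_reps,
    seed = derive_seed(root, "fit-init", i, order),
    on_infeasible = "nearest"
  )
  hyper <- default_hyper(order)
  achieved <- NA_real_
  for (r in seq_len(cfg$calibration$rounds)) {
    hf <- optimize_hyperparams(order, ip$w0, ip$b0,
      sigma_r = sigma,
      mc_blocks = cfg$hyperopt$mc_blocks, n_starts = cfg$hyperopt$n_starts,
      maxit = cfg$hyperopt$maxit, reltol = cfg$hyperopt$reltol,
      seed = derive_seed(root, "hyperopt", i, order, r)
    )
    hyper <- hf$hyper
    sf <- fit_sigma_r(profile$long_term_median, order, design,
      ip$w0, ip$b0,
      hyper = hyper, mc_reps = cfg$calibration$sigma_mc_reps,
      seed = derive_seed(root, "fit-sigma", i, order, r)
    )
    sigma <- sf$sigma_r
    achieved <- sf$achieved
  }
  list(
    w0 = ip$w0, b0 = ip$b0, sigma_r = sigma, hyper = hyper,
    objective = hf$objective, achieved_first_shot = ip$achieved,
    achieved_long_median = achieved
  )
}

#' Run the full study pipeline
#'
#' Cohort generation, per-subject calibration (block-start parameters and
#' response noise), per-order hyperparameter optimization, the individual
#' and group brute-force contests, and the optional variability-scaling
#' robustness contests.  Everything derives from `config$root_seed`, so the
#' same config reproduces the same report byte for byte.
#'
#' @param config A [vml_config()].
#' @return A `vml_pipeline` list: `cohort`, `calibration` (tibble),
#'   `contests` (per subject x order tibble), `group` (per order tibble),
#'   `curves` (per-shot mean doppelganger curves), `robustness` (tibble,
#'   possibly empty), and `config`.
#' @export
run_pipeline <- function(config = vml_config()) {
  cfg <- config
  cohort <- make_cohort(cfg$n_subjects,
    model = cfg$model,
    seed = derive_seed(cfg$root_seed, "cohort")
  )
  profiles <- cohort_profiles(cohort)

  calib <- list()
  contests <- list()
  curves <- list()
  robust <- list()
  early_mats <- setNames(
    lapply(cfg$orders, function(o) matrix(NA_real_, cfg$n_reps, cfg$n_subjects)),
    cfg$orders
  )

  for (i in seq_len(cfg$n_subjects)) {
    su <- cohort$subjects[[i]]
    prof <- su$profile
    for (order in cfg$orders) {
      cal <- calibrate_and_optimize(order, prof, su$design, cfg)
      calib[[length(calib) + 1]] <- tibble::tibble(
        subject = i, order = order, w0 = cal$w0, b0 = cal$b0,
        sigma_r = cal$sigma_r,
        hyper = list(cal$hyper),
        objective = cal$objective,
        target_first_shot = prof$mean_first_shot_error,
        achieved_first_shot = cal$achieved_first_shot,
        target_long_median = prof$long_term_median,
        achieved_long_median = cal$achieved_long_median
      )
      rc <- run_experiment(order, su$design, cal$w0, cal$b0,
        hyper = cal$hyper, sigma_r = cal$sigma_r, n_reps = cfg$n_reps,
        seed = derive_seed(cfg$root_seed, "contest", i, order)
      )
      early <- rep_early_errors(rc)
      early_mats[[order]][, i] <- early
      ct <- brute_force_p(prof$early_error, early)
      contests[[length(contests) + 1]] <- dplyr::mutate(
        tidy(ct),
        subject = i, order = order, .before = 1
      )
      curves[[length(curves) + 1]] <- dplyr::mutate(
        tidy(rc),
        subject = i, .before = 1
      )
      for (sc in cfg$variability_scales) {
        if (order == "zeroth") next
        vs <- variability_scaling_contest(sc, order, su$design,
          cal$w0, cal$b0, cal$hyper, cal$sigma_r,
          human_curve = prof$error_curve[[1]], n_reps = cfg$n_reps,
          seed = derive_seed(cfg$root_seed, "robust", i, order, round(100 * sc))
        )
        robust[[length(robust) + 1]] <- dplyr::mutate(
          tidy(vs$early),
          subject = i, order = order, scale = sc, .before = 1
        )
      }
    }
  }

  group <- purrr::map_dfr(cfg$orders, function(order) {
    gc <- group_contest(profiles$early_error, early_mats[[order]])
    dplyr::mutate(tidy(gc), order = order, .before = 1) |>
      dplyr::rename(human_group_early = "human_early")
  })

  out <- structure(
    list(
      cohort = cohort,
      calibration = dplyr::bind_rows(calib),
      contests = dplyr::bind_rows(contests),
      group = group,
      curves = dplyr::bind_rows(curves),
      robustness = if (length(robust)) dplyr::bind_rows(robust) else tibble::tibble(),
      early_matrices = early_mats,
      config = cfg
    ),
    class = "vml_pipeline"
  )
  if (!is.null(cfg$out_dir)) write_pipeline_reports(out, cfg$out_dir)
  out
}

#' @export
print.vml_pipeline <- function(x, ...) {
  cat("<vml_pipeline> ", x$config$n_subjects, " subjects, orders: ",
    paste(x$config$orders, collapse = ", "), ", ",
    x$config$n_reps, " contest repetitions\n",
    sep = ""
  )
  print(x$group)
  invisible(x)
}

#' Tidy the per-subject contest table of a pipeline run
#'
#' @param x A `vml_pipeline`.
#' @param ... Unused.
#' @return `tidy()`: one row per subject x order with the contest summary;
#'   `glance()`: the group-level contests, one row per order.
#' @export
tidy.vml_pipeline <- function(x, ...) x$contests

#' @rdname tidy.vml_pipeline
#' @export
glance.vml_pipeline <- function(x, ...) x$group

write_pipeline_reports <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  export_cohort(result$cohort, file.path(dir, "cohort"))
  result$calibration |>
    dplyr::mutate(hyper = purrr::map_chr(
      .data$hyper,
      \(h) jsonlite::toJSON(h, auto_unbox = TRUE, digits = NA)
    )) |>
    readr::write_csv(file.path(dir, "calibration.csv"))
  readr::write_csv(result$contests, file.path(dir, "contests.csv"))
  readr::write_csv(result$curves, file.path(dir, "doppelganger_curves.csv"))
  if (nrow(result$robustness)) {
    readr::write_csv(result$robustness, file.path(dir, "robustness.csv"))
  }
  jsonlite::write_json(
    list(
      root_seed = result$config$root_seed,
      n_subjects = result$config$n_subjects,
      n_reps = result$config$n_reps,
      orders = result$config$orders,
      group_contests = result$group
    ),
    file.path(dir, "run_manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
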