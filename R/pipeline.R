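#' Default pipeline configuration
#'
#' Nested-list run configuration for [run_pipeline()]: study designs with
#' default sample sizes, the packaged population model values as simulation
#' truths and fit initials, explicit seeds for every stochastic stage, and
#' stage toggles. Round-trips through YAML via [read_run_config()] /
#' [write_run_config()].
#'
#' @param seed Base seed; stage seeds default to consecutive offsets of it.
#' @return A named list of class `run_config`.
#' @export
default_config <- function(seed = 1) {
  structure(list(
    seeds = list(cohort_rich = seed, cohort_sparse = seed + 1,
                 trial_rich = seed + 2, trial_sparse = seed + 3,
                 vpc = seed + 4, dose_sim = seed + 5),
    designs = list(rich = list(n_subjects = 38),
                   sparse = list(n_subjects = 107,
                                 uptitrate_frac = 0.3,
                                 downtitrate_frac = 0.05)),
    population = list(),  # overrides to population_model() arguments
    stages = list(simulate = TRUE, prepare = TRUE, fit = TRUE,
                  diagnose = TRUE, dose_sim = TRUE),
    fit = list(se = TRUE, polish_maxit = 200),
    vpc = list(n_sim = 100),
    dose_sim = list(ages = 1:17, doses_mg_per_kg = c(0.02, 0.04, 0.06))
  ), class = "run_config")
}

#' @rdname default_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- unclass(default_config())
  merge_lists <- function(a, b) {
    for (nm in names(b)) {
      a[[nm]] <- if (is.list(a[[nm]]) && is.list(b[[nm]])) {
        merge_lists(a[[nm]], b[[nm]])
      } else {
        b[[nm]]
      }
    }
    a
  }
  structure(merge_lists(base, cfg), class = "run_config")
}

#' @rdname default_config
#' @param config A `run_config` list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Simulate and prepare the joint two-study dataset
#'
#' Convenience wrapper for simulation-based evaluation of the estimator:
#' generates a rich-design cohort and a sparse-design cohort at the given
#' population model ("truths"), simulates both trials, applies the
#' record-exclusion filter, and returns the combined analysis-ready
#' dataset (sparse-study subject ids offset by 1000 to stay disjoint).
#'
#' @param pop A [population_model()] used as the simulation truth.
#' @param seed Base seed; the cohort and trial stages use consecutive
#'   offsets of it.
#' @param n_rich,n_sparse Cohort sizes.
#' @return A list with `data` (combined filtered `pk_dataset`), `reports`
#'   (per-study exclusion reports), and the raw `datasets`.
#' @export
simulate_joint_trial <- function(pop = population_model(), seed = 1,
                                 n_rich = 38, n_sparse = 107) {
  d_rich <- design_rich(n_rich)
  d_sparse <- design_sparse(n_sparse)
  ds_r <- simulate_trial(generate_cohort(d_rich, seed = seed), d_rich,
                         pop, seed = seed + 2)
  ds_s <- simulate_trial(generate_cohort(d_sparse, seed = seed + 1),
                         d_sparse, pop, seed = seed + 3)
  ds_s$id <- ds_s$id + 1000L
  p_r <- filter_records(ds_r)
  p_s <- filter_records(ds_s)
  list(data = dplyr::bind_rows(p_r$data, p_s$data),
       reports = dplyr::bind_rows(
         dplyr::mutate(p_r$report, study = "rich", .before = 1),
         dplyr::mutate(p_s$report, study = "sparse", .before = 1)),
       datasets = list(rich = ds_r, sparse = ds_s))
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> prepare -> fit -> diagnose -> dose-simulate
#' from a single configuration. All randomness flows from the explicit
#' stage seeds in the configuration, so an identical configuration yields
#' identical artifacts. When `out_dir` is given, each stage writes its
#' artifacts (CSV/JSON) as soon as it completes, so a failing later stage
#' preserves earlier output; a stage failure halts with an error tagged
#' with the stage name.
#'
#' @param config A [default_config()]-style configuration.
#' @param out_dir Optional output directory for artifacts.
#' @return A list with (depending on toggles) `datasets`, `prepared`,
#'   `reports`, `fit`, `residuals`, `vpc`, `dose_grid`, `adult`, `ratios`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit_csv <- function(x, name) {
    if (!is.null(out_dir)) {
      readr::write_csv(x, file.path(out_dir, paste0(name, ".csv")))
    }
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage [", name, "] failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  pop <- do.call(population_model, config$population)
  out <- list(config = config, pop = pop)

  if (isTRUE(config$stages$simulate)) {
    out$datasets <- stage("simulate", {
      d_rich <- design_rich(config$designs$rich$n_subjects)
      d_sparse <- design_sparse(config$designs$sparse$n_subjects,
                                config$designs$sparse$uptitrate_frac,
                                config$designs$sparse$downtitrate_frac)
      coh_r <- generate_cohort(d_rich, seed = config$seeds$cohort_rich)
      coh_s <- generate_cohort(d_sparse, seed = config$seeds$cohort_sparse)
      ds_r <- simulate_trial(coh_r, d_rich, pop,
                             seed = config$seeds$trial_rich)
      ds_s <- simulate_trial(coh_s, d_sparse, pop,
                             seed = config$seeds$trial_sparse)
      ds_s$id <- ds_s$id + 1000L  # keep ids disjoint across studies
      if (!is.null(out_dir)) {
        write_pk_dataset(ds_r, file.path(out_dir, "dataset_rich.csv"))
        write_pk_dataset(ds_s, file.path(out_dir, "dataset_sparse.csv"))
      }
      list(rich = ds_r, sparse = ds_s, designs = list(rich = d_rich,
                                                      sparse = d_sparse))
    })
  }

  if (isTRUE(config$stages$prepare) && !is.null(out$datasets)) {
    out$prepared <- stage("prepare", {
      p_r <- filter_records(out$datasets$rich)
      p_s <- filter_records(out$datasets$sparse)
      combined <- dplyr::bind_rows(p_r$data, p_s$data)
      reports <- dplyr::bind_rows(
        dplyr::mutate(p_r$report, study = "rich", .before = 1),
        dplyr::mutate(p_s$report, study = "sparse", .before = 1))
      emit_csv(reports, "exclusion_report")
      list(data = combined, reports = reports)
    })
  }

  if (isTRUE(config$stages$fit) && !is.null(out$prepared)) {
    out$fit <- stage("fit", {
      fit <- fit_population(out$prepared$data, init = pop,
                            se = isTRUE(config$fit$se),
                            control = list(
                              polish_maxit = config$fit$polish_maxit))
      emit_csv(tidy(fit), "fit_parameters")
      emit_csv(fit$ebe, "fit_ebe")
      emit_csv(fit$shrinkage, "fit_shrinkage")
      if (!is.null(out_dir)) {
        jsonlite::write_json(as.list(glance(fit)),
                             file.path(out_dir, "fit_glance.json"),
                             auto_unbox = TRUE, digits = NA)
      }
      fit
    })
  }

  if (isTRUE(config$stages$diagnose) && !is.null(out$fit)) {
    out <- c(out, stage("diagnose", {
      res <- compute_cwres(out$fit, out$prepared$data)
      rich_data <- out$prepared$data[out$prepared$data$study == "rich", ]
      v <- NULL
      if (nrow(rich_data) > 0) {
        fit_rich <- out$fit
        keep <- vapply(fit_rich$subjects,
                       function(s) s$study_label == "rich", logical(1))
        fit_rich$subjects <- fit_rich$subjects[keep]
        fit_rich$details <- fit_rich$details[keep]
        v <- vpc(fit_rich, rich_data, n_sim = config$vpc$n_sim,
                 seed = config$seeds$vpc)
        emit_csv(v, "vpc_rich")
      }
      emit_csv(res, "residuals")
      list(residuals = res, vpc = v)
    }))
  }

  if (isTRUE(config$stages$dose_sim)) {
    out <- c(out, stage("dose_sim", {
      grid <- simulate_dose_grid(pop,
                                 ages = config$dose_sim$ages,
                                 doses_mg_per_kg =
                                   config$dose_sim$doses_mg_per_kg,
                                 seed = config$seeds$dose_sim)
      adult <- adult_reference(pop = pop)
      ratios <- compare_to_adult(grid$metrics, adult)
      emit_csv(grid$metrics, "dose_grid_metrics")
      emit_csv(ratios, "dose_grid_ratios")
      list(dose_grid = grid, adult = adult, ratios = ratios)
    }))
  }
  out
}
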