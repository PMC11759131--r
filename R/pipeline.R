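# Config-driven end-to-end runs.

default_run_config <- function() {
  list(
    paths = list(cohort_in = NULL, cohort_out = "cohort.csv",
                 results_dir = "results"),
    sim = as.list(formals(sim_config))[
      setdiff(names(formals(sim_config)), "")],
    # forest-practice profile: no single-tree significance stop (alpha 1);
    # forest_config()'s standalone default keeps the stricter 0.05
    forest = list(n_trees = 500, mtry = NULL, alpha_split = 1,
                  subsample_fraction = 0.632, min_node_size = 20,
                  importance_mode = "conditional",
                  n_importance_permutations = 1),
    pipeline = list(folds = 10, repetitions = 10, n_reshuffles = 5000,
                    contrasts = c("multiplicity", "duration", "severity")),
    sensitivity = list(age_grouping = "tertiles",
                       exposures = c("duration", "multiplicity", "severity")),
    stratifier = "gender",
    seed = 1L
  )
}

# recursively check for unknown keys (typo protection)
check_unknown_keys <- function(x, template, path = "") {
  errs <- character()
  for (k in names(x)) {
    if (!k %in% names(template)) {
      errs <- c(errs, sprintf("unknown key `%s%s`", path, k))
    } else if (is.list(template[[k]]) && !is.null(names(template[[k]])) &&
               is.list(x[[k]])) {
      errs <- c(errs, check_unknown_keys(x[[k]], template[[k]],
                                         paste0(path, k, ".")))
    }
  }
  errs
}

#' Validate and normalize a run configuration
#'
#' Accepts a YAML or JSON file path, a named list, or `NULL` (full
#' defaults).  Unknown keys are rejected; all validation errors are
#' reported at once with field paths.  An absent `sim` block (explicitly
#' set to `NULL` in a list, or `sim: null` in YAML) means an existing
#' cohort CSV is read from `paths$cohort_in`.
#'
#' @param config Path, list, or `NULL`.
#' @return A normalized `run_config` list with all defaults filled in.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(sprintf("config file not found: %s",
                                            config))
    txt <- paste(readLines(config, warn = FALSE), collapse = "\n")
    config <- if (grepl("\\.json$", config)) {
      jsonlite::fromJSON(txt, simplifyVector = TRUE)
    } else {
      yaml::yaml.load(txt) %||% list()
    }
  }
  config <- config %||% list()
  if (!is.list(config)) abort("config must be a list, file path, or NULL.")

  defaults <- default_run_config()
  errs <- check_unknown_keys(config, defaults)
  if (!is.null(config$seed)) config$seed <- as.integer(config$seed)

  sim_absent <- ("sim" %in% names(config)) && is.null(config$sim)
  cfg <- utils::modifyList(defaults, config, keep.null = TRUE)
  if (sim_absent) cfg$sim <- NULL

  # evaluate default expressions captured from sim_config formals
  if (!is.null(cfg$sim)) {
    sim_args <- lapply(cfg$sim, function(v) if (is.language(v)) eval(v)
                       else v)
    if (!"seed" %in% names(config$sim %||% list()))
      sim_args$seed <- cfg$seed
    sim_try <- tryCatch(do.call(sim_config, sim_args),
                        error = function(e) conditionMessage(e))
    if (is.character(sim_try)) errs <- c(errs, paste0("sim: ", sim_try))
    else cfg$sim <- sim_try
  } else if (is.null(cfg$paths$cohort_in)) {
    errs <- c(errs, "paths.cohort_in is required when `sim` is absent")
  }

  fc_try <- tryCatch(
    do.call(forest_config, c(cfg$forest, list(seed = cfg$seed))),
    error = function(e) conditionMessage(e))
  if (is.character(fc_try)) errs <- c(errs, paste0("forest: ", fc_try))
  else cfg$forest <- fc_try

  pl <- cfg$pipeline
  if (!is.numeric(pl$folds) || pl$folds < 2)
    errs <- c(errs, "pipeline.folds must be >= 2")
  if (!is.numeric(pl$repetitions) || pl$repetitions < 1)
    errs <- c(errs, "pipeline.repetitions must be >= 1")
  if (!is.numeric(pl$n_reshuffles) || pl$n_reshuffles < 19)
    errs <- c(errs, "pipeline.n_reshuffles must be >= 19")

  # cross-field CV feasibility when the generator supplies the cohort
  if (!length(errs) && !is.null(cfg$sim)) {
    n_min <- floor(cfg$sim$n_respondents *
                     min(cfg$sim$prop_women, 1 - cfg$sim$prop_women))
    need <- pl$folds * cfg$forest$min_node_size
    if (!is.null(cfg$stratifier) && n_min < need)
      errs <- c(errs, sprintf(
        "infeasible CV: smallest stratum ~%d rows < folds * min_node_size = %d",
        n_min, need))
  }

  if (length(errs))
    abort(paste0("Invalid run config:\n", paste("-", errs, collapse = "\n")))
  structure(cfg, class = "run_config")
}

write_stage_csv <- function(x, dir, name) {
  readr::write_csv(x, file.path(dir, name), na = "NA")
}

#' Run the full analysis pipeline
#'
#' Generates (or reads) a cohort, derives features, and emits the complete
#' set of result tables: the stratified descriptive table, group means of
#' the outcome by multiplicity, cross-validated variable importance, all
#' type/timing-vs-global-score contrasts, the outcome-reshuffling
#' permutation null, the interaction sensitivity models, and the predicted
#' outcome surface — plus a JSON run manifest.  One global seed fans out
#' deterministically per stage, so two runs with the same config are
#' byte-identical.
#'
#' @param config A [validate_config()] input (path, list, or `NULL`).
#' @param outdir Output directory (created if needed); overrides
#'   `paths$results_dir`.
#' @return The output directory path, invisibly; the run manifest lists
#'   every file written.
#' @export
run_pipeline <- function(config = NULL, outdir = NULL) {
  cfg <- if (inherits(config, "run_config")) config else
    validate_config(config)
  outdir <- outdir %||% cfg$paths$results_dir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  log_lines <- character()
  stage <- function(name, expr) {
    ts <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      abort(sprintf("stage `%s` failed: %s", name, conditionMessage(e))))
    log_lines <<- c(log_lines, sprintf(
      "%s\t%.2fs", name, as.numeric(Sys.time() - ts, units = "secs")))
    res
  }

  cohort <- stage("cohort", {
    if (!is.null(cfg$sim)) {
      ch <- generate_cohort(cfg$sim)
      if (!is.null(cfg$paths$cohort_out))
        write_cohort(ch, file.path(outdir, basename(cfg$paths$cohort_out)))
      ch
    } else {
      read_cohort(cfg$paths$cohort_in)
    }
  })

  feats <- stage("features", feature_matrix(cohort))

  stage("table1", {
    write_stage_csv(table1(feats, cfg$stratifier), outdir, "table1.csv")
  })
  stage("figure1", {
    gm <- group_means_ci(feats, stratifier = cfg$stratifier)
    write_stage_csv(gm, outdir, "figure1_means.csv")
  })

  # small-n degradation: with too few rows for the requested CV or for the
  # interaction models, those stages are skipped with a warning instead of
  # aborting the run
  min_stratum <- min(vapply(split_strata(feats, cfg$stratifier), nrow,
                            integer(1)))
  cv_feasible <- min_stratum >= cfg$pipeline$folds * cfg$forest$min_node_size

  if (cv_feasible) {
    cvres <- stage("importance", {
      cv <- cv_importance(feats, cfg$forest, folds = cfg$pipeline$folds,
                          repetitions = cfg$pipeline$repetitions,
                          stratifier = cfg$stratifier, seed = cfg$seed)
      write_stage_csv(tidy(cv), outdir, "importance.csv")
      write_stage_csv(glance(cv), outdir, "validity.csv")
      cv
    })

    stage("contrasts", {
      ct <- contrast_table(cvres, references = cfg$pipeline$contrasts)
      write_stage_csv(ct, outdir, "contrasts.csv")
    })

    stage("null", {
      pn <- permutation_null(feats, cfg$forest,
                             n_reshuffles = cfg$pipeline$n_reshuffles,
                             stratifier = cfg$stratifier, seed = cfg$seed)
      write_stage_csv(tidy(pn), outdir, "permutation_null.csv")
    })
  } else {
    warn(sprintf(
      "smallest stratum (%d rows) too small for %d-fold CV with min_node_size %d; importance, contrast and null stages skipped.",
      min_stratum, cfg$pipeline$folds, cfg$forest$min_node_size))
  }

  if (min_stratum > 12 + length(cfg$sensitivity$exposures)) {
    stage("sensitivity", {
      res <- purrr::map(cfg$sensitivity$exposures, function(ex) {
        fit <- fit_interaction_model(
          feats, exposure = ex, age_grouping = cfg$sensitivity$age_grouping,
          stratifier = cfg$stratifier)
        list(tidy = dplyr::mutate(tidy(fit), exposure = ex),
             glance = dplyr::mutate(glance(fit), exposure = ex),
             fit = fit)
      })
      write_stage_csv(dplyr::bind_rows(purrr::map(res, "tidy")), outdir,
                      "sensitivity.csv")
      write_stage_csv(dplyr::bind_rows(purrr::map(res, "glance")), outdir,
                      "sensitivity_fit.csv")
      surf <- predicted_surface(res[[1]]$fit)
      write_stage_csv(surf, outdir, "surface.csv")
    })
  } else {
    warn("strata too small for the interaction sensitivity models; skipped.")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("cmforest")),
    seed = cfg$seed,
    config_hash = str_hash31(jsonlite::toJSON(
      unclass(cfg), auto_unbox = TRUE, digits = NA, null = "null",
      force = TRUE)),
    wall_time_s = as.numeric(Sys.time() - t0, units = "secs"),
    stages = log_lines,
    files = sort(list.files(outdir))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  writeLines(log_lines, file.path(outdir, "run.log"))
  invisible(outdir)
}
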