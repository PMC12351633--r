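#' Run configuration
#'
#' Bundles everything one end-to-end run needs: the synthetic cohort
#' specification, the optimization settings, evaluation options, output
#' directory and the global seed from which all stage seeds derive. Can be
#' read from a flat YAML file whose sections mirror the constructor
#' arguments (`cohort:`, `optimization:`, `evaluation:`).
#'
#' @param out_dir output directory for all artifacts.
#' @param cohort a [cohort_spec()] or list of its arguments.
#' @param optimization an [optimization_config()] or list of arguments.
#' @param seed global integer seed; stage seeds derive from it.
#' @param n_templates number of unjittered template head models optimized
#'   and evaluated as non-cohort standards (default 1).
#' @param compute_features logical; run the anatomy/regression stage.
#' @param log_level `"info"`, `"debug"` or `"quiet"`.
#' @return object of class `run_config`.
#' @export
run_config <- function(out_dir, cohort = list(), optimization = list(),
                       seed = 1L, n_templates = 1L,
                       compute_features = TRUE, log_level = "info") {
  if (!inherits(cohort, "cohort_spec")) {
    cohort$seed <- cohort$seed %||% (seed + 1000L)
    cohort <- do.call(cohort_spec, cohort)
  }
  if (!inherits(optimization, "optimization_config")) {
    optimization$seed <- optimization$seed %||% (seed + 2000L)
    optimization <- do.call(optimization_config, optimization)
  }
  structure(list(out_dir = out_dir, cohort = cohort,
                 optimization = optimization, seed = as.integer(seed),
                 n_templates = as.integer(n_templates),
                 compute_features = isTRUE(compute_features),
                 log_level = log_level),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname run_config
#' @param path YAML file path.
#' @param out_dir_override optional output directory overriding the file.
#' @export
read_run_config <- function(path, out_dir_override = NULL) {
  y <- yaml::read_yaml(path)
  run_config(out_dir = out_dir_override %||% y$out_dir %||% "tesgroup-run",
             cohort = y$cohort %||% list(),
             optimization = y$optimization %||% list(),
             seed = y$seed %||% 1L,
             n_templates = y$n_templates %||% 1L,
             compute_features = y$compute_features %||% TRUE,
             log_level = y$log_level %||% "info")
}

pipe_log <- function(config, level, ...) {
  lv <- c(quiet = 0, info = 1, debug = 2)
  if (lv[[config$log_level %||% "info"]] >= lv[[level]])
    message(format(Sys.time(), "%H:%M:%S"), " [", level, "] ", ...)
}

#' Run the full planning pipeline
#'
#' Orchestrates: synthetic-cohort generation, per-subject personalized
#' optimization, leave-one-out group optimization, template and
#' non-personalized-individual protocol evaluation, protocol comparison
#' statistics, the NERNI-vs-mean-En quadratic fit, and (optionally) the
#' anatomical-feature regressions. Every stage writes its artifacts under
#' `config$out_dir` together with the seed provenance; with
#' `resume = TRUE`, stages whose outputs already exist are skipped, so a
#' deleted intermediate is rebuilt while finished stages are reused.
#'
#' @param config a [run_config()].
#' @param resume reuse existing stage outputs (default `TRUE`).
#' @return (invisibly) a list with the cohort, optimization results,
#'   transfer table, comparison, quadratic fit, and regression results.
#' @export
run_pipeline <- function(config, resume = TRUE) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(seed = config$seed, cohort_seed = config$cohort$seed,
         optimization_seed = config$optimization$seed,
         n_subjects = config$cohort$n_subjects),
    file.path(out, "provenance.json"), auto_unbox = TRUE, digits = NA)

  # stage 1: cohort -----------------------------------------------------
  cohort_dir <- file.path(out, "cohort")
  index_path <- file.path(cohort_dir, "index.json")
  if (resume && file.exists(index_path)) {
    pipe_log(config, "info", "cohort: reusing ", index_path)
    idx <- jsonlite::read_json(index_path, simplifyVector = TRUE)
    cohort <- lapply(idx$path, read_subject)
  } else {
    pipe_log(config, "info", "cohort: generating ",
             config$cohort$n_subjects, " subjects")
    cohort <- generate_cohort(config$cohort,
                              compute_features = config$compute_features)
    dir.create(cohort_dir, showWarnings = FALSE)
    paths <- vapply(cohort, function(s) {
      p <- file.path(cohort_dir, s$subject_id)
      write_subject(s, p)
      p
    }, character(1))
    idx <- data.frame(subject_id = vapply(cohort, `[[`, "", "subject_id"),
                      path = paths, seed = config$cohort$seed)
    jitter <- t(vapply(cohort, function(s) attr(s, "radius_factors"),
                       numeric(length(config$cohort$radius_jitter))))
    colnames(jitter) <- paste0("radius_factor_",
                               names(config$cohort$base$shell_radii))
    jsonlite::write_json(cbind(idx, jitter), index_path,
                         dataframe = "rows", digits = NA)
  }
  ids <- vapply(cohort, `[[`, "", "subject_id")

  # template head model: the unjittered base head, outside the cohort
  tpl_spec <- config$cohort
  tpl_spec$n_subjects <- config$n_templates
  tpl_spec$radius_jitter <- rep(0, length(tpl_spec$radius_jitter))
  tpl_spec$conductivity_jitter <- rep(0, length(tpl_spec$conductivity_jitter))
  templates <- generate_cohort(tpl_spec,
                               compute_features = config$compute_features)
  for (i in seq_along(templates))
    templates[[i]]$subject_id <- sprintf("template%02d", i)

  # stage 2: optimizations ----------------------------------------------
  mont_dir <- file.path(out, "montages")
  dir.create(mont_dir, showWarnings = FALSE)
  opt_stage <- function(tag, fun) {
    p <- file.path(mont_dir, paste0(tag, ".json"))
    if (resume && file.exists(p)) {
      pipe_log(config, "info", "optimize ", tag, ": reusing")
      return(read_montage(p))
    }
    pipe_log(config, "info", "optimize ", tag)
    res <- fun()
    write_montage(res$montage, p)
    jsonlite::write_json(
      list(objective = res$objective, generations = res$generations_run,
           history = res$history, seed = res$config$seed),
      file.path(mont_dir, paste0(tag, "_result.json")),
      auto_unbox = TRUE, digits = NA)
    res$montage
  }
  personalized <- list(); pers_obj <- numeric(0)
  for (i in seq_along(cohort)) {
    cfg <- config$optimization; cfg$seed <- cfg$seed + 10L * i
    personalized[[ids[i]]] <- opt_stage(
      paste0("pers_", ids[i]),
      function() ga_optimize(cohort[[i]], config = cfg))
  }
  loo <- list()
  for (i in seq_along(cohort)) {
    cfg <- config$optimization; cfg$seed <- cfg$seed + 10L * i + 5L
    loo[[ids[i]]] <- opt_stage(
      paste0("group_loo_", ids[i]),
      function() ga_optimize(cohort[-i], config = cfg))
  }
  tpl_mont <- list()
  for (i in seq_along(templates)) {
    cfg <- config$optimization; cfg$seed <- cfg$seed + 7L * i + 3L
    tpl_mont[[templates[[i]]$subject_id]] <- opt_stage(
      paste0("template_", templates[[i]]$subject_id),
      function() ga_optimize(templates[[i]], config = cfg))
  }

  # stage 3: transfer evaluation ---------------------------------------
  protocols <- protocol_set(personalized = personalized, group_loo = loo,
                            templates = tpl_mont, individual = personalized)
  for (m in protocols$montage) validate_montage(m, config$optimization)
  pipe_log(config, "info", "evaluate: ", nrow(protocols), " protocols x ",
           length(cohort), " subjects")
  table <- evaluate_transfer(protocols, cohort)
  write_transfer_table(table, file.path(out, "transfer_table.tsv"))
  # paired comparisons need complete crossing: non-personalized individual
  # protocols skip their source subject, so compare the fully crossed kinds
  comparison <- compare_protocols(
    dplyr::filter(table, .data$protocol_kind != "non_personalized_individual"))
  write_comparison_report(comparison, file.path(out, "comparison.json"))
  quad_fit <- nerni_vs_mean_en_fit(table)
  jsonlite::write_json(
    list(coefficients = quad_fit$coefficients, r_squared = quad_fit$r_squared),
    file.path(out, "nerni_vs_mean_en.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")

  # stage 4: anatomy features + regressions -----------------------------
  regression <- NULL
  if (config$compute_features) {
    pipe_log(config, "info", "features: regression of transfer outcomes")
    feats <- cohort_features(cohort)
    utils::write.table(feats, file.path(out, "features.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    fd <- transfer_feature_data(table, cohort, protocols)
    regression <- list(
      mean_en_linear = fit_feature_regression(fd, "mean_en", order = 1,
                                              use_pca = TRUE,
                                              pca_components = "cv"),
      nerni_order2 = fit_feature_regression(fd, "nerni", order = 2,
                                            use_pca = TRUE,
                                            pca_components = "cv"))
    jsonlite::write_json(
      lapply(regression, function(f) as.list(glance(f))),
      file.path(out, "feature_regression.json"),
      auto_unbox = TRUE, digits = NA)
  }
  pipe_log(config, "info", "done: artifacts in ", out)
  invisible(list(cohort = cohort, personalized = personalized,
                 group_loo = loo, templates = tpl_mont,
                 transfer_table = table, comparison = comparison,
                 quadratic_fit = quad_fit, regression = regression))
}

#' Join transfer outcomes with anatomical feature differences
#'
#' For every non-personalized-individual protocol (a montage from one
#' cohort member applied to the others), pairs the observed NERNI and mean
#' En with the anatomical feature differences between the source (template)
#' subject and the evaluated subject; optionally aggregates to one row per
#' source subject (the mean outcome its montage produces in everyone else
#' against its mean feature differences).
#'
#' @param table transfer table.
#' @param cohort list of `subject_model`s with features.
#' @param protocols the [protocol_set()] used to build `table`.
#' @param aggregate `"pairs"` (one row per source-target pair) or
#'   `"template_mean"` (one row per source subject, column means).
#' @return tibble with `template_id`, (for pairs) `subject_id`, `nerni`,
#'   `mean_en` and the `d_*` feature-difference columns.
#' @export
transfer_feature_data <- function(table, cohort, protocols,
                                  aggregate = c("pairs", "template_mean")) {
  aggregate <- match.arg(aggregate)
  np <- protocols[protocols$kind == "non_personalized_individual", ]
  if (!nrow(np)) stop("no non-personalized individual protocols in the set")
  rows <- purrr::map_dfr(seq_len(nrow(np)), function(i) {
    src <- np$own_subject[[i]]
    if (is.na(src)) stop("non-personalized protocol without a source subject")
    fd <- feature_diffs(cohort, src)
    tr <- table[table$protocol_id == np$protocol_id[[i]] &
                  is.na(table$error), ]
    dplyr::inner_join(
      dplyr::select(tr, "subject_id", "nerni", "mean_en"),
      fd, by = "subject_id")
  })
  if (aggregate == "pairs") return(rows)
  dplyr::summarise(dplyr::group_by(rows, .data$template_id),
                   dplyr::across(dplyr::where(is.numeric), mean),
                   .groups = "drop")
}
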