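## ---- end-to-end pipeline --------------------------------------------------
## simulate/ingest -> CA drug scoring -> drug measure merge & exclusion ->
## fit all K -> select -> report. Every artifact is stamped with the seed
## and a hash of the configuration; failures carry the stage name.

#' Build and validate a pipeline run configuration
#'
#' @param seed mandatory integer master seed.
#' @param cohort_path optional path to a patient table written by
#'   [write_cohort()]; when `NULL` a synthetic cohort is generated.
#' @param generator a [generator_config()] used when `cohort_path` is
#'   `NULL`; defaults to [default_paper_config()].
#' @param n cohort size when simulating (default: the generator's).
#' @param missing_policy drug-measure missing policy, `"exclude"` or
#'   `"impute_zero"`.
#' @param k_min,k_max class-count range to fit.
#' @param n_starts EM starts per class count.
#' @param tol,max_iter EM controls.
#' @param blrt_B bootstrap LRT replicates in the selection battery
#'   (0 = skip; the BIC rule decides either way).
#' @param reference_class reference class for odds ratios (`NULL` = the
#'   last, healthiest class of the chosen fit).
#' @param compute_se whether to compute standard errors / odds ratios
#'   (the slowest reporting step).
#' @param out_dir output directory for artifacts (created if needed).
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed,
                       cohort_path = NULL,
                       generator = default_paper_config(),
                       n = NULL,
                       missing_policy = c("exclude", "impute_zero"),
                       k_min = 4L, k_max = 7L,
                       n_starts = 20L, tol = 1e-6, max_iter = 1000L,
                       blrt_B = 0L,
                       reference_class = NULL,
                       compute_se = TRUE,
                       out_dir = tempfile("fallclass_run_")) {
  if (missing(seed)) stop("run_config: seed is mandatory", call. = FALSE)
  missing_policy <- match.arg(missing_policy)
  if (!is.null(cohort_path) && !file.exists(cohort_path)) {
    stop("run_config: cohort_path does not exist: ", cohort_path,
         call. = FALSE)
  }
  stopifnot(k_min >= 1L, k_min <= k_max, n_starts >= 1L)
  structure(list(seed = as.integer(seed), cohort_path = cohort_path,
                 generator = generator, n = n,
                 missing_policy = missing_policy,
                 k_min = as.integer(k_min), k_max = as.integer(k_max),
                 n_starts = as.integer(n_starts), tol = tol,
                 max_iter = as.integer(max_iter),
                 blrt_B = as.integer(blrt_B),
                 reference_class = reference_class,
                 compute_se = isTRUE(compute_se),
                 out_dir = out_dir),
            class = "run_config")
}

#' Serialize / restore a run configuration
#'
#' YAML round-trip; the generator block is stored field by field with full
#' numeric precision.
#' @param config a [run_config()].
#' @param path file path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   a `run_config`.
#' @export
write_run_config <- function(config, path) {
  num <- function(v) format(as.numeric(v), digits = 17, trim = TRUE)
  g <- config$generator
  gen <- list(
    n_patients = g$n_patients,
    class_proportions = num(g$class_proportions),
    indicator_profiles = num(t(g$indicator_profiles)),
    age_mean = num(g$age_mean), age_sd = num(g$age_sd),
    female_prob = num(g$female_prob),
    medcount_mean = num(g$medcount_mean),
    medcount_dispersion = num(g$medcount_dispersion),
    medcount_min = num(g$medcount_min),
    usage_tilt = num(g$usage_tilt),
    usage_tilt_sd = num(g$usage_tilt_sd),
    popularity_power = num(g$popularity_power),
    min_users = num(g$min_users),
    max_abs_hazard = num(g$max_abs_hazard),
    hazard_aversion = num(g$hazard_aversion),
    simple_regimen_popularity = num(g$simple_regimen_popularity),
    fall_intercepts = num(g$fall_intercepts),
    fall_covariate_coefs = as.list(setNames(num(g$fall_covariate_coefs),
                                            names(g$fall_covariate_coefs))),
    catalog_name = g$medication_catalog$name,
    catalog_n_users = g$medication_catalog$n_users,
    catalog_hazard = num(g$medication_catalog$hazard),
    seed = g$seed)
  obj <- config
  obj$generator <- gen
  class(obj) <- NULL
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  obj <- yaml::read_yaml(path)
  g <- obj$generator
  K <- length(g$class_proportions)
  cfg <- generator_config(
    n_patients = g$n_patients,
    class_proportions = as.numeric(g$class_proportions),
    indicator_profiles = matrix(as.numeric(g$indicator_profiles), K, 7L,
                                byrow = TRUE,
                                dimnames = list(NULL, indicator_names())),
    age_mean = as.numeric(g$age_mean), age_sd = as.numeric(g$age_sd),
    female_prob = as.numeric(g$female_prob),
    medcount_mean = as.numeric(g$medcount_mean),
    medcount_dispersion = as.numeric(g$medcount_dispersion),
    medcount_min = as.numeric(g$medcount_min),
    medication_catalog = data.frame(name = g$catalog_name,
                                    n_users = as.integer(g$catalog_n_users),
                                    hazard = as.numeric(g$catalog_hazard),
                                    stringsAsFactors = FALSE),
    usage_tilt = as.numeric(g$usage_tilt),
    usage_tilt_sd = as.numeric(g$usage_tilt_sd),
    popularity_power = as.numeric(g$popularity_power),
    min_users = as.numeric(g$min_users),
    max_abs_hazard = as.numeric(g$max_abs_hazard),
    hazard_aversion = as.numeric(g$hazard_aversion),
    simple_regimen_popularity = as.numeric(g$simple_regimen_popularity),
    fall_intercepts = as.numeric(g$fall_intercepts),
    fall_covariate_coefs = setNames(
      as.numeric(unlist(g$fall_covariate_coefs)),
      names(g$fall_covariate_coefs)),
    seed = g$seed)
  run_config(seed = obj$seed, cohort_path = obj$cohort_path,
             generator = cfg, n = obj$n,
             missing_policy = obj$missing_policy,
             k_min = obj$k_min, k_max = obj$k_max,
             n_starts = obj$n_starts, tol = obj$tol,
             max_iter = obj$max_iter, blrt_B = obj$blrt_B,
             reference_class = obj$reference_class,
             compute_se = obj$compute_se, out_dir = obj$out_dir)
}

#' Run the full two-step pipeline
#'
#' Executes all stages on one configuration: obtain the cohort (simulated or
#' read from disk), score the medications by correspondence analysis, merge
#' the drug falling measure and apply the missing policy, fit every class
#' count in range, choose one by BIC, and write the reporting surfaces. Six
#' artifacts land in `config$out_dir`: `drug_scores.tsv`,
#' `selection_report.tsv`, `classification_table.tsv`,
#' `class_profiles.tsv`, `odds_ratios.tsv` and `run_summary.yaml` (seed,
#' configuration hash, per-stage timings). The latent-class stages never see
#' the generator's `true_class` bookkeeping column.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with `cohort`, `ca`, `lca_data`, `selection`,
#'   `fit` (the chosen fit), `classification`, `profiles`, `odds_ratios`
#'   (or `NULL` when `compute_se = FALSE`) and `summary`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- list()
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      if (inherits(e, "fallclass_stage_error")) stop(e)
      stage_stop(stage, conditionMessage(e))
    })
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  cohort <- tick("ingest", {
    if (!is.null(config$cohort_path)) read_cohort(config$cohort_path)
    else generate_cohort(config$generator, seed = config$seed,
                         n = config$n %||% config$generator$n_patients)
  })
  ## estimation must never see generator bookkeeping
  cohort_blind <- cohort
  cohort_blind$true_class <- NULL

  ca_bits <- tick("ca_scoring", {
    tab <- build_medication_table(
      cohort_blind, catalog = config$generator$medication_catalog$name)
    ca <- compute_ca(tab)
    write_drug_scores(ca, tab, file.path(config$out_dir, "drug_scores.tsv"))
    list(tab = tab, ca = ca)
  })

  lca_data <- tick("drug_measure", {
    prepare_lca_data(cohort_blind, ca_bits$ca,
                     missing_policy = config$missing_policy)
  })

  selection <- tick("model_selection", {
    sel <- select_classes(lca_data, config$k_min, config$k_max,
                          n_starts = config$n_starts, seed = config$seed,
                          blrt_B = config$blrt_B, tol = config$tol,
                          max_iter = config$max_iter)
    write_selection_report(sel, file.path(config$out_dir,
                                          "selection_report.tsv"))
    sel
  })
  fit <- selection$fits[[paste0("K", selection$chosen_K)]]

  reports <- tick("reporting", {
    ct <- classification_table(fit)
    write_report_table(ct, file.path(config$out_dir,
                                     "classification_table.tsv"))
    prof <- class_profiles(fit, lca_data)
    write_report_table(prof, file.path(config$out_dir, "class_profiles.tsv"))
    ors <- NULL
    if (config$compute_se) {
      ref <- config$reference_class %||% fit$K
      ors <- distal_odds_ratios(fit, lca_data, reference = ref)
      write_report_table(ors, file.path(config$out_dir, "odds_ratios.tsv"))
    } else {
      writeLines("standard errors not computed (compute_se = FALSE)",
                 file.path(config$out_dir, "odds_ratios.tsv"))
    }
    list(ct = ct, prof = prof, ors = ors)
  })

  summary <- list(
    seed = config$seed,
    config_hash = rlang::hash(config),
    n_cohort = nrow(cohort),
    n_analyzed = nrow(lca_data),
    chosen_K = selection$chosen_K,
    loglik = format(fit$loglik, digits = 12),
    entropy = if (fit$K >= 2L)
      format(relative_entropy(fit$posteriors), digits = 8) else NA,
    stage_seconds = timings)
  yaml::write_yaml(summary, file.path(config$out_dir, "run_summary.yaml"))

  invisible(list(cohort = cohort, ca = ca_bits$ca, lca_data = lca_data,
                 selection = selection, fit = fit,
                 classification = reports$ct, profiles = reports$prof,
                 odds_ratios = reports$ors, summary = summary))
}
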