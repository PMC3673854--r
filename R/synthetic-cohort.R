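## ---- synthetic cohort generator ------------------------------------------
## Emulates a community-dwelling elderly cohort with a known latent class
## structure: class-specific morbidity indicator profiles, demographics,
## over-dispersed prescription counts, class-tilted medication usage, and a
## logistic fall model with class intercepts plus covariate effects.

#' Names of the seven binary morbidity indicators
#' @return Character vector of length 7.
#' @export
indicator_names <- function() {
  c("arthritis", "hbp", "diabetes", "heart_disease",
    "foot_disorder", "parkinsons", "stroke")
}

#' Build a synthetic-cohort generator configuration
#'
#' Bundles and validates every parameter of the cohort generator. Most users
#' will start from [default_paper_config()] and modify fields; this
#' constructor is the validated way to build a configuration from scratch.
#'
#' @param n_patients default cohort size.
#' @param class_proportions probability vector of length `K` (sums to 1).
#' @param indicator_profiles `K x 7` matrix of endorsement probabilities,
#'   strictly inside (0, 1); columns follow [indicator_names()].
#' @param age_mean,age_sd per-class age mean and SD in years; ages are drawn
#'   from a normal truncated below at 65.
#' @param female_prob per-class probability that a patient is female
#'   (gender coded 0 = male, 1 = female).
#' @param medcount_mean per-class expected number of prescriptions; counts
#'   are drawn from a negative binomial with dispersion
#'   `medcount_dispersion` (variance `mu + mu^2 / size`), capped at the
#'   catalog size.
#' @param medcount_dispersion negative-binomial size parameter (> 0).
#' @param medcount_min hard lower bound on the per-patient medication count:
#'   counts are drawn as `medcount_min + NB(mean - medcount_min)`, so every
#'   patient uses at least this many catalog drugs (0 disables the floor).
#' @param medication_catalog data.frame with columns `name` (unique),
#'   `n_users` (base popularity weight) and `hazard` (per-drug fall hazard
#'   weight, i.e. the published CA score).
#' @param usage_tilt per-class mean of the patient-level prescribing-risk
#'   propensity: patient `i` in class `t` draws a latent
#'   `theta_i ~ N(usage_tilt[t], usage_tilt_sd^2)` and samples drug `d` with
#'   weight `n_users[d]^popularity_power[t] * exp(theta_i * hazard[d])`, so
#'   positive propensities steer a patient toward high-hazard drugs and all
#'   of a patient's drugs share a common risk level (regimen coherence).
#' @param usage_tilt_sd standard deviation of the patient-level propensity
#'   (0 reduces to a purely class-determined tilt).
#' @param popularity_power per-class exponent on the popularity weight:
#'   values above 1 concentrate a class's prescriptions on the common
#'   first-line drugs, values below 1 flatten the distribution so rare
#'   agents appear mostly among heavily medicated patients (the usual
#'   polypharmacy pattern).
#' @param min_users popularity threshold: drugs whose catalog `n_users`
#'   falls below it receive sampling weight zero (they do not circulate in
#'   the cohort); 0 disables the cutoff.
#' @param max_abs_hazard circulation cap on the per-drug hazard magnitude:
#'   drugs with `|hazard|` above it receive sampling weight zero, modelling
#'   a formulary in which the high-risk agents are not dispensed to this
#'   population; 0 disables the cap.
#' @param hazard_aversion per-class nonnegative coefficient; sampling
#'   weights carry a factor `exp(-hazard_aversion[t] * |hazard|)`, steering
#'   a class toward low-risk agents. Used for the lightly medicated classes,
#'   whose patients typically receive common first-line drugs.
#' @param simple_regimen_popularity nonnegative scalar `b`; a patient
#'   drawing `m < 4` medications has every drug weight further multiplied by
#'   `n_users^(b * (4 - m)/3)`, so one-to-three-drug regimens concentrate on
#'   the most commonly dispensed agents while the less common adjuncts
#'   appear only in complex regimens.
#' @param signature_drugs optional list of `K` character vectors naming each
#'   class's indication-typical agents; their sampling weight is multiplied
#'   by `signature_boost` for members of that class (indication-driven
#'   prescribing). `NULL` disables the mechanism.
#' @param signature_boost multiplier (>= 1) applied to a class's signature
#'   drugs.
#' @param fall_intercepts per-class log-odds intercept of falling.
#' @param fall_covariate_coefs named numeric vector with elements `age`
#'   (per year, age centred at 77), `female`, `n_meds` (per prescription)
#'   and `hazard` (per unit of summed medication hazard).
#' @param seed integer seed recorded in the configuration (generation takes
#'   its own seed argument).
#' @return An object of class `generator_config`.
#' @seealso [default_paper_config()], [generate_cohort()]
#' @export
generator_config <- function(n_patients,
                             class_proportions,
                             indicator_profiles,
                             age_mean, age_sd,
                             female_prob,
                             medcount_mean,
                             medcount_dispersion = 8,
                             medcount_min = 0,
                             medication_catalog = drug_catalog(),
                             usage_tilt = rep(0, length(class_proportions)),
                             usage_tilt_sd = 0,
                             popularity_power = rep(1, length(class_proportions)),
                             min_users = 0,
                             max_abs_hazard = 0,
                             hazard_aversion = rep(0, length(class_proportions)),
                             simple_regimen_popularity = 0,
                             signature_drugs = NULL,
                             signature_boost = 1,
                             fall_intercepts,
                             fall_covariate_coefs = c(age = 0, female = 0,
                                                      n_meds = 0, hazard = 0),
                             seed = 1L) {
  cfg <- structure(
    list(
      n_patients = n_patients,
      class_proportions = as.numeric(class_proportions),
      indicator_profiles = as.matrix(indicator_profiles),
      age_mean = as.numeric(age_mean),
      age_sd = as.numeric(age_sd),
      female_prob = as.numeric(female_prob),
      medcount_mean = as.numeric(medcount_mean),
      medcount_dispersion = as.numeric(medcount_dispersion),
      medcount_min = as.numeric(medcount_min),
      medication_catalog = medication_catalog,
      usage_tilt = as.numeric(usage_tilt),
      usage_tilt_sd = as.numeric(usage_tilt_sd),
      popularity_power = as.numeric(popularity_power),
      min_users = as.numeric(min_users),
      max_abs_hazard = as.numeric(max_abs_hazard),
      hazard_aversion = as.numeric(hazard_aversion),
      simple_regimen_popularity = as.numeric(simple_regimen_popularity),
      signature_drugs = signature_drugs,
      signature_boost = as.numeric(signature_boost),
      fall_intercepts = as.numeric(fall_intercepts),
      fall_covariate_coefs = fall_covariate_coefs,
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
  validate_generator_config(cfg)
  cfg
}

#' Validate a generator configuration
#'
#' Checks every invariant of a [generator_config()]; errors name the
#' offending field.
#' @param config object to validate.
#' @return `config`, invisibly, if valid.
#' @export
validate_generator_config <- function(config) {
  if (!inherits(config, "generator_config")) {
    stop("config: not a generator_config object", call. = FALSE)
  }
  K <- length(config$class_proportions)
  fail <- function(field, why) {
    stop(sprintf("invalid generator config field '%s': %s", field, why),
         call. = FALSE)
  }
  if (K < 1L) fail("class_proportions", "need at least one class")
  if (abs(sum(config$class_proportions) - 1) > 1e-12) {
    fail("class_proportions", "must sum to 1 within 1e-12")
  }
  if (any(config$class_proportions <= 0)) {
    fail("class_proportions", "entries must be positive")
  }
  if (!is.numeric(config$n_patients) || config$n_patients < 1) {
    fail("n_patients", "must be >= 1")
  }
  ip <- config$indicator_profiles
  if (!is.matrix(ip) || nrow(ip) != K || ncol(ip) != 7L) {
    fail("indicator_profiles", sprintf("must be a %d x 7 matrix", K))
  }
  if (any(ip <= 0 | ip >= 1)) {
    fail("indicator_profiles", "probabilities must lie strictly in (0, 1)")
  }
  for (f in c("age_mean", "age_sd", "female_prob", "medcount_mean",
              "fall_intercepts", "usage_tilt", "popularity_power",
              "hazard_aversion")) {
    if (length(config[[f]]) != K) fail(f, sprintf("must have length %d", K))
    if (any(!is.finite(config[[f]]))) fail(f, "must be finite")
  }
  if (any(config$age_sd <= 0)) fail("age_sd", "must be positive")
  if (any(config$female_prob <= 0 | config$female_prob >= 1)) {
    fail("female_prob", "probabilities must lie strictly in (0, 1)")
  }
  if (any(config$medcount_mean < 0)) fail("medcount_mean", "must be >= 0")
  if (config$medcount_dispersion <= 0) {
    fail("medcount_dispersion", "must be positive")
  }
  if (length(config$medcount_min) != 1L || config$medcount_min < 0) {
    fail("medcount_min", "must be a single nonnegative count")
  }
  if (any(config$medcount_mean < config$medcount_min)) {
    fail("medcount_min", "class mean medication counts must be >= the floor")
  }
  if (length(config$min_users) != 1L || config$min_users < 0) {
    fail("min_users", "must be a single nonnegative number")
  }
  if (length(config$max_abs_hazard) != 1L || config$max_abs_hazard < 0) {
    fail("max_abs_hazard", "must be a single nonnegative number")
  }
  circ <- config$medication_catalog$n_users >= config$min_users
  if (config$max_abs_hazard > 0) {
    circ <- circ &
      abs(config$medication_catalog$hazard) <= config$max_abs_hazard
  }
  if (config$min_users > 0 || config$max_abs_hazard > 0) {
    if (!any(circ)) {
      fail("min_users", "no catalog drug satisfies the circulation rules")
    }
  }
  if (any(config$hazard_aversion < 0)) {
    fail("hazard_aversion", "must be nonnegative")
  }
  if (length(config$simple_regimen_popularity) != 1L ||
      config$simple_regimen_popularity < 0) {
    fail("simple_regimen_popularity", "must be a single nonnegative number")
  }
  if (!is.null(config$signature_drugs)) {
    if (!is.list(config$signature_drugs) ||
        length(config$signature_drugs) != K) {
      fail("signature_drugs", sprintf("must be a list of %d drug-name sets", K))
    }
    unknown <- setdiff(unlist(config$signature_drugs),
                       config$medication_catalog$name)
    if (length(unknown)) {
      fail("signature_drugs",
           paste("names not in the catalog:", paste(unknown, collapse = ", ")))
    }
  }
  if (length(config$signature_boost) != 1L || config$signature_boost < 1) {
    fail("signature_boost", "must be a single number >= 1")
  }
  if (length(config$usage_tilt_sd) != 1L || config$usage_tilt_sd < 0) {
    fail("usage_tilt_sd", "must be a single nonnegative number")
  }
  cat <- config$medication_catalog
  if (!is.data.frame(cat) ||
      !all(c("name", "n_users", "hazard") %in% names(cat))) {
    fail("medication_catalog",
         "must be a data.frame with columns name, n_users, hazard")
  }
  if (anyDuplicated(cat$name)) fail("medication_catalog",
                                    "drug names must be unique")
  if (nrow(cat) < 1L) fail("medication_catalog", "must contain drugs")
  if (any(cat$n_users <= 0)) fail("medication_catalog",
                                  "n_users must be positive")
  cc <- config$fall_covariate_coefs
  if (!all(c("age", "female", "n_meds", "hazard") %in% names(cc))) {
    fail("fall_covariate_coefs",
         "must name coefficients age, female, n_meds, hazard")
  }
  invisible(config)
}

## per-class drug sampling weights implied by a config (catalog rows x K)
usage_weights <- function(config) {
  cat <- config$medication_catalog
  K <- length(config$class_proportions)
  avail <- as.numeric(cat$n_users >= config$min_users &
                        (config$max_abs_hazard == 0 |
                           abs(cat$hazard) <= config$max_abs_hazard))
  w <- vapply(seq_len(K), function(t) {
    cat$n_users^config$popularity_power[t] *
      exp(config$usage_tilt[t] * cat$hazard -
            config$hazard_aversion[t] * abs(cat$hazard)) * avail
  }, numeric(nrow(cat)))
  if (nrow(cat) == 1L) w <- matrix(w, 1L, K)
  sweep(w, 2L, colSums(w), "/")
}

## draw medication lists for patients; returns list(meds = list of character
## vectors, hazard = summed hazard per patient). n_meds already capped.
sample_medications <- function(n_meds, class, config, theta = NULL) {
  cat <- config$medication_catalog
  hz <- cat$hazard
  nm <- cat$name
  K <- length(config$class_proportions)
  avail <- as.numeric(cat$n_users >= config$min_users &
                        (config$max_abs_hazard == 0 |
                           abs(cat$hazard) <= config$max_abs_hazard))
  ## class-level base weight (popularity, aversion, signature, availability)
  base <- vapply(seq_len(K), function(t) {
    w <- cat$n_users^config$popularity_power[t] *
      exp(-config$hazard_aversion[t] * abs(hz)) * avail
    if (!is.null(config$signature_drugs)) {
      sig <- cat$name %in% config$signature_drugs[[t]]
      w[sig] <- w[sig] * config$signature_boost
    }
    w
  }, numeric(nrow(cat)))
  if (nrow(cat) == 1L) base <- matrix(base, 1L, K)
  if (is.null(theta)) theta <- config$usage_tilt[class]
  srp <- config$simple_regimen_popularity
  gate <- lapply(0:3, function(m) cat$n_users^(srp * max(0, 4 - m) / 3))
  meds <- vector("list", length(n_meds))
  hazard <- numeric(length(n_meds))
  for (i in seq_along(n_meds)) {
    k <- n_meds[i]
    if (k == 0L) {
      meds[[i]] <- character(0)
    } else {
      wi <- base[, class[i]] * exp(theta[i] * hz)
      if (srp > 0 && k < 4L) wi <- wi * gate[[k + 1L]]
      idx <- sample.int(nrow(cat), k, replace = FALSE, prob = wi)
      meds[[i]] <- nm[idx]
      hazard[i] <- sum(hz[idx])
    }
  }
  list(meds = meds, hazard = hazard)
}

## fall-model linear predictor without the class intercept
fall_eta <- function(age, female, n_meds, hazard, coefs) {
  coefs[["age"]] * (age - 77) + coefs[["female"]] * female +
    coefs[["n_meds"]] * n_meds + coefs[["hazard"]] * hazard
}

## Solve per-class fall intercepts so that the marginal class fall rate hits
## `targets` at the class covariate distribution (Monte-Carlo root finding).
solve_fall_intercepts <- function(config, targets, m = 12000L,
                                  solver_seed = 870313L) {
  K <- length(config$class_proportions)
  vapply(seq_len(K), function(t) {
    with_seed(solver_seed + t, {
      age <- rtruncnorm_floor(m, config$age_mean[t], config$age_sd[t], 65)
      female <- rbinom(m, 1L, config$female_prob[t])
      n_meds <- pmin(config$medcount_min +
                       rnbinom(m, size = config$medcount_dispersion,
                               mu = config$medcount_mean[t] -
                                 config$medcount_min),
                     sum(usage_weights(config)[, t] > 0))
      theta <- rnorm(m, config$usage_tilt[t], config$usage_tilt_sd)
      hz <- sample_medications(n_meds, rep(t, m), config, theta)$hazard
      eta <- fall_eta(age, female, n_meds, hz, config$fall_covariate_coefs)
      uniroot(function(a) mean(plogis(a + eta)) - targets[t],
              interval = c(-12, 12), tol = 1e-9)$root
    })
  }, numeric(1))
}

#' Default study-calibrated generator configuration
#'
#' Returns the six-class configuration that the package's recovery studies
#' use. Class structure: classes 1-2 endorse all seven morbidity indicators
#' at high rates (poorest-health groups), classes 3 and 6 at low rates
#' (healthy groups), class 4 is an arthritis-dominated class, class 5 a
#' cardiometabolic class (high blood pressure, diabetes, heart disease, foot
#' disorders). Class proportions are (.17, .28, .17, .20, .08, .10); class
#' mean ages (77.78, 76.89, 78.83, 78.69, 77.53, 78.87) with SDs
#' (7.01, 7.02, 6.63, 7.32, 7.04, 7.48); class mean prescription counts
#' (4.7, 7.5, 7.8, 2.6, 3.1, 4.3); the medication catalog is
#' [drug_catalog()] with its published per-drug hazard scores. Class fall
#' intercepts are solved numerically at construction time so that the
#' marginal class fall probabilities equal
#' (.47, .46, .16, .26, .29, .15) at each class's covariate distribution.
#'
#' The high/low endorsement values, the usage tilt toward hazardous drugs in
#' the high-fall classes, and the fall covariate coefficients are package
#' design choices documented in the methods vignette.
#'
#' @return A validated [generator_config()] with `K = 6` and
#'   `n_patients = 2814`.
#' @examples
#' cfg <- default_paper_config()
#' cfg$class_proportions
#' @export
default_paper_config <- function() {
  if (!is.null(.fallclass_env$default_config)) {
    return(.fallclass_env$default_config)
  }
  ind <- rbind(
    rep(0.85, 7),                                  # poorest health I: all
    c(0.85, 0.85, 0.85, 0.85, 0.85, 0.12, 0.12),   # poorest health II: all
                                                   #  common chronic, little
                                                   #  neuro-cerebrovascular
    c(0.08, 0.30, 0.30, 0.08, 0.08, 0.04, 0.04),   # healthy I: mild
                                                   #  cardiometabolic only
    c(0.88, rep(0.06, 6)),                         # arthritis class
    c(0.06, 0.82, 0.82, 0.82, 0.82, 0.06, 0.06),   # cardiometabolic class
    rep(0.03, 7)                                   # healthy II
  )
  colnames(ind) <- indicator_names()
  cfg <- generator_config(
    n_patients = 2814L,
    class_proportions = c(.17, .28, .17, .20, .08, .10),
    indicator_profiles = ind,
    age_mean = c(77.78, 76.89, 78.83, 78.69, 77.53, 78.87),
    age_sd = c(7.01, 7.02, 6.63, 7.32, 7.04, 7.48),
    female_prob = c(.78, .78, .73, .74, .75, .72),
    medcount_mean = c(4.7, 7.5, 7.8, 2.6, 3.1, 4.3),
    medcount_dispersion = 8,
    medcount_min = 2,
    medication_catalog = drug_catalog(),
    usage_tilt = c(0.5, 0.3, -0.3, 0.0, 0.0, -0.3),
    usage_tilt_sd = 0,
    popularity_power = c(1.0, 1.0, 1.0, 1.0, 1.0, 1.0),
    min_users = 100,
    max_abs_hazard = 0.1,
    hazard_aversion = c(0, 0, 0, 0, 0, 0),
    simple_regimen_popularity = 0,
    signature_drugs = NULL,
    signature_boost = 1,
    fall_intercepts = rep(0, 6),   # placeholder, solved below
    fall_covariate_coefs = c(age = 0.03, female = 0.35,
                             n_meds = 0.02, hazard = 2.0),
    seed = 1L
  )
  targets <- c(.47, .46, .16, .26, .29, .15)
  cfg$fall_intercepts <- solve_fall_intercepts(cfg, targets)
  cfg$fall_rate_targets <- targets
  .fallclass_env$default_config <- cfg
  cfg
}

#' Generate a synthetic patient cohort
#'
#' Draws `n` patients from the class structure in `config`: a latent class
#' from `class_proportions`, seven Bernoulli morbidity indicators from the
#' class profile, age from a normal truncated below at 65, gender, a
#' negative-binomial prescription count, a medication list sampled without
#' replacement from the catalog with class-tilted weights, and a Bernoulli
#' fall outcome from the class intercept plus covariate log-odds. The same
#' `(config, seed, n)` always yields the identical table.
#'
#' @param config a validated [generator_config()].
#' @param seed integer seed for this draw.
#' @param n number of patients (defaults to `config$n_patients`).
#' @return A data.frame of class `patient_cohort`: `id`, the seven indicator
#'   columns, `age`, `gender` (0 = male, 1 = female), `n_meds`,
#'   `medications` (list column of catalog names), `fall`, and the
#'   generator-bookkeeping column `true_class` (never used by estimation).
#'   The seed is stored in `attr(, "seed")`.
#' @examples
#' coh <- generate_cohort(default_paper_config(), seed = 1, n = 50)
#' table(coh$true_class)
#' @export
generate_cohort <- function(config, seed, n = config$n_patients) {
  validate_generator_config(config)
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("invalid generator config field 'n_patients': n must be >= 1",
         call. = FALSE)
  }
  n <- as.integer(n)
  K <- length(config$class_proportions)
  with_seed(seed, {
    cls <- sample.int(K, n, replace = TRUE, prob = config$class_proportions)
    p_ind <- config$indicator_profiles[cls, , drop = FALSE]
    ind <- matrix(as.integer(runif(n * 7L) < p_ind), n, 7L)
    colnames(ind) <- indicator_names()
    age <- rtruncnorm_floor(n, config$age_mean[cls], config$age_sd[cls], 65)
    gender <- rbinom(n, 1L, config$female_prob[cls])
    n_avail <- colSums(usage_weights(config) > 0)
    n_meds <- pmin(config$medcount_min +
                     rnbinom(n, size = config$medcount_dispersion,
                             mu = config$medcount_mean[cls] -
                               config$medcount_min),
                   n_avail[cls])
    theta <- rnorm(n, config$usage_tilt[cls], config$usage_tilt_sd)
    ms <- sample_medications(n_meds, cls, config, theta)
    eta <- config$fall_intercepts[cls] +
      fall_eta(age, gender, n_meds, ms$hazard, config$fall_covariate_coefs)
    fall <- rbinom(n, 1L, plogis(eta))
    out <- data.frame(id = sprintf("P%05d", seq_len(n)), ind,
                      age = age, gender = gender, n_meds = n_meds,
                      stringsAsFactors = FALSE)
    out$medications <- ms$meds
    out$fall <- fall
    out$true_class <- cls
    class(out) <- c("patient_cohort", "data.frame")
    attr(out, "seed") <- as.integer(seed)
    out
  })
}

#' Write / read a patient cohort as delimited text
#'
#' Tab-separated with a header; the medication list is stored as a
#' semicolon-joined field; the generation seed is kept in a `# seed:`
#' comment line and restored on read.
#'
#' @param cohort a `patient_cohort` data.frame.
#' @param path file path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns a
#'   `patient_cohort` data.frame.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(is.data.frame(cohort))
  flat <- cohort
  flat$medications <- vapply(cohort$medications, paste, "", collapse = ";")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# fallclass patient cohort",
               sprintf("# seed: %s", attr(cohort, "seed") %||% NA)), con)
  write.table(flat, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  hdr <- readLines(path, n = 5L)
  seed_line <- grep("^# seed:", hdr, value = TRUE)
  flat <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  flat$medications <- lapply(strsplit(as.character(flat$medications), ";",
                                      fixed = TRUE),
                             function(x) x[nzchar(x)])
  class(flat) <- c("patient_cohort", "data.frame")
  if (length(seed_line)) {
    sd <- suppressWarnings(as.integer(sub("^# seed:\\s*", "", seed_line[1])))
    if (!is.na(sd)) attr(flat, "seed") <- sd
  }
  flat
}

`%||%` <- function(a, b) if (is.null(a)) b else a
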