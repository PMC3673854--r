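test_that("parameter sets are validated and counted correctly", {
  p <- make_params(3)
  expect_s3_class(p, "lca_parameters")
  expect_error(lca_parameters(2, matrix(0, 1, 4), matrix(0.5, 2, 7),
                              mu = c(0, 0), sigma2 = -1,
                              beta = rep(0, 5)), "sigma2")
  expect_error(lca_parameters(2, matrix(0, 1, 4),
                              matrix(c(0, rep(0.5, 13)), 2, 7),
                              mu = c(0, 0), sigma2 = 1,
                              beta = rep(0, 5)), "rho")
  ## free-parameter count for this model family
  expect_equal(n_lca_params(1), 0 + 7 + 1 + 1 + 4)
  expect_equal(n_lca_params(6), 4 * 5 + 42 + 6 + 1 + 5 + 4)
})

test_that("the likelihood matches the enumeration oracle", {
  ## hand-written 5-patient, K = 2 case
  dat <- data.frame(
    arthritis = c(1, 0, 1, 1, 0), hbp = c(1, 1, 0, 1, 0),
    diabetes = c(0, 0, 1, 1, 0), heart_disease = c(1, 0, 0, 1, 0),
    foot_disorder = c(0, 1, 0, 1, 0), parkinsons = c(0, 0, 0, 1, 0),
    stroke = c(1, 0, 0, 0, 0),
    age = c(70, 82, 77.5, 91, 68), gender = c(1, 1, 0, 1, 0),
    n_meds = c(2, 7, 4, 9, 0), drug_measure = c(0.1, -0.2, 0.4, 1.1, -0.6),
    fall = c(1, 0, 0, 1, 0))
  p2 <- make_params(2, seed = 4)
  expect_equal(observed_loglik(p2, dat), oracle_loglik(p2, dat),
               tolerance = 1e-12)
  ## property: random small instances, K up to 3, match to 1e-10
  for (s in 1:6) {
    K <- 1 + (s %% 3)
    p <- make_params(K, seed = s)
    d <- sim_data(p, n = sample(3:8, 1), seed = 100 + s)
    expect_equal(observed_loglik(p, d), oracle_loglik(p, d),
                 tolerance = 1e-10, label = sprintf("instance %d", s))
  }
  ## duplicating a patient adds exactly its own contribution
  d1 <- sim_data(p2, n = 6, seed = 9)
  d2 <- rbind(d1, d1[3, ])
  expect_equal(observed_loglik(p2, d2) - observed_loglik(p2, d1),
               oracle_loglik(p2, d1[3, , drop = FALSE]), tolerance = 1e-10)
})

test_that("posteriors follow Bayes rule and never underflow", {
  p2 <- make_params(2, seed = 5)
  d <- sim_data(p2, n = 3, seed = 21)
  expect_equal(posterior_probabilities(p2, d), oracle_posterior(p2, d),
               tolerance = 1e-12)
  ## K = 1: certainty
  p1 <- make_params(1)
  expect_equal(unname(posterior_probabilities(p1, d)), matrix(1, 3, 1))
  ## a class whose item probabilities forbid the observed pattern
  pb <- lca_parameters(
    2, gamma = matrix(0, 1, 4),
    rho = rbind(rep(1e-4, 7), rep(0.5, 7)),
    mu = c(0, 0), sigma2 = 1, beta = c(0, 0, 0, 0, 0))
  d1 <- d[1, ]; d1[indicator_names()] <- 1
  post <- posterior_probabilities(pb, d1)
  expect_lt(post[1, 1], 1e-20)
  ## extreme parameters stay finite and normalized
  pe <- lca_parameters(
    3, gamma = matrix(c(30, -30, rep(0, 6)), 2, 4),
    rho = matrix(rep(c(1e-4, 1 - 1e-4, 0.5), each = 7), 3, 7,
                 byrow = TRUE),
    mu = c(-50, 0, 50), sigma2 = 1e-4, beta = c(-20, 40, 10, 0, 0, 0))
  de <- sim_data(make_params(3), n = 20, seed = 8)
  pp <- posterior_probabilities(pe, de)
  expect_true(all(is.finite(pp)))
  expect_equal(rowSums(pp), rep(1, 20), tolerance = 1e-10)
})

test_that("a one-class fit is the closed-form solution", {
  d <- sim_data(make_params(2, seed = 2), n = 200, seed = 31)
  fit <- fit_em(d, K = 1, seed = 1)
  expect_true(fit$converged)
  expect_equal(fit$iterations, 1L)
  expect_equal(unname(fit$params$rho[1, ]),
               unname(pmin(pmax(colMeans(d[, indicator_names()]), 1e-4),
                           1 - 1e-4)))
  expect_equal(fit$params$mu, mean(d$drug_measure))
  expect_equal(fit$params$sigma2,
               mean((d$drug_measure - mean(d$drug_measure))^2))
  ## distal block equals an ordinary logistic regression
  gl <- stats::glm(fall ~ I(age - 77) + gender + n_meds, binomial(), d)
  expect_equal(unname(fit$params$beta), unname(coef(gl)), tolerance = 1e-6)
  expect_equal(fit$loglik, oracle_loglik(fit$params, d), tolerance = 1e-10)
})

test_that("EM separates a two-atom dataset and is monotone", {
  ## 10 patients endorsing everything, 10 endorsing nothing
  y <- rbind(matrix(1L, 10, 7), matrix(0L, 10, 7))
  d <- data.frame(y); names(d) <- indicator_names()
  d$age <- 77; d$gender <- 1; d$n_meds <- 3
  d$drug_measure <- rep(c(0.5, -0.5), each = 10)
  d$fall <- rep(c(1L, 0L), each = 10)
  fit <- suppressWarnings(fit_em(d, K = 2, n_starts = 5, seed = 2))
  expect_equal(unname(colMeans(fit$posteriors)), c(0.5, 0.5),
               tolerance = 1e-6)
  ## item probabilities pushed to their bounds, one class per atom
  expect_true(all(fit$params$rho < 1e-3 | fit$params$rho > 1 - 1e-3))
  expect_equal(fit$loglik, oracle_loglik(fit$params, d), tolerance = 1e-10)
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))
})

test_that("fits are seeded-deterministic and monotone on realistic data", {
  p <- sep2_params()
  d <- sim_data(p, n = 500, seed = 13)
  f1 <- fit_em(d, K = 2, n_starts = 4, seed = 10, tol = 1e-9)
  f2 <- fit_em(d, K = 2, n_starts = 4, seed = 10, tol = 1e-9)
  expect_identical(f1$loglik, f2$loglik)
  expect_identical(f1$params, f2$params)
  expect_true(all(diff(f1$loglik_trace) >= -1e-8))
  ## posterior rows sum to one
  expect_equal(rowSums(f1$posteriors), rep(1, 500), tolerance = 1e-10)
  ## mean posterior equals fitted marginal class shares at the empirical
  ## covariate distribution (score equation of the membership logit)
  pri <- fallclass:::prior_matrix(f1$params, fallclass:::lca_frame(d))
  expect_equal(colMeans(f1$posteriors), colMeans(pri), tolerance = 1e-6)
  ## label convention: class 1 has the higher fitted fall probability
  fr <- fallclass:::class_fall_probs(f1$params, fallclass:::lca_frame(d),
                                     f1$posteriors)
  expect_true(all(diff(fr) <= 0))
})

test_that("a two-class structure is recovered from moderate samples", {
  p <- sep2_params()
  d <- sim_data(p, n = 1500, seed = 17)
  fit <- fit_em(d, K = 2, n_starts = 6, seed = 3)
  expect_true(fit$converged)
  ## the high-endorsement class must be row 1 after the fall-prob ordering
  ## (class 1 = high fall = high morbidity in sep2_params)
  expect_true(all(abs(fit$params$rho[1, ] - 0.85) < 0.05))
  expect_true(all(abs(fit$params$rho[2, ] - 0.10) < 0.05))
  expect_lt(abs(fit$params$mu[1] - 0.4), 0.05)
  expect_lt(abs(fit$params$mu[2] + 0.3), 0.05)
})

test_that("small samples and bad inputs are rejected", {
  d <- sim_data(make_params(2), n = 8, seed = 1)
  expect_error(fit_em(d, K = 2, seed = 1), "5 patients per class")
  d2 <- sim_data(make_params(2), n = 30, seed = 1)
  d2$drug_measure[4] <- NA
  expect_error(fit_em(d2, K = 2, seed = 1), "prepare_lca_data")
})

test_that("standard errors match closed forms and both methods agree", {
  p <- sep2_params()
  set.seed(44)
  d <- sim_data(p, n = 400, seed = 44)
  ## force a known Bernoulli proportion on one indicator
  d$arthritis <- rep(c(1L, 0L), times = c(100, 300))
  fit1 <- fit_em(d, K = 1, seed = 1)
  se1 <- standard_errors(fit1, d, method = "observed_information")
  expect_true(all(se1$se > 0))
  phat <- mean(d$arthritis)
  closed <- sqrt(phat * (1 - phat) / 400)
  got <- se1$se[se1$parameter == "rho1.arthritis"]
  expect_lt(abs(got - closed) / closed, 0.02)
  ## sandwich ~= observed information under correct specification
  d2 <- sim_data(p, n = 5000, seed = 45)
  fit2 <- fit_em(d2, K = 2, n_starts = 4, seed = 6)
  sw <- standard_errors(fit2, d2, method = "sandwich")
  oi <- standard_errors(fit2, d2, method = "observed_information")
  rel <- abs(sw$se - oi$se) / oi$se
  expect_true(all(rel < 0.15))
  expect_true(all(sw$se > 0))
})

test_that("parameters round-trip exactly through text serialization", {
  p <- make_params(3, seed = 12)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_lca_parameters(p, path)
  back <- read_lca_parameters(path)
  expect_identical(back$gamma, p$gamma)
  expect_identical(back$rho, p$rho)
  expect_identical(back$mu, p$mu)
  expect_identical(back$sigma2, p$sigma2)
  expect_identical(back$beta, p$beta)
  ## fit metadata is embedded when a full fit is written
  d <- sim_data(sep2_params(), n = 120, seed = 3)
  fit <- fit_em(d, K = 2, n_starts = 2, seed = 9)
  write_lca_parameters(fit, path)
  meta <- attr(read_lca_parameters(path), "meta")
  expect_equal(meta$seed, 9L)
  expect_equal(meta$n_starts, 2L)
})

test_that("M-step maximizers agree with independent reference fits", {
  set.seed(99)
  n <- 300
  Z <- cbind(1, rnorm(n), rbinom(n, 1, 0.5), rpois(n, 3))
  ## weighted multinomial logit vs nnet::multinom (class 3 as reference)
  W <- matrix(rgamma(n * 3, 2), n, 3); W <- W / rowSums(W)
  G <- fallclass:::fit_weighted_multinomial(Z, W)
  ref <- suppressWarnings(nnet::multinom(W[, c(3, 1, 2)] ~ Z[, -1],
                                         trace = FALSE, maxit = 1000,
                                         reltol = 1e-14))
  expect_equal(unname(G), unname(coef(ref)), tolerance = 1e-3)
  ## fractionally weighted logistic vs stats::glm.fit
  w <- runif(n, 0.1, 1); y <- rbinom(n, 1, 0.4)
  b <- fallclass:::fit_weighted_logistic(Z, y, w)
  gl <- suppressWarnings(stats::glm.fit(Z, y, weights = w,
                                        family = binomial()))
  expect_equal(unname(b), unname(gl$coefficients), tolerance = 1e-6)
})
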