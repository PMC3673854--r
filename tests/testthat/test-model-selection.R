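fake_fit <- function(params, n) {
  structure(list(params = params, K = params$K,
                 posteriors = matrix(1 / params$K, n, params$K),
                 converged = TRUE, n_params = n_lca_params(params$K)),
            class = "lca_fit")
}

test_that("information criteria match their closed forms", {
  expect_equal(bic(-100, 5, 100), 200 + 5 * log(100))
  expect_equal(bic(-100, 5, 100), 223.0259, tolerance = 1e-4)
  expect_lt(bic(-100, 5, 100), bic(-100, 6, 100))     # monotone in p
  ## independent arithmetic on a published-scale input
  expect_equal(bic(-11672, 74, 2814), 2 * 11672 + 74 * log(2814))
  expect_equal(aic(-100, 5), 210)
})

test_that("relative entropy spans its degenerate and uniform extremes", {
  n <- 10
  crisp <- matrix(0, n, 3); crisp[cbind(1:n, rep(1:3, length.out = n))] <- 1
  expect_equal(relative_entropy(crisp), 1)
  expect_equal(relative_entropy(matrix(1 / 4, n, 4)), 0)
  ## hand computation on a 2 x 2 posterior
  post <- rbind(c(0.9, 0.1), c(0.6, 0.4))
  hand <- 1 - (-(0.9 * log(0.9) + 0.1 * log(0.1) +
                   0.6 * log(0.6) + 0.4 * log(0.4))) / (2 * log(2))
  expect_equal(relative_entropy(post), hand, tolerance = 1e-12)
  expect_error(relative_entropy(matrix(1, 5, 1)), "single class")
})

test_that("pattern goodness of fit vanishes on a saturated toy case", {
  ## one patient per response pattern, item probabilities all one half:
  ## every expected count is exactly 1, matching the observed counts
  pat <- as.matrix(expand.grid(rep(list(0:1), 7)))
  d <- data.frame(pat); names(d) <- indicator_names()
  d$age <- 77; d$gender <- 1; d$n_meds <- 2; d$drug_measure <- 0; d$fall <- 0L
  p1 <- lca_parameters(1, matrix(0, 0, 4), matrix(0.5, 1, 7),
                       mu = 0, sigma2 = 1, beta = rep(0, 4))
  gof <- pattern_gof(fake_fit(p1, 128), d)
  expect_equal(gof$pearson_chi2, 0, tolerance = 1e-10)
  expect_equal(gof$lr_chi2, 0, tolerance = 1e-10)
  expect_equal(gof$df, 127 - 7)
})

test_that("pattern statistics match an explicit hand computation", {
  p2 <- make_params(2, seed = 3)
  d <- sim_data(p2, n = 40, seed = 23)
  gof <- pattern_gof(fake_fit(p2, 40), d)
  ## independent computation with explicit loops
  pat <- as.matrix(expand.grid(rep(list(0:1), 7)))
  y <- as.matrix(d[, indicator_names()])
  obs <- integer(128)
  for (i in seq_len(40)) {
    code <- 1 + sum(y[i, ] * 2^(0:6))
    obs[code] <- obs[code] + 1L
  }
  m <- numeric(128)
  for (g in seq_len(128)) {
    for (i in seq_len(40)) {
      z <- c(1, d$age[i] - 77, d$gender[i], d$n_meds[i])
      et <- c(sum(p2$gamma[1, ] * z), 0)
      pri <- exp(et) / sum(exp(et))
      for (t in 1:2) {
        pp <- 1
        for (j in 1:7) {
          pp <- pp * if (pat[g, j] == 1) p2$rho[t, j] else 1 - p2$rho[t, j]
        }
        m[g] <- m[g] + pri[t] * pp
      }
    }
  }
  expect_equal(gof$pearson_chi2, sum((obs - m)^2 / m), tolerance = 1e-8)
  expect_equal(gof$lr_chi2,
               2 * sum(obs[obs > 0] * log(obs[obs > 0] / m[obs > 0])),
               tolerance = 1e-8)
  expect_equal(gof$df, 127 - (14 + 4))
})

test_that("Pearson and likelihood-ratio statistics agree under the model", {
  ## central item probabilities keep all 128 expected cells comfortably
  ## away from zero, the regime where the two statistics are equivalent
  p <- lca_parameters(
    2, gamma = matrix(c(0.4, 0, 0, 0), 1, 4),
    rho = rbind(rep(0.60, 7), rep(0.42, 7)),
    mu = c(0.2, -0.2), sigma2 = 0.2, beta = c(-1, 0.8, 0, 0.2, 0.05))
  d <- sim_data(p, n = 6000, seed = 31)
  gof <- pattern_gof(fake_fit(p, 6000), d)
  expect_lt(abs(gof$pearson_chi2 / gof$lr_chi2 - 1), 0.10)
})

test_that("the bootstrap LRT rejects extra structure at its formula floor", {
  d <- sim_data(sep2_params(), n = 400, seed = 51)
  p <- blrt(d, K0 = 1, B = 19, seed = 5, n_starts = 4, n_starts_boot = 2,
            max_iter = 300)
  ## two well-separated classes: no null replicate can beat the observed LR
  expect_equal(as.numeric(p), 1 / 20)
  expect_gt(attr(p, "T_obs"), max(attr(p, "T_boot")))
  expect_error(blrt(d, K0 = 1, B = 0), "B must be")
})

test_that("the bootstrap LRT keeps its size under a one-class truth", {
  p1 <- make_params(1, seed = 6)
  pvals <- vapply(1:6, function(r) {
    d <- sim_data(p1, n = 250, seed = 60 + r)
    as.numeric(blrt(d, K0 = 1, B = 19, seed = 600 + r, n_starts = 2,
                    n_starts_boot = 2, max_iter = 200))
  }, numeric(1))
  expect_true(all(pvals > 0 & pvals <= 1))
  expect_gte(sum(pvals > 0.05), 5)
})

test_that("the bootstrap LRT detects a well-separated extra class", {
  pvals <- vapply(1:4, function(r) {
    d <- sim_data(sep2_params(), n = 800, seed = 80 + r)
    as.numeric(blrt(d, K0 = 1, B = 19, seed = 800 + r, n_starts = 2,
                    n_starts_boot = 2, max_iter = 300))
  }, numeric(1))
  expect_gte(sum(pvals <= 0.05), 3)
})

test_that("class-count selection is coherent on a one-class truth", {
  d <- sim_data(make_params(1, seed = 9), n = 400, seed = 71)
  sel <- suppressWarnings(
    select_classes(d, 1, 3, n_starts = 4, seed = 2, max_iter = 300))
  expect_s3_class(sel, "selection_report")
  expect_equal(nrow(sel$table), 3L)
  expect_equal(sel$chosen_K, 1L)
  ## BIC recomputed from the stored ingredients matches bit-for-bit
  expect_identical(sel$table$bic,
                   bic(sel$table$loglik, sel$table$n_params, 400))
  ok <- !is.na(sel$table$entropy)
  expect_true(all(sel$table$entropy[ok] >= 0 & sel$table$entropy[ok] <= 1))
  ## log-likelihood non-decreasing in K when optimized
  conv <- sel$table$converged
  expect_true(all(diff(sel$table$loglik[conv]) >= -1e-4))
  ## report export round-trips through text
  path <- withr::local_tempfile(fileext = ".tsv")
  write_selection_report(sel, path)
  expect_match(readLines(path, n = 1), "chosen_K: 1")
  expect_equal(nrow(read.delim(path, comment.char = "#")), 9L)
})

test_that("simulation from fitted parameters is seeded and well-formed", {
  p <- sep2_params()
  base <- sim_data(p, n = 100, seed = 1)
  a <- simulate_lca(p, base, seed = 4)
  b <- simulate_lca(p, base, seed = 4)
  expect_identical(a, b)
  expect_equal(nrow(a), 100L)
  expect_true(all(as.matrix(a[, indicator_names()]) %in% 0:1))
  expect_true(all(a$fall %in% 0:1))
  ## covariates are resampled rows of the source data
  expect_true(all(a$age %in% base$age))
})
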