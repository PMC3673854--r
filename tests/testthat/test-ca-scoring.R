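make_patients <- function(meds, fall) {
  d <- data.frame(id = sprintf("P%d", seq_along(fall)),
                  stringsAsFactors = FALSE)
  d$medications <- meds
  d$fall <- fall
  d
}

test_that("medication tabulation counts users by outcome", {
  pats <- make_patients(list(c("X"), c("X", "Y")), fall = c(1L, 0L))
  tab <- build_medication_table(pats, catalog = c("X", "Y", "Z"))
  expect_equal(tab$row_labels, c("X", "Y"))   # Z unused, dropped
  expect_equal(unname(tab$counts["X", ]), c(1L, 1L))
  expect_equal(unname(tab$counts["Y", ]), c(1L, 0L))
  ## empty medication list contributes nowhere
  pats2 <- make_patients(list(character(0), c("X")), fall = c(1L, 0L))
  tab2 <- build_medication_table(pats2, catalog = c("X"))
  expect_equal(sum(tab2$counts), 1L)
  ## no catalog drug in use is an explicit error
  expect_error(build_medication_table(pats2, catalog = "Q"), "no catalog")
})

test_that("row totals equal an independent per-drug user scan", {
  coh <- generate_cohort(default_paper_config(), seed = 1, n = 800)
  tab <- build_medication_table(coh)
  brute <- vapply(tab$row_labels, function(d) {
    sum(vapply(coh$medications, function(m) d %in% m, logical(1)))
  }, integer(1))
  expect_equal(unname(rowSums(tab$counts)), unname(brute))
})

test_that("independence tables give zero scores and zero chi-square", {
  counts <- outer(c(10, 30, 60), c(0.4, 0.6)) * 10   # rows prop. to margins
  tab <- list(row_labels = c("A", "B", "C"), counts = counts)
  ca <- compute_ca(tab)
  expect_equal(unname(ca$row_scores), c(0, 0, 0))
  expect_equal(ca$chi_square, 0, tolerance = 1e-8)
})

test_that("row scores match a brute-force eigen oracle and order by fall share", {
  counts <- rbind(X = c(90, 10), Y = c(50, 50), Z = c(10, 90))
  tab <- list(row_labels = rownames(counts), counts = counts)
  ca <- compute_ca(tab)
  expect_equal(unname(ca$row_scores), oracle_ca_row_scores(counts),
               tolerance = 1e-10)
  expect_true(ca$row_scores["X"] < ca$row_scores["Y"])
  expect_true(ca$row_scores["Y"] < ca$row_scores["Z"])
})

test_that("two-column CA has one dimension and reproduces Pearson chi-square", {
  set.seed(42)
  for (rep in 1:5) {
    R <- sample(3:12, 1)
    counts <- matrix(rpois(2 * R, lambda = 30) + 1L, R, 2)
    tab <- list(row_labels = paste0("D", seq_len(R)), counts = counts)
    ca <- compute_ca(tab)
    expect_equal(sum(ca$singular_values > 1e-10), 1L)
    classical <- suppressWarnings(
      stats::chisq.test(counts, correct = FALSE)$statistic)
    expect_equal(ca$chi_square, unname(classical), tolerance = 1e-8)
    expect_equal(ca$total_inertia, sum(ca$singular_values^2),
                 tolerance = 1e-10)
    ## weighted centering of the residual matrix
    S <- diag(1 / sqrt(ca$r)) %*% (ca$P - ca$r %o% ca$c) %*%
      diag(1 / sqrt(ca$c))
    expect_lt(max(abs(colSums(sqrt(ca$r) * S))), 1e-10)
    expect_lt(max(abs(rowSums(t(t(S) * sqrt(ca$c))))), 1e-10)
    ## orientation: scores strictly increasing in row-wise fall share
    share <- counts[, 2] / rowSums(counts)
    o <- order(share)
    if (!any(duplicated(share))) {
      expect_true(all(diff(ca$row_scores[o]) > 0))
    }
  }
})

test_that("degenerate tables are rejected", {
  tab <- list(row_labels = c("A", "B"), counts = rbind(c(5, 0), c(3, 0)))
  expect_error(compute_ca(tab), "outcome")
  tab2 <- list(row_labels = "A", counts = matrix(c(5, 3), 1, 2))
  expect_error(compute_ca(tab2), "two medication rows")
})

test_that("the drug falling measure is the mean of scored medications", {
  ca <- list(row_scores = c(A = -0.30, B = 0.20, C = 1.20, D = 5))
  ## three-medication worked example, rounded to two decimals
  expect_equal(round(drug_falling_measure(c("A", "B", "C"), ca), 2), 0.37)
  expect_equal(drug_falling_measure("C", ca), 1.20)   # mean of one
  expect_true(is.na(drug_falling_measure(character(0), ca)))
  expect_true(is.na(drug_falling_measure("UNSCORED", ca)))
})

test_that("patients without scored medication are excluded (or imputed)", {
  coh <- generate_cohort(default_paper_config(), seed = 2, n = 400)
  ca <- compute_ca(build_medication_table(coh))
  withm <- add_drug_measure(coh, ca)
  expect_identical(withm$measure_missing, lengths(coh$medications) == 0L)
  dat <- prepare_lca_data(coh, ca)
  expect_equal(nrow(dat), sum(!withm$measure_missing))
  expect_false(anyNA(dat$drug_measure))
  dat0 <- prepare_lca_data(coh, ca, missing_policy = "impute_zero")
  expect_equal(nrow(dat0), nrow(coh))
  expect_true(all(dat0$drug_measure[withm$measure_missing] == 0))
  ## per-patient operation agrees with the vectorized column
  i <- which(!withm$measure_missing)[1]
  expect_equal(drug_falling_measure(coh$medications[[i]], ca),
               withm$drug_measure[i])
})

test_that("the drug measure correlates positively with falling", {
  coh <- generate_cohort(default_paper_config(), seed = 3, n = 2000)
  ca <- compute_ca(build_medication_table(coh))
  dat <- prepare_lca_data(coh, ca)
  expect_gt(stats::cor(dat$drug_measure, dat$fall), 0.02)
})
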