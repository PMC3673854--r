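## ---- reporting ------------------------------------------------------------
## Result surfaces: modal classification quality, per-class profiles, and
## distal-outcome odds ratios with Wald intervals against a reference class.

Z975 <- 1.959964   # two-sided 95% normal quantile

#' Modal classification table
#'
#' Assigns each patient to the class with the highest posterior probability
#' (ties broken toward the lower class index; the tie count is attached as
#' an attribute) and reports, per assigned class, the count, the sample
#' proportion, and the mean posterior probability of membership in every
#' class — the standard classification-quality matrix whose diagonal is the
#' average posterior accuracy of each assigned class.
#'
#' @param fit an [fit_em()] result with `K >= 2`.
#' @return An object of class `classification_table`: list with `counts`,
#'   `proportions`, `matrix` (K x K mean posteriors) and `modal`
#'   (assignments).
#' @export
classification_table <- function(fit) {
  W <- fit$posteriors
  K <- ncol(W)
  if (K < 2L) stop("classification table needs K >= 2", call. = FALSE)
  modal <- max.col(W, ties.method = "first")
  ties <- sum(abs(W[cbind(seq_len(nrow(W)), modal)] -
                    apply(W, 1L, function(r) max(r[-which.max(r)]))) < 1e-12)
  counts <- tabulate(modal, nbins = K)
  M <- matrix(NA_real_, K, K,
              dimnames = list(assigned = paste0("class", seq_len(K)),
                              membership = paste0("class", seq_len(K))))
  for (s in seq_len(K)) {
    if (counts[s] > 0L) M[s, ] <- colMeans(W[modal == s, , drop = FALSE])
  }
  structure(list(counts = counts, proportions = counts / nrow(W),
                 matrix = M, modal = modal, n = nrow(W)),
            class = "classification_table", ties = ties)
}

#' @export
print.classification_table <- function(x, ...) {
  cat("Most likely latent class membership\n")
  df <- data.frame(count = x$counts,
                   proportion = round(x$proportions, 3),
                   round(x$matrix, 2))
  print(df)
  invisible(x)
}

#' Per-class profiles
#'
#' For each class: the seven fitted indicator endorsement probabilities
#' (from `rho`), posterior-weighted mean age, number of medications and
#' drug falling measure, the fitted class share, and the fitted fall
#' probability from the distal logit evaluated at the class's
#' posterior-weighted mean covariates.
#'
#' @param fit an [fit_em()] result.
#' @param data the analysis table the model was fitted to.
#' @return A data.frame with one row per class.
#' @export
class_profiles <- function(fit, data) {
  frame <- lca_frame(data)
  W <- fit$posteriors
  colw <- colSums(W)
  wmean <- function(x) as.numeric(crossprod(W, x) / colw)
  rho <- fit$params$rho
  colnames(rho) <- indicator_names()
  out <- data.frame(
    class = seq_len(fit$K),
    share = colw / frame$n,
    rho,
    mean_age = wmean(frame$C[, "age"]) + AGE_CENTER,
    mean_n_meds = wmean(frame$C[, "n_meds"]),
    mean_drug_measure = wmean(frame$d),
    fall_prob = class_fall_probs(fit$params, frame, W)
  )
  rownames(out) <- NULL
  out
}

#' Distal-outcome odds ratios against a reference class
#'
#' Re-expresses the fitted distal class contrasts against the chosen
#' reference class (by convention the healthiest, lowest-fall class, which
#' under the package's label ordering is class `K`) and reports, per
#' non-reference class, the odds ratio of falling, the two-sided Wald
#' p-value and the 95% Wald confidence interval
#' `exp(coefficient +/- 1.959964 * SE)`.
#'
#' @param fit a converged [fit_em()] result.
#' @param data the analysis table.
#' @param reference reference class index in `1:K`.
#' @param se optionally, a precomputed [standard_errors()] table (with its
#'   `vcov` attribute); computed if omitted.
#' @return A data.frame of class `odds_ratio_table` with columns `class`,
#'   `reference`, `coef`, `se`, `odds_ratio`, `p_value`, `lower95`,
#'   `upper95`.
#' @export
distal_odds_ratios <- function(fit, data, reference = fit$K, se = NULL) {
  K <- fit$K
  if (!(reference %in% seq_len(K))) {
    stop("reference class out of range", call. = FALSE)
  }
  if (is.null(se)) se <- standard_errors(fit, data)
  V <- attr(se, "vcov")
  est <- setNames(se$estimate, se$parameter)
  ## class log-odds effects relative to class K (a_K = 0)
  anames <- sprintf("beta.class%d", seq_len(K - 1L))
  a <- c(est[anames], 0)
  avar <- matrix(0, K, K)
  avar[seq_len(K - 1L), seq_len(K - 1L)] <- V[anames, anames]
  rows <- lapply(setdiff(seq_len(K), reference), function(t) {
    cf <- a[t] - a[reference]
    v <- avar[t, t] + avar[reference, reference] - 2 * avar[t, reference]
    s <- sqrt(v)
    z <- cf / s
    data.frame(class = t, reference = reference, coef = cf, se = s,
               odds_ratio = exp(cf),
               p_value = 2 * pnorm(-abs(z)),
               lower95 = exp(cf - Z975 * s),
               upper95 = exp(cf + Z975 * s))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("odds_ratio_table", "data.frame")
  out
}

#' Export reporting surfaces as delimited text
#'
#' @param x a `classification_table`, class-profile data.frame or
#'   `odds_ratio_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report_table <- function(x, path) {
  if (inherits(x, "classification_table")) {
    x <- data.frame(class = seq_along(x$counts), count = x$counts,
                    proportion = x$proportions, x$matrix)
  }
  write.table(format(as.data.frame(x), digits = 6), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simple overlay plot of class indicator profiles
#'
#' Line plot of the fitted endorsement probability of each indicator by
#' class, the usual way latent class morbidity profiles are displayed.
#'
#' @param fit an [fit_em()] result.
#' @param ... passed to [graphics::matplot()].
#' @return Invisibly, the `K x 7` profile matrix.
#' @export
plot_class_profiles <- function(fit, ...) {
  rho <- fit$params$rho
  graphics::matplot(t(rho), type = "b", pch = 19, lty = 1,
                    xaxt = "n", ylim = c(0, 1),
                    xlab = "indicator", ylab = "endorsement probability",
                    ...)
  graphics::axis(1, at = 1:7, labels = indicator_names(), las = 2,
                 cex.axis = 0.8)
  graphics::legend("topright", legend = paste("class", seq_len(fit$K)),
                   col = seq_len(fit$K), lty = 1, pch = 19, cex = 0.8)
  invisible(rho)
}
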