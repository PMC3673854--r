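## ---- model selection ------------------------------------------------------
## The per-K fit battery: BIC (the deciding criterion), relative entropy,
## Pearson / likelihood-ratio chi-square over the 2^7 indicator response
## patterns, and a parametric bootstrap likelihood ratio test comparing
## K against K - 1 classes.

#' Bayesian information criterion
#'
#' `-2 loglik + p log(n)`; lower is better.
#' @param loglik maximized log-likelihood.
#' @param p number of free parameters.
#' @param n sample size.
#' @return Numeric BIC value.
#' @examples
#' bic(-100, 5, 100)  # 200 + 5 log(100)
#' @export
bic <- function(loglik, p, n) {
  stopifnot(n >= 1, p >= 1)
  -2 * loglik + p * log(n)
}

#' Akaike information criterion
#' @inheritParams bic
#' @return Numeric AIC value.
#' @export
aic <- function(loglik, p) -2 * loglik + 2 * p

#' Relative entropy of a posterior classification
#'
#' `1 - sum(-p log p) / (n log K)`: 1 for a perfectly crisp classification,
#' 0 when every posterior row is uniform.
#'
#' @param posteriors `n x K` posterior matrix with `K >= 2`.
#' @return A value in `[0, 1]`.
#' @export
relative_entropy <- function(posteriors) {
  posteriors <- as.matrix(posteriors)
  K <- ncol(posteriors)
  if (K < 2L) {
    stop("relative entropy is undefined for a single class", call. = FALSE)
  }
  plp <- posteriors * log(posteriors)
  plp[posteriors == 0] <- 0
  1 - sum(-plp) / (nrow(posteriors) * log(K))
}

#' Response-pattern goodness of fit
#'
#' Compares observed and model-expected frequencies over the `2^7 = 128`
#' binary indicator response patterns. Expected counts average the
#' covariate-dependent class weights over the empirical covariate
#' distribution: `m_i = sum_t P(pattern_i | class t) * sum_j pi_t(z_j)`.
#' Degrees of freedom are `127` minus the free parameters of the categorical
#' measurement model (`7 K`) and the class-weight logit (`4 (K - 1)`).
#'
#' @param fit a converged [fit_em()] result.
#' @param data the analysis table the model was fitted to.
#' @return A list with `pearson_chi2`, `lr_chi2` and `df`.
#' @export
pattern_gof <- function(fit, data) {
  if (!isTRUE(fit$converged)) stop("fit must be converged", call. = FALSE)
  frame <- lca_frame(data)
  params <- fit$params
  K <- params$K
  pat <- as.matrix(expand.grid(rep(list(0:1), 7L)))
  colnames(pat) <- indicator_names()
  code <- as.integer(frame$y %*% 2^(0:6)) + 1L
  obs <- tabulate(code, nbins = 128L)
  logp <- pat %*% t(log(params$rho)) + (1 - pat) %*% t(log(1 - params$rho))
  Wtot <- colSums(prior_matrix(params, frame))
  m <- as.numeric(exp(logp) %*% Wtot)
  m_fl <- pmax(m, 1e-12)
  pearson <- sum((obs - m)^2 / m_fl)
  pos <- obs > 0
  lr <- 2 * sum(obs[pos] * log(obs[pos] / m_fl[pos]))
  df <- 127L - (7L * K + 4L * (K - 1L))
  list(pearson_chi2 = pearson, lr_chi2 = lr, df = df)
}

#' Simulate an analysis table from fitted latent class parameters
#'
#' Parametric simulation used by the bootstrap likelihood ratio test:
#' covariate rows (age, gender, n_meds) are resampled with replacement from
#' `data`, a class is drawn from the covariate-dependent weights, indicators
#' from the class item probabilities, the drug measure from the class
#' Gaussian, and the fall outcome from the distal logistic model.
#'
#' @param params an [lca_parameters()] object.
#' @param data analysis table supplying the empirical covariate
#'   distribution.
#' @param seed integer seed.
#' @param n number of rows (default `nrow(data)`).
#' @return An analysis table with the same columns as
#'   [prepare_lca_data()] output.
#' @export
simulate_lca <- function(params, data, seed, n = nrow(data)) {
  frame <- lca_frame(data)
  K <- params$K
  with_seed(seed, {
    idx <- sample.int(frame$n, n, replace = TRUE)
    C <- frame$C[idx, , drop = FALSE]
    sub <- list(Z = cbind(intercept = 1, C), C = C, n = n)
    pr <- if (K == 1L) matrix(1, n, 1L) else
      softmax_rows(cbind(sub$Z %*% t(params$gamma), 0))
    cls <- vapply(seq_len(n),
                  function(i) sample.int(K, 1L, prob = pr[i, ]), 1L)
    p_ind <- params$rho[cls, , drop = FALSE]
    y <- matrix(as.integer(runif(n * 7L) < p_ind), n, 7L)
    colnames(y) <- indicator_names()
    d <- rnorm(n, params$mu[cls], sqrt(params$sigma2))
    a <- c(if (K > 1L) params$beta[2:K], 0)
    eta <- params$beta[1L] + a[cls] +
      as.numeric(C %*% params$beta[(K + 1L):(K + 3L)])
    f <- rbinom(n, 1L, plogis(eta))
    out <- data.frame(y, age = C[, "age"] + AGE_CENTER,
                      gender = C[, "gender"], n_meds = C[, "n_meds"],
                      drug_measure = d, fall = f)
    rownames(out) <- NULL
    out
  })
}

#' Bootstrap likelihood ratio test for K0 + 1 versus K0 classes
#'
#' Fits both models on the data, then simulates `B` parametric bootstrap
#' datasets from the fitted `K0` model (covariates resampled, same `n`),
#' refits both models on each, and returns
#' `p = (1 + #\{T_b >= T_obs\}) / (B + 1)` for
#' `T = 2 (loglik_{K0+1} - loglik_{K0})`. Bootstrap replicates whose refits
#' fail to converge are redrawn (the redraw count is attached as an
#' attribute).
#'
#' @param data analysis table.
#' @param K0 null number of classes (`>= 1`).
#' @param B number of bootstrap replicates (`>= 19` recommended; `B = 0`
#'   is an error).
#' @param seed master seed.
#' @param n_starts EM starts for the fits on the observed data.
#' @param n_starts_boot EM starts for each bootstrap refit (small by
#'   convention; the replicates only need the LR null distribution).
#' @param max_iter EM iteration cap passed through to [fit_em()].
#' @return The bootstrap p-value, with attributes `T_obs`, `T_boot` and
#'   `redraws`.
#' @export
blrt <- function(data, K0, B = 99L, seed = 1L, n_starts = 10L,
                 n_starts_boot = 2L, max_iter = 500L) {
  if (B < 1L) stop("B must be at least 1", call. = FALSE)
  if (K0 < 1L) stop("K0 must be >= 1", call. = FALSE)
  fit0 <- suppressWarnings(fit_em(data, K0, n_starts = n_starts,
                                  seed = seed, max_iter = max_iter))
  fit1 <- suppressWarnings(fit_em(data, K0 + 1L, n_starts = n_starts,
                                  seed = seed + 1L, max_iter = max_iter))
  T_obs <- 2 * (fit1$loglik - fit0$loglik)
  seeds <- derive_seeds(seed + 2L, 4L * B)
  T_boot <- numeric(B)
  redraws <- 0L
  si <- 0L
  for (b in seq_len(B)) {
    repeat {
      si <- si + 1L
      if (si > length(seeds)) {
        stop("too many non-convergent bootstrap replicates", call. = FALSE)
      }
      bd <- simulate_lca(fit0$params, data, seed = seeds[si])
      b0 <- suppressWarnings(
        tryCatch(fit_em(bd, K0, n_starts = n_starts_boot, seed = seeds[si],
                        max_iter = max_iter),
                 error = function(e) NULL))
      b1 <- suppressWarnings(
        tryCatch(fit_em(bd, K0 + 1L, n_starts = n_starts_boot,
                        seed = seeds[si] + 1L, max_iter = max_iter),
                 error = function(e) NULL))
      ok <- !is.null(b0) && !is.null(b1) && b0$converged && b1$converged
      if (ok) break
      redraws <- redraws + 1L
    }
    T_boot[b] <- 2 * (b1$loglik - b0$loglik)
  }
  p <- (1 + sum(T_boot >= T_obs)) / (B + 1)
  attr(p, "T_obs") <- T_obs
  attr(p, "T_boot") <- T_boot
  attr(p, "redraws") <- redraws
  p
}

#' Fit a range of class counts and choose one
#'
#' Fits every `K` in `K_min:K_max` with [fit_em()], assembles the fit
#' battery (log-likelihood, parameter count, BIC, AIC, relative entropy,
#' pattern chi-square statistics) and selects the class count with the
#' minimum BIC among converged fits. Bootstrap LRT p-values (each `K`
#' against `K - 1`) are computed when `blrt_B > 0` and reported as
#' corroboration; they never override the BIC rule.
#'
#' @param data analysis table from [prepare_lca_data()].
#' @param K_min,K_max class-count range (`K_min <= K_max`).
#' @param n_starts EM starts per `K`.
#' @param seed master seed.
#' @param blrt_B bootstrap replicates for the LRT column (0 = skip).
#' @param blrt_starts EM starts per bootstrap refit.
#' @param tol,max_iter passed to [fit_em()].
#' @return An object of class `selection_report`: list with `table` (one row
#'   per `K`), `chosen_K`, `rule` and `fits` (named list of `lca_fit`
#'   objects, kept for reporting).
#' @export
select_classes <- function(data, K_min, K_max, n_starts = 20L, seed = 1L,
                           blrt_B = 0L, blrt_starts = 2L, tol = 1e-6,
                           max_iter = 1000L) {
  stopifnot(K_min >= 1L, K_min <= K_max)
  Ks <- seq.int(K_min, K_max)
  fits <- vector("list", length(Ks))
  names(fits) <- paste0("K", Ks)
  rows <- vector("list", length(Ks))
  seeds <- derive_seeds(seed, length(Ks) + 1L)
  for (i in seq_along(Ks)) {
    K <- Ks[i]
    fit <- suppressWarnings(
      fit_em(data, K, n_starts = n_starts, seed = seeds[i], tol = tol,
             max_iter = max_iter))
    fits[[i]] <- fit
    gof <- if (fit$converged) pattern_gof(fit, data) else
      list(pearson_chi2 = NA_real_, lr_chi2 = NA_real_, df = NA_integer_)
    rows[[i]] <- data.frame(
      K = K, loglik = fit$loglik, n_params = fit$n_params,
      bic = bic(fit$loglik, fit$n_params, nrow(data)),
      aic = aic(fit$loglik, fit$n_params),
      entropy = if (K >= 2L) relative_entropy(fit$posteriors) else NA_real_,
      pearson_chi2 = gof$pearson_chi2, lr_chi2 = gof$lr_chi2,
      chi2_df = gof$df, converged = fit$converged,
      blrt_p = NA_real_)
  }
  tab <- do.call(rbind, rows)
  if (blrt_B > 0L) {
    for (i in seq_along(Ks)) {
      if (Ks[i] >= 2L) {
        tab$blrt_p[i] <- as.numeric(
          blrt(data, K0 = Ks[i] - 1L, B = blrt_B, seed = seeds[i] + 1L,
               n_starts = n_starts, n_starts_boot = blrt_starts,
               max_iter = max_iter))
      }
    }
  }
  ok <- tab$converged
  if (!any(ok)) stop("no class count converged", call. = FALSE)
  if (any(diff(tab$loglik[ok]) < -1e-4)) {
    warning(paste("log-likelihood decreased with K; some fits are likely",
                  "under-optimized (increase n_starts)"), call. = FALSE)
  }
  chosen_K <- tab$K[ok][which.min(tab$bic[ok])]
  structure(list(table = tab, chosen_K = chosen_K,
                 rule = "minimum BIC among converged fits (BLRT advisory)",
                 fits = fits, seed = as.integer(seed)),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("Class-count selection (", x$rule, ")\n", sep = "")
  print(format(x$table, digits = 6), row.names = FALSE)
  cat("chosen K:", x$chosen_K, "\n")
  invisible(x)
}

#' Export a selection report as delimited text
#'
#' Statistics as rows, class counts as columns (the conventional layout of
#' fit-battery tables).
#' @param report a [select_classes()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_selection_report <- function(report, path) {
  tab <- report$table
  stats <- c("loglik", "n_params", "bic", "aic", "entropy", "pearson_chi2",
             "lr_chi2", "chi2_df", "blrt_p")
  out <- data.frame(statistic = stats,
                    vapply(seq_len(nrow(tab)), function(i) {
                      unlist(tab[i, stats])
                    }, numeric(length(stats))))
  names(out)[-1L] <- paste0("K", tab$K)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# chosen_K: %d", report$chosen_K), con)
  write.table(format(out, digits = 8), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
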