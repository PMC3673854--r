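## ---- latent class model ---------------------------------------------------
## Measurement model: 7 Bernoulli indicators + 1 Gaussian drug measure,
## conditionally independent within class. Class membership follows a
## multinomial logit on covariates (age centred at 77, gender, n_meds);
## the distal fall outcome follows a logistic model with class contrasts
## (reference = class K) plus the same covariates. Estimation is EM with
## exact conditional maximizations, so the observed log-likelihood is
## non-decreasing across iterations.

AGE_CENTER <- 77

## canonical internal representation of an analysis table
lca_frame <- function(data) {
  need <- c(indicator_names(), "age", "gender", "n_meds", "drug_measure",
            "fall")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("analysis data lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(data$drug_measure)) {
    stop(paste("missing drug measures present; exclude or impute them",
               "upstream with prepare_lca_data()"), call. = FALSE)
  }
  y <- as.matrix(data[, indicator_names()])
  if (!is_binary01(y)) stop("indicators must be coded 0/1", call. = FALSE)
  C <- cbind(age = data$age - AGE_CENTER, gender = data$gender,
             n_meds = data$n_meds)
  if (anyNA(C) || anyNA(data$fall)) {
    stop("covariates and fall outcome must be complete", call. = FALSE)
  }
  list(y = y, d = as.numeric(data$drug_measure),
       Z = cbind(intercept = 1, C), C = C,
       f = as.numeric(data$fall), n = nrow(data))
}

#' Construct a latent class parameter set
#'
#' @param K number of classes.
#' @param gamma `(K-1) x 4` matrix of class-membership logit coefficients
#'   (columns intercept, age, gender, n_meds; reference class `K`). For
#'   `K = 1` a 0-row matrix.
#' @param rho `K x 7` matrix of item-response probabilities, bounded in
#'   `[1e-4, 1 - 1e-4]`.
#' @param mu length-`K` vector of class means of the drug measure.
#' @param sigma2 pooled (class-invariant) drug-measure variance, > 0.
#' @param beta distal logistic coefficients: intercept, `K - 1` class
#'   contrasts (reference class `K`), then age, gender, n_meds.
#' @return An object of class `lca_parameters`.
#' @export
lca_parameters <- function(K, gamma, rho, mu, sigma2, beta) {
  K <- as.integer(K)
  gamma <- as.matrix(gamma)
  rho <- as.matrix(rho)
  stopifnot(K >= 1L)
  if (!(nrow(gamma) == K - 1L && (K == 1L || ncol(gamma) == 4L))) {
    stop("gamma must be a (K-1) x 4 matrix", call. = FALSE)
  }
  if (!(nrow(rho) == K && ncol(rho) == 7L)) {
    stop("rho must be a K x 7 matrix", call. = FALSE)
  }
  if (any(rho < 1e-4 - 1e-12 | rho > 1 - 1e-4 + 1e-12)) {
    stop("rho must be bounded in [1e-4, 1 - 1e-4]", call. = FALSE)
  }
  if (length(mu) != K) stop("mu must have length K", call. = FALSE)
  if (!(length(sigma2) == 1L && sigma2 > 0)) {
    stop("sigma2 must be a positive scalar", call. = FALSE)
  }
  if (length(beta) != K + 3L) {
    stop("beta must have length K + 3", call. = FALSE)
  }
  structure(list(K = K, gamma = gamma, rho = rho, mu = as.numeric(mu),
                 sigma2 = as.numeric(sigma2), beta = as.numeric(beta)),
            class = "lca_parameters")
}

#' Number of free parameters of the latent class model
#'
#' `4(K-1)` membership logits + `7K` item probabilities + `K` drug-measure
#' means + 1 pooled variance + `K + 3` distal coefficients.
#' @param K number of classes.
#' @return Integer count.
#' @export
n_lca_params <- function(K) {
  as.integer(4L * (K - 1L) + 7L * K + K + 1L + (K - 1L) + 3L + 1L)
}

## covariate-dependent class weights pi_t(z): n x K
prior_matrix <- function(params, frame) {
  K <- params$K
  if (K == 1L) return(matrix(1, frame$n, 1L))
  eta <- cbind(frame$Z %*% t(params$gamma), 0)
  softmax_rows(eta)
}

## distal fall logit per patient and class: n x K
distal_logits <- function(params, frame) {
  K <- params$K
  a <- c(if (K > 1L) params$beta[2:K], 0)
  base <- params$beta[1L] +
    as.numeric(frame$C %*% params$beta[(K + 1L):(K + 3L)])
  outer(base, a, "+")
}

## per-patient per-class complete log-density (including class weight)
class_logdens <- function(params, frame) {
  K <- params$K
  logB <- frame$y %*% t(log(params$rho)) +
    (1 - frame$y) %*% t(log(1 - params$rho))
  s <- sqrt(params$sigma2)
  logN <- vapply(seq_len(K),
                 function(t) dnorm(frame$d, params$mu[t], s, log = TRUE),
                 numeric(frame$n))
  if (frame$n == 1L) logN <- matrix(logN, 1L, K)
  eta <- distal_logits(params, frame)
  logF <- frame$f * plogis(eta, log.p = TRUE) +
    (1 - frame$f) * plogis(-eta, log.p = TRUE)
  log(prior_matrix(params, frame)) + logB + logN + logF
}

#' Observed-data log-likelihood of the latent class model
#'
#' Sums, over patients, the log of the class-weighted product of the seven
#' Bernoulli indicator densities, the Gaussian drug-measure density and the
#' Bernoulli distal fall density — the conditional-independence mixture
#' likelihood with covariate-dependent class weights.
#'
#' @param params an [lca_parameters()] object.
#' @param data analysis table as produced by [prepare_lca_data()].
#' @return A single finite numeric value.
#' @export
observed_loglik <- function(params, data) {
  frame <- if (is.list(data) && !is.data.frame(data)) data else
    lca_frame(data)
  sum(logsumexp_rows(class_logdens(params, frame)))
}

#' Posterior class membership probabilities
#'
#' Bayes rule over the mixture components, accumulated in the log domain so
#' small densities cannot underflow; each row sums to 1.
#'
#' @inheritParams observed_loglik
#' @return An `n x K` matrix of posterior probabilities.
#' @export
posterior_probabilities <- function(params, data) {
  frame <- if (is.list(data) && !is.data.frame(data)) data else
    lca_frame(data)
  L <- class_logdens(params, frame)
  softmax_rows(L)
}

## ---- weighted M-step maximizers ------------------------------------------

## weighted multinomial logit: maximize sum_i sum_t W[i,t] log softmax_t(G z)
## Newton with step-halving; gamma0 warm start. Returns (K-1) x q matrix.
fit_weighted_multinomial <- function(Z, W, gamma0 = NULL, tol = 1e-9,
                                     max_iter = 100L) {
  n <- nrow(Z); q <- ncol(Z); K <- ncol(W)
  stopifnot(K >= 2L)
  G <- if (is.null(gamma0)) matrix(0, K - 1L, q) else gamma0
  qfun <- function(G) {
    eta <- cbind(Z %*% t(G), 0)
    sum(W * (eta - logsumexp_rows(eta)))
  }
  qold <- qfun(G)
  for (iter in seq_len(max_iter)) {
    P <- softmax_rows(cbind(Z %*% t(G), 0))
    grad <- numeric((K - 1L) * q)
    H <- matrix(0, (K - 1L) * q, (K - 1L) * q)
    for (t in seq_len(K - 1L)) {
      it <- ((t - 1L) * q + 1L):(t * q)
      grad[it] <- crossprod(Z, W[, t] - P[, t])
      for (u in seq_len(K - 1L)) {
        iu <- ((u - 1L) * q + 1L):(u * q)
        w <- if (t == u) P[, t] * (1 - P[, t]) else -P[, t] * P[, u]
        H[it, iu] <- -crossprod(Z, Z * w)
      }
    }
    if (max(abs(grad)) < tol) break
    step <- tryCatch(solve(-H + diag(1e-10, nrow(H)), grad),
                     error = function(e) grad / (n + 1))
    lam <- 1
    repeat {
      Gnew <- G + lam * matrix(step, K - 1L, q, byrow = TRUE)
      qnew <- qfun(Gnew)
      if (is.finite(qnew) && qnew >= qold - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-8) { Gnew <- G; qnew <- qold; break }
    }
    if (qnew <= qold + 1e-12 && max(abs(grad)) < 1e-6) { G <- Gnew; break }
    G <- Gnew; qold <- qnew
  }
  dimnames(G) <- list(NULL, colnames(Z))
  G
}

## weighted logistic regression (fractional weights), Newton + step-halving
fit_weighted_logistic <- function(X, y, w, beta0 = NULL, tol = 1e-10,
                                  max_iter = 100L) {
  p <- ncol(X)
  b <- if (is.null(beta0)) numeric(p) else beta0
  qfun <- function(b) {
    eta <- as.numeric(X %*% b)
    sum(w * (y * plogis(eta, log.p = TRUE) +
               (1 - y) * plogis(-eta, log.p = TRUE)))
  }
  qold <- qfun(b)
  for (iter in seq_len(max_iter)) {
    pr <- plogis(as.numeric(X %*% b))
    grad <- as.numeric(crossprod(X, w * (y - pr)))
    if (max(abs(grad)) < tol) break
    Wd <- w * pr * (1 - pr)
    H <- crossprod(X, X * Wd)
    step <- tryCatch(solve(H + diag(1e-10, p), grad),
                     error = function(e) grad / (sum(w) + 1))
    lam <- 1
    repeat {
      bn <- b + lam * step
      qn <- qfun(bn)
      if (is.finite(qn) && qn >= qold - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-8) { bn <- b; qn <- qold; break }
    }
    if (qn <= qold + 1e-12 && max(abs(grad)) < 1e-6) { b <- bn; break }
    b <- bn; qold <- qn
  }
  b
}

## one M-step given posteriors W; returns lca_parameters
m_step <- function(W, frame, K, prev = NULL) {
  colw <- colSums(W)
  rho <- clamp_prob(crossprod(W, frame$y) / colw)
  mu <- as.numeric(crossprod(W, frame$d) / colw)
  sigma2 <- max(sum(W * (outer(frame$d, mu, "-"))^2) / frame$n, 1e-8)
  gamma <- if (K == 1L) matrix(0, 0L, 4L) else {
    fit_weighted_multinomial(frame$Z, W,
                             gamma0 = if (!is.null(prev)) prev$gamma)
  }
  ## distal logistic on K weighted pseudo-observations per patient
  Xd <- distal_design(frame, K)
  beta <- fit_weighted_logistic(Xd, rep(frame$f, K), as.vector(W),
                                beta0 = if (!is.null(prev)) prev$beta)
  lca_parameters(K, gamma, rho, mu, sigma2, beta)
}

## expanded distal design matrix: (n*K) x (K+3), class-t block has dummy t
distal_design <- function(frame, K) {
  n <- frame$n
  Xd <- matrix(0, n * K, K + 3L)
  Xd[, 1L] <- 1
  for (t in seq_len(K - 1L)) {
    Xd[((t - 1L) * n + 1L):(t * n), 1L + t] <- 1
  }
  Xd[, (K + 1L):(K + 3L)] <- do.call(rbind, rep(list(frame$C), K))
  colnames(Xd) <- c("(Intercept)",
                    if (K > 1L) paste0("class", seq_len(K - 1L)),
                    "age", "gender", "n_meds")
  Xd
}

## fitted class-specific fall probability at posterior-weighted mean
## covariates; used for the deterministic label ordering and reporting
class_fall_probs <- function(params, frame, W) {
  K <- params$K
  colw <- colSums(W)
  cbar <- crossprod(W, frame$C) / colw       # K x 3
  a <- c(if (K > 1L) params$beta[2:K], 0)
  plogis(params$beta[1L] + a +
           as.numeric(cbar %*% params$beta[(K + 1L):(K + 3L)]))
}

## permute class labels of a parameter set (perm[j] = old label of new j)
permute_params <- function(params, perm) {
  K <- params$K
  if (K == 1L) return(params)
  Gfull <- rbind(params$gamma, 0)[perm, , drop = FALSE]
  gamma <- sweep(Gfull, 2L, Gfull[K, ], "-")[-K, , drop = FALSE]
  afull <- c(params$beta[2:K], 0)[perm]
  beta <- c(params$beta[1L] + afull[K], afull[-K] - afull[K],
            params$beta[(K + 1L):(K + 3L)])
  lca_parameters(K, gamma, params$rho[perm, , drop = FALSE],
                 params$mu[perm], params$sigma2, beta)
}

## random initial parameter set for one EM start
random_start_params <- function(frame, K, start_seed) {
  with_seed(start_seed, {
    pbar <- colMeans(frame$y)
    rho0 <- clamp_prob(matrix(rep(pbar, each = K) +
                                runif(K * 7L, -0.35, 0.35), K, 7L), 0.02)
    mu0 <- as.numeric(stats::quantile(frame$d,
                                      sort(runif(K, 0.05, 0.95)))) +
      rnorm(K, 0, 0.02)
    gamma0 <- if (K == 1L) matrix(0, 0L, 4L) else
      matrix(c(rnorm(K - 1L, 0, 0.3), rep(0, 3L * (K - 1L))), K - 1L, 4L)
    fbar <- min(max(mean(frame$f), 0.02), 0.98)
    beta0 <- c(qlogis(fbar), if (K > 1L) rnorm(K - 1L, 0, 0.3),
               0, 0, 0)
    lca_parameters(K, gamma0, rho0, mu0,
                   sigma2 = max(stats::var(frame$d), 1e-6), beta0)
  })
}

## continue EM from a run state until the iteration budget is exhausted or
## the relative log-likelihood improvement drops below tol
run_em <- function(state, frame, K, tol, budget) {
  params <- state$params
  ll_prev <- state$ll
  trace <- state$trace
  iters <- state$iters
  converged <- FALSE
  W <- state$W
  used <- 0L
  while (used < budget) {
    used <- used + 1L
    iters <- iters + 1L
    L <- class_logdens(params, frame)
    ll_i <- logsumexp_rows(L)
    ll <- sum(ll_i)
    W <- exp(L - ll_i)
    trace <- c(trace, ll)
    if (is.finite(ll_prev) && (ll - ll_prev) < tol * (abs(ll_prev) + 0.1)) {
      converged <- TRUE
      ll_prev <- ll
      break
    }
    ll_prev <- ll
    params <- m_step(W, frame, K, prev = params)
  }
  list(params = params, ll = ll_prev, W = W, trace = trace,
       iters = iters, converged = converged)
}

#' Fit the latent class model by EM
#'
#' Runs EM from `n_starts` random initial parameter sets (item
#' probabilities perturbed around the sample endorsement rates, class means
#' spread over the drug-measure quantiles; per-start seeds derived
#' deterministically from `seed`). Every start is first run for a short
#' screening phase and the best fifth are polished to convergence — the
#' standard multistart scheme of latent-class software. The E-step is
#' [posterior_probabilities()]; the M-step sets the item probabilities and
#' Gaussian moments to posterior-weighted estimates (variance pooled across
#' classes) and maximizes the membership multinomial logit and the distal
#' logistic exactly by Newton iteration, so the observed log-likelihood
#' never decreases. Classes are relabeled in descending fitted
#' class-specific fall probability.
#'
#' @param data analysis table from [prepare_lca_data()] (indicators, age,
#'   gender, n_meds, drug_measure, fall).
#' @param K number of latent classes (`n >= 5 K` required).
#' @param n_starts number of random starts.
#' @param seed master seed; the same `(data, K, n_starts, seed)` always
#'   returns the identical fit.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations per start.
#' @param verbose print per-start progress.
#' @return An object of class `lca_fit`: `params` ([lca_parameters()]),
#'   `loglik`, `n_params`, `iterations`, `converged`, `n_starts_used`,
#'   `posteriors`, `seed`, `K`, `loglik_trace` (best start) and
#'   `degenerate` (any class with average weight below `1/n`).
#' @export
fit_em <- function(data, K, n_starts = 20L, seed = 1L, tol = 1e-6,
                   max_iter = 1000L, verbose = FALSE) {
  frame <- lca_frame(data)
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1", call. = FALSE)
  if (frame$n < 5L * K) {
    stop("need at least 5 patients per class", call. = FALSE)
  }
  if (K == 1L) {
    W <- matrix(1, frame$n, 1L)
    params <- m_step(W, frame, 1L)
    ll <- observed_loglik(params, frame)
    fit <- structure(
      list(params = params, loglik = ll, n_params = n_lca_params(1L),
           iterations = 1L, converged = TRUE, n_starts_used = 1L,
           posteriors = W, seed = as.integer(seed), K = 1L,
           loglik_trace = ll, degenerate = FALSE),
      class = "lca_fit")
    return(fit)
  }
  seeds <- derive_seeds(seed, n_starts)
  burn_iter <- min(40L, max_iter)
  runs <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    state <- list(params = random_start_params(frame, K, seeds[s]),
                  ll = -Inf, W = NULL, trace = numeric(0), iters = 0L)
    runs[[s]] <- run_em(state, frame, K, tol, budget = burn_iter)
    if (verbose) {
      message(sprintf("start %d: screening loglik %.4f (%d iterations)",
                      s, runs[[s]]$ll, runs[[s]]$iters))
    }
  }
  ## polish the most promising starts to full convergence
  n_polish <- max(2L, ceiling(n_starts / 5))
  order_ll <- order(vapply(runs, `[[`, 0, "ll"), decreasing = TRUE)
  polish <- order_ll[seq_len(min(n_polish, n_starts))]
  for (s in polish) {
    if (!runs[[s]]$converged) {
      runs[[s]] <- run_em(runs[[s]], frame, K, tol,
                          budget = max_iter - runs[[s]]$iters)
    }
    if (verbose) {
      message(sprintf("polish start %d: loglik %.4f (%d iterations%s)",
                      s, runs[[s]]$ll, runs[[s]]$iters,
                      if (runs[[s]]$converged) "" else ", not converged"))
    }
  }
  sbest <- polish[which.max(vapply(runs[polish], `[[`, 0, "ll"))]
  best <- list(params = runs[[sbest]]$params, loglik = runs[[sbest]]$ll,
               iterations = runs[[sbest]]$iters,
               converged = runs[[sbest]]$converged,
               posteriors = runs[[sbest]]$W, trace = runs[[sbest]]$trace)
  ## deterministic label order: descending fitted class fall probability
  pf <- class_fall_probs(best$params, frame, best$posteriors)
  perm <- order(pf, decreasing = TRUE)
  params <- permute_params(best$params, perm)
  W <- best$posteriors[, perm, drop = FALSE]
  degenerate <- any(colMeans(W) < 1 / frame$n)
  if (degenerate) {
    warning("degenerate class: a fitted class carries less than 1/n weight",
            call. = FALSE)
  }
  if (!best$converged) {
    warning(sprintf("EM did not converge in %d iterations", max_iter),
            call. = FALSE)
  }
  structure(
    list(params = params, loglik = best$loglik,
         n_params = n_lca_params(K), iterations = best$iterations,
         converged = best$converged, n_starts_used = n_starts,
         posteriors = W, seed = as.integer(seed), K = K,
         loglik_trace = best$trace, degenerate = degenerate),
    class = "lca_fit")
}

#' @export
print.lca_fit <- function(x, ...) {
  cat(sprintf("Latent class fit: K = %d, loglik = %.3f, %d parameters\n",
              x$K, x$loglik, x$n_params))
  cat(sprintf("  %d iterations (%s), %d starts, seed %d\n", x$iterations,
              if (x$converged) "converged" else "NOT converged",
              x$n_starts_used, x$seed))
  cat("  fitted class shares:",
      paste(sprintf("%.3f", colMeans(x$posteriors)), collapse = " "), "\n")
  invisible(x)
}

## ---- parameter (un)packing and standard errors ---------------------------

pack_params <- function(params) {
  K <- params$K
  th <- c(as.numeric(t(params$gamma)), as.numeric(t(params$rho)),
          params$mu, params$sigma2, params$beta)
  nm <- c(
    if (K > 1L) as.vector(t(outer(seq_len(K - 1L),
                                  c("(Intercept)", "age", "gender", "n_meds"),
                                  function(t, v) sprintf("gamma%d.%s", t, v)))),
    as.vector(t(outer(seq_len(K), indicator_names(),
                      function(t, v) sprintf("rho%d.%s", t, v)))),
    sprintf("mu%d", seq_len(K)), "sigma2",
    c("beta.(Intercept)",
      if (K > 1L) sprintf("beta.class%d", seq_len(K - 1L)),
      "beta.age", "beta.gender", "beta.n_meds"))
  setNames(th, nm)
}

unpack_params <- function(theta, K) {
  q <- 4L
  i <- 0L
  gamma <- matrix(theta[seq_len((K - 1L) * q)], K - 1L, q, byrow = TRUE)
  i <- (K - 1L) * q
  rho <- matrix(theta[i + seq_len(7L * K)], K, 7L, byrow = TRUE)
  i <- i + 7L * K
  mu <- theta[i + seq_len(K)]; i <- i + K
  sigma2 <- theta[i + 1L]; i <- i + 1L
  beta <- theta[i + seq_len(K + 3L)]
  lca_parameters(K, gamma, pmin(pmax(rho, 1e-12), 1 - 1e-12) , mu,
                 max(sigma2, 1e-12), beta)
}

## per-patient log-likelihood vector at packed parameters
ll_vector <- function(theta, K, frame) {
  p <- unpack_params_raw(theta, K)
  logsumexp_rows(class_logdens(p, frame))
}

## like unpack_params but without bound validation (needed when numeric
## differentiation steps slightly outside the rho box)
unpack_params_raw <- function(theta, K) {
  q <- 4L
  gamma <- matrix(theta[seq_len((K - 1L) * q)], K - 1L, q, byrow = TRUE)
  i <- (K - 1L) * q
  rho <- matrix(theta[i + seq_len(7L * K)], K, 7L, byrow = TRUE)
  i <- i + 7L * K
  mu <- theta[i + seq_len(K)]; i <- i + K
  sigma2 <- theta[i + 1L]; i <- i + 1L
  beta <- theta[i + seq_len(K + 3L)]
  structure(list(K = K, gamma = gamma, rho = rho, mu = mu,
                 sigma2 = sigma2, beta = as.numeric(beta)),
            class = "lca_parameters")
}

## finite-difference steps per packed parameter
fd_steps <- function(theta, scale = 1e-4) {
  h <- scale * pmax(1, abs(theta))
  is_rho <- grepl("^rho", names(theta))
  h[is_rho] <- pmin(scale, theta[is_rho] / 2, (1 - theta[is_rho]) / 2)
  is_s2 <- names(theta) == "sigma2"
  h[is_s2] <- scale * theta[is_s2]
  h
}

#' Standard errors of the latent class parameters
#'
#' Numerically differentiates the observed log-likelihood at the MLE.
#' `"observed_information"` inverts the negative Hessian;
#' `"sandwich"` (the default, the robust choice) computes
#' `H^{-1} B H^{-1}` with `B` the outer product of per-patient score
#' vectors obtained by central differences.
#'
#' @param fit a converged [fit_em()] result.
#' @param data the analysis table the model was fitted to.
#' @param method `"sandwich"` or `"observed_information"`.
#' @return A data.frame with columns `parameter`, `estimate`, `se`; the full
#'   covariance matrix is attached as `attr(, "vcov")`.
#' @export
standard_errors <- function(fit, data,
                            method = c("sandwich",
                                       "observed_information")) {
  method <- match.arg(method)
  if (!isTRUE(fit$converged)) {
    stop("standard errors require a converged fit", call. = FALSE)
  }
  frame <- lca_frame(data)
  K <- fit$K
  theta <- pack_params(fit$params)
  p <- length(theta)
  h <- fd_steps(theta)
  ## per-patient scores by central differences: n x p
  S <- matrix(0, frame$n, p)
  for (j in seq_len(p)) {
    tp <- theta; tp[j] <- tp[j] + h[j]
    tm <- theta; tm[j] <- tm[j] - h[j]
    S[, j] <- (ll_vector(tp, K, frame) - ll_vector(tm, K, frame)) /
      (2 * h[j])
  }
  ## Hessian of the total log-likelihood by second differences
  f0 <- sum(ll_vector(theta, K, frame))
  H <- matrix(0, p, p)
  fp <- fm <- numeric(p)
  for (j in seq_len(p)) {
    tp <- theta; tp[j] <- tp[j] + h[j]
    tm <- theta; tm[j] <- tm[j] - h[j]
    fp[j] <- sum(ll_vector(tp, K, frame))
    fm[j] <- sum(ll_vector(tm, K, frame))
    H[j, j] <- (fp[j] - 2 * f0 + fm[j]) / h[j]^2
  }
  for (j in seq_len(p - 1L)) {
    for (k in (j + 1L):p) {
      tpp <- theta; tpp[j] <- tpp[j] + h[j]; tpp[k] <- tpp[k] + h[k]
      tpm <- theta; tpm[j] <- tpm[j] + h[j]; tpm[k] <- tpm[k] - h[k]
      tmp <- theta; tmp[j] <- tmp[j] - h[j]; tmp[k] <- tmp[k] + h[k]
      tmm <- theta; tmm[j] <- tmm[j] - h[j]; tmm[k] <- tmm[k] - h[k]
      H[j, k] <- H[k, j] <-
        (sum(ll_vector(tpp, K, frame)) - sum(ll_vector(tpm, K, frame)) -
           sum(ll_vector(tmp, K, frame)) + sum(ll_vector(tmm, K, frame))) /
        (4 * h[j] * h[k])
    }
  }
  Hinv <- tryCatch(solve(-H), error = function(e) {
    qrH <- qr(-H)
    bad <- names(theta)[qrH$pivot[(qrH$rank + 1L):p]]
    stop(sprintf("singular Hessian; offending parameter block: %s",
                 paste(unique(sub("[0-9.].*$", "", bad)), collapse = ", ")),
         call. = FALSE)
  })
  V <- if (method == "sandwich") Hinv %*% crossprod(S) %*% Hinv else Hinv
  se <- sqrt(pmax(diag(V), 0))
  if (any(!is.finite(se) | se == 0)) {
    bad <- names(theta)[!is.finite(se) | se == 0]
    stop(sprintf("non-positive standard error in parameter block: %s",
                 paste(unique(sub("[0-9.].*$", "", bad)), collapse = ", ")),
         call. = FALSE)
  }
  out <- data.frame(parameter = names(theta), estimate = unname(theta),
                    se = unname(se), stringsAsFactors = FALSE)
  dimnames(V) <- list(names(theta), names(theta))
  attr(out, "vcov") <- V
  attr(out, "method") <- method
  out
}

## ---- parameter serialization ---------------------------------------------

#' Serialize / restore latent class parameters as structured text
#'
#' YAML with all numerics rendered at 17 significant digits, so the
#' round-trip is exact for doubles. Fit metadata (seed, starts, iterations)
#' is embedded when a full `lca_fit` is given.
#'
#' @param x an [lca_parameters()] or `lca_fit` object.
#' @param path file path.
#' @return `write_lca_parameters` returns `path` invisibly;
#'   `read_lca_parameters` returns an [lca_parameters()] object (with a
#'   `meta` attribute when metadata was stored).
#' @export
write_lca_parameters <- function(x, path) {
  meta <- NULL
  if (inherits(x, "lca_fit")) {
    meta <- list(seed = x$seed, n_starts = x$n_starts_used,
                 iterations = x$iterations, converged = x$converged,
                 loglik = format(x$loglik, digits = 17))
    x <- x$params
  }
  num <- function(v) format(as.numeric(v), digits = 17, trim = TRUE)
  obj <- list(K = x$K,
              gamma = num(t(x$gamma)), rho = num(t(x$rho)),
              mu = num(x$mu), sigma2 = num(x$sigma2), beta = num(x$beta))
  if (!is.null(meta)) obj$meta <- meta
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_lca_parameters
#' @export
read_lca_parameters <- function(path) {
  obj <- yaml::read_yaml(path)
  K <- as.integer(obj$K)
  params <- lca_parameters(
    K,
    gamma = matrix(as.numeric(obj$gamma), K - 1L, 4L, byrow = TRUE),
    rho = matrix(as.numeric(obj$rho), K, 7L, byrow = TRUE),
    mu = as.numeric(obj$mu),
    sigma2 = as.numeric(obj$sigma2),
    beta = as.numeric(obj$beta))
  if (!is.null(obj$meta)) attr(params, "meta") <- obj$meta
  params
}
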