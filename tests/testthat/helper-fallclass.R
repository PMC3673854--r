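## Shared fixtures and independent oracles for the test suite. Oracles are
## written with explicit loops and textbook formulas so they share no code
## with the implementation paths they check.

## ---- enumeration oracle for the mixture log-likelihood -------------------
## Loops over patients and classes with explicit arithmetic.
oracle_loglik <- function(params, data) {
  K <- params$K
  y <- as.matrix(data[, indicator_names()])
  total <- 0
  for (i in seq_len(nrow(data))) {
    z <- c(1, data$age[i] - 77, data$gender[i], data$n_meds[i])
    if (K == 1) {
      pri <- 1
    } else {
      et <- c(as.numeric(params$gamma %*% z), 0)
      pri <- exp(et) / sum(exp(et))
    }
    li <- 0
    for (t in seq_len(K)) {
      term <- pri[t]
      for (j in 1:7) {
        term <- term * if (y[i, j] == 1) params$rho[t, j] else
          1 - params$rho[t, j]
      }
      term <- term *
        exp(-(data$drug_measure[i] - params$mu[t])^2 /
              (2 * params$sigma2)) / sqrt(2 * pi * params$sigma2)
      a <- if (K > 1 && t < K) params$beta[1 + t] else 0
      eta <- params$beta[1] + a +
        sum(params$beta[(K + 1):(K + 3)] *
              c(data$age[i] - 77, data$gender[i], data$n_meds[i]))
      pfall <- 1 / (1 + exp(-eta))
      term <- term * if (data$fall[i] == 1) pfall else 1 - pfall
      li <- li + term
    }
    total <- total + log(li)
  }
  as.numeric(total)
}

## per-patient class terms (unnormalized posteriors), same explicit style
oracle_posterior <- function(params, data) {
  K <- params$K
  out <- matrix(NA_real_, nrow(data), K)
  for (i in seq_len(nrow(data))) {
    row <- data[i, , drop = FALSE]
    terms <- numeric(K)
    for (t in seq_len(K)) {
      ## reuse oracle_loglik on a 1-patient, class-t-only device: compute
      ## the class term directly instead
      z <- c(1, row$age - 77, row$gender, row$n_meds)
      pri <- if (K == 1) 1 else {
        et <- c(as.numeric(params$gamma %*% z), 0)
        (exp(et) / sum(exp(et)))[t]
      }
      term <- pri
      y <- as.numeric(row[, indicator_names()])
      for (j in 1:7) {
        term <- term * if (y[j] == 1) params$rho[t, j] else
          1 - params$rho[t, j]
      }
      term <- term *
        exp(-(row$drug_measure - params$mu[t])^2 / (2 * params$sigma2)) /
        sqrt(2 * pi * params$sigma2)
      a <- if (K > 1 && t < K) params$beta[1 + t] else 0
      eta <- params$beta[1] + a +
        sum(params$beta[(K + 1):(K + 3)] *
              c(row$age - 77, row$gender, row$n_meds))
      pfall <- 1 / (1 + exp(-eta))
      terms[t] <- term * if (row$fall == 1) pfall else 1 - pfall
    }
    out[i, ] <- terms / sum(terms)
  }
  out
}

## ---- brute-force CA row scores -------------------------------------------
## Eigen-decomposition of S'S (not svd of S), plus explicit matrix algebra.
oracle_ca_row_scores <- function(counts) {
  n <- sum(counts)
  P <- counts / n
  r <- rowSums(P)
  cm <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - r %o% cm) %*% diag(1 / sqrt(cm))
  ev <- eigen(t(S) %*% S, symmetric = TRUE)
  v1 <- ev$vectors[, 1]
  sigma <- sqrt(max(ev$values[1], 0))
  u1 <- as.numeric(S %*% v1) / sigma
  scores <- u1 / sqrt(r)
  ## orient toward fall share like the implementation's stated rule
  share <- counts[, 2] / rowSums(counts)
  if (sum((scores - mean(scores)) * (share - mean(share))) < 0) {
    scores <- -scores
  }
  as.numeric(scores)
}

## ---- small parameter sets and simulated analysis tables ------------------
make_params <- function(K, seed = 1) {
  set.seed(seed)
  lca_parameters(
    K,
    gamma = if (K > 1) matrix(c(rnorm(K - 1, 0, 0.5),
                                rnorm(3 * (K - 1), 0, 0.1)),
                              K - 1, 4) else matrix(0, 0, 4),
    rho = matrix(runif(7 * K, 0.1, 0.9), K, 7),
    mu = seq(-0.5, 0.5, length.out = K),
    sigma2 = 0.2,
    beta = c(-0.5, if (K > 1) seq(1, 0.2, length.out = K - 1), 0.02, 0.3,
             0.05))
}

## covariate scaffold used by simulate_lca in tests
base_covariates <- function(n, seed = 99) {
  set.seed(seed)
  data.frame(
    matrix(0L, n, 7, dimnames = list(NULL, indicator_names())),
    age = round(runif(n, 66, 92), 1),
    gender = rbinom(n, 1, 0.75),
    n_meds = rpois(n, 4),
    drug_measure = 0, fall = 0L)
}

sim_data <- function(params, n, seed) {
  simulate_lca(params, base_covariates(max(n, 50)), seed = seed, n = n)
}

## well-separated two-class parameter set (for recovery / BLRT power)
sep2_params <- function() {
  lca_parameters(
    2,
    gamma = matrix(c(0.3, 0, 0, 0.1), 1, 4),
    rho = rbind(rep(0.85, 7), rep(0.10, 7)),
    mu = c(0.4, -0.3), sigma2 = 0.15,
    beta = c(-1.5, 1.2, 0.02, 0.3, 0.05))
}

## all permutations of 1:k (k small)
all_perms <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (p in all_perms(k - 1)) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
    }
  }
  out
}

## permutation aligning fitted classes to true classes: perm[fitted] = true
## maximizes the matched count of the modal-vs-true cross table
align_to_truth <- function(modal, true_class, K) {
  cm <- table(factor(true_class, levels = 1:K),
              factor(modal, levels = 1:K))
  best <- NULL; best_n <- -1
  for (p in all_perms(K)) {
    matched <- sum(cm[cbind(p, 1:K)])
    if (matched > best_n) { best_n <- matched; best <- p }
  }
  unlist(best)
}
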