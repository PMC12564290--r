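# Shared fixtures: tiny cohorts and independent reference implementations
# used as oracles. Everything is generated in code at test time.

tiny_spec <- function(n = 20, sites = 2, m = 6, seed = 3, effect = 1,
                      pairs = list(list(atlas = 1, pair = c(2, 5)))) {
  cohort_spec(n_subjects = n, n_sites = sites, atlas_sizes = c(A = m),
              n_timepoints = 60, effect_pairs = pairs, effect_size = effect,
              seed = seed)
}

tiny_train_config <- function(seed = 1, epochs = 8) {
  cfg <- desk_config(seed)
  cfg$train$epochs <- epochs
  cfg$train$es_start <- max(2, epochs - 4)
  cfg$train$patience <- 3
  cfg
}

# Naive reference for the population-graph construction: explicit loops over
# subject pairs and phenotype columns, independent of the package's
# vectorised path.
naive_population_graph <- function(X, P, theta1, theta2, phenotypes, seed,
                                   embed_dim) {
  n <- nrow(X)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      num <- sum(X[i, ] * X[j, ])
      den <- sqrt(sum(X[i, ]^2)) * sqrt(sum(X[j, ]^2))
      sim <- if (den == 0) 0 else num / den
      ssum <- 0
      for (cl in phenotypes) {
        v <- P[[cl]]
        ssum <- ssum + if (is.numeric(v)) {
          as.numeric(abs(v[i] - v[j]) < theta2)
        } else {
          as.numeric(v[i] == v[j])
        }
      }
      A[i, j] <- sim * ssum
    }
  }
  F_mask <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && A[i, j] >= theta1) F_mask[i, j] <- 1
  }
  E <- phenotype_embedding(P, phenotypes = phenotypes, embed_dim = embed_dim,
                           seed = seed)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || F_mask[i, j] == 0) next
      den <- sqrt(sum(E[i, ]^2)) * sqrt(sum(E[j, ]^2))
      cw <- if (den == 0) -1 else sum(E[i, ] * E[j, ]) / den
      W[i, j] <- (cw + 1) / 2
    }
  }
  list(A = A, F = F_mask, W = W)
}

# Dense reference for one renormalised graph-convolution layer.
naive_gcn_layer <- function(H, W, Theta) {
  At <- W + diag(nrow(W))
  Dt <- diag(rowSums(At))
  L <- solve(sqrt(Dt)) %*% At %*% solve(sqrt(Dt))
  pmax(L %*% H %*% Theta, 0)
}

# Brute-force AUC: pairwise concordance over all (positive, negative) pairs.
naive_auc <- function(y, p) {
  pos <- p[y == 1]; neg <- p[y == 0]
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

# Finite-difference derivative of f at x (scalar-in, scalar-out).
fd_grad <- function(f, x, eps = 1e-5) (f(x + eps) - f(x - eps)) / (2 * eps)

expect_symmetric <- function(M, tol = 1e-12) {
  expect_lt(max(abs(M - t(M))), tol)
}
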