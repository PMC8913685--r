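# independent numerical oracles used by the tests

# Gauss-Hermite rule for integrals against the standard normal density:
# int f(u) dnorm(u) du  ~=  sum w_i f(x_i)
# nodes/weights by Golub-Welsch on the Hermite Jacobi matrix.
gauss_hermite_normal <- function(n) {
  if (n == 1L) return(list(x = 0, w = 1))
  off <- sqrt(seq_len(n - 1) / 2)
  J <- diag(0, n)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1L)] <- off
  J[cbind(seq_len(n - 1) + 1L, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  # physicists' nodes -> probabilists': x * sqrt(2); weights sum to 1
  list(x = e$values * sqrt(2), w = e$vectors[1, ]^2)
}

# marginal log-likelihood of the gamma log-link model with correlated
# per-tree (intercept, slope) random effects, by dense 2-D adaptive-free
# Gauss-Hermite quadrature. Independent of the package's fitting route.
marginal_loglik_quadrature <- function(y, X, intercept, beta, tree, slope_z,
                                       Sigma, shape, n_nodes = 40L) {
  gh <- gauss_hermite_normal(n_nodes)
  L <- t(chol(Sigma))
  eta0 <- intercept + drop(X %*% beta)
  ll <- 0
  for (g in levels(tree)) {
    i <- which(tree == g)
    vals <- matrix(NA_real_, n_nodes, n_nodes)
    for (a in seq_len(n_nodes)) for (b in seq_len(n_nodes)) {
      re <- L %*% c(gh$x[a], gh$x[b])
      eta <- eta0[i] + re[1] + re[2] * slope_z[i]
      vals[a, b] <- sum(dgamma(y[i], shape = shape, rate = shape / exp(eta),
                               log = TRUE))
    }
    m <- max(vals)
    ll <- ll + m + log(sum(outer(gh$w, gh$w) * exp(vals - m)))
  }
  ll
}
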