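# Independent oracles and fixture helpers shared across the suite.
# Oracles deliberately avoid the code paths they check.

# brute-force pairwise-overlap NODF / stable-NODF: loops over unordered
# pairs without sorting the matrix
oracle_nodf <- function(B, stable = FALSE) {
  half <- function(M) {
    d <- rowSums(M)
    tot <- 0
    n <- nrow(M)
    if (n < 2) return(0)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      hi <- if (d[i] >= d[j]) i else j
      lo <- if (d[i] >= d[j]) j else i
      if (d[lo] == 0) next
      if (!stable && d[hi] == d[lo]) next
      tot <- tot + sum(M[hi, ] * M[lo, ]) / d[lo]
    }
    tot
  }
  K <- (nrow(B) * (nrow(B) - 1) + ncol(B) * (ncol(B) - 1)) / 200
  (half(B) + half(t(B))) / K
}

# normal-equations OLS oracle: coefficients, standard errors, t, p,
# adjusted R^2, straight from the textbook formulas
oracle_ols <- function(y, X) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  n <- length(y); p <- ncol(X)
  sigma2 <- sum(res^2) / (n - p)
  se <- sqrt(diag(solve(XtX)) * sigma2)
  tval <- beta / se
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  list(beta = as.vector(beta), se = as.vector(se), t = as.vector(tval),
       p = 2 * pt(-abs(as.vector(tval)), df = n - p),
       adj_r2 = 1 - (1 - r2) * (n - 1) / (n - p))
}

# random binary matrix with guaranteed at least one link
random_net <- function(n, m, fill, seed) {
  net <- gen_bernoulli(n, m, fill, seed = seed)
  if (network_size(net) == 0L) net$matrix[1, 1] <- 1L
  net
}

# canonical matrices in which every node has at least one link: the
# regime in which the perfect-nestedness identities are exact
full_coverage_cases <- function() {
  list(c(2, 2, 3), c(7, 7, 28), c(10, 10, 55), c(15, 5, 50),
       c(8, 12, 60), c(12, 30, 200), c(20, 20, 250))
}

expect_full_coverage <- function(n, m, E) {
  B <- canonical_nested(n, m, E)$matrix
  expect_true(all(rowSums(B) > 0) && all(colSums(B) > 0))
}

# direct metric evaluation on a bare matrix, for ensemble simulations
metric_one <- function(B, name) {
  net <- bipartite_network(B)
  switch(name,
         stable_nodf = nest_stable_nodf(net),
         spectral_radius = spectral_radius(net),
         nodf = nest_nodf(net),
         stop("unsupported metric in metric_one: ", name))
}
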