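# Independent oracles used across tests: written as directly as possible,
# sharing no code path with the package implementation.

# partial correlation of each pair given all remaining variables, via the
# Schur complement of the covariance (the regression-residual construction)
oracle_pcc <- function(S) {
  p <- nrow(S)
  out <- matrix(0, p, p, dimnames = dimnames(S))
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      rest <- setdiff(seq_len(p), c(i, j))
      if (length(rest) == 0) {
        r <- S[i, j] / sqrt(S[i, i] * S[j, j])
      } else {
        cond <- S[c(i, j), c(i, j)] -
          S[c(i, j), rest] %*% solve(S[rest, rest], S[rest, c(i, j)])
        r <- cond[1, 2] / sqrt(cond[1, 1] * cond[2, 2])
      }
      out[i, j] <- out[j, i] <- r
    }
  }
  out
}

# joint log-density of residual rows under N(0, solve(K))
oracle_mvn_loglik <- function(E, K) {
  sigma <- solve(K)
  ch <- chol(sigma)
  p <- ncol(E)
  z <- E %*% solve(ch)         # rows become iid standard normal under H0
  -0.5 * sum(z^2) - nrow(E) * (sum(log(diag(ch))) + p / 2 * log(2 * pi))
}

# fixed-point iteration for the stationary covariance of a VAR(1)
oracle_lyapunov <- function(B, Q, iter = 10000, tol = 1e-14) {
  S <- Q
  for (i in seq_len(iter)) {
    S_new <- B %*% S %*% t(B) + Q
    if (max(abs(S_new - S)) < tol) return(S_new)
    S <- S_new
  }
  S
}

# brute-force centrality sums, one explicit loop per definition
oracle_strength <- function(W, i) {
  s <- 0
  for (j in seq_len(ncol(W))) if (j != i) s <- s + abs(W[i, j])
  s
}
oracle_in_strength <- function(B, i) {   # B[i, j] = edge j -> i
  s <- 0
  for (j in seq_len(ncol(B))) if (j != i) s <- s + abs(B[i, j])
  s
}
oracle_out_strength <- function(B, i) {
  s <- 0
  for (j in seq_len(nrow(B))) if (j != i) s <- s + abs(B[j, i])
  s
}
oracle_bridge <- function(W, comm, i, mode = c("undirected", "in", "out")) {
  mode <- match.arg(mode)
  s <- 0
  for (j in seq_len(ncol(W))) {
    if (j == i || comm[j] == comm[i]) next
    s <- s + switch(mode,
                    undirected = abs(W[i, j]),
                    "in" = abs(W[i, j]),
                    "out" = abs(W[j, i]))
  }
  s
}

# random symmetric positive-definite matrix with off-diagonal structure
rand_pd <- function(p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(p * p), p, p)
  S <- crossprod(A) / p + diag(p) * 0.5
  (S + t(S)) / 2
}
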