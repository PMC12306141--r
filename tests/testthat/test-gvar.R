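test_that("standardization yields pooled mean 0 / variance 1 and inverts", {
  tr <- make_truth(seed = 41)
  pr <- pairs_from_truth(tr, 150, seed = 42)
  std <- standardize_pairs(pr)
  pooled <- rbind(std$pairs$x, std$pairs$y)
  expect_lt(max(abs(colMeans(pooled))), 1e-10)
  expect_lt(max(abs(apply(pooled, 2, sd) - 1)), 1e-10)

  back <- sweep(sweep(std$pairs$x, 2, std$scale, "*"), 2, std$center, "+")
  expect_lt(max(abs(back - pr$x)), 1e-10)

  flat <- pr
  flat$x[, 2] <- 3; flat$y[, 2] <- 3
  expect_error(standardize_pairs(flat), colnames(pr$x)[2])
})

test_that("the B coordinate descent matches glmnet at identity precision", {
  library(glmnet)
  set.seed(43)
  n <- 300; p <- 5
  X <- matrix(rnorm(n * p), n, p)
  Y <- X %*% matrix(rnorm(p * p, sd = 0.3), p, p) + matrix(rnorm(n * p), n, p)
  G <- crossprod(X) / n
  C <- crossprod(X, Y) / n
  for (lambda in c(0.02, 0.1)) {
    B <- idionet:::cd_beta(G, C, diag(p), matrix(0, p, p), lambda,
                           tol = 1e-12, max_sweeps = 10000L)
    for (i in seq_len(p)) {
      ref <- as.numeric(coef(glmnet(X, Y[, i], lambda = lambda,
                                    standardize = FALSE, intercept = FALSE,
                                    thresh = 1e-14)))[-1]
      expect_lt(max(abs(B[i, ] - ref)), 1e-6)
    }
  }
})

test_that("penalty-free fits reduce to least squares and direct inversion", {
  tr <- make_truth(p_per_community = 3, seed = 44)
  pr <- standardize_pairs(pairs_from_truth(tr, 800, seed = 45))$pairs
  fit <- fit_gvar(pr, 0, 0)
  expect_true(fit$converged)
  for (i in seq_along(pr$nodes)) {
    ols <- coef(lm(pr$y[, i] ~ 0 + pr$x))
    expect_lt(max(abs(fit$B[i, ] - ols)), 1e-6)
  }
  E <- pr$y - pr$x %*% t(fit$B)
  S <- crossprod(E) / nrow(E)
  expect_lt(max(abs(fit$K - solve(S))), 1e-6)
})

test_that("extreme penalties empty both networks", {
  tr <- make_truth(seed = 46)
  pr <- standardize_pairs(pairs_from_truth(tr, 200, seed = 47))$pairs
  fit <- fit_gvar(pr, 50, 50)
  expect_true(all(fit$B == 0))
  expect_true(all(fit$K[row(fit$K) != col(fit$K)] == 0))
})

test_that("the graphical lasso satisfies its optimality conditions", {
  for (s in 1:3) {
    S <- cov2cor(rand_pd(6, seed = 50 + s))
    rho <- 0.08
    gl <- idionet:::glasso_cd(S, rho, tol = 1e-10, max_iter = 1000L)
    expect_true(gl$converged)
    K <- gl$K
    expect_lt(max(abs(K - t(K))), 1e-8)
    expect_true(all(eigen(K, symmetric = TRUE, only.values = TRUE)$values > 0))
    Sigma <- solve(K)
    # diagonal is unpenalised: Sigma_ii = S_ii
    expect_lt(max(abs(diag(Sigma) - diag(S))), 1e-6)
    for (i in 1:5) for (j in (i + 1):6) {
      if (abs(K[i, j]) > 1e-10) {
        expect_lt(abs(S[i, j] - Sigma[i, j] + rho * sign(K[i, j])), 1e-6)
      } else {
        expect_lte(abs(S[i, j] - Sigma[i, j]), rho + 1e-6)
      }
    }
  }
})

test_that("EBIC equals BIC at gamma 0 and its likelihood matches the density oracle", {
  tr <- make_truth(seed = 61)
  pr <- standardize_pairs(pairs_from_truth(tr, 300, seed = 62))$pairs
  fit <- fit_gvar(pr, 0.05, 0.05)
  E <- pr$y - pr$x %*% t(fit$B)
  # likelihood evaluated at the *fitted* (penalised) K, as EBIC requires;
  # the density oracle gets the same K but no other shared code
  ll_direct <- oracle_mvn_loglik(E, fit$K)
  expect_equal(fit$loglik, ll_direct, tolerance = 1e-8)

  df <- fit$df
  expect_equal(ebic_score(fit, 0), -2 * fit$loglik + log(fit$n_pairs) * df,
               tolerance = 1e-10)
  expect_equal(ebic_score(fit, 0.5),
               ebic_score(fit, 0) + 4 * 0.5 * log(length(fit$nodes)) * df,
               tolerance = 1e-10)

  # an extra nonzero temporal edge costs exactly one df
  denser <- fit
  free <- which(fit$B == 0 & row(fit$B) != col(fit$B))[1]
  denser$B[free] <- 0.1
  denser$df <- idionet:::gvar_df(denser)
  expect_equal(ebic_score(denser, 0.5) - ebic_score(fit, 0.5),
               log(fit$n_pairs) + 4 * 0.5 * log(length(fit$nodes)),
               tolerance = 1e-10)
})

test_that("EBIC grid selection returns the argmin, favouring sparsity on ties", {
  tr <- make_truth(seed = 63)
  pr <- pairs_from_truth(tr, 300, seed = 64)

  single <- validate_penalty_grid(list(lambda_beta = 0.2, lambda_kappa = 0.2,
                                       gamma = 0.5))
  sel1 <- select_model(pr, grid = single)
  expect_identical(nrow(sel1$table), 1L)
  expect_equal(sel1$fit$lambda_beta, 0.2)

  sel <- select_model(pr)
  expect_identical(nrow(sel$table), 100L)
  best <- ebic_score(sel$fit, sel$gamma)
  expect_lte(best, min(sel$table$ebic, na.rm = TRUE) + 1e-9)

  # penalty monotonicity at the extremes: the largest grid point is empty
  top <- sel$table[1, ]
  expect_identical(top$n_edges_temporal + top$n_edges_contemporaneous, 0L)
})

test_that("fits are equivariant to positive rescaling of raw node scores", {
  tr <- make_truth(seed = 65)
  pr <- pairs_from_truth(tr, 250, seed = 66)
  scaled <- pr
  scaled$x[, 3] <- 7 * scaled$x[, 3]
  scaled$y[, 3] <- 7 * scaled$y[, 3]
  a <- select_model(pr)
  b <- select_model(scaled)
  na <- extract_networks(a$fit); nb <- extract_networks(b$fit)
  expect_lt(max(abs(na$contemporaneous - nb$contemporaneous)), 1e-8)
  expect_lt(max(abs(na$temporal - nb$temporal)), 1e-8)
})

test_that("estimation error shrinks as the series lengthens", {
  mae <- function(n_pairs) {
    errs <- sapply(1:20, function(s) {
      tr <- make_truth(seed = 700 + s)
      pr <- pairs_from_truth(tr, n_pairs, seed = 800 + s)
      fit <- fit_gvar(standardize_pairs(pr)$pairs, 0.05, 0.05)
      c(B = mean(abs(fit$B - tr$B)),
        pcc = mean(abs(precision_to_pcc(fit$K) - precision_to_pcc(tr$K))))
    })
    rowMeans(errs)
  }
  small <- mae(500); big <- mae(5000)
  expect_lte(big["B"], small["B"])
  expect_lte(big["pcc"], small["pcc"])
})

test_that("network extraction applies the partial-correlation formula", {
  K2 <- matrix(c(1, -0.5, -0.5, 1), 2, 2)
  expect_equal(precision_to_pcc(K2)[1, 2], 0.5, tolerance = 1e-12)
  expect_true(all(precision_to_pcc(diag(4)) == 0))

  K <- rand_pd(6, seed = 67)
  pcc <- precision_to_pcc(K)
  expect_lt(max(abs(pcc - oracle_pcc(solve(K)))), 1e-8)
  expect_true(all(abs(pcc) <= 1))
  expect_true(all(diag(pcc) == 0))

  tr <- make_truth(seed = 68)
  fit <- fit_gvar(standardize_pairs(pairs_from_truth(tr, 300, seed = 69))$pairs,
                  0.05, 0.05)
  nets <- extract_networks(fit)
  expect_lt(max(abs(nets$contemporaneous - t(nets$contemporaneous))), 1e-12)
  expect_identical(nets$temporal, fit$B)

  el <- export_edge_list(nets)
  expect_true(all(el$type %in% c("contemporaneous", "temporal")))
  expect_true(all(el$is_self_loop[el$type == "contemporaneous"] == FALSE))
  f <- withr::local_tempfile(fileext = ".graphml")
  export_graphml(nets, f, "temporal", tr$communities)
  g <- igraph::read_graph(f, format = "graphml")
  expect_true(igraph::is_directed(g))
  expect_identical(sort(igraph::V(g)$name), sort(tr$nodes))
})
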