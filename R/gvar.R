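#' Standardize lagged pairs
#'
#' Each node is centred and scaled to unit variance using the pooled values
#' appearing in the pairs (predictor and outcome rows stacked), so both
#' sides of every lag-1 regression share one location/scale per node. The
#' transform parameters are returned for reporting and back-transformation.
#'
#' @param pairs a `lagged_pairs` object with at least 2 pairs.
#' @return list with elements `pairs` (standardized `lagged_pairs`),
#'   `center` and `scale` (named per-node vectors).
#' @export
standardize_pairs <- function(pairs) {
  assert_that(inherits(pairs, "lagged_pairs"), "need a `lagged_pairs` object")
  assert_that(pairs$n_pairs >= 2, "need at least 2 lagged pairs")
  pooled <- rbind(pairs$x, pairs$y)
  center <- colMeans(pooled)
  scale <- apply(pooled, 2, stats::sd)
  zero <- names(scale)[scale < 1e-12]
  if (length(zero)) {
    stop(sprintf("zero-variance node(s): %s", paste(zero, collapse = ", ")),
         call. = FALSE)
  }
  std <- pairs
  std$x <- sweep(sweep(pairs$x, 2, center), 2, scale, "/")
  std$y <- sweep(sweep(pairs$y, 2, center), 2, scale, "/")
  list(pairs = std, center = center, scale = scale)
}

#' Fit a sparse graphical VAR at fixed penalties
#'
#' Jointly estimates the lag-1 coefficient matrix `B` (entry `B[i, j]` =
#' effect of node j at t-1 on node i at t) and the residual precision matrix
#' `K` by alternating optimization of the penalised Gaussian conditional
#' likelihood:
#' \enumerate{
#'   \item with `K` fixed, `B` minimises
#'     `tr(K (Y - X B')'(Y - X B')) / (2n) + lambda_beta * ||B||_1`
#'     by cyclical coordinate descent (at `lambda_beta = 0` the exact
#'     least-squares solution is used);
#'   \item with `B` fixed, `K` solves the graphical lasso on the residual
#'     covariance with penalty `lambda_kappa` on off-diagonal entries (at
#'     `lambda_kappa = 0` the residual covariance is inverted directly).
#' }
#' The loop stops when the largest absolute parameter change falls below
#' `tol` or after `max_iter` outer iterations (then `converged = FALSE`
#' with a warning).
#'
#' Inputs are expected on a standardized scale (see [standardize_pairs()];
#' [select_model()] standardizes automatically).
#'
#' @param pairs a `lagged_pairs` object (standardized).
#' @param lambda_beta temporal lasso penalty (>= 0).
#' @param lambda_kappa contemporaneous (precision) lasso penalty (>= 0).
#' @param tol convergence tolerance on the maximum parameter change.
#' @param max_iter maximum outer alternations.
#' @param warm optional `gvar_fit` used to warm-start `B` and `K`.
#' @return An object of class `gvar_fit` with elements `nodes`, `B`, `K`,
#'   `S_resid`, `lambda_beta`, `lambda_kappa`, `n_pairs`, `converged`,
#'   `n_iter`, `loglik`, `df`.
#' @export
fit_gvar <- function(pairs, lambda_beta, lambda_kappa, tol = 1e-6,
                     max_iter = 200, warm = NULL) {
  assert_that(inherits(pairs, "lagged_pairs"), "need a `lagged_pairs` object")
  p <- length(pairs$nodes)
  n <- pairs$n_pairs
  assert_that(p >= 2, "need at least 2 nodes")
  assert_that(n >= 1, "need at least 1 lagged pair")
  assert_that(lambda_beta >= 0 && lambda_kappa >= 0,
              "penalties must be non-negative")
  if (n < p + 1) {
    warning(sprintf("only %d lagged pairs for %d nodes; estimates will be unstable",
                    n, p), call. = FALSE)
  }
  X <- pairs$x; Y <- pairs$y
  G <- crossprod(X) / n
  C <- crossprod(X, Y) / n
  Syy <- crossprod(Y) / n

  B <- if (!is.null(warm)) warm$B else matrix(0, p, p)
  K <- if (!is.null(warm)) warm$K else diag(p)
  converged <- FALSE
  iter <- 0L
  S_E <- Syy
  for (iter in seq_len(max_iter)) {
    B_new <- if (lambda_beta == 0) {
      t(solve(G, C))
    } else {
      cd_beta(G, C, K, B, lambda_beta, tol = 1e-2 * tol, max_sweeps = 2000L)
    }
    BC <- B_new %*% C
    S_E <- Syy - BC - t(BC) + B_new %*% G %*% t(B_new)
    S_E <- (S_E + t(S_E)) / 2
    if (lambda_kappa == 0) {
      ch <- try(chol(S_E), silent = TRUE)
      if (inherits(ch, "try-error")) {
        stop("residual covariance is singular at lambda_kappa = 0; use a positive contemporaneous penalty",
             call. = FALSE)
      }
      K_new <- chol2inv(ch)
    } else {
      gl <- glasso_cd(S_E, lambda_kappa, tol = 1e-2 * tol, max_iter = 500L)
      K_new <- gl$K
    }
    delta <- max(max(abs(B_new - B)), max(abs(K_new - K)))
    B <- B_new; K <- K_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning(sprintf("gVAR alternation did not converge in %d iterations", max_iter),
            call. = FALSE)
  }
  dimnames(B) <- dimnames(K) <- dimnames(S_E) <- list(pairs$nodes, pairs$nodes)
  fit <- structure(list(nodes = pairs$nodes, B = B, K = K, S_resid = S_E,
                        lambda_beta = lambda_beta, lambda_kappa = lambda_kappa,
                        n_pairs = n, converged = converged, n_iter = iter,
                        loglik = NA_real_, df = NA_integer_),
                   class = "gvar_fit")
  fit$loglik <- gvar_loglik(fit)
  fit$df <- gvar_df(fit)
  fit
}

# conditional Gaussian log-likelihood of the fitted model
gvar_loglik <- function(fit) {
  n <- fit$n_pairs
  p <- length(fit$nodes)
  assert_that(is_pd(fit$K), "precision matrix K is not positive definite")
  n / 2 * (logdet_pd(fit$K) - sum(fit$S_resid * fit$K)) -
    n * p / 2 * log(2 * pi)
}

# free nonzero parameters: off-diagonal B + upper-triangle off-diagonal K,
# plus both (always-free) diagonals
gvar_df <- function(fit, zero_tol = 1e-10) {
  p <- length(fit$nodes)
  offB <- sum(abs(fit$B[row(fit$B) != col(fit$B)]) > zero_tol)
  offK <- sum(abs(fit$K[upper.tri(fit$K)]) > zero_tol)
  as.integer(offB + offK + 2L * p)
}

#' Extended BIC of a graphical VAR fit
#'
#' `EBIC = -2 loglik + log(n) df + 4 gamma log(p) df`, where `df` counts the
#' free nonzero parameters (off-diagonal `B` entries, nonzero upper-triangle
#' `K` entries, plus both diagonals, which are always free). `gamma = 0`
#' reduces to the ordinary BIC; larger `gamma` favours sparser models.
#' Lower is better.
#'
#' @param fit a `gvar_fit` on standardized data.
#' @param gamma EBIC hyperparameter (>= 0; default 0.5).
#' @return The EBIC score (numeric scalar).
#' @export
ebic_score <- function(fit, gamma = 0.5) {
  assert_that(inherits(fit, "gvar_fit"), "need a `gvar_fit`")
  assert_that(gamma >= 0, "`gamma` must be >= 0")
  ll <- gvar_loglik(fit)
  df <- gvar_df(fit)
  p <- length(fit$nodes)
  -2 * ll + log(fit$n_pairs) * df + 4 * gamma * log(p) * df
}

#' Build a penalty grid from the data
#'
#' Log-spaced descending sequences for both penalties, from the smallest
#' value that yields an empty model (`lambda_max`, computed from the
#' standardized data: the largest absolute cross-covariance for the temporal
#' penalty, the largest absolute off-diagonal outcome covariance for the
#' contemporaneous penalty) down to `lambda_min_ratio * lambda_max`.
#'
#' @param pairs standardized `lagged_pairs`.
#' @param n_lambda grid points per penalty (default 10, i.e. a 10 x 10 grid).
#' @param lambda_min_ratio smallest penalty as a fraction of `lambda_max`.
#' @param gamma EBIC hyperparameter stored with the grid.
#' @return An object of class `penalty_grid` with descending positive
#'   sequences `lambda_beta`, `lambda_kappa` and the `gamma` value.
#' @export
penalty_grid <- function(pairs, n_lambda = 10, lambda_min_ratio = 0.01,
                         gamma = 0.5) {
  assert_that(inherits(pairs, "lagged_pairs"), "need a `lagged_pairs` object")
  n <- pairs$n_pairs
  C <- crossprod(pairs$x, pairs$y) / n
  Syy <- crossprod(pairs$y) / n
  lb_max <- max(abs(C))
  lk_max <- max(abs(Syy[row(Syy) != col(Syy)]))
  lb_max <- max(lb_max, 1e-4)
  lk_max <- max(lk_max, 1e-4)
  grid <- list(
    lambda_beta = exp(seq(log(lb_max), log(lb_max * lambda_min_ratio),
                          length.out = n_lambda)),
    lambda_kappa = exp(seq(log(lk_max), log(lk_max * lambda_min_ratio),
                           length.out = n_lambda)),
    gamma = gamma)
  validate_penalty_grid(grid)
}

validate_penalty_grid <- function(grid) {
  assert_that(is.list(grid) &&
                all(c("lambda_beta", "lambda_kappa") %in% names(grid)),
              "grid needs lambda_beta and lambda_kappa sequences")
  for (nm in c("lambda_beta", "lambda_kappa")) {
    v <- grid[[nm]]
    assert_that(length(v) >= 1 && !is.unsorted(rev(v)),
                sprintf("%s must be a non-empty descending sequence", nm))
    assert_that(all(v[-length(v)] > 0) && v[length(v)] >= 0,
                sprintf("%s must be positive (optionally ending in 0)", nm))
  }
  grid$gamma <- grid$gamma %||% 0.5
  assert_that(grid$gamma >= 0, "gamma must be >= 0")
  structure(grid, class = "penalty_grid")
}

#' Select penalties by EBIC over a grid
#'
#' Standardizes the pairs (optional), fits every `(lambda_beta,
#' lambda_kappa)` combination with warm starts, scores each fit by
#' [ebic_score()], and returns the minimizer. The grid is traversed from the
#' largest penalties downward and a fit replaces the incumbent only when its
#' EBIC is strictly smaller, so exact ties resolve toward the sparser
#' (larger-penalty) model. The full score table is retained for diagnostics.
#'
#' @param pairs a `lagged_pairs` object (raw scale is fine when
#'   `standardize = TRUE`).
#' @param grid a `penalty_grid`, or `NULL` to build the default
#'   10 x 10 grid from the data.
#' @param gamma EBIC hyperparameter; overrides the grid's value when given.
#' @param standardize standardize pairs first (default `TRUE`).
#' @param tol,max_iter passed to [fit_gvar()].
#' @return An object of class `gvar_selection`: `$fit` (best `gvar_fit`),
#'   `$table` (one row per grid point: penalties, ebic, loglik, df, edge
#'   counts, convergence), `$grid`, `$gamma`, `$center`, `$scale`.
#' @export
select_model <- function(pairs, grid = NULL, gamma = NULL, standardize = TRUE,
                         tol = 1e-6, max_iter = 200) {
  assert_that(inherits(pairs, "lagged_pairs"), "need a `lagged_pairs` object")
  center <- scale <- NULL
  if (standardize) {
    std <- standardize_pairs(pairs)
    pairs <- std$pairs
    center <- std$center
    scale <- std$scale
  }
  if (is.null(grid)) grid <- penalty_grid(pairs, gamma = gamma %||% 0.5)
  grid <- validate_penalty_grid(grid)
  gamma <- gamma %||% grid$gamma

  lb <- sort(grid$lambda_beta, decreasing = TRUE)
  lk <- sort(grid$lambda_kappa, decreasing = TRUE)
  rows <- vector("list", length(lb) * length(lk))
  best <- NULL
  best_score <- Inf
  warm <- NULL
  r <- 0L
  for (b in lb) {
    warm_row <- NULL
    for (k in lk) {
      r <- r + 1L
      fit <- tryCatch(
        withCallingHandlers(
          fit_gvar(pairs, b, k, tol = tol, max_iter = max_iter,
                   warm = warm %||% warm_row),
          warning = function(w) invokeRestart("muffleWarning")),
        error = function(e) e)
      if (inherits(fit, "error")) {
        rows[[r]] <- data.frame(lambda_beta = b, lambda_kappa = k,
                                ebic = NA_real_, loglik = NA_real_,
                                df = NA_integer_, n_edges_temporal = NA_integer_,
                                n_edges_contemporaneous = NA_integer_,
                                converged = FALSE, error = conditionMessage(fit),
                                stringsAsFactors = FALSE)
        next
      }
      score <- tryCatch(ebic_score(fit, gamma), error = function(e) NA_real_)
      p <- length(fit$nodes)
      rows[[r]] <- data.frame(
        lambda_beta = b, lambda_kappa = k, ebic = score, loglik = fit$loglik,
        df = fit$df,
        n_edges_temporal = sum(abs(fit$B[row(fit$B) != col(fit$B)]) > 1e-10),
        n_edges_contemporaneous = sum(abs(fit$K[upper.tri(fit$K)]) > 1e-10),
        converged = fit$converged, error = NA_character_,
        stringsAsFactors = FALSE)
      if (k == lk[1]) warm_row <- fit
      warm <- fit
      if (fit$converged && !is.na(score) && score < best_score) {
        best <- fit
        best_score <- score
      }
    }
    warm <- warm_row
  }
  table <- do.call(rbind, rows)
  if (is.null(best)) {
    stop(paste0("no grid point produced a convergent fit; diagnostics:\n",
                paste(utils::capture.output(print(table)), collapse = "\n")),
         call. = FALSE)
  }
  structure(list(fit = best, table = table, grid = grid, gamma = gamma,
                 center = center, scale = scale),
            class = "gvar_selection")
}

#' @export
print.gvar_selection <- function(x, ...) {
  f <- x$fit
  cat(sprintf("gVAR model selected by EBIC (gamma = %g) over %d grid points\n",
              x$gamma, nrow(x$table)))
  cat(sprintf("  lambda_beta = %.4g, lambda_kappa = %.4g, EBIC = %.2f\n",
              f$lambda_beta, f$lambda_kappa, ebic_score(f, x$gamma)))
  cat(sprintf("  %d temporal and %d contemporaneous edges from %d lagged pairs\n",
              sum(abs(f$B[row(f$B) != col(f$B)]) > 1e-10),
              sum(abs(f$K[upper.tri(f$K)]) > 1e-10), f$n_pairs))
  invisible(x)
}

#' @export
print.gvar_fit <- function(x, ...) {
  cat(sprintf("gVAR fit: %d nodes, %d pairs, lambda_beta = %.4g, lambda_kappa = %.4g, %s in %d iteration(s)\n",
              length(x$nodes), x$n_pairs, x$lambda_beta, x$lambda_kappa,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Partial contemporaneous correlations from a precision matrix
#'
#' `pcc[i, j] = -K[i, j] / sqrt(K[i, i] * K[j, j])`, with a zero diagonal:
#' the correlation between nodes i and j after conditioning on all other
#' nodes (and, through the residual structure, on the previous timepoint).
#'
#' @param K symmetric positive-definite precision matrix.
#' @return Symmetric matrix of partial correlations in \[-1, 1\], diagonal 0.
#' @export
precision_to_pcc <- function(K) {
  assert_that(is_pd(K), "K must be symmetric positive definite")
  d <- sqrt(diag(K))
  pcc <- -K / outer(d, d)
  diag(pcc) <- 0
  (pcc + t(pcc)) / 2
}

#' Extract the contemporaneous and temporal networks from a fit
#'
#' The contemporaneous network is the signed, symmetric matrix of partial
#' contemporaneous correlations derived from the residual precision; the
#' temporal network is the signed directed matrix of standardized lag-1
#' coefficients, where entry `[i, j]` is the edge node j (t-1) -> node i
#' (t). Autoregressive self-loops remain on the temporal diagonal and are
#' marked in exports; centrality excludes them by default.
#'
#' @param fit a `gvar_fit`.
#' @return An object of class `network_pair` with elements
#'   `contemporaneous`, `temporal` and `nodes`.
#' @export
extract_networks <- function(fit) {
  assert_that(inherits(fit, "gvar_fit"), "need a `gvar_fit`")
  pcc <- precision_to_pcc(fit$K)
  structure(list(contemporaneous = pcc, temporal = fit$B, nodes = fit$nodes),
            class = "network_pair")
}

#' @export
print.network_pair <- function(x, ...) {
  cat(sprintf("network pair over %d nodes: %d contemporaneous edge(s), %d temporal edge(s) (+%d self-loop(s))\n",
              length(x$nodes),
              sum(abs(x$contemporaneous[upper.tri(x$contemporaneous)]) > 1e-10),
              sum(abs(x$temporal[row(x$temporal) != col(x$temporal)]) > 1e-10),
              sum(abs(diag(x$temporal)) > 1e-10)))
  invisible(x)
}

#' Export a network pair as an edge list
#'
#' @param pair a `network_pair`.
#' @param path optional CSV path; when given the edge list is also written.
#' @param zero_tol absolute weights at or below this are not edges.
#' @return data frame with columns `source`, `target`, `weight`,
#'   `type` (contemporaneous/temporal), `is_self_loop`.
#' @export
export_edge_list <- function(pair, path = NULL, zero_tol = 1e-10) {
  assert_that(inherits(pair, "network_pair"), "need a `network_pair`")
  nodes <- pair$nodes
  ut <- which(upper.tri(pair$contemporaneous) &
                abs(pair$contemporaneous) > zero_tol, arr.ind = TRUE)
  cont <- data.frame(source = nodes[ut[, 1]], target = nodes[ut[, 2]],
                     weight = pair$contemporaneous[ut],
                     type = rep("contemporaneous", nrow(ut)),
                     is_self_loop = rep(FALSE, nrow(ut)),
                     stringsAsFactors = FALSE)
  tm <- which(abs(pair$temporal) > zero_tol, arr.ind = TRUE)
  temp <- data.frame(source = nodes[tm[, 2]], target = nodes[tm[, 1]],
                     weight = pair$temporal[tm],
                     type = rep("temporal", nrow(tm)),
                     is_self_loop = tm[, 1] == tm[, 2],
                     stringsAsFactors = FALSE)
  out <- rbind(cont, temp)
  rownames(out) <- NULL
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}

#' Export one network of a pair as GraphML
#'
#' Node attributes carry the community when a partition is supplied; edges
#' carry signed weights. The contemporaneous network is written undirected,
#' the temporal network directed (self-loops included, flagged).
#'
#' @param pair a `network_pair`.
#' @param path output file path.
#' @param which `"contemporaneous"` or `"temporal"`.
#' @param partition optional named item_id -> community vector.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(pair, path,
                           which = c("contemporaneous", "temporal"),
                           partition = NULL) {
  which <- match.arg(which)
  el <- export_edge_list(pair)
  el <- el[el$type == which, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    el[, c("source", "target", "weight", "is_self_loop")],
    directed = which == "temporal",
    vertices = data.frame(name = pair$nodes, stringsAsFactors = FALSE))
  if (!is.null(partition)) {
    igraph::V(g)$community <- unname(partition[pair$nodes])
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
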