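#' Construct a synthetic ground truth
#'
#' Low-level constructor validating a hand-specified truth; most users want
#' [make_truth()]. The latent process is a stationary VAR(1),
#' `x_t = B x_{t-1} + e_t` with `e_t ~ N(0, solve(K))`; per-node `location`
#' and `scale` map latent units onto the bounded 0-100 slider scale.
#'
#' @param B p x p lag-1 coefficient matrix with spectral radius < 1.
#' @param K p x p positive-definite innovation precision matrix.
#' @param nodes node names (default taken from `B`'s dimnames).
#' @param communities named vector node -> community (`ED`/`SUI`).
#' @param location per-node latent-to-score intercepts (within \[0, 100\]).
#' @param scale per-node positive latent-to-score slopes.
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(B, K, nodes = NULL, communities = NULL,
                            location = NULL, scale = NULL) {
  B <- as.matrix(B); K <- as.matrix(K)
  p <- nrow(B)
  assert_that(all(dim(B) == p) && all(dim(K) == p),
              "B and K must be square matrices of the same size")
  nodes <- nodes %||% rownames(B) %||% paste0("V", seq_len(p))
  dimnames(B) <- dimnames(K) <- list(nodes, nodes)
  sr <- max(Mod(eigen(B, only.values = TRUE)$values))
  assert_that(sr < 1, sprintf("B must be stable (spectral radius %.3f >= 1)", sr))
  assert_that(is_pd(K), "K must be symmetric positive definite")
  communities <- communities %||%
    stats::setNames(rep(valid_communities, length.out = p), nodes)
  assert_that(all(nodes %in% names(communities)),
              "communities must cover all nodes")
  location <- location %||% stats::setNames(rep(50, p), nodes)
  scale <- scale %||% stats::setNames(rep(15, p), nodes)
  assert_that(all(location >= 0 & location <= 100),
              "locations must lie in [0, 100]")
  assert_that(all(scale > 0), "scales must be positive")
  structure(list(nodes = nodes, B = B, K = K,
                 communities = communities[nodes],
                 location = location, scale = scale,
                 spectral_radius = sr),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("synthetic gVAR truth: %d nodes, %d temporal + %d contemporaneous edge(s), spectral radius %.2f\n",
              length(x$nodes), sum(x$B[row(x$B) != col(x$B)] != 0),
              sum(x$K[upper.tri(x$K)] != 0), x$spectral_radius))
  invisible(x)
}

# default node ids for a 4 + 4 truth mirror the bundled manifest
default_truth_nodes <- function(p_per_community) {
  if (p_per_community == 4) {
    list(ed = c("feel_fat", "fear_weight", "worth_weight", "skip_meals_urge"),
         sui = c("desire_live", "fear_death", "reasons_die",
                 "passive_ideation_1"))
  } else {
    list(ed = paste0("ed_", seq_len(p_per_community)),
         sui = paste0("sui_", seq_len(p_per_community)))
  }
}

#' Draw a random sparse ground truth
#'
#' Generates a stable sparse lag-1 coefficient matrix (autoregressive
#' diagonal in `ar_range`, off-diagonal edges at `edge_density` with
#' magnitudes in `effect_size_range` and random signs) and a sparse
#' positive-definite innovation precision with unit diagonal. At least one
#' inter-community edge is forced into each matrix so bridge statistics are
#' non-trivial. `B` is rescaled, if necessary, to spectral radius <= 0.9;
#' precision off-diagonals are shrunk until the matrix is comfortably
#' positive definite. Latent scales map the stationary process to the 0-100
#' score scale with marginal SD ~15 and means in \[35, 65\], keeping
#' boundary clipping around 1%.
#'
#' @param p_per_community nodes per community (default 4, i.e. 8 nodes).
#' @param edge_density probability of each off-diagonal edge (default 0.15).
#' @param effect_size_range magnitude range for nonzero weights
#'   (default `c(0.25, 0.4)`).
#' @param ar_range range of autoregressive diagonal values.
#' @param seed integer seed for reproducibility.
#' @return A `synthetic_truth`.
#' @export
make_truth <- function(p_per_community = 4, edge_density = 0.15,
                       effect_size_range = c(0.25, 0.4),
                       ar_range = c(0.2, 0.5), seed = NULL) {
  assert_that(p_per_community >= 1, "need at least 1 node per community")
  p <- 2L * as.integer(p_per_community)
  assert_that(p >= 2, "need p >= 2 nodes in total")
  assert_that(edge_density > 0 && edge_density <= 1,
              "`edge_density` must lie in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  ids <- default_truth_nodes(p_per_community)
  nodes <- c(ids$ed, ids$sui)
  communities <- stats::setNames(rep(c("ED", "SUI"), each = p_per_community),
                                 nodes)
  rmag <- function(n) stats::runif(n, effect_size_range[1], effect_size_range[2]) *
    sample(c(-1, 1), n, replace = TRUE)
  cross_pair <- function() c(sample(seq_len(p_per_community), 1),
                             p_per_community + sample(seq_len(p_per_community), 1))

  # temporal coefficients
  B <- diag(stats::runif(p, ar_range[1], ar_range[2]))
  off <- which(row(B) != col(B))
  on <- off[stats::runif(length(off)) < edge_density]
  B[on] <- rmag(length(on))
  cross <- outer(communities, communities, "!=")
  if (!any(B[cross & row(B) != col(B)] != 0)) {
    ij <- cross_pair()
    B[ij[1], ij[2]] <- rmag(1)
  }
  sr <- max(Mod(eigen(B, only.values = TRUE)$values))
  if (sr > 0.9) B <- B * (0.9 / sr)

  # innovation precision with unit diagonal
  K <- diag(p)
  ut <- which(upper.tri(K))
  on <- ut[stats::runif(length(ut)) < edge_density]
  K[on] <- rmag(length(on))
  ij <- cross_pair()
  if (K[min(ij), max(ij)] == 0) K[min(ij), max(ij)] <- rmag(1)
  K[lower.tri(K)] <- t(K)[lower.tri(K)]
  while (min(eigen(K, symmetric = TRUE, only.values = TRUE)$values) < 0.05) {
    K[row(K) != col(K)] <- 0.9 * K[row(K) != col(K)]
  }

  dimnames(B) <- dimnames(K) <- list(nodes, nodes)
  sig <- stationary_covariance(B, chol2inv(chol(K)))
  sd_lat <- sqrt(diag(sig))
  truth <- synthetic_truth(
    B, K, nodes, communities,
    location = stats::setNames(stats::runif(p, 35, 65), nodes),
    scale = stats::setNames(15 / sd_lat, nodes))
  truth
}

#' Stationary covariance of a VAR(1) process
#'
#' Solves the discrete Lyapunov equation `Sigma = B Sigma B' + Q` in closed
#' form via vectorization: `vec(Sigma) = (I - B (x) B)^{-1} vec(Q)`.
#'
#' @param B stable lag-1 coefficient matrix.
#' @param Q innovation covariance matrix.
#' @return The stationary covariance matrix.
#' @export
stationary_covariance <- function(B, Q) {
  p <- nrow(B)
  vecS <- solve(diag(p * p) - kronecker(B, B), as.vector(Q))
  S <- matrix(vecS, p, p, dimnames = dimnames(Q))
  (S + t(S)) / 2
}

#' Simulate the latent VAR(1) chain
#'
#' One continuous, unclipped chain of length `n`, initialized from the
#' stationary distribution -- the raw material for checking simulator
#' fidelity against the closed-form stationary covariance.
#'
#' @param truth a `synthetic_truth`.
#' @param n number of timepoints.
#' @param seed integer seed.
#' @return n x p matrix of latent values.
#' @export
simulate_latent <- function(truth, n, seed = NULL) {
  assert_that(inherits(truth, "synthetic_truth"), "need a `synthetic_truth`")
  if (!is.null(seed)) set.seed(seed)
  p <- length(truth$nodes)
  Q <- chol2inv(chol(truth$K))
  sig0 <- stationary_covariance(truth$B, Q)
  x <- matrix(NA_real_, n, p, dimnames = list(NULL, truth$nodes))
  innov <- rmvn(n, Q)
  x[1, ] <- rmvn(1, sig0)
  tB <- t(truth$B)
  for (t in seq_len(n - 1L)) x[t + 1L, ] <- x[t, ] %*% tB + innov[t + 1L, ]
  x
}

#' Simulate an EMA dataset from a known truth
#'
#' Latent day-blocks follow the VAR(1) truth; under the default
#' `"within_day"` policy each day restarts from the stationary distribution
#' (consistent with excluding overnight lags at estimation), while
#' `"across_all"` simulates one continuous chain. Latent values are mapped
#' through each node's location/scale and clipped to \[0, 100\]; whole beeps
#' are then deleted completely at random at `missing_rate`, matching how EMA
#' nonresponse actually arises (a skipped survey, not a skipped item).
#' Item-level deletion is available via `missing_unit = "item"`.
#'
#' @param truth a `synthetic_truth`.
#' @param schedule an [ema_schedule()] (default 21 x 5).
#' @param day_boundary_policy `"within_day"` (default) or `"across_all"`.
#' @param missing_rate beep-deletion probability in \[0, 1).
#' @param seed integer seed.
#' @param missing_unit `"beep"` (default) or `"item"`.
#' @param participant_id participant token for the dataset.
#' @return An `ema_dataset`; the realized clipping rate is attached as
#'   attribute `"clip_rate"` and the generating truth as `"truth"`.
#' @export
simulate_ema <- function(truth, schedule = ema_schedule(),
                         day_boundary_policy = c("within_day", "across_all"),
                         missing_rate = 0, seed = NULL,
                         missing_unit = c("beep", "item"),
                         participant_id = "synthetic") {
  policy <- match.arg(day_boundary_policy)
  missing_unit <- match.arg(missing_unit)
  assert_that(inherits(truth, "synthetic_truth"), "need a `synthetic_truth`")
  assert_that(inherits(schedule, "ema_schedule"), "need an `ema_schedule`")
  assert_that(missing_rate >= 0 && missing_rate < 1,
              "`missing_rate` must lie in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  p <- length(truth$nodes)
  Q <- chol2inv(chol(truth$K))
  sig0 <- stationary_covariance(truth$B, Q)
  nb <- schedule$beeps_per_day
  nd <- schedule$n_days
  tB <- t(truth$B)

  lat <- matrix(NA_real_, nd * nb, p)
  if (policy == "within_day") {
    for (d in seq_len(nd)) {
      x <- rmvn(1, sig0)
      lat[(d - 1L) * nb + 1L, ] <- x
      if (nb > 1L) {
        innov <- rmvn(nb - 1L, Q)
        for (b in seq_len(nb - 1L)) {
          x <- x %*% tB + innov[b, , drop = FALSE]
          lat[(d - 1L) * nb + b + 1L, ] <- x
        }
      }
    }
  } else {
    lat <- simulate_latent(truth, nd * nb)
  }

  scores <- sweep(sweep(lat, 2, truth$scale[truth$nodes], "*"), 2,
                  truth$location[truth$nodes], "+")
  clip_rate <- mean(scores < 0 | scores > 100)
  scores <- pmin(pmax(scores, 0), 100)

  if (missing_rate > 0) {
    if (missing_unit == "beep") {
      drop <- stats::runif(nrow(scores)) < missing_rate
      scores[drop, ] <- NA_real_
    } else {
      scores[stats::runif(length(scores)) < missing_rate] <- NA_real_
    }
  }

  manifest <- truth_manifest(truth)
  df <- data.frame(day = rep(seq_len(nd), each = nb),
                   beep = rep(seq_len(nb), times = nd))
  for (j in seq_len(p)) df[[truth$nodes[j]]] <- scores[, j]
  ds <- ema_dataset(participant_id, manifest, schedule, df)
  attr(ds, "clip_rate") <- clip_rate
  attr(ds, "truth") <- truth
  ds
}

# manifest for a synthetic truth; reuses bundled labels/prompts when the
# node ids match the shipped manifest
truth_manifest <- function(truth) {
  bundled <- tryCatch(default_manifest(), error = function(e) NULL)
  rows <- lapply(truth$nodes, function(nd) {
    if (!is.null(bundled) && nd %in% bundled$item_id) {
      bundled[bundled$item_id == nd, ]
    } else {
      data.frame(item_id = nd, label = nd, prompt = nd,
                 community = unname(truth$communities[nd]),
                 stringsAsFactors = FALSE)
    }
  })
  as_ema_manifest(do.call(rbind, rows))
}

#' Simulate a cohort with fixed completion counts
#'
#' Produces one synthetic participant per entry of `completed_beeps`, each
#' with *exactly* that many observed beeps (the remainder deleted completely
#' at random). The default trio spans the realistic compliance range of a
#' 105-point protocol: high (96), moderate (75) and low (45) completion.
#'
#' @param completed_beeps integer vector of observed-beep counts.
#' @param schedule an [ema_schedule()].
#' @param seed integer seed.
#' @param truth optional shared `synthetic_truth`; default: a fresh
#'   [make_truth()] per participant.
#' @return Named list of `ema_dataset` objects (`patient_1`, `patient_2`, ...).
#' @export
simulate_patients <- function(completed_beeps = c(96L, 75L, 45L),
                              schedule = ema_schedule(), seed = NULL,
                              truth = NULL) {
  if (!is.null(seed)) set.seed(seed)
  size <- schedule_size(schedule)
  assert_that(all(completed_beeps >= 0 & completed_beeps <= size),
              sprintf("completed_beeps must lie in 0..%d", size))
  out <- lapply(seq_along(completed_beeps), function(i) {
    tr <- truth %||% make_truth(seed = sample.int(.Machine$integer.max, 1))
    ds <- simulate_ema(tr, schedule, missing_rate = 0,
                       participant_id = sprintf("patient_%d", i))
    drop <- sample.int(size, size - completed_beeps[i])
    items <- tr$nodes
    ds$scores[drop, items] <- NA_real_
    attr(ds, "truth") <- tr
    ds
  })
  names(out) <- sprintf("patient_%d", seq_along(out))
  out
}

#' Support-recovery metrics against a known truth
#'
#' Compares the nonzero supports (|weight| > `threshold`) and signs of the
#' estimated temporal and contemporaneous networks with the generating
#' truth. Off-diagonal entries only: the autoregressive diagonal is always
#' present and would inflate recovery scores. When no edges are predicted,
#' precision is 1 by convention (there are no false positives to punish).
#'
#' @param truth a `synthetic_truth`.
#' @param fit a `gvar_fit` sharing the truth's node order.
#' @param threshold absolute weight above which an entry counts as an edge.
#' @return list of class `recovery_metrics` with elements `temporal` and
#'   `contemporaneous`, each holding `precision`, `recall`, `f1`,
#'   `sign_agreement`, `weight_correlation`.
#' @export
recovery_metrics <- function(truth, fit, threshold = 1e-6) {
  assert_that(inherits(truth, "synthetic_truth"), "need a `synthetic_truth`")
  assert_that(inherits(fit, "gvar_fit"), "need a `gvar_fit`")
  assert_that(identical(truth$nodes, fit$nodes),
              "truth and fit must share the same node order")
  score <- function(true_w, est_w, mask) {
    tw <- true_w[mask]; ew <- est_w[mask]
    ts <- abs(tw) > threshold; es <- abs(ew) > threshold
    tp <- sum(ts & es)
    precision <- if (sum(es) == 0) 1 else tp / sum(es)
    recall <- if (sum(ts) == 0) 1 else tp / sum(ts)
    f1 <- if (precision + recall == 0) 0 else
      2 * precision * recall / (precision + recall)
    both <- ts & es
    sign_agreement <- if (sum(both) == 0) NA_real_ else
      mean(sign(tw[both]) == sign(ew[both]))
    un <- ts | es
    weight_correlation <- if (sum(un) >= 2 && stats::sd(tw[un]) > 0 &&
                              stats::sd(ew[un]) > 0)
      stats::cor(tw[un], ew[un]) else NA_real_
    list(precision = precision, recall = recall, f1 = f1,
         sign_agreement = sign_agreement,
         weight_correlation = weight_correlation)
  }
  offd <- row(truth$B) != col(truth$B)
  upper <- upper.tri(truth$K)
  structure(list(
    temporal = score(truth$B, fit$B, offd),
    contemporaneous = score(precision_to_pcc(truth$K),
                            precision_to_pcc(fit$K), upper),
    threshold = threshold),
    class = "recovery_metrics")
}

#' @export
print.recovery_metrics <- function(x, ...) {
  for (nm in c("temporal", "contemporaneous")) {
    m <- x[[nm]]
    cat(sprintf("%s: precision %.2f, recall %.2f, F1 %.2f, sign agreement %s\n",
                nm, m$precision, m$recall, m$f1,
                ifelse(is.na(m$sign_agreement), "NA",
                       sprintf("%.2f", m$sign_agreement))))
  }
  invisible(x)
}
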