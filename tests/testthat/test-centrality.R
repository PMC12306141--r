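sym_net <- function(p, seed) {
  W <- matrix(0, p, p, dimnames = list(paste0("n", 1:p), paste0("n", 1:p)))
  set.seed(seed)
  W[upper.tri(W)] <- rnorm(p * (p - 1) / 2) * rbinom(p * (p - 1) / 2, 1, 0.6)
  W[lower.tri(W)] <- t(W)[lower.tri(W)]
  W
}
dir_net <- function(p, seed) {
  set.seed(seed)
  matrix(rnorm(p * p) * rbinom(p * p, 1, 0.5), p, p,
         dimnames = list(paste0("n", 1:p), paste0("n", 1:p)))
}
alt_comm <- function(p) setNames(rep(c("ED", "SUI"), length.out = p),
                                 paste0("n", 1:p))

test_that("strength sums absolute incident weights", {
  W <- matrix(0, 3, 3, dimnames = rep(list(c("a", "b", "c")), 2))
  W["a", "b"] <- W["b", "a"] <- 0.5
  W["a", "c"] <- W["c", "a"] <- -0.3
  expect_equal(unname(node_strength(W, "a")), 0.8)
  expect_equal(unname(node_strength(W, "b")), 0.5)
  expect_equal(unname(node_strength(matrix(0, 3, 3))), rep(0, 3))
  expect_error(node_strength(W, "zzz"), "not in network")
  # signed variant lets opposite-sign edges cancel
  expect_equal(unname(node_strength(W, "a", signed = TRUE)), 0.2)
})

test_that("in/out strength follow edge direction and skip self-loops", {
  B <- matrix(0, 2, 2, dimnames = rep(list(c("A", "B")), 2))
  B["B", "A"] <- 0.4   # A -> B
  io <- in_out_strength(B)
  expect_equal(unname(io$out_strength), c(0.4, 0))
  expect_equal(unname(io$in_strength), c(0, 0.4))

  selfy <- diag(c(0.5, 0.9))
  io2 <- in_out_strength(selfy)
  expect_true(all(io2$in_strength == 0) && all(io2$out_strength == 0))
  io3 <- in_out_strength(selfy, include_self_loops = TRUE)
  expect_equal(unname(io3$in_strength), c(0.5, 0.9))
})

test_that("bridge strength restricts to cross-community edges", {
  W <- matrix(0, 3, 3, dimnames = rep(list(c("A", "B", "C")), 2))
  W["A", "B"] <- W["B", "A"] <- 0.4
  W["A", "C"] <- W["C", "A"] <- 0.2
  part <- c(A = "ED", B = "ED", C = "SUI")
  expect_equal(unname(bridge_strength(W, part, "A")), 0.2)
  expect_equal(unname(node_strength(W, "A")), 0.6)

  within_only <- W; within_only["A", "C"] <- within_only["C", "A"] <- 0
  expect_true(all(bridge_strength(within_only, part) == 0))
  expect_error(bridge_strength(W, c(A = "ED", B = "ED"), "C"), "unmapped")
})

test_that("centrality matches brute-force summation over 100 random networks", {
  p <- 8
  for (s in 1:100) {
    W <- sym_net(p, 1000 + s)
    B <- dir_net(p, 2000 + s)
    comm <- alt_comm(p)
    st <- node_strength(W)
    io <- in_out_strength(B)
    bu <- bridge_strength(W, comm)
    bi <- bridge_strength(B, comm, direction = "incoming")
    bo <- bridge_strength(B, comm, direction = "outgoing")
    for (i in seq_len(p)) {
      expect_equal(unname(st[i]), oracle_strength(W, i), tolerance = 1e-12)
      expect_equal(unname(io$in_strength[i]), oracle_in_strength(B, i),
                   tolerance = 1e-12)
      expect_equal(unname(io$out_strength[i]), oracle_out_strength(B, i),
                   tolerance = 1e-12)
      expect_equal(unname(bu[i]), oracle_bridge(W, comm, i, "undirected"),
                   tolerance = 1e-12)
      expect_equal(unname(bi[i]), oracle_bridge(B, comm, i, "in"),
                   tolerance = 1e-12)
      expect_equal(unname(bo[i]), oracle_bridge(B, comm, i, "out"),
                   tolerance = 1e-12)
    }
    # conservation: every directed edge leaves one node and enters another
    expect_equal(sum(io$in_strength), sum(io$out_strength), tolerance = 1e-12)
    expect_equal(sum(bi), sum(bo), tolerance = 1e-12)
    # a bridge sum can never exceed its unrestricted counterpart
    expect_true(all(bu <= st + 1e-15))
    expect_true(all(bi <= io$in_strength + 1e-15))
    expect_true(all(bo <= io$out_strength + 1e-15))
  }
})

test_that("bridge values are invariant to relabeling the two communities", {
  W <- sym_net(8, 7)
  B <- dir_net(8, 8)
  comm <- alt_comm(8)
  flipped <- setNames(ifelse(comm == "ED", "SUI", "ED"), names(comm))
  expect_equal(bridge_strength(W, comm), bridge_strength(W, flipped))
  expect_equal(bridge_strength(B, comm, direction = "outgoing"),
               bridge_strength(B, flipped, direction = "outgoing"))
})

test_that("the centrality table agrees with its single-node components", {
  tr <- make_truth(seed = 71)
  fit <- fit_gvar(standardize_pairs(pairs_from_truth(tr, 400, seed = 72))$pairs,
                  0.03, 0.03)
  nets <- extract_networks(fit)
  tab <- centrality_table(nets, tr$communities)
  expect_identical(tab$node, tr$nodes)
  expect_false(anyDuplicated(tab$node) > 0)
  io <- in_out_strength(nets$temporal)
  for (i in seq_along(tr$nodes)) {
    nd <- tr$nodes[i]
    expect_equal(tab$contemporaneous_strength[i],
                 unname(node_strength(nets$contemporaneous, nd)))
    expect_equal(tab$contemporaneous_bridge_strength[i],
                 unname(bridge_strength(nets$contemporaneous,
                                        tr$communities, nd)))
    expect_equal(tab$in_strength[i], unname(io$in_strength[nd]))
    expect_equal(tab$out_strength[i], unname(io$out_strength[nd]))
    expect_equal(tab$bridge_out_strength[i],
                 unname(bridge_strength(nets$temporal, tr$communities, nd,
                                        direction = "outgoing")))
  }
  expect_true(all(as.matrix(tab[, idionet:::centrality_statistics]) >= 0))
  # z columns are centred and unit-scaled (or all zero when flat)
  for (col in idionet:::centrality_statistics) {
    z <- tab[[paste0("z_", col)]]
    if (sd(tab[[col]]) > 0) {
      expect_lt(abs(mean(z)), 1e-12)
      expect_equal(sd(z), 1, tolerance = 1e-12)
    }
  }
})
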