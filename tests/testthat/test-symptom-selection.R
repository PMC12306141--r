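test_that("item summaries use observed values only, with sample SD", {
  m <- matrix(NA_real_, 5, 2)
  m[1:3, 1] <- c(10, 20, 30)
  m[, 2] <- 50
  ds <- dataset_from_matrix(m, 1, 5, toy_manifest(1, 1))
  sm <- item_summaries(ds)
  expect_equal(sm$mean, c(20, 50))
  expect_equal(sm$sd, c(10, 0))
  expect_identical(sm$n_observed, c(3L, 5L))
})

test_that("summary means match a brute-force accumulation oracle", {
  tr <- make_truth(seed = 21)
  ds <- simulate_ema(tr, missing_rate = 0.25, seed = 22)
  sm <- item_summaries(ds)
  m <- ds$scores[, tr$nodes]
  for (it in tr$nodes) {
    tot <- 0; n <- 0
    for (v in m[[it]]) if (!is.na(v)) { tot <- tot + v; n <- n + 1 }
    expect_equal(sm$mean[sm$item_id == it], tot / n, tolerance = 1e-12)
  }
})

test_that("zero-observation items are excluded and reported", {
  m <- matrix(50 + runif(10), 5, 2)
  ds <- dataset_from_matrix(m, 1, 5, toy_manifest(1, 1))
  ds$scores$sui1 <- NA_real_
  expect_message(sm <- item_summaries(ds), "zero observations")
  expect_identical(attr(sm, "excluded"), "sui1")
  expect_false("sui1" %in% sm$item_id)
})

test_that("selection keeps the k highest-mean items per community", {
  # means in the published Patient-1 pattern: the four largest ED means win
  sm <- data.frame(
    item_id = c("feel_fat", "fear_weight", "worth_weight", "skip_meals_urge",
                "binge", "purge", "exercise",
                "desire_live", "fear_death", "reasons_die",
                "passive_ideation_1", "method"),
    community = rep(c("ED", "SUI"), c(7, 5)),
    mean = c(72.27, 66.63, 66.31, 63.01, 40.2, 21.5, 55.0,
             50.80, 31.98, 16.73, 15.31, 9.9),
    sd = c(16.56, 14.95, 14.18, 12.69, 10, 8, 12,
           13.87, 19.34, 11.05, 6.48, 5),
    n_observed = 96L, stringsAsFactors = FALSE)
  ns <- select_top_k_per_community(sm, k = 4)
  expect_setequal(ns$by_community$ED,
                  c("feel_fat", "fear_weight", "worth_weight", "skip_meals_urge"))
  expect_identical(ns$by_community$ED[1], "feel_fat")  # descending mean
  expect_setequal(ns$by_community$SUI,
                  c("desire_live", "fear_death", "reasons_die",
                    "passive_ideation_1"))
  expect_length(ns$nodes, 8)
  expect_false(ns$ties)
})

test_that("selection is permutation-invariant and respects dominance", {
  set.seed(31)
  sm <- data.frame(item_id = sprintf("it%02d", 1:12),
                   community = rep(c("ED", "SUI"), each = 6),
                   mean = runif(12, 10, 90), sd = runif(12, 5, 20),
                   n_observed = 50L, stringsAsFactors = FALSE)
  ref <- select_top_k_per_community(sm, k = 4)
  for (i in 1:5) {
    shuffled <- sm[sample.int(nrow(sm)), ]
    expect_identical(select_top_k_per_community(shuffled, k = 4)$nodes,
                     ref$nodes)
  }
  for (cm in c("ED", "SUI")) {
    sel <- ref$by_community[[cm]]
    rest <- setdiff(sm$item_id[sm$community == cm], sel)
    expect_true(min(sm$mean[sm$item_id %in% sel]) >=
                  max(sm$mean[sm$item_id %in% rest]))
  }
})

test_that("ties break by sd then item_id, and are flagged", {
  sm <- data.frame(item_id = c("a", "b", "c", "s1", "s2"),
                   community = c("ED", "ED", "ED", "SUI", "SUI"),
                   mean = c(60, 50, 50, 40, 30),
                   sd = c(10, 5, 9, 4, 3),
                   n_observed = 50L, stringsAsFactors = FALSE)
  expect_message(ns <- select_top_k_per_community(sm, k = 2), "tie")
  expect_identical(ns$by_community$ED, c("a", "c"))  # c beats b on sd
  expect_true(ns$ties)

  smx <- sm; smx$sd[2:3] <- 7  # equal sd: lexicographic item_id
  expect_message(ns2 <- select_top_k_per_community(smx, k = 2), "tie")
  expect_identical(ns2$by_community$ED, c("a", "b"))
})

test_that("boundaries and degenerate communities are handled", {
  sm <- data.frame(item_id = c("a", "b", "s1", "s2"),
                   community = c("ED", "ED", "SUI", "SUI"),
                   mean = c(60, 50, 40, 30), sd = c(1, 2, 3, 4),
                   n_observed = 10L, stringsAsFactors = FALSE)
  ns <- select_top_k_per_community(sm, k = 2)
  expect_setequal(ns$nodes, sm$item_id)  # k = community size

  expect_error(select_top_k_per_community(sm, k = 3), "community ED")

  flat <- sm; flat$sd[1] <- 0
  expect_message(
    expect_error(select_top_k_per_community(flat, k = 2), "community ED"),
    "zero-variance")
  ns3 <- select_top_k_per_community(flat, k = 2, skip_zero_variance = FALSE)
  expect_identical(ns3$by_community$ED, c("a", "b"))
})
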