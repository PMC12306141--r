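test_that("schedule arithmetic is exact integer multiplication", {
  expect_identical(schedule_size(ema_schedule(21, 5)), 105L)
  expect_identical(schedule_size(ema_schedule(1, 1)), 1L)
  expect_identical(schedule_size(ema_schedule(20, 5)), 100L)
  expect_error(ema_schedule(0, 5), "n_days")
  expect_error(ema_schedule(3, 0), "beeps_per_day")
})

test_that("dataset construction validates ranges, uniqueness and fills gaps", {
  man <- toy_manifest(1, 1)
  sch <- ema_schedule(2, 5)
  df <- data.frame(day = rep(1:2, each = 5), beep = rep(1:5, 2),
                   ed1 = seq(0, 90, 10), sui1 = seq(100, 10, -10))
  ds <- ema_dataset("p1", man, sch, df)
  expect_s3_class(ds, "ema_dataset")
  expect_identical(n_observed_beeps(ds), 10L)

  bad <- df; bad$ed1[3] <- 101
  expect_error(ema_dataset("p1", man, sch, bad), "ed1.*101|101.*ed1")
  dup <- df; dup$beep[2] <- 1
  expect_error(ema_dataset("p1", man, sch, dup), "duplicate")

  # absent scheduled rows become fully missing beeps
  part <- df[1:7, ]
  ds2 <- ema_dataset("p1", man, sch, part)
  expect_identical(nrow(ds2$scores), 10L)
  expect_identical(n_observed_beeps(ds2), 7L)
  expect_true(all(is.na(ds2$scores[8:10, c("ed1", "sui1")])))

  # 0 is a valid score, distinct from missing
  zero <- df; zero$ed1[1] <- 0
  expect_identical(ema_dataset("p1", man, sch, zero)$scores$ed1[1], 0)
})

test_that("write/load round-trips scores exactly in both dialects", {
  tr <- make_truth(seed = 11)
  ds <- simulate_ema(tr, ema_schedule(4, 5), missing_rate = 0.2, seed = 12)
  for (fmt in c("long", "wide")) {
    f <- withr::local_tempfile(fileext = ".csv")
    write_ema_table(ds, f, fmt)
    back <- load_ema_table(f, ds$manifest, ds$schedule)
    expect_identical(back$scores, ds$scores)
    expect_identical(back$participant_id, ds$participant_id)
  }
})

test_that("malformed tables are rejected with row-level diagnostics", {
  man <- toy_manifest(1, 1)
  sch <- ema_schedule(1, 5)
  f <- withr::local_tempfile(fileext = ".csv")

  writeLines(c("day,beep,ed1", "1,1,5"), f)
  expect_error(load_ema_table(f, man, sch), "malformed header")

  writeLines(c("participant_id,day,beep,item_id,score",
               "p,1,1,ed1,50", "p,1,2,ed1,101"), f)
  expect_error(load_ema_table(f, man, sch), "row 3.*ed1|ed1.*row 3")

  writeLines(c("participant_id,day,beep,item_id,score",
               "p,1,2,ed1,50", "p,1,2,ed1,60"), f)
  expect_error(load_ema_table(f, man, sch), "duplicate")

  writeLines(c("participant_id,day,beep,ed1,sui1",
               "p,1,2,10,20", "p,1,2,30,40"), f)
  expect_error(load_ema_table(f, man, sch), "duplicate")

  writeLines(c("participant_id,day,beep,item_id,score",
               "p,1,1,nope,50"), f)
  expect_error(load_ema_table(f, man, sch), "not in manifest")
})

test_that("completeness summary uses half-up rounding over the scheduled total", {
  sch <- ema_schedule(21, 5)
  m <- matrix(50, 105, 2)
  m[5 * (1:9) - 4, 1] <- NA             # beep 1 of days 1-9: 96 observed
  m[c(5 * (1:15) - 4, 5 * (1:15) - 3), 2] <- NA  # 75 observed
  ds <- dataset_from_matrix(m, 21, 5, toy_manifest(1, 1))
  cs <- completeness_summary(ds)
  expect_identical(cs$n_observed, c(96L, 75L))
  expect_identical(cs$available_percent, c(91.43, 71.43))
  expect_identical(cs$n_days_observed, c(21L, 21L))

  full <- dataset_from_matrix(matrix(50, 105, 2), 21, 5, toy_manifest(1, 1))
  expect_identical(completeness_summary(full)$available_percent, c(100, 100))

  # percentages live in [0, 100] and hit 100 iff nothing is missing
  for (s in 1:5) {
    tr <- make_truth(seed = 300 + s)
    ds <- simulate_ema(tr, missing_rate = 0.3, seed = 400 + s)
    cs <- completeness_summary(ds)
    expect_true(all(cs$available_percent >= 0 & cs$available_percent <= 100))
    expect_identical(cs$available_percent == 100, cs$n_observed == 105L)
  }
})

test_that("lagged pairs honour day boundaries and drop incomplete beeps", {
  man <- toy_manifest(1, 1)
  one_day <- dataset_from_matrix(matrix(runif(10, 10, 90), 5, 2), 1, 5, man)
  expect_identical(to_lagged_pairs(one_day)$n_pairs, 4L)

  gappy <- matrix(runif(10, 10, 90), 5, 2)
  gappy[3, ] <- NA
  expect_identical(
    to_lagged_pairs(dataset_from_matrix(gappy, 1, 5, man))$n_pairs, 2L)

  two_days <- dataset_from_matrix(matrix(runif(20, 10, 90), 10, 2), 2, 5, man)
  expect_identical(to_lagged_pairs(two_days, day_boundary_policy = "within_day")$n_pairs, 8L)
  expect_identical(to_lagged_pairs(two_days, day_boundary_policy = "across_all")$n_pairs, 9L)

  # a single observed record cannot form a pair
  lone <- matrix(NA_real_, 5, 2); lone[2, ] <- c(40, 60)
  expect_identical(to_lagged_pairs(dataset_from_matrix(lone, 1, 5, man))$n_pairs, 0L)

  expect_error(to_lagged_pairs(two_days, nodes = "ghost"), "not in manifest")
})

test_that("emitted pairs are complete and bounded by observed records", {
  for (s in 1:5) {
    tr <- make_truth(seed = 500 + s)
    ds <- simulate_ema(tr, missing_rate = 0.35, seed = 600 + s)
    pr <- to_lagged_pairs(ds, tr$nodes)
    expect_false(anyNA(pr$x))
    expect_false(anyNA(pr$y))
    expect_lte(pr$n_pairs, max(n_observed_beeps(ds) - 1L, 0L))
  }
})
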