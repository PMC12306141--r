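#' EMA sampling schedule
#'
#' Describes the fixed signal-contingent sampling protocol: `beeps_per_day`
#' surveys per day at `beep_interval`-hour spacing inside a participant's
#' waking window, repeated for `n_days` days. The default mirrors a common
#' intensive protocol: 21 days x 5 beeps/day every 2.5 h, each survey open
#' for a 2-hour response window, i.e. 105 scheduled assessment points.
#'
#' @param n_days number of study days (>= 1).
#' @param beeps_per_day number of scheduled surveys per day (>= 1).
#' @param beep_interval hours between consecutive beeps within a day.
#' @param response_window hours a survey stays open after notification.
#' @return An object of class `ema_schedule`.
#' @seealso [schedule_size()]
#' @export
#' @examples
#' sch <- ema_schedule()        # 21 x 5
#' schedule_size(sch)           # 105
ema_schedule <- function(n_days = 21L, beeps_per_day = 5L,
                         beep_interval = 2.5, response_window = 2) {
  n_days <- as.integer(n_days)
  beeps_per_day <- as.integer(beeps_per_day)
  assert_that(length(n_days) == 1 && !is.na(n_days) && n_days >= 1L,
              "`n_days` must be a single integer >= 1")
  assert_that(length(beeps_per_day) == 1 && !is.na(beeps_per_day) &&
                beeps_per_day >= 1L,
              "`beeps_per_day` must be a single integer >= 1")
  assert_that(is.numeric(beep_interval) && beep_interval > 0,
              "`beep_interval` must be a positive number of hours")
  assert_that(is.numeric(response_window) && response_window > 0,
              "`response_window` must be a positive number of hours")
  structure(list(n_days = n_days, beeps_per_day = beeps_per_day,
                 beep_interval = beep_interval,
                 response_window = response_window),
            class = "ema_schedule")
}

#' Total number of scheduled assessment points
#'
#' @param schedule an [ema_schedule()].
#' @return `n_days * beeps_per_day` as an integer.
#' @export
schedule_size <- function(schedule) {
  assert_that(inherits(schedule, "ema_schedule"),
              "`schedule` must be an `ema_schedule` object")
  schedule$n_days * schedule$beeps_per_day
}

#' @export
print.ema_schedule <- function(x, ...) {
  cat(sprintf("EMA schedule: %d days x %d beeps/day (every %g h, %g h window) = %d points\n",
              x$n_days, x$beeps_per_day, x$beep_interval, x$response_window,
              schedule_size(x)))
  invisible(x)
}

valid_communities <- c("ED", "SUI")

#' Validate a symptom-item manifest
#'
#' A manifest lists the EMA items: a short unique `item_id`, a display
#' `label`, the full item `prompt`, and the clinical `community` the item
#' belongs to (`"ED"` for eating-disorder items, `"SUI"` for suicidality
#' items). Communities are pre-defined clinically, never inferred from data.
#'
#' @param manifest data frame with columns `item_id`, `label`, `prompt`,
#'   `community`.
#' @return The validated manifest (invisibly classed `ema_manifest`).
#' @export
as_ema_manifest <- function(manifest) {
  req <- c("item_id", "label", "prompt", "community")
  assert_that(is.data.frame(manifest) && all(req %in% names(manifest)),
              sprintf("manifest must be a data frame with columns %s",
                      paste(req, collapse = ", ")))
  manifest <- as.data.frame(manifest[, req], stringsAsFactors = FALSE)
  manifest$item_id <- as.character(manifest$item_id)
  manifest$community <- as.character(manifest$community)
  dup <- manifest$item_id[duplicated(manifest$item_id)]
  assert_that(length(dup) == 0,
              sprintf("duplicated item_id in manifest: %s",
                      paste(unique(dup), collapse = ", ")))
  bad <- setdiff(unique(manifest$community), valid_communities)
  assert_that(length(bad) == 0,
              sprintf("community must be one of %s; found: %s",
                      paste(valid_communities, collapse = "/"),
                      paste(bad, collapse = ", ")))
  class(manifest) <- c("ema_manifest", "data.frame")
  manifest
}

#' Read a symptom manifest CSV
#'
#' Expects a UTF-8 CSV with mandatory header
#' `item_id,label,prompt,community`.
#'
#' @param path file path.
#' @return An `ema_manifest` data frame.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  as_ema_manifest(df)
}

#' Default symptom manifest
#'
#' The twelve EMA items (seven eating-disorder, five suicidality) used in the
#' demo analyses, shipped with the package.
#'
#' @return An `ema_manifest` data frame.
#' @export
default_manifest <- function() {
  read_manifest(system.file("extdata", "symptom_manifest.csv",
                            package = "idionet", mustWork = TRUE))
}

#' Community partition of a node set
#'
#' @param manifest an `ema_manifest` (or data frame with `item_id` and
#'   `community`).
#' @return Named character vector mapping item_id -> community.
#' @export
community_partition <- function(manifest) {
  assert_that(is.data.frame(manifest) &&
                all(c("item_id", "community") %in% names(manifest)),
              "need columns item_id and community")
  part <- stats::setNames(as.character(manifest$community),
                          as.character(manifest$item_id))
  assert_that(all(part %in% valid_communities),
              "communities must be ED or SUI")
  part
}

#' Construct a validated EMA dataset
#'
#' The canonical time axis is the integer pair (day, beep); wall-clock
#' timestamps are deliberately not part of the container. `scores` may omit
#' scheduled (day, beep) combinations entirely -- these are recorded as fully
#' missing beeps. A missing response is always `NA`, never 0: 0 is a valid
#' score on the 0-100 slider.
#'
#' @param participant_id opaque participant token.
#' @param manifest an `ema_manifest`.
#' @param schedule an [ema_schedule()].
#' @param scores data frame with integer columns `day`, `beep` and one
#'   numeric column per manifest `item_id` (values in \[0, 100\] or `NA`).
#' @return An object of class `ema_dataset` whose `$scores` holds one row per
#'   scheduled point, ordered chronologically.
#' @export
ema_dataset <- function(participant_id, manifest, schedule, scores) {
  manifest <- as_ema_manifest(manifest)
  assert_that(inherits(schedule, "ema_schedule"),
              "`schedule` must be an `ema_schedule`")
  assert_that(is.data.frame(scores) && all(c("day", "beep") %in% names(scores)),
              "`scores` must be a data frame with columns day and beep")
  items <- manifest$item_id
  extra <- setdiff(names(scores), c("day", "beep", items))
  assert_that(length(extra) == 0,
              sprintf("score columns not in manifest: %s",
                      paste(extra, collapse = ", ")))
  day <- as.integer(scores$day)
  beep <- as.integer(scores$beep)
  assert_that(!anyNA(day) && all(day >= 1L & day <= schedule$n_days),
              sprintf("day indices must lie in 1..%d", schedule$n_days))
  assert_that(!anyNA(beep) && all(beep >= 1L & beep <= schedule$beeps_per_day),
              sprintf("beep indices must lie in 1..%d", schedule$beeps_per_day))
  key <- paste(day, beep)
  dup <- key[duplicated(key)]
  assert_that(length(dup) == 0,
              sprintf("duplicate (day, beep) rows: %s",
                      paste(unique(dup), collapse = "; ")))

  full <- expand.grid(beep = seq_len(schedule$beeps_per_day),
                      day = seq_len(schedule$n_days))[, c("day", "beep")]
  mat <- matrix(NA_real_, nrow(full), length(items),
                dimnames = list(NULL, items))
  ridx <- match(key, paste(full$day, full$beep))
  for (it in items) {
    if (it %in% names(scores)) {
      v <- as.numeric(scores[[it]])
      bad <- which(!is.na(v) & (v < 0 | v > 100))
      if (length(bad)) {
        stop(sprintf("score out of [0,100] for item '%s' at (day %d, beep %d): %g",
                     it, day[bad[1]], beep[bad[1]], v[bad[1]]), call. = FALSE)
      }
      mat[ridx, it] <- v
    }
  }
  out <- cbind(full, as.data.frame(mat))
  structure(list(participant_id = as.character(participant_id),
                 manifest = manifest, schedule = schedule, scores = out),
            class = "ema_dataset")
}

#' @export
print.ema_dataset <- function(x, ...) {
  cat(sprintf("EMA dataset '%s': %d items, %d/%d beeps with any response\n",
              x$participant_id, nrow(x$manifest), n_observed_beeps(x),
              schedule_size(x$schedule)))
  invisible(x)
}

#' Number of beeps with at least one observed item
#'
#' @param dataset an `ema_dataset`.
#' @return Integer count of observed records.
#' @export
n_observed_beeps <- function(dataset) {
  m <- score_matrix(dataset)
  sum(rowSums(!is.na(m)) > 0)
}

# scheduled-point x item score matrix (rows chronological)
score_matrix <- function(dataset) {
  as.matrix(dataset$scores[, dataset$manifest$item_id, drop = FALSE])
}

#' Read an EMA score table
#'
#' Two CSV dialects are accepted (detected from the header unless `format`
#' is given):
#' \describe{
#'   \item{long}{columns `participant_id, day, beep, item_id, score`.}
#'   \item{wide}{columns `participant_id, day, beep`, then one column per
#'     item; an empty cell is a missing response.}
#' }
#' Rows are validated against the manifest and schedule; scores outside
#' \[0, 100\], unknown items and duplicate cells raise errors naming the
#' offending row. Scheduled (day, beep) combinations absent from the file
#' become fully missing beeps.
#'
#' @param path CSV file path (UTF-8, mandatory header).
#' @param manifest an `ema_manifest`.
#' @param schedule an [ema_schedule()].
#' @param format `"auto"` (default), `"long"` or `"wide"`.
#' @return An `ema_dataset`.
#' @export
load_ema_table <- function(path, manifest, schedule,
                           format = c("auto", "long", "wide")) {
  format <- match.arg(format)
  manifest <- as_ema_manifest(manifest)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  base_cols <- c("participant_id", "day", "beep")
  assert_that(all(base_cols %in% names(df)),
              sprintf("malformed header in %s: need columns %s", path,
                      paste(base_cols, collapse = ", ")))
  if (format == "auto") {
    format <- if (all(c("item_id", "score") %in% names(df))) "long" else "wide"
  }
  pid <- unique(as.character(df$participant_id))
  assert_that(length(pid) == 1,
              "file must contain exactly one participant_id")

  if (format == "long") {
    assert_that(all(c("item_id", "score") %in% names(df)),
                sprintf("malformed header in %s: long format needs item_id and score", path))
    unknown <- setdiff(unique(df$item_id), manifest$item_id)
    assert_that(length(unknown) == 0,
                sprintf("items not in manifest: %s",
                        paste(unknown, collapse = ", ")))
    key <- paste(df$day, df$beep, df$item_id)
    dup <- which(duplicated(key))
    if (length(dup)) {
      stop(sprintf("duplicate cell at row %d: (day %s, beep %s, item %s)",
                   dup[1] + 1L, df$day[dup[1]], df$beep[dup[1]],
                   df$item_id[dup[1]]), call. = FALSE)
    }
    sc <- as.numeric(df$score)
    bad <- which(!is.na(sc) & (sc < 0 | sc > 100))
    if (length(bad)) {
      stop(sprintf("score out of [0,100] at row %d (day %s, beep %s, item %s): %s",
                   bad[1] + 1L, df$day[bad[1]], df$beep[bad[1]],
                   df$item_id[bad[1]], df$score[bad[1]]), call. = FALSE)
    }
    wide <- unique(df[, c("day", "beep")])
    for (it in manifest$item_id) {
      sub <- df[df$item_id == it, ]
      idx <- match(paste(wide$day, wide$beep), paste(sub$day, sub$beep))
      wide[[it]] <- ifelse(is.na(idx), NA_real_, sc[df$item_id == it][idx])
    }
    scores <- wide
  } else {
    item_cols <- setdiff(names(df), base_cols)
    unknown <- setdiff(item_cols, manifest$item_id)
    assert_that(length(unknown) == 0,
                sprintf("columns not in manifest: %s",
                        paste(unknown, collapse = ", ")))
    key <- paste(df$day, df$beep)
    dup <- which(duplicated(key))
    if (length(dup)) {
      stop(sprintf("duplicate (day %s, beep %s) at row %d",
                   df$day[dup[1]], df$beep[dup[1]], dup[1] + 1L),
           call. = FALSE)
    }
    for (it in item_cols) {
      v <- suppressWarnings(as.numeric(df[[it]]))
      bad <- which(!is.na(v) & (v < 0 | v > 100))
      if (length(bad)) {
        stop(sprintf("score out of [0,100] at row %d (day %s, beep %s, item %s): %s",
                     bad[1] + 1L, df$day[bad[1]], df$beep[bad[1]], it,
                     df[[it]][bad[1]]), call. = FALSE)
      }
      df[[it]] <- v
    }
    scores <- df[, c("day", "beep", item_cols)]
  }
  ema_dataset(pid, manifest, schedule, scores)
}

#' Write an EMA dataset to CSV
#'
#' Scores are written with full (round-trip exact) precision. In long format
#' only observed cells are written; absent beeps reload as fully missing.
#'
#' @param dataset an `ema_dataset`.
#' @param path output file path.
#' @param format `"long"` or `"wide"`.
#' @return `path`, invisibly.
#' @export
write_ema_table <- function(dataset, path, format = c("long", "wide")) {
  format <- match.arg(format)
  m <- score_matrix(dataset)
  sc <- dataset$scores
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))
  if (format == "long") {
    rows <- which(!is.na(m), arr.ind = TRUE)
    out <- data.frame(participant_id = dataset$participant_id,
                      day = sc$day[rows[, 1]], beep = sc$beep[rows[, 1]],
                      item_id = colnames(m)[rows[, 2]],
                      score = sprintf("%.17g", m[rows]),
                      stringsAsFactors = FALSE)
    out <- out[order(out$day, out$beep, match(out$item_id, colnames(m))), ]
  } else {
    out <- data.frame(participant_id = dataset$participant_id,
                      day = sc$day, beep = sc$beep, stringsAsFactors = FALSE)
    for (it in colnames(m)) out[[it]] <- fmt(m[, it])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Per-item completeness summary
#'
#' For each manifest item: the number of scheduled points at which it was
#' observed, the number of distinct days with at least one observation, and
#' the availability percentage `100 * n_observed / schedule_size`, rounded
#' half-up to two decimals (so 96 of 105 points prints as 91.43). The
#' scheduled total is always the denominator.
#'
#' @param dataset an `ema_dataset`.
#' @return data frame with columns `item_id`, `n_observed`,
#'   `n_days_observed`, `available_percent`.
#' @export
completeness_summary <- function(dataset) {
  assert_that(inherits(dataset, "ema_dataset"), "need an `ema_dataset`")
  assert_that(nrow(dataset$manifest) > 0, "manifest is empty")
  m <- score_matrix(dataset)
  size <- schedule_size(dataset$schedule)
  obs <- colSums(!is.na(m))
  days <- vapply(colnames(m), function(it) {
    length(unique(dataset$scores$day[!is.na(m[, it])]))
  }, integer(1))
  data.frame(item_id = colnames(m),
             n_observed = as.integer(obs),
             n_days_observed = as.integer(days),
             available_percent = round_half_up(100 * obs / size, 2),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Build complete lagged (t-1, t) observation pairs
#'
#' Lag-1 estimation uses only available data, without imputation: a pair is
#' emitted only when both beeps are consecutive scheduled points and every
#' selected node is observed at both. Under the default `"within_day"`
#' policy, pairs never span the overnight gap (the within-day inter-beep
#' interval is short and approximately equal-spaced, the overnight gap is
#' not); `"across_all"` additionally pairs the last beep of one day with the
#' first beep of the next.
#'
#' @param dataset an `ema_dataset`.
#' @param nodes character vector of item_ids to use (default: all items).
#' @param day_boundary_policy `"within_day"` (default) or `"across_all"`.
#' @return An object of class `lagged_pairs`: matrices `x` (scores at t-1)
#'   and `y` (scores at t), one row per pair in chronological order, plus
#'   `day` and `within_day` markers.
#' @export
to_lagged_pairs <- function(dataset, nodes = NULL,
                            day_boundary_policy = c("within_day", "across_all")) {
  policy <- match.arg(day_boundary_policy)
  assert_that(inherits(dataset, "ema_dataset"), "need an `ema_dataset`")
  nodes <- nodes %||% dataset$manifest$item_id
  missing_nodes <- setdiff(nodes, dataset$manifest$item_id)
  assert_that(length(missing_nodes) == 0,
              sprintf("nodes not in manifest: %s",
                      paste(missing_nodes, collapse = ", ")))
  m <- score_matrix(dataset)[, nodes, drop = FALSE]
  day <- dataset$scores$day
  beep <- dataset$scores$beep
  complete <- rowSums(is.na(m)) == 0
  n <- nrow(m)
  if (n < 2 || sum(complete) < 2) {
    return(lagged_pairs(matrix(numeric(0), 0, length(nodes),
                               dimnames = list(NULL, nodes)),
                        matrix(numeric(0), 0, length(nodes),
                               dimnames = list(NULL, nodes)),
                        integer(0), logical(0), nodes))
  }
  t2 <- 2:n
  t1 <- t2 - 1L
  same_day <- day[t2] == day[t1] & beep[t2] == beep[t1] + 1L
  cross_day <- day[t2] == day[t1] + 1L & beep[t1] == dataset$schedule$beeps_per_day &
    beep[t2] == 1L
  keep <- complete[t1] & complete[t2] &
    (same_day | (policy == "across_all" & cross_day))
  lagged_pairs(m[t1[keep], , drop = FALSE], m[t2[keep], , drop = FALSE],
               day[t2[keep]], same_day[keep], nodes)
}

#' Construct a lagged-pairs object directly
#'
#' Mostly useful for simulation studies and oracle checks where the
#' (t-1, t) design is built by hand rather than from an `ema_dataset`.
#'
#' @param x numeric matrix of predictor scores at t-1 (one row per pair).
#' @param y numeric matrix of outcome scores at t, same dimensions as `x`.
#' @param day optional integer day index per pair.
#' @param within_day optional logical marker per pair.
#' @param nodes node names (default: column names of `x`).
#' @return A `lagged_pairs` object.
#' @export
lagged_pairs <- function(x, y, day = NULL, within_day = NULL, nodes = NULL) {
  x <- as.matrix(x); y <- as.matrix(y)
  assert_that(all(dim(x) == dim(y)), "x and y must have identical dimensions")
  nodes <- nodes %||% colnames(x) %||% paste0("V", seq_len(ncol(x)))
  colnames(x) <- colnames(y) <- nodes
  n <- nrow(x)
  assert_that(!anyNA(x) && !anyNA(y),
              "lagged pairs must be fully observed (no NA)")
  structure(list(x = x, y = y,
                 day = day %||% rep(NA_integer_, n),
                 within_day = within_day %||% rep(TRUE, n),
                 nodes = nodes, n_pairs = n),
            class = "lagged_pairs")
}

#' @export
print.lagged_pairs <- function(x, ...) {
  cat(sprintf("lagged pairs: %d pairs over %d nodes\n", x$n_pairs,
              length(x$nodes)))
  invisible(x)
}
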