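#' Per-item observed-score summaries
#'
#' Means and standard deviations are computed over observed values only
#' (missing beeps excluded; no imputation), with the sample (n-1) SD.
#' Items never observed are dropped from the summary and listed in the
#' `"excluded"` attribute.
#'
#' @param dataset an `ema_dataset`.
#' @return data frame with columns `item_id`, `label`, `community`, `mean`,
#'   `sd`, `n_observed`, ordered as in the manifest.
#' @export
item_summaries <- function(dataset) {
  assert_that(inherits(dataset, "ema_dataset"), "need an `ema_dataset`")
  m <- score_matrix(dataset)
  n_obs <- colSums(!is.na(m))
  out <- data.frame(item_id = dataset$manifest$item_id,
                    label = dataset$manifest$label,
                    community = dataset$manifest$community,
                    mean = colMeans(m, na.rm = TRUE),
                    sd = apply(m, 2, stats::sd, na.rm = TRUE),
                    n_observed = as.integer(n_obs),
                    row.names = NULL, stringsAsFactors = FALSE)
  excluded <- out$item_id[out$n_observed == 0]
  if (length(excluded)) {
    message("items with zero observations excluded from summaries: ",
            paste(excluded, collapse = ", "))
  }
  out <- out[out$n_observed > 0, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Select the k highest-mean items per community
#'
#' Implements the a priori node-selection rule for idiographic networks:
#' within each clinical community, keep the `k` items with the highest mean
#' over the whole assessment period (default k = 4 per community, i.e. an
#' eight-node network). Ties at the k-th rank are broken deterministically:
#' higher SD first (more dynamic range carries more information for network
#' estimation), then lexicographic `item_id`; any tie actually encountered
#' is flagged so it can be surfaced for human review.
#'
#' Items with zero variance cannot carry edges after standardization, so by
#' default they are skipped in favour of the next-ranked item (disable with
#' `skip_zero_variance = FALSE`).
#'
#' @param summaries output of [item_summaries()] (or any data frame with
#'   `item_id`, `mean`, `sd`, `n_observed` and either a `community` column
#'   or a `partition` argument).
#' @param partition optional named vector item_id -> community; defaults to
#'   the `community` column of `summaries`.
#' @param k items to keep per community (default 4).
#' @param skip_zero_variance skip sd == 0 items (default `TRUE`).
#' @return An object of class `node_set`: `$nodes` (all selected item_ids,
#'   ED block then SUI block, each ordered by descending mean),
#'   `$by_community`, `$ties` (logical), `$skipped` (zero-variance items
#'   passed over), `$summaries` (selected rows).
#' @export
select_top_k_per_community <- function(summaries, partition = NULL, k = 4,
                                       skip_zero_variance = TRUE) {
  assert_that(is.data.frame(summaries) &&
                all(c("item_id", "mean", "sd") %in% names(summaries)),
              "`summaries` needs columns item_id, mean, sd")
  if (is.null(partition)) {
    assert_that("community" %in% names(summaries),
                "supply `partition` or a community column")
    partition <- stats::setNames(summaries$community, summaries$item_id)
  }
  unmapped <- setdiff(summaries$item_id, names(partition))
  assert_that(length(unmapped) == 0,
              sprintf("items missing from partition: %s",
                      paste(unmapped, collapse = ", ")))
  comm <- partition[summaries$item_id]
  if ("n_observed" %in% names(summaries)) {
    summaries <- summaries[summaries$n_observed >= 1, , drop = FALSE]
    comm <- partition[summaries$item_id]
  }

  skipped <- character(0)
  ties <- FALSE
  pick <- function(cm) {
    sub <- summaries[comm == cm, , drop = FALSE]
    if (skip_zero_variance) {
      zv <- sub$item_id[sub$sd == 0]
      if (length(zv)) {
        skipped <<- c(skipped, zv)
        message(sprintf("zero-variance item(s) skipped in community %s: %s",
                        cm, paste(zv, collapse = ", ")))
        sub <- sub[sub$sd > 0, , drop = FALSE]
      }
    }
    if (nrow(sub) < k) {
      stop(sprintf("community %s has %d eligible item(s); %d required",
                   cm, nrow(sub), k), call. = FALSE)
    }
    ord <- order(-sub$mean, -sub$sd, sub$item_id)
    sub <- sub[ord, , drop = FALSE]
    if (nrow(sub) > k && sub$mean[k] == sub$mean[k + 1]) {
      ties <<- TRUE
      message(sprintf(
        "tie at rank %d in community %s (mean %.4g): resolved by sd, then item_id",
        k, cm, sub$mean[k]))
    }
    sub[seq_len(k), , drop = FALSE]
  }

  present <- intersect(valid_communities, unique(comm))
  assert_that(length(present) == 2,
              "both communities (ED, SUI) must have eligible items")
  sel <- lapply(valid_communities, pick)
  names(sel) <- valid_communities
  chosen <- do.call(rbind, sel)
  rownames(chosen) <- NULL
  structure(list(nodes = chosen$item_id,
                 by_community = lapply(sel, function(s) s$item_id),
                 ties = ties, skipped = skipped, summaries = chosen,
                 k = k),
            class = "node_set")
}

#' @export
print.node_set <- function(x, ...) {
  cat(sprintf("node set: %d nodes (%s)\n", length(x$nodes),
              paste(sprintf("%s: %d", names(x$by_community),
                            lengths(x$by_community)), collapse = ", ")))
  for (cm in names(x$by_community)) {
    cat(sprintf("  %s: %s\n", cm, paste(x$by_community[[cm]], collapse = ", ")))
  }
  if (x$ties) cat("  note: tie(s) at the selection boundary were broken by sd/item_id\n")
  invisible(x)
}
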