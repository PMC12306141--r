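#' Default nomination statistics
#'
#' The four centrality statistics used to nominate treatment targets:
#' contemporaneous strength, contemporaneous bridge strength, temporal
#' OutStrength, and temporal bridge OutStrength. (InStrength variants are
#' computed upstream but a symptom's *outgoing* influence is what makes it
#' a candidate intervention target.)
#'
#' @return Character vector of statistic names.
#' @export
nomination_statistics <- function() {
  c("contemporaneous_strength", "contemporaneous_bridge_strength",
    "out_strength", "bridge_out_strength")
}

#' Rank the top k nodes on each centrality statistic
#'
#' Value ties are broken deterministically -- by the node's aggregate
#' centrality (sum over all six statistics), then by `item_id` -- and any
#' tie at or inside the selection boundary is flagged, since a tied
#' nomination warrants human review.
#'
#' @param table a `centrality_table`.
#' @param statistics statistic names to rank (default:
#'   [nomination_statistics()]).
#' @param k nodes to keep per statistic (default 2).
#' @return list of `statistic_ranking` data frames (columns `node`,
#'   `value`, `rank`), one per statistic, each carrying a `tie` attribute.
#' @export
top_k_per_statistic <- function(table, statistics = nomination_statistics(),
                                k = 2) {
  assert_that(is.data.frame(table) && "node" %in% names(table),
              "`table` must be a centrality table with a node column")
  unknown <- setdiff(statistics, centrality_statistics)
  assert_that(length(unknown) == 0,
              sprintf("unknown statistic(s): %s; available: %s",
                      paste(unknown, collapse = ", "),
                      paste(centrality_statistics, collapse = ", ")))
  have <- intersect(centrality_statistics, names(table))
  missing <- setdiff(statistics, have)
  assert_that(length(missing) == 0,
              sprintf("table lacks column(s): %s", paste(missing, collapse = ", ")))
  assert_that(k >= 1 && k <= nrow(table), "`k` must be in 1..number of nodes")
  agg <- rowSums(as.matrix(table[, have, drop = FALSE]))
  out <- lapply(statistics, function(st) {
    v <- table[[st]]
    ord <- order(-v, -agg, table$node)
    sel <- ord[seq_len(k)]
    tie <- k < length(ord) && v[ord[k]] == v[ord[k + 1]]
    tie <- tie || anyDuplicated(v[sel]) > 0
    rk <- data.frame(node = table$node[sel], value = v[sel],
                     rank = seq_len(k), row.names = NULL,
                     stringsAsFactors = FALSE)
    attr(rk, "statistic") <- st
    attr(rk, "tie") <- tie
    class(rk) <- c("statistic_ranking", "data.frame")
    rk
  })
  names(out) <- statistics
  out
}

#' Intervention registry bundled with the package
#'
#' Maps symptom item_ids to evidence-based intervention modules (e.g.
#' exposure, CBT-E self-monitoring, DBT skills). Shipped as an editable CSV
#' (`extdata/intervention_registry.csv`); options are `;`-separated within
#' the `options` column.
#'
#' @return data frame with columns `item_id`, `label`, `options`.
#' @export
default_intervention_registry <- function() {
  read_intervention_registry(system.file("extdata",
                                         "intervention_registry.csv",
                                         package = "idionet", mustWork = TRUE))
}

#' Read an intervention registry CSV
#'
#' @param path CSV with columns `item_id`, `options` (and optionally
#'   `label`); `options` holds `;`-separated intervention module names.
#' @return Validated registry data frame.
#' @export
read_intervention_registry <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  assert_that(all(c("item_id", "options") %in% names(df)),
              "registry needs columns item_id and options")
  assert_that(!anyDuplicated(df$item_id),
              "registry item_id values must be unique")
  assert_that(all(nzchar(trimws(df$options))),
              "every registry entry must list at least one option")
  df
}

registry_options <- function(registry, item) {
  row <- match(item, registry$item_id)
  if (is.na(row)) return(NULL)
  trimws(strsplit(registry$options[row], ";", fixed = TRUE)[[1]])
}

#' Build the deduplicated treatment-target report
#'
#' Takes the per-statistic rankings and produces the union of nominated
#' symptoms: a node nominated by several statistics appears once, listing
#' every nominating statistic with its value. Each target is matched to the
#' intervention registry; targets absent from the registry are kept and
#' flagged unmatched rather than dropped. Targets are ordered by number of
#' nominations (then best value, then item_id), so the report does not
#' depend on the order in which statistics were processed.
#'
#' @param rankings list of `statistic_ranking` objects from
#'   [top_k_per_statistic()].
#' @param registry intervention registry data frame (default: the bundled
#'   one); an empty registry is allowed and produces all-unmatched targets
#'   with a warning.
#' @return An object of class `target_report`: `$targets` (data-frame-like
#'   list per target with nominating statistics, values, interventions,
#'   matched flag), `$rankings`, `$ties`.
#' @export
build_target_report <- function(rankings,
                                registry = default_intervention_registry()) {
  assert_that(is.list(rankings) && length(rankings) >= 1,
              "`rankings` must be a non-empty list")
  assert_that(all(vapply(rankings, inherits, logical(1), "statistic_ranking")),
              "`rankings` must come from top_k_per_statistic()")
  if (is.null(registry) || nrow(registry) == 0) {
    warning("empty intervention registry: all targets will be unmatched",
            call. = FALSE)
    registry <- data.frame(item_id = character(0), options = character(0),
                           stringsAsFactors = FALSE)
  }
  noms <- do.call(rbind, lapply(rankings, function(rk) {
    data.frame(node = rk$node, statistic = attr(rk, "statistic"),
               value = rk$value, stringsAsFactors = FALSE)
  }))
  nodes <- unique(noms$node)
  targets <- lapply(nodes, function(nd) {
    sub <- noms[noms$node == nd, , drop = FALSE]
    opts <- registry_options(registry, nd)
    list(node = nd,
         statistics = stats::setNames(sub$value, sub$statistic),
         n_nominations = nrow(sub),
         interventions = opts %||% character(0),
         matched = !is.null(opts))
  })
  ord <- order(-vapply(targets, `[[`, numeric(1), "n_nominations"),
               -vapply(targets, function(t) max(t$statistics), numeric(1)),
               vapply(targets, `[[`, character(1), "node"))
  targets <- targets[ord]
  names(targets) <- vapply(targets, `[[`, character(1), "node")
  ties <- vapply(rankings, function(rk) isTRUE(attr(rk, "tie")), logical(1))
  unmatched <- names(targets)[!vapply(targets, `[[`, logical(1), "matched")]
  if (length(unmatched)) {
    message("target(s) without registry match: ",
            paste(unmatched, collapse = ", "))
  }
  structure(list(targets = targets, rankings = rankings, ties = ties),
            class = "target_report")
}

#' @export
print.target_report <- function(x, ...) {
  cat(sprintf("treatment-target report: %d target(s) from %d statistic(s)\n",
              length(x$targets), length(x$rankings)))
  for (t in x$targets) {
    cat(sprintf("  %s [%d nomination(s): %s]\n    interventions: %s\n",
                t$node, t$n_nominations,
                paste(sprintf("%s = %.2f", names(t$statistics), t$statistics),
                      collapse = "; "),
                if (t$matched) paste(t$interventions, collapse = "; ")
                else "(no registry match)"))
  }
  if (any(x$ties)) {
    cat("  note: tie(s) at a nomination boundary were broken deterministically\n")
  }
  invisible(x)
}

#' Export a target report as JSON or markdown
#'
#' @param report a `target_report`.
#' @param path output file path.
#' @param format `"json"` or `"markdown"`.
#' @return `path`, invisibly.
#' @export
export_target_report <- function(report, path, format = c("json", "markdown")) {
  format <- match.arg(format)
  assert_that(inherits(report, "target_report"), "need a `target_report`")
  if (format == "json") {
    payload <- list(
      targets = lapply(report$targets, function(t) {
        list(node = t$node,
             statistics = as.list(t$statistics),
             interventions = t$interventions,
             matched = t$matched)
      }),
      ties = as.list(report$ties))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  } else {
    lines <- c("# Treatment-target report", "",
               "| Target | Nominating statistics | Intervention options |",
               "|---|---|---|")
    for (t in report$targets) {
      lines <- c(lines, sprintf(
        "| %s | %s | %s |", t$node,
        paste(sprintf("%s = %.2f", names(t$statistics), t$statistics),
              collapse = "; "),
        if (t$matched) paste(t$interventions, collapse = "; ")
        else "*unmatched*"))
    }
    writeLines(lines, path)
  }
  invisible(path)
}
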