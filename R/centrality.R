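check_square_named <- function(network) {
  network <- as.matrix(network)
  assert_that(nrow(network) == ncol(network), "network matrix must be square")
  if (is.null(rownames(network))) {
    rownames(network) <- colnames(network) <-
      colnames(network) %||% paste0("V", seq_len(ncol(network)))
  }
  network
}

resolve_nodes <- function(network, nodes) {
  all_nodes <- rownames(network)
  nodes <- nodes %||% all_nodes
  missing <- setdiff(nodes, all_nodes)
  assert_that(length(missing) == 0,
              sprintf("node(s) not in network: %s",
                      paste(missing, collapse = ", ")))
  nodes
}

weight_fun <- function(signed) if (signed) identity else abs

#' Strength centrality in an undirected network
#'
#' The sum of edge weights between a node and all its neighbours. By the
#' dominant convention absolute weights are summed, so negative edges add to
#' (rather than cancel) a node's strength; `signed = TRUE` gives the signed
#' "expected influence" variant instead.
#'
#' @param network symmetric weighted adjacency matrix, zero diagonal.
#' @param nodes node name(s) to return (default: all).
#' @param signed sum signed weights instead of absolute values.
#' @return Named numeric vector of strengths.
#' @export
node_strength <- function(network, nodes = NULL, signed = FALSE) {
  network <- check_square_named(network)
  assert_that(max(abs(network - t(network))) < 1e-8,
              "contemporaneous network must be symmetric")
  nodes <- resolve_nodes(network, nodes)
  w <- weight_fun(signed)(network)
  diag(w) <- 0
  rowSums(w)[nodes]
}

#' In- and out-strength in a directed (temporal) network
#'
#' InStrength is the sum of incoming edge weights (what a symptom receives
#' from the rest of the network one beep earlier); OutStrength is the sum of
#' outgoing weights (the influence a symptom exerts on the next beep).
#' Autoregressive self-loops are excluded by default: an effect of a symptom
#' on its own future is not influence on other symptoms.
#'
#' @param network directed weight matrix with entry `[i, j]` = edge j -> i.
#' @param nodes node name(s) to return (default: all).
#' @param signed sum signed weights instead of absolute values.
#' @param include_self_loops count the diagonal in both sums.
#' @return list with named numeric vectors `in_strength` and `out_strength`.
#' @export
in_out_strength <- function(network, nodes = NULL, signed = FALSE,
                            include_self_loops = FALSE) {
  network <- check_square_named(network)
  nodes <- resolve_nodes(network, nodes)
  w <- weight_fun(signed)(network)
  if (!include_self_loops) diag(w) <- 0
  list(in_strength = rowSums(w)[nodes], out_strength = colSums(w)[nodes])
}

check_partition <- function(network, partition) {
  unmapped <- setdiff(rownames(network), names(partition))
  assert_that(length(unmapped) == 0,
              sprintf("node(s) unmapped in partition: %s",
                      paste(unmapped, collapse = ", ")))
  partition[rownames(network)]
}

#' Bridge strength across symptom communities
#'
#' Strength (or In/OutStrength) restricted to edges whose endpoints lie in
#' different communities: the connectivity between a node and the *other*
#' disorder's symptoms. With the clinically pre-defined eating-disorder vs.
#' suicidality partition, high bridge values mark candidate links between
#' the two conditions.
#'
#' @param network weight matrix; symmetric for `direction = "undirected"`,
#'   directed (`[i, j]` = j -> i) otherwise.
#' @param partition named vector item_id -> community covering all nodes.
#' @param nodes node name(s) to return (default: all).
#' @param direction `"undirected"` (contemporaneous strength),
#'   `"incoming"` or `"outgoing"` (temporal).
#' @param signed sum signed weights instead of absolute values.
#' @param include_self_loops count the diagonal (never a bridge; kept for
#'   interface symmetry).
#' @return Named numeric vector of bridge strengths.
#' @export
bridge_strength <- function(network, partition, nodes = NULL,
                            direction = c("undirected", "incoming", "outgoing"),
                            signed = FALSE, include_self_loops = FALSE) {
  direction <- match.arg(direction)
  network <- check_square_named(network)
  part <- check_partition(network, partition)
  nodes <- resolve_nodes(network, nodes)
  w <- weight_fun(signed)(network)
  if (!include_self_loops) diag(w) <- 0
  cross <- outer(part, part, "!=") # cross[i, j]: i and j in different communities
  w <- w * cross
  vals <- switch(direction,
                 undirected = {
                   assert_that(max(abs(network - t(network))) < 1e-8,
                               "contemporaneous network must be symmetric")
                   rowSums(w)
                 },
                 incoming = rowSums(w),
                 outgoing = colSums(w))
  vals[nodes]
}

#' Assemble the per-node centrality table
#'
#' Computes the six statistics used for treatment-target selection --
#' contemporaneous strength and bridge strength; temporal InStrength,
#' OutStrength, bridge InStrength and bridge OutStrength -- plus
#' z-standardized versions of each column for plotting.
#'
#' @param pair a `network_pair` from [extract_networks()].
#' @param partition named vector item_id -> community covering all nodes.
#' @param signed sum signed weights instead of absolute values.
#' @param include_self_loops count temporal self-loops in In/OutStrength.
#' @return A data frame (class `centrality_table`) with one row per node:
#'   `node`, `community`, the six raw statistics, and `z_`-prefixed
#'   standardized columns.
#' @export
centrality_table <- function(pair, partition, signed = FALSE,
                             include_self_loops = FALSE) {
  assert_that(inherits(pair, "network_pair"), "need a `network_pair`")
  cont <- check_square_named(pair$contemporaneous)
  temp <- check_square_named(pair$temporal)
  part <- check_partition(cont, partition)
  io <- in_out_strength(temp, signed = signed,
                        include_self_loops = include_self_loops)
  tab <- data.frame(
    node = pair$nodes,
    community = unname(part[pair$nodes]),
    contemporaneous_strength = unname(node_strength(cont, signed = signed)),
    contemporaneous_bridge_strength =
      unname(bridge_strength(cont, part, direction = "undirected",
                             signed = signed)),
    in_strength = unname(io$in_strength),
    out_strength = unname(io$out_strength),
    bridge_in_strength =
      unname(bridge_strength(temp, part, direction = "incoming",
                             signed = signed,
                             include_self_loops = include_self_loops)),
    bridge_out_strength =
      unname(bridge_strength(temp, part, direction = "outgoing",
                             signed = signed,
                             include_self_loops = include_self_loops)),
    row.names = NULL, stringsAsFactors = FALSE)
  for (col in centrality_statistics) {
    s <- stats::sd(tab[[col]])
    tab[[paste0("z_", col)]] <-
      if (is.na(s) || s == 0) rep(0, nrow(tab)) else
        (tab[[col]] - mean(tab[[col]])) / s
  }
  class(tab) <- c("centrality_table", "data.frame")
  tab
}

centrality_statistics <- c(
  "contemporaneous_strength", "contemporaneous_bridge_strength",
  "in_strength", "out_strength", "bridge_in_strength", "bridge_out_strength")
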