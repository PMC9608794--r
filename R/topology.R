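as_igraph <- function(net) {
  stopifnot(inherits(net, "cerna_network"))
  if (nrow(net$edges) == 0) stop_("network has no edges")
  g <- igraph::graph_from_data_frame(
    net$edges[, c("lnc", "mrna")], directed = FALSE,
    vertices = data.frame(name = c(net$lnc_nodes, net$mrna_nodes),
                          type = rep(c("lncRNA", "mRNA"),
                                     c(length(net$lnc_nodes),
                                       length(net$mrna_nodes)))))
  g
}

#' Node degrees of a ceRNA network
#' @param net a `cerna_network` with >= 1 edge.
#' @return named integer vector, node -> number of incident edges.
#' @export
degree_centrality <- function(net) {
  g <- as_igraph(net)
  d <- igraph::degree(g)
  d[order(names(d))]
}

#' Betweenness centrality of a ceRNA network
#'
#' Undirected, unweighted, unnormalized shortest-path betweenness (Brandes'
#' algorithm via igraph): each unordered source-target pair is counted once,
#' endpoints are excluded from their own paths, and disconnected components
#' contribute no cross-component paths. Normalization would cancel in the
#' rank-based hub call, but the convention is fixed so values are comparable
#' across tools.
#'
#' @param net a `cerna_network` with >= 1 edge.
#' @return named numeric vector, node -> betweenness.
#' @export
betweenness_centrality <- function(net) {
  g <- as_igraph(net)
  b <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  b[order(names(b))]
}

#' Select hub lncRNAs by top-k rank intersection of degree and betweenness
#'
#' Ranks the lncRNA nodes (only) by degree and by betweenness, each
#' descending; retains the top `k` per metric with all ties at the k-th
#' value included; hubs are the lncRNAs in both retained sets. If fewer than
#' `k` lncRNAs exist, all are retained per metric (with a warning).
#'
#' @param net a `cerna_network` with >= 1 lncRNA node.
#' @param k rank cutoff (default 8).
#' @return object of class `centrality_report`: data frame with columns
#'   `node`, `type`, `degree`, `betweenness`, `degree_rank`,
#'   `betweenness_rank` (ranks among lncRNAs; `NA` for mRNA nodes), and
#'   `is_hub`; rows ordered by betweenness desc, degree desc, id asc.
#'   Attributes `k` and `hubs` carry the cutoff and the hub id vector.
#' @export
select_hubs <- function(net, k = 8) {
  k <- assert_count(k, "k", min = 1)
  if (length(net$lnc_nodes) == 0) stop_("network has no lncRNA nodes")
  deg <- degree_centrality(net)
  btw <- betweenness_centrality(net)
  nodes <- names(deg)
  type <- ifelse(nodes %in% net$lnc_nodes, "lncRNA", "mRNA")
  is_lnc <- type == "lncRNA"
  if (sum(is_lnc) < k)
    warn_("only %d lncRNA node(s) < k = %d; all are retained per metric",
          sum(is_lnc), k)
  top_set <- function(vals) {
    v <- vals[is_lnc]
    thr <- sort(v, decreasing = TRUE)[min(k, length(v))]
    names(v)[v >= thr]
  }
  hub_deg <- top_set(deg)
  hub_btw <- top_set(btw)
  hubs <- sort(intersect(hub_deg, hub_btw))
  rank_lnc <- function(vals) {
    r <- rep(NA_integer_, length(nodes))
    r[is_lnc] <- rank(-vals[is_lnc], ties.method = "min")
    r
  }
  rep_df <- data.frame(node = nodes, type = type,
                       degree = as.integer(deg),
                       betweenness = as.numeric(btw),
                       degree_rank = rank_lnc(deg),
                       betweenness_rank = rank_lnc(btw),
                       is_hub = nodes %in% hubs,
                       stringsAsFactors = FALSE)
  rep_df <- rep_df[order(-rep_df$betweenness, -rep_df$degree, rep_df$node), ]
  rownames(rep_df) <- NULL
  structure(rep_df, k = k, hubs = hubs, class = c("centrality_report", "data.frame"))
}

#' Hub ids of a centrality report
#' @param report a `centrality_report` from [select_hubs()].
#' @return character vector of hub lncRNA ids.
#' @export
hub_ids <- function(report) attr(report, "hubs")

#' Write a centrality report as TSV (plus a plain-text hub list)
#' @param report a `centrality_report`.
#' @param path output TSV; the hub list goes to `<path>.hubs.txt` unless
#'   `hubs_path` is given.
#' @param hubs_path optional path for the hub list.
#' @export
write_centrality <- function(report, path, hubs_path = NULL) {
  df <- as.data.frame(report)
  df$betweenness <- sprintf("%.10g", df$betweenness)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(hub_ids(report), hubs_path %||% paste0(path, ".hubs.txt"))
  invisible(path)
}
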