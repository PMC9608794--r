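#' Extract the tripartite ceRNA subnetwork of one hub lncRNA
#'
#' Takes the hub's adjacent mRNA neighbors in the parent network and the
#' shared-miRNA set stored on each retained edge, and assembles a tripartite
#' lncRNA-miRNA-mRNA graph: typed edges (hub, miRNA) for every miRNA in the
#' union of shared sets, and (miRNA, mRNA) for every miRNA in that mRNA's
#' shared set. The miRNAs come from the tested pairs themselves, not from
#' the full background, so the subnetwork reflects exactly the retained
#' hypotheses; there are no direct lncRNA-mRNA edges.
#'
#' @param hub a lncRNA id present in `net$lnc_nodes`.
#' @param net a `cerna_network`.
#' @return object of class `cerna_subnetwork`: list with `hub`, `mrnas`,
#'   `mirnas` (both sorted), and `edges` (data frame `from`, `type`, `to`
#'   with types `sponges` for hub-miRNA and `targets` for miRNA-mRNA).
#' @export
extract_subnetwork <- function(hub, net) {
  stopifnot(inherits(net, "cerna_network"))
  if (!hub %in% net$lnc_nodes) stop_("hub `%s` not in network", hub)
  e <- net$edges[net$edges$lnc == hub, , drop = FALSE]
  mrnas <- sort(e$mrna)
  mirnas <- sort(unique(unlist(e$shared, use.names = FALSE)))
  mm <- data.frame(
    from = unlist(e$shared, use.names = FALSE),
    type = "targets",
    to = rep(e$mrna, lengths(e$shared)),
    stringsAsFactors = FALSE)
  hm <- data.frame(from = hub, type = "sponges", to = mirnas,
                   stringsAsFactors = FALSE)
  edges <- rbind(hm, mm)
  edges <- edges[order(edges$type, edges$from, edges$to), ]
  rownames(edges) <- NULL
  structure(list(hub = hub, mrnas = mrnas, mirnas = mirnas, edges = edges),
            class = "cerna_subnetwork")
}

#' @export
print.cerna_subnetwork <- function(x, ...) {
  cat(sprintf("cerna_subnetwork of %s: %d mRNAs, %d miRNAs, %d typed edges\n",
              x$hub, length(x$mrnas), length(x$mirnas), nrow(x$edges)))
  invisible(x)
}

#' Export a subnetwork (typed SIF + node table + JSON summary)
#'
#' Writes `subnetwork.sif` (`lnc<TAB>sponges<TAB>mirna`,
#' `mirna<TAB>targets<TAB>mrna`; rows sorted by type then id),
#' `nodes.tsv` (id, type) and `summary.json` (counts) under `outdir`.
#'
#' @param sub a `cerna_subnetwork`.
#' @param outdir output directory (created if missing).
#' @return character vector of paths, invisibly.
#' @export
export_subnetwork <- function(sub, outdir) {
  stopifnot(inherits(sub, "cerna_subnetwork"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sif <- file.path(outdir, "subnetwork.sif")
  writeLines(sprintf("%s\t%s\t%s", sub$edges$from, sub$edges$type, sub$edges$to),
             sif)
  nodes <- data.frame(
    id = c(sub$hub, sub$mirnas, sub$mrnas),
    type = rep(c("lncRNA", "miRNA", "mRNA"),
               c(1L, length(sub$mirnas), length(sub$mrnas))),
    stringsAsFactors = FALSE)
  node_path <- file.path(outdir, "nodes.tsv")
  utils::write.table(nodes, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  json_path <- file.path(outdir, "summary.json")
  jsonlite::write_json(
    list(hub = sub$hub, n_mrna = length(sub$mrnas),
         n_mirna = length(sub$mirnas), n_edges = nrow(sub$edges)),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(sif = sif, nodes = node_path, summary = json_path))
}

#' Read a typed SIF file back into an edge data frame
#' @param path SIF file with lines `from<TAB>type<TAB>to`.
#' @return data frame `from`, `type`, `to` sorted by type, from, to.
#' @export
read_sif <- function(path) {
  rows <- strsplit(readLines(path), "\t", fixed = TRUE)
  bad <- which(lengths(rows) != 3)
  if (length(bad)) stop_("malformed SIF line %d in %s", bad[1], path)
  df <- data.frame(from = vapply(rows, `[[`, "", 1),
                   type = vapply(rows, `[[`, "", 2),
                   to = vapply(rows, `[[`, "", 3),
                   stringsAsFactors = FALSE)
  df <- df[order(df$type, df$from, df$to), ]
  rownames(df) <- NULL
  df
}
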