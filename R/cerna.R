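#' Score one candidate lncRNA-mRNA ceRNA pair
#'
#' Computes the shared-miRNA count `r` between the lncRNA's and the mRNA's
#' clipped target sets and its hypergeometric upper-tail probability
#' `P(X >= r)` against the background universe.
#'
#' @param lnc,mrna ids present in the background.
#' @param bg an `interaction_background` from [build_background()].
#' @return list of class `cerna_pair`: `lnc`, `mrna`, `r`, `n`, `t`, `m`,
#'   `shared` (sorted miRNA ids), `p`.
#' @export
score_pair <- function(lnc, mrna, bg) {
  stopifnot(inherits(bg, "interaction_background"))
  ls <- bg$lnc_targets[[lnc]]
  ms <- bg$mrna_targets[[mrna]]
  if (is.null(ls)) stop_("lncRNA `%s` not in background", lnc)
  if (is.null(ms)) stop_("mRNA `%s` not in background", mrna)
  shared <- sort(intersect(ls, ms))
  r <- length(shared); n <- length(ls); t <- length(ms)
  m <- length(bg$universe)
  structure(list(lnc = lnc, mrna = mrna, r = r, n = n, t = t, m = m,
                 shared = shared, p = hypergeom_tail(r, m, n, t)),
            class = "cerna_pair")
}

#' Build the ceRNA network over DEL x DEG candidate pairs
#'
#' Scores every differentially-expressed lncRNA against every
#' differentially-expressed mRNA present in the background and retains the
#' pairs passing the shared-miRNA hypergeometric filter: `p < p_max` and
#' shared count strictly above `min_shared` (both filters strict; the defaults `p_max = 0.01`,
#' `min_shared = 3` therefore require a shared count of at least 4). Candidates absent from the
#' background are skipped and counted, not errors.
#'
#' @param dels character vector of DE lncRNA ids.
#' @param degs character vector of DE mRNA ids.
#' @param bg an `interaction_background`.
#' @param p_max retain only pairs with `p < p_max`.
#' @param min_shared retain only pairs whose shared count exceeds `min_shared` (set to 2 to
#'   read a "more than 3 shared" rule inclusively, i.e. 3 or more).
#' @param adjust_pairs if `TRUE`, apply Benjamini-Hochberg across all scored
#'   pairs and filter on the adjusted value instead of the raw `p`.
#' @return object of class `cerna_network`: list with `edges` (data frame
#'   `lnc`, `mrna`, `r`, `n`, `t`, `m`, `p`, plus list column `shared`),
#'   `lnc_nodes`, `mrna_nodes` (nodes with >= 1 retained edge), the
#'   thresholds, and skip/score counts.
#' @export
build_network <- function(dels, degs, bg, p_max = 0.01, min_shared = 3,
                          adjust_pairs = FALSE) {
  stopifnot(inherits(bg, "interaction_background"))
  if (length(dels) == 0 || length(degs) == 0)
    stop_("DEL and DEG lists must be non-empty")
  if (!is.numeric(p_max) || length(p_max) != 1 || is.na(p_max) || p_max < 0)
    stop_("p_max must be a single value >= 0")
  min_shared <- assert_count(min_shared, "min_shared")
  clash <- intersect(dels, degs)
  if (length(clash))
    stop_("id(s) present in both DEL and DEG lists (bipartiteness would break): %s",
          paste(utils::head(clash, 5), collapse = ", "))
  lncs <- sort(intersect(unique(dels), names(bg$lnc_targets)))
  mrnas <- sort(intersect(unique(degs), names(bg$mrna_targets)))
  skipped <- c(lnc = length(unique(dels)) - length(lncs),
               mrna = length(unique(degs)) - length(mrnas))
  if (length(lncs) == 0 || length(mrnas) == 0) {
    warn_("no candidate pair has both ids in the background")
    return(empty_network(p_max, min_shared, skipped))
  }
  m <- length(bg$universe)
  cand <- expand.grid(lnc = lncs, mrna = mrnas, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  shared <- Map(function(l, g) sort(intersect(bg$lnc_targets[[l]],
                                              bg$mrna_targets[[g]])),
                cand$lnc, cand$mrna)
  cand$r <- lengths(shared)
  cand$n <- lengths(bg$lnc_targets)[cand$lnc]
  cand$t <- lengths(bg$mrna_targets)[cand$mrna]
  cand$m <- m
  cand$p <- mapply(hypergeom_tail, cand$r, m, cand$n, cand$t)
  crit <- if (adjust_pairs) bh_adjust(cand$p) else cand$p
  keep <- crit < p_max & cand$r > min_shared
  edges <- cand[keep, , drop = FALSE]
  edges$shared <- I(unname(shared[keep]))
  edges <- edges[order(edges$lnc, edges$mrna), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges,
                 lnc_nodes = sort(unique(edges$lnc)),
                 mrna_nodes = sort(unique(edges$mrna)),
                 p_max = p_max, min_shared = min_shared,
                 adjust_pairs = adjust_pairs,
                 n_scored = nrow(cand), skipped = skipped),
            class = "cerna_network")
}

empty_network <- function(p_max, min_shared, skipped) {
  structure(list(
    edges = data.frame(lnc = character(0), mrna = character(0),
                       r = integer(0), n = integer(0), t = integer(0),
                       m = integer(0), p = numeric(0),
                       shared = I(list()), stringsAsFactors = FALSE),
    lnc_nodes = character(0), mrna_nodes = character(0),
    p_max = p_max, min_shared = min_shared, adjust_pairs = FALSE,
    n_scored = 0L, skipped = skipped), class = "cerna_network")
}

#' @export
print.cerna_network <- function(x, ...) {
  cat(sprintf(
    "cerna_network: %d edges (%d lncRNAs, %d mRNAs) of %d scored pairs [p < %g, shared > %d]\n",
    nrow(x$edges), length(x$lnc_nodes), length(x$mrna_nodes), x$n_scored,
    x$p_max, x$min_shared))
  invisible(x)
}

#' Write a ceRNA network (edge TSV + SIF + JSON summary)
#'
#' `edges.tsv` has columns lnc, mrna, r, n, t, m, p and the shared miRNAs
#' comma-joined and sorted; `network.sif` has one `lnc<TAB>ceRNA<TAB>mrna`
#' line per edge for graph-viewer import; `summary.json` records node/edge
#' counts and the thresholds.
#'
#' @param net a `cerna_network`.
#' @param outdir output directory (created if missing).
#' @return character vector of the three paths, invisibly.
#' @export
write_network <- function(net, outdir) {
  stopifnot(inherits(net, "cerna_network"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  df <- net$edges
  df$shared_mirnas <- vapply(df$shared, paste, "", collapse = ",")
  df$shared <- NULL
  df$p <- sprintf("%.15g", df$p)
  edge_path <- file.path(outdir, "edges.tsv")
  utils::write.table(df, edge_path, sep = "\t", quote = FALSE, row.names = FALSE)
  sif_path <- file.path(outdir, "network.sif")
  writeLines(sprintf("%s\tceRNA\t%s", df$lnc, df$mrna), sif_path)
  json_path <- file.path(outdir, "summary.json")
  jsonlite::write_json(
    list(n_edges = nrow(df), n_lnc = length(net$lnc_nodes),
         n_mrna = length(net$mrna_nodes), n_scored = net$n_scored,
         skipped = as.list(net$skipped),
         p_max = net$p_max, min_shared = net$min_shared,
         adjust_pairs = net$adjust_pairs),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(edges = edge_path, sif = sif_path, summary = json_path))
}

#' Read a ceRNA network back from an edge TSV written by [write_network()]
#' @param path `edges.tsv` file.
#' @param p_max,min_shared thresholds to record on the object (metadata
#'   only; no re-filtering).
#' @return a `cerna_network`.
#' @export
read_network <- function(path, p_max = NA_real_, min_shared = NA_integer_) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("lnc", "mrna", "r", "n", "t", "m", "p", "shared_mirnas")
  if (!all(need %in% names(df)))
    stop_("edge table must have columns: %s", paste(need, collapse = ", "))
  df$shared <- I(lapply(strsplit(as.character(df$shared_mirnas), ",", fixed = TRUE),
                        function(v) v[nzchar(v)]))
  df$shared_mirnas <- NULL
  df <- df[order(df$lnc, df$mrna), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(edges = df,
                 lnc_nodes = sort(unique(df$lnc)),
                 mrna_nodes = sort(unique(df$mrna)),
                 p_max = p_max, min_shared = min_shared,
                 adjust_pairs = FALSE,
                 n_scored = NA_integer_, skipped = c(lnc = NA, mrna = NA)),
            class = "cerna_network")
}
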