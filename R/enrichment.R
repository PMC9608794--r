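#' Read a GMT gene-set collection
#'
#' Standard GMT dialect: one set per tab-separated line — set id,
#' description, then member gene ids. Duplicate members within a line are
#' deduplicated.
#'
#' @param path GMT file.
#' @return object of class `geneset_collection`: list with `sets` (named
#'   list of member vectors), `descriptions` (named character vector) and
#'   `source` (the file path).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop_("no gene sets in %s", path)
  rows <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(rows) < 3)
  if (length(bad))
    stop_("GMT line %d has %d field(s), expected >= 3 (id, description, members)",
          bad[1], lengths(rows)[bad[1]])
  ids <- vapply(rows, `[[`, "", 1)
  if (anyDuplicated(ids)) stop_("duplicate set id(s) in %s", path)
  sets <- lapply(rows, function(r) unique(r[-(1:2)]))
  names(sets) <- ids
  structure(list(sets = sets,
                 descriptions = stats::setNames(vapply(rows, `[[`, "", 2), ids),
                 source = path),
            class = "geneset_collection")
}

#' Write a gene-set collection as GMT
#' @param collection a `geneset_collection` (or named list of member
#'   vectors, in which case descriptions default to the set ids).
#' @param path output file.
#' @export
write_gmt <- function(collection, path) {
  if (!inherits(collection, "geneset_collection"))
    collection <- structure(list(sets = collection,
                                 descriptions = stats::setNames(names(collection),
                                                                names(collection)),
                                 source = NA_character_),
                            class = "geneset_collection")
  lines <- vapply(names(collection$sets), function(id)
    paste(c(id, collection$descriptions[[id]], collection$sets[[id]]),
          collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation analysis against gene-set collections
#'
#' For each set, counts the overlap `k` between the query and the set (both
#' restricted to the universe) and computes the hypergeometric upper tail
#' `P(X >= k)` with universe size `U`, query size `q` and restricted set
#' size `K` — the same statistic [hypergeom_tail()] used for ceRNA pair
#' scoring. Benjamini-Hochberg adjustment is applied across all tested sets.
#'
#' @param query character vector of gene ids; ids outside the universe are
#'   dropped with a warning.
#' @param sets a `geneset_collection` from [read_gmt()].
#' @param universe character vector of background gene ids; defaults to the
#'   union of all set members (supplying the measured-gene list is
#'   statistically preferable).
#' @param p_max sets with `p < p_max` are flagged `significant` (default
#'   0.05); nothing is removed from the output.
#' @param use_raw_p if `TRUE`, the `significant` flag uses the raw `p`
#'   (mirroring analyses that report unadjusted enrichment p-values);
#'   default `FALSE` flags on the BH-adjusted `fdr`.
#' @return data frame sorted by `p` ascending (ties by set id): `set`,
#'   `description`, `k`, `K`, `q`, `U`, `p`, `fdr`, `significant`,
#'   `overlap` (comma-joined sorted overlapping ids).
#' @export
ora <- function(query, sets, universe = NULL, p_max = 0.05, use_raw_p = FALSE) {
  stopifnot(inherits(sets, "geneset_collection"))
  p_max <- assert_prob(p_max, "p_max")
  universe <- unique(universe %||% unlist(sets$sets, use.names = FALSE))
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warn_("dropping %d query gene(s) outside the universe", length(outside))
    query <- intersect(query, universe)
  }
  if (length(query) == 0) stop_("query is empty after restriction to the universe")
  U <- length(universe); q <- length(query)
  res <- lapply(names(sets$sets), function(id) {
    members <- intersect(sets$sets[[id]], universe)
    overlap <- sort(intersect(members, query))
    k <- length(overlap); K <- length(members)
    p <- if (k == 0) 1 else hypergeom_tail(k, U, q, K)
    data.frame(set = id, description = unname(sets$descriptions[[id]]),
               k = k, K = K, q = q, U = U, p = p,
               overlap = paste(overlap, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- bh_adjust(out$p)
  crit <- if (use_raw_p) out$p else out$fdr
  out$significant <- crit < p_max
  out <- out[order(out$p, out$set),
             c("set", "description", "k", "K", "q", "U", "p", "fdr",
               "significant", "overlap")]
  rownames(out) <- NULL
  out
}

#' Write an ORA result table as TSV
#' @param result data frame from [ora()].
#' @param path output file.
#' @export
write_ora <- function(result, path) {
  result$p <- sprintf("%.10g", result$p)
  result$fdr <- sprintf("%.10g", result$fdr)
  utils::write.table(result, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
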