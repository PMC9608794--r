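#' Read an interaction TSV into a source -> miRNA-set map
#'
#' Dialect: tab-separated, first header line, two required columns `source`
#' and `mirna` (extra columns ignored); `#` comment lines and empty lines
#' skipped; duplicate rows collapse to one membership; identifiers are taken
#' verbatim (case-sensitive). Covers both lncRNA-miRNA tables (starBase
#' style) and miRNA-mRNA tables (miRTarBase style) — `source` is the lncRNA
#' or the mRNA respectively.
#'
#' @param path TSV file.
#' @return named list: source id -> sorted character vector of miRNA ids.
#' @export
read_interactions <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  if (length(lines) <= 1) {
    warn_("no interaction rows in %s", path)
    return(stats::setNames(list(), character(0)))
  }
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  ic <- match(c("source", "mirna"), header)
  if (anyNA(ic))
    stop_("interaction table %s must have columns `source` and `mirna`", path)
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  nf <- lengths(rows)
  bad <- which(nf < max(ic))
  if (length(bad))
    stop_("malformed interaction row at line %d of %s (%d field(s), expected >= %d)",
          which(keep)[bad[1] + 1L], path, nf[bad[1]], max(ic))
  src <- vapply(rows, `[[`, "", ic[1])
  mir <- vapply(rows, `[[`, "", ic[2])
  lapply(split(mir, src), function(v) sort(unique(v)))
}

#' Build the hypergeometric test's sampling frame
#'
#' Defines the miRNA universe (the `m` of the pair statistic) from the two
#' interaction maps and clips every target set to it, so that `n <= m` and
#' `t <= m` hold by construction. Entries whose clipped set is empty are
#' dropped with a warning and counted.
#'
#' @param lnc_map named list lncRNA -> miRNA ids.
#' @param mrna_map named list mRNA -> miRNA ids.
#' @param policy universe policy: `"mrna_db"` (default; all miRNAs appearing
#'   in the mRNA table, i.e. `m` = the size of the miRNA-mRNA database's
#'   miRNA complement), `"union"`, or `"intersection"` of the two tables'
#'   miRNA sets.
#' @return object of class `interaction_background`: list with `universe`
#'   (sorted character vector), `lnc_targets`, `mrna_targets` (clipped,
#'   sorted), `policy`, and `dropped` (per-side counts of entries lost to
#'   clipping).
#' @export
build_background <- function(lnc_map, mrna_map,
                             policy = c("mrna_db", "union", "intersection")) {
  policy <- match.arg(policy)
  if (length(lnc_map) == 0 || length(mrna_map) == 0)
    stop_("both interaction maps must be non-empty")
  lnc_mirnas <- unique(unlist(lnc_map, use.names = FALSE))
  mrna_mirnas <- unique(unlist(mrna_map, use.names = FALSE))
  universe <- sort(switch(policy,
    mrna_db = mrna_mirnas,
    union = union(lnc_mirnas, mrna_mirnas),
    intersection = intersect(lnc_mirnas, mrna_mirnas)))
  if (length(universe) == 0) stop_("empty miRNA universe under policy `%s`", policy)
  clip <- function(m) {
    cl <- lapply(m, function(v) sort(intersect(unique(v), universe)))
    cl[order(names(cl))]
  }
  lnc <- clip(lnc_map); mrna <- clip(mrna_map)
  dropped <- c(lnc = sum(lengths(lnc) == 0), mrna = sum(lengths(mrna) == 0))
  if (any(dropped > 0))
    warn_("dropped %d lncRNA and %d mRNA entries with no miRNA in the universe",
          dropped[["lnc"]], dropped[["mrna"]])
  structure(list(universe = universe,
                 lnc_targets = lnc[lengths(lnc) > 0],
                 mrna_targets = mrna[lengths(mrna) > 0],
                 policy = policy, dropped = dropped),
            class = "interaction_background")
}

#' Summary statistics of an interaction background
#'
#' Reports the analogous counts a database snapshot is usually described by:
#' pair counts and distinct-entity counts per table, the universe size `m`,
#' and clipping losses.
#'
#' @param bg an `interaction_background`.
#' @return list of counts.
#' @export
background_stats <- function(bg) {
  stopifnot(inherits(bg, "interaction_background"))
  list(
    m = length(bg$universe),
    n_lnc = length(bg$lnc_targets),
    n_mrna = length(bg$mrna_targets),
    n_mirna_lnc_table = length(unique(unlist(bg$lnc_targets, use.names = FALSE))),
    n_mirna_mrna_table = length(unique(unlist(bg$mrna_targets, use.names = FALSE))),
    lnc_mirna_pairs = sum(lengths(bg$lnc_targets)),
    mirna_mrna_pairs = sum(lengths(bg$mrna_targets)),
    dropped_lnc = unname(bg$dropped[["lnc"]]),
    dropped_mrna = unname(bg$dropped[["mrna"]]),
    policy = bg$policy
  )
}

#' @export
print.interaction_background <- function(x, ...) {
  s <- background_stats(x)
  cat(sprintf(
    "interaction_background (policy %s): m = %d miRNAs\n  %d lncRNAs (%d pairs), %d mRNAs (%d pairs); dropped %d/%d\n",
    s$policy, s$m, s$n_lnc, s$lnc_mirna_pairs, s$n_mrna, s$mirna_mrna_pairs,
    s$dropped_lnc, s$dropped_mrna))
  invisible(x)
}
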