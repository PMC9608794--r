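#' Assemble and validate a pipeline run configuration
#'
#' @param expr,groups,biotypes,lnc_mirna,mirna_mrna input file paths (see
#'   the reader functions for the dialects).
#' @param gmt optional GMT file; when given, over-representation of the
#'   network's mRNAs is computed.
#' @param outdir output directory.
#' @param fdr_max,lfc_min differential-expression thresholds.
#' @param pair_p_max,min_shared ceRNA edge filter (`p < pair_p_max`,
#'   shared count `> min_shared`).
#' @param k hub rank cutoff.
#' @param enrich_p_max enrichment significance cutoff.
#' @param de_use_raw_p,enrich_use_raw_p filter on raw instead of adjusted
#'   p-values at the respective stage.
#' @param universe_policy miRNA universe policy, see [build_background()].
#' @param quantile apply quantile normalization before testing (default
#'   `TRUE`).
#' @param log2_offset if non-`NULL`, apply `log2(x + offset)` when reading
#'   the expression matrix.
#' @param seed integer recorded in the summary (the pipeline itself is
#'   deterministic; the seed feeds any upstream simulation).
#' @return validated list of class `run_config`.
#' @export
run_config <- function(expr, groups, biotypes, lnc_mirna, mirna_mrna,
                       gmt = NULL, outdir = "cernet_out",
                       fdr_max = 0.05, lfc_min = 1.0,
                       pair_p_max = 0.01, min_shared = 3, k = 8,
                       enrich_p_max = 0.05,
                       de_use_raw_p = FALSE, enrich_use_raw_p = FALSE,
                       universe_policy = c("mrna_db", "union", "intersection"),
                       quantile = TRUE, log2_offset = NULL, seed = 1L) {
  cfg <- list(expr = expr, groups = groups, biotypes = biotypes,
              lnc_mirna = lnc_mirna, mirna_mrna = mirna_mrna, gmt = gmt,
              outdir = outdir,
              fdr_max = fdr_max, lfc_min = lfc_min,
              pair_p_max = pair_p_max,
              min_shared = assert_count(min_shared, "min_shared"),
              k = assert_count(k, "k", 1),
              enrich_p_max = assert_prob(enrich_p_max, "enrich_p_max"),
              de_use_raw_p = isTRUE(de_use_raw_p),
              enrich_use_raw_p = isTRUE(enrich_use_raw_p),
              universe_policy = match.arg(universe_policy),
              quantile = isTRUE(quantile), log2_offset = log2_offset,
              seed = assert_count(seed, "seed"))
  if (cfg$fdr_max <= 0 || cfg$lfc_min <= 0)
    stop_("fdr_max and lfc_min must be > 0")
  if (cfg$pair_p_max < 0) stop_("pair_p_max must be >= 0")
  for (f in c("expr", "groups", "biotypes", "lnc_mirna", "mirna_mrna", "gmt")) {
    p <- cfg[[f]]
    if (!is.null(p) && !file.exists(p))
      stop_("input file for `%s` does not exist: %s", f, p)
  }
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; `...` overrides any key
#' (CLI flags take precedence over the file).
#'
#' @param path YAML file.
#' @param ... overrides passed to [run_config()].
#' @return a `run_config`.
#' @export
read_run_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  dots <- list(...)
  vals[names(dots)] <- dots
  do.call(run_config, vals)
}

stage_msg <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full ceRNA network pipeline
#'
#' Executes preprocessing (optional quantile normalization, per-gene Welch
#' t, BH adjustment, DEL/DEG filtering), background construction, ceRNA
#' network assembly, hub selection, per-hub subnetwork extraction and —
#' when a GMT collection is configured — over-representation analysis of
#' the network's mRNAs. Every intermediate artifact is written under
#' `cfg$outdir`, progress is logged to stderr with stage tags, and a
#' machine-readable `summary.json` records the counts at each stage plus
#' the resolved configuration. An empty network downstream of filtering is
#' a graceful stop (status `"empty_network"`), not an error.
#'
#' @param cfg a `run_config`.
#' @return the run summary (list), invisibly the same as what is written to
#'   `summary.json`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(config = unclass(cfg), status = "ok", stages = list())

  stage_msg("preprocess", "reading expression, groups and biotypes")
  mat <- read_expression(cfg$expr, log2_offset = cfg$log2_offset)
  groups <- read_groups(cfg$groups)
  biotypes <- read_biotypes(cfg$biotypes)
  if (cfg$quantile) mat <- quantile_normalize(mat)
  de <- welch_t(mat, groups)
  flt <- filter_de(de, biotypes, fdr_max = cfg$fdr_max, lfc_min = cfg$lfc_min,
                   use_raw_p = cfg$de_use_raw_p)
  write_de_table(flt$table, file.path(cfg$outdir, "de_table.tsv"))
  writeLines(sort(flt$dels), file.path(cfg$outdir, "dels.txt"))
  writeLines(sort(flt$degs), file.path(cfg$outdir, "degs.txt"))
  stage_msg("preprocess", "%d genes tested; %d DELs, %d DEGs retained",
            nrow(de), length(flt$dels), length(flt$degs))
  summary$stages$preprocess <- list(n_genes = nrow(de),
                                    n_dels = length(flt$dels),
                                    n_degs = length(flt$degs))
  if (length(flt$dels) == 0 || length(flt$degs) == 0) {
    summary$status <- "no_de_genes"
    return(finish_summary(summary, cfg))
  }

  stage_msg("background", "building interaction background (policy %s)",
            cfg$universe_policy)
  lnc_map <- read_interactions(cfg$lnc_mirna)
  mrna_map <- read_interactions(cfg$mirna_mrna)
  bg <- build_background(lnc_map, mrna_map, policy = cfg$universe_policy)
  stats <- background_stats(bg)
  jsonlite::write_json(stats, file.path(cfg$outdir, "background_stats.json"),
                       auto_unbox = TRUE, digits = NA)
  stage_msg("background", "m = %d miRNAs, %d lncRNAs, %d mRNAs",
            stats$m, stats$n_lnc, stats$n_mrna)
  summary$stages$background <- stats

  stage_msg("cerna", "scoring DEL x DEG pairs")
  net <- build_network(flt$dels, flt$degs, bg,
                       p_max = cfg$pair_p_max, min_shared = cfg$min_shared)
  write_network(net, file.path(cfg$outdir, "network"))
  stage_msg("cerna", "%d/%d pairs retained (%d lncRNAs, %d mRNAs); skipped %d+%d ids",
            nrow(net$edges), net$n_scored, length(net$lnc_nodes),
            length(net$mrna_nodes), net$skipped[["lnc"]], net$skipped[["mrna"]])
  summary$stages$cerna <- list(n_scored = net$n_scored,
                               n_edges = nrow(net$edges),
                               n_lnc = length(net$lnc_nodes),
                               n_mrna = length(net$mrna_nodes),
                               skipped = as.list(net$skipped))
  if (nrow(net$edges) == 0) {
    summary$status <- "empty_network"
    stage_msg("cerna", "no edges pass the filter; stopping gracefully")
    return(finish_summary(summary, cfg))
  }

  stage_msg("topology", "ranking lncRNAs by degree and betweenness (k = %d)", cfg$k)
  report <- select_hubs(net, k = cfg$k)
  write_centrality(report, file.path(cfg$outdir, "centrality.tsv"),
                   hubs_path = file.path(cfg$outdir, "hubs.txt"))
  hubs <- hub_ids(report)
  stage_msg("topology", "hubs: %s", paste(hubs, collapse = ", "))
  summary$stages$topology <- list(k = cfg$k, hubs = hubs)

  stage_msg("subnetwork", "extracting %d hub subnetwork(s)", length(hubs))
  subs <- lapply(hubs, function(h) {
    sub <- extract_subnetwork(h, net)
    export_subnetwork(sub, file.path(cfg$outdir, "subnets", h))
    list(hub = h, n_mrna = length(sub$mrnas), n_mirna = length(sub$mirnas),
         n_edges = nrow(sub$edges))
  })
  summary$stages$subnetwork <- subs

  if (!is.null(cfg$gmt)) {
    stage_msg("enrichment", "over-representation of %d network mRNAs",
              length(net$mrna_nodes))
    sets <- read_gmt(cfg$gmt)
    universe <- names(biotypes)[biotypes == "protein_coding"]
    res <- ora(net$mrna_nodes, sets, universe = universe,
               p_max = cfg$enrich_p_max, use_raw_p = cfg$enrich_use_raw_p)
    write_ora(res, file.path(cfg$outdir, "enrichment.tsv"))
    summary$stages$enrichment <- list(n_sets = nrow(res),
                                      n_significant = sum(res$significant))
  }
  finish_summary(summary, cfg)
}

finish_summary <- function(summary, cfg) {
  jsonlite::write_json(summary, file.path(cfg$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(summary)
}
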