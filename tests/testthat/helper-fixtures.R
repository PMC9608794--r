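# Build a cerna_network directly from an edge table, bypassing the scoring
# stage, for topology/subnetwork tests on hand-crafted graphs.
make_net <- function(edges, p_max = 0.01, min_shared = 3) {
  if (!"shared" %in% names(edges))
    edges$shared <- I(replicate(nrow(edges), character(0), simplify = FALSE))
  for (col in c("r", "n", "t", "m"))
    if (!col %in% names(edges)) edges[[col]] <- 0L
  if (!"p" %in% names(edges)) edges$p <- 0
  edges <- edges[order(edges$lnc, edges$mrna), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges,
                 lnc_nodes = sort(unique(edges$lnc)),
                 mrna_nodes = sort(unique(edges$mrna)),
                 p_max = p_max, min_shared = min_shared,
                 adjust_pairs = FALSE,
                 n_scored = nrow(edges), skipped = c(lnc = 0L, mrna = 0L)),
            class = "cerna_network")
}

# Random bipartite cerna_network with <= n_lnc + n_mrna nodes; every node is
# guaranteed at least one edge (isolated candidates never enter a network).
random_bipartite_net <- function(n_lnc, n_mrna, p_edge = 0.35) {
  repeat {
    lncs <- sprintf("L%02d", seq_len(n_lnc))
    mrnas <- sprintf("G%02d", seq_len(n_mrna))
    grid <- expand.grid(lnc = lncs, mrna = mrnas, stringsAsFactors = FALSE)
    keep <- stats::runif(nrow(grid)) < p_edge
    if (!any(keep)) next
    edges <- grid[keep, , drop = FALSE]
    return(make_net(edges))
  }
}

# Write the benchmark study to `dir` and assemble a matching run_config.
pipeline_fixture <- function(dir, seed = 101L, gmt = FALSE) {
  cfg <- planted_hub_config(seed)
  st <- simulate_to_dir(cfg, dir)
  gmt_path <- NULL
  if (gmt) {
    mrnas <- names(st$background$mrna_targets)
    net_mrnas <- st$truth$planted_pairs$mrna
    sets <- list(planted = unique(net_mrnas),
                 decoy = setdiff(mrnas, net_mrnas)[1:40])
    gmt_path <- file.path(dir, "sets.gmt")
    write_gmt(sets, gmt_path)
  }
  list(cfg = run_config(
    expr = file.path(dir, "expression.tsv"),
    groups = file.path(dir, "groups.tsv"),
    biotypes = file.path(dir, "biotypes.tsv"),
    lnc_mirna = file.path(dir, "lnc_mirna.tsv"),
    mirna_mrna = file.path(dir, "mirna_mrna.tsv"),
    gmt = gmt_path,
    outdir = file.path(dir, "out"),
    universe_policy = "union", seed = seed),
    truth = st$truth)
}

# The end-to-end benchmark condition (see benchmark_config()).
planted_hub_config <- function(seed = 101L) benchmark_config(seed)
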