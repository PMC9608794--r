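#' Configuration for the synthetic study generator
#'
#' Bundles and validates every knob of the synthetic benchmark: the size of
#' the miRNA/lncRNA/mRNA id spaces, the sparsity of random ("base") miRNA
#' targeting, the planted ceRNA structure, and the two-group expression model
#' (log2-scale mean shift plus i.i.d. Gaussian noise). The defaults emulate a
#' granulosa-cell microarray cohort of 10 case vs 10 control samples with a
#' scaled-down interaction background.
#'
#' Planted pairs receive `planted_shared` dedicated miRNAs each, reserved out
#' of the universe so that their sharing is controlled exactly; base targeting
#' draws uniformly without replacement from the unreserved remainder. Setting
#' `n_hub_lnc > 0` with `mrnas_per_hub > 0` concentrates planted pairs on a
#' few hub lncRNAs (each hub paired with `mrnas_per_hub` distinct mRNAs), in
#' addition to `n_planted_pairs` one-to-one planted pairs.
#'
#' @param n_mirna,n_lnc,n_mrna sizes of the miRNA universe and of the lncRNA
#'   and mRNA id spaces.
#' @param base_targets_per_lnc,base_targets_per_mrna number of miRNAs each
#'   lncRNA / mRNA receives at random.
#' @param n_planted_pairs number of one-to-one planted lncRNA-mRNA pairs.
#' @param planted_shared dedicated miRNAs forced common to each planted pair.
#' @param n_hub_lnc,mrnas_per_hub optional planted hub structure (see above).
#' @param n_genes total genes in the expression matrix; in a coupled study
#'   ([simulate_study()]) the lncRNA and mRNA ids come first and the rest
#'   are filler protein-coding genes without interactions.
#' @param n_per_group samples per group (case and control).
#' @param de_fraction fraction of genes that are differentially expressed.
#' @param effect_size log2-scale mean shift added to the case group of DE
#'   genes (sign drawn 50/50 per gene).
#' @param noise_sd log2-scale standard deviation of the i.i.d. Gaussian noise.
#' @param baseline_mean,baseline_sd per-gene baseline log2 intensities are
#'   drawn from N(baseline_mean, baseline_sd).
#' @param seed integer seed; all randomness flows from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_mirna = 250, n_lnc = 120, n_mrna = 300,
                       base_targets_per_lnc = 5, base_targets_per_mrna = 5,
                       n_planted_pairs = 0, planted_shared = 8,
                       n_hub_lnc = 0, mrnas_per_hub = 0,
                       n_genes = 1000, n_per_group = 10,
                       de_fraction = 0.1, effect_size = 2.0, noise_sd = 0.5,
                       baseline_mean = 8, baseline_sd = 2.5,
                       seed = 1L) {
  cfg <- list(
    n_mirna = assert_count(n_mirna, "n_mirna", 1),
    n_lnc = assert_count(n_lnc, "n_lnc"),
    n_mrna = assert_count(n_mrna, "n_mrna"),
    base_targets_per_lnc = assert_count(base_targets_per_lnc, "base_targets_per_lnc"),
    base_targets_per_mrna = assert_count(base_targets_per_mrna, "base_targets_per_mrna"),
    n_planted_pairs = assert_count(n_planted_pairs, "n_planted_pairs"),
    planted_shared = assert_count(planted_shared, "planted_shared"),
    n_hub_lnc = assert_count(n_hub_lnc, "n_hub_lnc"),
    mrnas_per_hub = assert_count(mrnas_per_hub, "mrnas_per_hub"),
    n_genes = assert_count(n_genes, "n_genes"),
    n_per_group = assert_count(n_per_group, "n_per_group"),
    de_fraction = assert_prob(de_fraction, "de_fraction"),
    effect_size = as.numeric(effect_size),
    noise_sd = as.numeric(noise_sd),
    baseline_mean = as.numeric(baseline_mean),
    baseline_sd = as.numeric(baseline_sd),
    seed = assert_count(seed, "seed")
  )
  if (cfg$noise_sd < 0) stop_("`noise_sd` must be >= 0")
  if (cfg$n_hub_lnc > 0 && cfg$mrnas_per_hub == 0)
    stop_("`mrnas_per_hub` must be > 0 when `n_hub_lnc` > 0")
  n_pp <- n_planted_total(cfg)
  reserved <- n_pp * cfg$planted_shared
  if (reserved > cfg$n_mirna)
    stop_("infeasible: %d planted pairs x planted_shared %d = %d reserved miRNAs > n_mirna %d",
          n_pp, cfg$planted_shared, reserved, cfg$n_mirna)
  free <- cfg$n_mirna - reserved
  if (cfg$base_targets_per_lnc > free)
    stop_("infeasible: base_targets_per_lnc %d > %d unreserved miRNAs",
          cfg$base_targets_per_lnc, free)
  if (cfg$base_targets_per_mrna > free)
    stop_("infeasible: base_targets_per_mrna %d > %d unreserved miRNAs",
          cfg$base_targets_per_mrna, free)
  if (cfg$n_hub_lnc + cfg$n_planted_pairs > cfg$n_lnc)
    stop_("infeasible: planted lncRNAs exceed n_lnc")
  if (cfg$n_hub_lnc * cfg$mrnas_per_hub + cfg$n_planted_pairs > cfg$n_mrna)
    stop_("infeasible: planted mRNAs exceed n_mrna")
  structure(cfg, class = "sim_config")
}

n_planted_total <- function(cfg) {
  cfg$n_hub_lnc * cfg$mrnas_per_hub + cfg$n_planted_pairs
}

pad_ids <- function(prefix, n) {
  if (n == 0) return(character(0))
  sprintf("%s%0*d", prefix, max(4L, nchar(n)), seq_len(n))
}

#' Generate a synthetic interaction background with planted ceRNA pairs
#'
#' Draws, for every lncRNA and mRNA, a random set of target miRNAs from a
#' common universe, then forces each planted lncRNA-mRNA pair to share
#' `planted_shared` dedicated miRNAs. Deterministic under `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return A list with `background` (an `interaction_background`, see
#'   [build_background()]) and `truth` (class `sim_truth`: a data frame
#'   `planted_pairs` with columns `lnc`, `mrna` and the per-pair dedicated
#'   miRNA sets as a list column `mirnas`).
#' @export
generate_background <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    mirnas <- pad_ids("miR-", cfg$n_mirna)
    lncs <- pad_ids("lnc-", cfg$n_lnc)
    mrnas <- pad_ids("mRNA-", cfg$n_mrna)

    # planted pairs: hubs first (each hub x mrnas_per_hub distinct mRNAs),
    # then one-to-one pairs on fresh ids
    hub_lncs <- lncs[seq_len(cfg$n_hub_lnc)]
    pp_lnc <- c(rep(hub_lncs, each = cfg$mrnas_per_hub),
                lncs[cfg$n_hub_lnc + seq_len(cfg$n_planted_pairs)])
    pp_mrna <- mrnas[seq_len(length(pp_lnc))]
    n_pp <- length(pp_lnc)

    reserved <- mirnas[seq_len(n_pp * cfg$planted_shared)]
    free <- setdiff(mirnas, reserved)
    dedicated <- if (n_pp > 0)
      split(reserved, rep(seq_len(n_pp), each = cfg$planted_shared))
    else list()

    lnc_targets <- lapply(lncs, function(id)
      sort(sample(free, cfg$base_targets_per_lnc)))
    names(lnc_targets) <- lncs
    mrna_targets <- lapply(mrnas, function(id)
      sort(sample(free, cfg$base_targets_per_mrna)))
    names(mrna_targets) <- mrnas
    for (j in seq_len(n_pp)) {
      d <- dedicated[[j]]
      lnc_targets[[pp_lnc[j]]] <- sort(union(lnc_targets[[pp_lnc[j]]], d))
      mrna_targets[[pp_mrna[j]]] <- sort(union(mrna_targets[[pp_mrna[j]]], d))
    }

    truth <- structure(list(
      planted_pairs = data.frame(lnc = pp_lnc, mrna = pp_mrna,
                                 stringsAsFactors = FALSE),
      planted_mirnas = dedicated,
      hub_lncs = hub_lncs
    ), class = "sim_truth")
    bg <- build_background(lnc_targets, mrna_targets, policy = "union")
    list(background = bg, truth = truth)
  })
}

#' Generate a two-group log2 expression matrix with planted DE genes
#'
#' Each gene gets a baseline log2 intensity; a `de_fraction` subset is shifted
#' by `+/- effect_size` in the case group (direction 50/50 at random);
#' i.i.d. Gaussian noise with sd `noise_sd` is added throughout.
#'
#' @param cfg a [sim_config()].
#' @param gene_ids optional character vector of gene ids to use (defaults to
#'   `gene-0001 ...` of length `cfg$n_genes`).
#' @param force_de optional gene ids guaranteed to be differentially
#'   expressed (counted inside the `de_fraction` budget, which is raised to
#'   `length(force_de)` if smaller).
#' @return list with `matrix` (genes x samples, log2 scale), `groups` (named
#'   character vector, values `"case"`/`"control"`), and `truth` (class
#'   `sim_truth`: data frame `de_genes` with columns `gene`, `direction`).
#' @export
generate_expression <- function(cfg, gene_ids = NULL, force_de = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_per_group < 2)
    stop_("`n_per_group` must be >= 2 (group variance undefined otherwise)")
  gene_ids <- gene_ids %||% pad_ids("gene-", cfg$n_genes)
  if (anyDuplicated(gene_ids)) stop_("duplicate gene ids")
  if (!all(force_de %in% gene_ids)) stop_("`force_de` ids missing from gene ids")
  ng <- length(gene_ids)
  n_de <- max(round(cfg$de_fraction * ng), length(force_de))
  n_de <- min(n_de, ng)

  with_seed(cfg$seed + 1L, {
    pool <- setdiff(gene_ids, force_de)
    extra <- sample(pool, n_de - length(force_de))
    de_genes <- c(force_de, extra)
    direction <- sample(c("up", "down"), n_de, replace = TRUE)

    samples <- c(sprintf("case_%02d", seq_len(cfg$n_per_group)),
                 sprintf("ctrl_%02d", seq_len(cfg$n_per_group)))
    groups <- stats::setNames(rep(c("case", "control"), each = cfg$n_per_group),
                              samples)
    baseline <- stats::rnorm(ng, cfg$baseline_mean, cfg$baseline_sd)
    mu <- matrix(baseline, nrow = ng, ncol = length(samples),
                 dimnames = list(gene_ids, samples))
    shift <- ifelse(direction == "up", cfg$effect_size, -cfg$effect_size)
    mu[de_genes, groups == "case"] <- mu[de_genes, groups == "case"] + shift
    x <- mu + matrix(stats::rnorm(length(mu), 0, cfg$noise_sd),
                     nrow = ng, ncol = length(samples))
    truth <- structure(list(
      de_genes = data.frame(gene = de_genes, direction = direction,
                            stringsAsFactors = FALSE)
    ), class = "sim_truth")
    list(matrix = x, groups = groups, truth = truth)
  })
}

#' Generate a complete coherent synthetic study
#'
#' Couples [generate_background()] and [generate_expression()]: the gene
#' space of the expression matrix is the union of the background's lncRNA and
#' mRNA ids, every gene in a planted ceRNA pair is forced to be
#' differentially expressed, and the biotype table labels lncRNAs vs
#' protein-coding genes. This is the end-to-end benchmark on which the full
#' pipeline's recovery of the planted structure can be measured.
#'
#' If `cfg$n_genes` exceeds the number of background genes, the matrix is
#' padded with filler protein-coding genes that have no interactions — as on
#' a real array, where most measured genes never enter the candidate pool.
#' A well-populated matrix also keeps quantile normalization from
#' compressing fold changes of genes in the distribution tails.
#'
#' @param cfg a [sim_config()].
#' @return list with `background`, `matrix`, `groups`, `biotypes` (named
#'   character vector: `"lncRNA"` or `"protein_coding"`), and `truth`
#'   (planted pairs, hub lncRNAs and DE genes combined).
#' @export
simulate_study <- function(cfg) {
  bgres <- generate_background(cfg)
  net_genes <- c(names(bgres$background$lnc_targets),
                 names(bgres$background$mrna_targets))
  filler <- pad_ids("gene-", max(0, cfg$n_genes - length(net_genes)))
  gene_ids <- c(net_genes, filler)
  planted_genes <- unique(unlist(bgres$truth$planted_pairs[c("lnc", "mrna")]))
  ex <- generate_expression(cfg, gene_ids = gene_ids, force_de = planted_genes)
  biotypes <- stats::setNames(
    rep(c("lncRNA", "protein_coding", "protein_coding"),
        c(length(bgres$background$lnc_targets),
          length(bgres$background$mrna_targets),
          length(filler))),
    gene_ids)
  truth <- structure(c(bgres$truth[c("planted_pairs", "planted_mirnas", "hub_lncs")],
                       ex$truth["de_genes"]), class = "sim_truth")
  list(background = bgres$background, matrix = ex$matrix, groups = ex$groups,
       biotypes = biotypes, truth = truth)
}

#' Study conditions of the planted-hub benchmark
#'
#' The reference configuration on which the package's end-to-end recovery is
#' measured: a 10 vs 10 two-group cohort over 4000 measured genes with 10%
#' differentially expressed (log2 shift 2, noise sd 0.5), and an interaction
#' background of 600 miRNAs, 120 lncRNAs and 300 mRNAs (sparse base targeting
#' of 5 miRNAs per gene) in which 4 hub lncRNAs each share 8 dedicated miRNAs
#' with 6 mRNAs.
#'
#' @param seed integer seed.
#' @return a [sim_config()].
#' @export
benchmark_config <- function(seed = 101L) {
  sim_config(n_mirna = 600, n_lnc = 120, n_mrna = 300, n_genes = 4000,
             base_targets_per_lnc = 5, base_targets_per_mrna = 5,
             n_hub_lnc = 4, mrnas_per_hub = 6, planted_shared = 8,
             n_per_group = 10, de_fraction = 0.1,
             effect_size = 2.0, noise_sd = 0.5, seed = seed)
}

# ---- writers: the same TSV/GMT dialects the readers consume -----------------

#' Write an interaction map as a two-column TSV (`source<TAB>mirna`)
#'
#' @param targets named list: source id -> character vector of miRNA ids.
#' @param path output file.
#' @export
write_interactions <- function(targets, path) {
  src <- rep(names(targets), lengths(targets))
  df <- data.frame(source = src, mirna = unlist(targets, use.names = FALSE),
                   stringsAsFactors = FALSE)
  df <- df[order(df$source, df$mirna), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an expression matrix as TSV (genes x samples, header = sample ids)
#' @param mat numeric matrix with gene rownames and sample colnames.
#' @param path output file.
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a sample-group table (`sample<TAB>group`)
#' @param groups named character vector, sample id -> group.
#' @param path output file.
#' @export
write_groups <- function(groups, path) {
  df <- data.frame(sample = names(groups), group = unname(groups),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a gene-biotype table (`gene<TAB>biotype`)
#' @param biotypes named character vector, gene id -> biotype.
#' @param path output file.
#' @export
write_biotypes <- function(biotypes, path) {
  df <- data.frame(gene = names(biotypes), biotype = unname(biotypes),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a full synthetic study to a directory
#'
#' Emits `expression.tsv`, `groups.tsv`, `biotypes.tsv`, `lnc_mirna.tsv`,
#' `mirna_mrna.tsv` and `truth.json` under `outdir`.
#'
#' @param cfg a [sim_config()].
#' @param outdir output directory (created if missing).
#' @return the study list from [simulate_study()], invisibly.
#' @export
simulate_to_dir <- function(cfg, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  st <- simulate_study(cfg)
  write_expression(st$matrix, file.path(outdir, "expression.tsv"))
  write_groups(st$groups, file.path(outdir, "groups.tsv"))
  write_biotypes(st$biotypes, file.path(outdir, "biotypes.tsv"))
  write_interactions(st$background$lnc_targets, file.path(outdir, "lnc_mirna.tsv"))
  write_interactions(st$background$mrna_targets, file.path(outdir, "mirna_mrna.tsv"))
  jsonlite::write_json(
    list(planted_pairs = st$truth$planted_pairs,
         hub_lncs = st$truth$hub_lncs,
         de_genes = st$truth$de_genes),
    file.path(outdir, "truth.json"))
  invisible(st)
}
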