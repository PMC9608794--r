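test_that("null configuration plants nothing", {
  cfg <- sim_config(n_planted_pairs = 0, n_hub_lnc = 0, seed = 1)
  res <- generate_background(cfg)
  expect_equal(nrow(res$truth$planted_pairs), 0)
  expect_length(res$truth$hub_lncs, 0)
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- sim_config(n_planted_pairs = 3, planted_shared = 6, seed = 77)
  a <- generate_background(cfg)
  b <- generate_background(cfg)
  expect_identical(a, b)
  ea <- generate_expression(cfg)
  eb <- generate_expression(cfg)
  expect_identical(ea, eb)
  # serialized form is byte-identical too
  expect_identical(serialize(a, NULL), serialize(b, NULL))
})

test_that("planted pairs share their dedicated miRNAs; random pairs share few", {
  cfg <- sim_config(n_mirna = 50, n_lnc = 30, n_mrna = 60,
                    base_targets_per_lnc = 5, base_targets_per_mrna = 5,
                    n_planted_pairs = 2, planted_shared = 8, seed = 12)
  res <- generate_background(cfg)
  bg <- res$background
  pp <- res$truth$planted_pairs
  for (i in seq_len(nrow(pp))) {
    shared <- intersect(bg$lnc_targets[[pp$lnc[i]]],
                        bg$mrna_targets[[pp$mrna[i]]])
    expect_gte(length(shared), 8)
  }
  set.seed(1)
  decoy_lnc <- sample(setdiff(names(bg$lnc_targets), pp$lnc), 10)
  decoy_mrna <- sample(setdiff(names(bg$mrna_targets), pp$mrna), 10)
  combos <- expand.grid(l = decoy_lnc, g = decoy_mrna,
                        stringsAsFactors = FALSE)
  sharing <- mapply(function(l, g)
    length(intersect(bg$lnc_targets[[l]], bg$mrna_targets[[g]])),
    combos$l, combos$g)
  expect_lte(mean(sharing), 2)
})

test_that("infeasible configurations fail with the violated bound named", {
  expect_error(sim_config(n_mirna = 10, n_planted_pairs = 2, planted_shared = 8),
               "reserved miRNAs > n_mirna")
  expect_error(sim_config(n_mirna = 20, base_targets_per_lnc = 15,
                          n_planted_pairs = 1, planted_shared = 8),
               "base_targets_per_lnc")
  expect_error(sim_config(n_lnc = 2, n_hub_lnc = 3, mrnas_per_hub = 1),
               "exceed n_lnc")
  expect_error(sim_config(de_fraction = 1.3), "\\[0, 1\\]")
})

test_that("truth ids always exist in the generated objects", {
  cfg <- sim_config(n_hub_lnc = 2, mrnas_per_hub = 3, n_planted_pairs = 2,
                    planted_shared = 5, seed = 9)
  st <- simulate_study(cfg)
  expect_true(all(st$truth$planted_pairs$lnc %in% names(st$background$lnc_targets)))
  expect_true(all(st$truth$planted_pairs$mrna %in% names(st$background$mrna_targets)))
  expect_true(all(st$truth$de_genes$gene %in% rownames(st$matrix)))
  expect_true(all(st$truth$hub_lncs %in% st$truth$planted_pairs$lnc))
})

test_that("noiseless expression shifts are exact and directions balanced", {
  cfg <- sim_config(n_genes = 400, de_fraction = 0.25, effect_size = 2,
                    noise_sd = 0, n_per_group = 5, seed = 4)
  ex <- generate_expression(cfg)
  case_mean <- rowMeans(ex$matrix[, ex$groups == "case"])
  ctrl_mean <- rowMeans(ex$matrix[, ex$groups == "control"])
  lfc <- case_mean - ctrl_mean
  de <- ex$truth$de_genes
  expect_equal(nrow(de), 100)
  expect_equal(unname(abs(lfc[de$gene])), rep(2, 100), tolerance = 1e-12)
  expect_equal(unname(sign(lfc[de$gene])),
               ifelse(de$direction == "up", 1, -1))
  expect_equal(unname(lfc[setdiff(names(lfc), de$gene)]),
               rep(0, length(lfc) - 100), tolerance = 1e-12)
})

test_that("null effect size leaves realized fold changes centred at zero", {
  cfg <- sim_config(n_genes = 2000, de_fraction = 0.5, effect_size = 0,
                    noise_sd = 0.5, n_per_group = 10, seed = 8)
  ex <- generate_expression(cfg)
  lfc <- rowMeans(ex$matrix[, ex$groups == "case"]) -
    rowMeans(ex$matrix[, ex$groups == "control"])
  expect_lt(abs(mean(lfc[ex$truth$de_genes$gene])), 0.02)
})

test_that("fewer than two samples per group is rejected", {
  expect_error(generate_expression(sim_config(n_per_group = 1)),
               "n_per_group")
})

test_that("planted DE genes are recovered by the preprocess stage", {
  cfg <- sim_config(n_genes = 1000, de_fraction = 0.1, effect_size = 2,
                    noise_sd = 0.5, n_per_group = 10, seed = 2024)
  ex <- generate_expression(cfg)
  de <- welch_t(quantile_normalize(ex$matrix), ex$groups)
  bio <- setNames(rep("protein_coding", nrow(ex$matrix)), rownames(ex$matrix))
  res <- filter_de(de, bio, fdr_max = 0.05, lfc_min = 1)
  truth <- ex$truth$de_genes$gene
  recovery <- length(intersect(res$degs, truth)) / length(truth)
  false_pos <- length(setdiff(res$degs, truth)) / max(1, length(res$degs))
  expect_gte(recovery, 0.9)
  expect_lte(false_pos, 0.1)
})

test_that("writers and readers round-trip every dialect", {
  cfg <- sim_config(n_mirna = 40, n_lnc = 8, n_mrna = 12, n_genes = 20,
                    n_per_group = 3, n_planted_pairs = 1, planted_shared = 4,
                    seed = 5)
  st <- simulate_study(cfg)
  td <- withr::local_tempdir()
  write_interactions(st$background$lnc_targets, file.path(td, "lnc.tsv"))
  expect_identical(read_interactions(file.path(td, "lnc.tsv")),
                   st$background$lnc_targets)
  write_expression(st$matrix, file.path(td, "expr.tsv"))
  expect_equal(read_expression(file.path(td, "expr.tsv")), st$matrix,
               tolerance = 1e-12)
  write_groups(st$groups, file.path(td, "groups.tsv"))
  expect_identical(read_groups(file.path(td, "groups.tsv")), st$groups)
  write_biotypes(st$biotypes, file.path(td, "bio.tsv"))
  expect_identical(read_biotypes(file.path(td, "bio.tsv")), st$biotypes)
})
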