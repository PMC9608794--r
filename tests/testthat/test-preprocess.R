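test_that("quantile normalization reproduces the worked 3x2 examples", {
  m1 <- cbind(a = c(2, 4, 6), b = c(6, 8, 10))
  out1 <- quantile_normalize(m1)
  expect_equal(unname(out1), cbind(c(4, 6, 8), c(4, 6, 8)))
  # second column's values 10,6,8 have ranks 3,1,2 against reference (4,6,8)
  m2 <- cbind(a = c(2, 4, 6), b = c(10, 6, 8))
  out2 <- quantile_normalize(m2)
  expect_equal(unname(out2), cbind(c(4, 6, 8), c(8, 4, 6)))
})

test_that("quantile normalization is a fixed point on identical columns", {
  m <- cbind(x = c(1, 5, 3), y = c(1, 5, 3), z = c(1, 5, 3))
  expect_equal(quantile_normalize(m), m)
})

test_that("normalized columns share one multiset and preserve rank order", {
  set.seed(11)
  m <- matrix(rnorm(200 * 6, 8, 2), 200, 6,
              dimnames = list(sprintf("g%03d", 1:200), sprintf("s%d", 1:6)))
  out <- quantile_normalize(m)
  ref <- sort(unname(out[, 1]))
  for (j in 2:ncol(out)) expect_equal(sort(unname(out[, j])), ref)
  for (j in seq_len(ncol(out)))
    expect_true(all(diff(out[order(m[, j]), j]) >= 0))
})

test_that("non-finite input is rejected with cell coordinates", {
  m <- cbind(a = c(1, NA, 3), b = c(4, 5, 6))
  rownames(m) <- c("g1", "g2", "g3")
  expect_error(quantile_normalize(m), "non-finite.*row 2.*g2")
})

test_that("welch_t reproduces a hand-computed textbook case", {
  mat <- rbind(g1 = c(5, 6, 7, 1, 2, 3))
  colnames(mat) <- sprintf("s%d", 1:6)
  groups <- setNames(rep(c("case", "control"), each = 3), colnames(mat))
  de <- welch_t(mat, groups)
  expect_equal(de$log2fc, 4)
  # t = 4 / sqrt(1/3 + 1/3) = 4.89898, Welch-Satterthwaite df = 4
  t_stat <- 4 / sqrt(1 / 3 + 1 / 3)
  expect_equal(de$p, 2 * pt(t_stat, df = 4, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(de$direction, "up")
})

test_that("welch_t agrees with stats::t.test across random genes", {
  set.seed(5)
  mat <- matrix(rnorm(50 * 9, 8, 1), 50, 9,
                dimnames = list(sprintf("g%02d", 1:50), sprintf("s%d", 1:9)))
  groups <- setNames(rep(c("case", "control"), c(4, 5)), colnames(mat))
  de <- welch_t(mat, groups)
  for (i in c(1, 17, 50)) {
    tt <- t.test(mat[i, 1:4], mat[i, 5:9])
    expect_equal(de$p[i], tt$p.value, tolerance = 1e-12)
    expect_equal(de$log2fc[i], unname(diff(rev(tt$estimate))), tolerance = 1e-12)
  }
})

test_that("welch_t degenerate zero-variance rules apply", {
  mat <- rbind(same = rep(5, 8), shifted = rep(c(7, 5), each = 4))
  colnames(mat) <- sprintf("s%d", 1:8)
  groups <- setNames(rep(c("case", "control"), each = 4), colnames(mat))
  de <- welch_t(mat, groups)
  expect_equal(de[de$gene == "same", "p"], 1)
  expect_equal(de[de$gene == "same", "log2fc"], 0)
  expect_equal(de[de$gene == "shifted", "p"], 0)
  expect_equal(de[de$gene == "shifted", "log2fc"], 2)
})

test_that("welch_t validates groups and group sizes", {
  mat <- matrix(rnorm(12), 3, 4, dimnames = list(letters[1:3], LETTERS[1:4]))
  expect_error(welch_t(mat, c(A = "case", B = "case", C = "control")),
               "without group")
  expect_error(
    welch_t(mat, setNames(c("case", "control", "control", "control"),
                          LETTERS[1:4])),
    ">= 2 samples")
})

test_that("bh_adjust reproduces hand-derived step-up values", {
  # min over j >= i of p_(j) * 4 / j collapses all four to 0.04
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, -0.1)), "\\[0, 1\\]")
})

test_that("bh_adjust equals the literal step-up formula on random vectors", {
  set.seed(99)
  for (len in c(1, 2, 7, 40, 500)) {
    p <- runif(len)^2
    expect_equal(bh_adjust(p), brute_bh(p), tolerance = 1e-14)
  }
})

test_that("filter_de handles empty and single-gene tables", {
  bio <- c(g1 = "lncRNA")
  empty <- data.frame(gene = character(0), log2fc = numeric(0),
                      p = numeric(0), fdr = numeric(0),
                      direction = character(0))
  res <- filter_de(empty, bio)
  expect_identical(res$dels, character(0))
  expect_identical(res$degs, character(0))
  one <- data.frame(gene = "g1", log2fc = 1.5, p = 0.001, fdr = 0.04,
                    direction = "up")
  res1 <- filter_de(one, bio)
  expect_identical(res1$dels, "g1")
  expect_identical(res1$degs, character(0))
})

test_that("filter_de thresholds are strict and split by biotype", {
  de <- data.frame(gene = c("l1", "l2", "m1", "m2"),
                   log2fc = c(1.5, 1.0, -2, 3),
                   p = c(0.001, 0.001, 0.001, 0.2),
                   fdr = c(0.01, 0.01, 0.05, 0.4),
                   direction = c("up", "up", "down", "up"))
  bio <- c(l1 = "lncRNA", l2 = "lncRNA",
           m1 = "protein_coding", m2 = "protein_coding")
  res <- filter_de(de, bio, fdr_max = 0.05, lfc_min = 1)
  expect_identical(res$dels, "l1")          # l2 fails |lfc| > 1 (equality)
  expect_identical(res$degs, character(0))  # m1 fails fdr < 0.05 (equality)
  raw <- filter_de(de, bio, use_raw_p = TRUE)
  expect_identical(raw$degs, "m1")
})

test_that("filter_de is monotone in both thresholds", {
  set.seed(3)
  de <- data.frame(gene = sprintf("g%03d", 1:200),
                   log2fc = rnorm(200, 0, 2), p = runif(200))
  de$fdr <- bh_adjust(de$p)
  de$direction <- ifelse(de$log2fc > 0, "up", "down")
  bio <- setNames(rep(c("lncRNA", "protein_coding"), 100), de$gene)
  tight <- filter_de(de, bio, fdr_max = 0.05, lfc_min = 1.5)
  loose_fdr <- filter_de(de, bio, fdr_max = 0.2, lfc_min = 1.5)
  loose_lfc <- filter_de(de, bio, fdr_max = 0.05, lfc_min = 0.5)
  expect_true(all(tight$dels %in% loose_fdr$dels))
  expect_true(all(tight$degs %in% loose_fdr$degs))
  expect_true(all(tight$dels %in% loose_lfc$dels))
  expect_true(all(tight$degs %in% loose_lfc$degs))
})

test_that("genes missing a biotype are dropped with warning or error on request", {
  de <- data.frame(gene = c("known", "unknown"), log2fc = c(2, 2),
                   p = c(0.001, 0.001), fdr = c(0.01, 0.01),
                   direction = c("up", "up"))
  bio <- c(known = "lncRNA")
  expect_warning(res <- filter_de(de, bio), "dropping 1 gene")
  expect_identical(res$dels, "known")
  expect_error(filter_de(de, bio, missing_biotype = "error"), "missing")
})

test_that("welch_t p-values are calibrated under the global null", {
  set.seed(314)
  n_genes <- 6000
  mat <- matrix(rnorm(n_genes * 20, 8, 0.5), n_genes, 20,
                dimnames = list(sprintf("g%04d", 1:n_genes), sprintf("s%d", 1:20)))
  groups <- setNames(rep(c("case", "control"), each = 10), colnames(mat))
  de <- welch_t(mat, groups)
  rate <- mean(de$p < 0.05)
  se <- sqrt(0.05 * 0.95 / n_genes)
  expect_lt(abs(rate - 0.05), 2 * se + 1e-12)
})

test_that("duplicate gene rows collapse to the highest-mean probe", {
  mat <- rbind(g1 = c(1, 1), g2 = c(5, 5), g1 = c(3, 3))
  colnames(mat) <- c("s1", "s2")
  expect_warning(out <- collapse_duplicate_genes(mat), "collapsed 1")
  expect_equal(nrow(out), 2)
  expect_equal(out["g1", ], c(s1 = 3, s2 = 3))
})
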