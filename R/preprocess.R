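#' Read an expression TSV (genes x samples, header row = sample ids)
#'
#' First column holds gene ids; remaining columns are numeric log2
#' intensities. Duplicate gene ids are collapsed to the row with highest mean
#' expression (the usual probe-collapse convention).
#'
#' @param path TSV file.
#' @param log2_offset if non-`NULL`, apply `log2(x + log2_offset)` to the
#'   values; by default the input is assumed to be on the log2 scale already
#'   (no auto-detection — silent transforms are a reproducibility hazard).
#' @return numeric matrix, genes x samples.
#' @export
read_expression <- function(path, log2_offset = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop_("expression table needs a gene column plus >=1 sample")
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- as.character(df[[1]])
  if (!is.null(log2_offset)) mat <- log2(mat + log2_offset)
  collapse_duplicate_genes(mat)
}

#' Collapse duplicate gene ids to the highest-mean-expression row
#' @param mat genes x samples matrix with rownames.
#' @return matrix with unique rownames.
#' @export
collapse_duplicate_genes <- function(mat) {
  if (!anyDuplicated(rownames(mat))) return(mat)
  means <- rowMeans(mat)
  keep <- unlist(lapply(split(seq_len(nrow(mat)), rownames(mat)),
                        function(idx) idx[which.max(means[idx])]))
  n_dropped <- nrow(mat) - length(keep)
  warn_("collapsed %d duplicate gene row(s) to the highest-mean probe", n_dropped)
  mat[sort(keep), , drop = FALSE]
}

#' Read a sample-group table (`sample<TAB>group`)
#' @param path TSV with columns `sample`, `group`.
#' @return named character vector sample -> group.
#' @export
read_groups <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(df)))
    stop_("group table must have columns `sample` and `group`")
  stats::setNames(as.character(df$group), as.character(df$sample))
}

#' Read a gene-biotype table (`gene<TAB>biotype`)
#' @param path TSV with columns `gene`, `biotype` (values `lncRNA` or
#'   `protein_coding`).
#' @return named character vector gene -> biotype.
#' @export
read_biotypes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "biotype") %in% names(df)))
    stop_("biotype table must have columns `gene` and `biotype`")
  bad <- setdiff(unique(df$biotype), c("lncRNA", "protein_coding"))
  if (length(bad))
    stop_("unknown biotype(s): %s", paste(bad, collapse = ", "))
  stats::setNames(as.character(df$biotype), as.character(df$gene))
}

#' Quantile-normalize a log2 expression matrix
#'
#' Forces every sample (column) onto the common reference distribution given
#' by the row means of the column-sorted matrix, preserving within-column
#' rank order; ties within a column receive the mean of the reference values
#' at their tied positions. Computation is delegated to
#' [limma::normalizeQuantiles()] with `ties = TRUE`, the same normalization
#' used for two-color/one-channel microarray intensities.
#'
#' @param mat numeric genes x samples matrix; all values must be finite.
#' @return matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) stop_("need >= 2 samples to quantile normalize")
  if (any(!is.finite(mat))) {
    bad <- which(!is.finite(mat), arr.ind = TRUE)
    stop_("non-finite values at %d cell(s), first at row %d (%s), column %d",
          nrow(bad), bad[1, 1], rownames(mat)[bad[1, 1]] %||% "?", bad[1, 2])
  }
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Per-gene two-sided Welch unequal-variance t-test
#'
#' For every gene (row), tests case vs control means with the Welch statistic
#' and Welch-Satterthwaite degrees of freedom. `log2fc` is case mean minus
#' control mean (the matrix is assumed to be on the log2 scale, so this is a
#' log2 fold change). Degenerate genes with zero variance in both groups get
#' `p = 1` if the means are equal and `p = 0` otherwise.
#'
#' @param mat numeric genes x samples log2 matrix.
#' @param groups named character vector mapping every column of `mat` to
#'   `"case"` or `"control"`; both groups need >= 2 samples.
#' @return data frame (one row per gene): `gene`, `log2fc`, `p`, `fdr`
#'   (Benjamini-Hochberg across all genes), `direction` (`up` iff
#'   `log2fc > 0`).
#' @export
welch_t <- function(mat, groups) {
  mat <- as.matrix(mat)
  miss <- setdiff(colnames(mat), names(groups))
  if (length(miss)) stop_("samples without group: %s", paste(miss, collapse = ", "))
  g <- groups[colnames(mat)]
  if (!all(g %in% c("case", "control")))
    stop_("groups must be `case` or `control`")
  x1 <- mat[, g == "case", drop = FALSE]
  x2 <- mat[, g == "control", drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  if (n1 < 2 || n2 < 2) stop_("each group needs >= 2 samples (got %d and %d)", n1, n2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  lfc <- m1 - m2
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(abs(lfc) / sqrt(se2), df, lower.tail = FALSE)
  zero <- se2 == 0
  p[zero] <- ifelse(lfc[zero] == 0, 1, 0)
  lfc[zero & lfc == 0] <- 0
  data.frame(gene = rownames(mat), log2fc = lfc, p = p,
             fdr = bh_adjust(p),
             direction = ifelse(lfc > 0, "up", "down"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validates the input and applies the BH step-up procedure (capped at 1,
#' order-preserving with input positions).
#'
#' @param pvals numeric vector of probabilities in `[0, 1]`.
#' @return adjusted values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1))
    stop_("p-values must all lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Filter a DE table and split retained genes by biotype
#'
#' A gene is retained iff `fdr < fdr_max` and `|log2fc| > lfc_min` (both
#' strict). Retained genes are split into DELs (biotype `lncRNA`) and DEGs
#' (`protein_coding`).
#'
#' @param de data frame from [welch_t()].
#' @param biotypes named character vector gene -> biotype.
#' @param fdr_max,lfc_min positive thresholds (defaults 0.05 and 1).
#' @param use_raw_p if `TRUE`, filter on the raw `p` column instead of `fdr`.
#' @param missing_biotype `"drop"` (default; drop with a warning) or
#'   `"error"` for genes absent from the biotype table.
#' @return list with `dels`, `degs` (character vectors), `table` (the DE
#'   table with `biotype` and `retained` columns) and `counts` (up/down per
#'   biotype).
#' @export
filter_de <- function(de, biotypes, fdr_max = 0.05, lfc_min = 1.0,
                      use_raw_p = FALSE,
                      missing_biotype = c("drop", "error")) {
  missing_biotype <- match.arg(missing_biotype)
  if (fdr_max <= 0 || lfc_min <= 0) stop_("thresholds must be > 0")
  unknown <- setdiff(de$gene, names(biotypes))
  if (length(unknown)) {
    if (missing_biotype == "error")
      stop_("%d gene(s) missing from the biotype table", length(unknown))
    warn_("dropping %d gene(s) missing from the biotype table", length(unknown))
    de <- de[de$gene %in% names(biotypes), , drop = FALSE]
  }
  if (nrow(de) == 0)
    return(list(dels = character(0), degs = character(0), table = de,
                counts = data.frame()))
  de$biotype <- unname(biotypes[de$gene])
  crit <- if (use_raw_p) de$p else de$fdr
  de$retained <- crit < fdr_max & abs(de$log2fc) > lfc_min
  kept <- de[de$retained, , drop = FALSE]
  counts <- as.data.frame(table(biotype = kept$biotype, direction = kept$direction))
  list(dels = kept$gene[kept$biotype == "lncRNA"],
       degs = kept$gene[kept$biotype == "protein_coding"],
       table = de, counts = counts)
}

#' Write a DE table as TSV
#' @param de data frame from [welch_t()] (optionally after [filter_de()]).
#' @param path output file.
#' @export
write_de_table <- function(de, path) {
  utils::write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
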