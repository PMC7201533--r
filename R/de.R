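# Cell-type-specific differential expression (negative-binomial likelihood
# ratio test), ROC marker discovery, signature correlation, hormone-positive
# fraction curves, and cross-species fold-change comparison.

# internal: per-group mean expression on the counts-per-million-like scale
.norm_means <- function(counts, lib_sizes) {
  x <- sweep(as.matrix(counts), 2, lib_sizes, "/") * 1e6
  rowMeans(x)
}

#' Negative-binomial differential expression test
#'
#' Per gene, a negative-binomial regression of counts on the group indicator
#' with a log-library-size offset. The gene-wise dispersion is estimated by
#' maximum likelihood on the pooled data under the null and reused in the
#' alternative fit; the p-value comes from the likelihood-ratio test of the
#' group coefficient (1 df). Genes are pre-filtered to an absolute
#' natural-log fold change of at least `min_logfc`; p-values are
#' Benjamini-Hochberg adjusted across tested genes, and a gene is called
#' significant when its linear-scale fold change is at least `fold_min` (in
#' either direction) and the adjusted p-value is below 0.05.
#'
#' @param counts_group1,counts_group2 raw count matrices (genes x cells) with
#'   identical rownames.
#' @param lib_sizes1,lib_sizes2 per-cell library sizes (default: column
#'   sums).
#' @param min_logfc pre-filter on `|ln fold change|` (default 0.1).
#' @param fold_min linear fold-change threshold for significance
#'   (default 1.25).
#' @param alpha adjusted-p threshold for significance (default 0.05).
#' @param pseudo pseudocount (per-million scale) used in fold-change
#'   computation (default 1).
#' @return data.frame `gene`, `log_fold_change` (natural log),
#'   `p_value`, `p_adjusted`, `significant` for tested genes.
#' @export
nb_test <- function(counts_group1, counts_group2,
                    lib_sizes1 = NULL, lib_sizes2 = NULL,
                    min_logfc = 0.1, fold_min = 1.25, alpha = 0.05,
                    pseudo = 1) {
  c1 <- as.matrix(counts_group1)
  c2 <- as.matrix(counts_group2)
  if (!identical(rownames(c1), rownames(c2))) {
    stop("count matrices must share an identical gene space")
  }
  if (ncol(c1) < 3 || ncol(c2) < 3) stop("each group needs at least 3 cells")
  if (is.null(lib_sizes1)) lib_sizes1 <- colSums(c1)
  if (is.null(lib_sizes2)) lib_sizes2 <- colSums(c2)

  m1 <- .norm_means(c1, lib_sizes1)
  m2 <- .norm_means(c2, lib_sizes2)
  lfc <- log((m1 + pseudo) / (m2 + pseudo))
  nonzero <- (m1 + m2) > 0
  test_genes <- rownames(c1)[nonzero & abs(lfc) >= min_logfc]
  if (length(test_genes) == 0) {
    return(data.frame(gene = character(), log_fold_change = numeric(),
                      p_value = numeric(), p_adjusted = numeric(),
                      significant = logical(), stringsAsFactors = FALSE))
  }

  grp <- factor(rep(c("a", "b"), c(ncol(c1), ncol(c2))))
  off <- log(c(lib_sizes1, lib_sizes2))
  pvals <- vapply(test_genes, function(g) {
    y <- c(c1[g, ], c2[g, ])
    .nb_lrt_pvalue(y, grp, off)
  }, numeric(1))

  padj <- adjust_bh(pvals)
  fold <- (m1[test_genes] + pseudo) / (m2[test_genes] + pseudo)
  data.frame(gene = test_genes,
             log_fold_change = unname(lfc[test_genes]),
             p_value = unname(pvals),
             p_adjusted = unname(padj),
             significant = unname((fold >= fold_min | fold <= 1 / fold_min) &
                                    padj < alpha),
             stringsAsFactors = FALSE)
}

# internal: NB LRT p-value for one gene. Null MLE under offset-only model is
# closed form (common rate times library size); theta is estimated there by
# ML and held fixed in both fits so the deviance difference is the LRT.
.nb_lrt_pvalue <- function(y, grp, off) {
  lib <- exp(off)
  mu0 <- lib * sum(y) / sum(lib)
  if (all(y == y[1]) && length(unique(tapply(y / lib, grp, mean))) == 1) {
    # identical constant groups carry no signal
  }
  theta <- tryCatch(
    suppressWarnings(as.numeric(MASS::theta.ml(y, mu0, limit = 25))),
    error = function(e) 1e8)
  if (!is.finite(theta) || theta <= 0) theta <- 1e8
  fam <- MASS::negative.binomial(theta)
  fit0 <- suppressWarnings(glm(y ~ 1 + offset(off), family = fam))
  fit1 <- suppressWarnings(glm(y ~ grp + offset(off), family = fam))
  lr <- max(0, fit0$deviance - fit1$deviance)
  pchisq(lr, df = 1, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a p-value vector.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @return adjusted p-values (same order), capped at 1.
#' @export
adjust_bh <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must be in [0, 1] and non-missing")
  }
  p.adjust(p_values, method = "BH")
}

#' Remove hormone genes and renormalize
#'
#' Drops the hormone genes from a count matrix and recomputes the TPM layer
#' over the remaining genes, so that highly expressed hormones cannot bias
#' differential expression of other genes.
#'
#' @param cm a `CountMatrix`.
#' @param hormones character vector of hormone gene identifiers.
#' @return list with `counts` (hormone-free `CountMatrix`) and `tpm`
#'   (renormalized `ExpressionMatrix`).
#' @export
prepare_hormone_free <- function(cm, hormones) {
  stopifnot(inherits(cm, "CountMatrix"))
  present <- intersect(hormones, genes(cm))
  if (length(present) == 0) {
    warning("no hormone gene present in the matrix; returning input")
    return(list(counts = cm, tpm = suppressWarnings(tpm_normalize(cm))))
  }
  keep <- setdiff(genes(cm), present)
  cm2 <- subset_counts(cm, genes = keep)
  list(counts = cm2, tpm = suppressWarnings(tpm_normalize(cm2)))
}

# internal: AUC of x as a classifier of membership in the positive group,
# computed from the rank-sum statistic (ties get average ranks, i.e. count
# one half).
.rank_auc <- function(x_pos, x_neg) {
  n1 <- length(x_pos)
  n2 <- length(x_neg)
  r <- rank(c(x_pos, x_neg))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' ROC-based marker-gene discovery
#'
#' For each cell type, genes passing an absolute mean log-expression
#' difference pre-filter are scored by the AUC of their expression as a
#' classifier of type membership (one type versus rest); genes with AUC
#' strictly above `auc_min` are markers.
#'
#' @param em `ExpressionMatrix` (`log_tpm`).
#' @param labels character vector of cell-type labels parallel to the
#'   barcodes.
#' @param types which types to score (default: all labels with >= 3 cells).
#' @param auc_min AUC threshold (default 0.75, strict `>`).
#' @param min_logfc pre-filter on the absolute difference of mean log
#'   expression (default 0.7, natural-log scale).
#' @return data.frame `cell_type`, `gene`, `auc`, `log_fold_change`.
#' @export
roc_markers <- function(em, labels, types = NULL, auc_min = 0.75,
                        min_logfc = 0.7) {
  stopifnot(inherits(em, "ExpressionMatrix"), em$layer == "log_tpm",
            length(labels) == ncol(em$values))
  if (is.null(types)) {
    tab <- table(labels)
    types <- names(tab)[tab >= 3]
  }
  x <- as.matrix(em$values)
  out <- list()
  for (ty in types) {
    pos <- labels == ty
    if (sum(pos) < 3) stop("type '", ty, "' has fewer than 3 cells")
    d <- rowMeans(x[, pos, drop = FALSE]) - rowMeans(x[, !pos, drop = FALSE])
    cand <- names(d)[abs(d) >= min_logfc]
    if (length(cand) == 0) next
    auc <- vapply(cand, function(g) .rank_auc(x[g, pos], x[g, !pos]),
                  numeric(1))
    keep <- auc > auc_min
    if (!any(keep)) next
    out[[ty]] <- data.frame(cell_type = ty, gene = cand[keep],
                            auc = unname(auc[keep]),
                            log_fold_change = unname(d[cand[keep]]),
                            stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(cell_type = character(), gene = character(),
                      auc = numeric(), log_fold_change = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Correlate cells to cell-type signatures
#'
#' Spearman correlation of each cell to mean cell-type profiles over the
#' union of marker genes (hormone genes should be excluded from
#' `marker_genes` beforehand so correlations are not driven by the defining
#' hormones).
#'
#' @param em `ExpressionMatrix` (`log_tpm`).
#' @param marker_genes character vector of marker genes (union over
#'   signatures, hormones excluded).
#' @param mean_profiles genes x signatures matrix of mean log-TPM values
#'   from control-condition cells of each type.
#' @return cells x signatures matrix of Spearman correlations.
#' @export
signature_correlation <- function(em, marker_genes, mean_profiles) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  g <- Reduce(intersect, list(marker_genes, rownames(mean_profiles),
                              genes(em)))
  if (length(g) < 5) stop("fewer than 5 usable marker genes")
  cor(as.matrix(em$values[g, , drop = FALSE]),
      mean_profiles[g, , drop = FALSE], method = "spearman")
}

#' Hormone-positive fraction curve
#'
#' Inverse cumulative distribution: for each expression level `t` in the
#' grid, the fraction of cells expressing strictly above `t`. Monotone
#' non-increasing in `t`.
#'
#' @param expression numeric vector of per-cell expression values for one
#'   hormone in one cell population.
#' @param grid expression levels at which to evaluate the curve.
#' @return data.frame `threshold`, `fraction`.
#' @export
hormone_positive_fraction <- function(expression, grid) {
  if (length(expression) == 0) stop("empty cell set")
  data.frame(threshold = grid,
             fraction = vapply(grid, function(t) mean(expression > t),
                               numeric(1)))
}

#' Compare fold changes across species through one-to-one orthologs
#'
#' Joins two differential-expression tables through an ortholog map
#' restricted to strictly one-to-one pairs (genes appearing in more than one
#' pair are excluded), keeps genes significant in either species, and
#' reports the Spearman correlation of the log fold changes.
#'
#' @param de_a,de_b data.frames from [nb_test()] (columns `gene`,
#'   `log_fold_change`, `significant`).
#' @param ortholog_map data.frame whose first two columns pair species-a and
#'   species-b gene identifiers.
#' @param significant_only keep only genes significant in either table
#'   (default TRUE).
#' @return list with `table` (paired fold changes), `rho` (Spearman
#'   correlation), `n`.
#' @export
compare_species <- function(de_a, de_b, ortholog_map,
                            significant_only = TRUE) {
  map <- ortholog_map[, 1:2]
  names(map) <- c("gene_a", "gene_b")
  map <- map[!(duplicated(map$gene_a) | duplicated(map$gene_a,
                                                   fromLast = TRUE) |
                 duplicated(map$gene_b) | duplicated(map$gene_b,
                                                     fromLast = TRUE)), ,
             drop = FALSE]
  tab <- merge(map,
               de_a[, c("gene", "log_fold_change", "significant")],
               by.x = "gene_a", by.y = "gene")
  tab <- merge(tab,
               de_b[, c("gene", "log_fold_change", "significant")],
               by.x = "gene_b", by.y = "gene",
               suffixes = c("_a", "_b"))
  if (significant_only) {
    tab <- tab[tab$significant_a | tab$significant_b, , drop = FALSE]
  }
  if (nrow(tab) == 0) stop("empty ortholog join")
  rho <- cor(tab$log_fold_change_a, tab$log_fold_change_b,
             method = "spearman")
  list(table = tab, rho = rho, n = nrow(tab))
}
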