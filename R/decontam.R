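# Core decontamination method. Contamination is modeled as a shared
# per-sample transcriptional signature S_c added to every cell's own
# signature in a cell-specific proportion f_c:
#
#   observed_cell = (1 - f_c) * true_cell + f_c * S_c   (on the TPM scale)
#
# Cross-species spike-ins give direct access to both quantities: reads on the
# sample genome inside a spike-in are contamination, so f_c is measured as a
# read fraction, and S_c is recovered by comparing contaminated spike-ins to
# clean reference profiles. For ordinary cells f_c is predicted from the most
# contaminating marker genes with per-gene no-intercept linear models.

#' Measure contamination fractions in cross-species spike-ins
#'
#' For barcodes labeled `spikein_species`, the contamination fraction is the
#' fraction of reads aligned to the sample genome over all aligned reads in
#' the combined alignment.
#'
#' @param calls data.frame from [assign_species()].
#' @return data.frame with `barcode`, `f_c`, `source = "measured"`.
#' @export
measure_fc <- function(calls) {
  stopifnot(is.data.frame(calls),
            all(c("barcode", "reads_sample", "reads_spikein", "label")
                %in% names(calls)))
  sub <- calls[calls$label == "spikein_species", , drop = FALSE]
  total <- sub$reads_sample + sub$reads_spikein
  if (any(total == 0)) stop("spike-in barcode with zero aligned reads")
  data.frame(barcode = sub$barcode,
             f_c = sub$reads_sample / total,
             source = "measured",
             stringsAsFactors = FALSE)
}

#' Estimate the per-sample contamination signature
#'
#' Per spike-in cell, sample-genome expression (TPM) is divided by
#' `1 - f_c` and the clean reference profile is subtracted; negative entries
#' are set to zero and the remainder is scaled back to the TPM scale (sum
#' 1e6). These per-cell contamination vectors are then averaged and the mean
#' renormalized to 1e6, giving one signature per sample.
#'
#' @param em_spikeins `ExpressionMatrix` (`layer = "tpm"`) of cross-species
#'   spike-ins over sample-species genes.
#' @param f_c_measured measured fractions: data.frame from [measure_fc()] or
#'   a named numeric vector.
#' @param reference clean spike-in reference profile on the same gene space
#'   (TPM; named vector, matrix, or `ExpressionMatrix`). Genes absent from
#'   the reference are treated as zero (fully attributable to contamination).
#' @param min_spikeins minimum usable spike-ins (default 20).
#' @return object of class `ContaminationSignature`: list with `sample_id`
#'   and `s_c`, a named non-negative vector summing to 1e6.
#' @export
estimate_signature <- function(em_spikeins, f_c_measured, reference,
                               min_spikeins = 20) {
  stopifnot(inherits(em_spikeins, "ExpressionMatrix"),
            em_spikeins$layer == "tpm")
  fc <- .as_fc_vector(f_c_measured)
  use <- intersect(barcodes(em_spikeins), names(fc))
  if (length(use) < min_spikeins) {
    stop("only ", length(use), " usable spike-ins (< ", min_spikeins, ")")
  }
  fc <- fc[use]
  if (any(fc >= 1)) stop("f_c must be < 1 for signature estimation")

  g <- genes(em_spikeins)
  ref <- .as_profile_vector(reference)
  refv <- setNames(numeric(length(g)), g)
  shared <- intersect(g, names(ref))
  refv[shared] <- ref[shared]

  x <- as.matrix(em_spikeins$values[, use, drop = FALSE])
  contam <- sweep(x, 2, 1 - fc, "/") - refv
  contam[contam < 0] <- 0
  cs <- colSums(contam)
  nonzero <- cs > 0
  contam[, nonzero] <- sweep(contam[, nonzero, drop = FALSE], 2,
                             cs[nonzero], "/") * 1e6
  if (!any(nonzero)) {
    stop("no contamination detected in any spike-in; empty signature")
  }
  s <- rowMeans(contam)
  s <- s / sum(s) * 1e6
  structure(list(sample_id = em_spikeins$sample_id, s_c = s),
            class = "ContaminationSignature")
}

#' @export
print.ContaminationSignature <- function(x, ...) {
  top <- head(sort(x$s_c, decreasing = TRUE), 5)
  cat(sprintf("ContaminationSignature '%s' over %d genes; top genes: %s\n",
              x$sample_id, length(x$s_c),
              paste(sprintf("%s (%.0f)", names(top), top), collapse = ", ")))
  invisible(x)
}

# internal: coerce ContaminationSignature or named vector to named numeric
.as_signature_vector <- function(s_c) {
  if (inherits(s_c, "ContaminationSignature")) s_c$s_c
  else {
    stopifnot(is.numeric(s_c), !is.null(names(s_c)))
    s_c
  }
}

#' Select predictor genes from the contamination signature
#'
#' Intersects a configured marker-gene list with the 100 most contaminating
#' genes (largest signature entries); the result is ordered by decreasing
#' signature contribution.
#'
#' @param s_c a `ContaminationSignature` (or named vector).
#' @param configured_markers character vector of candidate marker genes.
#' @param top_n how many top signature genes to intersect with (default 100).
#' @return character vector of selected genes.
#' @export
select_predictor_genes <- function(s_c, configured_markers, top_n = 100) {
  s <- .as_signature_vector(s_c)
  top <- names(sort(s, decreasing = TRUE))[seq_len(min(top_n, length(s)))]
  sel <- top[top %in% configured_markers]
  if (length(sel) == 0) {
    stop("no configured marker gene among the top ", top_n,
         " contaminating genes")
  }
  sel
}

#' Fit the per-gene contamination-fraction predictor
#'
#' For each selected gene, a linear model without intercept regresses the
#' measured f_c of the spike-ins on the gene's TPM. Negative slopes are
#' unphysical and clipped to zero with a warning; all-zero genes are dropped.
#' Predictions are the per-cell median of the per-gene predictions, clipped
#' to `[0, cap]`.
#'
#' @param em_spikeins `ExpressionMatrix` (tpm) of spike-ins over
#'   sample-species genes.
#' @param f_c_measured measured fractions ([measure_fc()] output or named
#'   vector).
#' @param predictor_genes genes from [select_predictor_genes()].
#' @param cap prediction cap: 0.1 when the sample species is human, 0.2 when
#'   mouse (default 0.1).
#' @return object of class `FcPredictor` with `genes`, `slopes`, `cap`.
#' @export
fit_fc_predictor <- function(em_spikeins, f_c_measured, predictor_genes,
                             cap = 0.1) {
  stopifnot(inherits(em_spikeins, "ExpressionMatrix"),
            em_spikeins$layer == "tpm")
  fc <- .as_fc_vector(f_c_measured)
  use <- intersect(barcodes(em_spikeins), names(fc))
  if (length(use) < 3) stop("need at least 3 spike-ins to fit the predictor")
  fc <- fc[use]
  missing <- setdiff(predictor_genes, genes(em_spikeins))
  if (length(missing)) stop("predictor genes absent from matrix: ",
                            paste(missing, collapse = ", "))
  x <- as.matrix(em_spikeins$values[predictor_genes, use, drop = FALSE])

  slopes <- numeric(0)
  for (g in predictor_genes) {
    xg <- x[g, ]
    if (all(xg == 0)) {
      warning("gene ", g, " has all-zero expression; dropped from predictor")
      next
    }
    b <- unname(coef(lm(fc ~ 0 + xg))[1])
    if (b < 0) {
      warning("negative fitted slope for ", g, " clipped to 0")
      b <- 0
    }
    slopes[g] <- b
  }
  if (length(slopes) == 0) stop("no usable predictor gene")
  structure(list(genes = names(slopes), slopes = slopes, cap = cap,
                 aggregation = "median"),
            class = "FcPredictor")
}

#' @export
print.FcPredictor <- function(x, ...) {
  cat(sprintf("FcPredictor: %d genes, cap %.2f, median aggregation\n",
              length(x$genes), x$cap))
  invisible(x)
}

#' Predict contamination fractions for all cells
#'
#' Per cell, the median over predictor genes of `slope * TPM`, clipped to
#' `[0, cap]`.
#'
#' @param em `ExpressionMatrix` (tpm) over sample-species genes.
#' @param predictor an `FcPredictor`.
#' @return data.frame with `barcode`, `f_c`, `source = "predicted"`.
#' @export
predict_fc <- function(em, predictor) {
  stopifnot(inherits(em, "ExpressionMatrix"), em$layer == "tpm",
            inherits(predictor, "FcPredictor"))
  missing <- setdiff(predictor$genes, genes(em))
  if (length(missing)) stop("predictor genes absent from matrix: ",
                            paste(missing, collapse = ", "))
  x <- as.matrix(em$values[predictor$genes, , drop = FALSE])
  preds <- x * predictor$slopes
  f <- apply(preds, 2, median)
  f <- pmin(pmax(f, 0), predictor$cap)
  data.frame(barcode = barcodes(em), f_c = unname(f), source = "predicted",
             stringsAsFactors = FALSE)
}

#' Cross-validated contamination-fraction prediction
#'
#' Splits spike-ins into folds, refits the per-gene slopes on the training
#' folds and predicts the held-out cells, so every spike-in receives an
#' out-of-sample prediction.
#'
#' @inheritParams fit_fc_predictor
#' @param folds number of folds (default 3).
#' @param seed RNG seed for the fold shuffle.
#' @return data.frame `barcode`, `f_c_measured`, `f_c_predicted` with the
#'   Pearson correlation in attribute `"r"`.
#' @export
crossval_fc_predictor <- function(em_spikeins, f_c_measured, predictor_genes,
                                  cap = 0.1, folds = 3, seed = 1) {
  fc <- .as_fc_vector(f_c_measured)
  use <- intersect(barcodes(em_spikeins), names(fc))
  if (length(use) < folds) stop("fewer spike-ins than folds")
  fc <- fc[use]
  set.seed(seed)
  ord <- sample(use)
  fold_id <- setNames(rep(seq_len(folds), length.out = length(ord)), ord)

  pred <- setNames(numeric(length(use)), use)
  for (k in seq_len(folds)) {
    test_bc <- names(fold_id)[fold_id == k]
    train_bc <- setdiff(use, test_bc)
    em_train <- expression_matrix(
      em_spikeins$values[, train_bc, drop = FALSE], layer = "tpm",
      sample_id = em_spikeins$sample_id, check = FALSE)
    em_test <- expression_matrix(
      em_spikeins$values[, test_bc, drop = FALSE], layer = "tpm",
      sample_id = em_spikeins$sample_id, check = FALSE)
    p <- fit_fc_predictor(em_train, fc[train_bc], predictor_genes, cap = cap)
    out <- predict_fc(em_test, p)
    pred[out$barcode] <- out$f_c
  }
  res <- data.frame(barcode = use, f_c_measured = unname(fc[use]),
                    f_c_predicted = unname(pred[use]),
                    stringsAsFactors = FALSE)
  attr(res, "r") <- cor(res$f_c_measured, res$f_c_predicted)
  res
}

#' Correct expression values for ambient contamination
#'
#' Subtracts `f_c * S_c` from each cell's TPM values, sets negative values to
#' zero, and rescales every non-empty column back to the TPM scale.
#'
#' @param em `ExpressionMatrix` (tpm).
#' @param f_c per-cell fractions covering every barcode (data.frame or named
#'   vector; measured for spike-ins, predicted elsewhere).
#' @param s_c `ContaminationSignature` (or named vector). Its genes must all
#'   be present in `em`; genes of `em` missing from the signature are treated
#'   as zero contamination.
#' @return corrected `ExpressionMatrix` (tpm).
#' @export
correct_expression <- function(em, f_c, s_c) {
  stopifnot(inherits(em, "ExpressionMatrix"), em$layer == "tpm")
  fc <- .as_fc_vector(f_c)
  s <- .as_signature_vector(s_c)
  bc <- barcodes(em)
  if (!all(bc %in% names(fc))) {
    stop("f_c missing for ", sum(!(bc %in% names(fc))), " barcode(s)")
  }
  fc <- fc[bc]
  g <- genes(em)
  if (!all(names(s) %in% g)) {
    stop("signature gene space does not match expression matrix")
  }
  sv <- setNames(numeric(length(g)), g)
  sv[names(s)] <- s

  x <- as.matrix(em$values)
  x <- x - outer(sv, unname(fc))
  x[x < 0] <- 0
  cs <- colSums(x)
  nz <- cs > 0
  x[, nz] <- sweep(x[, nz, drop = FALSE], 2, cs[nz], "/") * 1e6
  expression_matrix(x, layer = "tpm", sample_id = em$sample_id, check = FALSE)
}

#' Evaluate correction against a clean reference
#'
#' Per-cell Pearson correlation of raw and corrected expression to a clean
#' reference profile of the evaluated population.
#'
#' @param em_raw,em_corrected `ExpressionMatrix` objects over the same cells.
#' @param reference clean profile (named vector, matrix, or
#'   `ExpressionMatrix`).
#' @return data.frame `barcode`, `r_raw`, `r_corrected`.
#' @export
evaluate_correction <- function(em_raw, em_corrected, reference) {
  stopifnot(inherits(em_raw, "ExpressionMatrix"),
            inherits(em_corrected, "ExpressionMatrix"))
  bc <- intersect(barcodes(em_raw), barcodes(em_corrected))
  ref <- .as_profile_vector(reference)
  shared <- Reduce(intersect, list(genes(em_raw), genes(em_corrected),
                                   names(ref)))
  if (length(shared) < 3) stop("too few shared genes for evaluation")
  r_raw <- as.numeric(cor(as.matrix(em_raw$values[shared, bc, drop = FALSE]),
                          ref[shared]))
  r_cor <- as.numeric(cor(
    as.matrix(em_corrected$values[shared, bc, drop = FALSE]), ref[shared]))
  data.frame(barcode = bc, r_raw = r_raw, r_corrected = r_cor,
             stringsAsFactors = FALSE)
}
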