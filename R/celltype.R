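# Cell-type assignment: hormone-threshold rules for clear representatives,
# an L1-regularized multinomial classifier for everything else, and two
# doublet filters (class-probability ratio, detected-gene count).

#' Assign endocrine cell types by hormone thresholds
#'
#' Cells exceeding the log-TPM threshold for exactly one hormone gene are
#' clear representatives of the corresponding type (insulin -> beta,
#' glucagon -> alpha, somatostatin -> delta, pancreatic polypeptide ->
#' gamma). Cells above the threshold for zero or for two or more hormones
#' are labeled `endocrine_unassigned`. The comparison is strict.
#'
#' @param em_corrected `ExpressionMatrix` with `layer = "log_tpm"`
#'   (contamination-corrected).
#' @param hormones named character vector mapping labels to gene identifiers,
#'   e.g. `c(beta = "INS", alpha = "GCG", delta = "SST", gamma = "PPY")`
#'   (use prefixed identifiers where applicable).
#' @param threshold log-TPM threshold (default 7.5, strict `>`).
#' @return data.frame `barcode`, `label`, `assigned_by` (`"hormone"` or NA).
#' @export
assign_by_hormone <- function(em_corrected,
                              hormones = c(beta = "INS", alpha = "GCG",
                                           delta = "SST", gamma = "PPY"),
                              threshold = 7.5) {
  stopifnot(inherits(em_corrected, "ExpressionMatrix"),
            em_corrected$layer == "log_tpm")
  missing <- setdiff(hormones, genes(em_corrected))
  if (length(missing)) {
    stop("hormone genes absent from matrix: ", paste(missing, collapse = ", "))
  }
  h <- as.matrix(em_corrected$values[hormones, , drop = FALSE])
  above <- h > threshold
  n_above <- colSums(above)
  label <- rep("endocrine_unassigned", ncol(h))
  one <- n_above == 1
  label[one] <- names(hormones)[apply(above[, one, drop = FALSE], 2, which)]
  data.frame(barcode = barcodes(em_corrected),
             label = label,
             assigned_by = ifelse(one, "hormone", NA_character_),
             stringsAsFactors = FALSE)
}

#' Assign acinar-like cells by a marker threshold
#'
#' Relabels still-unassigned cells whose marker gene (REG1A by default)
#' exceeds the log-TPM threshold. This replaces a cluster-level assignment
#' with a direct per-cell rule.
#'
#' @param em `ExpressionMatrix` (`log_tpm`).
#' @param assignments data.frame from [assign_by_hormone()].
#' @param gene marker gene identifier (default `"REG1A"`).
#' @param threshold log-TPM threshold (default 7.5, strict `>`).
#' @param label label to assign (default `"acinar_like"`).
#' @return updated assignments data.frame.
#' @export
assign_acinar_like <- function(em, assignments, gene = "REG1A",
                               threshold = 7.5, label = "acinar_like") {
  stopifnot(inherits(em, "ExpressionMatrix"), em$layer == "log_tpm")
  if (!gene %in% genes(em)) stop("marker gene absent from matrix: ", gene)
  x <- setNames(as.numeric(em$values[gene, ]), barcodes(em))
  hit <- assignments$label == "endocrine_unassigned" &
    x[assignments$barcode] > threshold
  assignments$label[hit] <- label
  assignments$assigned_by[hit] <- "hormone"
  assignments
}

#' Subsample training cells for the classifier
#'
#' Restricts to control-condition cells of classes with strictly more than
#' `min_class_size` control representatives, then subsamples to at most
#' `max_per_class_sample` cells per (class, sample) to reduce class
#' imbalance. Deterministic given the seed.
#'
#' @param assignments data.frame with `barcode`, `label`, `assigned_by`
#'   (only `assigned_by == "hormone"` cells are eligible).
#' @param sample_id,treatment character vectors parallel to
#'   `assignments` rows (or length-1, recycled).
#' @param control treatment label of the control condition (default
#'   `"DMSO"`).
#' @param max_per_class_sample cap per (class, sample) (default 100).
#' @param min_class_size minimum control-class size (exclusive; default 50).
#' @param seed RNG seed.
#' @return data.frame `barcode`, `label` of training cells.
#' @export
subsample_training <- function(assignments, sample_id = "sample",
                               treatment = "DMSO", control = "DMSO",
                               max_per_class_sample = 100,
                               min_class_size = 50, seed = 1) {
  n <- nrow(assignments)
  sample_id <- rep_len(sample_id, n)
  treatment <- rep_len(treatment, n)
  eligible <- !is.na(assignments$assigned_by) &
    assignments$assigned_by == "hormone" &
    treatment == control
  df <- assignments[eligible, c("barcode", "label")]
  df$sample_id <- sample_id[eligible]

  sizes <- table(df$label)
  keep_classes <- names(sizes)[sizes > min_class_size]
  if (length(keep_classes) == 0) {
    stop("no class has more than ", min_class_size, " control representatives")
  }
  df <- df[df$label %in% keep_classes, , drop = FALSE]

  set.seed(seed)
  picked <- unlist(lapply(split(seq_len(nrow(df)),
                                list(df$label, df$sample_id), drop = TRUE),
                          function(idx) {
    if (length(idx) > max_per_class_sample) {
      sample(idx, max_per_class_sample)
    } else idx
  }), use.names = FALSE)
  out <- df[sort(picked), c("barcode", "label")]
  rownames(out) <- NULL
  out
}

#' Train the marker-free cell-type classifier
#'
#' Fits an L1-penalized (lasso) multinomial logistic regression on the
#' training cells, with the penalty strength chosen by 5-fold
#' cross-validated deviance. The hormone genes used to define the training
#' labels are removed from the feature space before fitting, so the
#' classifier is marker-free by construction.
#'
#' @param em `ExpressionMatrix` (`log_tpm`) covering the training barcodes.
#' @param training data.frame `barcode`, `label` from
#'   [subsample_training()].
#' @param exclude_genes genes removed from the feature space (the four
#'   hormone genes).
#' @param nfolds cross-validation folds (default 5).
#' @param alpha elastic-net mixing parameter (default 1 = lasso).
#' @param lambda which penalty to use at prediction time
#'   (`"lambda.1se"` default, or `"lambda.min"`).
#' @param seed RNG seed for fold assignment.
#' @return object of class `CellTypeClassifier`.
#' @export
train_classifier <- function(em, training, exclude_genes = character(),
                             nfolds = 5, alpha = 1, lambda = "lambda.1se",
                             seed = 1) {
  stopifnot(inherits(em, "ExpressionMatrix"), em$layer == "log_tpm")
  y <- factor(training$label)
  if (nlevels(y) < 2) stop("need at least 2 classes to train a classifier")
  features <- setdiff(genes(em), exclude_genes)
  x <- Matrix::t(em$values[features, training$barcode, drop = FALSE])
  set.seed(seed)
  fit <- glmnet::cv.glmnet(x, y, family = "multinomial", alpha = alpha,
                           nfolds = nfolds)
  structure(list(fit = fit, classes = levels(y), features = features,
                 excluded_genes = exclude_genes, lambda = lambda),
            class = "CellTypeClassifier")
}

#' @export
print.CellTypeClassifier <- function(x, ...) {
  cat(sprintf("CellTypeClassifier: %d classes (%s), %d features, %d excluded\n",
              length(x$classes), paste(x$classes, collapse = ", "),
              length(x$features), length(x$excluded_genes)))
  invisible(x)
}

#' Non-zero classifier coefficients
#'
#' @param model a `CellTypeClassifier`.
#' @return named list (per class) of named numeric vectors of non-zero gene
#'   coefficients (intercept excluded).
#' @export
classifier_coefficients <- function(model) {
  stopifnot(inherits(model, "CellTypeClassifier"))
  cf <- coef(model$fit, s = model$lambda)
  lapply(cf, function(m) {
    v <- as.numeric(m)
    names(v) <- rownames(m)
    v <- v[names(v) != "(Intercept)"]
    v[v != 0]
  })
}

#' Predict cell types with class probabilities
#'
#' Computes the class-probability vector for every cell and the argmax
#' label. Labels already assigned by the hormone rule are never overwritten:
#' only `endocrine_unassigned` cells are relabeled when `assignments` is
#' supplied.
#'
#' @param model a `CellTypeClassifier`.
#' @param em `ExpressionMatrix` (`log_tpm`). Feature mismatches are resolved
#'   by intersection with zero fill (logged as a message).
#' @param assignments optional data.frame from [assign_by_hormone()]; when
#'   given, a `label` column with the merged (no-overwrite) labels is
#'   returned.
#' @return list with `barcode`, `probs` (cells x classes matrix, rows sum to
#'   1), `predicted` (argmax label), and `label` (merged labels if
#'   `assignments` given).
#' @export
predict_celltype <- function(model, em, assignments = NULL) {
  stopifnot(inherits(model, "CellTypeClassifier"),
            inherits(em, "ExpressionMatrix"), em$layer == "log_tpm")
  bc <- barcodes(em)
  present <- intersect(model$features, genes(em))
  if (length(present) < length(model$features)) {
    message(length(model$features) - length(present),
            " classifier feature(s) absent from matrix; zero-filled")
  }
  x <- Matrix::Matrix(0, nrow = length(bc), ncol = length(model$features),
                      dimnames = list(bc, model$features), sparse = TRUE)
  x[, present] <- Matrix::t(em$values[present, , drop = FALSE])
  pr <- predict(model$fit, newx = x, s = model$lambda, type = "response")
  probs <- matrix(pr[, , 1], nrow = length(bc),
                  dimnames = list(bc, dimnames(pr)[[2]]))
  predicted <- colnames(probs)[max.col(probs, ties.method = "first")]
  out <- list(barcode = bc, probs = probs, predicted = predicted)
  if (!is.null(assignments)) {
    lab <- setNames(assignments$label, assignments$barcode)[bc]
    relabel <- !is.na(lab) & lab == "endocrine_unassigned"
    lab[relabel] <- predicted[relabel]
    out$label <- unname(lab)
    out$assigned_by <- unname(ifelse(relabel, "classifier",
                                     setNames(assignments$assigned_by,
                                              assignments$barcode)[bc]))
  }
  out
}

#' Doublet filter by class-probability ratio
#'
#' A singlet should have high probability for exactly one class; a doublet
#' spreads probability over the classes of its constituent cells. Cells
#' whose ratio of highest to second-highest class probability is strictly
#' below `ratio_min` are flagged as doublets. With a second-highest
#' probability of exactly zero the ratio is infinite and the cell is kept.
#'
#' @param probs cells x classes probability matrix (rows sum to 1).
#' @param ratio_min minimum p1/p2 ratio (default 3, strict `<` flags).
#' @return named logical vector, TRUE = flagged doublet.
#' @export
filter_doublets_probability <- function(probs, ratio_min = 3) {
  stopifnot(is.matrix(probs))
  if (ncol(probs) < 2) {
    return(setNames(rep(FALSE, nrow(probs)), rownames(probs)))
  }
  flags <- apply(probs, 1, function(p) {
    p <- sort(p, decreasing = TRUE)
    p[2] > 0 && (p[1] / p[2]) < ratio_min
  })
  setNames(as.logical(flags), rownames(probs))
}

# internal: mode of the kernel-density estimate of x (Gaussian kernel,
# Silverman bandwidth, grid spanning the data range); degenerate groups with
# a single distinct value return that value. In bimodal groups the
# higher-density peak wins.
.density_mode <- function(x, bw = "nrd0", n_grid = 512) {
  if (length(unique(x)) == 1) return(x[1])
  d <- density(x, bw = bw, n = n_grid, from = min(x), to = max(x))
  d$x[which.max(d$y)]
}

#' Doublet filter by detected-gene count
#'
#' Within each (cell type, sample) group, the expected number of detected
#' genes is the mode of a kernel-density estimate of `n_genes`; cells with
#' strictly more than twice the expected value are flagged. Groups smaller
#' than `min_group_size` are skipped with a warning (no cell flagged).
#'
#' @param n_genes named numeric vector of detected genes per cell.
#' @param group character/factor vector parallel to `n_genes` giving the
#'   (cell type, sample) group of each cell.
#' @param min_group_size minimum group size (default 30).
#' @param multiplier flag cells with `n_genes > multiplier * mode`
#'   (default 2).
#' @param bw,n_grid kernel-density bandwidth rule and grid size.
#' @return named logical vector, TRUE = flagged doublet.
#' @export
filter_doublets_ngenes <- function(n_genes, group, min_group_size = 30,
                                   multiplier = 2, bw = "nrd0",
                                   n_grid = 512) {
  stopifnot(length(n_genes) == length(group))
  flags <- setNames(rep(FALSE, length(n_genes)), names(n_genes))
  for (idx in split(seq_along(n_genes), as.character(group))) {
    if (length(idx) < min_group_size) {
      warning("group with ", length(idx), " cells (< ", min_group_size,
              ") skipped by n_genes doublet filter")
      next
    }
    m <- .density_mode(n_genes[idx], bw = bw, n_grid = n_grid)
    flags[idx] <- n_genes[idx] > multiplier * m
  }
  flags
}
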