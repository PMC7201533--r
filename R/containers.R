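# Lightweight S3 containers for gene x barcode matrices. Counts are held as
# sparse dgCMatrix with gene identifiers in rownames and barcodes in colnames.

#' Construct a CountMatrix
#'
#' A `CountMatrix` holds non-negative integer UMI counts for genes (rows) by
#' droplet barcodes (columns), together with a sample identifier. Gene
#' identifiers may carry a species prefix (e.g. `"hs:INS"`, `"mm:Ins1"`) when
#' they originate from a combined two-species alignment.
#'
#' @param counts matrix or sparse Matrix of non-negative integral counts.
#' @param sample_id character scalar naming the sample.
#' @param genes,barcodes optional character vectors overriding the dimnames of
#'   `counts`; must be unique.
#' @return An object of class `CountMatrix`: a list with elements `counts`
#'   (dgCMatrix with dimnames), and `sample_id`.
#' @examples
#' m <- matrix(c(1, 0, 2, 3, 0, 0), nrow = 3,
#'             dimnames = list(c("g1", "g2", "g3"), c("b1", "b2")))
#' cm <- count_matrix(m, sample_id = "demo")
#' dim(cm)
#' @export
count_matrix <- function(counts, sample_id = "sample",
                         genes = rownames(counts),
                         barcodes = colnames(counts)) {
  counts <- as(as(as(Matrix(counts, sparse = TRUE), "dMatrix"),
                  "generalMatrix"), "CsparseMatrix")
  if (is.null(genes)) {
    if (nrow(counts) > 0) {
      stop("counts must have gene names (rownames)")
    }
    genes <- character()
  }
  if (is.null(barcodes)) {
    if (ncol(counts) > 0) {
      stop("counts must have barcode names (colnames)")
    }
    barcodes <- character()
  }
  if (length(genes) != nrow(counts) || length(barcodes) != ncol(counts)) {
    stop("gene/barcode name lengths do not match matrix dimensions")
  }
  if (anyDuplicated(genes)) stop("gene identifiers must be unique")
  if (anyDuplicated(barcodes)) stop("barcodes must be unique within a sample")
  if (length(counts@x) && any(counts@x < 0)) stop("counts must be non-negative")
  if (length(counts@x) && any(counts@x != round(counts@x))) {
    stop("counts must be integral")
  }
  dimnames(counts) <- list(as.character(genes), as.character(barcodes))
  structure(list(counts = counts, sample_id = sample_id),
            class = "CountMatrix")
}

#' Construct an ExpressionMatrix
#'
#' An `ExpressionMatrix` holds a normalized expression layer derived from a
#' [count_matrix()]: either transcripts-per-million (`"tpm"`, every non-empty
#' cell column sums to 1e6) or its natural-log transform
#' (`"log_tpm"`, values `log(TPM + 1)`).
#'
#' @param values numeric matrix or sparse Matrix (genes x barcodes) with
#'   dimnames.
#' @param layer `"tpm"` or `"log_tpm"`.
#' @param sample_id character scalar.
#' @param check validate the TPM column-sum contract (default TRUE).
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, layer = c("tpm", "log_tpm"),
                              sample_id = "sample", check = TRUE) {
  layer <- match.arg(layer)
  values <- as(as(as(Matrix(values, sparse = TRUE), "dMatrix"),
                  "generalMatrix"), "CsparseMatrix")
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must have gene and barcode names")
  }
  if (length(values@x) && any(values@x < 0)) stop("values must be non-negative")
  if (check && layer == "tpm") {
    cs <- Matrix::colSums(values)
    bad <- cs > 0 & abs(cs - 1e6) > 1e-6 * 1e6
    if (any(bad)) {
      stop("tpm layer: ", sum(bad), " column(s) do not sum to 1e6")
    }
  }
  structure(list(values = values, layer = layer, sample_id = sample_id),
            class = "ExpressionMatrix")
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Gene identifiers of a matrix container
#' @param x a `CountMatrix` or `ExpressionMatrix`.
#' @return character vector of gene identifiers.
#' @export
genes <- function(x) UseMethod("genes")

#' @export
genes.CountMatrix <- function(x) {
  g <- rownames(x$counts)
  if (is.null(g)) character() else g
}

#' @export
genes.ExpressionMatrix <- function(x) {
  g <- rownames(x$values)
  if (is.null(g)) character() else g
}

#' Barcodes of a matrix container
#' @param x a `CountMatrix` or `ExpressionMatrix`.
#' @return character vector of droplet barcodes.
#' @export
barcodes <- function(x) UseMethod("barcodes")

#' @export
barcodes.CountMatrix <- function(x) {
  b <- colnames(x$counts)
  if (is.null(b)) character() else b
}

#' @export
barcodes.ExpressionMatrix <- function(x) {
  b <- colnames(x$values)
  if (is.null(b)) character() else b
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix '%s': %d genes x %d barcodes (%.0f UMIs)\n",
              x$sample_id, nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix '%s' [%s]: %d genes x %d barcodes\n",
              x$sample_id, x$layer, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Subset a CountMatrix by genes and/or barcodes
#'
#' @param cm a `CountMatrix`.
#' @param genes,barcodes character vectors (or indices) to retain; NULL keeps
#'   all.
#' @return a `CountMatrix`.
#' @export
subset_counts <- function(cm, genes = NULL, barcodes = NULL) {
  stopifnot(inherits(cm, "CountMatrix"))
  m <- cm$counts
  if (!is.null(genes)) m <- m[genes, , drop = FALSE]
  if (!is.null(barcodes)) m <- m[, barcodes, drop = FALSE]
  count_matrix(m, sample_id = cm$sample_id)
}

# internal: accept a ContaminationFraction data.frame or a named numeric and
# return a named numeric vector of f_c
.as_fc_vector <- function(f_c) {
  if (is.data.frame(f_c)) {
    stopifnot(all(c("barcode", "f_c") %in% names(f_c)))
    setNames(f_c$f_c, f_c$barcode)
  } else {
    stopifnot(is.numeric(f_c), !is.null(names(f_c)))
    f_c
  }
}

# internal: accept an ExpressionMatrix, matrix, or named vector as a
# reference profile; return named numeric vector (mean over columns)
.as_profile_vector <- function(reference) {
  if (inherits(reference, "ExpressionMatrix")) {
    v <- Matrix::rowMeans(reference$values)
  } else if (is.matrix(reference) || is(reference, "Matrix")) {
    v <- Matrix::rowMeans(reference)
  } else {
    stopifnot(is.numeric(reference), !is.null(names(reference)))
    v <- reference
  }
  v
}
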