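# Reading/writing 10x-style MTX triplets, cell calling, and the TPM / log-TPM
# normalizations used throughout the pipeline.

.find_triplet_file <- function(dir, stems) {
  for (stem in stems) {
    for (ext in c("", ".gz")) {
      p <- file.path(dir, paste0(stem, ext))
      if (file.exists(p)) return(p)
    }
  }
  stop("no file matching '", paste(stems, collapse = "'/'"),
       "' found in ", dir)
}

.read_lines_maybe_gz <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  readLines(con)
}

#' Read a 10x-style MTX triplet
#'
#' Reads a directory containing a MatrixMarket `matrix.mtx`, a
#' `features.tsv` (or `genes.tsv`) and a `barcodes.tsv`, each optionally
#' gzip-compressed (detected by the `.gz` extension), into a
#' [count_matrix()].
#'
#' @param dir path to the directory holding the triplet.
#' @param sample_id sample identifier; defaults to the directory name.
#' @param gene_column which column of the features file to use as gene
#'   identifier (10x files carry id, name; default 1).
#' @return a `CountMatrix`.
#' @export
read_mtx <- function(dir, sample_id = basename(normalizePath(dir)),
                     gene_column = 1L) {
  if (!dir.exists(dir)) stop("directory not found: ", dir)
  mtx_path <- .find_triplet_file(dir, "matrix.mtx")
  feat_path <- .find_triplet_file(dir, c("features.tsv", "genes.tsv"))
  bc_path <- .find_triplet_file(dir, "barcodes.tsv")

  m <- if (grepl("\\.gz$", mtx_path)) {
    con <- gzfile(mtx_path, "rt")
    on.exit(close(con), add = TRUE)
    Matrix::readMM(con)
  } else {
    Matrix::readMM(mtx_path)
  }
  feat_lines <- .read_lines_maybe_gz(feat_path)
  bc <- .read_lines_maybe_gz(bc_path)
  feats <- strsplit(feat_lines, "\t", fixed = TRUE)
  gene_ids <- vapply(feats, function(f) {
    if (length(f) < gene_column) stop("features file has too few columns")
    f[[gene_column]]
  }, character(1))

  if (nrow(m) != length(gene_ids)) {
    stop(sprintf("dimension mismatch: matrix has %d rows but %d features",
                 nrow(m), length(gene_ids)))
  }
  if (ncol(m) != length(bc)) {
    stop(sprintf("dimension mismatch: matrix has %d columns but %d barcodes",
                 ncol(m), length(bc)))
  }
  m <- as(as(as(m, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (length(m@x) && any(m@x != round(m@x))) {
    stop("matrix contains non-integer entries")
  }
  dimnames(m) <- list(gene_ids, bc)
  count_matrix(m, sample_id = sample_id)
}

#' Write a CountMatrix as an MTX triplet
#'
#' Writes `matrix.mtx`, `features.tsv` (id and name columns) and
#' `barcodes.tsv` so that [read_mtx()] round-trips the object.
#'
#' @param cm a `CountMatrix`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_mtx <- function(cm, dir) {
  stopifnot(inherits(cm, "CountMatrix"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop("cannot create directory: ", dir)
  }
  Matrix::writeMM(cm$counts, file.path(dir, "matrix.mtx"))
  writeLines(paste(genes(cm), genes(cm), sep = "\t"),
             file.path(dir, "features.tsv"))
  writeLines(barcodes(cm), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Call cells from a raw barcode matrix
#'
#' Retains barcodes with strictly more than `min_umi` total UMIs and strictly
#' more than `min_genes` detected genes (count > 0) — barcodes at exactly the
#' threshold are dropped.
#'
#' @param cm a `CountMatrix` of all barcodes.
#' @param min_umi minimum total UMI count (exclusive; default 500).
#' @param min_genes minimum number of detected genes (exclusive; default 200).
#' @return a `CountMatrix` restricted to called cells (possibly 0 columns).
#' @export
call_cells <- function(cm, min_umi = 500, min_genes = 200) {
  stopifnot(inherits(cm, "CountMatrix"))
  umi <- Matrix::colSums(cm$counts)
  ngene <- Matrix::colSums(cm$counts > 0)
  keep <- umi > min_umi & ngene > min_genes
  count_matrix(cm$counts[, keep, drop = FALSE], sample_id = cm$sample_id)
}

#' Number of detected genes per barcode
#' @param cm a `CountMatrix`.
#' @return named integer vector (barcode -> genes with count > 0).
#' @export
n_genes_per_cell <- function(cm) {
  stopifnot(inherits(cm, "CountMatrix"))
  setNames(as.integer(Matrix::colSums(cm$counts > 0)), barcodes(cm))
}

#' Transcripts-per-million normalization
#'
#' Scales every non-empty cell column to sum to 1e6. All-zero columns are
#' left all-zero with a warning.
#'
#' @param cm a `CountMatrix`.
#' @return an `ExpressionMatrix` with `layer = "tpm"`.
#' @export
tpm_normalize <- function(cm) {
  stopifnot(inherits(cm, "CountMatrix"))
  cs <- Matrix::colSums(cm$counts)
  zero <- cs == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero cell(s) left unnormalized")
  }
  scale <- ifelse(zero, 0, 1e6 / cs)
  v <- cm$counts %*% Matrix::Diagonal(x = scale)
  dimnames(v) <- dimnames(cm$counts)
  expression_matrix(v, layer = "tpm", sample_id = cm$sample_id, check = FALSE)
}

#' Natural-log transform of a TPM layer
#'
#' Computes `log(TPM + 1)` (natural logarithm).
#'
#' @param em an `ExpressionMatrix` with `layer = "tpm"`.
#' @return an `ExpressionMatrix` with `layer = "log_tpm"`.
#' @export
log_transform <- function(em) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (em$layer != "tpm") stop("log_transform expects a tpm layer")
  v <- em$values
  v@x <- log1p(v@x)
  expression_matrix(v, layer = "log_tpm", sample_id = em$sample_id,
                    check = FALSE)
}
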