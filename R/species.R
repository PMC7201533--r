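# Species assignment from a combined two-species alignment, identification of
# same-species spike-ins by reference correlation, and the barcode-overlap
# index-switching check.

#' Assign barcodes to species from a combined-genome alignment
#'
#' Each barcode is labeled by the log2 ratio of UMIs on sample-species genes
#' to UMIs on spike-in-species genes (gene identifiers must carry the species
#' prefixes). A pseudocount is added to both totals so the ratio is defined
#' for one-sided barcodes. The cutoff is inclusive: `log2_ratio >= cutoff`
#' labels `sample_species`, `<= -cutoff` labels `spikein_species`, everything
#' in between is `ambiguous` (droplets containing material from both species)
#' and is excluded from all downstream estimation.
#'
#' @param cm_combined `CountMatrix` from the combined two-species alignment.
#' @param sample_prefix,spikein_prefix gene-identifier prefixes (default
#'   `"hs:"` and `"mm:"`).
#' @param cutoff absolute log2-ratio cutoff (default 2).
#' @param pseudocount added to both per-species totals (default 1).
#' @return data.frame with columns `barcode`, `reads_sample`,
#'   `reads_spikein`, `log2_ratio`, `label`.
#' @export
assign_species <- function(cm_combined, sample_prefix = "hs:",
                           spikein_prefix = "mm:", cutoff = 2,
                           pseudocount = 1) {
  stopifnot(inherits(cm_combined, "CountMatrix"))
  g <- genes(cm_combined)
  is_sample <- startsWith(g, sample_prefix)
  is_spike <- startsWith(g, spikein_prefix)
  if (!any(is_sample) || !any(is_spike)) {
    stop("no species-prefixed genes found for both '", sample_prefix,
         "' and '", spikein_prefix, "'")
  }
  rs <- Matrix::colSums(cm_combined$counts[is_sample, , drop = FALSE])
  rk <- Matrix::colSums(cm_combined$counts[is_spike, , drop = FALSE])
  ratio <- log2((rs + pseudocount) / (rk + pseudocount))
  label <- ifelse(ratio >= cutoff, "sample_species",
                  ifelse(ratio <= -cutoff, "spikein_species", "ambiguous"))
  data.frame(barcode = barcodes(cm_combined),
             reads_sample = as.numeric(rs),
             reads_spikein = as.numeric(rk),
             log2_ratio = as.numeric(ratio),
             label = label,
             stringsAsFactors = FALSE)
}

#' Identify same-species spike-ins by reference correlation
#'
#' Returns barcodes whose Pearson correlation (over the shared gene space) to
#' the mean clean spike-in profile exceeds `r_min`. Same-species spike-ins
#' cannot be separated by genome of alignment, but their homogeneous,
#' well-characterized transcriptome makes them stand out by correlation.
#'
#' @param em `ExpressionMatrix` (log-TPM recommended) of candidate cells.
#' @param reference_profile mean log-TPM profile of clean, externally
#'   sequenced spike-ins: a named numeric vector, a matrix of reference cells
#'   (averaged), or an `ExpressionMatrix`.
#' @param r_min Pearson correlation threshold (exclusive; default 0.9).
#' @return character vector of selected barcodes.
#' @export
identify_same_species_spikeins <- function(em, reference_profile,
                                           r_min = 0.9) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  ref <- .as_profile_vector(reference_profile)
  shared <- intersect(genes(em), names(ref))
  if (length(shared) < 10) {
    stop("fewer than 10 shared genes between cells and reference profile")
  }
  x <- as.matrix(em$values[shared, , drop = FALSE])
  r <- as.numeric(cor(x, ref[shared]))
  barcodes(em)[!is.na(r) & r > r_min]
}

#' Barcode overlap between two experiments
#'
#' Overlap index `|A n B| / min(|A|, |B|)` between two barcode sets, used to
#' check for index switching between libraries sequenced on the same lane
#' (true cross-sample contamination by index switching would require large
#' barcode overlap).
#'
#' @param barcodes_a,barcodes_b character vectors of barcodes.
#' @return overlap fraction in `[0, 1]`.
#' @export
barcode_overlap <- function(barcodes_a, barcodes_b) {
  a <- unique(barcodes_a)
  b <- unique(barcodes_b)
  if (length(a) == 0 || length(b) == 0) {
    stop("barcode overlap undefined for an empty set")
  }
  length(intersect(a, b)) / min(length(a), length(b))
}
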