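# Two-species droplet scRNA-seq simulator with ambient contamination,
# cross-species spike-ins, and doublets, emitting full ground truth.
#
# Each cell draws a library size L and a contamination fraction f_c and its
# counts are Multinomial(L, (1 - f_c) * program + f_c * ambient), where the
# ambient pool is one fixed per-sample vector over sample-species genes (the
# library-size-weighted mean of the clean sample-species cell programs, i.e.
# what lysing cells release in proportion to their RNA content). Spike-in
# cells use the other species' program, so every sample-genome read they
# carry is contamination by construction.

#' Simulation configuration
#'
#' Builds the configuration for [simulate_sample()]. Defaults emulate a
#' human islet sample with a mouse spike-in population: hormone genes
#' dominate endocrine cell programs (40% of a cell's transcripts from its
#' defining hormone), endocrine cells are a minority of the suspension so
#' that insulin and glucagon each account for roughly 5-6% of all reads,
#' spike-ins are ~5% of cells, and per-cell contamination fractions are
#' uniform on 0.02-0.2 (reaching the ~20% worst case seen in primary
#' tissue).
#'
#' @param n_cells named integer vector of sample-species cells per type.
#'   Endocrine types among `alpha`, `beta`, `delta`, `gamma` get a dominant
#'   hormone; `ductal` is the non-endocrine type.
#' @param n_genes_sample,n_genes_spikein genes per species (default 2000).
#' @param spikein_fraction fraction of all cells that are spike-ins
#'   (default 0.05); `n_spikeins` overrides the implied count.
#' @param n_spikeins explicit spike-in cell count (default NULL).
#' @param fc_range range of the uniform contamination-fraction distribution
#'   (default `c(0.02, 0.2)`).
#' @param hormone_dominance fraction of an endocrine cell's transcripts from
#'   its defining hormone (default 0.4).
#' @param marker_block_share total probability mass on a type's non-hormone
#'   marker block (default 0.15).
#' @param marker_block_size genes per marker block (default 20).
#' @param marker_overlap fraction of a type's marker-block mass leaking into
#'   the other types' blocks (default 0.3): cell types share most of their
#'   transcriptional program, so type-specific markers are enriched, not
#'   exclusive.
#' @param ambient_hormone_share optional named vector fixing ambient-pool
#'   shares for specific genes (e.g. `c("hs:GCG" = 0.06)`); remaining genes
#'   are rescaled.
#' @param cell_noise_sdlog per-cell multiplicative (log-normal) noise on the
#'   expression program, applied gene-wise before sampling (default 0.294,
#'   i.e. a coefficient of variation of 0.3); models transcriptional
#'   heterogeneity within a type.
#' @param doublet_rate fraction of sample cells duplicated as doublet
#'   barcodes (default 0.05).
#' @param doublet_capture fraction of a doublet's pooled transcripts that is
#'   captured (default 0.8): a doublet contains two cells' RNA, so its
#'   library is `doublet_capture * (L1 + L2)` reads drawn from the merged
#'   counts.
#' @param library_size median library size (default 20000); sizes are drawn
#'   log-normal with `library_sdlog` (default 0.3).
#' @param library_sdlog log-scale sd of library sizes.
#' @param sample_prefix,spikein_prefix species prefixes for gene
#'   identifiers.
#' @param sample_id sample name.
#' @param seed RNG seed; the whole simulation is deterministic given it.
#' @return list of class `SimConfig`.
#' @export
sim_config <- function(n_cells = c(alpha = 140, beta = 140, delta = 70,
                                   gamma = 70, ductal = 530),
                       n_genes_sample = 2000, n_genes_spikein = 2000,
                       spikein_fraction = 0.05, n_spikeins = NULL,
                       fc_range = c(0.02, 0.2), hormone_dominance = 0.4,
                       marker_block_share = 0.15, marker_block_size = 20,
                       marker_overlap = 0.3,
                       ambient_hormone_share = NULL,
                       cell_noise_sdlog = sqrt(log(1 + 0.3^2)),
                       doublet_rate = 0.05, doublet_capture = 0.8,
                       library_size = 20000, library_sdlog = 0.3,
                       sample_prefix = "hs:", spikein_prefix = "mm:",
                       sample_id = "sim1", seed = 1) {
  stopifnot(!is.null(names(n_cells)), all(n_cells >= 0),
            hormone_dominance >= 0, hormone_dominance < 1,
            marker_block_share >= 0,
            hormone_dominance + marker_block_share < 1,
            doublet_rate >= 0, doublet_rate <= 1,
            spikein_fraction >= 0, spikein_fraction < 1,
            fc_range[1] >= 0, fc_range[2] <= 1, fc_range[1] <= fc_range[2])
  if (is.null(n_spikeins)) {
    n_spikeins <- round(spikein_fraction * sum(n_cells) /
                          (1 - spikein_fraction))
  }
  structure(list(n_cells = n_cells, n_genes_sample = n_genes_sample,
                 n_genes_spikein = n_genes_spikein,
                 spikein_fraction = spikein_fraction,
                 n_spikeins = n_spikeins, fc_range = fc_range,
                 hormone_dominance = hormone_dominance,
                 marker_block_share = marker_block_share,
                 marker_block_size = marker_block_size,
                 marker_overlap = marker_overlap,
                 ambient_hormone_share = ambient_hormone_share,
                 cell_noise_sdlog = cell_noise_sdlog,
                 doublet_rate = doublet_rate,
                 doublet_capture = doublet_capture,
                 library_size = library_size,
                 library_sdlog = library_sdlog,
                 sample_prefix = sample_prefix,
                 spikein_prefix = spikein_prefix,
                 sample_id = sample_id, seed = seed),
            class = "SimConfig")
}

# hormone gene (unprefixed) per endocrine type
.hormone_map <- c(beta = "INS", alpha = "GCG", delta = "SST", gamma = "PPY")

# anchor marker gene placed first in each type's marker block
.anchor_map <- c(alpha = "TTR", beta = "IAPP", ductal = "REG1A")

#' Build per-type expression programs
#'
#' Constructs proper probability vectors over each species' gene space. Each
#' endocrine type places `hormone_dominance` on its defining hormone and
#' `marker_block_share` on a disjoint block of type-specific genes (with an
#' anchor gene such as TTR for alpha or IAPP for beta); the remainder is a
#' shared housekeeping background drawn once from a flat Dirichlet. The
#' non-endocrine `ductal` type has no hormone and puts fixed mass on REG1A.
#' The spike-in species program is a single hormone-free Dirichlet profile
#' with a high-expression housekeeping block.
#'
#' @param config a `SimConfig`.
#' @param seed RNG seed (default `config$seed`); set to NULL to use the
#'   current RNG state.
#' @return list with `sample` (list of per-type probability vectors over
#'   prefixed sample genes), `spikein` (one vector over prefixed spike-in
#'   genes), `genes_sample`, `genes_spikein`, `hormones` (named, prefixed),
#'   and `markers` (prefixed candidate marker genes).
#' @export
make_programs <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "SimConfig"))
  if (!is.null(seed)) set.seed(seed)
  pre <- config$sample_prefix
  special <- c("INS", "GCG", "SST", "PPY", "IAPP", "TTR", "REG1A")
  n_fill <- config$n_genes_sample - length(special)
  stopifnot(n_fill > 10 * config$marker_block_size)
  genes_sample <- paste0(pre, c(special, sprintf("G%04d", seq_len(n_fill))))
  genes_spikein <- paste0(config$spikein_prefix,
                          sprintf("G%04d", seq_len(config$n_genes_spikein)))

  types <- names(config$n_cells)
  bad <- setdiff(types, c(names(.hormone_map), "ductal"))
  if (length(bad)) stop("unknown cell type(s): ", paste(bad, collapse = ", "))

  # disjoint marker blocks from the filler genes
  filler <- setdiff(genes_sample, paste0(pre, special))
  blocks <- list()
  cursor <- 1
  for (ty in types) {
    k <- config$marker_block_size
    anchor <- if (ty %in% names(.anchor_map)) {
      paste0(pre, .anchor_map[[ty]])
    } else character()
    take <- filler[cursor:(cursor + k - 1 - length(anchor))]
    cursor <- cursor + k - length(anchor)
    blocks[[ty]] <- c(anchor, take)
  }

  block_genes <- unlist(blocks, use.names = FALSE)
  hormone_genes <- paste0(pre, unname(.hormone_map))
  bg_genes <- setdiff(genes_sample, c(block_genes, hormone_genes))
  bg <- rgamma(length(bg_genes), shape = 1)
  bg <- setNames(bg / sum(bg), bg_genes)

  programs <- list()
  for (ty in types) {
    p <- setNames(numeric(length(genes_sample)), genes_sample)
    block <- blocks[[ty]]
    if (ty %in% names(.hormone_map)) {
      h_share <- config$hormone_dominance
      b_share <- config$marker_block_share
      p[paste0(pre, .hormone_map[[ty]])] <- h_share
      if (ty %in% names(.anchor_map)) {
        # anchor marker (TTR, IAPP) takes a fixed 40% of its block so it
        # reliably ranks among the top contaminating genes
        p[block[1]] <- 0.4 * b_share
        block <- block[-1]
        b_share <- 0.6 * b_share
      }
    } else {
      # non-endocrine: fixed anchor share (REG1A) instead of a hormone
      h_share <- 0.15
      b_share <- 0.10
      p[block[1]] <- h_share
      block <- block[-1]
    }
    w <- rgamma(length(block), shape = 5)
    p[block] <- b_share * w / sum(w)
    p[bg_genes] <- (1 - sum(p)) * bg
    programs[[ty]] <- p
  }

  # marker overlap: types share a fraction of their marker-block mass with
  # the other types' blocks (markers are enriched, not exclusive); hormone
  # entries are untouched and the background is rescaled so each program
  # still sums to 1
  ov <- config$marker_overlap
  if (ov > 0 && length(types) > 1) {
    B <- vapply(programs, function(p) p[block_genes],
                numeric(length(block_genes)))
    for (k in seq_along(types)) {
      ty <- types[k]
      mixed <- (1 - ov) * B[, k] +
        ov * rowMeans(B[, -k, drop = FALSE])
      p <- programs[[ty]]
      p[block_genes] <- mixed
      fixed <- sum(p) - sum(p[bg_genes])
      p[bg_genes] <- p[bg_genes] / sum(p[bg_genes]) * (1 - fixed)
      programs[[ty]] <- p
    }
  }

  # spike-in program: 50-gene high-expression housekeeping block + long tail
  w <- c(rgamma(50, shape = 20), rgamma(config$n_genes_spikein - 50,
                                        shape = 0.5))
  spike <- setNames(w / sum(w), genes_spikein)

  list(sample = programs, spikein = spike,
       genes_sample = genes_sample, genes_spikein = genes_spikein,
       hormones = setNames(paste0(pre, unname(.hormone_map)),
                           names(.hormone_map)),
       markers = paste0(pre, special))
}

# internal: unique random droplet barcodes
.random_barcodes <- function(n, width = 14) {
  repeat {
    bc <- apply(matrix(sample(c("A", "C", "G", "T"), n * width,
                              replace = TRUE), nrow = n), 1, paste,
                collapse = "")
    bc <- paste0(bc, "-1")
    if (!anyDuplicated(bc)) return(bc)
  }
}

#' Simulate one two-species droplet sample
#'
#' Draws cells, library sizes, contamination fractions, doublets, and
#' multinomial counts as described in [sim_config()], and returns the
#' combined-genome matrix, the sample-genome matrix (its sample-gene rows,
#' as produced by a single-species alignment), and the ground truth.
#'
#' @param config a `SimConfig`.
#' @return list of class `SpikeSim` with elements `cm_sample`,
#'   `cm_combined` (`CountMatrix`), `truth` (data.frame: `barcode`,
#'   `species`, `cell_type`, `true_fc`, `is_doublet`, `partner_type`),
#'   `ambient_pool` (named probability vector over sample genes),
#'   `programs`, `reference` (list: `spikein_tpm` clean spike-in profile on
#'   the combined gene space, `type_tpm` clean per-type profiles), and
#'   `config`.
#' @export
simulate_sample <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  programs <- make_programs(config, seed = config$seed)
  genes_all <- c(programs$genes_sample, programs$genes_spikein)
  n_hs <- length(programs$genes_sample)
  n_mm <- length(programs$genes_spikein)

  types <- rep(names(config$n_cells), config$n_cells)
  n_sample <- length(types)
  n_spike <- config$n_spikeins
  n_single <- n_sample + n_spike
  species <- c(rep("sample", n_sample), rep("spikein", n_spike))
  cell_type <- c(types, rep("spikein", n_spike))

  L <- pmax(500, round(rlnorm(n_single, log(config$library_size),
                              config$library_sdlog)))
  fc <- runif(n_single, config$fc_range[1], config$fc_range[2])

  # ambient pool: library-size-weighted mean of clean sample-cell programs
  pool <- setNames(numeric(n_hs), programs$genes_sample)
  wsum <- 0
  for (i in seq_len(n_sample)) {
    pool <- pool + L[i] * programs$sample[[types[i]]]
    wsum <- wsum + L[i]
  }
  pool <- pool / wsum
  if (!is.null(config$ambient_hormone_share)) {
    tgt <- config$ambient_hormone_share
    stopifnot(all(names(tgt) %in% names(pool)), sum(tgt) < 1)
    rest <- setdiff(names(pool), names(tgt))
    pool[rest] <- pool[rest] / sum(pool[rest]) * (1 - sum(tgt))
    pool[names(tgt)] <- tgt
  }

  counts <- matrix(0, nrow = length(genes_all), ncol = n_single,
                   dimnames = list(genes_all, NULL))
  sdl <- config$cell_noise_sdlog
  for (i in seq_len(n_single)) {
    prob <- numeric(length(genes_all))
    if (species[i] == "sample") {
      own <- programs$sample[[types[i]]]
    } else {
      own <- programs$spikein
    }
    if (sdl > 0) {
      # per-cell transcriptional heterogeneity: gene-wise log-normal
      # perturbation of the program, renormalized
      own <- own * rlnorm(length(own), -sdl^2 / 2, sdl)
      own <- own / sum(own)
    }
    if (species[i] == "sample") {
      prob[seq_len(n_hs)] <- (1 - fc[i]) * own + fc[i] * pool
    } else {
      prob[seq_len(n_hs)] <- fc[i] * pool
      prob[n_hs + seq_len(n_mm)] <- (1 - fc[i]) * own
    }
    counts[, i] <- rmultinom(1, L[i], prob)
  }

  # doublets: pairs of distinct sample-species cells, summed then
  # downsampled to a fresh library size
  n_doub <- round(config$doublet_rate * n_sample)
  doub_counts <- NULL
  doub_truth <- NULL
  if (n_doub > 0) {
    pairs <- t(vapply(seq_len(n_doub),
                      function(i) sample(n_sample, 2), integer(2)))
    doub_counts <- matrix(0, nrow = length(genes_all), ncol = n_doub,
                          dimnames = list(genes_all, NULL))
    for (j in seq_len(n_doub)) {
      merged <- counts[, pairs[j, 1]] + counts[, pairs[j, 2]]
      tot <- sum(merged)
      Ld <- round(config$doublet_capture * tot)
      doub_counts[, j] <- if (Ld < tot) {
        rmultinom(1, Ld, merged)
      } else merged
    }
    w1 <- L[pairs[, 1]]
    w2 <- L[pairs[, 2]]
    doub_truth <- data.frame(
      species = "sample",
      cell_type = types[pairs[, 1]],
      true_fc = (w1 * fc[pairs[, 1]] + w2 * fc[pairs[, 2]]) / (w1 + w2),
      is_doublet = TRUE,
      partner_type = types[pairs[, 2]],
      stringsAsFactors = FALSE)
  }

  all_counts <- cbind(counts, doub_counts)
  bc <- .random_barcodes(ncol(all_counts))
  colnames(all_counts) <- bc
  truth <- rbind(
    data.frame(species = species, cell_type = cell_type, true_fc = fc,
               is_doublet = FALSE, partner_type = NA_character_,
               stringsAsFactors = FALSE),
    doub_truth)
  truth <- cbind(barcode = bc, truth)
  rownames(truth) <- NULL

  cm_combined <- count_matrix(all_counts, sample_id = config$sample_id)
  cm_sample <- count_matrix(
    all_counts[programs$genes_sample, , drop = FALSE],
    sample_id = config$sample_id)

  reference <- list(
    spikein_tpm = setNames(c(numeric(n_hs), programs$spikein * 1e6),
                           genes_all),
    type_tpm = vapply(programs$sample, function(p) p * 1e6,
                      numeric(n_hs)))

  structure(list(cm_sample = cm_sample, cm_combined = cm_combined,
                 truth = truth, ambient_pool = pool, programs = programs,
                 reference = reference, config = config),
            class = "SpikeSim")
}

#' @export
print.SpikeSim <- function(x, ...) {
  cat(sprintf(
    "SpikeSim '%s': %d barcodes (%d spike-ins, %d doublets), %d + %d genes\n",
    x$config$sample_id, nrow(x$truth), sum(x$truth$species == "spikein"),
    sum(x$truth$is_doublet), length(x$programs$genes_sample),
    length(x$programs$genes_spikein)))
  invisible(x)
}

#' Write a simulated sample to disk
#'
#' Writes `sample/` and `combined/` MTX triplets (loadable by
#' [read_mtx()]), the ground-truth table `truth.tsv`, and the ambient pool
#' `ambient_pool.tsv`.
#'
#' @param sim a `SpikeSim`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(sim, dir) {
  stopifnot(inherits(sim, "SpikeSim"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop("cannot create directory: ", dir)
  }
  write_mtx(sim$cm_sample, file.path(dir, "sample"))
  write_mtx(sim$cm_combined, file.path(dir, "combined"))
  write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(gene = names(sim$ambient_pool),
                         share = sim$ambient_pool),
              file.path(dir, "ambient_pool.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
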