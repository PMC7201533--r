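# End-to-end orchestration: simulate/ingest -> cell calling -> species
# assignment -> decontamination -> cell-type assignment -> differential
# expression, with a machine-readable run report.

#' Pipeline configuration
#'
#' Assembles the configuration for [run_pipeline()]. Either a simulation
#' config (`sim`) or paths to MTX triplets (`sample_dir`, `combined_dir`)
#' must be provided. All thresholds default to the method's standard values.
#'
#' @param sim optional [sim_config()] used to generate the input in-memory.
#' @param sample_dir,combined_dir optional MTX triplet directories for the
#'   sample-genome and combined-genome alignments.
#' @param marker_file optional path to a one-column text file of candidate
#'   predictor marker genes; defaults to the simulator's marker list when
#'   `sim` is given.
#' @param markers character vector of candidate predictor genes (overrides
#'   `marker_file`).
#' @param sample_prefix,spikein_prefix species prefixes in the combined
#'   alignment.
#' @param min_umi,min_genes cell-calling thresholds (defaults 500 / 200).
#' @param species_cutoff log2-ratio cutoff (default 2).
#' @param fc_cap prediction cap (default 0.1, the human-sample value; use
#'   0.2 for mouse samples).
#' @param hormone_threshold log-TPM threshold for hormone assignment
#'   (default 7.5).
#' @param prob_ratio_min doublet probability-ratio threshold (default 3).
#' @param de_types which two cell-type labels the DE stage contrasts
#'   (default alpha vs beta).
#' @param min_spikeins minimum usable spike-ins (default 20).
#' @param exclude flag this sample as excluded from analysis (judgment
#'   call, never automatic; default FALSE).
#' @param out_dir optional output directory for result tables and the JSON
#'   run report.
#' @param seed seed for every stochastic step (default 1).
#' @return list of class `RunConfig`.
#' @export
run_config <- function(sim = NULL, sample_dir = NULL, combined_dir = NULL,
                       marker_file = NULL, markers = NULL,
                       sample_prefix = "hs:", spikein_prefix = "mm:",
                       min_umi = 500, min_genes = 200, species_cutoff = 2,
                       fc_cap = 0.1, hormone_threshold = 7.5,
                       prob_ratio_min = 3, de_types = c("alpha", "beta"),
                       min_spikeins = 20, exclude = FALSE, out_dir = NULL,
                       seed = 1) {
  if (is.null(sim) && (is.null(sample_dir) || is.null(combined_dir))) {
    stop("provide either a simulation config or sample/combined directories")
  }
  structure(list(sim = sim, sample_dir = sample_dir,
                 combined_dir = combined_dir, marker_file = marker_file,
                 markers = markers, sample_prefix = sample_prefix,
                 spikein_prefix = spikein_prefix, min_umi = min_umi,
                 min_genes = min_genes, species_cutoff = species_cutoff,
                 fc_cap = fc_cap, hormone_threshold = hormone_threshold,
                 prob_ratio_min = prob_ratio_min, de_types = de_types,
                 min_spikeins = min_spikeins, exclude = exclude,
                 out_dir = out_dir, seed = seed),
            class = "RunConfig")
}

# internal: run one stage, prefixing any error with the stage name
.stage <- function(name, report, expr) {
  res <- tryCatch(expr, error = function(e) {
    stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)
  })
  res
}

#' Run the full pipeline
#'
#' Executes the stages simulate (or ingest-from-disk), ingest (cell
#' calling), species, decontam, celltype, and de in order, logging the
#' parameters of every stage into a run report. Any stage error is
#' propagated with the stage name. Deterministic given `config$seed`.
#'
#' @param config a [run_config()].
#' @return list with per-stage results (`sim`, `cells`, `species`,
#'   `decontam`, `celltype`, `de`) and `report` (also written as JSON to
#'   `out_dir` when set).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  report <- list(parameters = config[!vapply(config, is.null, logical(1)) &
                                       names(config) != "sim"],
                 stages = list())
  t0 <- Sys.time()

  # -- stage 1: simulate or load --------------------------------------------
  sim <- NULL
  if (!is.null(config$sim)) {
    sim <- .stage("simulate", report, simulate_sample(config$sim))
    cm_sample <- sim$cm_sample
    cm_combined <- sim$cm_combined
    report$stages$simulate <- list(
      n_barcodes = nrow(sim$truth),
      n_spikeins = sum(sim$truth$species == "spikein"),
      seed = config$sim$seed)
  } else {
    cm_sample <- .stage("simulate", report, read_mtx(config$sample_dir))
    cm_combined <- .stage("simulate", report, read_mtx(config$combined_dir))
    report$stages$simulate <- list(loaded_from = c(config$sample_dir,
                                                   config$combined_dir))
  }

  # -- stage 2: ingest (cell calling) ---------------------------------------
  cells <- .stage("ingest", report, {
    called <- call_cells(cm_combined, config$min_umi, config$min_genes)
    list(combined = called,
         sample = subset_counts(cm_sample,
                                barcodes = intersect(barcodes(cm_sample),
                                                     barcodes(called))))
  })
  report$stages$ingest <- list(min_umi = config$min_umi,
                               min_genes = config$min_genes,
                               n_cells = ncol(cells$combined$counts))

  # -- stage 3: species assignment ------------------------------------------
  calls <- .stage("species", report,
                  assign_species(cells$combined,
                                 sample_prefix = config$sample_prefix,
                                 spikein_prefix = config$spikein_prefix,
                                 cutoff = config$species_cutoff))
  keep <- calls$barcode[calls$label != "ambiguous"]
  report$stages$species <- list(cutoff = config$species_cutoff,
                                n_sample = sum(calls$label ==
                                                 "sample_species"),
                                n_spikein = sum(calls$label ==
                                                  "spikein_species"),
                                n_ambiguous = sum(calls$label == "ambiguous"))

  # -- stage 4: decontamination ---------------------------------------------
  dec <- .stage("decontam", report, {
    markers <- config$markers
    if (is.null(markers) && !is.null(config$marker_file)) {
      if (!file.exists(config$marker_file)) {
        stop("marker file not found: ", config$marker_file)
      }
      markers <- readLines(config$marker_file)
    }
    if (is.null(markers) && !is.null(sim)) markers <- sim$programs$markers
    if (is.null(markers)) stop("no marker gene list provided")

    cm_cells <- subset_counts(cells$sample,
                              barcodes = intersect(barcodes(cells$sample),
                                                   keep))
    em <- suppressWarnings(tpm_normalize(cm_cells))
    fc_meas <- measure_fc(calls)
    spike_bc <- intersect(barcodes(em), fc_meas$barcode)
    # spike-ins are taken from the combined-alignment TPM layer (their
    # sample-genome slice alone is pure contamination, so per-cell
    # renormalization of that slice would erase the f_c signal)
    em_comb <- suppressWarnings(tpm_normalize(cells$combined))
    sample_genes <- genes(cm_cells)
    em_spike <- expression_matrix(
      em_comb$values[sample_genes, spike_bc, drop = FALSE],
      layer = "tpm", sample_id = em$sample_id, check = FALSE)
    # clean spike-ins carry no sample-genome transcripts
    ref0 <- setNames(numeric(length(sample_genes)), sample_genes)
    sig <- estimate_signature(em_spike, fc_meas, ref0,
                              min_spikeins = config$min_spikeins)
    pred_genes <- select_predictor_genes(sig, markers)
    predictor <- fit_fc_predictor(em_spike, fc_meas, pred_genes,
                                  cap = config$fc_cap)
    sample_bc <- setdiff(barcodes(em), spike_bc)
    em_sample <- expression_matrix(em$values[, sample_bc, drop = FALSE],
                                   layer = "tpm", sample_id = em$sample_id,
                                   check = FALSE)
    fc_pred <- predict_fc(em_sample, predictor)
    fc_all <- rbind(fc_meas[fc_meas$barcode %in% spike_bc,
                            c("barcode", "f_c", "source")], fc_pred)
    em_corr <- correct_expression(em, fc_all, sig)
    list(em_raw = em, em_corrected = em_corr, signature = sig,
         predictor = predictor, f_c = fc_all, counts = cm_cells)
  })
  report$stages$decontam <- list(cap = config$fc_cap,
                                 predictor_genes = dec$predictor$genes,
                                 median_measured_fc = median(
                                   dec$f_c$f_c[dec$f_c$source == "measured"]))

  # -- stage 5: cell typing and doublet removal -----------------------------
  ct <- .stage("celltype", report, {
    log_corr <- log_transform(dec$em_corrected)
    pre <- config$sample_prefix
    horm <- setNames(paste0(pre, unname(.hormone_map)), names(.hormone_map))
    sample_bc <- dec$f_c$barcode[dec$f_c$source == "predicted"]
    em_cells <- expression_matrix(
      log_corr$values[, sample_bc, drop = FALSE], layer = "log_tpm",
      sample_id = log_corr$sample_id, check = FALSE)
    asg <- assign_by_hormone(em_cells, horm, config$hormone_threshold)
    assignment_genes <- unname(horm)
    reg1a <- paste0(pre, "REG1A")
    if (reg1a %in% genes(em_cells)) {
      asg <- assign_acinar_like(em_cells, asg, gene = reg1a,
                                threshold = config$hormone_threshold)
      # every gene used to assign representatives is excluded from the
      # classifier features, REG1A included
      assignment_genes <- c(assignment_genes, reg1a)
    }
    training <- subsample_training(asg, sample_id = dec$counts$sample_id,
                                   seed = config$seed)
    model <- train_classifier(em_cells, training,
                              exclude_genes = assignment_genes,
                              seed = config$seed)
    pred <- predict_celltype(model, em_cells, assignments = asg)
    flag_p <- filter_doublets_probability(pred$probs, config$prob_ratio_min)
    ng <- n_genes_per_cell(subset_counts(dec$counts, barcodes = sample_bc))
    flag_n <- filter_doublets_ngenes(ng, paste(pred$label,
                                               dec$counts$sample_id))
    assignments <- data.frame(
      barcode = pred$barcode, label = pred$label,
      assigned_by = pred$assigned_by,
      doublet_flag = unname(flag_p[pred$barcode] | flag_n[pred$barcode]),
      n_genes = unname(ng[pred$barcode]),
      stringsAsFactors = FALSE)
    list(assignments = assignments, model = model, probs = pred$probs,
         em_cells = em_cells)
  })
  report$stages$celltype <- list(
    threshold = config$hormone_threshold,
    prob_ratio_min = config$prob_ratio_min,
    n_doublets_flagged = sum(ct$assignments$doublet_flag),
    label_counts = as.list(table(ct$assignments$label)))

  # -- stage 6: differential expression (cell-type contrast) ----------------
  de <- .stage("de", report, {
    kept <- ct$assignments[!ct$assignments$doublet_flag, ]
    a_bc <- kept$barcode[kept$label == config$de_types[1]]
    b_bc <- kept$barcode[kept$label == config$de_types[2]]
    if (length(a_bc) < 3 || length(b_bc) < 3) {
      stop("fewer than 3 cells in a DE group (",
           paste(config$de_types, collapse = " vs "), ")")
    }
    pre <- config$sample_prefix
    horm <- paste0(pre, unname(.hormone_map))
    hf <- prepare_hormone_free(dec$counts, horm)
    res_h <- nb_test(dec$counts$counts[intersect(horm, genes(dec$counts)),
                                       a_bc, drop = FALSE],
                     dec$counts$counts[intersect(horm, genes(dec$counts)),
                                       b_bc, drop = FALSE],
                     lib_sizes1 = Matrix::colSums(
                       dec$counts$counts[, a_bc, drop = FALSE]),
                     lib_sizes2 = Matrix::colSums(
                       dec$counts$counts[, b_bc, drop = FALSE]))
    res_o <- nb_test(hf$counts$counts[, a_bc, drop = FALSE],
                     hf$counts$counts[, b_bc, drop = FALSE])
    rbind(cbind(res_h, pass = "hormones"), cbind(res_o, pass = "other"))
  })
  report$stages$de <- list(contrast = config$de_types,
                           n_tested = nrow(de),
                           n_significant = sum(de$significant))

  report$n_stages <- length(report$stages)
  report$elapsed_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  report$seed <- config$seed

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    write.table(ct$assignments, file.path(config$out_dir, "celltypes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(dec$f_c, file.path(config$out_dir, "fc.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(de, file.path(config$out_dir, "de.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  list(sim = sim, cells = cells, species = calls, decontam = dec,
       celltype = ct, de = de, report = report)
}
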