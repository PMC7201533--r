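# Shared fixtures, built in code at test time.

# small random count matrix
random_count_matrix <- function(n_genes = 50, n_cells = 100, seed = 1,
                                lambda = 2) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_cells, lambda), nrow = n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("bc%04d", seq_len(n_cells))))
  m[sample(length(m), length(m) %/% 2)] <- 0
  count_matrix(m, sample_id = "fix")
}

# small fast simulation for unit tests
quick_sim <- function(seed = 1, ...) {
  simulate_sample(sim_config(
    n_cells = c(alpha = 40, beta = 40, delta = 20, gamma = 20, ductal = 60),
    n_genes_sample = 400, n_genes_spikein = 400, n_spikeins = 30,
    library_size = 5000, seed = seed, ...))
}

# TPM expression matrix from a plain matrix of values (no validation sums)
as_tpm <- function(m, renorm = TRUE) {
  if (renorm) {
    cs <- colSums(m)
    cs[cs == 0] <- 1
    m <- sweep(m, 2, cs, "/") * 1e6
  }
  expression_matrix(m, layer = "tpm", check = FALSE)
}

# independent brute-force step-up BH oracle
bh_bruteforce <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, n / i * p[o[i]])
    adj[o[i]] <- val
    prev <- val
  }
  pmin(adj, 1)
}

# independent O(n^2) pairwise-concordance AUC oracle (ties count 1/2)
auc_bruteforce <- function(x_pos, x_neg) {
  s <- 0
  for (xp in x_pos) for (xn in x_neg) {
    s <- s + (xp > xn) + 0.5 * (xp == xn)
  }
  s / (length(x_pos) * length(x_neg))
}

# decontamination front-end shared by several tests: measured f_c, signature,
# predictor from a SpikeSim
decontam_frontend <- function(sim, cap = 0.2) {
  calls <- assign_species(sim$cm_combined,
                          sample_prefix = sim$config$sample_prefix,
                          spikein_prefix = sim$config$spikein_prefix)
  fc <- measure_fc(calls)
  em_comb <- suppressWarnings(tpm_normalize(sim$cm_combined))
  hs <- sim$programs$genes_sample
  spike_bc <- intersect(colnames(em_comb$values), fc$barcode)
  em_sp <- expression_matrix(em_comb$values[hs, spike_bc, drop = FALSE],
                             layer = "tpm", check = FALSE)
  ref0 <- setNames(numeric(length(hs)), hs)
  sig <- estimate_signature(em_sp, fc, ref0, min_spikeins = 10)
  list(calls = calls, fc = fc, em_comb = em_comb, em_spike = em_sp,
       sig = sig, spike_bc = spike_bc)
}
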