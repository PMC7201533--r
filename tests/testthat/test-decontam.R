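test_that("measured f_c is the sample-genome read fraction", {
  calls <- data.frame(
    barcode = c("s1", "s2", "cell"),
    reads_sample = c(0, 10, 500),
    reads_spikein = c(90, 90, 2),
    log2_ratio = c(-10, -3.1, 8),
    label = c("spikein_species", "spikein_species", "sample_species"))
  fc <- measure_fc(calls)
  expect_equal(fc$barcode, c("s1", "s2"))
  expect_equal(fc$f_c, c(0, 0.10))
  expect_equal(unique(fc$source), "measured")
  calls$reads_spikein[1] <- 0
  expect_error(measure_fc(calls), "zero aligned reads")
})

test_that("signature estimation follows divide, subtract, clip, rescale, average", {
  # one spike-in, two genes, f_c = 0.2:
  # x/(1-fc) - ref = (750000,500000) - (500000,500000) = (250000, 0)
  x <- matrix(c(600000, 400000), ncol = 1,
              dimnames = list(c("g1", "g2"), "s1"))
  em <- expression_matrix(x, layer = "tpm", check = FALSE)
  ref <- c(g1 = 500000, g2 = 500000)
  sig <- estimate_signature(em, c(s1 = 0.2), ref, min_spikeins = 1)
  expect_equal(unname(sig$s_c), c(1e6, 0), tolerance = 1e-9)
  expect_equal(sum(sig$s_c), 1e6, tolerance = 1e-6)

  # spike-ins identical to the reference with f_c = 0: nothing to estimate
  x0 <- matrix(rep(c(500000, 500000), 3), nrow = 2,
               dimnames = list(c("g1", "g2"), c("a", "b", "c")))
  em0 <- expression_matrix(x0, layer = "tpm", check = FALSE)
  expect_error(estimate_signature(em0, c(a = 0, b = 0, c = 0), ref,
                                  min_spikeins = 1), "no contamination")
  expect_error(estimate_signature(em, c(s1 = 1), ref, min_spikeins = 1),
               "< 1")
  expect_error(estimate_signature(em, c(s1 = 0.2), ref, min_spikeins = 5),
               "usable spike-ins")
})

test_that("estimated signature matches the planted ambient pool", {
  sim <- simulate_sample(sim_config(n_spikeins = 300, seed = 5))
  d <- decontam_frontend(sim)
  pool <- sim$ambient_pool * 1e6
  cossim <- sum(d$sig$s_c * pool) /
    sqrt(sum(d$sig$s_c^2) * sum(pool^2))
  expect_gte(cossim, 0.99)
})

test_that("predictor genes are the marker intersection with the top-100", {
  s <- setNames(c(1000, 500, 200, 50, 10), paste0("g", 1:5))
  sig <- structure(list(sample_id = "x", s_c = s / sum(s) * 1e6),
                   class = "ContaminationSignature")
  expect_equal(select_predictor_genes(sig, c("g2", "g9", "g1")),
               c("g1", "g2"))
  expect_equal(select_predictor_genes(sig, paste0("g", 1:3), top_n = 3),
               paste0("g", 1:3))
  expect_error(select_predictor_genes(sig, "absent"), "no configured marker")
})

test_that("no-intercept slopes recover exact linear relations", {
  set.seed(2)
  tpm <- matrix(runif(40, 1000, 50000), nrow = 1,
                dimnames = list("gA", sprintf("s%02d", 1:40)))
  fc <- 1e-7 * tpm[1, ]
  em <- expression_matrix(tpm, layer = "tpm", check = FALSE)
  p <- fit_fc_predictor(em, fc, "gA", cap = 1)
  expect_equal(unname(p$slopes["gA"]), 1e-7, tolerance = 1e-12)
  pred <- predict_fc(em, p)
  expect_equal(pred$f_c, unname(fc), tolerance = 1e-9)

  # all-zero gene dropped with a warning (a negative no-intercept slope
  # cannot arise from non-negative f_c and TPM, so clipping is defensive)
  tpm2 <- rbind(tpm, gC = 0)
  em2 <- expression_matrix(tpm2, layer = "tpm", check = FALSE)
  expect_warning(p2 <- fit_fc_predictor(em2, fc, c("gA", "gC"), cap = 1),
                 "all-zero")
  expect_false("gC" %in% p2$genes)
  expect_true(all(p2$slopes >= 0))
})

test_that("prediction is the capped median across predictor genes", {
  # two genes predicting 0.05 and 0.15: median 0.10, capped at 0.10
  tpm <- matrix(c(50000, 150000), ncol = 1,
                dimnames = list(c("gA", "gB"), "cell"))
  em <- expression_matrix(tpm, layer = "tpm", check = FALSE)
  p <- structure(list(genes = c("gA", "gB"),
                      slopes = c(gA = 1e-6, gB = 1e-6), cap = 0.1,
                      aggregation = "median"), class = "FcPredictor")
  expect_equal(predict_fc(em, p)$f_c, 0.1)
  # zero expression of all predictor genes -> 0
  em0 <- expression_matrix(matrix(0, 2, 1,
                                  dimnames = list(c("gA", "gB"), "c0")),
                           layer = "tpm", check = FALSE)
  expect_equal(predict_fc(em0, p)$f_c, 0)
  # clipping contract on random inputs
  set.seed(8)
  emr <- expression_matrix(
    matrix(runif(200, 0, 5e5), nrow = 2,
           dimnames = list(c("gA", "gB"), sprintf("c%03d", 1:100))),
    layer = "tpm", check = FALSE)
  expect_true(all(predict_fc(emr, p)$f_c <= p$cap + 1e-15))
})

test_that("cross-validated prediction is accurate under multiplicative noise", {
  # f_c recovery conditions: 300 spike-ins, f_c ~ U(0.02, 0.2), CV-0.3 noise
  set.seed(31)
  n <- 300
  fc <- runif(n, 0.02, 0.2)
  k <- c(gA = 4e5, gB = 6e5, gC = 2e5, gD = 5e5, gE = 3e5, gF = 1e5,
         gG = 7e5)
  sdl <- sqrt(log(1 + 0.3^2))
  tpm <- vapply(seq_len(n), function(i) {
    fc[i] * k * rlnorm(7, -sdl^2 / 2, sdl)
  }, numeric(7))
  dimnames(tpm) <- list(names(k), sprintf("s%03d", seq_len(n)))
  names(fc) <- colnames(tpm)
  em <- expression_matrix(tpm, layer = "tpm", check = FALSE)
  cv <- crossval_fc_predictor(em, fc, names(k), cap = 0.2, folds = 3,
                              seed = 1)
  expect_gte(attr(cv, "r"), 0.8)
  # deterministic given the seed
  cv2 <- crossval_fc_predictor(em, fc, names(k), cap = 0.2, folds = 3,
                               seed = 1)
  expect_identical(cv$f_c_predicted, cv2$f_c_predicted)
})

test_that("correction subtracts f_c * S_c, clips, and renormalizes", {
  x <- matrix(c(500000, 300000, 200000), ncol = 1,
              dimnames = list(c("g1", "g2", "g3"), "cell"))
  em <- expression_matrix(x, layer = "tpm", check = FALSE)
  s <- c(g1 = 1e6, g2 = 0, g3 = 0)
  out <- correct_expression(em, c(cell = 0.2), s)
  expect_equal(as.numeric(out$values[, 1]), c(375000, 375000, 250000),
               tolerance = 1e-9)
  # f_c = 0 leaves the input unchanged
  out0 <- correct_expression(em, c(cell = 0), s)
  expect_equal(as.matrix(out0$values), as.matrix(em$values))
  # a gene below f_c * s_c is clipped to exactly zero
  out2 <- correct_expression(em, c(cell = 0.6), s)
  expect_equal(as.numeric(out2$values["g1", 1]), 0)
  expect_error(correct_expression(em, c(cell = 0.2), c(gX = 1e6)),
               "gene space")
  expect_error(correct_expression(em, c(other = 0.2), s), "missing")
})

test_that("corrected columns stay non-negative and sum to 1e6", {
  sim <- quick_sim(seed = 3)
  d <- decontam_frontend(sim)
  em <- suppressWarnings(tpm_normalize(sim$cm_sample))
  fcv <- setNames(sim$truth$true_fc, sim$truth$barcode)[barcodes(em)]
  out <- correct_expression(em, fcv, d$sig)
  v <- as.matrix(out$values)
  expect_true(all(v >= 0))
  cs <- colSums(v)
  expect_true(all(cs == 0 | abs(cs - 1e6) <= 1))
})

test_that("raising f_c never raises a signature gene before renormalization", {
  x <- matrix(runif(30, 0, 2e5), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), sprintf("c%02d", 1:10)))
  s <- c(g1 = 6e5, g2 = 3e5, g3 = 1e5)
  prev <- NULL
  for (f in seq(0, 0.5, by = 0.1)) {
    sub <- pmax(0, x - outer(s, rep(f, 10)))
    if (!is.null(prev)) expect_true(all(sub <= prev + 1e-12))
    prev <- sub
  }
})

test_that("correction moves spike-ins toward the clean reference", {
  sim <- simulate_sample(sim_config(n_spikeins = 100, seed = 13))
  d <- decontam_frontend(sim)
  em_full <- expression_matrix(d$em_comb$values[, d$spike_bc, drop = FALSE],
                               layer = "tpm", check = FALSE)
  sigv <- setNames(numeric(nrow(d$em_comb$values)),
                   rownames(d$em_comb$values))
  sigv[names(d$sig$s_c)] <- d$sig$s_c
  fcv <- setNames(d$fc$f_c, d$fc$barcode)
  emc <- correct_expression(em_full, fcv[d$spike_bc], sigv)
  ev <- evaluate_correction(em_full, emc, sim$reference$spikein_tpm)
  expect_gt(median(ev$r_corrected), median(ev$r_raw))
  # corrected == reference exactly gives correlation 1
  ref <- sim$reference$spikein_tpm
  em_ref <- expression_matrix(matrix(ref, ncol = 1,
                                     dimnames = list(names(ref), "r")),
                              layer = "tpm", check = FALSE)
  ev1 <- evaluate_correction(em_ref, em_ref, ref)
  expect_equal(ev1$r_corrected, 1)
  # uncontaminated input is untouched
  un <- correct_expression(em_ref, c(r = 0), sigv)
  expect_equal(as.matrix(un$values), as.matrix(em_ref$values),
               tolerance = 1e-12)
})
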