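test_that("null envelope self-calibrates to the requested F_ST", {
  cfg <- island_model_config(n_a = 40, n_b = 40, n_sim_loci = 6000,
                             seed = 2)
  env <- simulate_null_envelope(cfg, target_fst = 0.05)
  expect_lt(abs(env$realized_fst - 0.05), 1e-3)
  # a locus sitting at the envelope median gets P near 0.5
  b <- env$bins[[length(env$bins) %/% 2]]
  p_med <- envelope_p(env, median(b$fst), b$he_mid)
  expect_lt(abs(p_med - 0.5), 0.05)
  expect_error(simulate_null_envelope(cfg, 0.95), "target F_ST")
})

test_that("panmixia-like targets centre the null F_ST near zero", {
  cfg <- island_model_config(n_a = 60, n_b = 60, n_sim_loci = 4000,
                             seed = 3)
  env <- simulate_null_envelope(cfg, target_fst = 0.005)
  fst_all <- unlist(lapply(env$bins, `[[`, "fst"))
  expect_lt(abs(median(fst_all)), 0.02)
})

test_that("scan on clean data converges quickly with an empty outlier set", {
  pr <- make_pair_dataset(seed = 13, n_loci = 200, n_a = 80, n_b = 80,
                          target_fst = 0.05)
  ft <- estimate_dominant_freq_table(pr$dataset$dominant,
                                     pr$dataset$samples)
  cfg <- island_model_config(n_a = 80, n_b = 80, n_sim_loci = 6000,
                             seed = 4)
  fd <- fdist_scan(ft, "OL", "RL", cfg)
  expect_lte(sum(fd$loci$outlier), ceiling(0.03 * sum(fd$loci$tested)))
  expect_true(fd$converged)
  expect_gt(median(fd$loci$p, na.rm = TRUE), 0.4)
  expect_lt(median(fd$loci$p, na.rm = TRUE), 0.6)
  # excluded-loci counts never decrease over iterations
  expect_true(all(diff(fd$history$n_excluded) >= 0))
})

test_that("a planted strongly divergent locus is flagged by the scan", {
  pr <- make_pair_dataset(seed = 17, n_loci = 250, n_a = 80, n_b = 80,
                          target_fst = 0.05,
                          plant = list(p_a = 0.98, p_b = 0.05))
  ft <- estimate_dominant_freq_table(pr$dataset$dominant,
                                     pr$dataset$samples)
  cfg <- island_model_config(n_a = 80, n_b = 80, n_sim_loci = 8000,
                             seed = 6)
  fd <- fdist_scan(ft, "OL", "RL", cfg)
  row <- fd$loci[fd$loci$locus == "L001", ]
  expect_true(row$tested)
  expect_true(row$outlier)
  expect_lt(row$p, 0.01)
  expect_gt(row$fst, 0.5)
})

test_that("near-fixed loci are reported untested, never flagged", {
  pr <- make_pair_dataset(seed = 19, n_loci = 100, n_a = 40, n_b = 40,
                          target_fst = 0.05,
                          plant = list(p_a = 0.999, p_b = 0.999))
  ft <- estimate_dominant_freq_table(pr$dataset$dominant,
                                     pr$dataset$samples)
  cfg <- island_model_config(n_a = 40, n_b = 40, n_sim_loci = 4000,
                             seed = 7)
  fd <- fdist_scan(ft, "OL", "RL", cfg)
  row <- fd$loci[fd$loci$locus == "L001", ]
  expect_false(row$tested)
  expect_false(row$outlier)
})

test_that("Jeffreys categories follow the published bins", {
  expect_identical(jeffreys_category(c(0.5, 1, 2, 5, 20, 50, 150)),
                   c("none", "none", "barely", "substantial", "strong",
                     "very strong", "decisive"))
  expect_error(jeffreys_category(-1), "non-negative")
})

test_that("posterior odds equal to the prior leaves the odds ratio at one", {
  # odds-ratio identity: posterior inclusion = prior inclusion
  prior_odds <- 1 / 10
  post_p <- prior_odds / (1 + prior_odds)
  expect_equal((post_p / (1 - post_p)) / prior_odds, 1)
})

test_that("RJ-MCMC flags a planted outlier and stays quiet on null loci", {
  pr <- make_pair_dataset(seed = 23, n_loci = 150, n_a = 60, n_b = 60,
                          target_fst = 0.05,
                          plant = list(p_a = 0.98, p_b = 0.05))
  bcfg <- bayescan_config(n_pilot = 5, pilot_len = 200, burn_in = 2000,
                          n_iter = 5000, thin = 5, seed = 11)
  bs <- bayescan_scan(pr$dataset, "OL", "RL", "dominant", bcfg)
  row <- bs$loci[bs$loci$locus == "L001", ]
  expect_gt(row$bf, 32)
  expect_true(row$category %in% c("very strong", "decisive"))
  others <- bs$loci[bs$loci$locus != "L001" & bs$loci$tested, ]
  expect_lt(mean(others$category %in% c("very strong", "decisive"),
                 na.rm = TRUE), 0.02)
})

test_that("Bayes factors are invariant to relabeling the populations", {
  pr <- make_pair_dataset(seed = 29, n_loci = 60, n_a = 30, n_b = 30,
                          target_fst = 0.1)
  bcfg <- bayescan_config(n_pilot = 3, pilot_len = 150, burn_in = 1000,
                          n_iter = 2500, thin = 5, seed = 13)
  b1 <- bayescan_scan(pr$dataset, "OL", "RL", "dominant", bcfg)
  b2 <- bayescan_scan(pr$dataset, "RL", "OL", "dominant", bcfg)
  # same model, swapped deme labels: evidence agrees up to MC noise
  expect_gt(cor(log(b1$loci$bf[b1$loci$tested] + 0.01),
                log(b2$loci$bf[b2$loci$tested] + 0.01)), 0.5)
  expect_equal(mean(b1$loci$bf, na.rm = TRUE),
               mean(b2$loci$bf, na.rm = TRUE), tolerance = 0.5)
})

test_that("consensus table combines methods and feeds the neutral set", {
  fd_loci <- data.frame(locus = c("L1", "L2", "L3"),
                        he = 0.3, fst = c(0.6, 0.05, 0.05),
                        p = c(0.001, 0.5, 0.5),
                        outlier = c(TRUE, FALSE, FALSE),
                        tested = TRUE)
  bs_loci <- data.frame(locus = c("L1", "L2", "L3"), tested = TRUE,
                        post_incl = c(0.99, 0.1, 0.1),
                        bf = c(120, 0.2, 1.5),
                        odds_ratio = c(1200, 2, 15),
                        category = c("decisive", "none", "barely"),
                        post_fst = 0.1, alpha = 0)
  fd <- structure(list(loci = fd_loci), class = "fdist_result")
  bs <- structure(list(loci = bs_loci), class = "bayescan_result")
  cons <- build_consensus(list("OL-RL" = fd), list("OL-RL" = bs))
  expect_true(cons$strong_outlier[cons$locus == "L1"])
  expect_false(any(cons$strong_outlier[cons$locus != "L1"]))
  expect_identical(cons$any_flag, c(TRUE, FALSE, TRUE))
  ns <- build_neutral_set(cons, all_loci = c("L1", "L2", "L3", "L4"))
  expect_setequal(ns$retained, c("L2", "L4"))
  expect_setequal(ns$excluded, c("L1", "L3"))
  # no flags anywhere keeps everything
  cons0 <- cons; cons0$any_flag <- FALSE
  expect_setequal(build_neutral_set(cons0, c("L1", "L2"))$retained,
                  c("L1", "L2"))
  # mismatched locus sets are rejected
  bs2 <- bs; bs2$loci <- bs_loci[1:2, ]
  expect_error(build_consensus(list("OL-RL" = fd), list("OL-RL" = bs2)),
               "mismatched")
})

test_that("the codominant null envelope calibrates and scores multiallelic loci", {
  cfg <- island_model_config(n_a = 40, n_b = 40, n_sim_loci = 3000,
                             system = "codominant", k_alleles = 4,
                             seed = 31)
  env <- simulate_null_envelope(cfg, target_fst = 0.08)
  expect_lt(abs(env$realized_fst - 0.08), 1e-3)
  # score a small codominant dataset against it through the scan
  set.seed(32)
  n <- 40
  a1 <- matrix(sample.int(4, n * 2 * 30, TRUE), n * 2, 30)
  a2 <- matrix(sample.int(4, n * 2 * 30, TRUE), n * 2, 30)
  colnames(a1) <- colnames(a2) <- sprintf("S%02d", 1:30)
  samp <- sample_table(sprintf("I%03d", 1:(2 * n)),
                       sprintf("A%03d", 1:(2 * n)),
                       rep(c("OL", "RL"), each = n))
  rownames(a1) <- rownames(a2) <- samp$individual
  ds <- genotype_dataset(samp, codominant = codominant_matrix(a1, a2))
  ft <- count_codominant_freq(ds$codominant, ds$samples)
  fd <- suppressWarnings(fdist_scan(ft, "OL", "RL", cfg))
  expect_true(all(fd$loci$p >= 0 & fd$loci$p <= 1, na.rm = TRUE))
  # identical draws for both pools: no outliers expected
  expect_lte(sum(fd$loci$outlier), 1)
})
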