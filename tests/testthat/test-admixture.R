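# Short chains are enough for the properties checked here; the
# acceptance suite exercises recovery at the test-profile lengths.
quick_acfg <- function(seed, K = 2L, len = 600L)
  admixture_config(K = K, burn_in = len, mcmc_reps = len,
                   final_burn_in = len, final_reps = len, seed = seed)

test_that("K = 1 forces unit membership and q rows always sum to one", {
  pr <- make_pair_dataset(seed = 1, n_loci = 60, n_a = 20, n_b = 20,
                          target_fst = 0.2)
  f1 <- run_admixture(pr$dataset, quick_acfg(5, K = 1L, len = 200L))
  expect_true(all(abs(f1$q - 1) < 1e-9))
  f2 <- run_admixture(pr$dataset, quick_acfg(5, K = 3L, len = 200L))
  expect_true(all(abs(rowSums(f2$q) - 1) < 1e-9))
  expect_error(run_admixture(pr$dataset,
                             quick_acfg(5, K = 50L, len = 10L)),
               "exceeds")
})

test_that("two diverged pools are recovered with high own-cluster membership", {
  pr <- make_pair_dataset(seed = 21, n_loci = 150, n_a = 40, n_b = 40,
                          target_fst = 0.2)
  fit <- anchor_clusters(run_admixture(pr$dataset, quick_acfg(8)), "OL")
  s <- fit$samples
  expect_gt(mean(fit$q[s$population == "OL", 1L]), 0.9)
  expect_gt(mean(fit$q[s$population == "RL", 2L]), 0.9)
  # accession means are arithmetic means of member individuals
  acc1 <- s$accession[1L]
  expect_equal(unname(fit$q_accession[acc1, 1L]),
               mean(fit$q[s$accession == acc1, 1L]), tolerance = 1e-12)
})

test_that("F1 crosses between the pools recover intermediate ancestry", {
  set.seed(31)
  pr <- make_pair_dataset(seed = 31, n_loci = 150, n_a = 40, n_b = 40,
                          target_fst = 0.2)
  # append 12 synthetic F1 individuals: one allele from each pool
  p_a <- pr$p_a; p_b <- pr$p_b
  n_f1 <- 12
  g1 <- matrix(rbinom(n_f1 * length(p_a), 1, rep(p_a, each = n_f1)), n_f1)
  g2 <- matrix(rbinom(n_f1 * length(p_b), 1, rep(p_b, each = n_f1)), n_f1)
  ph <- pmax(g1, g2)
  colnames(ph) <- colnames(pr$dataset$dominant)
  M <- rbind(unclass(pr$dataset$dominant), ph)
  ids <- c(pr$dataset$samples$individual, sprintf("F1_%02d", 1:n_f1))
  rownames(M) <- ids
  samp <- sample_table(ids,
                       c(pr$dataset$samples$accession,
                         rep("F1A", n_f1)),
                       c(pr$dataset$samples$population,
                         rep("NI", n_f1)))
  ds <- genotype_dataset(samp, dominant = dominant_matrix(M))
  fit <- anchor_clusters(run_admixture(ds, quick_acfg(9, len = 800L)), "OL")
  q_f1 <- mean(fit$q[samp$population == "NI", 1L])
  expect_lt(abs(q_f1 - 0.5), 0.15)
})

test_that("Evanno delta-K reproduces the hand-worked oracle", {
  L <- cbind(K1 = c(-100, -100), K2 = c(-48, -52), K3 = c(-49, -49),
             K4 = c(-48, -50))
  attr(L, "k_range") <- 1:4
  # K3 has zero run-to-run sd: its delta-K is undefined, with a warning
  expect_warning(ks <- select_k(L), "zero sd")
  expect_true(is.na(ks$delta_k[3L]))
  # per-run |second difference| = {53, 45}, mean 49; sd(L(2)) = 2.828
  expect_equal(ks$delta_k[2L], 49 / sd(c(-48, -52)), tolerance = 1e-9)
  expect_equal(round(ks$delta_k[2L], 2), 17.32)
  expect_identical(attr(ks, "best_k"), 2L)
  # exactly linear lnL in K has zero second difference
  L2 <- cbind(K1 = c(-30, -31), K2 = c(-20, -21), K3 = c(-10, -11))
  attr(L2, "k_range") <- 1:3
  expect_equal(select_k(L2)$delta_k[2L], 0)
})

test_that("cluster anchoring fixes label switching deterministically", {
  pr <- make_pair_dataset(seed = 41, n_loci = 100, n_a = 30, n_b = 30,
                          target_fst = 0.2)
  fit <- run_admixture(pr$dataset, quick_acfg(3, len = 400L))
  anchored <- anchor_clusters(fit, "OL")
  s <- fit$samples
  expect_gte(mean(anchored$q[s$population == "OL", 1L]),
             mean(anchored$q[s$population == "OL", 2L]))
  expect_error(anchor_clusters(fit, "FMM"), "no individuals")
})

test_that("recent-landrace accessions are classified against the OL threshold", {
  # construct a fit object directly: the rule is deterministic
  samp <- sample_table(sprintf("i%02d", 1:10),
                       rep(c("O1", "O2", "O3", "R1", "R2"), each = 2),
                       rep(c("OL", "OL", "OL", "RL", "RL"), each = 2))
  q <- cbind(c(.95, .95, .87, .87, .92, .92, .90, .90, .70, .70))
  q <- cbind(q, 1 - q)
  rownames(q) <- samp$individual
  fit <- structure(list(
    q = q,
    q_accession = apply(q, 2, function(col) tapply(col, samp$accession, mean)),
    K = 2L, samples = samp), class = "admix_fit")
  colnames(fit$q_accession) <- c("q1", "q2")
  cl <- classify_rl(fit)
  expect_equal(cl$threshold, 0.87)
  expect_identical(cl$classes$class, c("RL_A", "RL_B"))
})
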