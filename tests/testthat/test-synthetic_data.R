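small_cfg <- function(seed, ...) {
  sim_config(seed = seed, n_dominant_loci = 80, n_codominant_loci = 6,
             accessions = c(OL = 6, RL = 6, NI = 2, FMM = 2, DMM = 4),
             genotypes = c(OL = 24, RL = 24, NI = 6, FMM = 4, DMM = 12),
             m = rep(0.01, 6), ...)
}

test_that("identical seed and config give byte-identical datasets", {
  s1 <- simulate_study(small_cfg(123))
  s2 <- simulate_study(small_cfg(123))
  expect_identical(unclass(s1$dataset$dominant),
                   unclass(s2$dataset$dominant))
  expect_identical(s1$dataset$codominant, s2$dataset$codominant)
  expect_identical(s1$truth$ancestry, s2$truth$ancestry)
  s3 <- simulate_study(small_cfg(124))
  expect_false(identical(unclass(s1$dataset$dominant),
                         unclass(s3$dataset$dominant)))
})

test_that("no-evolution limit keeps recent landraces at the source frequencies", {
  cfg <- small_cfg(7)
  cfg$m[] <- 0
  cfg$t_recent <- 0L
  cfg$f_target[["RL"]] <- 0
  sim <- simulate_study(cfg)
  ft <- estimate_dominant_freq_table(sim$dataset$dominant,
                                     sim$dataset$samples)
  th <- pairwise_fst(system = "dominant", pop_a = "OL", pop_b = "RL",
                     freqs = ft)$theta
  expect_lt(abs(th), 0.05)  # binomial sampling error only
  expect_true(all(sim$truth$ancestry$ancestry[
    sim$truth$ancestry$accession != "RL_CTRL"] == 0))
})

test_that("migrant ancestry matches the closed-form replacement expectation", {
  m <- 0.02; t <- 50
  expected <- 1 - (1 - m)^t
  means <- vapply(1:20, function(r) {
    cfg <- sim_config(seed = 1000 + r, n_dominant_loci = 30,
                      n_codominant_loci = 0,
                      accessions = c(OL = 2, RL = 4, NI = 1, FMM = 1,
                                     DMM = 2),
                      genotypes = c(OL = 8, RL = 16, NI = 2, FMM = 2,
                                    DMM = 8),
                      m = rep(m, 4), include_control = FALSE)
    sim <- simulate_study(cfg)
    mean(sim$truth$ancestry$ancestry)
  }, numeric(1))
  expect_equal(mean(means), expected, tolerance = 0.05)
})

test_that("split-time default lands near the target divergence", {
  # realized multi-locus F_ST(OL, DMM) within +/- 0.03 of 0.22 on
  # average over 10 replicates of the default (bisection-calibrated)
  # design; fewer loci keep the run short
  fst <- vapply(1:10, function(r) {
    cfg <- sim_config(seed = 4000 + r, n_dominant_loci = 120)
    sim <- simulate_study(cfg)
    ft <- estimate_dominant_freq_table(sim$dataset$dominant,
                                       sim$dataset$samples)
    pairwise_fst(system = "dominant", pop_a = "OL", pop_b = "DMM",
                 freqs = ft)$theta
  }, numeric(1))
  expect_lt(abs(mean(fst) - 0.22), 0.03)
})

test_that("dominant masking implements dominance with missing propagation", {
  a1 <- matrix(c(1L, 1L, 0L, -9L), 4, 1, dimnames = list(NULL, "L1"))
  a2 <- matrix(c(1L, 0L, 0L, -9L), 4, 1, dimnames = list(NULL, "L1"))
  dm <- mask_dominant(codominant_matrix(a1, a2))
  expect_equal(unname(unclass(dm)[, 1]), c(1L, 1L, 0L, -9L))
  # all-absence locus stays all absent
  z <- matrix(0L, 3, 1, dimnames = list(NULL, "L1"))
  expect_true(all(unclass(mask_dominant(codominant_matrix(z, z))) == 0L))
  # >2 alleles rejected
  a3 <- matrix(c(1L, 2L, 3L), 3, 1, dimnames = list(NULL, "L1"))
  expect_error(mask_dominant(codominant_matrix(a3, a3)), "more than 2")
})

test_that("masked phenotype frequency matches the HWE expectation", {
  set.seed(42)
  for (p in seq(0.1, 0.9, by = 0.2)) {
    n <- 4000
    a1 <- matrix(rbinom(n, 1L, p), n, 1, dimnames = list(NULL, "L1"))
    a2 <- matrix(rbinom(n, 1L, p), n, 1, dimnames = list(NULL, "L1"))
    dm <- mask_dominant(codominant_matrix(a1, a2))
    expect_lt(abs(mean(unclass(dm)) - (1 - (1 - p)^2)), 0.02)
  }
})

test_that("selection moves recent-landrace frequencies toward or away from the donor", {
  sel <- data.frame(locus = c("L001", "L002"), s = c(0.08, 0.08),
                    direction = c("favor", "barrier"))
  cfg <- small_cfg(55, selected_loci = sel)
  cfg$m <- rep(0.01, 6)
  sim <- simulate_study(cfg)
  tf <- sim$truth$freqs$dominant
  # favored locus: RL moves from OL toward (possibly beyond) the
  # DMM-characteristic allele
  dir_dmm <- sign(tf["DMM", "L001"] - tf["OL", "L001"])
  moved <- (tf["RL", "L001"] - tf["OL", "L001"]) * dir_dmm
  expect_gt(moved, -0.02)
  expect_identical(sim$truth$loci$class[1:2], c("selected", "selected"))
  expect_error(simulate_study(small_cfg(1, selected_loci =
    data.frame(locus = "nope", s = 0.1, direction = "favor"))),
    "unknown selected locus")
})

test_that("control accession is a modern-type outgroup inside RL", {
  sim <- simulate_study(small_cfg(99))
  s <- sim$dataset$samples
  expect_true(any(s$control))
  expect_true(all(s$population[s$control] == "RL"))
  anc <- sim$truth$ancestry
  expect_true(all(anc$ancestry[anc$accession == "RL_CTRL"] == 1))
})

test_that("the default design reproduces the study-scale sample layout", {
  sim <- simulate_study(sim_config(seed = 1, n_dominant_loci = 20,
                                   n_codominant_loci = 2))
  s <- sim$dataset$samples
  expect_identical(nrow(s), 218L)
  expect_identical(length(unique(s$accession)), 104L)
  tab <- table(s$population)
  expect_identical(as.integer(tab[c("OL", "RL", "NI", "FMM", "DMM")]),
                   c(83L, 77L, 22L, 12L, 24L))
  acc <- table(tapply(s$population, s$accession, `[`, 1L))
  expect_identical(as.integer(acc[c("OL", "RL", "NI", "FMM", "DMM")]),
                   c(43L, 20L, 11L, 8L, 22L))
})
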