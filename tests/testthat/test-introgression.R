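test_that("standardisation maps the anchors to 0 and 1 and is affine-invariant", {
  expect_equal(standardized_q2(0.06, 0.06, 0.98), 0)
  expect_equal(standardized_q2(0.98, 0.06, 0.98), 1)
  # published whole-population inputs: q2(RL)=0.37, anchors 0.06 / 0.98
  expect_equal(round(standardized_q2(0.37, 0.06, 0.98), 4), 0.3370)
  # monotone / affine invariance
  q <- c(0.1, 0.2, 0.5)
  s1 <- standardized_q2(q, 0.05, 0.9)
  s2 <- standardized_q2(2 * q + 1, 2 * 0.05 + 1, 2 * 0.9 + 1)
  expect_equal(s1, s2)
  expect_true(all(diff(s1) > 0))
  expect_error(standardized_q2(0.5, 0.4, 0.4), "anchor")
})

test_that("diversity-change contrast separates neutral and outlier classes", {
  # freq table built by hand: outlier loci lose diversity in pop A
  loci <- sprintf("L%02d", 1:10)
  mk_cell <- function(p) c(present = p, absent = 1 - p)
  fa <- lapply(c(rep(0.45, 7), 0.02, 0.03, 0.05), mk_cell)
  fb <- lapply(c(rep(0.5, 7), 0.4, 0.45, 0.5), mk_cell)
  names(fa) <- names(fb) <- loci
  ft <- structure(list(populations = c("OL", "RL"), loci = loci,
                       freq = list(OL = fa, RL = fb),
                       n = list(OL = setNames(rep(40L, 10), loci),
                                RL = setNames(rep(40L, 10), loci)),
                       system = "dominant"), class = "freq_table")
  dh <- delta_h_by_class(ft, outlier_loci = c("L08", "L09", "L10"),
                         "OL", "RL")
  expect_identical(dh$class, c("neutral", "outlier"))
  expect_gt(dh$delta_h[dh$class == "outlier"],
            dh$delta_h[dh$class == "neutral"])
  expect_lt(attr(dh, "p_value"), 0.05)
  # identical diversities give zero change
  ft0 <- ft; ft0$freq$RL <- ft0$freq$OL
  dh0 <- delta_h_by_class(ft0, "L08", "OL", "RL")
  expect_equal(dh0$delta_h, c(0, 0))
})

test_that("neutral-set contrast requires enough retained loci", {
  pr <- make_pair_dataset(seed = 3, n_loci = 40, n_a = 20, n_b = 20)
  ns <- structure(list(retained = sprintf("L%03d", 1:5),
                       excluded = character(0), reasons = list()),
                  class = "neutral_set")
  cfg <- admixture_config(K = 2, burn_in = 100, mcmc_reps = 100,
                          final_burn_in = 100, final_reps = 100, seed = 1)
  expect_error(introgression_contrast(pr$dataset, ns, cfg), "too small")
})

test_that("self-comparison neutral set reproduces the all-loci estimate", {
  pr <- make_pair_dataset(seed = 47, n_loci = 120, n_a = 30, n_b = 30,
                          target_fst = 0.2, pops = c("OL", "DMM"))
  # add a small RL group drawn as 75/25 mixture of the pools
  set.seed(48)
  n_rl <- 20
  p_mix <- 0.75 * pr$p_a + 0.25 * pr$p_b
  M_rl <- matrix(rbinom(n_rl * length(p_mix), 1,
                        rep(1 - (1 - p_mix)^2, each = n_rl)), n_rl)
  colnames(M_rl) <- colnames(pr$dataset$dominant)
  M <- rbind(unclass(pr$dataset$dominant), M_rl)
  ids <- c(pr$dataset$samples$individual, sprintf("RL%02d", 1:n_rl))
  rownames(M) <- ids
  samp <- sample_table(ids,
                       c(pr$dataset$samples$accession,
                         rep(sprintf("RA%02d", 1:5), each = 4)),
                       c(pr$dataset$samples$population, rep("RL", n_rl)))
  ds <- genotype_dataset(samp, dominant = dominant_matrix(M))
  ns <- structure(list(retained = colnames(M), excluded = character(0),
                       reasons = list()), class = "neutral_set")
  cfg <- admixture_config(K = 2, burn_in = 400, mcmc_reps = 400,
                          final_burn_in = 800, final_reps = 800, seed = 5)
  ic <- introgression_contrast(ds, ns, cfg)
  # identical locus sets: only MCMC noise separates the two runs
  expect_lt(abs(ic$q2_all - ic$q2_neutral), 0.05)
  expect_gt(ic$p_value, 0.05)
  # RL true modern-ancestry share is 0.25; the standardised estimate
  # recovers it within MCMC and sampling error
  expect_lt(abs(ic$q2_all_std - 0.25), 0.12)
})
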