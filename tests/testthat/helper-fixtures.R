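# Shared fixture builders: everything is generated in code.

# Small two-population dominant dataset with known allele frequencies.
make_pair_dataset <- function(seed, n_loci = 120, n_a = 40, n_b = 40,
                              target_fst = 0.05, ne = 500,
                              pops = c("OL", "RL"), plant = NULL) {
  set.seed(seed)
  t_gen <- ceiling(log(1 - target_fst) / log(1 - 1 / (2 * ne)))
  p0 <- runif(n_loci, 0.05, 0.95)
  drift <- function(p, t) {
    for (g in seq_len(t)) p <- rbinom(length(p), 2 * ne, p) / (2 * ne)
    p
  }
  pa <- drift(p0, t_gen)
  pb <- drift(p0, t_gen)
  if (!is.null(plant)) {
    pa[seq_along(plant$p_a)] <- plant$p_a
    pb[seq_along(plant$p_b)] <- plant$p_b
  }
  mk <- function(p, n) matrix(rbinom(n * length(p), 1,
                                     rep(1 - (1 - p)^2, each = n)), n)
  M <- rbind(mk(pa, n_a), mk(pb, n_b))
  colnames(M) <- sprintf("L%03d", seq_len(n_loci))
  n_tot <- n_a + n_b
  samp <- sample_table(
    sprintf("I%03d", seq_len(n_tot)),
    rep(sprintf("A%02d", seq_len(ceiling(n_tot / 5))), each = 5,
        length.out = n_tot),
    rep(pops, c(n_a, n_b)))
  rownames(M) <- samp$individual
  list(dataset = genotype_dataset(samp, dominant = dominant_matrix(M)),
       p_a = pa, p_b = pb)
}

# Tiny codominant dataset drawn from explicit genotype frequencies.
make_codominant_dataset <- function(seed, n = 20, n_loci = 3, k = 4,
                                    pops = "OL", selfed = FALSE) {
  set.seed(seed)
  a1 <- matrix(sample.int(k, n * n_loci, replace = TRUE), n, n_loci)
  a2 <- if (selfed) a1
        else matrix(sample.int(k, n * n_loci, replace = TRUE), n, n_loci)
  colnames(a1) <- colnames(a2) <- sprintf("S%02d", seq_len(n_loci))
  samp <- sample_table(sprintf("I%03d", seq_len(n)),
                       sprintf("A%03d", seq_len(n)),
                       rep(pops, length.out = n))
  rownames(a1) <- rownames(a2) <- samp$individual
  genotype_dataset(samp, codominant = codominant_matrix(a1, a2))
}

# Table of published dominant band frequencies / He used by the
# worked-example checks (band-presence frequency, population, He).
published_he_cases <- function() {
  data.frame(
    locus = c("26d", "15d", "11c", "40f", "33f"),
    population = c("OL", "DMM", "FMM", "OL", "DMM"),
    p = c(0.98, 0.83, 0.07, 0.03, 0.00),
    he = c(0.04, 0.28, 0.13, 0.06, 0.00))
}

# Independent brute-force Weir-Cockerham components for two
# populations, coded straight from the published theta formulas.
oracle_wc_theta <- function(geno_a, geno_b) {
  # geno_* : list(a1=, a2=) vectors for one locus
  pops <- list(geno_a, geno_b)
  r <- 2
  n <- vapply(pops, function(g) length(g$a1), numeric(1))
  alleles <- sort(unique(unlist(lapply(pops, function(g) c(g$a1, g$a2)))))
  nbar <- mean(n); nsum <- sum(n)
  nc <- (nsum - sum(n^2) / nsum) / (r - 1)
  A <- B <- C <- 0
  for (al in alleles) {
    p <- vapply(pops, function(g)
      mean(c(g$a1, g$a2) == al), numeric(1))
    h <- vapply(pops, function(g)
      mean((g$a1 == al) != (g$a2 == al)), numeric(1))
    pbar <- sum(n * p) / nsum
    s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * h) / nsum
    A <- A + (nbar / nc) * (s2 - (1 / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    B <- B + (nbar / (nbar - 1)) * (pbar * (1 - pbar) -
      (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    C <- C + hbar / 2
  }
  c(a = A, b = B, c = C)
}
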