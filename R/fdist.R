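# Vectorised Weir-Cockerham theta for a biallelic locus scored in two
# populations, from allele frequencies and gene-copy counts.
theta_freq_pair <- function(p1, p2, n1, n2) {
  nbar <- (n1 + n2) / 2
  nsum <- n1 + n2
  nc <- nsum - (n1^2 + n2^2) / nsum
  pbar <- (n1 * p1 + n2 * p2) / nsum
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 / 2) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 / 2)
  ifelse(a + b != 0, a / (a + b), NA_real_)
}

#' Configuration for the island-model null envelope
#'
#' @param n_a,n_b sample sizes of the two demes (individuals).
#' @param n_sim_loci simulated neutral loci (100,000 in the full
#'   protocol; smaller values are appropriate desk-scale).
#' @param system `"dominant"` or `"codominant"`.
#' @param f_is inbreeding coefficient assumed when scoring dominant
#'   phenotypes (also used by the Bayesian frequency estimator applied
#'   to the simulated loci).
#' @param k_alleles alleles per simulated codominant locus.
#' @param trim trimmed-mean fraction removed from each tail of the
#'   per-locus F_ST distribution.
#' @param alpha significance level of the conditional test.
#' @param max_iter maximum calibration iterations of the scan.
#' @param n_bins target number of equal-count heterozygosity bins.
#' @param min_bin minimum simulated loci per bin (smaller bins are
#'   merged with neighbours).
#' @param max_allele_freq loci whose pooled commonest-allele frequency
#'   reaches this value are excluded from calibration and reported
#'   untested (dominant mode).
#' @param seed mandatory RNG seed.
#' @return An `island_model_config` object.
#' @export
island_model_config <- function(n_a, n_b, n_sim_loci = 100000L,
                                system = c("dominant", "codominant"),
                                f_is = 0, k_alleles = 5L, trim = 0.30,
                                alpha = 0.01, max_iter = 10L,
                                n_bins = 50L, min_bin = 200L,
                                max_allele_freq = 0.98, seed) {
  if (missing(seed)) stop("seed is mandatory")
  system <- match.arg(system)
  stopifnot(trim >= 0, trim < 0.5, alpha > 0, alpha < 1,
            n_a >= 2, n_b >= 2)
  structure(list(n_a = as.integer(n_a), n_b = as.integer(n_b),
                 n_sim_loci = as.integer(n_sim_loci), system = system,
                 f_is = f_is, k_alleles = as.integer(k_alleles),
                 trim = trim, alpha = alpha,
                 max_iter = as.integer(max_iter),
                 n_bins = as.integer(n_bins), min_bin = as.integer(min_bin),
                 max_allele_freq = max_allele_freq, seed = seed),
            class = "island_model_config")
}

trimmed_mean <- function(x, trim) {
  x <- sort(x[is.finite(x)])
  k <- floor(length(x) * trim)
  if (2 * k >= length(x)) return(mean(x))
  mean(x[(k + 1):(length(x) - k)])
}

# Simulate one batch of neutral loci at island-model parameter nu
# (deme frequencies ~ Beta around a common ancestral frequency with
# F_ST-like variance parameter 1/(1+nu)), scored and re-estimated with
# the same machinery as the observed data.  Returns He/F_ST per locus.
# Ancestral frequencies are resampled from `p0_pool` (typically the
# pooled observed allele frequencies, so the simulated heterozygosity
# mixture matches the data) or drawn uniform when no pool is given.
simulate_null_batch <- function(cfg, nu, p0_pool = NULL) {
  L <- cfg$n_sim_loci
  if (cfg$system == "dominant") {
    p0 <- if (is.null(p0_pool)) runif(L, 0.02, 0.98)
          else pmin(0.99, pmax(0.01, sample(p0_pool, L, replace = TRUE)))
    p1 <- rbeta(L, p0 * nu, (1 - p0) * nu)
    p2 <- rbeta(L, p0 * nu, (1 - p0) * nu)
    q1 <- 1 - p1; q2 <- 1 - p2
    f <- cfg$f_is
    x1 <- rbinom(L, cfg$n_a, q1^2 + f * q1 * (1 - q1))
    x2 <- rbinom(L, cfg$n_b, q2^2 + f * q2 * (1 - q2))
    # same Bayesian estimator as the observed pipeline (memoised over
    # the finitely many (x, n) pairs)
    tab_a <- vapply(0:cfg$n_a, function(x)
      estimate_dominant_freq(x, cfg$n_a, F = f)$p, numeric(1))
    tab_b <- vapply(0:cfg$n_b, function(x)
      estimate_dominant_freq(x, cfg$n_b, F = f)$p, numeric(1))
    ph1 <- tab_a[x1 + 1L]; ph2 <- tab_b[x2 + 1L]
    fst <- theta_freq_pair(ph1, ph2, 2 * cfg$n_a, 2 * cfg$n_b)
    he <- (2 * ph1 * (1 - ph1) + 2 * ph2 * (1 - ph2)) / 2
  } else {
    k <- cfg$k_alleles
    f0 <- matrix(rgamma(L * k, 1), L, k)
    f0 <- f0 / rowSums(f0)
    g1 <- matrix(rgamma(L * k, rep(t(f0 * nu), 1)), L, k, byrow = TRUE)
    g2 <- matrix(rgamma(L * k, rep(t(f0 * nu), 1)), L, k, byrow = TRUE)
    p1 <- g1 / rowSums(g1); p2 <- g2 / rowSums(g2)
    # multinomial sampling of 2n allele copies per deme
    c1 <- t(vapply(seq_len(L), function(i)
      as.numeric(rmultinom(1L, 2 * cfg$n_a, p1[i, ])), numeric(k)))
    c2 <- t(vapply(seq_len(L), function(i)
      as.numeric(rmultinom(1L, 2 * cfg$n_b, p2[i, ])), numeric(k)))
    ph1 <- c1 / (2 * cfg$n_a); ph2 <- c2 / (2 * cfg$n_b)
    fst <- he <- numeric(L)
    for (i in seq_len(L)) {
      comp <- wc_components_freq_multi(rbind(ph1[i, ], ph2[i, ]),
                                       c(2 * cfg$n_a, 2 * cfg$n_b))
      fst[i] <- if (sum(comp) != 0) comp[1L] / sum(comp) else NA_real_
      he[i] <- (1 - sum(ph1[i, ]^2) + 1 - sum(ph2[i, ]^2)) / 2
    }
  }
  data.frame(he = he, fst = fst)
}

# Multi-allele frequency-based WC components: freqs is a 2 x k matrix.
wc_components_freq_multi <- function(freqs, n_copies) {
  nbar <- mean(n_copies); nsum <- sum(n_copies)
  nc <- nsum - sum(n_copies^2) / nsum
  asum <- bsum <- 0
  for (a in seq_len(ncol(freqs))) {
    p <- freqs[, a]
    pbar <- sum(n_copies * p) / nsum
    s2 <- sum(n_copies * (p - pbar)^2) / nbar
    asum <- asum + (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - s2 / 2) / (nbar - 1))
    bsum <- bsum + (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 / 2)
  }
  c(a = asum, b = bsum)
}

#' Simulate the neutral F_ST | He envelope
#'
#' Solves (by bisection on the island-model variance parameter) for the
#' migration-drift intensity at which the trimmed-mean F_ST of the
#' simulated neutral loci matches `target_fst`, then returns the
#' simulated loci binned by heterozygosity, from which conditional
#' P-values P(F_ST >= f | He) are evaluated by empirical tail
#' probabilities with linear interpolation between bin centres.
#'
#' @param cfg an [island_model_config()].
#' @param target_fst target neutral F_ST, in (0, 0.9).
#' @param tol calibration tolerance on the trimmed-mean F_ST.
#' @param p0_pool optional pool of observed pooled allele frequencies
#'   from which simulated ancestral frequencies are resampled, so the
#'   simulated heterozygosity mixture matches the data; uniform when
#'   `NULL`.
#' @return A `null_envelope` object (use [envelope_p()] to evaluate
#'   conditional P-values).
#' @export
simulate_null_envelope <- function(cfg, target_fst, tol = 1e-3,
                                   p0_pool = NULL) {
  if (target_fst <= 0 || target_fst >= 0.9)
    stop("target F_ST must be in (0, 0.9)")
  set.seed(cfg$seed)
  # nu = (1-FST)/FST at the process level; the realised estimator mean
  # differs through sampling, hence the bisection.
  lo <- log((1 - min(0.89, target_fst * 4 + 0.05)) /
              min(0.89, target_fst * 4 + 0.05))
  hi <- log((1 - max(0.0005, target_fst / 8)) /
              max(0.0005, target_fst / 8))
  batch <- NULL; realized <- NA_real_
  for (it in seq_len(30L)) {
    mid <- (lo + hi) / 2
    nu <- exp(mid)
    batch <- simulate_null_batch(cfg, nu, p0_pool)
    # same zero-clipping as the observed-side calibration target, so
    # the two centres are computed identically
    realized <- trimmed_mean(pmax(batch$fst, 0), cfg$trim)
    if (abs(realized - target_fst) <= tol) break
    if (realized > target_fst) lo <- mid else hi <- mid
  }
  if (abs(realized - target_fst) > 50 * tol)
    stop("unattainable target F_ST ", target_fst)
  ok <- is.finite(batch$fst) & is.finite(batch$he)
  sim <- batch[ok, ]
  ord <- order(sim$he)
  sim <- sim[ord, ]
  n <- nrow(sim)
  per <- max(cfg$min_bin, ceiling(n / cfg$n_bins))
  starts <- seq(1L, n, by = per)
  bins <- lapply(seq_along(starts), function(b) {
    i0 <- starts[b]; i1 <- min(n, i0 + per - 1L)
    list(he_mid = median(sim$he[i0:i1]), fst = sort(sim$fst[i0:i1]))
  })
  if (length(bins) > 1L) {
    last <- bins[[length(bins)]]
    if (length(last$fst) < cfg$min_bin) {   # merge ragged tail bin
      prev <- bins[[length(bins) - 1L]]
      bins[[length(bins) - 1L]] <- list(
        he_mid = median(c(prev$he_mid, last$he_mid)),
        fst = sort(c(prev$fst, last$fst)))
      bins[[length(bins)]] <- NULL
    }
  }
  structure(list(bins = bins, nu = exp((lo + hi) / 2),
                 realized_fst = realized, target_fst = target_fst,
                 config = cfg),
            class = "null_envelope")
}

#' Conditional P-values against a null envelope
#'
#' @param env a `null_envelope`.
#' @param fst,he per-locus observed values.
#' @return Vector of P(F_ST >= observed | He), via the empirical tail
#'   probability (+1 corrected) in the He bin, interpolated linearly
#'   between the two nearest bin centres.
#' @export
envelope_p <- function(env, fst, he) {
  mids <- vapply(env$bins, `[[`, numeric(1L), "he_mid")
  p_in_bin <- function(b, f) {
    v <- env$bins[[b]]$fst
    (1 + length(v) - findInterval(f - 1e-12, v)) / (length(v) + 1)
  }
  vapply(seq_along(fst), function(i) {
    f <- fst[i]; h <- he[i]
    if (!is.finite(f) || !is.finite(h)) return(NA_real_)
    j <- findInterval(h, mids)
    if (j <= 0L) return(p_in_bin(1L, f))
    if (j >= length(mids)) return(p_in_bin(length(mids), f))
    w <- (h - mids[j]) / (mids[j + 1L] - mids[j])
    (1 - w) * p_in_bin(j, f) + w * p_in_bin(j + 1L, f)
  }, numeric(1L))
}

#' Iteratively calibrated F_ST-outlier scan
#'
#' The simulated-null scan: per-locus F_ST and He for a population pair
#' are compared against a neutral envelope whose target F_ST is the
#' trimmed mean of the retained loci; loci departing from the envelope
#' at the significance level are excluded and the envelope re-targeted,
#' until no further locus falls outside (or `max_iter`).  A final pass
#' evaluates every locus (including any excluded up front for a pooled
#' commonest-allele frequency at or above the cutoff, which are
#' reported untested) against the converged envelope.
#'
#' @param freqs a `freq_table` for the pair's marker system.
#' @param pop_a,pop_b population labels.
#' @param cfg an [island_model_config()].
#' @return An `fdist_result`: data frame `loci` (locus, he, fst, p,
#'   outlier, tested) plus the calibration history.
#' @export
fdist_scan <- function(freqs, pop_a, pop_b, cfg) {
  obs <- observed_pair_stats(freqs, pop_a, pop_b)
  testable <- obs$tested
  retained <- testable & is.finite(obs$fst)
  flagged <- rep(FALSE, length(obs$fst))
  history <- list()
  env <- NULL
  converged <- FALSE
  for (it in seq_len(cfg$max_iter)) {
    target <- trimmed_mean(pmax(obs$fst[retained], 0), cfg$trim)
    target <- min(max(target, 0.004), 0.89)
    cfg_it <- cfg
    cfg_it$seed <- cfg$seed + it
    pool <- obs$pool[retained]
    pool <- pool[is.finite(pool)]
    if (length(pool) < 10L) pool <- NULL
    env <- simulate_null_envelope(cfg_it, target, p0_pool = pool)
    p <- envelope_p(env, obs$fst, obs$he)
    new_flag <- testable & !is.na(p) & p < cfg$alpha
    history[[it]] <- data.frame(iteration = it, target_fst = target,
                                realized_fst = env$realized_fst,
                                n_excluded = sum(new_flag | flagged))
    converged <- !any(new_flag & !flagged)
    flagged <- flagged | new_flag
    retained <- testable & is.finite(obs$fst) & !flagged
    if (converged) break
  }
  if (!converged)
    warning("calibration did not converge within ", cfg$max_iter,
            " iterations; reporting the last envelope")
  # final pass: every locus with a finite F_ST is evaluated against the
  # converged envelope; up-front excluded loci keep tested = FALSE and
  # are never flagged
  p_final <- envelope_p(env, obs$fst, obs$he)
  loci <- data.frame(locus = obs$locus, he = obs$he, fst = obs$fst,
                     p = p_final,
                     outlier = obs$tested & !is.na(p_final) &
                       p_final < cfg$alpha,
                     tested = obs$tested, stringsAsFactors = FALSE)
  structure(list(loci = loci, history = do.call(rbind, history),
                 envelope = env, pops = c(pop_a, pop_b),
                 converged = converged),
            class = "fdist_result")
}

# Observed per-locus F_ST / He / testability for a population pair,
# from a frequency table of either marker system.
observed_pair_stats <- function(freqs, pop_a, pop_b,
                                max_allele_freq = 0.98) {
  loci <- freqs$loci
  if (freqs$system == "dominant") {
    pa <- vapply(freqs$freq[[pop_a]], function(f)
      if (length(f)) f[["present"]] else NA_real_, numeric(1))
    pb <- vapply(freqs$freq[[pop_b]], function(f)
      if (length(f)) f[["present"]] else NA_real_, numeric(1))
    na <- freqs$n[[pop_a]]; nb <- freqs$n[[pop_b]]
    fst <- theta_freq_pair(pa, pb, 2 * na, 2 * nb)
    he <- (2 * pa * (1 - pa) + 2 * pb * (1 - pb)) / 2
    # commonest-allele screen on the raw phenotype-implied allele
    # frequency (the Bayesian posterior mean is shrunk away from the
    # boundary and would never trip the rule)
    if (!is.null(freqs$raw)) {
      phen <- (na * freqs$raw[[pop_a]] + nb * freqs$raw[[pop_b]]) /
        (na + nb)
      pool <- 1 - sqrt(pmax(0, 1 - phen))
    } else {
      pool <- (na * pa + nb * pb) / (na + nb)
    }
    tested <- pmax(pool, 1 - pool) < max_allele_freq & is.finite(fst)
    pool_freq <- (na * pa + nb * pb) / (na + nb)
  } else {
    fst <- he <- rep(NA_real_, length(loci))
    tested <- rep(FALSE, length(loci))
    for (i in seq_along(loci)) {
      fa <- freqs$freq[[pop_a]][[loci[i]]]
      fb <- freqs$freq[[pop_b]][[loci[i]]]
      if (length(fa) == 0L || length(fb) == 0L) next
      alleles <- union(names(fa), names(fb))
      m <- rbind(fa[alleles], fb[alleles])
      m[is.na(m)] <- 0
      n2 <- c(2 * freqs$n[[pop_a]][loci[i]], 2 * freqs$n[[pop_b]][loci[i]])
      comp <- wc_components_freq_multi(m, n2)
      fst[i] <- if (sum(comp) != 0) comp[1L] / sum(comp) else NA_real_
      he[i] <- (1 - sum(m[1L, ]^2) + 1 - sum(m[2L, ]^2)) / 2
      pool <- (n2[1L] * m[1L, ] + n2[2L] * m[2L, ]) / sum(n2)
      tested[i] <- max(pool) < max_allele_freq & is.finite(fst[i])
    }
    pool_freq <- rep(NA_real_, length(loci))
  }
  list(locus = loci, fst = unname(fst), he = unname(he),
       tested = unname(tested), pool = unname(pool_freq))
}
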