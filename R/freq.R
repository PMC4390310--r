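#' Prior specification for dominant allele-frequency estimation
#'
#' @param family `"uniform"`, `"beta"` or `"empirical-beta"` (a beta
#'   prior whose shape was fitted from the data, see
#'   [fit_empirical_prior()]).
#' @param a,b beta shape parameters (ignored for `"uniform"`).
#' @return A `prior_spec` object.
#' @export
prior_spec <- function(family = c("uniform", "beta", "empirical-beta"),
                       a = 1, b = 1) {
  family <- match.arg(family)
  if (family == "uniform") { a <- 1; b <- 1 }
  stopifnot(a > 0, b > 0)
  structure(list(family = family, a = a, b = b), class = "prior_spec")
}

#' Posterior mean allele frequency for a dominant locus
#'
#' The dominant phenotype hides the heterozygote: with band-absence
#' allele frequency q and inbreeding coefficient F, the probability of
#' the recessive (band-absent) phenotype is
#' \deqn{P(absent) = q^2 + F q (1 - q),}
#' the identity-by-descent decomposition of homozygote frequency.  With
#' x band-absent individuals among n scored, the posterior of q under a
#' Beta(a, b) prior is proportional to
#' \deqn{q^{a-1} (1-q)^{b-1} \pi(q)^x (1 - \pi(q))^{n-x}}
#' and its mean is evaluated by adaptive quadrature (no MCMC: the
#' problem is one-dimensional and deterministic).
#'
#' @param x number of band-absent individuals.
#' @param n number of scored individuals.
#' @param F inbreeding coefficient in `[0, 1]`.
#' @param prior a [prior_spec()].
#' @param rel_tol relative tolerance of the quadrature.
#' @return List with `q` (posterior mean band-absence frequency) and
#'   `p = 1 - q` (band-presence allele frequency).
#' @export
estimate_dominant_freq <- function(x, n, F = 0, prior = prior_spec(),
                                   rel_tol = 1e-8) {
  if (n == 0) stop("no scored individuals")
  stopifnot(x >= 0, x <= n, F >= 0, F <= 1)
  log_post <- function(q) {
    pi_abs <- q^2 + F * q * (1 - q)
    (prior$a - 1) * log(q) + (prior$b - 1) * log1p(-q) +
      x * log(pi_abs) + (n - x) * log1p(-pi_abs)
  }
  # Normalise by the mode to keep exp() in range.
  opt <- optimize(log_post, c(1e-12, 1 - 1e-12), maximum = TRUE)
  m <- opt$objective
  f0 <- function(q) exp(log_post(q) - m)
  f1 <- function(q) q * exp(log_post(q) - m)
  z0 <- integrate(f0, 0, 1, rel.tol = rel_tol, subdivisions = 500L)$value
  z1 <- integrate(f1, 0, 1, rel.tol = rel_tol, subdivisions = 500L)$value
  q_hat <- z1 / z0
  list(q = q_hat, p = 1 - q_hat)
}

# Vectorised, memoised version used by the scans: unique (x, n) pairs are
# estimated once.  F and prior are fixed within a call.
dominant_freq_vec <- function(x, n, F = 0, prior = prior_spec()) {
  key <- paste(x, n)
  uk <- unique(key)
  qs <- vapply(uk, function(k) {
    xn <- as.numeric(strsplit(k, " ", fixed = TRUE)[[1L]])
    estimate_dominant_freq(xn[1L], xn[2L], F = F, prior = prior)$q
  }, numeric(1L))
  unname(qs[match(key, uk)])
}

#' Fit an empirical beta prior for dominant allele frequencies
#'
#' Two-pass empirical Bayes: every locus is first estimated with the
#' uniform prior (pooled over populations, with the mean per-population
#' inbreeding coefficient); a Beta(a, b) is then fitted to the
#' distribution of those estimates by the method of moments.  If the
#' moment fit is degenerate (sample variance at least mean(1-mean)) the
#' uniform prior is returned with a warning.
#'
#' @param dominant a [dominant_matrix()].
#' @param samples a [sample_table()] (controls are excluded).
#' @param F scalar inbreeding coefficient, or named per-population
#'   vector (averaged for the pooled pass).
#' @return A [prior_spec()] with family `"empirical-beta"` (or
#'   `"uniform"` on fallback).
#' @export
fit_empirical_prior <- function(dominant, samples, F = 0) {
  keep <- !samples$control
  m <- unclass(dominant)[keep, , drop = FALSE]
  if (ncol(m) < 20L)
    stop("prior fitting needs at least 20 loci")
  Fbar <- min(max(mean(F, na.rm = TRUE), 0), 1)
  scored <- m != MISSING_CODE
  n <- colSums(scored)
  xa <- colSums(m == 0L & scored)
  ok <- n > 0
  q_hat <- dominant_freq_vec(xa[ok], n[ok], F = Fbar, prior = prior_spec())
  mu <- mean(q_hat)
  v <- var(q_hat)
  if (!is.finite(v) || v <= 0 || v >= mu * (1 - mu)) {
    warning("degenerate moment fit for empirical prior; using uniform")
    return(prior_spec("uniform"))
  }
  s <- mu * (1 - mu) / v - 1
  prior_spec("empirical-beta", a = mu * s, b = (1 - mu) * s)
}

#' Allele frequencies for codominant loci by direct counting
#'
#' @param codominant a [codominant_matrix()].
#' @param samples a [sample_table()]; controls are excluded.
#' @return A `freq_table`: list with `pop`, `locus`-indexed structures;
#'   `freq[[pop]][[locus]]` is a named allele-frequency vector and
#'   `n[[pop]][locus]` the number of non-missing individuals.
#' @export
count_codominant_freq <- function(codominant, samples) {
  keep <- !samples$control
  pops <- sort(unique(samples$population[keep]))
  loci <- colnames(codominant$a1)
  freq <- list(); nn <- list()
  for (pop in pops) {
    sel <- keep & samples$population == pop
    a1 <- codominant$a1[sel, , drop = FALSE]
    a2 <- codominant$a2[sel, , drop = FALSE]
    fl <- vector("list", length(loci)); names(fl) <- loci
    nv <- setNames(integer(length(loci)), loci)
    for (j in seq_along(loci)) {
      obs <- a1[, j] != MISSING_CODE
      nv[j] <- sum(obs)
      if (nv[j] == 0L) { fl[[j]] <- numeric(0); next }
      alleles <- c(a1[obs, j], a2[obs, j])
      tab <- table(alleles)
      fl[[j]] <- setNames(as.numeric(tab) / length(alleles), names(tab))
    }
    freq[[pop]] <- fl
    nn[[pop]] <- nv
  }
  structure(list(populations = pops, loci = loci, freq = freq, n = nn,
                 system = "codominant"),
            class = "freq_table")
}

#' Allele frequencies for dominant loci (Bayesian)
#'
#' Per population x locus, band-absence counts are converted to
#' posterior-mean allele frequencies with [estimate_dominant_freq()].
#'
#' @param dominant a [dominant_matrix()].
#' @param samples a [sample_table()]; controls are excluded.
#' @param F scalar inbreeding coefficient, or named per-population
#'   vector (e.g. the codominant F_IS of the same populations).
#' @param prior a [prior_spec()]; pass the result of
#'   [fit_empirical_prior()] for the non-uniform-prior procedure.
#' @return A `freq_table` with, per population x locus, the allele
#'   frequency vector `c(present = p, absent = q)`.
#' @export
estimate_dominant_freq_table <- function(dominant, samples, F = 0,
                                         prior = prior_spec()) {
  keep <- !samples$control
  pops <- sort(unique(samples$population[keep]))
  loci <- colnames(dominant)
  m <- unclass(dominant)
  freq <- list(); nn <- list(); raw <- list()
  for (pop in pops) {
    sel <- keep & samples$population == pop
    sub <- m[sel, , drop = FALSE]
    scored <- sub != MISSING_CODE
    n <- colSums(scored)
    xa <- colSums(sub == 0L & scored)
    Fp <- if (length(F) > 1L) unname(F[pop]) else F
    if (is.na(Fp)) Fp <- mean(F, na.rm = TRUE)
    Fp <- min(max(Fp, 0), 1)  # slightly negative F_IS estimates clamp to 0
    fl <- vector("list", length(loci)); names(fl) <- loci
    ok <- n > 0
    q <- rep(NA_real_, length(loci))
    q[ok] <- dominant_freq_vec(xa[ok], n[ok], F = Fp, prior = prior)
    for (j in seq_along(loci)) {
      fl[[j]] <- if (ok[j]) c(present = 1 - q[j], absent = q[j]) else numeric(0)
    }
    freq[[pop]] <- fl
    nn[[pop]] <- setNames(as.integer(n), loci)
    # raw band-phenotype presence frequency (used e.g. by the
    # commonest-allele exclusion rule of the outlier scans)
    raw[[pop]] <- setNames(ifelse(ok, 1 - xa / n, NA_real_), loci)
  }
  structure(list(populations = pops, loci = loci, freq = freq, n = nn,
                 raw = raw, system = "dominant"),
            class = "freq_table")
}

#' @export
print.freq_table <- function(x, ...) {
  cat("freq_table (", x$system, "): ", length(x$populations),
      " populations x ", length(x$loci), " loci\n", sep = "")
  invisible(x)
}

#' Write a frequency table as TSV
#' @param ft a `freq_table`.
#' @param path output path.
#' @export
write_freq_table <- function(ft, path) {
  rows <- list()
  for (pop in ft$populations)
    for (locus in ft$loci) {
      f <- ft$freq[[pop]][[locus]]
      if (length(f) == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        population = pop, locus = locus, allele = names(f),
        frequency = as.numeric(f), n = ft$n[[pop]][locus],
        stringsAsFactors = FALSE)
    }
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
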