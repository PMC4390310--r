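# Weir-Cockerham (1984) theta variance components.
#
# Genotype-based components for one locus across r populations.  For
# every allele: a (among-population), b (among-individual within
# population) and c (within-individual) components; theta is the ratio
# a / (a + b + c), multi-locus by summing components before dividing.

wc_components_locus <- function(a1_by_pop, a2_by_pop) {
  r <- length(a1_by_pop)
  n <- numeric(r); pl <- list(); hl <- list()
  alleles <- integer(0)
  for (i in seq_len(r)) {
    obs <- a1_by_pop[[i]] != MISSING_CODE
    a1 <- a1_by_pop[[i]][obs]; a2 <- a2_by_pop[[i]][obs]
    n[i] <- length(a1)
    pl[[i]] <- list(a1 = a1, a2 = a2)
    alleles <- union(alleles, c(a1, a2))
  }
  if (any(n < 1) || length(alleles) < 2L)
    return(c(a = 0, b = 0, c = 0))
  nbar <- mean(n)
  nsum <- sum(n)
  nc <- (nsum - sum(n^2) / nsum) / (r - 1)
  if (nbar <= 1 || nc <= 0) return(c(a = 0, b = 0, c = 0))
  asum <- bsum <- csum <- 0
  for (A in alleles) {
    p <- vapply(pl, function(g)
      (sum(g$a1 == A) + sum(g$a2 == A)) / (2 * length(g$a1)), numeric(1))
    h <- vapply(pl, function(g)
      sum((g$a1 == A) != (g$a2 == A)) / length(g$a1), numeric(1))
    pbar <- sum(n * p) / nsum
    s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * h) / nsum
    a <- (nbar / nc) *
      (s2 - (1 / (nbar - 1)) *
         (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - s2 * (r - 1) / r -
         hbar * (2 * nbar - 1) / (4 * nbar))
    asum <- asum + a; bsum <- bsum + b; csum <- csum + hbar / 2
  }
  c(a = asum, b = bsum, c = csum)
}

# Frequency-based components (no heterozygosity information): the
# two-level ANOVA on allele frequencies used for dominant loci, with
# sample sizes counted in gene copies.
wc_components_freq <- function(p, n_copies) {
  r <- length(p)
  keep <- !is.na(p) & n_copies > 0
  p <- p[keep]; n <- n_copies[keep]
  if (length(p) < 2L) return(c(a = 0, b = 0))
  nbar <- mean(n); nsum <- sum(n)
  nc <- (nsum - sum(n^2) / nsum) / (r - 1)
  if (nbar <= 1 || nc <= 0) return(c(a = 0, b = 0))
  asum <- bsum <- 0
  for (q in list(p, 1 - p)) {  # both alleles of the biallelic locus
    pbar <- sum(n * q) / nsum
    s2 <- sum(n * (q - pbar)^2) / ((r - 1) * nbar)
    a <- (nbar / nc) *
      (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - s2 * (r - 1) / r)
    asum <- asum + a; bsum <- bsum + b
  }
  c(a = asum, b = bsum)
}

#' Pairwise F_ST between two populations
#'
#' Codominant loci: Weir-Cockerham theta from genotype counts.
#' Dominant loci: the frequency-based variance-component analog applied
#' to Bayesian allele-frequency estimates with sample sizes in gene
#' copies.  The multi-locus value is the ratio of summed components
#' (the Weir-Cockerham convention); negative per-locus values are
#' reported as computed.
#'
#' @param dataset a [genotype_dataset()] (codominant path), or `NULL`
#'   when `freqs` is given.
#' @param pop_a,pop_b population labels.
#' @param system `"codominant"` or `"dominant"`.
#' @param freqs a dominant `freq_table` (required for the dominant
#'   path; see [estimate_dominant_freq_table()]).
#' @return List with `theta` (multi-locus), `per_locus` (named vector)
#'   and `he` (per-locus mean within-pair expected heterozygosity, used
#'   by the outlier scans for conditioning).
#' @export
pairwise_fst <- function(dataset = NULL, pop_a, pop_b,
                         system = c("codominant", "dominant"),
                         freqs = NULL) {
  system <- match.arg(system)
  if (system == "codominant") {
    stopifnot(!is.null(dataset), !is.null(dataset$codominant))
    s <- dataset$samples
    keep <- !s$control
    sel_a <- keep & s$population == pop_a
    sel_b <- keep & s$population == pop_b
    cod <- dataset$codominant
    loci <- colnames(cod$a1)
    comps <- matrix(0, 3L, length(loci),
                    dimnames = list(c("a", "b", "c"), loci))
    he <- setNames(rep(NA_real_, length(loci)), loci)
    for (j in seq_along(loci)) {
      comps[, j] <- wc_components_locus(
        list(cod$a1[sel_a, j], cod$a1[sel_b, j]),
        list(cod$a2[sel_a, j], cod$a2[sel_b, j]))
      he[j] <- mean(c(locus_he_geno(cod$a1[sel_a, j], cod$a2[sel_a, j]),
                      locus_he_geno(cod$a1[sel_b, j], cod$a2[sel_b, j])),
                    na.rm = TRUE)
    }
    denom <- colSums(comps)
    per_locus <- ifelse(denom != 0, comps["a", ] / denom, NA_real_)
    tot <- sum(comps["a", ]) / sum(denom)
  } else {
    stopifnot(!is.null(freqs), freqs$system == "dominant")
    loci <- freqs$loci
    pa <- vapply(freqs$freq[[pop_a]], function(f)
      if (length(f)) f[["present"]] else NA_real_, numeric(1))
    pb <- vapply(freqs$freq[[pop_b]], function(f)
      if (length(f)) f[["present"]] else NA_real_, numeric(1))
    na <- 2 * freqs$n[[pop_a]]; nb <- 2 * freqs$n[[pop_b]]
    comps <- vapply(seq_along(loci), function(j)
      wc_components_freq(c(pa[j], pb[j]), c(na[j], nb[j])), numeric(2L))
    dimnames(comps) <- list(c("a", "b"), loci)
    denom <- colSums(comps)
    per_locus <- ifelse(denom != 0, comps["a", ] / denom, NA_real_)
    tot <- sum(comps["a", ]) / sum(denom)
    he <- (2 * pa * (1 - pa) + 2 * pb * (1 - pb)) / 2
    names(he) <- loci
  }
  if (all(is.na(per_locus)))
    stop("no shared polymorphic loci between ", pop_a, " and ", pop_b)
  list(theta = tot, per_locus = per_locus, he = he,
       pops = c(pop_a, pop_b), system = system)
}

locus_he_geno <- function(a1, a2) {
  obs <- a1 != MISSING_CODE
  n <- sum(obs)
  if (n < 2) return(NA_real_)
  tab <- table(c(a1[obs], a2[obs]))
  p <- as.numeric(tab) / (2 * n)
  (2 * n / (2 * n - 1)) * (1 - sum(p^2))
}

#' Pairwise F_ST matrix over all populations
#'
#' @param dataset a [genotype_dataset()].
#' @param system marker system, see [pairwise_fst()].
#' @param freqs dominant `freq_table` (dominant path).
#' @param clip report range; values are clipped to `[-0.05, 1]`.
#' @return A symmetric `divergence_matrix` (population x population)
#'   with zero diagonal.
#' @export
fst_matrix <- function(dataset, system = c("codominant", "dominant"),
                       freqs = NULL, clip = c(-0.05, 1)) {
  system <- match.arg(system)
  pops <- sort(unique(dataset$samples$population[!dataset$samples$control]))
  m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops))
    for (j in seq_len(i - 1L)) {
      th <- pairwise_fst(dataset, pops[i], pops[j], system, freqs)$theta
      m[i, j] <- m[j, i] <- min(max(th, clip[1L]), clip[2L])
    }
  class(m) <- c("divergence_matrix", class(m))
  m
}

#' Mantel test between two divergence matrices
#'
#' Pearson correlation of the off-diagonal entries, with significance
#' from random row/column permutations of the second matrix and the
#' +1-corrected permutation p-value
#' \eqn{p = (1 + \#\{r_{perm} \ge r_{obs}\}) / (1 + n_{perm})}.
#'
#' @param mat_a,mat_b symmetric matrices over the same populations.
#' @param n_perm number of permutations.
#' @param seed RNG seed (mandatory: permutation tests must be
#'   reproducible).
#' @return List with `r`, `r2`, `p`, `n_perm`.
#' @export
mantel_test <- function(mat_a, mat_b, n_perm = 999, seed) {
  stopifnot(identical(dim(mat_a), dim(mat_b)), !missing(seed))
  n <- nrow(mat_a)
  if (n < 4) stop("need at least 4 populations for a meaningful null")
  low <- lower.tri(mat_a)
  va <- mat_a[low]
  if (sd(va) == 0 || sd(mat_b[low]) == 0)
    stop("constant matrix: correlation undefined")
  r_obs <- cor(va, mat_b[low])
  set.seed(seed)
  count <- 0L
  for (k in seq_len(n_perm)) {
    perm <- sample.int(n)
    r_p <- cor(va, mat_b[perm, perm][low])
    if (r_p >= r_obs) count <- count + 1L
  }
  list(method = "mantel", r = r_obs, r2 = r_obs^2,
       p = (count + 1) / (n_perm + 1), n_perm = n_perm)
}

#' Nonparametric rank tests
#'
#' Thin wrappers around the standard rank tests, returning a uniform
#' record.  `wilcoxon-signed` uses the exact distribution for up to 25
#' untied pairs and the normal approximation with continuity correction
#' otherwise; all-zero differences give p = 1 with a warning.
#'
#' @param x first vector (or values for `kruskal-wallis`).
#' @param y second vector (paired for `wilcoxon-signed`, second sample
#'   for `spearman`), or grouping factor for `kruskal-wallis`.
#' @param method `"wilcoxon-signed"`, `"kruskal-wallis"` or
#'   `"spearman"`.
#' @return List with `method`, `statistic`, `p`, `n` and (for
#'   spearman) `rho`.
#' @export
rank_tests <- function(x, y, method = c("wilcoxon-signed",
                                        "kruskal-wallis", "spearman")) {
  method <- match.arg(method)
  if (method == "wilcoxon-signed") {
    d <- x - y
    if (all(d == 0)) {
      warning("all paired differences are zero; p set to 1")
      return(list(method = method, statistic = NA_real_, p = 1,
                  n = length(x)))
    }
    keep <- d != 0   # zero differences are dropped (standard handling)
    exact <- sum(keep) <= 25 && !any(duplicated(abs(d[keep])))
    wt <- suppressWarnings(
      wilcox.test(x[keep], y[keep], paired = TRUE, exact = exact,
                  correct = TRUE))
    list(method = method, statistic = unname(wt$statistic),
         p = wt$p.value, n = length(x))
  } else if (method == "kruskal-wallis") {
    kt <- kruskal.test(x, as.factor(y))
    list(method = method, statistic = unname(kt$statistic),
         p = kt$p.value, n = length(x))
  } else {
    ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
    list(method = method, statistic = unname(ct$statistic),
         rho = unname(ct$estimate), p = ct$p.value, n = length(x))
  }
}
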