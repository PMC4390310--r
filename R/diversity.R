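#' Unbiased expected heterozygosity
#'
#' For codominant loci Nei's unbiased gene diversity
#' \deqn{He = \frac{2n}{2n-1}\left(1 - \sum_i p_i^2\right)}
#' from a full allele-frequency vector.  For dominant biallelic loci the
#' default is the raw form `2 p (1 - p)` on the Bayesian frequency
#' estimate (maximum 0.5); the small-sample factor `2n/(2n-1)` can be
#' switched on with `correction = "unbiased"`.
#'
#' @param p allele-frequency vector (codominant) or band-presence
#'   frequency scalar (dominant).
#' @param n sample size (individuals).
#' @param system `"codominant"` or `"dominant"`.
#' @param correction for dominant loci: `"raw"` (default) or
#'   `"unbiased"`.
#' @return Expected heterozygosity in `[0, 1]`.
#' @export
expected_het <- function(p, n, system = c("codominant", "dominant"),
                         correction = c("raw", "unbiased")) {
  system <- match.arg(system)
  correction <- match.arg(correction)
  if (n < 2) stop("sample size must be at least 2")
  if (system == "codominant") {
    if (length(p) == 0L) return(NA_real_)
    (2 * n / (2 * n - 1)) * (1 - sum(p^2))
  } else {
    he <- 2 * p * (1 - p)
    if (correction == "unbiased") he <- he * 2 * n / (2 * n - 1)
    he
  }
}

#' Effective number of alleles
#'
#' \deqn{n_e = 1 / \sum_i p_i^2.}
#' For a dominant locus pass the two-allele vector `c(p, 1-p)`.
#'
#' @param p allele-frequency vector.
#' @return Effective allele number, at least 1 for a valid frequency
#'   vector.
#' @export
effective_alleles <- function(p) {
  if (length(p) == 0L) stop("empty frequency vector")
  1 / sum(p^2)
}

# Weir-Cockerham within-population variance components for one
# population at one locus.  Returns the b and c components summed over
# alleles; f = 1 - sum(c)/sum(b + c) across loci.
wc_within_components <- function(a1, a2) {
  obs <- a1 != MISSING_CODE
  n <- sum(obs)
  if (n < 2) return(c(b = 0, c = 0))
  al1 <- a1[obs]; al2 <- a2[obs]
  alleles <- sort(unique(c(al1, al2)))
  if (length(alleles) < 2L) return(c(b = 0, c = 0))
  bsum <- 0; csum <- 0
  for (A in alleles) {
    p <- (sum(al1 == A) + sum(al2 == A)) / (2 * n)
    hbar <- sum((al1 == A) != (al2 == A)) / n   # observed het freq for A
    b <- (n / (n - 1)) * (p * (1 - p) - (2 * n - 1) / (4 * n) * hbar)
    bsum <- bsum + b
    csum <- csum + hbar / 2
  }
  c(b = bsum, c = csum)
}

#' Within-population inbreeding coefficient (Weir-Cockerham f)
#'
#' Multi-locus F_IS per population from codominant genotypes, computed
#' from the Weir-Cockerham within-population variance components with
#' the ratio taken after summing components over loci and alleles.
#'
#' @param codominant a [codominant_matrix()].
#' @param samples a [sample_table()]; controls are excluded.
#' @return Named numeric vector of per-population F_IS (NA where
#'   undefined, i.e. no polymorphic locus).
#' @export
inbreeding_fis <- function(codominant, samples) {
  keep <- !samples$control
  pops <- sort(unique(samples$population[keep]))
  out <- setNames(rep(NA_real_, length(pops)), pops)
  for (pop in pops) {
    sel <- keep & samples$population == pop
    a1 <- codominant$a1[sel, , drop = FALSE]
    a2 <- codominant$a2[sel, , drop = FALSE]
    comps <- vapply(seq_len(ncol(a1)), function(j)
      wc_within_components(a1[, j], a2[, j]), numeric(2L))
    bsum <- sum(comps[1L, ]); csum <- sum(comps[2L, ])
    if (bsum + csum > 0) out[pop] <- 1 - csum / (bsum + csum)
  }
  out
}

#' Per-population diversity statistics
#'
#' Computes per-locus and mean effective allele number and unbiased
#' expected heterozygosity from a frequency table, plus F_IS when
#' codominant genotypes are supplied.
#'
#' @param ft a `freq_table` (see [count_codominant_freq()] /
#'   [estimate_dominant_freq_table()]).
#' @param codominant optional [codominant_matrix()] for F_IS.
#' @param samples required with `codominant`.
#' @param he_correction dominant He variant, see [expected_het()].
#' @return A `diversity_stats` object: list with `per_locus`
#'   (data frame) and `summary` (population, mean n_e, mean He, F_IS).
#' @export
diversity_stats <- function(ft, codominant = NULL, samples = NULL,
                            he_correction = c("raw", "unbiased")) {
  he_correction <- match.arg(he_correction)
  rows <- list()
  for (pop in ft$populations)
    for (locus in ft$loci) {
      f <- ft$freq[[pop]][[locus]]
      if (length(f) == 0L) next
      n <- ft$n[[pop]][locus]
      if (n < 2) next
      he <- if (ft$system == "codominant")
        expected_het(f, n, "codominant")
      else expected_het(f[["present"]], n, "dominant", he_correction)
      rows[[length(rows) + 1L]] <- data.frame(
        population = pop, locus = locus, n = n,
        ne = effective_alleles(f), he = he, stringsAsFactors = FALSE)
    }
  per_locus <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(per_locus, per_locus$population),
    function(d) data.frame(population = d$population[1L],
                           ne = mean(d$ne), he = mean(d$he))))
  rownames(agg) <- NULL
  fis <- NULL
  if (!is.null(codominant)) {
    stopifnot(!is.null(samples))
    fis <- inbreeding_fis(codominant, samples)
    agg$fis <- fis[agg$population]
  }
  structure(list(per_locus = per_locus, summary = agg, fis = fis,
                 system = ft$system),
            class = "diversity_stats")
}

#' @export
print.diversity_stats <- function(x, ...) {
  cat("diversity_stats (", x$system, ")\n", sep = "")
  print(x$summary, digits = 3)
  invisible(x)
}

#' Relative change in gene diversity between two populations
#'
#' Per locus, \deqn{\Delta H = 1 - He_A / He_B.}  Two aggregations are
#' reported: the mean of per-locus values (default) and the ratio of
#' mean diversities `1 - mean(He_A)/mean(He_B)`; both are legitimate
#' readings of a class-level diversity change and can differ when He
#' varies strongly across loci.  Loci with `He_B = 0` are skipped with a
#' warning.
#'
#' @param he_a,he_b paired per-locus He vectors (same loci, same order).
#' @param label comparison label carried through to the output.
#' @return A `delta_h` record: list with per-locus values and both
#'   aggregates.
#' @export
delta_h <- function(he_a, he_b, label = "A-B") {
  stopifnot(length(he_a) == length(he_b))
  drop <- he_b == 0 | is.na(he_a) | is.na(he_b)
  if (any(drop, na.rm = TRUE))
    warning(sum(drop), " locus/loci skipped (He_B = 0 or missing)")
  a <- he_a[!drop]; b <- he_b[!drop]
  per_locus <- 1 - a / b
  structure(list(label = label, per_locus = per_locus,
                 mean_of_ratios = mean(per_locus),
                 ratio_of_means = 1 - mean(a) / mean(b),
                 n_loci = length(per_locus)),
            class = "delta_h")
}

#' @export
print.delta_h <- function(x, ...) {
  cat(sprintf("deltaH %s: mean per-locus %.3f (ratio-of-means %.3f, %d loci)\n",
              x$label, x$mean_of_ratios, x$ratio_of_means, x$n_loci))
  invisible(x)
}
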