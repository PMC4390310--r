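#' Standardise introgression estimates between the population anchors
#'
#' Linearly rescales a modern-cluster membership value q2 so that the
#' old-landrace population mean maps to 0 and the modern dent
#' population mean maps to 1:
#' \deqn{q_2' = (q_2 - q_2^{OL}) / (q_2^{DMM} - q_2^{OL}).}
#'
#' @param q2 value(s) to standardise.
#' @param q2_ol,q2_dmm anchor values (lower and upper).
#' @return Standardised value(s).
#' @export
standardized_q2 <- function(q2, q2_ol, q2_dmm) {
  if (q2_dmm <= q2_ol) stop("upper anchor must exceed lower anchor")
  (q2 - q2_ol) / (q2_dmm - q2_ol)
}

#' Neutral-versus-all-loci introgression contrast
#'
#' The headline computation: the admixture model (K = 2) is fitted
#' twice, once on all loci and once on the neutral set, cluster labels
#' are re-anchored to the old landraces independently in each run, and
#' the introgression level of the recent-landrace accessions (their
#' mean modern-cluster membership q2, controls excluded) is compared
#' between the two locus sets with the unpaired rank
#' (Wilcoxon/Kruskal-Wallis) test across accessions — changing the
#' locus set shifts every accession's q2 coherently by a small amount,
#' so a paired test would reject for any locus-set change regardless of
#' selection; the unpaired form compares the shift against the
#' between-accession spread.  Raw and anchor-standardised means are
#' both reported.
#'
#' @param dataset a [genotype_dataset()].
#' @param neutral a `neutral_set` (see [build_neutral_set()]).
#' @param config an [admixture_config()] with K = 2.
#' @param old_pop,recent_pop,modern_pop population labels of the
#'   anchors and the introgressed population.
#' @param min_loci minimum neutral-set size for a stable fit.
#' @return An `introgression_contrast` object: per-accession q2 under
#'   both locus sets, raw and standardised means, and the rank-test
#'   p-value.
#' @export
introgression_contrast <- function(dataset, neutral, config,
                                   old_pop = "OL", recent_pop = "RL",
                                   modern_pop = "DMM", min_loci = 20L) {
  stopifnot(config$K == 2L)
  n_neutral <- sum(neutral$retained %in% c(
    if (!is.null(dataset$dominant)) colnames(dataset$dominant),
    if (!is.null(dataset$codominant)) colnames(dataset$codominant$a1)))
  if (n_neutral < min_loci)
    stop("neutral set too small for a stable admixture fit (",
         n_neutral, " loci)")
  fit_all <- anchor_clusters(run_admixture(dataset, config), old_pop)
  cfg2 <- config
  cfg2$seed <- config$seed + 1L
  fit_neu <- anchor_clusters(
    run_admixture(subset_loci(dataset, neutral$retained), cfg2), old_pop)

  extract <- function(fit) {
    s <- fit$samples
    acc_pop <- tapply(s$population, s$accession, `[`, 1L)
    acc_ctrl <- tapply(s$control, s$accession, any)
    rl_acc <- names(acc_pop)[acc_pop == recent_pop & !acc_ctrl]
    q2_rl <- fit$q_accession[rl_acc, 2L]
    pop_mean <- function(p) {
      sel <- !s$control & s$population == p
      mean(fit$q[sel, 2L])
    }
    list(q2 = q2_rl, q2_ol = pop_mean(old_pop),
         q2_dmm = pop_mean(modern_pop))
  }
  ea <- extract(fit_all); en <- extract(fit_neu)
  acc <- intersect(names(ea$q2), names(en$q2))
  test <- rank_tests(c(ea$q2[acc], en$q2[acc]),
                     rep(c("all", "neutral"), each = length(acc)),
                     "kruskal-wallis")
  std_all <- standardized_q2(ea$q2[acc], ea$q2_ol, ea$q2_dmm)
  std_neu <- standardized_q2(en$q2[acc], en$q2_ol, en$q2_dmm)
  structure(list(
    accessions = data.frame(accession = acc,
                            q2_all = unname(ea$q2[acc]),
                            q2_neutral = unname(en$q2[acc]),
                            q2_all_std = unname(std_all),
                            q2_neutral_std = unname(std_neu),
                            stringsAsFactors = FALSE),
    q2_all = mean(ea$q2[acc]), q2_neutral = mean(en$q2[acc]),
    q2_all_std = mean(std_all), q2_neutral_std = mean(std_neu),
    anchors = list(all = ea[c("q2_ol", "q2_dmm")],
                   neutral = en[c("q2_ol", "q2_dmm")]),
    p_value = test$p, test_method = test$method,
    n_accessions = length(acc),
    fit_all = fit_all, fit_neutral = fit_neu),
    class = "introgression_contrast")
}

#' @export
print.introgression_contrast <- function(x, ...) {
  cat(sprintf(
    "introgression contrast over %d accessions:\n  q2(all) = %.3f, q2(neutral) = %.3f (rank test P = %.3g)\n  standardised: %.3f vs %.3f\n",
    x$n_accessions, x$q2_all, x$q2_neutral, x$p_value,
    x$q2_all_std, x$q2_neutral_std))
  invisible(x)
}

#' Diversity-change contrast by locus class
#'
#' Computes the relative diversity change between two populations
#' separately for neutral and outlier loci and tests the
#' neutral-versus-outlier difference in per-locus values with the rank
#' test.
#'
#' @param ft a `freq_table` (dominant or codominant).
#' @param outlier_loci character vector of outlier locus ids; the
#'   remaining loci in `ft` form the neutral class.
#' @param pop_a,pop_b populations compared (\eqn{\Delta H = 1 -
#'   He_A/He_B}).
#' @param he_correction dominant He variant, see [expected_het()].
#' @return Data frame with one row per class (ΔH under both
#'   aggregations, locus count) plus the between-class rank-test
#'   p-value as attribute `p_value`.
#' @export
delta_h_by_class <- function(ft, outlier_loci, pop_a, pop_b,
                             he_correction = "raw") {
  he_of <- function(pop, locus) {
    f <- ft$freq[[pop]][[locus]]
    if (length(f) == 0L) return(NA_real_)
    n <- ft$n[[pop]][locus]
    if (ft$system == "codominant") expected_het(f, n, "codominant")
    else expected_het(f[["present"]], n, "dominant", he_correction)
  }
  he_a <- vapply(ft$loci, he_of, numeric(1L), pop = pop_a)
  he_b <- vapply(ft$loci, he_of, numeric(1L), pop = pop_b)
  classes <- ifelse(ft$loci %in% outlier_loci, "outlier", "neutral")
  recs <- list(); per_locus <- list()
  for (cl in c("neutral", "outlier")) {
    sel <- classes == cl & !is.na(he_a) & !is.na(he_b) & he_b > 0
    if (!any(sel)) {
      warning("empty locus class: ", cl)
      next
    }
    dh <- suppressWarnings(delta_h(he_a[sel], he_b[sel],
                                   paste0(pop_a, "-", pop_b)))
    per_locus[[cl]] <- dh$per_locus
    recs[[cl]] <- data.frame(class = cl,
                             delta_h = dh$mean_of_ratios,
                             delta_h_ratio_of_means = dh$ratio_of_means,
                             n_loci = dh$n_loci,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  if (length(per_locus) == 2L) {
    kt <- rank_tests(c(per_locus$neutral, per_locus$outlier),
                     rep(c("neutral", "outlier"),
                         c(length(per_locus$neutral),
                           length(per_locus$outlier))),
                     "kruskal-wallis")
    attr(out, "p_value") <- kt$p
  }
  out
}
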