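#' Configuration for the RJ-MCMC locus-effect scan
#'
#' Defaults follow the published protocol of the reference software: 20
#' pilot runs of 5,000 iterations, 50,000 burn-in, 100,000 iterations
#' sampled with thinning 10, prior inclusion odds 1:10.  Desk-scale
#' analyses shorten the chains roughly tenfold.
#'
#' @param n_pilot,pilot_len pilot runs and their length (proposal-scale
#'   adaptation).
#' @param burn_in,n_iter,thin main-run burn-in, iterations, thinning.
#' @param prior_odds prior inclusion odds of the selection model
#'   (included : excluded), default 1/10.
#' @param max_allele_freq exclusion cutoff on the pooled
#'   commonest-allele frequency.
#' @param seed mandatory RNG seed.
#' @return A `bayescan_config` object.
#' @export
bayescan_config <- function(n_pilot = 20L, pilot_len = 5000L,
                            burn_in = 50000L, n_iter = 100000L,
                            thin = 10L, prior_odds = 1 / 10,
                            max_allele_freq = 0.98, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_pilot >= 0, pilot_len > 0, burn_in >= 0, n_iter > 0,
            thin >= 1, prior_odds > 0)
  structure(list(n_pilot = as.integer(n_pilot),
                 pilot_len = as.integer(pilot_len),
                 burn_in = as.integer(burn_in),
                 n_iter = as.integer(n_iter), thin = as.integer(thin),
                 prior_odds = prior_odds,
                 max_allele_freq = max_allele_freq, seed = seed),
            class = "bayescan_config")
}

#' Jeffreys evidence category for a Bayes factor
#'
#' Bins: BF in (1,3] barely worth mentioning, (3,10] substantial,
#' (10,32] strong, (32,100] very strong, >100 decisive; BF <= 1 maps to
#' `"none"`.
#'
#' @param bf non-negative Bayes factor(s).
#' @return Character vector of categories.
#' @export
jeffreys_category <- function(bf) {
  if (any(bf < 0)) stop("Bayes factor must be non-negative")
  cut(bf, breaks = c(-Inf, 1, 3, 10, 32, 100, Inf),
      labels = c("none", "barely", "substantial", "strong",
                 "very strong", "decisive"),
      right = TRUE) |> as.character()
}

#' RJ-MCMC selection scan for a population pair
#'
#' Fits the locus-effect F-model `logit(F_ST,ij) = alpha_i + beta_j` by
#' reversible-jump MCMC: a locus-specific effect alpha_i is toggled in
#' and out of the model, and the per-locus Bayes factor of the
#' with-selection model is the posterior inclusion odds divided by the
#' prior odds.  Codominant loci enter through their allele counts
#' (Dirichlet-multinomial likelihood); dominant loci through
#' band-phenotype counts with a latent per-population allele frequency
#' and the inbreeding coefficient integrated under a uniform prior on
#' `[0, 1]`.  Loci with a pooled commonest-allele frequency at or above
#' the cutoff are excluded.
#'
#' The per-locus evidence value `bf` is the posterior odds of the
#' with-selection model, the quantity the field's reference program
#' reports and bins on the Jeffreys scale (with the default 1:10 prior
#' odds, a locus with no information sits near 0.1, not 1);
#' `odds_ratio` gives the prior-odds-normalised version.
#'
#' @param dataset a [genotype_dataset()] (controls excluded
#'   internally).
#' @param pop_a,pop_b population labels.
#' @param system `"codominant"` or `"dominant"`.
#' @param cfg a [bayescan_config()].
#' @return A `bayescan_result`: data frame `loci` with posterior
#'   inclusion probability, Bayes factor, Jeffreys category, posterior
#'   F_ST, and a `tested` flag.
#' @export
bayescan_scan <- function(dataset, pop_a, pop_b,
                          system = c("codominant", "dominant"), cfg) {
  system <- match.arg(system)
  stopifnot(inherits(cfg, "bayescan_config"))
  s <- dataset$samples
  keep <- !s$control
  sel_a <- keep & s$population == pop_a
  sel_b <- keep & s$population == pop_b
  if (system == "codominant") {
    cod <- dataset$codominant
    stopifnot(!is.null(cod))
    loci <- colnames(cod$a1)
    counts <- list(); tested <- logical(length(loci))
    for (j in seq_along(loci)) {
      cnts <- lapply(list(sel_a, sel_b), function(sel) {
        a1 <- cod$a1[sel, j]; a2 <- cod$a2[sel, j]
        obs <- a1 != MISSING_CODE
        c(a1[obs], a2[obs])
      })
      alleles <- sort(unique(unlist(cnts)))
      m <- vapply(cnts, function(v)
        as.numeric(table(factor(v, levels = alleles))),
        numeric(length(alleles)))
      if (length(alleles) < 2L) {
        tested[j] <- FALSE
        m <- rbind(m, 0)  # keep 2 rows so the sampler sees a shape
      } else {
        pool <- rowSums(m) / sum(m)
        tested[j] <- max(pool) < cfg$max_allele_freq
      }
      counts[[j]] <- m
    }
    use <- which(tested)
    dom_x <- matrix(0, 0, 2); dom_n <- matrix(0, 0, 2)
    cod_counts <- counts[use]
  } else {
    dom <- unclass(dataset$dominant)
    stopifnot(!is.null(dom))
    loci <- colnames(dom)
    xs <- ns <- matrix(0, length(loci), 2L)
    for (j in seq_along(loci)) {
      for (g in 1:2) {
        v <- dom[list(sel_a, sel_b)[[g]], j]
        obs <- v != MISSING_CODE
        ns[j, g] <- sum(obs)
        xs[j, g] <- sum(v[obs] == 0L)
      }
    }
    phen_pres <- 1 - rowSums(xs) / rowSums(ns)
    # pooled allele-frequency screen on the sqrt-scale phenotype map
    p_allele <- 1 - sqrt(pmax(0, 1 - phen_pres))
    tested <- pmax(p_allele, 1 - p_allele) < cfg$max_allele_freq &
      rowSums(ns) > 0
    use <- which(tested)
    cod_counts <- list()
    dom_x <- xs[use, , drop = FALSE]
    dom_n <- ns[use, , drop = FALSE]
  }
  set.seed(cfg$seed)
  res <- bayescan_rj(cod_counts, dom_x, dom_n, cfg$n_pilot,
                     cfg$pilot_len, cfg$burn_in, cfg$n_iter, cfg$thin,
                     cfg$prior_odds)
  S <- res$n_samples
  # continuity-corrected posterior inclusion so odds stay finite at the
  # chain ends.  The evidence value categorised on the Jeffreys scale
  # is the posterior odds of the with-selection model (the reference
  # program's reporting convention); the prior-odds-normalised ratio is
  # also returned.
  post_p <- (res$post_incl * S + 0.5) / (S + 1)
  post_odds <- post_p / (1 - post_p)
  out <- data.frame(locus = loci, tested = tested,
                    post_incl = NA_real_, bf = NA_real_,
                    odds_ratio = NA_real_,
                    category = NA_character_, post_fst = NA_real_,
                    alpha = NA_real_, stringsAsFactors = FALSE)
  out$post_incl[use] <- res$post_incl
  out$bf[use] <- post_odds
  out$odds_ratio[use] <- post_odds / cfg$prior_odds
  out$category[use] <- jeffreys_category(post_odds)
  out$post_fst[use] <- res$post_fst
  out$alpha[use] <- res$post_alpha
  structure(list(loci = out, pops = c(pop_a, pop_b), system = system,
                 fis = res$fis, beta = res$beta, n_samples = S),
            class = "bayescan_result")
}

#' Consensus of the two outlier-detection methods
#'
#' One row per locus per comparison, with the simulated-null scan flag
#' (at its significance level) and the RJ-MCMC Jeffreys category.  A
#' locus is marked a strong outlier in a comparison when both methods
#' flag it there (simulated-null P below its level and Jeffreys
#' category at least "very strong").
#'
#' @param fdist_results named list of `fdist_result`s, one per
#'   comparison (names like `"OL-RL"`).
#' @param bayescan_results named list of `bayescan_result`s with the
#'   same names.
#' @return A `consensus_table` data frame: locus, comparison,
#'   fdist_outlier, bayescan category, any_flag, strong_outlier.
#' @export
build_consensus <- function(fdist_results, bayescan_results) {
  comps <- names(fdist_results)
  stopifnot(identical(sort(comps), sort(names(bayescan_results))))
  rows <- list()
  for (cmp in comps) {
    fd <- fdist_results[[cmp]]$loci
    bs <- bayescan_results[[cmp]]$loci
    if (!setequal(fd$locus, bs$locus))
      stop("mismatched locus sets in comparison ", cmp)
    bs <- bs[match(fd$locus, bs$locus), ]
    cat_rank <- match(bs$category,
                      c("none", "barely", "substantial", "strong",
                        "very strong", "decisive"))
    bayes_flag <- !is.na(cat_rank) & cat_rank >= 5L
    any_flag <- fd$outlier | (!is.na(bs$category) & bs$category != "none")
    rows[[cmp]] <- data.frame(
      locus = fd$locus, comparison = cmp,
      fdist_outlier = fd$outlier, fdist_p = fd$p,
      bayescan_category = bs$category, bayes_factor = bs$bf,
      any_flag = any_flag,
      strong_outlier = fd$outlier & bayes_flag,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("consensus_table", "data.frame")
  out
}

#' Build the neutral locus set from a consensus table
#'
#' Excludes every locus carrying any flag, at any level (including
#' "barely worth mentioning"), in any comparison, by either method.
#'
#' @param consensus a `consensus_table`.
#' @param all_loci optional full locus id vector (defaults to the loci
#'   present in the table).
#' @return A `neutral_set`: list with `retained`, `excluded` and the
#'   per-locus exclusion reasons.
#' @export
build_neutral_set <- function(consensus, all_loci = NULL) {
  if (is.null(all_loci)) all_loci <- unique(consensus$locus)
  flagged <- consensus[consensus$any_flag, , drop = FALSE]
  excluded <- unique(flagged$locus)
  retained <- setdiff(all_loci, excluded)
  if (length(retained) == 0L) stop("neutral set is empty")
  reasons <- lapply(split(flagged, flagged$locus), function(d)
    paste(ifelse(d$fdist_outlier, "fdist", ""),
          ifelse(!is.na(d$bayescan_category) & d$bayescan_category != "none",
                 paste0("bayescan:", d$bayescan_category), ""),
          d$comparison, sep = "|"))
  structure(list(retained = retained, excluded = excluded,
                 reasons = reasons),
            class = "neutral_set")
}
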