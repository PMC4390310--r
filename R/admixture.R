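#' Configuration for the admixture sampler
#'
#' Chain-length defaults match the published protocol: 20 exploratory
#' runs of 30,000 burn-in + 30,000 recorded sweeps per K, and one final
#' run of 100,000 + 100,000 for the reported membership coefficients.
#' Desk-scale analyses should shorten these (the test profile uses
#' 2,000/2,000).
#'
#' @param K number of clusters.
#' @param n_runs exploratory runs per K (for the K-selection scan).
#' @param burn_in,mcmc_reps exploratory-run chain lengths.
#' @param final_burn_in,final_reps final-run chain lengths.
#' @param alpha initial value of the shared admixture parameter (it is
#'   updated by Metropolis steps under a uniform prior).
#' @param seed mandatory RNG seed.
#' @return An `admixture_config` object.
#' @export
admixture_config <- function(K = 2L, n_runs = 20L, burn_in = 30000L,
                             mcmc_reps = 30000L, final_burn_in = 100000L,
                             final_reps = 100000L, alpha = 1, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(K >= 1, n_runs >= 1, burn_in > 0, mcmc_reps > 0,
            final_burn_in > 0, final_reps > 0)
  structure(list(K = as.integer(K), n_runs = as.integer(n_runs),
                 burn_in = as.integer(burn_in),
                 mcmc_reps = as.integer(mcmc_reps),
                 final_burn_in = as.integer(final_burn_in),
                 final_reps = as.integer(final_reps),
                 alpha = alpha, seed = seed),
            class = "admixture_config")
}

# Recode a dataset into the integer arrays the sampler consumes.
encode_for_admixture <- function(dataset) {
  N <- nrow(dataset$samples)
  if (!is.null(dataset$codominant)) {
    a1 <- dataset$codominant$a1; a2 <- dataset$codominant$a2
    Lc <- ncol(a1)
    c1 <- matrix(-1L, N, Lc); c2 <- matrix(-1L, N, Lc)
    n_all <- integer(Lc)
    for (j in seq_len(Lc)) {
      obs <- a1[, j] != MISSING_CODE
      alleles <- sort(unique(c(a1[obs, j], a2[obs, j])))
      n_all[j] <- max(length(alleles), 1L)
      c1[obs, j] <- match(a1[obs, j], alleles) - 1L
      c2[obs, j] <- match(a2[obs, j], alleles) - 1L
    }
  } else {
    c1 <- c2 <- matrix(integer(0), N, 0)
    n_all <- integer(0)
  }
  if (!is.null(dataset$dominant)) {
    d <- unclass(dataset$dominant)
    d[d == MISSING_CODE] <- -1L
    storage.mode(d) <- "integer"
  } else {
    d <- matrix(integer(0), N, 0)
  }
  list(c1 = c1, c2 = c2, n_all = n_all, d = d)
}

#' Fit the admixture model
#'
#' Runs the Gibbs sampler (one long final run) on a mixed-marker
#' dataset and returns posterior-mean membership coefficients.
#' Control accessions take part (admixture is the one analysis that
#' displays them).  Cluster labels are arbitrary on exit; use
#' [anchor_clusters()] to fix label switching against a reference
#' population.
#'
#' @param dataset a [genotype_dataset()].
#' @param config an [admixture_config()].
#' @return An `admix_fit` object: `q` (individuals x K posterior-mean
#'   membership), `q_accession` (accession means), `loglik` trace,
#'   `lnPD` (model-evidence proxy used by the K-selection rule), `K`,
#'   `seed`.
#' @export
run_admixture <- function(dataset, config) {
  stopifnot(inherits(config, "admixture_config"))
  enc <- encode_for_admixture(dataset)
  set.seed(config$seed)
  res <- admix_gibbs(enc$c1, enc$c2, enc$n_all, enc$d, config$K,
                     config$final_burn_in, config$final_reps,
                     config$alpha)
  q <- res$q
  rownames(q) <- dataset$samples$individual
  colnames(q) <- paste0("q", seq_len(config$K))
  acc <- dataset$samples$accession
  q_acc <- apply(q, 2L, function(col) tapply(col, acc, mean))
  q_acc <- matrix(q_acc, ncol = config$K,
                  dimnames = list(sort(unique(acc)),
                                  colnames(q)))
  fit <- list(q = q, q_accession = q_acc, loglik = res$loglik,
              lnPD = res$lnPD, alpha = res$alpha, F = res$F,
              K = config$K, seed = config$seed,
              samples = dataset$samples)
  class(fit) <- "admix_fit"
  fit
}

#' @export
print.admix_fit <- function(x, ...) {
  cat(sprintf("admix_fit: K = %d, %d individuals, lnPD = %.1f\n",
              x$K, nrow(x$q), x$lnPD))
  invisible(x)
}

#' @export
summary.admix_fit <- function(object, ...) {
  s <- object$samples
  keep <- !s$control
  pops <- sort(unique(s$population[keep]))
  tab <- t(vapply(pops, function(p)
    colMeans(object$q[keep & s$population == p, , drop = FALSE]),
    numeric(object$K)))
  cat("Mean membership by population (controls excluded):\n")
  print(round(tab, 3))
  invisible(tab)
}

#' @export
coef.admix_fit <- function(object, ...) object$q

#' @export
plot.admix_fit <- function(x, ...) {
  ord <- order(x$samples$population, x$samples$accession)
  barplot(t(x$q[ord, , drop = FALSE]), col = seq_len(x$K) + 1L,
          border = NA, space = 0, names.arg = rep("", nrow(x$q)),
          ylab = "membership (q)", ...)
  invisible(x)
}

#' Resolve label switching against an anchor population
#'
#' Reorders clusters so that cluster 1 is the cluster with the highest
#' mean membership among individuals of `anchor_pop` (ties broken by
#' first index).
#'
#' @param fit an `admix_fit`.
#' @param anchor_pop population label (default `"OL"`).
#' @return The fit with reordered columns.
#' @export
anchor_clusters <- function(fit, anchor_pop = "OL") {
  s <- fit$samples
  sel <- !s$control & s$population == anchor_pop
  if (!any(sel)) stop("no individuals in anchor population ", anchor_pop)
  mq <- colMeans(fit$q[sel, , drop = FALSE])
  ord <- order(-mq)
  fit$q <- fit$q[, ord, drop = FALSE]
  fit$q_accession <- fit$q_accession[, ord, drop = FALSE]
  colnames(fit$q) <- colnames(fit$q_accession) <-
    paste0("q", seq_len(fit$K))
  fit
}

#' Exploratory K scan
#'
#' Runs `n_runs` short chains per K and collects the model-evidence
#' proxy of every run, as input to [select_k()].
#'
#' @param dataset a [genotype_dataset()].
#' @param k_range integer vector of K values (at least 3 consecutive
#'   values for the ΔK rule).
#' @param config an [admixture_config()]; `burn_in`/`mcmc_reps` are the
#'   per-run chain lengths.
#' @return Matrix of ln-likelihood proxies, runs x K.
#' @export
scan_k <- function(dataset, k_range, config) {
  enc <- encode_for_admixture(dataset)
  out <- matrix(NA_real_, config$n_runs, length(k_range),
                dimnames = list(NULL, paste0("K", k_range)))
  for (ki in seq_along(k_range)) {
    for (r in seq_len(config$n_runs)) {
      set.seed(config$seed + 1009L * ki + r)
      res <- admix_gibbs(enc$c1, enc$c2, enc$n_all, enc$d,
                         as.integer(k_range[ki]), config$burn_in,
                         config$mcmc_reps, config$alpha)
      out[r, ki] <- res$lnPD
    }
  }
  attr(out, "k_range") <- k_range
  out
}

#' Evanno delta-K rule
#'
#' For interior K, \deqn{\Delta K = mean_r |L_r(K-1) - 2 L_r(K) +
#' L_r(K+1)| / sd_r(L_r(K))} over runs r; the K with the largest ΔK is
#' reported.  K values with zero run-to-run standard deviation are
#' excluded with a warning.
#'
#' @param likelihoods runs x K matrix of per-run ln-likelihood values
#'   (as from [scan_k()]); at least 3 consecutive K and 2 runs.
#' @return A `k_selection` data frame with per-K mean, sd and ΔK, and
#'   attribute `best_k`.
#' @export
select_k <- function(likelihoods) {
  k_range <- attr(likelihoods, "k_range") %||%
    as.integer(sub("^K", "", colnames(likelihoods)))
  stopifnot(ncol(likelihoods) >= 3L, nrow(likelihoods) >= 2L)
  mu <- colMeans(likelihoods)
  s <- apply(likelihoods, 2L, sd)
  dk <- rep(NA_real_, length(k_range))
  for (i in seq_along(k_range)[-c(1L, length(k_range))]) {
    if (s[i] == 0) {
      warning("zero sd at K = ", k_range[i], "; ΔK undefined there")
      next
    }
    second <- abs(likelihoods[, i - 1L] - 2 * likelihoods[, i] +
                    likelihoods[, i + 1L])
    dk[i] <- mean(second) / s[i]
  }
  out <- data.frame(K = k_range, mean_lnL = mu, sd_lnL = s, delta_k = dk)
  rownames(out) <- NULL
  attr(out, "best_k") <- if (all(is.na(dk))) NA_integer_
                         else k_range[which.max(dk)]
  class(out) <- c("k_selection", "data.frame")
  out
}

#' Classify recent-landrace accessions by introgression level
#'
#' With a K=2 fit anchored so cluster 1 is the old-landrace cluster,
#' the classification threshold is the minimum accession-mean q1 among
#' OL accessions; RL accessions at or above the threshold are class
#' `RL_A` (no/low introgression), the rest `RL_B` (admixed/high
#' introgression).  Control accessions are excluded.
#'
#' @param fit an anchored K=2 `admix_fit` (see [anchor_clusters()]).
#' @param old_pop,recent_pop population labels of the old and recent
#'   landraces.
#' @return List with `threshold` and `classes` (data frame: accession,
#'   mean q1, class).
#' @export
classify_rl <- function(fit, old_pop = "OL", recent_pop = "RL") {
  stopifnot(fit$K == 2L)
  s <- fit$samples
  acc_pop <- tapply(s$population, s$accession, `[`, 1L)
  acc_ctrl <- tapply(s$control, s$accession, any)
  ol_acc <- names(acc_pop)[acc_pop == old_pop & !acc_ctrl]
  if (length(ol_acc) == 0L) stop("no accessions in ", old_pop)
  thr <- min(fit$q_accession[ol_acc, 1L])
  rl_acc <- names(acc_pop)[acc_pop == recent_pop & !acc_ctrl]
  q1 <- fit$q_accession[rl_acc, 1L]
  classes <- data.frame(accession = rl_acc, q1 = unname(q1),
                        class = ifelse(q1 >= thr, "RL_A", "RL_B"),
                        stringsAsFactors = FALSE)
  rownames(classes) <- NULL
  list(threshold = thr, classes = classes)
}
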