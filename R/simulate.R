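#' Configuration for the study-design forward simulator
#'
#' The defaults emulate the sampling design of the study system: five
#' populations (OL, RL, NI, FMM, DMM) with 43/20/11/8/22 accessions and
#' 83/77/22/12/24 genotypes (the RL figures include one 4-genotype
#' control accession that is a modern dent hybrid), 168 dominant and 21
#' codominant loci, a flint-dent split deep enough to give
#' F_ST(OL, DMM) near 0.22, and 50 generations of recent-landrace
#' evolution with pollen-mediated migration from DMM.
#'
#' Effective sizes and migration rates are free parameters of the
#' simulator, not estimates of the real system (the study never states
#' them); the defaults and the reasoning behind them are documented in
#' the methods vignette.
#'
#' @param seed mandatory RNG seed.
#' @param n_dominant_loci,n_codominant_loci locus counts.
#' @param k_alleles allele-count cap for codominant loci (k-allele
#'   mutation model).
#' @param ssr_mutation_rate per-generation mutation rate of codominant
#'   loci.
#' @param ne named vector: `main` (lineage demes), `accession`
#'   (recent-landrace accession demes), `modern` (modern-variety
#'   demes).
#' @param t_split generations since the flint-dent divergence.
#' @param t_sub generations since the OL/NI split (within flint).
#' @param t_fmm drift generations of the flint-modern pool after
#'   admixture of its parents.
#' @param fmm_dent_fraction dent contribution to the flint-modern pool.
#' @param t_recent generations of recent-landrace evolution (50: one
#'   generation per year for an annual crop).
#' @param m per-generation migrant-gamete fraction from DMM into each
#'   RL accession; scalar or vector of length `accessions["RL"]`.
#' @param accessions named integer vector of accession counts per
#'   population (RL excluding the control accession).
#' @param genotypes named integer vector of sampled genotypes per
#'   population (RL excluding the control genotypes).
#' @param include_control add the dent-hybrid control accession to RL.
#' @param control_size genotypes in the control accession.
#' @param f_target named per-population inbreeding targets.  The RL
#'   value is the *within-accession* target, produced mechanistically
#'   by partial selfing (selfing rate `2F/(1+F)`); the population-level
#'   RL inbreeding coefficient additionally contains the fragmentation
#'   (Wahlund) component contributed by drift among accession demes.
#'   The other populations are sampled directly at their target.
#' @param selected_loci `NULL` (all loci neutral) or a data frame with
#'   columns `locus` (id), `s` (selection coefficient, >= 0) and
#'   `direction` (`"favor"` = selection for the DMM-characteristic
#'   allele in RL, `"barrier"` = selection against it).
#' @return A `sim_config` object.
#' @export
sim_config <- function(seed,
                       n_dominant_loci = 168L,
                       n_codominant_loci = 21L,
                       k_alleles = 8L,
                       ssr_mutation_rate = 5e-4,
                       ne = c(main = 500, accession = 80, modern = 200),
                       t_split = 330L,
                       t_sub = 120L,
                       t_fmm = 30L,
                       fmm_dent_fraction = 0.7,
                       t_recent = 50L,
                       m = c(rep(0.001, 12), rep(0.008, 7)),
                       accessions = c(OL = 43L, RL = 19L, NI = 11L,
                                      FMM = 8L, DMM = 22L),
                       genotypes = c(OL = 83L, RL = 73L, NI = 22L,
                                     FMM = 12L, DMM = 24L),
                       include_control = TRUE,
                       control_size = 4L,
                       f_target = c(OL = 0.23, RL = 0.15, NI = 0.34,
                                    FMM = 0.28, DMM = 0.80),
                       selected_loci = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  if (length(m) == 1L) m <- rep(m, accessions[["RL"]])
  stopifnot(all(m >= 0), all(m <= 1),
            length(m) == accessions[["RL"]],
            all(accessions > 0), all(genotypes > 0),
            n_dominant_loci > 0, n_codominant_loci >= 0,
            t_recent >= 0, t_split >= t_sub,
            all(f_target >= 0), all(f_target <= 1))
  if (!is.null(selected_loci)) {
    stopifnot(is.data.frame(selected_loci),
              all(c("locus", "s", "direction") %in% names(selected_loci)),
              all(selected_loci$s >= 0),
              all(selected_loci$direction %in% c("favor", "barrier")))
  }
  structure(list(seed = seed, n_dominant_loci = as.integer(n_dominant_loci),
                 n_codominant_loci = as.integer(n_codominant_loci),
                 k_alleles = as.integer(k_alleles),
                 ssr_mutation_rate = ssr_mutation_rate, ne = ne,
                 t_split = as.integer(t_split), t_sub = as.integer(t_sub),
                 t_fmm = as.integer(t_fmm),
                 fmm_dent_fraction = fmm_dent_fraction,
                 t_recent = as.integer(t_recent), m = m,
                 accessions = accessions, genotypes = genotypes,
                 include_control = include_control,
                 control_size = as.integer(control_size),
                 f_target = f_target, selected_loci = selected_loci),
            class = "sim_config")
}

# Biallelic frequency drift with mutation, vectorised over loci.
drift_biallelic <- function(p, n2, t, mu = 0) {
  for (g in seq_len(t)) {
    p <- rbinom(length(p), n2, p) / n2
    if (mu > 0) p <- p * (1 - mu) + mu / 2
  }
  p
}

# Multi-allelic drift (k-allele mutation), one locus.
drift_kallele <- function(f, n2, t, mu, k) {
  for (g in seq_len(t)) {
    f <- as.numeric(rmultinom(1L, n2, f)) / n2
    f <- f * (1 - mu) + mu / k
  }
  f
}

# Sample diploid genotypes with inbreeding F from population
# frequencies.  Dominant loci: returns 0/1 allele matrices.
sample_dominant_genotypes <- function(p, n, F) {
  L <- length(p)
  a1 <- matrix(rbinom(n * L, 1L, rep(p, each = n)), n, L)
  a2 <- matrix(rbinom(n * L, 1L, rep(p, each = n)), n, L)
  ibd <- matrix(runif(n * L) < F, n, L)
  a2[ibd] <- a1[ibd]
  list(a1 = a1, a2 = a2)
}

sample_codominant_genotypes <- function(freqs, n, F) {
  L <- length(freqs)
  a1 <- matrix(0L, n, L); a2 <- matrix(0L, n, L)
  for (j in seq_len(L)) {
    k <- length(freqs[[j]])
    a1[, j] <- sample.int(k, n, replace = TRUE, prob = freqs[[j]])
    a2[, j] <- sample.int(k, n, replace = TRUE, prob = freqs[[j]])
  }
  ibd <- matrix(runif(n * L) < F, n, L)
  a2[ibd] <- a1[ibd]
  list(a1 = a1, a2 = a2)
}

#' Collapse diploid biallelic genotypes to dominant band phenotypes
#'
#' A band is scored present if the individual carries at least one copy
#' of the band-presence allele; missing genotypes propagate to missing
#' phenotypes.
#'
#' @param geno a [codominant_matrix()] whose allele codes are restricted
#'   to two values per locus.
#' @param presence_allele allele code whose carriers show the band.
#' @return A [dominant_matrix()].
#' @export
mask_dominant <- function(geno, presence_allele = 1L) {
  a1 <- geno$a1; a2 <- geno$a2
  obs <- a1 != MISSING_CODE
  n_alleles <- apply(rbind(a1, a2), 2L, function(v)
    length(unique(v[v != MISSING_CODE])))
  if (any(n_alleles > 2L))
    stop("locus with more than 2 alleles cannot be masked: ",
         paste(colnames(a1)[n_alleles > 2L], collapse = ", "))
  out <- matrix(MISSING_CODE, nrow(a1), ncol(a1),
                dimnames = dimnames(a1))
  out[obs] <- as.integer(a1[obs] == presence_allele |
                           a2[obs] == presence_allele)
  dominant_matrix(out)
}

#' Forward simulation of the study design
#'
#' Wright-Fisher forward simulation.  An ancestral pool splits into a
#' flint lineage (ancestor of OL, NI and, via admixture with dent, FMM)
#' and a dent lineage (DMM) that drift for `t_split` generations.  OL is
#' sampled at the end of that history; RL then evolves from OL for
#' `t_recent` generations in accession-level demes with partial selfing
#' (producing the within-accession inbreeding target), receiving
#' migrant gametes (pollen flow: gametes, not individuals) from DMM at
#' rate `m` per accession, with optional per-locus viability selection
#' on the DMM-characteristic allele.  Diploid genotypes are emitted;
#' dominant loci are biallelic and masked to band phenotypes,
#' codominant loci follow a k-allele mutation model.
#'
#' @param config a [sim_config()].
#' @return List with `dataset` (a [genotype_dataset()]) and `truth`
#'   (list: `ancestry` data frame with the pedigree-expected DMM
#'   ancestry fraction of every RL individual, `loci` data frame with
#'   the neutral/selected class of every locus, `freqs` terminal
#'   population allele frequencies, `warnings`).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cfg <- config
  Ld <- cfg$n_dominant_loci; Lc <- cfg$n_codominant_loci
  k <- cfg$k_alleles
  n2main <- 2 * cfg$ne[["main"]]
  n2mod <- 2 * cfg$ne[["modern"]]
  dom_ids <- sprintf("L%03d", seq_len(Ld))
  cod_ids <- if (Lc > 0) sprintf("S%02d", seq_len(Lc)) else character(0)

  # --- ancestral pool ---
  p_anc <- runif(Ld, 0.05, 0.95)
  f_anc <- replicate(Lc, {
    f <- rgamma(k, 1); f / sum(f)
  }, simplify = FALSE)

  drift_all <- function(pd, fc, n2, t) {
    list(d = drift_biallelic(pd, n2, t),
         c = lapply(fc, drift_kallele, n2 = n2, t = t,
                    mu = cfg$ssr_mutation_rate, k = k))
  }

  # --- deep history: flint vs dent, then OL/NI within flint ---
  t_pre <- cfg$t_split - cfg$t_sub
  flint <- drift_all(p_anc, f_anc, n2main, t_pre)
  dent <- drift_all(p_anc, f_anc, n2main, cfg$t_split)
  ol <- drift_all(flint$d, flint$c, n2main, cfg$t_sub)
  ni <- drift_all(flint$d, flint$c, n2main, cfg$t_sub)
  wd <- cfg$fmm_dent_fraction
  fmm0_d <- (1 - wd) * ni$d + wd * dent$d
  fmm0_c <- Map(function(a, b) (1 - wd) * a + wd * b, ni$c, dent$c)
  fmm <- drift_all(fmm0_d, fmm0_c, n2mod, cfg$t_fmm)
  dmm <- dent

  # --- locus truth / selection setup ---
  loci_truth <- data.frame(locus = c(dom_ids, cod_ids),
                           system = c(rep("dominant", Ld),
                                      rep("codominant", Lc)),
                           class = "neutral", s = 0,
                           direction = NA_character_,
                           stringsAsFactors = FALSE)
  sel <- cfg$selected_loci
  sel_dom <- NULL
  if (!is.null(sel) && nrow(sel) > 0L) {
    bad <- setdiff(sel$locus, loci_truth$locus)
    if (length(bad) > 0L)
      stop("unknown selected locus id(s): ", paste(bad, collapse = ", "))
    idx <- match(sel$locus, loci_truth$locus)
    loci_truth$class[idx] <- "selected"
    loci_truth$s[idx] <- sel$s
    loci_truth$direction[idx] <- sel$direction
    dsel <- sel[sel$locus %in% dom_ids, , drop = FALSE]
    if (nrow(dsel) > 0L) {
      j <- match(dsel$locus, dom_ids)
      # DMM-characteristic allele: presence (1) if the band is commoner
      # in DMM than in OL, else absence (0).
      target <- ifelse(dmm$d[j] >= ol$d[j], 1L, 0L)
      sel_dom <- data.frame(j = j, s = dsel$s, dir = dsel$direction,
                            target = target)
    }
    if (any(sel$locus %in% cod_ids))
      warning("selection on codominant loci is not modelled; ignored")
  }

  # --- RL: individual-based accession demes with selfing + migration ---
  n_acc <- cfg$accessions[["RL"]]
  Na <- cfg$ne[["accession"]]
  Nrl <- n_acc * Na
  acc_of <- rep(seq_len(n_acc), each = Na)
  sigma <- 2 * cfg$f_target[["RL"]] / (1 + cfg$f_target[["RL"]])
  founders_d <- sample_dominant_genotypes(ol$d, Nrl, cfg$f_target[["OL"]])
  founders_c <- sample_codominant_genotypes(ol$c, Nrl, cfg$f_target[["OL"]])
  D1 <- founders_d$a1; D2 <- founders_d$a2
  C1 <- founders_c$a1; C2 <- founders_c$a2
  anc <- rep(0, Nrl)
  m_acc <- cfg$m

  migrant_gametes <- function(nm) {
    gd <- matrix(rbinom(nm * Ld, 1L, rep(dmm$d, each = nm)), nm, Ld)
    gc <- matrix(0L, nm, Lc)
    for (j in seq_len(Lc))
      gc[, j] <- sample.int(k, nm, replace = TRUE, prob = dmm$c[[j]])
    list(d = gd, c = gc)
  }

  pool_mult <- if (is.null(sel_dom)) 1L else 2L
  Np <- Nrl * pool_mult
  acc_pool <- rep(seq_len(n_acc), each = Na * pool_mult)
  offset <- (acc_pool - 1L) * Na

  for (g in seq_len(cfg$t_recent)) {
    par1 <- offset + sample.int(Na, Np, replace = TRUE)
    self <- runif(Np) < sigma
    par2 <- offset + sample.int(Na, Np, replace = TRUE)
    par2[self] <- par1[self]
    mig1 <- runif(Np) < m_acc[acc_pool]
    mig2 <- runif(Np) < m_acc[acc_pool]

    gam <- function(par, mig) {
      u <- matrix(runif(Np * Ld) < 0.5, Np, Ld)
      gd <- D1[par, , drop = FALSE]
      gd[u] <- D2[par, , drop = FALSE][u]
      u <- matrix(runif(Np * Lc) < 0.5, Np, Lc)
      gc <- C1[par, , drop = FALSE]
      gc[u] <- C2[par, , drop = FALSE][u]
      if (cfg$ssr_mutation_rate > 0 && Lc > 0) {
        mu_hit <- matrix(runif(Np * Lc) < cfg$ssr_mutation_rate, Np, Lc)
        gc[mu_hit] <- sample.int(k, sum(mu_hit), replace = TRUE)
      }
      ga <- anc[par]
      nm <- sum(mig)
      if (nm > 0L) {
        mg <- migrant_gametes(nm)
        gd[mig, ] <- mg$d
        if (Lc > 0) gc[mig, ] <- mg$c
        ga[mig] <- 1
      }
      list(d = gd, c = gc, a = ga)
    }
    g1 <- gam(par1, mig1); g2 <- gam(par2, mig2)
    nD1 <- g1$d; nD2 <- g2$d; nC1 <- g1$c; nC2 <- g2$c
    nanc <- (g1$a + g2$a) / 2
    if (!is.null(sel_dom)) {
      w <- rep(1, Np)
      for (r in seq_len(nrow(sel_dom))) {
        j <- sel_dom$j[r]
        copies <- (nD1[, j] == sel_dom$target[r]) +
          (nD2[, j] == sel_dom$target[r])
        fac <- if (sel_dom$dir[r] == "favor") 1 + sel_dom$s[r]
               else 1 - sel_dom$s[r]
        w <- w * fac^copies
      }
      keep <- integer(Nrl)
      for (a in seq_len(n_acc)) {
        rows <- which(acc_pool == a)
        keep[((a - 1L) * Na + 1L):(a * Na)] <-
          sample(rows, Na, replace = TRUE, prob = w[rows])
      }
      D1 <- nD1[keep, , drop = FALSE]; D2 <- nD2[keep, , drop = FALSE]
      C1 <- nC1[keep, , drop = FALSE]; C2 <- nC2[keep, , drop = FALSE]
      anc <- nanc[keep]
    } else {
      D1 <- nD1; D2 <- nD2; C1 <- nC1; C2 <- nC2; anc <- nanc
    }
  }

  # --- assemble samples ---
  split_sizes <- function(total, parts) {
    base <- rep(total %/% parts, parts)
    extra <- total %% parts
    if (extra > 0) base[seq_len(extra)] <- base[seq_len(extra)] + 1L
    base
  }

  rows <- list(); gd1 <- list(); gd2 <- list(); gc1 <- list(); gc2 <- list()
  truth_anc <- list()
  add_pop <- function(pop, pd, fc, Fv) {
    nacc <- cfg$accessions[[pop]]
    sizes <- split_sizes(cfg$genotypes[[pop]], nacc)
    ntot <- sum(sizes)
    gd <- sample_dominant_genotypes(pd, ntot, Fv)
    gc <- if (Lc > 0) sample_codominant_genotypes(fc, ntot, Fv)
          else list(a1 = matrix(0L, ntot, 0), a2 = matrix(0L, ntot, 0))
    accs <- rep(sprintf("%s_A%02d", pop, seq_len(nacc)), sizes)
    ids <- sprintf("%s_%03d", pop, seq_len(ntot))
    rows[[length(rows) + 1L]] <<- data.frame(
      individual = ids, accession = accs, population = pop,
      control = FALSE, stringsAsFactors = FALSE)
    gd1[[length(gd1) + 1L]] <<- gd$a1; gd2[[length(gd2) + 1L]] <<- gd$a2
    gc1[[length(gc1) + 1L]] <<- gc$a1; gc2[[length(gc2) + 1L]] <<- gc$a2
  }
  add_pop("OL", ol$d, ol$c, cfg$f_target[["OL"]])

  # RL: sample genotypes from the evolved accession demes
  rl_sizes <- split_sizes(cfg$genotypes[["RL"]], n_acc)
  rl_idx <- unlist(lapply(seq_len(n_acc), function(a)
    (a - 1L) * Na + sample.int(Na, rl_sizes[a])))
  rl_ids <- sprintf("RL_%03d", seq_along(rl_idx))
  rows[[length(rows) + 1L]] <- data.frame(
    individual = rl_ids,
    accession = rep(sprintf("RL_A%02d", seq_len(n_acc)), rl_sizes),
    population = "RL", control = FALSE, stringsAsFactors = FALSE)
  gd1[[length(gd1) + 1L]] <- D1[rl_idx, , drop = FALSE]
  gd2[[length(gd2) + 1L]] <- D2[rl_idx, , drop = FALSE]
  gc1[[length(gc1) + 1L]] <- C1[rl_idx, , drop = FALSE]
  gc2[[length(gc2) + 1L]] <- C2[rl_idx, , drop = FALSE]
  truth_anc[[1L]] <- data.frame(
    individual = rl_ids,
    accession = rep(sprintf("RL_A%02d", seq_len(n_acc)), rl_sizes),
    ancestry = anc[rl_idx], stringsAsFactors = FALSE)

  if (cfg$include_control) {
    nc <- cfg$control_size
    gd <- sample_dominant_genotypes(dmm$d, nc, cfg$f_target[["DMM"]])
    gc <- if (Lc > 0) sample_codominant_genotypes(dmm$c, nc,
                                                  cfg$f_target[["DMM"]])
          else list(a1 = matrix(0L, nc, 0), a2 = matrix(0L, nc, 0))
    ids <- sprintf("RLC_%03d", seq_len(nc))
    rows[[length(rows) + 1L]] <- data.frame(
      individual = ids, accession = "RL_CTRL", population = "RL",
      control = TRUE, stringsAsFactors = FALSE)
    gd1[[length(gd1) + 1L]] <- gd$a1; gd2[[length(gd2) + 1L]] <- gd$a2
    gc1[[length(gc1) + 1L]] <- gc$a1; gc2[[length(gc2) + 1L]] <- gc$a2
    truth_anc[[2L]] <- data.frame(individual = ids, accession = "RL_CTRL",
                                  ancestry = 1, stringsAsFactors = FALSE)
  }
  add_pop("NI", ni$d, ni$c, cfg$f_target[["NI"]])
  add_pop("FMM", fmm$d, fmm$c, cfg$f_target[["FMM"]])
  add_pop("DMM", dmm$d, dmm$c, cfg$f_target[["DMM"]])

  samp_df <- do.call(rbind, rows)
  samples <- sample_table(samp_df$individual, samp_df$accession,
                          samp_df$population, samp_df$control)
  A1 <- do.call(rbind, gd1); A2 <- do.call(rbind, gd2)
  dimnames(A1) <- dimnames(A2) <- list(samples$individual, dom_ids)
  dom_geno <- codominant_matrix(A1, A2)
  dominant <- mask_dominant(dom_geno, presence_allele = 1L)
  codominant <- NULL
  if (Lc > 0) {
    B1 <- do.call(rbind, gc1); B2 <- do.call(rbind, gc2)
    dimnames(B1) <- dimnames(B2) <- list(samples$individual, cod_ids)
    codominant <- codominant_matrix(B1, B2)
  }
  dataset <- genotype_dataset(samples, codominant, dominant)

  rl_dom_freq <- colMeans((D1 + D2) / 2)
  term_freqs <- list(
    dominant = rbind(OL = ol$d, RL = rl_dom_freq, NI = ni$d,
                     FMM = fmm$d, DMM = dmm$d),
    codominant = list(OL = ol$c, NI = ni$c, FMM = fmm$c, DMM = dmm$c))
  colnames(term_freqs$dominant) <- dom_ids

  list(dataset = dataset,
       truth = list(ancestry = do.call(rbind, truth_anc),
                    loci = loci_truth, freqs = term_freqs,
                    config = cfg))
}

#' Calibrate the split time to a target F_ST
#'
#' Bisects the flint-dent split time so that the realised multi-locus
#' dominant-marker F_ST between OL and DMM matches a target, averaging
#' over replicate simulations.
#'
#' @param config a [sim_config()]; its `t_split` is ignored.
#' @param target_fst target OL-DMM F_ST.
#' @param reps replicates per evaluation.
#' @param tol acceptable deviation of the mean realised F_ST.
#' @param t_range search interval (generations).
#' @param max_iter bisection iterations.
#' @return List with `t_split`, `realized_fst` and the search history.
#' @export
calibrate_t_split <- function(config, target_fst = 0.22, reps = 5,
                              tol = 0.01, t_range = c(20L, 2000L),
                              max_iter = 12L) {
  eval_t <- function(t) {
    vals <- vapply(seq_len(reps), function(r) {
      cfg <- config
      cfg$t_split <- as.integer(t)
      cfg$t_sub <- min(cfg$t_sub, as.integer(t))
      cfg$seed <- config$seed + 7919L * r
      sim <- simulate_study(cfg)
      ft <- estimate_dominant_freq_table(sim$dataset$dominant,
                                         sim$dataset$samples)
      pairwise_fst(system = "dominant", pop_a = "OL", pop_b = "DMM",
                   freqs = ft)$theta
    }, numeric(1))
    mean(vals)
  }
  lo <- t_range[1L]; hi <- t_range[2L]
  history <- list()
  for (i in seq_len(max_iter)) {
    mid <- as.integer(round((lo + hi) / 2))
    fst <- eval_t(mid)
    history[[i]] <- c(t = mid, fst = fst)
    if (abs(fst - target_fst) <= tol) break
    if (fst < target_fst) lo <- mid else hi <- mid
    if (hi - lo <= 1L) break
  }
  last <- history[[length(history)]]
  list(t_split = as.integer(last["t"]), realized_fst = unname(last["fst"]),
       history = do.call(rbind, history))
}
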