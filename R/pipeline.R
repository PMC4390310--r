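#' Pipeline run configuration
#'
#' Either reads the input files named in `paths` or simulates a dataset
#' from a [sim_config()].  The `"full"` profile pins the full published
#' protocol chain and simulation sizes (30k/30k exploratory and 100k/100k final
#' admixture sweeps, 100,000 simulated null loci, full RJ-MCMC
#' defaults); the `"test"` profile uses desk-scale sizes.
#'
#' @param seed global seed; per-stage child seeds are derived from it
#'   deterministically.
#' @param out_dir output directory.
#' @param profile `"test"` (desk-scale) or `"full"` (published protocol sizes).
#' @param paths optional named list: `samples`, `dominant`,
#'   `codominant` (file paths).
#' @param sim optional [sim_config()] for synthetic mode (its seed is
#'   overridden by the stage seed).
#' @param comparisons population pairs for the selection scans.
#' @param k_range K values scanned for the admixture rule.
#' @return A `run_config` object.
#' @export
run_config <- function(seed, out_dir, profile = c("test", "full"),
                       paths = NULL, sim = NULL,
                       comparisons = list(c("OL", "RL"), c("OL", "DMM"),
                                          c("RL", "DMM")),
                       k_range = 1:5) {
  profile <- match.arg(profile)
  if (is.null(paths) && is.null(sim))
    stop("either input paths or a simulation config is required")
  structure(list(seed = seed, out_dir = out_dir, profile = profile,
                 paths = paths, sim = sim, comparisons = comparisons,
                 k_range = k_range),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with fields mirroring [run_config()]; a `sim`
#'   block is passed to [sim_config()].
#' @param seed overrides the seed in the file when not `NULL`.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(seed)) y$seed <- seed
  sim <- NULL
  if (!is.null(y$sim)) {
    y$sim$seed <- y$seed
    if (!is.null(y$sim$selected_loci))
      y$sim$selected_loci <- do.call(rbind.data.frame, y$sim$selected_loci)
    sim <- do.call(sim_config, y$sim)
  }
  run_config(seed = y$seed, out_dir = y$out_dir %||% ".",
             profile = y$profile %||% "test", paths = y$paths, sim = sim)
}

# Deterministic per-stage child seed below 2^31.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

profile_sizes <- function(profile) {
  if (profile == "full")
    list(adm_burn = 30000L, adm_reps = 30000L, adm_runs = 20L,
         final_burn = 100000L, final_reps = 100000L,
         n_sim_loci = 100000L, bs_pilot = 20L, bs_pilot_len = 5000L,
         bs_burn = 50000L, bs_iter = 100000L, bs_thin = 10L)
  else
    list(adm_burn = 1000L, adm_reps = 1000L, adm_runs = 3L,
         final_burn = 1500L, final_reps = 1500L,
         n_sim_loci = 8000L, bs_pilot = 6L, bs_pilot_len = 250L,
         bs_burn = 2000L, bs_iter = 5000L, bs_thin = 5L)
}

#' Run the full analysis pipeline
#'
#' Stages: input (read or simulate) -> allele frequencies -> diversity
#' and divergence statistics -> admixture (K scan + final run +
#' accession classification) -> selection scans (both methods, all
#' comparisons) -> neutral set and introgression contrast.  Every
#' stage's tables are written as TSV under the output directory
#' together with a JSON manifest (seed, profile, versions, stage
#' seeds).  A rerun with the same seed reproduces every output.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with all stage results.
#' @export
run_all <- function(config) {
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  sizes <- profile_sizes(config$profile)
  manifest <- list(seed = config$seed, profile = config$profile,
                   package_version = as.character(utils::packageVersion("introscan")),
                   r_version = R.version.string,
                   sizes = sizes, stages = list())
  log_stage <- function(name, seed) {
    message(sprintf("[%s] stage %s (seed %d)",
                    format(Sys.time(), "%H:%M:%S"), name, seed))
    manifest$stages[[name]] <<- list(seed = seed, time = as.character(Sys.time()))
  }

  # --- inputs ---
  if (!is.null(config$sim)) {
    sseed <- stage_seed(config$seed, "simulate")
    log_stage("simulate", sseed)
    sim <- config$sim
    sim$seed <- sseed
    simres <- simulate_study(sim)
    dataset <- simres$dataset
    write_samples(dataset$samples, file.path(out, "samples.tsv"))
    write_dominant_matrix(dataset$dominant, file.path(out, "dominant.tsv"))
    if (!is.null(dataset$codominant))
      write_codominant_matrix(dataset$codominant,
                              file.path(out, "codominant.str"))
    write.table(simres$truth$ancestry, file.path(out, "truth.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    p <- config$paths
    if (is.null(p$samples) || !file.exists(p$samples))
      stop("missing input path: ", p$samples %||% "(samples unset)")
    samples <- read_samples(p$samples)
    dom <- cod <- NULL
    if (!is.null(p$dominant)) {
      if (!file.exists(p$dominant)) stop("missing input path: ", p$dominant)
      dom <- read_dominant_matrix(p$dominant, samples)
    }
    if (!is.null(p$codominant)) {
      if (!file.exists(p$codominant)) stop("missing input path: ", p$codominant)
      cod <- read_codominant_matrix(p$codominant, samples)
    }
    dataset <- genotype_dataset(samples, cod, dom)
    simres <- NULL
  }

  # --- allele frequencies ---
  fseed <- stage_seed(config$seed, "freqs")
  log_stage("freqs", fseed)
  fis <- if (!is.null(dataset$codominant))
    inbreeding_fis(dataset$codominant, dataset$samples) else 0
  prior <- fit_empirical_prior(dataset$dominant, dataset$samples,
                               F = mean(fis, na.rm = TRUE))
  ft_dom <- estimate_dominant_freq_table(dataset$dominant,
                                         dataset$samples, F = fis,
                                         prior = prior)
  write_freq_table(ft_dom, file.path(out, "freq_dominant.tsv"))
  ft_cod <- NULL
  if (!is.null(dataset$codominant)) {
    ft_cod <- count_codominant_freq(dataset$codominant, dataset$samples)
    write_freq_table(ft_cod, file.path(out, "freq_codominant.tsv"))
  }

  # --- diversity + divergence ---
  log_stage("stats", stage_seed(config$seed, "stats"))
  div_dom <- diversity_stats(ft_dom)
  write.table(div_dom$summary, file.path(out, "diversity_dominant.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  fstm_dom <- fst_matrix(dataset, "dominant", freqs = ft_dom)
  write.table(as.data.frame(unclass(fstm_dom)),
              file.path(out, "fst_dominant.tsv"), sep = "\t", quote = FALSE)
  div_cod <- fstm_cod <- mantel <- NULL
  if (!is.null(dataset$codominant)) {
    div_cod <- diversity_stats(ft_cod, dataset$codominant, dataset$samples)
    write.table(div_cod$summary, file.path(out, "diversity_codominant.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    fstm_cod <- fst_matrix(dataset, "codominant")
    write.table(as.data.frame(unclass(fstm_cod)),
                file.path(out, "fst_codominant.tsv"), sep = "\t",
                quote = FALSE)
    if (nrow(fstm_cod) >= 4)
      mantel <- mantel_test(fstm_cod, fstm_dom, n_perm = 999,
                            seed = stage_seed(config$seed, "mantel"))
  }

  # --- admixture ---
  aseed <- stage_seed(config$seed, "admix")
  log_stage("admix", aseed)
  acfg <- admixture_config(K = 2L, n_runs = sizes$adm_runs,
                           burn_in = sizes$adm_burn,
                           mcmc_reps = sizes$adm_reps,
                           final_burn_in = sizes$final_burn,
                           final_reps = sizes$final_reps, seed = aseed)
  kscan <- scan_k(dataset, config$k_range, acfg)
  ksel <- select_k(kscan)
  write.table(ksel, file.path(out, "k_selection.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  fit <- anchor_clusters(run_admixture(dataset, acfg), "OL")
  qidf <- data.frame(individual = rownames(fit$q), fit$q,
                     check.names = FALSE)
  write.table(qidf, file.path(out, "q_individuals.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  qadf <- data.frame(accession = rownames(fit$q_accession),
                     fit$q_accession, check.names = FALSE)
  write.table(qadf, file.path(out, "q_accessions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  classes <- classify_rl(fit)
  write.table(classes$classes, file.path(out, "classes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  # --- selection scans ---
  sseed2 <- stage_seed(config$seed, "scan")
  log_stage("scan", sseed2)
  nd <- table(dataset$samples$population[!dataset$samples$control])
  fdist_res <- list(); bayes_res <- list()
  for (cmp in config$comparisons) {
    key <- paste(cmp, collapse = "-")
    icfg <- island_model_config(n_a = nd[[cmp[1L]]], n_b = nd[[cmp[2L]]],
                                n_sim_loci = sizes$n_sim_loci,
                                system = "dominant",
                                f_is = mean(fis, na.rm = TRUE),
                                seed = stage_seed(sseed2, paste0("fd", key)))
    fdist_res[[key]] <- fdist_scan(ft_dom, cmp[1L], cmp[2L], icfg)
    write.table(fdist_res[[key]]$loci,
                file.path(out, paste0("fdist_", key, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    bcfg <- bayescan_config(n_pilot = sizes$bs_pilot,
                            pilot_len = sizes$bs_pilot_len,
                            burn_in = sizes$bs_burn,
                            n_iter = sizes$bs_iter, thin = sizes$bs_thin,
                            seed = stage_seed(sseed2, paste0("bs", key)))
    bayes_res[[key]] <- bayescan_scan(dataset, cmp[1L], cmp[2L],
                                      "dominant", bcfg)
    write.table(bayes_res[[key]]$loci,
                file.path(out, paste0("bayescan_", key, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  consensus <- build_consensus(fdist_res, bayes_res)
  write.table(consensus, file.path(out, "consensus.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  # --- neutral set + introgression contrast ---
  iseed <- stage_seed(config$seed, "introgress")
  log_stage("introgress", iseed)
  neutral <- build_neutral_set(consensus,
                               all_loci = colnames(dataset$dominant))
  write.table(data.frame(locus = c(neutral$retained, neutral$excluded),
                         class = rep(c("neutral", "excluded"),
                                     c(length(neutral$retained),
                                       length(neutral$excluded)))),
              file.path(out, "neutral_set.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  icfg2 <- acfg
  icfg2$seed <- iseed
  contrast <- tryCatch(
    introgression_contrast(dataset, neutral, icfg2),
    error = function(e) { warning(conditionMessage(e)); NULL })
  if (!is.null(contrast))
    write.table(contrast$accessions, file.path(out, "introgression.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  ol_rl_outliers <- unique(consensus$locus[consensus$any_flag])
  dh <- delta_h_by_class(ft_dom, ol_rl_outliers, "OL", "RL")
  write.table(dh, file.path(out, "delta_h.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  manifest$mantel <- mantel
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(dataset = dataset, sim = simres, prior = prior,
                 freq_dominant = ft_dom, freq_codominant = ft_cod,
                 diversity_dominant = div_dom, diversity_codominant = div_cod,
                 fst_dominant = fstm_dom, fst_codominant = fstm_cod,
                 mantel = mantel, k_selection = ksel, admixture = fit,
                 classes = classes, fdist = fdist_res, bayescan = bayes_res,
                 consensus = consensus, neutral = neutral,
                 contrast = contrast, delta_h = dh))
}
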