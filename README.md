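# introscan

Population-genetic analysis of recent introgression from modern crop
varieties into traditional landraces, for dual marker systems:
codominant microsatellite-style loci and dominant AFLP-style
band-presence loci.  The package is aimed at researchers who have
genotyped landrace collections sampled at two time points (before and
after the spread of modern varieties) together with modern reference
material, and who want to know **how much** modern germplasm has
introgressed and **whether selection** shaped that introgression.

## What it computes

Given a sample table (individuals → accessions → populations, with the
conventional labels OL = old landraces, RL = recent landraces,
NI = external landraces, FMM/DMM = modern flint/dent varieties):

* **Allele frequencies** — direct counts for codominant loci; for
  dominant loci the Bayesian posterior mean of the band-absence allele
  frequency under the phenotype model
  P(absent) = q² + F·q(1−q), with an empirically fitted (non-uniform)
  beta prior and the codominant F_IS of the same population plugged in
  as F.
* **Diversity and divergence** — effective allele number
  n_e = 1/Σp², unbiased expected heterozygosity
  He = (2n/(2n−1))(1−Σp²) (raw 2p(1−p) for dominant loci),
  Weir–Cockerham F_IS and pairwise θ (F_ST), ΔH = 1 − He_A/He_B,
  Mantel and rank tests.
* **Admixture** — a Gibbs sampler for the correlated-frequency
  admixture model handling mixed codominant + dominant data (latent
  genotypes for band-present phenotypes), the Evanno ΔK rule for K,
  accession-level membership, and the RL_A/RL_B introgression
  classification against the minimum-OL-accession threshold.
* **Selection scans** — an island-model simulated-null F_ST|He scan
  with 30% trimmed-mean calibration iterated to a fixed point
  (P < 0.01), and a reversible-jump MCMC locus-effect model
  (logit F_ST,ij = α_i + β_j) reporting posterior odds on the
  Jeffreys scale; plus the two-method consensus table.
* **The neutral-vs-all contrast** — a neutral locus set (every locus
  with any flag removed), admixture re-fitted on both locus sets, and
  the RL accessions' modern-cluster membership q₂ compared between
  them (raw and standardised to the OL→0 / DMM→1 anchors).
* **A forward Wright–Fisher simulator** (`simulate_study()`) that
  generates study-scale datasets — five populations, accession
  structure, ~50 generations of pollen-mediated migration, partial
  selfing, per-locus selection, dominant masking — with ground truth
  for every individual's donor ancestry and every locus's selection
  class.

## Worked example

```r
library(introscan)

# simulate a study-like dataset: 160 dominant loci, selection
# favouring donor alleles at 8 of them
sel <- data.frame(locus = sprintf("L%03d", 1:8), s = 0.06,
                  direction = "favor")
cfg <- sim_config(seed = 2013, n_dominant_loci = 160, n_codominant_loci = 0,
                  accessions = c(OL = 10, RL = 10, NI = 2, FMM = 2, DMM = 6),
                  genotypes  = c(OL = 60, RL = 60, NI = 4, FMM = 4, DMM = 24),
                  m = rep(0.004, 10), include_control = FALSE,
                  selected_loci = sel)
sim <- simulate_study(cfg)
ft  <- estimate_dominant_freq_table(sim$dataset$dominant, sim$dataset$samples)

# both selection scans over the three population pairs, then the
# consensus and the neutral locus set
fd <- list(); bs <- list()
for (cmp in list(c("OL","RL"), c("OL","DMM"), c("RL","DMM"))) {
  key  <- paste(cmp, collapse = "-")
  icfg <- island_model_config(n_a = 60, n_b = 60, n_sim_loci = 6000,
                              seed = 26)
  fd[[key]] <- fdist_scan(ft, cmp[1], cmp[2], icfg)
  bcfg <- bayescan_config(n_pilot = 4, pilot_len = 200, burn_in = 1500,
                          n_iter = 4000, thin = 5, seed = 24)
  bs[[key]] <- bayescan_scan(sim$dataset, cmp[1], cmp[2], "dominant", bcfg)
}
cons <- build_consensus(fd, bs)
ns   <- build_neutral_set(cons, all_loci = colnames(sim$dataset$dominant))
cat("flagged loci:", length(ns$excluded), "\n")
#> flagged loci: 5

# the headline contrast
acfg <- admixture_config(K = 2, burn_in = 500, mcmc_reps = 500,
                         final_burn_in = 1200, final_reps = 1200, seed = 28)
introgression_contrast(sim$dataset, ns, acfg)
#> introgression contrast over 10 accessions:
#>   q2(all) = 0.267, q2(neutral) = 0.222 (rank test P = 0.29)
#>   standardised: 0.256 vs 0.202
```

Read: with selection favouring donor alleles, introgression measured
on all loci (q₂ = 0.27) exceeds introgression measured on the loci
that show no selection signal (q₂ = 0.22) — selection inflated the
apparent gene flow.  At this desk scale the direction is clear while
the unpaired rank test across 10 accessions is not individually
significant; on a neutral simulation the two estimates coincide.

`run_all(run_config(...))` chains every stage (frequencies → statistics
→ admixture → scans → contrast) and writes TSV tables plus a JSON
manifest; `inst/scripts/introscan.R` is a thin command-line wrapper.

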