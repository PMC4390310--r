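---
title: "Models and methods behind introscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind introscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`introscan` quantifies recent introgression from modern crop varieties
into traditional landraces and asks whether selection shaped it.  The
pipeline combines two marker systems — codominant, multiallelic
microsatellite-style loci and dominant AFLP-style band
presence/absence loci — and runs: allele-frequency estimation,
diversity and divergence statistics, model-based admixture clustering,
two F~ST~-outlier selection scans, and the contrast between
introgression measured on all loci versus on a neutral locus subset.
This vignette explains each model, its assumptions, the parameters
that matter, and the choices made where the design was genuinely open.

## Study design assumed by the pipeline

Five populations organise every analysis: old landraces sampled before
the spread of modern hybrids (OL), the same landrace system sampled
~50 years later (RL), a geographically distinct landrace group used in
flint breeding (NI), and modern flint (FMM) and dent (DMM) variety
sets.  Individuals are nested in accessions (farmer fields or
cultivars); accessions are the replication unit for introgression
statements.  One RL accession can be a control — a modern dent hybrid
grown in situ — which takes part only in admixture displays and is
excluded from every other statistic.

## Dominant allele-frequency estimation

A dominant marker hides the heterozygote: with band-absence allele
frequency $q$ and inbreeding coefficient $F$, the band-absent
phenotype has probability
$$\pi(q) = q^2 + F\,q(1-q),$$
the identity-by-descent decomposition of homozygote frequency.  With
$x$ band-absent individuals among $n$, the posterior under a
Beta$(a,b)$ prior is $\propto q^{a-1}(1-q)^{b-1}\pi(q)^x(1-\pi(q))^{n-x}$.
We report the posterior mean, evaluated by adaptive quadrature
(relative tolerance $10^{-8}$) rather than MCMC: the problem is
one-dimensional, and a deterministic estimator is testable to the last
digit.  The non-uniform prior is fitted empirically in two passes:
uniform-prior estimates for all loci, then a method-of-moments
Beta fit across loci (falling back to uniform if the moment fit is
degenerate).  The $F$ plugged in per population is the Weir–Cockerham
F~IS~ of the same population computed from the codominant markers,
clamped to $[0,1]$.

## Diversity and divergence

Codominant expected heterozygosity uses Nei's unbiased form
$\frac{2n}{2n-1}(1-\sum_i p_i^2)$; dominant loci default to the raw
$2p(1-p)$ (maximum 0.5), with the small-sample factor selectable.  The
raw form reproduces the published per-locus values we use as worked
examples at two decimals.  The effective allele number is
$n_e = 1/\sum_i p_i^2$.

F-statistics are Weir–Cockerham variance components: genotype-based
$\theta$ (with heterozygosity terms) for codominant loci, and a
frequency-based two-level analysis applied to the Bayesian frequency
estimates (gene-copy sample sizes) for dominant loci.  Multi-locus
values are ratios of summed components; negative per-locus estimates
are reported as computed.  The relative diversity change between two
populations is $\Delta H = 1 - He_A/He_B$; because per-locus ratios
and ratios of mean diversities differ when He varies across loci, both
aggregations are always reported (on the published rounded inputs for
the recent-versus-old outlier loci they come out 0.65 and 0.62,
bracketing the published 0.63).

The Mantel test between the two marker systems' F~ST~ matrices is a
plain permutation test (Pearson r of off-diagonals, random row/column
permutations, $(1+\text{count})/(1+N)$ p-value, mandatory seed).  Rank
tests delegate to base R: exact signed-rank distributions up to 25
untied pairs (zero differences dropped first), midrank ties and
continuity correction otherwise.

## Admixture model

Population structure is inferred with a Gibbs sampler for the
admixture model with correlated cluster allele frequencies (the
F-model): cluster frequencies are Dirichlet-distributed around
ancestral frequencies with per-cluster drift parameters $F_k$, each
individual has a membership vector $q_i$ with a shared Dirichlet
parameter $\alpha$ (Metropolis-updated under a uniform prior), and
each allele copy carries a latent cluster assignment.  Dominant loci
are handled by their genotypic ambiguity: a band-present phenotype
carries a latent genotype (heterozygote versus presence-homozygote)
sampled each sweep jointly with the copy assignments under the current
cluster frequencies; band-absent phenotypes fix both copies.  The
sampler is implemented in C++ and runs on R's RNG, so a seed fixes the
chain exactly.

Model evidence per K is summarised by the usual proxy
$\widehat{\ln P(D)} = \overline{\ln L} - \mathrm{var}(\ln L)/2$ over
post-burn-in sweeps.  The number of clusters follows the
second-difference rule $\Delta K = \overline{|L(K-1) - 2L(K) +
L(K+1)|}/\mathrm{sd}(L(K))$ over replicate runs; only likelihoods
enter, so no label alignment across runs is needed.  Membership
coefficients come from one long final run; cluster 1 is anchored as
the cluster with the highest mean membership among OL individuals
(ties by first index).  The published protocol (20 runs of
30k+30k sweeps; final run 100k+100k, reading the ambiguous "100,000
burn-in periods and MCMC repetitions" as 100k of each) is preserved in
the `full` profile; the `test` profile uses short chains, which on
simulated data recovers two pools at F~ST~ ≈ 0.2 with ≥ 0.9
own-cluster membership.

RL accessions are split into low-introgression (RL~A~) and
admixed/high-introgression (RL~B~) classes by the minimum OL
accession-mean q~1~ threshold.

## Outlier scans

**Simulated-null scan.** Neutral expectation under drift and migration
is generated from a symmetric two-deme island model in its stationary
Beta approximation: ancestral frequencies are resampled from the
observed pooled frequencies, deme frequencies are Beta draws around
them with variance parameter chosen by bisection so that the
trimmed-mean (30% per tail) F~ST~ of the simulated loci — zero-clipped
exactly like the observed target — matches the calibration target, and
sampling noise is added by binomial phenotype draws at the observed
sample sizes.  Crucially, simulated loci are pushed through the *same*
estimator path as the data (Bayesian frequency estimation, the same
frequency-based $\theta$), cancelling estimator bias.  Conditional
P-values $P(F_{ST} \ge f \mid He)$ use ~50 equal-count He bins
(small bins merged) with linear interpolation between bin centres;
this binning is our approximation to the original program's
undocumented smoothing.  The scan iterates: trimmed-mean target over
retained loci → envelope → exclude loci with $P < 0.01$ → retarget,
until no new locus is excluded (exclusions are cumulative, hence
monotone); a final pass evaluates all loci against the converged
envelope.  Dominant loci whose pooled commonest-allele frequency
(computed from the raw phenotype frequency via the Hardy–Weinberg map
$p = 1-\sqrt{1-\text{phen}}$, since the Bayesian posterior mean never
reaches the boundary) is ≥ 0.98 are reported untested.

**Locus-effect RJ-MCMC scan.** The differentiation of locus $i$ in
population $j$ of a pair is decomposed as
$\mathrm{logit}(F_{ST,ij}) = \alpha_i + \beta_j$ with priors
$\alpha_i \sim N(0,1)$, $\beta_j \sim N(-1,1)$.  Codominant allele
counts enter through the Dirichlet-multinomial likelihood; dominant
loci carry a latent per-population band-absence frequency with a
binomial phenotype likelihood in which the inbreeding coefficient is a
sampled parameter with a uniform prior on $[0,1]$.  Reversible-jump
moves toggle each $\alpha_i$ with prior inclusion odds 1:10, using
independent normal proposals whose location and scale are adapted in
pilot runs (which also tune the random-walk scales toward 25–45%
acceptance).  The per-locus evidence reported and binned on the
Jeffreys scale is the **posterior odds** of the with-selection model
(the reference convention; with 1:10 prior odds an uninformative locus
sits near 0.1, so "barely worth mentioning" genuinely indicates
evidence); the prior-normalised odds ratio is also returned.  A small
continuity correction ($+0.5$ pseudo-samples) keeps the odds finite
when the chain never (or always) includes a locus.

A consensus table combines both scans across the three population
pairs; a "strong outlier" needs the simulated-null flag at $P<0.01$
and at least "very strong" posterior odds in the same comparison.

## Neutral set and the introgression contrast

The neutral set excludes every locus with any flag, at any level, in
any comparison, by either method.  The K = 2 admixture model is then
fitted twice — all loci and neutral loci — each run re-anchored to OL
independently.  Per-accession RL membership in the modern cluster
(q~2~) is compared between the locus sets with the *unpaired* rank
(Wilcoxon/Kruskal–Wallis) test across accessions.  The unpaired form
is deliberate: changing the locus set moves every accession's q~2~
coherently by a small amount (locus resampling noise exceeds MCMC
noise), so a paired test rejects for any locus-set change whether or
not selection is involved; the unpaired test instead asks whether the
shift is large relative to the between-accession spread, which is the
question of interest and matches the test named in the analysis
protocol we follow.  Raw and standardised q~2~ are both reported,
the standardisation mapping the OL population mean to 0 and the DMM
mean to 1.

## The forward simulator

The generator is first-class code used for calibration and recovery
testing.  Deep history is frequency-based Wright–Fisher: an ancestral
pool (dominant loci uniform on $[0.05,0.95]$; codominant loci
symmetric-Dirichlet over up to 8 alleles with k-allele mutation at
$5\times10^{-4}$) splits into flint and dent lineages (deme size 500)
for `t_split` generations; within flint, OL and NI split `t_sub`
generations ago; FMM is a 30:70 flint:dent admixture drifted briefly
at size 200; DMM is the dent terminus.  The default
`t_split = 330` was set by the package's bisection calibrator
(`calibrate_t_split()`) so that the realised multi-locus dominant
F~ST~(OL, DMM) — as measured by the package's own estimator at the
default sample sizes — averages ≈ 0.22; note the realised estimate,
not the process parameter, is calibrated.

The recent phase is individual-based: 19 RL accession demes of size 80
founded from OL evolve for 50 generations (one generation per year for
an annual crop) with partial selfing (rate $2F/(1+F)$ for the
within-accession inbreeding target $F = 0.15$; the population-level RL
F~IS~ then also carries the fragmentation (Wahlund) component from
drift among accessions, landing near the 0.35–0.40 range without
further tuning), pollen-mediated migration — each gamete is a DMM
migrant with accession-specific probability `m` — and optional
per-locus genic viability selection with coefficient `s` on the
DMM-characteristic allele, either favouring it ("favor") or opposing
it ("barrier").  The default `m` is bimodal (12 accessions at 0.001,
7 at 0.008), mirroring the observed dichotomy between
low-introgression and admixed accessions; effective sizes and
migration rates are free parameters of the simulator, not estimates of
any real system.  Ground truth records each RL individual's
pedigree-expected donor ancestry (migrant gametes count 1, otherwise
the parental mean), which obeys the closed form $1-(1-m)^t$ in
expectation, and each locus's selection class.

What the generator does *not* emulate: linkage and hitchhiking (loci
are unlinked, as the downstream methods assume), genotyping error and
band homoplasy in dominant markers, size homoplasy in microsatellites,
overlapping generations, and temporal variation in migration.  Passing
tests therefore demonstrate statistical correctness of the estimators
under the stated model, not robustness to those artefacts.

## Numerical choices and degenerate inputs

* Missing data use the single sentinel −9 in all text formats;
  genotypes are stored unordered (sorted pairs) as no phase exists.
* Quadrature posteriors are normalised at the mode before integration
  to avoid underflow; monomorphic cells return frequency 1 and are
  excluded from divergence.
* A fully monomorphic population yields undefined F~IS~ (reported
  missing); all-zero paired differences give p = 1 with a warning;
  constant matrices make the Mantel statistic undefined (error).
* Zero run-to-run variance makes ΔK undefined at that K; it is
  excluded from the argmax with a warning.
* MCMC chain failure modes: the Gibbs sampler clamps frequencies at
  $10^{-12}$ before normalisation; the RJ sampler clamps
  $\theta = e^{-(\alpha+\beta)}$ to $[10^{-6}, 10^8]$.

## Problem sizes used by the test-suite and reproduction script

Unit and acceptance tests run at desk scale as the package's own
standard verification sizes: 120–500 loci, 60–160 individuals,
5,000–8,000 simulated null loci, 2,000-sweep admixture chains and
RJ-MCMC chains of a few thousand iterations with short pilots; the
calibration and recovery thresholds they enforce are unchanged from
the full protocol.  The `full` profile of `run_config()` pins the
complete published-protocol sizes (100,000 null loci; 30k/30k ×20 and 100k/100k
admixture; 20×5,000 pilots, 50k burn-in, 100k iterations, thin 10) for
a faithful reproduction run.

A regime note on the diversity-change contrast: introgression under
weak selection leaves donor alleles at intermediate frequency in the
recipient, raising its diversity at selected loci (positive
ΔH gap between outlier and neutral classes).  Stronger
selection-time products drive those loci toward fixation of the donor
allele, so the recipient's diversity at detected outliers collapses
and the gap reverses sign.  Both regimes are produced by the
simulator depending on `s`·`t_recent` relative to the starting
frequencies; the sign of the reported gap should be read against the
scenario, not as a fixed expectation.

## Known limitations

The island-model Beta approximation reproduces the conditional
F~ST~–He null well in the central heterozygosity range but is slightly
conservative for low-He loci relative to explicit drift divergence, so
very-low-diversity outliers are flagged less readily than mid-range
ones.  Posterior odds near the "barely" boundary are Monte-Carlo noisy
at short chain lengths; neutral-set construction treats them as flags
regardless.  The admixture sampler assumes Hardy–Weinberg proportions
within clusters; strong within-accession selfing inflates apparent
admixture slightly.  None of these affect the direction of the
headline contrast in the scenarios tested.
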