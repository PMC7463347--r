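---
title: "Quantifying three-way introgression and its effect on heterozygosity in Mytilus"
author: "musselmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying three-way introgression and its effect on heterozygosity in Mytilus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(musselmix)
```

## The problem

The three European mussel species — *Mytilus edulis* (ME),
*M. galloprovincialis* (MG) and *M. trossulus* (MT) — hybridize wherever
they meet, producing a mosaic of populations whose genomes mix the three
backgrounds in varying proportions. Two questions drive the analysis this
package implements: *how much* of each species' ancestry does each
individual and each sampled site carry, and *what does that admixture do*
to genome-wide heterozygosity, a quantity repeatedly linked to growth,
viability and fecundity in mussels?

The inputs are reduced-representation (RAD-seq) SNP genotypes: a VCF with
`GT:DP:GQ` fields, a map from samples to sampling sites, a designation of
three sites as pure reference populations (one per species), and per-site
sea-surface temperature and salinity. Everything downstream — filtering,
reference panels, ancestry, heterozygosity, inference — is deterministic
given the data and the seeds recorded in the run manifest.

## Quality control

`run_qc()` applies, in order:

1. **Genotype masking** — calls with genotype quality or read depth of 5
   or less are set to missing (thresholds are strict: a call *at* the
   threshold is masked). Masking single genotypes, rather than dropping
   whole sites, follows standard VCF practice.
2. **Site call rate** — loci typed in fewer than 60% of individuals are
   removed (the boundary is kept).
3. **Depth cap** — loci whose mean depth exceeds twice the mean depth of
   the *raw* dataset are removed as likely collapsed paralogs. The raw
   mean is computed over all non-missing genotypes before any filtering
   and is reported in the QC report.
4. **Individual missingness** — samples with strictly more than 50%
   missing data are removed.
5. **Minor allele frequency** — loci with MAF of 0.01 or less (over all
   retained samples) are removed.
6. **Linkage pruning** — sliding windows of 50 SNPs advanced by 5, within
   each contig; in any window, for a retained pair with squared dosage
   correlation above 0.5 the lower-call-rate locus is dropped (tie: the
   later locus). Windows do not cross contigs: physical linkage does not
   either, and for de novo RAD loci — each tag its own contig — only SNPs
   on the same tag compete. This matters: species-informative loci are in
   near-perfect *ancestry* linkage across the whole genome, and a pruner
   that compared arbitrary locus pairs would strip most of them out.
   A pair sitting numerically at the threshold is kept (the comparison
   carries a 1e-12 guard so the outcome does not depend on floating-point
   summation order).

Site filters can invalidate each other's preconditions after individuals
are removed; `run_qc(fixed_point = TRUE)` re-runs the site filters to a
fixed point and records the number of passes. The default is a single
pass in protocol order.

## Reference panels, polymorphism classes, diagnostic loci

`build_panel()` estimates per-species alt-allele frequencies from the
pure-site samples only. A locus is *polymorphic in species s* when its
panel frequency lies strictly inside (0, 1) and at least `min_typed`
(default 10) pure samples of *s* were typed — the guard keeps fixation
calls off tiny denominators; the study-sized panels hold 16–18 samples.
The class of a locus is the subset of species in which it segregates;
classes feed both the cross-species polymorphism summary and
class-partitioned heterozygosity. A locus is *MT-diagnostic* when all
three panels are exactly fixed, ME and MG agree, and MT carries the other
allele — fixation in every panel, not merely strong differentiation.
`count_diagnostic_alleles()` then screens any population for MT alleles
at those loci.

## Supervised ancestry estimation

With the pure panels as fixed references, each individual's ancestry
vector $Q = (q_{ME}, q_{MG}, q_{MT})$ on the simplex is estimated by
maximum likelihood under a binomial mixture: the dosage at locus $l$ is
modeled as $g_l \sim \mathrm{Bin}(2, f_l)$ with
$f_l = \sum_s q_s p_{s,l}$. The EM algorithm attributes each observed
allele copy to a source species with posterior probability proportional
to $q_s p_{s,l}$ (alt copies) or $q_s (1 - p_{s,l})$ (ref copies), and
averages the posteriors. The log-likelihood is concave in $Q$, so the
optimum is global; the implementation still runs multiple starts (uniform
plus Dirichlet draws, default 5) as a numerical safeguard, and tests
compare the result against an exhaustive simplex grid. Panel frequencies
are clamped into $[\epsilon, 1-\epsilon]$ (default $10^{-3}$) so that an
introgressed allele absent from a finite pure panel cannot contribute an
infinite penalty. Individuals typed at fewer than 50 usable loci are
flagged and not estimated.

Reported per individual: $Q$; *ancestry dosage* $2Q$ (the expected number
of allele copies per species, on the 0–2 scale local-ancestry methods
use); *main ancestry*, the arg-max species (exact ties resolve in the
fixed order ME, MG, MT, with a flag); and *introgression*
$I = 1 - q_{main} \in [0, 2/3]$, the ancestry fraction not attributable
to the focal species. Site-level summaries average dosages within sites;
site introgression is computed from the site mean dosage (not as the
mean of individual $I$ — the two differ when main ancestry varies within
a site, and the individual values remain available).

## Heterozygosity

Population observed heterozygosity `population_ho()` is the unweighted
mean over loci of the heterozygote frequency among the site's typed
genotypes — averaging per-locus frequencies, not per-individual
proportions; the two differ under missingness.

Standardized multilocus heterozygosity `smlh()` for individual $i$ is
$\sum_{l \in T_i} \mathrm{het}_{il} / \sum_{l \in T_i} \bar H_l$, where
$T_i$ are the subset loci typed in $i$ and $\bar H_l$ is the heterozygote
frequency at $l$ over **all** individuals typed there. The baseline is
dataset-wide (the standard definition); with complete data the mean of
sMLH over individuals is exactly 1, which the tests assert to machine
precision. A per-population baseline is a plausible alternative the
definition leaves open; restricting the input matrix to one population
before calling `smlh()` produces it. `smlh_partitioned()` recomputes
sMLH (baselines included) within the three mutually exclusive classes
built from the pure panels: ME-only, MG-only, and ME+MG polymorphic loci.

## Inference

* Group contrasts: Welch *t* test by default (`pooled = TRUE` gives the
  classical test; the choice is exposed because either convention is
  common), classical one-way ANOVA for sMLH across main ancestries.
* Population level: least squares of Ho on main ancestry, introgression
  and their interaction, with sequential (type-I) F tests in that term
  order, plus within-species introgression slopes from per-level refits.
  Ancestry classes with fewer than two units are excluded from slope
  estimation — a lone population cannot support a slope, so the MT class
  typically drops out.
* Individual level: a Gaussian random-intercept model
  $y = X\beta + u_{site} + \varepsilon$ fitted by **maximum likelihood**
  (not REML — fixed-effect likelihood-ratio tests are invalid under
  REML). The fit profiles the exact log-likelihood over the variance
  ratio $\sigma^2_{site}/\sigma^2_{resid}$, solving the generalized
  least-squares problem in closed form at each ratio via per-site
  sufficient statistics; the boundary $\sigma^2_{site}=0$ (ordinary least
  squares) is checked explicitly. This makes a single fit cheap enough
  (well under a millisecond at these sizes) that full parametric
  bootstrap calibration studies run in minutes; tests verify agreement
  with `lme4::lmer(REML = FALSE)` and with exhaustive likelihood grids.
* Significance by parametric bootstrap: the observed statistic is
  $2(\ell_{full} - \ell_{null})$; responses are simulated from the fitted
  null (site intercepts, then residuals), both models refitted, and
  $p = (1 + \#\{LR^* \ge LR_{obs}\})/(B + 1)$ — the add-one convention
  keeps $p$ off zero. Default $B = 1000$; replicate fit failures are
  dropped and counted, with more than 5% failing treated as an error.
* Environment: Pearson correlations of the three site mean dosages with
  SST and salinity (six tests), two-sided p-values, Benjamini–Hochberg
  adjustment across the tests actually performed (a constant covariate is
  flagged and excluded from the family).

## The synthetic-data generator

`simulate_dataset()` generates data with the statistical structure the
analysis assumes, so the whole pipeline is testable without downloads.
What it emulates, and the choices behind it:

* **Design**: 3 pure reference sites (17/16/18 individuals) plus 12
  admixed sites of 14–18, about 250 individuals at 2,000 loci — the
  sampling structure of a European transect with Mediterranean MG,
  North-Sea ME and Canadian MT references, southern MG-dominant and
  northern ME-dominant admixed sites, and Baltic-proximal MT traces.
* **Locus classes**: 52.3% of loci private to one species, 24.3% shared
  by two, 9.0% shared by three, the remainder monomorphic; 60 MT-vs-rest
  fixed differences planted in the monomorphic pool. Ownership is split
  symmetrically across species and pairs. Real catalogs are asymmetric,
  but under Hardy–Weinberg sampling an asymmetric split is incompatible
  with the heterozygosity ordering the generator must reproduce (a
  species owning few polymorphic loci cannot be the most heterozygous);
  the weights are configurable for scenarios that need the asymmetry.
* **Frequency spectra**: symmetric Beta$(a_s, a_s)$ per species, with
  $a_s$ solved from $E[2p(1-p)] = a_s/(2a_s+1)$ against per-species
  heterozygosity targets 0.09 (ME), 0.11 (MG), 0.13 (MT). ME and MG
  draws are folded to the minor allele — the young sister species share
  no fixed differences — while MT keeps the unfolded spectrum: it is the
  anciently diverged outgroup and carries high-frequency private
  alleles, which is also what lets its variation survive a global MAF
  filter applied to a dataset in which MT ancestry is rare. Draws are
  stratified by quantile (one draw per equal-probability slice, shuffled)
  and ownership counts are rounded deterministically: marginal
  distributions are exactly Beta, but the realized per-species
  heterozygosity mass sits on its target instead of fluctuating by
  several percent, which is what makes the qualitative contrasts below
  reproducible seed after seed at this locus count.
* **Genotypes**: each individual's $Q$ comes from its site's Dirichlet
  (pure sites sit at the vertices); the two allele copies at a locus
  pick source species from $Q$, sharing the source with probability
  `ancestry_rho` (default 1), then draw alleles from that species'
  frequency. The default is the long-backcross mosaic limit: an admixed
  genome is a patchwork of ancestry-homozygous blocks, and expected
  heterozygosity responds *linearly* to ancestry — introgression pulls
  heterozygosity toward the donor species' level, up for ME backgrounds,
  down for MG backgrounds, which is the empirical structure this system
  shows. `ancestry_rho = 0` recovers instant admixture
  ($g \sim \mathrm{Bin}(2, \sum_s q_s p_{s,l})$, the estimator's model),
  which maximizes hybrid heterozygosity excess instead; intermediate
  values interpolate. Expected dosage is $2f$ for every value, so
  ancestry estimation is unaffected by the choice.
* **Degradation**: missingness completely at random (default 10%),
  negative-binomial depth (mean 17.2, so the depth cap sits at 34.4),
  genotype quality a deterministic multiple of depth, and optional
  planted violations of every QC rule (low call rate, inflated depth,
  high-missingness individuals, sub-MAF loci, duplicated SNPs on a
  shared tag) with a manifest for planted-truth tests.
* **Covariates**: site SST rises with mean MG and falls with mean ME
  ancestry; salinity falls with mean MT ancestry (the brackish-water
  species); Gaussian noise with configurable spread, defaults giving a
  signal-to-noise at which sign recovery is near-certain across seeds.

What the generator does **not** emulate: linkage beyond explicitly
planted duplicates (the analysis operates post-pruning), inbreeding
within ancestry sources (no Wahlund effect beyond the ancestry mosaic
itself), ascertainment against a real reference catalog, locus-specific
error rates, or selection. Passing tests therefore demonstrate the
pipeline's internal correctness and its behavior under the assumed
statistical structure — not robustness to every artifact of a real RAD
dataset.

## Numerical choices

* EM: relative log-likelihood tolerance $10^{-6}$, at most 1,000
  iterations, renormalization of $Q$ each step (the EM map does not
  contract floating-point drift in the simplex constraint, so without
  renormalization rounding error compounds geometrically).
* Panel clamp $\epsilon = 10^{-3}$; likelihood evaluations use `log1p`
  near 1.
* Profile-ML mixed model: the variance ratio is optimized on the log
  scale over $[e^{-18}, e^{12}]$ with the boundary checked; per-site
  sufficient statistics make each ratio evaluation $O(\mathrm{sites}
  \times p^2)$.
* Ties: main-ancestry ties resolve ME < MG < MT with a flag; linkage
  pruning ties remove the later locus; PCA signs follow the
  largest-magnitude loading.
* Degenerate inputs error early and loudly: empty sites, all-removed
  samples, subsets with no heterozygotes, rank-deficient designs.

## Problem sizes used in validation

The test suite validates at sizes chosen to finish in minutes while
leaving the conclusions stable: QC against brute-force oracles on 25
random matrices up to 50 × 120 plus explicit boundary fixtures; exact
planted-truth recovery on 2,000 loci with 200-sample pure panels and a
0.05 detectability floor; ancestry recovery on 100 Dirichlet-admixed
individuals at 2,000 loci (root-mean-square error under 0.05, grid-search
agreement at 0.001 resolution on 20 instances of 80 loci); mixed-model
recovery over 100 simulations of n = 500; bootstrap type-I calibration
with B = 200 over 500 outer replicates; and the full-pipeline contrasts
(heterozygosity ordering, slope signs, class-partitioned slope signs)
over 40 seeded replicates of the default design.

## Known limitations

* Ancestry is a single genome-wide coefficient per individual; there is
  no local (per-locus) ancestry, no tract lengths, no timing of
  admixture.
* The supervised estimator trusts the purity of the reference sites; a
  contaminated reference biases all downstream ancestry (the generator
  can plant contamination to probe this).
* ML variance components are biased low in few-site designs (the usual
  ML-vs-REML trade; REML is deliberately not used because the
  likelihood-ratio machinery needs ML).
* sMLH baselines default to the pooled dataset; with strong population
  structure the per-population alternative can be materially different.
* The LD pruner is a greedy within-window heuristic (as is standard);
  it guarantees no retained over-threshold pair within a window, not a
  maximum-size retained set.
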