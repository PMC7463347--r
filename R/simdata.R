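#' Symmetric Beta shape hitting a heterozygosity target
#'
#' For allele frequencies drawn from Beta(a, a), the expected Hardy-Weinberg
#' heterozygosity is `E[2p(1-p)] = a / (2a + 1)`. Solving for `a` gives the
#' shape whose frequency spectrum yields a desired expected heterozygosity
#' at polymorphic loci.
#'
#' @param ho target expected heterozygosity, in (0, 0.5).
#' @return The Beta shape parameter.
#' @export
beta_shape_from_ho <- function(ho) {
  stopifnot(ho > 0, ho < 0.5)
  ho / (1 - 2 * ho)
}


#' Default population layout for the simulator
#'
#' Three pure reference sites (fixed ancestry at the simplex vertices) plus
#' twelve admixed sites of 14-18 individuals whose ancestry vectors are
#' drawn from site-specific Dirichlet distributions: a southern,
#' MG-dominant group with increasing ME introgression, and a northern,
#' ME-dominant group with varying MG introgression and small MT fractions
#' that are strongest near the Baltic. Sample sizes follow the study design
#' this generator emulates.
#'
#' @return data.frame with columns `site`, `n`, `species` (pure label or
#'   `UNKNOWN`), `a_ME`, `a_MG`, `a_MT` (Dirichlet parameters; `NA` for
#'   pure sites, which use fixed vertex ancestry).
#' @export
default_populations <- function() {
  data.frame(
    site = c("GE1", "ITA", "CAN",
             "PO1", "PO2", "PO3", "FRA", "UK1", "NET", "GE2", "UK2", "UK3",
             "UK4", "SWE", "UK5"),
    n = c(17L, 16L, 18L,
          18L, 18L, 18L, 15L, 16L, 17L, 17L, 15L, 14L, 18L, 17L, 18L),
    species = c("ME", "MG", "MT", rep("UNKNOWN", 12)),
    a_ME = c(NA, NA, NA, 2.5, 3.5, 4.5, 6, 14, 15, 14, 16, 13, 15, 13, 12),
    a_MG = c(NA, NA, NA, 16, 15, 14, 12, 5, 4, 3, 3, 6, 3, 3, 6),
    a_MT = c(NA, NA, NA, 0.4, 0.4, 0.4, 0.5, 0.6, 0.6, 2.5, 0.6, 0.8, 1.5, 3, 1),
    stringsAsFactors = FALSE
  )
}

#' Simulator configuration
#'
#' Defines the statistical structure of a synthetic three-species hybrid
#' zone. Defaults are calibrated to the system the package models: locus
#' class fractions of 52.3\% private to one species, 24.3\% shared by two
#' and 9.0\% shared by all three, with the remainder monomorphic; class
#' ownership is split symmetrically across species so that each species'
#' genome-wide heterozygosity is ordered by its per-locus target (asymmetric
#' ownership is configurable); 60 MT-diagnostic fixed differences carved
#' from the monomorphic pool; symmetric Beta frequency spectra whose shapes
#' are solved from per-species expected-heterozygosity targets of 0.09 (ME),
#' 0.11 (MG) and 0.13 (MT), with the young sister species ME and MG folded
#' to the minor allele (so the only fixed interspecific differences involve
#' the anciently diverged MT); missingness 10\% at random; negative-binomial
#' read depth with mean 17.2 (so the depth cap sits at 34.4); genotype
#' quality a deterministic multiple of depth; and site covariates linearly
#' coupled to mean site ancestry with Gaussian noise.
#'
#' @param seed integer RNG seed; runs are bitwise reproducible.
#' @param n_loci number of loci.
#' @param class_fractions named fractions `private`, `two`, `three` of loci
#'   polymorphic in one, two and all three species (remainder monomorphic).
#' @param private_weights split of private loci among ME, MG, MT.
#' @param pair_weights split of two-species loci among ME+MG, ME+MT, MG+MT.
#' @param n_diagnostic number of MT-diagnostic fixed-difference loci.
#' @param ho_targets named per-species expected heterozygosity at
#'   polymorphic loci.
#' @param freq_bounds optional length-2 truncation interval for polymorphic
#'   allele frequencies before folding (default `NULL`: untruncated, so the
#'   analytic moment calibration is exact). Truncation guarantees planted
#'   polymorphism is detectable in finite panels (used by planted-truth
#'   scenarios) at the cost of inflating realized heterozygosity above the
#'   targets.
#' @param fold_species species whose polymorphic draws are folded to the
#'   minor allele (default ME and MG, the young sister pair that shares no
#'   fixed differences; MT, the divergent outgroup, keeps an unfolded
#'   spectrum and so carries high-frequency species-specific alleles).
#' @param populations population layout as in [default_populations()].
#' @param ancestry_rho probability that the two allele copies of a genotype
#'   derive from the same source species (default 1: the long-backcross
#'   mosaic limit, where an admixed genome is a patchwork of
#'   ancestry-homozygous blocks and heterozygosity responds linearly to
#'   ancestry; 0 gives instant admixture — independent copies, i.e. the
#'   binomial mixture — with maximal hybrid heterozygosity excess). The
#'   expected dosage is `2f` for any value, so ancestry estimation is
#'   unaffected.
#' @param missing_rate missing-completely-at-random genotype rate.
#' @param depth_mean,depth_size negative-binomial read-depth model.
#' @param gq_slope genotype quality = `min(99, gq_slope * depth)`.
#' @param env environment model: intercepts, slopes and noise standard
#'   deviations for SST (increasing in MG, decreasing in ME ancestry) and
#'   salinity (decreasing in MT ancestry).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_loci = 2000L,
                       class_fractions = c(private = 0.523, two = 0.243, three = 0.090),
                       private_weights = c(ME = 1, MG = 1, MT = 1) / 3,
                       pair_weights = c("ME+MG" = 1, "ME+MT" = 1, "MG+MT" = 1) / 3,
                       n_diagnostic = 60L,
                       ho_targets = c(ME = 0.09, MG = 0.11, MT = 0.13),
                       freq_bounds = NULL,
                       fold_species = c("ME", "MG"),
                       populations = default_populations(),
                       ancestry_rho = 1,
                       missing_rate = 0.10,
                       depth_mean = 17.2, depth_size = 4,
                       gq_slope = 4,
                       env = list(sst_base = 13, sst_slope = 4, sst_sd = 0.5,
                                  sal_base = 33, sal_slope = 20, sal_sd = 1.0)) {
  stopifnot(sum(class_fractions) <= 1, all(class_fractions >= 0),
            abs(sum(private_weights) - 1) < 1e-8,
            abs(sum(pair_weights) - 1) < 1e-8,
            all(ho_targets > 0 & ho_targets < 0.5),
            missing_rate >= 0, missing_rate < 1,
            ancestry_rho >= 0, ancestry_rho <= 1,
            is.null(freq_bounds) || (length(freq_bounds) == 2 &&
                                       freq_bounds[1] > 0 && freq_bounds[2] < 1))
  ok_pure <- stats::na.omit(populations$species[populations$species != "UNKNOWN"])
  stopifnot(all(c("ME", "MG", "MT") %in% ok_pure) || nrow(populations) > 0)
  structure(list(seed = as.integer(seed), n_loci = as.integer(n_loci),
                 class_fractions = class_fractions,
                 private_weights = private_weights, pair_weights = pair_weights,
                 n_diagnostic = as.integer(n_diagnostic),
                 ho_targets = ho_targets, freq_bounds = freq_bounds,
                 fold_species = fold_species,
                 populations = populations, ancestry_rho = ancestry_rho,
                 missing_rate = missing_rate,
                 depth_mean = depth_mean, depth_size = depth_size,
                 gq_slope = gq_slope, env = env),
            class = "sim_config")
}

# Stratified symmetric-Beta draw, optionally truncated to a detectability
# window and optionally folded to the minor allele (the alt allele is then
# the species' rarer variant). Stratification (one draw per equal-probability
# quantile slice, in random order) keeps the marginal distribution exactly
# Beta while pinning realized moments — in particular the per-species
# heterozygosity mass — to their calibration targets instead of leaving them
# to Monte-Carlo noise. Folding leaves 2p(1-p) untouched.
rbeta_fold <- function(n, a, bounds, fold) {
  lo <- 0; hi <- 1
  if (!is.null(bounds)) {
    lo <- stats::pbeta(bounds[1], a, a)
    hi <- stats::pbeta(bounds[2], a, a)
  }
  u <- lo + (hi - lo) * (sample.int(n) - stats::runif(n)) / n
  x <- stats::qbeta(u, a, a)
  if (fold) pmin(x, 1 - x) else x
}

# Deterministic split of n items among named weights (largest-remainder
# rounding), returned as a shuffled label vector.
split_counts <- function(n, weights) {
  k <- floor(weights * n)
  rem <- n - sum(k)
  if (rem > 0) {
    extra <- order(weights * n - k, decreasing = TRUE)[seq_len(rem)]
    k[extra] <- k[extra] + 1L
  }
  sample(rep(names(weights), times = k))
}

#' Simulate true per-species allele frequencies with class structure
#'
#' Assigns every locus a polymorphism class by the configured fractions,
#' then draws alternate-allele frequencies: private loci take a Beta draw
#' (folded to the minor allele for ME and MG) in the owner species and are
#' fixed at 0 elsewhere; shared loci draw independent Beta frequencies in
#' each member species; diagnostic loci (taken from the monomorphic pool)
#' are fixed at 1 in MT and 0 in ME and MG; remaining monomorphic loci are
#' 0 everywhere. ME and MG therefore share no fixed differences, while MT
#' carries planted fixed differences and, via its unfolded spectrum,
#' additional near-fixed private alleles.
#'
#' @param cfg a [sim_config].
#' @return list of class `sim_freqs`: `p` (3 x L true frequency matrix,
#'   rows ME/MG/MT), `class_true` (per-locus class label as produced by
#'   [classify_polymorphism()]), `diagnostic_true` (logical per locus),
#'   `loci` (locus table).
#' @export
simulate_panel_freqs <- function(cfg) {
  set.seed(cfg$seed)
  L <- cfg$n_loci
  n_priv <- round(cfg$class_fractions[["private"]] * L)
  n_two <- round(cfg$class_fractions[["two"]] * L)
  n_three <- round(cfg$class_fractions[["three"]] * L)
  n_mono <- L - n_priv - n_two - n_three
  if (cfg$n_diagnostic > n_mono) {
    stop("n_diagnostic (", cfg$n_diagnostic,
         ") exceeds the monomorphic locus pool (", n_mono, ")")
  }
  a <- vapply(cfg$ho_targets, beta_shape_from_ho, numeric(1))[SPECIES]

  owner_priv <- split_counts(n_priv, cfg$private_weights[SPECIES])
  owner_two <- split_counts(n_two, cfg$pair_weights[c("ME+MG", "ME+MT", "MG+MT")])

  class_lab <- c(owner_priv, owner_two, rep("ME+MG+MT", n_three), rep("NONE", n_mono))
  diag_true <- c(rep(FALSE, L - n_mono), rep(TRUE, cfg$n_diagnostic),
                 rep(FALSE, n_mono - cfg$n_diagnostic))
  ord <- sample.int(L)
  class_lab <- class_lab[ord]
  diag_true <- diag_true[ord]

  p <- matrix(0, 3, L, dimnames = list(SPECIES, NULL))
  for (s in SPECIES) {
    member <- vapply(strsplit(class_lab, "+", fixed = TRUE), function(v) s %in% v,
                     logical(1))
    p[s, member] <- rbeta_fold(sum(member), a[[s]], cfg$freq_bounds,
                               fold = s %in% cfg$fold_species)
  }
  p["MT", diag_true] <- 1

  ids <- sprintf("L%04d:%d", seq_len(L), 1L)
  colnames(p) <- ids
  loci <- data.frame(id = ids, chrom = sprintf("L%04d", seq_len(L)), pos = 1L,
                     ref = "A", alt = "T", stringsAsFactors = FALSE)
  structure(list(p = p, class_true = class_lab, diagnostic_true = diag_true,
                 loci = loci, config = cfg),
            class = "sim_freqs")
}

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha)
  x / sum(x)
}

#' Simulate admixed genotypes from true frequencies
#'
#' Draws each individual's ancestry vector Q from its site's Dirichlet (pure
#' sites use fixed vertex ancestry), then samples genotypes copy-wise: each
#' allele copy picks a source species from Q — the second copy re-uses the
#' first copy's source with probability `ancestry_rho` — and then draws the
#' allele from that species' frequency. With `ancestry_rho = 0` this is
#' exactly dosage ~ Binomial(2, f), `f = sum_s q_s p_{s,l}`, the model the
#' supervised ancestry estimator inverts; for any value of `ancestry_rho`
#' the expected dosage stays `2f`.
#'
#' @param freqs a `sim_freqs` from [simulate_panel_freqs()].
#' @param cfg the [sim_config] (defaults to the one inside `freqs`).
#' @return list: `gm` (a clean [genotype_matrix], no missingness yet) and
#'   `truth` (data.frame of true Q per individual).
#' @export
simulate_genotypes <- function(freqs, cfg = freqs$config) {
  set.seed(cfg$seed + 1L)
  pops <- cfg$populations
  n_total <- sum(pops$n)
  L <- ncol(freqs$p)

  samples <- character(0); sites <- character(0)
  Q <- matrix(NA_real_, 0, 3)
  for (k in seq_len(nrow(pops))) {
    row <- pops[k, ]
    ids <- sprintf("%s_%02d", row$site, seq_len(row$n))
    if (row$species %in% SPECIES) {
      qk <- matrix(rep(as.numeric(SPECIES == row$species), row$n), ncol = 3,
                   byrow = TRUE)
    } else {
      qk <- t(vapply(seq_len(row$n),
                     function(i) rdirichlet1(c(row$a_ME, row$a_MG, row$a_MT)),
                     numeric(3)))
    }
    samples <- c(samples, ids); sites <- c(sites, rep(row$site, row$n))
    Q <- rbind(Q, qk)
  }
  P <- freqs$p
  rho <- cfg$ancestry_rho
  if (rho == 0) {
    F <- Q %*% P                          # n x L mixture frequencies
    G <- matrix(stats::rbinom(n_total * L, 2L, as.vector(F)), n_total, L)
  } else {
    # copy-wise ancestry with within-locus correlation rho
    sA <- sB <- matrix(0L, n_total, L)
    for (i in seq_len(n_total)) {
      sA[i, ] <- sample.int(3L, L, replace = TRUE, prob = Q[i, ])
      sB[i, ] <- sample.int(3L, L, replace = TRUE, prob = Q[i, ])
    }
    same <- matrix(stats::runif(n_total * L) < rho, n_total, L)
    sB[same] <- sA[same]
    col3 <- rep((seq_len(L) - 1L) * 3L, each = n_total)
    pA <- matrix(P[col3 + as.vector(sA)], n_total, L)
    pB <- matrix(P[col3 + as.vector(sB)], n_total, L)
    G <- (matrix(stats::runif(n_total * L), n_total, L) < pA) +
      (matrix(stats::runif(n_total * L), n_total, L) < pB)
    storage.mode(G) <- "integer"
  }
  dimnames(G) <- list(samples, colnames(freqs$p))

  popmap <- stats::setNames(sites, samples)
  pure <- pops$species != "UNKNOWN"
  panelmap <- stats::setNames(pops$species[pure], pops$site[pure])
  gm <- genotype_matrix(G, freqs$loci, popmap, panelmap)
  truth <- data.frame(sample = samples, site = sites,
                      q_ME = Q[, 1], q_MG = Q[, 2], q_MT = Q[, 3],
                      stringsAsFactors = FALSE)
  list(gm = gm, truth = truth)
}

#' Degrade a clean genotype matrix for filter testing
#'
#' Applies missingness completely at random, attaches negative-binomial read
#' depths and depth-derived genotype qualities, and optionally plants known
#' violations of each QC rule: loci with low call rate, loci with inflated
#' depth, individuals with high missingness, near-monomorphic (sub-MAF)
#' loci, and duplicated locus pairs (r-squared 1) for linkage pruning. The
#' plant manifest is attached as attribute `"plants"`.
#'
#' @param gm a clean [genotype_matrix].
#' @param cfg a [sim_config] (missingness/depth/quality models and seed).
#' @param plants optional list with integer counts `n_low_callrate`,
#'   `n_high_depth`, `n_high_missing`, `n_low_maf`, `n_duplicate`.
#' @return The degraded `genotype_matrix` with DP and GQ, and attribute
#'   `"plants"` (named list of planted IDs).
#' @export
degrade <- function(gm, cfg, plants = NULL) {
  set.seed(cfg$seed + 2L)
  n <- nrow(gm$G); L <- ncol(gm$G)
  G <- gm$G
  manifest <- list()

  pool <- colnames(G)  # loci still unplanted, to keep plants disjoint
  take <- function(k) {
    ids <- sample(pool, k)
    pool <<- setdiff(pool, ids)
    ids
  }

  if (!is.null(plants)) {
    if (isTRUE(plants$n_duplicate > 0)) {
      src <- take(plants$n_duplicate); dst <- take(plants$n_duplicate)
      G[, dst] <- G[, src]
      # the copy becomes a second SNP on the source tag, so linkage pruning
      # (which works within contigs) can see the pair
      js <- match(src, colnames(G)); jd <- match(dst, colnames(G))
      gm$loci$chrom[jd] <- gm$loci$chrom[js]
      gm$loci$pos[jd] <- gm$loci$pos[js] + 1L
      manifest$duplicate_pairs <- data.frame(source = src, copy = dst,
                                             stringsAsFactors = FALSE)
    }
    if (isTRUE(plants$n_low_maf > 0)) {
      ids <- take(plants$n_low_maf)
      for (id in ids) {
        G[, id] <- 0L
        G[sample.int(n, 1), id] <- 1L   # single heterozygote: MAF 1/(2n)
      }
      manifest$low_maf_loci <- ids
    }
  }

  miss <- matrix(stats::runif(n * L) < cfg$missing_rate, n, L)

  if (!is.null(plants)) {
    if (isTRUE(plants$n_low_callrate > 0)) {
      ids <- take(plants$n_low_callrate)
      j <- match(ids, colnames(G))
      miss[, j] <- matrix(stats::runif(n * length(j)) < 0.5, n, length(j))
      # force below the 60% call-rate floor
      for (jj in j) {
        short <- ceiling(0.45 * n) - sum(miss[, jj])
        if (short > 0) miss[sample(which(!miss[, jj]), short), jj] <- TRUE
      }
      manifest$low_callrate_loci <- ids
    }
    if (isTRUE(plants$n_high_missing > 0)) {
      ids <- sample(rownames(G), plants$n_high_missing)
      i <- match(ids, rownames(G))
      for (ii in i) {
        extra <- ceiling(0.60 * L) - sum(miss[ii, ])
        if (extra > 0) miss[ii, sample(which(!miss[ii, ]), extra)] <- TRUE
      }
      manifest$high_missing_samples <- ids
    }
  }
  G[miss] <- NA_integer_

  DP <- matrix(stats::rnbinom(n * L, mu = cfg$depth_mean, size = cfg$depth_size),
               n, L, dimnames = dimnames(G))
  if (!is.null(plants) && isTRUE(plants$n_high_depth > 0)) {
    ids <- take(plants$n_high_depth)
    j <- match(ids, colnames(G))
    DP[, j] <- DP[, j] * 5L + 40L       # far beyond twice the raw mean
    manifest$high_depth_loci <- ids
  }
  GQ <- pmin(99L, as.integer(round(cfg$gq_slope * DP)))
  dim(GQ) <- dim(DP); dimnames(GQ) <- dimnames(DP)

  out <- genotype_matrix(G, gm$loci, gm$popmap, gm$panelmap, DP = DP, GQ = GQ)
  attr(out, "plants") <- manifest
  out
}

#' Simulate site-level environmental covariates
#'
#' SST increases with mean MG ancestry and decreases with mean ME ancestry;
#' salinity decreases with mean MT ancestry (the brackish-water species).
#' Gaussian noise is added with the configured standard deviations.
#'
#' @param truth data.frame of true per-individual Q (from
#'   [simulate_genotypes()]), or any data.frame with columns `site`, `q_ME`,
#'   `q_MG`, `q_MT`.
#' @param cfg a [sim_config].
#' @return data.frame with columns `site`, `sst_celsius`, `salinity_psu`
#'   and the true site mean ancestries.
#' @export
simulate_covariates <- function(truth, cfg) {
  set.seed(cfg$seed + 3L)
  agg <- stats::aggregate(truth[, c("q_ME", "q_MG", "q_MT")],
                          by = list(site = truth$site), FUN = mean)
  if (nrow(agg) < 2) stop("need at least two sites")
  e <- cfg$env
  data.frame(
    site = agg$site,
    sst_celsius = e$sst_base + e$sst_slope * (agg$q_MG - agg$q_ME) +
      stats::rnorm(nrow(agg), 0, e$sst_sd),
    salinity_psu = e$sal_base - e$sal_slope * agg$q_MT +
      stats::rnorm(nrow(agg), 0, e$sal_sd),
    q_ME = agg$q_ME, q_MG = agg$q_MG, q_MT = agg$q_MT,
    stringsAsFactors = FALSE
  )
}

#' Simulate a complete study dataset
#'
#' Runs the full generator: true frequencies with class structure, admixed
#' genotypes, degradation (missingness, depth, quality, optional plants) and
#' site covariates.
#'
#' @param cfg a [sim_config].
#' @param plants optional plant specification passed to [degrade()].
#' @param clean skip degradation entirely (no missingness, no DP/GQ).
#' @return list: `gm` (the degraded [genotype_matrix]), `clean_gm`, `freqs`
#'   (`sim_freqs` truth), `truth` (true Q), `covariates`, `plants`.
#' @export
simulate_dataset <- function(cfg = sim_config(), plants = NULL, clean = FALSE) {
  freqs <- simulate_panel_freqs(cfg)
  sim <- simulate_genotypes(freqs, cfg)
  gm <- if (clean) sim$gm else degrade(sim$gm, cfg, plants)
  cov <- simulate_covariates(sim$truth, cfg)
  list(gm = gm, clean_gm = sim$gm, freqs = freqs, truth = sim$truth,
       covariates = cov, plants = attr(gm, "plants"))
}

#' Write a simulated dataset to standard file formats
#'
#' Emits the VCF, popmap, panelmap and covariate TSVs plus a JSON truth
#' bundle (true Q, locus classes, plant manifest, seed) into a directory.
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory (created if absent).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "genotypes.vcf"),
             popmap = file.path(dir, "popmap.tsv"),
             panelmap = file.path(dir, "panelmap.tsv"),
             covariates = file.path(dir, "covariates.tsv"),
             truth = file.path(dir, "truth.json"))
  write_vcf(sim$gm, paths[["vcf"]])
  utils::write.table(data.frame(sample_id = names(sim$gm$popmap),
                                site = unname(sim$gm$popmap)),
                     paths[["popmap"]], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(site = names(sim$gm$panelmap),
                                species = unname(sim$gm$panelmap)),
                     paths[["panelmap"]], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$covariates[, c("site", "sst_celsius", "salinity_psu")],
                     paths[["covariates"]], sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(seed = sim$freqs$config$seed, truth_q = sim$truth,
         class_true = sim$freqs$class_true,
         diagnostic_true = sim$freqs$loci$id[sim$freqs$diagnostic_true],
         plants = sim$plants),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
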