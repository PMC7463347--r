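test_that("genotype masking is strict at the quality/depth boundary", {
  gm <- make_gm(n = 4, L = 3, seed = 2, missing = 0)
  gm$GQ[] <- 99L; gm$DP[] <- 30L
  gm$GQ[1, 1] <- 5L            # boundary: GQ of exactly 5 is masked
  gm$GQ[2, 1] <- 6L            # just above: kept
  gm$DP[3, 2] <- 5L
  gm$DP[4, 2] <- 6L
  out <- mask_low_quality_genotypes(gm, qc_config())
  expect_true(is.na(out$G[1, 1]))
  expect_false(is.na(out$G[2, 1]))
  expect_true(is.na(out$G[3, 2]))
  expect_false(is.na(out$G[4, 2]))
  # unmarked cells untouched
  expect_identical(out$G[, 3], gm$G[, 3])

  all_good <- make_gm(n = 4, L = 3, seed = 3, missing = 0)
  all_good$GQ[] <- 99L; all_good$DP[] <- 30L
  expect_identical(mask_low_quality_genotypes(all_good, qc_config())$G, all_good$G)

  no_fields <- make_gm(n = 3, L = 3, seed = 4, with_depth = FALSE)
  expect_warning(out2 <- mask_low_quality_genotypes(no_fields, qc_config()),
                 "no genotypes masked")
  expect_identical(out2$G, no_fields$G)
})

test_that("call-rate filter keeps exactly 60% and drops 59%", {
  # 100 samples: 40 missing -> 60% kept; 41 missing -> 59% dropped
  gm <- make_gm(n = 100, L = 3, seed = 5, missing = 0, with_depth = FALSE)
  gm$G[1:40, 1] <- NA_integer_
  gm$G[1:41, 2] <- NA_integer_
  out <- filter_site_callrate(gm, qc_config())
  expect_identical(colnames(out$G), c("loc001", "loc003"))
})

test_that("depth cap removes a locus just above twice the raw mean and keeps the boundary", {
  gm <- make_gm(n = 10, L = 3, seed = 6, missing = 0)
  gm$DP[, 1] <- 34L; gm$DP[, 2] <- 35L
  gm$DP[, 3] <- 34L; gm$DP[1, 3] <- 44L   # mean 35: above cap
  out <- filter_depth_cap(gm, qc_config(), raw_mean_depth = 17.2)  # cap 34.4
  expect_identical(colnames(out$G), "loc001")
  # boundary: mean exactly at the cap is kept
  gm$DP[, 2] <- 40L; gm$DP[, 3] <- 40L
  out2 <- filter_depth_cap(gm, qc_config(), raw_mean_depth = 20)
  expect_identical(ncol(out2$G), 3L)
  no_dp <- make_gm(n = 3, L = 3, with_depth = FALSE)
  expect_error(filter_depth_cap(no_dp, qc_config(), 17), "DP absent")
})

test_that("individual filter keeps exactly 50% missing and drops 51%", {
  gm <- make_gm(n = 3, L = 100, seed = 7, missing = 0, with_depth = FALSE)
  gm$G[1, 1:50] <- NA_integer_
  gm$G[2, 1:51] <- NA_integer_
  out <- filter_individuals(gm, qc_config())
  expect_identical(rownames(out$G), c("S001", "S003"))
  gm$G[] <- NA_integer_
  expect_error(filter_individuals(gm, qc_config()), "all samples")
})

test_that("MAF filter is strict at 0.01", {
  gm <- make_gm(n = 100, L = 3, seed = 8, missing = 0, with_depth = FALSE)
  gm$G[, 1] <- 0L; gm$G[1, 1] <- 1L          # MAF 0.005: dropped
  gm$G[, 2] <- 0L; gm$G[1:2, 2] <- 1L        # MAF exactly 0.01: dropped (strict)
  gm$G[, 3] <- 0L; gm$G[1:3, 3] <- 1L        # MAF 0.015: kept
  out <- filter_maf(gm, qc_config())
  expect_identical(colnames(out$G), "loc003")
})

test_that("linkage pruning removes duplicates, keeps r2 exactly 0.5, prefers call rate", {
  gm <- make_gm(n = 30, L = 6, seed = 9, missing = 0, with_depth = FALSE)
  gm$G[, 2] <- gm$G[, 1]                    # duplicate pair, equal call rate
  gm$G[3, 4] <- NA_integer_                 # locus 4 has lower call rate
  gm$G[, 3] <- gm$G[, 4]                    # duplicate pair, unequal call rate
  out <- ld_prune(gm, qc_config())
  expect_false("loc002" %in% colnames(out$G))  # tie -> later locus removed
  expect_true("loc001" %in% colnames(out$G))
  expect_false("loc004" %in% colnames(out$G))  # lower call rate removed
  expect_true("loc003" %in% colnames(out$G))

  # a pair with r-squared exactly 0.5 survives (threshold is strict)
  gm2 <- make_gm(n = 4, L = 2, seed = 10, missing = 0, with_depth = FALSE)
  gm2$G[, 1] <- c(0L, 1L, 1L, 2L)
  gm2$G[, 2] <- c(0L, 0L, 2L, 2L)
  r2 <- cor(gm2$G[, 1], gm2$G[, 2])^2
  expect_true(r2 <= 0.5 && r2 > 0.49)
  expect_identical(ncol(ld_prune(gm2, qc_config())$G), 2L)
})

test_that("pruning does not cross contigs", {
  gm <- make_gm(n = 30, L = 4, seed = 11, missing = 0, with_depth = FALSE)
  gm$G[, 3] <- gm$G[, 1]
  gm$loci$chrom <- c("tagA", "tagA", "tagB", "tagB")
  out <- ld_prune(gm, qc_config())
  # the duplicate pair sits on different contigs: both survive
  expect_identical(ncol(out$G), 4L)
})

test_that("the full chain runs in order, is idempotent, and reports attrition", {
  cfg <- qc_config()
  sim <- simulate_dataset(sim_config(seed = 41, n_loci = 300, n_diagnostic = 20L),
                          plants = list(n_low_callrate = 4, n_high_depth = 3,
                                        n_high_missing = 2, n_low_maf = 5,
                                        n_duplicate = 3))
  res <- run_qc(sim$gm, cfg)
  rep <- res$report
  steps <- stats::setNames(rep$steps, vapply(rep$steps, `[[`, "", "step"))
  plants <- sim$plants

  expect_true(all(plants$low_callrate_loci %in% steps$site_callrate$removed_loci))
  expect_true(all(plants$high_depth_loci %in% steps$depth_cap$removed_loci))
  expect_true(all(plants$high_missing_samples %in% steps$indiv_missing$removed_samples))
  expect_true(all(plants$low_maf_loci %in%
                    c(steps$site_callrate$removed_loci, steps$maf$removed_loci)))
  # one member of every surviving duplicate pair is pruned
  dup <- plants$duplicate_pairs
  for (k in seq_len(nrow(dup))) {
    pair <- c(dup$source[k], dup$copy[k])
    surviving_before_ld <- setdiff(pair, unlist(lapply(
      steps[c("site_callrate", "depth_cap", "maf")], `[[`, "removed_loci")))
    if (length(surviving_before_ld) == 2) {
      expect_length(intersect(pair, colnames(res$gm$G)), 1L)
    }
  }

  # counts are non-increasing along the chain
  n_loci <- vapply(rep$steps, `[[`, 0L, "n_loci_after")
  expect_true(all(diff(c(rep$steps[[1]]$n_loci_before, n_loci)) <= 0))

  # second pass removes nothing further (fixed point)
  res2 <- run_qc(res$gm, cfg)
  expect_identical(dim(res2$gm$G), dim(res$gm$G))

  # permissive thresholds leave the matrix untouched
  loose <- qc_config(min_gq = 0L, min_dp = 0L, min_site_callrate = 0,
                     depth_cap_multiplier = Inf, max_indiv_missing = 1,
                     min_maf = 0, ld_r2_max = 1)
  gm <- make_gm(n = 8, L = 12, seed = 12, missing = 0.1)
  gm$DP[gm$DP == 0L] <- 1L  # a zero depth would still be masked at min_dp = 0
  gm$GQ <- pmin(gm$DP * 4L, 99L)
  out <- run_qc(gm, loose)$gm
  expect_identical(out$G, gm$G)
})

test_that("every filter matches its brute-force oracle on random fixtures", {
  cfg <- qc_config()
  for (seed in 1:5) {
    gm <- make_gm(n = 15, L = 40, seed = 100 + seed, missing = 0.25)
    masked <- mask_low_quality_genotypes(gm, cfg)
    expect_identical(masked$G, oracle_mask(gm, cfg$min_gq, cfg$min_dp))

    expect_identical(colnames(filter_site_callrate(masked, cfg)$G),
                     oracle_callrate_keep(masked, cfg$min_site_callrate))
    rmd <- raw_mean_depth(gm)
    expect_identical(colnames(filter_depth_cap(masked, cfg, rmd)$G),
                     oracle_depthcap_keep(masked, cfg$depth_cap_multiplier, rmd))
    expect_identical(rownames(filter_individuals(masked, cfg)$G),
                     oracle_indiv_keep(masked, cfg$max_indiv_missing))
    expect_identical(colnames(filter_maf(masked, cfg)$G),
                     oracle_maf_keep(masked, cfg$min_maf))
    pruned <- ld_prune(masked, qc_config(ld_window = 10, ld_step = 2))
    expect_identical(oracle_ld_violations(masked, colnames(pruned$G),
                                          cfg$ld_r2_max, 10, 2), 0L)
  }
})
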