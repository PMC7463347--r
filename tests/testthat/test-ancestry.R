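# A minimal panel with planted structure: n_fix ME-vs-MG fixed differences
# plus shared polymorphic loci. Returns the clamped truth as a ref_panel-like
# list the estimator accepts.
toy_panel <- function(L = 200, n_fix = 60, seed = 1) {
  set.seed(seed)
  p <- matrix(runif(3 * L, 0.2, 0.8), 3, L, dimnames = list(c("ME", "MG", "MT"), NULL))
  p["ME", 1:n_fix] <- 1; p["MG", 1:n_fix] <- 0; p["MT", 1:n_fix] <- 0
  colnames(p) <- sprintf("loc%04d", seq_len(L))
  list(p = p, n = matrix(20, 3, L, dimnames = dimnames(p)))
}

gm_from_G <- function(G, site = "X") {
  loci <- data.frame(id = colnames(G), chrom = colnames(G), pos = 1L,
                     ref = "A", alt = "T", stringsAsFactors = FALSE)
  genotype_matrix(G, loci, stats::setNames(rep(site, nrow(G)), rownames(G)))
}

test_that("pure parental genotypes drive Q to the vertex", {
  panel <- toy_panel()
  L <- ncol(panel$p)
  G <- matrix(0L, 2, L, dimnames = list(c("a", "b"), colnames(panel$p)))
  G[, 1:60] <- 2L                      # homozygous for every ME-fixed allele
  G[, 61:L] <- t(replicate(2, rbinom(L - 60, 2, panel$p["ME", 61:L])))
  prof <- estimate_q(gm_from_G(G), panel, n_starts = 2)
  expect_true(all(abs(prof$q_ME - 1) < 1e-3))
  expect_identical(unique(prof$main_ancestry), "ME")
  expect_true(all(prof$introgression < 1e-3))
})

test_that("an F1 between ME and MG lands at an even split", {
  # reciprocal fixed differences: 100 loci fixed alt in ME only, 100 fixed
  # alt in MG only; an F1 is heterozygous at every one of them
  L <- 200
  p <- matrix(0, 3, L, dimnames = list(c("ME", "MG", "MT"),
                                       sprintf("loc%04d", 1:L)))
  p["ME", 1:100] <- 1
  p["MG", 101:200] <- 1
  panel <- list(p = p, n = matrix(20, 3, L, dimnames = dimnames(p)))
  G <- matrix(1L, 2, L, dimnames = list(c("f1a", "f1b"), colnames(p)))
  prof <- estimate_q(gm_from_G(G), panel)
  expect_true(all(abs(prof$q_ME - 0.5) < 0.02))
  expect_true(all(abs(prof$q_MG - 0.5) < 0.02))
  expect_true(all(prof$q_MT < 0.02))
  # the simplex grid oracle agrees
  g <- loglik_profile(G[1, ], pmin(pmax(panel$p, 1e-3), 1 - 1e-3),
                      resolution = 0.005)
  expect_lt(max(abs(g$argmax - unlist(prof[1, c("q_ME", "q_MG", "q_MT")]))),
            0.01)
})

test_that("the EM log-likelihood never decreases", {
  set.seed(3)
  panel <- toy_panel(L = 120)
  Q <- matrix(rexp(30), 10, 3); Q <- Q / rowSums(Q)
  F <- Q %*% panel$p
  G <- matrix(rbinom(length(F), 2, as.vector(F)), nrow(F),
              dimnames = list(sprintf("i%02d", 1:10), colnames(panel$p)))
  G[sample(length(G), 100)] <- NA_integer_
  P <- pmin(pmax(panel$p, 1e-3), 1 - 1e-3)
  fit <- musselmix:::em_admixture(G, P, c(1, 1, 1) / 3, tol = 1e-10,
                                  max_iter = 300, trace = TRUE)
  diffs <- diff(fit$ll_trace)
  expect_true(all(diffs > -1e-8))
})

test_that("permuting species labels permutes the estimates", {
  set.seed(4)
  panel <- toy_panel(L = 150)
  Q <- matrix(rexp(24), 8, 3); Q <- Q / rowSums(Q)
  F <- Q %*% panel$p
  G <- matrix(rbinom(length(F), 2, as.vector(F)), nrow(F),
              dimnames = list(sprintf("i%02d", 1:8), colnames(panel$p)))
  gm <- gm_from_G(G)
  prof <- estimate_q(gm, panel, tol = 1e-10, max_iter = 5000)
  perm_panel <- panel
  perm_panel$p <- panel$p[c("MG", "MT", "ME"), ]
  rownames(perm_panel$p) <- c("ME", "MG", "MT")
  prof_perm <- estimate_q(gm, perm_panel, tol = 1e-10, max_iter = 5000)
  expect_equal(prof_perm$q_ME, prof$q_MG, tolerance = 1e-4)
  expect_equal(prof_perm$q_MG, prof$q_MT, tolerance = 1e-4)
  expect_equal(prof_perm$q_MT, prof$q_ME, tolerance = 1e-4)
})

test_that("a symmetric panel yields a likelihood surface symmetric in ME and MG", {
  set.seed(5)
  p <- matrix(runif(60, 0.2, 0.8), 3, 20)
  p[2, ] <- p[1, ]                      # ME and MG identical
  rownames(p) <- c("ME", "MG", "MT"); colnames(p) <- sprintf("l%02d", 1:20)
  g <- rbinom(20, 2, p[1, ])
  surf <- loglik_profile(g, p, resolution = 0.05)
  # swap the first two grid coordinates: the surface must be identical
  key <- function(m) paste(round(m[, 1], 6), round(m[, 2], 6), round(m[, 3], 6))
  swapped <- surf$grid[, c(2, 1, 3)]
  idx <- match(key(swapped), key(surf$grid))
  expect_equal(surf$loglik, surf$loglik[idx], tolerance = 1e-9)
})

test_that("individuals below the locus floor are flagged, not estimated", {
  panel <- toy_panel(L = 120)
  G <- matrix(1L, 2, 120, dimnames = list(c("ok", "thin"), colnames(panel$p)))
  G["thin", 31:120] <- NA_integer_     # 30 typed loci < 50
  prof <- estimate_q(gm_from_G(G), panel)
  expect_identical(attr(prof, "flagged"), "thin")
  expect_identical(prof$sample, "ok")
})

test_that("population averages, main ancestry and ties follow the rules", {
  prof <- data.frame(
    sample = c("a", "b", "c"), site = c("X", "X", "Y"),
    q_ME = c(0.7, 0.7, 0.2), q_MG = c(0.2, 0.2, 0.7), q_MT = c(0.1, 0.1, 0.1),
    dosage_ME = c(1.4, 1.4, 0.4), dosage_MG = c(0.4, 0.4, 1.4),
    dosage_MT = c(0.2, 0.2, 0.2), stringsAsFactors = FALSE)
  pop <- population_ancestry(prof)
  expect_equal(pop$dosage_ME[pop$site == "X"], 1.4)
  expect_equal(pop$introgression[pop$site == "X"], 0.3)
  expect_identical(pop$main_ancestry, c("ME", "MG"))
  # single-individual site equals the individual
  expect_equal(pop$introgression[pop$site == "Y"], 0.3)

  expect_equal(assign_main_and_introgression(c(0.7, 0.2, 0.1)),
               list(main = "ME", introgression = 0.3, tie = FALSE))
  expect_equal(assign_main_and_introgression(c(1, 0, 0)),
               list(main = "ME", introgression = 0, tie = FALSE))
  tie <- assign_main_and_introgression(c(0.5, 0.5, 0))
  expect_identical(tie$main, "ME")
  expect_equal(tie$introgression, 0.5)
  expect_true(tie$tie)
})

test_that("simulated Dirichlet admixture is recovered with small error", {
  pops <- data.frame(site = c("pME", "pMG", "pMT", "mix"),
                     n = c(15L, 15L, 15L, 40L),
                     species = c("ME", "MG", "MT", "UNKNOWN"),
                     a_ME = c(NA, NA, NA, 1), a_MG = c(NA, NA, NA, 1),
                     a_MT = c(NA, NA, NA, 1), stringsAsFactors = FALSE)
  cfg <- sim_config(seed = 31, n_loci = 800, populations = pops,
                    missing_rate = 0.05)
  sim <- simulate_dataset(cfg)
  panel <- build_panel(sim$gm)
  prof <- estimate_q(sim$gm, panel, n_starts = 2)
  expect_lt(q_rmse(prof, sim$truth), 0.06)
})
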