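test_that("t statistics match closed-form hand computation", {
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  r <- t_test(x, y, pooled = TRUE)
  # pooled: s2 = (2*1 + 2*1)/4 = 1; t = (2-5)/sqrt(1*(1/3+1/3)); df = 4
  t_hand <- -3 / sqrt(2 / 3)
  expect_equal(r$t, t_hand, tolerance = 1e-12)
  expect_equal(r$df, 4)
  expect_equal(r$p, 2 * stats::pt(t_hand, 4), tolerance = 1e-12)

  # equal means, nonzero variance: t = 0, p = 1
  r0 <- t_test(c(1, 2, 3), c(0, 2, 4))
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)

  # swapping groups negates t, p unchanged
  rs <- t_test(y, x, pooled = TRUE)
  expect_equal(rs$t, -r$t)
  expect_equal(rs$p, r$p)

  expect_error(t_test(c(1, 1, 1), c(1, 1)), "undefined")
})

test_that("one-way ANOVA matches hand-computed sums of squares", {
  v <- c(1, 2, 3, 6, 7, 8, 11, 12, 13)
  g <- rep(c("a", "b", "c"), each = 3)
  r <- anova_oneway(v, g)
  # group means 2, 7, 12; grand mean 7; SSB = 3*(25+0+25) = 150
  # SSW = 3 groups * (1+0+1) = 6; F = (150/2)/(6/6) = 75
  expect_equal(r$F, 75, tolerance = 1e-12)
  expect_identical(c(r$df1, r$df2), c(2L, 6L))
  expect_equal(r$p, stats::pf(75, 2, 6, lower.tail = FALSE), tolerance = 1e-12)

  req <- anova_oneway(c(1, 2, 1, 2), rep(c("a", "b"), each = 2))
  expect_equal(req$F, 0)

  expect_error(anova_oneway(1:5, rep("a", 5)), "two groups")
})

test_that("the ancestry-introgression linear model matches the normal equations", {
  # noiseless: exact recovery
  d <- data.frame(anc = rep(c("ME", "MG"), each = 6),
                  intro = rep(seq(0, 0.5, 0.1), 2))
  y_exact <- ifelse(d$anc == "ME", 0.08 + 0.02 * d$intro, 0.10 - 0.05 * d$intro)
  r <- suppressWarnings(fit_lm(y_exact, d$anc, d$intro))  # perfect-fit notes
  expect_equal(r$slopes$b[r$slopes$ancestry == "ME"], 0.02, tolerance = 1e-10)
  expect_equal(r$slopes$b[r$slopes$ancestry == "MG"], -0.05, tolerance = 1e-10)
  expect_lt(sum(r$anova$`Sum Sq`[4]), 1e-20)

  # toy 8-point dataset against an explicit normal-equations solve
  set.seed(7)
  d8 <- data.frame(anc = rep(c("ME", "MG"), each = 4),
                   intro = c(0.1, 0.2, 0.3, 0.4, 0.1, 0.2, 0.3, 0.4))
  y8 <- round(rnorm(8, 0.1, 0.02), 4)
  X <- cbind(1, d8$anc == "MG", d8$intro, (d8$anc == "MG") * d8$intro)
  beta_hand <- solve(t(X) %*% X, t(X) %*% y8)
  r8 <- fit_lm(y8, d8$anc, d8$intro, min_group = 2)
  expect_equal(unname(r8$coefficients[, 1]), drop(beta_hand), tolerance = 1e-10)

  # a single-level factor cannot support the interaction
  expect_error(fit_lm(y8, rep("ME", 8), d8$intro), "single level")
  # lone-member ancestry classes are excluded before fitting
  r_ex <- fit_lm(c(y8, 0.2), c(d8$anc, "MT"), c(d8$intro, 0.1))
  expect_identical(r_ex$excluded_levels, "MT")
})

test_that("the mixed model collapses to least squares when sites are homogeneous", {
  set.seed(11)
  d <- data.frame(x = runif(60), site = rep(sprintf("s%d", 1:6), each = 10))
  d$y <- 2 + 3 * d$x + rnorm(60, 0, 0.3)    # no site effect
  fit <- fit_lmm(y ~ x, d, d$site)
  ols <- stats::lm(y ~ x, d)
  expect_equal(unname(fit$beta), unname(stats::coef(ols)), tolerance = 1e-6)
  expect_equal(fit$loglik, as.numeric(stats::logLik(ols)), tolerance = 1e-6)
  expect_gte(fit$loglik, as.numeric(stats::logLik(ols)) - 1e-8)
})

test_that("the profile-ML fit matches an exhaustive grid on a balanced layout", {
  set.seed(12)
  y <- rnorm(12, 5, 1) + rep(rnorm(3, 0, 0.8), each = 4)
  g <- rep(1:3, each = 4)
  fit <- fit_lmm(y ~ 1, data.frame(y = y), g)
  # direct evaluation of the exact marginal likelihood over a dense grid
  exact_ll <- function(mu, s2u, s2e) {
    ll <- 0
    for (k in 1:3) {
      yk <- y[g == k] - mu
      V <- diag(4) * s2e + s2u
      ll <- ll - 0.5 * (determinant(V)$modulus + t(yk) %*% solve(V, yk) +
                          4 * log(2 * pi))
    }
    as.numeric(ll)
  }
  grid <- expand.grid(mu = seq(mean(y) - 1, mean(y) + 1, 0.1),
                      s2u = seq(0, 2.5, 0.05), s2e = seq(0.2, 2.5, 0.05))
  lls <- mapply(exact_ll, grid$mu, grid$s2u, grid$s2e)
  best <- grid[which.max(lls), ]
  expect_gte(fit$loglik + 1e-6, max(lls))   # profile optimum beats the grid
  expect_lt(abs(unname(fit$beta[1]) - best$mu), 0.1)
  expect_lt(abs(fit$sigma2_site - best$s2u), 0.06)
  expect_lt(abs(fit$sigma2_resid - best$s2e), 0.06)
})

test_that("the profile-ML fit agrees with lme4 maximum likelihood", {
  skip_if_not_installed("lme4")
  set.seed(13)
  d <- data.frame(x = runif(120), site = rep(sprintf("s%d", 1:12), each = 10))
  d$y <- 1 + 0.5 * d$x + rep(rnorm(12, 0, 0.4), each = 10) + rnorm(120, 0, 0.6)
  fit <- fit_lmm(y ~ x, d, d$site)
  lmer_fit <- lme4::lmer(y ~ x + (1 | site), data = d, REML = FALSE)
  expect_equal(unname(fit$beta), unname(lme4::fixef(lmer_fit)), tolerance = 1e-4)
  expect_equal(fit$loglik, as.numeric(stats::logLik(lmer_fit)), tolerance = 1e-5)
  vc <- as.data.frame(lme4::VarCorr(lmer_fit))
  expect_equal(fit$sigma2_site, vc$vcov[1], tolerance = 1e-3)
  expect_equal(fit$sigma2_resid, vc$vcov[2], tolerance = 1e-3)
})

test_that("the parametric bootstrap is seeded, bounded and honest at the degenerate ends", {
  set.seed(14)
  d <- data.frame(x = runif(48), site = rep(sprintf("s%d", 1:8), each = 6))
  d$y <- 1 + rep(rnorm(8, 0, 0.3), each = 6) + rnorm(48, 0, 0.5)
  r1 <- parametric_bootstrap_lrt(y ~ x, y ~ 1, d, d$site, B = 60, seed = 42)
  r2 <- parametric_bootstrap_lrt(y ~ x, y ~ 1, d, d$site, B = 60, seed = 42)
  expect_identical(r1$LR_star, r2$LR_star)
  expect_identical(r1$p, r2$p)
  expect_gte(r1$p, 1 / 61)
  expect_lte(r1$p, 1)

  # identical models: LR = 0, p = 1
  r0 <- parametric_bootstrap_lrt(y ~ 1, y ~ 1, d, d$site, B = 30, seed = 1)
  expect_equal(r0$LR_obs, 0)
  expect_equal(r0$p, 1)

  # a strong effect is detected at the lower bound of the estimator
  d$y2 <- d$y + 5 * d$x
  rs <- parametric_bootstrap_lrt(y2 ~ x, y2 ~ 1, d, d$site, B = 60, seed = 3)
  expect_equal(rs$p, 1 / 61)
})

test_that("BH adjustment equals the hand step-up construction", {
  expect_equal(bh_adjust(0.037), 0.037)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")

  # random vectors against an explicit step-up implementation
  set.seed(15)
  for (k in 1:3) {
    p <- runif(7)
    o <- order(p); m <- length(p)
    q_sorted <- pmin(1, rev(cummin(rev(m * p[o] / seq_len(m)))))
    q_hand <- numeric(m); q_hand[o] <- q_sorted
    expect_equal(bh_adjust(p), q_hand)
    # order invariance
    perm <- sample(m)
    expect_equal(bh_adjust(p[perm]), q_hand[perm])
  }
})

test_that("environment correlations recover exact and degenerate structure", {
  pop <- data.frame(site = sprintf("s%d", 1:6),
                    dosage_ME = c(2, 1.8, 1.4, 1.0, 0.6, 0.2),
                    dosage_MG = c(0, 0.2, 0.6, 1.0, 1.4, 1.8),
                    dosage_MT = 0)
  cov <- data.frame(site = pop$site,
                    sst_celsius = 20 - 4 * pop$dosage_ME,   # exactly linear
                    salinity_psu = c(30, 31, 29, 30, 32, 28))
  r <- correlate_environment(pop, cov)
  expect_equal(r$r[r$species == "ME" & r$covariate == "sst_celsius"], -1)
  expect_equal(r$r[r$species == "MG" & r$covariate == "sst_celsius"], 1)
  # constant dosage: flagged, excluded from the adjustment family
  mt_rows <- r$species == "MT"
  expect_true(all(r$flagged[mt_rows]))
  expect_true(all(is.na(r$q[mt_rows])))
  expect_equal(r$q[!mt_rows], bh_adjust(r$p[!mt_rows]))

  expect_error(correlate_environment(pop[1:3, ], cov[1:3, ]), "4 sites")
})
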