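#' Two-sample t test
#'
#' Two-sided unpaired t test, Welch by default (Satterthwaite degrees of
#' freedom), with an optional pooled-variance version.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @param pooled use the pooled-variance (equal variances) statistic.
#' @return list with `t`, `df`, `p`, `mean_x`, `mean_y`.
#' @export
t_test <- function(x, y, pooled = FALSE) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (stats::var(x) == 0 && stats::var(y) == 0 && mean(x) == mean(y)) {
    stop("both groups constant and equal: t undefined")
  }
  ht <- stats::t.test(x, y, var.equal = pooled)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_x = mean(x), mean_y = mean(y))
}

#' One-way analysis of variance
#'
#' Classical (equal-variance) one-way F test of a group effect.
#'
#' @param values numeric response.
#' @param groups group labels, at least two distinct.
#' @return list with `F`, `df1`, `df2`, `p`.
#' @export
anova_oneway <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups")
  if (length(values) - nlevels(groups) < 1) stop("no residual degrees of freedom")
  tab <- stats::anova(stats::lm(values ~ groups))
  list(F = tab$`F value`[1], df1 = tab$Df[1], df2 = tab$Df[2],
       p = tab$`Pr(>F)`[1])
}

#' Linear model of heterozygosity on ancestry and introgression
#'
#' Least-squares fit of `y ~ ancestry * introgression` where `ancestry` is
#' the main-ancestry factor. Reports per-coefficient t statistics, a
#' sequential (type-I) ANOVA with terms in the order ancestry,
#' introgression, interaction, and within-species introgression slopes
#' obtained by refitting `y ~ introgression` inside each ancestry level.
#' Ancestry levels with fewer than `min_group` observations are excluded
#' from the fit (a lone population cannot support a slope).
#'
#' @param y numeric response (e.g. population Ho or individual sMLH).
#' @param ancestry character/factor of main-ancestry labels.
#' @param introgression numeric introgression scores.
#' @param min_group minimum observations per retained ancestry level
#'   (default 2).
#' @return list of class `model_result`: `coefficients` (matrix with
#'   estimate, se, t, p), `anova` (sequential F table), `slopes`
#'   (per-species introgression slope, se, t, p), `loglik`, `n`,
#'   `excluded_levels`.
#' @export
fit_lm <- function(y, ancestry, introgression, min_group = 2L) {
  stopifnot(length(y) == length(ancestry), length(y) == length(introgression))
  keep_lv <- names(which(table(ancestry) >= min_group))
  excluded <- setdiff(unique(as.character(ancestry)), keep_lv)
  keep <- ancestry %in% keep_lv
  d <- data.frame(y = y[keep], ancestry = factor(ancestry[keep]),
                  introgression = introgression[keep])
  if (nlevels(d$ancestry) < 2) {
    stop("interaction is not estimable: factor has a single level (aliased term: ancestry)")
  }
  if (nrow(d) <= nlevels(d$ancestry) * 2) stop("too few observations for the design")
  fit <- stats::lm(y ~ ancestry * introgression, data = d)
  if (any(is.na(stats::coef(fit)))) {
    stop("rank-deficient design; aliased: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "))
  }
  slopes <- lapply(levels(d$ancestry), function(lv) {
    sub <- d[d$ancestry == lv, ]
    sf <- summary(stats::lm(y ~ introgression, data = sub))$coefficients
    data.frame(ancestry = lv, b = sf["introgression", 1], se = sf["introgression", 2],
               t = sf["introgression", 3], p = sf["introgression", 4],
               n = nrow(sub), stringsAsFactors = FALSE)
  })
  structure(list(
    coefficients = summary(fit)$coefficients,
    anova = stats::anova(fit),
    slopes = do.call(rbind, slopes),
    loglik = as.numeric(stats::logLik(fit)),
    n = nrow(d), excluded_levels = excluded
  ), class = "model_result")
}

# Fast profile-ML fit of the Gaussian random-intercept model
#   y = X beta + u[group] + e,  u ~ N(0, s2_site), e ~ N(0, s2_resid).
# Profiles the likelihood over the variance ratio lambda = s2_site/s2_resid
# using the closed-form GLS solution at fixed lambda; all group reductions
# are precomputed so each lambda evaluation is O(G p^2).
lmm_core <- function(y, X, g, interval = c(-18, 12), tol = 1e-7) {
  n <- length(y); p <- ncol(X)
  if (n <= p) stop("more parameters than observations")
  gi <- as.integer(factor(g))
  G <- max(gi)
  ng <- tabulate(gi, G)
  S <- rowsum(X, gi)                 # G x p group sums of X
  tg <- drop(rowsum(y, gi))          # group sums of y
  XtX <- crossprod(X)
  Xty <- drop(crossprod(X, y))
  yty <- sum(y * y)

  prof <- function(lambda) {
    cg <- lambda / (1 + ng * lambda)
    A <- XtX - crossprod(S, S * cg)
    b <- Xty - drop(crossprod(S, cg * tg))
    ch <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(ch)) return(list(ll = -Inf))
    beta <- backsolve(ch, forwardsolve(t(ch), b))
    Q <- yty - sum(cg * tg^2) - sum(beta * b)
    if (Q <= 0) return(list(ll = -Inf))
    s2 <- Q / n
    ll <- -n / 2 * (log(2 * pi * s2) + 1) - sum(log1p(ng * lambda)) / 2
    list(ll = ll, beta = beta, s2 = s2, A = A)
  }

  opt <- stats::optimize(function(u) prof(exp(u))$ll, interval,
                         maximum = TRUE, tol = tol)
  lambda <- exp(opt$maximum)
  at0 <- prof(0)
  if (at0$ll >= opt$objective) lambda <- 0
  res <- prof(lambda)
  se <- sqrt(diag(solve(res$A)) * res$s2)
  list(beta = stats::setNames(drop(res$beta), colnames(X)),
       se = stats::setNames(se, colnames(X)),
       sigma2_site = lambda * res$s2, sigma2_resid = res$s2,
       lambda = lambda, loglik = res$ll, n = n, n_groups = G,
       converged = is.finite(res$ll))
}

#' Random-intercept linear mixed model by maximum likelihood
#'
#' Fits `y = X beta + u_site + e` with a single random intercept for
#' sampling site, by maximum likelihood (not REML, so that likelihood-ratio
#' tests on fixed effects are valid). Estimation profiles the exact
#' log-likelihood over the variance ratio `sigma2_site / sigma2_resid`,
#' solving the generalized least-squares problem in closed form at each
#' ratio; the boundary `sigma2_site = 0` (ordinary least squares) is checked
#' explicitly.
#'
#' @param formula fixed-effects formula, e.g. `smlh ~ ancestry * introgression`.
#' @param data data.frame holding the variables.
#' @param site grouping vector (or the name of a column of `data`).
#' @return list of class `model_result`: `beta` with `se` and t statistics,
#'   `sigma2_site`, `sigma2_resid`, `loglik`, `n`, `n_groups`, `converged`.
#' @export
fit_lmm <- function(formula, data, site) {
  if (is.character(site) && length(site) == 1) site <- data[[site]]
  if (length(unique(site)) < 2) stop("need at least two sites")
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  if (qr(X)$rank < ncol(X)) stop("rank-deficient fixed-effects design")
  fit <- lmm_core(y, X, site)
  fit$t <- fit$beta / fit$se
  fit$formula <- formula
  class(fit) <- "model_result"
  fit
}

#' @export
print.model_result <- function(x, ...) {
  if (!is.null(x$beta)) {
    cat("Random-intercept LMM (ML)\n")
    print(cbind(estimate = x$beta, se = x$se, t = x$beta / x$se))
    cat(sprintf("sigma2_site = %.5g, sigma2_resid = %.5g, loglik = %.4f\n",
                x$sigma2_site, x$sigma2_resid, x$loglik))
  } else {
    cat("Linear model\n")
    print(x$coefficients)
    if (!is.null(x$slopes)) { cat("Within-ancestry slopes:\n"); print(x$slopes) }
  }
  invisible(x)
}

#' Parametric-bootstrap likelihood-ratio test for mixed models
#'
#' Compares two nested fixed-effects specifications of the random-intercept
#' model. The observed statistic is `LR = 2 (loglik_full - loglik_null)`
#' (clamped at 0). For each of `B` replicates a response is simulated from
#' the fitted null — site intercepts drawn from `N(0, sigma2_site)`, then
#' residuals from `N(0, sigma2_resid)` — and both models are refitted; the
#' p-value is `(1 + #{LR* >= LR_obs}) / (B + 1)`.
#'
#' @param full,null fixed-effects formulas, `null` nested in `full`.
#' @param data data.frame with the model variables.
#' @param site grouping vector or column name.
#' @param B bootstrap replicates (default 1000).
#' @param seed RNG seed; the result is reproducible given (data, B, seed).
#' @return list with `LR_obs`, `p`, `B`, `LR_star` (replicate statistics),
#'   `n_failed`, and the two fitted models.
#' @export
parametric_bootstrap_lrt <- function(full, null, data, site, B = 1000L,
                                     seed = 1L) {
  if (is.character(site) && length(site) == 1) site <- data[[site]]
  fit_full <- fit_lmm(full, data, site)
  fit_null <- fit_lmm(null, data, site)
  LR_obs <- max(0, 2 * (fit_full$loglik - fit_null$loglik))

  gi <- as.integer(factor(site))
  G <- max(gi)
  mf <- stats::model.frame(null, data)
  Xn <- stats::model.matrix(null, mf)
  mu <- drop(Xn %*% fit_null$beta)
  Xf <- stats::model.matrix(full, stats::model.frame(full, data))
  sd_site <- sqrt(fit_null$sigma2_site)
  sd_resid <- sqrt(fit_null$sigma2_resid)
  n <- nrow(data)

  set.seed(seed)
  LR_star <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    ystar <- mu + stats::rnorm(G, 0, sd_site)[gi] + stats::rnorm(n, 0, sd_resid)
    LR_star[b] <- tryCatch({
      f1 <- lmm_core(ystar, Xf, gi)
      f0 <- lmm_core(ystar, Xn, gi)
      max(0, 2 * (f1$loglik - f0$loglik))
    }, error = function(e) NA_real_)
  }
  n_failed <- sum(is.na(LR_star))
  if (n_failed > 0.05 * B) stop(n_failed, " of ", B, " bootstrap refits failed")
  ok <- LR_star[!is.na(LR_star)]
  p <- (1 + sum(ok >= LR_obs)) / (length(ok) + 1)
  list(LR_obs = LR_obs, p = p, B = B, LR_star = LR_star, n_failed = n_failed,
       fit_full = fit_full, fit_null = fit_null)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control: the adjusted value of the i-th
#' smallest p is `min over j >= i of m p_(j) / j`, capped at 1, returned in
#' the original order.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @return Adjusted q-values, same order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Environment correlations of population ancestry
#'
#' Pearson correlations between each species' mean ancestry dosage and each
#' environmental covariate (sea-surface temperature and salinity), six tests
#' in all, with two-sided p-values from the t transform and
#' Benjamini-Hochberg adjustment across the tests actually performed.
#' A constant covariate or dosage leaves that test flagged and excluded
#' from the adjustment.
#'
#' @param pop_ancestry data.frame from [population_ancestry()].
#' @param covariates data.frame from [read_covariates()] (or
#'   [simulate_covariates()]): columns `site`, `sst_celsius`, `salinity_psu`.
#' @return data.frame with columns `species`, `covariate`, `r`, `p`, `q`,
#'   `n`, `flagged`.
#' @export
correlate_environment <- function(pop_ancestry, covariates) {
  d <- merge(pop_ancestry, covariates, by = "site")
  if (nrow(d) < 4) stop("need at least 4 sites with covariates")
  tests <- expand.grid(species = SPECIES,
                       covariate = c("sst_celsius", "salinity_psu"),
                       stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(tests)), function(i) {
    x <- d[[paste0("dosage_", tests$species[i])]]
    yv <- d[[tests$covariate[i]]]
    if (stats::sd(x) == 0 || stats::sd(yv) == 0) {
      return(data.frame(tests[i, ], r = NA_real_, p = NA_real_, n = nrow(d),
                        flagged = TRUE, stringsAsFactors = FALSE))
    }
    ct <- stats::cor.test(x, yv, method = "pearson")
    data.frame(tests[i, ], r = unname(ct$estimate), p = ct$p.value, n = nrow(d),
               flagged = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- NA_real_
  ok <- !out$flagged
  out$q[ok] <- bh_adjust(out$p[ok])
  rownames(out) <- NULL
  out[, c("species", "covariate", "r", "p", "q", "n", "flagged")]
}
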