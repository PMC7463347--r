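#' Estimate three-way admixture proportions by supervised EM
#'
#' Maximum-likelihood estimation of per-individual ancestry proportions
#' \eqn{Q = (q_{ME}, q_{MG}, q_{MT})} on the 3-simplex against fixed
#' reference-panel allele frequencies. The model treats the two allele
#' copies at each locus as independent draws from the mixture allele
#' frequency \eqn{f_l = \sum_s q_s p_{s,l}}, so the dosage likelihood is
#' \eqn{g_l \sim \mathrm{Binomial}(2, f_l)}. The EM update attributes each
#' observed allele copy to a source species with posterior probability
#' proportional to \eqn{q_s p_{s,l}} (alt copies) or \eqn{q_s (1-p_{s,l})}
#' (ref copies) and sets the new \eqn{q_s} to the mean posterior over
#' copies. The log-likelihood is concave in Q, and is non-decreasing over
#' iterations.
#'
#' Panel frequencies are clamped into \eqn{[\epsilon, 1-\epsilon]} so that
#' an allele unobserved in a finite pure panel cannot produce an infinite
#' penalty. Loci with an undefined panel frequency in any species are
#' excluded. Individuals typed at fewer than `min_loci` usable loci are
#' flagged and receive no estimate.
#'
#' @param gm a [genotype_matrix].
#' @param panel a `ref_panel` from [build_panel()].
#' @param eps panel-frequency clamp (default 1e-3).
#' @param tol relative log-likelihood convergence tolerance (default 1e-6).
#' @param max_iter maximum EM iterations per start (default 1000).
#' @param n_starts number of starts: the first is uniform
#'   \eqn{Q = (1/3, 1/3, 1/3)}, the rest are Dirichlet(1,1,1) draws
#'   (default 5); the start with the best final likelihood wins. The
#'   likelihood is concave so all starts agree to tolerance; extra starts
#'   guard the numerics.
#' @param min_loci minimum usable typed loci per individual (default 50).
#' @param seed seed for the Dirichlet starts (default 1).
#' @return An object of class `ancestry_profiles`: a data.frame with one row
#'   per estimated individual (`sample`, `site`, `q_ME`, `q_MG`, `q_MT`,
#'   `dosage_ME`, `dosage_MG`, `dosage_MT`, `main_ancestry`, `introgression`,
#'   `tie_flag`, `loglik`, `n_iter`, `n_loci`), with flagged (unestimated)
#'   samples in attribute `"flagged"`.
#' @export
estimate_q <- function(gm, panel, eps = 1e-3, tol = 1e-6, max_iter = 1000L,
                       n_starts = 5L, min_loci = 50L, seed = 1L) {
  ids <- colnames(gm$G)
  stopifnot(identical(ids, colnames(panel$p)))
  usable <- colSums(is.na(panel$p)) == 0
  P <- pmin(pmax(panel$p[, usable, drop = FALSE], eps), 1 - eps)
  G <- gm$G[, usable, drop = FALSE]

  n_typed <- rowSums(!is.na(G))
  flagged <- rownames(G)[n_typed < min_loci]
  est_idx <- which(n_typed >= min_loci)
  if (length(est_idx) == 0) stop("no individual typed at >= ", min_loci, " usable loci")
  G <- G[est_idx, , drop = FALSE]
  n <- nrow(G)

  starts <- matrix(1 / 3, 1, 3)
  if (n_starts > 1) {
    rs <- local({ set.seed(seed); matrix(stats::rexp(3 * (n_starts - 1)), ncol = 3) })
    starts <- rbind(starts, rs / rowSums(rs))
  }

  best <- NULL
  for (k in seq_len(nrow(starts))) {
    fit <- em_admixture(G, P, starts[k, ], tol, max_iter)
    if (is.null(best)) {
      best <- fit
    } else {
      gain <- fit$loglik > best$loglik + 1e-9
      best$Q[gain, ] <- fit$Q[gain, , drop = FALSE]
      best$loglik[gain] <- fit$loglik[gain]
      best$n_iter[gain] <- fit$n_iter[gain]
    }
  }

  Q <- best$Q
  colnames(Q) <- SPECIES
  main_i <- max.col(Q, ties.method = "first")
  tie <- apply(Q, 1, function(q) sum(q == max(q)) > 1)
  prof <- data.frame(
    sample = rownames(G),
    site = unname(gm$popmap[rownames(G)]),
    q_ME = Q[, 1], q_MG = Q[, 2], q_MT = Q[, 3],
    dosage_ME = 2 * Q[, 1], dosage_MG = 2 * Q[, 2], dosage_MT = 2 * Q[, 3],
    main_ancestry = SPECIES[main_i],
    introgression = 1 - Q[cbind(seq_len(n), main_i)],
    tie_flag = tie,
    loglik = best$loglik,
    n_iter = best$n_iter,
    n_loci = rowSums(!is.na(G)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(prof, flagged = flagged, class = c("ancestry_profiles", "data.frame"))
}

# Vectorized EM over all individuals at once. G: n x L dosages (NA missing),
# P: 3 x L clamped panel frequencies, q0: length-3 start. The E-step reduces
# to two n x 3 matrix products: A = (Gz/F %*% t(P) + Gc/(1-F) %*% t(1-P)) * Q.
# Returns Q (n x 3), loglik (n), n_iter (n), and optionally the per-iteration
# log-likelihood trace (iterations x individuals).
em_admixture <- function(G, P, q0, tol, max_iter, trace = FALSE) {
  n <- nrow(G); L <- ncol(G)
  Q <- matrix(q0, n, 3, byrow = TRUE)
  typed <- !is.na(G)
  two_n <- 2 * rowSums(typed)
  Gz <- G; Gz[!typed] <- 0          # zero-filled copies for sums
  Gc <- 2 - G; Gc[!typed] <- 0
  tP1 <- t(P); tP0 <- t(1 - P)
  lchoose_const <- rowSums(typed & G == 1) * log(2)  # binomial coefficient term

  loglik_of <- function(F) {
    # Gz, Gc are 0 at untyped cells, so those contribute nothing
    rowSums(Gz * log(F) + Gc * log1p(-F)) + lchoose_const
  }

  F <- Q %*% P
  ll <- loglik_of(F)
  n_iter <- rep(0L, n)
  active <- rep(TRUE, n)
  traces <- if (trace) list(ll) else NULL
  for (it in seq_len(max_iter)) {
    A <- ((Gz / F) %*% tP1 + (Gc / (1 - F)) %*% tP0) * Q
    Qn <- A / rowSums(A)     # rows of A sum to two_n; normalize exactly
    Q[active, ] <- Qn[active, , drop = FALSE]
    F <- Q %*% P
    ll_new <- loglik_of(F)
    n_iter[active] <- it
    conv <- abs(ll_new - ll) < tol * (abs(ll) + 1e-12)
    ll <- ll_new
    if (trace) traces[[it + 1L]] <- ll
    active <- active & !conv
    if (!any(active)) break
  }
  out <- list(Q = Q, loglik = ll, n_iter = n_iter)
  if (trace) out$ll_trace <- do.call(rbind, traces)
  out
}

#' Exact admixture log-likelihood over a simplex grid
#'
#' Evaluates the binomial admixture log-likelihood of one individual at every
#' point of a regular grid on the 3-simplex. Serves as an independent check
#' on [estimate_q()]: the likelihood is concave, so the grid argmax brackets
#' the true maximizer to grid resolution.
#'
#' @param g integer vector of dosages for one individual (NA = missing).
#' @param p 3 x L panel frequency matrix (rows ME, MG, MT), already clamped.
#' @param resolution grid spacing on each coordinate (default 0.01).
#' @param chunk rows per evaluation block, to bound memory (default 50000).
#' @return list with `grid` (matrix of simplex points), `loglik` (vector),
#'   and `argmax` (the best grid point).
#' @export
loglik_profile <- function(g, p, resolution = 0.01, chunk = 50000L) {
  typed <- !is.na(g)
  g <- g[typed]; p <- p[, typed, drop = FALSE]
  m <- round(1 / resolution)
  ij <- expand.grid(i = 0:m, j = 0:m)
  ij <- ij[ij$i + ij$j <= m, ]
  grid <- cbind(ij$i, ij$j, m - ij$i - ij$j) / m
  colnames(grid) <- SPECIES
  lc <- sum(g == 1) * log(2)
  ll <- numeric(nrow(grid))
  for (from in seq(1, nrow(grid), by = chunk)) {
    to <- min(from + chunk - 1L, nrow(grid))
    F <- grid[from:to, , drop = FALSE] %*% p
    ll[from:to] <- drop(log(F) %*% g + log1p(-F) %*% (2 - g)) + lc
  }
  list(grid = grid, loglik = ll, argmax = grid[which.max(ll), ])
}

#' Population-level mean ancestry
#'
#' Averages individual ancestry dosages within each sampling site and
#' assigns each site a main ancestry (the species with the highest mean
#' dosage) and a site-level introgression score
#' \eqn{1 - \bar d_{main} / 2}.
#'
#' @param profiles an `ancestry_profiles` object from [estimate_q()].
#' @return data.frame with one row per site: mean dosages, `main_ancestry`,
#'   `introgression`, `tie_flag`, `n_individuals`.
#' @export
population_ancestry <- function(profiles) {
  if (nrow(profiles) == 0) stop("no profiled individuals")
  sites <- sort(unique(profiles$site))
  out <- lapply(sites, function(st) {
    sub <- profiles[profiles$site == st, ]
    d <- c(ME = mean(sub$dosage_ME), MG = mean(sub$dosage_MG),
           MT = mean(sub$dosage_MT))
    main_i <- which.max(d)
    data.frame(site = st,
               dosage_ME = d[["ME"]], dosage_MG = d[["MG"]], dosage_MT = d[["MT"]],
               main_ancestry = SPECIES[main_i],
               introgression = 1 - d[[main_i]] / 2,
               tie_flag = sum(d == max(d)) > 1,
               n_individuals = nrow(sub),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Main ancestry and introgression of a Q vector
#'
#' The main ancestry is the species with the largest proportion; the
#' introgression score is the total proportion not attributable to it,
#' \eqn{I = 1 - q_{main} \in [0, 2/3]}. Exact ties resolve in the fixed
#' order ME, MG, MT and are flagged.
#'
#' @param q numeric length-3 vector of ancestry proportions (ME, MG, MT),
#'   or dosages summing to 2.
#' @return list with `main` (species label), `introgression`, `tie`.
#' @export
assign_main_and_introgression <- function(q) {
  stopifnot(length(q) == 3, all(q >= 0))
  q <- q / sum(q)
  i <- which.max(q)
  list(main = SPECIES[i], introgression = 1 - q[[i]],
       tie = sum(q == max(q)) > 1)
}

#' Write ancestry profiles to TSV
#' @param profiles an `ancestry_profiles` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  utils::write.table(as.data.frame(profiles), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
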