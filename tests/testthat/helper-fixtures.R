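# Shared fixture builders and independent brute-force oracles. The oracles
# deliberately use plain double loops and never call the package's own
# filter implementations.

make_gm <- function(n = 10, L = 20, seed = 1, missing = 0.1,
                    with_depth = TRUE, n_sites = 2, panel = FALSE) {
  set.seed(seed)
  G <- matrix(sample(0:2, n * L, replace = TRUE), n, L)
  G[matrix(runif(n * L) < missing, n, L)] <- NA_integer_
  rownames(G) <- sprintf("S%03d", seq_len(n))
  colnames(G) <- sprintf("loc%03d", seq_len(L))
  loci <- data.frame(id = colnames(G), chrom = "tag1", pos = seq_len(L),
                     ref = "A", alt = "T", stringsAsFactors = FALSE)
  sites <- sprintf("site%d", rep_len(seq_len(n_sites), n))
  popmap <- stats::setNames(sites, rownames(G))
  panelmap <- if (panel) {
    stats::setNames(c("ME", "MG", "MT")[rep_len(1:3, n_sites)],
                    sprintf("site%d", seq_len(n_sites)))
  } else character()
  DP <- GQ <- NULL
  if (with_depth) {
    DP <- matrix(rnbinom(n * L, mu = 17, size = 4), n, L, dimnames = dimnames(G))
    GQ <- matrix(pmin(99L, as.integer(DP * 4L)), n, L, dimnames = dimnames(G))
  }
  genotype_matrix(G, loci, popmap, panelmap, DP = DP, GQ = GQ)
}

# --- brute-force QC oracles -------------------------------------------------

oracle_mask <- function(gm, min_gq, min_dp) {
  G <- gm$G
  for (i in seq_len(nrow(G))) for (j in seq_len(ncol(G))) {
    bad <- FALSE
    if (!is.null(gm$GQ) && !is.na(gm$GQ[i, j]) && gm$GQ[i, j] <= min_gq) bad <- TRUE
    if (!is.null(gm$DP) && !is.na(gm$DP[i, j]) && gm$DP[i, j] <= min_dp) bad <- TRUE
    if (bad) G[i, j] <- NA_integer_
  }
  G
}

oracle_callrate_keep <- function(gm, min_cr) {
  keep <- logical(ncol(gm$G))
  for (j in seq_len(ncol(gm$G))) {
    keep[j] <- mean(!is.na(gm$G[, j])) >= min_cr
  }
  colnames(gm$G)[keep]
}

oracle_depthcap_keep <- function(gm, mult, raw_mean) {
  keep <- logical(ncol(gm$G))
  for (j in seq_len(ncol(gm$G))) {
    dp <- gm$DP[, j][!is.na(gm$G[, j])]
    keep[j] <- length(dp) == 0 || mean(dp) <= mult * raw_mean
  }
  colnames(gm$G)[keep]
}

oracle_indiv_keep <- function(gm, max_missing) {
  keep <- logical(nrow(gm$G))
  for (i in seq_len(nrow(gm$G))) {
    keep[i] <- mean(is.na(gm$G[i, ])) <= max_missing
  }
  rownames(gm$G)[keep]
}

oracle_maf_keep <- function(gm, min_maf) {
  keep <- logical(ncol(gm$G))
  for (j in seq_len(ncol(gm$G))) {
    g <- gm$G[, j][!is.na(gm$G[, j])]
    if (length(g) == 0) { keep[j] <- FALSE; next }
    p <- sum(g) / (2 * length(g))
    keep[j] <- min(p, 1 - p) > min_maf
  }
  colnames(gm$G)[keep]
}

# post-condition check for linkage pruning: enumerate the same positional
# windows (within each contig, over the ORIGINAL locus order) and count
# retained pairs exceeding the threshold in any window
oracle_ld_violations <- function(gm_before, kept_ids, r2_max, window, step) {
  viol <- 0L
  for (ch in unique(gm_before$loci$chrom)) {
    idx <- which(gm_before$loci$chrom == ch)
    Lc <- length(idx)
    if (Lc < 2) next
    kept <- gm_before$loci$id[idx] %in% kept_ids
    for (s in seq(1L, max(1L, Lc - 1L), by = step)) {
      w <- s:min(s + window - 1L, Lc)
      for (a in w) for (b in w) {
        if (b <= a || !kept[a] || !kept[b]) next
        r <- suppressWarnings(stats::cor(gm_before$G[, idx[a]],
                                         gm_before$G[, idx[b]],
                                         use = "pairwise.complete.obs"))
        if (!is.na(r) && r^2 > r2_max + 1e-12) viol <- viol + 1L
      }
    }
  }
  viol
}

# --- brute-force heterozygosity oracles ------------------------------------

oracle_pop_ho <- function(gm) {
  sites <- sort(unique(unname(gm$popmap)))
  out <- numeric(length(sites)); names(out) <- sites
  for (st in sites) {
    rows <- which(unname(gm$popmap) == st)
    hets <- c()
    for (j in seq_len(ncol(gm$G))) {
      g <- gm$G[rows, j]; g <- g[!is.na(g)]
      if (length(g) > 0) hets <- c(hets, mean(g == 1))
    }
    out[st] <- mean(hets)
  }
  out
}

oracle_smlh <- function(gm, subset = colnames(gm$G)) {
  G <- gm$G[, subset, drop = FALSE]
  hbar <- numeric(ncol(G))
  for (j in seq_len(ncol(G))) {
    g <- G[, j][!is.na(G[, j])]
    hbar[j] <- if (length(g) > 0) mean(g == 1) else 0
  }
  out <- numeric(nrow(G)); names(out) <- rownames(G)
  for (i in seq_len(nrow(G))) {
    typed <- which(!is.na(G[i, ]))
    out[i] <- if (length(typed) == 0) NA_real_ else
      sum(G[i, typed] == 1) / sum(hbar[typed])
  }
  out
}

q_rmse <- function(profiles, truth) {
  truth <- truth[match(profiles$sample, truth$sample), ]
  sqrt(mean((as.matrix(profiles[, c("q_ME", "q_MG", "q_MT")]) -
               as.matrix(truth[, c("q_ME", "q_MG", "q_MT")]))^2))
}
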