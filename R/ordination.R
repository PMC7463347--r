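# Mean-impute missing dosages per locus and drop loci with no calls at all.
impute_center <- function(gm, center = TRUE) {
  G <- gm$G
  all_missing <- colSums(!is.na(G)) == 0
  if (any(all_missing)) {
    warning(sum(all_missing), " all-missing locus/loci dropped")
    G <- G[, !all_missing, drop = FALSE]
  }
  mu <- colMeans(G, na.rm = TRUE)
  idx <- which(is.na(G), arr.ind = TRUE)
  if (nrow(idx) > 0) G[idx] <- mu[idx[, 2]]
  if (center) G <- sweep(G, 2, mu)
  G
}

#' Principal component analysis of the genotype matrix
#'
#' Mean-imputes missing dosages per locus, centers columns (no variance
#' scaling), and eigendecomposes the covariance. A deterministic sign
#' convention is applied: within each component the loading of largest
#' magnitude is positive.
#'
#' @param gm a [genotype_matrix] with at least 2 samples and 2 loci.
#' @param n_components number of components to return (default
#'   `min(n, L) - 1` capped at 10).
#' @return list of class `pca_result`: `scores` (samples x components),
#'   `var_frac` (fraction of total variance per component), `loadings`.
#' @export
gm_pca <- function(gm, n_components = NULL) {
  stopifnot(nrow(gm$G) >= 2, ncol(gm$G) >= 2)
  X <- impute_center(gm)
  pr <- stats::prcomp(X, center = FALSE, scale. = FALSE)
  k_all <- length(pr$sdev)
  if (is.null(n_components)) n_components <- min(k_all, 10L)
  k <- min(n_components, k_all)
  flip <- vapply(seq_len(k), function(j) {
    v <- pr$rotation[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(pr$x[, seq_len(k), drop = FALSE], 2, flip, `*`)
  loadings <- sweep(pr$rotation[, seq_len(k), drop = FALSE], 2, flip, `*`)
  tot <- sum(pr$sdev^2)
  structure(list(scores = scores,
                 var_frac = if (tot > 0) (pr$sdev^2 / tot)[seq_len(k)] else
                   rep(0, k),
                 loadings = loadings),
            class = "pca_result")
}

#' Ward hierarchical clustering of samples
#'
#' Computes pairwise Euclidean distances between samples on the
#' mean-imputed, centered dosage matrix and clusters them with Ward's
#' minimum-variance criterion (the squared-distance update, heights reported
#' on the distance scale, i.e. `hclust(method = "ward.D2")`).
#'
#' @param gm a [genotype_matrix] with at least 3 samples.
#' @return An `hclust` object.
#' @export
ward_tree <- function(gm) {
  stopifnot(nrow(gm$G) >= 3)
  X <- impute_center(gm)
  stats::hclust(stats::dist(X, method = "euclidean"), method = "ward.D2")
}

#' Locus-bootstrap support for tree nodes
#'
#' Resamples loci with replacement `B` times, rebuilds the Ward tree on each
#' resampled matrix, and scores every internal node of the reference tree by
#' the fraction of replicate trees containing the same leaf clade.
#'
#' @param gm a [genotype_matrix].
#' @param B bootstrap replicates (must be >= 1).
#' @param seed RNG seed.
#' @return list with `tree` (reference `hclust`), `phylo` (the [ape::phylo]
#'   version with node supports as node labels), `support` (numeric in
#'   \[0,1\] per internal node, root first).
#' @export
bootstrap_support <- function(gm, B = 100L, seed = 1L) {
  if (B < 1) stop("B must be >= 1")
  ref <- ward_tree(gm)
  ref_phy <- ape::as.phylo(ref)
  set.seed(seed)
  L <- ncol(gm$G)
  reps <- vector("list", B)
  for (b in seq_len(B)) {
    idx <- sample.int(L, L, replace = TRUE)
    sub <- gm
    sub$G <- gm$G[, idx, drop = FALSE]
    colnames(sub$G) <- make.unique(colnames(sub$G))
    sub$loci <- gm$loci[idx, , drop = FALSE]
    sub$loci$id <- colnames(sub$G)
    if (!is.null(sub$DP)) { sub$DP <- gm$DP[, idx, drop = FALSE]; colnames(sub$DP) <- colnames(sub$G) }
    if (!is.null(sub$GQ)) { sub$GQ <- gm$GQ[, idx, drop = FALSE]; colnames(sub$GQ) <- colnames(sub$G) }
    reps[[b]] <- ape::as.phylo(ward_tree(sub))
  }
  counts <- ape::prop.clades(ref_phy, reps, rooted = TRUE)
  counts[is.na(counts)] <- 0
  support <- counts / B
  ref_phy$node.label <- formatC(support, digits = 2, format = "f")
  list(tree = ref, phylo = ref_phy, support = support)
}

#' Write a dendrogram to Newick
#' @param phylo an [ape::phylo] tree (e.g. from [bootstrap_support()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(phylo, path) {
  ape::write.tree(phylo, file = path)
  invisible(path)
}
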