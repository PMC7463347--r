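#' Population observed heterozygosity
#'
#' For each sampling site, computes at every locus the frequency of
#' heterozygotes among the site's non-missing genotypes, then averages these
#' per-locus frequencies (unweighted) over all loci with at least one typed
#' genotype in the site.
#'
#' @param gm a [genotype_matrix].
#' @return data.frame with columns `site`, `ho`, `n_loci` (loci entering the
#'   average), `n_individuals`.
#' @export
population_ho <- function(gm) {
  sites <- sort(unique(unname(gm$popmap)))
  out <- lapply(sites, function(st) {
    sub <- gm$G[unname(gm$popmap) == st, , drop = FALSE]
    typed <- colSums(!is.na(sub))
    if (all(typed == 0)) stop("site ", st, " has no typed genotypes")
    het <- colSums(sub == 1L, na.rm = TRUE)[typed > 0] / typed[typed > 0]
    data.frame(site = st, ho = mean(het), n_loci = sum(typed > 0),
               n_individuals = nrow(sub), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Standardized multilocus heterozygosity
#'
#' sMLH of individual *i* over a locus subset is the number of loci at which
#' *i* is heterozygous divided by the sum, over the subset loci typed in
#' *i*, of the locus baseline \eqn{\bar H_l} — the heterozygote frequency at
#' locus *l* across all individuals typed there (whole-dataset baseline).
#' With complete data the mean of sMLH over individuals is exactly 1.
#'
#' @param gm a [genotype_matrix].
#' @param locus_subset character vector of locus IDs (default: all loci).
#' @return data.frame with columns `sample`, `site`, `smlh`, `n_loci`
#'   (typed subset loci); individuals typed at no subset locus get `NA`
#'   sMLH and are listed in attribute `"flagged"`.
#' @export
smlh <- function(gm, locus_subset = colnames(gm$G)) {
  if (length(locus_subset) == 0) stop("empty locus subset")
  missing_ids <- setdiff(locus_subset, colnames(gm$G))
  if (length(missing_ids) > 0) {
    stop("subset loci absent from matrix: ", paste(utils::head(missing_ids, 5),
                                                   collapse = ", "))
  }
  G <- gm$G[, locus_subset, drop = FALSE]
  typed <- !is.na(G)
  n_typed <- colSums(typed)
  hbar <- ifelse(n_typed > 0, colSums(G == 1L, na.rm = TRUE) / n_typed, 0)
  if (sum(hbar) == 0) stop("no heterozygote anywhere in the subset: sMLH undefined")
  het_i <- rowSums(G == 1L, na.rm = TRUE)
  denom <- typed %*% hbar
  n_loci_i <- rowSums(typed)
  val <- ifelse(n_loci_i > 0, het_i / denom, NA_real_)
  out <- data.frame(sample = rownames(G), site = unname(gm$popmap[rownames(G)]),
                    smlh = drop(val), n_loci = n_loci_i,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "flagged") <- rownames(G)[n_loci_i == 0]
  out
}

#' sMLH partitioned by SNP class
#'
#' Computes sMLH separately over the three mutually exclusive locus classes
#' built from the pure panels: loci polymorphic only in ME ("ME-SNPs"), only
#' in MG ("MG-SNPs"), and in both ME and MG but not MT ("ME/MG-SNPs").
#' Baselines are recomputed within each subset. Empty classes are skipped
#' with a warning.
#'
#' @param gm a [genotype_matrix].
#' @param panel a `ref_panel` processed by [classify_polymorphism()].
#' @return data.frame with columns `sample`, `site`, `smlh_ME`, `smlh_MG`,
#'   `smlh_MEMG` and the matching `n_loci_*` counts (`NA` where an
#'   individual has no typed loci in a class).
#' @export
smlh_partitioned <- function(gm, panel) {
  if (is.null(panel$poly_class)) stop("run classify_polymorphism() first")
  classes <- list(ME = "ME", MG = "MG", MEMG = "ME+MG")
  base <- data.frame(sample = rownames(gm$G),
                     site = unname(gm$popmap[rownames(gm$G)]),
                     stringsAsFactors = FALSE, row.names = NULL)
  for (nm in names(classes)) {
    ids <- colnames(panel$p)[panel$poly_class == classes[[nm]]]
    ids <- intersect(ids, colnames(gm$G))
    if (length(ids) == 0) {
      warning("SNP class ", classes[[nm]], " is empty; skipped")
      base[[paste0("smlh_", nm)]] <- NA_real_
      base[[paste0("n_loci_", nm)]] <- 0L
      next
    }
    s <- smlh(gm, ids)
    base[[paste0("smlh_", nm)]] <- s$smlh[match(base$sample, s$sample)]
    base[[paste0("n_loci_", nm)]] <- s$n_loci[match(base$sample, s$sample)]
  }
  base
}
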