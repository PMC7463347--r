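#' Genotype matrix container
#'
#' The central data object of the package: an individuals-by-loci matrix of
#' alternate-allele dosages (0, 1, 2 or `NA` for missing), optionally
#' accompanied by per-genotype read depth (`DP`) and genotype quality (`GQ`)
#' matrices of identical shape, a population map linking every sample to a
#' sampling site, and a panel map linking sites to pure-species labels
#' (`"ME"`, `"MG"`, `"MT"`) or `"UNKNOWN"`.
#'
#' @param G integer matrix of alt-allele dosages in \{0, 1, 2, NA\}; rownames
#'   are sample IDs, colnames are locus IDs.
#' @param loci data.frame with one row per locus: columns `id`, `chrom`,
#'   `pos`, `ref`, `alt`. Row order matches the columns of `G`.
#' @param popmap named character vector mapping each sample ID to a site
#'   label; must cover every row of `G`.
#' @param panelmap named character vector mapping site labels to species in
#'   `c("ME", "MG", "MT", "UNKNOWN")`. Sites absent from the map are treated
#'   as `"UNKNOWN"`.
#' @param DP,GQ optional integer matrices, same dimensions and dimnames as
#'   `G`, holding per-genotype read depth and genotype quality.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(G, loci, popmap, panelmap = character(), DP = NULL, GQ = NULL) {
  if (!is.matrix(G)) stop("G must be a matrix")
  storage.mode(G) <- "integer"
  if (is.null(rownames(G)) || is.null(colnames(G))) {
    stop("G must carry sample IDs as rownames and locus IDs as colnames")
  }
  bad <- !(G %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad)) stop("G entries must be 0, 1, 2 or NA")
  if (!is.data.frame(loci) || !all(c("id", "chrom", "pos", "ref", "alt") %in% names(loci))) {
    stop("loci must be a data.frame with columns id, chrom, pos, ref, alt")
  }
  if (nrow(loci) != ncol(G) || !identical(as.character(loci$id), colnames(G))) {
    stop("loci table must match the columns of G (same IDs, same order)")
  }
  if (anyDuplicated(rownames(G))) stop("duplicated sample IDs")
  if (anyDuplicated(colnames(G))) stop("duplicated locus IDs")
  missing_pm <- setdiff(rownames(G), names(popmap))
  if (length(missing_pm) > 0) {
    stop("samples absent from popmap: ", paste(missing_pm, collapse = ", "))
  }
  popmap <- popmap[rownames(G)]
  if (length(panelmap) > 0) {
    bad_sp <- setdiff(unname(panelmap), c("ME", "MG", "MT", "UNKNOWN"))
    if (length(bad_sp) > 0) {
      stop("panelmap species must be ME, MG, MT or UNKNOWN; got: ",
           paste(bad_sp, collapse = ", "))
    }
  }
  for (nm in c("DP", "GQ")) {
    M <- get(nm)
    if (!is.null(M)) {
      if (!is.matrix(M) || !identical(dim(M), dim(G))) {
        stop(nm, " must be a matrix with the same dimensions as G")
      }
      storage.mode(M) <- "integer"
      if (any(M < 0, na.rm = TRUE)) stop(nm, " entries must be non-negative")
      dimnames(M) <- dimnames(G)
      assign(nm, M)
    }
  }
  structure(
    list(G = G, loci = loci, popmap = popmap, panelmap = panelmap, DP = DP, GQ = GQ),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d loci\n", nrow(x$G), ncol(x$G)))
  cat(sprintf("  sites: %d; panel species: %s\n",
              length(unique(x$popmap)),
              if (length(x$panelmap) > 0) {
                paste(sort(unique(unname(x$panelmap))), collapse = ", ")
              } else "none"))
  cat(sprintf("  missing genotypes: %.1f%%; DP: %s; GQ: %s\n",
              100 * mean(is.na(x$G)),
              if (is.null(x$DP)) "absent" else "present",
              if (is.null(x$GQ)) "absent" else "present"))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$G)

#' Subset a genotype matrix by samples and/or loci
#'
#' Subsets `G`, `DP`, `GQ`, the locus table and the popmap consistently.
#' Indices follow the usual matrix conventions (names, integers or logicals).
#'
#' @param x a `genotype_matrix`.
#' @param i sample selector (rows).
#' @param j locus selector (columns).
#' @param ... ignored.
#' @return A `genotype_matrix` restricted to the selected samples and loci.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$G))
  if (missing(j)) j <- seq_len(ncol(x$G))
  G <- x$G[i, j, drop = FALSE]
  loci <- x$loci[match(colnames(G), x$loci$id), , drop = FALSE]
  rownames(loci) <- NULL
  genotype_matrix(
    G, loci, x$popmap[rownames(G)], x$panelmap,
    DP = if (!is.null(x$DP)) x$DP[i, j, drop = FALSE] else NULL,
    GQ = if (!is.null(x$GQ)) x$GQ[i, j, drop = FALSE] else NULL
  )
}

#' Species label of every sample
#'
#' Resolves each sample's site through the panel map, yielding `"ME"`,
#' `"MG"`, `"MT"` for samples from pure reference sites and `"UNKNOWN"`
#' otherwise.
#'
#' @param gm a `genotype_matrix`.
#' @return Named character vector, one entry per sample.
#' @export
sample_species <- function(gm) {
  sp <- gm$panelmap[unname(gm$popmap)]
  sp[is.na(sp)] <- "UNKNOWN"
  names(sp) <- names(gm$popmap)
  sp
}
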