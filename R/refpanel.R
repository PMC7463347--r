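SPECIES <- c("ME", "MG", "MT")

#' Build a pure-species reference allele-frequency panel
#'
#' Estimates, for every locus, the alt-allele frequency within each of the
#' three pure reference species (samples whose site maps to ME, MG or MT in
#' the panel map), together with the number of typed pure samples behind each
#' estimate. Frequencies with a zero denominator are `NA` and flagged.
#'
#' @param gm a [genotype_matrix] whose panelmap assigns at least one site to
#'   each of ME, MG and MT.
#' @return A list of class `ref_panel`: `p` (3 x L matrix of alt-allele
#'   frequencies, rows ME/MG/MT), `n` (3 x L typed-sample counts), `loci`
#'   (locus table). Polymorphism classes and diagnostic flags are added by
#'   [classify_polymorphism()] and [find_mt_diagnostic()].
#' @export
build_panel <- function(gm) {
  sp <- sample_species(gm)
  for (s in SPECIES) {
    if (!any(sp == s)) stop("no pure samples for species ", s)
  }
  L <- ncol(gm$G)
  p <- n <- matrix(NA_real_, 3, L, dimnames = list(SPECIES, colnames(gm$G)))
  for (s in SPECIES) {
    sub <- gm$G[sp == s, , drop = FALSE]
    n[s, ] <- colSums(!is.na(sub))
    p[s, ] <- colSums(sub, na.rm = TRUE) / (2 * n[s, ])
    p[s, n[s, ] == 0] <- NA_real_
  }
  structure(list(p = p, n = n, loci = gm$loci,
                 poly_class = NULL, mt_diagnostic = NULL, mt_allele = NULL),
            class = "ref_panel")
}

#' @export
print.ref_panel <- function(x, ...) {
  cat(sprintf("ref_panel: %d loci; pure panel sizes ME=%d MG=%d MT=%d (max typed)\n",
              ncol(x$p), max(x$n["ME", ]), max(x$n["MG", ]), max(x$n["MT", ])))
  if (!is.null(x$poly_class)) {
    print(table(x$poly_class))
  }
  if (!is.null(x$mt_diagnostic)) {
    cat(sprintf("  MT-diagnostic loci: %d\n", sum(x$mt_diagnostic)))
  }
  invisible(x)
}

#' Classify loci by within-species polymorphism
#'
#' A locus is polymorphic in species `s` when its panel frequency lies
#' strictly between 0 and 1 and at least `min_typed` pure samples of `s` were
#' typed there. The class of a locus is the set of species in which it is
#' polymorphic, written as a label such as `"ME"`, `"ME+MG"`, `"ME+MG+MT"`,
#' or `"NONE"` for loci polymorphic in no species. These classes are the
#' input to the cross-species polymorphism Venn and to class-partitioned
#' heterozygosity.
#'
#' @param panel a `ref_panel` from [build_panel()].
#' @param min_typed minimum typed pure samples per species for a
#'   polymorphism call (default 10).
#' @return The panel with `poly_class` (character vector per locus) filled
#'   in; a count table is attached as attribute `"class_counts"`.
#' @export
classify_polymorphism <- function(panel, min_typed = 10L) {
  poly <- !is.na(panel$p) & panel$p > 0 & panel$p < 1 & panel$n >= min_typed
  lab <- apply(poly, 2, function(v) {
    if (!any(v)) "NONE" else paste(SPECIES[v], collapse = "+")
  })
  panel$poly_class <- unname(lab)
  attr(panel$poly_class, "class_counts") <- table(lab)
  panel
}

#' Detect MT-diagnostic loci
#'
#' A locus is diagnostic of MT when all three panel frequencies are exactly
#' fixed (0 or 1), ME and MG are fixed for the same allele, MT is fixed for
#' the other, and every species has at least `min_typed` typed pure samples.
#' The MT-fixed allele (`"ref"` or `"alt"`) is recorded.
#'
#' @inheritParams classify_polymorphism
#' @return The panel with logical `mt_diagnostic` and character `mt_allele`
#'   per-locus vectors filled in.
#' @export
find_mt_diagnostic <- function(panel, min_typed = 10L) {
  p <- panel$p
  fixed <- !is.na(p) & (p == 0 | p == 1)
  enough <- panel$n >= min_typed
  diag <- fixed["ME", ] & fixed["MG", ] & fixed["MT", ] &
    p["ME", ] == p["MG", ] & p["ME", ] != p["MT", ] &
    enough["ME", ] & enough["MG", ] & enough["MT", ]
  diag[is.na(diag)] <- FALSE
  panel$mt_diagnostic <- unname(diag)
  panel$mt_allele <- unname(ifelse(diag, ifelse(p["MT", ] == 1, "alt", "ref"),
                                   NA_character_))
  panel
}

#' Locus IDs of MT-diagnostic loci
#' @param panel a `ref_panel` processed by [find_mt_diagnostic()].
#' @return Character vector of locus IDs.
#' @export
mt_diagnostic_loci <- function(panel) {
  if (is.null(panel$mt_diagnostic)) stop("run find_mt_diagnostic() first")
  colnames(panel$p)[panel$mt_diagnostic]
}

#' Count MT-diagnostic alleles per site
#'
#' For each sampling site, counts the diagnostic loci at which at least one
#' copy of the MT-fixed allele is carried by at least one sample of the site,
#' and the total number of MT allele copies across the site's samples and
#' diagnostic loci. This screens admixed populations for genuine MT
#' introgression.
#'
#' @param gm a [genotype_matrix].
#' @param panel a `ref_panel` processed by [find_mt_diagnostic()].
#' @return data.frame with columns `site`, `n_loci_with_mt_allele`,
#'   `n_mt_allele_copies`.
#' @export
count_diagnostic_alleles <- function(gm, panel) {
  ids <- intersect(mt_diagnostic_loci(panel), colnames(gm$G))
  if (length(ids) == 0) stop("no diagnostic loci present in the genotype matrix")
  allele <- panel$mt_allele[match(ids, colnames(panel$p))]
  G <- gm$G[, ids, drop = FALSE]
  # MT-allele copy count per genotype: dosage when alt is MT-fixed, 2-dosage otherwise
  copies <- sweep(G, 2, as.integer(allele == "ref") * 2L, function(g, r) abs(g - r))
  sites <- sort(unique(unname(gm$popmap)))
  out <- lapply(sites, function(st) {
    sub <- copies[unname(gm$popmap) == st, , drop = FALSE]
    per_locus <- colSums(sub, na.rm = TRUE)
    data.frame(site = st,
               n_loci_with_mt_allele = as.integer(sum(per_locus > 0)),
               n_mt_allele_copies = as.integer(sum(per_locus)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Export a reference panel as TSV
#' @param panel a `ref_panel` (ideally after classification and diagnostic
#'   detection).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  tab <- data.frame(
    locus = colnames(panel$p),
    p_ME = panel$p["ME", ], p_MG = panel$p["MG", ], p_MT = panel$p["MT", ],
    n_ME = panel$n["ME", ], n_MG = panel$n["MG", ], n_MT = panel$n["MT", ],
    class = if (is.null(panel$poly_class)) NA_character_ else panel$poly_class,
    mt_diagnostic = if (is.null(panel$mt_diagnostic)) NA else panel$mt_diagnostic,
    mt_allele = if (is.null(panel$mt_allele)) NA_character_ else panel$mt_allele,
    stringsAsFactors = FALSE
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
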