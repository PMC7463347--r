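#' QC configuration
#'
#' Thresholds for the post-genotyping filter chain. Defaults reproduce the
#' standard RAD-seq protocol for this system: genotypes with quality or depth
#' of coverage of five or less are masked, sites must be typed in at least
#' 60\% of individuals, sites whose mean depth exceeds twice the raw-dataset
#' mean are dropped as putative paralogs, individuals with more than 50\%
#' missing data are removed, minor allele frequency must exceed 0.01, and
#' linked loci are pruned at a squared-correlation threshold of 0.5 in
#' sliding windows of 50 SNPs advanced by 5.
#'
#' @param min_gq genotype-quality threshold (exclusive: GQ must be > this).
#' @param min_dp genotype-depth threshold (exclusive).
#' @param min_site_callrate minimum fraction of individuals typed at a site
#'   (inclusive).
#' @param depth_cap_multiplier multiplier of the raw-dataset mean depth above
#'   which a site is removed (exclusive).
#' @param max_indiv_missing maximum tolerated per-individual missing fraction
#'   (exclusive: strictly more is removed).
#' @param min_maf minor-allele-frequency threshold (exclusive).
#' @param ld_r2_max squared-correlation threshold for pruning (exclusive).
#' @param ld_window window size in SNPs for linkage pruning.
#' @param ld_step window step in SNPs.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(min_gq = 5L, min_dp = 5L, min_site_callrate = 0.60,
                      depth_cap_multiplier = 2.0, max_indiv_missing = 0.50,
                      min_maf = 0.01, ld_r2_max = 0.5,
                      ld_window = 50L, ld_step = 5L) {
  stopifnot(min_gq >= 0, min_dp >= 0,
            min_site_callrate >= 0, min_site_callrate <= 1,
            depth_cap_multiplier >= 0,
            max_indiv_missing >= 0, max_indiv_missing <= 1,
            min_maf >= 0, min_maf <= 1,
            ld_r2_max >= 0, ld_r2_max <= 1,
            ld_window >= 2, ld_step >= 1)
  structure(list(min_gq = min_gq, min_dp = min_dp,
                 min_site_callrate = min_site_callrate,
                 depth_cap_multiplier = depth_cap_multiplier,
                 max_indiv_missing = max_indiv_missing, min_maf = min_maf,
                 ld_r2_max = ld_r2_max, ld_window = as.integer(ld_window),
                 ld_step = as.integer(ld_step)),
            class = "qc_config")
}

#' Mask genotypes with low quality or depth
#'
#' Sets to missing every genotype whose GQ or DP is less than or equal to the
#' configured thresholds (strict "greater than" survives). Sites and samples
#' are untouched; only individual genotype calls change. When the matrix
#' carries neither DP nor GQ the operation is a no-op with a warning.
#'
#' @param gm a [genotype_matrix].
#' @param cfg a [qc_config].
#' @return The masked `genotype_matrix`.
#' @export
mask_low_quality_genotypes <- function(gm, cfg = qc_config()) {
  if (is.null(gm$DP) && is.null(gm$GQ)) {
    warning("neither DP nor GQ present; no genotypes masked")
    return(gm)
  }
  bad <- matrix(FALSE, nrow(gm$G), ncol(gm$G))
  if (!is.null(gm$GQ)) bad <- bad | (!is.na(gm$GQ) & gm$GQ <= cfg$min_gq)
  if (!is.null(gm$DP)) bad <- bad | (!is.na(gm$DP) & gm$DP <= cfg$min_dp)
  gm$G[bad] <- NA_integer_
  gm
}

#' Per-site call rate
#' @param gm a [genotype_matrix].
#' @return Numeric vector: fraction of non-missing genotypes per locus.
#' @export
site_callrate <- function(gm) colMeans(!is.na(gm$G))

#' Filter sites on call rate
#'
#' Keeps loci genotyped in at least `min_site_callrate` of the individuals
#' (the boundary is kept).
#'
#' @inheritParams mask_low_quality_genotypes
#' @return The filtered `genotype_matrix`.
#' @export
filter_site_callrate <- function(gm, cfg = qc_config()) {
  gm[, site_callrate(gm) >= cfg$min_site_callrate]
}

#' Filter sites exceeding the depth cap
#'
#' Removes loci whose mean depth of coverage over non-missing genotypes is
#' strictly greater than `depth_cap_multiplier` times the mean depth of the
#' raw (pre-filter) dataset — a screen against collapsed paralogs.
#'
#' @inheritParams mask_low_quality_genotypes
#' @param raw_mean_depth mean DP over all non-missing genotypes of the
#'   dataset before any filtering; see [raw_mean_depth()].
#' @return The filtered `genotype_matrix`.
#' @export
filter_depth_cap <- function(gm, cfg = qc_config(), raw_mean_depth) {
  if (is.null(gm$DP)) stop("DP absent: depth cap cannot be evaluated")
  stopifnot(is.numeric(raw_mean_depth), length(raw_mean_depth) == 1)
  dp <- gm$DP
  dp[is.na(gm$G)] <- NA_integer_
  mean_dp <- colMeans(dp, na.rm = TRUE)
  cap <- cfg$depth_cap_multiplier * raw_mean_depth
  keep <- is.nan(mean_dp) | mean_dp <= cap
  gm[, keep]
}

#' Mean depth of the raw dataset
#'
#' Mean of DP over all non-missing genotypes, evaluated on the unfiltered
#' matrix; this is the reference value for the depth cap.
#'
#' @param gm a [genotype_matrix] with DP.
#' @return A single number.
#' @export
raw_mean_depth <- function(gm) {
  if (is.null(gm$DP)) stop("DP absent")
  mean(gm$DP[!is.na(gm$G)], na.rm = TRUE)
}

#' Filter individuals on missingness
#'
#' Removes samples with strictly more than `max_indiv_missing` missing
#' genotypes (exactly the boundary is kept).
#'
#' @inheritParams mask_low_quality_genotypes
#' @return The filtered `genotype_matrix`.
#' @export
filter_individuals <- function(gm, cfg = qc_config()) {
  miss <- rowMeans(is.na(gm$G))
  keep <- miss <= cfg$max_indiv_missing
  if (!any(keep)) stop("all samples exceed the missingness threshold")
  gm[keep, ]
}

#' Minor allele frequency per locus
#' @param gm a [genotype_matrix].
#' @return Numeric vector of per-locus MAF over non-missing genotypes
#'   (`NaN` for loci with no calls).
#' @export
locus_maf <- function(gm) {
  p <- colMeans(gm$G, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' Filter sites on minor allele frequency
#'
#' Keeps loci with MAF strictly greater than `min_maf`, computed over
#' non-missing genotypes across all retained samples.
#'
#' @inheritParams mask_low_quality_genotypes
#' @return The filtered `genotype_matrix`.
#' @export
filter_maf <- function(gm, cfg = qc_config()) {
  maf <- locus_maf(gm)
  gm[, !is.nan(maf) & maf > cfg$min_maf]
}

#' Prune linked loci in sliding windows
#'
#' Slides a window of `ld_window` loci advanced by `ld_step` over the locus
#' order, separately within each contig (physical linkage does not cross
#' contigs, so for de novo RAD data — every tag its own contig — only SNPs
#' on the same tag compete; data on a single contig is pruned across its
#' full locus order). Within a window, whenever a retained pair has squared
#' Pearson correlation of dosages (pairwise-complete) strictly above
#' `ld_r2_max`, the locus with the lower call rate is removed (tie: the
#' later locus). On completion no retained pair within any window exceeds
#' the threshold.
#'
#' @inheritParams mask_low_quality_genotypes
#' @return The pruned `genotype_matrix`.
#' @export
ld_prune <- function(gm, cfg = qc_config()) {
  L <- ncol(gm$G)
  if (L < 2) return(gm)
  keep <- rep(TRUE, L)
  cr <- site_callrate(gm)
  for (loci_idx in split(seq_len(L), factor(gm$loci$chrom,
                                            levels = unique(gm$loci$chrom)))) {
    Lc <- length(loci_idx)
    if (Lc < 2) next
    starts <- seq(1L, max(1L, Lc - 1L), by = cfg$ld_step)
    for (s in starts) {
      w <- loci_idx[s:min(s + cfg$ld_window - 1L, Lc)]
      idx <- w[keep[w]]
      if (length(idx) < 2) next
      r2 <- suppressWarnings(stats::cor(gm$G[, idx, drop = FALSE],
                                        use = "pairwise.complete.obs"))^2
      r2[is.na(r2)] <- 0
      diag(r2) <- 0
      # strict threshold with rounding guard so a pair at exactly the
      # threshold is kept regardless of floating-point summation order
      thr <- cfg$ld_r2_max + 1e-12
      while (any(r2 > thr)) {
        hit <- which(r2 > thr, arr.ind = TRUE)[1, ]
        a <- idx[hit[1]]; b <- idx[hit[2]]
        # drop the lower-call-rate member; tie -> the later locus
        drop_locus <- if (cr[a] < cr[b]) a else if (cr[b] < cr[a]) b else max(a, b)
        keep[drop_locus] <- FALSE
        k <- which(idx == drop_locus)
        r2[k, ] <- 0
        r2[, k] <- 0
      }
    }
  }
  gm[, keep]
}

#' Run the full QC chain
#'
#' Applies, in order: genotype-level GQ/DP masking, site call-rate filtering,
#' the depth cap, individual-missingness removal, the MAF filter, and
#' linkage pruning. The depth cap is referenced to the mean depth of the
#' matrix as supplied (the raw dataset). With `fixed_point = TRUE` the site
#' filters are re-applied after individual removal until no further loci
#' drop, since individual removal can push a site's MAF or call rate back
#' under its threshold.
#'
#' @inheritParams mask_low_quality_genotypes
#' @param fixed_point re-run site filters to a fixed point after individual
#'   removal (default `FALSE`: single pass in protocol order).
#' @return A list with elements `gm` (the filtered [genotype_matrix]) and
#'   `report` (a `qc_report`: per-step locus/sample counts, removed IDs with
#'   their primary reason, the raw mean depth used for the cap, and the
#'   number of passes).
#' @export
run_qc <- function(gm, cfg = qc_config(), fixed_point = FALSE) {
  steps <- list()
  note <- function(prev, cur, step) {
    removed_loci <- setdiff(colnames(prev$G), colnames(cur$G))
    removed_samples <- setdiff(rownames(prev$G), rownames(cur$G))
    steps[[length(steps) + 1L]] <<- list(
      step = step,
      n_loci_before = ncol(prev$G), n_loci_after = ncol(cur$G),
      n_samples_before = nrow(prev$G), n_samples_after = nrow(cur$G),
      removed_loci = removed_loci, removed_samples = removed_samples
    )
    cur
  }

  has_depth <- !is.null(gm$DP)
  rmd <- if (has_depth) raw_mean_depth(gm) else NA_real_

  cur <- gm
  if (has_depth || !is.null(gm$GQ)) {
    cur <- note(cur, mask_low_quality_genotypes(cur, cfg), "mask_gq_dp")
  }
  cur <- note(cur, filter_site_callrate(cur, cfg), "site_callrate")
  if (has_depth) {
    cur <- note(cur, filter_depth_cap(cur, cfg, rmd), "depth_cap")
  }
  cur <- note(cur, filter_individuals(cur, cfg), "indiv_missing")
  cur <- note(cur, filter_maf(cur, cfg), "maf")
  cur <- note(cur, ld_prune(cur, cfg), "ld_prune")

  passes <- 1L
  if (fixed_point) {
    repeat {
      before <- ncol(cur$G)
      cur <- note(cur, filter_site_callrate(cur, cfg), "site_callrate_rerun")
      cur <- note(cur, filter_maf(cur, cfg), "maf_rerun")
      passes <- passes + 1L
      if (ncol(cur$G) == before) break
    }
  }

  report <- structure(list(steps = steps, raw_mean_depth = rmd, passes = passes,
                           n_loci_final = ncol(cur$G),
                           n_samples_final = nrow(cur$G)),
                      class = "qc_report")
  list(gm = cur, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report (raw mean depth", format(x$raw_mean_depth, digits = 4), ")\n")
  for (s in x$steps) {
    cat(sprintf("  %-18s loci %5d -> %5d   samples %4d -> %4d\n",
                s$step, s$n_loci_before, s$n_loci_after,
                s$n_samples_before, s$n_samples_after))
  }
  invisible(x)
}

#' Serialize a QC report to JSON
#' @param report a `qc_report` from [run_qc()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
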