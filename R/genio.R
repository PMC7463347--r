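#' Read a VCF file into a genotype matrix
#'
#' Parses a VCF v4.2 file (GT plus optional DP and GQ FORMAT fields) through
#' \pkg{vcfR} and encodes diploid genotypes as alt-allele dosages. Phase is
#' discarded: `0/1` and `0|1` both become dosage 1; `./.` and `.|.` become
#' `NA`. Locus order follows the file. Multi-allelic records are skipped with
#' a warning, or rejected when `multiallelic = "error"`.
#'
#' @param path path to a VCF file.
#' @param popmap_path path to a tab-separated population map with columns
#'   `sample_id` and `site`.
#' @param panelmap_path optional path to a tab-separated panel map with
#'   columns `site` and `species` (ME, MG, MT or UNKNOWN).
#' @param multiallelic `"skip"` (default) or `"error"`: what to do with
#'   records that are not biallelic.
#' @return A [genotype_matrix].
#' @export
read_vcf <- function(path, popmap_path, panelmap_path = NULL,
                     multiallelic = c("skip", "error")) {
  multiallelic <- match.arg(multiallelic)
  if (!file.exists(path)) stop("VCF file not found: ", path)
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("malformed VCF '", path, "': ", conditionMessage(e))
  )
  if (nrow(vcf@fix) == 0) stop("VCF '", path, "' contains no records")

  biallelic <- vcfR::is.biallelic(vcf)
  if (any(!biallelic)) {
    if (multiallelic == "error") {
      stop("multi-allelic records at: ",
           paste(vcf@fix[!biallelic, "CHROM"], vcf@fix[!biallelic, "POS"],
                 sep = ":", collapse = ", "))
    }
    warning(sum(!biallelic), " multi-allelic record(s) skipped")
    vcf <- vcf[biallelic, ]
  }

  fix <- vcf@fix
  ids <- unname(ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                       paste(fix[, "CHROM"], fix[, "POS"], sep = ":"),
                       fix[, "ID"]))
  loci <- data.frame(
    id = ids, chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"], stringsAsFactors = FALSE
  )

  gt <- vcfR::extract.gt(vcf, element = "GT")
  # dosage from unphased or phased diploid GT strings; each distinct string
  # is parsed once and looked up
  u <- unique(as.vector(gt))
  parsed <- vapply(u, function(g) {
    if (is.na(g)) return(NA_integer_)
    a <- strsplit(g, "[/|]")[[1]]
    if (length(a) != 2 || any(a == ".")) return(NA_integer_)
    sum(as.integer(a))
  }, integer(1))
  G <- t(matrix(parsed[match(as.vector(gt), u)], nrow(gt), ncol(gt)))
  rownames(G) <- colnames(gt)
  colnames(G) <- ids

  fmt <- unique(unlist(strsplit(vcf@gt[, "FORMAT"], ":")))
  grab <- function(el) {
    if (!(el %in% fmt)) return(NULL)
    M <- t(vcfR::extract.gt(vcf, element = el, as.numeric = TRUE))
    storage.mode(M) <- "integer"
    colnames(M) <- ids
    M
  }

  pm <- read_popmap(popmap_path)
  absent <- setdiff(rownames(G), names(pm))
  if (length(absent) > 0) {
    stop("VCF samples absent from popmap: ", paste(absent, collapse = ", "))
  }
  panel <- if (!is.null(panelmap_path)) read_panelmap(panelmap_path) else character()

  genotype_matrix(G, loci, pm, panel, DP = grab("DP"), GQ = grab("GQ"))
}

#' Write a genotype matrix to a VCF file
#'
#' Emits plain-text VCF v4.2 with FORMAT `GT:DP:GQ` (fields dropped when the
#' matrix does not carry them). Missing genotypes become `./.`; dosages 0, 1
#' and 2 become `0/0`, `0/1` and `1/1`. Reading the file back with
#' [read_vcf()] reproduces `G`, `DP`, `GQ` and the sample and locus order
#' exactly.
#'
#' @param gm a [genotype_matrix].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write '", path, "': ", conditionMessage(e)))
  on.exit(close(con))

  fields <- c("GT", if (!is.null(gm$DP)) "DP", if (!is.null(gm$GQ)) "GQ")
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=musselmix",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    if (!is.null(gm$DP)) '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read Depth">',
    if (!is.null(gm$GQ)) '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype Quality">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(gm$G)), collapse = "\t")
  )
  writeLines(hdr, con)

  gt_code <- c("0/0", "0/1", "1/1")
  n <- nrow(gm$G)
  for (j in seq_len(ncol(gm$G))) {
    g <- gm$G[, j]
    cell <- ifelse(is.na(g), "./.", gt_code[g + 1L])
    if (!is.null(gm$DP)) {
      dp <- gm$DP[, j]
      cell <- paste(cell, ifelse(is.na(dp), ".", dp), sep = ":")
    }
    if (!is.null(gm$GQ)) {
      gq <- gm$GQ[, j]
      cell <- paste(cell, ifelse(is.na(gq), ".", gq), sep = ":")
    }
    l <- gm$loci[j, ]
    writeLines(paste(c(l$chrom, l$pos, l$id, l$ref, l$alt, ".", "PASS", ".",
                       paste(fields, collapse = ":"), cell), collapse = "\t"), con)
  }
  invisible(path)
}

# Typed TSV reader: every `schema` entry maps a required column name to a
# conversion ("character" or "numeric"); extra columns pass through untouched.
read_table_schema <- function(path, schema, key_col = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  absent <- setdiff(names(schema), names(tab))
  if (length(absent) > 0) {
    stop("'", path, "' is missing required column(s): ",
         paste(absent, collapse = ", "))
  }
  for (col in names(schema)) {
    if (schema[[col]] == "numeric") {
      v <- suppressWarnings(as.numeric(tab[[col]]))
      if (any(is.na(v) & !is.na(tab[[col]]) & tab[[col]] != "")) {
        stop("column '", col, "' in '", path, "' is not numeric")
      }
      tab[[col]] <- v
    } else {
      tab[[col]] <- trimws(as.character(tab[[col]]))
    }
  }
  if (!is.null(key_col) && anyDuplicated(tab[[key_col]])) {
    stop("duplicated ", key_col, " in '", path, "': ",
         paste(unique(tab[[key_col]][duplicated(tab[[key_col]])]), collapse = ", "))
  }
  tab
}

#' Read a population map
#'
#' Tab-separated file with header columns `sample_id` and `site`.
#'
#' @param path file path.
#' @return Named character vector: site label per sample ID.
#' @export
read_popmap <- function(path) {
  tab <- read_table_schema(path, list(sample_id = "character", site = "character"),
                           key_col = "sample_id")
  stats::setNames(tab$site, tab$sample_id)
}

#' Read a reference-panel map
#'
#' Tab-separated file with header columns `site` and `species`, where species
#' is one of `ME`, `MG`, `MT` or `UNKNOWN`.
#'
#' @param path file path.
#' @return Named character vector: species label per site.
#' @export
read_panelmap <- function(path) {
  tab <- read_table_schema(path, list(site = "character", species = "character"),
                           key_col = "site")
  bad <- setdiff(tab$species, c("ME", "MG", "MT", "UNKNOWN"))
  if (length(bad) > 0) stop("invalid species label(s): ", paste(bad, collapse = ", "))
  stats::setNames(tab$species, tab$site)
}

#' Read a site-level environmental covariate table
#'
#' Tab-separated file with header columns `site`, `sst_celsius` (sea-surface
#' temperature) and `salinity_psu`.
#'
#' @param path file path.
#' @return data.frame with one row per site.
#' @export
read_covariates <- function(path) {
  read_table_schema(
    path,
    list(site = "character", sst_celsius = "numeric", salinity_psu = "numeric"),
    key_col = "site"
  )
}
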