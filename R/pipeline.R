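#' Pipeline run configuration
#'
#' Collects file paths, QC thresholds, ancestry-estimation settings, model
#' settings and stage toggles for [run_pipeline()]. Can be loaded from a
#' YAML file with [read_run_config()].
#'
#' @param vcf,popmap,panelmap,covariates input file paths (`covariates` may
#'   be `NULL` to skip the environment-correlation stage).
#' @param out_dir output directory.
#' @param qc a [qc_config].
#' @param ancestry list of [estimate_q()] settings: `eps`, `tol`,
#'   `max_iter`, `n_starts`, `min_loci`, `seed`.
#' @param models list of model settings: `B` (bootstrap replicates), `seed`.
#' @param ordination list: `bootstrap_B`, `seed`.
#' @param stages character vector of stages to run, a subset of
#'   `c("qc", "panel", "ancestry", "hetero", "ordination", "models")`.
#' @return list of class `run_config`.
#' @export
run_config <- function(vcf, popmap, panelmap, covariates = NULL,
                       out_dir = "musselmix_out",
                       qc = qc_config(),
                       ancestry = list(eps = 1e-3, tol = 1e-6, max_iter = 1000L,
                                       n_starts = 5L, min_loci = 50L, seed = 1L),
                       models = list(B = 1000L, seed = 17L),
                       ordination = list(bootstrap_B = 100L, seed = 1L),
                       stages = c("qc", "panel", "ancestry", "hetero",
                                  "ordination", "models")) {
  for (f in c(vcf, popmap, panelmap, covariates)) {
    if (!file.exists(f)) stop("input file not found: ", f)
  }
  stopifnot(all(stages %in% c("qc", "panel", "ancestry", "hetero",
                              "ordination", "models")))
  structure(list(vcf = vcf, popmap = popmap, panelmap = panelmap,
                 covariates = covariates, out_dir = out_dir, qc = qc,
                 ancestry = ancestry, models = models, ordination = ordination,
                 stages = stages),
            class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' The YAML mirrors the arguments of [run_config()]: top-level keys `vcf`,
#' `popmap`, `panelmap`, `covariates`, `out_dir`, and optional mappings
#' `qc`, `ancestry`, `models`, `ordination`, `stages`.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list(vcf = y$vcf, popmap = y$popmap, panelmap = y$panelmap,
               covariates = y$covariates,
               out_dir = if (is.null(y$out_dir)) "musselmix_out" else y$out_dir)
  if (!is.null(y$qc)) args$qc <- do.call(qc_config, y$qc)
  for (k in c("ancestry", "models", "ordination")) {
    if (!is.null(y[[k]])) {
      args[[k]] <- utils::modifyList(eval(formals(run_config)[[k]]), y[[k]])
    }
  }
  if (!is.null(y$stages)) args$stages <- unlist(y$stages)
  do.call(run_config, args)
}

#' Run the end-to-end analysis
#'
#' Executes, in order: QC filtering, reference-panel construction with
#' polymorphism classification and diagnostic-locus detection, supervised
#' ancestry estimation, heterozygosity (population Ho, individual sMLH,
#' class-partitioned sMLH), ordination (PCA and bootstrapped Ward tree),
#' and the inferential models (heterozygosity contrasts between main
#' ancestries, introgression slopes at population and individual level with
#' a parametric-bootstrap mixed-model test, and environment correlations).
#' Every stage writes its table under `out_dir`, and a JSON manifest records
#' configuration, seeds and per-stage counts.
#'
#' @param cfg a [run_config].
#' @return list with every stage's in-memory result plus `manifest`.
#' @export
run_pipeline <- function(cfg) {
  t0 <- Sys.time()
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  manifest <- list(started = format(t0), stages = list(),
                   seeds = list(ancestry = cfg$ancestry$seed,
                                models = cfg$models$seed,
                                ordination = cfg$ordination$seed))
  log_stage <- function(name, info) {
    manifest$stages[[name]] <<- c(list(wall_s = round(
      as.numeric(Sys.time() - t0, units = "secs"), 2)), info)
    message(sprintf("[%s] done (%s)", name,
                    paste(names(info), unlist(info), sep = "=", collapse = ", ")))
  }

  gm <- read_vcf(cfg$vcf, cfg$popmap, cfg$panelmap)
  log_stage("load", list(n_samples = nrow(gm$G), n_loci = ncol(gm$G)))

  if ("qc" %in% cfg$stages) {
    qc_out <- run_qc(gm, cfg$qc)
    gm <- qc_out$gm
    write_vcf(gm, file.path(cfg$out_dir, "filtered.vcf"))
    write_qc_report(qc_out$report, file.path(cfg$out_dir, "qc_report.json"))
    res$qc_report <- qc_out$report
    log_stage("qc", list(n_samples = nrow(gm$G), n_loci = ncol(gm$G)))
  }

  panel <- NULL
  if ("panel" %in% cfg$stages) {
    panel <- find_mt_diagnostic(classify_polymorphism(build_panel(gm)))
    write_panel(panel, file.path(cfg$out_dir, "panel.tsv"))
    res$panel <- panel
    res$diagnostic_counts <- if (any(panel$mt_diagnostic)) {
      count_diagnostic_alleles(gm, panel)
    } else NULL
    log_stage("panel", list(n_diagnostic = sum(panel$mt_diagnostic)))
  }

  profiles <- NULL
  if ("ancestry" %in% cfg$stages) {
    if (is.null(panel)) stop("ancestry stage requires the panel stage")
    a <- cfg$ancestry
    profiles <- estimate_q(gm, panel, eps = a$eps, tol = a$tol,
                           max_iter = a$max_iter, n_starts = a$n_starts,
                           min_loci = a$min_loci, seed = a$seed)
    write_profiles(profiles, file.path(cfg$out_dir, "ancestry.tsv"))
    res$profiles <- profiles
    res$pop_ancestry <- population_ancestry(profiles)
    utils::write.table(res$pop_ancestry,
                       file.path(cfg$out_dir, "population_ancestry.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_stage("ancestry", list(n_profiled = nrow(profiles)))
  }

  if ("hetero" %in% cfg$stages) {
    res$pop_ho <- population_ho(gm)
    het <- smlh(gm)
    if (!is.null(panel) && !is.null(panel$poly_class)) {
      part <- smlh_partitioned(gm, panel)
      het <- merge(het, part, by = c("sample", "site"), sort = FALSE)
    }
    res$het <- het
    utils::write.table(res$pop_ho, file.path(cfg$out_dir, "population_ho.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(het, file.path(cfg$out_dir, "smlh.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_stage("hetero", list(n_sites = nrow(res$pop_ho)))
  }

  if ("ordination" %in% cfg$stages) {
    res$pca <- gm_pca(gm)
    utils::write.table(
      data.frame(sample = rownames(res$pca$scores), res$pca$scores),
      file.path(cfg$out_dir, "pca_scores.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    bs <- bootstrap_support(gm, B = cfg$ordination$bootstrap_B,
                            seed = cfg$ordination$seed)
    write_newick(bs$phylo, file.path(cfg$out_dir, "ward_tree.nwk"))
    res$tree <- bs
    log_stage("ordination", list(pc1_frac = round(res$pca$var_frac[1], 3)))
  }

  if ("models" %in% cfg$stages) {
    if (is.null(profiles)) stop("models stage requires the ancestry stage")
    res$models <- fit_introgression_models(
      pop_ancestry = res$pop_ancestry, pop_ho = res$pop_ho,
      profiles = profiles, het = res$het,
      covariates = if (!is.null(cfg$covariates)) read_covariates(cfg$covariates),
      B = cfg$models$B, seed = cfg$models$seed)
    jsonlite::write_json(models_to_json(res$models),
                         file.path(cfg$out_dir, "models.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    log_stage("models", list(
      n_tests = length(res$models)))
  }

  manifest$finished <- format(Sys.time())
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}

#' Fit the introgression-heterozygosity model suite
#'
#' The inferential layer over the pipeline outputs: (i) a two-sample t test
#' of population Ho between ME- and MG-dominated populations; (ii) the
#' population-level linear model of Ho on main ancestry, introgression and
#' their interaction, with within-species slopes; (iii) a one-way ANOVA of
#' individual sMLH across main ancestries; (iv) the individual-level
#' random-intercept mixed model of sMLH with parametric-bootstrap
#' likelihood-ratio tests of introgression and the interaction; (v)
#' class-partitioned sMLH slopes on introgression within ME- and
#' MG-background individuals; and (vi) ancestry-environment correlations
#' with FDR adjustment (when covariates are given). Ancestry classes with
#' fewer than two members are excluded from slope estimation.
#'
#' @param pop_ancestry data.frame from [population_ancestry()].
#' @param pop_ho data.frame from [population_ho()].
#' @param profiles `ancestry_profiles` from [estimate_q()].
#' @param het individual heterozygosity table containing `smlh` and
#'   optionally the class-partitioned columns from [smlh_partitioned()].
#' @param covariates optional covariate table for [correlate_environment()].
#' @param B parametric-bootstrap replicates.
#' @param seed RNG seed for the bootstrap.
#' @return Named list of model results.
#' @export
fit_introgression_models <- function(pop_ancestry, pop_ho, profiles, het,
                                     covariates = NULL, B = 1000L, seed = 17L) {
  out <- list()

  pop <- merge(pop_ancestry, pop_ho, by = "site")
  me <- pop$ho[pop$main_ancestry == "ME"]
  mg <- pop$ho[pop$main_ancestry == "MG"]
  if (length(me) >= 2 && length(mg) >= 2) {
    out$ho_t_test <- t_test(me, mg)
  }
  out$pop_glm <- tryCatch(
    fit_lm(pop$ho, pop$main_ancestry, pop$introgression),
    error = function(e) structure(list(error = conditionMessage(e)),
                                  class = "model_result"))

  ind <- merge(profiles, het[, setdiff(names(het), "site")], by = "sample")
  out$smlh_anova <- anova_oneway(ind$smlh, ind$main_ancestry)

  keep_lv <- names(which(table(ind$main_ancestry) >= 2))
  d <- ind[ind$main_ancestry %in% keep_lv & !is.na(ind$smlh), ]
  d$main_ancestry <- factor(d$main_ancestry)
  if (nlevels(d$main_ancestry) >= 2) {
    out$smlh_lmm <- fit_lmm(smlh ~ main_ancestry * introgression, d, d$site)
    out$smlh_boot_interaction <- parametric_bootstrap_lrt(
      smlh ~ main_ancestry * introgression,
      smlh ~ main_ancestry + introgression, d, d$site, B = B, seed = seed)
    out$smlh_boot_introgression <- parametric_bootstrap_lrt(
      smlh ~ main_ancestry + introgression,
      smlh ~ main_ancestry, d, d$site, B = B, seed = seed + 1L)
    out$smlh_slopes <- do.call(rbind, lapply(levels(d$main_ancestry), function(lv) {
      sub <- d[d$main_ancestry == lv, ]
      sf <- summary(stats::lm(smlh ~ introgression, data = sub))$coefficients
      data.frame(ancestry = lv, b = sf["introgression", 1],
                 p = sf["introgression", 4], n = nrow(sub),
                 stringsAsFactors = FALSE)
    }))
  }

  cls <- intersect(c("smlh_ME", "smlh_MG", "smlh_MEMG"), names(d))
  if (length(cls) == 3) {
    rows <- list()
    for (bg in intersect(c("ME", "MG"), levels(d$main_ancestry))) {
      sub <- d[d$main_ancestry == bg, ]
      for (cl in cls) {
        ok <- !is.na(sub[[cl]])
        if (sum(ok) < 3 || stats::sd(sub$introgression[ok]) == 0) next
        sf <- summary(stats::lm(sub[[cl]][ok] ~ sub$introgression[ok]))$coefficients
        rows[[paste(bg, cl)]] <- data.frame(
          background = bg, snp_class = sub("smlh_", "", cl),
          b = sf[2, 1], p = sf[2, 4], n = sum(ok), stringsAsFactors = FALSE)
      }
    }
    if (length(rows) > 0) {
      out$class_slopes <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    }
  }

  if (!is.null(covariates)) {
    out$env_correlations <- correlate_environment(pop_ancestry, covariates)
  }
  out
}

# Flatten model results into JSON-ready structures.
models_to_json <- function(models) {
  lapply(models, function(m) {
    if (inherits(m, "model_result")) {
      u <- unclass(m)
      u$formula <- NULL
      u$anova <- if (!is.null(u$anova)) as.data.frame(u$anova)
      u$coefficients <- if (!is.null(u$coefficients)) as.data.frame(u$coefficients)
      u
    } else if (is.list(m) && !is.null(m$LR_star)) {
      m[c("LR_obs", "p", "B", "n_failed")]
    } else m
  })
}
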