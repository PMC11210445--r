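#' Configuration for a full pipeline run
#'
#' Exactly one of `synth` (a [synth_config()]) or `lipids_path` +
#' `samples_path` must be supplied.
#'
#' @param synth optional [synth_config()] for a generated cohort.
#' @param lipids_path,samples_path optional input CSV paths
#'   (see [read_cohort()]).
#' @param tissue "brain" or "serum"; serum runs use the mixed-model
#'   residualization and collapse to one donor record for association
#'   models.
#' @param covariates residualization covariates; default depends on tissue.
#' @param education_mode "ignore" or "covariate" (adds education to the
#'   residualization design, the education-corrected variant).
#' @param params a [network_params()].
#' @param k_range candidate cluster counts for sample clustering.
#' @param outcome association outcome column.
#' @param n_boot mediation bootstrap replicates.
#' @param seed master seed; every stochastic stage uses a derived child
#'   seed.
#' @param output_dir directory for the stage outputs and manifest.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = NULL, lipids_path = NULL,
                            samples_path = NULL,
                            tissue = c("brain", "serum"),
                            covariates = NULL,
                            education_mode = c("ignore", "covariate"),
                            params = network_params(), k_range = 2:10,
                            outcome = "cgrs", n_boot = 2000L, seed = 1L,
                            output_dir = tempfile("lipidlands_run")) {
  tissue <- match.arg(tissue)
  education_mode <- match.arg(education_mode)
  has_files <- !is.null(lipids_path) && !is.null(samples_path)
  if (is.null(synth) == !has_files) {
    stop("supply exactly one of 'synth' or ('lipids_path' + 'samples_path')")
  }
  if (is.null(covariates)) {
    covariates <- if (tissue == "brain") c("batch", "sex", "age", "pmi")
                  else c("batch", "sex", "age")
  }
  if (education_mode == "covariate") covariates <- union(covariates, "education")
  structure(list(synth = synth, lipids_path = lipids_path,
                 samples_path = samples_path, tissue = tissue,
                 covariates = covariates, education_mode = education_mode,
                 params = params, k_range = k_range, outcome = outcome,
                 n_boot = as.integer(n_boot), seed = as.integer(seed),
                 output_dir = output_dir),
            class = "pipeline_config")
}

write_stage <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full lipid co-regulation pipeline
#'
#' Executes, in order: cohort acquisition (synthetic or from CSV),
#' preprocessing (filter, zero imputation, mole percent, standardization,
#' covariate residualization; donor random-intercept model for serum),
#' differential screen against NCI-, WLCNA restricted to lipids significant
#' in at least one comparison, group-profile correlations, per-module group
#' statistics, sample k-means with per-cell Fisher enrichment on the most
#' group-differential module, per-lipid cognition-slope associations, and
#' mediation of education for the NCI-/NCI+ and NCI-/MCI- contrasts.
#' All stage tables are written as TSV to the output directory alongside a
#' JSON manifest with content hashes, so two runs with the same
#' configuration are diffable and hash-identical.
#'
#' @param config a [pipeline_config()].
#' @return the manifest (list) invisibly; also written as `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  warnings_log <- character(0)
  note <- function(...) {
    warnings_log <<- c(warnings_log, sprintf(...))
    message(sprintf(...))
  }

  # --- data ----------------------------------------------------------------
  if (!is.null(config$synth)) {
    synth_cfg <- config$synth
    synth_cfg$seed <- derive_seed(config$seed, "synth")
    cohort <- generate_lipidomics(synth_cfg, config$tissue)
    cohort_files <- write_cohort(cohort, config$output_dir)
    lipids <- cohort$lipids; info <- cohort$samples
  } else {
    dat <- read_cohort(config$lipids_path, config$samples_path)
    lipids <- dat$lipids; info <- dat$samples
  }

  # --- preprocess ----------------------------------------------------------
  processed <- preprocess_lipids(lipids, info, config$covariates,
                                 mixed = config$tissue == "serum")
  proc_df <- data.frame(sample_id = rownames(processed),
                        unclass(processed), check.names = FALSE)
  files <- c(processed = write_stage(proc_df, config$output_dir,
                                     sprintf("processed_%s.tsv", config$tissue)))

  # --- differential screen -------------------------------------------------
  screen <- screen_differential(processed, info)
  files["differential"] <- write_stage(as.data.frame(screen), config$output_dir,
                                       "differential_results.tsv")
  sig <- attr(screen, "significant_lipids")
  if (length(sig) < 10) {
    note("only %d lipids pass the differential screen; using all %d for the network",
         length(sig), ncol(processed))
    sig <- colnames(processed)
  }

  # --- network -------------------------------------------------------------
  fit <- wlcna(processed[, sig, drop = FALSE], info, params = config$params)
  files["modules"] <- write_stage(
    data.frame(lipid = names(fit$assignments), module = fit$assignments),
    config$output_dir, "modules.tsv")
  el_scores <- sapply(fit$eigenlipids, function(e) e$scores)
  if (length(fit$eigenlipids)) {
    files["eigenlipids"] <- write_stage(
      data.frame(sample_id = rownames(processed), el_scores, check.names = FALSE),
      config$output_dir, "eigenlipids.tsv")
    files["module_stats"] <- write_stage(
      data.frame(module = names(fit$group_stats),
                 anova_F = vapply(fit$group_stats, function(s) s$anova$statistic, 1),
                 anova_p = vapply(fit$group_stats, function(s) s$anova$p_value, 1)),
      config$output_dir, "module_stats.tsv")
  }
  files["mds"] <- write_stage(
    data.frame(lipid = rownames(fit$mds), fit$mds), config$output_dir,
    "mds_coords.tsv")

  # --- group-profile correlations -----------------------------------------
  gc <- mean_group_correlation(processed, info, lipid_subset = sig)
  files["group_correlations"] <- write_stage(
    data.frame(group = rownames(gc$values), gc$values, check.names = FALSE),
    config$output_dir, "group_correlations.tsv")

  # --- clustering + enrichment on the most group-differential module ------
  top_module <- NULL
  if (length(fit$eigenlipids)) {
    anova_p <- vapply(fit$group_stats, function(s) s$anova$p_value, numeric(1))
    top_module <- names(which.min(anova_p))
    members <- fit$eigenlipids[[top_module]]$members
    cl <- select_k(unclass(processed)[, members, drop = FALSE],
                   k_range = config$k_range,
                   seed = derive_seed(config$seed, "kmeans"))
    files["clusters"] <- write_stage(
      data.frame(sample_id = names(cl$assignments), cluster = cl$assignments),
      config$output_dir, "clusters.tsv")
    enr <- enrichment_table(cl$assignments, info)
    files["enrichment"] <- write_stage(as.data.frame(enr), config$output_dir,
                                       "enrichment.tsv")
    emb <- stats::prcomp(unclass(processed)[, members, drop = FALSE])$x[, 1:2]
    files["embedding"] <- write_stage(
      data.frame(sample_id = rownames(emb), PC1 = emb[, 1], PC2 = emb[, 2]),
      config$output_dir, "embedding.tsv")
  } else {
    note("no modules detected; clustering and mediation stages skipped")
  }

  # --- associations --------------------------------------------------------
  preset <- if (config$tissue == "brain") "lipid_brain" else "lipid_serum"
  assoc <- run_feature_associations(processed, info, outcome = config$outcome,
                                    covariates = preset,
                                    collapse_donors = config$tissue == "serum")
  files["associations"] <- write_stage(as.data.frame(assoc), config$output_dir,
                                       "associations_lipid.tsv")

  # --- mediation of education ---------------------------------------------
  if (!is.null(top_module)) {
    med_rows <- list()
    for (contrast in c("NCI+", "MCI-")) {
      in_pair <- info$group %in% c("NCI-", contrast)
      if (sum(in_pair & info$group == contrast) < 5) {
        note("contrast NCI-/%s has < 5 samples; mediation skipped", contrast)
        next
      }
      med <- mediation(fit$eigenlipids[[top_module]]$scores[in_pair],
                       info$education[in_pair],
                       as.integer(info$group[in_pair] == contrast),
                       info = info[in_pair, , drop = FALSE],
                       covariates = intersect(c("age", "sex", "pmi"),
                                              config$covariates),
                       n_boot = config$n_boot,
                       seed = derive_seed(config$seed, paste0("mediation", contrast)))
      med_rows[[contrast]] <- data.frame(
        contrast = paste0("NCI-/", contrast), module = top_module,
        a_path = med$a_path, b_path = med$b_path, direct = med$direct,
        total = med$total, indirect = med$indirect,
        ci_lo = med$bootstrap_ci[1], ci_hi = med$bootstrap_ci[2],
        p_direct = med$p_direct, p_indirect = med$p_indirect,
        n = med$n, n_boot = med$n_boot, seed = med$seed)
    }
    if (length(med_rows)) {
      files["mediation"] <- write_stage(do.call(rbind, med_rows),
                                        config$output_dir, "mediation.tsv")
    }
  }

  # --- manifest ------------------------------------------------------------
  if (!is.null(config$synth)) files <- c(files, cohort = cohort_files)
  hashes <- tools::md5sum(unname(files))
  manifest <- list(
    package_version = as.character(utils::packageVersion("lipidlands")),
    tissue = config$tissue, covariates = config$covariates,
    education_mode = config$education_mode, seed = config$seed,
    synthetic = !is.null(config$synth),
    n_samples = nrow(processed), n_lipids = ncol(processed),
    n_significant_lipids = length(attr(screen, "significant_lipids")),
    power = fit$power,
    modules = as.list(table(fit$assignments)),
    top_module = top_module,
    files = as.list(setNames(unname(hashes), basename(names(hashes)))),
    warnings = warnings_log)
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
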