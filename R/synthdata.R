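#' Configuration for the synthetic cohort generator
#'
#' Defines a synthetic study emulating a targeted lipid panel profiled in
#' post-mortem brain and longitudinal serum across the six diagnosis by
#' APOE-e4 carrier groups. Defaults mirror the cohort design the package
#' targets: 99 brain samples with group sizes (41, 6, 22, 6, 15, 9),
#' 542 expected serum draws from 271 donors, 119 species over five Biocrates
#' p180 lipid classes, limit-of-detection censoring, and education running
#' higher in cognitively intact carriers (NCI+).
#'
#' @param n_brain number of brain samples (one donor each).
#' @param n_donors_serum number of serum donors; each contributes a
#'   Poisson(mean)-truncated number of visits.
#' @param visits_per_donor numeric `c(mean=, max=)` for the visit-count
#'   distribution (serum only).
#' @param n_lipids_per_class named counts over classes C, PC.aa, PC.ae, SM,
#'   lysoPC.
#' @param n_modules number of planted co-regulated modules.
#' @param module_size species per planted module.
#' @param within_module_correlation target pairwise correlation of species
#'   within a planted module, in [0, 1].
#' @param group_effects `n_modules x 6` matrix of per-group mean shifts (SD
#'   units of the log abundance) applied to a module's species; columns named
#'   by [group_levels()]. Default plants a "blue-module-like" shift shared by
#'   NCI+ and MCI-, an acylcarnitine-like MCI+ shift, and a late-disease shift.
#' @param group_proportions probabilities over the six groups (sums to 1).
#' @param lod_quantile per-species fraction censored below the limit of
#'   detection, in [0, 1).
#' @param batch_count number of technical batches.
#' @param education_confounding years added to education for NCI+ donors
#'   (default 3.4, the observed NCI+ minus NCI- gap).
#' @param mediation_params numeric `c(a_path=, b_path=, direct=)`: module-1
#'   factor -> education path injected into the cohort, and the path values
#'   used by [simulate_mediation()].
#' @param noise_sd total SD of the log abundances around their per-species
#'   baseline (0.3, i.e. roughly a 30% coefficient of variation, is typical
#'   of targeted panels). Group shifts are expressed in units of this SD.
#' @param covariate_effect_sd SD of per-species age/sex/PMI/batch effects.
#' @param donor_sd donor random-intercept SD on the log scale (serum only).
#' @param seed integer seed; identical config + seed gives byte-identical
#'   output tables.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_brain = 99L,
                         n_donors_serum = 271L,
                         visits_per_donor = c(mean = 2, max = 5),
                         n_lipids_per_class = c(C = 24L, PC.aa = 38L,
                                                PC.ae = 30L, SM = 15L,
                                                lysoPC = 12L),
                         n_modules = 3L,
                         module_size = 20L,
                         within_module_correlation = 0.7,
                         group_effects = NULL,
                         group_proportions = c(41, 6, 22, 6, 15, 9) / 99,
                         lod_quantile = 0.05,
                         batch_count = 3L,
                         education_confounding = 3.4,
                         mediation_params = c(a_path = 0.6, b_path = 0.5,
                                              direct = 0.2),
                         noise_sd = 0.3,
                         covariate_effect_sd = 0.05,
                         donor_sd = 0.3,
                         seed = 1L) {
  for (nm in c("n_brain", "n_donors_serum", "n_modules", "module_size",
               "batch_count")) {
    stop_if_not_count(get(nm), nm)
  }
  if (any(n_lipids_per_class < 1) ||
      !setequal(names(n_lipids_per_class), c("C", "PC.aa", "PC.ae", "SM", "lysoPC"))) {
    stop("'n_lipids_per_class' must give positive counts for exactly the ",
         "classes C, PC.aa, PC.ae, SM, lysoPC")
  }
  if (abs(sum(group_proportions) - 1) > 1e-12) {
    stop("'group_proportions' must sum to 1")
  }
  if (within_module_correlation < 0 || within_module_correlation > 1) {
    stop("'within_module_correlation' must lie in [0, 1]")
  }
  if (lod_quantile < 0 || lod_quantile >= 1) {
    stop("'lod_quantile' must lie in [0, 1)")
  }
  if (n_modules * module_size > sum(n_lipids_per_class)) {
    stop("planted modules require more species than the panel provides")
  }
  if (is.null(group_effects)) {
    group_effects <- matrix(0, n_modules, 6,
                            dimnames = list(NULL, group_levels()))
    group_effects[1, c("NCI+", "MCI-")] <- 1        # shared early-disease shift
    if (n_modules >= 2) group_effects[2, "MCI+"] <- -0.8
    if (n_modules >= 3) group_effects[3, c("AD-", "AD+")] <- c(0.4, 0.6)
  }
  stopifnot(is.matrix(group_effects), nrow(group_effects) == n_modules,
            ncol(group_effects) == 6)
  colnames(group_effects) <- group_levels()
  structure(list(
    n_brain = as.integer(n_brain), n_donors_serum = as.integer(n_donors_serum),
    visits_per_donor = visits_per_donor,
    n_lipids_per_class = n_lipids_per_class,
    n_modules = as.integer(n_modules), module_size = as.integer(module_size),
    within_module_correlation = within_module_correlation,
    group_effects = group_effects, group_proportions = group_proportions,
    lod_quantile = lod_quantile, batch_count = as.integer(batch_count),
    education_confounding = education_confounding,
    mediation_params = mediation_params, noise_sd = noise_sd,
    covariate_effect_sd = covariate_effect_sd, donor_sd = donor_sd,
    seed = as.integer(seed)), class = "synth_config")
}

# plausible Biocrates p180-style species names, one set per class
make_species_names <- function(n_per_class) {
  acyl <- c("C0", "C2", "C3", "C4", "C5", "C6", "C8", "C9", "C10", "C12",
            "C14", "C14.1", "C14.2", "C16", "C16.1", "C16.2", "C18",
            "C18.1", "C18.2", "C3.DC", "C5.DC", "C5.OH", "C10.1", "C10.2",
            "C12.1", "C16.OH", "C18.1.OH", "C6.1", "C7.DC", "C4.OH")
  chain <- function(prefix, carbons, bonds) {
    grid <- expand.grid(b = bonds, c = carbons)
    paste0(prefix, ".C", grid$c, ".", grid$b)
  }
  pools <- list(
    C = acyl,
    PC.aa = chain("PC.aa", seq(24, 44, 2), 0:6),
    PC.ae = chain("PC.ae", seq(30, 44, 2), 0:6),
    SM = c(paste0("SM.C", c("16.0", "16.1", "18.0", "18.1", "20.2", "22.3",
                            "24.0", "24.1", "26.0", "26.1")),
           paste0("SM.OH.C", c("14.1", "16.1", "22.1", "22.2", "24.1"))),
    lysoPC = paste0("lysoPC.a.C", c("14.0", "16.0", "16.1", "17.0", "18.0",
                                    "18.1", "18.2", "20.3", "20.4", "24.0",
                                    "26.0", "26.1", "28.0", "28.1")))
  out <- character(0); cls <- character(0)
  for (k in names(n_per_class)) {
    n <- n_per_class[[k]]
    if (n > length(pools[[k]])) stop("class ", k, " supports at most ",
                                     length(pools[[k]]), " species")
    out <- c(out, pools[[k]][seq_len(n)])
    cls <- c(cls, rep(k, n))
  }
  names(cls) <- out
  cls
}

# planted module membership: module m draws its species from a preferred class
assign_modules <- function(lipid_class, n_modules, module_size) {
  prefer <- c("PC.aa", "C", "PC.ae", "SM", "lysoPC")
  modules <- setNames(rep(0L, length(lipid_class)), names(lipid_class))
  for (m in seq_len(n_modules)) {
    pool <- names(modules)[modules == 0L &
                             lipid_class == prefer[(m - 1L) %% 5L + 1L]]
    if (length(pool) < module_size) {
      spill <- setdiff(names(modules)[modules == 0L], pool)
      pool <- c(pool, spill[seq_len(module_size - length(pool))])
    }
    modules[pool[seq_len(module_size)]] <- m
  }
  modules
}

#' Generate a synthetic lipidomic cohort
#'
#' Log-normal abundances with planted co-regulated modules: the log
#' abundance of species i in sample s is
#' `mu_i + noise_sd * (sqrt(rho) * f_m(s) + sqrt(1-rho) * eps) + shift(m, g) +
#' covariate effects + donor intercept (serum)`, where `f_m` is the latent
#' factor of the species' module and `rho` the within-module correlation.
#' Values below the per-species `lod_quantile` are censored to missing.
#' Education is shifted upward for NCI+ donors and receives an `a_path`
#' contribution from the module-1 factor; the cognitive global random slope
#' (CGRS) is linear in the module-1 factor, education, and disease severity,
#' plus noise, so supervised and unsupervised stages share one planted signal.
#'
#' @param config a [synth_config()].
#' @param tissue "brain" (one draw per donor, PMI recorded) or "serum"
#'   (repeated draws, donor random intercept).
#' @return an object of class `synthetic_cohort`: list with `lipids`
#'   (a [lipid_table()]), `samples` (metadata data.frame with columns
#'   sample_id, donor_id, visit, diagnosis, apoe4, group, age, sex, pmi,
#'   education, batch, cgrs, cgrs_path, amyloid, tangles, rin), and `truth`
#'   (module map, group shifts, mediation paths, donor intercept SD).
#' @export
generate_lipidomics <- function(config, tissue = c("brain", "serum")) {
  stopifnot(inherits(config, "synth_config"))
  tissue <- match.arg(tissue)
  set.seed(config$seed)

  # --- design: donors, visits, groups -------------------------------------
  if (tissue == "brain") {
    n_donors <- config$n_brain
    visits <- rep(1L, n_donors)
  } else {
    n_donors <- config$n_donors_serum
    vm <- config$visits_per_donor
    if (vm[["max"]] < 1) stop("visits_per_donor max must be >= 1")
    visits <- pmin(pmax(stats::rpois(n_donors, vm[["mean"]]), 1L), vm[["max"]])
  }
  donor_id <- sprintf("D%04d", seq_len(n_donors))
  grp <- sample(group_levels(), n_donors, replace = TRUE,
                prob = config$group_proportions)
  severity <- c("NCI-" = 0, "NCI+" = 0.5, "MCI-" = 1, "MCI+" = 1.5,
                "AD-" = 2.5, "AD+" = 3)[grp]

  # --- donor-level covariates --------------------------------------------
  age <- if (tissue == "brain") stats::rnorm(n_donors, 90.6, 6.0) else
    stats::rnorm(n_donors, 83.8, 6.6)
  sex <- ifelse(stats::runif(n_donors) < ifelse(tissue == "brain", 0.26, 0.215),
                "male", "female")
  pmi <- if (tissue == "brain") stats::rgamma(n_donors, shape = 4, scale = 2.5)
         else rep(NA_real_, n_donors)
  amyloid <- pmax(0, 0.5 + 0.3 * severity + stats::rnorm(n_donors, 0, 0.3))
  tangles <- pmax(0, 1.8 + 0.9 * severity + stats::rnorm(n_donors, 0, 0.6))

  # donor-level module factors; education and CGRS hang off module 1
  u <- matrix(stats::rnorm(n_donors * config$n_modules), n_donors)
  a_path <- config$mediation_params[["a_path"]]
  education <- pmax(8, 14.8 + config$education_confounding * (grp == "NCI+") +
                      a_path * u[, 1] + stats::rnorm(n_donors, 0, 2.5))
  cgrs <- 0.06 - 0.05 * severity / 3 + 0.02 * u[, 1] +
    0.004 * (education - 14.8) + stats::rnorm(n_donors, 0, 0.04)
  cgrs_path <- cgrs + 0.015 * (severity - mean(severity)) +
    stats::rnorm(n_donors, 0, 0.01)

  # --- expand to samples --------------------------------------------------
  d_idx <- rep(seq_len(n_donors), visits)
  visit <- unlist(lapply(visits, seq_len), use.names = FALSE)
  n <- length(d_idx)
  sample_id <- if (tissue == "brain") donor_id else
    sprintf("%s_v%d", donor_id[d_idx], visit)
  batch <- sample(seq_len(config$batch_count), n, replace = TRUE)
  # sample-level factor: brain uses the donor factor directly; serum visits
  # share half their factor variance within donor
  f <- u[d_idx, , drop = FALSE]
  if (tissue == "serum") {
    f <- sqrt(0.5) * f +
      sqrt(0.5) * matrix(stats::rnorm(n * config$n_modules), n)
  }

  # --- species ------------------------------------------------------------
  lipid_class <- make_species_names(config$n_lipids_per_class)
  L <- length(lipid_class)
  modules <- assign_modules(lipid_class, config$n_modules, config$module_size)
  mu <- stats::rnorm(L, log(50), 1)
  rho <- config$within_module_correlation
  ces <- config$covariate_effect_sd
  b_age <- stats::rnorm(L, 0, ces / 6)
  b_sex <- stats::rnorm(L, 0, ces)
  b_pmi <- stats::rnorm(L, 0, ces / 5)
  b_batch <- matrix(stats::rnorm(L * config$batch_count, 0, ces), L)

  logab <- matrix(stats::rnorm(n * L, 0, sqrt(1 - rho) * config$noise_sd), n, L)
  for (i in seq_len(L)) {
    m <- modules[i]
    shared <- if (m > 0) {
      config$noise_sd * (sqrt(rho) * f[, m] +
                          config$group_effects[m, grp[d_idx]])
    } else 0
    logab[, i] <- mu[i] + shared + logab[, i] +
      b_age[i] * (age[d_idx] - mean(age)) +
      b_sex[i] * (sex[d_idx] == "male") +
      (if (tissue == "brain") b_pmi[i] * (pmi[d_idx] - mean(pmi)) else 0) +
      b_batch[i, batch]
  }
  if (tissue == "serum" && config$donor_sd > 0) {
    dint <- matrix(stats::rnorm(n_donors * L, 0, config$donor_sd), n_donors)
    logab <- logab + dint[d_idx, , drop = FALSE]
  }
  abundance <- exp(logab)
  dimnames(abundance) <- list(sample_id, names(lipid_class))

  # --- limit-of-detection censoring --------------------------------------
  if (config$lod_quantile > 0) {
    for (i in seq_len(L)) {
      thr <- stats::quantile(abundance[, i], config$lod_quantile, names = FALSE)
      abundance[abundance[, i] < thr, i] <- NA_real_
    }
  }

  samples <- data.frame(
    sample_id = sample_id, donor_id = donor_id[d_idx], visit = visit,
    diagnosis = sub("[+-]$", "", grp[d_idx]),
    apoe4 = ifelse(endsWith(grp[d_idx], "+"), "carrier", "noncarrier"),
    group = grp[d_idx], age = age[d_idx], sex = sex[d_idx], pmi = pmi[d_idx],
    education = education[d_idx], batch = batch, cgrs = cgrs[d_idx],
    cgrs_path = cgrs_path[d_idx], amyloid = amyloid[d_idx],
    tangles = tangles[d_idx], rin = NA_real_, stringsAsFactors = FALSE)

  truth <- list(modules = modules, group_shifts = config$group_effects,
                mediation = config$mediation_params,
                donor_sd = if (tissue == "serum") config$donor_sd else 0,
                within_module_correlation = rho)
  structure(list(lipids = lipid_table(abundance, lipid_class,
                                      donor_ids = donor_id[d_idx],
                                      visit = visit),
                 samples = as_sample_frame(samples), truth = truth,
                 tissue = tissue, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort (%s): %d samples, %d donors, %d species, %d planted modules\n",
              x$tissue, nrow(x$lipids$values),
              length(unique(x$lipids$donor_ids)),
              ncol(x$lipids$values), x$config$n_modules))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Writes RFC-4180 `lipids.csv` (sample_id, donor_id, visit, then one column
#' per species; empty field = missing), `samples.csv`, and `truth.json`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lt <- cohort$lipids
  lip <- data.frame(sample_id = lt$sample_ids, donor_id = lt$donor_ids,
                    visit = lt$visit, check.names = FALSE)
  lip <- cbind(lip, as.data.frame(lt$values, check.names = FALSE))
  paths <- file.path(dir, c("lipids.csv", "samples.csv", "truth.json"))
  utils::write.csv(lip, paths[1], row.names = FALSE, na = "")
  utils::write.csv(cohort$samples, paths[2], row.names = FALSE, na = "")
  jsonlite::write_json(
    list(modules = as.list(cohort$truth$modules),
         group_shifts = cohort$truth$group_shifts,
         mediation = as.list(cohort$truth$mediation),
         donor_sd = cohort$truth$donor_sd,
         within_module_correlation = cohort$truth$within_module_correlation),
    paths[3], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Generate synthetic gene expression with a cognition-slope signal
#'
#' Per-gene normalized expression with technical batch, RIN, age, and sex
#' effects. The cognitive global random slope is a linear combination of the
#' (standardized) expression of genes named in `assoc_betas`, plus
#' `config$noise_sd` noise, generated independently of amyloid/tangle
#' pathology so gene-cognition associations survive pathology adjustment.
#'
#' @param config a [synth_config()] (supplies sample size, batch count,
#'   noise SD, seed).
#' @param n_genes number of genes.
#' @param assoc_betas optional named numeric vector of per-gene effects on
#'   CGRS (per SD of expression); names must be generated gene names
#'   (`G001`, `G002`, ...). Unnamed genes have zero effect.
#' @return list with `expression` (samples x genes matrix) and `samples`
#'   (metadata data.frame including `rin`).
#' @export
generate_expression <- function(config, n_genes, assoc_betas = NULL) {
  stopifnot(inherits(config, "synth_config"))
  stop_if_not_count(n_genes, "n_genes")
  genes <- sprintf("G%03d", seq_len(n_genes))
  betas <- setNames(rep(0, n_genes), genes)
  if (!is.null(assoc_betas)) {
    unknown <- setdiff(names(assoc_betas), genes)
    if (length(unknown)) stop("assoc_betas references unknown gene(s): ",
                              paste(unknown, collapse = ", "))
    betas[names(assoc_betas)] <- assoc_betas
  }
  set.seed(derive_seed(config$seed, "expression"))
  n <- config$n_brain
  grp <- sample(group_levels(), n, TRUE, config$group_proportions)
  severity <- c("NCI-" = 0, "NCI+" = 0.5, "MCI-" = 1, "MCI+" = 1.5,
                "AD-" = 2.5, "AD+" = 3)[grp]
  info <- data.frame(
    sample_id = sprintf("E%04d", seq_len(n)), donor_id = sprintf("E%04d", seq_len(n)),
    visit = 1L, diagnosis = sub("[+-]$", "", grp),
    apoe4 = ifelse(endsWith(grp, "+"), "carrier", "noncarrier"), group = grp,
    age = stats::rnorm(n, 90.6, 6), sex = ifelse(stats::runif(n) < 0.345, "male", "female"),
    pmi = stats::rgamma(n, 4, scale = 2.5),
    education = pmax(8, stats::rnorm(n, 15, 3)),
    batch = sample(seq_len(config$batch_count), n, TRUE),
    amyloid = pmax(0, 0.5 + 0.3 * severity + stats::rnorm(n, 0, 0.3)),
    tangles = pmax(0, 1.8 + 0.9 * severity + stats::rnorm(n, 0, 0.6)),
    rin = pmin(10, pmax(4, stats::rnorm(n, 7.5, 1))), stringsAsFactors = FALSE)
  ces <- config$covariate_effect_sd
  expr <- matrix(stats::rnorm(n * n_genes), n, n_genes,
                 dimnames = list(info$sample_id, genes))
  b_batch <- matrix(stats::rnorm(n_genes * config$batch_count, 0, 2 * ces), n_genes)
  b_rin <- stats::rnorm(n_genes, 0, 2 * ces)
  b_age <- stats::rnorm(n_genes, 0, ces / 6)
  b_sex <- stats::rnorm(n_genes, 0, ces)
  for (g in seq_len(n_genes)) {
    expr[, g] <- expr[, g] + b_batch[g, info$batch] +
      b_rin[g] * (info$rin - 7.5) + b_age[g] * (info$age - 90.6) +
      b_sex[g] * (info$sex == "male")
  }
  z <- scale(expr)
  noise <- if (config$noise_sd > 0) stats::rnorm(n, 0, config$noise_sd) else 0
  cgrs <- drop(z %*% betas) + noise
  info$cgrs <- cgrs
  info$cgrs_path <- cgrs + stats::rnorm(n, 0, max(config$noise_sd, 1e-8) / 4)
  list(expression = expr, samples = as_sample_frame(info))
}

#' Simulate a three-variable mediation dataset
#'
#' Exposure x ~ N(0,1); mediator m = a_path * x + noise; outcome
#' y = direct * x + b_path * m + noise, so the true indirect effect is
#' `a_path * b_path` and the total effect `direct + a_path * b_path`.
#'
#' @param n sample size.
#' @param a_path,b_path,direct true path coefficients.
#' @param noise_sd residual SD of mediator and outcome.
#' @param seed integer seed.
#' @return data.frame with columns x, m, y.
#' @export
simulate_mediation <- function(n, a_path = 0.6, b_path = 0.5, direct = 0.2,
                               noise_sd = 1, seed = 1L) {
  set.seed(seed)
  x <- stats::rnorm(n)
  m <- a_path * x + stats::rnorm(n, 0, noise_sd)
  y <- direct * x + b_path * m + stats::rnorm(n, 0, noise_sd)
  data.frame(x = x, m = m, y = y)
}
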