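#' Remove lipid species with excess missingness
#'
#' Drops species whose fraction of missing values is strictly greater than
#' `max_missing_frac` (default 17%); species exactly at the threshold are
#' retained. Remaining missingness is handled by [impute_zero()].
#'
#' @param table a [lipid_table()].
#' @param max_missing_frac removal threshold in [0, 1).
#' @return the filtered `lipid_table`; removed species are recorded in
#'   `attr(, "removed")`.
#' @export
filter_lipids <- function(table, max_missing_frac = 0.17) {
  stopifnot(inherits(table, "lipid_table"))
  if (max_missing_frac < 0 || max_missing_frac >= 1) {
    stop("'max_missing_frac' must lie in [0, 1)")
  }
  if (ncol(table$values) == 0L || nrow(table$values) == 0L) stop("empty lipid table")
  miss <- colMeans(is.na(table$values))
  drop <- miss > max_missing_frac
  if (all(drop)) {
    stop(sprintf("all %d species exceed the %.0f%% missingness threshold",
                 length(drop), 100 * max_missing_frac))
  }
  out <- subset_lipids(table, !drop)
  attr(out, "removed") <- names(miss)[drop]
  out
}

#' Impute remaining missing abundances as zero
#'
#' Missing values that survive filtering sit below the assay's limit of
#' detection and are treated as true (near-)zero abundances.
#'
#' @param table a filtered [lipid_table()].
#' @return the `lipid_table` with every NA replaced by 0.
#' @export
impute_zero <- function(table) {
  stopifnot(inherits(table, "lipid_table"))
  v <- table$values
  v[is.na(v)] <- 0
  lipid_table(v, table$lipid_class, donor_ids = table$donor_ids,
              visit = table$visit)
}

new_processed <- function(values, stage, lineage) {
  structure(values, class = c("lipid_matrix", class(values)),
            stage = stage, lineage = lineage)
}

#' @export
print.lipid_matrix <- function(x, ...) {
  cat(sprintf("lipid_matrix [%s]: %d samples x %d species\n",
              attr(x, "stage"), nrow(x), ncol(x)))
  for (step in attr(x, "lineage")) cat("  -", step, "\n")
  invisible(x)
}

#' Coerce an externally preprocessed matrix into the pipeline's stage machine
#'
#' For data normalized outside this package (or for driving a single stage in
#' isolation): wraps a plain samples-by-lipids matrix as a `lipid_matrix` at
#' the declared stage, so downstream stages accept it.
#'
#' @param values numeric matrix, samples in rows.
#' @param stage one of "molpercent", "standardized", "residualized".
#' @return a `lipid_matrix`.
#' @export
as_lipid_matrix <- function(values,
                            stage = c("standardized", "molpercent", "residualized")) {
  stage <- match.arg(stage)
  values <- as.matrix(values)
  new_processed(values, stage,
                sprintf("external input declared at stage '%s'", stage))
}

#' Stage of a processed lipid matrix
#' @param m a `lipid_matrix`.
#' @return one of "molpercent", "standardized", "residualized".
#' @export
stage <- function(m) attr(m, "stage")

require_stage <- function(m, want, op) {
  if (!inherits(m, "lipid_matrix") || !identical(stage(m), want)) {
    stop(sprintf("%s() expects a matrix at stage '%s' (got '%s'); the pipeline order is filter -> impute -> mole_percent -> standardize -> residualize",
                 op, want, if (inherits(m, "lipid_matrix")) stage(m) else class(m)[1]))
  }
}

#' Mole-percent normalization
#'
#' Expresses each species as a percentage of the summed abundance of all
#' measured species in that sample, removing per-sample totals.
#'
#' @param table a complete (no missing values) [lipid_table()].
#' @return a `lipid_matrix` at stage "molpercent"; every row sums to 100.
#' @export
mole_percent <- function(table) {
  stopifnot(inherits(table, "lipid_table"))
  v <- table$values
  if (anyNA(v)) stop("mole_percent() requires a complete table; run impute_zero() first")
  tot <- rowSums(v)
  if (any(tot <= 0)) {
    stop("sample(s) with zero total abundance: ",
         paste(rownames(v)[tot <= 0], collapse = ", "))
  }
  new_processed(100 * v / tot, "molpercent",
                sprintf("mole_percent: %d species", ncol(v)))
}

#' Standardize species across samples
#'
#' Per-species z-score (mean 0, SD 1, denominator n-1) of the mole-percent
#' matrix, so species of very different absolute abundance are comparable.
#'
#' @param m a `lipid_matrix` at stage "molpercent".
#' @return a `lipid_matrix` at stage "standardized".
#' @export
standardize <- function(m) {
  require_stage(m, "molpercent", "standardize")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance species: ", paste(colnames(m)[sds == 0], collapse = ", "))
  }
  z <- scale(unclass(m))
  out <- z[, , drop = FALSE]
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  new_processed(out, "standardized", c(attr(m, "lineage"), "standardize: z-score per species"))
}

build_design <- function(info, covariates) {
  info <- as_sample_frame(info)
  missing_cov <- setdiff(covariates, names(info))
  if (length(missing_cov)) stop("covariate(s) not found in sample info: ",
                                paste(missing_cov, collapse = ", "))
  if (length(covariates) == 0L) {
    return(matrix(1, nrow(info), 1, dimnames = list(NULL, "(Intercept)")))
  }
  df <- info[, covariates, drop = FALSE]
  # drop factor levels absent from this sample set before dummy coding
  df[] <- lapply(df, function(x) if (is.factor(x)) droplevels(x) else x)
  X <- stats::model.matrix(~., df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[-seq_len(qrX$rank)]
    stop("rank-deficient covariate design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  X
}

#' Residualize species on covariates (ordinary least squares)
#'
#' Fits, per species, an OLS model of the standardized abundance on an
#' intercept plus the named covariates (categorical covariates dummy-coded)
#' and returns the residuals. This removes batch and demographic structure
#' before network analysis. Pass `education` among the covariates for
#' education-corrected runs.
#'
#' @param m a `lipid_matrix` at stage "standardized".
#' @param info sample metadata data.frame, rows aligned with `m`.
#' @param covariates character vector of column names in `info`
#'   (e.g. `c("batch", "sex", "age", "pmi")`); empty vector centers columns.
#' @return a `lipid_matrix` at stage "residualized".
#' @export
residualize <- function(m, info, covariates) {
  require_stage(m, "standardized", "residualize")
  stopifnot(nrow(info) == nrow(m))
  X <- build_design(info, covariates)
  if (nrow(X) <= ncol(X)) stop("more design columns than samples (n <= p)")
  res <- qr.resid(qr(X), unclass(m))
  dimnames(res) <- dimnames(m)
  new_processed(res, "residualized",
                c(attr(m, "lineage"),
                  sprintf("residualize (OLS): ~ %s",
                          paste(c("1", covariates), collapse = " + "))))
}

#' Residualize with a donor random intercept (repeated serum draws)
#'
#' Per species, fits a linear mixed model (REML) with the named covariates
#' as fixed effects and a random intercept per donor, and returns the
#' conditional residuals (observed minus fixed-effect prediction minus the
#' predicted donor intercept). Donors with a single visit are pooled into
#' one shared grouping level. If no donor has repeated visits the random
#' effect is unidentified and the function falls back to [residualize()]
#' with a message; per-species non-convergence likewise falls back to OLS
#' and is recorded in the lineage.
#'
#' @inheritParams residualize
#' @param donor_ids character vector of donor ids, one per sample; defaults
#'   to `info$donor_id`.
#' @return a `lipid_matrix` at stage "residualized"; the estimated donor
#'   intercept SD per species is stored in `attr(, "donor_sd")`.
#' @export
residualize_mixed <- function(m, info, covariates, donor_ids = info$donor_id) {
  require_stage(m, "standardized", "residualize_mixed")
  stopifnot(nrow(info) == nrow(m), length(donor_ids) == nrow(m))
  donor <- as.character(donor_ids)
  singletons <- names(which(table(donor) == 1L))
  if (length(singletons) == length(unique(donor))) {
    message("no donor has repeated visits; falling back to OLS residualization")
    out <- residualize(m, info, covariates)
    attr(out, "donor_sd") <- setNames(rep(NA_real_, ncol(m)), colnames(m))
    return(out)
  }
  donor[donor %in% singletons] <- ".single_visit"
  X <- build_design(info, covariates)
  if (nrow(X) <= ncol(X)) stop("more design columns than samples (n <= p)")
  df <- as.data.frame(X[, -1, drop = FALSE])
  names(df) <- make.names(colnames(X)[-1])
  df$.donor <- factor(donor)
  fixed <- if (ncol(df) > 1L) paste(names(df)[-ncol(df)], collapse = " + ") else "1"
  form <- stats::as.formula(paste("y ~", fixed, "+ (1 | .donor)"))
  res <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
  donor_sd <- setNames(rep(NA_real_, ncol(m)), colnames(m))
  fallback <- character(0)
  for (j in seq_len(ncol(m))) {
    df$y <- unclass(m)[, j]
    fit <- tryCatch(
      suppressMessages(lme4::lmer(form, data = df, REML = TRUE,
                                  control = lme4::lmerControl(calc.derivs = FALSE))),
      error = function(e) NULL)
    if (is.null(fit)) {
      fallback <- c(fallback, colnames(m)[j])
      res[, j] <- qr.resid(qr(X), df$y)
    } else {
      res[, j] <- stats::residuals(fit)   # conditional residuals
      donor_sd[j] <- attr(lme4::VarCorr(fit)$.donor, "stddev")[[1]]
    }
  }
  lineage <- c(attr(m, "lineage"),
               sprintf("residualize (mixed, REML, random intercept per donor): ~ %s",
                       paste(c("1", covariates), collapse = " + ")))
  if (length(fallback)) {
    lineage <- c(lineage, sprintf("OLS fallback (non-convergence): %s",
                                  paste(fallback, collapse = ", ")))
  }
  out <- new_processed(res, "residualized", lineage)
  attr(out, "donor_sd") <- donor_sd
  out
}

#' Run the full preprocessing pipeline
#'
#' Convenience wrapper enforcing the fixed stage order
#' filter -> impute -> mole percent -> standardize -> residualize.
#'
#' @param table a raw [lipid_table()].
#' @param info sample metadata aligned with `table`.
#' @param covariates covariate names for residualization.
#' @param max_missing_frac passed to [filter_lipids()].
#' @param mixed use [residualize_mixed()] (repeated-draw serum designs).
#' @return a `lipid_matrix` at stage "residualized".
#' @export
preprocess_lipids <- function(table, info, covariates,
                              max_missing_frac = 0.17, mixed = FALSE) {
  filtered <- filter_lipids(table, max_missing_frac)
  z <- standardize(mole_percent(impute_zero(filtered)))
  if (mixed) residualize_mixed(z, info, covariates)
  else residualize(z, info, covariates)
}
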