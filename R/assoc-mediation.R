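#' Covariate presets for feature association models
#'
#' Named covariate sets: `lipid_brain` (age, sex, education, PMI),
#' `lipid_serum` (age, sex, education), `gene` (batch, RIN, age, education,
#' sex) and `gene_pathology` (adds amyloid load and tangle density, probing
#' whether gene-cognition associations are pathology-independent).
#'
#' @param preset preset name.
#' @return character vector of covariate column names.
#' @export
covariate_preset <- function(preset = c("lipid_brain", "lipid_serum",
                                        "gene", "gene_pathology")) {
  switch(match.arg(preset),
         lipid_brain = c("age", "sex", "education", "pmi"),
         lipid_serum = c("age", "sex", "education"),
         gene = c("batch", "rin", "age", "education", "sex"),
         gene_pathology = c("batch", "rin", "age", "education", "sex",
                            "amyloid", "tangles"))
}

#' Linear model of an outcome on one feature plus covariates
#'
#' OLS of the outcome (a cognition slope) on the standardized feature and
#' the covariate design, complete cases only. The reported beta is the
#' effect per SD of the feature.
#'
#' @param feature numeric feature values (one lipid or gene).
#' @param outcome numeric outcome values, same length.
#' @param info sample metadata supplying the covariates.
#' @param covariates character vector of covariate names (see
#'   [covariate_preset()]).
#' @return one-row data.frame: beta, se, t, p_value, n.
#' @export
fit_feature_model <- function(feature, outcome, info, covariates) {
  stopifnot(length(feature) == length(outcome), nrow(info) == length(feature))
  X <- build_design(info, covariates)
  keep <- stats::complete.cases(feature, outcome, X)
  feature <- feature[keep]; outcome <- outcome[keep]
  X <- X[keep, , drop = FALSE]
  if (length(feature) <= ncol(X) + 2) stop("too few complete cases (n <= p + 2)")
  if (stats::sd(feature) == 0) stop("constant feature")
  z <- (feature - mean(feature)) / stats::sd(feature)
  fit <- stats::lm.fit(cbind(X, feature = z), outcome)
  if (fit$rank < ncol(X) + 1) stop("collinear design after adding the feature")
  dfree <- length(outcome) - fit$rank
  sigma2 <- sum(fit$residuals^2) / dfree
  XtXinv <- chol2inv(chol(crossprod(cbind(X, feature = z))))
  se <- sqrt(sigma2 * XtXinv[ncol(X) + 1, ncol(X) + 1])
  beta <- unname(fit$coefficients["feature"])
  tval <- beta / se
  data.frame(beta = beta, se = se, t = tval,
             p_value = 2 * stats::pt(-abs(tval), dfree), n = length(outcome))
}

#' Association of every feature with a cognition slope
#'
#' One linear model per feature (lipid species or gene), BH correction
#' across the feature family, flags at q < 0.05. For repeated-draw serum
#' designs, samples are first collapsed to one record per donor (the last
#' visit), so donors rather than draws are the units.
#'
#' @param m samples x features matrix (processed lipids or normalized
#'   expression).
#' @param info sample metadata aligned with `m`.
#' @param outcome outcome column: "cgrs" (cognitive global random slope) or
#'   "cgrs_path" (its pathology-adjusted variant).
#' @param covariates covariate names or a [covariate_preset()] name.
#' @param collapse_donors collapse to one record (last visit) per donor.
#' @return data.frame of class `association_result`: feature, beta, se,
#'   p_value, q_value, significant (q < 0.05), n.
#' @export
run_feature_associations <- function(m, info, outcome = c("cgrs", "cgrs_path"),
                                     covariates = "lipid_brain",
                                     collapse_donors = FALSE) {
  outcome <- match.arg(outcome)
  if (length(covariates) == 1 &&
      covariates %in% c("lipid_brain", "lipid_serum", "gene", "gene_pathology")) {
    covariates <- covariate_preset(covariates)
  }
  m <- unclass(m)
  stopifnot(nrow(info) == nrow(m))
  if (collapse_donors) {
    ord <- order(info$donor_id, info$visit)
    # keep the final visit of each donor
    last <- vapply(split(ord, info$donor_id[ord]), function(ix) ix[length(ix)],
                   integer(1))
    m <- m[last, , drop = FALSE]
    info <- info[last, , drop = FALSE]
  }
  y <- info[[outcome]]
  fits <- lapply(seq_len(ncol(m)), function(j)
    fit_feature_model(m[, j], y, info, covariates))
  out <- do.call(rbind, fits)
  out <- cbind(feature = colnames(m), out, stringsAsFactors = FALSE)
  out$q_value <- bh_adjust(out$p_value)
  out$significant <- out$q_value < 0.05
  rownames(out) <- NULL
  class(out) <- c("association_result", "data.frame")
  attr(out, "outcome") <- outcome
  attr(out, "covariates") <- covariates
  attr(out, "collapsed_donors") <- collapse_donors
  out
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("associations with %s (%d features, covariates: %s): %d at q < 0.05\n",
              attr(x, "outcome"), nrow(x),
              paste(attr(x, "covariates"), collapse = ", "),
              sum(x$significant)))
  invisible(x)
}

#' Mediation analysis with a percentile bootstrap
#'
#' Classic three-model mediation: path a from `mediator ~ x + covariates`,
#' paths b and c' (direct) from `y ~ x + mediator + covariates`, total c
#' from `y ~ x + covariates`; indirect effect a*b with a percentile
#' bootstrap confidence interval (resampling complete cases) and a Sobel z
#' as the secondary indirect-effect test. Binary outcomes (e.g. the NCI-
#' vs NCI+ contrast, reference coded 0) are fitted with a
#' linear-probability model, so for any outcome c = c' + a*b holds exactly
#' by OLS algebra.
#'
#' @param x exposure (e.g. module eigenlipid scores).
#' @param mediator candidate mediator (e.g. years of education).
#' @param y outcome; binary 0/1 group contrast or continuous.
#' @param info optional metadata supplying control covariates.
#' @param covariates character vector of control covariate names
#'   (e.g. `c("age", "sex", "pmi")`).
#' @param n_boot bootstrap replicates.
#' @param seed integer seed for the bootstrap.
#' @param conf confidence level of the percentile interval.
#' @return object of class `mediation_result` with paths a, b, direct,
#'   total, indirect, the bootstrap CI, p_direct, p_indirect (Sobel), and
#'   bootstrap metadata.
#' @export
mediation <- function(x, mediator, y, info = NULL, covariates = character(0),
                      n_boot = 2000L, seed = 1L, conf = 0.95) {
  stopifnot(length(x) == length(mediator), length(mediator) == length(y))
  if (stats::sd(mediator, na.rm = TRUE) == 0) stop("mediator is constant")
  yu <- unique(stats::na.omit(y))
  binary <- length(yu) == 2
  if (binary && !all(yu %in% c(0, 1))) stop("binary outcome must be coded 0/1")
  C <- if (length(covariates)) {
    stopifnot(!is.null(info), nrow(info) == length(x))
    build_design(info, covariates)[, -1, drop = FALSE]
  } else NULL
  keep <- stats::complete.cases(x, mediator, y, if (is.null(C)) rep(1, length(x)) else C)
  x <- x[keep]; mediator <- mediator[keep]; y <- y[keep]
  C <- if (is.null(C)) NULL else C[keep, , drop = FALSE]
  n <- length(x)
  paths <- function(xi, mi, yi, Ci) {
    Xa <- cbind(1, x = xi, Ci)
    Xb <- cbind(1, x = xi, m = mi, Ci)
    a <- stats::lm.fit(Xa, mi)$coefficients[["x"]]
    fb <- stats::lm.fit(Xb, yi)$coefficients
    c(a = a, b = fb[["m"]], direct = fb[["x"]])
  }
  est <- paths(x, mediator, y, C)
  with_cov <- function(df) if (is.null(C)) df else cbind(df, as.data.frame(C))
  total_fit <- summary(stats::lm(y ~ ., data = with_cov(data.frame(y = y, x = x))))
  direct_fit <- summary(stats::lm(y ~ ., data = with_cov(data.frame(y = y, x = x,
                                                                    m = mediator))))
  total <- total_fit$coefficients["x", "Estimate"]
  p_direct <- direct_fit$coefficients["x", "Pr(>|t|)"]
  # Sobel z from the two path SEs
  se_a <- summary(stats::lm(mediator ~ .,
                            data = with_cov(data.frame(mediator = mediator, x = x))))$
    coefficients["x", "Std. Error"]
  se_b <- direct_fit$coefficients["m", "Std. Error"]
  sobel_z <- (est[["a"]] * est[["b"]]) /
    sqrt(est[["b"]]^2 * se_a^2 + est[["a"]]^2 * se_b^2)
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(i) {
    ix <- sample.int(n, n, replace = TRUE)
    p <- tryCatch(paths(x[ix], mediator[ix], y[ix],
                        if (is.null(C)) NULL else C[ix, , drop = FALSE]),
                  error = function(e) c(a = NA_real_, b = NA_real_,
                                        direct = NA_real_))
    p[["a"]] * p[["b"]]
  }, numeric(1))
  boots <- boots[is.finite(boots)]
  alpha <- (1 - conf) / 2
  ci <- stats::quantile(boots, c(alpha, 1 - alpha), names = FALSE)
  structure(list(a_path = est[["a"]], b_path = est[["b"]],
                 direct = est[["direct"]], total = total,
                 indirect = est[["a"]] * est[["b"]],
                 bootstrap_ci = ci, bootstrap_se = stats::sd(boots),
                 p_direct = p_direct,
                 p_indirect = 2 * stats::pnorm(-abs(sobel_z)),
                 sobel_z = sobel_z, binary_outcome = binary,
                 n = n, n_boot = n_boot, seed = seed, conf = conf),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("mediation (%s outcome, n = %d):\n",
              if (x$binary_outcome) "binary, linear-probability" else "continuous", x$n))
  cat(sprintf("  a = %.4f, b = %.4f, direct c' = %.4f (p = %.3g), total c = %.4f\n",
              x$a_path, x$b_path, x$direct, x$p_direct, x$total))
  cat(sprintf("  indirect a*b = %.4f, %.0f%% bootstrap CI [%.4f, %.4f], Sobel p = %.3g\n",
              x$indirect, 100 * x$conf, x$bootstrap_ci[1], x$bootstrap_ci[2],
              x$p_indirect))
  invisible(x)
}
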