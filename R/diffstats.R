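new_stat_test <- function(statistic, df, p_value, method,
                          effect_direction = NA_real_, extra = list()) {
  structure(c(list(statistic = unname(statistic), df = unname(df),
                   p_value = unname(p_value), method = method,
                   effect_direction = unname(effect_direction)), extra),
            class = "stat_test")
}

#' @export
print.stat_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g\n", x$method,
              x$statistic, paste(signif(x$df, 4), collapse = ", "),
              x$p_value))
  invisible(x)
}

#' Two-sample t test (Welch by default)
#'
#' Unequal-variance t test with Welch-Satterthwaite degrees of freedom,
#' two-sided. Group sizes in diagnosis-genotype cohorts are highly
#' unbalanced, which makes the pooled-variance variant fragile; it remains
#' available via `var_equal = TRUE`.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @param var_equal use the pooled-variance Student variant.
#' @return a `stat_test` with fields statistic, df, p_value,
#'   effect_direction (sign of mean(x) - mean(y)).
#' @export
welch_t <- function(x, y, var_equal = FALSE) {
  stopifnot(length(x) >= 2, length(y) >= 2, all(is.finite(x)), all(is.finite(y)))
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y)) {
      return(new_stat_test(0, length(x) + length(y) - 2, 1,
                           if (var_equal) "student_t" else "welch_t",
                           effect_direction = 0))
    }
    stop("both groups are constant with unequal means; t statistic is degenerate")
  }
  ht <- stats::t.test(x, y, var.equal = var_equal)
  new_stat_test(ht$statistic, ht$parameter, ht$p.value,
                if (var_equal) "student_t" else "welch_t",
                effect_direction = sign(mean(x) - mean(y)))
}

#' Differential screen of lipids against the reference group
#'
#' Per lipid, tests each non-reference diagnosis-genotype group against the
#' reference ("NCI-") with a two-sample t test and flags p < 0.05. The union
#' of lipids significant in at least one comparison (the candidate set for
#' module and clustering analyses) is attached as
#' `attr(, "significant_lipids")`.
#'
#' @param m a `lipid_matrix` (normally residualized).
#' @param info sample metadata with a `group` column; rows aligned with `m`.
#' @param reference reference group label.
#' @param var_equal passed to [welch_t()].
#' @return data.frame of class `differential_screen` with one row per
#'   (lipid, comparison group): lipid, group, statistic, df, p_value,
#'   mean_diff (group minus reference), significant.
#' @export
screen_differential <- function(m, info, reference = "NCI-", var_equal = FALSE) {
  stopifnot(nrow(info) == nrow(m))
  grp <- as.character(info$group)
  if (!reference %in% grp) stop("reference group '", reference, "' has no samples")
  others <- setdiff(group_levels(), reference)
  others <- others[others %in% grp]
  sizes <- table(grp)
  if (sizes[[reference]] < 2) stop("reference group needs >= 2 samples")
  small <- others[sizes[others] < 2]
  if (length(small)) {
    warning("skipping group(s) with < 2 samples: ", paste(small, collapse = ", "))
    others <- setdiff(others, small)
  }
  ref_idx <- grp == reference
  rows <- vector("list", length(others) * ncol(m))
  k <- 0L
  for (g in others) {
    g_idx <- grp == g
    for (j in seq_len(ncol(m))) {
      tt <- welch_t(m[g_idx, j], m[ref_idx, j], var_equal = var_equal)
      k <- k + 1L
      rows[[k]] <- data.frame(
        lipid = colnames(m)[j], group = g, statistic = tt$statistic,
        df = tt$df, p_value = tt$p_value,
        mean_diff = mean(m[g_idx, j]) - mean(m[ref_idx, j]),
        significant = tt$p_value < 0.05, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows[seq_len(k)])
  class(out) <- c("differential_screen", "data.frame")
  attr(out, "reference") <- reference
  attr(out, "significant_lipids") <-
    sort(unique(out$lipid[out$significant]))
  out
}

#' @export
print.differential_screen <- function(x, ...) {
  sig <- attr(x, "significant_lipids")
  cat(sprintf("differential screen vs %s: %d tests, %d lipids significant (p < 0.05) in >= 1 comparison\n",
              attr(x, "reference"), nrow(x), length(sig)))
  invisible(x)
}

#' Mean pairwise sample-profile correlation between groups
#'
#' Entry (g, h) is the average Spearman correlation between the lipid
#' profiles (restricted to `lipid_subset`) of individual samples of group g
#' and individual samples of group h; the diagonal averages over unordered
#' within-group pairs (no self-pairs). Single-sample groups get an
#' undefined (NA) diagonal entry.
#'
#' @param m a `lipid_matrix`.
#' @param info sample metadata with a `group` column.
#' @param lipid_subset species names (>= 3) to correlate over.
#' @return object of class `group_correlation`: list with `values` (6x6
#'   symmetric matrix) and `n_pairs`.
#' @export
mean_group_correlation <- function(m, info, lipid_subset = colnames(m)) {
  stopifnot(nrow(info) == nrow(m), length(lipid_subset) >= 3,
            all(lipid_subset %in% colnames(m)))
  grp <- as.character(info$group)
  lv <- group_levels()[group_levels() %in% grp]
  if (length(lv) == 0) stop("no recognized groups in sample info")
  S <- suppressWarnings(stats::cor(t(unclass(m)[, lipid_subset, drop = FALSE]),
                                   method = "spearman"))
  values <- matrix(NA_real_, length(lv), length(lv), dimnames = list(lv, lv))
  n_pairs <- matrix(0L, length(lv), length(lv), dimnames = list(lv, lv))
  for (a in seq_along(lv)) {
    for (b in a:length(lv)) {
      i <- which(grp == lv[a]); j <- which(grp == lv[b])
      if (a == b) {
        if (length(i) < 2) next
        sub <- S[i, i, drop = FALSE]
        vals <- sub[upper.tri(sub)]
      } else {
        vals <- as.vector(S[i, j, drop = FALSE])
      }
      values[a, b] <- values[b, a] <- mean(vals)
      n_pairs[a, b] <- n_pairs[b, a] <- length(vals)
    }
  }
  structure(list(values = values, n_pairs = n_pairs, groups = lv,
                 lipid_subset = lipid_subset),
            class = "group_correlation")
}

#' @export
print.group_correlation <- function(x, ...) {
  cat(sprintf("mean pairwise Spearman correlations over %d lipids:\n",
              length(x$lipid_subset)))
  print(round(x$values, 3))
  invisible(x)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of p-values in [0, 1] (no NA).
#' @return adjusted q-values, order-aligned with the input.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(!is.finite(p))) stop("p-values must be finite (no NA/NaN)")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Mann-Whitney U test (two-sided)
#'
#' Exact null distribution by enumeration when the combined sample size is
#' at most 16 and there are no ties; otherwise the normal approximation with
#' tie and continuity corrections.
#'
#' @param x,y numeric vectors, each nonempty.
#' @return a `stat_test`; `statistic` is U for the first sample.
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("both samples must be nonempty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 16) && !ties
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  new_stat_test(ht$statistic, NA_real_, ht$p.value, "mann_whitney",
                effect_direction = sign(stats::median(x) - stats::median(y)),
                extra = list(exact = exact))
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p by the probability-mass rule: the sum of hypergeometric
#' probabilities of all tables no more probable than the observed one.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return a `stat_test` with the conditional odds-ratio estimate in
#'   `$odds_ratio` and direction relative to OR = 1.
#' @export
fisher_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)))
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be nonnegative integers")
  }
  ht <- stats::fisher.test(table)
  new_stat_test(NA_real_, NA_real_, ht$p.value, "fisher_exact",
                effect_direction = sign(unname(ht$estimate) - 1),
                extra = list(odds_ratio = unname(ht$estimate)))
}

#' Pearson chi-square test of independence
#'
#' Without continuity correction; df = (r-1)(c-1), upper-tail p.
#'
#' @param table r x c matrix of nonnegative integer counts with positive
#'   row and column sums.
#' @return a `stat_test`.
#' @export
chi_square_independence <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be nonnegative integers")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("row and column sums must be positive (zero expected counts)")
  }
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  new_stat_test(ht$statistic, ht$parameter, ht$p.value, "chi_square")
}

#' One-way ANOVA reconstructed from printed group summaries
#'
#' Recovers the F test from per-group sample sizes, means, and SDs, as
#' reported in a cohort-overview table: SSB = sum n_i (m_i - m)^2,
#' SSW = sum (n_i - 1) sd_i^2, F = (SSB/(k-1)) / (SSW/(N-k)).
#'
#' @param n integer group sizes (each >= 2).
#' @param mean,sd per-group means and standard deviations.
#' @return a `stat_test`; if SSW = 0 with SSB > 0 the result is flagged
#'   `degenerate = TRUE` with p = 0.
#' @export
anova_from_summary <- function(n, mean, sd) {
  stopifnot(length(n) >= 2, length(mean) == length(n), length(sd) == length(n),
            all(n >= 2), all(sd >= 0))
  k <- length(n); N <- sum(n)
  gm <- sum(n * mean) / N
  ssb <- sum(n * (mean - gm)^2)
  ssw <- sum((n - 1) * sd^2)
  if (ssw == 0) {
    if (ssb > 0) {
      return(new_stat_test(Inf, c(k - 1, N - k), 0, "anova_summary",
                           extra = list(degenerate = TRUE)))
    }
    return(new_stat_test(0, c(k - 1, N - k), 1, "anova_summary",
                         extra = list(degenerate = TRUE)))
  }
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  new_stat_test(f, c(k - 1, N - k),
                stats::pf(f, k - 1, N - k, lower.tail = FALSE),
                "anova_summary", extra = list(degenerate = FALSE))
}

#' Classical one-way ANOVA on raw values
#'
#' Equal-variance F test of a group mean difference; algebraically identical
#' to [anova_from_summary()] applied to the groups' exact summaries.
#'
#' @param values numeric vector.
#' @param groups group labels, same length; >= 2 groups with >= 2 values each.
#' @return a `stat_test`.
#' @export
anova_oneway <- function(values, groups) {
  groups <- factor(groups)
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need at least 2 groups")
  if (any(sizes < 2)) {
    stop("group(s) with < 2 values: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  if (stats::var(values) == 0) {
    # all observations identical: no variance to partition
    return(new_stat_test(0, c(length(sizes) - 1, length(values) - length(sizes)),
                         1, "anova"))
  }
  ht <- stats::oneway.test(values ~ groups, var.equal = TRUE)
  new_stat_test(ht$statistic, unname(ht$parameter), ht$p.value, "anova")
}
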