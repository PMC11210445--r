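#' Network parameters for weighted lipid correlation network analysis
#'
#' @param power_candidates candidate soft-threshold powers.
#' @param scale_free_r2_target signed R^2 of the log-log connectivity fit at
#'   which a candidate power is accepted.
#' @param default_power fallback power when no candidate reaches the target.
#' @param min_module_size clusters smaller than this become unassigned
#'   ("grey").
#' @param merge_correlation modules whose eigenlipids correlate (in absolute
#'   value) above this are merged.
#' @param correlation_kind correlation used for the network; Pearson on
#'   residualized z-scores is canonical, Spearman available.
#' @param cut_height_quantile static dendrogram cut as a fraction of the
#'   tallest merge height.
#' @return an object of class `network_params`.
#' @export
network_params <- function(power_candidates = 1:20,
                           scale_free_r2_target = 0.8,
                           default_power = 6L,
                           min_module_size = 5L,
                           merge_correlation = 0.75,
                           correlation_kind = c("pearson", "spearman"),
                           cut_height_quantile = 0.99) {
  correlation_kind <- match.arg(correlation_kind)
  stopifnot(all(power_candidates >= 1), min_module_size >= 2,
            merge_correlation > 0, merge_correlation < 1,
            cut_height_quantile > 0, cut_height_quantile <= 1)
  structure(list(power_candidates = as.integer(power_candidates),
                 scale_free_r2_target = scale_free_r2_target,
                 default_power = as.integer(default_power),
                 min_module_size = as.integer(min_module_size),
                 merge_correlation = merge_correlation,
                 correlation_kind = correlation_kind,
                 cut_height_quantile = cut_height_quantile),
            class = "network_params")
}

module_colors <- function(n) {
  base <- c("turquoise", "blue", "brown", "yellow", "green", "magenta",
            "red", "pink", "purple", "black", "cyan", "salmon", "tan",
            "greenyellow", "midnightblue", "lightcyan", "grey60", "royalblue")
  if (n <= length(base)) base[seq_len(n)] else
    c(base, sprintf("module%02d", seq_len(n - length(base))))
}

#' Unsigned adjacency from a correlation matrix
#'
#' `a_ij = |corr_ij|^power`, so strongly anti-correlated lipids are as
#' adjacent as strongly correlated ones; diagonal is 1.
#'
#' @param corr symmetric correlation matrix with unit diagonal.
#' @param power integer soft-threshold power >= 1.
#' @return adjacency matrix in [0, 1].
#' @export
adjacency_unsigned <- function(corr, power) {
  if (power < 1) stop("'power' must be >= 1")
  stopifnot(isSymmetric(unname(corr)))
  a <- abs(corr)^power
  diag(a) <- 1
  a
}

#' Topological overlap similarity
#'
#' `w_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_{u != i,j} a_iu a_uj` and connectivity `k_i = sum_{u != i}
#' a_iu`; `w_ii = 1`. Two lipids are topologically similar when they are
#' adjacent and share neighbors. The clustering dissimilarity is `1 - w`.
#'
#' @param a symmetric adjacency matrix, entries in [0, 1], unit diagonal.
#' @return the TOM similarity matrix.
#' @export
tom_similarity <- function(a) {
  a <- as.matrix(a)
  if (!isSymmetric(unname(a))) stop("adjacency must be symmetric")
  stopifnot(all(a >= 0), all(a <= 1))
  a0 <- a
  diag(a0) <- 0
  k <- rowSums(a0)
  l <- a0 %*% a0                      # l_ij = sum_u a_iu a_uj, u != i, j
  kmin <- outer(k, k, pmin)
  w <- (l + a0) / (kmin + 1 - a0)
  diag(w) <- 1
  dimnames(w) <- dimnames(a)
  w
}

#' Select the soft-threshold power by the scale-free topology criterion
#'
#' For each candidate power, builds the unsigned adjacency, computes node
#' connectivities, bins them into 10 bins, regresses log10 frequency on
#' log10 mean connectivity, and records the signed fit
#' `R^2 * sign(slope)`. Returns the smallest candidate whose signed R^2
#' reaches the target; otherwise the data-free default.
#'
#' @param corr correlation matrix of the lipids (>= 10 lipids for a
#'   meaningful fit; fewer returns the default with a warning).
#' @param params a [network_params()].
#' @return integer power with the signed-R^2 profile in
#'   `attr(, "fit_profile")`.
#' @export
select_power <- function(corr, params = network_params()) {
  if (ncol(corr) < 10) {
    warning("fewer than 10 lipids; using default power ", params$default_power)
    out <- params$default_power
    attr(out, "fit_profile") <- NULL
    return(out)
  }
  profile <- vapply(params$power_candidates, function(p) {
    a <- adjacency_unsigned(corr, p)
    diag(a) <- 0
    k <- rowSums(a)
    if (max(k) == min(k)) return(NA_real_)
    cuts <- cut(k, breaks = 10)
    freq <- tabulate(cuts, nbins = 10)
    mean_k <- tapply(k, cuts, mean)
    keep <- freq > 0 & mean_k > 0
    if (sum(keep) < 3) return(NA_real_)
    fit <- stats::lm(log10(freq[keep]) ~ log10(mean_k[keep]))
    summary(fit)$r.squared * sign(stats::coef(fit)[2])
  }, numeric(1))
  names(profile) <- params$power_candidates
  hit <- which(!is.na(profile) & profile >= params$scale_free_r2_target)
  out <- if (length(hit)) params$power_candidates[min(hit)] else params$default_power
  attr(out, "fit_profile") <- profile
  out
}

#' First-principal-component summary of a lipid module (eigenlipid)
#'
#' The eigenlipid is the first PC of the samples-by-members submatrix
#' (columns centered), giving a one-dimensional abundance summary of the
#' module. Because the network is unsigned the PC sign is arbitrary; it is
#' fixed so the mean correlation between scores and member profiles is
#' nonnegative.
#'
#' @param m a `lipid_matrix` (or plain matrix, samples x lipids).
#' @param members species names of the module (>= 2).
#' @return object of class `eigenlipid`: list with `scores` (per-sample,
#'   mean 0), `variance_explained`, `loadings`, `members`.
#' @export
eigenlipid <- function(m, members) {
  stopifnot(length(members) >= 2, all(members %in% colnames(m)))
  sub <- unclass(m)[, members, drop = FALSE]
  if (all(apply(sub, 2, stats::sd) == 0)) stop("module submatrix is constant")
  pc <- stats::prcomp(sub, center = TRUE, scale. = FALSE)
  scores <- pc$x[, 1]
  ve <- pc$sdev[1]^2 / sum(pc$sdev^2)
  mean_cor <- mean(suppressWarnings(stats::cor(scores, sub)), na.rm = TRUE)
  s <- if (mean_cor < 0) -1 else 1
  structure(list(scores = s * scores, variance_explained = ve,
                 loadings = s * pc$rotation[, 1], members = members),
            class = "eigenlipid")
}

#' @export
print.eigenlipid <- function(x, ...) {
  cat(sprintf("eigenlipid over %d species; variance explained %.1f%%\n",
              length(x$members), 100 * x$variance_explained))
  invisible(x)
}

merge_modules <- function(m, assignments, merge_correlation) {
  repeat {
    mods <- setdiff(unique(assignments), "0")
    mods <- mods[table(assignments)[mods] >= 2]
    if (length(mods) < 2) return(assignments)
    scores <- sapply(mods, function(mm)
      eigenlipid(m, names(assignments)[assignments == mm])$scores)
    cc <- abs(suppressWarnings(stats::cor(scores)))
    diag(cc) <- 0
    if (max(cc) <= merge_correlation) return(assignments)
    idx <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    assignments[assignments == mods[idx[2]]] <- mods[idx[1]]
  }
}

#' Detect modules from a topological overlap matrix
#'
#' Average-linkage hierarchical clustering of the dissimilarity `1 - TOM`,
#' cut statically at `cut_height_quantile` times the tallest merge height.
#' Clusters smaller than `min_module_size` are unassigned ("grey");
#' modules whose eigenlipids correlate above `merge_correlation` (absolute
#' value) are merged iteratively; surviving modules are labeled by
#' descending size with the conventional color sequence (turquoise, blue,
#' brown, ...).
#'
#' @param tom TOM similarity matrix (see [tom_similarity()]).
#' @param m the samples x lipids matrix the TOM came from (needed for
#'   eigenlipid-based merging).
#' @param params a [network_params()].
#' @return named character vector: species -> module color ("grey" =
#'   unassigned); the dendrogram is attached as `attr(, "dendrogram")`.
#' @export
detect_modules <- function(tom, m, params = network_params()) {
  stopifnot(isSymmetric(unname(tom)), ncol(tom) == ncol(m))
  d <- stats::as.dist(1 - tom)
  dend <- stats::hclust(d, method = "average")
  cut_h <- params$cut_height_quantile * max(dend$height)
  cl <- stats::cutree(dend, h = cut_h)
  names(cl) <- colnames(tom)
  sizes <- table(cl)
  assignments <- ifelse(sizes[as.character(cl)] >= params$min_module_size,
                        as.character(cl), "0")
  names(assignments) <- colnames(tom)
  if (all(assignments == "0")) {
    warning("no cluster reached min_module_size; all lipids unassigned (grey)")
    out <- setNames(rep("grey", length(assignments)), names(assignments))
    attr(out, "dendrogram") <- dend
    return(out)
  }
  assignments <- merge_modules(m, assignments, params$merge_correlation)
  # re-apply the size rule after merging, then label by descending size
  sizes <- table(assignments[assignments != "0"])
  keep <- names(sizes)[sizes >= params$min_module_size]
  assignments[!(assignments %in% keep)] <- "0"
  ord <- names(sort(sizes[keep], decreasing = TRUE))
  colors <- setNames(module_colors(length(ord)), ord)
  out <- ifelse(assignments == "0", "grey", colors[assignments])
  names(out) <- names(assignments)
  attr(out, "dendrogram") <- dend
  out
}

#' Group-level statistics of a module eigenlipid
#'
#' One-way ANOVA of the eigenlipid scores across the six diagnosis-genotype
#' groups, plus all pairwise two-sided Mann-Whitney tests (the
#' non-parametric choice guards against skewed eigenlipid distributions),
#' with significance stars at p < 0.10 (*), < 0.05 (**), < 0.01 (***).
#'
#' @param e an [eigenlipid()].
#' @param info sample metadata with a `group` column, aligned with the
#'   scores.
#' @return object of class `module_group_stats`: list with `anova`
#'   (a `stat_test`), `pairwise` (symmetric p-value matrix, NA diagonal),
#'   and `stars` (character matrix).
#' @export
module_group_stats <- function(e, info) {
  stopifnot(inherits(e, "eigenlipid"), nrow(info) == length(e$scores))
  grp <- factor(as.character(info$group), levels = group_levels())
  present <- levels(grp)[table(grp) > 0]
  usable <- levels(grp)[table(grp) >= 2]
  an <- anova_oneway(e$scores[grp %in% usable],
                     droplevels(grp[grp %in% usable]))
  p <- matrix(NA_real_, length(present), length(present),
              dimnames = list(present, present))
  for (a in seq_along(present)) {
    for (b in seq_along(present)) {
      if (b <= a) next
      x <- e$scores[grp == present[a]]; y <- e$scores[grp == present[b]]
      if (length(x) < 2 || length(y) < 2) next
      p[a, b] <- p[b, a] <- mann_whitney(x, y)$p_value
    }
  }
  stars <- matrix("", nrow(p), ncol(p), dimnames = dimnames(p))
  stars[!is.na(p) & p < 0.10] <- "*"
  stars[!is.na(p) & p < 0.05] <- "**"
  stars[!is.na(p) & p < 0.01] <- "***"
  structure(list(anova = an, pairwise = p, stars = stars),
            class = "module_group_stats")
}

#' @export
print.module_group_stats <- function(x, ...) {
  cat(sprintf("module ANOVA across groups: F = %.3f, p = %.4g\n",
              x$anova$statistic, x$anova$p_value))
  cat("pairwise Mann-Whitney p-values:\n")
  print(round(x$pairwise, 4))
  invisible(x)
}

#' Classical (Torgerson) metric multidimensional scaling
#'
#' Double-centers the squared dissimilarities and embeds on the top
#' eigenpairs; used for low-dimensional views of the lipid network
#' (e.g. the first three MDS dimensions of 1 - TOM).
#'
#' @param dissimilarity symmetric matrix with zero diagonal.
#' @param dims embedding dimension.
#' @return coordinates matrix (items x dims); if fewer positive eigenvalues
#'   than `dims` exist the remaining columns are zero, with a warning.
#' @export
mds_projection <- function(dissimilarity, dims = 3) {
  d <- as.matrix(dissimilarity)
  stopifnot(isSymmetric(unname(d)), all(abs(diag(d)) < 1e-12))
  fit <- suppressWarnings(stats::cmdscale(d, k = dims, eig = TRUE))
  pts <- fit$points
  if (ncol(pts) < dims) {
    pts <- cbind(pts, matrix(0, nrow(pts), dims - ncol(pts)))
  }
  # treat numerically-zero eigenvalues as unsupported dimensions
  pos <- fit$eig[seq_len(dims)] > max(fit$eig) * 1e-8
  pos[is.na(pos)] <- FALSE
  if (any(!pos)) {
    warning("only ", sum(pos), " positive MDS dimensions; padding with zeros")
    pts[, !pos] <- 0
  }
  colnames(pts) <- paste0("MDS", seq_len(dims))
  rownames(pts) <- rownames(d)
  pts
}

#' Weighted lipid correlation network analysis
#'
#' The package's core fit. From a preprocessed samples-by-lipids matrix it
#' builds the lipid-lipid correlation matrix, picks (or accepts) a
#' soft-threshold power, forms the unsigned adjacency `|r|^power` and its
#' topological overlap, detects modules by average-linkage clustering of
#' `1 - TOM` with a static cut, size filter, and eigenlipid-based merging,
#' and summarizes each module by its eigenlipid. If sample metadata is
#' supplied, per-module group statistics (ANOVA + pairwise Mann-Whitney
#' across the six diagnosis-genotype groups) are computed as well.
#'
#' @param m a `lipid_matrix` (normally residualized) or plain numeric
#'   matrix, samples in rows.
#' @param info optional sample metadata with a `group` column.
#' @param params a [network_params()].
#' @param power optional fixed soft-threshold power; default selects by the
#'   scale-free criterion via [select_power()].
#' @return an object of class `wlcna`: list with elements `power`, `corr`,
#'   `adjacency`, `tom`, `assignments` (species -> color, "grey" =
#'   unassigned), `dendrogram`, `eigenlipids` (named list), `group_stats`
#'   (named list or NULL), `mds` (3-D coordinates of the lipids), `params`.
#' @seealso [eigenlipid()], [module_group_stats()], [mds_projection()]
#' @examples
#' cohort <- generate_lipidomics(synth_config(n_brain = 60, seed = 42), "brain")
#' z <- preprocess_lipids(cohort$lipids, cohort$samples,
#'                        covariates = c("batch", "sex", "age", "pmi"))
#' fit <- wlcna(z, cohort$samples)
#' fit
#' @export
wlcna <- function(m, info = NULL, params = network_params(), power = NULL) {
  x <- unclass(m)
  stopifnot(is.matrix(x), ncol(x) >= 3)
  corr <- suppressWarnings(stats::cor(x, method = params$correlation_kind))
  if (anyNA(corr)) stop("constant lipid(s) produce undefined correlations")
  if (is.null(power)) power <- select_power(corr, params)
  adjacency <- adjacency_unsigned(corr, as.integer(power))
  tom <- tom_similarity(adjacency)
  assignments <- detect_modules(tom, x, params)
  dend <- attr(assignments, "dendrogram")
  attr(assignments, "dendrogram") <- NULL
  mods <- setdiff(unique(assignments), "grey")
  mods <- mods[order(match(mods, module_colors(length(mods) + 6)))]
  eigenlipids <- lapply(setNames(mods, mods), function(col)
    eigenlipid(x, names(assignments)[assignments == col]))
  group_stats <- NULL
  if (!is.null(info) && length(mods)) {
    group_stats <- lapply(eigenlipids, module_group_stats, info = info)
  }
  structure(list(power = as.integer(power),
                 power_profile = attr(power, "fit_profile"),
                 corr = corr, adjacency = adjacency, tom = tom,
                 assignments = assignments, dendrogram = dend,
                 eigenlipids = eigenlipids, group_stats = group_stats,
                 mds = mds_projection(1 - tom, dims = 3),
                 params = params, n_samples = nrow(x)),
            class = "wlcna")
}

#' @export
print.wlcna <- function(x, ...) {
  sizes <- table(x$assignments)
  grey <- if ("grey" %in% names(sizes)) sizes[["grey"]] else 0L
  mods <- sizes[setdiff(names(sizes), "grey")]
  cat(sprintf("wlcna fit: %d lipids, %d samples, soft power %d\n",
              length(x$assignments), x$n_samples, x$power))
  cat(sprintf("  %d module(s), %d unassigned (grey)\n", length(mods), grey))
  if (length(mods)) {
    for (col in names(sort(mods, decreasing = TRUE))) {
      ve <- x$eigenlipids[[col]]$variance_explained
      p <- if (!is.null(x$group_stats))
        sprintf(", group ANOVA p = %.3g", x$group_stats[[col]]$anova$p_value)
      else ""
      cat(sprintf("  %-10s %3d lipids, eigenlipid VE %.1f%%%s\n",
                  col, mods[[col]], 100 * ve, p))
    }
  }
  invisible(x)
}

#' @export
summary.wlcna <- function(object, ...) {
  mods <- setdiff(unique(object$assignments), "grey")
  df <- data.frame(
    module = mods,
    size = vapply(mods, function(c) sum(object$assignments == c), integer(1)),
    variance_explained = vapply(mods, function(c)
      object$eigenlipids[[c]]$variance_explained, numeric(1)),
    anova_p = if (is.null(object$group_stats)) NA_real_ else
      vapply(mods, function(c) object$group_stats[[c]]$anova$p_value, numeric(1)),
    row.names = NULL)
  df[order(-df$size), ]
}

#' @export
plot.wlcna <- function(x, ...) {
  cols <- x$assignments[rownames(x$mds)]
  cols[!(cols %in% grDevices::colors())] <- "grey"
  graphics::plot(x$mds[, 1], x$mds[, 2], col = cols, pch = 19,
                 xlab = "MDS 1", ylab = "MDS 2",
                 main = "Lipid network modules (1 - TOM embedding)", ...)
  invisible(x)
}
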