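#' K-means with multiple restarts
#'
#' Lloyd-style k-means on Euclidean distances, best of `restarts` random
#' initializations by within-cluster sum of squares; deterministic given
#' the seed.
#'
#' @param m numeric matrix, samples in rows (e.g. the module-lipid
#'   submatrix of the processed data).
#' @param k number of clusters (>= 2, fewer than the number of distinct
#'   points).
#' @param seed integer seed.
#' @param restarts number of random restarts.
#' @return list with `assignments` (named integer vector, ids 1..k),
#'   `inertia` (total within-cluster sum of squares), `centers`, `k`.
#' @export
kmeans_restarts <- function(m, k, seed = 1L, restarts = 50L) {
  m <- as.matrix(m)
  if (k < 2) stop("'k' must be >= 2")
  n_distinct <- nrow(unique(m))
  if (k > n_distinct) stop("k exceeds the number of distinct points (", n_distinct, ")")
  set.seed(seed)
  fit <- suppressWarnings(
    stats::kmeans(m, centers = k, nstart = restarts, iter.max = 300,
                  algorithm = "Lloyd"))
  assignments <- setNames(fit$cluster, rownames(m))
  list(assignments = assignments, inertia = fit$tot.withinss,
       centers = fit$centers, k = as.integer(k))
}

#' Choose k by mean silhouette over a candidate range
#'
#' Runs [kmeans_restarts()] for each k, scores each solution by the mean
#' silhouette width on Euclidean distances, and picks the maximizer (ties
#' go to the smaller k). The inertia curve is retained for elbow
#' inspection. Solutions with maximum mean silhouette below 0.25 are
#' flagged as weak structure.
#'
#' @param m numeric matrix, samples in rows.
#' @param k_range candidate cluster counts (default 2:10).
#' @param seed integer seed.
#' @param restarts restarts per k.
#' @return object of class `cluster_result`: list with `k`, `assignments`,
#'   `silhouette_by_k`, `inertia_by_k`, `weak_structure`, `seed`,
#'   `restarts`.
#' @export
select_k <- function(m, k_range = 2:10, seed = 1L, restarts = 50L) {
  m <- as.matrix(m)
  if (nrow(m) <= max(k_range)) stop("need more samples than max(k_range)")
  d <- stats::dist(m)
  sil <- setNames(rep(NA_real_, length(k_range)), k_range)
  inertia <- setNames(rep(NA_real_, length(k_range)), k_range)
  fits <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    fit <- tryCatch(kmeans_restarts(m, k, seed = derive_seed(seed, paste0("k", k)),
                                    restarts = restarts),
                    error = function(e) NULL)
    if (is.null(fit)) {
      warning("k = ", k, " skipped: ", "clustering undefined for this k")
      next
    }
    sw <- tryCatch(cluster::silhouette(fit$assignments, d),
                   error = function(e) NULL)
    if (is.null(sw)) {
      warning("k = ", k, " skipped: silhouette undefined")
      next
    }
    sil[i] <- mean(sw[, "sil_width"])
    inertia[i] <- fit$inertia
    fits[[i]] <- fit
  }
  if (all(is.na(sil))) stop("silhouette undefined for every candidate k")
  best <- which(sil == max(sil, na.rm = TRUE))[1]   # ties -> smaller k
  structure(list(k = k_range[best], assignments = fits[[best]]$assignments,
                 silhouette_by_k = sil, inertia_by_k = inertia,
                 weak_structure = max(sil, na.rm = TRUE) < 0.25,
                 seed = seed, restarts = restarts),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("k-means: chose k = %d (mean silhouette %.3f%s)\n", x$k,
              max(x$silhouette_by_k, na.rm = TRUE),
              if (x$weak_structure) "; weak structure" else ""))
  invisible(x)
}

#' Per-cell Fisher enrichment of groups in clusters
#'
#' For every (cluster, diagnosis-genotype group) cell, tests the 2x2
#' marginal table [in cluster & in group, in cluster & not, not in cluster
#' & in group, neither] with a two-sided Fisher exact test. P-values are
#' deliberately uncorrected across cells; direction is enrichment
#' (odds ratio > 1) or depletion.
#'
#' @param assignments cluster id per sample (named vector or plain).
#' @param info sample metadata with a `group` column, aligned with
#'   `assignments`.
#' @return data.frame of class `enrichment_table`: cluster, group, count,
#'   odds_ratio, p_value, significant (p < 0.05), direction.
#' @export
enrichment_table <- function(assignments, info) {
  stopifnot(length(assignments) == nrow(info))
  grp <- as.character(info$group)
  N <- length(assignments)
  clusters <- sort(unique(assignments))
  groups <- group_levels()[group_levels() %in% grp]
  rows <- list()
  for (cl in clusters) {
    in_c <- assignments == cl
    for (g in groups) {
      in_g <- grp == g
      n_cg <- sum(in_c & in_g)
      tab <- matrix(c(n_cg, sum(in_c) - n_cg,
                      sum(in_g) - n_cg, N - sum(in_c) - sum(in_g) + n_cg),
                    2, 2, byrow = TRUE)
      if (sum(in_c) == 0) {
        ft <- list(p_value = 1, odds_ratio = NA_real_, effect_direction = 0)
      } else {
        ft <- fisher_2x2(tab)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, group = g, count = n_cg,
        odds_ratio = ft$odds_ratio, p_value = ft$p_value,
        significant = ft$p_value < 0.05,
        direction = if (isTRUE(ft$effect_direction < 0)) "depleted" else "enriched",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("enrichment_table", "data.frame")
  out
}
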