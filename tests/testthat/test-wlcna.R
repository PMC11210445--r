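test_that("unsigned adjacency is the powered absolute correlation", {
  corr <- matrix(c(1, -0.5, -0.5, 1), 2)
  expect_equal(adjacency_unsigned(corr, 1)[1, 2], 0.5)
  expect_equal(adjacency_unsigned(corr, 6)[1, 2], 0.5^6)
  pm <- matrix(c(1, -1, -1, 1), 2)
  expect_true(all(adjacency_unsigned(pm, 7) == 1))
  set.seed(1)
  x <- matrix(rnorm(200), 20)
  cc <- cor(x)
  a <- adjacency_unsigned(cc, 6)
  expect_equal(a[lower.tri(a)], abs(cc[lower.tri(cc)])^6, tolerance = 1e-15)
  expect_error(adjacency_unsigned(cc, 0), ">= 1")
})

test_that("topological overlap equals the naive triple-loop oracle", {
  ones <- matrix(1, 3, 3)
  expect_true(all(tom_similarity(ones) == 1))
  empty <- diag(3)
  w0 <- tom_similarity(empty)
  expect_equal(w0[upper.tri(w0)], rep(0, 3))

  set.seed(2)
  cc <- cor(matrix(rnorm(30 * 10), 30))
  a <- adjacency_unsigned(cc, 6)
  w <- tom_similarity(a)
  # independent O(n^3) oracle
  n <- nrow(a)
  oracle <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      l <- 0
      for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
      ki <- sum(a[i, -i]); kj <- sum(a[j, -j])
      oracle[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
    }
  }
  expect_lt(max(abs(w - oracle)), 1e-12)
  expect_true(all(w >= 0 & w <= 1))
  expect_error(tom_similarity(matrix(runif(9), 3)), "symmetric")
})

test_that("soft power selection respects its contract", {
  set.seed(3)
  cc <- cor(matrix(rnorm(50 * 30), 50))
  params <- network_params()
  # mean connectivity strictly decreasing in the power
  ks <- sapply(1:6, function(p) {
    a <- adjacency_unsigned(cc, p); diag(a) <- 0; mean(rowSums(a))
  })
  expect_true(all(diff(ks) < 0))
  p <- select_power(cc, params)
  expect_true(as.integer(p) %in% c(params$power_candidates, params$default_power))
  small <- cor(matrix(rnorm(40), 10, 4))
  expect_warning(p2 <- select_power(small, params), "fewer than 10")
  expect_equal(as.integer(p2), params$default_power)
})

test_that("module detection recovers clean planted blocks exactly", {
  bm <- block_matrix(100, c(20, 20, 20), rho = 0.9, seed = 4)
  fit <- wlcna(std_matrix(bm$x))
  mods <- setdiff(unique(fit$assignments), "grey")
  expect_equal(length(mods), 3)
  expect_equal(adjusted_rand_index(fit$assignments, bm$block), 1.0)
  # agreement with an independent ARI implementation
  skip_if_not_installed("mclust")
  expect_equal(adjusted_rand_index(fit$assignments, bm$block),
               mclust::adjustedRandIndex(fit$assignments, bm$block))
})

test_that("pure noise lipids stay overwhelmingly unassigned", {
  grey_frac <- sapply(1:10, function(s) {
    set.seed(s)
    x <- matrix(rnorm(100 * 40), 100)
    fit <- suppressWarnings(wlcna(std_matrix(x)))
    mean(fit$assignments == "grey")
  })
  expect_gte(mean(grey_frac >= 0.8), 0.8)
})

test_that("blocks below the minimum module size are left grey", {
  params <- network_params(min_module_size = 5)
  bm <- block_matrix(100, c(20, 4), rho = 0.95, seed = 5)  # second block too small
  fit <- suppressWarnings(wlcna(std_matrix(bm$x), params = params))
  small_block <- names(bm$block)[bm$block == 2]
  expect_true(all(fit$assignments[small_block] == "grey"))
  expect_true(all(fit$assignments[bm$block == 1] != "grey"))
})

test_that("module assignment is invariant to lipid input order", {
  bm <- block_matrix(80, c(15, 15, 10), rho = 0.8, seed = 6)
  fit <- wlcna(std_matrix(bm$x))
  for (s in 1:5) {
    set.seed(s)
    perm <- sample(ncol(bm$x))
    fit_p <- wlcna(std_matrix(bm$x[, perm]))
    expect_equal(adjusted_rand_index(fit_p$assignments[colnames(bm$x)],
                                     fit$assignments), 1.0)
  }
})

test_that("eigenlipid matches an independent eigendecomposition", {
  # module of identical columns: scores proportional to the column, VE = 1
  set.seed(7)
  v <- rnorm(30)
  m <- matrix(v, 30, 4, dimnames = list(paste0("s", 1:30), paste0("L", 1:4)))
  e <- eigenlipid(m, colnames(m))
  expect_equal(e$variance_explained, 1)
  expect_equal(abs(cor(e$scores, v)), 1, tolerance = 1e-12)
  expect_equal(mean(e$scores), 0, tolerance = 1e-12)

  bm <- block_matrix(50, c(8), rho = 0.7, seed = 8)
  e2 <- eigenlipid(bm$x, colnames(bm$x))
  # oracle: leading eigenvector of the covariance matrix
  cen <- scale(bm$x, scale = FALSE)
  eig <- eigen(cov(cen), symmetric = TRUE)
  scores_oracle <- cen %*% eig$vectors[, 1]
  aligned <- if (cor(scores_oracle, e2$scores) < 0) -scores_oracle else scores_oracle
  expect_lt(max(abs(e2$scores - aligned)), 1e-9)
  expect_equal(e2$variance_explained, eig$values[1] / sum(eig$values),
               tolerance = 1e-12)
  # sign convention: mean correlation with members is nonnegative
  expect_gte(mean(cor(e2$scores, bm$x)), 0)
  # flipping every member column negates scores up to re-alignment
  e3 <- eigenlipid(-bm$x, colnames(bm$x))
  expect_equal(e3$variance_explained, e2$variance_explained, tolerance = 1e-12)
  expect_equal(abs(cor(e3$scores, e2$scores)), 1, tolerance = 1e-9)
  expect_error(eigenlipid(matrix(1, 5, 2, dimnames = list(NULL, c("a", "b"))),
                          c("a", "b")), "constant")
})

test_that("module group statistics follow the figure conventions", {
  grp <- rep(group_levels(), each = 10)
  e <- structure(list(scores = rep(0, 60), variance_explained = 1,
                      loadings = 1, members = "L1"),
                 class = "eigenlipid")
  st <- module_group_stats(e, data.frame(group = grp))
  expect_equal(st$anova$p_value, 1)
  expect_true(all(st$stars == "" | is.na(st$pairwise)))
  expect_true(isSymmetric(st$pairwise))

  # planted NCI+/MCI- pattern: both shifted vs NCI-, similar to each other
  # (1.5 SD shift: Mann-Whitney power ~0.91 per comparison at n = 15)
  pattern <- sapply(1:20, function(s) {
    set.seed(s)
    sc <- rnorm(90)
    g <- rep(group_levels(), each = 15)
    sc[g %in% c("NCI+", "MCI-")] <- sc[g %in% c("NCI+", "MCI-")] + 1.5
    e <- structure(list(scores = sc, variance_explained = 1, loadings = 1,
                        members = "L1"), class = "eigenlipid")
    st <- module_group_stats(e, data.frame(group = g))
    c(vs_ref = st$pairwise["NCI+", "NCI-"] < 0.05 &
        st$pairwise["MCI-", "NCI-"] < 0.05,
      not_each_other = st$pairwise["NCI+", "MCI-"] >= 0.05)
  })
  expect_gte(mean(pattern["vs_ref", ]), 0.8)
  expect_gte(mean(pattern["not_each_other", ]), 0.8)
})

test_that("classical MDS reproduces exact Euclidean configurations", {
  pts <- c(0, 1, 3, 7)
  d <- as.matrix(dist(pts))
  xy <- mds_projection(d, dims = 1)
  expect_lt(max(abs(as.matrix(dist(xy[, 1])) - d)), 1e-9)
  # relabeling invariance up to permutation
  perm <- c(3, 1, 4, 2)
  xy2 <- mds_projection(d[perm, perm], dims = 1)
  expect_equal(abs(xy2[order(perm), 1]), abs(xy[, 1]), tolerance = 1e-9,
               ignore_attr = TRUE)
  # asking for more dimensions than the configuration supports pads zeros
  expect_warning(xyz <- mds_projection(d, dims = 3), "padding")
  expect_equal(ncol(xyz), 3)
  expect_true(all(xyz[, 3] == 0))
})

test_that("end-to-end planted module recovery meets the target over seeds", {
  ari <- sapply(1:10, function(s) {
    cfg <- synth_config(n_brain = 100, n_modules = 3, module_size = 20,
                        within_module_correlation = 0.7, lod_quantile = 0,
                        seed = s)
    co <- generate_lipidomics(cfg, "brain")
    z <- preprocess_lipids(co$lipids, co$samples, c("batch", "sex", "age", "pmi"))
    fit <- suppressWarnings(wlcna(z))
    adjusted_rand_index(fit$assignments, co$truth$modules)
  })
  expect_gte(mean(ari), 0.9)
})
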