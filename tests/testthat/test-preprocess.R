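make_table <- function(values, classes = NULL) {
  if (is.null(rownames(values))) rownames(values) <- paste0("s", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- paste0("PC.aa.C", 30 + 2 * seq_len(ncol(values)), ".0")
  if (is.null(classes)) classes <- setNames(rep("PC.aa", ncol(values)), colnames(values))
  lipid_table(values, classes)
}

test_that("missingness filter removes strictly above the threshold", {
  v <- matrix(1, 6, 3)
  v[1, 1] <- NA                 # 1/6 = 16.7% -> retained
  v[1:2, 2] <- NA               # 2/6 = 33.3% -> removed
  tab <- make_table(v)
  kept <- filter_lipids(tab, 0.17)
  expect_equal(ncol(kept$values), 2)
  expect_identical(attr(kept, "removed"), colnames(tab$values)[2])

  # boundary: exactly 17/100 missing is retained (removal needs strictly >)
  v2 <- matrix(1, 100, 2)
  v2[1:17, 1] <- NA
  kept2 <- filter_lipids(make_table(v2), 0.17)
  expect_equal(ncol(kept2$values), 2)
  v2[18, 1] <- NA               # 18% -> removed
  expect_equal(ncol(filter_lipids(make_table(v2), 0.17)$values), 1)

  v3 <- matrix(NA_real_, 4, 2)
  expect_error(filter_lipids(make_table(v3)), "all 2 species")
})

test_that("zero imputation replaces exactly the missing cells", {
  v <- matrix(1:12 + 0, 4, 3)
  tab <- make_table(v)
  expect_identical(impute_zero(tab)$values, tab$values)
  v[2, 3] <- NA
  out <- impute_zero(make_table(v))
  expect_equal(out$values[2, 3], 0)
  expect_equal(out$values[-2, ], tab$values[-2, ])
  # end to end: zeros introduced equal censored cells surviving the filter
  co <- generate_lipidomics(synth_config(n_brain = 120, lod_quantile = 0.05,
                                         seed = 3), "brain")
  filt <- filter_lipids(co$lipids)
  n_missing <- sum(is.na(filt$values))
  imputed <- impute_zero(filt)
  expect_equal(sum(imputed$values == 0), n_missing)
})

test_that("mole percent rescales each sample to sum 100", {
  out <- mole_percent(make_table(matrix(c(2, 3, 5), 1, 3)))
  expect_equal(as.numeric(out), c(20, 30, 50))
  expect_identical(stage(out), "molpercent")
  single <- mole_percent(make_table(matrix(c(7, 0, 0), 1, 3)))
  expect_equal(as.numeric(single), c(100, 0, 0))
  set.seed(1)
  r <- mole_percent(make_table(matrix(rexp(200) + 0.01, 20, 10)))
  expect_true(all(abs(rowSums(r) - 100) < 1e-9))
  bad <- matrix(c(1, 0, 1, 0), 2, 2)
  rownames(bad) <- c("ok", "empty")
  expect_error(mole_percent(make_table(bad)), "empty")
})

test_that("standardization yields exact per-species z-scores", {
  m <- mole_percent(make_table(matrix(c(1, 2, 3, 3, 2, 1), 3, 2)))
  z <- standardize(m)
  expect_equal(unname(z[, 1]), c(-1, 0, 1))
  expect_identical(stage(z), "standardized")
  set.seed(2)
  r <- standardize(mole_percent(make_table(matrix(rexp(300) + 0.01, 30, 10))))
  expect_true(all(abs(colMeans(r)) < 1e-9))
  expect_true(all(abs(apply(r, 2, sd) - 1) < 1e-9))
  # stage machine refuses to standardize twice
  expect_error(standardize(z), "stage 'molpercent'")
  # proportional columns are constant after mole percent
  const <- mole_percent(make_table(matrix(c(1, 2, 3, 2, 4, 6), 3, 2)))
  expect_error(standardize(const), "zero-variance")
})

test_that("OLS residualization is exact and orthogonal to the design", {
  set.seed(3)
  n <- 60
  info <- toy_info(sample(group_levels(), n, TRUE), seed = 3)
  z <- std_matrix(matrix(rnorm(n * 5), n))
  # intercept-only: column centering
  cen <- residualize(z, info, character(0))
  expect_equal(unclass(cen), scale(unclass(z), scale = FALSE),
               ignore_attr = TRUE)
  res <- residualize(z, info, c("batch", "sex", "age", "pmi"))
  expect_identical(dim(res), dim(z))
  X <- model.matrix(~ factor(batch) + sex + age + pmi, info)
  for (j in 2:ncol(X)) {
    expect_lt(abs(cor(res[, 1], X[, j])), 1e-9)
  }
  # independent oracle: explicit normal-equations solve
  beta <- solve(crossprod(X), crossprod(X, unclass(z)))
  expect_equal(unclass(res), unclass(z) - X %*% beta, ignore_attr = TRUE,
               tolerance = 1e-9)
  info$age2 <- info$age
  expect_error(residualize(z, info, c("age", "age2")), "collinear")
  expect_error(residualize(std_matrix(matrix(rnorm(15), 3, 5)),
                           info[1:3, ], c("age", "pmi")), "n <= p")
})

test_that("mixed-model residualization recovers the donor intercept variance", {
  # planted donor SD 1.0, residual SD 0.5, 50 donors x 4 visits
  est <- sapply(1:20, function(s) {
    set.seed(s)
    u <- rnorm(50)
    y <- u[rep(1:50, each = 4)] + rnorm(200, 0, 0.5)
    m <- std_matrix(matrix(y, 200, 1))
    r <- residualize_mixed(m, data.frame(donor_id = rep(sprintf("D%02d", 1:50),
                                                        each = 4)),
                           character(0))
    attr(r, "donor_sd")[[1]]
  })
  expect_gt(mean(est), 0.7)
  expect_lt(mean(est), 1.3)
  # null: zero planted donor variance stays near zero
  null_var <- sapply(1:10, function(s) {
    set.seed(100 + s)
    m <- std_matrix(matrix(rnorm(200), 200, 1))
    r <- residualize_mixed(m, data.frame(donor_id = rep(sprintf("D%02d", 1:50),
                                                        each = 4)),
                           character(0))
    attr(r, "donor_sd")[[1]]^2
  })
  expect_lte(mean(null_var), 0.1)
})

test_that("mixed model degenerates to OLS when every donor has one visit", {
  set.seed(4)
  info <- toy_info(sample(group_levels(), 40, TRUE), seed = 4)
  z <- std_matrix(matrix(rnorm(40 * 3), 40))
  expect_message(rm_ <- residualize_mixed(z, info, c("age", "sex"),
                                          donor_ids = info$donor_id),
                 "falling back to OLS")
  expect_equal(unclass(rm_), unclass(residualize(z, info, c("age", "sex"))),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("the full preprocessing pipeline preserves shape and logs lineage", {
  co <- generate_lipidomics(synth_config(n_brain = 60, seed = 8), "brain")
  out <- preprocess_lipids(co$lipids, co$samples, c("batch", "sex", "age", "pmi"))
  expect_identical(stage(out), "residualized")
  expect_equal(nrow(out), 60)
  lin <- attr(out, "lineage")
  expect_true(any(grepl("mole_percent", lin)))
  expect_true(any(grepl("residualize", lin)))
})
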