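test_that("Welch t matches its closed form and handles degenerate input", {
  eq <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)

  x <- c(1, 2, 3, 4); y <- c(3, 4, 5, 6)
  tt <- welch_t(x, y)
  # closed-form Welch oracle
  se <- sqrt(var(x) / 4 + var(y) / 4)
  t_oracle <- (mean(x) - mean(y)) / se
  df_oracle <- se^4 / ((var(x) / 4)^2 / 3 + (var(y) / 4)^2 / 3)
  expect_equal(tt$statistic, t_oracle, tolerance = 1e-12)
  expect_equal(tt$df, df_oracle, tolerance = 1e-12)
  expect_equal(tt$df, 6)
  expect_equal(tt$p_value, 2 * pt(-abs(t_oracle), df_oracle), tolerance = 1e-12)

  sw <- welch_t(y, x)
  expect_equal(sw$statistic, -tt$statistic)
  expect_equal(sw$p_value, tt$p_value)
  expect_error(welch_t(c(1, 1, 1), c(2, 2, 2)), "degenerate")
  expect_equal(welch_t(c(5, 5), c(5, 5))$p_value, 1)
})

test_that("differential screen has power against planted shifts and controls type I", {
  flagged <- sapply(1:20, function(s) {
    set.seed(s)
    g <- rep(c("NCI-", "MCI-"), each = 40)
    m <- matrix(rnorm(80 * 10), 80, 10,
                dimnames = list(paste0("s", 1:80), paste0("L", 1:10)))
    m[g == "MCI-", ] <- m[g == "MCI-", ] + 1       # 1 SD shift in all 10 lipids
    sc <- screen_differential(std_matrix(m), data.frame(group = g))
    sum(sc$significant[sc$group == "MCI-"])
  })
  expect_gte(mean(flagged), 8)

  type1 <- sapply(1:10, function(s) {
    set.seed(100 + s)
    g <- rep(group_levels(), c(30, 10, 20, 10, 15, 15))
    m <- matrix(rnorm(100 * 100), 100, 100,
                dimnames = list(paste0("s", 1:100), paste0("L", 1:100)))
    sc <- screen_differential(std_matrix(m), data.frame(group = g))
    mean(sc$significant)
  })
  expect_lt(abs(mean(type1) - 0.05), 0.03)

  # identical values in both groups are never flagged
  m <- matrix(rep(rnorm(4), 2), 8, 1, byrow = FALSE,
              dimnames = list(paste0("s", 1:8), "L1"))
  m[5:8, 1] <- m[1:4, 1]
  sc <- screen_differential(std_matrix(m),
                            data.frame(group = rep(c("NCI-", "AD+"), each = 4)))
  expect_false(any(sc$significant))
})

test_that("mean group correlation equals the brute-force pair average", {
  # two groups of identical profiles correlate at exactly +1
  prof <- c(3, 1, 4, 1, 5, 9, 2, 6)
  m <- rbind(prof, prof, prof, prof)
  dimnames(m) <- list(paste0("s", 1:4), paste0("L", 1:8))
  info <- data.frame(group = rep(c("NCI-", "AD+"), each = 2))
  gc <- mean_group_correlation(std_matrix(m), info)
  expect_equal(gc$values["NCI-", "AD+"], 1)
  # rank reversal gives exactly -1
  m2 <- rbind(prof, prof, -prof, -prof)
  dimnames(m2) <- dimnames(m)
  gc2 <- mean_group_correlation(std_matrix(m2), info)
  expect_equal(gc2$values["NCI-", "AD+"], -1)

  # enumeration oracle on a random 3-group toy, 2 samples each
  set.seed(5)
  m3 <- matrix(rnorm(6 * 5), 6, 5,
               dimnames = list(paste0("s", 1:6), paste0("L", 1:5)))
  grp <- rep(c("NCI-", "MCI+", "AD-"), each = 2)
  gc3 <- mean_group_correlation(std_matrix(m3), data.frame(group = grp))
  for (a in c("NCI-", "MCI+", "AD-")) {
    for (b in c("NCI-", "MCI+", "AD-")) {
      ia <- which(grp == a); ib <- which(grp == b)
      pairs <- if (a == b) list(c(ia[1], ia[2])) else
        as.list(as.data.frame(t(expand.grid(ia, ib))))
      oracle <- mean(vapply(pairs, function(p)
        cor(m3[p[1], ], m3[p[2], ], method = "spearman"), numeric(1)))
      expect_equal(gc3$values[a, b], oracle, tolerance = 1e-12)
    }
  }
  # permutation invariance to sample order
  perm <- sample(6)
  gc4 <- mean_group_correlation(std_matrix(m3[perm, ]),
                                data.frame(group = grp[perm]))
  expect_equal(gc4$values, gc3$values, tolerance = 1e-12)
})

test_that("BH adjustment follows the step-up formula", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  # hand-computed step-up: q_(i) = min_{j >= i} m p_(j) / j
  expect_equal(bh_adjust(p), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(6)
  p2 <- runif(50)
  q <- bh_adjust(p2)
  expect_true(all(diff(q[order(p2)]) > -1e-12))     # monotone in sorted order
  perm <- sample(50)
  expect_equal(bh_adjust(p2[perm]), q[perm])        # permutation equivariant
  expect_error(bh_adjust(c(0.1, NA)), "finite")
})

test_that("Mann-Whitney agrees with full enumeration and its approximation", {
  r <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p_value, mw_enum_p(c(1, 2), c(3, 4)))
  expect_equal(r$p_value, 1 / 3, tolerance = 1e-12)
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # exact enumeration oracle on random small samples
  set.seed(7)
  for (i in 1:3) {
    x <- rnorm(4); y <- rnorm(5)
    expect_equal(mann_whitney(x, y)$p_value, mw_enum_p(x, y), tolerance = 1e-12)
  }
  # normal approximation close to exact at n = m = 8
  set.seed(8)
  dev <- replicate(10, {
    x <- rnorm(8); y <- rnorm(8)
    exact <- mann_whitney(x, y)$p_value        # total 16 -> enumerated
    approx <- suppressWarnings(wilcox.test(x, y, exact = FALSE,
                                           correct = TRUE)$p.value)
    abs(exact - approx)
  })
  expect_lt(max(dev), 0.02)
  expect_error(mann_whitney(numeric(0), 1), "nonempty")
})

test_that("Fisher exact test uses the probability-mass two-sided rule", {
  t1 <- matrix(c(3, 1, 1, 3), 2, byrow = TRUE)
  expect_equal(fisher_2x2(t1)$p_value, fisher_enum_p(t1), tolerance = 1e-12)
  expect_equal(fisher_2x2(t1)$p_value, 0.485714, tolerance = 1e-4)
  prop <- matrix(c(4, 6, 2, 3), 2, byrow = TRUE)
  expect_equal(fisher_2x2(prop)$p_value, 1)
  t2 <- matrix(c(5, 0, 0, 5), 2, byrow = TRUE)
  expect_equal(fisher_2x2(t2)$p_value, 2 / choose(10, 5), tolerance = 1e-12)
  expect_error(fisher_2x2(matrix(c(-1, 1, 1, 1), 2)), "nonnegative")
})

test_that("chi-square independence matches the textbook statistic", {
  same <- matrix(c(10, 20, 5, 10, 20, 5), 2, 3, byrow = TRUE)
  r <- chi_square_independence(same)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  set.seed(9)
  tab <- matrix(rpois(6, 20), 2, 3)
  r2 <- chi_square_independence(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  x2 <- sum((tab - E)^2 / E)
  expect_equal(r2$statistic, x2, tolerance = 1e-12)
  expect_equal(r2$df, 2)
  expect_equal(r2$p_value, pchisq(x2, 2, lower.tail = FALSE), tolerance = 1e-12)
  expect_error(chi_square_independence(matrix(c(0, 0, 1, 2), 2)), "positive")
})

test_that("summary-based and raw one-way ANOVA are algebraically identical", {
  eqm <- anova_from_summary(c(5, 5), c(3, 3), c(1, 2))
  expect_equal(eqm$statistic, 0)
  expect_equal(eqm$p_value, 1)
  set.seed(10)
  values <- rnorm(60)
  groups <- rep(letters[1:4], each = 15)
  raw <- anova_oneway(values, groups)
  summ <- anova_from_summary(tapply(values, groups, length),
                             tapply(values, groups, mean),
                             tapply(values, groups, sd))
  expect_equal(raw$statistic, summ$statistic, tolerance = 1e-10)
  expect_equal(raw$p_value, summ$p_value, tolerance = 1e-10)
  # two groups: F equals the square of the pooled t statistic
  x <- rnorm(12); y <- rnorm(15) + 0.5
  f2 <- anova_oneway(c(x, y), rep(c("a", "b"), c(12, 15)))
  tp <- t.test(x, y, var.equal = TRUE)
  expect_equal(f2$statistic, unname(tp$statistic)^2, tolerance = 1e-10)
  expect_error(anova_oneway(1:3, c("a", "a", "b")), "< 2 values")
})

test_that("one-way ANOVA power matches the noncentral-F oracle", {
  hits <- sapply(1:50, function(s) {
    set.seed(s)
    g <- rep(group_levels(), each = 20)
    v <- rnorm(120)
    v[g == "MCI+"] <- v[g == "MCI+"] + 1
    anova_oneway(v, g)$p_value < 0.05
  })
  # oracle: exact power from the noncentral F distribution
  mu <- c(0, 0, 0, 1, 0, 0)
  lambda <- 20 * sum((mu - mean(mu))^2)
  power_oracle <- 1 - pf(qf(0.95, 5, 114), 5, 114, ncp = lambda)
  expect_lt(abs(mean(hits) - power_oracle), 0.15)
  expect_gte(mean(hits), 0.75)
})
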