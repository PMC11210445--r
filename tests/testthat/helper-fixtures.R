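# small in-code fixtures shared across test files

# standardized-stage matrix wrapper for driving single stages in isolation
std_matrix <- function(values) {
  if (is.null(rownames(values))) rownames(values) <- paste0("s", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- paste0("L", seq_len(ncol(values)))
  as_lipid_matrix(values, "standardized")
}

# samples x lipids matrix with block-correlated columns:
# block b shares a latent factor at correlation rho
block_matrix <- function(n, block_sizes, rho, seed = 1) {
  set.seed(seed)
  L <- sum(block_sizes)
  block <- rep(seq_along(block_sizes), block_sizes)
  f <- matrix(rnorm(n * length(block_sizes)), n)
  x <- sqrt(rho) * f[, block] + sqrt(1 - rho) * matrix(rnorm(n * L), n)
  dimnames(x) <- list(paste0("s", seq_len(n)), paste0("L", seq_len(L)))
  list(x = x, block = setNames(block, colnames(x)))
}

# minimal sample-info frame with all six diagnosis-genotype groups
toy_info <- function(group, seed = 1) {
  set.seed(seed)
  n <- length(group)
  data.frame(
    sample_id = paste0("s", seq_len(n)), donor_id = paste0("s", seq_len(n)),
    visit = 1L, group = factor(group, levels = group_levels()),
    age = rnorm(n, 90, 6), sex = sample(c("male", "female"), n, TRUE),
    pmi = rgamma(n, 4, scale = 2.5), education = rnorm(n, 15, 3),
    batch = sample(1:3, n, TRUE), cgrs = rnorm(n, 0, 0.05),
    stringsAsFactors = FALSE)
}

# exact two-sided Fisher p for a 2x2 table by hypergeometric enumeration
fisher_enum_p <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact two-sided Mann-Whitney p by enumerating all group labelings
mw_enum_p <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  u_stat <- function(idx) {
    xs <- pooled[idx]; ys <- pooled[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- u_stat(seq_len(nx))
  combs <- utils::combn(length(pooled), nx)
  us <- apply(combs, 2, u_stat)
  mu <- length(x) * length(y) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}
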