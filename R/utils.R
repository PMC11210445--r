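#' Diagnosis-genotype group labels
#'
#' The six cohort groups: clinical diagnosis (NCI, MCI, AD) crossed with
#' APOE-e4 carrier status ("+" = carrier). "NCI-" is the reference group
#' throughout.
#'
#' @export
group_levels <- function() c("NCI-", "NCI+", "MCI-", "MCI+", "AD-", "AD+")

#' Derive a stage-specific child seed from a master seed
#'
#' Stable hash of the stage name mixed with the master seed, so each
#' stochastic stage of a run can be re-executed in isolation. Result is
#' always a valid 32-bit integer seed.
#'
#' @param seed master integer seed.
#' @param stage character stage name.
#' @return integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  code <- utf8ToInt(stage)
  h <- sum(code * seq_along(code))
  as.integer((abs(as.numeric(seed)) * 1009 + h * 9973) %% 2147483629)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 means identical partitions (up to label permutation), 0 is the
#' expectation under independent random partitions.
#'
#' @param a,b label vectors of equal length.
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

# coerce metadata columns to the types the model matrices expect
as_sample_frame <- function(info) {
  info <- as.data.frame(info)
  for (col in c("diagnosis", "apoe4", "sex")) {
    if (col %in% names(info)) info[[col]] <- factor(info[[col]])
  }
  if ("batch" %in% names(info)) info$batch <- factor(info$batch)
  if ("group" %in% names(info)) info$group <- factor(info$group, levels = group_levels())
  info
}

stop_if_not_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != round(x)) {
    stop(sprintf("'%s' must be a positive integer count", name), call. = FALSE)
  }
}
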