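#' Construct a lipid abundance table
#'
#' A samples-by-species abundance matrix with lipid class annotations and
#' explicit missingness (NA marks values below the limit of detection).
#' This is the raw container that enters the preprocessing pipeline.
#'
#' @param values numeric matrix, samples in rows (rownames = sample ids),
#'   lipid species in columns (colnames = species names, e.g. "PC.aa.C36.0").
#'   Entries must be nonnegative where present; NA marks missing.
#' @param lipid_class named character vector mapping each species to one of
#'   "C", "PC.aa", "PC.ae", "SM", "lysoPC".
#' @param donor_ids character vector of donor ids, one per sample (defaults
#'   to the sample ids for single-draw designs).
#' @param visit integer visit index per sample (serum repeated draws).
#' @return an object of class `lipid_table`.
#' @export
lipid_table <- function(values, lipid_class, donor_ids = rownames(values),
                        visit = rep(1L, nrow(values))) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("'values' needs sample ids as rownames and species names as colnames")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(values))) stop("duplicate lipid species names")
  if (any(values < 0, na.rm = TRUE)) stop("abundances must be nonnegative where present")
  lipid_class <- lipid_class[colnames(values)]
  if (anyNA(lipid_class)) stop("every species needs a lipid class annotation")
  bad <- setdiff(unique(lipid_class), c("C", "PC.aa", "PC.ae", "SM", "lysoPC"))
  if (length(bad)) stop("unknown lipid class(es): ", paste(bad, collapse = ", "))
  structure(
    list(values = values, lipid_class = lipid_class,
         sample_ids = rownames(values),
         donor_ids = as.character(donor_ids), visit = as.integer(visit)),
    class = "lipid_table")
}

#' @export
print.lipid_table <- function(x, ...) {
  cat(sprintf("lipid_table: %d samples x %d species\n",
              nrow(x$values), ncol(x$values)))
  cat("  classes:", paste(sprintf("%s=%d", names(table(x$lipid_class)),
                                  table(x$lipid_class)), collapse = ", "), "\n")
  miss <- mean(is.na(x$values))
  cat(sprintf("  missing: %.1f%%; donors: %d\n", 100 * miss,
              length(unique(x$donor_ids))))
  invisible(x)
}

#' @export
dim.lipid_table <- function(x) dim(x$values)

# subset a lipid_table by species (keeps all samples)
subset_lipids <- function(table, keep) {
  lipid_table(table$values[, keep, drop = FALSE],
              table$lipid_class[keep],
              donor_ids = table$donor_ids, visit = table$visit)
}

#' Read a cohort from `lipids.csv` + `samples.csv`
#'
#' `lipids.csv` has columns `sample_id, donor_id, visit` followed by one
#' column per species (empty field = missing). `samples.csv` carries the
#' per-sample metadata (see [generate_lipidomics()] for the schema). Lipid
#' classes are inferred from the species name prefix.
#'
#' @param lipids_path,samples_path file paths.
#' @return list with elements `lipids` (a [lipid_table()]) and `samples`
#'   (a data.frame).
#' @export
read_cohort <- function(lipids_path, samples_path) {
  raw <- utils::read.csv(lipids_path, check.names = FALSE)
  stopifnot(all(c("sample_id", "donor_id", "visit") %in% names(raw)[1:3]))
  species <- setdiff(names(raw), c("sample_id", "donor_id", "visit"))
  values <- as.matrix(raw[, species, drop = FALSE])
  rownames(values) <- raw$sample_id
  cls <- infer_lipid_class(species)
  lt <- lipid_table(values, cls, donor_ids = raw$donor_id, visit = raw$visit)
  samples <- utils::read.csv(samples_path, check.names = FALSE)
  list(lipids = lt, samples = as_sample_frame(samples))
}

infer_lipid_class <- function(species) {
  cls <- rep(NA_character_, length(species))
  cls[startsWith(species, "PC.aa")] <- "PC.aa"
  cls[startsWith(species, "PC.ae")] <- "PC.ae"
  cls[startsWith(species, "SM")] <- "SM"
  cls[startsWith(species, "lysoPC")] <- "lysoPC"
  cls[is.na(cls) & grepl("^C[0-9]", species)] <- "C"
  if (anyNA(cls)) stop("cannot infer lipid class for: ",
                       paste(species[is.na(cls)], collapse = ", "))
  names(cls) <- species
  cls
}
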