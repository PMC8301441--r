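#' Construct a genotype matrix
#'
#' The central in-memory container of the package: per-site alternate-allele
#' dosages (0, 1, 2 or `NA` for missing) for a set of sexed individuals,
#' with every site assigned to exactly one gene. Sites are rows, samples are
#' columns. All model fitting, calling and permutation functions consume
#' this class.
#'
#' @param sites data.frame with columns `gene_id`, `pos`, `ref`, `alt`
#'   (one row per variant site; `pos` is the 1-based VCF position, kept as a
#'   label only).
#' @param geno integer matrix, `nrow(sites)` x `nrow(samples)`, values in
#'   `{0, 1, 2, NA}` (alternate-allele dosage).
#' @param samples data.frame with columns `sample_id`, `sex` (`"F"`/`"M"`),
#'   as returned by [read_sex_map()].
#' @param drop_empty drop sites with no non-missing genotype (with a
#'   warning) instead of erroring. Every retained site has at least one
#'   non-missing genotype.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `sites`, `geno`, `samples`.
#' @seealso [read_vcf()], [filter_biallelic()], [filter_site_coverage()]
#' @export
genotype_matrix <- function(sites, geno, samples, drop_empty = TRUE) {
  stopifnot(is.data.frame(sites), is.data.frame(samples))
  req <- c("gene_id", "pos", "ref", "alt")
  if (!all(req %in% names(sites))) {
    stop("`sites` must have columns: ", paste(req, collapse = ", "))
  }
  samples <- validate_sex_map(samples, require_both = FALSE)
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(geno) != nrow(sites) || ncol(geno) != nrow(samples)) {
    stop("genotype matrix dimensions (", nrow(geno), "x", ncol(geno),
         ") inconsistent with ", nrow(sites), " sites and ",
         nrow(samples), " samples")
  }
  bad <- !(geno %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("genotypes must be 0, 1, 2 or NA")
  if (any(sites$pos < 1, na.rm = TRUE)) stop("positions must be >= 1")
  n_typed <- rowSums(!is.na(geno))
  if (any(n_typed == 0)) {
    if (!drop_empty) stop("site(s) with no non-missing genotype")
    k <- sum(n_typed == 0)
    warning(k, " site(s) with no non-missing genotype dropped")
    keep <- n_typed > 0
    sites <- sites[keep, , drop = FALSE]
    geno <- geno[keep, , drop = FALSE]
  }
  rownames(sites) <- NULL
  dimnames(geno) <- list(NULL, samples$sample_id)
  structure(
    list(sites = sites, geno = geno, samples = samples),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  n <- sex_counts(x)
  cat("genotype_matrix: ", nrow(x$sites), " sites in ",
      length(unique(x$sites$gene_id)), " genes; ",
      nrow(x$samples), " samples (", n[["F"]], "F/", n[["M"]], "M); ",
      sprintf("%.1f%%", 100 * mean(is.na(x$geno))), " missing\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

#' Female/male sample counts of a genotype matrix or sex map
#'
#' @param x a `genotype_matrix` or a sex-map data.frame.
#' @return Named integer vector with elements `F` and `M`.
#' @export
sex_counts <- function(x) {
  sex <- if (inherits(x, "genotype_matrix")) x$samples$sex else x$sex
  c(F = sum(sex == "F"), M = sum(sex == "M"))
}

## Subset sites by a logical/integer index, keeping samples untouched.
## Filters only ever drop rows; genotype values are never altered.
subset_sites <- function(mat, keep) {
  stopifnot(inherits(mat, "genotype_matrix"))
  out <- mat
  out$sites <- mat$sites[keep, , drop = FALSE]
  rownames(out$sites) <- NULL
  out$geno <- mat$geno[keep, , drop = FALSE]
  out
}

## Swap every sample's sex label (F <-> M). The XY model on swapped labels
## is by construction identical to the ZW model on the original labels.
swap_sexes <- function(mat) {
  stopifnot(inherits(mat, "genotype_matrix"))
  mat$samples$sex <- ifelse(mat$samples$sex == "F", "M", "F")
  mat
}

## Replace the sex labels with an arbitrary labeling (used by the
## permutation scan). `labels` is a character vector over samples.
relabel_sexes <- function(mat, labels) {
  stopifnot(length(labels) == nrow(mat$samples),
            all(labels %in% c("F", "M")))
  mat$samples$sex <- as.character(labels)
  mat
}
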