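## Biological calls from a fitted model: sex-linked genes by posterior
## threshold, and individual sites matching the fixed heterogametic-SNP
## pattern (every heterogametic-sex individual heterozygous, every
## homogametic-sex individual homozygous for the same allele).

#' Caller configuration
#'
#' @param posterior_threshold sex-linkage posterior above which a gene is
#'   called (strict inequality), in (0, 1). Default 0.8.
#' @param max_missing_per_sex missing individuals tolerated per sex in the
#'   fixed-pattern scan. Default 1, matching the observation that single
#'   individuals occasionally fail to genotype.
#' @return list of class `caller_config`.
#' @export
caller_config <- function(posterior_threshold = 0.8,
                          max_missing_per_sex = 1) {
  stopifnot(posterior_threshold > 0, posterior_threshold < 1,
            max_missing_per_sex >= 0)
  structure(list(posterior_threshold = posterior_threshold,
                 max_missing_per_sex = max_missing_per_sex),
            class = "caller_config")
}

#' Call sex-linked genes from a fitted heterogametic model
#'
#' Returns the genes whose sex-linkage posterior strictly exceeds the
#' threshold, sorted by descending posterior. A `NOSEX` fit is rejected:
#' its posteriors are identically zero by construction.
#'
#' @param fit a [fit_model()] result with model `"XY"` or `"ZW"`.
#' @param config a [caller_config()].
#' @return data.frame with columns `gene_id`, `posterior`, `n_sites`.
#' @export
call_sexlinked <- function(fit, config = caller_config()) {
  stopifnot(inherits(fit, "sexsys_fit"), inherits(config, "caller_config"))
  if (fit$model == "NOSEX") {
    stop("sex-linked genes can only be called from an XY or ZW fit")
  }
  pg <- fit$per_gene
  keep <- pg$posterior > config$posterior_threshold
  out <- pg[keep, c("gene_id", "posterior", "n_sites")]
  out <- out[order(-out$posterior, out$gene_id), ]
  rownames(out) <- NULL
  out
}

#' Flag sites with the fixed heterogametic-SNP pattern
#'
#' A site matches when every non-missing heterogametic-sex individual is
#' heterozygous (dosage 1) and every non-missing homogametic-sex
#' individual is homozygous for one and the same allele (all dosage 0 or
#' all dosage 2 -- VCF allele labeling is arbitrary with respect to the
#' gametologs), with at most `max_missing_per_sex` missing genotypes in
#' each sex and at least one typed individual per sex. This is the
#' signature of a fixed gametolog difference.
#'
#' @param mat a [genotype_matrix()].
#' @param het_sex heterogametic sex, `"F"` (ZW) or `"M"` (XY).
#' @param config a [caller_config()].
#' @return data.frame with columns `gene_id`, `pos`,
#'   `n_het_heterogametic`, `n_hom_homogametic` for the flagged sites.
#' @export
scan_fixed_pattern <- function(mat, het_sex, config = caller_config()) {
  stopifnot(inherits(mat, "genotype_matrix"), het_sex %in% c("F", "M"),
            inherits(config, "caller_config"))
  n <- sex_counts(mat)
  if (n[["F"]] == 0 || n[["M"]] == 0) stop("both sexes must be present")
  is_het <- mat$samples$sex == het_sex
  g_het <- mat$geno[, is_het, drop = FALSE]
  g_hom <- mat$geno[, !is_het, drop = FALSE]
  miss_het <- rowSums(is.na(g_het))
  miss_hom <- rowSums(is.na(g_hom))
  typed_het <- ncol(g_het) - miss_het
  typed_hom <- ncol(g_hom) - miss_hom
  n_het1 <- rowSums(g_het == 1L, na.rm = TRUE)
  n_hom0 <- rowSums(g_hom == 0L, na.rm = TRUE)
  n_hom2 <- rowSums(g_hom == 2L, na.rm = TRUE)
  flagged <- miss_het <= config$max_missing_per_sex &
    miss_hom <= config$max_missing_per_sex &
    typed_het > 0 & typed_hom > 0 &
    n_het1 == typed_het &
    (n_hom0 == typed_hom | n_hom2 == typed_hom)
  out <- data.frame(
    gene_id = mat$sites$gene_id[flagged],
    pos = mat$sites$pos[flagged],
    n_het_heterogametic = n_het1[flagged],
    n_hom_homogametic = pmax(n_hom0, n_hom2)[flagged],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Evaluate gene calls against simulator ground truth
#'
#' @param calls data.frame from [call_sexlinked()] (column `gene_id`), or
#'   a character vector of called gene ids.
#' @param truth data.frame with columns `gene_id`, `is_sexlinked` (the
#'   `genes` element of a [simulate_genotypes()] truth table). Every
#'   called gene must be present.
#' @return list with `recall` (called true / all true), `false_call_rate`
#'   (called false / all called; 0 when nothing is called) and a
#'   `confusion` vector (tp, fp, fn, tn).
#' @export
evaluate_calls <- function(calls, truth) {
  called <- if (is.data.frame(calls)) calls$gene_id else as.character(calls)
  stopifnot(is.data.frame(truth),
            all(c("gene_id", "is_sexlinked") %in% names(truth)))
  unknown <- setdiff(called, truth$gene_id)
  if (length(unknown)) {
    stop("called gene(s) absent from truth: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  pos <- truth$gene_id[truth$is_sexlinked]
  neg <- truth$gene_id[!truth$is_sexlinked]
  tp <- length(intersect(called, pos))
  fp <- length(intersect(called, neg))
  fn <- length(setdiff(pos, called))
  tn <- length(setdiff(neg, called))
  list(
    recall = if (length(pos) == 0) NA_real_ else tp / length(pos),
    false_call_rate = if (length(called) == 0) 0 else fp / length(called),
    confusion = c(tp = tp, fp = fp, fn = fn, tn = tn)
  )
}
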