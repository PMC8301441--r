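## VCF and sex-map input, site filters, and plain-text writers.
##
## The package consumes genotypes (GT fields) already called against
## gene/transcript reference sequences: CHROM is interpreted as the gene
## identifier. Variant calling itself, BAM processing and genotype
## likelihoods (PL/GL) are out of scope.

validate_sex_map <- function(map, require_both = TRUE) {
  if (!is.data.frame(map) || !all(c("sample_id", "sex") %in% names(map))) {
    stop("sex map must be a data.frame with columns `sample_id`, `sex`")
  }
  map$sample_id <- as.character(map$sample_id)
  map$sex <- toupper(trimws(as.character(map$sex)))
  if (nrow(map) == 0) stop("sex map is empty")
  if (anyDuplicated(map$sample_id)) {
    stop("duplicate sample id(s): ",
         paste(unique(map$sample_id[duplicated(map$sample_id)]),
               collapse = ", "))
  }
  bad <- !(map$sex %in% c("F", "M"))
  if (any(bad)) {
    stop("unknown sex token(s): ", paste(unique(map$sex[bad]), collapse = ", "),
         " (expected F or M)")
  }
  if (require_both && (!any(map$sex == "F") || !any(map$sex == "M"))) {
    stop("sex map must contain at least one F and one M sample")
  }
  rownames(map) <- NULL
  map[c("sample_id", "sex")]
}

#' Read a sample-to-sex map
#'
#' Reads a two-column TSV mapping sample identifiers to sex. A header line
#' is optional and detected by its sex-column value not being an F/M token.
#' Sex tokens are case-insensitive.
#'
#' @param path path to a TSV file (`sample<TAB>sex`).
#' @return data.frame with columns `sample_id` and `sex` (values `"F"` or
#'   `"M"`).
#' @examples
#' tsv <- tempfile()
#' writeLines(c("F1\tF", "F2\tF", "M1\tM", "M2\tM"), tsv)
#' read_sex_map(tsv)
#' @export
read_sex_map <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", comment.char = "#",
                           blank.lines.skip = TRUE, quote = "")
  if (ncol(raw) < 2) stop("sex map must have two tab-separated columns")
  raw <- raw[, 1:2]
  names(raw) <- c("sample_id", "sex")
  # drop an optional header row
  if (nrow(raw) > 0 && !toupper(trimws(raw$sex[1])) %in% c("F", "M") &&
      grepl("sex", raw$sex[1], ignore.case = TRUE)) {
    raw <- raw[-1, , drop = FALSE]
  }
  validate_sex_map(raw, require_both = FALSE)
}

## GT string -> alternate-allele dosage. Phased separators are treated as
## unphased; any allele index > 0 counts as alternate (multi-allelic
## records are removed later by filter_biallelic).
gt_to_dosage <- function(gt) {
  gt <- sub(":.*", "", gt)            # strip trailing FORMAT fields if any
  gt <- gsub("|", "/", gt, fixed = TRUE)
  out <- rep(NA_integer_, length(gt))
  known <- !is.na(gt) & gt != "." & gt != "./."
  if (!any(known)) return(out)
  parts <- strsplit(gt[known], "/", fixed = TRUE)
  dos <- vapply(parts, function(a) {
    if (length(a) != 2 || any(!grepl("^([0-9]+|\\.)$", a))) {
      return(NA_integer_)  # malformed or half-missing -> handled below
    }
    if (any(a == ".")) return(NA_integer_)
    sum(a != "0")
  }, integer(1))
  bad <- vapply(parts, function(a) {
    length(a) != 2 || any(!grepl("^([0-9]+|\\.)$", a))
  }, logical(1))
  if (any(bad)) {
    stop("malformed GT field(s): ",
         paste(utils::head(unique(gt[known][bad]), 3), collapse = ", "))
  }
  out[known] <- dos
  out
}

#' Read a VCF of biallelic SNP genotypes into a genotype matrix
#'
#' Loads GT fields for the samples listed in `sex_map` (in that order) and
#' converts them to alternate-allele dosages: `0/0` -> 0, `0/1` or `1/0`
#' -> 1, `1/1` -> 2, `./.` -> `NA`. Phased genotypes (`|`) are treated as
#' unphased. CHROM is taken as the gene identifier, matching a variant
#' call made against per-gene reference sequences; `gene_map` can override
#' this for genome-coordinate VCFs. Extra VCF samples not in the sex map
#' are ignored with a warning. Sites left without any non-missing genotype
#' are dropped.
#'
#' @param path path to a VCF (plain text or bgzipped) with GT fields.
#' @param sex_map data.frame from [read_sex_map()]; every `sample_id` must
#'   be present in the VCF.
#' @param gene_map optional data.frame with columns `gene_id`, `chrom`,
#'   `start`, `end` reassigning sites to genes by coordinate overlap;
#'   sites not covered are dropped.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, sex_map, gene_map = NULL) {
  sex_map <- validate_sex_map(sex_map, require_both = FALSE)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(vcf@fix) == 0) stop("VCF contains no variant records: ", path)
  fix <- vcfR::getFIX(vcf)
  vcf_samples <- colnames(vcf@gt)[-1]
  missing <- setdiff(sex_map$sample_id, vcf_samples)
  if (length(missing)) {
    stop("sample(s) in sex map absent from VCF: ",
         paste(missing, collapse = ", "))
  }
  extra <- setdiff(vcf_samples, sex_map$sample_id)
  if (length(extra)) {
    warning(length(extra), " VCF sample(s) not in the sex map ignored: ",
            paste(utils::head(extra, 5), collapse = ", "))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[, sex_map$sample_id, drop = FALSE]
  geno <- apply(gt, 2, gt_to_dosage)
  geno <- matrix(as.integer(geno), nrow = nrow(gt),
                 dimnames = list(NULL, sex_map$sample_id))
  sites <- data.frame(
    gene_id = as.character(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]),
    ref = as.character(fix[, "REF"]),
    alt = as.character(fix[, "ALT"]),
    stringsAsFactors = FALSE
  )
  if (!is.null(gene_map)) {
    stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(gene_map)))
    hit <- rep(NA_character_, nrow(sites))
    for (j in seq_len(nrow(gene_map))) {
      sel <- sites$gene_id == gene_map$chrom[j] &
        sites$pos >= gene_map$start[j] & sites$pos <= gene_map$end[j]
      hit[sel] <- gene_map$gene_id[j]
    }
    keep <- !is.na(hit)
    if (!all(keep)) {
      warning(sum(!keep), " site(s) outside the gene map dropped")
    }
    sites <- sites[keep, , drop = FALSE]
    geno <- geno[keep, , drop = FALSE]
    sites$gene_id <- hit[keep]
  }
  genotype_matrix(sites, geno, sex_map)
}

#' Keep only informative biallelic SNP sites
#'
#' Removes sites with more than one alternate allele, symbolic or
#' multi-nucleotide (indel) alleles, and sites monomorphic after
#' genotyping (only one allele observed among the non-missing genotypes:
#' all dosage 0 or all dosage 2). Surviving genotype values are never
#' altered.
#'
#' @param mat a [genotype_matrix()].
#' @return The filtered `genotype_matrix` (possibly with zero sites).
#' @export
filter_biallelic <- function(mat) {
  stopifnot(inherits(mat, "genotype_matrix"))
  ref <- mat$sites$ref
  alt <- mat$sites$alt
  snp <- !grepl(",", alt, fixed = TRUE) &
    nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  ref_seen <- rowSums(mat$geno < 2L, na.rm = TRUE) > 0
  alt_seen <- rowSums(mat$geno > 0L, na.rm = TRUE) > 0
  subset_sites(mat, snp & ref_seen & alt_seen)
}

#' Drop sites under-genotyped in either sex
#'
#' Removes sites with fewer than `min_typed_per_sex` non-missing genotypes
#' in females or in males. The default of 1 only requires each sex to be
#' observed at all; a threshold of 0 is the identity.
#'
#' @param mat a [genotype_matrix()].
#' @param min_typed_per_sex non-negative integer.
#' @return The filtered `genotype_matrix`.
#' @export
filter_site_coverage <- function(mat, min_typed_per_sex = 1) {
  stopifnot(inherits(mat, "genotype_matrix"), min_typed_per_sex >= 0)
  if (min_typed_per_sex == 0) return(mat)
  is_f <- mat$samples$sex == "F"
  typed_f <- rowSums(!is.na(mat$geno[, is_f, drop = FALSE]))
  typed_m <- rowSums(!is.na(mat$geno[, !is_f, drop = FALSE]))
  subset_sites(mat, typed_f >= min_typed_per_sex &
                 typed_m >= min_typed_per_sex)
}

#' Write a genotype matrix as a plain-text VCF
#'
#' Emits a minimal VCF 4.2 with GT-only FORMAT fields. The header carries
#' no timestamp, so identical matrices produce byte-identical files.
#'
#' @param mat a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(mat, path) {
  stopifnot(inherits(mat, "genotype_matrix"))
  gt_code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(mat$geno), ncol(mat$geno))
  ok <- !is.na(mat$geno)
  gt[ok] <- gt_code[mat$geno[ok] + 1L]
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=sexsys-", as.character(utils::packageVersion("sexsys"))),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", mat$samples$sample_id), collapse = "\t")
  )
  body <- paste(mat$sites$gene_id, mat$sites$pos, ".",
                mat$sites$ref, mat$sites$alt, ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a genotype matrix as a dosage TSV
#'
#' Sites as rows (`gene_id`, `pos`, `ref`, `alt`, then one column per
#' sample), missing genotypes as `NA`.
#'
#' @param mat a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dosage_tsv <- function(mat, path) {
  stopifnot(inherits(mat, "genotype_matrix"))
  df <- cbind(mat$sites, as.data.frame(mat$geno))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
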