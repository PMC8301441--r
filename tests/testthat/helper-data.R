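# Small in-code fixtures shared across test files.

make_sex_map <- function(n_f = 4, n_m = 4) {
  data.frame(
    sample_id = c(sprintf("F%d", seq_len(n_f)), sprintf("M%d", seq_len(n_m))),
    sex = c(rep("F", n_f), rep("M", n_m)),
    stringsAsFactors = FALSE
  )
}

# genotype matrix from a plain dosage matrix (rows = sites); genes of
# `sites_per_gene` consecutive sites
make_matrix <- function(geno, n_f = 4, n_m = 4, sites_per_gene = 1,
                        gene_ids = NULL) {
  geno <- rbind(geno)
  s <- nrow(geno)
  if (is.null(gene_ids)) {
    gene_ids <- sprintf("g%02d", rep(seq_len(ceiling(s / sites_per_gene)),
                                     each = sites_per_gene))[seq_len(s)]
  }
  sites <- data.frame(
    gene_id = gene_ids,
    pos = as.integer(stats::ave(seq_len(s), gene_ids, FUN = seq_along)),
    ref = "A", alt = "T", stringsAsFactors = FALSE
  )
  genotype_matrix(sites, geno, make_sex_map(n_f, n_m))
}

# random small genotype matrix for property tests (both sexes present,
# no all-missing sites by construction of genotype_matrix)
random_matrix <- function(n_sites = 12, n_f = 3, n_m = 3,
                          sites_per_gene = 2, p_missing = 0.1) {
  n <- n_f + n_m
  geno <- matrix(sample(0:2, n_sites * n, replace = TRUE), n_sites, n)
  geno[matrix(stats::runif(n_sites * n) < p_missing, n_sites, n)] <- NA
  geno[rowSums(!is.na(geno)) == 0, 1] <- 1L   # keep every site informative
  make_matrix(geno, n_f, n_m, sites_per_gene)
}

# hand-written VCF fixture: 3 biallelic records, 8 samples, known dosages
write_fixture_vcf <- function(path = tempfile(fileext = ".vcf")) {
  sm <- make_sex_map()
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sm$sample_id), collapse = "\t"),
    paste(c("geneA", "10", ".", "A", "G", ".", "PASS", ".", "GT",
            "0/0", "0/1", "1/1", "./.", "0/0", "1|0", "0/0", "0/1"),
          collapse = "\t"),
    paste(c("geneA", "25", ".", "C", "T", ".", "PASS", ".", "GT",
            "0/1", "0/1", "0/1", "0/1", "0/0", "0/0", "0/0", "0/0"),
          collapse = "\t"),
    paste(c("geneB", "7", ".", "G", "A", ".", "PASS", ".", "GT",
            "1/1", "1/1", "1/1", "1/1", "1/1", "1/1", "0/1", "1/1"),
          collapse = "\t")
  )
  writeLines(lines, path)
  path
}

# expected dosages of the fixture above, sites x samples
fixture_dosages <- function() {
  rbind(c(0, 1, 2, NA, 0, 1, 0, 1),
        c(1, 1, 1, 1, 0, 0, 0, 0),
        c(2, 2, 2, 2, 2, 2, 1, 2))
}

write_sex_map_tsv <- function(map = make_sex_map(),
                              path = tempfile(fileext = ".tsv"),
                              header = FALSE) {
  lines <- paste(map$sample_id, map$sex, sep = "\t")
  if (header) lines <- c("sample\tsex", lines)
  writeLines(lines, path)
  path
}
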