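## Seeded simulator of genotype matrices with the statistical structure
## the inference assumes, plus ground truth, so every stage of the
## pipeline is testable without sequencing data. Genes are drawn
## sex-linked with probability rho_true; autosomal sites follow HWE at a
## uniform random allele frequency; sex-linked sites either carry a fixed
## gametolog difference (x = 0, y = 1: the heterogametic sex is always
## heterozygous) or segregate on both chromosomes (recent recombination
## suppression means few fixed differences, hence f_fixed < 1). A
## symmetric genotyping-error channel and uniform missingness are then
## applied.

#' Simulation parameters
#'
#' Defaults emulate a desk-scale RNA-seq genotyping study: 500 genes
#' averaging 3 SNPs each, four individuals per sex, a 20% sex-linked gene
#' fraction of which half the sites carry a fixed gametolog difference,
#' 1% genotyping error and 5% missingness.
#'
#' @param n_genes number of genes.
#' @param mean_sites mean SNPs per gene; per-gene counts are
#'   `1 + Poisson(mean_sites - 1)` so every gene has at least one site.
#' @param n_f,n_m females/males simulated.
#' @param true_system `"NOSEX"`, `"XY"` or `"ZW"`.
#' @param rho_true sex-linked gene fraction (forced to 0 for NOSEX).
#' @param f_fixed fraction of sex-linked sites with a fixed gametolog
#'   difference (`x = 0`, `y = 1`; the sex-limited allele is coded as
#'   ALT -- allele labeling is arbitrary).
#' @param freq_range range of segregating allele frequencies (p, x, y).
#' @param epsilon_true genotyping-error probability.
#' @param missing_rate per-genotype missingness probability.
#' @param seed mandatory integer seed; one global stream drives the whole
#'   simulation, so equal seeds give byte-identical outputs.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(n_genes = 500, mean_sites = 3, n_f = 4, n_m = 4,
                       true_system = c("ZW", "XY", "NOSEX"),
                       rho_true = 0.2, f_fixed = 0.5,
                       freq_range = c(0.05, 0.95), epsilon_true = 0.01,
                       missing_rate = 0.05, seed) {
  true_system <- match.arg(true_system)
  if (missing(seed)) stop("`seed` is mandatory")
  stopifnot(n_genes >= 1, mean_sites >= 1, n_f >= 1, n_m >= 1,
            rho_true >= 0, rho_true <= 1,
            f_fixed >= 0, f_fixed <= 1,
            length(freq_range) == 2, freq_range[1] >= 0,
            freq_range[2] <= 1, freq_range[1] <= freq_range[2],
            epsilon_true >= 0, epsilon_true < 1,
            missing_rate >= 0, missing_rate < 1)
  if (true_system == "NOSEX") rho_true <- 0
  structure(list(
    n_genes = as.integer(n_genes), mean_sites = mean_sites,
    n_f = as.integer(n_f), n_m = as.integer(n_m),
    true_system = true_system, rho_true = rho_true, f_fixed = f_fixed,
    freq_range = freq_range, epsilon_true = epsilon_true,
    missing_rate = missing_rate, seed = as.integer(seed)
  ), class = "sim_params")
}

## error channel + missingness on a dosage matrix, consuming the current
## RNG stream (no reseeding here)
.apply_noise <- function(geno, epsilon, missing_rate) {
  n <- length(geno)
  if (epsilon > 0) {
    flip <- !is.na(geno) & stats::runif(n) < epsilon
    shift <- sample(c(1L, 2L), n, replace = TRUE)
    geno[flip] <- (geno[flip] + shift[flip]) %% 3L
  }
  if (missing_rate > 0) {
    geno[stats::runif(n) < missing_rate] <- NA_integer_
  }
  geno
}

#' Simulate a genotype matrix with ground truth
#'
#' See [sim_params()] for the generative model. Sites that end up with no
#' non-missing genotype are dropped from the matrix (they would carry no
#' information and violate the matrix invariant) but remain in the truth
#' table. Fully reproducible given the seed.
#'
#' @param params a [sim_params()].
#' @return list with elements `matrix` (a [genotype_matrix()]) and
#'   `truth` (list of data.frames `genes` (`gene_id`, `is_sexlinked`) and
#'   `sites` (`gene_id`, `pos`, `class`, `p`, `x`, `y`), where `class` is
#'   one of `autosomal`, `sexlinked_fixed`, `sexlinked_segregating`).
#' @export
simulate_genotypes <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  n_f <- params$n_f
  n_m <- params$n_m
  n_ind <- n_f + n_m
  samples <- data.frame(
    sample_id = c(sprintf("F%02d", seq_len(n_f)),
                  sprintf("M%02d", seq_len(n_m))),
    sex = c(rep("F", n_f), rep("M", n_m)),
    stringsAsFactors = FALSE
  )
  het_sex <- switch(params$true_system, ZW = "F", XY = "M", NOSEX = NA)
  is_het <- !is.na(het_sex) & samples$sex == het_sex

  gene_ids <- sprintf("g%04d", seq_len(params$n_genes))
  n_sites_g <- 1L + stats::rpois(params$n_genes,
                                 max(0, params$mean_sites - 1))
  linked <- stats::runif(params$n_genes) < params$rho_true

  site_gene <- rep(gene_ids, n_sites_g)
  site_linked <- rep(linked, n_sites_g)
  S <- length(site_gene)
  pos <- unlist(lapply(n_sites_g, function(k) 100L * seq_len(k)),
                use.names = FALSE)

  runif_range <- function(k) stats::runif(k, params$freq_range[1],
                                          params$freq_range[2])
  class <- rep("autosomal", S)
  p <- rep(NA_real_, S)
  x <- rep(NA_real_, S)
  y <- rep(NA_real_, S)
  p[!site_linked] <- runif_range(sum(!site_linked))
  fixed <- site_linked & stats::runif(S) < params$f_fixed
  class[fixed] <- "sexlinked_fixed"
  class[site_linked & !fixed] <- "sexlinked_segregating"
  x[fixed] <- 0
  y[fixed] <- 1
  seg <- site_linked & !fixed
  x[seg] <- runif_range(sum(seg))
  y[seg] <- runif_range(sum(seg))

  geno <- matrix(NA_integer_, S, n_ind)
  for (s in seq_len(S)) {
    if (!site_linked[s]) {
      geno[s, ] <- stats::rbinom(n_ind, 2L, p[s])
    } else {
      geno[s, !is_het] <- stats::rbinom(sum(!is_het), 2L, x[s])
      geno[s, is_het] <- stats::rbinom(sum(is_het), 1L, x[s]) +
        stats::rbinom(sum(is_het), 1L, y[s])
    }
  }
  geno <- .apply_noise(geno, params$epsilon_true, params$missing_rate)

  sites <- data.frame(gene_id = site_gene, pos = pos,
                      ref = "A", alt = "T", stringsAsFactors = FALSE)
  keep <- rowSums(!is.na(geno)) > 0
  mat <- genotype_matrix(sites[keep, , drop = FALSE],
                         geno[keep, , drop = FALSE], samples)
  truth <- list(
    genes = data.frame(gene_id = gene_ids, is_sexlinked = linked,
                       stringsAsFactors = FALSE),
    sites = data.frame(gene_id = site_gene, pos = pos, class = class,
                       p = p, x = x, y = y, stringsAsFactors = FALSE)
  )
  list(matrix = mat, truth = truth, params = params)
}

#' Apply the genotyping-error channel and missingness to a matrix
#'
#' Independently per non-missing genotype: with probability `epsilon`
#' replace the dosage by one of the other two uniformly, then with
#' probability `missing_rate` set it missing. Reproducible given `seed`.
#'
#' @param mat a [genotype_matrix()].
#' @param epsilon,missing_rate rates in \[0, 1).
#' @param seed integer seed.
#' @return The perturbed `genotype_matrix` (all-missing sites dropped
#'   with a warning, as per the matrix invariant).
#' @export
inject_errors <- function(mat, epsilon, missing_rate, seed) {
  stopifnot(inherits(mat, "genotype_matrix"),
            epsilon >= 0, epsilon < 1, missing_rate >= 0, missing_rate < 1)
  set.seed(seed)
  geno <- .apply_noise(mat$geno, epsilon, missing_rate)
  genotype_matrix(mat$sites, geno, mat$samples)
}

#' Write a simulation to disk
#'
#' Emits `sim.vcf` (plain-text VCF 4.2), `sex_map.tsv`, `truth_genes.tsv`,
#' `truth_sites.tsv` and `params.json` (echoing the full [sim_params()]
#' including the seed, so the run can be reproduced exactly). No output
#' carries a timestamp: re-running with the same parameters reproduces
#' identical files.
#'
#' @param sim result of [simulate_genotypes()].
#' @param out_dir output directory (created if absent).
#' @return Named character vector of the five file paths, invisibly.
#' @export
write_simulation <- function(sim, out_dir) {
  stopifnot(is.list(sim), !is.null(sim$matrix), !is.null(sim$truth))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    vcf = file.path(out_dir, "sim.vcf"),
    sex_map = file.path(out_dir, "sex_map.tsv"),
    truth_genes = file.path(out_dir, "truth_genes.tsv"),
    truth_sites = file.path(out_dir, "truth_sites.tsv"),
    params = file.path(out_dir, "params.json")
  )
  write_genotype_vcf(sim$matrix, paths[["vcf"]])
  utils::write.table(sim$matrix$samples, paths[["sex_map"]], sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(sim$truth$genes, paths[["truth_genes"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$sites, paths[["truth_sites"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(sim$params), paths[["params"]],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
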