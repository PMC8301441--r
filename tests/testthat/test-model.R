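# genotype probability laws, grid marginals, EM fit, model selection

test_that("HWE genotype probabilities match closed form and error channel", {
  expect_equal(genotype_prob_hwe(0.5, 0), c("0" = 0.25, "1" = 0.5, "2" = 0.25))
  expect_equal(genotype_prob_hwe(1, 0), c("0" = 0, "1" = 0, "2" = 1))
  # hand-applied 3x3 error channel on (0.25, 0.5, 0.25) at eps = 0.03
  expect_equal(unname(genotype_prob_hwe(0.5, 0.03)),
               c(0.25375, 0.49250, 0.25375), tolerance = 1e-12)
  expect_error(genotype_prob_hwe(1.2, 0))
  expect_error(genotype_prob_hwe(0.5, 0.5))
})

test_that("gametolog law: fixed difference forces heterozygosity; x=y=p reduces to HWE", {
  expect_equal(unname(genotype_prob_gametolog(0, 1, 0)), c(0, 1, 0))
  expect_equal(unname(genotype_prob_gametolog(0.3, 1, 0)), c(0, 0.7, 0.3),
               tolerance = 1e-12)
  for (p in c(0, 0.2, 0.5, 0.9)) {
    expect_equal(genotype_prob_gametolog(p, p, 0.07),
                 genotype_prob_hwe(p, 0.07), tolerance = 1e-12)
  }
})

test_that("probability triples are normalized over 1000 random draws", {
  set.seed(101)
  for (i in 1:1000) {
    e <- runif(1, 0, 0.49)
    s1 <- sum(genotype_prob_hwe(runif(1), e))
    s2 <- sum(genotype_prob_gametolog(runif(1), runif(1), e))
    expect_true(abs(s1 - 1) < 1e-12 && abs(s2 - 1) < 1e-12)
  }
})

test_that("site marginals reproduce small hand sums", {
  g3 <- freq_grid(support = c(0, 0.5, 1))
  # one heterozygote, eps 0: (0 + 0.5 + 0)/3
  expect_equal(site_marginal_autosomal(c(1, NA, NA), 0, g3), log(1 / 6))
  # impossible under a fixed-alt grid: degenerate -Inf
  g1 <- freq_grid(support = c(1), weights = 1)
  expect_equal(site_marginal_autosomal(c(0, NA), 0, g1), -Inf)
  # single homogametic G=2 on the 2-point grid: log(1/2)
  g2 <- freq_grid(support = c(0, 1))
  expect_equal(
    site_marginal_sexlinked(c(NA, NA, NA, NA, 2, NA, NA, NA),
                            rep(c("F", "M"), each = 4), "F", 0, g2),
    log(1 / 2))
  expect_error(site_marginal_autosomal(rep(NA, 4), 0.01), "non-missing")
})

test_that("site marginals agree with brute-force summation to 1e-12", {
  set.seed(102)
  grid <- freq_grid(5)
  sexes <- rep(c("F", "M"), each = 4)
  for (i in 1:25) {
    g <- sample(c(0:2, NA), 8, replace = TRUE)
    if (all(is.na(g))) g[1] <- 1
    e <- runif(1, 0, 0.2)
    expect_equal(site_marginal_autosomal(g, e, grid),
                 oracle_site_auto(g, e, grid), tolerance = 1e-12)
    for (hs in c("F", "M")) {
      expect_equal(site_marginal_sexlinked(g, sexes, hs, e, grid),
                   oracle_site_sl(g, sexes, hs, e, grid), tolerance = 1e-12)
    }
  }
  # full default grid against the oracle on one 8-genotype site
  gdef <- freq_grid()
  g <- c(0, 1, 1, 2, 0, 0, 1, NA)
  expect_equal(site_marginal_autosomal(g, 0.01, gdef),
               oracle_site_auto(g, 0.01, gdef), tolerance = 1e-12)
})

test_that("sex-linked marginal beats autosomal on a fixed heterogametic pattern", {
  g <- c(1, 1, 1, 1, 0, 0, 0, 0)   # females het, males hom-ref
  sexes <- rep(c("F", "M"), each = 4)
  grid <- freq_grid()
  expect_gt(site_marginal_sexlinked(g, sexes, "F", 0, grid),
            site_marginal_autosomal(g, 0, grid))
  # het_sex F on data equals het_sex M on sex-swapped data
  swapped <- ifelse(sexes == "F", "M", "F")
  set.seed(103)
  for (i in 1:10) {
    gg <- sample(c(0:2, NA), 8, replace = TRUE)
    if (all(is.na(gg))) gg[1] <- 1
    expect_equal(site_marginal_sexlinked(gg, sexes, "F", 0.02, grid),
                 site_marginal_sexlinked(gg, swapped, "M", 0.02, grid))
  }
})

test_that("gene components accumulate site marginals additively", {
  set.seed(104)
  mat <- random_matrix(n_sites = 10, sites_per_gene = 2, p_missing = 0.1)
  grid <- freq_grid(5)
  comp <- gene_component_logliks(mat, 0.03, "F", grid)
  oc <- oracle_components(mat, 0.03, "F", grid)
  expect_equal(comp$log_A, oc$log_A, tolerance = 1e-10)
  expect_equal(comp$log_Z, oc$log_Z, tolerance = 1e-10)
  # splitting a gene into two sub-genes and recombining adds exactly
  split <- mat
  split$sites$gene_id[2] <- "gX"
  cs <- gene_component_logliks(split, 0.03, "F", grid)
  expect_equal(cs$log_A[cs$gene_id == "g01"] + cs$log_A[cs$gene_id == "gX"],
               comp$log_A[comp$gene_id == "g01"], tolerance = 1e-10)
  # single-site gene equals its site marginal
  one <- make_matrix(rbind(c(0, 1, 2, 0, 1, 0, NA, 2)), sites_per_gene = 1)
  c1 <- gene_component_logliks(one, 0.05, "F", grid)
  expect_equal(c1$log_A, site_marginal_autosomal(one$geno[1, ], 0.05, grid))
})

test_that("ascertainment terms match brute force", {
  grid <- freq_grid(5)
  for (e in c(0.001, 0.05)) {
    comp_none <- gene_component_logliks(
      make_matrix(rbind(c(0, 1, 2, 0, 1, 0, NA, 2))), e, "F", grid)
    comp_poly <- gene_component_logliks(
      make_matrix(rbind(c(0, 1, 2, 0, 1, 0, NA, 2))), e, "F", grid,
      ascertainment = "polymorphic")
    expect_equal(comp_poly$log_A,
                 comp_none$log_A - oracle_poly_auto(7, e, grid),
                 tolerance = 1e-12)
    expect_equal(comp_poly$log_Z,
                 comp_none$log_Z - oracle_poly_sl(3, 4, e, grid),
                 tolerance = 1e-12)
  }
})

test_that("EM log-likelihood is monotone and fits respect nesting", {
  set.seed(105)
  for (i in 1:5) {
    sim <- simulate_genotypes(sim_params(n_genes = 30, seed = 500 + i))
    mat <- filter_site_coverage(filter_biallelic(sim$matrix))
    fits <- lapply(c("NOSEX", "XY", "ZW"), function(m) fit_model(mat, m))
    for (f in fits[2:3]) {
      expect_true(all(diff(f$loglik_trace) >= -1e-9))
      expect_gte(f$loglik, fits[[1]]$loglik - 1e-6)
      expect_true(all(f$per_gene$posterior >= 0 & f$per_gene$posterior <= 1))
    }
    expect_equal(fits[[1]]$per_gene$posterior, rep(0, fits[[1]]$n_genes))
    expect_true(all(vapply(fits, function(f) is.finite(f$bic), logical(1))))
  }
})

test_that("ZW on data equals XY on sex-swapped data exactly", {
  set.seed(106)
  for (i in 1:3) {
    sim <- simulate_genotypes(sim_params(n_genes = 25, seed = 600 + i))
    mat <- filter_site_coverage(filter_biallelic(sim$matrix))
    swapped <- mat
    swapped$samples$sex <- ifelse(mat$samples$sex == "F", "M", "F")
    fz <- fit_model(mat, "ZW")
    fx <- fit_model(swapped, "XY")
    expect_equal(fz$loglik, fx$loglik, tolerance = 1e-9)
    expect_equal(fz$rho, fx$rho, tolerance = 1e-9)
    expect_equal(fz$epsilon, fx$epsilon, tolerance = 1e-9)
  }
})

test_that("tiny-instance ML fit matches exhaustive grid search", {
  set.seed(107)
  grid <- freq_grid(support = c(0, 0.25, 0.5, 0.75, 1))
  geno <- rbind(c(1, 1, 1, 1, 0, 0, 0, 0),
                c(0, 1, 1, 2, 0, 1, 2, 1),
                c(2, 1, 1, 2, 2, 2, 1, 2))
  mat <- make_matrix(geno, gene_ids = c("gA", "gA", "gB"))
  for (model in c("NOSEX", "ZW", "XY")) {
    fit <- fit_model(mat, model, grid = grid)
    ora <- oracle_fit(mat, model, grid)
    expect_lt(abs(fit$loglik - ora$loglik), 1e-3)
  }
})

test_that("fitting under ZW when no genes are sex-linked keeps the NOSEX nesting", {
  sim <- simulate_genotypes(sim_params(n_genes = 60, true_system = "NOSEX",
                                       seed = 700))
  mat <- filter_site_coverage(filter_biallelic(sim$matrix))
  fz <- fit_model(mat, "ZW")
  fn <- fit_model(mat, "NOSEX")
  expect_gte(fz$loglik, fn$loglik - 1e-6)
})

test_that("fit preconditions are enforced", {
  sim <- simulate_genotypes(sim_params(n_genes = 5, seed = 9))
  mat <- sim$matrix
  onesex <- mat
  onesex$samples$sex <- rep("F", nrow(mat$samples))
  expect_error(fit_model(onesex, "ZW"), "both sexes")
  onegene <- mat
  onegene$sites$gene_id <- "g0001"
  expect_error(fit_model(onegene, "ZW"), "2 genes")
})

test_that("model selection picks lowest BIC with parsimony tie-break", {
  # BIC triple of the worked example: ZW lowest
  sel <- select_model(c(NOSEX = 4680685.91, XY = 4680725.39,
                        ZW = 4680670.66))
  expect_equal(sel$winner, "ZW")
  expect_false(sel$tie)
  expect_equal(sel$table$delta_bic[sel$table$model == "ZW"], 0)
  # exact tie resolved toward fewer parameters
  tie <- select_model(c(NOSEX = 100, ZW = 100))
  expect_equal(tie$winner, "NOSEX")
  expect_true(tie$tie)
  # single fit returns itself
  sim <- simulate_genotypes(sim_params(n_genes = 20, seed = 8))
  mat <- filter_site_coverage(filter_biallelic(sim$matrix))
  f <- fit_model(mat, "ZW")
  single <- select_model(list(f))
  expect_equal(single$winner, "ZW")
  expect_equal(nrow(single$table), 1)
  # fits on differing site sets are rejected
  f2 <- fit_model(subset_mat <- {
    m <- mat; m$sites <- m$sites[-1, ]; m$geno <- m$geno[-1, ]; m
  }, "NOSEX")
  expect_error(select_model(list(f, f2)), "differing site sets")
})
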