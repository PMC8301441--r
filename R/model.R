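## Genotype-frequency likelihood machinery.
##
## Three competing models for a set of genes genotyped in sexed diploids:
##   NOSEX - every gene autosomal: dosages follow Hardy-Weinberg
##           frequencies ((1-p)^2, 2p(1-p), p^2) at an unknown per-site
##           allele frequency p.
##   ZW    - a fraction rho of genes is sex-linked with females
##           heterogametic: homogametic males are HWE at the Z frequency
##           x, heterogametic females carry one Z allele (freq x) and one
##           W allele (freq y), giving ((1-x)(1-y), x(1-y)+(1-x)y, xy).
##   XY    - the mirror image, males heterogametic.
## Observed dosages pass through a symmetric genotyping-error channel: the
## true dosage is reported with probability 1-eps, either other dosage
## with probability eps/2. Nuisance frequencies (p, x, y) are integrated
## over a discrete uniform grid, so the only global free parameters are
## eps (all models) and rho (XY/ZW), and BIC is comparable across models.
##
## Likelihood:  lnL = sum_g log[(1-rho) A_g + rho Z_g]
## with A_g, Z_g products over the gene's sites of grid-marginal genotype
## probabilities. rho is maximised by EM (responsibility r_g of the
## sex-linked class; update rho <- mean r_g); eps by an outer bounded 1-D
## search of the profile likelihood. r_g at the optimum is the gene's
## sex-linkage posterior.

# any log-marginal below this is an impossible configuration (-Inf)
.LOG_FLOOR <- -1e9
.DEG_THRESHOLD <- -1e8

#' Discrete allele-frequency grid
#'
#' Uniform prior over equally spaced support points in \[0, 1\], used to
#' marginalize the per-site nuisance allele frequencies (autosomal p,
#' Z/X-linked x, W/Y-limited y).
#'
#' @param n_points number of support points (default 51).
#' @param support,weights optionally supply the grid directly; `weights`
#'   must sum to 1 and `support` be strictly increasing within \[0, 1\].
#' @return list with elements `support` and `weights`, class `freq_grid`.
#' @export
freq_grid <- function(n_points = 51, support = NULL, weights = NULL) {
  if (is.null(support)) {
    stopifnot(n_points >= 2)
    support <- seq(0, 1, length.out = n_points)
  }
  if (is.null(weights)) weights <- rep(1 / length(support), length(support))
  stopifnot(length(support) == length(weights),
            all(diff(support) > 0),
            all(support >= 0), all(support <= 1),
            abs(sum(weights) - 1) < 1e-9)
  structure(list(support = support, weights = weights), class = "freq_grid")
}

.check_eps <- function(epsilon) {
  if (!is.numeric(epsilon) || length(epsilon) != 1 ||
      epsilon < 0 || epsilon >= 0.5) {
    stop("epsilon must be a single value in [0, 0.5)")
  }
}

# 3x3 error channel: rows true dosage, columns observed dosage
.error_channel <- function(epsilon) {
  e <- matrix(epsilon / 2, 3, 3)
  diag(e) <- 1 - epsilon
  e
}

#' Genotype probabilities under Hardy-Weinberg equilibrium
#'
#' True-dosage HWE probabilities `((1-p)^2, 2p(1-p), p^2)` pushed through
#' the symmetric genotyping-error channel (observed = true with
#' probability `1 - epsilon`, either other dosage with probability
#' `epsilon/2`).
#'
#' @param p allele frequency (vectorized), in \[0, 1\].
#' @param epsilon genotyping-error probability in \[0, 0.5).
#' @return For scalar `p` a probability triple over dosage 0/1/2; for
#'   vector `p` a `length(p)` x 3 matrix. Rows sum to 1.
#' @examples
#' genotype_prob_hwe(0.5, 0)      # (0.25, 0.50, 0.25)
#' genotype_prob_hwe(0.5, 0.03)
#' @export
genotype_prob_hwe <- function(p, epsilon) {
  stopifnot(all(p >= 0), all(p <= 1))
  .check_eps(epsilon)
  true <- cbind((1 - p)^2, 2 * p * (1 - p), p^2)
  out <- true %*% .error_channel(epsilon)
  colnames(out) <- c("0", "1", "2")
  if (length(p) == 1) drop(out) else out
}

#' Genotype probabilities for the heterogametic sex at a sex-linked gene
#'
#' A heterogametic individual (ZW female, XY male) draws one gametolog
#' allele from each sex chromosome: alternate-allele frequency `x` on the
#' shared chromosome (Z or X) and `y` on the sex-limited one (W or Y).
#' True-dosage probabilities `((1-x)(1-y), x(1-y)+(1-x)y, xy)` are pushed
#' through the same error channel as [genotype_prob_hwe()]. A fixed
#' gametolog difference (`x = 0`, `y = 1`) makes every heterogametic
#' individual heterozygous. With `x == y == p` the law reduces exactly to
#' HWE at `p`.
#'
#' @param x,y allele frequencies in \[0, 1\] (vectorized in parallel).
#' @param epsilon genotyping-error probability in \[0, 0.5).
#' @return Probability triple (or matrix) over dosage 0/1/2, rows sum
#'   to 1.
#' @examples
#' genotype_prob_gametolog(0, 1, 0)   # always heterozygous
#' @export
genotype_prob_gametolog <- function(x, y, epsilon) {
  stopifnot(all(x >= 0), all(x <= 1), all(y >= 0), all(y <= 1))
  .check_eps(epsilon)
  n <- max(length(x), length(y))
  x <- rep_len(x, n)
  y <- rep_len(y, n)
  true <- cbind((1 - x) * (1 - y), x * (1 - y) + (1 - x) * y, x * y)
  out <- true %*% .error_channel(epsilon)
  colnames(out) <- c("0", "1", "2")
  if (n == 1) drop(out) else out
}

## ---- vectorized internals over per-site dosage-count matrices ----

# log with a finite floor so that 0-count x log(0) contributes 0 in the
# matrix products below; marginals that end up below .DEG_THRESHOLD are
# mapped back to -Inf.
.safe_log <- function(p) {
  out <- log(p)
  out[p <= 0] <- .LOG_FLOOR
  out
}

.row_lse <- function(m) {
  mx <- m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
  out <- log(rowSums(exp(m - mx))) + mx
  out[out < .DEG_THRESHOLD] <- -Inf
  out
}

# counts: S x 3 matrix of dosage counts; returns S log-marginals under the
# grid-integrated HWE law.
.logmarg_auto <- function(counts, epsilon, grid) {
  lp <- .safe_log(rbind(genotype_prob_hwe(grid$support, epsilon)))
  m <- counts %*% t(lp)                      # S x G
  .row_lse(sweep(m, 2, log(grid$weights), "+"))
}

# homo/het: S x 3 count matrices for the homogametic and heterogametic
# sex; joint grid over (x, y) with the homogametic part HWE(x) and the
# heterogametic part the gametolog law (x, y).
.logmarg_sexlinked <- function(homo, het, epsilon, grid) {
  gx <- length(grid$support)
  xy <- expand.grid(ix = seq_len(gx), iy = seq_len(gx))
  lph <- .safe_log(rbind(genotype_prob_hwe(grid$support, epsilon)))
  lpg <- .safe_log(rbind(genotype_prob_gametolog(
    grid$support[xy$ix], grid$support[xy$iy], epsilon)))
  mh <- homo %*% t(lph)                      # S x gx
  mg <- het %*% t(lpg)                       # S x (gx*gy)
  lw <- log(grid$weights[xy$ix]) + log(grid$weights[xy$iy])
  total <- mh[, xy$ix, drop = FALSE] + mg
  .row_lse(sweep(total, 2, lw, "+"))
}

.counts_from_geno <- function(geno, cols) {
  sub <- geno[, cols, drop = FALSE]
  cbind(rowSums(sub == 0L, na.rm = TRUE),
        rowSums(sub == 1L, na.rm = TRUE),
        rowSums(sub == 2L, na.rm = TRUE))
}

## ---- polymorphism-ascertainment correction ----
## The biallelic filter keeps only sites where both alleles were observed,
## so the data reaching the fit are conditioned on polymorphism. The
## corrected site marginal divides by P(polymorphic | component):
## 1 - P(all typed dosages 0) - P(all typed dosages 2), integrated over
## the same frequency grid. Sites only differ through their per-sex
## typed counts, so the term is computed once per unique count pattern.

# n_typed: per-site number of non-missing genotypes; returns per-site
# log P(polymorphic) under the autosomal law
.logpoly_auto <- function(n_typed, epsilon, grid) {
  p <- rbind(genotype_prob_hwe(grid$support, epsilon))
  uniq <- sort(unique(n_typed))
  lp <- vapply(uniq, function(n) {
    log1p(-sum(grid$weights * (p[, 1]^n + p[, 3]^n)))
  }, numeric(1))
  lp[match(n_typed, uniq)]
}

# n_homo/n_het: per-site typed counts in the homogametic/heterogametic
# sex; returns per-site log P(polymorphic) under the sex-linked law
.logpoly_sexlinked <- function(n_homo, n_het, epsilon, grid) {
  gx <- length(grid$support)
  xy <- expand.grid(ix = seq_len(gx), iy = seq_len(gx))
  ph <- rbind(genotype_prob_hwe(grid$support, epsilon))
  pg <- rbind(genotype_prob_gametolog(grid$support[xy$ix],
                                      grid$support[xy$iy], epsilon))
  w2 <- grid$weights[xy$ix] * grid$weights[xy$iy]
  key <- paste(n_homo, n_het)
  uniq <- !duplicated(key)
  lp <- vapply(which(uniq), function(i) {
    log1p(-sum(w2 * (ph[xy$ix, 1]^n_homo[i] * pg[, 1]^n_het[i] +
                       ph[xy$ix, 3]^n_homo[i] * pg[, 3]^n_het[i])))
  }, numeric(1))
  lp[match(key, key[uniq])]
}

#' Log marginal probability of one site under the autosomal law
#'
#' Integrates the per-site allele frequency over the grid:
#' `log sum_p w(p) prod_i P_hwe(p, eps)[g_i]`, with missing genotypes
#' contributing a factor of 1. Returns `-Inf` (degenerate) when the
#' observed genotypes are impossible under every grid point.
#'
#' @param site_genotypes integer vector of dosages (`NA` = missing).
#' @param epsilon genotyping-error probability.
#' @param grid a [freq_grid()].
#' @return Scalar log marginal probability.
#' @export
site_marginal_autosomal <- function(site_genotypes, epsilon, grid = freq_grid()) {
  if (all(is.na(site_genotypes))) stop("site has no non-missing genotype")
  counts <- rbind(c(sum(site_genotypes == 0L, na.rm = TRUE),
                    sum(site_genotypes == 1L, na.rm = TRUE),
                    sum(site_genotypes == 2L, na.rm = TRUE)))
  as.numeric(.logmarg_auto(counts, epsilon, grid))
}

#' Log marginal probability of one site under the sex-linked law
#'
#' Integrates the Z/X frequency `x` and the W/Y frequency `y` over the
#' grid product: homogametic individuals follow HWE at `x`, heterogametic
#' individuals the gametolog law at `(x, y)`.
#'
#' @param site_genotypes integer vector of dosages (`NA` = missing).
#' @param sexes character vector (`"F"`/`"M"`) parallel to
#'   `site_genotypes`.
#' @param het_sex which sex is heterogametic: `"F"` (ZW) or `"M"` (XY).
#' @param epsilon genotyping-error probability.
#' @param grid a [freq_grid()].
#' @return Scalar log marginal probability.
#' @export
site_marginal_sexlinked <- function(site_genotypes, sexes, het_sex,
                                    epsilon, grid = freq_grid()) {
  stopifnot(length(sexes) == length(site_genotypes),
            het_sex %in% c("F", "M"))
  if (all(is.na(site_genotypes))) stop("site has no non-missing genotype")
  het <- sexes == het_sex
  cnt <- function(g) c(sum(g == 0L, na.rm = TRUE),
                       sum(g == 1L, na.rm = TRUE),
                       sum(g == 2L, na.rm = TRUE))
  as.numeric(.logmarg_sexlinked(rbind(cnt(site_genotypes[!het])),
                                rbind(cnt(site_genotypes[het])),
                                epsilon, grid))
}

#' Per-gene component log-likelihoods
#'
#' Sums site log-marginals within genes under both laws: `log A_g`
#' (autosomal) and `log Z_g` (sex-linked with heterogametic sex
#' `het_sex`). Sites are independent given the gene's class.
#'
#' @param mat a [genotype_matrix()].
#' @param epsilon genotyping-error probability.
#' @param het_sex `"F"` or `"M"`.
#' @param grid a [freq_grid()].
#' @param ascertainment `"none"` for the plain site marginals;
#'   `"polymorphic"` to condition each site marginal on the site being
#'   observed-polymorphic, matching data that passed
#'   [filter_biallelic()]'s monomorphic-site removal.
#' @return data.frame with columns `gene_id`, `n_sites`, `log_A`, `log_Z`,
#'   genes in order of first appearance.
#' @export
gene_component_logliks <- function(mat, epsilon, het_sex, grid = freq_grid(),
                                   ascertainment = c("none", "polymorphic")) {
  ascertainment <- match.arg(ascertainment)
  stopifnot(inherits(mat, "genotype_matrix"), nrow(mat$sites) > 0,
            het_sex %in% c("F", "M"))
  is_het <- mat$samples$sex == het_sex
  cnt_het <- .counts_from_geno(mat$geno, is_het)
  cnt_homo <- .counts_from_geno(mat$geno, !is_het)
  la <- .logmarg_auto(cnt_het + cnt_homo, epsilon, grid)
  lz <- .logmarg_sexlinked(cnt_homo, cnt_het, epsilon, grid)
  if (ascertainment == "polymorphic") {
    n_het <- rowSums(cnt_het)
    n_homo <- rowSums(cnt_homo)
    la <- la - .logpoly_auto(n_het + n_homo, epsilon, grid)
    lz <- lz - .logpoly_sexlinked(n_homo, n_het, epsilon, grid)
  }
  gene <- factor(mat$sites$gene_id, levels = unique(mat$sites$gene_id))
  data.frame(
    gene_id = levels(gene),
    n_sites = as.integer(tabulate(gene)),
    log_A = as.numeric(rowsum(la, gene)),
    log_Z = as.numeric(rowsum(lz, gene)),
    stringsAsFactors = FALSE
  )
}

## EM over rho at fixed component log-likelihoods. Returns the maximised
## log-likelihood, rho, the per-gene responsibilities and the lnL trace
## (non-decreasing up to numerical noise).
.em_rho <- function(log_a, log_z, rho_init = 0.05, tol = 1e-6,
                    max_iter = 500) {
  rho <- rho_init
  trace <- numeric(0)
  ll_old <- -Inf
  r <- rep(0, length(log_a))
  converged <- FALSE
  iter <- max_iter
  for (iter in seq_len(max_iter)) {
    t1 <- log1p(-rho) + log_a
    t2 <- if (rho > 0) log(rho) + log_z else rep(-Inf, length(log_z))
    mx <- pmax(t1, t2)
    lse <- mx + log(exp(t1 - mx) + exp(t2 - mx))
    ll <- sum(lse)
    trace <- c(trace, ll)
    r <- exp(t2 - lse)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) <= tol * (abs(ll_old) + 1e-12)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    rho <- mean(r)
  }
  out <- list(loglik = ll, rho = rho, posterior = r, trace = trace,
              iterations = iter, converged = converged)
  # when the optimum sits on a boundary the EM only approaches it
  # geometrically and may stop short of the nested model's likelihood;
  # the boundaries are valid parameter values, so take them if better
  ll0 <- sum(log_a)
  ll1 <- sum(log_z)
  if (ll0 >= out$loglik || ll1 >= out$loglik) {
    if (ll0 >= ll1) {
      out <- list(loglik = ll0, rho = 0, posterior = rep(0, length(log_a)),
                  trace = c(trace, ll0), iterations = iter,
                  converged = TRUE)
    } else {
      out <- list(loglik = ll1, rho = 1, posterior = rep(1, length(log_a)),
                  trace = c(trace, ll1), iterations = iter,
                  converged = TRUE)
    }
  }
  out
}

#' Fit a sexual-system model to a genotype matrix
#'
#' Maximizes the mixture log-likelihood
#' `lnL = sum_g log[(1-rho) A_g + rho Z_g]` (for `NOSEX`,
#' `lnL = sum_g log A_g` with `rho` fixed at 0). The sex-linked gene
#' fraction `rho` is fitted by EM (responsibilities become the per-gene
#' sex-linkage posteriors); the genotyping error `epsilon` by a bounded
#' 1-D search of the profile likelihood on `eps_bounds`. The BIC is
#' `-2 lnL + k log(n_sites)` with `k = 1` (NOSEX: epsilon) or `k = 2`
#' (XY/ZW: epsilon, rho).
#'
#' By default the per-site marginals are conditioned on the site being
#' observed-polymorphic (`ascertainment = "polymorphic"`), because the
#' standard input pipeline removes monomorphic sites in
#' [filter_biallelic()]; fitting the unconditioned likelihood to
#' ascertained sites biases both `epsilon` and `rho` upwards. Set
#' `ascertainment = "none"` for data that was not filtered on
#' polymorphism.
#'
#' @param mat a [genotype_matrix()] with at least 2 genes and both sexes
#'   present.
#' @param model `"NOSEX"`, `"XY"` or `"ZW"`.
#' @param grid a [freq_grid()].
#' @param tol relative log-likelihood convergence tolerance of the EM.
#' @param max_iter maximum EM iterations.
#' @param eps_bounds search interval for epsilon.
#' @param rho_init EM starting value for rho.
#' @param ascertainment `"polymorphic"` (default) or `"none"`, see
#'   Details.
#' @return Object of class `sexsys_fit`: list with `model`, `het_sex`,
#'   `epsilon`, `rho`, `loglik`, `n_sites`, `n_genes`, `k`, `bic`,
#'   `converged`, `iterations`, `loglik_trace`, and `per_gene`
#'   (data.frame `gene_id`, `n_sites`, `log_A`, `log_Z`, `posterior`).
#' @export
fit_model <- function(mat, model = c("NOSEX", "XY", "ZW"),
                      grid = freq_grid(), tol = 1e-6, max_iter = 500,
                      eps_bounds = c(1e-6, 0.2), rho_init = 0.05,
                      ascertainment = c("polymorphic", "none")) {
  model <- match.arg(model)
  ascertainment <- match.arg(ascertainment)
  stopifnot(inherits(mat, "genotype_matrix"), tol > 0)
  if (nrow(mat$sites) == 0) stop("empty genotype matrix")
  n <- sex_counts(mat)
  if (n[["F"]] == 0 || n[["M"]] == 0) {
    stop("both sexes must be present to fit a sexual-system model")
  }
  genes <- unique(mat$sites$gene_id)
  if (length(genes) < 2) stop("at least 2 genes are required")
  het_sex <- switch(model, NOSEX = NA_character_, XY = "M", ZW = "F")
  # components under the relevant het sex (arbitrary for NOSEX; log_A
  # does not depend on it)
  comp <- function(eps) {
    gene_component_logliks(mat, eps, if (is.na(het_sex)) "F" else het_sex,
                           grid, ascertainment = ascertainment)
  }
  # the profile over epsilon can be multimodal (the mixture switches
  # between error-driven and frequency-driven explanations), so a plain
  # golden-section search may land on a local optimum: scan a coarse
  # log-spaced grid first, then refine inside the best bracket, and keep
  # whichever point (grid or refined) profiles best.
  best_eps <- function(prof) {
    cand <- exp(seq(log(eps_bounds[1]), log(eps_bounds[2]),
                    length.out = 9))
    vals <- vapply(cand, prof, numeric(1))
    i <- which.max(vals)
    lo <- if (i == 1) eps_bounds[1] else cand[i - 1]
    hi <- if (i == length(cand)) eps_bounds[2] else cand[i + 1]
    opt <- stats::optimize(prof, interval = c(lo, hi), maximum = TRUE,
                           tol = 1e-5)
    if (opt$objective >= vals[i]) opt$maximum else cand[i]
  }
  if (model == "NOSEX") {
    prof <- function(eps) sum(comp(eps)$log_A)
    eps_hat <- best_eps(prof)
    pg <- comp(eps_hat)
    if (any(!is.finite(pg$log_A))) {
      stop("gene(s) with -Inf autosomal marginal: ",
           paste(utils::head(pg$gene_id[!is.finite(pg$log_A)], 3),
                 collapse = ", "),
           " -- the frequency grid cannot explain the data")
    }
    ll <- sum(pg$log_A)
    pg$posterior <- 0
    res <- list(loglik = ll, rho = 0, posterior = pg$posterior,
                trace = ll, iterations = 1L, converged = TRUE)
  } else {
    prof <- function(eps) {
      pgc <- comp(eps)
      .em_rho(pgc$log_A, pgc$log_Z, rho_init, tol, max_iter)$loglik
    }
    eps_hat <- best_eps(prof)
    pg <- comp(eps_hat)
    if (any(!is.finite(pg$log_A) & !is.finite(pg$log_Z))) {
      bad <- !is.finite(pg$log_A) & !is.finite(pg$log_Z)
      stop("gene(s) impossible under both components: ",
           paste(utils::head(pg$gene_id[bad], 3), collapse = ", "),
           " -- the frequency grid cannot explain the data")
    }
    res <- .em_rho(pg$log_A, pg$log_Z, rho_init, tol, max_iter)
    pg$posterior <- res$posterior
  }
  n_sites <- nrow(mat$sites)
  k <- if (model == "NOSEX") 1L else 2L
  fit <- list(
    model = model, het_sex = het_sex,
    epsilon = eps_hat, rho = res$rho,
    loglik = res$loglik, n_sites = n_sites, n_genes = length(genes),
    k = k, bic = -2 * res$loglik + k * log(n_sites),
    converged = res$converged, iterations = res$iterations,
    loglik_trace = res$trace,
    per_gene = pg,
    ascertainment = ascertainment,
    grid_points = length(grid$support),
    site_ids = paste(mat$sites$gene_id, mat$sites$pos)
  )
  class(fit) <- "sexsys_fit"
  if (!res$converged) {
    warning(model, " fit did not converge in ", max_iter,
            " EM iterations (last lnL ", format(res$loglik), ")")
  }
  fit
}

#' @export
print.sexsys_fit <- function(x, ...) {
  cat("sexsys_fit [", x$model, "]  lnL = ", format(x$loglik),
      "  BIC = ", format(x$bic), "\n",
      "  epsilon = ", format(x$epsilon, digits = 4),
      "  rho = ", format(x$rho, digits = 4),
      "  (", x$n_sites, " sites, ", x$n_genes, " genes, k = ", x$k, ")\n",
      sep = "")
  invisible(x)
}

#' Select the sexual-system model with the lowest BIC
#'
#' Accepts either a list of [fit_model()] results on identical filtered
#' data, or a named numeric vector of BIC values (names among `NOSEX`,
#' `XY`, `ZW`) for a ready-made comparison. Ties are broken by fewer free
#' parameters, then by the fixed order NOSEX < XY < ZW, and reported.
#'
#' @param fits list of `sexsys_fit` objects, or a named numeric vector of
#'   BICs.
#' @return Object of class `sexsys_selection`: list with `winner` (model
#'   name), `table` (data.frame `model`, `k`, `loglik`, `bic`, `delta_bic`),
#'   `tie` (logical) and, when fits were supplied, `best_fit`.
#' @examples
#' select_model(c(NOSEX = 4680685.91, XY = 4680725.39, ZW = 4680670.66))
#' @export
select_model <- function(fits) {
  model_order <- c("NOSEX", "XY", "ZW")
  k_of <- c(NOSEX = 1L, XY = 2L, ZW = 2L)
  if (is.numeric(fits)) {
    if (is.null(names(fits)) || !all(names(fits) %in% model_order)) {
      stop("a numeric BIC vector must be named with models among ",
           paste(model_order, collapse = ", "))
    }
    tab <- data.frame(model = names(fits), k = k_of[names(fits)],
                      loglik = NA_real_, bic = as.numeric(fits),
                      stringsAsFactors = FALSE)
    best_fit <- NULL
  } else {
    if (inherits(fits, "sexsys_fit")) fits <- list(fits)
    stopifnot(all(vapply(fits, inherits, logical(1), "sexsys_fit")))
    ids <- lapply(fits, `[[`, "site_ids")
    if (length(fits) > 1 &&
        !all(vapply(ids[-1], identical, logical(1), ids[[1]]))) {
      stop("fits were computed on differing site sets; ",
           "filter once and fit all models on the same matrix")
    }
    tab <- data.frame(
      model = vapply(fits, `[[`, character(1), "model"),
      k = vapply(fits, `[[`, integer(1), "k"),
      loglik = vapply(fits, `[[`, numeric(1), "loglik"),
      bic = vapply(fits, `[[`, numeric(1), "bic"),
      stringsAsFactors = FALSE
    )
    if (anyDuplicated(tab$model)) stop("duplicate model fits supplied")
    best_fit <- NULL
  }
  ord <- order(tab$bic, tab$k, match(tab$model, model_order))
  winner <- tab$model[ord[1]]
  tie <- sum(tab$bic == min(tab$bic)) > 1
  tab$delta_bic <- tab$bic - min(tab$bic)
  tab <- tab[order(match(tab$model, model_order)), ]
  rownames(tab) <- NULL
  if (!is.numeric(fits)) {
    best_fit <- fits[[which(vapply(fits, `[[`, character(1), "model") ==
                              winner)]]
  }
  structure(list(winner = winner, table = tab, tie = tie,
                 best_fit = best_fit),
            class = "sexsys_selection")
}

#' @export
print.sexsys_selection <- function(x, ...) {
  cat("Model selection by BIC (lower is better):\n")
  print(x$table, row.names = FALSE)
  cat("Winner:", x$winner, if (x$tie) "(tie, broken by parsimony/order)",
      "\n")
  invisible(x)
}
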