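# Independent brute-force reference implementations, written as direct
# loop-based transcriptions of the model definitions. They share no code
# with the package internals and are deliberately slow; they are only run
# on tiny instances.

oracle_hwe <- function(p, e) {
  true <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  vapply(1:3, function(g) {
    true[g] * (1 - e) + sum(true[-g]) * (e / 2)
  }, numeric(1))
}

oracle_gam <- function(x, y, e) {
  true <- c((1 - x) * (1 - y), x * (1 - y) + (1 - x) * y, x * y)
  vapply(1:3, function(g) {
    true[g] * (1 - e) + sum(true[-g]) * (e / 2)
  }, numeric(1))
}

oracle_site_auto <- function(g, e, grid) {
  total <- 0
  for (k in seq_along(grid$support)) {
    lik <- grid$weights[k]
    probs <- oracle_hwe(grid$support[k], e)
    for (gi in g[!is.na(g)]) lik <- lik * probs[gi + 1]
    total <- total + lik
  }
  log(total)
}

oracle_site_sl <- function(g, sexes, het_sex, e, grid) {
  total <- 0
  for (i in seq_along(grid$support)) {
    for (j in seq_along(grid$support)) {
      lik <- grid$weights[i] * grid$weights[j]
      ph <- oracle_hwe(grid$support[i], e)
      pg <- oracle_gam(grid$support[i], grid$support[j], e)
      for (k in seq_along(g)) {
        if (is.na(g[k])) next
        lik <- lik * (if (sexes[k] == het_sex) pg[g[k] + 1] else ph[g[k] + 1])
      }
      total <- total + lik
    }
  }
  log(total)
}

# log P(site observed-polymorphic) under each component, for the
# ascertainment-corrected likelihood
oracle_poly_auto <- function(n_typed, e, grid) {
  mono <- 0
  for (k in seq_along(grid$support)) {
    probs <- oracle_hwe(grid$support[k], e)
    mono <- mono + grid$weights[k] * (probs[1]^n_typed + probs[3]^n_typed)
  }
  log(1 - mono)
}

oracle_poly_sl <- function(n_homo, n_het, e, grid) {
  mono <- 0
  for (i in seq_along(grid$support)) {
    for (j in seq_along(grid$support)) {
      ph <- oracle_hwe(grid$support[i], e)
      pg <- oracle_gam(grid$support[i], grid$support[j], e)
      mono <- mono + grid$weights[i] * grid$weights[j] *
        (ph[1]^n_homo * pg[1]^n_het + ph[3]^n_homo * pg[3]^n_het)
    }
  }
  log(1 - mono)
}

# per-gene component log-likelihoods by site-wise accumulation
oracle_components <- function(mat, e, het_sex, grid,
                              ascertainment = "none") {
  genes <- unique(mat$sites$gene_id)
  out <- data.frame(gene_id = genes, log_A = 0, log_Z = 0,
                    stringsAsFactors = FALSE)
  for (s in seq_len(nrow(mat$sites))) {
    g <- mat$geno[s, ]
    row <- match(mat$sites$gene_id[s], genes)
    la <- oracle_site_auto(g, e, grid)
    lz <- oracle_site_sl(g, mat$samples$sex, het_sex, e, grid)
    if (ascertainment == "polymorphic") {
      sexes <- mat$samples$sex
      n_het <- sum(!is.na(g[sexes == het_sex]))
      n_homo <- sum(!is.na(g[sexes != het_sex]))
      la <- la - oracle_poly_auto(n_het + n_homo, e, grid)
      lz <- lz - oracle_poly_sl(n_homo, n_het, e, grid)
    }
    out$log_A[row] <- out$log_A[row] + la
    out$log_Z[row] <- out$log_Z[row] + lz
  }
  out
}

# exhaustive (rho, eps) grid search of the mixture likelihood over the
# same parameter space fit_model searches (eps in [1e-6, 0.2], rho in
# [0, 1]); returns the best lnL and the maximizing parameters
oracle_fit <- function(mat, model, grid,
                       rho_grid = seq(0, 1, by = 0.01),
                       eps_grid = c(1e-6, 1e-5, 1e-4,
                                    seq(5e-4, 0.2, by = 5e-4)),
                       ascertainment = "polymorphic") {
  het_sex <- switch(model, NOSEX = "F", XY = "M", ZW = "F")
  best <- list(loglik = -Inf, rho = NA, epsilon = NA)
  for (e in eps_grid) {
    comp <- oracle_components(mat, e, het_sex, grid, ascertainment)
    if (model == "NOSEX") {
      ll <- sum(comp$log_A)
      if (ll > best$loglik) best <- list(loglik = ll, rho = 0, epsilon = e)
    } else {
      for (rho in rho_grid) {
        ll <- sum(log((1 - rho) * exp(comp$log_A) + rho * exp(comp$log_Z)))
        if (ll > best$loglik) {
          best <- list(loglik = ll, rho = rho, epsilon = e)
        }
      }
    }
  }
  best
}
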