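## Exhaustive sex-label permutation robustness test. With n_f females and
## n_m males there are C(n_f + n_m, n_f) distinct labelings preserving
## the sex counts; refitting the competing models on each asks whether
## the observed labeling's preference for a heterogametic model could
## arise from an arbitrary split of the individuals. With 4 + 4
## individuals this gives 8!/(4!4!) - 1 = 69 permuted datasets.

#' Enumerate sex labelings preserving the observed counts
#'
#' All distinct assignments of `n_f` F and `n_m` M labels to
#' `n_f + n_m` ordered individuals, excluding the observed labeling, in
#' deterministic lexicographic order (F sorts before M).
#'
#' @param n_f,n_m positive female/male counts.
#' @param observed the labeling to exclude, a character vector of length
#'   `n_f + n_m`; defaults to all-F-first (`F ... F M ... M`).
#' @return Character vector of labeling strings, e.g. `"FFMFMFMM"`, of
#'   length `choose(n_f + n_m, n_f) - 1`.
#' @examples
#' length(enumerate_labelings(4, 4))  # 69
#' @export
enumerate_labelings <- function(n_f, n_m,
                                observed = c(rep("F", n_f), rep("M", n_m))) {
  stopifnot(n_f >= 1, n_m >= 1)
  n <- n_f + n_m
  stopifnot(length(observed) == n, all(observed %in% c("F", "M")),
            sum(observed == "F") == n_f)
  idx <- utils::combn(n, n_f)
  labs <- apply(idx, 2, function(i) {
    v <- rep("M", n)
    v[i] <- "F"
    paste(v, collapse = "")
  })
  labs <- sort(labs)
  setdiff(labs, paste(observed, collapse = ""))
}

#' Refit competing models under every sex relabeling
#'
#' For the observed labeling and every permuted labeling, fits the
#' no-sex-chromosome and ZW models and records both BICs. Only these two
#' models are needed: the XY model on any labeling equals the ZW model on
#' the complementary (sex-swapped) labeling, which is itself in the
#' enumeration. The NOSEX likelihood does not involve the sex labels at
#' all, so it is computed once and shared across labelings (refitting it
#' per labeling would reproduce the identical number). `epsilon` and
#' `rho` of the ZW model are re-estimated from scratch for every
#' labeling.
#'
#' @param mat a [genotype_matrix()] passing the [fit_model()]
#'   preconditions.
#' @param grid a [freq_grid()].
#' @param tol,max_iter passed to [fit_model()].
#' @param max_enumerate guardrail: error when the number of labelings
#'   exceeds this unless `sample_n` is given.
#' @param sample_n draw this many distinct permuted labelings instead of
#'   enumerating (requires `sample_seed`).
#' @param sample_seed RNG seed for `sample_n`.
#' @return data.frame of class `permutation_result` with columns
#'   `labeling`, `bic_nosex`, `bic_zw`, `winner`, `is_observed`; the
#'   observed labeling is the first row.
#' @export
permutation_scan <- function(mat, grid = freq_grid(), tol = 1e-6,
                             max_iter = 500, max_enumerate = 10000,
                             sample_n = NULL, sample_seed = NULL) {
  stopifnot(inherits(mat, "genotype_matrix"))
  n <- sex_counts(mat)
  if (n[["F"]] < 1 || n[["M"]] < 1) stop("both sexes must be present")
  total <- choose(sum(n), n[["F"]])
  observed <- mat$samples$sex
  if (is.null(sample_n)) {
    if (total > max_enumerate) {
      stop("C(", sum(n), ", ", n[["F"]], ") = ", total,
           " labelings exceed the enumeration cap of ", max_enumerate,
           "; supply `sample_n` (with `sample_seed`) to subsample")
    }
    labelings <- enumerate_labelings(n[["F"]], n[["M"]], observed)
  } else {
    if (is.null(sample_seed)) stop("`sample_n` requires `sample_seed`")
    set.seed(sample_seed)
    obs_str <- paste(observed, collapse = "")
    seen <- character(0)
    while (length(seen) < sample_n) {
      draw <- paste(sample(observed), collapse = "")
      if (draw != obs_str) seen <- unique(c(seen, draw))
    }
    labelings <- seen
  }
  fit_nosex <- fit_model(mat, "NOSEX", grid = grid, tol = tol,
                         max_iter = max_iter)
  all_labs <- c(paste(observed, collapse = ""), labelings)
  res <- lapply(seq_along(all_labs), function(i) {
    labs <- strsplit(all_labs[i], "")[[1]]
    fit_zw <- tryCatch(
      fit_model(relabel_sexes(mat, labs), "ZW", grid = grid, tol = tol,
                max_iter = max_iter),
      error = function(e) {
        stop("ZW fit failed for labeling ", all_labs[i], ": ",
             conditionMessage(e))
      }
    )
    data.frame(
      labeling = all_labs[i],
      bic_nosex = fit_nosex$bic,
      bic_zw = fit_zw$bic,
      winner = if (fit_zw$bic < fit_nosex$bic) "ZW" else "NOSEX",
      is_observed = i == 1L,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  class(out) <- c("permutation_result", class(out))
  out
}

#' Summarize a permutation scan
#'
#' @param results data.frame from [permutation_scan()].
#' @return list with `n_permuted`, `zw_win_count` (permuted labelings
#'   where ZW had the lower BIC), `zw_win_fraction`, `observed_winner`,
#'   `observed_delta_bic` and `delta_bic` (vector `bic_nosex - bic_zw`
#'   over permuted labelings; positive favors ZW).
#' @export
robustness_summary <- function(results) {
  stopifnot(is.data.frame(results), nrow(results) > 0,
            all(c("labeling", "bic_nosex", "bic_zw", "winner",
                  "is_observed") %in% names(results)))
  perm <- results[!results$is_observed, , drop = FALSE]
  obs <- results[results$is_observed, , drop = FALSE]
  if (nrow(obs) != 1) stop("results must contain exactly one observed row")
  zw_wins <- sum(perm$winner == "ZW")
  list(
    n_permuted = nrow(perm),
    zw_win_count = zw_wins,
    zw_win_fraction = if (nrow(perm) == 0) NA_real_ else zw_wins / nrow(perm),
    observed_winner = obs$winner,
    observed_delta_bic = obs$bic_nosex - obs$bic_zw,
    delta_bic = perm$bic_nosex - perm$bic_zw
  )
}
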