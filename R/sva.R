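#' Estimate surrogate variables by residual-matrix SVD
#'
#' Captures unmodeled batch-like structure before differential methylation.
#' The candidate surrogate variables (SVs) are the right singular vectors
#' of the row-centered M-value matrix (the residual matrix of the
#' null, intercept-only probe model). Centering rather than regressing out
#' the outcome is deliberate: SVs must be able to correlate with the
#' outcome for the exclusion rule below to have anything to exclude, and
#' per-probe residuals on the outcome are exactly orthogonal to it. With `n_sv = "auto"` the number of SVs is chosen by parallel
#' analysis: the k-th singular value must exceed the 95th percentile of the
#' k-th singular values of `n_perm` row-permuted residual matrices
#' (counting stops at the first failure). SVs are unit-norm, mutually
#' orthogonal, and sign-fixed so their largest-magnitude loading is
#' positive. Each SV's Pearson (point-biserial) correlation with the
#' outcome is recorded and SVs with |correlation| above `corr_threshold`
#' are marked for exclusion, protecting the outcome contrast from
#' absorption into the covariates.
#'
#' @param dataset a [methylation_dataset()] (post-filtering).
#' @param n_sv `"auto"` for parallel analysis, or a fixed count
#'   (must be < number of samples).
#' @param corr_threshold exclusion cut on |cor(SV, outcome)| (default 0.2).
#' @param n_perm permutations for the parallel-analysis null (default 20).
#' @param perm_seed seed for the permutation null, so "auto" selection is
#'   deterministic.
#' @param eps clipping bound for the beta-to-M transform.
#' @return an object of class `surrogate_variables` with `values`
#'   (samples x k matrix), `outcome_corr`, `retained`, and the singular
#'   values in `d`.
#' @export
estimate_surrogates <- function(dataset, n_sv = "auto", corr_threshold = 0.2,
                                n_perm = 20, perm_seed = 0L, eps = 1e-6) {
  n <- ncol(dataset$beta)
  if (n < 3) stopf("surrogate estimation requires at least 3 samples")
  outcome <- dataset$outcome
  M <- beta_to_m(dataset$beta, eps = eps)
  R <- M - rowMeans(M)  # null-model residuals
  k_max <- min(nrow(R), n) - 1L
  sv <- svd(R, nu = 0, nv = k_max)
  d <- sv$d[seq_len(k_max)]

  if (identical(n_sv, "auto")) {
    perm_d <- with_seed(perm_seed, {
      vapply(seq_len(n_perm), function(b) {
        Rp <- matrix(R[order(stats::runif(length(R)))], nrow(R), n)
        svd(Rp, nu = 0, nv = 0)$d[seq_len(k_max)]
      }, numeric(k_max))
    })
    thr <- apply(perm_d, 1, stats::quantile, probs = 0.95, names = FALSE)
    exceeds <- d > thr
    k <- if (all(exceeds)) k_max else (which.min(exceeds) - 1L)
  } else {
    k <- as.integer(n_sv)
    if (k >= n) stopf("n_sv (%d) must be below the number of samples (%d)", k, n)
    if (k > k_max) stopf("n_sv (%d) exceeds the available %d singular vectors", k, k_max)
  }

  values <- sv$v[, seq_len(k), drop = FALSE]
  if (k > 0) {
    # sign convention: largest-magnitude loading positive
    for (j in seq_len(k)) {
      if (values[which.max(abs(values[, j])), j] < 0) values[, j] <- -values[, j]
    }
  }
  dimnames(values) <- list(sample_ids(dataset),
                           if (k > 0) sprintf("SV%d", seq_len(k)) else NULL)
  outcome_corr <- if (k > 0) {
    as.vector(stats::cor(values, outcome))
  } else {
    numeric(0)
  }
  structure(
    list(values = values, d = d[seq_len(max(k, 0))],
         outcome_corr = outcome_corr,
         retained = abs(outcome_corr) <= corr_threshold,
         corr_threshold = corr_threshold),
    class = "surrogate_variables"
  )
}

#' @export
print.surrogate_variables <- function(x, ...) {
  k <- ncol(x$values)
  cat(sprintf("surrogate_variables: %d SVs, excluded %d of %d (|cor with outcome| > %g)\n",
              k, sum(!x$retained), k, x$corr_threshold))
  if (k > 0) {
    print(data.frame(sv = colnames(x$values),
                     outcome_corr = round(x$outcome_corr, 4),
                     retained = x$retained, row.names = NULL))
  }
  invisible(x)
}

#' Retained surrogate variables as a covariate matrix
#'
#' Drops SVs whose |correlation with outcome| exceeds the exclusion cut,
#' preserving order, and logs "excluded m of k".
#'
#' @param svs a `surrogate_variables` object.
#' @return samples x retained-SVs numeric matrix (possibly zero columns).
#' @export
select_covariates <- function(svs) {
  stopifnot(inherits(svs, "surrogate_variables"))
  k <- ncol(svs$values)
  message(sprintf("surrogate variables: excluded %d of %d", sum(!svs$retained), k))
  svs$values[, svs$retained, drop = FALSE]
}

#' Surrogate-variable report table
#'
#' @param svs a `surrogate_variables` object.
#' @return data frame with one row per SV: index, outcome correlation,
#'   retained flag.
#' @export
sv_report <- function(svs) {
  data.frame(sv = seq_along(svs$outcome_corr),
             outcome_corr = svs$outcome_corr,
             retained = svs$retained)
}
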