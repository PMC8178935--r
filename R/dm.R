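#' Beta to M-value transform
#'
#' M = log2(beta / (1 - beta)) with beta clipped into \[eps, 1 - eps\] so
#' boundary values stay finite. M-values are the usual scale for linear
#' modeling of methylation because beta values are variance-compressed near
#' 0 and 1.
#'
#' @param beta numeric vector or matrix of beta values in \[0,1\].
#' @param eps clipping bound (default 1e-6).
#' @return M-values with the shape of `beta`.
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  b <- pmin(pmax(beta, eps), 1 - eps)
  log2(b / (1 - b))
}

#' Per-probe ordinary least squares fits
#'
#' Fits each probe's M-value on the design \[intercept, outcome,
#' covariates\] by OLS. The reported effect is the outcome coefficient (the
#' deceased-minus-survived M difference when there are no covariates).
#'
#' @param M probes x samples M-value matrix.
#' @param outcome binary 0/1 vector, one per sample.
#' @param covariates optional samples x k numeric matrix (e.g. retained
#'   surrogate variables).
#' @return an object of class `probe_fits`: per-probe `effect`, residual
#'   variance `s2`, shared residual `df`, and the outcome coefficient's
#'   unscaled variance `v` (design leverage).
#' @export
fit_probe_models <- function(M, outcome, covariates = NULL) {
  if (length(outcome) != ncol(M)) {
    stopf("need one outcome per sample: %d outcomes, %d samples",
          length(outcome), ncol(M))
  }
  X <- cbind(`(Intercept)` = 1, outcome = outcome)
  if (!is.null(covariates) && NCOL(covariates) > 0) {
    covariates <- as.matrix(covariates)
    if (is.null(colnames(covariates))) {
      colnames(covariates) <- sprintf("COV%d", seq_len(ncol(covariates)))
    }
    X <- cbind(X, covariates)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stopf("design matrix is rank deficient; collinear column(s): %s",
          paste(bad, collapse = ", "))
  }
  df <- nrow(X) - ncol(X)
  if (df < 1) stopf("no residual degrees of freedom (n = %d, p = %d)", nrow(X), ncol(X))
  XtX_inv <- chol2inv(chol(crossprod(X)))
  B <- M %*% X %*% XtX_inv
  res <- M - B %*% t(X)
  s2 <- rowSums(res^2) / df
  structure(
    list(probe_id = rownames(M), effect = unname(B[, 2]), s2 = unname(s2),
         df = df, v = XtX_inv[2, 2], n = nrow(X)),
    class = "probe_fits"
  )
}

# Newton inversion of the trigamma function (for the prior-df moment
# equation); monotone decreasing, so convergence is fast and global.
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif) < 1e-10 * x) break
  }
  x
}

#' Empirical-Bayes moderation of per-probe variances
#'
#' Shrinks each probe's residual variance toward a prior estimated from the
#' whole probe ensemble, then forms moderated t-statistics with augmented
#' degrees of freedom. The prior df `d0` and prior variance `s0_sq` are
#' estimated by closed-form method of moments on the log residual
#' variances: with e_g = log(s2_g) - digamma(df/2) + log(df/2),
#' trigamma(d0/2) = var(e) - trigamma(df/2) (d0 infinite when the
#' right-hand side is non-positive, i.e. the variances are essentially
#' identical and shrinkage is total), and
#' s0_sq = exp(mean(e) + digamma(d0/2) - log(d0/2)). The posterior variance
#' is s2_post = (d0 s0_sq + df s2) / (d0 + df), the moderated t is
#' effect / sqrt(s2_post v), and two-sided p-values use d0 + df degrees of
#' freedom. In the d0 -> 0 limit the moderated t equals the ordinary t; in
#' the d0 -> infinity limit it equals effect / sqrt(s0_sq v).
#'
#' @param fits a [fit_probe_models()] result (>= 2 probes with positive
#'   residual variance).
#' @param genes optional per-probe gene symbols carried into the result.
#' @return data frame of class `dm_result` with columns `probe_id`, `gene`,
#'   `logFC` (M-value difference), `t_mod`, `df_total`, `p`, `p_adj`
#'   (Benjamini-Hochberg), and `constant` (zero residual variance flag);
#'   hyperparameters in attributes `d0` and `s0_sq`.
#' @export
empirical_bayes_moderate <- function(fits, genes = NULL) {
  stopifnot(inherits(fits, "probe_fits"))
  s2 <- fits$s2
  df <- fits$df
  ok <- s2 > 0
  if (sum(ok) < 2) stopf("need at least 2 probes with positive residual variance")
  e <- log(s2[ok]) - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e)
  rhs <- evar - trigamma(df / 2)
  if (!is.finite(rhs) || rhs <= 0) {
    d0 <- Inf
    s0_sq <- exp(emean)
  } else {
    d0 <- 2 * trigamma_inverse(rhs)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  }
  s2_post <- if (is.finite(d0)) (d0 * s0_sq + df * s2) / (d0 + df) else rep(s0_sq, length(s2))
  t_mod <- fits$effect / sqrt(s2_post * fits$v)
  df_total <- d0 + df
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  out <- data.frame(
    probe_id = fits$probe_id %||% sprintf("probe%d", seq_along(s2)),
    gene = if (is.null(genes)) NA_character_ else genes,
    logFC = fits$effect, t_mod = t_mod, df_total = df_total,
    p = p, p_adj = adjust_bh(p), constant = !ok,
    stringsAsFactors = FALSE
  )
  attr(out, "d0") <- d0
  attr(out, "s0_sq") <- s0_sq
  class(out) <- c("dm_result", "data.frame")
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment.
#'
#' @param p numeric vector of p-values in \[0,1\].
#' @return adjusted p-values, same length and order as `p`.
#' @export
adjust_bh <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p-values must lie in [0,1]")
  stats::p.adjust(p, method = "BH")
}

#' Differential methylation between deceased and surviving patients
#'
#' Runs the full moderated-t stage: beta-to-M transform, per-probe OLS on
#' outcome plus covariates, empirical-Bayes moderation, and BH adjustment.
#' A companion `delta_beta_mean` column (difference of group mean betas,
#' deceased minus survived) is emitted alongside the M-scale `logFC`, since
#' the two effect scales answer different readers.
#'
#' @param dataset a [methylation_dataset()] (post-filtering).
#' @param covariates optional samples x k matrix of retained surrogate
#'   variables.
#' @param manifest optional manifest used to annotate probes with genes.
#' @param eps beta clipping bound for the M transform.
#' @return a `dm_result` data frame (see [empirical_bayes_moderate()]).
#' @export
differential_methylation <- function(dataset, covariates = NULL,
                                     manifest = NULL, eps = 1e-6) {
  M <- beta_to_m(dataset$beta, eps = eps)
  fits <- fit_probe_models(M, dataset$outcome, covariates)
  genes <- if (!is.null(manifest)) manifest_for(dataset, manifest)$gene else NULL
  out <- empirical_bayes_moderate(fits, genes = genes)
  dead <- dataset$outcome == 1
  out$delta_beta_mean <- rowMeans(dataset$beta[, dead, drop = FALSE]) -
    rowMeans(dataset$beta[, !dead, drop = FALSE])
  out
}

#' Select the methylation signature
#'
#' CpGs with adjusted p below `alpha` (the discovery threshold is 0.1,
#' reflecting the exploratory scale of the pilot analysis) form the
#' signature; the gene list is the deduplicated set of their symbols and
#' each gene's risk direction is the sign of its most significant CpG's
#' M-scale effect (hyper if positive).
#'
#' @param results a `dm_result` data frame.
#' @param alpha adjusted-p inclusion threshold (default 0.1).
#' @param max_cpgs optional cap; keeps the `max_cpgs` smallest adjusted p.
#' @return an object of class `dm_signature` with `cpgs` (probe_id, gene,
#'   direction, logFC, p_adj) and `genes`.
#' @export
select_signature <- function(results, alpha = 0.1, max_cpgs = NULL) {
  sel <- results[!is.na(results$p_adj) & results$p_adj < alpha, , drop = FALSE]
  sel <- sel[order(sel$p_adj, sel$p, sel$probe_id), , drop = FALSE]
  if (!is.null(max_cpgs) && nrow(sel) > max_cpgs) {
    sel <- sel[seq_len(max_cpgs), , drop = FALSE]
  }
  if (nrow(sel) == 0) warnf("empty signature: no CpG reached adjusted p < %g", alpha)
  cpgs <- data.frame(
    probe_id = sel$probe_id,
    gene = if ("gene" %in% names(sel)) sel$gene else NA_character_,
    direction = ifelse(sel$logFC > 0, "hyper", "hypo"),
    logFC = sel$logFC, p_adj = sel$p_adj,
    stringsAsFactors = FALSE
  )
  genes <- unique(cpgs$gene[!is.na(cpgs$gene) & cpgs$gene != ""])
  structure(list(cpgs = cpgs, genes = genes, alpha = alpha),
            class = "dm_signature")
}

#' @export
print.dm_signature <- function(x, ...) {
  cat(sprintf("dm_signature: %d CpGs over %d genes (adjusted p < %g)\n",
              nrow(x$cpgs), length(x$genes), x$alpha))
  if (nrow(x$cpgs)) print.data.frame(x$cpgs, row.names = FALSE)
  invisible(x)
}

# gene -> risk direction lookup from a signature: the direction of the
# gene's most significant CpG (cpgs are already ordered by p_adj)
signature_directions <- function(signature) {
  cpgs <- signature$cpgs
  first <- cpgs[!duplicated(cpgs$gene), , drop = FALSE]
  stats::setNames(first$direction, first$gene)
}
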