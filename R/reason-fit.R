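#' Fit the composite risk score
#'
#' End-to-end discovery fit on one cohort with aligned methylation and
#' clinical data. Runs, in order: the seven-stage probe-filter cascade;
#' surrogate-variable estimation with the 0.2 outcome-correlation
#' exclusion rule; moderated-t differential methylation on M-values with
#' retained surrogate variables as covariates; signature selection at
#' adjusted p < `alpha`; survivor-referenced state-transition molecular
#' scoring; the recursive-partitioning clinicopathologic integer score;
#' and additive combination of the two components, evaluated by
#' concordance index with bootstrap intervals.
#'
#' @param methylation a [methylation_dataset()] aligned with `clinical`
#'   (same patients, same order).
#' @param manifest probe manifest covering the dataset.
#' @param clinical clinical data frame with `patient_id`, the ten panel
#'   features, and binary `outcome`.
#' @param filter_params overrides for [run_cascade()].
#' @param n_sv surrogate-variable count or `"auto"`.
#' @param alpha signature inclusion threshold on adjusted p (default 0.1).
#' @param thresholds [state_thresholds()] for the molecular component.
#' @param clinico_params overrides for [fit_clinico_score()]
#'   (`min_leaf`, `max_depth`, `stop_alpha`, `candidate_cuts`).
#' @param n_boot bootstrap resamples for panel evaluation (0 disables).
#' @param seed seed for the bootstrap.
#' @return an object of class `reason_fit`.
#' @export
fit_reason <- function(methylation, manifest, clinical,
                       filter_params = list(), n_sv = "auto", alpha = 0.1,
                       thresholds = state_thresholds(), clinico_params = list(),
                       n_boot = 2000, seed = 1L) {
  stopifnot(inherits(methylation, "methylation_dataset"))
  if (!identical(sample_ids(methylation), clinical$patient_id)) {
    stopf("methylation samples and clinical patients disagree (ids or order)")
  }
  if (!identical(methylation$outcome, as.integer(clinical$outcome))) {
    stopf("methylation outcome and clinical outcome disagree")
  }
  manifest <- validate_manifest(manifest)

  cascade <- run_cascade(methylation, manifest, filter_params)
  filtered <- cascade$dataset

  svs <- estimate_surrogates(filtered, n_sv = n_sv)
  covariates <- suppressMessages(select_covariates(svs))
  if (ncol(covariates) == 0) covariates <- NULL

  dm <- differential_methylation(filtered, covariates = covariates,
                                 manifest = manifest)
  signature <- select_signature(dm, alpha = alpha)

  molecular <- if (nrow(signature$cpgs) > 0) {
    score_molecular(methylation, signature, thresholds)
  } else {
    NULL
  }

  clinico <- do.call(fit_clinico_score, c(list(cohort = clinical), clinico_params))
  clinico_scores <- attr(clinico, "training_scores")

  scores <- combine_scores(clinico_scores,
                           if (!is.null(molecular)) molecular$scores else NULL)
  panels <- list(clinico = scores$clinico_points,
                 molecular = scores$molecular_points,
                 reason = scores$total)
  evaluation <- tryCatch(
    evaluate_panels(clinical$outcome, panels, n_boot = n_boot, seed = seed),
    error = function(e) NULL
  )

  structure(
    list(filter_report = cascade$report, svs = svs, dm = dm,
         signature = signature, molecular = molecular, clinico = clinico,
         scores = scores, evaluation = evaluation,
         thresholds = thresholds, alpha = alpha,
         outcome = as.integer(clinical$outcome)),
    class = "reason_fit"
  )
}

#' @export
print.reason_fit <- function(x, ...) {
  cat("Composite clinicopathologic + methylation risk score fit\n")
  cat(sprintf("  probes after filtering: %d\n", utils::tail(x$filter_report$n_out, 1)))
  cat(sprintf("  surrogate variables: %d (excluded %d)\n",
              length(x$svs$outcome_corr), sum(!x$svs$retained)))
  cat(sprintf("  signature: %d CpGs over %d genes (adjusted p < %g)\n",
              nrow(x$signature$cpgs), length(x$signature$genes), x$alpha))
  cat(sprintf("  clinicopathologic rules: %d\n", length(x$clinico$rules)))
  if (!is.null(x$evaluation)) {
    for (i in seq_len(nrow(x$evaluation))) {
      cat(sprintf("  c-index (%s): %.3f\n",
                  x$evaluation$panel[i], x$evaluation$c_index[i]))
    }
  }
  invisible(x)
}

#' @export
summary.reason_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.reason_fit")
}

#' @export
print.summary.reason_fit <- function(x, ...) {
  fit <- x$fit
  print(fit)
  cat("\nFilter cascade:\n")
  print(fit$filter_report)
  cat("\nClinicopathologic scoring rules:\n")
  print(fit$clinico)
  if (nrow(fit$signature$cpgs)) {
    cat("\nMethylation signature:\n")
    print(fit$signature)
  }
  if (!is.null(fit$evaluation)) {
    cat("\nPanel evaluation:\n")
    print(fit$evaluation, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.reason_fit <- function(object, ...) {
  terms <- vapply(object$clinico$rules, function(r) {
    paste(vapply(r$conjuncts, condition_label, character(1)), collapse = " & ")
  }, character(1))
  rules <- data.frame(
    component = rep("clinico", length(terms)),
    term = terms,
    points = vapply(object$clinico$rules, function(r) as.numeric(r$points),
                    numeric(1)),
    stringsAsFactors = FALSE
  )
  genes <- if (length(object$signature$genes)) {
    data.frame(component = "molecular",
               term = paste0(object$signature$genes, " (",
                             signature_directions(object$signature)[object$signature$genes],
                             "methylated)"),
               points = 1, stringsAsFactors = FALSE)
  } else {
    NULL
  }
  rbind(rules, genes)
}

#' Score new patients with a fitted composite model
#'
#' Applies the frozen clinicopathologic rules and, when beta values are
#' supplied, the frozen signature with the training cohort's reference
#' states (the transition baseline travels with the model, not the new
#' data).
#'
#' @param object a `reason_fit`.
#' @param clinical clinical data frame for the new patients.
#' @param beta optional probes x samples beta matrix (or
#'   [methylation_dataset()]) holding the signature CpGs for the new
#'   patients.
#' @param ... unused.
#' @return `reason_scores` data frame for the new patients.
#' @export
predict.reason_fit <- function(object, clinical, beta = NULL, ...) {
  clinico <- score_patients(object$clinico, clinical)
  molecular <- NULL
  if (!is.null(beta) && !is.null(object$molecular) &&
      nrow(object$signature$cpgs) > 0) {
    if (!inherits(beta, "methylation_dataset")) {
      detp <- matrix(0, nrow(beta), ncol(beta), dimnames = dimnames(beta))
      outc <- clinical$outcome %||% rep(0L, ncol(beta))
      beta <- methylation_dataset(beta, detp, outc)
    }
    molecular <- score_molecular(beta, object$signature, object$thresholds,
                                 references = object$molecular$references)$scores
  }
  combine_scores(clinico, molecular)
}

#' Score distribution by outcome
#'
#' Strip chart of the composite training score split by 5-year vital
#' status.
#'
#' @param x a `reason_fit`.
#' @param ... passed to [graphics::stripchart()].
#' @export
plot.reason_fit <- function(x, ...) {
  graphics::stripchart(
    x$scores$total ~ factor(x$outcome, c(0, 1), c("Survived", "Died")),
    method = "jitter", vertical = TRUE, pch = 16,
    ylab = "Composite score", xlab = "5-year disease-specific status", ...
  )
  invisible(x)
}
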