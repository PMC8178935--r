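#' Concordance index for a binary 5-year outcome
#'
#' Over all (event, non-event) patient pairs, a pair is concordant when the
#' event patient's score is strictly higher, discordant when strictly
#' lower, and tied pairs receive half credit:
#' c = (concordant + 0.5 tied) / (events x non-events). Equivalent to the
#' area under the ROC curve; 0.5 is random concordance and 1 perfect
#' concordance. Two routes are provided and give identical results: exact
#' pair enumeration (default up to 10^4 patients) and a rank-based
#' O(n log n) computation used beyond that.
#'
#' @param scores numeric score vector.
#' @param outcome binary 0/1 vector; needs at least one event and one
#'   non-event.
#' @param method `"auto"`, `"exact"`, or `"rank"`.
#' @return object of class `concordance_result`: `c_index`,
#'   `n_concordant`, `n_discordant`, `n_tied`, `n_pairs_informative`.
#' @export
c_index <- function(scores, outcome, method = c("auto", "exact", "rank")) {
  method <- match.arg(method)
  if (length(scores) != length(outcome)) {
    stopf("scores and outcome lengths differ (%d vs %d)",
          length(scores), length(outcome))
  }
  if (anyNA(scores) || anyNA(outcome)) stopf("scores and outcome must not contain NA")
  ev <- outcome == 1
  n1 <- sum(ev); n0 <- sum(!ev)
  if (n1 == 0 || n0 == 0) {
    stopf("concordance needs at least one event and one non-event (got %d / %d)",
          n1, n0)
  }
  if (method == "auto") {
    method <- if (length(scores) <= 1e4) "exact" else "rank"
  }
  d <- scores[ev]; s <- scores[!ev]
  if (method == "exact") {
    conc <- 0; tied <- 0
    for (i in seq_len(n1)) {
      conc <- conc + sum(d[i] > s)
      tied <- tied + sum(d[i] == s)
    }
  } else {
    r <- rank(scores, ties.method = "average")
    w <- sum(r[ev]) - n1 * (n1 + 1) / 2
    dt <- table(d); st <- table(s)
    common <- intersect(names(dt), names(st))
    tied <- sum(as.numeric(dt[common]) * as.numeric(st[common]))
    conc <- w - 0.5 * tied
  }
  n_pairs <- as.numeric(n1) * n0
  structure(
    list(c_index = (conc + 0.5 * tied) / n_pairs,
         n_concordant = conc, n_discordant = n_pairs - conc - tied,
         n_tied = tied, n_pairs_informative = n_pairs,
         n_events = n1, n_nonevents = n0),
    class = "concordance_result"
  )
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("c-index = %.4f  (%g concordant, %g discordant, %g tied of %g pairs; %d events / %d non-events)\n",
              x$c_index, x$n_concordant, x$n_discordant, x$n_tied,
              x$n_pairs_informative, x$n_events, x$n_nonevents))
  invisible(x)
}

#' Combine clinicopathologic and molecular scores
#'
#' The composite score is additive: total = clinico points + count of
#' risk-positive signature genes. Patient sets must agree; a missing
#' molecular component degrades gracefully to the clinicopathologic score
#' alone, flagged in attribute `molecular_absent`.
#'
#' @param clinico named integer vector from [score_patients()].
#' @param molecular named integer vector from [score_molecular()]
#'   (`$scores`), or `NULL` when no methylation data exist.
#' @return data frame of class `reason_scores` with columns `patient_id`,
#'   `clinico_points`, `molecular_points`, `total`.
#' @export
combine_scores <- function(clinico, molecular = NULL) {
  if (is.null(names(clinico))) stopf("clinico scores must be named by patient")
  if (is.null(molecular)) {
    out <- data.frame(patient_id = names(clinico),
                      clinico_points = as.integer(clinico),
                      molecular_points = 0L,
                      total = as.integer(clinico),
                      stringsAsFactors = FALSE)
    attr(out, "molecular_absent") <- TRUE
    class(out) <- c("reason_scores", "data.frame")
    return(out)
  }
  only_c <- setdiff(names(clinico), names(molecular))
  only_m <- setdiff(names(molecular), names(clinico))
  if (length(only_c) || length(only_m)) {
    stopf("patient sets differ; only in clinico: {%s}; only in molecular: {%s}",
          paste(only_c, collapse = ", "), paste(only_m, collapse = ", "))
  }
  molecular <- molecular[names(clinico)]
  out <- data.frame(patient_id = names(clinico),
                    clinico_points = as.integer(clinico),
                    molecular_points = as.integer(molecular),
                    total = as.integer(clinico + molecular),
                    stringsAsFactors = FALSE)
  attr(out, "molecular_absent") <- FALSE
  class(out) <- c("reason_scores", "data.frame")
  out
}

#' Compare score panels by concordance index
#'
#' Computes the c-index of each panel (typically clinico-only,
#' molecular-only, and the composite) on the same cohort, with seeded
#' patient-level bootstrap percentile intervals.
#'
#' @param outcome binary 0/1 vector.
#' @param panels named list of score vectors aligned with `outcome`.
#' @param n_boot bootstrap resamples (default 2000; 0 disables intervals).
#' @param seed bootstrap seed.
#' @param conf interval coverage (default 0.95).
#' @return data frame: panel, c_index, lower, upper, n_pairs.
#' @export
evaluate_panels <- function(outcome, panels, n_boot = 2000, seed = 1L,
                            conf = 0.95) {
  stopifnot(is.list(panels), length(names(panels)) == length(panels))
  point <- vapply(panels, function(s) c_index(s, outcome)$c_index, numeric(1))
  n_pairs <- vapply(panels, function(s) c_index(s, outcome)$n_pairs_informative,
                    numeric(1))
  lower <- upper <- rep(NA_real_, length(panels))
  if (n_boot > 0) {
    n <- length(outcome)
    boots <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        repeat {
          idx <- sample.int(n, n, replace = TRUE)
          if (any(outcome[idx] == 1) && any(outcome[idx] == 0)) break
        }
        vapply(panels, function(s) c_index(s[idx], outcome[idx])$c_index,
               numeric(1))
      }, numeric(length(panels)))
    })
    boots <- matrix(boots, nrow = length(panels))
    alpha <- (1 - conf) / 2
    lower <- apply(boots, 1, stats::quantile, probs = alpha, names = FALSE)
    upper <- apply(boots, 1, stats::quantile, probs = 1 - alpha, names = FALSE)
  }
  data.frame(panel = names(panels), c_index = unname(point),
             lower = lower, upper = upper, n_pairs = unname(n_pairs),
             stringsAsFactors = FALSE)
}
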