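#' Methylation state thresholds
#'
#' The molecular component discretizes each CpG's beta value into three
#' ordered states: unmethylated (beta < 0.3), hemi-methylated (0.33-0.75),
#' and fully methylated (> 0.75). The unspecified interval \[0.30, 0.33) is
#' merged into the unmethylated state, giving a single lower boundary at
#' `hemi_low`; the hemi-methylated interval is closed at both ends. Both
#' choices are configurable here rather than hard-wired.
#'
#' @param unmeth_below nominal upper bound of the unmethylated state
#'   (default 0.3; documentation only, the operative boundary is
#'   `hemi_low`).
#' @param hemi_low lower closed bound of the hemi-methylated state
#'   (default 0.33).
#' @param hemi_high upper closed bound of the hemi-methylated state
#'   (default 0.75).
#' @return an object of class `state_thresholds`.
#' @export
state_thresholds <- function(unmeth_below = 0.3, hemi_low = 0.33, hemi_high = 0.75) {
  if (!(0 < unmeth_below && unmeth_below <= hemi_low &&
        hemi_low < hemi_high && hemi_high < 1)) {
    stopf("invalid state thresholds: need 0 < unmeth_below <= hemi_low < hemi_high < 1")
  }
  structure(list(unmeth_below = unmeth_below, hemi_low = hemi_low,
                 hemi_high = hemi_high),
            class = "state_thresholds")
}

STATE_LEVELS <- c("UNMETH", "HEMI", "FULL")

# integer state codes 1/2/3; vectorized over beta
state_code <- function(beta, thresholds) {
  if (anyNA(beta) || any(beta < 0 | beta > 1)) {
    stopf("beta values must lie in [0,1] for state assignment")
  }
  1L + (beta >= thresholds$hemi_low) + (beta > thresholds$hemi_high)
}

#' Assign methylation states
#'
#' Maps beta values onto the ordered states UNMETH < HEMI < FULL:
#' beta < `hemi_low` is UNMETH, `hemi_low` <= beta <= `hemi_high` is HEMI,
#' beta > `hemi_high` is FULL. Total and monotone in beta.
#'
#' @param beta numeric vector of beta values in \[0,1\].
#' @param thresholds a [state_thresholds()].
#' @return ordered factor with levels UNMETH < HEMI < FULL.
#' @export
assign_state <- function(beta, thresholds = state_thresholds()) {
  factor(STATE_LEVELS[state_code(beta, thresholds)],
         levels = STATE_LEVELS, ordered = TRUE)
}

#' Reference methylation states from 5-year survivors
#'
#' The transition baseline of each signature CpG is the state of the median
#' beta among event-free patients; with an even survivor count the
#' lower-middle order statistic is used so the reference stays an observed
#' beta.
#'
#' @param dataset a [methylation_dataset()] containing the signature CpGs.
#' @param signature a `dm_signature` (or data frame with `probe_id`,
#'   `gene`).
#' @param thresholds a [state_thresholds()].
#' @return data frame: `probe_id`, `gene`, `reference_beta`,
#'   `reference_state` (integer code 1-3).
#' @export
reference_states <- function(dataset, signature, thresholds = state_thresholds()) {
  cpgs <- if (inherits(signature, "dm_signature")) signature$cpgs else signature
  surv <- dataset$outcome == 0
  if (!any(surv)) stopf("reference states require at least one event-free patient")
  present <- cpgs$probe_id %in% probe_ids(dataset)
  cpgs <- cpgs[present, , drop = FALSE]
  ref_beta <- vapply(cpgs$probe_id, function(id) {
    b <- sort(dataset$beta[id, surv])
    b[floor((length(b) + 1) / 2)]  # lower-middle median
  }, numeric(1))
  data.frame(probe_id = cpgs$probe_id, gene = cpgs$gene,
             reference_beta = unname(ref_beta),
             reference_state = state_code(unname(ref_beta), thresholds),
             stringsAsFactors = FALSE)
}

#' Per-patient molecular risk calls and scores
#'
#' For every patient and signature CpG, assigns the methylation state,
#' compares it with the survivor-derived reference state, and classifies
#' the transition as HYPER (state above reference), HYPO (below), or NONE.
#' A change in methylation without a state change never contributes. A
#' gene is risk-positive for a patient when at least one of its CpGs shows
#' a transition matching the gene's differential-methylation risk
#' direction (HYPER for positive effect, HYPO for negative); the molecular
#' score is the count of risk-positive genes.
#'
#' @param dataset a [methylation_dataset()] holding the signature CpGs
#'   (genes with no CpG present are warned about and scored 0).
#' @param signature a `dm_signature`.
#' @param thresholds a [state_thresholds()].
#' @param references optional pre-computed [reference_states()] (e.g. from
#'   a training cohort); computed from `dataset` when omitted.
#' @return object of class `molecular_scores`: `calls` (long data frame of
#'   per-patient per-CpG state calls), `gene_flags` (patients x genes
#'   logical matrix), `scores` (named integer vector), `references`.
#' @export
score_molecular <- function(dataset, signature, thresholds = state_thresholds(),
                            references = NULL) {
  stopifnot(inherits(signature, "dm_signature"))
  if (is.null(references)) {
    references <- reference_states(dataset, signature, thresholds)
  }
  directions <- signature_directions(signature)
  cpgs <- signature$cpgs
  missing_genes <- setdiff(signature$genes,
                           cpgs$gene[cpgs$probe_id %in% probe_ids(dataset)])
  if (length(missing_genes)) {
    warnf("signature gene(s) with no CpG in the dataset, scored 0: %s",
          paste(missing_genes, collapse = ", "))
  }
  cpgs <- cpgs[cpgs$probe_id %in% probe_ids(dataset) &
                 cpgs$probe_id %in% references$probe_id, , drop = FALSE]
  patients <- sample_ids(dataset)
  genes <- signature$genes
  gene_flags <- matrix(FALSE, length(patients), length(genes),
                       dimnames = list(patients, genes))
  calls <- NULL
  if (nrow(cpgs)) {
    st <- state_code(dataset$beta[cpgs$probe_id, , drop = FALSE], thresholds)
    st <- matrix(st, nrow(cpgs), length(patients),
                 dimnames = list(cpgs$probe_id, patients))
    ref <- references$reference_state[match(cpgs$probe_id, references$probe_id)]
    trans <- matrix("NONE", nrow(cpgs), length(patients),
                    dimnames = dimnames(st))
    trans[st > ref] <- "HYPER"
    trans[st < ref] <- "HYPO"
    want <- toupper(directions[cpgs$gene])  # HYPER / HYPO per CpG row
    cpg_risk <- trans == want
    for (g in intersect(genes, cpgs$gene)) {
      rows <- which(cpgs$gene == g)
      gene_flags[, g] <- colSums(cpg_risk[rows, , drop = FALSE]) > 0
    }
    calls <- data.frame(
      patient_id = rep(patients, each = nrow(cpgs)),
      cpg_id = rep(cpgs$probe_id, length(patients)),
      gene = rep(cpgs$gene, length(patients)),
      state = STATE_LEVELS[as.vector(st)],
      reference_state = rep(STATE_LEVELS[ref], length(patients)),
      transition = as.vector(trans),
      risk_flag = as.vector(cpg_risk),
      stringsAsFactors = FALSE
    )
  }
  structure(
    list(calls = calls, gene_flags = gene_flags,
         scores = stats::setNames(as.integer(rowSums(gene_flags)), patients),
         references = references, thresholds = thresholds),
    class = "molecular_scores"
  )
}

#' @export
print.molecular_scores <- function(x, ...) {
  cat(sprintf("molecular_scores: %d patients, %d genes; score range %d-%d\n",
              length(x$scores), ncol(x$gene_flags),
              min(x$scores), max(x$scores)))
  invisible(x)
}
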