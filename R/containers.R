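#' Methylation dataset container
#'
#' Bundles an aligned beta-value matrix (probes x samples, values in
#' \[0,1\]), the matching detection p-value matrix, and the per-sample binary
#' 5-year disease-specific vital status (1 = died of disease by 5 years).
#' Both matrices must share dimensions and dimnames, and every sample must
#' carry an outcome.
#'
#' @param beta numeric matrix of beta values in \[0,1\] with probe rownames
#'   and sample colnames.
#' @param detection_p numeric matrix of detection p-values in \[0,1\], same
#'   shape and dimnames as `beta`.
#' @param outcome binary (0/1) vector, one per sample; may be named by
#'   sample id, in which case it is aligned to the column order of `beta`.
#' @return an object of class `methylation_dataset`.
#' @export
methylation_dataset <- function(beta, detection_p, outcome) {
  if (!is.matrix(beta) || !is.numeric(beta)) {
    stopf("beta must be a numeric matrix")
  }
  if (is.null(rownames(beta)) || is.null(colnames(beta))) {
    stopf("beta must carry probe rownames and sample colnames")
  }
  if (anyDuplicated(rownames(beta))) stopf("duplicated probe ids in beta")
  if (anyDuplicated(colnames(beta))) stopf("duplicated sample ids in beta")
  if (!is.matrix(detection_p) || !identical(dim(beta), dim(detection_p))) {
    stopf("detection_p must be a matrix with the same shape as beta")
  }
  if (!identical(dimnames(beta), dimnames(detection_p))) {
    stopf("beta and detection_p dimnames disagree")
  }
  rng <- range(beta)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 1) {
    stopf("beta values must lie in [0,1] and contain no NA")
  }
  rng <- range(detection_p)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 1) {
    stopf("detection p-values must lie in [0,1] and contain no NA")
  }
  if (!is.null(names(outcome))) {
    if (!setequal(names(outcome), colnames(beta))) {
      stopf("outcome names do not match the sample ids")
    }
    outcome <- outcome[colnames(beta)]
  }
  if (length(outcome) != ncol(beta)) {
    stopf("need one outcome per sample: %d outcomes for %d samples",
          length(outcome), ncol(beta))
  }
  if (anyNA(outcome) || !all(outcome %in% c(0, 1))) {
    stopf("outcome must be binary 0/1 with no missing values")
  }
  structure(
    list(beta = beta, detection_p = detection_p,
         outcome = as.integer(unname(outcome))),
    class = "methylation_dataset"
  )
}

#' @export
print.methylation_dataset <- function(x, ...) {
  cat(sprintf("methylation_dataset: %d probes x %d samples (%d events, %d non-events)\n",
              nrow(x$beta), ncol(x$beta), sum(x$outcome), sum(1 - x$outcome)))
  invisible(x)
}

#' @rdname methylation_dataset
#' @param x a `methylation_dataset`.
#' @export
probe_ids <- function(x) rownames(x$beta)

#' @rdname methylation_dataset
#' @export
sample_ids <- function(x) colnames(x$beta)

# retain a subset of probes, preserving alignment of both matrices
subset_probes <- function(dataset, keep) {
  dataset$beta <- dataset$beta[keep, , drop = FALSE]
  dataset$detection_p <- dataset$detection_p[keep, , drop = FALSE]
  dataset
}

VALID_CHROMS <- c(as.character(1:22), "X", "Y")

#' Validate a probe manifest
#'
#' A manifest is a data frame with one row per array probe and columns
#' `probe_id`, `chrom` ("1".."22", "X", "Y"), `pos` (1-based), `gene`
#' (semicolon-separated symbols, empty string when the probe maps to no gene
#' region), `snp_flag`, and `cross_reactive_flag` (probes that are cross
#' reactive or map to multiple genomic positions).
#'
#' @param manifest data frame to validate.
#' @return the manifest, invisibly, with flags coerced to logical.
#' @export
validate_manifest <- function(manifest) {
  required <- c("probe_id", "chrom", "pos", "gene", "snp_flag", "cross_reactive_flag")
  missing <- setdiff(required, names(manifest))
  if (length(missing)) {
    stopf("manifest is missing column(s): %s", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(manifest$probe_id)) {
    dup <- manifest$probe_id[duplicated(manifest$probe_id)][1]
    stopf("duplicated probe id in manifest: %s", dup)
  }
  bad <- setdiff(unique(manifest$chrom), VALID_CHROMS)
  if (length(bad)) {
    stopf("invalid chromosome name(s) in manifest: %s", paste(bad, collapse = ", "))
  }
  if (any(manifest$pos < 1, na.rm = TRUE)) stopf("manifest positions must be 1-based")
  manifest$snp_flag <- as.logical(manifest$snp_flag)
  manifest$cross_reactive_flag <- as.logical(manifest$cross_reactive_flag)
  manifest$gene[is.na(manifest$gene)] <- ""
  invisible(manifest)
}

# manifest rows for the dataset's probes, erroring on any probe absent
# from the manifest (named in the error)
manifest_for <- function(dataset, manifest) {
  idx <- match(probe_ids(dataset), manifest$probe_id)
  if (anyNA(idx)) {
    miss <- probe_ids(dataset)[is.na(idx)]
    stopf("probe(s) missing from manifest: %s%s",
          paste(utils::head(miss, 5), collapse = ", "),
          if (length(miss) > 5) sprintf(" (and %d more)", length(miss) - 5) else "")
  }
  manifest[idx, , drop = FALSE]
}
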