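#' Probe filter cascade
#'
#' The discovery pipeline reduces the 450K array through an ordered cascade
#' of probe filters, each recorded in an auditable per-stage report:
#' sex-chromosome removal, SNP-associated removal, gene-unmapped removal,
#' detection p-value filtering, cross-reactive removal, uninformative-beta
#' removal, and top-variance selection. Each stage function returns the
#' reduced dataset plus its report entry; [run_cascade()] chains all seven.
#'
#' @name probe_filters
NULL

report_entry <- function(stage, n_in, n_out) {
  data.frame(stage = stage, n_in = n_in, n_removed = n_in - n_out,
             n_out = n_out, stringsAsFactors = FALSE)
}

#' @describeIn probe_filters remove probes hybridizing to chromosomes X or Y.
#' @param dataset a [methylation_dataset()].
#' @param manifest a validated probe manifest covering every dataset probe.
#' @return each stage returns `list(dataset, report)`; `run_cascade()`
#'   returns `list(dataset, report)` with the full `filter_cascade_report`.
#' @export
filter_sex_chromosomes <- function(dataset, manifest) {
  ann <- manifest_for(dataset, manifest)
  keep <- !(ann$chrom %in% c("X", "Y"))
  list(dataset = subset_probes(dataset, keep),
       report = report_entry("sex_chromosomes", length(keep), sum(keep)))
}

#' @describeIn probe_filters remove SNP-associated probes, then probes that
#'   map to no gene region (two report entries, in that order; a probe with
#'   both flags is counted in the SNP stage).
#' @export
filter_snp_and_unmapped <- function(dataset, manifest) {
  ann <- manifest_for(dataset, manifest)
  keep <- !ann$snp_flag
  e1 <- report_entry("snp", length(keep), sum(keep))
  dataset <- subset_probes(dataset, keep)
  ann <- ann[keep, , drop = FALSE]
  keep <- !(is.na(ann$gene) | ann$gene == "")
  e2 <- report_entry("unmapped", length(keep), sum(keep))
  list(dataset = subset_probes(dataset, keep), report = rbind(e1, e2))
}

#' @describeIn probe_filters retain probes with detection p below
#'   `p_threshold` in at least `sample_fraction` of samples (boundary
#'   inclusive: exactly 50% passes).
#' @param p_threshold detection p-value cut (default 0.01).
#' @param sample_fraction minimum fraction of passing samples (default 0.5).
#' @export
filter_detection <- function(dataset, p_threshold = 0.01, sample_fraction = 0.5) {
  n <- ncol(dataset$detection_p)
  if (n == 0) stopf("detection filter requires at least one sample")
  pass <- rowSums(dataset$detection_p < p_threshold) / n
  keep <- pass >= sample_fraction
  list(dataset = subset_probes(dataset, keep),
       report = report_entry("detection_p", length(keep), sum(keep)))
}

#' @describeIn probe_filters remove probes flagged cross-reactive or mapped
#'   to multiple genomic positions.
#' @export
filter_cross_reactive <- function(dataset, manifest) {
  ann <- manifest_for(dataset, manifest)
  keep <- !ann$cross_reactive_flag
  list(dataset = subset_probes(dataset, keep),
       report = report_entry("cross_reactive", length(keep), sum(keep)))
}

#' @describeIn probe_filters remove probes whose beta is below `low` in all
#'   samples or above `high` in all samples.
#' @param low,high uninformative-beta cuts (defaults 0.1 and 0.9).
#' @export
filter_uninformative_beta <- function(dataset, low = 0.1, high = 0.9) {
  keep <- !(row_max(dataset$beta) < low | row_min(dataset$beta) > high)
  list(dataset = subset_probes(dataset, keep),
       report = report_entry("uninformative_beta", length(keep), sum(keep)))
}

#' @describeIn probe_filters retain the `floor(fraction * n)` probes with
#'   the largest unbiased sample variance of beta; ties at the cut broken by
#'   probe id, lexicographically.
#' @param fraction fraction of probes to keep (default 0.30).
#' @export
filter_top_variance <- function(dataset, fraction = 0.30) {
  n_in <- nrow(dataset$beta)
  if (n_in == 0) {
    return(list(dataset = dataset, report = report_entry("top_variance", 0L, 0L)))
  }
  if (ncol(dataset$beta) < 2) stopf("variance filter requires >= 2 samples")
  v <- row_var(dataset$beta)
  n_keep <- floor(fraction * n_in)
  ord <- order(-v, probe_ids(dataset))
  keep_ids <- probe_ids(dataset)[ord[seq_len(n_keep)]]
  keep <- probe_ids(dataset) %in% keep_ids
  list(dataset = subset_probes(dataset, keep),
       report = report_entry("top_variance", n_in, n_keep))
}

#' @describeIn probe_filters run the full seven-stage cascade in its fixed
#'   order: sex-chrom, SNP, unmapped, detection, cross-reactive,
#'   uninformative-beta, top-variance.
#' @param params optional overrides: `p_threshold`, `sample_fraction`,
#'   `beta_low`, `beta_high`, `variance_fraction`.
#' @export
run_cascade <- function(dataset, manifest, params = list()) {
  p <- utils::modifyList(
    list(p_threshold = 0.01, sample_fraction = 0.5,
         beta_low = 0.1, beta_high = 0.9, variance_fraction = 0.30),
    params
  )
  steps <- list(
    function(d) filter_sex_chromosomes(d, manifest),
    function(d) filter_snp_and_unmapped(d, manifest),
    function(d) filter_detection(d, p$p_threshold, p$sample_fraction),
    function(d) filter_cross_reactive(d, manifest),
    function(d) filter_uninformative_beta(d, p$beta_low, p$beta_high),
    function(d) filter_top_variance(d, p$variance_fraction)
  )
  report <- NULL
  for (step in steps) {
    res <- step(dataset)
    dataset <- res$dataset
    report <- rbind(report, res$report)
  }
  class(report) <- c("filter_cascade_report", "data.frame")
  list(dataset = dataset, report = report)
}

#' @export
print.filter_cascade_report <- function(x, ...) {
  cat("Probe filter cascade\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-18s %9d -> %9d  (removed %d)\n",
                x$stage[i], x$n_in[i], x$n_out[i], x$n_removed[i]))
  }
  invisible(x)
}

#' Write a filter cascade report as TSV
#'
#' @param report a `filter_cascade_report`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_filter_report <- function(report, path) {
  data.table::fwrite(as.data.frame(report), path, sep = "\t")
  invisible(path)
}
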