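PIPELINE_PARAM_KEYS <- c(
  "p_threshold", "sample_fraction", "beta_low", "beta_high",
  "variance_fraction", "n_sv", "alpha", "unmeth_below", "hemi_low",
  "hemi_high", "min_leaf", "max_depth", "stop_alpha", "n_boot",
  "min_count", "min_fraction"
)

#' Pipeline configuration
#'
#' Collects the input paths, output directory, per-stage parameters, and
#' the top-level seed for an end-to-end run. Unknown parameter keys are
#' rejected so typos fail loudly instead of silently using defaults.
#'
#' @param beta,detection_p,manifest,clinical input file paths (required).
#' @param counts,gmt optional expression counts and gene-set paths; the
#'   downstream stage runs only when both are present.
#' @param out output directory.
#' @param params named list of stage parameters; allowed keys:
#'   `p_threshold`, `sample_fraction`, `beta_low`, `beta_high`,
#'   `variance_fraction`, `n_sv`, `alpha`, `unmeth_below`, `hemi_low`,
#'   `hemi_high`, `min_leaf`, `max_depth`, `stop_alpha`, `n_boot`,
#'   `min_count`, `min_fraction`.
#' @param seed top-level seed.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(beta, detection_p, manifest, clinical,
                            counts = NULL, gmt = NULL, out = "reason_out",
                            params = list(), seed = 1L) {
  unknown <- setdiff(names(params), PIPELINE_PARAM_KEYS)
  if (length(unknown)) {
    stopf("unknown pipeline parameter(s): %s", paste(unknown, collapse = ", "))
  }
  structure(
    list(beta = beta, detection_p = detection_p, manifest = manifest,
         clinical = clinical, counts = counts, gmt = gmt, out = out,
         params = params, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Expected top-level keys: `inputs` (beta, detection_p, manifest,
#' clinical, optionally counts, gmt), `out`, optional `params`, optional
#' `seed`. Unknown keys at either level are rejected.
#'
#' @param path YAML file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  unknown <- setdiff(names(y), c("inputs", "out", "params", "seed"))
  if (length(unknown)) stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  inputs <- y$inputs %||% list()
  unknown <- setdiff(names(inputs),
                     c("beta", "detection_p", "manifest", "clinical", "counts", "gmt"))
  if (length(unknown)) stopf("unknown inputs key(s): %s", paste(unknown, collapse = ", "))
  pipeline_config(beta = inputs$beta, detection_p = inputs$detection_p,
                  manifest = inputs$manifest, clinical = inputs$clinical,
                  counts = inputs$counts, gmt = inputs$gmt,
                  out = y$out %||% "reason_out", params = y$params %||% list(),
                  seed = y$seed %||% 1L)
}

#' Run the full pipeline from files to an artifact directory
#'
#' Executes filter, surrogate-variable, differential-methylation,
#' state-scoring, clinicopathologic-scoring, combination/evaluation, and
#' (when expression inputs are configured) downstream stages, persisting
#' every intermediate as TSV/JSON, a run log echoing all parameters, and a
#' `manifest.json` listing the produced files with MD5 content hashes.
#'
#' @param config a [pipeline_config()] or a path to a YAML config.
#' @return invisibly, a list with the `reason_fit` object and the artifact
#'   paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out, "run.log")
  log_lines <- c(
    sprintf("seed: %d", config$seed),
    sprintf("param %s: %s", names(config$params),
            vapply(config$params, function(v) paste(format(v), collapse = ","),
                   character(1)))
  )

  clinical <- read_clinical(config$clinical)
  beta <- read_matrix(config$beta, "beta")
  detp <- read_matrix(config$detection_p, "detection_p")
  manifest <- read_manifest(config$manifest)
  dataset <- methylation_dataset(
    beta, detp, stats::setNames(clinical$outcome, clinical$patient_id))

  p <- config$params
  thresholds <- state_thresholds(p$unmeth_below %||% 0.3, p$hemi_low %||% 0.33,
                                 p$hemi_high %||% 0.75)
  fit <- fit_reason(
    dataset, manifest, clinical,
    filter_params = p[intersect(names(p), c("p_threshold", "sample_fraction",
                                            "beta_low", "beta_high",
                                            "variance_fraction"))],
    n_sv = p$n_sv %||% "auto", alpha = p$alpha %||% 0.1,
    thresholds = thresholds,
    clinico_params = p[intersect(names(p), c("min_leaf", "max_depth", "stop_alpha"))],
    n_boot = p$n_boot %||% 2000, seed = derive_seed(config$seed, "bootstrap")
  )

  paths <- character()
  emit <- function(name, writer) {
    path <- file.path(config$out, name)
    writer(path)
    paths[[name]] <<- path
  }
  emit("filter_report.tsv", function(f) write_filter_report(fit$filter_report, f))
  log_lines <- c(log_lines, utils::capture.output(print(fit$filter_report)))
  emit("sv.tsv", function(f) {
    sv <- suppressMessages(select_covariates(fit$svs))
    data.table::fwrite(data.table::data.table(sample_id = rownames(sv), sv),
                       f, sep = "\t")
  })
  emit("sv_report.tsv", function(f) data.table::fwrite(sv_report(fit$svs), f, sep = "\t"))
  emit("dm_results.tsv", function(f) data.table::fwrite(as.data.frame(fit$dm), f, sep = "\t"))
  emit("signature.json", function(f) {
    jsonlite::write_json(
      list(genes = fit$signature$genes, cpgs = fit$signature$cpgs,
           directions = as.list(signature_directions(fit$signature))),
      f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })
  if (!is.null(fit$molecular)) {
    emit("state_calls.tsv", function(f) data.table::fwrite(fit$molecular$calls, f, sep = "\t"))
    emit("molecular_scores.tsv", function(f) {
      data.table::fwrite(data.table::data.table(
        patient_id = names(fit$molecular$scores),
        molecular_score = fit$molecular$scores), f, sep = "\t")
    })
  }
  emit("clinico_model.json", function(f) {
    rules <- lapply(fit$clinico$rules, function(r) {
      list(condition = paste(vapply(r$conjuncts, condition_label, character(1)),
                             collapse = " & "),
           points = r$points, node_or = r$node_or, n = r$n)
    })
    jsonlite::write_json(list(rules = rules, cuts = fit$clinico$cuts),
                         f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })
  emit("clinico_scores.tsv", function(f) {
    s <- attr(fit$clinico, "training_scores")
    data.table::fwrite(data.table::data.table(patient_id = names(s),
                                              clinico_score = s), f, sep = "\t")
  })
  emit("reason_scores.tsv", function(f) {
    data.table::fwrite(as.data.frame(fit$scores), f, sep = "\t")
  })
  if (!is.null(fit$evaluation)) {
    emit("evaluation.json", function(f) {
      jsonlite::write_json(fit$evaluation, f, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
    })
  }

  if (!is.null(config$counts) && !is.null(config$gmt) &&
      nrow(fit$signature$cpgs) > 0) {
    counts <- read_matrix(config$counts, "counts")
    expressed <- filter_expressed(counts, p$min_count %||% 10,
                                  p$min_fraction %||% 0.9)
    shared <- intersect(colnames(expressed), sample_ids(dataset))
    if (length(shared) >= 3) {
      correlations <- correlate_expression_methylation(
        expressed[, shared, drop = FALSE],
        dataset$beta[, shared, drop = FALSE], fit$signature)
      emit("correlations.tsv", function(f) data.table::fwrite(correlations, f, sep = "\t"))
    }
    sets <- read_gmt(config$gmt)
    universe <- ora_universe(fit$dm)
    query <- intersect(fit$signature$genes, universe)
    if (length(query)) {
      enrichment <- ora(query, universe, sets)
      emit("ora_results.tsv", function(f) data.table::fwrite(as.data.frame(enrichment), f, sep = "\t"))
    }
  }

  writeLines(log_lines, log_path)
  paths[["run.log"]] <- log_path
  hashes <- tools::md5sum(unname(unlist(paths)))
  manifest_path <- file.path(config$out, "manifest.json")
  jsonlite::write_json(
    lapply(stats::setNames(names(paths), names(paths)),
           function(n) list(path = unname(paths[[n]]),
                            md5 = unname(hashes[[paths[[n]]]]))),
    manifest_path, auto_unbox = TRUE, pretty = TRUE)

  invisible(list(fit = fit, paths = c(paths, manifest.json = manifest_path)))
}
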