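#' Simulation configuration
#'
#' Describes a synthetic early-stage oral-cancer study: cohort size and
#' 5-year disease-specific event rate, array size and composition, the
#' planted methylation signature (13 CpGs over 12 genes by default, shifted
#' by `delta_beta` in deceased patients), planted clinicopathologic effects
#' (odds multipliers per risk factor), a batch structure optionally
#' correlated with outcome, and signed expression-methylation correlation
#' targets for chosen signature genes.
#'
#' Default array-composition fractions follow the published 450K filter
#' bookkeeping (X/Y 11,648 / 485,512, SNP 17,351 / 485,512, gene-unmapped
#' 111,977 / 485,512, cross-reactive 20,071 / 485,512); the categories are
#' generated disjointly so filter arithmetic chains exactly.
#'
#' @param n_patients number of patients.
#' @param n_probes number of array probes.
#' @param n_signature_genes number of planted signature genes (default 12).
#' @param n_signature_cpgs number of planted signature CpGs (default 13;
#'   must be >= `n_signature_genes`; extras are assigned to the first genes).
#' @param event_rate target proportion of 5-year disease-specific deaths,
#'   in (0,1).
#' @param delta_beta beta-scale shift planted at signature CpGs in deceased
#'   patients (clipped into \[0,1\], never an error).
#' @param clinical_effects named numeric vector of odds multipliers for the
#'   risk level of clinicopathologic features (see
#'   [default_clinical_effects()]).
#' @param n_batches number of processing batches.
#' @param batch_outcome_corr target phi correlation between the first batch
#'   indicator and outcome, in \[0,1).
#' @param batch_sd sd of per-probe batch loadings on the logit scale.
#' @param beta_sd sd of per-probe logit-normal measurement noise.
#' @param expr_corr named numeric vector of target Pearson correlations
#'   (|r| < 1) between a signature gene's expression and its CpG's beta.
#' @param n_genes_expr number of genes in the simulated count matrix.
#' @param frac_xy,frac_snp,frac_unmapped,frac_cross_reactive fractions of
#'   probes on X/Y, SNP-flagged, mapping to no gene region, and
#'   cross-reactive / multi-mapping.
#' @param frac_uninformative fraction of probes with beta < 0.1 in all
#'   samples or > 0.9 in all samples.
#' @param detp_fail_rate per-entry probability of a failed detection
#'   p-value (p >= 0.01).
#' @param n_bad_probes number of probes failing detection in > 50% of
#'   samples.
#' @param seed top-level integer seed; every stage derives its own stream
#'   from it.
#' @param design_seed seed for the array-design decisions (probe class
#'   assignment, gene mapping, baselines, signature placement and
#'   directions, batch loadings). Defaults to `seed`; hold it fixed while
#'   varying `seed` to draw independent patient cohorts measured on the
#'   same array design (see [replicate_config()]).
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_patients,
                              n_probes = 2000,
                              n_signature_genes = 12,
                              n_signature_cpgs = 13,
                              event_rate = 0.14,
                              delta_beta = 0.25,
                              clinical_effects = default_clinical_effects(),
                              n_batches = 2,
                              batch_outcome_corr = 0,
                              batch_sd = 0.5,
                              beta_sd = 0.4,
                              expr_corr = NULL,
                              n_genes_expr = 500,
                              frac_xy = 0.024,
                              frac_snp = 0.036,
                              frac_unmapped = 0.231,
                              frac_cross_reactive = 0.041,
                              frac_uninformative = 0.015,
                              detp_fail_rate = 0.002,
                              n_bad_probes = 5,
                              seed = 1L,
                              design_seed = NULL) {
  if (length(n_patients) != 1 || is.na(n_patients) || n_patients < 1) {
    stopf("configuration error: n_patients must be a positive count")
  }
  if (event_rate <= 0 || event_rate >= 1) {
    stopf("configuration error: event_rate must lie in (0,1)")
  }
  if (n_signature_cpgs < n_signature_genes) {
    stopf("configuration error: n_signature_cpgs (%d) < n_signature_genes (%d)",
          n_signature_cpgs, n_signature_genes)
  }
  if (event_rate * n_patients < 2) {
    stopf("configuration error: expected events event_rate * n_patients = %.2f < 2",
          event_rate * n_patients)
  }
  if (!is.null(expr_corr)) {
    if (is.null(names(expr_corr)) || any(names(expr_corr) == "")) {
      stopf("configuration error: expr_corr must be a named vector")
    }
    if (any(abs(expr_corr) >= 1)) {
      stopf("configuration error: |expr_corr| must be < 1")
    }
  }
  if (batch_outcome_corr < 0 || batch_outcome_corr >= 1) {
    stopf("configuration error: batch_outcome_corr must lie in [0,1)")
  }
  if (!is.null(clinical_effects)) {
    unknown <- setdiff(names(clinical_effects), clinico_panel_features())
    if (length(unknown)) {
      stopf("configuration error: unknown clinical_effects feature(s): %s",
            paste(unknown, collapse = ", "))
    }
    if (any(clinical_effects <= 0)) {
      stopf("configuration error: clinical_effects must be positive odds multipliers")
    }
  }
  structure(
    list(n_patients = as.integer(n_patients), n_probes = as.integer(n_probes),
         n_signature_genes = as.integer(n_signature_genes),
         n_signature_cpgs = as.integer(n_signature_cpgs),
         event_rate = event_rate, delta_beta = delta_beta,
         clinical_effects = clinical_effects, n_batches = as.integer(n_batches),
         batch_outcome_corr = batch_outcome_corr, batch_sd = batch_sd,
         beta_sd = beta_sd, expr_corr = expr_corr,
         n_genes_expr = as.integer(n_genes_expr),
         frac_xy = frac_xy, frac_snp = frac_snp, frac_unmapped = frac_unmapped,
         frac_cross_reactive = frac_cross_reactive,
         frac_uninformative = frac_uninformative,
         detp_fail_rate = detp_fail_rate, n_bad_probes = as.integer(n_bad_probes),
         seed = as.integer(seed),
         design_seed = as.integer(design_seed %||% seed)),
    class = "simulation_config"
  )
}

#' Replicate configuration on the same array design
#'
#' Returns a copy of `config` with a new patient-sampling seed but the
#' same `design_seed`, so the replicate cohort is measured on an identical
#' array (same probe classes, signature CpG ids and directions, batch
#' loadings) with independently drawn patients.
#'
#' @param config a [simulation_config()].
#' @param seed new patient-sampling seed.
#' @return a `simulation_config`.
#' @export
replicate_config <- function(config, seed) {
  stopifnot(inherits(config, "simulation_config"))
  config$seed <- as.integer(seed)
  config
}

#' The ten-feature clinicopathologic panel
#'
#' @return character vector of the ten panel feature names.
#' @export
clinico_panel_features <- function() {
  c("age", "race", "sex", "tobacco", "alcohol",
    "grade", "stage", "pni", "lvi", "margin")
}

#' Default planted clinicopathologic odds multipliers
#'
#' Moderate effect sizes (OR 1.2-2.5) typical of pathologic risk factors in
#' early-stage oral cancer cohorts; applied to the risk level of each
#' feature (age >= 65, male sex, non-white race, ever-tobacco, alcohol use,
#' moderate/poor grade, stage II, PNI, LVI, positive/close margins).
#'
#' @return named numeric vector of odds multipliers.
#' @export
default_clinical_effects <- function() {
  c(age = 1.8, sex = 1.2, race = 1.5, tobacco = 1.5, alcohol = 1.3,
    grade = 1.8, stage = 2.0, pni = 2.5, lvi = 2.0, margin = 2.0)
}

# 0/1 risk indicators for the ten panel features
clinical_risk_indicators <- function(cohort) {
  cbind(
    age = as.integer(cohort$age >= 65),
    race = as.integer(cohort$race != "White"),
    sex = as.integer(cohort$sex == "Male"),
    tobacco = as.integer(cohort$tobacco == "Ever"),
    alcohol = as.integer(cohort$alcohol == "Yes"),
    grade = as.integer(cohort$grade != "Well"),
    stage = as.integer(cohort$stage == "II"),
    pni = as.integer(cohort$pni == "Yes"),
    lvi = as.integer(cohort$lvi == "Yes"),
    margin = as.integer(cohort$margin == "Positive/close")
  )
}

#' Generate a synthetic clinical cohort
#'
#' Draws one row per patient with the ten scoring features plus tumor site
#' and ethnicity, using marginal prevalences matching a TCGA-like
#' early-stage oral-cavity cohort (60% male, 93% white, mean age 64, 68%
#' ever-smokers, 69% stage II, 35% PNI, 6.9% LVI, 21% positive/close
#' margins). The binary 5-year disease-specific vital status is drawn from
#' a logistic model over the configured odds multipliers, with the
#' intercept calibrated so the marginal event probability equals
#' `config$event_rate`.
#'
#' @param config a [simulation_config()].
#' @return a data frame of class `cohort_table`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_patients
  with_seed(derive_seed(config$seed, "cohort"), {
    cohort <- data.frame(
      patient_id = sprintf("P%04d", seq_len(n)),
      age = pmin(pmax(round(stats::rnorm(n, 64, 12)), 25), 90),
      sex = sample(c("Male", "Female"), n, TRUE, c(0.60, 0.40)),
      race = sample(c("White", "Black", "Asian", "Other"), n, TRUE,
                    c(0.93, 0.03, 0.02, 0.02)),
      ethnicity = sample(c("Hispanic", "Non-Hispanic"), n, TRUE, c(0.036, 0.964)),
      tobacco = sample(c("Ever", "Never"), n, TRUE, c(0.68, 0.32)),
      alcohol = sample(c("Yes", "No"), n, TRUE, c(0.61, 0.39)),
      site = sample(c("Tongue", "Floor of mouth", "Buccal mucosa",
                      "Alveolar ridge", "Other"), n, TRUE,
                    c(0.57, 0.15, 0.12, 0.05, 0.11)),
      grade = sample(c("Well", "Moderate", "Poor"), n, TRUE, c(0.19, 0.61, 0.20)),
      stage = sample(c("I", "II"), n, TRUE, c(0.31, 0.69)),
      pni = sample(c("Yes", "No"), n, TRUE, c(0.35, 0.65)),
      lvi = sample(c("Yes", "No"), n, TRUE, c(0.069, 0.931)),
      margin = sample(c("Positive/close", "Negative"), n, TRUE, c(0.21, 0.79)),
      stringsAsFactors = FALSE
    )
    lp <- rep(0, n)
    eff <- config$clinical_effects
    if (length(eff)) {
      ind <- clinical_risk_indicators(cohort)
      lp <- drop(ind[, names(eff), drop = FALSE] %*% log(eff))
    }
    # calibrate the intercept so mean event probability hits event_rate
    b0 <- stats::uniroot(
      function(b) mean(stats::plogis(b + lp)) - config$event_rate,
      c(-30, 30)
    )$root
    cohort$outcome <- stats::rbinom(n, 1, stats::plogis(b0 + lp))
    class(cohort) <- c("cohort_table", "data.frame")
    cohort
  })
}

# allocate batches so that cor(batch-1 indicator, outcome) ~= target;
# allocation probabilities to batch 1 are biased by outcome
allocate_batches <- function(outcome, n_batches, target_corr) {
  n <- length(outcome)
  if (n_batches < 2) return(rep(1L, n))
  p <- mean(outcome)
  q0 <- 1 / n_batches
  if (target_corr > 0 && p > 0 && p < 1) {
    phi <- function(d) {
      qd <- min(q0 + d, 0.99); qs <- max(q0 - d * p / (1 - p), 0.01)
      qbar <- p * qd + (1 - p) * qs
      (p * qd - p * qbar) / sqrt(p * (1 - p) * qbar * (1 - qbar))
    }
    d <- stats::uniroot(function(d) phi(d) - target_corr,
                        c(0, min(0.98 - q0, (1 - p) * 0.98 / p)))$root
    qd <- min(q0 + d, 0.99); qs <- max(q0 - d * p / (1 - p), 0.01)
    in1 <- stats::rbinom(n, 1, ifelse(outcome == 1, qd, qs))
  } else {
    in1 <- stats::rbinom(n, 1, q0)
  }
  batch <- integer(n)
  batch[in1 == 1] <- 1L
  rest <- which(in1 == 0)
  if (n_batches == 2) {
    batch[rest] <- 2L
  } else {
    batch[rest] <- sample(2:n_batches, length(rest), TRUE)
  }
  batch
}

#' Generate a synthetic methylation array
#'
#' Draws a probes x samples beta matrix from a per-probe two-component
#' logit-normal mixture (hypo- and hyper-methylated modes plus a small
#' intermediate class), plants `config$n_signature_cpgs` differential CpGs
#' shifted by `+/- delta_beta` on the beta scale in deceased patients
#' (clipped into \[0,1\]), applies an additive logit-scale batch effect with
#' per-probe loadings, and builds a matching detection p-value matrix with
#' random and systematic (bad-probe) failures. The manifest assigns
#' disjoint X/Y, SNP-flagged, gene-unmapped, cross-reactive, and
#' uninformative probe classes so downstream filter arithmetic chains
#' exactly.
#'
#' @param config a [simulation_config()].
#' @param cohort cohort from [generate_cohort()]; must be non-empty.
#' @return list with elements `manifest`, `dataset`
#'   (a [methylation_dataset()]), and `truth` (planted CpG ids with
#'   directions, batch assignment, planted clinical effects).
#' @export
generate_methylation <- function(config, cohort) {
  stopifnot(inherits(config, "simulation_config"))
  if (nrow(cohort) == 0) stopf("cohort must be non-empty")
  n <- nrow(cohort)
  p <- config$n_probes
  # array design: drawn from design_seed so replicate cohorts (new `seed`,
  # same `design_seed`) are measured on an identical array
  design <- with_seed(derive_seed(config$design_seed, "array_design"), {
    ids <- sprintf("cg%08d", seq_len(p))

    n_xy <- round(config$frac_xy * p)
    n_snp <- round(config$frac_snp * p)
    n_unm <- round(config$frac_unmapped * p)
    n_cross <- round(config$frac_cross_reactive * p)
    n_unin <- round(config$frac_uninformative * p)
    n_sig <- config$n_signature_cpgs
    if (n_xy + n_snp + n_unm + n_cross + n_unin + n_sig > p) {
      stopf("configuration error: probe class fractions exceed n_probes")
    }
    cls <- rep("informative", p)
    pool <- sample.int(p)  # random disjoint class assignment
    take <- function(k) {
      out <- pool[seq_len(k)]
      pool <<- pool[-seq_len(k)]
      out
    }
    i_xy <- take(n_xy); i_snp <- take(n_snp); i_unm <- take(n_unm)
    i_cross <- take(n_cross); i_unin <- take(n_unin); i_sig <- take(n_sig)
    cls[i_xy] <- "xy"; cls[i_snp] <- "snp"; cls[i_unm] <- "unmapped"
    cls[i_cross] <- "cross_reactive"; cls[i_unin] <- "uninformative"
    cls[i_sig] <- "signature"

    # manifest: signature CpGs map to SGENE symbols (first gene absorbs the
    # extra CpGs), other mapped probes to a generic gene pool
    sig_genes <- sprintf("SGENE%02d", seq_len(config$n_signature_genes))
    gene_of_sig <- c(sig_genes,
                     rep(sig_genes[1], n_sig - config$n_signature_genes))
    gene_pool <- sprintf("GENE%05d", seq_len(max(50L, ceiling(p / 4))))
    gene <- sample(gene_pool, p, TRUE)
    gene[i_unm] <- ""
    gene[i_sig] <- gene_of_sig
    chrom <- sample(as.character(1:22), p, TRUE)
    chrom[i_xy] <- sample(c("X", "Y"), n_xy, TRUE, c(0.85, 0.15))
    manifest <- data.frame(
      probe_id = ids, chrom = chrom,
      pos = sample.int(1e8, p, replace = TRUE), gene = gene,
      snp_flag = cls == "snp", cross_reactive_flag = cls == "cross_reactive",
      stringsAsFactors = FALSE
    )

    # per-probe baseline on the logit (natural log-odds) scale
    comp <- sample(1:3, p, TRUE, c(0.45, 0.45, 0.10))
    mu <- c(stats::qlogis(0.15), stats::qlogis(0.85), 0)[comp] +
      stats::rnorm(p, 0, 0.7)
    # uninformative probes: pinned low or high so all betas fall < 0.1 or > 0.9
    half <- i_unin[seq_len(floor(n_unin / 2))]
    mu[half] <- stats::qlogis(0.03)
    mu[setdiff(i_unin, half)] <- stats::qlogis(0.97)
    # signature baselines sit near a state boundary so a delta_beta shift
    # crosses it: hyper 0.55 -> up, hypo 0.45 -> down
    dir <- rep(c("hyper", "hypo"), length.out = n_sig)
    mu[i_sig] <- ifelse(dir == "hyper", stats::qlogis(0.55), stats::qlogis(0.45))

    sd_probe <- rep(config$beta_sd, p)
    sd_probe[i_unin] <- 0.1

    loading <- if (config$n_batches >= 2 && config$batch_sd > 0) {
      stats::rnorm(p, 0, config$batch_sd)
    } else {
      numeric(p)
    }
    bad <- if (config$n_bad_probes > 0) {
      informative <- which(cls == "informative")
      informative[seq_len(min(config$n_bad_probes, length(informative)))]
    } else {
      integer(0)
    }
    list(ids = ids, i_sig = i_sig, gene_of_sig = gene_of_sig, dir = dir,
         manifest = manifest, mu = mu, sd_probe = sd_probe,
         loading = loading, bad = bad)
  })

  ids <- design$ids; i_sig <- design$i_sig; dir <- design$dir
  manifest <- design$manifest; gene_of_sig <- design$gene_of_sig
  bad <- design$bad

  with_seed(derive_seed(config$seed, "methylation"), {
    batch <- allocate_batches(cohort$outcome, config$n_batches,
                              config$batch_outcome_corr)
    batch_val <- scale(batch == 1L, scale = FALSE)[, 1]  # centered indicator
    logit <- design$mu + outer(design$loading, batch_val) +
      matrix(stats::rnorm(p * n, 0, design$sd_probe), p, n)
    beta <- stats::plogis(logit)

    # plant the signature: beta-scale shift in deceased patients, clipped
    dead <- cohort$outcome == 1
    if (any(dead) && config$delta_beta != 0) {
      shift <- ifelse(dir == "hyper", config$delta_beta, -config$delta_beta)
      beta[i_sig, dead] <- beta[i_sig, dead] + shift
      beta <- pmin(pmax(beta, 0), 1)
    }

    detp <- matrix(stats::runif(p * n, 0, 0.005), p, n)
    fail <- matrix(stats::runif(p * n) < config$detp_fail_rate, p, n)
    if (length(bad)) {
      fail[bad, ] <- matrix(stats::runif(length(bad) * n) < 0.8, length(bad), n)
    }
    detp[fail] <- stats::runif(sum(fail), 0.01, 1)
    dimnames(beta) <- dimnames(detp) <- list(ids, cohort$patient_id)

    dataset <- methylation_dataset(beta, detp, cohort$outcome)
    truth <- list(
      signature = data.frame(probe_id = ids[i_sig], gene = gene_of_sig,
                             direction = dir, stringsAsFactors = FALSE),
      batch = stats::setNames(batch, cohort$patient_id),
      bad_probes = ids[bad],
      clinical_effects = config$clinical_effects,
      delta_beta = config$delta_beta,
      note = paste("synthetic stand-in: joint distributions are invented;",
                   "only marginal prevalences and filter-class fractions",
                   "follow published cohort/array summaries")
    )
    list(manifest = manifest, dataset = dataset, truth = truth)
  })
}

#' Generate synthetic expression counts
#'
#' Negative-binomial-like counts for `config$n_genes_expr` genes (always
#' including the signature genes). For each gene named in
#' `config$expr_corr`, the log2 mean is tied to the standardized beta of
#' the gene's first signature CpG so the realized Pearson correlation
#' between log2(count + 1) and beta carries the configured sign and
#' approximate magnitude; remaining genes are independent of methylation.
#' A 10% slice of filler genes is simulated at low depth so the expression
#' filter has something to remove.
#'
#' @param config a [simulation_config()].
#' @param methylation result of [generate_methylation()].
#' @return integer count matrix (genes x samples).
#' @export
generate_expression <- function(config, methylation) {
  stopifnot(inherits(config, "simulation_config"))
  truth <- methylation$truth
  sig <- truth$signature
  if (!is.null(config$expr_corr)) {
    missing <- setdiff(names(config$expr_corr), sig$gene)
    if (length(missing)) {
      stopf("expr_corr gene(s) not among signature genes: %s",
            paste(missing, collapse = ", "))
    }
  }
  beta <- methylation$dataset$beta
  n <- ncol(beta)
  with_seed(derive_seed(config$seed, "expression"), {
    n_fill <- max(config$n_genes_expr - length(unique(sig$gene)), 0L)
    genes <- c(unique(sig$gene), sprintf("EGENE%05d", seq_len(n_fill)))
    g <- length(genes)
    mu0 <- stats::runif(g, 5, 10)  # log2 baseline expression
    low <- seq_len(g) > g - floor(0.1 * g)
    mu0[low] <- stats::runif(sum(low), 0.5, 2)
    counts <- matrix(0L, g, n, dimnames = list(genes, colnames(beta)))
    for (i in seq_len(g)) {
      gene <- genes[i]
      rho <- if (!is.null(config$expr_corr) && gene %in% names(config$expr_corr)) {
        config$expr_corr[[gene]]
      } else {
        0
      }
      if (rho != 0) {
        cpg <- sig$probe_id[match(gene, sig$gene)]  # first CpG of the gene
        z <- scale(beta[cpg, ])[, 1]
        latent <- rho * z + sqrt(1 - rho^2) * stats::rnorm(n)
      } else {
        latent <- stats::rnorm(n)
      }
      m <- 2^(mu0[i] + latent)
      counts[i, ] <- as.integer(stats::rnbinom(n, mu = m, size = 50))
    }
    counts
  })
}

#' Generate a complete synthetic bundle
#'
#' Runs [generate_cohort()], [generate_methylation()], and
#' [generate_expression()] under one configuration and returns the aligned
#' set, together with the ground truth of everything planted.
#'
#' @param config a [simulation_config()].
#' @return an object of class `synthetic_bundle` with elements `manifest`,
#'   `methylation`, `clinical`, `expression`, `truth`, `config`.
#' @export
simulate_bundle <- function(config) {
  clinical <- generate_cohort(config)
  meth <- generate_methylation(config, clinical)
  expression <- generate_expression(config, meth)
  structure(
    list(manifest = meth$manifest, methylation = meth$dataset,
         clinical = clinical, expression = expression,
         truth = meth$truth, config = config),
    class = "synthetic_bundle"
  )
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat(sprintf(
    "synthetic_bundle: %d patients (%d events), %d probes, %d genes expressed\n",
    nrow(x$clinical), sum(x$clinical$outcome),
    nrow(x$methylation$beta), nrow(x$expression)))
  cat(sprintf("  planted signature: %d CpGs over %d genes, delta_beta = %g\n",
              nrow(x$truth$signature), length(unique(x$truth$signature$gene)),
              x$config$delta_beta))
  invisible(x)
}

#' Write a synthetic bundle to delimited-text files
#'
#' Writes `beta.tsv`, `detection_p.tsv` (probes x samples, first column
#' `probe_id`), `manifest.tsv`, `clinical.tsv`, `counts.tsv`, and
#' `truth.json` into `dir`. Numeric matrices are serialized with 17
#' significant digits so a read-back reproduces them bit-exactly.
#'
#' @param bundle a `synthetic_bundle`.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written file paths.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    beta = file.path(dir, "beta.tsv"),
    detection_p = file.path(dir, "detection_p.tsv"),
    manifest = file.path(dir, "manifest.tsv"),
    clinical = file.path(dir, "clinical.tsv"),
    counts = file.path(dir, "counts.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_matrix(bundle$methylation$beta, paths["beta"], id_col = "probe_id")
  write_matrix(bundle$methylation$detection_p, paths["detection_p"],
               id_col = "probe_id")
  data.table::fwrite(bundle$manifest, paths["manifest"], sep = "\t")
  data.table::fwrite(as.data.frame(bundle$clinical), paths["clinical"], sep = "\t")
  write_matrix(bundle$expression, paths["counts"], id_col = "gene_id")
  jsonlite::write_json(
    list(signature = bundle$truth$signature,
         batch = as.list(bundle$truth$batch),
         bad_probes = bundle$truth$bad_probes,
         clinical_effects = as.list(bundle$truth$clinical_effects),
         delta_beta = bundle$truth$delta_beta,
         note = bundle$truth$note),
    paths["truth"], auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(paths)
}

#' Read a bundle written by [write_bundle()]
#'
#' @param dir directory containing the bundle files.
#' @return a list with `manifest`, `methylation`, `clinical`, `expression`,
#'   `truth`.
#' @export
read_bundle <- function(dir) {
  clinical <- as.data.frame(data.table::fread(file.path(dir, "clinical.tsv")))
  beta <- read_matrix(file.path(dir, "beta.tsv"), kind = "beta")
  detp <- read_matrix(file.path(dir, "detection_p.tsv"), kind = "detection_p")
  manifest <- validate_manifest(
    as.data.frame(data.table::fread(file.path(dir, "manifest.tsv"),
                                    colClasses = list(character = "chrom")))
  )
  counts <- read_matrix(file.path(dir, "counts.tsv"), kind = "counts")
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  list(
    manifest = manifest,
    methylation = methylation_dataset(
      beta, detp, stats::setNames(clinical$outcome, clinical$patient_id)),
    clinical = clinical, expression = counts, truth = truth
  )
}

#' Synthetic array sized to the published 450K filter bookkeeping
#'
#' Builds a manifest and methylation dataset whose disjoint probe classes
#' match the printed filter-cascade counts of the 450K workflow: 485,512
#' probes of which 11,648 lie on X/Y, 17,351 are SNP-associated, 111,977
#' map to no gene region, 20,071 are cross-reactive, 7,449 are
#' uninformative (beta < 0.1 or > 0.9 in all samples), and 317,016 are
#' informative; all detection p-values pass. Running the filter cascade on
#' this object reproduces the published sequence 485,512 -> 473,864 ->
#' 344,536 -> ... -> 317,016 -> 95,104. Betas are deterministic given the
#' seed, with strictly distinct informative-probe variances so the
#' top-variance cut is unambiguous.
#'
#' @param n_samples number of samples to simulate (kept small; the counts
#'   are a property of the probe classes, not the cohort).
#' @param n_total,n_xy,n_snp,n_unmapped,n_cross_reactive,n_uninformative
#'   probe class sizes; defaults are the published counts.
#' @param seed integer seed.
#' @return list with `manifest` and `dataset`.
#' @export
simulate_array_composition <- function(n_samples = 4,
                                       n_total = 485512,
                                       n_xy = 11648,
                                       n_snp = 17351,
                                       n_unmapped = 111977,
                                       n_cross_reactive = 20071,
                                       n_uninformative = 7449,
                                       seed = 1L) {
  n_inf <- n_total - n_xy - n_snp - n_unmapped - n_cross_reactive - n_uninformative
  if (n_inf < 0) stopf("class sizes exceed n_total")
  if (n_samples < 2) stopf("need at least 2 samples for the variance stage")
  with_seed(derive_seed(seed, "array_composition"), {
    ids <- sprintf("cg%08d", seq_len(n_total))
    cls <- rep.int(
      c("xy", "snp", "unmapped", "cross_reactive", "uninformative", "informative"),
      c(n_xy, n_snp, n_unmapped, n_cross_reactive, n_uninformative, n_inf)
    )[order(stats::runif(n_total))]
    chrom <- sample(as.character(1:22), n_total, TRUE)
    chrom[cls == "xy"] <- sample(c("X", "Y"), sum(cls == "xy"), TRUE)
    gene <- sprintf("GENE%05d", sample.int(30000, n_total, TRUE))
    gene[cls == "unmapped"] <- ""
    manifest <- data.frame(
      probe_id = ids, chrom = chrom, pos = seq_len(n_total), gene = gene,
      snp_flag = cls == "snp", cross_reactive_flag = cls == "cross_reactive",
      stringsAsFactors = FALSE
    )
    # deterministic beta patterns per class; informative probes get strictly
    # increasing spread so their sample variances are distinct
    beta <- matrix(0.5, n_total, n_samples, dimnames = list(ids, sprintf("S%02d", seq_len(n_samples))))
    i_un <- which(cls == "uninformative")
    half <- i_un[seq_len(floor(length(i_un) / 2))]
    beta[half, ] <- 0.05
    beta[setdiff(i_un, half), ] <- 0.95
    i_inf <- which(cls == "informative")
    spread <- 0.05 + 0.35 * (seq_along(i_inf) - 1) / max(length(i_inf) - 1, 1)
    beta[i_inf, 1] <- 0.5 - spread
    beta[i_inf, 2] <- 0.5 + spread
    detp <- matrix(0.001, n_total, n_samples, dimnames = dimnames(beta))
    outcome <- rep_len(c(0L, 1L), n_samples)
    list(manifest = manifest,
         dataset = methylation_dataset(beta, detp, outcome))
  })
}
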