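test_that("matrix reader validates ranges, ids, and round-trips exactly", {
  dir <- withr::local_tempdir()
  m <- matrix(runif(12), 4, 3,
              dimnames = list(sprintf("cg%03d", 1:4), sprintf("S%d", 1:3)))
  path <- file.path(dir, "beta.tsv")
  write_matrix(m, path)
  expect_identical(read_matrix(path, "beta"), m)
  # out-of-range value errors with its coordinates
  bad <- m; bad[2, 3] <- 1.2
  write_matrix(bad, path)
  err <- tryCatch(read_matrix(path, "beta"), error = conditionMessage)
  expect_match(err, "cg002")
  expect_match(err, "S3")
  # duplicated probe id errors
  dup <- m; rownames(dup) <- c("cg001", "cg001", "cg003", "cg004")
  write_matrix(dup, path)
  expect_error(read_matrix(path, "beta"), "duplicated")
  # counts must be non-negative integers
  cpath <- file.path(dir, "counts.tsv")
  cm <- matrix(5L, 2, 2, dimnames = list(c("g1", "g2"), c("S1", "S2")))
  write_matrix(cm, cpath)
  expect_identical(read_matrix(cpath, "counts"), cm)
  writeLines(c("gene_id\tS1\tS2", "g1\t5\t-1", "g2\t2\t2"), cpath)
  expect_error(read_matrix(cpath, "counts"), "g1")
})

test_that("pipeline configs reject unknown keys", {
  expect_error(pipeline_config("b", "d", "m", "c", params = list(bogus = 1)),
               "unknown pipeline parameter")
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("inputs:", "  beta: b.tsv", "typo: 1"), path)
  expect_error(read_pipeline_config(path), "unknown config key")
})

test_that("the pipeline runs end to end, writes artifacts, and is deterministic", {
  dir <- withr::local_tempdir()
  cfg <- simulation_config(n_patients = 50, n_probes = 600, event_rate = 0.25,
                           delta_beta = 0.3, seed = 14,
                           expr_corr = c(SGENE01 = 0.5))
  b <- simulate_bundle(cfg)
  write_bundle(b, dir)
  gmt <- file.path(dir, "sets.gmt")
  writeLines(c(paste(c("sigset", "d", unique(b$truth$signature$gene)[1:5]),
                     collapse = "\t"),
               paste(c("noise", "d", sprintf("GENE%05d", 1:25)), collapse = "\t")),
             gmt)
  pc <- function(out) pipeline_config(
    beta = file.path(dir, "beta.tsv"), detection_p = file.path(dir, "detection_p.tsv"),
    manifest = file.path(dir, "manifest.tsv"), clinical = file.path(dir, "clinical.tsv"),
    counts = file.path(dir, "counts.tsv"), gmt = gmt, out = out,
    params = list(n_boot = 100, min_leaf = 10), seed = 4)
  res <- suppressMessages(suppressWarnings(run_pipeline(pc(file.path(dir, "o1")))))
  expect_true(file.exists(res$paths[["evaluation.json"]]))
  expect_true(file.exists(res$paths[["manifest.json"]]))
  # logged filter report equals the persisted filter_report.tsv
  rep_file <- as.data.frame(data.table::fread(res$paths[["filter_report.tsv"]]))
  expect_equal(rep_file$n_out, res$fit$filter_report$n_out)
  # re-running the same config and seed reproduces identical content hashes
  res2 <- suppressMessages(suppressWarnings(run_pipeline(pc(file.path(dir, "o2")))))
  h1 <- jsonlite::read_json(res$paths[["manifest.json"]], simplifyVector = TRUE)
  h2 <- jsonlite::read_json(res2$paths[["manifest.json"]], simplifyVector = TRUE)
  skip_artifacts <- "run.log"  # log has no payload guarantees beyond params
  for (nm in setdiff(names(h1), skip_artifacts)) {
    expect_identical(h1[[nm]]$md5, h2[[nm]]$md5)
  }
})

test_that("stage-wise reruns from persisted intermediates match the end-to-end fit", {
  cfg <- simulation_config(n_patients = 40, n_probes = 500, event_rate = 0.25,
                           delta_beta = 0.3, seed = 23)
  b <- simulate_bundle(cfg)
  fit <- suppressWarnings(fit_reason(b$methylation, b$manifest, b$clinical,
                                     n_boot = 0, clinico_params = list(min_leaf = 10)))
  # recompute the DM stage from the persisted filtered inputs
  cascade <- run_cascade(b$methylation, b$manifest)
  svs <- estimate_surrogates(cascade$dataset)
  cov <- suppressMessages(select_covariates(svs))
  dm <- differential_methylation(cascade$dataset,
                                 covariates = if (ncol(cov)) cov else NULL,
                                 manifest = b$manifest)
  expect_equal(dm$p, fit$dm$p)
  expect_identical(select_signature(dm)$cpgs$probe_id, fit$signature$cpgs$probe_id)
})

test_that("a null bundle yields held-out composite discrimination near chance", {
  null_eff <- setNames(rep(1, 10), clinico_panel_features())
  cs <- vapply(1:50, function(s) {
    cfg <- simulation_config(n_patients = 60, n_probes = 300, event_rate = 0.3,
                             delta_beta = 0, clinical_effects = null_eff,
                             batch_sd = 0.3, seed = s + 900)
    b <- simulate_bundle(cfg)
    fit <- suppressWarnings(fit_reason(b$methylation, b$manifest, b$clinical,
                                       n_boot = 0))
    rep <- simulate_bundle(replicate_config(cfg, s + 5000L))
    pred <- suppressMessages(suppressWarnings(
      predict(fit, rep$clinical, rep$methylation$beta)))
    c_index(pred$total, rep$clinical$outcome)$c_index
  }, numeric(1))
  expect_gte(mean(cs), 0.4)
  expect_lte(mean(cs), 0.6)
})

test_that("the fitted model object exposes the standard accessor surface", {
  cfg <- simulation_config(n_patients = 60, n_probes = 600, event_rate = 0.25,
                           delta_beta = 0.3, seed = 77)
  b <- simulate_bundle(cfg)
  fit <- suppressWarnings(fit_reason(b$methylation, b$manifest, b$clinical,
                                     n_boot = 50, clinico_params = list(min_leaf = 10)))
  expect_s3_class(fit, "reason_fit")
  expect_output(print(fit), "c-index")
  expect_output(print(summary(fit)), "Filter cascade")
  cf <- coef(fit)
  expect_true(all(c("component", "term", "points") %in% names(cf)))
  pred <- suppressMessages(predict(fit, b$clinical, b$methylation$beta))
  expect_identical(pred$total, fit$scores$total)
  path <- withr::local_tempfile(fileext = ".png")
  grDevices::png(path); plot(fit); grDevices::dev.off()
  expect_true(file.size(path) > 0)
})
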