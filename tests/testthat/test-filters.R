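test_that("sex-chromosome filter removes exactly the X/Y probes", {
  beta <- matrix(runif(12 * 4), 12, 4)
  ds <- make_dataset(beta, c(0, 0, 1, 1))
  man <- make_manifest(probe_ids(ds), chrom = c(rep("1", 8), "X", "X", "Y", "22"))
  res <- filter_sex_chromosomes(ds, man)
  expect_equal(res$report$n_out, 9)
  expect_false(any(c("cg009", "cg010", "cg011") %in% probe_ids(res$dataset)))
  # no X/Y -> identity
  man2 <- make_manifest(probe_ids(ds), chrom = "5")
  expect_identical(filter_sex_chromosomes(ds, man2)$dataset$beta, ds$beta)
  # all on X -> empty
  man3 <- make_manifest(probe_ids(ds), chrom = "X")
  expect_equal(filter_sex_chromosomes(ds, man3)$report$n_out, 0)
  # missing probe errors with its name
  expect_error(filter_sex_chromosomes(ds, man[-1, ]), "cg001")
})

test_that("SNP and unmapped stages apply sequentially, SNP first", {
  beta <- matrix(runif(10 * 2), 10, 2)
  ds <- make_dataset(beta, c(0, 1))
  man <- make_manifest(probe_ids(ds))
  man$snp_flag[1:3] <- TRUE
  man$gene[3:6] <- ""  # probe 3 carries both flags
  res <- filter_snp_and_unmapped(ds, man)
  expect_equal(res$report$stage, c("snp", "unmapped"))
  # overlapping probe counted in the SNP stage only
  expect_equal(res$report$n_removed, c(3, 3))
  expect_equal(res$report$n_out, c(7, 4))
  # no flags -> identity
  man2 <- make_manifest(probe_ids(ds))
  expect_identical(filter_snp_and_unmapped(ds, man2)$dataset$beta, ds$beta)
})

test_that("detection filter keeps the at-least-50% boundary inclusive", {
  detp <- rbind(
    c(0.001, 0.001, 0.5, 0.5),   # exactly half passing -> retained
    c(0.5, 0.5, 0.5, 0.5),       # failing everywhere -> removed
    c(0.001, 0.001, 0.001, 0.5)  # 3/4 -> retained
  )
  beta <- matrix(0.5, 3, 4)
  ds <- make_dataset(beta, c(0, 0, 1, 1), detection_p = detp)
  res <- filter_detection(ds)
  expect_identical(probe_ids(res$dataset), c("cg001", "cg003"))
  empty <- make_dataset(matrix(0.4, 2, 2), c(0, 1))
  empty$beta <- empty$beta[, 0, drop = FALSE]
  empty$detection_p <- empty$detection_p[, 0, drop = FALSE]
  empty$outcome <- integer(0)
  expect_error(filter_detection(empty), "at least one sample")
})

test_that("detection filter matches a brute-force recount on random patterns", {
  set.seed(42)
  for (rep in 1:5) {
    detp <- matrix(sample(c(0.001, 0.5), 40, replace = TRUE), 10, 4)
    ds <- make_dataset(matrix(0.5, 10, 4), c(0, 0, 1, 1), detection_p = detp)
    res <- filter_detection(ds)
    manual <- apply(detp, 1, function(r) sum(r < 0.01) / 4 >= 0.5)
    expect_identical(probe_ids(res$dataset), probe_ids(ds)[manual])
  }
})

test_that("cross-reactive filter removes flagged probes and matches recount", {
  set.seed(7)
  ds <- make_dataset(matrix(runif(20), 10, 2), c(0, 1))
  man <- make_manifest(probe_ids(ds))
  man$cross_reactive_flag <- sample(c(TRUE, FALSE), 10, replace = TRUE)
  res <- filter_cross_reactive(ds, man)
  expect_identical(probe_ids(res$dataset), man$probe_id[!man$cross_reactive_flag])
  expect_equal(res$report$n_removed, sum(man$cross_reactive_flag))
  # identity / all-removed extremes
  man$cross_reactive_flag <- FALSE
  expect_identical(filter_cross_reactive(ds, man)$dataset$beta, ds$beta)
  man$cross_reactive_flag <- TRUE
  expect_equal(filter_cross_reactive(ds, man)$report$n_out, 0)
})

test_that("uninformative-beta filter needs the condition across all samples", {
  beta <- rbind(c(0.05, 0.08),  # all < 0.1 -> removed
                c(0.05, 0.50),  # not across all samples -> retained
                c(0.95, 0.99),  # all > 0.9 -> removed
                c(0.50, 0.60))
  ds <- make_dataset(beta, c(0, 1))
  res <- filter_uninformative_beta(ds)
  expect_identical(probe_ids(res$dataset), c("cg002", "cg004"))
})

test_that("top-variance filter keeps floor(fraction*n) by variance then id", {
  # floor: 10 probes at 30% -> 3
  set.seed(11)
  beta <- matrix(runif(40), 10, 4)
  ds <- make_dataset(beta, c(0, 0, 1, 1))
  res <- filter_top_variance(ds, fraction = 0.30)
  expect_equal(res$report$n_out, 3)
  v <- apply(beta, 1, var)
  expect_setequal(probe_ids(res$dataset),
                  probe_ids(ds)[order(-v, probe_ids(ds))][1:3])
  # 20-probe brute-force comparison
  beta2 <- matrix(runif(80), 20, 4)
  ds2 <- make_dataset(beta2, c(0, 0, 1, 1))
  res2 <- filter_top_variance(ds2, 0.30)
  v2 <- apply(beta2, 1, var)
  expect_setequal(probe_ids(res2$dataset),
                  probe_ids(ds2)[order(-v2, probe_ids(ds2))][1:6])
  # ties at the cut break lexicographically by probe id
  beta3 <- matrix(0.2, 4, 2)
  beta3[, 2] <- c(0.8, 0.8, 0.8, 0.2)  # probes 1-3 tie, probe 4 constant
  ds3 <- make_dataset(beta3, c(0, 1))
  res3 <- filter_top_variance(ds3, 0.5)
  expect_identical(sort(probe_ids(res3$dataset)), c("cg001", "cg002"))
})

test_that("cascade report chains, is idempotent per predicate stage, and is order-invariant", {
  cfg <- simulation_config(n_patients = 30, n_probes = 500, event_rate = 0.3,
                           seed = 13)
  b <- simulate_bundle(cfg)
  out <- run_cascade(b$methylation, b$manifest)
  rep <- out$report
  expect_equal(rep$n_out, rep$n_in - rep$n_removed)
  expect_equal(rep$n_in[-1], rep$n_out[-nrow(rep)])
  # predicate filters are idempotent
  for (f in list(function(d) filter_sex_chromosomes(d, b$manifest),
                 function(d) filter_snp_and_unmapped(d, b$manifest),
                 function(d) filter_detection(d),
                 function(d) filter_cross_reactive(d, b$manifest),
                 function(d) filter_uninformative_beta(d))) {
    once <- f(b$methylation)$dataset
    twice <- f(once)$dataset
    expect_identical(twice$beta, once$beta)
  }
  # shuffled probe order yields the identical retained set
  perm <- sample(nrow(b$methylation$beta))
  shuffled <- subset_probes(b$methylation, perm)
  out2 <- run_cascade(shuffled, b$manifest)
  expect_setequal(probe_ids(out2$dataset), probe_ids(out$dataset))
  expect_equal(out2$report$n_out, out$report$n_out)
})
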