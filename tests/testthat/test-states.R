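test_that("state assignment matches the published interval map", {
  th <- state_thresholds()
  expect_equal(as.character(assign_state(0.2, th)), "UNMETH")
  expect_equal(as.character(assign_state(0.5, th)), "HEMI")
  expect_equal(as.character(assign_state(0.8, th)), "FULL")
  # the unspecified [0.30, 0.33) gap closes into UNMETH
  expect_equal(as.character(assign_state(0.31, th)), "UNMETH")
  # boundary inclusivity: hemi is closed [0.33, 0.75], full strictly above
  expect_equal(as.character(assign_state(0.33, th)), "HEMI")
  expect_equal(as.character(assign_state(0.75, th)), "HEMI")
  expect_equal(as.character(assign_state(0.7500001, th)), "FULL")
  expect_error(assign_state(1.2, th), "\\[0,1\\]")
  expect_error(assign_state(-0.1, th), "\\[0,1\\]")
  expect_error(state_thresholds(hemi_low = 0.8, hemi_high = 0.5), "invalid")
})

test_that("state assignment is total and monotone over a fine grid", {
  grid <- seq(0, 1, by = 0.001)
  st <- as.integer(assign_state(grid))
  expect_false(anyNA(st))
  expect_true(all(diff(st) >= 0))
})

test_that("reference states use the survivor lower-middle median", {
  beta <- rbind(c(0.1, 0.2, 0.25, 0.9), c(0.4, 0.5, 0.1, 0.9))
  ds <- make_dataset(beta, c(0, 0, 0, 1))
  sig <- data.frame(probe_id = c("cg001", "cg002"), gene = c("A", "B"),
                    stringsAsFactors = FALSE)
  refs <- reference_states(ds, sig)
  expect_equal(refs$reference_beta, c(0.2, 0.4))  # odd: true median; even n/a here
  expect_equal(refs$reference_state, c(1L, 2L))
  # even count: lower-middle value
  ds2 <- make_dataset(rbind(c(0.4, 0.5, 0.2)), c(0, 0, 1))
  refs2 <- reference_states(ds2, data.frame(probe_id = "cg001", gene = "A"))
  expect_equal(refs2$reference_beta, 0.4)
  # single survivor: that patient's state
  ds3 <- make_dataset(rbind(c(0.8, 0.2)), c(0, 1))
  expect_equal(reference_states(ds3, data.frame(probe_id = "cg001", gene = "A"))$reference_state, 3L)
  # no survivors is an error
  ds4 <- make_dataset(rbind(c(0.8, 0.2)), c(1, 1))
  expect_error(reference_states(ds4, data.frame(probe_id = "cg001", gene = "A")),
               "event-free")
})

test_that("risk calls require a direction-matched state transition", {
  # gene A hyper-directed, gene B hypo-directed
  sig <- structure(
    list(cpgs = data.frame(probe_id = c("cg001", "cg002", "cg003"),
                           gene = c("A", "A", "B"),
                           direction = c("hyper", "hyper", "hypo"),
                           logFC = c(1, 1, -1), p_adj = 0.01,
                           stringsAsFactors = FALSE),
         genes = c("A", "B"), alpha = 0.1),
    class = "dm_signature"
  )
  # survivors define references: cg001 HEMI (0.5), cg002 HEMI (0.5), cg003 HEMI (0.6)
  beta <- rbind(
    cg001 = c(0.50, 0.50, 0.80, 0.70, 0.20),
    cg002 = c(0.50, 0.50, 0.40, 0.40, 0.40),
    cg003 = c(0.60, 0.60, 0.90, 0.60, 0.60)
  )
  colnames(beta) <- sprintf("P%d", 1:5)
  ds <- make_dataset(beta, c(0, 0, 1, 1, 1))
  ms <- score_molecular(ds, sig)
  flags <- ms$gene_flags
  # P3: cg001 HEMI->FULL hyper transition matches gene A -> risk
  expect_true(flags["P3", "A"])
  # P4: beta moved 0.50 -> 0.70 but both HEMI: no state change, no risk
  expect_false(flags["P4", "A"])
  # P5: cg001 HYPO transition but gene A is hyper-directed -> no risk
  expect_false(flags["P5", "A"])
  # P3: cg003 HEMI->FULL is HYPER but gene B is hypo-directed -> no risk
  expect_false(flags["P3", "B"])
  # molecular score counts risk-positive genes
  expect_equal(unname(ms$scores["P3"]), 1L)
  expect_equal(unname(ms$scores["P4"]), 0L)
  # risk_flag implies a transition
  expect_true(all(ms$calls$transition[ms$calls$risk_flag] != "NONE"))
})

test_that("gene aggregation is an OR over CpGs and order-invariant", {
  sig <- structure(
    list(cpgs = data.frame(probe_id = c("cg001", "cg002"), gene = "A",
                           direction = "hyper", logFC = 1, p_adj = 0.01,
                           stringsAsFactors = FALSE),
         genes = "A", alpha = 0.1),
    class = "dm_signature"
  )
  beta <- rbind(cg001 = c(0.5, 0.5, 0.5), cg002 = c(0.5, 0.5, 0.9))
  colnames(beta) <- sprintf("P%d", 1:3)
  ds <- make_dataset(beta, c(0, 0, 1))
  ms <- score_molecular(ds, sig)
  expect_true(ms$gene_flags["P3", "A"])  # second CpG alone suffices
  # reversing CpG order changes nothing
  sig2 <- sig
  sig2$cpgs <- sig2$cpgs[2:1, ]
  ms2 <- score_molecular(ds, sig2)
  expect_identical(ms2$gene_flags, ms$gene_flags)
  expect_identical(ms2$scores, ms$scores)
})

test_that("within-state beta perturbations never change a call", {
  sig <- structure(
    list(cpgs = data.frame(probe_id = "cg001", gene = "A", direction = "hyper",
                           logFC = 1, p_adj = 0.01, stringsAsFactors = FALSE),
         genes = "A", alpha = 0.1),
    class = "dm_signature"
  )
  base <- rbind(cg001 = c(0.5, 0.5, 0.8))
  colnames(base) <- sprintf("P%d", 1:3)
  ref_flags <- score_molecular(make_dataset(base, c(0, 0, 1)), sig)$gene_flags
  for (b3 in c(0.76, 0.85, 0.99)) {  # anywhere in FULL
    beta <- base; beta[1, 3] <- b3
    # keep references fixed by perturbing only the deceased patient
    flags <- score_molecular(make_dataset(beta, c(0, 0, 1)), sig)$gene_flags
    expect_identical(flags, ref_flags)
  }
})

test_that("signature genes without measured CpGs warn and score zero", {
  sig <- structure(
    list(cpgs = data.frame(probe_id = c("cg001", "cg_missing"),
                           gene = c("A", "B"), direction = "hyper",
                           logFC = 1, p_adj = 0.01, stringsAsFactors = FALSE),
         genes = c("A", "B"), alpha = 0.1),
    class = "dm_signature"
  )
  beta <- rbind(cg001 = c(0.5, 0.5, 0.9))
  colnames(beta) <- sprintf("P%d", 1:3)
  ds <- make_dataset(beta, c(0, 0, 1))
  expect_warning(ms <- score_molecular(ds, sig), "B")
  expect_false(any(ms$gene_flags[, "B"]))
  expect_equal(unname(ms$scores["P3"]), 1L)
})

test_that("the molecular score is bounded by the gene-panel size", {
  cfg <- simulation_config(n_patients = 40, n_probes = 400, event_rate = 0.3,
                           delta_beta = 0.3, seed = 17)
  b <- simulate_bundle(cfg)
  ms <- score_molecular(b$methylation, truth_signature(b))
  expect_true(all(ms$scores >= 0 & ms$scores <= 12))
})
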