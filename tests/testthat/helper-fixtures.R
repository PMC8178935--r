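# small in-code fixtures shared across test files

# methylation_dataset from a beta matrix; detection p all passing unless given
make_dataset <- function(beta, outcome, detection_p = NULL) {
  if (is.null(dimnames(beta))) {
    dimnames(beta) <- list(sprintf("cg%03d", seq_len(nrow(beta))),
                           sprintf("S%02d", seq_len(ncol(beta))))
  }
  if (is.null(detection_p)) {
    detection_p <- matrix(0.001, nrow(beta), ncol(beta))
  }
  dimnames(detection_p) <- dimnames(beta)
  methylation_dataset(beta, detection_p, outcome)
}

# manifest covering the given probe ids, all autosomal and unflagged by default
make_manifest <- function(ids, chrom = "1", gene = NULL, snp = FALSE, cross = FALSE) {
  data.frame(
    probe_id = ids,
    chrom = rep_len(chrom, length(ids)),
    pos = seq_along(ids),
    gene = if (is.null(gene)) paste0("G", seq_along(ids)) else rep_len(gene, length(ids)),
    snp_flag = rep_len(snp, length(ids)),
    cross_reactive_flag = rep_len(cross, length(ids)),
    stringsAsFactors = FALSE
  )
}

# dm_signature built from a bundle's planted truth (directions as planted)
truth_signature <- function(bundle) {
  sig <- bundle$truth$signature
  structure(
    list(cpgs = data.frame(sig,
                           logFC = ifelse(sig$direction == "hyper", 1, -1),
                           p_adj = 0, stringsAsFactors = FALSE),
         genes = unique(sig$gene), alpha = 0.1),
    class = "dm_signature"
  )
}

# hand-rolled BH step-up, independent of stats::p.adjust
brute_force_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- Inf
  for (i in rev(seq_len(m))) {
    prev <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- min(prev, 1)
  }
  adj
}

# brute-force concordance by explicit double loop over all pairs
brute_force_cindex <- function(scores, outcome) {
  d <- scores[outcome == 1]; s <- scores[outcome == 0]
  conc <- 0; tied <- 0
  for (x in d) for (y in s) {
    if (x > y) conc <- conc + 1 else if (x == y) tied <- tied + 0.5
  }
  (conc + tied) / (length(d) * length(s))
}

# hypergeometric upper tail by exact combinatorial enumeration
brute_force_hyper_tail <- function(k, N, K, n) {
  js <- max(k, 0):min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}
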