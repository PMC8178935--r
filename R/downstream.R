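#' Filter the expression matrix to adequately measured genes
#'
#' Keeps a gene when it has at least `min_count` counts in at least
#' `min_fraction` of the samples (boundary inclusive).
#'
#' @param counts genes x samples non-negative integer matrix.
#' @param min_count minimum count (default 10).
#' @param min_fraction minimum fraction of samples at or above it
#'   (default 0.9).
#' @return the filtered count matrix.
#' @export
filter_expressed <- function(counts, min_count = 10, min_fraction = 0.9) {
  if (any(counts < 0)) stopf("counts must be non-negative")
  keep <- rowSums(counts >= min_count) / ncol(counts) >= min_fraction
  counts[keep, , drop = FALSE]
}

#' Correlate gene expression with signature-CpG methylation
#'
#' For each signature gene with expression data, computes the Pearson
#' correlation between the gene's (by default log2(count + 1)-transformed)
#' counts and the beta values of each of its signature CpGs over the shared
#' samples, with the two-sided p-value from the t transform of r
#' (t = r sqrt(n - 2) / sqrt(1 - r^2) on n - 2 df). Hypermethylation may
#' accompany either reduced or elevated expression, so the sign is
#' reported, not assumed.
#'
#' @param counts genes x samples count matrix.
#' @param beta probes x samples beta matrix (or a [methylation_dataset()]).
#' @param signature a `dm_signature`.
#' @param transform `"log2"` (log2(count + 1), default) or `"none"`.
#' @return data frame: gene, cpg_id, n, r, p (r is `NA` and flagged in
#'   `degenerate` when either vector is constant).
#' @export
correlate_expression_methylation <- function(counts, beta, signature,
                                             transform = c("log2", "none")) {
  transform <- match.arg(transform)
  if (inherits(beta, "methylation_dataset")) beta <- beta$beta
  cpgs <- signature$cpgs
  shared <- intersect(colnames(counts), colnames(beta))
  if (length(shared) < 3) stopf("need at least 3 shared samples, got %d", length(shared))
  rows <- cpgs[cpgs$gene %in% rownames(counts) &
                 cpgs$probe_id %in% rownames(beta), , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    x <- counts[rows$gene[i], shared]
    if (transform == "log2") x <- log2(x + 1)
    y <- beta[rows$probe_id[i], shared]
    n <- length(shared)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(data.frame(gene = rows$gene[i], cpg_id = rows$probe_id[i],
                        n = n, r = NA_real_, p = NA_real_, degenerate = TRUE,
                        stringsAsFactors = FALSE))
    }
    r <- stats::cor(x, y)
    tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
    data.frame(gene = rows$gene[i], cpg_id = rows$probe_id[i], n = n, r = r,
               p = 2 * stats::pt(-abs(tstat), df = n - 2), degenerate = FALSE,
               stringsAsFactors = FALSE)
  }))
  out %||% data.frame(gene = character(), cpg_id = character(), n = integer(),
                      r = numeric(), p = numeric(), degenerate = logical())
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line; tab-separated set name, description,
#' then member gene symbols.
#'
#' @param path GMT file path.
#' @return named list of character vectors of gene symbols.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, tests whether the query list overlaps the set more
#' than expected under sampling without replacement from the universe:
#' upper-tail p = P(X >= k) for X hypergeometric with universe size N, set
#' size K (after intersection with the universe), and query size n.
#' Bonferroni correction multiplies by the number of sets actually tested;
#' sets with no universe overlap are skipped and counted in a message.
#'
#' @param query_genes character vector, must be a subset of
#'   `universe_genes`.
#' @param universe_genes background universe (all genes surviving the
#'   differential-methylation stage, significant and non-significant; see
#'   [ora_universe()] for the alternative non-significant-only reading).
#' @param gene_sets named list of gene symbol vectors (see [read_gmt()]).
#' @return data frame of class `ora_result`: set_id, set_name, k, K, n, N,
#'   p_hyper, p_bonf.
#' @export
ora <- function(query_genes, universe_genes, gene_sets) {
  universe_genes <- unique(universe_genes)
  query_genes <- unique(query_genes)
  if (!length(universe_genes)) stopf("empty universe")
  extra <- setdiff(query_genes, universe_genes)
  if (length(extra)) {
    stopf("query gene(s) outside the universe: %s",
          paste(utils::head(extra, 5), collapse = ", "))
  }
  N <- length(universe_genes)
  n <- length(query_genes)
  sets <- lapply(gene_sets, intersect, y = universe_genes)
  sizes <- lengths(sets)
  skipped <- sum(sizes == 0)
  if (skipped) {
    message(sprintf("ora: skipped %d set(s) with no universe overlap", skipped))
  }
  keep <- which(sizes > 0)
  m <- length(keep)
  out <- do.call(rbind, lapply(keep, function(i) {
    K <- sizes[[i]]
    k <- length(intersect(query_genes, sets[[i]]))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_id = i, set_name = names(gene_sets)[i], k = k, K = K,
               n = n, N = N, p_hyper = p, p_bonf = min(1, p * m),
               stringsAsFactors = FALSE)
  }))
  out <- out %||% data.frame(set_id = integer(), set_name = character(),
                             k = integer(), K = integer(), n = integer(),
                             N = integer(), p_hyper = numeric(),
                             p_bonf = numeric())
  class(out) <- c("ora_result", "data.frame")
  out
}

#' Build the over-representation background universe
#'
#' Two readings of "non-significant genes as the background universe" are
#' supported: `"all"` (default) uses every gene surviving differential
#' methylation, significant and non-significant alike, so the query is a
#' subset of its own universe; `"nonsignificant"` uses the non-significant
#' genes plus the query (the query must be in the universe for the
#' hypergeometric model to be well defined).
#'
#' @param results a `dm_result` data frame with `gene` and `p_adj`.
#' @param query_genes the query list the universe must contain.
#' @param alpha signature threshold used to split significant from
#'   non-significant (default 0.1).
#' @param mode `"all"` or `"nonsignificant"`.
#' @return character vector of universe gene symbols.
#' @export
ora_universe <- function(results, query_genes = character(), alpha = 0.1,
                         mode = c("all", "nonsignificant")) {
  mode <- match.arg(mode)
  ok <- !is.na(results$gene) & results$gene != ""
  if (mode == "all") return(unique(c(results$gene[ok], query_genes)))
  nonsig <- ok & !(results$p_adj < alpha)
  unique(c(results$gene[nonsig], query_genes))
}
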