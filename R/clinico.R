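# Pearson chi-square (uncorrected) for a 2x2 indicator x outcome table;
# returns c(statistic, p); NA when a margin is empty.
chisq2x2 <- function(x, y) {
  a <- as.numeric(sum(x & y)); b <- as.numeric(sum(x & !y))
  c <- as.numeric(sum(!x & y)); d <- as.numeric(sum(!x & !y))
  n <- a + b + c + d
  m1 <- a + b; m2 <- c + d; m3 <- a + c; m4 <- b + d
  if (m1 == 0 || m2 == 0 || m3 == 0 || m4 == 0) return(c(NA_real_, NA_real_))
  stat <- n * (a * d - b * c)^2 / (m1 * m2 * m3 * m4)
  c(stat, stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Dichotomize a continuous clinical feature
#'
#' Chooses the cut maximizing the Pearson chi-square statistic of the 2x2
#' (at-or-above cut x outcome) table over a candidate grid; ties go to the
#' smaller cut. The default grid is the multiples of 5 strictly inside the
#' observed range, a proxy for clinically sensible round cut-offs.
#'
#' @param cohort clinical data frame with an `outcome` column.
#' @param feature name of a numeric column.
#' @param candidate_cuts optional numeric vector of cuts to consider.
#' @param outcome name of the binary outcome column.
#' @return the selected cut, with the chi-square statistic in attribute
#'   `statistic`.
#' @export
dichotomize_continuous <- function(cohort, feature, candidate_cuts = NULL,
                                   outcome = "outcome") {
  x <- cohort[[feature]]
  if (!is.numeric(x)) stopf("feature '%s' is not numeric", feature)
  if (length(unique(x[!is.na(x)])) < 2) {
    stopf("feature '%s' is constant and cannot be dichotomized", feature)
  }
  if (is.null(candidate_cuts)) {
    r <- range(x, na.rm = TRUE)
    candidate_cuts <- seq(ceiling(r[1] / 5) * 5, floor(r[2] / 5) * 5, by = 5)
    candidate_cuts <- candidate_cuts[candidate_cuts > r[1] & candidate_cuts <= r[2]]
  }
  if (!length(candidate_cuts)) stopf("no admissible candidate cuts for '%s'", feature)
  y <- cohort[[outcome]] == 1
  ok <- !is.na(x) & !is.na(y)
  stats_ <- vapply(candidate_cuts, function(cut) chisq2x2(x[ok] >= cut, y[ok])[1],
                   numeric(1))
  if (all(is.na(stats_))) stopf("no candidate cut yields a non-degenerate table for '%s'", feature)
  best <- which(stats_ == max(stats_, na.rm = TRUE))[1]  # ties -> smaller cut
  structure(candidate_cuts[best], statistic = stats_[best])
}

# condition: list(feature, type = "numeric"|"categorical", cut or levels,
# negate). A patient satisfies it when the (possibly negated) predicate is
# TRUE; NA propagates.
eval_condition <- function(cond, data, check_levels = NULL) {
  x <- data[[cond$feature]]
  if (cond$type == "numeric") {
    out <- x >= cond$cut
  } else {
    if (!is.null(check_levels)) {
      known <- check_levels[[cond$feature]]
      bad <- setdiff(unique(x[!is.na(x)]), known)
      if (length(bad)) {
        stopf("unknown level(s) for feature '%s': %s",
              cond$feature, paste(bad, collapse = ", "))
      }
    }
    out <- x %in% cond$levels
    out[is.na(x)] <- NA
  }
  if (isTRUE(cond$negate)) !out else out
}

condition_label <- function(cond) {
  base <- if (cond$type == "numeric") {
    sprintf("%s >= %g", cond$feature, cond$cut)
  } else {
    sprintf("%s in {%s}", cond$feature, paste(cond$levels, collapse = ","))
  }
  if (isTRUE(cond$negate)) paste0("not(", base, ")") else base
}

#' Grow a recursive-partitioning tree over clinical features
#'
#' Greedy binary tree predicting the binary 5-year vital status. At each
#' node the split with the smallest uncorrected Pearson chi-square p-value
#' over all features is chosen (numeric features are dichotomized once at
#' the root via [dichotomize_continuous()]; categorical features offer
#' one-level-versus-rest splits). In the classic chi-square partitioning
#' (CHAID) tradition, the winning p-value is Bonferroni-adjusted for the
#' number of candidate splits examined at the node, so `stop_alpha` is a
#' per-node family-wise level and pure-noise cohorts rarely split at all.
#' Splitting stops when the adjusted best p is at or above `stop_alpha`,
#' the node is below `2 * min_leaf`, a child would fall below `min_leaf`,
#' depth reaches `max_depth`, or the node is pure. A root with no
#' admissible split yields a single-leaf tree, not an error.
#'
#' @param cohort clinical data frame with an `outcome` column.
#' @param features feature names to consider (default: the ten-feature
#'   panel).
#' @param outcome name of the binary outcome column.
#' @param min_leaf minimum patients per child node (default 20).
#' @param max_depth maximum number of split levels (default 4).
#' @param stop_alpha chi-square p-value stopping threshold (default 0.05).
#' @param candidate_cuts optional named list of cut grids for numeric
#'   features.
#' @return object of class `partition_tree` (nested node list plus the
#'   dichotomization table and observed level sets).
#' @export
build_partition_tree <- function(cohort, features = clinico_panel_features(),
                                 outcome = "outcome", min_leaf = 20,
                                 max_depth = 4, stop_alpha = 0.05,
                                 candidate_cuts = NULL) {
  missing <- setdiff(features, names(cohort))
  if (length(missing)) stopf("feature(s) absent from cohort: %s",
                             paste(missing, collapse = ", "))
  y <- cohort[[outcome]] == 1
  if (anyNA(y)) stopf("outcome must not contain missing values")
  numeric_feats <- features[vapply(features, function(f) is.numeric(cohort[[f]]), logical(1))]
  cuts <- list()
  for (f in numeric_feats) {
    cuts[[f]] <- as.numeric(dichotomize_continuous(cohort, f, candidate_cuts[[f]],
                                                   outcome = outcome))
  }
  levels_map <- lapply(cohort[setdiff(features, numeric_feats)],
                       function(x) sort(unique(x[!is.na(x)])))

  candidates <- list()
  for (f in features) {
    if (f %in% numeric_feats) {
      candidates[[length(candidates) + 1]] <-
        list(feature = f, type = "numeric", cut = cuts[[f]])
    } else {
      for (lev in levels_map[[f]]) {
        candidates[[length(candidates) + 1]] <-
          list(feature = f, type = "categorical", levels = lev)
      }
    }
  }

  grow <- function(idx, depth) {
    node <- list(n = length(idx), n_event = sum(y[idx]), depth = depth)
    if (depth >= max_depth || length(idx) < 2 * min_leaf ||
        node$n_event == 0 || node$n_event == length(idx)) {
      node$leaf <- TRUE
      return(node)
    }
    best <- NULL
    n_tested <- 0L
    for (cand in candidates) {
      z <- eval_condition(cand, cohort[idx, , drop = FALSE])
      if (anyNA(z)) next  # a split cannot route missing values
      if (sum(z) < min_leaf || sum(!z) < min_leaf) next
      res <- chisq2x2(z, y[idx])
      if (is.na(res[2])) next
      n_tested <- n_tested + 1L
      if (is.null(best) || res[2] < best$p) {
        best <- list(cond = cand, p = res[2], statistic = res[1], z = z)
      }
    }
    if (is.null(best) || min(1, best$p * n_tested) >= stop_alpha) {
      node$leaf <- TRUE
      return(node)
    }
    node$leaf <- FALSE
    node$condition <- best$cond
    node$p_value <- min(1, best$p * n_tested)
    node$statistic <- best$statistic
    node$yes <- grow(idx[best$z], depth + 1)
    node$no <- grow(idx[!best$z], depth + 1)
    node
  }
  structure(
    list(root = grow(seq_len(nrow(cohort)), 0L), cuts = cuts,
         levels_map = levels_map, features = features,
         params = list(min_leaf = min_leaf, max_depth = max_depth,
                       stop_alpha = stop_alpha)),
    class = "partition_tree"
  )
}

tree_depth <- function(node) {
  if (isTRUE(node$leaf)) return(0L)
  1L + max(tree_depth(node$yes), tree_depth(node$no))
}

#' @export
print.partition_tree <- function(x, ...) {
  show <- function(node, indent, label) {
    pad <- strrep("  ", indent)
    if (isTRUE(node$leaf)) {
      cat(sprintf("%s%s leaf: n=%d, events=%d\n", pad, label, node$n, node$n_event))
    } else {
      cat(sprintf("%s%s split on %s (p=%.3g), n=%d\n", pad, label,
                  condition_label(node$condition), node$p_value, node$n))
      show(node$yes, indent + 1, "[yes]")
      show(node$no, indent + 1, "[no]")
    }
  }
  show(x$root, 0, "root")
  invisible(x)
}

#' Convert a partition tree into an integer scoring rule
#'
#' At each decision node the odds ratio of death for the risk-side branch
#' (the branch with the higher death rate) versus the other branch is
#' computed among the node's patients, with a Haldane-Anscombe 0.5
#' continuity correction when any cell is zero. The rule's points are the
#' odds ratio rounded to the nearest integer (round-half-even). A rule's
#' condition is the conjunction of its node-path conditions and the
#' risk-side condition, so a patient's score is the sum of points over
#' satisfied rules.
#'
#' @param tree a [build_partition_tree()] result.
#' @param cohort the cohort the tree was grown on.
#' @param outcome name of the binary outcome column.
#' @return object of class `clinico_score_model` with `rules` (each:
#'   conjuncts, points, node odds ratio, node size), the dichotomization
#'   table, and the observed level sets.
#' @export
tree_to_score <- function(tree, cohort, outcome = "outcome") {
  stopifnot(inherits(tree, "partition_tree"))
  y <- cohort[[outcome]] == 1
  rules <- list()
  walk <- function(node, idx, conjuncts) {
    if (isTRUE(node$leaf)) return(invisible())
    z <- eval_condition(node$condition, cohort[idx, , drop = FALSE])
    dead_yes <- sum(y[idx][z]); alive_yes <- sum(z) - dead_yes
    dead_no <- sum(y[idx][!z]); alive_no <- sum(!z) - dead_no
    rate_yes <- dead_yes / max(sum(z), 1)
    rate_no <- dead_no / max(sum(!z), 1)
    risk_yes <- rate_yes >= rate_no
    a <- if (risk_yes) dead_yes else dead_no    # risk-side deaths
    b <- if (risk_yes) alive_yes else alive_no  # risk-side survivors
    c_ <- if (risk_yes) dead_no else dead_yes
    d <- if (risk_yes) alive_no else alive_yes
    if (min(a, b, c_, d) == 0) {
      a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5
    }
    or <- (a * d) / (b * c_)
    risk_cond <- node$condition
    risk_cond$negate <- !risk_yes
    rules[[length(rules) + 1]] <<- list(
      conjuncts = c(conjuncts, list(risk_cond)),
      feature = node$condition$feature,
      points = round(or), node_or = or, n = node$n, depth = node$depth
    )
    yes_cond <- node$condition; yes_cond$negate <- FALSE
    no_cond <- node$condition; no_cond$negate <- TRUE
    walk(node$yes, idx[z], c(conjuncts, list(yes_cond)))
    walk(node$no, idx[!z], c(conjuncts, list(no_cond)))
  }
  walk(tree$root, seq_len(nrow(cohort)), list())
  structure(
    list(rules = rules, cuts = tree$cuts, levels_map = tree$levels_map,
         features = tree$features, tree = tree),
    class = "clinico_score_model"
  )
}

#' @export
print.clinico_score_model <- function(x, ...) {
  cat(sprintf("clinico_score_model: %d rule(s)\n", length(x$rules)))
  for (r in x$rules) {
    cat(sprintf("  +%d points if %s  (node OR %.2f, n=%d)\n", r$points,
                paste(vapply(r$conjuncts, condition_label, character(1)),
                      collapse = " & "),
                r$node_or, r$n))
  }
  if (length(x$cuts)) {
    cat("  dichotomization:",
        paste(sprintf("%s >= %g", names(x$cuts), unlist(x$cuts)), collapse = "; "),
        "\n")
  }
  invisible(x)
}

#' Score patients with a clinicopathologic model
#'
#' Sums the points of every satisfied rule. A missing value in a feature a
#' rule uses makes that rule unsatisfiable for the patient (skipped and
#' counted in a message); an unseen category level is an error naming the
#' level.
#'
#' @param model a `clinico_score_model`.
#' @param cohort clinical data frame to score.
#' @return named non-negative integer vector of scores.
#' @export
score_patients <- function(model, cohort) {
  stopifnot(inherits(model, "clinico_score_model"))
  n <- nrow(cohort)
  total <- integer(n)
  n_skipped <- 0L
  for (r in model$rules) {
    sat <- rep(TRUE, n)
    for (cond in r$conjuncts) {
      sat <- sat & eval_condition(cond, cohort, check_levels = model$levels_map)
    }
    n_skipped <- n_skipped + sum(is.na(sat))
    sat[is.na(sat)] <- FALSE
    total <- total + r$points * sat
  }
  if (n_skipped > 0) {
    message(sprintf("score_patients: skipped %d rule evaluation(s) due to missing values",
                    n_skipped))
  }
  ids <- cohort$patient_id %||% as.character(seq_len(n))
  stats::setNames(as.integer(total), ids)
}

#' Fit the clinicopathologic score
#'
#' One-call wrapper: dichotomizes continuous features, grows the
#' recursive-partitioning tree, converts decision-node odds ratios into
#' integer points, and scores the training cohort.
#'
#' @inheritParams build_partition_tree
#' @return a `clinico_score_model` with the training scores in attribute
#'   `training_scores`.
#' @export
fit_clinico_score <- function(cohort, features = clinico_panel_features(),
                              outcome = "outcome", min_leaf = 20, max_depth = 4,
                              stop_alpha = 0.05, candidate_cuts = NULL) {
  tree <- build_partition_tree(cohort, features, outcome, min_leaf, max_depth,
                               stop_alpha, candidate_cuts)
  model <- tree_to_score(tree, cohort, outcome)
  attr(model, "training_scores") <- score_patients(model, cohort)
  model
}

#' @export
predict.clinico_score_model <- function(object, newdata, ...) {
  score_patients(object, newdata)
}
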