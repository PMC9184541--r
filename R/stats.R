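#' Two-sample t test (Student or Welch)
#'
#' Two-tailed unpaired test. The classical pooled-variance (Student) variant
#' is the default; Welch is available. Conventions for degenerate input:
#' both groups constant with equal means gives t = 0, p = 1 (no evidence of
#' difference); both constant with different means gives |t| = Inf, p = 0.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @param variant `"student"` (default) or `"welch"`.
#' @return list with `t`, `df`, `p` (two-sided).
#' @export
two_sample_t <- function(x, y, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (length(x) < 2L || length(y) < 2L) {
    stopf("each group needs >= 2 values (got %d and %d)", length(x), length(y))
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      return(list(t = 0, df = length(x) + length(y) - 2L, p = 1))
    }
    return(list(t = sign(mean(x) - mean(y)) * Inf,
                df = length(x) + length(y) - 2L, p = 0))
  }
  ht <- stats::t.test(x, y, var.equal = (variant == "student"))
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Within-group pairwise Spearman correlations
#'
#' Replicate QC: rank correlations (average ranks for ties) between all
#' sample pairs within each (cohort, stage) group, plus the minimum and mean
#' over all within-group pairs. A constant sample has no rank variance; its
#' correlations are reported as `NA` with a warning.
#'
#' @param mat expression or count matrix (spike rows excluded).
#' @param sheet sample sheet.
#' @param universe optional gene IDs to restrict to.
#' @return list with `groups` (named list of per-group correlation
#'   matrices), `min` and `mean` over within-group pairs.
#' @export
pairwise_spearman <- function(mat, sheet, universe = NULL) {
  m <- mat[!spike_rows(mat), , drop = FALSE]
  if (!is.null(universe)) m <- m[intersect(rownames(m), universe), , drop = FALSE]
  groups <- unique(group_label(sheet$cohort, sheet$stage))
  const <- colnames(m)[apply(m, 2L, function(v) stats::sd(v) == 0)]
  if (length(const)) {
    warning(sprintf("constant sample(s), correlation undefined: %s",
                    paste(const, collapse = ", ")), call. = FALSE)
  }
  res <- list()
  pair_vals <- numeric()
  for (g in groups) {
    ids <- group_samples(sheet, g)
    if (length(ids) < 2L) next
    cc <- suppressWarnings(stats::cor(m[, ids, drop = FALSE], method = "spearman"))
    cc[, colnames(cc) %in% const] <- NA_real_
    cc[rownames(cc) %in% const, ] <- NA_real_
    diag(cc) <- 1
    res[[g]] <- cc
    pair_vals <- c(pair_vals, cc[upper.tri(cc)])
  }
  ok <- pair_vals[!is.na(pair_vals)]
  list(groups = res,
       min = if (length(ok)) min(ok) else NA_real_,
       mean = if (length(ok)) mean(ok) else NA_real_)
}

#' Complete-linkage hierarchical clustering
#'
#' Agglomerative clustering where the distance between clusters is the
#' maximum pairwise distance. Input is validated (symmetric, non-negative,
#' zero diagonal) before handing to the standard agglomeration.
#'
#' @param d square distance matrix (or `dist` object).
#' @param k,h optional: number of clusters, or cut height, for flat labels.
#' @return list with `tree` (an `hclust` object) and `labels` (flat cluster
#'   assignment when `k` or `h` is given, else `NULL`).
#' @export
cluster_complete <- function(d, k = NULL, h = NULL) {
  if (!inherits(d, "dist")) {
    d <- as.matrix(d)
    if (nrow(d) != ncol(d)) stopf("distance matrix must be square")
    if (!isTRUE(all.equal(d, t(d), tolerance = 1e-12))) {
      stopf("distance matrix must be symmetric")
    }
    if (any(d < 0)) stopf("distances must be non-negative")
    if (any(diag(d) != 0)) stopf("distance matrix must have a zero diagonal")
    d <- stats::as.dist(d)
  }
  if (attr(d, "Size") < 2L) {
    return(list(tree = NULL, labels = stats::setNames(1L, attr(d, "Labels"))))
  }
  tree <- stats::hclust(d, method = "complete")
  labels <- if (!is.null(k) || !is.null(h)) stats::cutree(tree, k = k, h = h) else NULL
  list(tree = tree, labels = labels)
}

#' Hypergeometric gene-set over-representation
#'
#' For each gene set, tests whether the selected genes over-represent the
#' set within the universe: upper-tail hypergeometric `P[X >= k]` with
#' overlap k, set size K (after intersection with the universe), selection
#' size n and universe size N; Benjamini-Hochberg q across the tested sets.
#'
#' @param selected character vector of selected genes (must be a subset of
#'   `universe`).
#' @param universe character vector, the analysis universe.
#' @param sets a `gene_sets` collection (see [read_gene_sets()]) or a named
#'   list of character vectors.
#' @return data frame of class `enrichment_result`, one row per set:
#'   `set`, `k`, `K`, `n`, `N`, `p`, `q`, ordered by p.
#' @export
hypergeom_enrichment <- function(selected, universe, sets) {
  universe <- unique(as.character(universe))
  selected <- unique(as.character(selected))
  out_of <- setdiff(selected, universe)
  if (length(out_of)) {
    stopf("selected gene(s) not in universe: %s",
          paste(utils::head(out_of, 5L), collapse = ", "))
  }
  N <- length(universe)
  n <- length(selected)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(unique(sets[[nm]]), universe)
    K <- length(members)
    k <- length(intersect(members, selected))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q <- stats::p.adjust(res$p, method = "BH")
  res <- res[order(res$p), ]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Relative qPCR levels from Ct values
#'
#' Relative level per sample is `2^(Ct_reference - Ct_target)` (a higher
#' target Ct means less transcript), normalized to an internal reference
#' gene (Gapdh role); fold change divides by the mean level of the control
#' condition. Setting `literal = TRUE` flips the exponent to
#' `2^(Ct_target - Ct_reference)`.
#'
#' @param ct data frame with columns `sample`, `condition`, `ct_target`,
#'   `ct_reference`.
#' @param control_condition condition label defining the control group.
#' @param literal use the inverted exponent sign (see Details).
#' @return `ct` with added columns `level` and `fold_change`.
#' @export
delta_ct_levels <- function(ct, control_condition, literal = FALSE) {
  need <- c("sample", "condition", "ct_target", "ct_reference")
  miss <- setdiff(need, colnames(ct))
  if (length(miss)) stopf("ct table missing column(s): %s", paste(miss, collapse = ", "))
  bad <- which(!is.finite(ct$ct_reference))
  if (length(bad)) {
    stopf("missing reference Ct for sample(s): %s",
          paste(ct$sample[bad], collapse = ", "))
  }
  if (!control_condition %in% ct$condition) {
    stopf("control condition \"%s\" not present in the table", control_condition)
  }
  delta <- if (literal) ct$ct_target - ct$ct_reference else ct$ct_reference - ct$ct_target
  ct$level <- 2^delta
  ct$fold_change <- ct$level / mean(ct$level[ct$condition == control_condition])
  ct
}
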