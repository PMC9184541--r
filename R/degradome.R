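#' Filter to expressed genes
#'
#' Two universes are used in the analyses: `any_sample` keeps genes whose
#' value strictly exceeds the threshold in at least one sample (the general
#' expressed universe, FPKM > 1); `group` keeps genes whose *group mean*
#' strictly exceeds the threshold in the named group (used with GV groups as
#' the M-decay universe).
#'
#' @param mat normalized expression matrix.
#' @param threshold expression cutoff (strict `>`), default 1.
#' @param scope `"any_sample"` or `"group"`.
#' @param sheet sample sheet (required for `scope = "group"`).
#' @param group `"cohort:stage"` descriptor (required for `scope = "group"`).
#' @return character vector of gene IDs (spike rows never included).
#' @export
filter_expressed <- function(mat, threshold = 1, scope = c("any_sample", "group"),
                             sheet = NULL, group = NULL) {
  scope <- match.arg(scope)
  sp <- spike_rows(mat)
  m <- mat[!sp, , drop = FALSE]
  if (scope == "any_sample") {
    keep <- apply(m, 1L, function(v) any(v > threshold))
  } else {
    if (is.null(sheet) || is.null(group)) {
      stopf("scope = \"group\" requires sheet and group")
    }
    ids <- require_group(sheet, group)
    keep <- rowMeans(m[, ids, drop = FALSE]) > threshold
  }
  rownames(m)[keep]
}

#' Per-gene mean over a sample group
#'
#' @param mat expression matrix.
#' @param sheet sample sheet.
#' @param group `"cohort:stage"` descriptor.
#' @param aggregate `"arithmetic"` (default) or `"geometric"` mean.
#' @return named numeric vector over endogenous genes.
#' @export
group_mean <- function(mat, sheet, group, aggregate = c("arithmetic", "geometric")) {
  aggregate <- match.arg(aggregate)
  ids <- require_group(sheet, group)
  m <- mat[!spike_rows(mat), ids, drop = FALSE]
  if (aggregate == "arithmetic") rowMeans(m) else exp(rowMeans(log(m)))
}

#' Pseudocounted fold change between two group-mean vectors
#'
#' `FC_i = (A_i + eps) / (B_i + eps)`. The pseudocount keeps fold changes
#' finite when the denominator group (typically MII means of decayed
#' transcripts) is at or near zero; `eps` is far below the FPKM > 1
#' expression filter, so calls are insensitive to it.
#'
#' @param means_a,means_b aligned named numeric vectors (numerator,
#'   denominator).
#' @param pseudocount eps added to both, default 0.01.
#' @param orientation label recorded on the result (e.g. `"GV/MII"`).
#' @return named numeric vector of fold changes with attribute
#'   `orientation`.
#' @export
fold_change <- function(means_a, means_b, pseudocount = 0.01, orientation = "A/B") {
  if (is.null(names(means_a)) || is.null(names(means_b)) ||
      !identical(names(means_a), names(means_b))) {
    stopf("fold_change requires identically named, aligned gene vectors")
  }
  if (!is_scalar_number(pseudocount) || pseudocount < 0) stopf("pseudocount must be >= 0")
  fc <- (means_a + pseudocount) / (means_b + pseudocount)
  attr(fc, "orientation") <- orientation
  fc
}

#' Directional classification at fold-change thresholds
#'
#' A gene is `up` at threshold t if FC > t, `down` if FC < 1/t, else
#' `unchanged`. Inequalities are strict ("more than t-fold"), so FC exactly
#' at a threshold is unchanged.
#'
#' @param fc fold changes oriented test/reference.
#' @param thresholds numeric thresholds, all > 1 (default `c(2, 5)`).
#' @return data frame, one row per gene, columns `dir_2x`, `dir_5x`, ...
#' @export
classify_direction <- function(fc, thresholds = c(2, 5)) {
  if (any(thresholds <= 1)) stopf("thresholds must be > 1")
  out <- data.frame(gene_id = names(fc), stringsAsFactors = FALSE)
  for (t in thresholds) {
    lab <- ifelse(fc > t, "up", ifelse(fc < 1 / t, "down", "unchanged"))
    out[[sprintf("dir_%gx", t)]] <- unname(lab)
  }
  out
}

#' Call M-decay transcripts
#'
#' Meiosis-coupled (M-)decay transcripts are genes that (i) pass the GV
#' expression filter (GV group mean strictly above `gv_filter`) and (ii)
#' drop more than `fc_threshold`-fold from GV to MII
#' (`FC[GV/MII] > fc_threshold`, strict).
#'
#' @param mat normalized expression matrix.
#' @param sheet sample sheet.
#' @param gv_group,mii_group `"cohort:stage"` descriptors for the GV and MII
#'   groups of one cohort.
#' @param fc_threshold fold-change cutoff, default 5.
#' @param gv_filter GV expression cutoff, default 1 (FPKM).
#' @param pseudocount passed to [fold_change()].
#' @param aggregate replicate aggregation, see [group_mean()].
#' @return character vector of called gene IDs.
#' @export
call_m_decay <- function(mat, sheet, gv_group, mii_group, fc_threshold = 5,
                         gv_filter = 1, pseudocount = 0.01,
                         aggregate = "arithmetic") {
  if (!is_scalar_number(fc_threshold) || fc_threshold <= 1) stopf("fc_threshold must be > 1")
  gv <- group_mean(mat, sheet, gv_group, aggregate)
  mii <- group_mean(mat, sheet, mii_group, aggregate)
  fc <- fold_change(gv, mii, pseudocount, orientation = "GV/MII")
  names(fc)[gv > gv_filter & fc > fc_threshold]
}

#' Partition a reference M-decay set by a test cohort
#'
#' Sensitivity is defined set-theoretically: `sensitive` transcripts are
#' M-decay in the reference cohort but not in the test cohort (decay failed
#' there); `insensitive` transcripts are M-decay in both; `test_only` are
#' M-decay only in the test cohort. By construction
#' `|sensitive| + |insensitive| = |reference|`.
#'
#' @param reference_set gene IDs called M-decay in the reference (young/WT)
#'   cohort.
#' @param test_set gene IDs called M-decay in the test (aged/mutant) cohort.
#' @return list of class `sensitivity_partition` with `sensitive`,
#'   `insensitive`, `test_only`.
#' @export
partition_sensitivity <- function(reference_set, test_set) {
  reference_set <- unique(as.character(reference_set))
  test_set <- unique(as.character(test_set))
  structure(list(
    sensitive = setdiff(reference_set, test_set),
    insensitive = intersect(reference_set, test_set),
    test_only = setdiff(test_set, reference_set)
  ), class = "sensitivity_partition")
}

#' @export
print.sensitivity_partition <- function(x, ...) {
  cat(sprintf("Sensitivity partition: %d sensitive, %d insensitive (reference %d), %d test-only\n",
              length(x$sensitive), length(x$insensitive),
              length(x$sensitive) + length(x$insensitive), length(x$test_only)))
  invisible(x)
}

#' @export
print.degradome_calls <- function(x, ...) {
  cat(sprintf("Degradome call set: %d genes, %d M-decay (reference), %d (test)\n",
              nrow(x), sum(x$m_decay_ref), sum(x$m_decay_test)))
  print(utils::head(as.data.frame(x)))
  invisible(x)
}

#' @export
summary.degradome_calls <- function(object, ...) {
  cat("Sensitivity labels:\n")
  print(table(object$sensitivity))
  cat("Direction at 5x (test MII vs reference MII):\n")
  print(table(object$dir_5x_mii))
  invisible(object)
}

#' Venn region counts for 2 or 3 gene sets
#'
#' @param sets named list of 2 or 3 character vectors.
#' @return named integer vector, one entry per intersection region (names
#'   join set names with `&`); region counts sum to the union size.
#' @export
venn_regions <- function(sets) {
  if (!is.list(sets) || length(sets) < 2L || length(sets) > 3L) {
    stopf("venn_regions takes 2 or 3 sets, got %d", length(sets))
  }
  if (is.null(names(sets))) names(sets) <- LETTERS[seq_along(sets)]
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (is.null(dim(member))) member <- matrix(member, nrow = length(universe))
  combos <- expand.grid(rep(list(c(TRUE, FALSE)), length(sets)))[-2^length(sets), , drop = FALSE]
  counts <- apply(combos, 1L, function(inc) {
    sum(apply(member, 1L, function(m) all(m == as.logical(inc))))
  })
  names(counts) <- apply(combos, 1L, function(inc) {
    paste(names(sets)[as.logical(inc)], collapse = "&")
  })
  counts[order(names(counts))]
}

#' Degradation-pattern trajectories and median curve
#'
#' For a gene set and an ordered sequence of groups (e.g. young GV, young
#' MII), returns each gene's trajectory of log2(group mean + eps) and the
#' per-group median across genes — the summary drawn as per-gene lines with
#' a median curve.
#'
#' @param mat normalized expression matrix.
#' @param sheet sample sheet.
#' @param genes non-empty character vector of gene IDs.
#' @param groups ordered `"cohort:stage"` descriptors (>= 2).
#' @param pseudocount eps inside the log, default 0.01.
#' @return list of class `degradation_pattern`: `trajectories`
#'   (genes x groups, log2 scale), `median` (per-group median), `groups`.
#' @export
degradation_pattern <- function(mat, sheet, genes, groups, pseudocount = 0.01) {
  if (length(genes) == 0L) stopf("empty gene set")
  if (length(groups) < 2L) stopf("need >= 2 ordered groups")
  genes <- intersect(genes, rownames(mat))
  if (length(genes) == 0L) stopf("none of the genes are in the matrix")
  traj <- vapply(groups, function(g) {
    log2(group_mean(mat, sheet, g)[genes] + pseudocount)
  }, numeric(length(genes)))
  if (is.null(dim(traj))) traj <- matrix(traj, nrow = length(genes),
                                         dimnames = list(genes, groups))
  structure(list(trajectories = traj,
                 median = apply(traj, 2L, stats::median),
                 groups = groups),
            class = "degradation_pattern")
}

#' @export
print.degradation_pattern <- function(x, ...) {
  cat(sprintf("Degradation pattern: %d genes over %d groups\n",
              nrow(x$trajectories), length(x$groups)))
  cat("  median log2 level:",
      paste(sprintf("%s=%.2f", x$groups, x$median), collapse = ", "), "\n")
  invisible(x)
}

#' Plot a degradation pattern
#'
#' Light per-gene trajectories with the group median overlaid.
#'
#' @param x a `degradation_pattern`.
#' @param col_genes,col_median line colours.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.degradation_pattern <- function(x, col_genes = "#9ecae1",
                                     col_median = "#de2d26", ...) {
  graphics::matplot(t(x$trajectories), type = "l", lty = 1, col = col_genes,
                    xaxt = "n", xlab = "", ylab = "log2 level", ...)
  graphics::axis(1, at = seq_along(x$groups), labels = x$groups)
  graphics::lines(seq_along(x$groups), x$median, col = col_median, lwd = 3)
  invisible(x)
}
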