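#' Convert fragment counts to FPKM
#'
#' `FPKM(r, j) = count(r, j) / (length_r / 1e3) / (total_j / 1e6)` where
#' `total_j` sums endogenous *and* spike-in rows (reads are mapped to a
#' composite reference; the spike anchoring ratio is invariant to this
#' convention, but it is fixed here for reproducibility).
#'
#' @param counts count matrix (rows genes + spikes, columns samples), e.g.
#'   from [read_count_matrix()] or [simulate_experiment()].
#' @param lengths named numeric vector of transcript lengths (bp) covering
#'   every row of `counts`.
#' @return matrix in state `"raw_fpkm"` (attribute `norm_state`), spike
#'   prefix carried over.
#' @export
#' @examples
#' m <- matrix(c(10, 0), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
#' # single row of length 1000 bp with all 10 fragments: depends on totals
compute_fpkm <- function(counts, lengths) {
  miss <- setdiff(rownames(counts), names(lengths))
  if (length(miss)) {
    stopf("no length for row(s): %s", paste(utils::head(miss, 5L), collapse = ", "))
  }
  len <- lengths[rownames(counts)]
  if (any(!is.finite(len) | len <= 0)) {
    bad <- rownames(counts)[!is.finite(len) | len <= 0][1L]
    stopf("non-positive length for row \"%s\"", bad)
  }
  totals <- colSums(counts)
  if (any(totals <= 0)) {
    stopf("zero-depth sample(s): %s",
          paste(colnames(counts)[totals <= 0], collapse = ", "))
  }
  fpkm <- sweep(counts / (len / 1e3), 2L, totals / 1e6, "/")
  attr(fpkm, "spike_prefix") <- attr(counts, "spike_prefix") %||% "ERCC-"
  attr(fpkm, "norm_state") <- "raw_fpkm"
  fpkm
}

#' Per-sample scale factors from spike-in signal
#'
#' Because every sample received the same absolute quantity of spike-in
#' molecules, differences in per-sample spike FPKM reflect the compositional
#' (total mRNA content) differences that library-size scaling would erase.
#' The factor for sample j is `S_ref / S_j`, where `S_j` is the summed spike
#' FPKM of sample j and `S_ref` the anchor's (grand mean by default). The
#' robust variant takes, per sample, the median across spike species of the
#' per-species ratios `ref_s / value_sj`, which resists a misbehaving
#' species.
#'
#' @param fpkm matrix in state `"raw_fpkm"`.
#' @param reference optional spike-in reference table; when supplied, every
#'   spike row of the matrix must resolve in it (unmatched rows are an
#'   error).
#' @param anchor `"mean"` (grand mean over all samples) or a character vector
#'   of sample IDs whose mean spike signal defines the reference.
#' @param method `"sum"` (default: ratio of summed spike FPKM) or
#'   `"median_ratio"` (robust median of per-species ratios).
#' @return named numeric vector of per-sample factors, class
#'   `"scale_factors"`, with attributes `type = "spikein"`, `method` and a
#'   human-readable `reference` description.
#' @export
spikein_scale_factors <- function(fpkm, reference = NULL, anchor = "mean",
                                  method = c("sum", "median_ratio")) {
  method <- match.arg(method)
  check_state(fpkm, "raw_fpkm", "spikein_scale_factors")
  sp <- spike_rows(fpkm)
  if (!any(sp)) stopf("no spike-in rows (prefix \"%s\") found",
                      attr(fpkm, "spike_prefix") %||% "ERCC-")
  if (!is.null(reference)) {
    unmatched <- setdiff(rownames(fpkm)[sp], reference$spike_id)
    if (length(unmatched)) {
      stopf("spike row(s) not in the reference table: %s",
            paste(utils::head(unmatched, 5L), collapse = ", "))
    }
  }
  spk <- fpkm[sp, , drop = FALSE]
  totals <- colSums(spk)
  if (any(totals <= 0)) {
    stopf("zero total spike signal in sample(s): %s (normalization undefined)",
          paste(colnames(fpkm)[totals <= 0], collapse = ", "))
  }
  anchor_samples <- if (identical(anchor, "mean")) colnames(fpkm) else {
    miss <- setdiff(anchor, colnames(fpkm))
    if (length(miss)) stopf("anchor sample(s) not in matrix: %s", paste(miss, collapse = ", "))
    anchor
  }
  if (method == "sum") {
    s_ref <- mean(totals[anchor_samples])
    factors <- s_ref / totals
  } else {
    ref_species <- rowMeans(spk[, anchor_samples, drop = FALSE])
    keep <- ref_species > 0
    factors <- apply(spk[keep, , drop = FALSE], 2L, function(v) {
      ok <- v > 0
      stats::median(ref_species[keep][ok] / v[ok])
    })
  }
  structure(factors, class = "scale_factors", type = "spikein", method = method,
            reference = if (identical(anchor, "mean")) "grand mean of spike totals"
                        else paste("mean spike total of:", paste(anchor, collapse = ", ")))
}

#' Per-sample scale factors from total endogenous signal
#'
#' Library-size scaling: factors equalize each sample's total endogenous
#' FPKM to the anchor's. This is the conventional normalization that a
#' spike-in-free analysis is forced into; it is provided as the contrast arm
#' for demonstrating compositional masking (a genuine global decline in
#' mRNA content is invisible after library-size scaling), not as a default.
#'
#' @inheritParams spikein_scale_factors
#' @return `scale_factors` vector with `type = "library_size"`.
#' @export
library_size_factors <- function(fpkm, anchor = "mean") {
  check_state(fpkm, "raw_fpkm", "library_size_factors")
  sp <- spike_rows(fpkm)
  totals <- colSums(fpkm[!sp, , drop = FALSE])
  if (any(totals <= 0)) {
    stopf("zero total endogenous signal in sample(s): %s",
          paste(colnames(fpkm)[totals <= 0], collapse = ", "))
  }
  anchor_samples <- if (identical(anchor, "mean")) colnames(fpkm) else anchor
  structure(mean(totals[anchor_samples]) / totals, class = "scale_factors",
            type = "library_size", method = "sum",
            reference = "mean endogenous total")
}

#' @export
print.scale_factors <- function(x, ...) {
  cat(sprintf("Scale factors (%s, %s; reference: %s)\n", attr(x, "type"),
              attr(x, "method"), attr(x, "reference")))
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Apply per-sample scale factors
#'
#' Multiplies every value of sample j by `factors[j]`. Spike rows are scaled
#' with the rest (after spike-in factors, per-sample spike totals therefore
#' equal the reference) but remain flagged as calibrators and are excluded
#' from all downstream biological analyses.
#'
#' @param fpkm matrix in state `"raw_fpkm"`.
#' @param factors a `scale_factors` vector covering all samples.
#' @return matrix in state `"ercc_normalized"`, attribute `factor_type`
#'   recording whether spike-in or library-size factors were applied.
#' @export
apply_normalization <- function(fpkm, factors) {
  check_state(fpkm, "raw_fpkm", "apply_normalization")
  miss <- setdiff(colnames(fpkm), names(factors))
  if (length(miss)) stopf("factors missing for sample(s): %s", paste(miss, collapse = ", "))
  if (any(factors <= 0)) stopf("scale factors must be positive")
  out <- sweep(fpkm, 2L, as.numeric(factors[colnames(fpkm)]), "*")
  attr(out, "spike_prefix") <- attr(fpkm, "spike_prefix")
  attr(out, "norm_state") <- "ercc_normalized"
  attr(out, "factor_type") <- attr(factors, "type") %||% "spikein"
  if (identical(attr(factors, "type"), "spikein") &&
      identical(attr(factors, "method"), "sum")) {
    st <- colSums(out[spike_rows(out), , drop = FALSE])
    dev <- max(abs(st - mean(st)) / mean(st))
    if (dev > 1e-9) stopf("spike totals deviate after normalization (%.3g)", dev)
  }
  out
}

#' Anchor batches to a reference condition
#'
#' Samples prepared in different batches are put on a common scale by one
#' multiplicative factor per batch, chosen so that the mean per-sample total
#' endogenous signal of the anchor group (e.g. wild-type GV oocytes) in each
#' batch equals that of the first batch. Acting on sample totals (not
#' per-gene) leaves within-batch fold-change structure untouched.
#'
#' @param mat matrix in state `"ercc_normalized"`.
#' @param sheet sample sheet covering the matrix columns.
#' @param anchor_group `"cohort:stage"` descriptor of the anchor condition.
#' @return matrix in state `"batch_anchored"`.
#' @export
batch_anchor <- function(mat, sheet, anchor_group) {
  check_state(mat, "ercc_normalized", "batch_anchor")
  g <- parse_group(anchor_group)
  batches <- unique(sheet$batch)
  sp <- spike_rows(mat)
  anchor_total <- function(b) {
    ids <- sheet$sample_id[sheet$batch == b & sheet$cohort == g$cohort &
                             sheet$stage == g$stage]
    if (length(ids) == 0L) {
      stopf("batch \"%s\" has no samples of anchor group \"%s\"", b,
            group_label(g$cohort, g$stage))
    }
    mean(colSums(mat[!sp, ids, drop = FALSE]))
  }
  ref <- anchor_total(batches[1L])
  out <- mat
  for (b in batches) {
    f <- ref / anchor_total(b)
    ids <- sheet$sample_id[sheet$batch == b]
    out[, ids] <- out[, ids, drop = FALSE] * f
  }
  attr(out, "norm_state") <- "batch_anchored"
  out
}

#' Per-sample total mRNA level and per-gene group means
#'
#' After spike-in anchoring, per-sample totals of endogenous signal track
#' absolute mRNA content per oocyte pool — the quantity whose decline with
#' age (at GV) and whose failure to decline (at MII, when decay is impaired)
#' the box plots display.
#'
#' @param mat matrix in state `"ercc_normalized"` or `"batch_anchored"`.
#' @param sheet sample sheet.
#' @param universe optional gene IDs to restrict to (default: all endogenous
#'   genes). Must be non-empty.
#' @param groups optional `"cohort:stage"` descriptors (default: every group
#'   present in the sheet).
#' @return list with `per_sample` (named totals) and `group_means`
#'   (genes x groups matrix of per-gene group means, the distribution drawn
#'   in the box plots).
#' @export
total_mrna_level <- function(mat, sheet, universe = NULL, groups = NULL) {
  check_state(mat, c("ercc_normalized", "batch_anchored"), "total_mrna_level")
  sp <- spike_rows(mat)
  genes <- rownames(mat)[!sp]
  if (!is.null(universe)) {
    genes <- intersect(genes, universe)
    if (length(genes) == 0L) stopf("empty universe after intersection with matrix rows")
  }
  if (is.null(groups)) {
    groups <- unique(group_label(sheet$cohort, sheet$stage))
  }
  sub <- mat[genes, , drop = FALSE]
  per_sample <- colSums(sub[, sheet$sample_id, drop = FALSE])
  gm <- vapply(groups, function(g) {
    ids <- require_group(sheet, g)
    rowMeans(sub[, ids, drop = FALSE])
  }, numeric(length(genes)))
  if (is.null(dim(gm))) gm <- matrix(gm, ncol = length(groups),
                                     dimnames = list(genes, groups))
  list(per_sample = per_sample, group_means = gm)
}
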