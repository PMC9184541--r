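#' Synthetic ERCC92-style spike-in reference
#'
#' Builds the packaged synthetic spike-in concentration table: 92 species on a
#' 2-fold concentration ladder spanning roughly six orders of magnitude, split
#' into four subgroups (A--D) whose Mix 1 : Mix 2 concentration ratios are
#' 4, 1, 0.67 and 0.25, mirroring the layout of the standard External RNA
#' Controls Consortium (ERCC) analysis table. Concentrations are attomoles per
#' microlitre; lengths are nucleotides. The table is synthetic: it reproduces
#' the *design* of the ERCC pool (known ladder, fixed per-sample quantity),
#' not the certified concentrations.
#'
#' @param n_spikeins number of spike-in species (default 92).
#' @return A data frame with columns `spike_id`, `subgroup`,
#'   `concentration_mix1`, `concentration_mix2`, `length`.
#' @seealso [read_spikein_reference()] for reading ERCC-style tables from disk.
#' @export
#' @examples
#' ref <- make_spikein_reference()
#' nrow(ref)  # 92
make_spikein_reference <- function(n_spikeins = 92L) {
  if (!is_scalar_number(n_spikeins) || n_spikeins < 1) {
    stopf("n_spikeins must be a positive integer, got %s", deparse(n_spikeins))
  }
  n <- as.integer(n_spikeins)
  subgroups <- c("A", "B", "C", "D")
  mix2_ratio <- c(A = 4, B = 1, C = 0.67, D = 0.25)
  n_levels <- ceiling(n / 4)
  # 2-fold ladder from ~0.02 to ~20000 amol/ul
  ladder <- 2^seq(log2(0.02), log2(20000), length.out = n_levels)
  idx <- seq_len(n)
  level <- ((idx - 1L) %/% 4L) + 1L
  sub <- subgroups[((idx - 1L) %% 4L) + 1L]
  conc1 <- ladder[level]
  # deterministic pseudo-random lengths in 250..2000 nt (golden-ratio hash)
  frac <- (idx * 0.6180339887498949) %% 1
  len <- as.integer(round(250 + frac * 1750))
  data.frame(
    spike_id = sprintf("ERCC-%05d", idx),
    subgroup = sub,
    concentration_mix1 = conc1,
    concentration_mix2 = conc1 * mix2_ratio[sub],
    length = len,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Load the packaged synthetic spike-in reference
#'
#' Reads `ercc92_synthetic.tsv` shipped with the package (see
#' [make_spikein_reference()] for how it was built) and returns it in the
#' validated form produced by [read_spikein_reference()].
#'
#' @param mix which mix concentration to use, `"Mix 1"` or `"Mix 2"`.
#' @return A spike-in reference data frame (`spike_id`, `concentration`,
#'   `length`).
#' @export
load_spikein_reference <- function(mix = "Mix 1") {
  path <- system.file("extdata", "ercc92_synthetic.tsv", package = "oodecay",
                      mustWork = TRUE)
  read_spikein_reference(path, mix = mix)
}
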