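# shared fixtures, built in code at test time

# tiny deterministic count matrix with spike rows
toy_counts <- function(n_genes = 3, n_spikes = 2, n_samples = 2, seed = 11) {
  set.seed(seed)
  ids <- c(sprintf("gene_%d", seq_len(n_genes)),
           sprintf("ERCC-%05d", seq_len(n_spikes)))
  m <- matrix(rpois((n_genes + n_spikes) * n_samples, 50),
              nrow = n_genes + n_spikes,
              dimnames = list(ids, sprintf("s%d", seq_len(n_samples))))
  attr(m, "spike_prefix") <- "ERCC-"
  attr(m, "norm_state") <- "counts"
  m
}

toy_lengths <- function(mat) setNames(rep(1000, nrow(mat)), rownames(mat))

toy_sheet <- function(mat, cohort = "young", stage = "GV") {
  data.frame(sample_id = colnames(mat), stage = stage, cohort = cohort,
             batch = "B1", replicate = seq_len(ncol(mat)),
             stringsAsFactors = FALSE)
}

# small simulated experiment used across tests
small_sim <- function(scenario = "cxxc1_knockout", n_genes = 400, seed = 42, ...) {
  simulate_experiment(default_config(scenario, n_genes = n_genes, seed = seed, ...))
}

# normalize a sim with spike-in anchoring
normalize_sim <- function(sim, anchor_group = NULL, robust = FALSE) {
  fpkm <- compute_fpkm(sim$counts, sim$gene_lengths)
  anchor <- if (is.null(anchor_group)) "mean" else {
    g <- strsplit(anchor_group, ":", fixed = TRUE)[[1]]
    sim$sheet$sample_id[sim$sheet$cohort == g[1] & sim$sheet$stage == g[2]]
  }
  f <- spikein_scale_factors(fpkm, reference = sim$spikes, anchor = anchor,
                             method = if (robust) "median_ratio" else "sum")
  apply_normalization(fpkm, f)
}

truth_m_decay <- function(sim) {
  names(sim$truth$decay_class)[sim$truth$decay_class != "stable"]
}

truth_sensitive <- function(sim) {
  names(sim$truth$decay_class)[sim$truth$decay_class == "m_decay_sensitive"]
}

group_samples_for <- function(sheet, cohort, stage) {
  sheet$sample_id[sheet$cohort == cohort & sheet$stage == stage]
}

write_tsv_lines <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
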