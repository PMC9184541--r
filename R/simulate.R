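#' Simulation presets for the three oocyte study designs
#'
#' Returns a fully populated [sim_config()] for one of three scenarios:
#'
#' * `human_aging`: four maternal-age bands (`lt30`, `a30_35`, `a36_39`,
#'   `ge40`) at both GV and MII stages (8 conditions). Storage of maternal
#'   transcripts at GV declines from the 36--39 band onward and
#'   meiosis-coupled decay is impaired in the two oldest bands. The two
#'   oldest MII groups carry 2 replicates, all others 3.
#' * `mouse_aging`: `young` and `aged` cohorts at GV and MII, plus an
#'   `aged_noPB1` MII-only condition (oocytes that failed to extrude the
#'   first polar body; 2 replicates) with more severely impaired decay.
#' * `cxxc1_knockout`: `WT` and `cxxc1_null` cohorts at GV and MII
#'   (4 conditions, 3 replicates each); the knockout loses both GV storage
#'   and decay competence.
#'
#' @param scenario one of `"human_aging"`, `"mouse_aging"`,
#'   `"cxxc1_knockout"`.
#' @param ... overrides passed on to [sim_config()] (e.g. `n_genes`, `seed`).
#' @return a `sim_config` object.
#' @export
#' @examples
#' cfg <- default_config("cxxc1_knockout", n_genes = 500, seed = 1)
#' nrow(cfg$conditions)  # 4
default_config <- function(scenario, ...) {
  valid <- c("human_aging", "mouse_aging", "cxxc1_knockout")
  if (!is.character(scenario) || length(scenario) != 1L || !scenario %in% valid) {
    stopf("unknown scenario %s; valid scenarios: %s", deparse(scenario),
          paste(valid, collapse = ", "))
  }
  cond <- function(cohort, stage, storage_factor, decay_impaired, replicates) {
    data.frame(cohort = cohort, stage = stage, storage_factor = storage_factor,
               decay_impaired = decay_impaired, replicates = replicates,
               stringsAsFactors = FALSE)
  }
  conditions <- switch(
    scenario,
    human_aging = rbind(
      cond("lt30",   "GV",  1.00, FALSE, 3),
      cond("a30_35", "GV",  1.00, FALSE, 3),
      cond("a36_39", "GV",  0.85, TRUE,  3),
      cond("ge40",   "GV",  0.75, TRUE,  3),
      cond("lt30",   "MII", 1.00, FALSE, 3),
      cond("a30_35", "MII", 1.00, FALSE, 2),
      cond("a36_39", "MII", 0.85, TRUE,  3),
      cond("ge40",   "MII", 0.75, TRUE,  2)
    ),
    mouse_aging = rbind(
      cond("young",      "GV",  1.00, FALSE, 3),
      cond("aged",       "GV",  0.90, TRUE,  3),
      cond("young",      "MII", 1.00, FALSE, 3),
      cond("aged",       "MII", 0.90, TRUE,  3),
      cond("aged_noPB1", "MII", 0.90, TRUE,  2)
    ),
    cxxc1_knockout = rbind(
      cond("WT",         "GV",  1.00, FALSE, 3),
      cond("cxxc1_null", "GV",  0.85, TRUE,  3),
      cond("WT",         "MII", 1.00, FALSE, 3),
      cond("cxxc1_null", "MII", 0.85, TRUE,  3)
    )
  )
  # scenario-specific sensitive fractions mirror the reported partitions
  # (human ~0.91, knockout ~0.74); explicit overrides in ... win
  preset_args <- switch(scenario,
    human_aging = list(frac_age_sensitive = 0.91),
    mouse_aging = list(frac_age_sensitive = 0.55),
    cxxc1_knockout = list(frac_age_sensitive = 0.74))
  args <- utils::modifyList(c(list(scenario = scenario, conditions = conditions),
                              preset_args), list(...))
  do.call(sim_config, args)
}

#' Construct a simulation configuration
#'
#' The generative model: per gene, germinal-vesicle (GV) copies in the
#' reference cohort are log-normal; cohorts with a storage factor `s < 1`
#' multiply GV copies by `s` times a per-gene log-normal jitter (sd 0.25,
#' mean-preserving), so aged storage loss is heterogeneous rather than a
#' uniform rescale. MII copies are GV copies times a retained fraction set by
#' the gene's decay class: `retain_decay` for M-decay genes in
#' decay-competent cohorts, `retain_failed` for sensitive M-decay genes in
#' decay-impaired cohorts, `retain_stable` for stable genes. Because fully
#' grown oocytes are transcriptionally silent, MII copies never exceed GV
#' copies. Spike-ins receive identical absolute copies in every sample (the
#' property that makes spike-in anchoring valid). Each sample draws
#' `fragments_per_sample` fragments (+/- 10%) allocated proportionally to
#' copies x length, with negative-binomial noise (variance
#' `mu + nb_dispersion * mu^2`); `nb_dispersion = 0` yields the exact
#' expected allocation (noiseless limit).
#'
#' @param scenario label recorded in the config.
#' @param conditions data frame with columns `cohort`, `stage`,
#'   `storage_factor`, `decay_impaired`, `replicates`.
#' @param n_genes number of endogenous genes.
#' @param n_spikeins number of spike-in species (default 92).
#' @param replicates_per_condition default replicate count where
#'   `conditions$replicates` is absent.
#' @param baseline_copy_log_mean,baseline_copy_log_sd log-scale location and
#'   spread of per-gene GV copies (per pool of 10 oocytes) in the reference
#'   cohort.
#' @param frac_m_decay fraction of genes that are true M-decay.
#' @param retain_decay retained fraction at MII for decayed genes.
#' @param retain_stable retained fraction at MII for stable genes.
#' @param frac_age_sensitive fraction of M-decay genes whose decay fails in
#'   impaired cohorts.
#' @param retain_failed retained fraction for failed-decay genes at MII in
#'   impaired cohorts.
#' @param aged_storage_factor canonical GV copy decline of an aged/mutant
#'   cohort, kept for custom condition tables (presets carry explicit
#'   per-cohort factors).
#' @param spike_copies_per_sample total spike molecules added per sample
#'   (constant across samples).
#' @param fragments_per_sample mean sequencing depth per sample.
#' @param nb_dispersion count overdispersion phi (variance `mu + phi mu^2`).
#' @param gene_length_range length-2 integer vector, transcript length range
#'   in bp.
#' @param storage_jitter_sd log-scale sd of the per-gene aging jitter.
#' @param spikein_reference spike-in reference table (default: packaged
#'   synthetic ERCC92-style table, Mix 1).
#' @param seed integer seed; all randomness flows from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(scenario = "custom",
                       conditions,
                       n_genes = 2000L,
                       n_spikeins = 92L,
                       replicates_per_condition = 3L,
                       baseline_copy_log_mean = log(500),
                       baseline_copy_log_sd = 1.5,
                       frac_m_decay = 0.35,
                       retain_decay = 0.05,
                       retain_stable = 0.9,
                       frac_age_sensitive = 0.55,
                       retain_failed = 0.8,
                       aged_storage_factor = 0.6,
                       spike_copies_per_sample = 2.5e5,
                       fragments_per_sample = 2e6,
                       nb_dispersion = 0.1,
                       gene_length_range = c(500L, 5000L),
                       storage_jitter_sd = 0.25,
                       spikein_reference = NULL,
                       seed = 1L) {
  if (!is_scalar_number(n_genes) || n_genes < 1) stopf("n_genes must be a positive integer")
  if (!is_scalar_number(fragments_per_sample) || fragments_per_sample <= 0) {
    stopf("fragments_per_sample must be positive")
  }
  if (!is_scalar_number(nb_dispersion) || nb_dispersion < 0) {
    stopf("nb_dispersion must be >= 0, got %s", deparse(nb_dispersion))
  }
  fracs <- c(frac_m_decay = frac_m_decay, retain_decay = retain_decay,
             retain_stable = retain_stable, frac_age_sensitive = frac_age_sensitive,
             retain_failed = retain_failed)
  bad <- fracs[fracs < 0 | fracs > 1]
  if (length(bad)) stopf("fraction(s) outside [0,1]: %s", paste(names(bad), collapse = ", "))
  if (retain_decay >= retain_stable) stopf("retain_decay must be < retain_stable")
  if (retain_decay >= retain_failed) stopf("retain_decay must be < retain_failed")
  need <- c("cohort", "stage", "storage_factor", "decay_impaired")
  miss <- setdiff(need, colnames(conditions))
  if (length(miss)) stopf("conditions is missing column(s): %s", paste(miss, collapse = ", "))
  if (is.null(conditions$replicates)) conditions$replicates <- replicates_per_condition
  bad_stage <- setdiff(unique(conditions$stage), c("GV", "MII"))
  if (length(bad_stage)) stopf("unknown stage(s) in conditions: %s", paste(bad_stage, collapse = ", "))
  if (is.null(spikein_reference)) spikein_reference <- make_spikein_reference(n_spikeins)
  structure(list(
    scenario = scenario,
    conditions = conditions,
    n_genes = as.integer(n_genes),
    n_spikeins = as.integer(n_spikeins),
    baseline_copy_log_mean = baseline_copy_log_mean,
    baseline_copy_log_sd = baseline_copy_log_sd,
    frac_m_decay = frac_m_decay,
    retain_decay = retain_decay,
    retain_stable = retain_stable,
    frac_age_sensitive = frac_age_sensitive,
    retain_failed = retain_failed,
    aged_storage_factor = aged_storage_factor,
    spike_copies_per_sample = spike_copies_per_sample,
    fragments_per_sample = fragments_per_sample,
    nb_dispersion = nb_dispersion,
    gene_length_range = as.integer(gene_length_range),
    storage_jitter_sd = storage_jitter_sd,
    spikein_reference = spikein_reference,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Simulation config (scenario \"%s\")\n", x$scenario))
  cat(sprintf("  %d genes + %d spike-ins; %d conditions, %d samples\n",
              x$n_genes, x$n_spikeins, nrow(x$conditions), sum(x$conditions$replicates)))
  cat(sprintf("  M-decay fraction %.2f (sensitive fraction %.2f); retain decay/stable/failed = %.2f/%.2f/%.2f\n",
              x$frac_m_decay, x$frac_age_sensitive, x$retain_decay, x$retain_stable, x$retain_failed))
  cat(sprintf("  depth ~%g fragments/sample, dispersion %g, seed %d\n",
              x$fragments_per_sample, x$nb_dispersion, x$seed))
  invisible(x)
}

#' Simulate a spike-in-bearing oocyte RNA-seq experiment
#'
#' Draws an experiment from the generative model described in
#' [sim_config()] and returns the count matrix together with complete ground
#' truth, so downstream normalization and degradome calls can be scored
#' against known absolute copies and decay classes.
#'
#' A single global seed drives gene-level draws; each sample's count noise
#' uses a deterministic per-sample substream, so identical seeds give
#' bit-identical output.
#'
#' @param config a `sim_config` object.
#' @return A list of class `sim_experiment`:
#' \describe{
#'   \item{counts}{(genes+spikes) x samples matrix; spike rows have the
#'     `ERCC-` prefix. Integer unless `nb_dispersion = 0` (exact expected
#'     allocation).}
#'   \item{sheet}{sample sheet (`sample_id`, `stage`, `cohort`, `batch`,
#'     `replicate`).}
#'   \item{spikes}{spike-in reference table used.}
#'   \item{gene_lengths}{named length vector covering every row.}
#'   \item{truth}{`sim_truth` list: per-gene `decay_class`
#'     (`m_decay_sensitive`, `m_decay_insensitive`, `stable`), absolute
#'     `copies` per cohort:stage, `spike_copies`, per-sample `depths`.}
#' }
#' @export
#' @examples
#' sim <- simulate_experiment(default_config("cxxc1_knockout", n_genes = 200, seed = 7))
#' dim(sim$counts)
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_genes
  genes <- sprintf("gene_%05d", seq_len(n))

  # decay classes at configured fractions (integer rounding)
  n_md <- round(cfg$frac_m_decay * n)
  n_sens <- round(cfg$frac_age_sensitive * n_md)
  classes <- rep("stable", n)
  md_idx <- sample.int(n, n_md)
  classes[md_idx] <- "m_decay_insensitive"
  classes[sample(md_idx, n_sens)] <- "m_decay_sensitive"

  lengths <- sample(seq(cfg$gene_length_range[1L], cfg$gene_length_range[2L]), n,
                    replace = TRUE)
  base_gv <- stats::rlnorm(n, cfg$baseline_copy_log_mean, cfg$baseline_copy_log_sd)

  cohorts <- unique(cfg$conditions[, c("cohort", "storage_factor", "decay_impaired")])
  copies <- matrix(NA_real_, n, 2L * nrow(cohorts))
  cn <- character(2L * nrow(cohorts))
  k <- 0L
  for (i in seq_len(nrow(cohorts))) {
    sf <- cohorts$storage_factor[i]
    jit <- if (sf != 1) {
      stats::rlnorm(n, -cfg$storage_jitter_sd^2 / 2, cfg$storage_jitter_sd)
    } else rep(1, n)
    gv <- base_gv * sf * jit
    retain <- ifelse(classes == "stable", cfg$retain_stable,
              ifelse(classes == "m_decay_sensitive" & cohorts$decay_impaired[i],
                     cfg$retain_failed, cfg$retain_decay))
    mii <- gv * retain
    copies[, k + 1L] <- gv
    copies[, k + 2L] <- mii
    cn[k + 1L] <- group_label(cohorts$cohort[i], "GV")
    cn[k + 2L] <- group_label(cohorts$cohort[i], "MII")
    k <- k + 2L
  }
  dimnames(copies) <- list(genes, cn)

  ref <- cfg$spikein_reference[seq_len(min(cfg$n_spikeins, nrow(cfg$spikein_reference))), ]
  conc <- if ("concentration" %in% names(ref)) ref$concentration else ref$concentration_mix1
  spike_copies <- conc / sum(conc) * cfg$spike_copies_per_sample
  names(spike_copies) <- ref$spike_id
  spike_len <- if (!is.null(ref$length)) ref$length else rep(1000, nrow(ref))
  names(spike_len) <- ref$spike_id

  # sample sheet: one batch, rows ordered as in the conditions table
  sheet <- do.call(rbind, lapply(seq_len(nrow(cfg$conditions)), function(i) {
    cd <- cfg$conditions[i, ]
    data.frame(
      sample_id = sprintf("%s_%s_r%d", cd$cohort, cd$stage, seq_len(cd$replicates)),
      stage = cd$stage, cohort = cd$cohort, batch = "B1",
      replicate = seq_len(cd$replicates), stringsAsFactors = FALSE
    )
  }))
  rownames(sheet) <- NULL
  n_samples <- nrow(sheet)
  depths <- round(cfg$fragments_per_sample * stats::runif(n_samples, 0.9, 1.1))

  all_len <- c(stats::setNames(lengths, genes), spike_len)
  counts <- matrix(0, n + length(spike_copies), n_samples,
                   dimnames = list(c(genes, names(spike_copies)), sheet$sample_id))
  for (j in seq_len(n_samples)) {
    cond <- group_label(sheet$cohort[j], sheet$stage[j])
    row_copies <- c(copies[, cond], spike_copies)
    w <- row_copies * all_len
    mu <- depths[j] * w / sum(w)
    if (cfg$nb_dispersion == 0) {
      counts[, j] <- mu
    } else {
      set.seed(cfg$seed + 7919L * j)
      counts[, j] <- stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion)
    }
  }
  attr(counts, "spike_prefix") <- "ERCC-"
  attr(counts, "norm_state") <- "counts"

  truth <- structure(list(
    decay_class = stats::setNames(classes, genes),
    copies = copies,
    spike_copies = spike_copies,
    depths = stats::setNames(depths, sheet$sample_id),
    conditions = cfg$conditions
  ), class = "sim_truth")

  structure(list(counts = counts, sheet = sheet, spikes = ref,
                 gene_lengths = all_len, truth = truth, config = cfg),
            class = "sim_experiment")
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat(sprintf("Simulated oocyte experiment (scenario \"%s\")\n", x$config$scenario))
  cat(sprintf("  counts: %d rows (%d genes + %d spike-ins) x %d samples\n",
              nrow(x$counts), x$config$n_genes, nrow(x$spikes), ncol(x$counts)))
  tab <- table(x$truth$decay_class)
  cat("  truth decay classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Write a simulated experiment to disk
#'
#' Emits the standard file set consumed by the pipeline: `counts.tsv`,
#' `sample_sheet.tsv`, `spikein_reference.tsv`, `gene_lengths.tsv` and
#' `truth.tsv` (per-gene decay class plus absolute copies per cohort:stage).
#'
#' @param sim a `sim_experiment`.
#' @param outdir output directory (created if needed).
#' @return the output directory, invisibly.
#' @export
write_experiment <- function(sim, outdir) {
  stopifnot(inherits(sim, "sim_experiment"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_matrix(round(sim$counts), file.path(outdir, "counts.tsv"))
  write_sample_sheet(sim$sheet, file.path(outdir, "sample_sheet.tsv"))
  utils::write.table(sim$spikes, file.path(outdir, "spikein_reference.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene_id = names(sim$gene_lengths), length = sim$gene_lengths),
    file.path(outdir, "gene_lengths.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  truth_df <- data.frame(gene_id = names(sim$truth$decay_class),
                         decay_class = sim$truth$decay_class,
                         sim$truth$copies, check.names = FALSE,
                         stringsAsFactors = FALSE)
  utils::write.table(truth_df, file.path(outdir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(outdir)
}
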