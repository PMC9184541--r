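#' Build a pipeline run configuration
#'
#' Either simulation mode (`scenario` + `seed`) or file mode (paths to
#' counts, sheet, lengths, spike reference). Thresholds default to the
#' analysis settings used throughout: FC[GV/MII] > 5 for M-decay, GV group
#' mean > 1 as the M-decay universe, value > 1 in any sample as the
#' expressed universe, pseudocount 0.01.
#'
#' @param scenario simulation scenario (see [default_config()]); `NULL` for
#'   file mode.
#' @param seed integer seed (simulation mode).
#' @param counts,sheet,lengths,spikes file paths (file mode).
#' @param anchor_group `"cohort:stage"` anchor for batch anchoring and the
#'   reference description of the spike factors.
#' @param comparisons list of comparisons; each a list with `name`,
#'   `ref_gv`, `ref_mii`, `test_gv`, `test_mii` group descriptors. `NULL`
#'   uses the scenario's canonical comparison.
#' @param fc_threshold,gv_filter,expression_threshold,pseudocount analysis
#'   thresholds.
#' @param robust use the median-of-ratios spike factor variant.
#' @param gene_sets optional path to a GMT file for enrichment.
#' @param sim_overrides named list passed to [default_config()]
#'   (e.g. `n_genes`).
#' @return list of class `run_config`.
#' @export
run_config <- function(scenario = NULL, seed = 1L,
                       counts = NULL, sheet = NULL, lengths = NULL, spikes = NULL,
                       anchor_group = NULL, comparisons = NULL,
                       fc_threshold = 5, gv_filter = 1,
                       expression_threshold = 1, pseudocount = 0.01,
                       robust = FALSE, gene_sets = NULL,
                       sim_overrides = list()) {
  if (any(c(fc_threshold, gv_filter, expression_threshold) <= 0)) {
    stopf("thresholds must be positive")
  }
  if (fc_threshold <= 1) stopf("fc_threshold must be > 1")
  if (is.null(scenario) && is.null(counts)) {
    stopf("either a simulation scenario or input file paths must be given")
  }
  defaults <- if (!is.null(scenario)) scenario_defaults(scenario)
  structure(list(
    scenario = scenario, seed = as.integer(seed),
    counts = counts, sheet = sheet, lengths = lengths, spikes = spikes,
    anchor_group = anchor_group %||% defaults$anchor_group,
    comparisons = comparisons %||% defaults$comparisons,
    fc_threshold = fc_threshold, gv_filter = gv_filter,
    expression_threshold = expression_threshold, pseudocount = pseudocount,
    robust = robust, gene_sets = gene_sets, sim_overrides = sim_overrides
  ), class = "run_config")
}

# canonical anchor and reference-vs-test comparison per scenario
scenario_defaults <- function(scenario) {
  switch(scenario,
    human_aging = list(
      anchor_group = "lt30:GV",
      comparisons = list(list(name = "lt30_vs_ge40",
                              ref_gv = "lt30:GV", ref_mii = "lt30:MII",
                              test_gv = "ge40:GV", test_mii = "ge40:MII"))),
    mouse_aging = list(
      anchor_group = "young:GV",
      comparisons = list(list(name = "young_vs_aged",
                              ref_gv = "young:GV", ref_mii = "young:MII",
                              test_gv = "aged:GV", test_mii = "aged:MII"))),
    cxxc1_knockout = list(
      anchor_group = "WT:GV",
      comparisons = list(list(name = "WT_vs_cxxc1_null",
                              ref_gv = "WT:GV", ref_mii = "WT:MII",
                              test_gv = "cxxc1_null:GV", test_mii = "cxxc1_null:MII"))),
    stopf("unknown scenario \"%s\"", scenario)
  )
}

#' Run the full degradome pipeline
#'
#' simulate/read -> FPKM -> spike-in anchoring -> batch anchoring (when the
#' sheet has > 1 batch) -> per-comparison M-decay calling, sensitivity
#' partition, direction classes, degradation patterns -> replicate QC ->
#' optional gene-set enrichment. All thresholds come from the config; all
#' randomness flows from its seed, so identical config + seed gives
#' identical artifacts.
#'
#' When `outdir` is given, writes `normalized_matrix.tsv`,
#' `scale_factors.tsv`, `totals.tsv`, `qc_correlations.tsv`, per-comparison
#' `calls_<name>.tsv`, `regions_<name>.json`, `pattern_<name>.tsv`, optional
#' `enrichment_<name>.tsv`, and `manifest.json` (config, thresholds actually
#' applied, config hash, seed, package version — no timestamps, so reruns
#' are byte-identical). Any stage error aborts with the stage name and
#' removes partially written outputs.
#'
#' @param config a `run_config`.
#' @param outdir optional output directory.
#' @return list of class `degradome_run` with the normalized matrix, scale
#'   factors, per-comparison results (`calls`, `partition`, `regions`,
#'   `patterns`), QC correlations, per-sample totals, truth (simulation
#'   mode) and the manifest.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("stage \"%s\" failed: %s", name, conditionMessage(e))
    })
  }

  inputs <- stage("inputs", {
    if (!is.null(config$scenario)) {
      cfg <- do.call(default_config,
                     c(list(scenario = config$scenario, seed = config$seed),
                       config$sim_overrides))
      simulate_experiment(cfg)
    } else {
      counts <- read_count_matrix(config$counts)
      sheet <- read_sample_sheet(config$sheet)
      lt <- utils::read.delim(config$lengths, stringsAsFactors = FALSE)
      list(counts = counts, sheet = sheet,
           gene_lengths = stats::setNames(lt$length, lt$gene_id),
           spikes = if (!is.null(config$spikes)) read_spikein_reference(config$spikes),
           truth = NULL)
    }
  })
  sheet <- inputs$sheet

  stage("validate", {
    miss <- setdiff(colnames(inputs$counts), sheet$sample_id)
    if (length(miss)) stopf("samples missing from sheet: %s", paste(miss, collapse = ", "))
    require_group(sheet, config$anchor_group, "anchor group")
    for (cmp in config$comparisons) {
      for (g in c(cmp$ref_gv, cmp$ref_mii, cmp$test_gv, cmp$test_mii)) {
        require_group(sheet, g, "comparison group")
      }
    }
  })

  norm <- stage("normalize", {
    fpkm <- compute_fpkm(inputs$counts, inputs$gene_lengths)
    anchor_ids <- group_samples(sheet, config$anchor_group)
    factors <- spikein_scale_factors(
      fpkm, reference = inputs$spikes, anchor = anchor_ids,
      method = if (config$robust) "median_ratio" else "sum")
    mat <- apply_normalization(fpkm, factors)
    if (length(unique(sheet$batch)) > 1L) {
      mat <- batch_anchor(mat, sheet, config$anchor_group)
    }
    list(mat = mat, factors = factors)
  })
  mat <- norm$mat

  expressed <- stage("filter", {
    filter_expressed(mat, config$expression_threshold, "any_sample")
  })

  comparisons <- stage("degradome", {
    lapply(config$comparisons, function(cmp) {
      ref_set <- call_m_decay(mat, sheet, cmp$ref_gv, cmp$ref_mii,
                              config$fc_threshold, config$gv_filter,
                              config$pseudocount)
      test_set <- call_m_decay(mat, sheet, cmp$test_gv, cmp$test_mii,
                               config$fc_threshold, config$gv_filter,
                               config$pseudocount)
      part <- partition_sensitivity(ref_set, test_set)
      regions <- venn_regions(stats::setNames(list(ref_set, test_set),
                                              c("reference", "test")))
      gv_ref <- group_mean(mat, sheet, cmp$ref_gv)
      mii_ref <- group_mean(mat, sheet, cmp$ref_mii)
      fc_ref <- fold_change(gv_ref, mii_ref, config$pseudocount, "GV/MII")
      dir_mii <- classify_direction(
        fold_change(group_mean(mat, sheet, cmp$test_mii), mii_ref,
                    config$pseudocount, "testMII/refMII"))
      sens_label <- rep("not_m_decay", length(gv_ref))
      names(sens_label) <- names(gv_ref)
      sens_label[part$sensitive] <- "sensitive"
      sens_label[part$insensitive] <- "insensitive"
      sens_label[part$test_only] <- "test_only"
      calls <- data.frame(
        gene_id = names(gv_ref),
        gv_mean_ref = unname(gv_ref),
        mii_mean_ref = unname(mii_ref),
        fc_gv_mii_ref = unname(fc_ref),
        dir_2x_mii = dir_mii$dir_2x,
        dir_5x_mii = dir_mii$dir_5x,
        m_decay_ref = names(gv_ref) %in% ref_set,
        m_decay_test = names(gv_ref) %in% test_set,
        sensitivity = unname(sens_label),
        stringsAsFactors = FALSE
      )
      class(calls) <- c("degradome_calls", "data.frame")
      patterns <- list()
      for (set_name in c("sensitive", "insensitive")) {
        genes <- part[[set_name]]
        if (length(genes) >= 1L) {
          patterns[[set_name]] <- degradation_pattern(
            mat, sheet, genes,
            c(cmp$ref_gv, cmp$ref_mii, cmp$test_gv, cmp$test_mii),
            config$pseudocount)
        }
      }
      list(name = cmp$name, groups = cmp, m_decay_ref = ref_set,
           m_decay_test = test_set, partition = part, regions = regions,
           calls = calls, patterns = patterns)
    })
  })

  qc <- stage("qc", pairwise_spearman(mat, sheet, universe = expressed))
  totals <- stage("totals", total_mrna_level(mat, sheet))

  enrichment <- NULL
  if (!is.null(config$gene_sets)) {
    enrichment <- stage("enrich", {
      sets <- read_gene_sets(config$gene_sets)
      lapply(comparisons, function(cmp) {
        sel <- intersect(cmp$partition$sensitive, expressed)
        hypergeom_enrichment(sel, expressed, sets)
      })
    })
  }

  manifest <- stage("manifest", {
    cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                                 null = "null")
    tmp <- tempfile(); on.exit(unlink(tmp), add = TRUE)
    writeLines(as.character(cfg_json), tmp)
    list(
      package = "oodecay",
      version = as.character(utils::packageVersion("oodecay")),
      seed = config$seed,
      config = unclass(config),
      config_hash = unname(tools::md5sum(tmp)),
      thresholds = list(fc_threshold = config$fc_threshold,
                        gv_filter = config$gv_filter,
                        expression_threshold = config$expression_threshold,
                        pseudocount = config$pseudocount),
      n_samples = ncol(inputs$counts),
      n_genes = sum(!spike_rows(inputs$counts)),
      n_expressed = length(expressed),
      comparisons = lapply(comparisons, function(cmp) {
        list(name = cmp$name,
             m_decay_reference = length(cmp$m_decay_ref),
             m_decay_test = length(cmp$m_decay_test),
             sensitive = length(cmp$partition$sensitive),
             insensitive = length(cmp$partition$insensitive),
             test_only = length(cmp$partition$test_only))
      })
    )
  })

  run <- structure(list(
    config = config, matrix = mat, factors = norm$factors,
    expressed = expressed, comparisons = comparisons, qc = qc,
    totals = totals, enrichment = enrichment, truth = inputs$truth,
    sheet = sheet, manifest = manifest
  ), class = "degradome_run")

  if (!is.null(outdir)) {
    written <- character()
    tryCatch({
      dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
      emit <- function(path) { written <<- c(written, path); path }
      write_matrix(mat, emit(file.path(outdir, "normalized_matrix.tsv")))
      utils::write.table(
        data.frame(sample_id = names(norm$factors),
                   factor = as.numeric(norm$factors)),
        emit(file.path(outdir, "scale_factors.tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(
        data.frame(sample_id = names(totals$per_sample),
                   total = as.numeric(totals$per_sample)),
        emit(file.path(outdir, "totals.tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(
        data.frame(metric = c("min", "mean"),
                   spearman = c(qc$min, qc$mean)),
        emit(file.path(outdir, "qc_correlations.tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      for (cmp in comparisons) {
        write_calls(cmp$calls,
                    emit(file.path(outdir, sprintf("calls_%s.tsv", cmp$name))))
        jsonlite::write_json(as.list(cmp$regions),
                             emit(file.path(outdir, sprintf("regions_%s.json", cmp$name))),
                             auto_unbox = TRUE)
        if (length(cmp$patterns)) {
          pat <- do.call(rbind, lapply(names(cmp$patterns), function(s) {
            data.frame(set = s, group = cmp$patterns[[s]]$groups,
                       median_log2 = as.numeric(cmp$patterns[[s]]$median),
                       stringsAsFactors = FALSE)
          }))
          utils::write.table(pat,
                             emit(file.path(outdir, sprintf("pattern_%s.tsv", cmp$name))),
                             sep = "\t", quote = FALSE, row.names = FALSE)
        }
      }
      if (!is.null(enrichment)) {
        for (i in seq_along(enrichment)) {
          utils::write.table(as.data.frame(enrichment[[i]]),
                             emit(file.path(outdir, sprintf("enrichment_%s.tsv",
                                                            comparisons[[i]]$name))),
                             sep = "\t", quote = FALSE, row.names = FALSE)
        }
      }
      jsonlite::write_json(manifest, emit(file.path(outdir, "manifest.json")),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }, error = function(e) {
      unlink(written)
      stopf("stage \"write\" failed: %s", conditionMessage(e))
    })
  }
  run
}

#' @export
print.degradome_run <- function(x, ...) {
  cat(sprintf("Degradome pipeline run (%s, seed %d)\n",
              x$config$scenario %||% "file inputs", x$config$seed))
  cat(sprintf("  %d genes (%d expressed), %d samples\n",
              x$manifest$n_genes, x$manifest$n_expressed, x$manifest$n_samples))
  for (cmp in x$comparisons) {
    cat(sprintf("  %s: %d M-decay (ref), %d sensitive + %d insensitive\n",
                cmp$name, length(cmp$m_decay_ref),
                length(cmp$partition$sensitive), length(cmp$partition$insensitive)))
  }
  invisible(x)
}

#' @export
summary.degradome_run <- function(object, ...) {
  cat(report(object))
  invisible(object)
}

#' Human-readable run report
#'
#' Markdown summary of a completed run: M-decay set sizes, the
#' sensitive/insensitive split, up/down counts at each threshold, and the
#' replicate-correlation QC.
#'
#' @param run a `degradome_run`.
#' @return character scalar (markdown).
#' @export
report <- function(run) {
  if (!inherits(run, "degradome_run")) stopf("report() needs a degradome_run")
  lines <- c(
    sprintf("# Degradome run report (%s)", run$config$scenario %||% "file inputs"),
    "",
    sprintf("- genes: %d (%d expressed at > %g in any sample)",
            run$manifest$n_genes, run$manifest$n_expressed,
            run$config$expression_threshold),
    sprintf("- samples: %d; replicate Spearman min %.3f, mean %.3f",
            run$manifest$n_samples, run$qc$min, run$qc$mean),
    sprintf("- thresholds: FC[GV/MII] > %g, GV mean > %g, pseudocount %g",
            run$config$fc_threshold, run$config$gv_filter, run$config$pseudocount),
    "")
  for (cmp in run$comparisons) {
    up2 <- sum(cmp$calls$dir_2x_mii == "up")
    dn2 <- sum(cmp$calls$dir_2x_mii == "down")
    up5 <- sum(cmp$calls$dir_5x_mii == "up")
    dn5 <- sum(cmp$calls$dir_5x_mii == "down")
    lines <- c(lines,
      sprintf("## Comparison %s", cmp$name),
      sprintf("- M-decay (reference): %d; M-decay (test): %d",
              length(cmp$m_decay_ref), length(cmp$m_decay_test)),
      sprintf("- partition: %d sensitive + %d insensitive = %d",
              length(cmp$partition$sensitive), length(cmp$partition$insensitive),
              length(cmp$partition$sensitive) + length(cmp$partition$insensitive)),
      sprintf("- test MII vs reference MII: %d up / %d down at 2x; %d up / %d down at 5x",
              up2, dn2, up5, dn5),
      "")
  }
  paste(lines, collapse = "\n")
}
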