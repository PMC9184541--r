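#' Read a gene x sample fragment-count matrix
#'
#' Reads a tab-delimited count matrix (header row of sample IDs, first column
#' row IDs, `#` comment lines ignored) and validates it strictly: unique row
#' and column identifiers, non-negative integer values, rectangular layout.
#' Rows whose identifier starts with `spike_prefix` are flagged as spike-in
#' calibrators.
#'
#' @param path path to the TSV file.
#' @param spike_prefix row-identifier prefix marking spike-in rows
#'   (default `"ERCC-"`).
#' @return A numeric matrix (genes as rows, samples as columns) with
#'   attributes `spike_prefix` and `norm_state = "counts"`.
#' @export
read_count_matrix <- function(path, spike_prefix = "ERCC-") {
  fields <- utils::count.fields(path, sep = "\t", comment.char = "#",
                                quote = "")
  fields <- fields[!is.na(fields)]
  if (length(unique(fields)) > 1L) {
    bad <- which(fields != fields[1L])[1L]
    stopf("ragged rows in %s: line %d has %d fields, expected %d",
          path, bad, fields[bad], fields[1L])
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", quote = "")
  if (ncol(df) < 2L) stopf("count matrix %s needs a row-ID column plus >= 1 sample", path)
  ids <- df[[1L]]
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stopf("duplicate row identifier(s) in %s: %s", path,
          paste(dup, collapse = ", "))
  }
  samples <- colnames(df)[-1L]
  if (anyDuplicated(samples)) {
    dup <- unique(samples[duplicated(samples)])
    stopf("duplicate sample identifier(s) in %s: %s", path,
          paste(dup, collapse = ", "))
  }
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stopf("non-numeric count in %s at row \"%s\", sample \"%s\": \"%s\"",
          path, ids[bad[1L]], samples[bad[2L]], vals[bad[1L], bad[2L]])
  }
  if (any(num < 0)) {
    bad <- which(num < 0, arr.ind = TRUE)[1L, ]
    stopf("negative count in %s at row \"%s\", sample \"%s\": %s",
          path, ids[bad[1L]], samples[bad[2L]], num[bad[1L], bad[2L]])
  }
  if (any(num != round(num))) {
    bad <- which(num != round(num), arr.ind = TRUE)[1L, ]
    stopf("non-integer count in %s at row \"%s\", sample \"%s\": %s",
          path, ids[bad[1L]], samples[bad[2L]], num[bad[1L], bad[2L]])
  }
  m <- num
  dimnames(m) <- list(ids, samples)
  attr(m, "spike_prefix") <- spike_prefix
  attr(m, "norm_state") <- "counts"
  m
}

#' Read an ERCC-style spike-in concentration reference
#'
#' Accepts both the packaged synthetic layout (`concentration_mix1`, ...) and
#' the standard ERCC analysis-table headers ("concentration in Mix 1
#' (attomoles/ul)"). The mix is selected by name.
#'
#' @param path path to the TSV file.
#' @param mix `"Mix 1"` or `"Mix 2"` (case-insensitive; `"mix1"` also works).
#' @return data frame with columns `spike_id`, `concentration` and, when the
#'   file carries one, `length`.
#' @export
read_spikein_reference <- function(path, mix = "Mix 1") {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  cols <- colnames(df)
  mix_cols <- grep("mix[ _]?[0-9]", cols, ignore.case = TRUE, value = TRUE)
  if (length(mix_cols) == 0L) {
    stopf("no mix concentration column found in %s; columns: %s",
          path, paste(cols, collapse = ", "))
  }
  want <- gsub("[^0-9]", "", mix)
  if (!nzchar(want)) stopf("mix must name a mix number, e.g. \"Mix 1\"; got \"%s\"", mix)
  hit <- mix_cols[gsub(".*mix[ _]?([0-9]+).*", "\\1", tolower(mix_cols)) == want]
  if (length(hit) == 0L) {
    avail <- sort(unique(paste("Mix", gsub(".*mix[ _]?([0-9]+).*", "\\1",
                                           tolower(mix_cols)))))
    stopf("\"%s\" not available in %s; available: %s", mix, path,
          paste(avail, collapse = ", "))
  }
  id_col <- cols[grep("id$|^ERCC", cols, ignore.case = TRUE)][1L]
  if (is.na(id_col)) id_col <- cols[1L]
  out <- data.frame(
    spike_id = as.character(df[[id_col]]),
    concentration = as.numeric(df[[hit[1L]]]),
    stringsAsFactors = FALSE
  )
  len_col <- cols[grep("length", cols, ignore.case = TRUE)]
  if (length(len_col)) out$length <- as.numeric(df[[len_col[1L]]])
  if (anyDuplicated(out$spike_id)) {
    dup <- unique(out$spike_id[duplicated(out$spike_id)])
    stopf("duplicate spike identifier(s) in %s: %s", path,
          paste(dup, collapse = ", "))
  }
  bad <- which(!is.finite(out$concentration) | out$concentration <= 0)
  if (length(bad)) {
    stopf("non-positive concentration in %s for spike(s): %s", path,
          paste(out$spike_id[bad], collapse = ", "))
  }
  out
}

#' Read a per-sample condition sheet
#'
#' Columns: `sample_id`, `stage` (GV or MII), `cohort`, `batch`, `replicate`.
#'
#' @param path path to the TSV file.
#' @return validated data frame in file order.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "stage", "cohort", "batch", "replicate")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) {
    stopf("sample sheet %s is missing column(s): %s", path,
          paste(miss, collapse = ", "))
  }
  validate_sample_sheet(df, where = path)
}

validate_sample_sheet <- function(df, where = "sample sheet") {
  bad <- setdiff(unique(df$stage), c("GV", "MII"))
  if (length(bad)) {
    stopf("unknown stage value(s) in %s: %s (allowed: GV, MII)", where,
          paste(sprintf("\"%s\"", bad), collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) {
    dup <- unique(df$sample_id[duplicated(df$sample_id)])
    stopf("duplicate sample_id(s) in %s: %s", where, paste(dup, collapse = ", "))
  }
  df$sample_id <- as.character(df$sample_id)
  df$replicate <- as.integer(df$replicate)
  df
}

#' Read a GMT gene-set file
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `name`, `description`, members... Duplicate members within a set are
#' removed with a warning; sets must be non-empty.
#'
#' @param path path to the GMT file.
#' @return a named list of character vectors with attribute `descriptions`;
#'   class `"gene_sets"`, input order preserved.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  sets <- list()
  desc <- character()
  for (i in keep) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stopf("malformed GMT line %d in %s: need name, description and >= 1 member",
            i, path)
    }
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    if (length(members) == 0L) {
      stopf("empty member list for set \"%s\" (line %d) in %s", fields[1L], i, path)
    }
    if (anyDuplicated(members)) {
      warning(sprintf("set \"%s\" (line %d): duplicate members removed",
                      fields[1L], i), call. = FALSE)
      members <- unique(members)
    }
    sets[[fields[1L]]] <- members
    desc[fields[1L]] <- fields[2L]
  }
  attr(sets, "descriptions") <- desc
  class(sets) <- "gene_sets"
  sets
}

#' Write a matrix as TSV
#'
#' Genes as rows, samples as columns; the row-identifier column is named
#' `gene_id`. Lossless round-trip partner of [read_count_matrix()] for
#' integer matrices.
#'
#' @param mat matrix with row and column names.
#' @param path output path.
#' @export
write_matrix <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a degradome call set as TSV
#'
#' One row per gene with direction labels at each threshold, the M-decay flag
#' and the sensitivity label.
#'
#' @param calls a `degradome_calls` data frame (see [run_pipeline()]).
#' @param path output path.
#' @export
write_calls <- function(calls, path) {
  utils::write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a sample sheet as TSV
#' @param sheet sample-sheet data frame.
#' @param path output path.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
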