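# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# group descriptors are "cohort:stage" strings, e.g. "young:GV"
parse_group <- function(group) {
  if (is.list(group) && all(c("cohort", "stage") %in% names(group))) {
    return(list(cohort = group$cohort, stage = group$stage))
  }
  if (!is.character(group) || length(group) != 1L || !grepl(":", group, fixed = TRUE)) {
    stop("group must be a single \"cohort:stage\" string (e.g. \"young:GV\"), got: ",
         deparse(group), call. = FALSE)
  }
  parts <- strsplit(group, ":", fixed = TRUE)[[1L]]
  list(cohort = parts[1L], stage = parts[2L])
}

group_label <- function(cohort, stage) paste(cohort, stage, sep = ":")

# sample IDs of a (cohort, stage) group, in sample-sheet order
group_samples <- function(sheet, group) {
  g <- parse_group(group)
  ids <- sheet$sample_id[sheet$cohort == g$cohort & sheet$stage == g$stage]
  as.character(ids)
}

require_group <- function(sheet, group, what = "group") {
  ids <- group_samples(sheet, group)
  if (length(ids) == 0L) {
    stop(sprintf("%s \"%s\" has no samples in the sample sheet", what,
                 if (is.character(group)) group else group_label(group$cohort, group$stage)),
         call. = FALSE)
  }
  ids
}

spike_rows <- function(mat, spike_prefix = attr(mat, "spike_prefix") %||% "ERCC-") {
  startsWith(rownames(mat), spike_prefix)
}

norm_state <- function(mat) attr(mat, "norm_state") %||% "counts"

check_state <- function(mat, allowed, fn) {
  st <- norm_state(mat)
  if (!st %in% allowed) {
    stop(sprintf("%s expects a matrix in state %s, got \"%s\"", fn,
                 paste(sprintf("\"%s\"", allowed), collapse = " or "), st),
         call. = FALSE)
  }
  invisible(st)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
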