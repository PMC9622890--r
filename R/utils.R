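# Internal helpers shared across modules.

# Convert a counts tibble (first column = feature ids, remaining columns =
# samples) into an integer-ish numeric matrix with feature rownames.
as_count_matrix <- function(counts, id_col = NULL) {
  stopifnot(is.data.frame(counts))
  id_col <- id_col %||% names(counts)[1]
  ids <- as.character(counts[[id_col]])
  if (anyDuplicated(ids)) {
    abort("feature ids must be unique")
  }
  m <- as.matrix(counts[setdiff(names(counts), id_col)])
  if (!is.numeric(m)) {
    abort("count columns must be numeric")
  }
  if (any(m < 0, na.rm = TRUE)) {
    abort("counts must be non-negative")
  }
  rownames(m) <- ids
  m
}

# Matrix back to a tibble with an id column first.
matrix_to_tibble <- function(m, id_col = "feature_id") {
  out <- tibble::as_tibble(m)
  out <- tibble::add_column(out, !!id_col := rownames(m), .before = 1)
  out
}

# Look up the group label of each sample column from a metadata tibble.
sample_groups <- function(samples, meta, group_col,
                          sample_col = "sample") {
  if (!all(c(sample_col, group_col) %in% names(meta))) {
    abort(sprintf("metadata must have columns '%s' and '%s'",
                  sample_col, group_col))
  }
  idx <- match(samples, meta[[sample_col]])
  if (anyNA(idx)) {
    abort(sprintf("samples missing from metadata: %s",
                  paste(samples[is.na(idx)], collapse = ", ")))
  }
  setNames(as.character(meta[[group_col]][idx]), samples)
}

check_positive_int <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min ||
      x != as.integer(x)) {
    abort(sprintf("`%s` must be an integer >= %d", name, min))
  }
  as.integer(x)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be in [0, 1]", name))
  }
  as.numeric(x)
}
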