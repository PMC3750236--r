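# internal helpers shared across modules

# first column = feature ids, remaining columns numeric -> named matrix
tfa_matrix <- function(df, what = "value") {
  if (is.matrix(df)) {
    if (is.null(rownames(df))) abort("matrix input must carry rownames")
    return(df)
  }
  if (!is.data.frame(df) || ncol(df) < 2) {
    abort(sprintf("expected a data frame with an id column plus %s columns", what))
  }
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) abort("duplicate ids in column 1")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) abort(sprintf("%s columns must all be numeric", what))
  rownames(m) <- ids
  m
}

tfa_tibble <- function(mat, id_col = "gene") {
  out <- as_tibble(mat, .name_repair = "minimal")
  out <- bind_cols(tibble(!!id_col := rownames(mat)), out)
  out
}

# deterministic substream seeds below 2^31
tfa_child_seed <- function(seed, k) {
  (as.integer(seed) + 1013L * as.integer(k)) %% .Machine$integer.max
}

check_labels <- function(labels, samples, case = "case", control = "control") {
  if (!all(c("sample", "group") %in% names(labels))) {
    abort("labels must have columns `sample` and `group`")
  }
  labels <- as_tibble(labels)
  miss <- setdiff(samples, labels$sample)
  if (length(miss) > 0) {
    abort(sprintf("no group label for sample(s): %s", paste(head(miss, 5), collapse = ", ")))
  }
  grp <- labels$group[match(samples, labels$sample)]
  bad <- setdiff(unique(grp), c(case, control))
  if (length(bad) > 0) {
    abort(sprintf("unknown group(s) %s; expected '%s'/'%s'",
                  paste(bad, collapse = ", "), case, control))
  }
  grp == case
}
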