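#' Read an expression matrix
#'
#' Tab-delimited matrix with gene (or probe) ids in column 1 and sample ids in
#' the header. Leading metadata lines prefixed with `!` (GEO series-matrix
#' style) are skipped. Rows containing any missing value are dropped with a
#' message; missing-value imputation is out of scope.
#'
#' @param path Path to the TSV file.
#' @return A tibble: first column `gene`, remaining columns numeric samples.
#' @export
read_expression <- function(path) {
  x <- readr::read_tsv(path, comment = "!", show_col_types = FALSE)
  names(x)[1] <- "gene"
  x$gene <- as.character(x$gene)
  keep <- complete.cases(x)
  if (any(!keep)) {
    inform(sprintf("dropped %d row(s) with missing values", sum(!keep)))
    x <- x[keep, , drop = FALSE]
  }
  as_tibble(x)
}

#' Read sample group labels
#'
#' Two-column TSV mapping sample id to group (header optional but must be
#' `sample`/`group` if present).
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `sample` and `group`.
#' @export
read_sample_labels <- function(path) {
  first <- strsplit(readLines(path, n = 1), "\t")[[1]]
  if (identical(first[1:2], c("sample", "group"))) {
    readr::read_tsv(path, show_col_types = FALSE)
  } else {
    readr::read_tsv(path, col_names = c("sample", "group"), show_col_types = FALSE)
  }
}

#' Read a case/control sample pairing
#'
#' Two-column TSV mapping each case sample to its matched control (header
#' `case_sample`/`control_sample` optional).
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `case_sample` and `control_sample`.
#' @export
read_pairing <- function(path) {
  first <- strsplit(readLines(path, n = 1), "\t")[[1]]
  if (identical(first[1:2], c("case_sample", "control_sample"))) {
    readr::read_tsv(path, show_col_types = FALSE)
  } else {
    readr::read_tsv(path, col_names = c("case_sample", "control_sample"),
                    show_col_types = FALSE)
  }
}

#' Collapse probe-level expression to gene level
#'
#' Two conventions, matching the two microarray platforms they come from:
#' `mode = "average"` (two-channel arrays) averages all probes of a gene per
#' sample; `mode = "max_mean"` (one-channel arrays) keeps the single probe
#' with the highest mean across samples. Probes absent from the map are
#' dropped with a message.
#'
#' @param probe_matrix Tibble: first column probe id, remaining columns
#'   numeric samples.
#' @param probe_map Tibble with columns `probe` and `gene`; each probe maps to
#'   at most one gene.
#' @param mode `"average"` or `"max_mean"`.
#' @return A gene-level expression tibble (`gene` + sample columns).
#' @export
collapse_probes <- function(probe_matrix, probe_map, mode = c("average", "max_mean")) {
  mode <- match.arg(mode)
  if (!all(c("probe", "gene") %in% names(probe_map))) {
    abort("probe_map needs columns probe and gene")
  }
  if (nrow(probe_map) == 0) abort("empty probe-to-gene mapping")
  if (anyDuplicated(probe_map$probe)) abort("each probe may map to at most one gene")
  X <- tfa_matrix(probe_matrix, "expression")
  idx <- match(rownames(X), probe_map$probe)
  unmapped <- sum(is.na(idx))
  if (unmapped > 0) inform(sprintf("dropped %d unmapped probe(s)", unmapped))
  keep <- !is.na(idx)
  if (!any(keep)) abort("no probe matched the mapping")
  X <- X[keep, , drop = FALSE]
  genes <- probe_map$gene[idx[keep]]
  if (mode == "average") {
    G <- rowsum(X, group = genes, reorder = TRUE) /
      as.vector(table(genes)[sort(unique(genes))])
  } else {
    means <- rowMeans(X)
    pick <- tapply(seq_along(genes), genes, function(ii) ii[which.max(means[ii])])
    G <- X[unlist(pick), , drop = FALSE]
    rownames(G) <- names(pick)
  }
  tfa_tibble(G)
}

# vectorized unequal-variance t with degenerate-variance clamping:
# both group variances 0 and equal means -> 0; unequal means -> +/-(max|t|+1)
welch_t <- function(X, is_case) {
  n1 <- sum(is_case)
  n2 <- sum(!is_case)
  X1 <- X[, is_case, drop = FALSE]
  X2 <- X[, !is_case, drop = FALSE]
  m1 <- rowMeans(X1)
  m2 <- rowMeans(X2)
  v1 <- rowSums((X1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((X2 - m2)^2) / (n2 - 1)
  se <- sqrt(v1 / n1 + v2 / n2)
  t <- (m1 - m2) / se
  unname(clamp_degenerate_t(t, num = m1 - m2, zero_se = se == 0))
}

clamp_degenerate_t <- function(t, num, zero_se) {
  if (any(zero_se)) {
    t[zero_se & num == 0] <- 0
    bad <- zero_se & num != 0
    if (any(bad)) {
      finite_max <- suppressWarnings(max(abs(t[is.finite(t)]), 0))
      t[bad] <- sign(num[bad]) * (finite_max + 1)
    }
  }
  t
}

#' Per-gene t-scores for a case-control design
#'
#' Unequal-variance t statistic
#' `t = (mu1 - mu2) / sqrt(d1^2/n1 + d2^2/n2)` per gene, with sample standard
#' deviations (n - 1 denominator). Genes whose two group variances are both
#' zero get `t = 0` when the means agree, otherwise the maximum finite
#' absolute t in the profile plus one (signed) so ranking stays well defined.
#'
#' @param expr Expression tibble (`gene` + sample columns).
#' @param labels Tibble with columns `sample` and `group`.
#' @param case,control Group labels identifying the two arms.
#' @return A tibble with columns `gene` and `t`, plus attributes `n_case` and
#'   `n_control`.
#' @export
t_score_profile <- function(expr, labels, case = "case", control = "control") {
  X <- tfa_matrix(expr, "expression")
  is_case <- check_labels(labels, colnames(X), case, control)
  if (sum(is_case) < 2) abort(sprintf("group '%s' has fewer than 2 samples", case))
  if (sum(!is_case) < 2) abort(sprintf("group '%s' has fewer than 2 samples", control))
  t <- welch_t(X, is_case)
  out <- tibble(gene = rownames(X), t = t)
  attr(out, "n_case") <- sum(is_case)
  attr(out, "n_control") <- sum(!is_case)
  attr(out, "paired") <- FALSE
  out
}

#' Per-gene paired t-scores
#'
#' For designs where each case sample has a matched control (tumour versus
#' adjacent normal), the per-pair difference `d = case - control` feeds a
#' standard paired t statistic `t = mean(d) / (sd(d)/sqrt(n))`. All-zero
#' difference variance is clamped as in [t_score_profile()].
#'
#' @param expr Expression tibble (`gene` + sample columns).
#' @param pairing Tibble with columns `case_sample` and `control_sample`; a
#'   bijection between the two sample subsets, at least two pairs.
#' @return A tibble with columns `gene` and `t`; attribute `n_pairs`.
#' @export
paired_t_score_profile <- function(expr, pairing) {
  if (!all(c("case_sample", "control_sample") %in% names(pairing))) {
    abort("pairing needs columns case_sample and control_sample")
  }
  if (nrow(pairing) < 2) abort("need at least 2 pairs")
  if (anyDuplicated(pairing$case_sample) || anyDuplicated(pairing$control_sample) ||
      length(intersect(pairing$case_sample, pairing$control_sample)) > 0) {
    abort("pairing must be a bijection between disjoint case and control samples")
  }
  X <- tfa_matrix(expr, "expression")
  miss <- setdiff(c(pairing$case_sample, pairing$control_sample), colnames(X))
  if (length(miss) > 0) {
    abort(sprintf("unpaired/unknown sample(s): %s", paste(head(miss, 5), collapse = ", ")))
  }
  D <- X[, pairing$case_sample, drop = FALSE] - X[, pairing$control_sample, drop = FALSE]
  np <- ncol(D)
  mu <- rowMeans(D)
  sdev <- sqrt(rowSums((D - mu)^2) / (np - 1))
  se <- sdev / sqrt(np)
  t <- unname(clamp_degenerate_t(mu / se, num = mu, zero_se = se == 0))
  out <- tibble(gene = rownames(X), t = t)
  attr(out, "n_pairs") <- np
  attr(out, "paired") <- TRUE
  out
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) to the same empirical distribution: the
#' row-wise mean of the per-sample sorted values. Ties within a column receive
#' the mean of the quantile values they span. A single-sample matrix is
#' returned unchanged with a warning.
#'
#' @param expr Expression tibble (`gene` + sample columns) of absolute values.
#' @return The normalized expression tibble.
#' @export
quantile_normalize <- function(expr) {
  X <- tfa_matrix(expr, "expression")
  if (ncol(X) < 2) {
    warn("single-sample matrix: quantile normalization is a no-op")
    return(as_tibble(expr))
  }
  Q <- limma::normalizeQuantiles(X, ties = TRUE)
  dimnames(Q) <- dimnames(X)
  tfa_tibble(Q)
}

#' Absolute to relative expression
#'
#' Divides each gene's values by the gene's median across samples and takes
#' log10: `r = log10(x / median(x))`. Requires strictly positive input (as
#' produced by one-channel intensity arrays).
#'
#' @param expr Expression tibble (`gene` + sample columns), all values > 0.
#' @return A relative (signed, log10-scale) expression tibble.
#' @export
relative_expression <- function(expr) {
  X <- tfa_matrix(expr, "expression")
  if (any(X <= 0)) {
    bad <- which(X <= 0, arr.ind = TRUE)[1, ]
    abort(sprintf("non-positive expression for gene '%s', sample '%s'",
                  rownames(X)[bad[1]], colnames(X)[bad[2]]))
  }
  med <- apply(X, 1, median)
  tfa_tibble(log10(X / med))
}
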