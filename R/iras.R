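#' Pre-score of one sample's relative expression profile
#'
#' The case-control t-profile is replaced by a single sample's relative
#' (signed, log-ratio) expression profile: genes are ranked by relative
#' expression descending and the same squared-weight running sums give the
#' pre-score. A positive pre-score means the profile's high-potential genes
#' sit at the top of the sample's expression ranking.
#'
#' @param rel_profile Tibble with columns `gene` and `r` (relative
#'   expression), e.g. one sample of [relative_expression()] output.
#' @param potentials Tibble with `gene` plus one potential column (or use
#'   `profile` to pick one).
#' @param profile Column name when `potentials` has several.
#' @return A one-row tibble as from [pre_score()].
#' @export
sample_pre_score <- function(rel_profile, potentials, profile = NULL) {
  if (!all(c("gene", "r") %in% names(rel_profile))) {
    abort("rel_profile needs columns gene and r")
  }
  if (all(rel_profile$r == 0)) abort("all-zero relative profile: pre-score undefined")
  S <- tfa_matrix(potentials, "potential")
  if (is.null(profile)) {
    if (ncol(S) != 1) abort("give `profile` to pick one of several potential columns")
    profile <- colnames(S)[1]
  }
  common <- intersect(rel_profile$gene, rownames(S))
  if (length(common) == 0) abort("no genes shared between profile and potentials")
  r <- rel_profile$r[match(common, rel_profile$gene)]
  pr <- prescore_cols(r, common, S[common, profile, drop = FALSE])
  if (!is.na(pr$failure[1])) abort(pr$failure[[1]])
  tibble(ps = unname(pr$ps), ps_plus = unname(pr$ps_plus),
         ps_minus = unname(pr$ps_minus), location = unname(pr$location))
}

#' Gene-permutation null for a sample pre-score
#'
#' Shuffles the gene-to-expression assignment (implemented as permuting the
#' potential vector against the fixed expression ranking, which is
#' equivalent and cheaper) and recomputes `ps+`/`ps-` `m` times.
#'
#' @inheritParams sample_pre_score
#' @param m Number of gene permutations.
#' @param seed Integer seed.
#' @return A list with vectors `perm_plus`, `perm_minus` plus `m` and `seed`.
#' @export
gene_permutation_null <- function(rel_profile, potentials, m = 1000, seed = 1,
                                  profile = NULL) {
  stopifnot(m >= 1)
  S <- tfa_matrix(potentials, "potential")
  if (is.null(profile)) {
    if (ncol(S) != 1) abort("give `profile` to pick one of several potential columns")
    profile <- colnames(S)[1]
  }
  common <- intersect(rel_profile$gene, rownames(S))
  r <- rel_profile$r[match(common, rel_profile$gene)]
  s <- S[common, profile]
  perms <- withr::with_seed(seed,
    replicate(m, sample.int(length(s)), simplify = FALSE))
  null <- sample_null_engine(r, common, s, perms)
  list(perm_plus = null$plus, perm_minus = null$minus, m = m, seed = seed)
}

# fixed ranking of r; permuted potential vectors; cumulative-gap extrema
sample_null_engine <- function(r, gene_ids, s, perms) {
  o <- order(-r, gene_ids, method = "radix")
  w <- r[o]^2
  tot <- sum(w)
  if (tot == 0) abort("all-zero profile")
  g <- length(w)
  m <- length(perms)
  plus <- minus <- rep(NA_real_, m)
  const <- max(s) == min(s)
  # permuting genes leaves the ranking of r fixed; only the aligned s changes
  for (k in seq_len(m)) {
    if (const) {
      if (s[1] == 0 || s[1] == 1) abort("degenerate constant potential column")
      plus[k] <- 0; minus[k] <- 0
      next
    }
    sp <- (s[perms[[k]]])[o]
    cf <- cumsum(w * sp)
    cb <- cumsum(w * (1 - sp))
    d <- cf / cf[g] - cb / cb[g]
    plus[k] <- max(max(d), 0)
    minus[k] <- min(min(d), 0)
  }
  list(plus = plus, minus = minus)
}

#' Sample-wise regulatory activity (iRAS)
#'
#' Computes a normalized activity score for every factor profile in every
#' sample. Absolute expression is first quantile-normalized and converted to
#' relative values (log10 of the gene-median ratio); relative input is used
#' directly. Each cell's score is normalized against a gene-permutation
#' null; one seeded permutation set is shared by every sample and profile,
#' so identical samples score identically and cells stay comparable.
#' A positive score means the profile's high-potential genes
#' concentrate among the sample's most highly expressed genes.
#'
#' @param expr Expression tibble (`gene` + sample columns).
#' @param potentials `tf_potentials` tibble.
#' @param value_type `"absolute"` (one-channel intensities) or `"relative"`
#'   (signed log-ratios, used as-is).
#' @param m Gene permutations per sample (default 1000).
#' @param seed Integer seed; per-sample streams are derived from it.
#' @return A `tfa_iras` tibble in long form: `tf`, `sample`, `ps`, `iras`.
#'   Cells whose null mean is zero are `NA` (undefined, not zero).
#' @examples
#' sim <- simulate_study(sim_config(n_genes = 200, n_tfs = 3, seed = 3,
#'                                  value_type = "relative"))
#' act <- iras(sim$expression, sim$potentials, value_type = "relative",
#'             m = 30, seed = 3)
#' @export
iras <- function(expr, potentials, value_type = c("absolute", "relative"),
                 m = 1000, seed = 1) {
  value_type <- match.arg(value_type)
  stopifnot(m >= 1)
  if (value_type == "absolute") {
    expr <- relative_expression(quantile_normalize(expr))
  }
  X <- tfa_matrix(expr, "expression")
  S <- tfa_matrix(potentials, "potential")
  common <- intersect(rownames(X), rownames(S))
  if (length(common) == 0) abort("no genes shared between expression and potentials")
  X <- X[common, , drop = FALSE]
  S <- S[common, , drop = FALSE]
  g <- length(common)
  samples <- colnames(X)
  res <- vector("list", length(samples))
  # one seeded permutation set shared by every sample and profile: keeps
  # duplicate samples byte-identical and nulls comparable across cells
  perms <- withr::with_seed(seed, replicate(m, sample.int(g), simplify = FALSE))
  for (si in seq_along(samples)) {
    r <- X[, si]
    obs <- prescore_cols(r, common, S)
    score <- rep(NA_real_, ncol(S))
    for (j in seq_len(ncol(S))) {
      if (!is.na(obs$failure[j])) next
      null <- sample_null_engine(r, common, S[, j], perms)
      denom <- if (obs$ps[j] >= 0) mean(null$plus) else abs(mean(null$minus))
      if (is.finite(denom) && denom > 0) score[j] <- obs$ps[j] / denom
    }
    res[[si]] <- tibble(tf = colnames(S), sample = samples[si],
                        ps = unname(obs$ps), iras = score)
  }
  out <- bind_rows(res)
  class(out) <- c("tfa_iras", class(out))
  attr(out, "m") <- m
  attr(out, "seed") <- seed
  out
}

#' Write an activity matrix as TSV (profiles x samples)
#'
#' @param activity A `tfa_iras` long tibble.
#' @param path Output path.
#' @param value Which column to spread (`"iras"` or `"ps"`).
#' @return `path`, invisibly.
#' @export
write_activity <- function(activity, path, value = "iras") {
  wide <- tidyr::pivot_wider(activity, id_cols = "tf", names_from = "sample",
                             values_from = dplyr::all_of(value))
  readr::write_tsv(wide, path)
  invisible(path)
}

#' Read an activity matrix written by [write_activity()]
#'
#' @param path TSV path (profile rows, sample columns).
#' @return A `tfa_iras` long tibble with columns `tf`, `sample`, `iras`.
#' @export
read_activity <- function(path) {
  wide <- readr::read_tsv(path, show_col_types = FALSE)
  out <- tidyr::pivot_longer(wide, -1, names_to = "sample", values_to = "iras")
  names(out)[1] <- "tf"
  class(out) <- c("tfa_iras", class(out))
  out
}

#' Compare activity between two sample groups
#'
#' Per profile, a one-sided Wilcoxon rank-sum test of whether activity in the
#' `case` group exceeds the `control` group (exact for small untied samples,
#' normal approximation with tie and continuity correction otherwise; with
#' identical groups the one-sided p sits just above 0.5 because of the
#' continuity correction).
#'
#' @param activity A `tfa_iras` long tibble (`tf`, `sample`, `iras`).
#' @param labels Tibble with columns `sample` and `group`.
#' @param case,control Group labels; the alternative is `case > control`.
#' @return A tibble with columns `tf`, `p_value`, sorted by `p_value`.
#' @export
compare_activity_groups <- function(activity, labels, case = "case",
                                    control = "control") {
  if (!all(c("tf", "sample", "iras") %in% names(activity))) {
    abort("activity needs columns tf, sample, iras")
  }
  is_case <- check_labels(labels, unique(activity$sample), case, control)
  grp <- tibble(sample = unique(activity$sample),
                group = ifelse(is_case, case, control))
  if (length(unique(grp$group)) < 2) abort("need samples in both groups")
  act <- left_join(activity, grp, by = "sample")
  act |>
    group_by(.data$tf) |>
    summarise(p_value = {
      x <- .data$iras[.data$group == case]
      y <- .data$iras[.data$group == control]
      suppressWarnings(wilcox.test(x, y, alternative = "greater")$p.value)
    }) |>
    arrange(.data$p_value)
}
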