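# ---- internal engine ---------------------------------------------------
# Pre-scores of every potential column against one t-profile.
# Genes ranked by t descending, ties broken by gene id; running foreground
# f(i) = cumsum(t^2 s')/total and background b(i) = cumsum(t^2 (1-s'))/total;
# the pre-score is the signed larger of max(f-b, 0) and min(f-b, 0).
# Constant potential columns in (0,1) short-circuit to ps = 0 exactly
# (f and b coincide analytically; this avoids spurious rounding residue).
prescore_cols <- function(t, gene_ids, S) {
  g <- length(t)
  tf_names <- colnames(S)
  n_tf <- ncol(S)
  ps_plus <- ps_minus <- ps <- loc <- rep(NA_real_, n_tf)
  failure <- rep(NA_character_, n_tf)
  o <- order(-t, gene_ids, method = "radix")
  t2 <- t[o]^2
  if (sum(t2) == 0) {
    failure[] <- "all t-scores are zero"
  } else {
    So <- S[o, , drop = FALSE]
    rng <- apply(S, 2, function(x) max(x) - min(x))
    for (j in seq_len(n_tf)) {
      s <- So[, j]
      if (rng[j] == 0) {
        if (s[1] == 0) {
          failure[j] <- "potential column is all zero (foreground weight vanishes)"
        } else if (s[1] == 1) {
          failure[j] <- "potential column is all one (background weight vanishes)"
        } else {
          ps_plus[j] <- 0; ps_minus[j] <- 0; ps[j] <- 0; loc[j] <- 1 / g
        }
        next
      }
      cf <- cumsum(t2 * s)
      cb <- cumsum(t2 * (1 - s))
      if (cf[g] <= 0) { failure[j] <- "foreground weight sum is zero"; next }
      if (cb[g] <= 0) { failure[j] <- "background weight sum is zero"; next }
      d <- cf / cf[g] - cb / cb[g]
      imax <- which.max(d)
      imin <- which.min(d)
      pp <- max(d[imax], 0)
      pm <- min(d[imin], 0)
      ps_plus[j] <- pp
      ps_minus[j] <- pm
      if (pp > abs(pm)) {
        ps[j] <- pp; loc[j] <- imax / g
      } else {
        ps[j] <- pm; loc[j] <- imin / g
      }
    }
  }
  list(ps_plus = setNames(ps_plus, tf_names),
       ps_minus = setNames(ps_minus, tf_names),
       ps = setNames(ps, tf_names),
       location = setNames(loc, tf_names),
       failure = setNames(failure, tf_names))
}

# ---- exported building blocks ------------------------------------------

#' Rank genes by t-score and align regulatory potentials
#'
#' Sorts genes in decreasing t order (ties broken by gene id for
#' determinism) and carries the matching potential along. The analysis is
#' restricted to the gene-id intersection of the two inputs, with a message
#' when genes are dropped.
#'
#' @param tscores Tibble with columns `gene` and `t`
#'   (e.g. from [t_score_profile()]), or any signed per-gene score.
#' @param potentials Tibble with column `gene` plus exactly one potential
#'   column, or a `tf_potentials` tibble and `profile` naming the column.
#' @param profile Column to use when `potentials` has several.
#' @return A tibble with columns `gene`, `t`, `s`, ranked by decreasing `t`.
#' @export
rank_genes <- function(tscores, potentials, profile = NULL) {
  if (!all(c("gene", "t") %in% names(tscores))) abort("tscores needs columns gene, t")
  S <- tfa_matrix(potentials, "potential")
  if (is.null(profile)) {
    if (ncol(S) != 1) abort("give `profile` to pick one of several potential columns")
    profile <- colnames(S)[1]
  }
  common <- intersect(tscores$gene, rownames(S))
  if (length(common) == 0) abort("no genes shared between t-scores and potentials")
  dropped <- (length(tscores$gene) - length(common)) + (nrow(S) - length(common))
  if (dropped > 0) inform(sprintf("restricted to %d shared gene(s)", length(common)))
  t <- tscores$t[match(common, tscores$gene)]
  s <- unname(S[common, profile])
  o <- order(-t, common, method = "radix")
  tibble(gene = common[o], t = t[o], s = s[o])
}

#' Foreground and background running sums over a ranked gene list
#'
#' Along the t-ranked list, `f(i)` accumulates the share of total `t^2 * s`
#' weight seen so far (potential-weighted, the "foreground") and `b(i)` the
#' share of `t^2 * (1 - s)` weight (the complement, "background"). Both are
#' non-decreasing and reach exactly 1 at the last gene. Their gap `f - b`
#' measures how strongly high-potential genes concentrate among extreme
#' t-scores.
#'
#' @param ranked Output of [rank_genes()].
#' @return The input tibble with columns `f` and `b` appended.
#' @export
running_sums <- function(ranked) {
  if (!all(c("t", "s") %in% names(ranked))) abort("ranked needs columns t and s")
  g <- nrow(ranked)
  w_f <- ranked$t^2 * ranked$s
  w_b <- ranked$t^2 * (1 - ranked$s)
  cf <- cumsum(w_f)
  cb <- cumsum(w_b)
  if (cf[g] <= 0) abort("foreground weight sum is zero (all potentials 0 or all t zero)")
  if (cb[g] <= 0) abort("background weight sum is zero (all potentials 1 or all t zero)")
  mutate(ranked, f = cf / cf[g], b = cb / cb[g])
}

#' Pre-score: maximal deviation between running sums
#'
#' `ps+` is the maximum of `f - b` floored at 0, `ps-` the minimum capped at
#' 0. The pre-score is `ps+` when `ps+ > |ps-|` and `ps-` otherwise; its
#' location is the rank fraction `i/g` of the winning extremum (earliest
#' index on ties).
#'
#' @param rf Output of [running_sums()].
#' @return A one-row tibble: `ps`, `ps_plus`, `ps_minus`, `location`.
#' @export
pre_score <- function(rf) {
  if (!all(c("f", "b") %in% names(rf))) abort("rf needs columns f and b")
  g <- nrow(rf)
  d <- rf$f - rf$b
  imax <- which.max(d)
  imin <- which.min(d)
  pp <- max(d[imax], 0)
  pm <- min(d[imin], 0)
  if (pp > abs(pm)) {
    tibble(ps = pp, ps_plus = pp, ps_minus = pm, location = imax / g)
  } else {
    tibble(ps = pm, ps_plus = pp, ps_minus = pm, location = imin / g)
  }
}

# shuffled-case mask: floor(n1/2) cases + floor(n2/2) controls
balanced_case_mask <- function(is_case) {
  ci <- which(is_case)
  ki <- which(!is_case)
  pick <- c(ci[sample.int(length(ci), length(ci) %/% 2)],
            ki[sample.int(length(ki), length(ki) %/% 2)])
  mask <- logical(length(is_case))
  mask[pick] <- TRUE
  mask
}

#' Balanced permutation of case/control labels
#'
#' Forms a shuffled case group from `floor(n1/2)` random case samples plus
#' `floor(n2/2)` random control samples; the remainder becomes the shuffled
#' control group. Balancing preserves the within-dataset correlation
#' structure under the null better than a free label shuffle.
#'
#' @param labels Tibble with columns `sample` and `group`.
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @param case,control Group labels.
#' @param allow_unbalanced If a group has fewer than 2 samples, fall back to a
#'   free (unbalanced) shuffle instead of erroring.
#' @return A labels tibble with permuted `group`.
#' @export
balanced_permutation <- function(labels, seed = NULL, case = "case",
                                 control = "control", allow_unbalanced = FALSE) {
  is_case <- check_labels(labels, labels$sample, case, control)
  draw <- function() {
    if (sum(is_case) < 2 || sum(!is_case) < 2) {
      if (!allow_unbalanced) {
        abort(paste("a group has fewer than 2 samples; set allow_unbalanced = TRUE",
                    "for a free label shuffle"))
      }
      mask <- logical(length(is_case))
      mask[sample.int(length(is_case), sum(is_case))] <- TRUE
      mask
    } else {
      balanced_case_mask(is_case)
    }
  }
  mask <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  tibble(sample = labels$sample, group = ifelse(mask, case, control))
}

#' Deterministic permutation plan
#'
#' Pre-draws `m` balanced label shuffles from one seed. All potential columns
#' share this plan, which keeps their permutation nulls comparable (required
#' for the pooled FDR) and the whole run reproducible.
#'
#' @param labels Tibble with columns `sample` and `group`.
#' @param m Number of permutations.
#' @param seed Integer seed.
#' @inheritParams balanced_permutation
#' @return A list of `m` logical shuffled-case masks over `labels$sample`.
#' @export
permutation_plan <- function(labels, m, seed, case = "case", control = "control") {
  is_case <- check_labels(labels, labels$sample, case, control)
  if (sum(is_case) < 2 || sum(!is_case) < 2) {
    abort("balanced permutation needs at least 2 samples per group")
  }
  withr::with_seed(seed, replicate(m, balanced_case_mask(is_case), simplify = FALSE))
}

#' Permutation null of pre-scores
#'
#' For each balanced label shuffle, recomputes t-scores, re-ranks genes and
#' recomputes `ps+`/`ps-` for every potential column. Failed permutations
#' (degenerate t-profiles) are recorded; more than 10% failures aborts.
#'
#' @param expr Expression tibble (`gene` + sample columns).
#' @param labels Tibble with columns `sample` and `group`.
#' @param potentials `tf_potentials` tibble (or `gene` + potential columns).
#' @param m Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param case,control Group labels.
#' @return A list with `perm_plus` and `perm_minus` (`m` x profiles matrices),
#'   `m`, `seed` and the failure count.
#' @export
ras_null <- function(expr, labels, potentials, m = 1000, seed = 1,
                     case = "case", control = "control") {
  stopifnot(m >= 1)
  X <- tfa_matrix(expr, "expression")
  S <- tfa_matrix(potentials, "potential")
  common <- intersect(rownames(X), rownames(S))
  if (length(common) == 0) abort("no genes shared between expression and potentials")
  X <- X[common, , drop = FALSE]
  S <- S[common, , drop = FALSE]
  plan <- permutation_plan(labels, m, seed, case, control)
  build_null_masks(X, S, common, plan, seed = seed)
}

# shared by ras(); X/S already aligned to `genes`
build_null_masks <- function(X, S, genes, plan, seed) {
  X <- X[, , drop = FALSE]
  m <- length(plan)
  perm_plus <- matrix(NA_real_, m, ncol(S), dimnames = list(NULL, colnames(S)))
  perm_minus <- perm_plus
  failures <- 0L
  for (k in seq_len(m)) {
    mask <- plan[[k]]
    tk <- welch_t(X, mask)
    pr <- prescore_cols(tk, genes, S)
    if (all(!is.na(pr$failure))) {
      failures <- failures + 1L
      next
    }
    perm_plus[k, ] <- pr$ps_plus
    perm_minus[k, ] <- pr$ps_minus
  }
  if (failures > 0.1 * m) {
    abort(sprintf("%d of %d permutations failed; inputs too degenerate", failures, m))
  }
  list(perm_plus = perm_plus, perm_minus = perm_minus, m = m, seed = seed,
       failures = failures)
}

#' Normalize a pre-score against its permutation null
#'
#' `ras = ps / mean(perm_plus)` for `ps >= 0`, else
#' `ps / |mean(perm_minus)|`. A zero null mean leaves the score undefined
#' (`NA`) with a warning.
#'
#' @param ps Observed pre-score (scalar).
#' @param perm_plus,perm_minus Null vectors of permuted `ps+` / `ps-`.
#' @return The normalized regulatory activity score (scalar).
#' @export
normalize_ras <- function(ps, perm_plus, perm_minus) {
  if (is.na(ps)) return(NA_real_)
  denom <- if (ps >= 0) mean(perm_plus, na.rm = TRUE) else abs(mean(perm_minus, na.rm = TRUE))
  if (!is.finite(denom) || denom == 0) {
    warn("zero/undefined null mean; normalized score is NA")
    return(NA_real_)
  }
  ps / denom
}

#' Empirical permutation p-value of a pre-score
#'
#' For `ps >= 0`, the fraction of permuted `ps+` values at least as large;
#' for `ps < 0`, the fraction of permuted `ps-` values at least as small.
#' The raw fraction can be exactly 0; the add-one variant `(k + 1)/(m + 1)`
#' is reported alongside as a conservative alternative.
#'
#' @inheritParams normalize_ras
#' @return A one-row tibble with `p_value` (raw) and `p_value_addone`.
#' @export
empirical_pvalue <- function(ps, perm_plus, perm_minus) {
  if (is.na(ps)) return(tibble(p_value = NA_real_, p_value_addone = NA_real_))
  if (ps >= 0) {
    null <- perm_plus[!is.na(perm_plus)]
    k <- sum(null >= ps)
  } else {
    null <- perm_minus[!is.na(perm_minus)]
    k <- sum(null <= ps)
  }
  m <- length(null)
  tibble(p_value = k / m, p_value_addone = (k + 1) / (m + 1))
}

#' Pooled-permutation false discovery rate
#'
#' Permuted pre-scores are first normalized by each profile's own null means
#' (the same denominators used for the observed scores), then pooled across
#' profiles. For a non-negative score `r`, `FDR = P(pooled normalized
#' perm_plus >= r) / P(observed non-negative scores >= r)`, mirrored for
#' negative scores, and capped at 1.
#'
#' @param ras_values Named vector of observed normalized scores (one per
#'   profile; `NA` allowed).
#' @param perm_plus,perm_minus `m` x profiles matrices of permuted
#'   `ps+`/`ps-` (columns matching `ras_values` names).
#' @return Numeric vector of FDR values aligned with `ras_values`.
#' @export
pooled_fdr <- function(ras_values, perm_plus, perm_minus) {
  mplus <- colMeans(perm_plus, na.rm = TRUE)
  mminus <- colMeans(perm_minus, na.rm = TRUE)
  ok_plus <- is.finite(mplus) & mplus > 0
  ok_minus <- is.finite(mminus) & mminus < 0
  pool_plus <- as.vector(sweep(perm_plus[, ok_plus, drop = FALSE], 2,
                               mplus[ok_plus], "/"))
  pool_minus <- as.vector(sweep(perm_minus[, ok_minus, drop = FALSE], 2,
                                abs(mminus[ok_minus]), "/"))
  pool_plus <- pool_plus[!is.na(pool_plus)]
  pool_minus <- pool_minus[!is.na(pool_minus)]
  obs_plus <- ras_values[!is.na(ras_values) & ras_values >= 0]
  obs_minus <- ras_values[!is.na(ras_values) & ras_values < 0]
  vapply(ras_values, function(r) {
    if (is.na(r)) return(NA_real_)
    if (r >= 0) {
      num <- if (length(pool_plus)) mean(pool_plus >= r) else 0
      den <- mean(obs_plus >= r)
    } else {
      num <- if (length(pool_minus)) mean(pool_minus <= r) else 0
      den <- mean(obs_minus <= r)
    }
    min(num / den, 1)
  }, numeric(1))
}

#' Differential regulatory activity of transcription factors
#'
#' Full case-control activity screen: per-gene t-scores, potential-weighted
#' running sums per factor profile, pre-scores, balanced-permutation
#' normalization into regulatory activity scores (RAS), empirical p-values
#' and a pooled-permutation FDR. A positive RAS means high-potential genes of
#' the factor concentrate among genes up-regulated in cases; negative, among
#' down-regulated genes.
#'
#' All profiles share one permutation plan (identical label shuffles per
#' permutation index), which makes normalized null scores comparable across
#' profiles and the run reproducible from `seed`.
#'
#' @param expr Expression tibble (`gene` + sample columns).
#' @param potentials `tf_potentials` tibble (`gene` + one column per profile).
#' @param labels Tibble with columns `sample` and `group`.
#' @param m Number of balanced permutations (default 1000).
#' @param seed Integer seed (default 1).
#' @param case,control Group labels (defaults `"case"`/`"control"`).
#' @return A `tfa_ras` tibble, one row per profile sorted by `|ras|`
#'   descending: `tf`, `ps`, `ras`, `location`, `p_value` (sign-conditional
#'   permutation fraction), `p_value_addone` (conservative `(k+1)/(m+1)`),
#'   `p_value_twosided` (calibrated two-sided diagnostic comparing `|ps|`
#'   with each permutation's larger extremum), `fdr`, `n_genes`.
#'   Attributes keep `m`, `seed`, group sizes and the
#'   permutation null matrices. Profiles that fail (degenerate potentials)
#'   are kept as `NA` rows with the failure message in column `note`.
#' @examples
#' sim <- simulate_study(sim_config(n_genes = 300, n_tfs = 4, seed = 7))
#' res <- ras(sim$expression, sim$potentials, sim$labels, m = 50, seed = 7)
#' head(res)
#' @export
ras <- function(expr, potentials, labels, m = 1000, seed = 1,
                case = "case", control = "control") {
  stopifnot(m >= 1)
  X <- tfa_matrix(expr, "expression")
  S <- tfa_matrix(potentials, "potential")
  common <- intersect(rownames(X), rownames(S))
  if (length(common) == 0) abort("no genes shared between expression and potentials")
  if (length(common) < nrow(X) || length(common) < nrow(S)) {
    inform(sprintf("analysis restricted to %d shared gene(s)", length(common)))
  }
  X <- X[common, , drop = FALSE]
  S <- S[common, , drop = FALSE]
  is_case <- check_labels(labels, colnames(X), case, control)
  if (sum(is_case) < 2 || sum(!is_case) < 2) abort("need >= 2 samples per group")

  t_obs <- welch_t(X, is_case)
  obs <- prescore_cols(t_obs, common, S)
  if (any(!is.na(obs$failure))) {
    bad <- which(!is.na(obs$failure))
    warn(sprintf("%d profile(s) failed and are reported as NA (e.g. %s: %s)",
                 length(bad), names(bad)[1], obs$failure[bad[1]]))
  }

  plan <- permutation_plan(tibble(sample = colnames(X),
                                  group = ifelse(is_case, case, control)),
                           m, seed, case, control)
  null <- build_null_masks(X, S, common, plan, seed = seed)

  mplus <- colMeans(null$perm_plus, na.rm = TRUE)
  mminus <- colMeans(null$perm_minus, na.rm = TRUE)
  n_tf <- ncol(S)
  ras_v <- p_raw <- p_add <- p_two <- rep(NA_real_, n_tf)
  for (j in seq_len(n_tf)) {
    if (!is.na(obs$failure[j])) next
    denom <- if (obs$ps[j] >= 0) mplus[j] else abs(mminus[j])
    ras_v[j] <- if (is.finite(denom) && denom > 0) obs$ps[j] / denom else NA_real_
    pv <- empirical_pvalue(obs$ps[j], null$perm_plus[, j], null$perm_minus[, j])
    p_raw[j] <- pv$p_value
    p_add[j] <- pv$p_value_addone
    # two-sided diagnostic: |ps| against each permutation's larger extremum.
    # Unlike the sign-conditional p above it is calibrated under a global
    # null (the sign-conditional comparison inherits a selection effect
    # from reporting the winning side only).
    mx <- pmax(null$perm_plus[, j], abs(null$perm_minus[, j]))
    p_two[j] <- mean(mx >= abs(obs$ps[j]), na.rm = TRUE)
  }
  fdr <- pooled_fdr(setNames(ras_v, colnames(S)), null$perm_plus, null$perm_minus)

  out <- tibble(
    tf = colnames(S),
    ps = unname(obs$ps),
    ras = ras_v,
    location = unname(obs$location),
    p_value = p_raw,
    p_value_addone = p_add,
    p_value_twosided = p_two,
    fdr = unname(fdr),
    n_genes = length(common),
    note = unname(obs$failure)
  )
  out <- arrange(out, dplyr::desc(abs(.data$ras)))
  class(out) <- c("tfa_ras", class(out))
  attr(out, "m") <- m
  attr(out, "seed") <- seed
  attr(out, "n_case") <- sum(is_case)
  attr(out, "n_control") <- sum(!is_case)
  attr(out, "null") <- null
  out
}
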