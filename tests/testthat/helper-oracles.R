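# Independent, deliberately naive reference implementations used as oracles.
# Everything here is plain loops over definitions; none of it shares code
# with the package internals.

oracle_t <- function(X, is_case) {
  n1 <- sum(is_case)
  n2 <- sum(!is_case)
  t <- numeric(nrow(X))
  for (i in seq_len(nrow(X))) {
    x1 <- X[i, is_case]
    x2 <- X[i, !is_case]
    se <- sqrt(var(x1) / n1 + var(x2) / n2)
    t[i] <- if (se == 0) {
      if (mean(x1) == mean(x2)) 0 else NaN  # clamped afterwards
    } else {
      (mean(x1) - mean(x2)) / se
    }
  }
  if (any(is.nan(t))) {
    mx <- max(abs(t[!is.nan(t)]), 0)
    for (i in which(is.nan(t))) {
      t[i] <- sign(mean(X[i, is_case]) - mean(X[i, !is_case])) * (mx + 1)
    }
  }
  t
}

# ranked running sums and pre-score for one potential column, all loops
oracle_prescore <- function(t, genes, s) {
  o <- order(-t, genes)
  tt <- t[o]
  ss <- s[o]
  g <- length(tt)
  num_f <- num_b <- 0
  den_f <- sum(tt^2 * ss)
  den_b <- sum(tt^2 * (1 - ss))
  f <- b <- numeric(g)
  for (i in seq_len(g)) {
    num_f <- num_f + tt[i]^2 * ss[i]
    num_b <- num_b + tt[i]^2 * (1 - ss[i])
    f[i] <- num_f / den_f
    b[i] <- num_b / den_b
  }
  d <- f - b
  imax <- 1
  imin <- 1
  for (i in seq_len(g)) {
    if (d[i] > d[imax]) imax <- i
    if (d[i] < d[imin]) imin <- i
  }
  pp <- max(d[imax], 0)
  pm <- min(d[imin], 0)
  if (pp > abs(pm)) {
    list(f = f, b = b, ps_plus = pp, ps_minus = pm, ps = pp, location = imax / g)
  } else {
    list(f = f, b = b, ps_plus = pp, ps_minus = pm, ps = pm, location = imin / g)
  }
}

# full naive activity screen sharing the package's permutation plan
oracle_ras <- function(X, is_case, S, plan) {
  genes <- rownames(X)
  m <- length(plan)
  n_tf <- ncol(S)
  t_obs <- oracle_t(X, is_case)
  obs <- lapply(seq_len(n_tf), function(j) oracle_prescore(t_obs, genes, S[, j]))
  perm_plus <- matrix(NA_real_, m, n_tf)
  perm_minus <- matrix(NA_real_, m, n_tf)
  for (k in seq_len(m)) {
    tk <- oracle_t(X, plan[[k]])
    for (j in seq_len(n_tf)) {
      pr <- oracle_prescore(tk, genes, S[, j])
      perm_plus[k, j] <- pr$ps_plus
      perm_minus[k, j] <- pr$ps_minus
    }
  }
  ras <- p <- p1 <- numeric(n_tf)
  for (j in seq_len(n_tf)) {
    ps <- obs[[j]]$ps
    if (ps >= 0) {
      ras[j] <- ps / mean(perm_plus[, j])
      k <- sum(perm_plus[, j] >= ps)
    } else {
      ras[j] <- ps / abs(mean(perm_minus[, j]))
      k <- sum(perm_minus[, j] <= ps)
    }
    p[j] <- k / m
    p1[j] <- (k + 1) / (m + 1)
  }
  pool_plus <- c()
  pool_minus <- c()
  for (j in seq_len(n_tf)) {
    pool_plus <- c(pool_plus, perm_plus[, j] / mean(perm_plus[, j]))
    pool_minus <- c(pool_minus, perm_minus[, j] / abs(mean(perm_minus[, j])))
  }
  fdr <- numeric(n_tf)
  for (j in seq_len(n_tf)) {
    r <- ras[j]
    if (r >= 0) {
      num <- sum(pool_plus >= r) / length(pool_plus)
      den <- sum(ras[ras >= 0] >= r) / sum(ras >= 0)
    } else {
      num <- sum(pool_minus <= r) / length(pool_minus)
      den <- sum(ras[ras < 0] <= r) / sum(ras < 0)
    }
    fdr[j] <- min(num / den, 1)
  }
  data.frame(tf = colnames(S),
             ps = vapply(obs, function(x) x$ps, 1),
             ras = ras,
             location = vapply(obs, function(x) x$location, 1),
             p_value = p, p_value_addone = p1, fdr = fdr)
}

# all-pairs strand-oriented promoter overlap scan
oracle_peak_targets <- function(peaks, ann, upstream, downstream) {
  hit <- character(0)
  for (i in seq_len(nrow(ann))) {
    if (ann$strand[i] == "+") {
      lo <- ann$tss[i] - upstream
      hi <- ann$tss[i] + downstream
    } else {
      lo <- ann$tss[i] - downstream
      hi <- ann$tss[i] + upstream
    }
    for (j in seq_len(nrow(peaks))) {
      if (peaks$chrom[j] != ann$chrom[i]) next
      # peak covers bases [start, end - 1]; window covers [lo, hi]
      if (peaks$start[j] <= hi && (peaks$end[j] - 1) >= lo) {
        hit <- c(hit, ann$gene[i])
        break
      }
    }
  }
  sort(unique(hit))
}

rand_labels <- function(n1, n2) {
  tibble::tibble(
    sample = c(sprintf("a%02d", 1:n1), sprintf("b%02d", 1:n2)),
    group = rep(c("case", "control"), c(n1, n2))
  )
}

rand_instance <- function(g, n1, n2, n_tf, seed) {
  withr::with_seed(seed, {
    genes <- sprintf("g%03d", seq_len(g))
    X <- matrix(rnorm(g * (n1 + n2)), g,
                dimnames = list(genes, rand_labels(n1, n2)$sample))
    S <- matrix(runif(g * n_tf), g, dimnames = list(genes, sprintf("TF%02d", 1:n_tf)))
    list(X = X, S = S, labels = rand_labels(n1, n2))
  })
}
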