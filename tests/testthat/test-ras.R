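micro_ranked <- function() {
  # three genes already ordered t = (2, 1, -1) with potentials (1, 0, 0.5)
  rank_genes(tibble::tibble(gene = c("gA", "gB", "gC"), t = c(2, 1, -1)),
             tibble::tibble(gene = c("gA", "gB", "gC"), s = c(1, 0, 0.5)))
}

test_that("gene ranking sorts by decreasing t with deterministic tie-breaks", {
  ts <- tibble::tibble(gene = c("A", "B", "C"), t = c(1, 3, 2))
  S <- tibble::tibble(gene = c("A", "B", "C"), s = c(0.1, 0.2, 0.3))
  expect_equal(rank_genes(ts, S)$gene, c("B", "C", "A"))
  # ties break by gene id
  tie <- tibble::tibble(gene = c("B", "A"), t = c(2, 2))
  expect_equal(rank_genes(tie, S)$gene, c("A", "B"))
  # random input equals a stable reference sort
  withr::with_seed(51, {
    g <- sprintf("g%03d", sample(100))
    t <- round(rnorm(100), 1)  # force some ties
  })
  ranked <- rank_genes(tibble::tibble(gene = g, t = t),
                       tibble::tibble(gene = g, s = runif(100)))
  o <- order(-t, g)
  expect_equal(ranked$gene, g[o])
  expect_error(rank_genes(ts, tibble::tibble(gene = "zz", s = 1)), "shared")
})

test_that("running sums and pre-score reproduce the hand-worked micro-example", {
  rf <- running_sums(micro_ranked())
  expect_equal(rf$f, c(8 / 9, 8 / 9, 1), tolerance = 1e-12)
  expect_equal(rf$b, c(0, 2 / 3, 1), tolerance = 1e-12)
  ps <- pre_score(rf)
  expect_equal(ps$ps, 8 / 9, tolerance = 1e-12)
  expect_equal(ps$ps_plus, 8 / 9, tolerance = 1e-12)
  expect_equal(ps$ps_minus, 0)
  expect_equal(ps$location, 1 / 3)
})

test_that("running sums error on vanishing weight and equalize for constant potentials", {
  ts <- tibble::tibble(gene = c("A", "B"), t = c(1, -1))
  expect_error(running_sums(rank_genes(ts, tibble::tibble(gene = c("A", "B"), s = c(0, 0)))),
               "foreground")
  expect_error(running_sums(rank_genes(ts, tibble::tibble(gene = c("A", "B"), s = c(1, 1)))),
               "background")
  rf <- running_sums(rank_genes(ts, tibble::tibble(gene = c("A", "B"), s = c(0.3, 0.3))))
  expect_equal(rf$f, rf$b, tolerance = 1e-12)
  expect_equal(pre_score(rf)$ps, 0, tolerance = 1e-12)
})

test_that("pre-score is antisymmetric under t-profile negation (tie-free)", {
  withr::with_seed(52, {
    for (rep in 1:20) {
      g <- 30
      genes <- sprintf("g%02d", 1:g)
      t <- rnorm(g)
      s <- runif(g)
      ps <- pre_score(running_sums(rank_genes(
        tibble::tibble(gene = genes, t = t), tibble::tibble(gene = genes, s = s))))
      nps <- pre_score(running_sums(rank_genes(
        tibble::tibble(gene = genes, t = -t), tibble::tibble(gene = genes, s = s))))
      expect_equal(nps$ps_plus, -ps$ps_minus, tolerance = 1e-12)
      expect_equal(nps$ps_minus, -ps$ps_plus, tolerance = 1e-12)
    }
  })
})

test_that("balanced permutation draws half of each group into the shuffled cases", {
  labs <- rand_labels(4, 6)
  perm <- balanced_permutation(labs, seed = 7)
  new_case <- perm$sample[perm$group == "case"]
  expect_length(new_case, 5)
  expect_equal(sum(grepl("^a", new_case)), 2)
  expect_equal(sum(grepl("^b", new_case)), 3)

  tiny <- balanced_permutation(rand_labels(2, 2), seed = 1)
  expect_equal(sum(grepl("^a", tiny$sample[tiny$group == "case"])), 1)

  one <- tibble::tibble(sample = c("a1", "b1", "b2"),
                        group = c("case", "control", "control"))
  expect_error(balanced_permutation(one), "allow_unbalanced")
  free <- balanced_permutation(one, seed = 2, allow_unbalanced = TRUE)
  expect_equal(sum(free$group == "case"), 1)

  # selection frequencies match the n/2 draw probabilities (binomial 3 sigma)
  labs2 <- rand_labels(4, 6)
  n_draw <- 10000
  counts <- setNames(numeric(10), labs2$sample)
  withr::with_seed(99, {
    for (k in seq_len(n_draw)) {
      p <- balanced_permutation(labs2)
      cs <- p$sample[p$group == "case"]
      counts[cs] <- counts[cs] + 1
    }
  })
  for (s in labs2$sample) {
    pr <- if (grepl("^a", s)) 2 / 4 else 3 / 6
    se <- sqrt(pr * (1 - pr) / n_draw)
    expect_lt(abs(counts[[s]] / n_draw - pr), 3 * se + 1e-9)
  }
})

test_that("permutation nulls are deterministic under a seed", {
  inst <- rand_instance(40, 5, 5, 2, seed = 61)
  expr <- dplyr::bind_cols(tibble::tibble(gene = rownames(inst$X)),
                           tibble::as_tibble(inst$X))
  S <- dplyr::bind_cols(tibble::tibble(gene = rownames(inst$S)),
                        tibble::as_tibble(inst$S))
  n1 <- ras_null(expr, inst$labels, S, m = 25, seed = 17)
  n2 <- ras_null(expr, inst$labels, S, m = 25, seed = 17)
  expect_identical(n1$perm_plus, n2$perm_plus)
  expect_identical(n1$perm_minus, n2$perm_minus)
  expect_true(all(n1$perm_plus >= 0))
  expect_true(all(n1$perm_minus <= 0))
})

test_that("normalization, empirical p and pooled FDR match counting oracles", {
  expect_equal(normalize_ras(0.3, perm_plus = c(0.1, 0.1, 0.1), perm_minus = -1), 3)
  expect_equal(normalize_ras(-0.2, perm_plus = 1, perm_minus = c(-0.1, -0.1)), -2)
  expect_warning(expect_true(is.na(normalize_ras(0.2, perm_plus = c(0, 0),
                                                 perm_minus = -1))), "null mean")

  nullp <- c(0.1, 0.2, 0.3)
  expect_equal(empirical_pvalue(0.25, nullp, -nullp)$p_value, 1 / 3)
  expect_equal(empirical_pvalue(0.4, nullp, -nullp)$p_value, 0)
  expect_equal(empirical_pvalue(0.4, nullp, -nullp)$p_value_addone, 1 / 4)
  expect_equal(empirical_pvalue(0.1, nullp, -nullp)$p_value, 1)
  expect_equal(empirical_pvalue(-0.25, nullp, -nullp)$p_value, 1 / 3)

  # hand-built pooled FDR: per-profile normalized nulls pool to
  # (0.5, 1.5, 0.5, 1.5); observed scores (3, 1)
  pp <- cbind(TF1 = c(0.5, 1.5), TF2 = c(1, 3))
  pm <- -pp
  fdr <- pooled_fdr(c(TF1 = 3, TF2 = 1), pp, pm)
  expect_equal(unname(fdr), c(0 / (1 / 2), (2 / 4) / 1))

  # random instance vs loop oracle, including the cap at 1 and monotonicity
  withr::with_seed(71, {
    m <- 40; k <- 6
    perm_plus <- matrix(rexp(m * k, 10), m, k, dimnames = list(NULL, paste0("T", 1:k)))
    perm_minus <- -matrix(rexp(m * k, 10), m, k, dimnames = list(NULL, paste0("T", 1:k)))
    obs <- setNames(rnorm(k, 0, 2), paste0("T", 1:k))
  })
  got <- pooled_fdr(obs, perm_plus, perm_minus)
  poolp <- as.vector(sweep(perm_plus, 2, colMeans(perm_plus), "/"))
  poolm <- as.vector(sweep(perm_minus, 2, abs(colMeans(perm_minus)), "/"))
  for (j in seq_len(k)) {
    r <- obs[j]
    if (r >= 0) {
      expe <- min((sum(poolp >= r) / length(poolp)) /
                    (sum(obs[obs >= 0] >= r) / sum(obs >= 0)), 1)
    } else {
      expe <- min((sum(poolm <= r) / length(poolm)) /
                    (sum(obs[obs < 0] <= r) / sum(obs < 0)), 1)
    }
    expect_equal(unname(got[j]), expe, tolerance = 1e-12)
  }
  expect_true(all(got <= 1))
})

test_that("the activity screen is invariant to gene order and potential duplication", {
  inst <- rand_instance(60, 6, 6, 2, seed = 81)
  expr <- dplyr::bind_cols(tibble::tibble(gene = rownames(inst$X)),
                           tibble::as_tibble(inst$X))
  Sdup <- tibble::tibble(gene = rownames(inst$S),
                         TFa = inst$S[, 1], TFb = inst$S[, 1])
  res <- ras(expr, Sdup, inst$labels, m = 30, seed = 5)
  expect_equal(res$ras[res$tf == "TFa"], res$ras[res$tf == "TFb"])
  expect_equal(res$fdr[res$tf == "TFa"], res$fdr[res$tf == "TFb"])

  # permuting gene order of both inputs consistently changes nothing
  perm <- withr::with_seed(9, sample(60))
  res2 <- ras(expr[perm, ], Sdup[perm, ], inst$labels, m = 30, seed = 5)
  expect_equal(tidy(res2), tidy(res), tolerance = 1e-12)
})

test_that("injected factor activity is recovered with the right sign", {
  cfg <- sim_config(n_genes = 500, n_tfs = 5, n_case = 12, n_control = 12,
                    active_tfs = c(TF02 = 1.5), value_type = "relative", seed = 13)
  st <- simulate_study(cfg)
  res <- ras(st$expression, st$potentials, st$labels, m = 60, seed = 13)
  expect_equal(res$tf[1], "TF02")
  expect_gt(res$ras[1], 0)
  expect_lte(res$p_value[1], 0.05)
  expect_true(res$fdr[res$tf == "TF02"] <= min(res$fdr))

  # a down-shift flips the sign
  cfg2 <- sim_config(n_genes = 500, n_tfs = 5, n_case = 12, n_control = 12,
                     active_tfs = c(TF02 = -1.5), value_type = "relative", seed = 14)
  st2 <- simulate_study(cfg2)
  res2 <- ras(st2$expression, st2$potentials, st2$labels, m = 60, seed = 14)
  expect_equal(res2$tf[1], "TF02")
  expect_lt(res2$ras[1], 0)
})

test_that("degenerate potential columns are reported, not fatal", {
  inst <- rand_instance(30, 4, 4, 1, seed = 91)
  expr <- dplyr::bind_cols(tibble::tibble(gene = rownames(inst$X)),
                           tibble::as_tibble(inst$X))
  S <- tibble::tibble(gene = rownames(inst$X), ok = inst$S[, 1],
                      dead = rep(0, 30))
  res <- suppressWarnings(ras(expr, S, inst$labels, m = 10, seed = 3))
  expect_true(is.na(res$ras[res$tf == "dead"]))
  expect_match(res$note[res$tf == "dead"], "all zero")
  expect_false(is.na(res$ras[res$tf == "ok"]))
})
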