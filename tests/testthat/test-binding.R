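make_track <- function(start, values, chrom = "chr1") {
  pos <- start + seq_along(values) - 1L
  tibble::tibble(chrom = chrom, start = pos, end = pos + 1L, value = values)
}

test_that("characteristic profile recovers an identical bump and flattens uniform coverage", {
  W <- 100
  bump <- exp(-(seq(-W, W))^2 / (2 * 20^2))
  tss <- c(500L, 3000L, 7000L)
  ann <- tibble::tibble(gene = c("gA", "gB", "gC"), chrom = "chr1",
                        tss = tss, strand = "+")
  track <- dplyr::bind_rows(lapply(tss, function(p) make_track(p - W, bump)))
  prof <- tss_binding_profile(track, ann, half_window = W)
  expect_equal(prof$weight, bump / sum(bump), tolerance = 1e-12)
  expect_equal(sum(prof$weight), 1)

  flat <- tibble::tibble(chrom = "chr1", start = 0L, end = 10000L, value = 2)
  prof_flat <- tss_binding_profile(flat, ann, half_window = W)
  expect_equal(prof_flat$weight, rep(1 / (2 * W + 1), 2 * W + 1), tolerance = 1e-12)
})

test_that("characteristic profile equals the per-gene window-averaging oracle", {
  W <- 50
  n <- 50
  withr::with_seed(11, {
    tss <- sort(sample(seq(200L, 60000L, by = 150L), n))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    amp <- rlnorm(n, 2, 0.5)
  })
  ann <- tibble::tibble(gene = sprintf("g%02d", 1:n), chrom = "chr1",
                        tss = tss, strand = strand)
  offs <- seq(-W, W)
  segs <- withr::with_seed(12, lapply(seq_len(n), function(i) {
    vals <- amp[i] * exp(-offs^2 / (2 * 15^2)) + runif(2 * W + 1, 0, 0.5)
    make_track(tss[i] - W, vals)
  }))
  track <- dplyr::bind_rows(segs)
  prof <- tss_binding_profile(track, ann, half_window = W)

  # loop oracle: extract each oriented window directly, scale, average
  by_pos <- setNames(numeric(0), character(0))
  get_cov <- function(p) {
    row <- track[track$start <= p & track$end > p, ]
    if (nrow(row) == 0) 0 else row$value[1]
  }
  mat <- matrix(0, n, 2 * W + 1)
  for (i in seq_len(n)) {
    pos <- if (strand[i] == "+") tss[i] + offs else tss[i] - offs
    mat[i, ] <- vapply(pos, get_cov, 1)
    mat[i, ] <- mat[i, ] / sum(mat[i, ])
  }
  expected <- colMeans(mat)
  expect_equal(prof$weight, expected / sum(expected), tolerance = 1e-10)
})

test_that("binding affinity is the profile-weighted window coverage", {
  W <- 20
  ann <- tibble::tibble(gene = c("g1", "g2"), chrom = "chr1",
                        tss = c(100L, 400L), strand = c("+", "-"))
  flat_prof <- tibble::tibble(offset = seq(-W, W), weight = rep(1 / (2 * W + 1), 2 * W + 1))

  # flat profile => window mean coverage
  vals <- withr::with_seed(3, runif(2 * W + 1, 0, 5))
  track <- make_track(100L - W, vals)
  aff <- suppressWarnings(binding_affinity(track, ann, flat_prof))
  expect_equal(aff$affinity[1], mean(vals), tolerance = 1e-12)
  expect_equal(aff$affinity[2], 0)  # zero coverage at g2's window

  # random profile: dot-product oracle, including a minus-strand gene
  w <- withr::with_seed(4, runif(2 * W + 1))
  prof <- tibble::tibble(offset = seq(-W, W), weight = w / sum(w))
  track2 <- dplyr::bind_rows(make_track(100L - W, vals),
                             make_track(400L - W, rev(vals)))
  aff2 <- binding_affinity(track2, ann, prof)
  get_cov <- function(p) {
    row <- track2[track2$start <= p & track2$end > p, ]
    if (nrow(row) == 0) 0 else row$value[1]
  }
  for (i in 1:2) {
    pos <- if (ann$strand[i] == "+") ann$tss[i] + prof$offset else ann$tss[i] - prof$offset
    expect_equal(aff2$affinity[i], sum(prof$weight * vapply(pos, get_cov, 1)),
                 tolerance = 1e-12)
  }

  # gene on a chromosome absent from the track scores zero with a warning
  ann3 <- tibble::tibble(gene = "g3", chrom = "chrX", tss = 100L, strand = "+")
  expect_warning(a3 <- binding_affinity(track, ann3, flat_prof), "absent")
  expect_equal(a3$affinity, 0)
})

test_that("z-scores standardize columns and tolerate degenerate ones", {
  aff <- tibble::tibble(gene = c("g1", "g2", "g3"), p1 = c(1, 2, 3), p2 = c(5, 5, 5))
  expect_warning(z <- affinity_zscores(aff), "constant")
  expect_equal(z$p1, c(-1, 0, 1))
  expect_equal(z$p2, c(0, 0, 0))

  withr::with_seed(8, {
    a <- rnorm(100, 5, 3)
    tib <- tibble::tibble(gene = sprintf("g%03d", 1:100), p = a)
    zz <- affinity_zscores(tib)
    expect_equal(zz$p, (a - mean(a)) / sd(a), tolerance = 1e-12)
    # invariance under shift and positive scaling
    expect_equal(affinity_zscores(dplyr::mutate(tib, p = 3 * p + 7))$p, zz$p,
                 tolerance = 1e-12)
  })
})

test_that("potential transform caps at 10, scales to [0,1] and matches a loop oracle", {
  z <- tibble::tibble(gene = c("g1", "g2", "g3"),
                      p1 = c(0, 2, 40), p2 = c(-1, 1, 3))
  s <- potentials_from_zscores(z, cap = 10)
  M <- as.matrix(s[, -1])
  # stepwise loop oracle
  zm <- as.matrix(z[, -1])
  sp <- matrix(0, 3, 2)
  for (i in 1:3) for (j in 1:2) {
    p <- pnorm(zm[i, j], lower.tail = FALSE)
    sp[i, j] <- min(-log10(p), 10)
  }
  expected <- (sp - min(sp)) / (max(sp) - min(sp))
  expect_equal(unname(M), expected, tolerance = 1e-12)
  # z = 40 underflows the normal tail -> capped exactly at 10 -> global max 1
  expect_equal(sp[3, 1], 10)
  expect_equal(unname(M[3, 1]), 1)
  expect_equal(min(M), 0)
  # z = 0 corresponds to -log10(0.5) before scaling
  expect_equal(sp[1, 1], -log10(0.5), tolerance = 1e-12)
  expect_error(potentials_from_zscores(tibble::tibble(gene = c("a", "b"),
                                                      p = c(0, 0))),
               "undefined")
})

test_that("promoter targets honour strand-oriented windows", {
  ann <- tibble::tibble(gene = c("plus", "minus"), chrom = "chr1",
                        tss = c(10000L, 10000L), strand = c("+", "-"))
  # within 1000 bp upstream of the + gene
  expect_equal(promoter_targets(tibble::tibble(chrom = "chr1", start = 9400L, end = 9500L),
                                ann[1, ])$gene, "plus")
  # beyond 500 bp downstream of the + gene
  expect_equal(nrow(promoter_targets(tibble::tibble(chrom = "chr1", start = 10600L, end = 10700L),
                                     ann[1, ])), 0)
  # the same peak is 600 bp upstream of the - gene
  expect_equal(promoter_targets(tibble::tibble(chrom = "chr1", start = 10600L, end = 10700L),
                                ann[2, ])$gene, "minus")
  expect_error(promoter_targets(tibble::tibble(chrom = "chr1", start = 50L, end = 50L),
                                ann), "line 1")
})

test_that("coverage and annotation round-trip through their file formats", {
  dir <- withr::local_tempdir()
  track <- make_track(100L, c(1, 1, 2, 3, 3, 3))
  p <- file.path(dir, "cov.bedgraph")
  write_coverage(track, p)
  back <- read_coverage(p)
  # merged runs expand to the same per-base values
  probe <- tibble::tibble(gene = "g1", chrom = "chr1", tss = 102L, strand = "+")
  prof <- tibble::tibble(offset = -2:2, weight = rep(0.2, 5))
  expect_equal(binding_affinity(back, probe, prof)$affinity,
               binding_affinity(track, probe, prof)$affinity)

  ann <- tibble::tibble(gene = c("gA", "gB"), chrom = "chr1",
                        tss = c(100L, 250L), strand = c("+", "-"))
  ap <- file.path(dir, "ann.tsv")
  readr::write_tsv(ann, ap)
  expect_equal(read_gene_annotation(ap), ann)
})
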