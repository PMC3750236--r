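#' Validate a coverage track
#'
#' A coverage track is a tibble of non-overlapping, sorted genomic intervals
#' with a read-depth value per interval: columns `chrom`, `start`, `end`
#' (0-based, half-open) and `value` (non-negative). This is the in-memory form
#' of a bedGraph/wiggle file.
#'
#' @param x A data frame with columns `chrom`, `start`, `end`, `value`.
#' @return The validated track as a tibble, sorted by chromosome and start.
#' @export
coverage_track <- function(x) {
  need <- c("chrom", "start", "end", "value")
  if (!all(need %in% names(x))) {
    abort("coverage track needs columns chrom, start, end, value")
  }
  x <- as_tibble(x[need])
  if (any(x$value < 0)) abort("coverage values must be non-negative")
  if (any(x$end <= x$start)) abort("coverage intervals must satisfy end > start")
  x <- arrange(x, .data$chrom, .data$start)
  overlap <- x |>
    group_by(.data$chrom) |>
    summarise(bad = any(.data$start[-1] < .data$end[-length(.data$end)])) |>
    pull(.data$bad)
  if (any(overlap)) abort("coverage intervals overlap within a chromosome")
  x
}

#' Read a coverage track from bedGraph, wiggle or bigWig
#'
#' @param path Path to a `.bedgraph`/`.bdg`, `.wig` or `.bw`/`.bigwig` file.
#' @param format Override the extension-based format guess
#'   (`"bedGraph"`, `"wig"` or `"BigWig"`).
#' @return A coverage track tibble (see [coverage_track()]), 0-based half-open.
#' @export
read_coverage <- function(path, format = NULL) {
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      bedgraph = , bdg = , bg = "bedGraph",
      wig = "wig",
      bw = , bigwig = "BigWig",
      abort(sprintf("cannot guess coverage format from extension '%s'", ext))
    )
  }
  gr <- rtracklayer::import(path, format = format)
  coverage_track(tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    value = as.numeric(gr$score)
  ))
}

#' Write a coverage track as bedGraph
#'
#' Adjacent intervals with identical values are merged before writing.
#'
#' @param track A coverage track tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(track, path) {
  track <- coverage_track(track)
  merged <- track |>
    group_by(.data$chrom) |>
    mutate(run = cumsum(c(TRUE, .data$value[-1] != .data$value[-n()] |
                            .data$start[-1] != .data$end[-n()]))) |>
    group_by(.data$chrom, .data$run) |>
    summarise(start = min(.data$start), end = max(.data$end),
              value = .data$value[1], .groups = "drop") |>
    arrange(.data$chrom, .data$start) |>
    select("chrom", "start", "end", "value")
  readr::write_tsv(merged, path, col_names = FALSE)
  invisible(path)
}

#' Read a gene annotation (TSS table)
#'
#' Accepts a refFlat-like TSV with columns `gene`, `chrom`, `strand`, `tss`
#' (header required) or a BED6 file whose thickStart-free 6 columns are
#' chrom/start/end/name/score/strand, where the TSS is taken as `start` on
#' `+` genes and `end - 1` on `-` genes.
#'
#' @param path Path to the annotation file.
#' @return A tibble with columns `gene`, `chrom`, `tss` (0-based), `strand`.
#' @export
read_gene_annotation <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("gene", first) && grepl("tss", first)) {
    ann <- readr::read_tsv(path, show_col_types = FALSE)
    ann <- select(ann, "gene", "chrom", "tss", "strand")
  } else {
    bed <- readr::read_tsv(path, col_names = c("chrom", "start", "end",
                                               "gene", "score", "strand"),
                           show_col_types = FALSE)
    ann <- tibble(
      gene = as.character(bed$gene), chrom = bed$chrom,
      tss = ifelse(bed$strand == "+", bed$start, bed$end - 1L),
      strand = bed$strand
    )
  }
  gene_annotation(ann)
}

#' Validate a gene annotation tibble
#'
#' @param x Data frame with columns `gene`, `chrom`, `tss`, `strand`.
#' @return Validated tibble.
#' @export
gene_annotation <- function(x) {
  need <- c("gene", "chrom", "tss", "strand")
  if (!all(need %in% names(x))) abort("annotation needs columns gene, chrom, tss, strand")
  x <- as_tibble(x[need])
  x$gene <- as.character(x$gene)
  if (anyDuplicated(x$gene)) abort("gene ids must be unique in an annotation set")
  if (any(x$tss < 0)) abort("tss coordinates must be >= 0")
  if (!all(x$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  x
}

# coverage values at 0-based positions on one chromosome; off-track = 0
cov_values_chr <- function(track_chr, pos) {
  out <- numeric(length(pos))
  if (nrow(track_chr) == 0) return(out)
  idx <- findInterval(pos, track_chr$start)
  hit <- idx > 0
  hit[hit] <- pos[hit] < track_chr$end[idx[hit]]
  out[hit] <- track_chr$value[idx[hit]]
  out
}

# oriented window positions: offset o maps to tss + o (+ strand) / tss - o (-)
window_positions <- function(tss, strand, offsets) {
  if (strand == "+") tss + offsets else tss - offsets
}

# genes x (2W+1) matrix of strand-oriented window coverage
window_matrix <- function(coverage, annotation, half_window, warn_missing = FALSE) {
  offsets <- seq.int(-half_window, half_window)
  by_chr <- split(coverage, coverage$chrom)
  missing_chr <- setdiff(unique(annotation$chrom), names(by_chr))
  if (warn_missing && length(missing_chr) > 0) {
    warn(sprintf("chromosome(s) absent from coverage, scored as zero: %s",
                 paste(missing_chr, collapse = ", ")))
  }
  W <- matrix(0, nrow(annotation), length(offsets),
              dimnames = list(annotation$gene, offsets))
  for (i in seq_len(nrow(annotation))) {
    chr <- annotation$chrom[i]
    if (!chr %in% names(by_chr)) next
    pos <- window_positions(annotation$tss[i], annotation$strand[i], offsets)
    W[i, ] <- cov_values_chr(by_chr[[chr]], pos)
  }
  W
}

#' Build a characteristic TSS binding profile
#'
#' Averages strand-oriented coverage windows around every annotated TSS into a
#' single characteristic profile of where a factor binds relative to
#' transcription start. Each gene's window is scaled to sum to one before
#' averaging so highly covered genes do not dominate; genes with all-zero
#' windows contribute zero rows. The returned profile is normalized to sum
#' to one.
#'
#' @param coverage A coverage track tibble.
#' @param annotation A gene annotation tibble (see [gene_annotation()]).
#' @param half_window Half-width of the TSS window in bp (default 10000).
#' @return A tibble with columns `offset` (relative to TSS, 5'->3' of the
#'   gene) and `weight` (non-negative, summing to 1).
#' @export
tss_binding_profile <- function(coverage, annotation, half_window = 10000) {
  stopifnot(half_window >= 1)
  coverage <- coverage_track(coverage)
  annotation <- gene_annotation(annotation)
  W <- window_matrix(coverage, annotation, half_window)
  sums <- rowSums(W)
  scaled <- W
  nz <- sums > 0
  scaled[nz, ] <- W[nz, , drop = FALSE] / sums[nz]
  prof <- unname(colMeans(scaled))
  tot <- sum(prof)
  if (tot <= 0) abort("no usable gene windows: all coverage windows are zero")
  tibble(offset = seq.int(-half_window, half_window), weight = prof / tot)
}

#' Score per-gene binding affinity with a characteristic profile
#'
#' Weights the coverage in each gene's strand-oriented TSS window by the
#' characteristic profile: `a_i = sum_o weight(o) * coverage(tss_i +/- o)`.
#' Positions beyond chromosome bounds (or off the track) count as zero
#' coverage; genes on chromosomes absent from the track score zero with a
#' warning.
#'
#' @param coverage A coverage track tibble.
#' @param annotation A gene annotation tibble.
#' @param profile Profile tibble from [tss_binding_profile()]; its `weight`
#'   column must sum to 1.
#' @return A tibble with columns `gene` and `affinity`.
#' @export
binding_affinity <- function(coverage, annotation, profile) {
  coverage <- coverage_track(coverage)
  annotation <- gene_annotation(annotation)
  if (!all(c("offset", "weight") %in% names(profile))) {
    abort("profile needs columns offset and weight")
  }
  if (abs(sum(profile$weight) - 1) > 1e-8) abort("profile weights must sum to 1")
  half_window <- (nrow(profile) - 1L) %/% 2L
  W <- window_matrix(coverage, annotation, half_window, warn_missing = TRUE)
  tibble(gene = annotation$gene, affinity = as.numeric(W %*% profile$weight))
}

#' Column-standardize a binding-affinity matrix
#'
#' For each binding profile (column), computes `z = (a - mean(a)) / sd(a)`
#' across genes, with the sample standard deviation (n - 1 denominator).
#' A constant column is mapped to all-zero z-scores with a warning: such a
#' profile carries no information to distinguish genes.
#'
#' @param affinity A tibble whose first column is `gene` and remaining columns
#'   are per-profile binding affinities (or a matrix with gene rownames).
#' @return A tibble of the same shape holding z-scores.
#' @export
affinity_zscores <- function(affinity) {
  A <- tfa_matrix(affinity, "affinity")
  if (nrow(A) < 2) abort("need at least 2 genes per profile to standardize")
  mu <- colMeans(A)
  sdev <- apply(A, 2, sd)
  Z <- sweep(A, 2, mu, "-")
  flat <- sdev == 0
  if (any(flat)) {
    warn(sprintf("constant affinity column(s) set to z = 0: %s",
                 paste(colnames(A)[flat], collapse = ", ")))
    sdev[flat] <- 1  # numerator already all zero
  }
  Z <- sweep(Z, 2, sdev, "/")
  tfa_tibble(Z)
}

#' Transform z-scores into regulatory potentials
#'
#' Converts each z-score to an upper-tail standard-normal p-value (strong
#' binding gives a small p), takes `-log10(p)` truncated at `cap`, then
#' min-max scales over the whole matrix so the global minimum is 0 and the
#' global maximum is 1. The result is a probability-like regulatory potential
#' per gene and binding profile.
#'
#' @param zscores Tibble (`gene` + profile columns) or matrix of z-scores.
#' @param cap Truncation for `-log10(p)` (default 10); guards against extreme
#'   values dominating downstream running sums.
#' @return A `tf_potentials` tibble (`gene` + profile columns, values in
#'   \[0, 1\]) with attributes `cap` and the pre-scaling extrema.
#' @export
potentials_from_zscores <- function(zscores, cap = 10) {
  Z <- tfa_matrix(zscores, "z-score")
  if (any(!is.finite(Z))) abort("z-scores must be finite")
  P <- pnorm(Z, lower.tail = FALSE)
  Sp <- pmin(-log10(P), cap)
  lo <- min(Sp)
  hi <- max(Sp)
  if (hi == lo) abort("all transformed scores identical; min-max normalization undefined")
  S <- (Sp - lo) / (hi - lo)
  out <- tfa_tibble(S)
  class(out) <- c("tf_potentials", class(out))
  attr(out, "cap") <- cap
  attr(out, "tail") <- "upper"
  attr(out, "extrema") <- c(min = lo, max = hi)
  out
}

#' Binding affinities to regulatory potentials in one step
#'
#' Convenience wrapper: [affinity_zscores()] then [potentials_from_zscores()].
#'
#' @inheritParams affinity_zscores
#' @inheritParams potentials_from_zscores
#' @return A `tf_potentials` tibble.
#' @export
affinity_to_potentials <- function(affinity, cap = 10) {
  potentials_from_zscores(affinity_zscores(affinity), cap = cap)
}

#' Write / read a regulatory-potential matrix
#'
#' The matrix is written as TSV (gene column + one column per profile) with a
#' YAML sidecar (`<path>.meta.yaml`) recording the log-p cap, the normal-tail
#' choice and the pre-scaling extrema.
#'
#' @param potentials A `tf_potentials` tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_potentials <- function(potentials, path) {
  readr::write_tsv(potentials, path)
  meta <- list(
    cap = attr(potentials, "cap"),
    tail = attr(potentials, "tail") %||% "upper",
    extrema = as.list(attr(potentials, "extrema"))
  )
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname write_potentials
#' @export
read_potentials <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  class(out) <- c("tf_potentials", class(out))
  meta_path <- paste0(path, ".meta.yaml")
  if (file.exists(meta_path)) {
    meta <- yaml::read_yaml(meta_path)
    attr(out, "cap") <- meta$cap
    attr(out, "tail") <- meta$tail
    attr(out, "extrema") <- unlist(meta$extrema)
  }
  out
}

#' Read BED peak calls
#'
#' @param path BED3+ file.
#' @return Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @export
read_peaks <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

#' Promoter-window peak targets
#'
#' A gene is a target of a factor if at least one peak overlaps its promoter
#' window, `upstream` bp towards the gene's 5' end to `downstream` bp towards
#' its 3' end of the TSS. The window is strand-oriented: on `-` genes
#' "upstream" extends to higher coordinates. Intervals are 0-based half-open;
#' the window covers the closed base range `[tss - upstream, tss + downstream]`
#' in oriented coordinates and any shared base counts as an overlap.
#'
#' @param peaks Tibble of peaks (`chrom`, `start`, `end`; 0-based half-open).
#' @param annotation A gene annotation tibble.
#' @param upstream Window extent 5' of the TSS in bp (default 1000).
#' @param downstream Window extent 3' of the TSS in bp (default 500).
#' @return A tibble with columns `gene` and `n_peaks` (one row per target
#'   gene, sorted by gene id).
#' @export
promoter_targets <- function(peaks, annotation, upstream = 1000, downstream = 500) {
  stopifnot(upstream >= 0, downstream >= 0)
  annotation <- gene_annotation(annotation)
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(peaks))) abort("peaks need columns chrom, start, end")
  bad <- which(peaks$end <= peaks$start)
  if (length(bad) > 0) {
    abort(sprintf("malformed peak interval (end <= start) at line %d", bad[1]))
  }
  win_lo <- ifelse(annotation$strand == "+",
                   annotation$tss - upstream, annotation$tss - downstream)
  win_hi <- ifelse(annotation$strand == "+",
                   annotation$tss + downstream, annotation$tss + upstream)
  hits <- integer(nrow(annotation))
  for (chr in unique(annotation$chrom)) {
    gi <- which(annotation$chrom == chr)
    pk <- peaks[peaks$chrom == chr, , drop = FALSE]
    if (nrow(pk) == 0) next
    # 0-based closed base p <-> 1-based coordinate p + 1
    gene_ir <- IRanges::IRanges(start = win_lo[gi] + 1L, end = win_hi[gi] + 1L)
    peak_ir <- IRanges::IRanges(start = pk$start + 1L, end = pk$end)
    ov <- IRanges::countOverlaps(gene_ir, peak_ir)
    hits[gi] <- ov
  }
  tibble(gene = annotation$gene, n_peaks = hits) |>
    filter(.data$n_peaks > 0) |>
    arrange(.data$gene)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
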