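#' Simulation configuration
#'
#' Bundles every knob of the seeded fixture generators. Defaults describe a
#' moderate two-arm microarray study: 2000 genes, 20 factor profiles, 20
#' case and 20 control samples, one active factor whose high-potential genes
#' shift by one within-group standard deviation in cases.
#'
#' @param n_genes,n_tfs,n_case,n_control Problem sizes.
#' @param active_tfs Named numeric vector: names are profile labels (must
#'   exist among the `n_tfs` generated, `TF01`, `TF02`, ...), values are
#'   effect sizes in units of the within-group expression sd (sign = up/down
#'   regulation in cases). Use `numeric(0)` for a global null.
#' @param potential_quantile Genes with potential at or above this quantile
#'   of an active profile receive the shift (default 0.9, the top decile).
#' @param potential_shape1,potential_shape2 Beta parameters of raw
#'   potentials; the defaults put heavy mass near 0 with a thin upper tail,
#'   mimicking sparse genome-wide binding.
#' @param noise_sd Within-group sd of log10 expression (default 0.3).
#' @param baseline_mean,baseline_sd Per-gene baseline log10 expression level
#'   distribution.
#' @param value_type `"absolute"` (intensities `10^x`) or `"relative"`
#'   (mean-centred log10 values emitted directly).
#' @param coverage_background,peak_height,peak_sd,gene_spacing,target_fraction
#'   Coverage-track generator: flat background depth, mean bump amplitude,
#'   bump sd in bp, spacing between simulated TSSs, fraction of genes that
#'   are binding targets.
#' @param baseline_hazard,survival_beta,censor_rate Survival generator:
#'   exponential baseline hazard, log-hazard coefficient on the designated
#'   activity, independent exponential censoring rate.
#' @param seed Mandatory integer seed; every generator derives its stream
#'   from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000, n_tfs = 20, n_case = 20, n_control = 20,
                       active_tfs = c(TF01 = 1), potential_quantile = 0.9,
                       potential_shape1 = 0.5, potential_shape2 = 4,
                       noise_sd = 0.3, baseline_mean = 2, baseline_sd = 0.5,
                       value_type = c("absolute", "relative"),
                       coverage_background = 1, peak_height = 20,
                       peak_sd = 100, gene_spacing = 5000,
                       target_fraction = 0.3,
                       baseline_hazard = 0.1, survival_beta = 0.5,
                       censor_rate = 0.02, seed = 1) {
  value_type <- match.arg(value_type)
  stopifnot(n_genes >= 1, n_tfs >= 1, n_case >= 1, n_control >= 1,
            all(is.finite(active_tfs)), length(seed) == 1, is.finite(seed))
  cfg <- list(
    n_genes = n_genes, n_tfs = n_tfs, n_case = n_case, n_control = n_control,
    active_tfs = active_tfs, potential_quantile = potential_quantile,
    potential_shape1 = potential_shape1, potential_shape2 = potential_shape2,
    noise_sd = noise_sd, baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    value_type = value_type,
    coverage_background = coverage_background, peak_height = peak_height,
    peak_sd = peak_sd, gene_spacing = gene_spacing,
    target_fraction = target_fraction,
    baseline_hazard = baseline_hazard, survival_beta = survival_beta,
    censor_rate = censor_rate, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

tf_ids <- function(n) sprintf("TF%02d", seq_len(n))
gene_ids <- function(n) sprintf("g%05d", seq_len(n))

#' Simulate a regulatory-potential matrix
#'
#' Draws Beta-distributed potentials per profile (heavy mass near zero, thin
#' upper tail) and min-max rescales the whole matrix so the global extrema
#' are exactly 0 and 1, matching the contract of [potentials_from_zscores()].
#'
#' @param cfg A [sim_config()].
#' @return A `tf_potentials` tibble.
#' @export
simulate_potentials <- function(cfg) {
  withr::with_seed(tfa_child_seed(cfg$seed, 1L), {
    S <- matrix(rbeta(cfg$n_genes * cfg$n_tfs, cfg$potential_shape1,
                      cfg$potential_shape2),
                cfg$n_genes, cfg$n_tfs,
                dimnames = list(gene_ids(cfg$n_genes), tf_ids(cfg$n_tfs)))
    S <- (S - min(S)) / (max(S) - min(S))
    out <- tfa_tibble(S)
    class(out) <- c("tf_potentials", class(out))
    attr(out, "cap") <- NA_real_
    out
  })
}

#' Simulate case-control expression with injected factor activity
#'
#' Baseline log10 expression is Gaussian per gene (`baseline_mean`,
#' `baseline_sd`) plus within-group noise of sd `noise_sd`. For each active
#' profile, genes whose potential is at or above `potential_quantile` are
#' shifted by `effect * noise_sd` (on the log10 scale) in case samples only.
#' `value_type = "absolute"` emits `10^x` intensities; `"relative"` emits
#' mean-centred log10 values directly.
#'
#' @param cfg A [sim_config()].
#' @param potentials Output of [simulate_potentials()] (defines which genes
#'   each active profile shifts).
#' @return A list: `expression` tibble, `labels` tibble, `shifted_genes`
#'   (named list per active profile) and `value_type`.
#' @export
simulate_expression <- function(cfg, potentials) {
  S <- tfa_matrix(potentials, "potential")
  stopifnot(nrow(S) == cfg$n_genes)
  n <- cfg$n_case + cfg$n_control
  samples <- c(sprintf("case_%02d", seq_len(cfg$n_case)),
               sprintf("ctrl_%02d", seq_len(cfg$n_control)))
  labels <- tibble(sample = samples,
                   group = rep(c("case", "control"), c(cfg$n_case, cfg$n_control)))
  withr::with_seed(tfa_child_seed(cfg$seed, 2L), {
    base <- rnorm(cfg$n_genes, cfg$baseline_mean, cfg$baseline_sd)
    X <- matrix(rnorm(cfg$n_genes * n, 0, cfg$noise_sd), cfg$n_genes, n,
                dimnames = list(rownames(S), samples))
    shifted <- list()
    for (tf in names(cfg$active_tfs)) {
      if (!tf %in% colnames(S)) abort(sprintf("active profile '%s' not in potentials", tf))
      thr <- quantile(S[, tf], cfg$potential_quantile)
      idx <- which(S[, tf] >= thr)
      shifted[[tf]] <- rownames(S)[idx]
      X[idx, seq_len(cfg$n_case)] <- X[idx, seq_len(cfg$n_case)] +
        cfg$active_tfs[[tf]] * cfg$noise_sd
    }
    expr <- if (cfg$value_type == "absolute") 10^(base + X) else X
    list(expression = tfa_tibble(expr), labels = labels,
         shifted_genes = shifted, value_type = cfg$value_type)
  })
}

#' Simulate a coverage track and matching peak calls
#'
#' Lays genes on one chromosome (`chr1`) at `gene_spacing` intervals,
#' alternating strand, puts a Gaussian-shaped read pileup (random lognormal
#' amplitude, sd `peak_sd` bp) at the TSS of each designated target gene on
#' top of a flat background of depth `coverage_background`, and writes a
#' matching peak interval (+/- 2 `peak_sd`) per target.
#'
#' @param cfg A [sim_config()].
#' @param annotation Optional gene annotation; by default one is generated
#'   from `cfg` and returned.
#' @return A list: `coverage` track tibble, `peaks` tibble, `targets`
#'   (character vector) and `annotation`.
#' @export
simulate_coverage <- function(cfg, annotation = NULL) {
  if (is.null(annotation)) {
    n <- cfg$n_genes
    annotation <- tibble(
      gene = gene_ids(n), chrom = "chr1",
      tss = as.integer(seq_len(n) * cfg$gene_spacing),
      strand = rep_len(c("+", "-"), n)
    )
  }
  annotation <- gene_annotation(annotation)
  withr::with_seed(tfa_child_seed(cfg$seed, 3L), {
    n <- nrow(annotation)
    n_targets <- max(0L, round(cfg$target_fraction * n))
    targets <- sort(sample(annotation$gene, n_targets))
    chrom_end <- max(annotation$tss) + cfg$gene_spacing
    segs <- list()
    cuts <- c(0L)
    target_order <- targets[order(annotation$tss[match(targets, annotation$gene)])]
    for (g in target_order) {
      tss <- annotation$tss[annotation$gene == g]
      amp <- stats::rlnorm(1, log(cfg$peak_height), 0.25)
      lo <- max(0L, tss - 3L * cfg$peak_sd)
      hi <- tss + 3L * cfg$peak_sd
      pos <- seq.int(lo, hi - 1L)
      segs[[g]] <- tibble(
        chrom = "chr1", start = pos, end = pos + 1L,
        value = cfg$coverage_background +
          amp * exp(-(pos - tss)^2 / (2 * cfg$peak_sd^2))
      )
      cuts <- c(cuts, lo, hi)
    }
    cuts <- c(cuts, chrom_end)
    gaps <- matrix(cuts, ncol = 2, byrow = TRUE)
    background <- tibble(chrom = "chr1", start = gaps[, 1], end = gaps[, 2],
                         value = cfg$coverage_background)
    background <- background[background$end > background$start, ]
    coverage <- coverage_track(bind_rows(c(segs, list(background))))
    peaks <- if (length(targets) > 0) {
      tibble(
        chrom = "chr1",
        start = pmax(0L, annotation$tss[match(targets, annotation$gene)] -
                       2L * cfg$peak_sd),
        end = annotation$tss[match(targets, annotation$gene)] + 2L * cfg$peak_sd
      )
    } else {
      tibble(chrom = character(), start = integer(), end = integer())
    }
    list(coverage = coverage, peaks = peaks, targets = targets,
         annotation = annotation)
  })
}

#' Simulate survival times driven by an activity profile
#'
#' Event times are exponential with hazard
#' `baseline_hazard * exp(survival_beta * score)`; censoring is an
#' independent exponential at `censor_rate` (rate 0 means no censoring).
#'
#' @param cfg A [sim_config()].
#' @param activity Tibble with columns `sample` and `score` (the designated
#'   profile's per-sample activity).
#' @return A survival table tibble (`sample`, `time`, `event`).
#' @export
simulate_survival <- function(cfg, activity) {
  if (!all(c("sample", "score") %in% names(activity))) {
    abort("activity needs columns sample and score")
  }
  withr::with_seed(tfa_child_seed(cfg$seed, 4L), {
    n <- nrow(activity)
    hz <- cfg$baseline_hazard * exp(cfg$survival_beta * activity$score)
    t_event <- rexp(n, hz)
    t_cens <- if (cfg$censor_rate > 0) rexp(n, cfg$censor_rate) else rep(Inf, n)
    tibble(sample = activity$sample,
           time = pmin(t_event, t_cens),
           event = as.integer(t_event <= t_cens))
  })
}

#' Simulate a full study in one call
#'
#' Potentials plus expression (and labels) from one config; the convenience
#' entry used by examples and the end-to-end pipeline test.
#'
#' @param cfg A [sim_config()].
#' @return A list: `potentials`, `expression`, `labels`, `shifted_genes`,
#'   `value_type`, `config`.
#' @export
simulate_study <- function(cfg) {
  S <- simulate_potentials(cfg)
  ex <- simulate_expression(cfg, S)
  c(list(potentials = S, config = cfg), ex)
}
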