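#' @export
print.tfa_ras <- function(x, ...) {
  cat(sprintf("Regulatory activity screen: %d profile(s), %d genes, m = %d permutations\n",
              nrow(x), x$n_genes[1], attr(x, "m")))
  NextMethod()
}

#' Tidy a regulatory activity result
#'
#' @param x A `tfa_ras` tibble.
#' @param ... Unused.
#' @return A plain tibble of per-profile results.
#' @method tidy tfa_ras
#' @export
tidy.tfa_ras <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' One-row summary of a regulatory activity screen
#'
#' @param x A `tfa_ras` tibble.
#' @param ... Unused.
#' @return A one-row tibble: problem sizes, permutation count, number of
#'   profiles with `fdr < 0.05`.
#' @method glance tfa_ras
#' @export
glance.tfa_ras <- function(x, ...) {
  tibble(
    n_profiles = nrow(x), n_genes = x$n_genes[1],
    n_case = attr(x, "n_case"), n_control = attr(x, "n_control"),
    m = attr(x, "m"), seed = attr(x, "seed"),
    n_significant = sum(x$fdr < 0.05, na.rm = TRUE)
  )
}

#' Lollipop plot of regulatory activity scores
#'
#' @param object A `tfa_ras` tibble.
#' @param fdr_cutoff Profiles at or below this FDR are highlighted.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tfa_ras
#' @export
autoplot.tfa_ras <- function(object, fdr_cutoff = 0.05, ...) {
  d <- tidy(object)
  d <- mutate(d, tf = stats::reorder(.data$tf, .data$ras),
              sig = !is.na(.data$fdr) & .data$fdr <= fdr_cutoff)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ras, y = .data$tf, colour = .data$sig)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$ras, yend = .data$tf)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                                 name = sprintf("FDR <= %.2g", fdr_cutoff)) +
    ggplot2::labs(x = "regulatory activity score (case vs control)", y = NULL)
}

#' Tidy a sample-wise activity matrix
#'
#' @param x A `tfa_iras` tibble.
#' @param ... Unused.
#' @return A plain long tibble (`tf`, `sample`, `ps`, `iras`).
#' @method tidy tfa_iras
#' @export
tidy.tfa_iras <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' Heatmap of sample-wise activity
#'
#' @param object A `tfa_iras` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tfa_iras
#' @export
autoplot.tfa_iras <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$sample, y = .data$tf, fill = .data$iras)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick",
                                  name = "activity") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Tidy a survival screen
#'
#' @param x A `tfa_cox` tibble.
#' @param ... Unused.
#' @return A plain tibble.
#' @method tidy tfa_cox
#' @export
tidy.tfa_cox <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' One-row summary of a survival screen
#'
#' @param x A `tfa_cox` tibble.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance tfa_cox
#' @export
glance.tfa_cox <- function(x, ...) {
  tibble(
    n_profiles = nrow(x),
    n_significant = sum(x$significant, na.rm = TRUE),
    n_failed = sum(!is.na(x$note)),
    confounders = paste(attr(x, "confounders"), collapse = ","),
    p_threshold = attr(x, "p_threshold")
  )
}

#' Forest plot of hazard ratios
#'
#' Shows the covariate-adjusted hazard ratio when present, otherwise the
#' single-variable one.
#'
#' @param object A `tfa_cox` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tfa_cox
#' @export
autoplot.tfa_cox <- function(object, ...) {
  d <- tidy(object)
  if ("hazard_ratio_cov" %in% names(d)) {
    d <- mutate(d, hr = .data$hazard_ratio_cov, lo = .data$conf_low_cov,
                hi = .data$conf_high_cov)
  } else {
    d <- mutate(d, hr = .data$hazard_ratio, lo = .data$conf_low,
                hi = .data$conf_high)
  }
  d <- filter(d, is.na(.data$note))
  d <- mutate(d, tf = stats::reorder(.data$tf, .data$hr))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$hr, y = .data$tf)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.2) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant), size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "hazard ratio (95% CI)", y = NULL)
}

#' Running-sum diagnostic plot for one profile
#'
#' Plots the foreground and background running sums along the ranked gene
#' list and marks the maximal gap (the pre-score).
#'
#' @param rf Output of [running_sums()].
#' @return A ggplot object.
#' @export
plot_running_sums <- function(rf) {
  g <- nrow(rf)
  ps <- pre_score(rf)
  d <- tibble(rank = rep(seq_len(g) / g, 2),
              value = c(rf$f, rf$b),
              curve = rep(c("foreground f(i)", "background b(i)"), each = g))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$value,
                                  colour = .data$curve)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = ps$location, linetype = 3) +
    ggplot2::labs(x = "rank fraction (genes sorted by decreasing t)",
                  y = "cumulative weight share",
                  subtitle = sprintf("pre-score %.3f at rank fraction %.3f",
                                     ps$ps, ps$location)) +
    ggplot2::theme(legend.title = ggplot2::element_blank())
}
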