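#' Read a clinical survival table
#'
#' TSV with columns `sample`, `time`, `event` and any number of numeric or
#' 0/1-coded covariate columns.
#'
#' @param path Path to the TSV.
#' @return A validated tibble.
#' @export
read_clinical <- function(path) {
  survival_table(readr::read_tsv(path, show_col_types = FALSE))
}

#' Validate a survival table
#'
#' @param x Data frame with `sample`, `time` (>= 0), `event` (0/1) and
#'   optional covariate columns.
#' @return The validated tibble.
#' @export
survival_table <- function(x) {
  need <- c("sample", "time", "event")
  if (!all(need %in% names(x))) abort("survival table needs columns sample, time, event")
  x <- as_tibble(x)
  if (any(x$time < 0)) abort("survival times must be >= 0")
  if (!all(x$event %in% c(0, 1))) abort("event indicator must be 0 or 1")
  if (anyDuplicated(x$sample)) abort("duplicate sample ids")
  x
}

coxph_strict <- function(formula, data) {
  fit <- withCallingHandlers(
    survival::coxph(formula, data = data, ties = "efron"),
    warning = function(w) {
      if (grepl("Ran out of iterations", conditionMessage(w))) {
        abort(paste("Cox model did not converge:", conditionMessage(w)))
      }
      invokeRestart("muffleWarning")
    }
  )
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    abort(sprintf("collinear covariate(s) dropped by the Cox fit: %s",
                  paste(bad, collapse = ", ")))
  }
  fit
}

#' Data-driven confounder selection
#'
#' Fits one Cox proportional-hazards model containing all clinical
#' covariates and keeps those with Wald `p < alpha`. Selection and screening
#' are deliberately separate steps so confounders can also be pinned by hand.
#'
#' @param clinical A survival table (see [survival_table()]).
#' @param covariates Covariate column names; default all columns beyond
#'   `sample`/`time`/`event`. Zero covariates return an empty selection.
#' @param alpha Wald p-value cut-off (default 0.01).
#' @return Character vector of retained covariate names.
#' @export
select_confounders <- function(clinical, covariates = NULL, alpha = 0.01) {
  clinical <- survival_table(clinical)
  if (is.null(covariates)) {
    covariates <- setdiff(names(clinical), c("sample", "time", "event"))
  }
  if (length(covariates) == 0) return(character(0))
  if (sum(clinical$event) < 2) abort("need at least 2 events")
  mm <- as.matrix(clinical[covariates])
  if (qr(cbind(1, mm))$rank < length(covariates) + 1) {
    cm <- abs(stats::cor(mm))
    diag(cm) <- 0
    pair <- which(cm > 1 - 1e-8, arr.ind = TRUE)
    if (nrow(pair) > 0) {
      abort(sprintf("collinear covariates: %s and %s",
                    covariates[pair[1, 1]], covariates[pair[1, 2]]))
    }
    abort("covariates are collinear (model matrix rank-deficient)")
  }
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(covariates, collapse = " + ")))
  fit <- coxph_strict(fml, clinical)
  p <- summary(fit)$coefficients[, "Pr(>|z|)"]
  covariates[p < alpha]
}

cox_row <- function(fit, term) {
  sm <- summary(fit)$coefficients
  b <- sm[term, "coef"]
  se <- sm[term, "se(coef)"]
  z <- qnorm(0.975)
  tibble(estimate = b, hazard_ratio = exp(b),
         conf_low = exp(b - z * se), conf_high = exp(b + z * se),
         p_value = sm[term, "Pr(>|z|)"])
}

#' Cox association of one activity profile with survival
#'
#' Fits `Surv(time, event) ~ activity` (single-variable model) and, when
#' confounders are given, `Surv(time, event) ~ activity + confounders`.
#' Reports coefficient, hazard ratio, Wald 95% CI and Wald p for both
#' models (`_cov` suffix for the covariate-adjusted one).
#'
#' @param activity Tibble with columns `sample` and `score` (one factor's
#'   per-sample activity).
#' @param clinical A survival table.
#' @param confounders Covariate names to adjust for (default none).
#' @return A one-row tibble.
#' @export
cox_association <- function(activity, clinical, confounders = character(0)) {
  if (!all(c("sample", "score") %in% names(activity))) {
    abort("activity needs columns sample and score")
  }
  clinical <- survival_table(clinical)
  dat <- left_join(clinical, activity, by = "sample")
  dat <- dat[is.finite(dat$score), , drop = FALSE]
  if (sum(dat$event) == 0) abort("all samples are censored")
  if (sum(dat$event) < 2) abort("need at least 2 events")
  if (sd(dat$score) == 0) abort("constant activity vector: no variation to model")
  uni <- coxph_strict(survival::Surv(time, event) ~ score, dat)
  out <- cox_row(uni, "score")
  if (length(confounders) > 0) {
    fml <- stats::as.formula(paste("survival::Surv(time, event) ~ score +",
                                   paste(confounders, collapse = " + ")))
    multi <- coxph_strict(fml, dat)
    adj <- cox_row(multi, "score")
    names(adj) <- paste0(names(adj), "_cov")
    out <- bind_cols(out, adj)
  }
  out
}

#' Screen activity profiles for survival association
#'
#' Runs [cox_association()] for every factor profile, flags profiles whose
#' covariate-adjusted Wald p (single-variable p when no confounders) falls
#' below `p_threshold`, and reports Benjamini-Hochberg adjusted p-values for
#' both model variants. Per-profile failures are recorded in `note` and the
#' screen continues.
#'
#' @param activity A `tfa_iras` long tibble (`tf`, `sample`, `iras`).
#' @param clinical A survival table.
#' @param confounders Covariate names, or `"auto"` to run
#'   [select_confounders()] first.
#' @param p_threshold Significance cut-off on the screening p (default 0.001).
#' @param alpha_confounder Passed to [select_confounders()] for `"auto"`.
#' @return A `tfa_cox` tibble, one row per profile sorted by screening p:
#'   the [cox_association()] columns plus `fdr` (+ `fdr_cov`), `significant`
#'   and `note`. The selected confounders are kept as an attribute.
#' @export
screen_survival <- function(activity, clinical, confounders = character(0),
                            p_threshold = 0.001, alpha_confounder = 0.01) {
  if (!all(c("tf", "sample", "iras") %in% names(activity))) {
    abort("activity needs columns tf, sample, iras")
  }
  clinical <- survival_table(clinical)
  if (identical(confounders, "auto")) {
    confounders <- select_confounders(clinical, alpha = alpha_confounder)
  }
  tfs <- unique(activity$tf)
  rows <- purrr::map(tfs, function(tf_id) {
    a <- activity[activity$tf == tf_id, c("sample", "iras")]
    names(a) <- c("sample", "score")
    tryCatch(
      mutate(cox_association(a, clinical, confounders), tf = tf_id,
             note = NA_character_),
      error = function(e) tibble(tf = tf_id, note = conditionMessage(e))
    )
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(tf = character(), estimate = numeric(), hazard_ratio = numeric(),
                  conf_low = numeric(), conf_high = numeric(), p_value = numeric(),
                  fdr = numeric(), significant = logical(), note = character())
    class(out) <- c("tfa_cox", class(out))
    attr(out, "confounders") <- confounders
    attr(out, "p_threshold") <- p_threshold
    return(out)
  }
  out$fdr <- p.adjust(out$p_value, method = "BH")
  screen_p <- if ("p_value_cov" %in% names(out)) {
    out$fdr_cov <- p.adjust(out$p_value_cov, method = "BH")
    out$p_value_cov
  } else {
    out$p_value
  }
  out$significant <- !is.na(screen_p) & screen_p < p_threshold
  out <- out[order(!is.na(out$note), screen_p), ]
  out <- select(out, "tf", dplyr::everything())
  class(out) <- c("tfa_cox", class(out))
  attr(out, "confounders") <- confounders
  attr(out, "p_threshold") <- p_threshold
  out
}

#' Kaplan-Meier curve export for an activity dichotomy
#'
#' Splits samples at the median of a profile's activity and exports the
#' Kaplan-Meier survival estimates of the two strata as a plain tibble
#' (no rendering).
#'
#' @param activity Tibble with columns `sample` and `score`.
#' @param clinical A survival table.
#' @return A tibble with `group`, `time`, `surv`, `n_risk`, `n_event`.
#' @export
km_curves <- function(activity, clinical) {
  clinical <- survival_table(clinical)
  dat <- left_join(clinical, activity, by = "sample")
  dat$group <- ifelse(dat$score > median(dat$score, na.rm = TRUE),
                      "high activity", "low activity")
  sf <- survival::survfit(survival::Surv(time, event) ~ group, data = dat)
  tibble(
    group = rep(sub("^group=", "", names(sf$strata)), sf$strata),
    time = sf$time, surv = sf$surv, n_risk = sf$n.risk, n_event = sf$n.event
  )
}
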