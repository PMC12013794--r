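#' Cohen's d effect size (pooled SD)
#'
#' `d = (mean(x) - mean(y)) / s_pooled` with the classical pooled standard
#' deviation `sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))`.
#'
#' @param x,y numeric samples (each of length >= 2).
#' @return d (dimensionless); `NA` with a warning when the pooled SD is zero.
#' @examples
#' cohens_d(c(1, 2, 3), c(2, 3, 4)) # -1
#' @export
cohens_d <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("each sample needs at least 2 observations")
  sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
               (n1 + n2 - 2))
  if (sp == 0) {
    warning("pooled SD is zero; Cohen's d undefined")
    return(NA_real_)
  }
  (mean(x) - mean(y)) / sp
}

#' Fit a linear mixed model with likelihood-ratio tests and marginal means
#'
#' Thin, logged delegation to \pkg{lme4}: fits
#' `response ~ fixed (all interactions) + covariate + (1 | random)`, obtains
#' per-factor p-values by likelihood-ratio tests of the full model against
#' the model without the factor (and its interactions), and computes
#' estimated marginal means with Tukey-adjusted pairwise comparisons via
#' \pkg{emmeans}. The numeric covariate (e.g. trial number) is centred.
#'
#' @param table long-format data.frame.
#' @param response name of the response column.
#' @param fixed character vector of fixed-effect factor names (crossed with
#'   interactions when more than one).
#' @param random name of the random-intercept grouping column (default
#'   `"participant"`).
#' @param covariate optional name of a numeric covariate column (centred).
#' @param marginal_means logical; compute emmeans contrasts (default `TRUE`;
#'   disable in tight simulation loops).
#' @return object of class `mixed_model_fit`: list with `model`, `formula`,
#'   `lrt` (data.frame factor, chisq, df, p), `effects` (fixed-effect
#'   estimates with 95% Wald CIs), `emmeans` (per-factor emmGrid contrasts or
#'   `NULL`), `singular` flag.
#' @export
fit_mixed_model <- function(table, response, fixed, random = "participant",
                            covariate = NULL, marginal_means = TRUE) {
  stopifnot(is.data.frame(table), all(c(response, fixed, random) %in%
                                        names(table)))
  if (length(unique(table[[random]])) < 2)
    stop("need at least 2 levels of the random grouping factor (participants)")
  for (f in fixed) {
    if (length(unique(table[[f]])) < 2)
      stop(sprintf("fixed factor '%s' needs at least 2 levels", f))
    table[[f]] <- factor(table[[f]])
  }
  cov_term <- NULL
  if (!is.null(covariate)) {
    stopifnot(covariate %in% names(table))
    table$.cov_c <- as.numeric(table[[covariate]]) -
      mean(as.numeric(table[[covariate]]))
    cov_term <- ".cov_c"
  }
  fixed_term <- paste(fixed, collapse = " * ")
  rhs <- paste(c(fixed_term, cov_term, sprintf("(1 | %s)", random)),
               collapse = " + ")
  full_formula <- stats::as.formula(paste(response, "~", rhs))
  model <- lme4::lmer(full_formula, data = table, REML = FALSE)
  singular <- lme4::isSingular(model)
  if (singular)
    warning("singular mixed-model fit (variance component at boundary)")

  # per-factor LRT: drop the factor and every interaction containing it
  lrt <- lapply(fixed, function(f) {
    keep <- setdiff(fixed, f)
    red_fixed <- if (length(keep)) paste(keep, collapse = " * ") else "1"
    red_rhs <- paste(c(red_fixed, cov_term, sprintf("(1 | %s)", random)),
                     collapse = " + ")
    red <- lme4::lmer(stats::as.formula(paste(response, "~", red_rhs)),
                      data = table, REML = FALSE)
    a <- stats::anova(red, model)
    data.frame(factor = f, chisq = a$Chisq[2], df = a$Df[2],
               p = a$`Pr(>Chisq)`[2], stringsAsFactors = FALSE)
  })
  lrt <- do.call(rbind, lrt)

  est <- lme4::fixef(model)
  ci <- tryCatch(stats::confint(model, parm = "beta_", method = "Wald"),
                 error = function(e) NULL)
  effects <- data.frame(term = names(est), estimate = as.numeric(est),
                        stringsAsFactors = FALSE)
  if (!is.null(ci)) {
    effects$ci_lo <- ci[, 1][effects$term]
    effects$ci_hi <- ci[, 2][effects$term]
  }

  emm <- NULL
  if (marginal_means) {
    emm <- lapply(stats::setNames(fixed, fixed), function(f) {
      emmeans::emmeans(model, stats::as.formula(paste("pairwise ~", f)),
                       adjust = "tukey")
    })
  }
  structure(list(model = model, formula = full_formula, lrt = lrt,
                 effects = effects, emmeans = emm, singular = singular),
            class = "mixed_model_fit")
}

#' @export
print.mixed_model_fit <- function(x, ...) {
  cat("<mixed_model_fit> ", deparse(x$formula), "\n")
  print(x$lrt, row.names = FALSE)
  if (x$singular) cat("  (singular fit)\n")
  invisible(x)
}

#' Build summary report tables mirroring the analysis figures
#'
#' Aggregates per-trial and per-unit metric tables into the per-condition
#' summaries of the analysis: delta torque-CV by contraction type, brim-unit
#' plateau rate change by muscle length, cap counts and sustained-discharge
#' proportions by length, delta-F by length and descending duration by
#' length. Empty inputs yield headers-only tables with a warning.
#'
#' @param trial_summaries data.frame with per-trial columns (any of
#'   `contraction`, `length`, `delta_cv`, `n_cap`, `prop_sustained`).
#' @param unit_metrics data.frame with per-unit columns (any of `length`,
#'   `category`, `delta_rate`, `mean_delta_f`, `descend_dur`).
#' @return named list of data.frames.
#' @export
build_report <- function(trial_summaries = NULL, unit_metrics = NULL) {
  agg <- function(df, value, by) {
    if (is.null(df) || !nrow(df) || !all(c(value, by) %in% names(df))) {
      out <- data.frame(group = character(0), mean = numeric(0),
                        sd = numeric(0), n = integer(0))
      names(out)[1] <- by
      return(out)
    }
    sub <- df[!is.na(df[[value]]), , drop = FALSE]
    res <- stats::aggregate(sub[[value]], by = list(sub[[by]]), FUN = function(v)
      c(mean = mean(v), sd = stats::sd(v), n = length(v)))
    out <- data.frame(res[[1]], mean = res$x[, "mean"], sd = res$x[, "sd"],
                      n = as.integer(res$x[, "n"]))
    names(out)[1] <- by
    out
  }
  if ((is.null(trial_summaries) || !nrow(trial_summaries)) &&
      (is.null(unit_metrics) || !nrow(unit_metrics)))
    warning("empty inputs; returning headers-only report")
  list(
    delta_cv_by_contraction = agg(trial_summaries, "delta_cv", "contraction"),
    cap_count_by_length = agg(trial_summaries, "n_cap", "length"),
    prop_sustained_by_length = agg(trial_summaries, "prop_sustained", "length"),
    brim_rate_delta_by_length = agg(
      if (!is.null(unit_metrics) && "category" %in% names(unit_metrics))
        unit_metrics[unit_metrics$category %in% "brim", , drop = FALSE]
      else unit_metrics, "delta_rate", "length"),
    delta_f_by_length = agg(unit_metrics, "mean_delta_f", "length"),
    descend_dur_by_length = agg(unit_metrics, "descend_dur", "length")
  )
}
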