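# Covariate-adjusted logistic regression, cross-adjustment of FH and PRS
# effects, proportional log-odds attenuation, PRS percentile bands,
# interaction tests with Bonferroni correction, and the parental
# age-at-death tertile analysis.

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise significance level, in (0, 1).
#' @param n_tests Number of tests, >= 1.
#' @return \code{alpha / n_tests}.  Display at two significant digits
#'   (e.g. \code{signif(x, 2)}): 0.05 over 39 tests prints as 0.0013.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)", call. = FALSE)
  if (!is.numeric(n_tests) || n_tests < 1)
    stop("n_tests must be >= 1", call. = FALSE)
  alpha / n_tests
}

#' Covariate-adjusted logistic regression
#'
#' Maximum-likelihood logistic regression (IRLS via \code{stats::glm}) with
#' Wald standard errors and 95\% confidence intervals on the odds-ratio
#' scale.  Continuous exposures are standardized to zero mean and unit
#' variance within the analysis set, so the coefficient of a continuous PRS
#' is the per-SD effect.  Complete separation and non-convergence raise
#' explicit errors; covariates without variation in the analysis set (e.g.
#' sex in a sex-restricted disease) are dropped with a message.
#'
#' @param data Analysis frame (see \code{\link{analysis_frame}}).
#' @param exposures Character vector of exposure columns; factors yield one
#'   row per non-reference level.
#' @param covariates Character vector of adjustment columns.
#' @param outcome Name of the binary 0/1 outcome column.
#' @param scale_continuous Standardize continuous (more than two distinct
#'   values) numeric exposures before fitting.
#' @return Data frame, one row per exposure term: \code{exposure},
#'   \code{beta} (log odds), \code{se}, \code{or_}, \code{ci_low},
#'   \code{ci_high}, \code{p}, \code{covariates}, \code{n}, \code{n_cases}.
#' @export
fit_logistic <- function(data, exposures, covariates = c("sex", "birth_year"),
                         outcome = "case", scale_continuous = TRUE) {
  stopifnot(is.data.frame(data), length(exposures) >= 1L)
  miss <- setdiff(c(outcome, exposures, covariates), names(data))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  y <- data[[outcome]]
  if (!all(y %in% c(0, 1)))
    stop("outcome must be binary 0/1", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("outcome has no variation", call. = FALSE)

  mf <- data.frame(.y = y)
  for (e in exposures) {
    x <- data[[e]]
    if (is.numeric(x)) {
      if (anyNA(x)) stop("exposure '", e, "' has missing values",
                         call. = FALSE)
      if (stats::sd(x) == 0)
        stop("zero-variance exposure '", e, "'", call. = FALSE)
      if (scale_continuous && length(unique(x)) > 2L)
        x <- as.numeric(scale(x))
      mf[[e]] <- x
    } else {
      x <- droplevels(as.factor(x))
      if (nlevels(x) < 2L)
        stop("zero-variance exposure '", e, "'", call. = FALSE)
      mf[[e]] <- x
    }
  }
  used_cov <- character(0)
  for (cv in covariates) {
    x <- data[[cv]]
    if (length(unique(x)) < 2L) {
      message("dropping constant covariate '", cv, "'")
      next
    }
    mf[[cv]] <- if (is.character(x)) factor(x) else x
    used_cov <- c(used_cov, cv)
  }

  fml <- stats::as.formula(paste(".y ~",
    paste(c(exposures, used_cov), collapse = " + ")))
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, family = stats::binomial(), data = mf,
               control = stats::glm.control(maxit = 50)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (separation || any(fit$fitted.values < 1e-8) ||
      any(fit$fitted.values > 1 - 1e-8))
    stop("complete (or quasi-complete) separation in logistic model",
         call. = FALSE)
  if (!fit$converged)
    stop("logistic regression did not converge", call. = FALSE)

  sm <- stats::summary.glm(fit)$coefficients
  rows <- list()
  for (e in exposures) {
    if (is.factor(mf[[e]])) {
      lv <- levels(mf[[e]])[-1]
      terms <- paste0(e, lv)
      labels <- paste0(e, ":", lv)
    } else {
      terms <- e
      labels <- e
    }
    for (k in seq_along(terms)) {
      b <- sm[terms[k], "Estimate"]; s <- sm[terms[k], "Std. Error"]
      rows[[length(rows) + 1L]] <- data.frame(
        exposure = labels[k], beta = b, se = s, or_ = exp(b),
        ci_low = exp(b - 1.96 * s), ci_high = exp(b + 1.96 * s),
        p = sm[terms[k], "Pr(>|z|)"],
        covariates = paste(used_cov, collapse = "+"),
        n = nrow(mf), n_cases = sum(y == 1),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cross-adjustment of PRS and family-history effects
#'
#' Fits three models with the same covariates -- PRS alone, FH alone, and
#' both jointly -- and reports the proportional change in each exposure's
#' log odds when the other is added: \code{ratio = beta_adj / beta_unadj}
#' and \code{decrease = 1 - ratio} (positive decrease = attenuation).
#'
#' @param data Analysis frame with \code{prs} and the FH column.
#' @param fh_kind One of \code{"fh1"}, \code{"fh2"}, \code{"fhp"}.
#' @param covariates Adjustment columns.
#' @return Data frame with two rows (PRS adjusted by FH; FH adjusted by
#'   PRS): \code{exposure}, \code{adjustment}, \code{beta_unadj},
#'   \code{beta_adj}, \code{ratio}, \code{decrease}.
#' @export
cross_adjust <- function(data, fh_kind = c("fh1", "fh2", "fhp"),
                         covariates = c("sex", "birth_year")) {
  fh_kind <- match.arg(fh_kind)
  data <- data[!is.na(data[[fh_kind]]), , drop = FALSE]
  fh <- data[[fh_kind]]
  if (length(unique(fh)) < 2L)
    stop("FH prevalence is 0 or 1 in the analysis set", call. = FALSE)
  m_prs <- fit_logistic(data, "prs", covariates)
  m_fh <- fit_logistic(data, fh_kind, covariates)
  m_both <- fit_logistic(data, c("prs", fh_kind), covariates)
  b_prs_u <- m_prs$beta[m_prs$exposure == "prs"]
  b_fh_u <- m_fh$beta[m_fh$exposure == fh_kind]
  b_prs_a <- m_both$beta[m_both$exposure == "prs"]
  b_fh_a <- m_both$beta[m_both$exposure == fh_kind]
  out <- data.frame(
    exposure = c("prs", fh_kind),
    adjustment = c(fh_kind, "prs"),
    beta_unadj = c(b_prs_u, b_fh_u),
    beta_adj = c(b_prs_a, b_fh_a),
    stringsAsFactors = FALSE)
  out$ratio <- out$beta_adj / out$beta_unadj
  out$decrease <- 1 - out$ratio
  out
}

#' Summarize attenuation across diseases
#'
#' Unweighted mean and SD of the proportional log-odds decreases, grouped
#' by (exposure, adjustment).  Decreases are ratios of log odds, so the
#' summary is on the log-odds scale.
#'
#' @param att Row-bound \code{\link{cross_adjust}} results over at least
#'   two diseases.
#' @return Data frame: \code{exposure}, \code{adjustment},
#'   \code{mean_decrease}, \code{sd_decrease}, \code{n_diseases}.
#' @export
attenuation_summary <- function(att) {
  stopifnot(all(c("exposure", "adjustment", "decrease") %in% names(att)))
  key <- interaction(att$exposure, att$adjustment, drop = TRUE)
  if (any(table(key) < 2L))
    stop("attenuation summary needs >= 2 diseases per group", call. = FALSE)
  agg <- do.call(rbind, lapply(split(att, key), function(g)
    data.frame(exposure = g$exposure[1], adjustment = g$adjustment[1],
               mean_decrease = mean(g$decrease),
               sd_decrease = stats::sd(g$decrease),
               n_diseases = nrow(g), stringsAsFactors = FALSE)))
  rownames(agg) <- NULL
  agg
}

#' Test for FH-by-PRS interaction
#'
#' Adds the product of the FH indicator and the standardized PRS to the
#' adjusted logistic model and returns the Wald p-value of the product
#' term, flagged against a Bonferroni-corrected threshold.
#'
#' @inheritParams cross_adjust
#' @param alpha Family-wise level for the Bonferroni flag.
#' @param n_tests Number of tests in the family (39 = 24 + 15 reproduces
#'   the 0.0013 threshold).
#' @return One-row data frame: \code{fh_kind}, \code{beta_int}, \code{se},
#'   \code{p}, \code{threshold}, \code{significant}, \code{n},
#'   \code{n_cases}.
#' @export
interaction_test <- function(data, fh_kind = c("fh1", "fh2", "fhp"),
                             covariates = c("sex", "birth_year"),
                             alpha = 0.05, n_tests = 1) {
  fh_kind <- match.arg(fh_kind)
  data <- data[!is.na(data[[fh_kind]]), , drop = FALSE]
  if (length(unique(data[[fh_kind]])) < 2L)
    stop("FH prevalence is 0 or 1 in the analysis set", call. = FALSE)
  d2 <- data
  d2$prs <- as.numeric(scale(d2$prs))
  d2$fh_x_prs <- d2$prs * d2[[fh_kind]]
  fit <- fit_logistic(d2, c("prs", fh_kind, "fh_x_prs"), covariates,
                      scale_continuous = FALSE)
  r <- fit[fit$exposure == "fh_x_prs", ]
  thr <- bonferroni_threshold(alpha, n_tests)
  data.frame(fh_kind = fh_kind, beta_int = r$beta, se = r$se, p = r$p,
             threshold = thr, significant = r$p < thr,
             n = r$n, n_cases = r$n_cases, stringsAsFactors = FALSE)
}

#' PRS percentile bands
#'
#' Percentiles are computed within the supplied values (the per-disease
#' analysis set); ties are resolved by rank with boundary values assigned
#' to the lower band.  Schemes: \code{top_decile} (>90\% vs rest,
#' reference rest), \code{seven_band} (0-10/10-20/20-40/40-60/60-80/80-90/
#' 90-100, reference 40-60), \code{three_group} (low <33\%, average
#' 33-90\%, high >90\%, reference average).
#'
#' @param prs Numeric vector of PRS values.
#' @param scheme Categorization scheme.
#' @return Factor with the scheme's reference band as first level.
#' @export
prs_band <- function(prs, scheme = c("top_decile", "seven_band",
                                     "three_group")) {
  scheme <- match.arg(scheme)
  if (anyNA(prs)) stop("PRS has missing values", call. = FALSE)
  p <- rank(prs, ties.method = "max") / length(prs)
  sch <- switch(scheme,
    top_decile = list(breaks = c(0, 0.9, 1),
                      labels = c("rest", "top_decile"), ref = "rest"),
    seven_band = list(breaks = c(0, .1, .2, .4, .6, .8, .9, 1),
                      labels = c("0-10", "10-20", "20-40", "40-60",
                                 "60-80", "80-90", "90-100"),
                      ref = "40-60"),
    three_group = list(breaks = c(0, 1 / 3, 0.9, 1),
                       labels = c("low", "average", "high"),
                       ref = "average"))
  f <- cut(p, breaks = sch$breaks, labels = sch$labels, right = TRUE,
           include.lowest = TRUE)
  stats::relevel(f, ref = sch$ref)
}

#' Per-band PRS effects
#'
#' Odds ratios of the PRS percentile bands against the scheme's reference
#' band, from one covariate-adjusted logistic model.
#'
#' @inheritParams cross_adjust
#' @param scheme Categorization scheme, see \code{\link{prs_band}}.
#' @return \code{\link{fit_logistic}}-style rows, one per non-reference
#'   band, with columns \code{band} and \code{scheme} added.
#' @export
prs_banded_effects <- function(data, scheme = c("top_decile", "seven_band",
                                                "three_group"),
                               covariates = c("sex", "birth_year")) {
  scheme <- match.arg(scheme)
  data$prs_cat <- prs_band(data$prs, scheme)
  if (any(table(data$prs_cat) == 0L))
    stop("empty PRS band", call. = FALSE)
  out <- fit_logistic(data, "prs_cat", covariates, scale_continuous = FALSE)
  out$band <- sub("^prs_cat:", "", out$exposure)
  out$scheme <- scheme
  out
}

#' FH_P effects by tertile of parental age at death
#'
#' Odds ratios of FH_P split by tertile of the cause-positive parent's age
#' at death, versus FH_P-negative individuals, with and without adjustment
#' for the standardized PRS, plus the per-tertile proportional log-odds
#' decreases.  Tertiles without cases are flagged and omitted from the
#' fits.
#'
#' @inheritParams cross_adjust
#' @return List with \code{effects} (per tertile x model), \code{attenuation}
#'   (per tertile) and \code{omitted} (tertiles dropped for lack of cases).
#' @export
fhp_age_tertile_effects <- function(data,
                                    covariates = c("sex", "birth_year")) {
  d <- data[!is.na(data$fhp), , drop = FALSE]
  d <- d[d$fhp == 0L | !is.na(d$fhp_age_tertile), , drop = FALSE]
  grp <- ifelse(d$fhp == 0L, "negative", paste0("t", d$fhp_age_tertile))
  tab <- table(grp[d$case == 1])
  omitted <- setdiff(c("t1", "t2", "t3"),
                     names(tab)[tab > 0 & names(tab) != "negative"])
  keep <- !(grp %in% omitted)
  d <- d[keep, , drop = FALSE]
  d$fhp_group <- factor(grp[keep],
                        levels = c("negative",
                                   setdiff(c("t1", "t2", "t3"), omitted)))
  un <- fit_logistic(d, "fhp_group", covariates, scale_continuous = FALSE)
  un$model <- "unadjusted"
  d$prs_sd <- as.numeric(scale(d$prs))
  ad <- fit_logistic(d, c("fhp_group", "prs_sd"), covariates,
                     scale_continuous = FALSE)
  ad <- ad[grepl("^fhp_group:", ad$exposure), , drop = FALSE]
  ad$model <- "prs_adjusted"
  att <- data.frame(tertile = sub("^fhp_group:", "", un$exposure),
                    beta_unadj = un$beta, beta_adj = ad$beta,
                    stringsAsFactors = FALSE)
  att$ratio <- att$beta_adj / att$beta_unadj
  att$decrease <- 1 - att$ratio
  list(effects = rbind(un, ad[names(un)]), attenuation = att,
       omitted = omitted)
}

#' PRS effects stratified by family history
#'
#' Per-SD PRS odds ratios fitted separately in the FH-positive and
#' FH-negative subsets; strata without cases are flagged rather than
#' fitted.
#'
#' @inheritParams cross_adjust
#' @return Data frame with one row per stratum and an \code{ok} flag.
#' @export
stratified_prs_effects <- function(data, fh_kind = c("fh1", "fh2", "fhp"),
                                   covariates = c("sex", "birth_year")) {
  fh_kind <- match.arg(fh_kind)
  data <- data[!is.na(data[[fh_kind]]), , drop = FALSE]
  rows <- lapply(c(1L, 0L), function(s) {
    sub <- data[data[[fh_kind]] == s, , drop = FALSE]
    lab <- if (s == 1L) "fh_positive" else "fh_negative"
    if (nrow(sub) == 0L || sum(sub$case) == 0L ||
        length(unique(sub$case)) < 2L) {
      return(data.frame(stratum = lab, exposure = "prs", beta = NA_real_,
                        se = NA_real_, or_ = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p = NA_real_, covariates = "",
                        n = nrow(sub), n_cases = sum(sub$case), ok = FALSE,
                        stringsAsFactors = FALSE))
    }
    r <- fit_logistic(sub, "prs", covariates)
    cbind(stratum = lab, r, ok = TRUE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare two nested PRSs of different capture
#'
#' For a genome-wide-like score (\code{prs}, liability variance rho2) and a
#' nested smaller score (\code{prs_small}, variance rho2_small < rho2),
#' reports the per-SD effect of each and the attenuation of FH when
#' adjusting with each score.
#'
#' @inheritParams cross_adjust
#' @return Data frame with one row per score: per-SD \code{beta},
#'   \code{or_}, and \code{fh_decrease} (proportional decrease of the FH
#'   log odds when adjusting for the score).
#' @export
compare_prs_capture <- function(data, fh_kind = c("fh1", "fh2", "fhp"),
                                covariates = c("sex", "birth_year")) {
  fh_kind <- match.arg(fh_kind)
  if (!"prs_small" %in% names(data) || all(is.na(data$prs_small)))
    stop("no nested small PRS in the data (set rho2_small in the disease config)",
         call. = FALSE)
  data <- data[!is.na(data[[fh_kind]]), , drop = FALSE]
  m_fh <- fit_logistic(data, fh_kind, covariates)
  b_fh_u <- m_fh$beta[1]
  rows <- lapply(c("prs", "prs_small"), function(sc) {
    d2 <- data
    d2$score <- d2[[sc]]
    m <- fit_logistic(d2, "score", covariates)
    m2 <- fit_logistic(d2, c("score", fh_kind), covariates)
    b_fh_a <- m2$beta[m2$exposure == fh_kind]
    data.frame(score = sc, beta = m$beta[1], se = m$se[1], or_ = m$or_[1],
               fh_beta_unadj = b_fh_u, fh_beta_adj = b_fh_a,
               fh_decrease = 1 - b_fh_a / b_fh_u, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
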