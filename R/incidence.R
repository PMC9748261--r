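# Kaplan-Meier cumulative incidence by age, stratified jointly by family
# history and PRS group (high >90%, average 33-90%, low <33%).

#' Product-limit curve
#'
#' Kaplan-Meier estimate (via \code{survival::survfit}) returned as a
#' plain table of event times with cumulative incidence
#' \code{1 - S(t)}.
#'
#' @param time Follow-up times (age scale).
#' @param event 1 = event, 0 = censored.
#' @return Data frame: \code{time}, \code{n_risk}, \code{n_event},
#'   \code{n_censor}, \code{surv}, \code{cum_inc}.
#' @export
km_curve <- function(time, event) {
  stopifnot(length(time) == length(event), all(event %in% c(0, 1)))
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
             n_censor = sf$n.censor, surv = sf$surv,
             cum_inc = 1 - sf$surv)
}

# survival at a given age from a fitted curve table (step function,
# carried forward beyond the last observed time)
.surv_at <- function(curve, age) {
  ev <- curve[curve$n_event > 0, , drop = FALSE]
  if (!nrow(ev) || age < min(ev$time)) return(1)
  ev$surv[max(which(ev$time <= age))]
}

#' Cumulative incidence by age 80 in FH-by-PRS strata
#'
#' Kaplan-Meier cumulative incidence on the age scale (entry at birth),
#' with cases contributing their onset age and non-cases censored at death
#' or at their age at the end of registry follow-up.  Individuals are
#' stratified by the family-history flag crossed with the three-group PRS
#' categorization (high >90th percentile, average 33rd-90th, low <33rd,
#' percentiles within the analysis set).  Strata with fewer than
#' \code{min_cases} events are flagged and their estimate omitted.
#'
#' @param data Analysis frame (see \code{\link{analysis_frame}}) with
#'   \code{onset_age}, \code{death_age}, \code{birth_year} and the FH
#'   column.
#' @param registry A \code{\link{registry_windows}} (for the end of
#'   follow-up).
#' @param fh_kind FH exposure defining the strata.
#' @param age_eval Age at which cumulative incidence is reported.
#' @param min_cases Minimum events per stratum.
#' @return List with \code{curves} (long table of per-stratum curves) and
#'   \code{summary} (one row per stratum: \code{n}, \code{n_events},
#'   \code{cum_inc_at}, \code{ok}).
#' @export
km_cumulative_incidence <- function(data, registry,
                                    fh_kind = c("fh1", "fh2", "fhp"),
                                    age_eval = 80, min_cases = 10) {
  fh_kind <- match.arg(fh_kind)
  stopifnot(inherits(registry, "famprs_registry"))
  d <- data[!is.na(data[[fh_kind]]), , drop = FALSE]
  d$prs_group <- prs_band(d$prs, "three_group")
  admin_age <- registry$followup_end - d$birth_year
  cens_age <- pmin(ifelse(is.na(d$death_age), Inf, d$death_age), admin_age)
  event <- as.integer(d$case == 1L & !is.na(d$onset_age) &
                        d$onset_age <= cens_age)
  time <- ifelse(event == 1L, d$onset_age, cens_age)

  curves <- list(); summ <- list()
  for (fh in c(0L, 1L)) for (g in c("low", "average", "high")) {
    sel <- d[[fh_kind]] == fh & d$prs_group == g
    lab <- sprintf("%s=%d,prs=%s", fh_kind, fh, g)
    n_ev <- sum(event[sel])
    ok <- sum(sel) > 0L && n_ev >= min_cases
    ci <- NA_real_
    if (ok) {
      cv <- km_curve(time[sel], event[sel])
      cv$stratum <- lab; cv$fh <- fh; cv$prs_group <- g
      curves[[lab]] <- cv
      ci <- 1 - .surv_at(cv, age_eval)
    }
    summ[[lab]] <- data.frame(stratum = lab, fh = fh, prs_group = g,
                              n = sum(sel), n_events = n_ev,
                              cum_inc_at = ci, age_eval = age_eval,
                              ok = ok, stringsAsFactors = FALSE)
  }
  list(curves = if (length(curves)) do.call(rbind, curves) else NULL,
       summary = {
         s <- do.call(rbind, summ); rownames(s) <- NULL; s
       })
}
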