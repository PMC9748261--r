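# Relationship classification and derivation of the three family-history
# exposures: FH_1st (any affected first-degree relative in the cohort),
# FH_2nd (any affected second-degree relative), FH_P (disease among a
# parent's registered causes of death).

#' Classify a relative pair by kinship coefficient
#'
#' Uses the standard KING inference ranges: first degree for kinship in
#' (0.177, 0.354], second degree for (0.0884, 0.177], otherwise
#' \code{"other"}.  Boundary values belong to the closer-degree class
#' (half-open lower bound, closed upper bound).
#'
#' @param kinship Numeric vector of kinship coefficients in [0, 0.5].
#' @return Character vector: \code{"first"}, \code{"second"} or
#'   \code{"other"}.
#' @export
classify_relationship <- function(kinship) {
  if (!is.numeric(kinship) || any(is.na(kinship)) ||
      any(kinship < 0 | kinship > 0.5))
    stop("kinship must lie in [0, 0.5]", call. = FALSE)
  out <- rep("other", length(kinship))
  out[kinship > 0.177 & kinship <= 0.354] <- "first"
  out[kinship > 0.0884 & kinship <= 0.177] <- "second"
  out
}

# registry-observable affection: diagnosed inside the relevant diagnosis
# registry window and before death, or listed among registered causes of
# death inside the death-registry window
.affected_observable <- function(cohort, disease, registry) {
  sfx <- disease$disease_id
  status <- cohort[[paste0("status_", sfx)]]
  onset <- cohort[[paste0("onset_age_", sfx)]]
  cod <- cohort[[paste0("cod_", sfx)]]
  diag_start <- if (isTRUE(disease$cancer_registry))
    registry$cancer_registry_start else registry$discharge_registry_start
  onset_year <- cohort$birth_year + floor(onset)
  diag_ok <- status == 1L & !is.na(onset) &
    onset_year >= diag_start & onset_year <= registry$followup_end &
    (is.na(cohort$death_age) | onset <= cohort$death_age)
  death_ok <- !is.na(cohort$death_year) & !is.na(cod) & cod &
    cohort$death_year >= registry$death_registry_start &
    cohort$death_year <= registry$death_registry_end
  diag_ok | death_ok
}

.check_disease <- function(cohort, disease) {
  if (!inherits(disease, "famprs_disease"))
    stop("disease must be a disease_config() object", call. = FALSE)
  if (!paste0("status_", disease$disease_id) %in% names(cohort))
    stop(sprintf("disease '%s' not present in cohort", disease$disease_id),
         call. = FALSE)
}

.index_set <- function(cohort, disease) {
  if (disease$sex == "both") cohort else
    cohort[cohort$sex == disease$sex, , drop = FALSE]
}

.derive_fh_degree <- function(cohort, pairs, disease, registry, degree) {
  .check_disease(cohort, disease)
  idx <- .index_set(cohort, disease)
  aff <- .affected_observable(cohort, disease, registry)
  names(aff) <- cohort$id
  pr <- pairs[pairs$degree == degree, , drop = FALSE]
  if (disease$sex != "both") {
    rel_sex <- cohort$sex[match(pr$relative_id, cohort$id)]
    pr <- pr[rel_sex == disease$sex, , drop = FALSE]
  }
  rel_aff <- as.integer(aff[pr$relative_id])
  any_aff <- tapply(rel_aff, pr$index_id, max)
  n_rel <- tapply(rel_aff, pr$index_id, length)
  m <- match(idx$id, names(any_aff))
  fh <- ifelse(is.na(m), 0L, as.integer(any_aff[m]))
  data.frame(individual_id = idx$id,
             fh = fh,
             n_rel = ifelse(is.na(m), 0L, as.integer(n_rel[m])),
             stringsAsFactors = FALSE)
}

#' First-degree family history
#'
#' \code{fh1 = 1} iff at least one first-degree relative present in the
#' cohort is observably affected (diagnosis inside the diagnosis-registry
#' window, or the disease among registered causes of death).  For
#' sex-restricted diseases both the index set and the relatives considered
#' are restricted to the relevant sex.  Individuals without first-degree
#' relatives in the cohort get \code{fh1 = 0} with \code{n_rel1 = 0}
#' (low-information: ascertainment rests on relatives actually present).
#'
#' @param cohort Cohort table.
#' @param pairs Relative-pair table (both ordered directions).
#' @param disease A \code{\link{disease_config}}.
#' @param registry A \code{\link{registry_windows}}.
#' @return Data frame with \code{individual_id}, \code{fh1}, \code{n_rel1}.
#' @export
derive_fh1 <- function(cohort, pairs, disease, registry) {
  out <- .derive_fh_degree(cohort, pairs, disease, registry, "first")
  names(out) <- c("individual_id", "fh1", "n_rel1")
  out
}

#' Second-degree family history
#'
#' As \code{\link{derive_fh1}} but over second-degree relatives
#' (grandparental and avuncular pairs).  First-degree relatives never
#' contribute: the two exposures are defined independently.
#'
#' @inheritParams derive_fh1
#' @return Data frame with \code{individual_id}, \code{fh2}, \code{n_rel2}.
#' @export
derive_fh2 <- function(cohort, pairs, disease, registry) {
  out <- .derive_fh_degree(cohort, pairs, disease, registry, "second")
  names(out) <- c("individual_id", "fh2", "n_rel2")
  out
}

#' Parental-cause-of-death family history
#'
#' \code{fhp = 1} iff any observable parental death record (death year
#' inside the death-registry window) lists the disease among its causes.
#' Individuals whose parents both died before the registry start, or whose
#' parental records are both missing, are ineligible and carry
#' \code{fhp = NA}.  Among \code{fhp = 1} individuals the parental age at
#' death (the younger one if both parents are cause-positive) is split into
#' tertiles, boundary values assigned to the lower tertile.
#'
#' @inheritParams derive_fh1
#' @param cohort Cohort processed by \code{\link{record_parental_deaths}}.
#' @return Data frame with \code{individual_id}, \code{fhp_eligible},
#'   \code{fhp}, \code{fhp_parent_death_age}, \code{fhp_age_tertile}.
#' @export
derive_fhp <- function(cohort, disease, registry) {
  .check_disease(cohort, disease)
  if (!"father_death_observable" %in% names(cohort))
    stop("run record_parental_deaths() on the cohort first", call. = FALSE)
  idx <- .index_set(cohort, disease)
  sfx <- disease$disease_id

  pre <- function(side) {
    inc <- idx[[paste0(side, "_in_cohort")]]
    dy <- idx[[paste0(side, "_death_year")]]
    inc & !is.na(dy) & dy < registry$death_registry_start
  }
  both_missing <- !idx$father_in_cohort & !idx$mother_in_cohort
  both_pre <- pre("father") & pre("mother")
  eligible <- !(both_missing | both_pre)

  # sex-restricted diseases: only the relevant-sex parent can carry the cause
  sides <- switch(disease$sex, both = c("father", "mother"),
                  male = "father", female = "mother")
  pos_age <- matrix(NA_real_, nrow(idx), length(sides))
  pos <- rep(FALSE, nrow(idx))
  for (j in seq_along(sides)) {
    side <- sides[j]
    obs <- idx[[paste0(side, "_death_observable")]]
    cod <- idx[[paste0(side, "_cod_", sfx)]]
    p <- !is.na(obs) & obs & !is.na(cod) & cod
    pos <- pos | p
    pos_age[p, j] <- idx[[paste0(side, "_death_age")]][p]
  }
  fhp <- ifelse(eligible, as.integer(pos), NA_integer_)
  age <- suppressWarnings(apply(pos_age, 1, min, na.rm = TRUE))
  age[!is.finite(age)] <- NA_real_
  age[is.na(fhp) | fhp == 0L] <- NA_real_

  tert <- rep(NA_integer_, nrow(idx))
  sel <- !is.na(fhp) & fhp == 1L & !is.na(age)
  if (sum(sel) >= 3L) {
    qs <- stats::quantile(age[sel], c(1 / 3, 2 / 3), names = FALSE)
    tert[sel] <- ifelse(age[sel] <= qs[1], 1L,
                        ifelse(age[sel] <= qs[2], 2L, 3L))
  }
  data.frame(individual_id = idx$id, fhp_eligible = eligible, fhp = fhp,
             fhp_parent_death_age = age, fhp_age_tertile = tert,
             stringsAsFactors = FALSE)
}

#' Derive all three family-history exposures
#'
#' Convenience wrapper joining \code{\link{derive_fh1}},
#' \code{\link{derive_fh2}} and \code{\link{derive_fhp}} for one disease.
#'
#' @inheritParams derive_fhp
#' @param pairs Relative-pair table.
#' @return One data frame keyed by \code{individual_id}.
#' @export
derive_family_history <- function(cohort, pairs, disease, registry) {
  f1 <- derive_fh1(cohort, pairs, disease, registry)
  f2 <- derive_fh2(cohort, pairs, disease, registry)
  fp <- derive_fhp(cohort, disease, registry)
  out <- merge(merge(f1, f2, by = "individual_id"), fp,
               by = "individual_id")
  out[order(out$individual_id), , drop = FALSE]
}

#' Assemble a per-disease analysis frame
#'
#' Joins the cohort and a family-history table into the flat frame the
#' association functions operate on: \code{case} (lifetime threshold
#' status), \code{prs} (and \code{prs_small} when generated), the FH
#' columns, and the covariates \code{sex} and \code{birth_year}.
#'
#' @param cohort Cohort table.
#' @param fh Family-history table from \code{\link{derive_family_history}}
#'   (or any frame keyed by \code{individual_id}).
#' @param disease A \code{\link{disease_config}}.
#' @param one_per_family Keep a single index individual (from the youngest
#'   generation) per family, so rows are independent across families.
#' @return A data frame, one row per analyzed individual.
#' @export
analysis_frame <- function(cohort, fh, disease, one_per_family = FALSE) {
  .check_disease(cohort, disease)
  sfx <- disease$disease_id
  df <- data.frame(id = cohort$id, family_id = cohort$family_id,
                   generation = cohort$generation, sex = cohort$sex,
                   birth_year = cohort$birth_year,
                   case = cohort[[paste0("status_", sfx)]],
                   prs = cohort[[paste0("PRS_", sfx)]],
                   onset_age = cohort[[paste0("onset_age_", sfx)]],
                   death_age = cohort$death_age,
                   stringsAsFactors = FALSE)
  ps <- paste0("PRS_small_", sfx)
  if (ps %in% names(cohort)) df$prs_small <- cohort[[ps]]
  df <- merge(df, fh, by.x = "id", by.y = "individual_id")
  if (one_per_family) {
    df <- df[order(-df$generation, df$id), , drop = FALSE]
    df <- df[!duplicated(df$family_id), , drop = FALSE]
  }
  df <- df[order(df$id), , drop = FALSE]
  rownames(df) <- NULL
  df
}
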