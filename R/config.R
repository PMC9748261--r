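#' Disease model configuration
#'
#' Parameters of one disease under the liability-threshold model.  Liability
#' is decomposed as L = G + C + E with Var(L) = 1: G is the total additive
#' genetic component (variance \code{h2}), C a shared-family environment
#' (variance \code{c2}) and E the unique environment (variance
#' \code{1 - h2 - c2}).  The polygenic risk score measures an additive
#' sub-component of G with variance \code{rho2}; the standardized PRS
#' therefore correlates \code{sqrt(rho2)} with liability.  Disease occurs
#' when L exceeds the threshold set by the lifetime prevalence \code{K}.
#'
#' @param disease_id Character identifier (used as a column suffix).
#' @param K Lifetime prevalence, in (0, 1).
#' @param h2 Narrow-sense heritability of liability, in [0, 1].
#' @param rho2 Liability variance captured by the PRS, in [0, h2].  With
#'   \code{rho2 = 0} no PRS is generated for this disease.
#' @param c2 Shared-family environment variance, in [0, 1 - h2].
#' @param onset_mean,onset_sd Mean and SD (years) of the age-at-onset
#'   distribution (normal truncated to (0, 100]).
#' @param onset_shift Years of earlier onset per unit of liability in excess
#'   of the disease threshold (default 0: onset independent of liability).
#'   A positive value links high liability to early onset, which is what the
#'   parental age-at-death tertile analysis probes.
#' @param cause_of_death_prob Probability that a deceased case's death
#'   record lists the disease among its causes (immediate, contributing and
#'   underlying causes are not distinguished).
#' @param survival_after_onset_mean,survival_after_onset_sd Mean and SD
#'   (years) of survival after onset, normal truncated to [0, 60]; a case
#'   dies at the earlier of the background death age and onset plus this
#'   survival.  The default \code{Inf} leaves mortality independent of the
#'   disease.  A finite value, combined with \code{onset_shift > 0}, links
#'   high liability to early onset and hence to early, cause-positive
#'   parental death -- the structure the parental age-at-death tertile
#'   analysis probes.
#' @param cancer_registry Logical; if \code{TRUE} relatives' diagnoses are
#'   ascertainable from the cancer-registry start year rather than the
#'   hospital-discharge start year.
#' @param sex One of \code{"both"}, \code{"female"}, \code{"male"}: restrict
#'   the disease (and its analysis set) to one sex, as for breast and
#'   prostate cancer.
#' @param rho2_small Optional variance of a nested sub-score (a PRS built
#'   from fewer variants); must be < \code{rho2}.  Enables
#'   \code{\link{compare_prs_capture}}.
#' @return An object of class \code{famprs_disease}.
#' @export
disease_config <- function(disease_id, K, h2, rho2, c2 = 0,
                           onset_mean = 60, onset_sd = 12, onset_shift = 0,
                           cause_of_death_prob = 0.7,
                           survival_after_onset_mean = Inf,
                           survival_after_onset_sd = 8,
                           cancer_registry = FALSE,
                           sex = c("both", "female", "male"),
                           rho2_small = NULL) {
  sex <- match.arg(sex)
  stopifnot(is.character(disease_id), length(disease_id) == 1L,
            nchar(disease_id) > 0L)
  if (!is.numeric(K) || length(K) != 1L || K <= 0 || K >= 1)
    stop("K must be in (0, 1)", call. = FALSE)
  if (h2 < 0 || h2 > 1) stop("h2 must be in [0, 1]", call. = FALSE)
  if (rho2 < 0 || rho2 > h2)
    stop("rho2 must be in [0, h2]", call. = FALSE)
  if (c2 < 0 || h2 + c2 > 1)
    stop("h2 + c2 must not exceed 1", call. = FALSE)
  if (onset_sd <= 0) stop("onset_sd must be positive", call. = FALSE)
  if (cause_of_death_prob <= 0 || cause_of_death_prob > 1)
    stop("cause_of_death_prob must be in (0, 1]", call. = FALSE)
  if (!is.null(rho2_small)) {
    if (rho2_small <= 0 || rho2_small >= rho2)
      stop("rho2_small must be in (0, rho2)", call. = FALSE)
  }
  if (!is.infinite(survival_after_onset_mean) &&
      (survival_after_onset_mean < 0 || survival_after_onset_sd <= 0))
    stop("invalid survival-after-onset parameters", call. = FALSE)
  structure(list(disease_id = disease_id, K = K, h2 = h2, rho2 = rho2,
                 c2 = c2, onset_mean = onset_mean, onset_sd = onset_sd,
                 onset_shift = onset_shift,
                 cause_of_death_prob = cause_of_death_prob,
                 survival_after_onset_mean = survival_after_onset_mean,
                 survival_after_onset_sd = survival_after_onset_sd,
                 cancer_registry = cancer_registry, sex = sex,
                 rho2_small = rho2_small),
            class = "famprs_disease")
}

#' Registry availability windows
#'
#' Calendar windows during which the national registries record events.
#' Defaults mirror the Finnish registries: causes of death from 1964
#' (records used through 2018), hospital discharges from 1968, cancer
#' registry from 1953, with study follow-up ending in 2019.  Events outside
#' a registry's window are invisible to family-history derivation.
#'
#' @param death_registry_start,death_registry_end Window of the causes of
#'   death registry as used for parental records.
#' @param discharge_registry_start First year of hospital discharge records.
#' @param cancer_registry_start First year of cancer-registry records.
#' @param followup_end Last year of diagnosis follow-up.
#' @return An object of class \code{famprs_registry}.
#' @export
registry_windows <- function(death_registry_start = 1964,
                             discharge_registry_start = 1968,
                             cancer_registry_start = 1953,
                             death_registry_end = 2018,
                             followup_end = 2019) {
  if (death_registry_start >= death_registry_end)
    stop("death registry start must precede its end", call. = FALSE)
  if (discharge_registry_start >= followup_end ||
      cancer_registry_start >= followup_end)
    stop("registry starts must precede the end of follow-up", call. = FALSE)
  structure(list(death_registry_start = death_registry_start,
                 discharge_registry_start = discharge_registry_start,
                 cancer_registry_start = cancer_registry_start,
                 death_registry_end = death_registry_end,
                 followup_end = followup_end),
            class = "famprs_registry")
}

#' Simulation plan
#'
#' Full description of a synthetic cohort: pedigree structure, birth-year
#' placement, mortality, registry windows and the disease models.  With
#' \code{generations = 3} each family consists of two founder couples
#' (paternal and maternal grandparents), their children (the father, the
#' mother, and their full siblings -- the index generation's aunts/uncles),
#' and the index-generation children, so that first-degree
#' (parent-offspring, full sibling) and second-degree (grandparental,
#' avuncular) pairs arise from one coherent pedigree.
#'
#' @param n_families Number of families.
#' @param diseases List of \code{\link{disease_config}} objects.
#' @param generations 2 or 3.
#' @param seed Integer root seed.  Families are simulated in fixed-size
#'   blocks with per-block substreams derived from the root seed, so
#'   enlarging \code{n_families} appends families without altering the ones
#'   already generated.
#' @param birth_year_range Two calendar years bounding the index
#'   generation's birth years (uniform within).
#' @param registry A \code{\link{registry_windows}} object.
#' @param n_children Children per nuclear family (the index generation).
#' @param n_paternal_sibs,n_maternal_sibs Full siblings of the father and
#'   of the mother (three-generation plans only).
#' @param parent_gap_mean,parent_gap_sd Parental age at (first) birth,
#'   normal truncated to [18, 45] years.
#' @param death_age_mean,death_age_sd Age at death, normal truncated to
#'   [20, 105] years; individuals whose death falls after the end of
#'   follow-up are alive (missing death record).
#' @param c_parent_share Fraction of the shared environment C that a parent
#'   shares with their children (full siblings always share C fully); must
#'   lie in [0, sqrt(0.5)].
#' @param block_size Families per random-number block.
#' @return An object of class \code{famprs_plan}.
#' @export
simulation_plan <- function(n_families, diseases, generations = 3, seed = 1,
                            birth_year_range = c(1945, 1975),
                            registry = registry_windows(),
                            n_children = 2, n_paternal_sibs = 1,
                            n_maternal_sibs = 1,
                            parent_gap_mean = 28, parent_gap_sd = 4,
                            death_age_mean = 76, death_age_sd = 12,
                            c_parent_share = 0.5, block_size = 1000) {
  if (!is.numeric(n_families) || n_families < 1)
    stop("n_families must be >= 1", call. = FALSE)
  if (!generations %in% c(2, 3))
    stop("generations must be 2 or 3", call. = FALSE)
  if (inherits(diseases, "famprs_disease")) diseases <- list(diseases)
  if (!length(diseases) || !all(vapply(diseases, inherits, logical(1),
                                       "famprs_disease")))
    stop("diseases must be a list of disease_config() objects", call. = FALSE)
  ids <- vapply(diseases, `[[`, character(1), "disease_id")
  if (anyDuplicated(ids)) stop("duplicate disease_id", call. = FALSE)
  names(diseases) <- ids
  stopifnot(inherits(registry, "famprs_registry"),
            length(birth_year_range) == 2L,
            birth_year_range[1] <= birth_year_range[2],
            n_children >= 1, n_paternal_sibs >= 0, n_maternal_sibs >= 0)
  if (c_parent_share < 0 || c_parent_share > sqrt(0.5) + 1e-12)
    stop("c_parent_share must lie in [0, sqrt(0.5)]", call. = FALSE)
  structure(list(n_families = as.integer(n_families), diseases = diseases,
                 generations = as.integer(generations),
                 seed = as.integer(seed),
                 birth_year_range = as.integer(birth_year_range),
                 registry = registry, n_children = as.integer(n_children),
                 n_paternal_sibs = as.integer(n_paternal_sibs),
                 n_maternal_sibs = as.integer(n_maternal_sibs),
                 parent_gap_mean = parent_gap_mean,
                 parent_gap_sd = parent_gap_sd,
                 death_age_mean = death_age_mean,
                 death_age_sd = death_age_sd,
                 c_parent_share = c_parent_share,
                 block_size = as.integer(block_size)),
            class = "famprs_plan")
}

#' @export
print.famprs_plan <- function(x, ...) {
  cat(sprintf("famprs simulation plan: %d families, %d generations, seed %d\n",
              x$n_families, x$generations, x$seed))
  for (d in x$diseases)
    cat(sprintf("  %s: K=%.3g h2=%.2f rho2=%.2f c2=%.2f%s\n", d$disease_id,
                d$K, d$h2, d$rho2, d$c2,
                if (d$sex != "both") paste0(" (", d$sex, " only)") else ""))
  invisible(x)
}
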