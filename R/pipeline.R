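# End-to-end orchestration: simulate -> derive FH -> association analyses
# -> concordance -> cumulative incidence, with a machine-readable summary
# and a run manifest.

.stage <- function(label, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", label, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes every stage on one simulated cohort and writes a bundle of
#' TSV tables, a versioned JSON summary with the headline statistics
#' (per-disease effects, mean attenuations, interaction-test counts,
#' concordances, cumulative incidences) and a run manifest.  Identical
#' plan and seed yield a byte-identical summary.  Non-fatal issues
#' (omitted strata, skipped analyses) are collected as warnings in the
#' summary rather than aborting, while stage errors abort with a
#' stage-labeled message.
#'
#' @param plan A \code{famprs_plan}, or the path of a YAML/JSON config.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional integer overriding the plan's seed.
#' @param n_tests Number of tests for the Bonferroni flag of the
#'   interaction tests; defaults to the number performed in this run.
#' @return Invisibly, the summary list.
#' @export
run_pipeline <- function(plan, out_dir, seed = NULL, n_tests = NULL) {
  if (is.character(plan)) {
    config_path <- plan
    plan <- .stage("config", read_plan(plan, seed = seed))
  } else {
    stopifnot(inherits(plan, "famprs_plan"))
    config_path <- NULL
    if (!is.null(seed)) plan$seed <- as.integer(seed)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  sim <- .stage("simulate", simulate_cohort(plan))
  cohort <- .stage("parental-deaths",
                   record_parental_deaths(sim$cohort, plan$registry))
  write_tsv(cohort, file.path(out_dir, "cohort.tsv"))
  write_tsv(sim$pairs, file.path(out_dir, "pairs.tsv"))

  warnings <- character(0)
  reg_rows <- list(); att_rows <- list(); int_rows <- list()
  km_rows <- list(); conc_rows <- list()
  if (is.null(n_tests)) n_tests <- max(1L, length(plan$diseases))

  for (d in plan$diseases) {
    id <- d$disease_id
    fh <- .stage(paste0("derive-fh:", id),
                 derive_family_history(cohort, sim$pairs, d, plan$registry))
    write_tsv(fh, file.path(out_dir, paste0("fh_", id, ".tsv")))
    af <- analysis_frame(cohort, fh, d)
    if (all(is.na(af$prs))) {
      warnings <- c(warnings, sprintf("%s: no PRS (rho2 = 0), skipped", id))
      next
    }
    r <- .stage(paste0("analyze:", id), {
      r_prs <- fit_logistic(af, "prs")
      r_fh <- fit_logistic(af, "fh1")
      r_band <- prs_banded_effects(af, "top_decile")
      rbind(cbind(disease = id, model = "prs", r_prs),
            cbind(disease = id, model = "fh1", r_fh),
            cbind(disease = id, model = "top_decile",
                  r_band[names(r_prs)]))
    })
    reg_rows[[id]] <- r
    att <- .stage(paste0("cross-adjust:", id),
                  cbind(disease = id, cross_adjust(af, "fh1")))
    att_rows[[id]] <- att
    it <- .stage(paste0("interaction:", id),
                 cbind(disease = id,
                       interaction_test(af, "fh1", n_tests = n_tests)))
    int_rows[[id]] <- it
    km <- .stage(paste0("incidence:", id),
                 km_cumulative_incidence(af, plan$registry, "fh1"))
    km_rows[[id]] <- cbind(disease = id, km$summary)
    if (any(!km$summary$ok))
      warnings <- c(warnings,
                    sprintf("%s: %d incidence strata omitted (<10 cases)",
                            id, sum(!km$summary$ok)))
    conc_rows[[id]] <- .stage(paste0("concordance:", id),
      cbind(disease = id,
            observed_concordance(sim$pairs, cohort, d,
                                 stratify_by_disease = TRUE)))
  }

  reg <- do.call(rbind, reg_rows); att <- do.call(rbind, att_rows)
  ints <- do.call(rbind, int_rows); kms <- do.call(rbind, km_rows)
  conc <- do.call(rbind, conc_rows)
  if (!is.null(reg)) write_tsv(reg, file.path(out_dir, "regression.tsv"))
  if (!is.null(att)) write_tsv(att, file.path(out_dir, "attenuation.tsv"))
  if (!is.null(ints)) write_tsv(ints, file.path(out_dir, "interaction.tsv"))
  if (!is.null(kms)) write_tsv(kms, file.path(out_dir, "km_summary.tsv"))
  if (!is.null(conc)) write_tsv(conc, file.path(out_dir, "concordance.tsv"))

  summary <- list(
    schema_version = "1.0",
    seed = plan$seed,
    n_families = plan$n_families,
    n_individuals = nrow(cohort),
    diseases = names(plan$diseases),
    attenuation_summary = if (!is.null(att) &&
                              length(unique(att$disease)) >= 2)
      attenuation_summary(att) else NULL,
    interaction_tests = if (!is.null(ints))
      list(n = nrow(ints), n_significant = sum(ints$significant),
           threshold = ints$threshold[1]) else NULL,
    concordance = conc,
    cumulative_incidence = kms,
    warnings = warnings)
  json_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE, dataframe = "columns")

  plan_path <- file.path(out_dir, "plan.json")
  jsonlite::write_json(.plan_as_list(plan), plan_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest <- list(
    config_hash = unname(tools::md5sum(plan_path)),
    config_file = config_path,
    seed = plan$seed,
    package_version = as.character(utils::packageVersion("famprs")),
    outputs = list.files(out_dir),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(summary)
}

.plan_as_list <- function(plan) {
  p <- unclass(plan)
  p$registry <- unclass(p$registry)
  p$diseases <- lapply(p$diseases, unclass)
  p
}
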