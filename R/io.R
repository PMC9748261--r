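# Tab-separated I/O for the cohort, pair and result tables, PED-like
# pedigree export, and plan configuration files (YAML or JSON).

#' Write a table as TSV
#'
#' Tab-separated, no quoting, missing values as empty strings -- the
#' package's documented on-disk format for cohort, pair, FH and result
#' tables.
#'
#' @param x Data frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by \code{\link{write_tsv}}
#'
#' @param path Input path.
#' @return Data frame; empty fields become \code{NA}, identifiers stay
#'   character.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, na.strings = "",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Export pedigree links in PED-like format
#'
#' Columns family, id, father, mother, sex (1 = male, 2 = female),
#' phenotype (2 = affected, 1 = unaffected for the given disease, -9 if no
#' disease requested); founders' parent fields are 0.
#'
#' @param cohort Cohort table.
#' @param path Output path.
#' @param disease Optional \code{\link{disease_config}} supplying the
#'   phenotype column.
#' @return \code{path}, invisibly.
#' @export
write_ped <- function(cohort, path, disease = NULL) {
  phe <- rep(-9L, nrow(cohort))
  if (!is.null(disease)) {
    .check_disease(cohort, disease)
    phe <- cohort[[paste0("status_", disease$disease_id)]] + 1L
  }
  ped <- data.frame(family = cohort$family_id, id = cohort$id,
                    father = ifelse(is.na(cohort$father_id), "0",
                                    cohort$father_id),
                    mother = ifelse(is.na(cohort$mother_id), "0",
                                    cohort$mother_id),
                    sex = ifelse(cohort$sex == "male", 1L, 2L),
                    phenotype = phe, stringsAsFactors = FALSE)
  utils::write.table(ped, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a simulation plan from a YAML or JSON config file
#'
#' The file maps directly onto \code{\link{simulation_plan}} arguments,
#' with \code{diseases} a list of \code{\link{disease_config}} argument
#' sets and \code{registry} an optional \code{\link{registry_windows}}
#' argument set.  Validation happens at construction, before any
#' simulation starts.
#'
#' @param path Config file path (YAML; JSON is a YAML subset).
#' @param seed Optional integer overriding the file's seed.
#' @return A \code{famprs_plan}.
#' @export
read_plan <- function(path, seed = NULL) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$diseases)) stop("config has no diseases", call. = FALSE)
  diseases <- lapply(cfg$diseases, function(d) do.call(disease_config, d))
  cfg$diseases <- diseases
  if (!is.null(cfg$registry))
    cfg$registry <- do.call(registry_windows, cfg$registry)
  if (!is.null(cfg$birth_year_range))
    cfg$birth_year_range <- unlist(cfg$birth_year_range)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  do.call(simulation_plan, cfg)
}
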