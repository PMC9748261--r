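test_that("kinship classification follows the KING ranges", {
  expect_identical(classify_relationship(0.25), "first")
  expect_identical(classify_relationship(0.125), "second")
  expect_identical(classify_relationship(0.05), "other")
  # boundary values belong to the closer-degree class
  expect_identical(classify_relationship(c(0.354, 0.177, 0.0884)),
                   c("first", "second", "other"))
  expect_identical(classify_relationship(0.177 + 1e-9), "first")
  expect_error(classify_relationship(0.6), "kinship")
  expect_error(classify_relationship(-0.1), "kinship")
  # the simulator's pair table is internally consistent with the ranges
  pr <- big_sim()$pairs
  expect_identical(unname(classify_relationship(pr$kinship)), pr$degree)
})

test_that("first-degree FH flags affected relatives, not the index person", {
  reg <- registry_windows()
  d <- disease_config("d1", K = 0.1, h2 = 0.4, rho2 = 0.2)
  co <- record_parental_deaths(toy_cohort(), reg)
  f1 <- derive_fh1(co, toy_pairs(), d, reg)
  # children have an affected father (diagnosed 1985, inside window)
  expect_equal(f1$fh1[f1$individual_id %in% c("c1", "c2")], c(1L, 1L))
  # the mother's only first-degree relatives in the cohort are her
  # children, both healthy
  expect_equal(f1$fh1[f1$individual_id == "mo"], 0L)
  # fa's father gf is affected (cause of death 1990, observable)
  expect_equal(f1$fh1[f1$individual_id == "fa"], 1L)
  expect_equal(f1$n_rel1[f1$individual_id == "gf"], 1L)
})

test_that("diagnosis outside the registry window does not create FH", {
  reg <- registry_windows()
  d <- disease_config("d1", K = 0.1, h2 = 0.4, rho2 = 0.2)
  co <- toy_cohort()
  co$onset_age_d1[co$id == "fa"] <- 20   # 1960: before discharge registry
  co$cod_d1[co$id == "gf"] <- FALSE      # no registered cause either
  co <- record_parental_deaths(co, reg)
  f1 <- derive_fh1(co, toy_pairs(), d, reg)
  expect_equal(f1$fh1[f1$individual_id == "c1"], 0L)
  # cancer-registry diseases reach further back
  dc <- disease_config("d1", K = 0.1, h2 = 0.4, rho2 = 0.2,
                       cancer_registry = TRUE)
  f1c <- derive_fh1(co, toy_pairs(), dc, reg)
  expect_equal(f1c$fh1[f1c$individual_id == "c1"], 1L)
})

test_that("second-degree FH is independent of first-degree relatives", {
  reg <- registry_windows()
  d <- disease_config("d1", K = 0.1, h2 = 0.4, rho2 = 0.2)
  co <- record_parental_deaths(toy_cohort(), reg)
  f2 <- derive_fh2(co, toy_pairs(), d, reg)
  # c1's grandparent gf is affected -> fh2 = 1
  expect_equal(f2$fh2[f2$individual_id == "c1"], 1L)
  # the affected father is first-degree: he must not contribute to fh2
  co2 <- co
  co2$status_d1[co2$id == "gf"] <- 0L
  co2$cod_d1[co2$id == "gf"] <- FALSE
  f2b <- derive_fh2(co2, toy_pairs(), d, reg)
  expect_equal(f2b$fh2[f2b$individual_id == "c1"], 0L)
  # no second-degree relatives in cohort -> fh2 = 0, flagged low-information
  expect_equal(f2$n_rel2[f2$individual_id == "mo"], 0L)
  expect_equal(f2$fh2[f2$individual_id == "mo"], 0L)
})

test_that("sex-restricted diseases restrict index set and relatives", {
  reg <- registry_windows()
  dp <- disease_config("d1", K = 0.1, h2 = 0.4, rho2 = 0.2, sex = "male")
  co <- record_parental_deaths(toy_cohort(), reg)
  f1 <- derive_fh1(co, toy_pairs(), dp, reg)
  # female index persons are excluded from the analysis set entirely
  expect_false("c1" %in% f1$individual_id)
  expect_false("mo" %in% f1$individual_id)
  expect_true(all(c("fa", "c2", "gf") %in% f1$individual_id))
})

test_that("FH_P eligibility excludes exactly the both-unobservable rows", {
  reg <- registry_windows()
  d <- disease_config("dx", K = 0.1, h2 = 0.4, rho2 = 0.2)
  # five index individuals with parental death years:
  # {1950/1955, 1970/1980, missing/missing, 1990/alive, 1960/2019}
  par_defs <- list(c(1950, 1955), c(1970, 1980), NULL, c(1990, NA),
                   c(1960, 2019))
  rows <- list()
  for (i in seq_along(par_defs)) {
    pd <- par_defs[[i]]
    has_par <- !is.null(pd)
    rows[[length(rows) + 1L]] <- data.frame(
      id = sprintf("i%d", i), family_id = sprintf("F%d", i), role = "c1",
      generation = 2L,
      father_id = if (has_par) sprintf("fa%d", i) else NA_character_,
      mother_id = if (has_par) sprintf("mo%d", i) else NA_character_,
      sex = "female", birth_year = 1945L, death_year = NA_integer_,
      death_age = NA_real_, G_dx = 0, L_dx = 0, PRS_dx = 0,
      status_dx = 0L, onset_age_dx = NA_real_, cod_dx = NA,
      stringsAsFactors = FALSE)
    if (has_par) {
      for (j in 1:2) {
        dy <- pd[j]
        rows[[length(rows) + 1L]] <- data.frame(
          id = sprintf(c("fa%d", "mo%d")[j], i),
          family_id = sprintf("F%d", i), role = c("fa", "mo")[j],
          generation = 1L, father_id = NA_character_,
          mother_id = NA_character_,
          sex = c("male", "female")[j], birth_year = 1915L,
          death_year = if (is.na(dy)) NA_integer_ else as.integer(dy),
          death_age = if (is.na(dy)) NA_real_ else dy - 1915,
          G_dx = 0, L_dx = 0, PRS_dx = 0, status_dx = 1L,
          onset_age_dx = 30, cod_dx = if (is.na(dy)) NA else TRUE,
          stringsAsFactors = FALSE)
      }
    }
  }
  co <- record_parental_deaths(do.call(rbind, rows), reg)
  fp <- derive_fhp(co, d, reg)
  fp <- fp[fp$individual_id %in% sprintf("i%d", 1:5), ]
  fp <- fp[order(fp$individual_id), ]
  # i1 (both pre-1964) and i3 (both missing) are excluded; 2 of 5
  expect_identical(fp$fhp_eligible, c(FALSE, TRUE, FALSE, TRUE, TRUE))
  expect_equal(sum(!fp$fhp_eligible), 2L)
  # bookkeeping: total = eligible + excluded
  expect_equal(nrow(fp), sum(fp$fhp_eligible) + sum(!fp$fhp_eligible))
  # i2: observable cause-positive parents -> fhp = 1
  expect_equal(fp$fhp[fp$individual_id == "i2"], 1L)
  # i5: one parent pre-1964, the other died 2019 (after the 2018 cutoff):
  # eligible but no observable cause-positive record
  expect_equal(fp$fhp[fp$individual_id == "i5"], 0L)
  # ineligible rows carry NA
  expect_true(all(is.na(fp$fhp[!fp$fhp_eligible])))
})

test_that("FH_P tertiles split cause-positive parents by age at death", {
  sim <- big_sim(); d <- big_disease()
  fp <- derive_fhp(sim$cohort, d, sim$plan$registry)
  pos <- fp[!is.na(fp$fhp) & fp$fhp == 1L, ]
  expect_gt(nrow(pos), 100)
  tab <- table(pos$fhp_age_tertile)
  expect_identical(sort(names(tab)), c("1", "2", "3"))
  # tertile sizes balanced up to ties
  expect_lt(max(tab) / min(tab), 1.25)
  # ordering of ages respects tertile membership
  expect_lt(max(pos$fhp_parent_death_age[pos$fhp_age_tertile == 1]),
            min(pos$fhp_parent_death_age[pos$fhp_age_tertile == 3]))
  # exclusion bookkeeping on the full cohort
  expect_equal(nrow(fp), sum(fp$fhp_eligible) + sum(!fp$fhp_eligible))
})

test_that("FH_1st prevalence rises with disease prevalence", {
  reg <- registry_windows()
  fh_prev <- vapply(c(0.05, 0.15, 0.3), function(K) {
    d <- disease_config("dk", K = K, h2 = 0.5, rho2 = 0.2)
    sim <- simulate_cohort(simulation_plan(800, d, generations = 2,
                                           seed = 77, block_size = 800))
    co <- record_parental_deaths(sim$cohort, reg)
    mean(derive_fh1(co, sim$pairs, d, reg)$fh1)
  }, numeric(1))
  expect_true(all(diff(fh_prev) > 0))
})

test_that("fitted FH_1st effect exceeds FH_2nd under heritable liability", {
  sim <- big_sim(); d <- big_disease()
  fh <- derive_family_history(sim$cohort, sim$pairs, d, sim$plan$registry)
  af <- analysis_frame(sim$cohort, fh, d)
  b1 <- fit_logistic(af, "fh1")$beta
  af2 <- af[af$n_rel2 > 0, ]
  b2 <- fit_logistic(af2, "fh2")$beta
  expect_gt(b1, b2)
  expect_gt(b2, 0)
})
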