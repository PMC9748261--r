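# Helper: a 2x2 exposure/outcome frame with the given cell counts
tab2x2 <- function(case_exp, ctrl_exp, case_unexp, ctrl_unexp) {
  data.frame(
    case = rep(c(1, 0, 1, 0), c(case_exp, ctrl_exp, case_unexp, ctrl_unexp)),
    x = rep(c(1, 1, 0, 0), c(case_exp, ctrl_exp, case_unexp, ctrl_unexp)),
    sex = "female", birth_year = 1950)
}

test_that("single-binary-predictor logistic equals the contingency OR", {
  suppressMessages({
    r <- fit_logistic(tab2x2(20, 80, 10, 90), "x")
  })
  expect_equal(r$or_, (20 * 90) / (80 * 10), tolerance = 1e-7)
  expect_equal(r$or_, 2.25, tolerance = 1e-7)
  # and on further tables without zero cells
  for (cc in list(c(30, 70, 15, 85), c(5, 95, 40, 60))) {
    suppressMessages(r2 <- fit_logistic(do.call(tab2x2, as.list(cc)), "x"))
    expect_equal(r2$or_, (cc[1] * cc[4]) / (cc[2] * cc[3]),
                 tolerance = 1e-7)
  }
  # Wald CI identity
  expect_equal(r$ci_low, exp(r$beta - 1.96 * r$se))
  expect_equal(r$ci_high, exp(r$beta + 1.96 * r$se))
})

test_that("separation and degenerate exposures raise explicit errors", {
  d <- data.frame(case = rep(c(0, 1), 50), sex = "f", birth_year = 1950)
  d$x <- d$case
  suppressMessages({
    expect_error(fit_logistic(d, "x"), "separation")
    d$z <- 1
    expect_error(fit_logistic(d, "z"), "zero-variance")
  })
})

test_that("Bonferroni threshold reproduces the 24 + 15 test correction", {
  expect_equal(signif(bonferroni_threshold(0.05, 24 + 15), 2), 0.0013)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 10), 0.001)
  expect_error(bonferroni_threshold(0.05, 0), "n_tests")
  expect_error(bonferroni_threshold(1.5, 10), "alpha")
})

test_that("attenuation arithmetic and summary follow the log-odds scale", {
  att <- data.frame(exposure = "prs", adjustment = "fh1",
                    decrease = c(0.0, 0.2))
  s <- attenuation_summary(att)
  expect_equal(s$mean_decrease, 0.10)
  expect_equal(s$sd_decrease, 0.1414, tolerance = 1e-3)
  att2 <- data.frame(exposure = "prs", adjustment = "fh1",
                     decrease = c(0.1, 0.1))
  s2 <- attenuation_summary(att2)
  expect_equal(s2$mean_decrease, 0.1)
  expect_equal(s2$sd_decrease, 0)
  expect_error(attenuation_summary(att[1, ]), ">= 2 diseases")
})

test_that("cross-adjustment identities hold on simulated data", {
  sim <- big_sim(); d <- big_disease()
  fh <- derive_family_history(sim$cohort, sim$pairs, d, sim$plan$registry)
  af <- analysis_frame(sim$cohort, fh, d)
  ca <- cross_adjust(af, "fh1")
  expect_equal(ca$ratio * ca$beta_unadj, ca$beta_adj)
  expect_equal(ca$decrease + ca$ratio, rep(1, 2))
  # both exposures attenuate (shared genetic signal), FH more than PRS
  expect_true(all(ca$decrease > 0))
  expect_gt(ca$decrease[ca$exposure == "fh1"],
            ca$decrease[ca$exposure == "prs"])
})

test_that("PRS independent of FH by construction is not attenuated", {
  # FH signal driven purely by shared environment (h2 = rho2 only feeds
  # the PRS channel through a tiny rho2-independent component): simulate
  # C-only familial clustering with a PRS present
  d <- disease_config("ind", K = 0.2, h2 = 0.1, rho2 = 0.1, c2 = 0.35)
  plan <- simulation_plan(4000, d, generations = 2, seed = 21,
                          block_size = 2000)
  sim <- simulate_cohort(plan)
  co <- record_parental_deaths(sim$cohort, plan$registry)
  fh <- derive_family_history(co, sim$pairs, d, plan$registry)
  af <- analysis_frame(co, fh, d)
  ca <- cross_adjust(af, "fh1")
  # the PRS channel is a small share of the FH signal: its attenuation by
  # FH stays near zero
  expect_lt(abs(ca$decrease[ca$exposure == "prs"]), 0.06)
})

test_that("interaction test p-value, flagging and threshold work together", {
  sim <- big_sim(); d <- big_disease()
  fh <- derive_family_history(sim$cohort, sim$pairs, d, sim$plan$registry)
  af <- analysis_frame(sim$cohort, fh, d)
  it <- interaction_test(af, "fh1", n_tests = 39)
  expect_equal(it$threshold, 0.05 / 39)
  expect_identical(it$significant, it$p < 0.05 / 39)
  expect_true(it$p > 0 && it$p <= 1)
})

test_that("PRS percentile bands place values and references correctly", {
  prs <- qnorm((1:1000 - 0.5) / 1000)
  b7 <- prs_band(prs, "seven_band")
  expect_identical(levels(b7)[1], "40-60")
  # the value at the 50th percentile falls in the reference band
  expect_identical(as.character(b7[500]), "40-60")
  # band edge: exactly the 10th percentile belongs to the lower band
  expect_identical(as.character(b7[100]), "0-10")
  expect_identical(as.character(b7[101]), "10-20")
  b3 <- prs_band(prs, "three_group")
  expect_identical(levels(b3)[1], "average")
  expect_equal(unname(table(b3)["high"]), 100)
  bt <- prs_band(prs, "top_decile")
  expect_equal(mean(bt == "top_decile"), 0.1)
})

test_that("banded odds ratios are monotone for a monotone generative effect", {
  sim <- big_sim(); d <- big_disease()
  fh <- derive_family_history(sim$cohort, sim$pairs, d, sim$plan$registry)
  af <- analysis_frame(sim$cohort, fh, d)
  be <- prs_banded_effects(af, "seven_band")
  ord <- c("0-10", "10-20", "20-40", "60-80", "80-90", "90-100")
  betas <- be$beta[match(paste0("prs_cat:", ord), be$exposure)]
  expect_true(all(diff(betas) > 0))
  # bands below the reference have OR < 1, above > 1
  expect_lt(be$or_[be$band == "0-10"], 1)
  expect_gt(be$or_[be$band == "90-100"], 1)
})

test_that("null top-decile effect when the PRS carries no signal", {
  d <- disease_config("nul", K = 0.3, h2 = 0.4, rho2 = 0.4, c2 = 0)
  plan <- simulation_plan(3000, d, generations = 2, seed = 13,
                          block_size = 3000)
  sim <- simulate_cohort(plan)
  af <- sim$cohort
  af$case <- af$status_nul
  # replace the PRS by pure noise: per-SD and band ORs must be ~1
  set.seed(1)
  af$prs <- rnorm(nrow(af))
  r <- prs_banded_effects(af, "top_decile")
  expect_equal(r$or_, 1, tolerance = 0.15)
})

test_that("FH_P age-tertile effects: exchangeable when onset is unlinked,
           youngest tertile strongest when liability shortens onset", {
  reg <- registry_windows()
  # (a) no liability-onset link: tertile ORs equal within MC error
  d0 <- disease_config("t0", K = 0.25, h2 = 0.6, rho2 = 0.3,
                       cause_of_death_prob = 0.9)
  plan0 <- simulation_plan(6000, d0, generations = 2, seed = 31,
                           block_size = 2000,
                           birth_year_range = c(1950, 1970))
  sim0 <- simulate_cohort(plan0)
  co0 <- record_parental_deaths(sim0$cohort, reg)
  fh0 <- derive_family_history(co0, sim0$pairs, d0, reg)
  af0 <- analysis_frame(co0, fh0, d0)
  af0 <- af0[af0$generation == 2, ]
  r0 <- fhp_age_tertile_effects(af0)
  expect_identical(r0$omitted, character(0))
  b0 <- r0$attenuation$beta_unadj
  expect_lt(max(b0) - min(b0), 0.45)

  # (b) early-onset/high-liability link: youngest tertile largest OR
  d1 <- disease_config("t1", K = 0.25, h2 = 0.6, rho2 = 0.3,
                       onset_mean = 65, onset_sd = 10, onset_shift = 12,
                       cause_of_death_prob = 0.9,
                       survival_after_onset_mean = 6,
                       survival_after_onset_sd = 3)
  plan1 <- simulation_plan(6000, d1, generations = 2, seed = 32,
                           block_size = 2000,
                           birth_year_range = c(1950, 1970))
  sim1 <- simulate_cohort(plan1)
  co1 <- record_parental_deaths(sim1$cohort, reg)
  fh1 <- derive_family_history(co1, sim1$pairs, d1, reg)
  af1 <- analysis_frame(co1, fh1, d1)
  af1 <- af1[af1$generation == 2, ]
  r1 <- fhp_age_tertile_effects(af1)
  a1 <- r1$attenuation
  expect_gt(a1$beta_unadj[a1$tertile == "t1"],
            a1$beta_unadj[a1$tertile == "t3"])
})

test_that("stratified PRS effects are similar across FH strata without
           generative interaction", {
  sim <- big_sim(); d <- big_disease()
  fh <- derive_family_history(sim$cohort, sim$pairs, d, sim$plan$registry)
  af <- analysis_frame(sim$cohort, fh, d)
  st <- stratified_prs_effects(af, "fh1")
  expect_true(all(st$ok))
  # per-SD effects of comparable magnitude in both strata (conditioning
  # on FH mildly shrinks the within-stratum liability variance, so exact
  # equality is not expected even without a generative interaction)
  ratio <- st$beta[st$stratum == "fh_positive"] /
    st$beta[st$stratum == "fh_negative"]
  expect_gt(ratio, 0.7)
  expect_lt(ratio, 1.3)
  expect_true(all(st$beta > 0.5))
  # smaller stratum has the wider CI
  expect_gt(st$se[st$stratum == "fh_positive"],
            st$se[st$stratum == "fh_negative"])
})

test_that("larger PRS capture gives larger per-SD effect and FH attenuation", {
  d <- disease_config("cap", K = 0.15, h2 = 0.6, rho2 = 0.4, c2 = 0,
                      rho2_small = 0.1)
  plan <- simulation_plan(6000, d, generations = 2, seed = 41,
                          block_size = 2000)
  sim <- simulate_cohort(plan)
  co <- record_parental_deaths(sim$cohort, plan$registry)
  fh <- derive_family_history(co, sim$pairs, d, plan$registry)
  af <- analysis_frame(co, fh, d)
  cp <- compare_prs_capture(af, "fh1")
  expect_gt(cp$beta[cp$score == "prs"], cp$beta[cp$score == "prs_small"])
  expect_gt(cp$fh_decrease[cp$score == "prs"],
            cp$fh_decrease[cp$score == "prs_small"])
  # sibling correlation of the small score is also 2*kinship
  prs_s <- co$PRS_small_cap
  pr <- sim$pairs[sim$pairs$relationship == "full-sibling", ]
  expect_equal(cor(prs_s[match(pr$index_id, co$id)],
                   prs_s[match(pr$relative_id, co$id)]),
               0.5, tolerance = 0.05)
})
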