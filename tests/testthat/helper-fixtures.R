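# Shared fixtures and independent oracles.  The large three-generation
# cohort is simulated once per test run and reused by the property and
# acceptance tests.

.fx <- new.env(parent = emptyenv())

big_disease <- function() {
  disease_config("d1", K = 0.10, h2 = 0.5, rho2 = 0.25, c2 = 0.1)
}

# 12,000 three-generation families: ~120k individuals, 180k unordered
# first-degree and 144k unordered second-degree pairs
big_sim <- function() {
  if (is.null(.fx$big)) {
    plan <- simulation_plan(n_families = 12000, diseases = big_disease(),
                            generations = 3, seed = 101, block_size = 2000)
    sim <- simulate_cohort(plan)
    sim$cohort <- record_parental_deaths(sim$cohort, plan$registry)
    .fx$big <- sim
  }
  .fx$big
}

# small toy pedigree for FH rule tests: one family, explicit records
toy_cohort <- function() {
  df <- data.frame(
    id = c("fa", "mo", "c1", "c2", "gf"),
    family_id = "F1",
    role = c("fa", "mo", "c1", "c2", "gf"),
    generation = c(2L, 2L, 3L, 3L, 1L),
    father_id = c("gf", NA, "fa", "fa", NA),
    mother_id = c(NA, NA, "mo", "mo", NA),
    sex = c("male", "female", "female", "male", "male"),
    birth_year = c(1940L, 1942L, 1970L, 1972L, 1915L),
    death_year = c(NA, NA, NA, NA, 1990L),
    death_age = c(NA, NA, NA, NA, 75),
    G_d1 = 0, L_d1 = 0,
    PRS_d1 = c(0.5, -0.2, 1.1, 0.3, 0.0),
    status_d1 = c(1L, 0L, 0L, 0L, 1L),
    onset_age_d1 = c(45, NA, NA, NA, 60),
    cod_d1 = c(NA, NA, NA, NA, TRUE),
    stringsAsFactors = FALSE)
  df
}

toy_pairs <- function() {
  one <- data.frame(
    index_id = c("fa", "mo", "fa", "mo", "c1", "gf", "gf", "gf"),
    relative_id = c("c1", "c1", "c2", "c2", "c2", "fa", "c1", "c2"),
    kinship = c(.25, .25, .25, .25, .25, .25, .125, .125),
    degree = c("first", "first", "first", "first", "first", "first",
               "second", "second"),
    relationship = c("parent-offspring", "parent-offspring",
                     "parent-offspring", "parent-offspring",
                     "full-sibling", "parent-offspring",
                     "grandparent", "grandparent"),
    stringsAsFactors = FALSE)
  rbind(one, data.frame(index_id = one$relative_id,
                        relative_id = one$index_id,
                        kinship = one$kinship, degree = one$degree,
                        relationship = one$relationship,
                        stringsAsFactors = FALSE))
}

# --- independent oracles -------------------------------------------------

# invert the standard normal upper tail by bisection (oracle for
# liability_threshold, which uses qnorm)
bisect_threshold <- function(K, tol = 1e-10) {
  lo <- -10; hi <- 10
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (1 - pnorm(mid) > K) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# brute-force 2-D Riemann sum for the bivariate normal conditional tail
# (oracle for theoretical_concordance's 1-D quadrature)
grid_concordance <- function(r, q, lim = 8, n = 1200) {
  zq <- qnorm(q)
  x <- seq(zq, lim, length.out = n)
  y <- seq(zq, lim, length.out = n)
  hx <- x[2] - x[1]; hy <- y[2] - y[1]
  xm <- (x[-1] + x[-n]) / 2
  ym <- (y[-1] + y[-n]) / 2
  det <- 1 - r^2
  dens <- outer(xm, ym, function(a, b)
    exp(-(a^2 - 2 * r * a * b + b^2) / (2 * det)) / (2 * pi * sqrt(det)))
  sum(dens) * hx * hy / (1 - q)
}

# population logistic slope implied by the liability model: solve the
# expected score equations for P(D | PRS = s) over a normal grid
implied_prs_beta <- function(K, rho2) {
  thr <- qnorm(K, lower.tail = FALSE)
  s <- seq(-8, 8, length.out = 4001)
  w <- dnorm(s); w <- w / sum(w)
  p_true <- pnorm((thr - sqrt(rho2) * s) / sqrt(1 - rho2),
                  lower.tail = FALSE)
  nll <- function(b) {
    eta <- b[1] + b[2] * s
    pr <- 1 / (1 + exp(-eta))
    -sum(w * (p_true * log(pr) + (1 - p_true) * log(1 - pr)))
  }
  stats::optim(c(qnorm(K), 0.5), nll, method = "BFGS",
               control = list(reltol = 1e-12))$par[2]
}
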