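# Pedigree-structured liability-threshold simulator.
#
# Families are generated in fixed-size blocks; each block draws from its own
# substream (seed derived from the root seed and block index) and always
# simulates a full block even when only part of it is needed, so that
# enlarging n_families appends new families without changing existing ones.
# All truncated draws use a single inverse-CDF uniform, and per-individual
# conditional quantities (onset age, cause-of-death inclusion) consume a
# uniform for every individual whether or not it is used, keeping the draw
# layout independent of realized data.

#' Liability threshold for a given prevalence
#'
#' Returns the threshold T such that the upper tail of a standard normal
#' beyond T has probability \code{K}; disease occurs when liability exceeds
#' T, so simulated lifetime prevalence matches \code{K}.
#'
#' @param K Lifetime prevalence, in (0, 1).
#' @return The threshold on the standard-normal liability scale.
#' @examples
#' liability_threshold(0.5)   # 0
#' liability_threshold(0.01)  # 2.326
#' @export
liability_threshold <- function(K) {
  if (!is.numeric(K) || any(K <= 0) || any(K >= 1))
    stop("K must be in (0, 1)", call. = FALSE)
  stats::qnorm(K, lower.tail = FALSE)
}

# inverse-CDF truncated normal: one uniform per draw, vectorized over mean
.rtnorm_u <- function(u, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + u * (phi - plo), mean, sd)
}

# deterministic per-block substream seed (kept below 2^31)
.block_seed <- function(seed, block) {
  x <- (as.double(seed) %% 2147483647) + 1
  x <- (x * 48271) %% 2147483647
  x <- (x + as.double(block) * 1103515245 + 12345) %% 2147483647
  as.integer(x)
}

# role table: one row per pedigree position within a family
.plan_roles <- function(plan) {
  if (plan$generations == 3L) {
    ps <- if (plan$n_paternal_sibs > 0)
      paste0("ps", seq_len(plan$n_paternal_sibs)) else character(0)
    ms <- if (plan$n_maternal_sibs > 0)
      paste0("ms", seq_len(plan$n_maternal_sibs)) else character(0)
    ch <- paste0("c", seq_len(plan$n_children))
    data.frame(
      role = c("gf_p", "gm_p", "gf_m", "gm_m", "fa", ps, "mo", ms, ch),
      gen = c(1L, 1L, 1L, 1L, 2L, rep(2L, length(ps)), 2L,
              rep(2L, length(ms)), rep(3L, length(ch))),
      father = c(NA, NA, NA, NA, "gf_p", rep("gf_p", length(ps)), "gf_m",
                 rep("gf_m", length(ms)), rep("fa", length(ch))),
      mother = c(NA, NA, NA, NA, "gm_p", rep("gm_p", length(ps)), "gm_m",
                 rep("gm_m", length(ms)), rep("mo", length(ch))),
      sex = c("male", "female", "male", "female", "male",
              rep(NA, length(ps)), "female", rep(NA, length(ms)),
              rep(NA, length(ch))),
      stringsAsFactors = FALSE)
  } else {
    ch <- paste0("c", seq_len(plan$n_children))
    data.frame(
      role = c("fa", "mo", ch),
      gen = c(1L, 1L, rep(2L, length(ch))),
      father = c(NA, NA, rep("fa", length(ch))),
      mother = c(NA, NA, rep("mo", length(ch))),
      sex = c("male", "female", rep(NA, length(ch))),
      stringsAsFactors = FALSE)
  }
}

# additive component transmitted through the pedigree: founders ~ N(0, v),
# children = midparent + Mendelian term ~ N(0, v/2)
.transmit <- function(roles, B, v) {
  out <- vector("list", nrow(roles))
  names(out) <- roles$role
  for (i in seq_len(nrow(roles))) {
    if (is.na(roles$father[i])) {
      out[[i]] <- stats::rnorm(B, 0, sqrt(v))
    } else {
      out[[i]] <- (out[[roles$father[i]]] + out[[roles$mother[i]]]) / 2 +
        stats::rnorm(B, 0, sqrt(v / 2))
    }
  }
  out
}

# shared-family environment: full siblings share their natal-family factor
# fully; a parent's natal factor enters the children's factor so that
# corr(C_parent, C_child) = c_parent_share
.family_env <- function(roles, B, share) {
  p <- 2 * share^2
  fnat <- vector("list", nrow(roles))
  names(fnat) <- roles$role
  units <- list()
  for (i in seq_len(nrow(roles))) {
    if (is.na(roles$father[i])) {
      fnat[[i]] <- stats::rnorm(B)
    } else {
      key <- paste(roles$father[i], roles$mother[i], sep = "+")
      if (is.null(units[[key]])) {
        units[[key]] <- sqrt(p) * (fnat[[roles$father[i]]] +
                                     fnat[[roles$mother[i]]]) / sqrt(2) +
          sqrt(1 - p) * stats::rnorm(B)
      }
      fnat[[i]] <- units[[key]]
    }
  }
  fnat
}

.simulate_block <- function(plan, block) {
  B <- plan$block_size
  fams <- (block - 1L) * B + seq_len(B)
  roles <- .plan_roles(plan)
  nr <- nrow(roles)
  set.seed(.block_seed(plan$seed, block))

  r1 <- plan$birth_year_range[1]; r2 <- plan$birth_year_range[2]
  ch_idx <- which(roles$gen == max(roles$gen))
  by <- matrix(NA_real_, B, nr, dimnames = list(NULL, roles$role))
  for (i in ch_idx) by[, i] <- floor(stats::runif(B, r1, r2 + 1))
  eldest <- do.call(pmin, as.data.frame(by[, ch_idx, drop = FALSE]))
  by[, "fa"] <- eldest - round(.rtnorm_u(stats::runif(B),
    plan$parent_gap_mean, plan$parent_gap_sd, 18, 45))
  by[, "mo"] <- eldest - round(.rtnorm_u(stats::runif(B),
    plan$parent_gap_mean, plan$parent_gap_sd, 18, 45))
  if (plan$generations == 3L) {
    for (r in roles$role[startsWith(roles$role, "ps")])
      by[, r] <- by[, "fa"] + floor(stats::runif(B, -5, 6))
    for (r in roles$role[startsWith(roles$role, "ms")])
      by[, r] <- by[, "mo"] + floor(stats::runif(B, -5, 6))
    pat <- c("fa", roles$role[startsWith(roles$role, "ps")])
    mat <- c("mo", roles$role[startsWith(roles$role, "ms")])
    eldest_p <- do.call(pmin, as.data.frame(by[, pat, drop = FALSE]))
    eldest_m <- do.call(pmin, as.data.frame(by[, mat, drop = FALSE]))
    for (r in c("gf_p", "gm_p"))
      by[, r] <- eldest_p - round(.rtnorm_u(stats::runif(B),
        plan$parent_gap_mean, plan$parent_gap_sd, 18, 45))
    for (r in c("gf_m", "gm_m"))
      by[, r] <- eldest_m - round(.rtnorm_u(stats::runif(B),
        plan$parent_gap_mean, plan$parent_gap_sd, 18, 45))
  }

  sex <- matrix(NA_character_, B, nr, dimnames = list(NULL, roles$role))
  for (i in seq_len(nr)) {
    sex[, i] <- if (is.na(roles$sex[i]))
      ifelse(stats::runif(B) < 0.5, "male", "female") else roles$sex[i]
  }

  death_age <- matrix(NA_real_, B, nr, dimnames = list(NULL, roles$role))
  for (i in seq_len(nr))
    death_age[, i] <- .rtnorm_u(stats::runif(B), plan$death_age_mean,
                                plan$death_age_sd, 20, 105)

  # per-disease latent structure and phenotypes
  dis_cols <- list()
  for (d in plan$diseases) {
    r2s <- if (is.null(d$rho2_small)) 0 else d$rho2_small
    comp_v <- c(small = r2s, extra = d$rho2 - r2s, rest = d$h2 - d$rho2)
    comps <- lapply(comp_v, function(v) {
      if (v > 0) .transmit(roles, B, v)
      else stats::setNames(rep(list(numeric(B)), nr), roles$role)
    })
    cf <- if (d$c2 > 0) .family_env(roles, B, plan$c_parent_share) else NULL
    ev <- 1 - d$h2 - d$c2
    thr <- liability_threshold(d$K)
    m <- list()
    for (i in seq_len(nr)) {
      r <- roles$role[i]
      G <- comps$small[[r]] + comps$extra[[r]] + comps$rest[[r]]
      C <- if (is.null(cf)) numeric(B) else sqrt(d$c2) * cf[[r]]
      E <- if (ev > 0) stats::rnorm(B, 0, sqrt(ev)) else numeric(B)
      L <- G + C + E
      status <- as.integer(L > thr)
      u_onset <- stats::runif(B)
      onset <- .rtnorm_u(u_onset,
                         d$onset_mean - d$onset_shift * pmax(L - thr, 0),
                         d$onset_sd, 0, 100)
      onset[status == 0L] <- NA_real_
      u_cod <- stats::runif(B)
      u_surv <- stats::runif(B)
      # disease-attributable mortality: a case dies no later than onset
      # plus a truncated-normal survival time (only when configured)
      if (is.finite(d$survival_after_onset_mean)) {
        surv <- .rtnorm_u(u_surv, d$survival_after_onset_mean,
                          d$survival_after_onset_sd, 0, 60)
        cap <- ifelse(status == 1L, onset + surv, Inf)
        death_age[, i] <- pmin(death_age[, i], cap)
      }
      prs <- if (d$rho2 > 0)
        (comps$small[[r]] + comps$extra[[r]]) / sqrt(d$rho2) else
          rep(NA_real_, B)
      m[[r]] <- list(G = G, C = C, L = L, status = status, onset = onset,
                     u_cod = u_cod, prs = prs,
                     prs_small = if (r2s > 0) comps$small[[r]] / sqrt(r2s)
                                 else NULL)
    }
    dis_cols[[d$disease_id]] <- m
  }

  # assemble one data.frame per role, then stack
  fu_end <- plan$registry$followup_end
  fam_id <- sprintf("F%07d", fams)
  out <- vector("list", nr)
  for (i in seq_len(nr)) {
    r <- roles$role[i]
    dy <- by[, i] + floor(death_age[, i])
    alive <- dy > fu_end
    df <- data.frame(
      id = paste0(fam_id, "_", r),
      family_id = fam_id,
      role = r,
      generation = roles$gen[i],
      father_id = if (is.na(roles$father[i])) NA_character_ else
        paste0(fam_id, "_", roles$father[i]),
      mother_id = if (is.na(roles$mother[i])) NA_character_ else
        paste0(fam_id, "_", roles$mother[i]),
      sex = sex[, i],
      birth_year = as.integer(by[, i]),
      death_year = ifelse(alive, NA_integer_, as.integer(dy)),
      death_age = ifelse(alive, NA_real_, round(death_age[, i], 2)),
      stringsAsFactors = FALSE)
    for (d in plan$diseases) {
      v <- dis_cols[[d$disease_id]][[r]]
      dead <- !alive
      cod <- dead & v$status == 1L & !is.na(v$onset) &
        v$onset <= death_age[, i] & v$u_cod < d$cause_of_death_prob
      cod[alive] <- NA
      sfx <- d$disease_id
      df[[paste0("G_", sfx)]] <- v$G
      df[[paste0("C_", sfx)]] <- v$C
      df[[paste0("L_", sfx)]] <- v$L
      df[[paste0("PRS_", sfx)]] <- v$prs
      if (!is.null(v$prs_small))
        df[[paste0("PRS_small_", sfx)]] <- v$prs_small
      df[[paste0("status_", sfx)]] <- v$status
      df[[paste0("onset_age_", sfx)]] <- round(v$onset, 2)
      df[[paste0("cod_", sfx)]] <- cod
    }
    out[[i]] <- df
  }
  do.call(rbind, out)
}

# relationship templates implied by the role table (within one family)
.role_pairs <- function(roles) {
  po <- fs <- gp <- av <- NULL
  nonf <- roles[!is.na(roles$father), ]
  if (nrow(nonf)) {
    po <- rbind(data.frame(a = nonf$father, b = nonf$role),
                data.frame(a = nonf$mother, b = nonf$role))
    po$relationship <- "parent-offspring"; po$kinship <- 0.25
    key <- paste(nonf$father, nonf$mother)
    fs_list <- lapply(split(nonf$role, key), function(s) {
      if (length(s) < 2) return(NULL)
      t(utils::combn(s, 2))
    })
    fs_m <- do.call(rbind, fs_list)
    if (!is.null(fs_m) && nrow(fs_m)) {
      fs <- data.frame(a = fs_m[, 1], b = fs_m[, 2],
                       relationship = "full-sibling", kinship = 0.25)
    }
    parent_of <- stats::setNames(roles$father, roles$role)
    mother_of <- stats::setNames(roles$mother, roles$role)
    sib_of <- function(r) {
      f <- parent_of[[r]]; m <- mother_of[[r]]
      if (is.na(f)) return(character(0))
      setdiff(roles$role[!is.na(roles$father) & roles$father == f &
                           roles$mother == m], r)
    }
    gp_rows <- av_rows <- list()
    for (r in nonf$role) {
      for (par in c(nonf$father[nonf$role == r], nonf$mother[nonf$role == r])) {
        pf <- parent_of[[par]]; pm <- mother_of[[par]]
        if (!is.na(pf)) {
          gp_rows[[length(gp_rows) + 1L]] <-
            data.frame(a = c(pf, pm), b = r,
                       relationship = c("grandparent", "grandparent"),
                       kinship = 0.125)
        }
        for (s in sib_of(par)) {
          av_rows[[length(av_rows) + 1L]] <-
            data.frame(a = s, b = r, relationship = "avuncular",
                       kinship = 0.125)
        }
      }
    }
    gp <- if (length(gp_rows)) do.call(rbind, gp_rows) else NULL
    av <- if (length(av_rows)) do.call(rbind, av_rows) else NULL
  }
  pr <- rbind(po, fs, gp, av)
  pr$degree <- ifelse(pr$kinship > 0.177, "first", "second")
  pr
}

.build_pairs <- function(plan, fam_id) {
  tpl <- .role_pairs(.plan_roles(plan))
  one_dir <- do.call(rbind, lapply(seq_len(nrow(tpl)), function(i) {
    data.frame(index_id = paste0(fam_id, "_", tpl$a[i]),
               relative_id = paste0(fam_id, "_", tpl$b[i]),
               kinship = tpl$kinship[i], degree = tpl$degree[i],
               relationship = tpl$relationship[i], stringsAsFactors = FALSE)
  }))
  both <- rbind(one_dir,
                data.frame(index_id = one_dir$relative_id,
                           relative_id = one_dir$index_id,
                           kinship = one_dir$kinship, degree = one_dir$degree,
                           relationship = one_dir$relationship,
                           stringsAsFactors = FALSE))
  both[order(both$index_id, both$relative_id), , drop = FALSE]
}

#' Simulate a family-structured cohort
#'
#' Generates a cohort of pedigreed families under the liability-threshold
#' model of the plan's disease configurations, together with the table of
#' all within-cohort first-degree (parent-offspring, full-sibling) and
#' second-degree (grandparental, avuncular) relative pairs with their
#' expected kinship coefficients.  Additive genetic components are
#' transmitted as midparent value plus a Mendelian-sampling deviation, so
#' relative-pair correlations of the PRS equal twice the kinship
#' coefficient exactly in expectation.
#'
#' @param plan A \code{\link{simulation_plan}}.
#' @return A list of class \code{famprs_sim} with elements \code{cohort}
#'   (one row per individual) and \code{pairs} (both ordered directions of
#'   every relative pair).
#' @export
simulate_cohort <- function(plan) {
  stopifnot(inherits(plan, "famprs_plan"))
  n_blocks <- ceiling(plan$n_families / plan$block_size)
  cohort <- do.call(rbind, lapply(seq_len(n_blocks), function(b)
    .simulate_block(plan, b)))
  keep_fam <- sprintf("F%07d", seq_len(plan$n_families))
  cohort <- cohort[cohort$family_id %in% keep_fam, , drop = FALSE]
  cohort <- cohort[order(cohort$family_id, cohort$generation, cohort$id), ,
                   drop = FALSE]
  rownames(cohort) <- NULL
  pairs <- .build_pairs(plan, keep_fam)
  rownames(pairs) <- NULL
  structure(list(cohort = cohort, pairs = pairs, plan = plan),
            class = "famprs_sim")
}

#' @export
print.famprs_sim <- function(x, ...) {
  cat(sprintf("famprs simulated cohort: %d individuals, %d families, %d pair rows\n",
              nrow(x$cohort), length(unique(x$cohort$family_id)),
              nrow(x$pairs)))
  invisible(x)
}

#' Attach registry-windowed parental death records
#'
#' Links each individual's parental death records and marks whether each
#' record is observable through the causes-of-death registry: a parent's
#' record is visible only if the death year falls inside
#' \code{[death_registry_start, death_registry_end]}.  Deaths outside the
#' window (including deaths after the registry's last covered year) are
#' flagged unobservable; parents alive at the end of follow-up contribute
#' an observable "no death" record.
#'
#' @param cohort Cohort table from \code{\link{simulate_cohort}}.
#' @param registry A \code{\link{registry_windows}} object.
#' @return The cohort with added columns \code{father_death_year},
#'   \code{father_death_age}, \code{father_death_observable},
#'   \code{father_cod_<disease>} (and the mother analogues) plus
#'   \code{father_in_cohort}/\code{mother_in_cohort}.
#' @export
record_parental_deaths <- function(cohort, registry) {
  stopifnot(inherits(registry, "famprs_registry"))
  cod_cols <- grep("^cod_", names(cohort), value = TRUE)
  for (side in c("father", "mother")) {
    idx <- match(cohort[[paste0(side, "_id")]], cohort$id)
    dy <- cohort$death_year[idx]
    cohort[[paste0(side, "_in_cohort")]] <- !is.na(idx)
    cohort[[paste0(side, "_death_year")]] <- dy
    cohort[[paste0(side, "_death_age")]] <- cohort$death_age[idx]
    cohort[[paste0(side, "_death_observable")]] <-
      ifelse(is.na(dy), NA,
             dy >= registry$death_registry_start &
               dy <= registry$death_registry_end)
    for (cc in cod_cols)
      cohort[[paste0(side, "_", cc)]] <- cohort[[cc]][idx]
  }
  cohort
}
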