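# Concordance of high PRS among relatives: the probability that a
# relative's PRS lies beyond the q-quantile given that the index person's
# does.  Under the additive model two relatives' standardized PRSs are
# bivariate normal with correlation twice the kinship coefficient, so the
# theoretical value is a bivariate-normal conditional tail probability.

#' Theoretical high-PRS concordance between relatives
#'
#' P(X2 > z_q | X1 > z_q) for a standard bivariate normal with correlation
#' \code{r}, where z_q is the q-quantile.  Computed by numerical
#' integration of the conditional tail,
#' \deqn{P = \frac{1}{1-q}\int_{z_q}^{\infty} \phi(x)\,
#'   \bar\Phi\!\left(\frac{z_q - r x}{\sqrt{1-r^2}}\right) dx,}
#' to relative tolerance below 1e-6.  With first-degree relatives
#' (r = 0.5) and the top decile (q = 0.9) this gives 0.324; with
#' second-degree relatives (r = 0.25), 0.193.
#'
#' @param r Correlation of the two scores, in [0, 1); use twice the
#'   kinship coefficient for relatives under an additive model.
#' @param q Percentile threshold defining "high", in (0, 1); default top
#'   decile.
#' @return The conditional probability, vectorized over \code{r}.
#' @examples
#' theoretical_concordance(0.5, 0.9)
#' theoretical_concordance(0, 0.9)  # independence: 1 - q
#' @export
theoretical_concordance <- function(r, q = 0.9) {
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 1)
    stop("q must be in (0, 1)", call. = FALSE)
  if (!is.numeric(r) || any(r < 0) || any(r >= 1))
    stop("r must be in [0, 1)", call. = FALSE)
  zq <- stats::qnorm(q)
  vapply(r, function(ri) {
    if (ri == 0) return(1 - q)
    f <- function(x) stats::dnorm(x) *
      stats::pnorm((zq - ri * x) / sqrt(1 - ri^2), lower.tail = FALSE)
    orthant <- stats::integrate(f, zq, Inf, rel.tol = 1e-9,
                                abs.tol = 0)$value
    orthant / (1 - q)
  }, numeric(1))
}

#' Observed high-PRS concordance among relative pairs
#'
#' Fraction of pairs whose relative exceeds the within-cohort q-quantile of
#' the PRS, among pairs whose index person exceeds it, computed per degree
#' of relatedness.  The pair table carries both ordered directions of each
#' pair, so the pooled estimate conditions symmetrically.  Optionally
#' stratified by the relative's disease status.
#'
#' @param pairs Relative-pair table (\code{index_id}, \code{relative_id},
#'   \code{kinship}, \code{degree}).
#' @param cohort Cohort table holding the PRS (and status) columns.
#' @param disease A \code{\link{disease_config}} naming the PRS column;
#'   also used for stratification by the relative's status.
#' @param q Percentile threshold, default 0.9 (top decile).
#' @param stratify_by_disease Also report concordance given the relative's
#'   disease status and their difference.
#' @return Data frame, one row per degree present: \code{degree}, \code{q},
#'   \code{n_pairs}, \code{n_index_high}, \code{observed},
#'   \code{theoretical} (at r = twice the degree's kinship), and, when
#'   stratified, \code{observed_given_affected_relative},
#'   \code{observed_given_unaffected_relative}, \code{difference}.
#' @export
observed_concordance <- function(pairs, cohort, disease, q = 0.9,
                                 stratify_by_disease = FALSE) {
  .check_disease(cohort, disease)
  prs_col <- paste0("PRS_", disease$disease_id)
  prs <- cohort[[prs_col]]
  if (all(is.na(prs)))
    stop("no PRS generated for this disease (rho2 = 0)", call. = FALSE)
  thr <- stats::quantile(prs, q, na.rm = TRUE, names = FALSE)
  idx_prs <- prs[match(pairs$index_id, cohort$id)]
  rel_prs <- prs[match(pairs$relative_id, cohort$id)]
  rel_status <- cohort[[paste0("status_", disease$disease_id)]][
    match(pairs$relative_id, cohort$id)]
  rows <- list()
  for (dg in intersect(c("first", "second"), unique(pairs$degree))) {
    sel <- pairs$degree == dg & !is.na(idx_prs) & !is.na(rel_prs)
    hi <- sel & idx_prs > thr
    if (!any(hi))
      stop("no index individuals above the threshold for degree ", dg,
           call. = FALSE)
    obs <- mean(rel_prs[hi] > thr)
    r <- 2 * stats::median(pairs$kinship[sel])
    row <- data.frame(degree = dg, q = q, n_pairs = sum(sel),
                      n_index_high = sum(hi), observed = obs,
                      theoretical = theoretical_concordance(r, q),
                      stringsAsFactors = FALSE)
    if (stratify_by_disease) {
      aff <- hi & rel_status == 1L
      una <- hi & rel_status == 0L
      row$observed_given_affected_relative <-
        if (any(aff)) mean(rel_prs[aff] > thr) else NA_real_
      row$observed_given_unaffected_relative <-
        if (any(una)) mean(rel_prs[una] > thr) else NA_real_
      row$difference <- row$observed_given_affected_relative -
        row$observed_given_unaffected_relative
    }
    rows[[dg]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
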