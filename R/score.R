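# Mahalanobis dysregulation scoring.
#
# The dysregulation score of an observation x is
#   D_M = sqrt((x - mu)' S^{-1} (x - mu)),
# the covariance-aware distance of the standardized biomarker profile from
# the reference population mean mu; S is the reference variance-covariance
# matrix. The reference centroid has distance 0; larger scores mean profiles
# further from the homeostatic signature.

#' Estimate reference moments with covariance conditioning
#'
#' Column means and the sample covariance (n-1 divisor) of a standardized
#' reference matrix. When the covariance condition number exceeds
#' `cond_threshold`, diagonal shrinkage `S <- (1-lambda) S + lambda diag(S)`
#' is applied with the minimal `lambda` (found by bisection) that passes.
#'
#' @param x Numeric matrix, rows = reference members, no missing cells,
#'   more rows than columns.
#' @param cond_threshold Condition-number ceiling (default 1e8).
#' @return List: `mu`, `S` (conditioned), `S_raw`, `lambda`,
#'   `condition_number` (after conditioning), `n`, `p`.
#' @export
estimate_moments <- function(x, cond_threshold = 1e8) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (anyNA(x)) stop_dysreg("reference matrix has missing cells",
                            "dysregkit_input_error")
  if (n <= p) stop_dysreg(sprintf(
    "reference too small to condition: n = %d rows <= p = %d markers; use shrinkage on a larger reference or fewer markers",
    n, p), "dysregkit_conditioning_error")
  mu <- colMeans(x)
  S <- stats::cov(x)
  cond_of <- function(lam) {
    Sl <- (1 - lam) * S + lam * diag(diag(S), p)
    ev <- eigen(Sl, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) Inf else max(ev) / min(ev)
  }
  lambda <- 0
  if (!is.finite(cond_of(0)) || cond_of(0) > cond_threshold) {
    if (!is.finite(cond_of(1)) || cond_of(1) > cond_threshold) {
      stop_dysreg("covariance singular even at full diagonal shrinkage",
                  "dysregkit_conditioning_error")
    }
    lo <- 0; hi <- 1
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (is.finite(cond_of(mid)) && cond_of(mid) <= cond_threshold) hi <- mid
      else lo <- mid
    }
    lambda <- hi
  }
  S_cond <- (1 - lambda) * S + lambda * diag(diag(S), p)
  list(mu = mu, S = S_cond, S_raw = S, lambda = lambda,
       condition_number = cond_of(lambda), n = n, p = p)
}

#' Mahalanobis distance of standardized profiles from a reference
#'
#' Computed through the Cholesky factor of `S` (a triangular solve), never an
#' explicit inverse.
#'
#' @param x Numeric vector (one profile) or matrix (rows = profiles).
#' @param mu Reference mean vector.
#' @param S Reference covariance matrix, positive definite.
#' @return Numeric vector of nonnegative distances.
#' @export
dm_mahalanobis <- function(x, mu, S) {
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(x) != length(mu) || any(dim(S) != length(mu))) {
    stop_dysreg("dimension mismatch between x, mu, S", "dysregkit_input_error")
  }
  R <- chol(S)
  centered <- t(x) - mu
  w <- backsolve(R, centered, transpose = TRUE)
  sqrt(colSums(w^2))
}

#' Score a cohort against a reference population
#'
#' Applies the reference's transform spec to the cohort's markers (rows with
#' domain violations dropped and counted), computes each retained
#' observation's Mahalanobis distance from the reference moments, and
#' standardizes the score within species (centered to 0, scaled to sd 1
#' over all scored visits of that species) for cross-species comparability.
#'
#' @param cohort A `cohort_table` complete on the reference's markers.
#' @param reference A [reference_population()].
#' @param keep_z Attach the standardized marker matrix as attribute
#'   `marker_z` (used by diagnostics); default `FALSE`.
#' @return A `score_table`: data frame with `species`, `individual_id`,
#'   `age_at_obs`, `sex`, `population`, `dm`, `dm_z`, `reference_id`;
#'   attribute `n_dropped` counts domain-violation row drops.
#' @export
score_cohort <- function(cohort, reference, keep_z = FALSE) {
  ap <- apply_spec(cohort, reference$spec, domain_violation = "drop_row")
  if (nrow(ap$z) == 0) {
    stop_dysreg("no observations scoreable under this reference (all rows dropped by transform-domain rules)",
                "dysregkit_input_error")
  }
  rows <- as.data.frame(cohort)[ap$kept, , drop = FALSE]
  dm <- dm_mahalanobis(ap$z, reference$mu, reference$S)
  out <- data.frame(
    species = rows$species, individual_id = rows$individual_id,
    age_at_obs = rows$age_at_obs, sex = rows$sex,
    population = rows$population, dm = dm,
    dm_z = NA_real_, reference_id = reference$id,
    stringsAsFactors = FALSE)
  for (sp in unique(out$species)) {
    i <- out$species == sp
    s <- stats::sd(out$dm[i])
    out$dm_z[i] <- if (is.na(s) || s == 0) 0 else (out$dm[i] - mean(out$dm[i])) / s
  }
  structure(out,
            n_dropped = sum(!ap$kept),
            marker_z = if (keep_z) ap$z else NULL,
            class = c("score_table", "data.frame"))
}

#' Emergence diagnostic: score vs single-marker correlations
#'
#' The dysregulation score is meant to be an emergent property of the joint
#' marker distribution, not a proxy for any one marker. Reports the Pearson
#' correlation between the score and each standardized marker, the maximum
#' absolute correlation, and the share of markers with |r| < 0.1; flags the
#' score as non-emergent when the maximum exceeds `flag_threshold`.
#'
#' @param scores A `score_table`.
#' @param marker_z Standardized marker matrix aligned row-for-row with
#'   `scores` (e.g. attribute `marker_z` from [score_cohort()]).
#' @param flag_threshold Maximum |r| beyond which the score is flagged
#'   (default 0.3).
#' @return List: `per_marker` (marker, r), `max_abs_r`, `share_below_0.1`,
#'   `emergent` flag. Constant markers yield `NA` correlations and are
#'   excluded from the summaries.
#' @export
marker_score_correlations <- function(scores, marker_z, flag_threshold = 0.3) {
  stopifnot(nrow(scores) == nrow(marker_z))
  r <- vapply(seq_len(ncol(marker_z)), function(j) {
    v <- marker_z[, j]
    if (stats::sd(v) == 0) return(NA_real_)
    stats::cor(scores$dm, v)
  }, numeric(1))
  per <- data.frame(marker = colnames(marker_z), r = r,
                    stringsAsFactors = FALSE)
  ok <- !is.na(r)
  list(per_marker = per,
       max_abs_r = if (any(ok)) max(abs(r[ok])) else NA_real_,
       share_below_0.1 = if (any(ok)) mean(abs(r[ok]) < 0.1) else NA_real_,
       emergent = if (any(ok)) max(abs(r[ok])) <= flag_threshold else NA)
}

#' Write a score table to CSV
#' @param scores A `score_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  utils::write.csv(as.data.frame(scores), path, row.names = FALSE)
  invisible(path)
}
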