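# Per-marker normality-approximating transforms and reference standardization.
#
# Mahalanobis scoring assumes approximate multivariate normality, so each
# marker is natural-log- or square-root-transformed when that improves
# normality in the reference population, then centered and scaled by the
# reference mean and standard deviation. Transform choice and moments are
# specific to each reference population.

TRANSFORMS <- list(
  identity = list(fn = function(x) x,       domain = function(x) TRUE),
  sqrt     = list(fn = sqrt,                domain = function(x) all(x >= 0)),
  log      = list(fn = log,                 domain = function(x) all(x > 0))
)

#' Choose the normality-maximizing transform for one marker
#'
#' Among the admissible transforms (log requires strictly positive reference
#' values, square root nonnegative), returns the one maximizing the
#' Shapiro-Wilk W statistic on the transformed reference values. Ties are
#' broken identity > sqrt > log. For samples larger than `w_max_n` (where W
#' is unreliable) the criterion falls back to minimizing |skewness|.
#'
#' @param values Numeric reference values for one marker.
#' @param floor_n Minimum finite values required (default 10).
#' @param w_max_n Sample-size ceiling for the Shapiro-Wilk criterion
#'   (default 5000).
#' @return One of `"identity"`, `"sqrt"`, `"log"`, with attribute `score`
#'   (the winning W, or negative |skewness| under the fallback).
#' @export
select_transform <- function(values, floor_n = 10L, w_max_n = 5000L) {
  v <- values[is.finite(values)]
  if (length(v) < floor_n) {
    stop_dysreg(sprintf(
      "only %d finite values (< %d); pass transform 'identity' explicitly",
      length(v), floor_n), "dysregkit_input_error")
  }
  admissible <- names(TRANSFORMS)[vapply(TRANSFORMS,
                                         function(tr) tr$domain(v), logical(1))]
  score <- vapply(admissible, function(nm) {
    tv <- TRANSFORMS[[nm]]$fn(v)
    if (stats::sd(tv) == 0) return(-Inf)
    if (length(tv) <= w_max_n) {
      unname(stats::shapiro.test(tv)$statistic)
    } else {
      -abs(skewness(tv))
    }
  }, numeric(1))
  # preference order identity > sqrt > log on exact ties
  pref <- match(admissible, c("identity", "sqrt", "log"))
  best <- admissible[order(-score, pref)][1]
  structure(best, score = unname(score[best]))
}

#' Fit a transform-and-standardize specification on a reference sample
#'
#' Selects a transform per marker on the reference values and records the
#' transformed-scale mean and standard deviation (n-1 divisor) used for
#' z-scoring. Specs are reference-specific by construction.
#'
#' @param reference A `cohort_table` (or data frame) complete on `marker_names`.
#' @param marker_names Markers to fit.
#' @param floor_n,w_max_n Passed to [select_transform()].
#' @return A `transform_spec`: data frame with columns `marker`, `transform`,
#'   `ref_mean`, `ref_sd`, `normality_score`.
#' @export
fit_transform_spec <- function(reference, marker_names = markers(reference),
                               floor_n = 10L, w_max_n = 5000L) {
  rows <- lapply(marker_names, function(mk) {
    v <- reference[[mk]]
    if (anyNA(v)) stop_dysreg(paste0("reference not complete on marker ", mk),
                              "dysregkit_input_error")
    if (stats::sd(v) == 0) {
      stop_dysreg(paste0("zero-variance marker in reference: ", mk),
                  "dysregkit_input_error")
    }
    choice <- select_transform(v, floor_n = floor_n, w_max_n = w_max_n)
    tv <- TRANSFORMS[[choice]]$fn(v)
    data.frame(marker = mk, transform = as.character(choice),
               ref_mean = mean(tv), ref_sd = stats::sd(tv),
               normality_score = attr(choice, "score"),
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("transform_spec", "data.frame"))
}

#' Transform and standardize marker values per a fitted spec
#'
#' Each cell is transformed per the spec's per-marker choice, then z-scored
#' with the spec's reference mean and sd. Cells violating a transform's
#' domain (e.g. nonpositive under log) arise when one population's spec is
#' applied to another population's values; the `domain_violation` policy
#' either drops the whole row (default, since the distance needs a complete
#' vector) or blanks the cell.
#'
#' @param values Data frame or matrix holding at least the spec's markers.
#' @param spec A `transform_spec`.
#' @param domain_violation `"drop_row"` (default) or `"set_missing"`.
#' @return List: `z` (numeric matrix, one column per spec marker, rows
#'   surviving the policy), `kept` (logical vector over input rows),
#'   `violations` (per-marker domain-violation counts).
#' @export
apply_spec <- function(values, spec,
                       domain_violation = c("drop_row", "set_missing")) {
  domain_violation <- match.arg(domain_violation)
  values <- as.data.frame(values)
  miss <- setdiff(spec$marker, names(values))
  if (length(miss) > 0) {
    stop_dysreg(paste0("values lack spec marker(s): ",
                       paste(miss, collapse = ", ")),
                "dysregkit_input_error")
  }
  n <- nrow(values)
  z <- matrix(NA_real_, nrow = n, ncol = nrow(spec),
              dimnames = list(NULL, spec$marker))
  bad <- matrix(FALSE, nrow = n, ncol = nrow(spec))
  for (j in seq_len(nrow(spec))) {
    v <- values[[spec$marker[j]]]
    viol <- switch(spec$transform[j],
                   identity = rep(FALSE, n),
                   sqrt = !is.na(v) & v < 0,
                   log = !is.na(v) & v <= 0)
    viol <- viol | is.na(v)
    tv <- rep(NA_real_, n)
    ok <- !viol
    tv[ok] <- TRANSFORMS[[spec$transform[j]]]$fn(v[ok])
    z[, j] <- (tv - spec$ref_mean[j]) / spec$ref_sd[j]
    bad[, j] <- viol
  }
  violations <- stats::setNames(colSums(bad), spec$marker)
  if (domain_violation == "drop_row") {
    kept <- rowSums(bad) == 0
    z <- z[kept, , drop = FALSE]
  } else {
    kept <- rep(TRUE, n)
  }
  list(z = z, kept = kept, violations = violations)
}

#' Serialize a transform spec to JSON
#' @param spec A `transform_spec`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transform_spec <- function(spec, path) {
  # 17 significant digits round-trips IEEE doubles exactly
  jsonlite::write_json(as.data.frame(spec), path, digits = I(17),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Reload a transform spec written by [write_transform_spec()]
#' @param path JSON path.
#' @return A `transform_spec`.
#' @export
read_transform_spec <- function(path) {
  df <- jsonlite::fromJSON(path)
  structure(as.data.frame(df), class = c("transform_spec", "data.frame"))
}
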