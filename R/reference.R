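# Reference population construction.
#
# A reference population operationalizes "homeostasis": the per-marker
# transform choices plus the mean vector mu and covariance S of the
# (standardized) reference sample. Three schemes are supported: each species
# as its own reference (first observations, approximating a younger and
# presumably healthier state), one species as a reference for others, and a
# balanced multispecies pool subsampled so no well-sampled species dominates.

#' Construct a reference population object
#'
#' Usually produced by [build_self_reference()], [build_cross_reference()] or
#' [build_combined_reference()] rather than called directly.
#'
#' @param scheme `"self"`, `"cross"` or `"combined"`.
#' @param source_species Species label, or `"combined"`.
#' @param spec A `transform_spec`.
#' @param mu,S Reference moments on the standardized scale.
#' @param n_ref Reference sample size.
#' @param member_keys Data frame (`species`, `individual_id`) of members.
#' @param seed Seed used for subsampling, or `NULL`.
#' @param lambda Shrinkage weight applied to `S` (0 when none was needed).
#' @return A `reference_population` list with a provenance `id`.
#' @export
reference_population <- function(scheme, source_species, spec, mu, S, n_ref,
                                 member_keys, seed = NULL, lambda = 0) {
  stopifnot(scheme %in% c("self", "cross", "combined"),
            length(mu) == nrow(spec), all(dim(S) == length(mu)),
            n_ref > length(mu))
  structure(list(
    id = paste0(scheme, ":", source_species),
    scheme = scheme, source_species = source_species,
    spec = spec, mu = mu, S = S, n_ref = n_ref,
    member_keys = member_keys, seed = seed, lambda = lambda
  ), class = "reference_population")
}

#' @export
print.reference_population <- function(x, ...) {
  cat(sprintf("<reference_population> %s (n_ref = %d, %d markers, lambda = %.3g)\n",
              x$id, x$n_ref, length(x$mu), x$lambda))
  invisible(x)
}

#' First (youngest) observation of each individual
#'
#' One row per individual: the visit with minimal `age_at_obs`; ties broken
#' by stable input order.
#'
#' @param cohort A `cohort_table`.
#' @return A `cohort_table` with exactly one row per individual.
#' @export
first_observations <- function(cohort) {
  ord <- order(cohort$individual_id, cohort$age_at_obs,
               seq_len(nrow(cohort)), method = "radix")
  sorted <- cohort[ord, , drop = FALSE]
  keep <- !duplicated(sorted$individual_id)
  out <- sorted[keep, , drop = FALSE]
  # restore original encounter order of individuals
  out <- out[order(match(out$individual_id, cohort$individual_id)), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "markers") <- markers(cohort)
  class(out) <- c("cohort_table", "data.frame")
  out
}

build_reference_from_rows <- function(rows, marker_names, scheme,
                                      source_species, seed = NULL,
                                      cond_threshold = 1e8,
                                      floor_n = 10L) {
  p <- length(marker_names)
  if (nrow(rows) <= p) {
    stop_dysreg(sprintf(
      "reference has n_ref = %d individuals <= %d markers; enable shrinkage via a larger reference or reduce the marker panel",
      nrow(rows), p), "dysregkit_conditioning_error")
  }
  spec <- fit_transform_spec(rows, marker_names, floor_n = floor_n)
  z <- apply_spec(rows, spec, domain_violation = "drop_row")$z
  mom <- estimate_moments(z, cond_threshold = cond_threshold)
  reference_population(
    scheme = scheme, source_species = source_species, spec = spec,
    mu = mom$mu, S = mom$S, n_ref = mom$n,
    member_keys = data.frame(species = rows$species,
                             individual_id = rows$individual_id,
                             stringsAsFactors = FALSE),
    seed = seed, lambda = mom$lambda)
}

#' Build a species-self reference population
#'
#' Reference members are the first observations of every individual of the
#' species; the transform spec and moments are fitted on them, so the
#' reference's own mu is the zero vector and S has unit diagonal on the
#' standardized scale.
#'
#' @param species_cohort Single-species `cohort_table`, complete on
#'   `marker_names`.
#' @param marker_names Markers to use (default: the cohort's panel).
#' @param cond_threshold Condition-number ceiling for [estimate_moments()].
#' @param floor_n Minimum reference size for transform selection.
#' @return A `reference_population` with `scheme = "self"`.
#' @export
build_self_reference <- function(species_cohort,
                                 marker_names = markers(species_cohort),
                                 cond_threshold = 1e8, floor_n = 10L) {
  sp <- unique(species_cohort$species)
  if (length(sp) != 1) {
    stop_dysreg("self reference requires a single-species cohort",
                "dysregkit_input_error")
  }
  build_reference_from_rows(first_observations(species_cohort), marker_names,
                            scheme = "self", source_species = sp,
                            cond_threshold = cond_threshold, floor_n = floor_n)
}

#' Build a cross-species reference
#'
#' Identical to [build_self_reference()] but tagged `scheme = "cross"` for
#' provenance: consumers apply its spec and moments to other species' rows.
#' Applied back to its own species it reproduces the self-scheme scores
#' exactly.
#'
#' @inheritParams build_self_reference
#' @return A `reference_population` with `scheme = "cross"`.
#' @export
build_cross_reference <- function(species_cohort,
                                  marker_names = markers(species_cohort),
                                  cond_threshold = 1e8, floor_n = 10L) {
  ref <- build_self_reference(species_cohort, marker_names,
                              cond_threshold = cond_threshold,
                              floor_n = floor_n)
  ref$scheme <- "cross"
  ref$id <- paste0("cross:", ref$source_species)
  ref
}

#' Build a balanced combined (multispecies) reference
#'
#' Pools first observations across species, subsampling every species without
#' replacement to m = the minimum per-species first-observation count, so the
#' best-sampled species cannot dominate the pooled homeostatic signature.
#' Optionally z-scores each species' markers within species before pooling
#' (recommended for direct cross-species comparisons, where among-species
#' mean differences would otherwise dominate the pooled covariance).
#'
#' @param cohorts Named list of per-species `cohort_table`s, complete on the
#'   shared `marker_names`.
#' @param marker_names Shared marker panel.
#' @param seed Integer seed for the subsample (mandatory; recorded).
#' @param standardize_within_species Z-score within species before pooling
#'   (default `FALSE`).
#' @param cond_threshold,floor_n As in [build_self_reference()].
#' @return A `reference_population` with `scheme = "combined"`.
#' @export
build_combined_reference <- function(cohorts, marker_names, seed,
                                     standardize_within_species = FALSE,
                                     cond_threshold = 1e8, floor_n = 10L) {
  if (length(marker_names) == 0) {
    stop_dysreg("shared marker set is empty", "dysregkit_input_error")
  }
  firsts <- lapply(cohorts, first_observations)
  m <- min(vapply(firsts, nrow, integer(1)))
  sampled <- with_seed(seed, lapply(firsts, function(f) {
    f[sort(sample.int(nrow(f), m)), , drop = FALSE]
  }))
  pooled <- do.call(rbind, lapply(sampled, function(f) {
    f <- as.data.frame(f)[, c("species", "individual_id", marker_names),
                          drop = FALSE]
    if (standardize_within_species) {
      for (mk in marker_names) {
        f[[mk]] <- (f[[mk]] - mean(f[[mk]])) / stats::sd(f[[mk]])
      }
    }
    f
  }))
  rownames(pooled) <- NULL
  build_reference_from_rows(pooled, marker_names, scheme = "combined",
                            source_species = "combined", seed = seed,
                            cond_threshold = cond_threshold, floor_n = floor_n)
}

#' Serialize a reference population to JSON
#' @param ref A `reference_population`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(ref, path) {
  jsonlite::write_json(list(
    id = ref$id, scheme = ref$scheme, source_species = ref$source_species,
    spec = as.data.frame(ref$spec), mu = ref$mu, S = ref$S,
    n_ref = ref$n_ref, member_keys = ref$member_keys,
    seed = ref$seed, lambda = ref$lambda
  ), path, digits = I(17), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Reload a reference written by [write_reference()]
#' @param path JSON path.
#' @return A `reference_population`.
#' @export
read_reference <- function(path) {
  obj <- jsonlite::fromJSON(path)
  ref <- reference_population(
    scheme = obj$scheme, source_species = obj$source_species,
    spec = structure(as.data.frame(obj$spec),
                     class = c("transform_spec", "data.frame")),
    mu = stats::setNames(as.numeric(obj$mu), obj$spec$marker),
    S = matrix(unlist(obj$S), nrow = length(obj$mu),
               dimnames = list(obj$spec$marker, obj$spec$marker)),
    n_ref = obj$n_ref, member_keys = as.data.frame(obj$member_keys),
    seed = obj$seed, lambda = obj$lambda %||% 0)
  ref
}
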