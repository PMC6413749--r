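# Cohort filtering: adults only, plausibility screening, marker-panel selection.

#' Keep sexually mature individuals only
#'
#' Retains rows with `age_at_obs >= maturation_age` of the row's species
#' (boundary inclusive). Idempotent.
#'
#' @param cohort A `cohort_table`.
#' @param meta A [species_meta()] covering every species in `cohort`.
#' @return Filtered `cohort_table`; attribute `n_removed` reports the count of
#'   dropped rows.
#' @export
filter_adults <- function(cohort, meta) {
  sp_tab <- meta$species
  miss <- setdiff(unique(cohort$species), sp_tab$species)
  if (length(miss) > 0) {
    stop_dysreg(paste0("species missing maturation age: ",
                       paste(miss, collapse = ", ")),
                "dysregkit_config_error")
  }
  mat <- sp_tab$maturation_age[match(cohort$species, sp_tab$species)]
  keep <- cohort$age_at_obs >= mat
  out <- cohort[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0) warning("filter_adults removed every row (all juveniles)")
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Blank biologically implausible marker values
#'
#' Marker cells outside their configured open interval `(low, high)` are set
#' to missing. Screening is cell-wise: rows are never removed here; the
#' complete-case rule in [select_marker_set()] governs row retention. Values
#' exactly on a bound are retained. Markers without bounds pass through.
#'
#' @param cohort A `cohort_table`.
#' @param meta A [species_meta()]; its `bounds` table drives screening.
#' @return `cohort_table` with implausible cells blanked; attribute
#'   `implausible_counts` reports per-marker removal counts.
#' @export
filter_implausible <- function(cohort, meta) {
  bounds <- meta$bounds
  counts <- stats::setNames(integer(length(markers(cohort))), markers(cohort))
  if (!is.null(bounds)) {
    for (i in seq_len(nrow(bounds))) {
      mk <- bounds$marker[i]
      if (!mk %in% markers(cohort)) next
      rows <- if (is.na(bounds$species[i])) rep(TRUE, nrow(cohort))
              else cohort$species == bounds$species[i]
      v <- cohort[[mk]]
      bad <- rows & !is.na(v) & (v < bounds$low[i] | v > bounds$high[i])
      cohort[[mk]][bad] <- NA_real_
      counts[mk] <- counts[mk] + sum(bad)
    }
  }
  attr(cohort, "implausible_counts") <- counts
  cohort
}

#' Select a marker panel and apply the complete-case rule
#'
#' Two panel modes mirror the two analysis designs supported: `"variable"`
#' keeps, per species, the markers observed in at least `availability`
#' fraction of that species' rows (a species is dropped with a warning when
#' fewer than `min_markers` qualify); `"fixed"` keeps exactly `fixed_panel`
#' for every species (a species entirely lacking a panel marker is dropped
#' with a warning). In both modes only rows complete on the selected markers
#' are retained.
#'
#' @param cohort A `cohort_table`.
#' @param mode `"variable"` or `"fixed"`.
#' @param fixed_panel Marker names, required when `mode = "fixed"`.
#' @param min_markers Minimum panel size in variable mode (default 10).
#' @param availability Per-species availability fraction threshold in
#'   variable mode (default 0.7).
#' @return Named list of per-species `cohort_table`s, complete on their panel.
#' @export
select_marker_set <- function(cohort, mode = c("variable", "fixed"),
                              fixed_panel = NULL, min_markers = 10L,
                              availability = 0.7) {
  mode <- match.arg(mode)
  if (mode == "fixed" && is.null(fixed_panel)) {
    stop_dysreg("fixed mode requires fixed_panel", "dysregkit_config_error")
  }
  out <- list()
  for (sp in unique(cohort$species)) {
    sub <- cohort[cohort$species == sp, , drop = FALSE]
    if (mode == "fixed") {
      panel <- fixed_panel
      absent <- panel[vapply(panel, function(mk) all(is.na(sub[[mk]])), logical(1))]
      if (length(absent) > 0) {
        warning(sprintf("species %s dropped: fixed-panel marker(s) absent: %s",
                        sp, paste(absent, collapse = ", ")))
        next
      }
    } else {
      avail <- vapply(markers(cohort),
                      function(mk) mean(!is.na(sub[[mk]])), numeric(1))
      panel <- names(avail)[avail >= availability]
      if (length(panel) < min_markers) {
        warning(sprintf("species %s dropped: %d markers available, %d required",
                        sp, length(panel), min_markers))
        next
      }
    }
    complete <- stats::complete.cases(sub[, panel, drop = FALSE])
    sub <- sub[complete, c(setdiff(names(sub), markers(cohort)), panel),
               drop = FALSE]
    rownames(sub) <- NULL
    attr(sub, "markers") <- panel
    attr(sub, "n_incomplete_removed") <- sum(!complete)
    class(sub) <- c("cohort_table", "data.frame")
    out[[sp]] <- sub
  }
  out
}
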