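# Cross-species conservation of the homeostatic signature.
#
# If homeostasis is conserved, dysregulation scores computed against a
# foreign species' reference should track the scores computed against the
# species' own reference; the species-by-species matrix of those
# correlations, compared against phylogenetic distance, is the conservation
# test.

#' Per-species correlation between self- and combined-reference scores
#'
#' Matches observations across the two score tables by (species,
#' individual_id, age_at_obs) and returns one Pearson r per species. Species
#' with fewer than 3 matched observations are skipped with a warning.
#'
#' @param scores_self,scores_combined `score_table`s over the same cohort.
#' @return Data frame: `species`, `r`, `n`.
#' @export
self_vs_combined_correlation <- function(scores_self, scores_combined) {
  key <- function(s) paste(s$species, s$individual_id, s$age_at_obs, sep = "\r")
  merged <- merge(
    data.frame(key = key(scores_self), species = scores_self$species,
               dm_self = scores_self$dm, stringsAsFactors = FALSE),
    data.frame(key = key(scores_combined), dm_comb = scores_combined$dm,
               stringsAsFactors = FALSE),
    by = "key")
  out <- lapply(unique(merged$species), function(sp) {
    sub <- merged[merged$species == sp, ]
    if (nrow(sub) < 3) {
      warning(sprintf("species %s skipped: only %d matched observations",
                      sp, nrow(sub)))
      return(NULL)
    }
    data.frame(species = sp, r = stats::cor(sub$dm_self, sub$dm_comb),
               n = nrow(sub), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Cross-reference correlation matrix
#'
#' For every ordered species pair (A, B), scores A's observations against
#' A's own (self) reference and against B's reference, and records the
#' Pearson correlation over A's observations retained under both (rows
#' dropped by transform-domain rules are excluded pairwise). Rows of the
#' result are the species being scored; columns are the species serving as
#' the reference; the diagonal is exactly 1. The matrix is not symmetric in
#' general. Optionally appends a combined-reference column and row.
#'
#' @param cohorts Named list of per-species `cohort_table`s sharing
#'   `marker_names`.
#' @param marker_names Shared marker panel.
#' @param combined Optional `reference_population` (scheme `"combined"`); when
#'   given, a `"combined"` column (each species scored against it) and row
#'   (the pooled sample scored against each species) are appended for display.
#' @param min_pair_n Minimum scoreable observations per cell (default 3);
#'   smaller cells are set `NA` with a message.
#' @return A `crossref_matrix`: square numeric matrix with attribute
#'   `pair_n` (observation counts per cell).
#' @export
cross_reference_matrix <- function(cohorts, marker_names,
                                   combined = NULL, min_pair_n = 3L) {
  species <- names(cohorts)
  refs <- lapply(species, function(sp) {
    ref <- build_cross_reference(cohorts[[sp]], marker_names)
    ref
  })
  names(refs) <- species
  labels <- c(species, if (!is.null(combined)) "combined")
  r <- matrix(NA_real_, length(labels), length(labels),
              dimnames = list(target = labels, reference = labels))
  n_mat <- r
  self_scores <- lapply(species, function(sp)
    score_cohort(cohorts[[sp]], refs[[sp]]))
  names(self_scores) <- species
  cell <- function(target_cohort, self_sc, ref) {
    sc <- tryCatch(score_cohort(target_cohort, ref), error = function(e) NULL)
    if (is.null(sc)) return(c(NA_real_, 0))
    key <- function(s) paste(s$individual_id, s$age_at_obs, sep = "\r")
    m <- merge(data.frame(key = key(self_sc), a = self_sc$dm),
               data.frame(key = key(sc), b = sc$dm), by = "key")
    if (nrow(m) < min_pair_n) return(c(NA_real_, nrow(m)))
    c(stats::cor(m$a, m$b), nrow(m))
  }
  for (a in species) {
    for (b in labels) {
      if (a == b) {
        r[a, b] <- 1
        n_mat[a, b] <- nrow(self_scores[[a]])
        next
      }
      ref_b <- if (b == "combined") combined else refs[[b]]
      res <- cell(cohorts[[a]], self_scores[[a]], ref_b)
      r[a, b] <- res[1]; n_mat[a, b] <- res[2]
    }
  }
  if (!is.null(combined)) {
    # combined row: the pooled member sample scored against each reference
    pooled <- do.call(rbind, lapply(species, function(sp) {
      f <- as.data.frame(first_observations(cohorts[[sp]]))
      mk <- combined$member_keys
      f[f$individual_id %in% mk$individual_id[mk$species == sp], , drop = FALSE]
    }))
    pooled <- cohort_table(pooled, marker_names, validate = FALSE)
    comb_self <- score_cohort(pooled, combined)
    key2 <- function(s) paste(s$species, s$individual_id, s$age_at_obs, sep = "\r")
    for (b in species) {
      sc <- tryCatch(score_cohort(pooled, refs[[b]]), error = function(e) NULL)
      if (is.null(sc)) next
      m <- merge(data.frame(key = key2(comb_self), a = comb_self$dm),
                 data.frame(key = key2(sc), b = sc$dm), by = "key")
      if (nrow(m) >= min_pair_n) {
        r["combined", b] <- stats::cor(m$a, m$b)
        n_mat["combined", b] <- nrow(m)
      }
    }
    r["combined", "combined"] <- NA_real_  # subsample vs pool, not identical
  }
  if (any(!is.finite(r[species, species][row(diag(length(species))) != col(diag(length(species)))]))) {
    message("some cross-reference cells are missing (too few scoreable observations)")
  }
  structure(r, pair_n = n_mat, class = c("crossref_matrix", "matrix", "array"))
}

#' Phylogenetic conservation test (matrix rank correlation)
#'
#' Spearman rank correlation between the off-diagonal cells of the
#' cross-reference correlation matrix and phylogenetic proximity (negative
#' patristic distance), with a Mantel-style permutation p-value: species
#' labels are permuted jointly over rows and columns of the distance matrix,
#' which respects the dependence among cells sharing a species. The naive
#' cell-independence p-value from the rank correlation test is also reported.
#' Any `combined` row/column must be excluded before calling (and is,
#' defensively, here).
#'
#' @param crm A `crossref_matrix` (species x species).
#' @param pdm A patristic distance matrix over the same species.
#' @param halves `"full"` (all off-diagonal cells, default), `"upper"` or
#'   `"lower"` triangle only.
#' @param n_perm Number of label permutations (default 9999).
#' @param seed Seed for the permutations.
#' @param max_missing Error when more than this fraction of cells is missing
#'   (default 0.2); missing cells are otherwise deleted pairwise.
#' @return List: `rho`, `p_permutation` (one-sided, positive association),
#'   `p_naive`, `n_cells`, `halves`, `n_perm`.
#' @export
phylo_conservation_test <- function(crm, pdm, halves = c("full", "upper", "lower"),
                                    n_perm = 9999L, seed = 1L,
                                    max_missing = 0.2) {
  halves <- match.arg(halves)
  sp <- setdiff(rownames(crm), "combined")
  if (!setequal(sp, rownames(pdm))) {
    stop_dysreg("species sets of the two matrices differ",
                "dysregkit_input_error")
  }
  crm <- crm[sp, sp, drop = FALSE]
  pdm <- pdm[sp, sp, drop = FALSE]
  k <- length(sp)
  mask <- switch(halves,
                 full = row(crm) != col(crm),
                 upper = upper.tri(crm),
                 lower = lower.tri(crm))
  x <- crm[mask]
  if (mean(is.na(x)) > max_missing) {
    stop_dysreg(sprintf("%.0f%% of cross-reference cells missing (> %.0f%% allowed)",
                        100 * mean(is.na(x)), 100 * max_missing),
                "dysregkit_input_error")
  }
  prox_full <- -pdm
  stat <- function(perm) {
    y <- prox_full[perm, perm][mask]
    ok <- !is.na(x)
    stats::cor(x[ok], y[ok], method = "spearman")
  }
  rho <- stat(seq_len(k))
  perm_rhos <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    stat(sample.int(k)) }, numeric(1)))
  p_perm <- (1 + sum(perm_rhos >= rho)) / (n_perm + 1)
  ok <- !is.na(x)
  p_naive <- suppressWarnings(
    stats::cor.test(x[ok], prox_full[mask][ok], method = "spearman",
                    alternative = "greater")$p.value)
  list(rho = rho, p_permutation = p_perm, p_naive = p_naive,
       n_cells = sum(ok), halves = halves, n_perm = n_perm)
}

#' Write a square labelled matrix as CSV
#' @param m Matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(m, path) {
  df <- data.frame(species = rownames(m), as.data.frame(unclass(m)),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
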