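# Per-species longitudinal models: dysregulation on age and sex, and body
# mass analyses. Model fitting delegates to lme4; the bespoke content here is
# design-matrix assembly, standardization, random-structure selection rules,
# and uniform reporting. Inference uses the Wald normal approximation.

model_result <- function(species, formula_desc, coefs, random_effects,
                         n_obs, n_ids, dv_log_transformed, fit) {
  structure(list(
    species = species, formula = formula_desc, coefficients = coefs,
    random_effects = random_effects, n_obs = n_obs, n_ids = n_ids,
    dv_log_transformed = dv_log_transformed, fit = fit
  ), class = "dysreg_model_result")
}

#' @export
print.dysreg_model_result <- function(x, ...) {
  cat(sprintf("<model_result> %s | %s | n_obs = %d, n_ids = %d%s\n",
              x$species, x$formula, x$n_obs, x$n_ids,
              if (x$dv_log_transformed) " | dv log-transformed" else ""))
  print(x$coefficients, digits = 4)
  invisible(x)
}

z_scale <- function(v) {
  s <- stats::sd(v)
  if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
}

# Random-structure selection rules shared by the longitudinal models:
#  - individual random intercept only when repeated observations exist for
#    more than `repeat_floor` of individuals;
#  - population random intercept only when there is more than one population.
random_terms_for <- function(df, slope_age = FALSE, repeat_floor = 0.01) {
  n_per_id <- table(df$individual_id)
  share_repeated <- mean(n_per_id > 1)
  terms <- character(0)
  if (share_repeated > repeat_floor) {
    terms <- c(terms, if (slope_age) "(1 + age_z | individual_id)"
                      else "(1 | individual_id)")
  }
  if (length(unique(df$population)) > 1) terms <- c(terms, "(1 | population)")
  terms
}

fit_lmm_or_lm <- function(df, fixed, random_terms) {
  if (length(random_terms) > 0) {
    form <- stats::as.formula(paste(fixed, "+", paste(random_terms, collapse = " + ")))
    fit <- lme4::lmer(form, data = df, REML = TRUE,
                      control = lme4::lmerControl(check.conv.singular = "ignore"))
    sm <- summary(fit)$coefficients
    list(fit = fit, est = sm[, "Estimate"], se = sm[, "Std. Error"],
         resid = stats::resid(fit),
         random = paste(random_terms, collapse = " + "))
  } else {
    fit <- stats::lm(stats::as.formula(fixed), data = df)
    sm <- summary(fit)$coefficients
    list(fit = fit, est = sm[, "Estimate"], se = sm[, "Std. Error"],
         resid = stats::resid(fit), random = "none")
  }
}

#' Mixed model of dysregulation on age and sex (per species)
#'
#' Fits, for one species' score table, `dm_z ~ age_z * sex` with random
#' intercepts for individual (dropped when repeated observations are absent
#' for >= 99% of individuals) and for population (included only with more
#' than one population). Both the score and age are centered to 0 and scaled
#' to sd 1 so effect sizes are comparable across species. Sex terms are
#' dropped automatically (with a note) for single-sex species; rows with
#' unknown sex are excluded whenever a sex term is present. When the
#' residual skewness of the initial fit exceeds `skew_threshold` the
#' dependent variable is recomputed as the within-species z-score of
#' log(dm) and the model refitted, flagged in the result.
#'
#' @param scores A single-species `score_table`.
#' @param skew_threshold |skewness| beyond which the score is log-transformed
#'   before scaling (default 1).
#' @return A `dysreg_model_result` (coefficient table with Wald 95% CIs).
#' @export
fit_age_sex_model <- function(scores, skew_threshold = 1) {
  sp <- unique(scores$species)
  if (length(sp) != 1) stop_dysreg("fit one species at a time",
                                   "dysregkit_input_error")
  df <- as.data.frame(scores)
  sexes <- setdiff(unique(df$sex), "unknown")
  use_sex <- length(sexes) >= 2
  if (use_sex) df <- df[df$sex != "unknown", , drop = FALSE]
  df$age_z <- z_scale(df$age_at_obs)
  df$dv <- z_scale(df$dm_z)
  if (use_sex) df$sex <- factor(df$sex, levels = c("female", "male"))
  fixed <- if (use_sex) "dv ~ age_z * sex" else "dv ~ age_z"
  rts <- random_terms_for(df)
  res <- fit_lmm_or_lm(df, fixed, rts)
  logged <- FALSE
  if (is.finite(skew_threshold) && abs(skewness(res$resid)) > skew_threshold &&
      all(df$dm > 0)) {
    df$dv <- z_scale(log(df$dm))
    res <- fit_lmm_or_lm(df, fixed, rts)
    logged <- TRUE
  }
  model_result(sp, paste0(fixed, if (length(rts)) paste0(" + ", res$random) else ""),
               wald_coef_table(res$est, res$se), res$random,
               n_obs = nrow(df), n_ids = length(unique(df$individual_id)),
               dv_log_transformed = logged, fit = res$fit)
}

#' Subsequent body-mass change rate per observation
#'
#' For every observation with a later observation of the same individual,
#' the rate (kg/year) of mass change to the next observation:
#' `(mass[i+1] - mass[i]) / (age[i+1] - age[i])`, attached to observation i.
#' The last observation per individual contributes no rate; nonpositive age
#' gaps are skipped and counted.
#'
#' @param cohort A `cohort_table` with `body_mass`.
#' @return Data frame `species`, `individual_id`, `age_at_obs`, `sex`,
#'   `population`, `mass`, `mass_change_rate`; attribute `n_skipped` counts
#'   nonpositive-gap rows.
#' @export
mass_change_rate <- function(cohort) {
  df <- as.data.frame(cohort)
  df <- df[!is.na(df$body_mass), , drop = FALSE]
  df <- df[order(df$individual_id, df$age_at_obs), , drop = FALSE]
  n_skipped <- 0L
  out <- lapply(split(df, df$individual_id), function(d) {
    if (nrow(d) < 2) return(NULL)
    gap <- diff(d$age_at_obs)
    rate <- diff(d$body_mass) / gap
    keep <- gap > 0
    n_skipped <<- n_skipped + sum(!keep)
    d <- d[seq_len(nrow(d) - 1), , drop = FALSE][keep, , drop = FALSE]
    if (nrow(d) == 0) return(NULL)
    data.frame(species = d$species, individual_id = d$individual_id,
               age_at_obs = d$age_at_obs, sex = d$sex,
               population = d$population, mass = d$body_mass,
               mass_change_rate = rate[keep], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

merge_dm <- function(df, scores) {
  key <- function(s, a) paste(s, a, sep = "\r")
  idx <- match(key(df$individual_id, df$age_at_obs),
               key(scores$individual_id, scores$age_at_obs))
  df$dm_z <- scores$dm_z[idx]
  df[!is.na(df$dm_z), , drop = FALSE]
}

#' Mixed model of body mass on age, sex and (optionally) dysregulation
#'
#' `mass ~ age + age^2 + sex + age:sex (+ dm_z)`, with a random intercept and
#' a random age slope per individual, and a population intercept when there
#' is more than one population. Sex terms are dropped for single-sex species.
#' Mass is log-transformed (flagged) when residual skewness demands it.
#'
#' @param cohort Single-species `cohort_table` with `body_mass`.
#' @param scores Optional `score_table`; when given, `dm_z` is added as a
#'   fixed effect (matched on individual and age).
#' @param skew_threshold As in [fit_age_sex_model()].
#' @return A `dysreg_model_result`.
#' @export
fit_mass_model <- function(cohort, scores = NULL, skew_threshold = 1) {
  sp <- unique(cohort$species)
  if (length(sp) != 1) stop_dysreg("fit one species at a time",
                                   "dysregkit_input_error")
  df <- as.data.frame(cohort)
  df <- df[!is.na(df$body_mass), , drop = FALSE]
  if (!is.null(scores)) df <- merge_dm(df, scores)
  if (nrow(df) == 0) stop_dysreg("no usable body-mass rows",
                                 "dysregkit_input_error")
  sexes <- setdiff(unique(df$sex), "unknown")
  use_sex <- length(sexes) >= 2
  if (use_sex) {
    df <- df[df$sex != "unknown", , drop = FALSE]
    df$sex <- factor(df$sex, levels = c("female", "male"))
  }
  df$age_z <- z_scale(df$age_at_obs)
  df$dv <- df$body_mass
  fixed <- paste0("dv ~ age_z + I(age_z^2)",
                  if (use_sex) " + sex + age_z:sex" else "",
                  if (!is.null(scores)) " + dm_z" else "")
  rts <- random_terms_for(df, slope_age = TRUE)
  res <- fit_lmm_or_lm(df, fixed, rts)
  logged <- FALSE
  if (is.finite(skew_threshold) && abs(skewness(res$resid)) > skew_threshold &&
      all(df$body_mass > 0)) {
    df$dv <- log(df$body_mass)
    res <- fit_lmm_or_lm(df, fixed, rts)
    logged <- TRUE
  }
  model_result(sp, paste0(fixed, if (length(rts)) paste0(" + ", res$random) else ""),
               wald_coef_table(res$est, res$se), res$random,
               n_obs = nrow(df), n_ids = length(unique(df$individual_id)),
               dv_log_transformed = logged, fit = res$fit)
}

#' Mixed model of subsequent mass-change rate on dysregulation
#'
#' `rate ~ sex + age_z + dm_z + all two-way interactions`, with a random
#' intercept per individual and a population intercept when applicable.
#'
#' @param rates Output of [mass_change_rate()] for one species.
#' @param scores A `score_table` for the same species.
#' @return A `dysreg_model_result`.
#' @export
fit_mass_change_model <- function(rates, scores) {
  if (is.null(rates) || nrow(rates) == 0) {
    stop_dysreg("empty mass-change rate table", "dysregkit_input_error")
  }
  sp <- unique(rates$species)
  if (length(sp) != 1) stop_dysreg("fit one species at a time",
                                   "dysregkit_input_error")
  df <- merge_dm(rates, scores)
  if (nrow(df) == 0) stop_dysreg("no rate rows matched to scores",
                                 "dysregkit_input_error")
  sexes <- setdiff(unique(df$sex), "unknown")
  use_sex <- length(sexes) >= 2
  if (use_sex) {
    df <- df[df$sex != "unknown", , drop = FALSE]
    df$sex <- factor(df$sex, levels = c("female", "male"))
  }
  df$age_z <- z_scale(df$age_at_obs)
  df$dv <- df$mass_change_rate
  fixed <- if (use_sex) "dv ~ (sex + age_z + dm_z)^2" else "dv ~ (age_z + dm_z)^2"
  rts <- random_terms_for(df, slope_age = FALSE)
  res <- fit_lmm_or_lm(df, fixed, rts)
  model_result(sp, paste0(fixed, if (length(rts)) paste0(" + ", res$random) else ""),
               wald_coef_table(res$est, res$se), res$random,
               n_obs = nrow(df), n_ids = length(unique(df$individual_id)),
               dv_log_transformed = FALSE, fit = res$fit)
}

#' Export a list of model results as one CSV table
#' @param results List of `dysreg_model_result`s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_results <- function(results, path) {
  tab <- do.call(rbind, lapply(results, function(r) {
    cbind(species = r$species, r$coefficients,
          n_obs = r$n_obs, n_ids = r$n_ids,
          dv_log_transformed = r$dv_log_transformed)
  }))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
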