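# Counting-process coding of longitudinal scores and Cox PH mortality models
# with age as the timescale.
#
# Each observation opens a risk interval at the age at observation. The
# interval ends at the age at the next observation (if any), else at the age
# of confirmed death (if any), else 0.25 years after the observation — the
# minimum inter-observation gap in the source data, so an individual with
# unknown final status is censored shortly after last being seen. The event
# indicator is 1 only on the last observation of an individual with a
# confirmed death.

#' Code score observations as counting-process risk intervals
#'
#' @param scores A `score_table` (any number of species; intervals are coded
#'   per individual).
#' @param death_ages Named numeric vector mapping `individual_id` to
#'   confirmed death age (years); individuals absent from it are treated as
#'   unknown final status. When `NULL`, death ages are taken from a
#'   `death_age` column of `scores` if present.
#' @param gap Censoring horizon after a final observation with no confirmed
#'   death (default 0.25 years).
#' @return Data frame with `individual_id`, `species`, `population`, `sex`,
#'   `start_age`, `stop_age`, `event`, `dm_z`.
#' @export
code_intervals <- function(scores, death_ages = NULL, gap = 0.25) {
  df <- as.data.frame(scores)
  if (is.null(death_ages)) {
    if ("death_age" %in% names(df)) {
      d <- tapply(df$death_age, df$individual_id,
                  function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
      death_ages <- d[!is.na(d)]
    } else {
      death_ages <- stats::setNames(numeric(0), character(0))
    }
  }
  out <- lapply(split(df, df$individual_id), function(d) {
    d <- d[order(d$age_at_obs), , drop = FALSE]
    id <- d$individual_id[1]
    death <- unname(death_ages[id])
    if (length(death) == 0 || is.na(death)) death <- NA_real_
    # duplicate observation ages cannot open two intervals at the same age
    dup <- duplicated(d$age_at_obs)
    if (any(dup)) {
      warning(sprintf("individual %s: duplicate observation age(s) shifted by 1e-6 y",
                      id))
      while (any(dup <- duplicated(d$age_at_obs))) {
        d$age_at_obs[dup] <- d$age_at_obs[dup] + 1e-6
      }
      d <- d[order(d$age_at_obs), , drop = FALSE]
    }
    n <- nrow(d)
    if (!is.na(death) && death < d$age_at_obs[n]) {
      stop_dysreg(sprintf("individual %s: death age %.4g precedes last observation %.4g",
                          id, death, d$age_at_obs[n]),
                  "dysregkit_input_error")
    }
    start <- d$age_at_obs
    stop_ <- c(d$age_at_obs[-1],
               if (!is.na(death)) death else start[n] + gap)
    event <- c(rep(0L, n - 1), if (!is.na(death)) 1L else 0L)
    if (stop_[n] <= start[n]) {
      # confirmed death exactly at the last observation age
      warning(sprintf("individual %s: death at last observation age; stop shifted by 1e-6 y", id))
      stop_[n] <- start[n] + 1e-6
    }
    data.frame(individual_id = id, species = d$species,
               population = d$population, sex = d$sex,
               start_age = start, stop_age = stop_, event = event,
               dm_z = d$dm_z, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Cox proportional-hazards model on risk intervals
#'
#' Partial-likelihood fit on `(start, stop, event]` data with age as the
#' timescale (Efron tie handling), via the survival package. The default
#' covariates are the time-dependent standardized dysregulation score and
#' sex; any numeric column of `intervals` can be substituted (e.g. mass or
#' mass-change rate). When both `dm_z` and `sex` are among the terms and
#' `screen_dm_sex_interaction` is `TRUE`, the dm_z:sex interaction is
#' prefitted and dropped when non-significant at `screen_alpha` (kept
#' otherwise). `center_effect = "random"` adds a gamma frailty term for
#' population when there is more than one population.
#'
#' @param intervals Output of [code_intervals()] (one species).
#' @param terms Covariate names (default `c("dm_z", "sex")`; sex dropped
#'   automatically for single-sex data).
#' @param center_effect `"none"` or `"random"`.
#' @param screen_dm_sex_interaction Screen and (usually) drop the dm_z-by-sex
#'   interaction (default `TRUE`).
#' @param screen_alpha Screening level (default 0.05).
#' @return List: `hr_table` (term, HR, CI, p), `coefficients` (log-hazard
#'   scale), `n_events`, `n_ids`, `interaction_kept`, `fit`.
#' @export
fit_cox <- function(intervals, terms = c("dm_z", "sex"),
                    center_effect = c("none", "random"),
                    screen_dm_sex_interaction = TRUE, screen_alpha = 0.05) {
  center_effect <- match.arg(center_effect)
  df <- intervals
  if (sum(df$event) == 0) {
    stop_dysreg("no events in the risk intervals", "dysregkit_input_error")
  }
  if ("sex" %in% terms) {
    sexes <- setdiff(unique(df$sex), "unknown")
    if (length(sexes) < 2) {
      terms <- setdiff(terms, "sex")
    } else {
      df <- df[df$sex != "unknown", , drop = FALSE]
      df$sex <- factor(df$sex, levels = c("female", "male"))
    }
  }
  rhs <- paste(terms, collapse = " + ")
  interaction_kept <- FALSE
  if (screen_dm_sex_interaction && all(c("dm_z", "sex") %in% terms)) {
    f_int <- stats::as.formula(paste(
      "survival::Surv(start_age, stop_age, event) ~", rhs, "+ dm_z:sex"))
    fit_int <- survival::coxph(f_int, data = df, ties = "efron")
    p_int <- summary(fit_int)$coefficients["dm_z:sexmale", "Pr(>|z|)"]
    if (!is.na(p_int) && p_int < screen_alpha) {
      rhs <- paste(rhs, "+ dm_z:sex")
      interaction_kept <- TRUE
    }
  }
  if (center_effect == "random" && length(unique(df$population)) > 1) {
    rhs <- paste(rhs, "+ survival::frailty(population)")
  }
  form <- stats::as.formula(paste(
    "survival::Surv(start_age, stop_age, event) ~", rhs))
  fit <- survival::coxph(form, data = df, ties = "efron")
  sm <- summary(fit)
  co <- sm$coefficients
  fixed <- rownames(co)[!grepl("^frailty", rownames(co))]
  est <- co[fixed, "coef"]
  se <- co[fixed, if ("se(coef)" %in% colnames(co)) "se(coef)" else "se2"]
  ct <- wald_coef_table(stats::setNames(est, fixed), stats::setNames(se, fixed))
  hr <- data.frame(term = ct$term, hr = exp(ct$estimate),
                   hr_lower = exp(ct$ci_lower), hr_upper = exp(ct$ci_upper),
                   p_value = ct$p_value, stringsAsFactors = FALSE)
  list(hr_table = hr, coefficients = ct,
       n_events = sum(df$event), n_ids = length(unique(df$individual_id)),
       interaction_kept = interaction_kept, fit = fit)
}
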