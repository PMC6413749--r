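# End-to-end orchestration: simulate/ingest -> filter -> reference -> score
# -> models -> survival -> conservation, from a single configuration, with a
# run manifest for provenance.

#' Run the dysregulation pipeline from a configuration
#'
#' Stages run in dependency order; each writes its artifacts under
#' `config$output_dir` and registers them in the manifest. Re-running with
#' the same configuration reproduces all stochastic stages bit-identically
#' (every source of randomness is seeded from the configuration).
#'
#' Configuration fields: either `simulate` (a list of [sim_config()]
#' arguments) or `cohort_csv` + `meta` (+ optional `tree_newick`);
#' `marker_set` (list: `mode`, optional `fixed_panel`, `min_markers`,
#' `availability`); `stages` (character subset of `simulate`, `score`,
#' `models`, `survival`, `conservation`); `combined_seed`,
#' `conservation_seed`; `output_dir`.
#'
#' @param config Named list as above (or a YAML/JSON path already parsed by
#'   [read_run_config()]).
#' @return The run manifest (list), invisibly written to
#'   `manifest.json` in the output directory.
#' @export
run_pipeline <- function(config) {
  stages <- config$stages %||% c("simulate", "score", "models", "survival",
                                 "conservation")
  if (length(stages) == 0) {
    stop_dysreg("no stages enabled", "dysregkit_config_error")
  }
  out_dir <- config$output_dir %||% "dysregkit_run"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(stages = list(), files = character(0),
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   package_version = as.character(utils::packageVersion("dysregkit")))
  register <- function(stage, files, counts) {
    manifest$stages[[stage]] <<- list(files = files, counts = counts)
    manifest$files <<- c(manifest$files, files)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop_dysreg(sprintf("stage '%s' failed: %s (artifacts so far under %s)",
                          stage, conditionMessage(e), out_dir),
                  "dysregkit_stage_error")
    })
  }

  # --- inputs ---------------------------------------------------------------
  tree <- NULL; meta <- NULL; truth <- NULL
  if ("simulate" %in% stages || !is.null(config$simulate)) {
    run_stage("simulate", {
      cf <- do.call(sim_config, config$simulate)
      sim <- simulate_cohort(cf)
      cohort <- sim$cohort; tree <- sim$tree; meta <- sim$meta
      truth <- sim$truth
      f1 <- file.path(out_dir, "cohort.csv")
      write_cohort(cohort, f1)
      f2 <- file.path(out_dir, "tree.nwk")
      ape::write.tree(tree, f2)
      f3 <- file.path(out_dir, "truth.json")
      jsonlite::write_json(list(
        params = truth$params,
        individuals = truth$individuals,
        visits = truth$visits), f3, digits = NA, auto_unbox = TRUE)
      register("simulate", c(f1, f2, f3),
               list(n_obs = nrow(cohort),
                    n_ids = length(unique(cohort$individual_id))))
    })
  } else {
    cohort <- read_cohort(config$cohort_csv, schema = config$schema)
    meta <- config$meta
    if (!is.null(config$tree_newick)) {
      tree <- read_tree(config$tree_newick, unique(cohort$species))
    }
  }

  # --- filtering and panel selection (only when a downstream stage needs it)
  downstream <- intersect(stages, c("score", "models", "survival",
                                    "conservation"))
  cohorts <- NULL; shared <- NULL
  if (length(downstream) > 0) {
    if (!is.null(meta)) {
      cohort <- filter_adults(cohort, meta)
      cohort <- filter_implausible(cohort, meta)
    }
    ms <- config$marker_set %||% list(mode = "variable")
    cohorts <- select_marker_set(
      cohort, mode = ms$mode %||% "variable",
      fixed_panel = ms$fixed_panel,
      min_markers = ms$min_markers %||% 10L,
      availability = ms$availability %||% 0.7)
    shared <- Reduce(intersect, lapply(cohorts, markers))
  }

  scores <- NULL
  if ("score" %in% stages) {
    run_stage("score", {
      refs <- lapply(cohorts, build_self_reference)
      sc <- do.call(rbind, lapply(names(cohorts), function(sp)
        as.data.frame(score_cohort(cohorts[[sp]], refs[[sp]]))))
      scores <- structure(sc, class = c("score_table", "data.frame"))
      f <- file.path(out_dir, "scores.csv")
      write_scores(scores, f)
      register("score", f, list(n_scored = nrow(scores)))
    })
  }

  if ("models" %in% stages && !is.null(scores)) {
    run_stage("models", {
      res <- lapply(split(scores, scores$species), function(s)
        fit_age_sex_model(structure(s, class = c("score_table", "data.frame"))))
      f <- file.path(out_dir, "age_sex_models.csv")
      write_model_results(res, f)
      files <- f; counts <- list(n_species = length(res))
      mass_ok <- names(cohorts)[vapply(cohorts, function(cc)
        sum(!is.na(cc$body_mass)) >= 10, logical(1))]
      if (length(mass_ok) > 0) {
        mres <- lapply(mass_ok, function(sp)
          fit_mass_model(cohorts[[sp]],
                         scores[scores$species == sp, , drop = FALSE]))
        f2 <- file.path(out_dir, "mass_models.csv")
        write_model_results(mres, f2)
        files <- c(files, f2); counts$n_mass_species <- length(mres)
      }
      register("models", files, counts)
    })
  }

  if ("survival" %in% stages && !is.null(scores)) {
    run_stage("survival", {
      hr <- list(); files <- character(0)
      for (sp in names(cohorts)) {
        s <- scores[scores$species == sp, , drop = FALSE]
        d <- cohorts[[sp]]
        dd <- tapply(d$death_age, d$individual_id, function(v)
          if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
        dd <- dd[!is.na(dd)]
        iv <- code_intervals(s, death_ages = dd)
        if (sum(iv$event) == 0) next
        hr[[sp]] <- cbind(species = sp, fit_cox(iv)$hr_table)
      }
      if (length(hr) > 0) {
        f <- file.path(out_dir, "cox_hr.csv")
        utils::write.csv(do.call(rbind, hr), f, row.names = FALSE)
        files <- f
      }
      register("survival", files, list(n_species = length(hr)))
    })
  }

  if ("conservation" %in% stages) {
    run_stage("conservation", {
      comb <- build_combined_reference(cohorts, shared,
                                       seed = config$combined_seed %||% 1L)
      crm <- cross_reference_matrix(cohorts, shared, combined = comb)
      files <- file.path(out_dir, "crossref_matrix.csv")
      write_matrix_csv(crm, files)
      counts <- list(n_species = length(cohorts))
      if (!is.null(tree)) {
        pdm <- patristic_distance_matrix(tree, names(cohorts))
        f2 <- file.path(out_dir, "phylo_distance.csv")
        write_matrix_csv(pdm, f2)
        ct <- phylo_conservation_test(crm, pdm,
                                      seed = config$conservation_seed %||% 1L)
        f3 <- file.path(out_dir, "conservation_test.json")
        jsonlite::write_json(ct, f3, digits = NA, auto_unbox = TRUE)
        files <- c(files, f2, f3)
        counts$rho <- ct$rho
      }
      register("conservation", files, counts)
    })
  }

  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a pipeline run configuration from YAML or JSON
#' @param path Configuration file path (`.yaml`/`.yml` or `.json`).
#' @return Named list usable by [run_pipeline()].
#' @export
read_run_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_dysreg("yaml package not available; use a JSON config",
                  "dysregkit_config_error")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
}

#' Command-line entry point
#'
#' Invoked by the `exec/dysregkit` script:
#' `dysregkit run --config run.yaml`, `dysregkit simulate --config sim.yaml
#' --out cohort.csv --truth truth.json`. Exit codes: 0 success, 2
#' configuration error, 3 stage failure.
#'
#' @param args Command-line arguments (default `commandArgs(TRUE)`).
#' @return Exit status, invisibly.
#' @export
dysregkit_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) < 1) stop_dysreg("usage: dysregkit <run|simulate> --config <path> [--out <path>] [--truth <path>]",
                                      "dysregkit_config_error")
    cmd <- args[1]
    opt <- function(flag) {
      i <- which(args == flag)
      if (length(i) == 1 && i < length(args)) args[i + 1] else NULL
    }
    cfg_path <- opt("--config")
    if (is.null(cfg_path)) stop_dysreg("--config is required",
                                       "dysregkit_config_error")
    config <- read_run_config(cfg_path)
    if (cmd == "run") {
      run_pipeline(config)
    } else if (cmd == "simulate") {
      cf <- do.call(sim_config, config$simulate %||% config)
      sim <- simulate_cohort(cf)
      write_cohort(sim$cohort, opt("--out") %||% "cohort.csv")
      jsonlite::write_json(list(params = sim$truth$params,
                                individuals = sim$truth$individuals,
                                visits = sim$truth$visits),
                           opt("--truth") %||% "truth.json",
                           digits = NA, auto_unbox = TRUE)
    } else {
      stop_dysreg(paste0("unknown subcommand: ", cmd),
                  "dysregkit_config_error")
    }
    0L
  },
  dysregkit_config_error = function(e) { message(conditionMessage(e)); 2L },
  dysregkit_stage_error = function(e) { message(conditionMessage(e)); 3L },
  error = function(e) { message(conditionMessage(e)); 3L })
  invisible(status)
}
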