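#' Validate a pipeline configuration
#'
#' A run configuration is a named list (or YAML file) with a global `seed`
#' and one section per stage: `simulate`, `qc`, `extract`, `shells`,
#' `stats` are required; `train` and `eval` are optional. Per-stage seeds
#' are derived from the global seed by fixed offsets, so one number
#' reproduces the whole run.
#'
#' @param config named list or path to a YAML file.
#' @return the validated config list.
#' @export
validate_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a named list or a YAML file path")
  for (key in c("seed", "simulate", "extract", "shells", "stats")) {
    if (!key %in% names(config)) {
      stop("config validation: missing required stage key '", key, "'")
    }
  }
  if (!is.numeric(config$seed)) stop("config validation: 'seed' must be numeric")
  config
}

run_stage <- function(manifest, name, expr) {
  t0 <- proc.time()[["elapsed"]]
  val <- force(expr)
  manifest$timings[[name]] <- round(proc.time()[["elapsed"]] - t0, 3)
  list(manifest = manifest, value = val)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate, quality control, morphometry extraction, shell
#' profiling, cohort statistics and (optionally) classifier training and
#' bootstrap AUROC evaluation as one reproducible run. Result tables are
#' written to `out_dir` along with a JSON manifest recording the config
#' hash, derived seeds, stage outputs and timings. Completed table outputs
#' are reused when `resume = TRUE`.
#'
#' @param config run configuration (list or YAML path), see
#'   [validate_run_config()].
#' @param out_dir output directory.
#' @param resume reuse existing stage outputs in `out_dir`.
#' @return the run manifest (list), invisibly; its `tables` element holds
#'   the in-memory results.
#' @export
run_all <- function(config, out_dir = tempfile("tomoshell_run_"), resume = FALSE) {
  config <- validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA, null = "null")
  seeds <- derive_seeds(config$seed, 4L)
  manifest <- list(package_version = as.character(utils::packageVersion("tomoshell")),
                   config_hash = unname(tools::md5sum(cfg_path)),
                   global_seed = config$seed,
                   stage_seeds = list(simulate = seeds[1], split = seeds[2],
                                      train = seeds[3], eval = seeds[4]),
                   paths = list(), timings = list(), tables = list())

  sim <- config$simulate
  base_args <- if (is.null(sim$base)) list() else sim$base
  base <- do.call(phantom_spec, base_args)
  groups <- if (is.null(sim$groups)) {
    do.call(default_cohort_groups,
            sim[intersect(names(sim), "cells_per_subject")])
  } else {
    lapply(sim$groups, function(g) do.call(group_effect_spec, g))
  }
  covars <- if (is.null(sim$covariates)) default_covariates() else {
    lapply(sim$covariates, function(cv) do.call(clinical_covariate_spec, cv))
  }
  st <- run_stage(manifest, "simulate",
                  make_cohort(groups, covars, base, seed = seeds[1]))
  manifest <- st$manifest; cohort <- st$value

  st <- run_stage(manifest, "qc", do.call(qc_filter, c(list(cohort$tomograms),
                                                       config$qc)))
  manifest <- st$manifest; qc <- st$value
  manifest$tables$qc_rejected <- qc$rejected
  kept_ids <- vapply(qc$kept, `[[`, "", "cell_id")
  tab <- cohort$table[cohort$table$cell_id %in% kept_ids, ]

  mcfg_args <- config$extract[intersect(names(config$extract),
                                        names(formals(morphometry_config)))]
  mcfg <- do.call(morphometry_config, mcfg_args)

  feat_path <- file.path(out_dir, "features.csv")
  if (resume && file.exists(feat_path)) {
    features <- read.csv(feat_path, stringsAsFactors = FALSE)
    manifest$timings$extract <- 0
  } else {
    st <- run_stage(manifest, "extract", extract_features(qc$kept, mcfg))
    manifest <- st$manifest; features <- st$value
    features <- merge(features, tab[, setdiff(names(tab), c("group", "outcome", "subject_id"))],
                      by = "cell_id", sort = TRUE)
    write.csv(features, feat_path, row.names = FALSE)
  }
  manifest$paths$features <- feat_path
  manifest$tables$features <- features

  shell_path <- file.path(out_dir, "shells.csv")
  if (resume && file.exists(shell_path)) {
    shtab <- read.csv(shell_path, stringsAsFactors = FALSE)
    manifest$timings$shells <- 0
  } else {
    sh_args <- config$shells[intersect(names(config$shells), c("n_shells", "restrict"))]
    st <- run_stage(manifest, "shells",
                    do.call(shell_profiles_for_cohort,
                            c(list(qc$kept, mcfg), sh_args)))
    manifest <- st$manifest; shtab <- st$value
    write.csv(shtab, shell_path, row.names = FALSE)
  }
  manifest$paths$shells <- shell_path
  manifest$tables$shells <- shtab

  st <- run_stage(manifest, "stats", {
    cmp <- group_comparisons(features)
    groups_present <- unique(shtab$group)
    has_prog <- all(c("survivor", "non-survivor") %in%
                      shtab$outcome[shtab$group == "T1"])
    shc <- shell_comparisons(shtab, groups = groups_present,
                             include_prognosis = has_prog)
    covnames <- vapply(covars, `[[`, "", "name")
    corr <- if (length(unique(features$group)) >= 3) {
      correlate_features(features, covnames, mode = "timepoint_means")
    } else NULL
    list(anova = cmp$anova, pairwise = cmp$pairwise, shells = shc,
         correlations = corr)
  })
  manifest <- st$manifest; statres <- st$value
  for (nm in names(statres)) {
    if (!is.null(statres[[nm]])) {
      p <- file.path(out_dir, paste0("stats_", nm, ".csv"))
      write.csv(statres[[nm]], p, row.names = FALSE)
      manifest$paths[[paste0("stats_", nm)]] <- p
    }
  }
  manifest$tables$stats <- statres

  if (!is.null(config$train)) {
    trc <- config$train
    task <- if (is.null(trc$task)) "diagnosis" else trc$task
    sel <- if (task == "diagnosis") {
      which(features$group %in% c("H", "T1"))
    } else {
      which(features$group == "T1" &
              features$outcome %in% c("survivor", "non-survivor"))
    }
    lab_col <- if (task == "diagnosis") "group" else "outcome"
    ids <- features$cell_id[sel]
    labels <- features[[lab_col]][sel]
    subj <- features$subject_id[sel]
    mc <- do.call(model_config, c(trc$model, list(task = task)))
    tc <- do.call(train_config, if (is.null(trc$train)) list() else trc$train)
    pc_args <- if (is.null(trc$preprocess)) list() else trc$preprocess
    pc <- do.call(preprocess_config, pc_args)
    toms <- cohort$tomograms[ids]
    if (identical(pc$resize_target, "median")) {
      pc$resize_target <- median_crop_shape(toms, mcfg, mc$n_blocks)
    }
    st <- run_stage(manifest, "preprocess",
                    lapply(toms, preprocess_volume, cfg = pc, config = mcfg))
    manifest <- st$manifest; vols <- st$value
    sp <- split_dataset(labels, seed = seeds[2], subject = subj,
                        by_subject = isTRUE(trc$by_subject))
    st <- run_stage(manifest, "train",
                    train_classifier(vols[sp$train], labels[sp$train],
                                     vols[sp$val], labels[sp$val],
                                     mc, tc, seed = seeds[3]))
    manifest <- st$manifest; model <- st$value
    manifest$tables$model <- model
    split_path <- file.path(out_dir, "split.json")
    jsonlite::write_json(lapply(sp, function(ix) ids[ix]), split_path)
    manifest$paths$split <- split_path

    ev <- if (is.null(config$eval)) list() else config$eval
    cells <- if (is.null(ev$cells)) 1:5 else ev$cells
    iters <- if (is.null(ev$iterations)) 1000L else ev$iterations
    test_subj <- subj[sp$test]
    subj_lab <- tapply(as.character(labels[sp$test]), test_subj, `[`, 1)
    if (length(unique(subj_lab)) < 2L) test_subj <- NULL
    st <- run_stage(manifest, "eval",
                    eval_classifier(model, vols[sp$test], labels[sp$test],
                                    cells = cells, subject = test_subj,
                                    iterations = iters, seed = seeds[4]))
    manifest <- st$manifest
    auroc_path <- file.path(out_dir, "auroc.csv")
    write.csv(st$value, auroc_path, row.names = FALSE)
    manifest$paths$auroc <- auroc_path
    manifest$tables$auroc <- st$value
  }

  man_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest[setdiff(names(manifest), "tables")], man_path,
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  manifest$paths$manifest <- man_path
  invisible(manifest)
}
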