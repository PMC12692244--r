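#' Default pipeline configuration
#'
#' Nested configuration of the end-to-end synthetic experiment. The `sim`
#' section is the full study design (3 varieties x 100 eggs x 3 days, 3
#' replicate scans); `cars` drives the two-stage cross-temporal band
#' selection; `train` uses a 200-epoch cosine-annealing budget (the full
#' 800-epoch protocol is a `train$epochs` change away); `run_seeds` are the
#' per-run seeds over which variants are compared.
#'
#' @param seed global seed; every stage derives its substream from it.
#' @return Nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 42L) {
  list(seed = as.integer(seed),
       sim = default_egg_sim_config(),
       cars = cars_config(seed = as.integer(seed)),
       model = model_config(),
       train = train_config(epochs = 200L, seed = as.integer(seed)),
       variants = c("mt_ctse", "st_ctse_task1", "mt_cnn_transformer",
                    "mt_transformer_se", "mt_transformer"),
       run_seeds = 1:5,
       test_fraction = 0.2,
       stage2_task = "joint")
}

#' Validate and resolve a pipeline configuration
#'
#' Fills unset fields with [pipeline_config()] defaults, rejects unknown
#' keys, and applies cross-field checks (e.g. `d_model` divisible by
#' `n_heads`). Accepts a YAML file path or a nested list; scalar fields of
#' the nested sections may be overridden from YAML.
#'
#' @param x path to a YAML file, a nested list, or `NULL` for pure defaults.
#' @return A resolved `pipeline_config` list.
#' @export
validate_config <- function(x = NULL) {
  base <- pipeline_config()
  if (is.null(x)) return(base)
  if (is.character(x)) {
    if (!file.exists(x)) stop("config file not found: ", x)
    x <- yaml::read_yaml(x)
    if (is.null(x)) x <- list()
  }
  if (!is.list(x)) stop("config must be a list or a YAML file path")
  unknown <- setdiff(names(x), names(base))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(x$seed)) base <- pipeline_config(seed = as.integer(x$seed))
  for (section in c("sim", "cars", "model", "train")) {
    over <- x[[section]]
    if (is.null(over)) next
    if (!is.list(over)) stop("section '", section, "' must be a mapping")
    bad <- setdiff(names(over), names(base[[section]]))
    if (length(bad) > 0) {
      stop("unknown key(s) in '", section, "': ", paste(bad, collapse = ", "))
    }
    for (nm in names(over)) base[[section]][[nm]] <- over[[nm]]
  }
  for (nm in c("variants", "run_seeds", "test_fraction", "stage2_task")) {
    if (!is.null(x[[nm]])) base[[nm]] <- x[[nm]]
  }
  if (base$model$d_model %% base$model$n_heads != 0) {
    stop("model$d_model (", base$model$d_model,
         ") must be divisible by model$n_heads (", base$model$n_heads, ")")
  }
  bad_v <- setdiff(base$variants, model_variants())
  if (length(bad_v) > 0) stop("unknown variant(s): ", paste(bad_v, collapse = ", "))
  if (base$test_fraction <= 0 || base$test_fraction >= 1) {
    stop("test_fraction must lie in (0, 1)")
  }
  base
}

log_stage <- function(log_con, stage, msg) {
  line <- sprintf("[%s] [%s] %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
  message(line)
  if (!is.null(log_con)) writeLines(line, log_con)
}

#' Run the full synthetic cross-temporal experiment
#'
#' The end-to-end harness: simulate the labelled dataset, average replicate
#' scans per egg and day, SNV-transform, split eggs 80/20 once (fixed test
#' set, isolated from band selection), run two-stage CARS on the training
#' portion, train every requested variant at every run seed on the
#' CARS-selected bands, and evaluate both slicings on the fixed test set.
#'
#' @param config a `pipeline_config` (see [validate_config()]).
#' @param out_dir optional directory; when given, comparison tables, the
#'   selected bands, the resolved configuration and a stage-tagged log are
#'   written there.
#' @param quiet suppress progress messages.
#' @return List of class `reproduce_result` with the selected bands, per-run
#'   evaluations, and `variety_by_day` / `period_by_variety` comparison
#'   tables.
#' @export
reproduce <- function(config = pipeline_config(), out_dir = NULL, quiet = FALSE) {
  log_con <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    log_con <- file(file.path(out_dir, "log.txt"), "w")
    on.exit(close(log_con))
  }
  say <- function(stage, msg) if (!quiet) log_stage(log_con, stage, msg)

  sim_cfg <- config$sim
  sim_cfg$seed <- config$seed
  say("simulate", sprintf("%d eggs x %d days x %d scans",
                          length(sim_cfg$varieties) * sim_cfg$n_eggs_per_variety,
                          length(sim_cfg$days), sim_cfg$scans_per_egg))
  scans <- simulate_dataset(sim_cfg)

  say("average", "averaging replicate scans per egg and day")
  averaged <- average_scans(scans)

  say("snv", "row-wise standard normal variate")
  snv_tab <- snv_table(averaged)

  say("split", sprintf("egg-level %d/%d split",
                       round(100 * (1 - config$test_fraction)),
                       round(100 * config$test_fraction)))
  split <- stratified_egg_split(snv_tab, config$test_fraction, seed = config$seed)
  train_tab <- st_subset(snv_tab, snv_tab$egg_id %in% split$train_eggs)
  test_tab <- st_subset(snv_tab, snv_tab$egg_id %in% split$test_eggs)

  say("cars", sprintf("two-stage CARS (%d runs/stage) on the training eggs",
                      config$cars$R))
  cars_cfg <- config$cars
  cars_cfg$seed <- config$seed
  selection <- two_stage_select(train_tab, cars_cfg,
                                stage2_task = config$stage2_task)
  bands <- selection$final
  say("cars", sprintf("%d bands selected: %s nm", length(bands),
                      paste(round(train_tab$wavelengths[bands]), collapse = ", ")))

  mcfg <- config$model
  mcfg$n_bands_in <- length(bands)
  runs <- list()
  for (variant in config$variants) {
    fl <- variant_flags(variant)
    for (seed in config$run_seeds) {
      tcfg <- config$train
      tcfg$seed <- as.integer(seed)
      net <- build_network(mcfg, variant, seed = seed)
      t0 <- Sys.time()
      net <- fit_network(net, train_tab, bands, tcfg)
      ev <- list(variant = variant, seed = seed)
      if (fl$task1) ev$by_day <- evaluate_sliced(net, test_tab, "by_day")
      if (fl$task2) ev$by_variety <- evaluate_sliced(net, test_tab, "by_variety")
      runs[[paste(variant, seed, sep = "_")]] <- ev
      say("train", sprintf(
        "%s seed %d: best epoch %d, %.1fs%s%s", variant, seed, net$best_epoch,
        as.numeric(difftime(Sys.time(), t0, units = "secs")),
        if (fl$task1) sprintf(", variety acc %.3f", ev$by_day$pooled$accuracy) else "",
        if (fl$task2) sprintf(", period acc %.3f", ev$by_variety$pooled$accuracy) else ""))
    }
  }

  task1_runs <- Filter(function(r) !is.null(r$by_day), runs)
  task2_runs <- Filter(function(r) !is.null(r$by_variety), runs)
  variety_by_day <- compare_runs(lapply(task1_runs, function(r) {
    list(variant = r$variant, seed = r$seed, eval = r$by_day)
  }))
  period_by_variety <- if (length(task2_runs) > 0) {
    compare_runs(lapply(task2_runs, function(r) {
      list(variant = r$variant, seed = r$seed, eval = r$by_variety)
    }))
  } else NULL

  out <- structure(list(
    config = config, split = split, selection = selection, bands = bands,
    wavelengths = train_tab$wavelengths[bands], runs = runs,
    variety_by_day = variety_by_day, period_by_variety = period_by_variety
  ), class = "reproduce_result")

  if (!is.null(out_dir)) {
    utils::write.csv(variety_by_day$per_run,
                     file.path(out_dir, "variety_by_day_runs.csv"), row.names = FALSE)
    utils::write.csv(variety_by_day$summary,
                     file.path(out_dir, "variety_by_day_summary.csv"), row.names = FALSE)
    if (!is.null(period_by_variety)) {
      utils::write.csv(period_by_variety$per_run,
                       file.path(out_dir, "period_by_variety_runs.csv"), row.names = FALSE)
      utils::write.csv(period_by_variety$summary,
                       file.path(out_dir, "period_by_variety_summary.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(
      list(final = bands, wavelengths_nm = train_tab$wavelengths[bands],
           vip = selection$vip, union = selection$union),
      file.path(out_dir, "bands.json"), digits = NA, auto_unbox = FALSE)
    writeLines(yaml::as.yaml(serialize_config(config)),
               file.path(out_dir, "config.yaml"))
    say("done", sprintf("artifacts written to %s", out_dir))
  }
  out
}

# flatten class'd sections so the config snapshot is plain YAML
serialize_config <- function(config) {
  strip <- function(x) {
    if (inherits(x, "peak_spec") || is.list(x)) {
      x <- unclass(x)
      lapply(x, strip)
    } else x
  }
  strip(config)
}

#' Average replicate scans of a spectra table
#'
#' Collapses the `scans_per_egg` replicate scans of each (egg, day) pair to
#' their mean spectrum (with the CV stability check of
#' [average_replicates()]), yielding one record per egg and storage day —
#' the per-sample spectrum used by modelling.
#'
#' @param table a [spectra_table()] with replicate scans.
#' @param warn_above CV warning ceiling per band (default 0.02).
#' @return A [spectra_table()] with one row per (egg, day).
#' @export
average_scans <- function(table, warn_above = 0.02) {
  key <- paste(table$egg_id, table$day, sep = "@")
  groups <- split(seq_along(key), key)
  n <- length(groups)
  refl <- matrix(NA_real_, n, ncol(table$reflectance))
  scan_id <- egg_id <- variety <- character(n)
  day <- integer(n)
  for (i in seq_along(groups)) {
    idx <- groups[[i]]
    avg <- average_replicates(table$reflectance[idx, , drop = FALSE],
                              warn_above = warn_above)
    refl[i, ] <- avg$mean
    egg_id[i] <- table$egg_id[idx[1]]
    variety[i] <- table$variety[idx[1]]
    day[i] <- table$day[idx[1]]
    scan_id[i] <- sprintf("%s_d%02d_avg", egg_id[i], day[i])
  }
  ord <- order(egg_id, day)
  spectra_table(scan_id[ord], egg_id[ord], variety[ord], day[ord],
                refl[ord, , drop = FALSE], table$wavelengths)
}

#' @export
print.reproduce_result <- function(x, ...) {
  cat("<reproduce_result>\n")
  cat(sprintf("  bands: %d selected (%s nm)\n", length(x$bands),
              paste(round(x$wavelengths), collapse = ", ")))
  cat("  variety task (accuracy mean over seeds):\n")
  s <- x$variety_by_day$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("    %-20s %-8s %.3f +/- %.3f\n", s$variant[i], s$slice[i],
                s$accuracy_mean[i], s$accuracy_sd[i]))
  }
  invisible(x)
}
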