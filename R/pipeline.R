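#' Pipeline configuration
#'
#' Assembles and validates the configuration driving [run_pipeline]. All
#' stage parameters mirror CLI flags; unknown keys are rejected to catch
#' typos in config files.
#'
#' @param ... configuration overrides, or a single named list (e.g. parsed
#'   from a YAML/JSON file).
#' @return validated config list of class `pipeline_config` with defaults
#'   filled in.
#' @export
pipeline_config <- function(...) {
  user <- list(...)
  if (length(user) == 1L && is.null(names(user)) && is.list(user[[1L]]))
    user <- user[[1L]]
  defaults <- list(
    seed = 1L,
    out_dir = "stepdyn_out",
    n_participants = 45L,
    n_days = 182L,
    library_sizes = c(54L, 54L, 27L),
    delivery_failure_prob = 0,
    noise_sd = 25,
    order = ARX_ORDER,
    ridge = 0,
    horizon = 40L,
    bootstrap_B = 500L,
    alpha = 0.05,
    gg = "mauchly",
    stages = c("simulate", "preprocess", "fit", "respond", "stats"))
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, user)
  stopifnot(cfg$seed == as.integer(cfg$seed), cfg$n_participants >= 1,
            cfg$n_days >= 1, cfg$bootstrap_B >= 0, cfg$horizon >= 1,
            all(cfg$stages %in% defaults$stages))
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#' @param path config file (`.yaml`/`.yml` or `.json`).
#' @return a [pipeline_config].
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is needed to read YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  pipeline_config(raw)
}

#' Validate a cohort input directory
#'
#' Report-only structural checks on the CSV/JSON bundle layout consumed by
#' the preprocessing stage: required columns, value ranges, monotone
#' timestamps.
#'
#' @param dir directory of participant bundles.
#' @return `data.table` of violations (zero rows when everything is
#'   well-formed) with columns `participant_id`, `file`, `problem`.
#' @export
validate_inputs <- function(dir) {
  if (!dir.exists(dir)) stop("input directory not found: ", dir)
  probs <- list()
  note <- function(pid, f, msg)
    probs[[length(probs) + 1L]] <<- data.table(participant_id = pid,
                                               file = f, problem = msg)
  min_files <- list.files(dir, pattern = "_minutes\\.csv$")
  for (f in min_files) {
    pid <- sub("_minutes\\.csv$", "", f)
    dt <- fread(file.path(dir, f))
    if (!all(c("timestamp", "steps", "hr_present") %in% names(dt))) {
      note(pid, f, "missing required columns")
      next
    }
    if (any(dt$steps < 0)) note(pid, f, "negative step counts")
    if (!all(dt$hr_present %in% c(0L, 1L)))
      note(pid, f, "hr_present not 0/1")
    st <- parse_stamp(dt$timestamp)
    key <- as.numeric(st$date) * 1440 + st$minute
    if (is.unsorted(key, strictly = TRUE))
      note(pid, f, "timestamps not strictly increasing")
    mf <- file.path(dir, paste0(pid, "_messages.csv"))
    wf <- file.path(dir, paste0(pid, "_window.json"))
    if (!file.exists(mf)) note(pid, basename(mf), "message log missing")
    if (!file.exists(wf)) note(pid, basename(wf), "window file missing")
    if (file.exists(mf)) {
      mm <- fread(mf)
      if (nrow(mm) && !all(c("timestamp", "library", "delivered")
                           %in% names(mm)))
        note(pid, basename(mf), "missing required columns")
      else if (nrow(mm) && !all(mm$library %in% MESSAGE_TYPES))
        note(pid, basename(mf), "unknown message library")
    }
  }
  if (!length(min_files))
    note(NA_character_, NA_character_, "no *_minutes.csv files found")
  rbindlist(probs)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> preprocess -> fit -> respond -> stats under a
#' single seed, writing each stage's artifacts beneath `out_dir` and an
#' MD5 manifest of everything written. Reruns with the same config
#' reproduce the manifest checksums.
#'
#' @param config a [pipeline_config] (or list coercible to one).
#' @param specs optional list of [participant_spec] for the simulate stage;
#'   defaults to [paper_like_specs] draws.
#' @param quiet suppress progress messages.
#' @return invisibly, a list with `feature_table`, `stats`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), specs = NULL,
                         quiet = FALSE) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  say <- function(...) if (!quiet) message(...)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  raw_dir <- file.path(config$out_dir, "raw")
  model_dir <- file.path(config$out_dir, "models")
  stats_dir <- file.path(config$out_dir, "stats")
  sim_cfg <- simulation_config(
    n_participants = config$n_participants, n_days = config$n_days,
    seed = config$seed, library_sizes = config$library_sizes,
    delivery_failure_prob = config$delivery_failure_prob)
  if ("simulate" %in% config$stages) {
    say("simulate: ", config$n_participants, " participants x ",
        config$n_days, " days")
    set.seed(config$seed)
    if (is.null(specs))
      specs <- paper_like_specs(config$n_participants,
                                noise_sd = config$noise_sd)
    generate_cohort(sim_cfg, specs = specs, out_dir = raw_dir)
  }
  pids <- sub("_minutes\\.csv$", "",
              list.files(raw_dir, pattern = "_minutes\\.csv$"))
  if (!length(pids)) stop("no participant bundles found in ", raw_dir)
  models <- list()
  if (any(c("preprocess", "fit") %in% config$stages)) {
    dir.create(model_dir, showWarnings = FALSE)
    for (pid in pids) {
      bundle <- read_participant_bundle(raw_dir, pid)
      series <- preprocess_participant(bundle$minutes, bundle$messages,
                                       bundle$window, participant_id = pid)
      fits <- fit_switched_models(series, ridge = config$ridge)
      models[[pid]] <- fits
      for (dt in c("weekday", "weekend"))
        if (!is.null(fits[[dt]]))
          write_arx_model(fits[[dt]],
                          file.path(model_dir,
                                    paste0(pid, "_", dt, "_model.json")))
      say("fit: ", pid, " (weekday rows ",
          if (is.null(fits$weekday)) 0 else fits$weekday$n_rows,
          ", weekend rows ",
          if (is.null(fits$weekend)) 0 else fits$weekend$n_rows, ")")
    }
  }
  ft <- NULL
  stats_out <- NULL
  if ("respond" %in% config$stages && length(models)) {
    say("respond: extracting features (B = ", config$bootstrap_B, ")")
    set.seed(config$seed + 1L)
    ft <- feature_table(models, B = config$bootstrap_B,
                        horizon = config$horizon)
    dir.create(stats_dir, showWarnings = FALSE)
    fwrite(ft, file.path(stats_dir, "features.csv"))
  }
  if ("stats" %in% config$stages && !is.null(ft)) {
    say("stats: descriptives, ANOVA / Friedman, post hocs")
    stats_out <- feature_statistics_report(ft, alpha = config$alpha,
                                           gg = config$gg)
    fwrite(stats_out$descriptives,
           file.path(stats_dir, "table1_descriptives.csv"))
    fwrite(stats_out$tests, file.path(stats_dir, "table2_tests.csv"))
    if (!is.null(stats_out$posthoc) && nrow(stats_out$posthoc))
      fwrite(stats_out$posthoc, file.path(stats_dir, "posthoc.csv"))
    jsonlite::write_json(stats_out$heterogeneity,
                         file.path(stats_dir, "heterogeneity.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  files <- list.files(config$out_dir, recursive = TRUE, full.names = TRUE)
  manifest <- data.table(path = sub(paste0("^", config$out_dir, "/?"), "",
                                    files),
                         md5 = unname(tools::md5sum(files)))
  fwrite(manifest, file.path(config$out_dir, "manifest.csv"))
  say("done: ", nrow(manifest), " artifacts")
  invisible(list(feature_table = ft, stats = stats_out, manifest = manifest,
                 models = models))
}

#' Group-level statistics report for a feature table
#'
#' Applies the full statistical-analysis recipe: descriptives for every
#' feature; a per-cell Shapiro-Wilk normality gate; two-way
#' repeated-measures ANOVA (message x day) for features passing the gate;
#' Friedman tests per day type with Kendall W for features failing it;
#' Bonferroni pairwise post hocs for significant main effects; and the
#' per-participant best-message heterogeneity summary.
#'
#' @param ft long feature table.
#' @param alpha significance level for gates and post hoc triggers.
#' @param gg Greenhouse-Geisser policy, see [rm_anova_2way].
#' @return list: `descriptives`, `tests` (one row per effect),
#'   `posthoc`, `heterogeneity`, `normality`.
#' @export
feature_statistics_report <- function(ft, alpha = 0.05, gg = "mauchly") {
  ft <- as.data.table(ft)
  feats <- setdiff(unique(ft$feature), "initial_delay")
  feats <- feats[vapply(feats, function(f)
    any(!is.na(ft[feature == f]$value)), logical(1L))]
  desc <- describe_features(ft, feats)
  tests <- list()
  posthoc <- list()
  normality <- list()
  for (f in feats) {
    nrm <- check_normality(ft, f, alpha = alpha)
    normality[[f]] <- nrm$normal
    if (nrm$normal) {
      res <- tryCatch(rm_anova_2way(ft, f, gg = gg), error = function(e) NULL)
      if (is.null(res)) next
      eff <- copy(res$effects)
      eff[, `:=`(feature = f, test = "rm_anova", statistic = F,
                 effect_size = ges)]
      tests[[length(tests) + 1L]] <-
        eff[, .(feature, effect, test, statistic, df1, df2, p,
                effect_size)]
      sig <- eff[p < alpha]
      if ("message" %in% sig$effect)
        posthoc[[length(posthoc) + 1L]] <-
          cbind(feature = f, effect = "message",
                pairwise_posthoc(ft, f, "message", parametric = TRUE))
      if ("day" %in% sig$effect)
        posthoc[[length(posthoc) + 1L]] <-
          cbind(feature = f, effect = "day",
                pairwise_posthoc(ft, f, "day", parametric = TRUE))
    } else {
      for (dtp in c("weekday", "weekend")) {
        fr <- tryCatch(friedman_by_daytype(ft, f, dtp),
                       error = function(e) NULL)
        if (is.null(fr)) next
        tests[[length(tests) + 1L]] <- data.table(
          feature = f, effect = paste0("message_", dtp),
          test = "friedman", statistic = fr$chi2, df1 = fr$df,
          df2 = NA_real_, p = fr$p, effect_size = fr$kendall_w)
        if (fr$p < alpha)
          posthoc[[length(posthoc) + 1L]] <-
            cbind(feature = f, effect = paste0("message_", dtp),
                  pairwise_posthoc(ft, f, "message", parametric = FALSE,
                                   day_type = dtp))
      }
    }
  }
  het <- best_message_summary(ft)
  list(descriptives = desc,
       tests = if (length(tests)) rbindlist(tests) else data.table(),
       posthoc = if (length(posthoc)) rbindlist(posthoc) else data.table(),
       heterogeneity = het,
       normality = normality)
}

utils::globalVariables(c("ges", "effect_size", "df1", "df2", "p",
                         "corrected", "test"))
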