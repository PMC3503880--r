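# -- Full-assessment pipeline and report ---------------------------------

#' Default pipeline configuration
#'
#' One JSON-serializable list controls every stage. Defaults follow the
#' reference bedside protocol: 5 blocks of 36 trials, resample to 100 Hz
#' then zero-phase 1--40 Hz FIR filtering, 6 s offset-relative epochs,
#' automated rejection (150 uV peak-to-peak, log-variance z > 5), bipolar
#' C3'/C4', 1--40 Hz TFR with cluster permutation statistics (1000
#' permutations, cell alpha .05, cluster alpha .05/4) and 10-fold naive
#' Bayes classification with the familywise randomization test (1000
#' permutations, alpha .05/2 one-tailed).
#'
#' @param seed Master seed; per-stage seeds are derived from it.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    simulate = list(
      n_blocks = 5,
      artifact_rate = 0.4,
      noise = list(one_over_f_exponent = 1, broadband_sd = 5,
                   mu_amplitude = 2, beta_amplitude = 1.5,
                   delta_boost = NULL),
      effects = list()
    ),
    input = NULL,
    preprocess = list(target_rate = 100, band = c(1, 40),
                      filter_before_resample = FALSE,
                      ptp_threshold = 150, var_zmax = 5,
                      target_counts = NULL),
    spectral = list(freq_range = c(1, 40), n_perm = 1000,
                    sample_alpha = 0.05, cluster_alpha = 0.0125),
    classify = list(k = 10, n_perm = 1000, alpha = 0.025, bands = NULL),
    figures = FALSE
  )
}

#' Validate (and complete) a pipeline configuration
#'
#' Unknown top-level keys, malformed effects and out-of-range thresholds
#' raise errors of class `smr_config_error`; missing keys are filled from
#' [default_config()].
#'
#' @param config A list, or path to a JSON file.
#' @return The completed config list.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  fail <- function(...) {
    stop(structure(class = c("smr_config_error", "error", "condition"),
                   list(message = paste0(...), call = NULL)))
  }
  if (!is.list(config)) fail("config must be a list or JSON file path")
  defaults <- default_config(config$seed %||% 1)
  unknown <- setdiff(names(config), c(names(defaults), "out_dir"))
  if (length(unknown) > 0) {
    fail("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  # effects are a *list of records*, not a nested option block: keep them
  # out of the recursive default merge (JSON readers also hand them over
  # as a data.frame)
  effs <- NULL
  if (!is.null(config$simulate$effects)) {
    effs <- config$simulate$effects
    if (is.data.frame(effs)) {
      effs <- lapply(seq_len(nrow(effs)), function(i) as.list(effs[i, ]))
    }
    config$simulate$effects <- NULL
  }
  cfg <- modifyList(defaults, config, keep.null = TRUE)
  if (!is.null(effs)) cfg$simulate$effects <- effs
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1) fail("seed must be a number")
  if (!is.null(cfg$input)) {
    if (is.null(cfg$input$path)) fail("input needs a 'path'")
  } else {
    if (cfg$simulate$n_blocks < 1) fail("simulate.n_blocks must be >= 1")
    if (cfg$simulate$artifact_rate < 0 || cfg$simulate$artifact_rate > 1) {
      fail("simulate.artifact_rate must be in [0, 1]")
    }
    for (ef in cfg$simulate$effects) {
      if (!is.list(ef)) fail("simulate.effects must be a list of effect records")
      if (is.null(ef$condition) || is.null(ef$band) || is.null(ef$depth)) {
        fail("each effect needs condition, band, depth")
      }
    }
  }
  pp <- cfg$preprocess
  if (pp$ptp_threshold <= 0 || pp$var_zmax <= 0) {
    fail("preprocess thresholds must be positive")
  }
  if (length(pp$band) != 2 || pp$band[1] <= 0 || pp$band[2] <= pp$band[1]) {
    fail("preprocess.band must be (lo, hi) with 0 < lo < hi")
  }
  sp <- cfg$spectral
  if (sp$n_perm < 1 || sp$sample_alpha <= 0 || sp$sample_alpha >= 1 ||
      sp$cluster_alpha <= 0 || sp$cluster_alpha >= 1) {
    fail("spectral parameters out of range")
  }
  cl <- cfg$classify
  if (cl$k < 2 || cl$n_perm < 1 || cl$alpha <= 0 || cl$alpha >= 1) {
    fail("classify parameters out of range")
  }
  if (!is.null(cl$bands) && !all(unlist(cl$bands) %in% names(smr_bands))) {
    fail("classify.bands must be a subset of: ",
         paste(names(smr_bands), collapse = ", "))
  }
  cfg
}

config_to_sim <- function(cfg, seed) {
  sim <- cfg$simulate
  nz <- sim$noise
  effects <- lapply(sim$effects, function(ef) {
    effect_spec(condition = ef$condition,
                band = as.numeric(unlist(ef$band)),
                depth = ef$depth,
                channel_side = ef$channel_side %||% "ipsilateral",
                latency = ef$latency %||% 1,
                duration = ef$duration %||% 1,
                ramp = ef$ramp %||% 0.25)
  })
  db <- nz$delta_boost
  if (!is.null(db)) db <- unlist(db)
  sim_config(
    n_blocks = sim$n_blocks,
    noise = noise_spec(
      one_over_f_exponent = nz$one_over_f_exponent %||% 1,
      broadband_sd = nz$broadband_sd %||% 5,
      oscillators = default_oscillators(nz$mu_amplitude %||% 2,
                                        nz$beta_amplitude %||% 1.5),
      delta_boost = db),
    effects = effects,
    artifact_rate = sim$artifact_rate,
    seed = seed)
}

#' Run the full covert command-following assessment
#'
#' Executes simulate (or load) -> preprocess -> average-level spectral
#' statistics -> single-trial classification from one config, and returns
#' an `assessment_report`. Deterministic given the config (one master
#' seed is split into independent per-stage seeds). When `out_dir` is
#' given, machine-readable stage outputs (JSON) and a Markdown report are
#' written; reruns of the same config produce byte-identical JSON.
#'
#' @param config Config list or JSON path (see [default_config()]).
#' @param out_dir Optional output directory.
#' @return An `assessment_report` (list; see the fields in the report
#'   JSON), invisibly carrying the stage objects in
#'   `attr(, "stage_objects")`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- validate_config(config)
  seeds <- derive_seeds(cfg$seed,
                        c("simulate", "match",
                          "cluster_left", "cluster_right",
                          "classify_left", "classify_right"))

  rec <- if (!is.null(cfg$input)) {
    read_recording(cfg$input$path,
                   format = cfg$input$format %||% "csv",
                   srate = cfg$input$srate)
  } else {
    simulate_recording(config_to_sim(cfg, seeds[["simulate"]]))
  }

  pp <- cfg$preprocess
  if (isTRUE(pp$filter_before_resample)) {
    rec <- bandpass_filter(rec, pp$band[1], pp$band[2])
    rec <- resample_recording(rec, pp$target_rate)
  } else {
    rec <- resample_recording(rec, pp$target_rate)
    rec <- bandpass_filter(rec, pp$band[1], pp$band[2])
  }
  epochs <- rereference_bipolar(epoch_recording(rec))
  rej <- reject_artifacts(epochs, pp$ptp_threshold, pp$var_zmax)
  epochs <- rej$epochs
  if (!is.null(pp$target_counts)) {
    epochs <- match_trial_counts(epochs, unlist(pp$target_counts),
                                 seed = seeds[["match"]])
  }

  sp <- cfg$spectral
  freqs <- seq(sp$freq_range[1], sp$freq_range[2])
  tfr <- compute_tfr(epochs, freqs = freqs)
  features <- extract_bandpower(epochs)
  if (!is.null(cfg$classify$bands)) {
    features <- subset_bands(features, unlist(cfg$classify$bands))
  }
  welch <- lapply(unique(epochs$conditions), function(cond)
    welch_spectrum(epochs, cond))
  names(welch) <- unique(epochs$conditions)

  comparisons <- list()
  stage_objects <- list(recording = rec, epochs = epochs,
                        rejection = rej$report, tfr = tfr,
                        features = features, welch = welch)
  for (cond in c("left", "right")) {
    if (sum(epochs$conditions == cond) < 2 ||
        sum(epochs$conditions == "rest") < 2) next
    idx_a <- which(epochs$conditions == cond)
    idx_r <- which(epochs$conditions == "rest")
    clus <- cluster_permutation_test(
      subset_tfr_trials(tfr, idx_a), subset_tfr_trials(tfr, idx_r),
      sample_alpha = sp$sample_alpha, n_perm = sp$n_perm,
      cluster_alpha = sp$cluster_alpha,
      seed = seeds[[paste0("cluster_", cond)]])
    idx_all <- c(idx_a, idx_r)
    fw <- familywise_permutation_test(
      subset_feature_trials(features, idx_all),
      epochs$conditions[idx_all],
      k = cfg$classify$k, n_perm = cfg$classify$n_perm,
      alpha = cfg$classify$alpha,
      seed = seeds[[paste0("classify_", cond)]])
    comp <- paste0(cond, "_vs_rest")
    stage_objects[[paste0("clusters_", cond)]] <- clus
    stage_objects[[paste0("classification_", cond)]] <- fw
    comparisons[[comp]] <- summarize_comparison(clus, fw)
  }

  report <- structure(list(
    package_version = as.character(utils::packageVersion("smrdetect")),
    seed = cfg$seed,
    stage_seeds = as.list(seeds),
    config = cfg,
    trial_counts = list(
      total = length(rej$report$kept) + length(rej$report$rejected),
      rejected = length(rej$report$rejected),
      kept_by_condition = as.list(table(epochs$conditions))),
    comparisons = comparisons
  ), class = "assessment_report")
  attr(report, "stage_objects") <- stage_objects

  if (!is.null(out_dir)) write_report_artifacts(report, out_dir)
  report
}

summarize_comparison <- function(clus, fw) {
  cl_df <- summary(clus)
  obs <- fw$observed
  iu <- which.max(obs$raw)
  list(
    clusters = cl_df,
    n_significant_clusters = sum(cl_df$significant),
    max_smoothed = fw$max_accuracy,
    max_smoothed_time_ms = round(1000 * fw$max_time),
    max_unsmoothed = max(obs$raw),
    max_unsmoothed_time_ms = round(1000 * obs$times[iu]),
    significant = any(fw$significant),
    n_significant_timepoints = sum(fw$significant),
    significant_times_ms = round(1000 * obs$times[fw$significant]),
    p_min = min(fw$p),
    n_perm = fw$n_perm,
    alpha = fw$alpha
  )
}

#' @export
print.assessment_report <- function(x, ...) {
  cat("<assessment_report> smrdetect", x$package_version,
      "| seed", x$seed, "\n")
  counts <- x$trial_counts
  cat(sprintf("  trials: %d total, %d rejected, kept: %s\n",
              counts$total, counts$rejected,
              paste(sprintf("%s=%d", names(counts$kept_by_condition),
                            unlist(counts$kept_by_condition)),
                    collapse = ", ")))
  print(tabulate_results(x))
  invisible(x)
}

format_acc <- function(acc, time_ms, star = FALSE) {
  sprintf("%d%% (%d ms)%s", round(100 * acc), round(time_ms),
          if (star) "*" else "")
}

#' Tabulate maximum classification accuracies
#'
#' One row per comparison with the maximum smoothed and unsmoothed
#' accuracies and their offset-relative times, e.g. `"67% (1250 ms)*"`;
#' the asterisk marks familywise significance at the configured alpha
#' (computed on smoothed accuracies only — unsmoothed maxima are
#' descriptive), plus the number of significant ERD/ERS clusters.
#'
#' @param report An `assessment_report` from [run_pipeline()].
#' @return A data.frame.
#' @export
tabulate_results <- function(report) {
  stopifnot(inherits(report, "assessment_report"))
  rows <- lapply(names(report$comparisons), function(comp) {
    cm <- report$comparisons[[comp]]
    data.frame(
      comparison = gsub("_", " ", comp),
      max_smoothed = format_acc(cm$max_smoothed, cm$max_smoothed_time_ms,
                                cm$significant),
      max_unsmoothed = format_acc(cm$max_unsmoothed,
                                  cm$max_unsmoothed_time_ms),
      significant_clusters = cm$n_significant_clusters,
      stringsAsFactors = FALSE)
  })
  if (length(rows) == 0) {
    return(data.frame(comparison = character(0),
                      max_smoothed = character(0),
                      max_unsmoothed = character(0),
                      significant_clusters = integer(0)))
  }
  do.call(rbind, rows)
}

# Strip non-serializable attributes for stable JSON output.
as_plain <- function(x) {
  if (inherits(x, "table")) return(as.list(x))
  if (is.data.frame(x)) return(x)
  if (is.list(x)) {
    attrs_ok <- x
    attributes(attrs_ok) <- list(names = names(x))
    return(lapply(attrs_ok, as_plain))
  }
  x
}

write_json_stable <- function(x, path) {
  jsonlite::write_json(as_plain(x), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
}

write_report_artifacts <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  so <- attr(report, "stage_objects")
  write_json_stable(unclass(report), file.path(out_dir, "report.json"))
  write_json_stable(unclass(so$rejection), file.path(out_dir, "rejection.json"))
  for (cond in c("left", "right")) {
    cl <- so[[paste0("clusters_", cond)]]
    if (!is.null(cl)) {
      write_json_stable(list(params = cl$params, clusters = summary(cl)),
                        file.path(out_dir, paste0("clusters_", cond, ".json")))
    }
    fw <- so[[paste0("classification_", cond)]]
    if (!is.null(fw)) {
      write_json_stable(
        list(times = fw$observed$times, raw = fw$observed$raw,
             smoothed = fw$observed$smoothed, p = fw$p,
             significant = fw$significant, null_summary =
               list(mean = mean(fw$null), q95 = unname(stats::quantile(fw$null, 0.95)),
                    max = max(fw$null)),
             alpha = fw$alpha, n_perm = fw$n_perm),
        file.path(out_dir, paste0("classification_", cond, ".json")))
    }
  }
  write_json_stable(
    lapply(so$welch, function(w)
      list(condition = w$condition, freqs = w$freqs,
           channels = w$channels, power_db = w$power_db,
           scheme = w$scheme)),
    file.path(out_dir, "welch.json"))
  writeLines(render_report_md(unclass(report)),
             file.path(out_dir, "report.md"))
  if (isTRUE(report$config$figures)) write_report_figures(so, out_dir)
  invisible(out_dir)
}

render_report_md <- function(report) {
  lines <- c(
    "# Covert command-following assessment",
    "",
    sprintf("smrdetect %s | master seed %s", report$package_version,
            format(report$seed)),
    "",
    sprintf("Trials: %d total, %d rejected; kept: %s", report$trial_counts$total,
            report$trial_counts$rejected,
            paste(sprintf("%s=%s", names(report$trial_counts$kept_by_condition),
                          unlist(report$trial_counts$kept_by_condition)),
                  collapse = ", ")),
    "",
    "| Comparison | Max smoothed accuracy (time) | Max unsmoothed accuracy (time) | Significant clusters |",
    "|---|---|---|---|")
  for (comp in names(report$comparisons)) {
    cm <- report$comparisons[[comp]]
    lines <- c(lines, sprintf(
      "| %s | %s | %s | %d |",
      gsub("_", " ", comp),
      format_acc(cm$max_smoothed, cm$max_smoothed_time_ms, isTRUE(cm$significant)),
      format_acc(cm$max_unsmoothed, cm$max_unsmoothed_time_ms),
      cm$n_significant_clusters))
  }
  lines <- c(lines, "",
             "Asterisk: familywise-significant (max-statistic randomization",
             "test on smoothed accuracies). Unsmoothed maxima are descriptive.",
             "Times are relative to instruction offset.")
  for (comp in names(report$comparisons)) {
    cm <- report$comparisons[[comp]]
    cl <- cm$clusters
    if (is.null(cl) || nrow(cl) == 0 || !any(cl$significant)) next
    lines <- c(lines, "", sprintf("## Significant clusters: %s",
                                  gsub("_", " ", comp)))
    sig <- cl[cl$significant, , drop = FALSE]
    for (i in seq_len(nrow(sig))) {
      lines <- c(lines, sprintf(
        "- %s: %s cluster %g-%g Hz x %d-%d ms, sum(t) = %.1f, p = %.4f",
        sig$channel[i], sig$sign[i], sig$f_min[i], sig$f_max[i],
        round(1000 * sig$t_min[i]), round(1000 * sig$t_max[i]),
        sig$stat[i], sig$p[i]))
    }
  }
  lines
}

#' Regenerate the Markdown report from serialized stage outputs
#'
#' Reads `report.json` in `out_dir` (no recomputation) and rewrites
#' `report.md`; the result is byte-identical to the original render.
#'
#' @param out_dir Directory previously written by [run_pipeline()].
#' @return Path to the regenerated report, invisibly.
#' @export
regenerate_report <- function(out_dir) {
  rj <- jsonlite::read_json(file.path(out_dir, "report.json"),
                            simplifyVector = TRUE)
  comps <- rj$comparisons
  rj$comparisons <- lapply(comps, function(cm) cm)
  path <- file.path(out_dir, "report.md")
  writeLines(render_report_md(rj), path)
  invisible(path)
}
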