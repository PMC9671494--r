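#' Pipeline configuration
#'
#' Bundles every stage parameter; defaults reproduce the standard analysis
#' settings exactly: 3-30 Hz filter band for R-peak detection, 550 ms
#' minimum peak distance, hold-duration exclusion bounds 100/5000 ms, +/-3 SD
#' outlier rule, 1.5x-median R-T consistency factor, alpha = 0.05.
#'
#' @param out_dir output directory (created if missing).
#' @param seed root RNG seed (propagated to the synthetic generator).
#' @param synth a `synth_config` used when `simulate = TRUE`.
#' @param input_beats,input_trials paths to event-table TSVs to import
#'   instead of simulating.
#' @param input_signals optional named list of raw signal file paths
#'   (participant -> ECG TSV) for the detection stage.
#' @param simulate generate synthetic data (default TRUE when no inputs).
#' @param band_r,band_t filter bands (Hz) for R-peak detection and T-wave
#'   delineation.
#' @param min_distance minimum R-peak separation (ms).
#' @param rt_factor R-T consistency multiplier.
#' @param bounds hold-duration exclusion bounds (ms).
#' @param sd_mult duration-outlier SD multiplier.
#' @param sd_pooling `"pooled"` or `"per_level"` outlier pooling.
#' @param alpha significance level.
#' @param min_trials minimum assigned events per proportion cell.
#' @param hold_grid grid (ms) for hold-phase circular averaging.
#' @param compute_hold_phase compute the (expensive) hold-phase means.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir = tempfile("cardiotouch_run_"),
                            seed = 1L,
                            synth = synth_config(seed = seed),
                            input_beats = NULL, input_trials = NULL,
                            input_signals = NULL,
                            simulate = is.null(input_beats),
                            band_r = c(3, 30), band_t = c(0.5, 40),
                            min_distance = 550, rt_factor = 1.5,
                            bounds = c(100, 5000), sd_mult = 3,
                            sd_pooling = "pooled",
                            alpha = 0.05, min_trials = 5, hold_grid = 1,
                            compute_hold_phase = TRUE) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed), synth = synth,
              input_beats = input_beats, input_trials = input_trials,
              input_signals = input_signals, simulate = simulate,
              band_r = band_r, band_t = band_t,
              min_distance = min_distance, rt_factor = rt_factor,
              bounds = bounds, sd_mult = sd_mult, sd_pooling = sd_pooling,
              alpha = alpha, min_trials = min_trials, hold_grid = hold_grid,
              compute_hold_phase = compute_hold_phase)
  class(cfg) <- "pipeline_config"
  cfg
}

config_fingerprint <- function(config) {
  flat <- unclass(config)
  flat$synth <- unclass(flat$synth)
  flat$out_dir <- NULL
  json <- jsonlite::toJSON(flat, auto_unbox = TRUE, digits = NA, null = "null")
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(json, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or import) -> detect (optional, from raw signals)
#' -> trial exclusions and participant inclusion -> cardiac-phase assignment
#' -> behavioural/circular analyses -> TSV reports + a JSON manifest.
#' Reruns with the same configuration are bit-identical on synthetic inputs.
#'
#' @param config a `pipeline_config`.
#' @param verbose print stage-level progress and exclusion counts.
#' @return (invisibly) list with `trials`, `beats`, `summaries`, `analyses`
#'   and `manifest`.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "input"
  res <- tryCatch({
    if (!is.null(config$input_signals)) {
      stage <- "detect"
      say("[detect] delineating %d raw recordings", length(config$input_signals))
      beats <- lapply(config$input_signals, function(p) {
        detect_ecg_events(read_signal_file(p), band_r = config$band_r,
                          band_t = config$band_t,
                          min_distance = config$min_distance,
                          rt_factor = config$rt_factor)
      })
      if (is.null(config$input_trials)) {
        stop("configuration error: raw-signal input requires `input_trials`")
      }
      trials <- read_trials_tsv(config$input_trials)
    } else if (config$simulate) {
      stage <- "simulate"
      say("[simulate] %d participants, seed %d",
          config$synth$n_participants, config$synth$seed)
      ds <- simulate_dataset(config$synth)
      beats <- ds$beats
      trials <- ds$trials
    } else {
      stage <- "import"
      if (is.null(config$input_beats) || is.null(config$input_trials)) {
        stop("configuration error: need `input_beats` and `input_trials` (or simulate = TRUE)")
      }
      for (p in c(config$input_beats, config$input_trials)) {
        if (!file.exists(p)) stop(sprintf("configuration error: input path not found: %s", p))
      }
      imp <- import_event_tables(config$input_beats, config$input_trials)
      beats <- imp$beats
      trials <- imp$trials
    }

    stage <- "trials"
    beats <- lapply(beats, rt_consistency_filter, factor = config$rt_factor)
    trials <- apply_exclusions(trials, beats = beats, bounds = config$bounds,
                               sd_mult = config$sd_mult,
                               sd_pooling = config$sd_pooling)
    excl <- table(trials$exclusion_reason[trials$excluded])
    say("[trials] %d trials, %.1f%% retained (%s)", nrow(trials),
        100 * attr(trials, "retained"),
        if (length(excl)) paste(names(excl), excl, sep = "=", collapse = ", ")
        else "no exclusions")
    inclusion <- lapply(split(trials, trials$participant), include_participant,
                        alpha = config$alpha)
    keep_ids <- names(inclusion)[vapply(inclusion, `[[`, logical(1), "keep")]
    dropped <- setdiff(unique(trials$participant), keep_ids)
    if (length(dropped)) {
      say("[trials] dropping %d participant(s) at chance: %s",
          length(dropped), paste(dropped, collapse = ", "))
    }
    trials_kept <- trials[trials$participant %in% keep_ids, ]
    if (!nrow(trials_kept)) {
      stop("no participant passed the chance-performance inclusion test ",
           "(too few trials per difficulty level?)")
    }
    summaries <- lapply(split(trials_kept, trials_kept$participant),
                        behaviour_summary)

    stage <- "phases"
    events <- c("onset", "offset", if (config$compute_hold_phase) "hold")
    phased <- annotate_phases(trials_kept, beats, events = events,
                              hold_grid = config$hold_grid)
    say("[phases] annotated %d retained trials", sum(!phased$excluded))

    stage <- "analyse"
    props <- phase_proportions(phased, min_trials = config$min_trials)
    durs <- duration_by_initiation_phase(phased)
    medians <- duration_by_initiation_phase(phased, stat = "median")
    acc <- accuracy_by_phase(phased)
    circ <- group_circular_summary(phased, by_level = TRUE)
    covar <- variability_covariate_analysis(phased)
    ctx <- list()
    for (cond in unique(phased$condition)) {
      ctx[[cond]] <- ibi_contexts(kept_trials(phased), beats, condition = cond)
    }
    ibi <- lapply(ctx, ibi_position_analysis)

    stage <- "report"
    out <- function(f) file.path(config$out_dir, f)
    write_beats_tsv(beats, out("beats.tsv"))
    write_trials_tsv(trials, out("trials.tsv"))
    ph_tab <- phased[c("participant", "condition", "level",
                       "onset_angle", "onset_window", "hold_angle",
                       "offset_angle", "offset_window")]
    write_tsv(ph_tab, out("phases.tsv"))
    write_tsv(props$table, out("phase_proportions.tsv"))
    write_tsv(durs$per_participant, out("durations_by_phase.tsv"))
    write_tsv(durs$contrasts, out("duration_contrasts.tsv"))
    write_tsv(acc, out("accuracy_by_phase.tsv"))
    write_tsv(circ, out("circular_summary.tsv"))
    write_tsv(covar$table, out("variability_covariate.tsv"))
    for (cond in names(ibi)) {
      write_tsv(ibi[[cond]]$per_participant,
                out(sprintf("ibi_positions_%s.tsv", cond)))
      write_tsv(ibi[[cond]]$posthoc, out(sprintf("ibi_posthoc_%s.tsv", cond)))
    }
    manifest <- list(
      package = "cardiotouch",
      version = as.character(utils::packageVersion("cardiotouch")),
      seed = config$seed,
      config_md5 = config_fingerprint(config),
      n_participants = length(keep_ids),
      n_participants_dropped = length(dropped),
      n_trials = nrow(trials),
      retained_fraction = attr(trials, "retained"),
      exclusion_counts = as.list(excl),
      outputs = sort(list.files(config$out_dir, pattern = "\\.tsv$")))
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    say("[report] wrote %d files to %s", length(manifest$outputs) + 1,
        config$out_dir)
    list(trials = phased, beats = beats, summaries = summaries,
         inclusion = inclusion,
         analyses = list(proportions = props, durations = durs,
                         durations_median = medians, accuracy = acc,
                         circular = circ, covariate = covar, ibi = ibi),
         manifest = manifest)
  }, error = function(e) {
    stop(sprintf("pipeline stage `%s` failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
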