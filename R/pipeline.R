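# End-to-end orchestration on the synthetic test bed: simulate -> preprocess
# -> decode -> temporal generalisation -> dynamics -> sequence simulation ->
# latency -> group statistics, with per-stage artefacts written as
# plain-text tables plus a resolved-config echo.

pipeline_stage_names <- function() {
  c("simulate", "preprocess", "b2b", "tempgen", "dynamics", "seqsim",
    "latency", "stats")
}

#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()]. Unknown keys are rejected.
#' The defaults run every stage at desk scale (tens of words, a coarse
#' 50 Hz analysis grid, a few simulated subjects) in a couple of minutes;
#' the canonical single-analysis grid (250 Hz, 201 samples) remains the
#' default of the underlying functions.
#'
#' @param preset simulation preset name (see [sim_preset()]).
#' @param seed master integer seed; all stage seeds derive from it.
#' @param out_dir output directory (default: a fresh temporary directory).
#' @param stages character vector of stages to run, a subset of
#'   `r paste(pipeline_stage_names(), collapse = ", ")`.
#' @param n_words words per simulated recording.
#' @param n_channels simulated sensor count.
#' @param n_subjects simulated subjects for group-level stages.
#' @param n_splits B2B splits per timepoint.
#' @param fs_epoch epoch sampling rate for the analysis grid (Hz; must
#'   divide 1000).
#' @param epoch_window epoch window in seconds.
#' @param features feature columns decoded by the B2B stages.
#' @param n_perm permutations for the statistics/null stages.
#' @return a validated list of class `phonseq_config`.
#' @export
pipeline_config <- function(preset = "clean", seed = 1, out_dir = NULL,
                            stages = pipeline_stage_names(),
                            n_words = 40, n_channels = 32, n_subjects = 3,
                            n_splits = 5, fs_epoch = 50,
                            epoch_window = c(-0.2, 0.6),
                            features = c("voicing", "plosive", "vowel",
                                         "coronal", "surprisal", "pos_in_word"),
                            n_perm = 500) {
  cfg <- list(preset = preset, seed = seed, out_dir = out_dir,
              stages = stages, n_words = n_words, n_channels = n_channels,
              n_subjects = n_subjects, n_splits = n_splits,
              fs_epoch = fs_epoch, epoch_window = epoch_window,
              features = features, n_perm = n_perm)
  validate_pipeline_config(cfg)
}

#' @param cfg a named list (e.g. parsed from YAML with [read_config()]).
#' @rdname pipeline_config
#' @export
validate_pipeline_config <- function(cfg) {
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    abort(paste("unknown config key(s):", paste(unknown, collapse = ", ")))
  }
  defaults <- formals(pipeline_config)
  for (nm in setdiff(known, names(cfg))) cfg[[nm]] <- eval(defaults[[nm]])
  if (!cfg$preset %in% c("clean", "paper-like", "static-control")) {
    abort(sprintf("unknown preset '%s'", cfg$preset))
  }
  bad <- setdiff(cfg$stages, pipeline_stage_names())
  if (length(bad)) abort(paste("unknown stage(s):", paste(bad, collapse = ", ")))
  if (1000 %% cfg$fs_epoch != 0) abort("fs_epoch must divide 1000")
  structure(cfg, class = "phonseq_config")
}

#' Read a pipeline config from YAML
#'
#' @param path YAML file with `pipeline_config()` keys.
#' @return a validated `phonseq_config`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$epoch_window)) cfg$epoch_window <- as.numeric(cfg$epoch_window)
  validate_pipeline_config(cfg)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

position_label <- function(pos_on, pos_off, max_pos = 3) {
  lab <- rep(NA_character_, length(pos_on))
  lab[pos_on <= max_pos] <- paste0("P", pos_on[pos_on <= max_pos])
  back <- -pos_off <= 2 & pos_on > max_pos
  lab[back] <- paste0("P", pos_off[back])
  lab
}

#' Run the analysis pipeline on synthetic data
#'
#' Executes the requested stages in dependency order on data from the
#' configured simulation preset, writing per-stage artefacts (TSV/JSON), a
#' resolved config echo (`config.yaml`) and a timing log (`run.log`) into
#' the output directory. Running a stage whose upstream artefact is missing
#' raises an error naming the stage to run first. Identical config and seed
#' give identical artefacts.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list of in-memory stage results plus `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  config <- validate_pipeline_config(unclass(config))
  out_dir <- config$out_dir %||% tempfile("phonseq_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_echo <- unclass(config)
  cfg_echo$out_dir <- NULL
  yaml::write_yaml(cfg_echo, file.path(out_dir, "config.yaml"))
  log_path <- file.path(out_dir, "run.log")
  log_line <- function(...) {
    msg <- sprintf(...)
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"), msg),
        file = log_path, append = TRUE)
    inform(msg)
  }
  art <- list(out_dir = out_dir)
  need <- function(what, stage_needed) {
    if (is.null(art[[what]])) {
      abort(sprintf("missing upstream artefact '%s': run stage '%s' first",
                    what, stage_needed))
    }
    art[[what]]
  }
  preset <- sim_preset(config$preset)
  phonetic <- intersect(config$features, phonetic_feature_names())
  run_stage <- function(name, f) {
    t0 <- Sys.time()
    res <- f()
    log_line("stage %-10s done in %.1f s", name,
             as.numeric(difftime(Sys.time(), t0, units = "secs")))
    res
  }
  stages <- intersect(pipeline_stage_names(), config$stages)

  if ("simulate" %in% stages) {
    art$sim <- run_stage("simulate", function() {
      lex <- toy_lexicon()
      layout <- sensor_layout(config$n_channels)
      code <- make_code(layout, c(phonetic, "onset"),
                        drift_rate = preset$drift_rate,
                        seed = child_seed(config$seed, 1))
      subjects <- lapply(seq_len(config$n_subjects), function(s) {
        events <- sample_stream(lex, config$n_words, preset$config,
                                seed = child_seed(config$seed, 10 + s))
        ann <- annotate_stream(events, lex)
        rec <- simulate_recording(events, ann, code, preset$config,
                                  seed = child_seed(config$seed, 100 + s))
        list(events = events, annotation = ann, recording = rec)
      })
      write_annotation(subjects[[1]]$annotation,
                       file.path(out_dir, "annotation.tsv"))
      list(lexicon = lex, layout = layout, code = code, subjects = subjects)
    })
  }

  if ("preprocess" %in% stages) {
    sim <- need("sim", "simulate")
    art$epochs <- run_stage("preprocess", function() {
      lapply(sim$subjects, function(su) {
        trf <- fit_trf(su$recording)
        res <- residualize(su$recording, trf)
        ep <- epoch_events(res, fs_out = config$fs_epoch,
                           window = config$epoch_window,
                           lowpass = min(50, config$fs_epoch / 2 - 1))
        ep
      })
    })
  }

  get_Y <- function(su, ep) {
    feature_matrix(su$annotation)[ep$annotation_index, config$features,
                                  drop = FALSE]
  }

  if ("b2b" %in% stages) {
    sim <- need("sim", "simulate"); eps <- need("epochs", "preprocess")
    art$b2b <- run_stage("b2b", function() {
      res <- lapply(seq_along(eps), function(s) {
        Y <- get_Y(sim$subjects[[s]], eps[[s]])
        variance_shares(b2b_timecourse(eps[[s]], Y, n_splits = config$n_splits,
                                       seed = child_seed(config$seed, 200 + s)))
      })
      write_tsv(generics::tidy(res[[1]]), file.path(out_dir, "b2b_beta.tsv"))
      res
    })
  }

  if ("tempgen" %in% stages) {
    sim <- need("sim", "simulate"); eps <- need("epochs", "preprocess")
    art$tempgen <- run_stage("tempgen", function() {
      per_subject <- lapply(seq_along(eps), function(s) {
        su <- sim$subjects[[s]]; ep <- eps[[s]]
        ann <- su$annotation[ep$annotation_index, ]
        pos <- position_label(ann$pos_from_onset, ann$pos_from_offset)
        tg_fit_eval(ep, get_Y(su, ep), features = phonetic,
                    n_splits = config$n_splits,
                    seed = child_seed(config$seed, 300 + s), groups = pos)
      })
      positions <- Reduce(intersect, lapply(per_subject, names))
      tmaps <- lapply(stats::setNames(positions, positions), function(p) {
        tg_tmap(lapply(per_subject, `[[`, p))
      })
      aligned <- align_to_word_clock(tmaps, step_ms = 80)
      write_tsv(aligned$composite, file.path(out_dir, "tg_composite.tsv"))
      write_tsv(generics::tidy(tmaps[[1]]), file.path(out_dir, "tg_tmap_P1.tsv"))
      list(per_subject = per_subject, tmaps = tmaps, aligned = aligned,
           overlap_pct = overlap_fraction(aligned$tg, threshold = 4))
    })
  }

  if ("dynamics" %in% stages) {
    sim <- need("sim", "simulate"); eps <- need("epochs", "preprocess")
    art$dynamics <- run_stage("dynamics", function() {
      Ws <- lapply(seq_along(eps), function(s) {
        unregularized_coefficients(eps[[s]], get_Y(sim$subjects[[s]], eps[[s]]))
      })
      traj <- project_trajectory(Ws, sim$layout, times = eps[[1]]$times)
      st <- trajectory_structure(traj)
      write_tsv(traj, file.path(out_dir, "trajectory.tsv"))
      write_tsv(st, file.path(out_dir, "trajectory_structure.tsv"))
      list(weights = Ws, trajectory = traj, structure = st)
    })
  }

  if ("seqsim" %in% stages) {
    sim <- need("sim", "simulate")
    art$seqsim <- run_stage("seqsim", function() {
      tmpl <- make_code(sensor_layout(config$n_channels), c("voicing", "plosive"),
                        drift_rate = preset$drift_rate,
                        seed = child_seed(config$seed, 400), fs = 100)
      resp <- synthesize_sequence_responses(enumerate_anagrams(), tmpl,
                                            noise_sd = 0.1,
                                            seed = child_seed(config$seed, 401))
      rec <- reconstruct_history(resp, n_perm = config$n_perm,
                                 seed = child_seed(config$seed, 402))
      write_tsv(rec, file.path(out_dir, "seqsim.tsv"))
      rec
    })
  }

  if ("latency" %in% stages) {
    eps <- need("epochs", "preprocess")
    art$latency <- run_stage("latency", function() {
      lat <- decode_latency(eps[[1]], crop = c(0.1, 0.4),
                            n_latency = min(16, sum(eps[[1]]$times >= 0.1 &
                                                      eps[[1]]$times <= 0.4)),
                            seed = child_seed(config$seed, 500))
      write_tsv(lat$predictions, file.path(out_dir, "latency_predictions.tsv"))
      lat
    })
  }

  if ("stats" %in% stages) {
    b2b <- need("b2b", "b2b")
    art$stats <- run_stage("stats", function() {
      mat <- do.call(rbind, lapply(b2b, function(r) colMeans(r$beta[phonetic, , drop = FALSE])))
      if (nrow(mat) < 5) {
        inform("stats stage needs at least 5 simulated subjects; skipped")
        return(NULL)
      }
      cl <- one_sample_cluster_test(mat, n_perm = config$n_perm,
                                    seed = child_seed(config$seed, 600),
                                    times = b2b[[1]]$times)
      jsonlite::write_json(cl$clusters, file.path(out_dir, "clusters.json"),
                           auto_unbox = TRUE, digits = NA)
      cl
    })
  }

  invisible(art)
}

#' Render report figures and summary tables from a run directory
#'
#' Regenerates standard figure panels (feature share timecourses, word-clock
#' TG composite, trajectory, lag-similarity curve, latency scatter) from the
#' plain-text artefacts of a [run_pipeline()] directory. Panels whose
#' artefacts are missing are skipped with a warning.
#'
#' @param run_dir a [run_pipeline()] output directory.
#' @param format `"png"` or `"pdf"`.
#' @return character vector of written file paths.
#' @export
make_report <- function(run_dir, format = c("png", "pdf")) {
  format <- match.arg(format)
  if (!dir.exists(run_dir) || !length(list.files(run_dir))) {
    abort("empty or missing run directory")
  }
  written <- character(0)
  save_plot <- function(p, name) {
    path <- file.path(run_dir, paste0(name, ".", format))
    ggplot2::ggsave(path, p, width = 6, height = 4, dpi = 120)
    written <<- c(written, path)
  }
  try_panel <- function(file, fn) {
    path <- file.path(run_dir, file)
    if (!file.exists(path)) {
      warn(sprintf("artefact %s missing; panel skipped", file))
      return(invisible(NULL))
    }
    fn(utils::read.delim(path))
  }
  try_panel("b2b_beta.tsv", function(df) {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = time, y = rhat, colour = feature)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "time from phoneme onset (s)",
                    y = "share of explainable variance") +
      ggplot2::theme_minimal()
    save_plot(p, "fig_shares")
  })
  try_panel("tg_composite.tsv", function(df) {
    df <- df[is.finite(df$score), ]
    p <- ggplot2::ggplot(df, ggplot2::aes(x = time_ms, y = score, fill = position)) +
      ggplot2::geom_area(position = "stack") +
      ggplot2::labs(x = "time from word onset (ms)", y = "summed score") +
      ggplot2::theme_minimal()
    save_plot(p, "fig_tg_composite")
  })
  try_panel("trajectory.tsv", function(df) {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = x, y = y, colour = time)) +
      ggplot2::geom_path() + ggplot2::facet_wrap(~feature) +
      ggplot2::labs(x = "left-right projection", y = "posterior-anterior projection") +
      ggplot2::theme_minimal()
    save_plot(p, "fig_trajectory")
  })
  try_panel("seqsim.tsv", function(df) {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = lag, y = similarity)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "history lag (1 = current phoneme)",
                    y = "cosine similarity") +
      ggplot2::theme_minimal()
    save_plot(p, "fig_seqsim")
  })
  try_panel("latency_predictions.tsv", function(df) {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = true_ms, y = predicted_ms)) +
      ggplot2::geom_jitter(alpha = 0.2, width = 3) +
      ggplot2::geom_abline(linetype = 2) +
      ggplot2::labs(x = "true latency (ms)", y = "predicted latency (ms)") +
      ggplot2::theme_minimal()
    save_plot(p, "fig_latency")
  })
  written
}
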