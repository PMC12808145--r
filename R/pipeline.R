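#' Default pipeline configuration
#'
#' All analysis defaults in one flat list: 60-trial sessions (30/30),
#' 500 ms feature windows, 5-100 Hz Morse CWT, 1000 permutations at
#' point-wise alpha 0.05, 25-bin minimum extent, mean |d| > 0.4, the three
#' standard choice contrasts and the three layers of the layer-resolved
#' contrasts.
#'
#' @return Named list of defaults (see [validate_config()]).
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    n_sessions = 4L,
    rates = NULL,                      # fixed c(hit, fa); NULL -> agent curves
    agent = list(),                    # agent_params() overrides
    session = list(),                  # session_config() overrides
    truth = list(),                    # laminar_ground_truth() overrides
    burst_specs = NULL,                # full burst list overriding the default
    csd = list(),                      # csd_config() overrides
    cwt = list(),                      # cwt_config() overrides
    comparison = list(),               # tf_comparison() overrides
    contrasts = list(c("hit", "miss"),
                     c("false_alarm", "correct_rejection"),
                     c("hit", "correct_rejection")),
    layers = c("I/II", "III/IV", "VI"),
    anchor = "cs4",
    spectral_window_ms = c(0, 700),
    time_downsample = 10L,
    glmm_outcome_pair = c("hit", "miss"),
    glmm_random = "(1 + z | subject)",
    subject_id = "s1",
    detect_clipping = FALSE,
    stages = c("simulate", "preprocess", "features", "behavior",
               "spectral", "clusters", "glmm"),
    out_dir = NULL
  )
}

#' Validate and complete a run configuration
#'
#' Fills every omitted key from [default_run_config()], rejects unknown
#' keys and out-of-range values with an itemized error, and records every
#' deviation from the defaults in the returned object's `deviations`
#' attribute (so a manifest can echo them).
#'
#' @param raw Named list of overrides, or a path to a JSON file of them,
#'   or `NULL` for pure defaults.
#' @return A `lam_run_config` list.
#' @export
#' @examples
#' cfg <- validate_config(list(n_sessions = 2))
#' attr(cfg, "deviations")
validate_config <- function(raw = NULL) {
  if (is.character(raw)) raw <- read_run_config(raw)
  raw <- raw %||% list()
  defaults <- default_run_config()
  errors <- character(0)
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown)) {
    errors <- c(errors, paste0("unknown config key(s): ",
                               paste(unknown, collapse = ", ")))
  }
  # sub-config lists merge key-by-key; everything else replaces wholesale
  merge_keys <- c("agent", "session", "truth", "csd", "cwt", "comparison")
  cfg <- defaults
  for (k in setdiff(names(raw), unknown)) {
    cfg[[k]] <- if (k %in% merge_keys && is.list(raw[[k]])) {
      utils::modifyList(defaults[[k]], raw[[k]], keep.null = TRUE)
    } else {
      raw[[k]]
    }
  }
  # structural checks (sub-configs are validated by their constructors)
  cmp <- cfg$comparison
  if (!is.null(cmp$n_permutations) && cmp$n_permutations < 1) {
    errors <- c(errors, "comparison$n_permutations must be >= 1")
  }
  if (!is.null(cmp$alpha_pointwise) &&
      (cmp$alpha_pointwise <= 0 || cmp$alpha_pointwise >= 1)) {
    errors <- c(errors, "comparison$alpha_pointwise must be in (0, 1)")
  }
  if (!is.null(cfg$rates) &&
      (length(cfg$rates) != 2 || any(cfg$rates < 0 | cfg$rates > 1))) {
    errors <- c(errors, "rates must be c(hit, fa) in [0, 1]")
  }
  # normalise contrast shapes coming from JSON (matrix / bare pair)
  if (is.matrix(cfg$contrasts)) {
    cfg$contrasts <- lapply(seq_len(nrow(cfg$contrasts)),
                            function(i) as.character(cfg$contrasts[i, ]))
  } else if (is.character(cfg$contrasts)) {
    cfg$contrasts <- list(cfg$contrasts)
  } else if (is.list(cfg$contrasts)) {
    cfg$contrasts <- lapply(cfg$contrasts, function(x) unlist(x))
  }
  labs <- c("hit", "miss", "false_alarm", "correct_rejection")
  for (ct in cfg$contrasts) {
    if (length(ct) != 2 || !all(ct %in% labs)) {
      errors <- c(errors, paste0("bad contrast: ", paste(ct, collapse = " vs ")))
    }
  }
  truth_layers <- names(if (length(cfg$truth) && !is.null(cfg$truth$layer_map))
    cfg$truth$layer_map else default_layer_map())
  missing_layers <- setdiff(cfg$layers, truth_layers)
  if (length(missing_layers)) {
    errors <- c(errors, paste0("config references missing layer(s): ",
                               paste(missing_layers, collapse = ", ")))
  }
  if (!all(cfg$stages %in% defaults$stages)) {
    errors <- c(errors, "unknown stage name in `stages`")
  }
  if (length(errors)) {
    abort(paste0("invalid configuration:\n", paste0("- ", errors, collapse = "\n")))
  }
  dev <- names(raw)[vapply(names(raw), function(k) {
    !identical(raw[[k]], defaults[[k]])
  }, logical(1))]
  structure(cfg, class = "lam_run_config", deviations = dev)
}

build_pipeline_objects <- function(cfg) {
  truth_args <- cfg$truth
  if (!is.null(cfg$burst_specs)) truth_args$burst_specs <- cfg$burst_specs
  list(
    session = do.call(session_config, cfg$session),
    agent = do.call(agent_params, cfg$agent),
    truth = do.call(laminar_ground_truth, truth_args),
    geometry = probe_geometry(),
    csd = do.call(csd_config, cfg$csd),
    cwt = do.call(cwt_config, cfg$cwt),
    comparison = do.call(tf_comparison, cfg$comparison)
  )
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> preprocess (bad-channel screen, interpolation,
#' optional clipping mask) -> CSD -> RMS features -> behavior binning ->
#' per-layer spectral power -> cluster-mass contrasts -> time-resolved GLMM
#' effect sizes, with per-stage accounting. Outputs are deterministic given
#' `config$seed`; when `config$out_dir` is set, trial tables, feature
#' tables, behavior summaries, cluster JSON/TSV and the manifest are
#' written there.
#'
#' @param config A `lam_run_config` from [validate_config()] (or a raw list
#'   / JSON path, validated on the fly).
#' @return List with `manifest`, `trials`, `behavior`, `features`
#'   (anchor-named list of feature tibbles), `clusters` (tibble of contrast
#'   x layer results with a `result` list-column), `glmm_series`.
#' @export
run_pipeline <- function(config = validate_config()) {
  if (!inherits(config, "lam_run_config")) config <- validate_config(config)
  obj <- build_pipeline_objects(config)
  stages <- config$stages
  manifest <- list(
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    deviations = as.list(attr(config, "deviations") %||% character(0)),
    package_version = as.character(utils::packageVersion("lamcsd")),
    stages_completed = character(0),
    counts = list()
  )
  out <- list(manifest = manifest)

  # -- simulate + per-session heavy stages (one session in memory at a time)
  assert_that("simulate" %in% stages, "pipeline requires the simulate stage")
  curves <- if (is.null(config$rates)) {
    simulate_learning_curves(obj$agent, config$n_sessions, config$seed)
  } else {
    tibble::tibble(session = seq_len(config$n_sessions), phase_block = 0L,
                   hit_rate = config$rates[1], fa_rate = config$rates[2])
  }
  all_trials <- list()
  feat_cs4 <- list()
  feat_each <- list()
  layer_power <- setNames(vector("list", length(config$layers)), config$layers)
  n_bad_channels <- 0L
  n_clipped_windows <- 0L
  spectral_axes <- NULL

  for (s in seq_len(config$n_sessions)) {
    sess <- generate_session(obj$session,
                             c(curves$hit_rate[s], curves$fa_rate[s]),
                             obj$truth, obj$geometry,
                             seed = child_seed(config$seed, paste0("session", s)),
                             session_id = s)
    rec <- sess$recording
    if ("preprocess" %in% stages) {
      bad <- detect_bad_channels(rec)
      n_bad_channels <- n_bad_channels + length(bad)
      if (length(bad)) rec <- interpolate_channels(rec, bad)
      if (isTRUE(config$detect_clipping)) rec <- remove_clipping(rec)
    }
    csd <- compute_csd(rec, config = obj$csd)
    if ("features" %in% stages) {
      f1 <- rms_features(csd, sess$trials, window_anchor = config$anchor)
      n_clipped_windows <- n_clipped_windows + attr(f1, "excluded")[["clipped"]]
      feat_cs4[[s]] <- f1
      feat_each[[s]] <- rms_features(csd, sess$trials, window_anchor = "each_cs")
    }
    if (any(c("spectral", "clusters") %in% stages)) {
      for (lay in config$layers) {
        ps <- layer_power_set(csd, lay, sess$trials$trial_id,
                              window_ms = config$spectral_window_ms,
                              config = obj$cwt,
                              time_downsample = config$time_downsample)
        if (is.null(spectral_axes)) {
          spectral_axes <- list(freqs = ps$freqs, time_ms = ps$time_ms,
                                coi = ps$coi)
        }
        layer_power[[lay]] <- c(layer_power[[lay]], list(ps$power))
      }
    }
    all_trials[[s]] <- sess$trials
  }
  trials <- dplyr::bind_rows(all_trials)
  out$trials <- trials
  manifest$counts$trials_in <- nrow(trials)
  manifest$counts$bad_channels_interpolated <- n_bad_channels
  manifest$stages_completed <- c(manifest$stages_completed, "simulate",
                                 intersect("preprocess", stages))

  if ("behavior" %in% stages) {
    behav <- summarize_behavior(trials)
    trials <- dplyr::left_join(
      trials, dplyr::select(behav, "session_id", "phase"), by = "session_id")
    out$behavior <- behav
    out$trials <- trials
    out$bins <- summarize_bins(trials)
    manifest$stages_completed <- c(manifest$stages_completed, "behavior")
  }

  if ("features" %in% stages) {
    out$features <- list(anchor = dplyr::bind_rows(feat_cs4),
                         each_cs = dplyr::bind_rows(feat_each))
    manifest$counts$clipped_windows_excluded <- n_clipped_windows
    manifest$counts$feature_rows <- nrow(out$features$anchor)
    manifest$stages_completed <- c(manifest$stages_completed, "features")
  }

  if ("clusters" %in% stages && length(config$contrasts)) {
    cluster_rows <- list()
    for (lay in config$layers) {
      pw <- do.call(abind3, layer_power[[lay]])
      for (ct in config$contrasts) {
        ia <- which(trials$choice == ct[1])
        ib <- which(trials$choice == ct[2])
        if (length(ia) < 2 || length(ib) < 2) {
          cluster_rows[[length(cluster_rows) + 1]] <- tibble::tibble(
            layer = lay, contrast = paste(ct, collapse = " vs "),
            n_a = length(ia), n_b = length(ib), n_significant = NA_integer_,
            result = list(NULL))
          next
        }
        res <- tf_cluster_test(
          pw[ia, , , drop = FALSE], pw[ib, , , drop = FALSE],
          comparison = obj$comparison,
          seed = child_seed(config$seed, paste0("perm-", lay, "-", ct[1])),
          freqs = spectral_axes$freqs, time_ms = spectral_axes$time_ms,
          exclude = spectral_axes$coi)
        cluster_rows[[length(cluster_rows) + 1]] <- tibble::tibble(
          layer = lay, contrast = paste(ct, collapse = " vs "),
          n_a = length(ia), n_b = length(ib),
          n_significant = sum(res$significant), result = list(res))
      }
    }
    out$clusters <- dplyr::bind_rows(cluster_rows)
    manifest$stages_completed <- c(manifest$stages_completed,
                                   intersect(c("spectral", "clusters"), stages))
  }

  if ("glmm" %in% stages && "features" %in% stages) {
    feats <- out$features$each_cs
    # sessions act as the repeated grouping unit of a single-animal run
    feats$subject <- paste0(config$subject_id, "-", feats$session_id)
    out$glmm_series <- effect_size_series(
      feats, config$glmm_outcome_pair,
      layers = intersect(config$layers, unique(feats$layer)),
      random = config$glmm_random)
    manifest$stages_completed <- c(manifest$stages_completed, "glmm")
  }

  manifest$counts$trials_analyzed <- nrow(trials)
  out$manifest <- manifest

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_trial_table(out$trials, file.path(config$out_dir, "trials.csv"))
    if (!is.null(out$behavior)) {
      write_behavior_summary(out$behavior,
                             file.path(config$out_dir, "behavior.csv"))
    }
    if (!is.null(out$features)) {
      write.csv(out$features$anchor,
                file.path(config$out_dir, "features.csv"), row.names = FALSE)
    }
    if (!is.null(out$clusters)) {
      for (i in seq_len(nrow(out$clusters))) {
        if (is.null(out$clusters$result[[i]])) next
        slug <- gsub("[^a-z0-9]+", "-",
                     tolower(paste(out$clusters$layer[i],
                                   out$clusters$contrast[i])))
        write_cluster_results(
          out$clusters$result[[i]],
          json_path = file.path(config$out_dir,
                                paste0("clusters-", slug, ".json")),
          tsv_path = file.path(config$out_dir,
                               paste0("clusters-", slug, ".tsv")))
      }
    }
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

# rbind 3-D arrays along the first (observation) axis
abind3 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])[2:3]
  tot <- sum(vapply(parts, function(p) dim(p)[1], integer(1)))
  out <- array(0, dim = c(tot, d))
  at <- 0L
  for (p in parts) {
    n <- dim(p)[1]
    out[at + seq_len(n), , ] <- p
    at <- at + n
  }
  out
}
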