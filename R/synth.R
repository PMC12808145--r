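#' Laminar probe geometry
#'
#' Describes a single-shank laminar probe: number of contacts, inter-contact
#' spacing and the cortical depth of each contact. Defaults follow a
#' 32-channel, 50-micrometre-spaced single-shank silicon probe spanning a
#' cortical column, with channel 1 most superficial.
#'
#' @param n_channels Number of contacts (at least 5).
#' @param spacing_um Spacing between adjacent contacts in micrometres.
#' @param depth0_um Depth of the first (most superficial) contact.
#' @return A `probe_geometry` object: list with `n_channels`, `spacing_um`
#'   and `depths_um` (strictly increasing with channel index).
#' @export
#' @examples
#' geom <- probe_geometry()
#' geom$depths_um[1:4]
probe_geometry <- function(n_channels = 32, spacing_um = 50, depth0_um = 0) {
  assert_that(is_count(n_channels) && n_channels >= 5,
              "`n_channels` must be an integer >= 5")
  assert_that(is.numeric(spacing_um) && spacing_um > 0, "`spacing_um` must be > 0")
  depths <- depth0_um + (seq_len(n_channels) - 1) * spacing_um
  structure(
    list(n_channels = as.integer(n_channels),
         spacing_um = spacing_um,
         depths_um = depths),
    class = "probe_geometry"
  )
}

#' Go/NoGo session configuration
#'
#' Trial and stimulus timing for one shuttle-box session: 60 trials
#' (30 CS+, 30 CS-), 200 ms pure tones repeated with a 1.5 s inter-stimulus
#' interval inside a 6 s observation window, sampled at 2 kHz. With these
#' defaults four CS presentations fit in the window (onsets 0, 1.7, 3.4 and
#' 5.1 s; trial time zero is the first CS onset).
#'
#' @param n_trials,n_go,n_nogo Trial counts; `n_go + n_nogo` must equal
#'   `n_trials`.
#' @param tone_duration_ms,isi_ms CS duration and inter-stimulus interval.
#' @param observation_window_s Response window length in seconds.
#' @param sampling_rate LFP sampling rate in Hz.
#' @param go_freq_khz,nogo_freq_khz Pure-tone frequencies of the CS+ and CS-.
#' @return A `session_config` object (list).
#' @export
session_config <- function(n_trials = 60, n_go = 30, n_nogo = 30,
                           tone_duration_ms = 200, isi_ms = 1500,
                           observation_window_s = 6, sampling_rate = 2000,
                           go_freq_khz = 1, nogo_freq_khz = 4) {
  assert_that(is_count(n_trials) && is_count(n_go) && is_count(n_nogo),
              "trial counts must be non-negative integers")
  assert_that(n_go + n_nogo == n_trials, "`n_go + n_nogo` must equal `n_trials`")
  assert_that(observation_window_s * 1000 >= tone_duration_ms + isi_ms,
              "observation window must cover at least one tone + ISI")
  assert_that(sampling_rate > 0, "`sampling_rate` must be > 0")
  cfg <- list(n_trials = as.integer(n_trials), n_go = as.integer(n_go),
              n_nogo = as.integer(n_nogo), tone_duration_ms = tone_duration_ms,
              isi_ms = isi_ms, observation_window_s = observation_window_s,
              sampling_rate = sampling_rate, go_freq_khz = go_freq_khz,
              nogo_freq_khz = nogo_freq_khz)
  class(cfg) <- "session_config"
  cfg
}

#' CS onset times of a session configuration
#'
#' @param config A [session_config()].
#' @return Numeric vector of CS onsets in ms from trial start (first CS at 0).
#' @export
cs_onsets_ms <- function(config) {
  period <- config$tone_duration_ms + config$isi_ms
  total <- config$observation_window_s * 1000
  onsets <- seq(0, total - config$tone_duration_ms, by = period)
  onsets[onsets + config$tone_duration_ms <= total]
}

#' Reversal-learning agent parameters
#'
#' A session-level stochastic learner used to emulate hit / false-alarm
#' trajectories across an initial discrimination phase and contingency
#' reversals: rates relax exponentially towards their asymptotes at
#' `learning_rate` per session; at each session listed in
#' `reversal_schedule` the hit rate drops by `perseveration_depth` and the
#' false-alarm rate jumps up by `fa_rise` (perseverative responding under
#' the old rule), after which re-learning resumes.
#'
#' @param initial_hit_rate,initial_fa_rate Session-1 rates (chance-level
#'   defaults).
#' @param asymptote_hit,asymptote_fa Stable late-phase rates.
#' @param learning_rate Fraction of the remaining distance to the asymptote
#'   closed per session, in (0, 1].
#' @param perseveration_depth Post-reversal drop applied to the hit rate.
#' @param fa_rise Post-reversal jump applied to the false-alarm rate.
#' @param reversal_schedule Strictly increasing 1-based session indices at
#'   which the CS contingencies switch.
#' @return An `agent_params` object (list).
#' @export
agent_params <- function(initial_hit_rate = 0.35, initial_fa_rate = 0.35,
                         asymptote_hit = 0.8, asymptote_fa = 0.2,
                         learning_rate = 0.5, perseveration_depth = 0.65,
                         fa_rise = 0.25,
                         reversal_schedule = c(7L, 13L, 19L, 25L)) {
  rates <- c(initial_hit_rate, initial_fa_rate, asymptote_hit, asymptote_fa)
  assert_that(all(rates >= 0 & rates <= 1), "all rates must lie in [0, 1]")
  assert_that(learning_rate >= 0 && learning_rate <= 1,
              "`learning_rate` must lie in [0, 1]")
  assert_that(perseveration_depth >= 0 && perseveration_depth <= 1 &&
                fa_rise >= 0 && fa_rise <= 1,
              "`perseveration_depth` and `fa_rise` must lie in [0, 1]")
  sched <- as.integer(reversal_schedule)
  assert_that(length(sched) == 0 || all(diff(sched) > 0),
              "`reversal_schedule` must be strictly increasing")
  structure(
    list(initial_hit_rate = initial_hit_rate, initial_fa_rate = initial_fa_rate,
         asymptote_hit = asymptote_hit, asymptote_fa = asymptote_fa,
         learning_rate = learning_rate, perseveration_depth = perseveration_depth,
         fa_rise = fa_rise, reversal_schedule = sched),
    class = "agent_params"
  )
}

#' Simulate per-session hit and false-alarm rates
#'
#' Deterministic expected learning curves of the agent model: exponential
#' relaxation towards the asymptotes, interrupted at every scheduled reversal
#' by a perseverative drop in hit rate and rise in false-alarm rate.
#'
#' @param agent An [agent_params()].
#' @param n_sessions Number of sessions to simulate (>= 1).
#' @param seed Integer seed; retained for interface symmetry with the other
#'   generators (the expected-rate model itself is deterministic).
#' @return A tibble with columns `session`, `phase_block` (0 = initial
#'   discrimination, k = k-th reversal), `hit_rate`, `fa_rate`.
#' @export
#' @examples
#' curves <- simulate_learning_curves(agent_params(), n_sessions = 30, seed = 1)
#' head(curves)
simulate_learning_curves <- function(agent, n_sessions, seed = 1L) {
  assert_that(inherits(agent, "agent_params"), "`agent` must be agent_params()")
  assert_that(is_count(n_sessions) && n_sessions >= 1, "`n_sessions` must be >= 1")
  if (length(agent$reversal_schedule) &&
      any(agent$reversal_schedule > n_sessions)) {
    abort("`reversal_schedule` contains an index beyond `n_sessions`")
  }
  hit <- numeric(n_sessions)
  fa <- numeric(n_sessions)
  h <- agent$initial_hit_rate
  f <- agent$initial_fa_rate
  block <- integer(n_sessions)
  b <- 0L
  for (s in seq_len(n_sessions)) {
    if (s %in% agent$reversal_schedule) {
      h <- clamp01(h - agent$perseveration_depth)
      f <- clamp01(f + agent$fa_rise)
      b <- b + 1L
    }
    hit[s] <- h
    fa[s] <- f
    block[s] <- b
    h <- h + agent$learning_rate * (agent$asymptote_hit - h)
    f <- f + agent$learning_rate * (agent$asymptote_fa - f)
  }
  tibble::tibble(session = seq_len(n_sessions), phase_block = block,
                 hit_rate = hit, fa_rate = fa)
}

#' Columnar ground truth for the synthetic recordings
#'
#' Defines what the generator injects into the laminar LFP: a layer map over
#' a contiguous channel block, per-layer tone-evoked dipoles (sink flanked by
#' passive sources, Gaussian in depth and time) and band-limited oscillatory
#' bursts whose power may depend on the trial's behavioral choice, on top of
#' white noise. The default layer map mirrors a canonical auditory cortical
#' column on a 32-channel probe with early granular/infragranular input sinks.
#'
#' @param layer_map Named list mapping layer labels (`I/II`, `III/IV`, `Va`,
#'   `Vb`, `VI`) to contiguous, disjoint, superficial-to-deep channel ranges.
#' @param evoked Data frame with columns `layer`, `latency_ms` (sink onset
#'   delay after each CS onset), `amp_go`, `amp_nogo` (sink amplitudes in
#'   volts at the layer centre).
#' @param burst_specs List of burst descriptors; each a list with `layer`,
#'   `center_hz`, `window_ms` (length-2, relative to each CS onset),
#'   `base_amp` (volts), `gains` (named power multipliers per choice label,
#'   default 1), and `phase_locked` (logical; `FALSE` draws a random phase
#'   per trial).
#' @param noise_sd White-noise standard deviation in volts.
#' @return A `laminar_ground_truth` object (list).
#' @export
laminar_ground_truth <- function(layer_map = default_layer_map(),
                                 evoked = default_evoked_table(),
                                 burst_specs = default_burst_specs(),
                                 noise_sd = 5e-5) {
  validate_layer_map(layer_map)
  assert_that(is.data.frame(evoked) &&
                all(c("layer", "latency_ms", "amp_go", "amp_nogo") %in% names(evoked)),
              "`evoked` needs columns layer, latency_ms, amp_go, amp_nogo")
  assert_that(all(evoked$layer %in% names(layer_map)),
              "`evoked$layer` must appear in `layer_map`")
  bands <- band_table()$band
  for (b in burst_specs) {
    assert_that(all(c("layer", "center_hz", "window_ms", "base_amp") %in% names(b)),
                "each burst spec needs layer, center_hz, window_ms, base_amp")
    assert_that(b$layer %in% names(layer_map), "burst layer must be in layer_map")
    if (!is.null(b$band)) {
      assert_that(b$band %in% bands, "burst band label must be one of the six bands")
    }
  }
  assert_that(is.numeric(noise_sd) && noise_sd >= 0, "`noise_sd` must be >= 0")
  structure(
    list(layer_map = layer_map, evoked = evoked, burst_specs = burst_specs,
         noise_sd = noise_sd),
    class = "laminar_ground_truth"
  )
}

#' @rdname laminar_ground_truth
#' @export
default_layer_map <- function() {
  list("I/II" = 2:6, "III/IV" = 7:12, "Va" = 13:17, "Vb" = 18:24, "VI" = 25:30)
}

#' @rdname laminar_ground_truth
#' @export
default_evoked_table <- function() {
  tibble::tibble(
    layer = c("I/II", "III/IV", "Va", "Vb", "VI"),
    latency_ms = c(28, 14, 22, 12, 18),
    amp_go = c(0.8e-4, 2.0e-4, 1.0e-4, 2.2e-4, 1.4e-4),
    amp_nogo = c(0.8e-4, 2.0e-4, 1.0e-4, 2.2e-4, 1.4e-4)
  )
}

#' @rdname laminar_ground_truth
#' @export
default_burst_specs <- function() {
  list(
    list(layer = "Vb", band = "high_beta", center_hz = 25,
         window_ms = c(50, 350), base_amp = 3e-5, gains = NULL,
         phase_locked = FALSE),
    list(layer = "III/IV", band = "low_gamma", center_hz = 40,
         window_ms = c(50, 300), base_amp = 3e-5, gains = NULL,
         phase_locked = FALSE)
  )
}

validate_layer_map <- function(layer_map) {
  labs <- c("I/II", "III/IV", "Va", "Vb", "VI")
  assert_that(identical(names(layer_map), labs),
              "layer_map must name I/II, III/IV, Va, Vb, VI in order")
  chans <- unlist(layer_map, use.names = FALSE)
  assert_that(!anyDuplicated(chans), "layer ranges must be disjoint")
  for (r in layer_map) {
    assert_that(all(diff(r) == 1), "each layer range must be contiguous")
  }
  assert_that(all(diff(chans) == 1),
              "layer ranges must partition a contiguous channel block, superficial to deep")
  invisible(TRUE)
}

# Gaussian depth profile across channels for a layer: the potential bump whose
# second spatial derivative yields a sink at the layer centre flanked by
# sources. Negative sign so the CSD sign convention (sinks negative) holds.
depth_profile <- function(n_channels, channels) {
  centre <- mean(channels)
  sd_ch <- max(1, (length(channels)) / 2.5)
  -exp(-((seq_len(n_channels) - centre)^2) / (2 * sd_ch^2))
}

gauss_env <- function(t_ms, centre_ms, sd_ms) {
  exp(-((t_ms - centre_ms)^2) / (2 * sd_ms^2))
}

#' Generate one synthetic session (recording + trial table)
#'
#' Draws per-trial choices from the supplied session-level hit / false-alarm
#' rates (independent Bernoulli per trial), then builds the laminar LFP:
#' for each CS presentation every layer receives its evoked dipole (Gaussian
#' depth bump whose second spatial derivative is a sink flanked by balancing
#' sources, so the injected current sums to ~0 across depth), plus the
#' configured band-limited bursts, on white noise. Reaction times on response
#' trials are uniform on \[0.3 s, observation window\].
#'
#' @param config A [session_config()].
#' @param rates Length-2 numeric `c(hit_rate, fa_rate)` or a one-row data
#'   frame with `hit_rate` / `fa_rate` columns.
#' @param truth A [laminar_ground_truth()].
#' @param geometry A [probe_geometry()].
#' @param seed Integer seed; identical seeds give identical output.
#' @param session_id Label stored in the trial table.
#' @return A list with `recording` (a `laminar_recording`) and `trials`
#'   (tibble: trial_id, session_id, cs_type, responded, choice,
#'   reaction_time_s, cs_onsets_ms).
#' @export
#' @examples
#' sess <- generate_session(session_config(), c(0.8, 0.2),
#'                          laminar_ground_truth(), probe_geometry(), seed = 7)
#' dim(sess$recording$lfp)
#' table(sess$trials$cs_type)
generate_session <- function(config, rates, truth, geometry, seed,
                             session_id = 1L) {
  assert_that(inherits(config, "session_config"), "`config` must be session_config()")
  assert_that(inherits(truth, "laminar_ground_truth"),
              "`truth` must be laminar_ground_truth()")
  assert_that(inherits(geometry, "probe_geometry"), "`geometry` must be probe_geometry()")
  if (is.data.frame(rates)) rates <- c(rates$hit_rate[1], rates$fa_rate[1])
  assert_that(is.numeric(rates) && length(rates) == 2, "`rates` must be c(hit, fa)")
  if (any(rates < 0 | rates > 1)) abort("rates must lie in [0, 1]")
  assert_that(max(unlist(truth$layer_map)) <= geometry$n_channels,
              "layer_map exceeds probe channels")

  fs <- config$sampling_rate
  ns <- round(config$observation_window_s * fs)
  t_ms <- (seq_len(ns) - 1) / fs * 1000
  onsets <- cs_onsets_ms(config)
  nch <- geometry$n_channels
  ntr <- config$n_trials

  with_seed(seed, {
    cs_type <- sample(rep(c("go", "nogo"), times = c(config$n_go, config$n_nogo)))
    responded <- ifelse(cs_type == "go",
                        rbinom(ntr, 1, rates[1]) == 1,
                        rbinom(ntr, 1, rates[2]) == 1)
    choice <- mapply(classify_choice,
                     ifelse(cs_type == "go", "CS+", "CS-"), responded)
    rt <- ifelse(responded,
                 runif(ntr, 0.3, config$observation_window_s), NA_real_)

    lfp <- array(0, dim = c(nch, ns, ntr))
    if (truth$noise_sd > 0) {
      lfp[] <- rnorm(nch * ns * ntr, sd = truth$noise_sd)
    }
    profiles <- lapply(truth$layer_map, function(r) depth_profile(nch, r))
    for (tr in seq_len(ntr)) {
      sig <- matrix(0, nch, ns)
      amp_col <- if (cs_type[tr] == "go") "amp_go" else "amp_nogo"
      for (k in seq_len(nrow(truth$evoked))) {
        lay <- truth$evoked$layer[k]
        amp <- truth$evoked[[amp_col]][k]
        if (amp == 0) next
        env <- numeric(ns)
        for (on in onsets) {
          env <- env + gauss_env(t_ms, on + truth$evoked$latency_ms[k] + 20, 15)
        }
        sig <- sig + amp * tcrossprod(profiles[[lay]], env)
      }
      for (b in truth$burst_specs) {
        gain <- 1
        if (!is.null(b$gains) && choice[tr] %in% names(b$gains)) {
          gain <- b$gains[[choice[tr]]]
        }
        amp <- b$base_amp * sqrt(gain)
        if (amp == 0) next
        phase <- if (isTRUE(b$phase_locked)) 0 else runif(1, 0, 2 * pi)
        carrier <- numeric(ns)
        for (on in onsets) {
          centre <- on + mean(b$window_ms)
          sd_ms <- diff(range(b$window_ms)) / 4
          carrier <- carrier +
            gauss_env(t_ms, centre, sd_ms) *
            sin(2 * pi * b$center_hz * (t_ms - on) / 1000 + phase)
        }
        sig <- sig + amp * tcrossprod(profiles[[b$layer]], carrier)
      }
      lfp[, , tr] <- lfp[, , tr] + sig
    }

    trials <- tibble::tibble(
      trial_id = seq_len(ntr),
      session_id = session_id,
      cs_type = cs_type,
      responded = responded,
      choice = unname(choice),
      reaction_time_s = rt,
      cs_onsets_ms = paste(onsets, collapse = ";")
    )
    rec <- new_laminar_recording(lfp, fs, geometry, t_ms,
                                 layer_map = truth$layer_map)
    list(recording = rec, trials = trials)
  })
}

#' Inject artifacts into a recording
#'
#' Adds controlled positives for the preprocessing screens: channel-gain
#' events (a channel scaled on chosen trials, as a noisy contact would be)
#' and shock-like clipping blocks (all channels saturated to a constant rail
#' over a time range of one trial).
#'
#' @param recording A `laminar_recording`.
#' @param spec List of events. A gain event:
#'   `list(type = "scale", channel =, factor =, trials = NULL)` (all trials if
#'   `NULL`). A clipping event:
#'   `list(type = "clip", trial =, t_range_ms = c(a, b), level = 5e-3)`.
#' @param seed Integer seed (reserved; current events are deterministic).
#' @return The modified recording, with an `artifact_log` tibble attached
#'   listing every injected event.
#' @export
inject_artifacts <- function(recording, spec, seed = 1L) {
  assert_that(inherits(recording, "laminar_recording"),
              "`recording` must be a laminar_recording")
  lfp <- recording$lfp
  nch <- dim(lfp)[1]
  ntr <- dim(lfp)[3]
  log <- list()
  for (ev in spec) {
    type <- ev$type %||% abort("artifact event needs a `type`")
    if (type == "scale") {
      ch <- ev$channel
      assert_that(is_count(ch) && ch >= 1 && ch <= nch,
                  "unknown channel in artifact spec")
      trs <- ev$trials %||% seq_len(ntr)
      assert_that(all(trs >= 1 & trs <= ntr), "unknown trial in artifact spec")
      lfp[ch, , trs] <- lfp[ch, , trs] * ev$factor
      log[[length(log) + 1]] <- tibble::tibble(
        type = "scale", channel = as.integer(ch),
        trial = NA_integer_, t0_ms = NA_real_, t1_ms = NA_real_,
        value = ev$factor)
    } else if (type == "clip") {
      tr <- ev$trial
      assert_that(is_count(tr) && tr >= 1 && tr <= ntr,
                  "unknown trial in artifact spec")
      level <- ev$level %||% 5e-3
      idx <- which(recording$time_ms >= ev$t_range_ms[1] &
                     recording$time_ms < ev$t_range_ms[2])
      assert_that(length(idx) > 0, "clip range outside recording")
      lfp[, idx, tr] <- level
      log[[length(log) + 1]] <- tibble::tibble(
        type = "clip", channel = NA_integer_, trial = as.integer(tr),
        t0_ms = ev$t_range_ms[1], t1_ms = ev$t_range_ms[2], value = level)
    } else {
      abort(paste0("unknown artifact type: ", type))
    }
  }
  recording$lfp <- lfp
  recording$artifact_log <- if (length(log)) dplyr::bind_rows(log) else
    tibble::tibble(type = character(), channel = integer(), trial = integer(),
                   t0_ms = numeric(), t1_ms = numeric(), value = numeric())
  recording
}

#' Simulate a multi-session experiment
#'
#' Convenience wrapper: runs the learning-curve agent, then generates one
#' recording + trial table per session at that session's rates.
#'
#' @param agent An [agent_params()].
#' @param n_sessions Number of sessions.
#' @param config,truth,geometry Passed to [generate_session()].
#' @param seed Integer master seed; per-session seeds are derived from it.
#' @return List with `curves` (tibble) and `sessions` (list of
#'   [generate_session()] results).
#' @export
simulate_experiment <- function(agent = agent_params(), n_sessions = 6,
                                config = session_config(),
                                truth = laminar_ground_truth(),
                                geometry = probe_geometry(), seed = 1L) {
  curves <- simulate_learning_curves(agent, n_sessions, seed)
  sessions <- lapply(seq_len(n_sessions), function(s) {
    generate_session(config, c(curves$hit_rate[s], curves$fa_rate[s]),
                     truth, geometry,
                     seed = child_seed(seed, paste0("session", s)),
                     session_id = s)
  })
  list(curves = curves, sessions = sessions)
}
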