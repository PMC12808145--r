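#' Laminar recording container
#'
#' Channels x samples x trials voltage array with probe geometry, sampling
#' rate and bookkeeping for screened channels and masked (clipped) segments.
#'
#' @param lfp 3-D numeric array `[channels, samples, trials]` in volts.
#' @param sampling_rate Hz.
#' @param geometry A [probe_geometry()].
#' @param time_ms Sample times in ms (trial time zero at the first CS onset).
#' @param layer_map Optional layer -> channel map carried from the generator.
#' @param bad_channels Integer channel indices flagged by screening.
#' @param clip_mask Optional logical `[samples, trials]` matrix of masked
#'   samples.
#' @return A `laminar_recording` object.
#' @export
new_laminar_recording <- function(lfp, sampling_rate, geometry,
                                  time_ms = NULL, layer_map = NULL,
                                  bad_channels = integer(0),
                                  clip_mask = NULL) {
  assert_that(is.array(lfp) && length(dim(lfp)) == 3,
              "`lfp` must be a channels x samples x trials array")
  assert_that(dim(lfp)[1] == geometry$n_channels,
              "`lfp` channel count must match geometry")
  if (is.null(time_ms)) time_ms <- (seq_len(dim(lfp)[2]) - 1) / sampling_rate * 1000
  assert_that(length(time_ms) == dim(lfp)[2], "`time_ms` length mismatch")
  assert_that(all(bad_channels %in% seq_len(dim(lfp)[1])),
              "`bad_channels` must be valid channel indices")
  structure(
    list(lfp = lfp, sampling_rate = sampling_rate, geometry = geometry,
         time_ms = time_ms, layer_map = layer_map,
         bad_channels = as.integer(bad_channels), clip_mask = clip_mask),
    class = "laminar_recording"
  )
}

#' @export
print.laminar_recording <- function(x, ...) {
  d <- dim(x$lfp)
  cat(sprintf("<laminar_recording> %d channels x %d samples x %d trials @ %g Hz\n",
              d[1], d[2], d[3], x$sampling_rate))
  if (length(x$bad_channels)) {
    cat("  bad channels:", paste(x$bad_channels, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Screen channels for excessive amplitude
#'
#' For each channel the per-trial peak-to-peak amplitude is reduced to its
#' median across trials; channels whose statistic exceeds (strictly) the
#' across-channel mean plus `k` standard deviations of that statistic are
#' flagged as bad.
#'
#' @param recording A `laminar_recording` (at least 2 trials).
#' @param k SD multiplier (default 3).
#' @return Integer vector of flagged channel indices (possibly empty).
#' @export
detect_bad_channels <- function(recording, k = 3) {
  assert_that(inherits(recording, "laminar_recording"),
              "`recording` must be a laminar_recording")
  d <- dim(recording$lfp)
  if (d[3] < 2) abort("bad-channel screening needs at least 2 trials")
  # peak-to-peak per channel x trial
  ptp <- apply(recording$lfp, c(1, 3), function(v) diff(range(v)))
  stat <- apply(ptp, 1, median)
  thr <- mean(stat) + k * sd(stat)
  which(stat > thr)
}

#' Replace bad channels by depth-linear interpolation
#'
#' Each flagged channel is replaced, per sample and trial, by linear
#' interpolation in depth between its nearest good neighbours; a flagged
#' channel with good neighbours on one side only receives a copy of the
#' nearest good channel. Good channels are untouched.
#'
#' @param recording A `laminar_recording`.
#' @param bad Integer channel indices (default: `recording$bad_channels`).
#' @return The recording with interpolated channels and `bad_channels`
#'   updated.
#' @export
interpolate_channels <- function(recording, bad = recording$bad_channels) {
  assert_that(inherits(recording, "laminar_recording"),
              "`recording` must be a laminar_recording")
  nch <- dim(recording$lfp)[1]
  bad <- sort(unique(as.integer(bad)))
  if (length(bad) == 0) return(recording)
  assert_that(all(bad %in% seq_len(nch)), "`bad` contains unknown channels")
  good <- setdiff(seq_len(nch), bad)
  if (length(good) == 0) abort("all channels flagged bad; nothing to interpolate from")
  depths <- recording$geometry$depths_um
  # interpolation weights depend only on depth: precompute per bad channel
  lfp <- recording$lfp
  for (b in bad) {
    below <- good[good < b]
    above <- good[good > b]
    if (length(below) && length(above)) {
      lo <- max(below); hi <- min(above)
      w <- (depths[b] - depths[lo]) / (depths[hi] - depths[lo])
      lfp[b, , ] <- (1 - w) * lfp[lo, , ] + w * lfp[hi, , ]
    } else if (length(below)) {
      lfp[b, , ] <- lfp[max(below), , ]
    } else {
      lfp[b, , ] <- lfp[min(above), , ]
    }
  }
  recording$lfp <- lfp
  recording$bad_channels <- bad
  recording
}

#' Detect shock-induced clipping
#'
#' Saturated segments show as flat runs pinned at a rail value across many
#' channels. A sample is flagged when, on at least `min_frac` of channels,
#' the signal equals its previous sample exactly and its magnitude exceeds
#' `level_thr`.
#'
#' @param recording A `laminar_recording`.
#' @param level_thr Rail magnitude threshold in volts (default 10x the
#'   robust signal SD).
#' @param min_frac Minimum fraction of simultaneously pinned channels.
#' @return Logical `[samples, trials]` mask of clipped samples.
#' @export
detect_clipping <- function(recording, level_thr = NULL, min_frac = 0.25) {
  assert_that(inherits(recording, "laminar_recording"),
              "`recording` must be a laminar_recording")
  lfp <- recording$lfp
  d <- dim(lfp)
  if (is.null(level_thr)) {
    level_thr <- 10 * median(abs(lfp[, , 1] - median(lfp[, , 1]))) / 0.6745
    if (level_thr == 0) level_thr <- .Machine$double.eps
  }
  mask <- matrix(FALSE, d[2], d[3])
  for (tr in seq_len(d[3])) {
    x <- lfp[, , tr]
    flat <- cbind(FALSE, x[, -1, drop = FALSE] == x[, -d[2], drop = FALSE])
    pinned <- flat & abs(x) > level_thr
    frac <- colMeans(pinned)
    hit <- frac >= min_frac
    # include the first sample of each flat run
    mask[, tr] <- hit | c(hit[-1], FALSE)
  }
  mask
}

#' Mask clipped segments
#'
#' Attaches a clipping mask to the recording. Masked samples are excluded
#' from all downstream feature windows: [rms_features()] drops any trial
#' window that intersects the mask.
#'
#' @param recording A `laminar_recording`.
#' @param events Optional tibble/data.frame with `trial`, `t0_ms`, `t1_ms`
#'   giving known shock times; if `NULL`, clipping is auto-detected with
#'   [detect_clipping()].
#' @return The recording with `clip_mask` set (logical samples x trials).
#' @export
remove_clipping <- function(recording, events = NULL) {
  assert_that(inherits(recording, "laminar_recording"),
              "`recording` must be a laminar_recording")
  d <- dim(recording$lfp)
  if (is.null(events)) {
    mask <- detect_clipping(recording)
  } else {
    mask <- matrix(FALSE, d[2], d[3])
    for (i in seq_len(nrow(events))) {
      idx <- which(recording$time_ms >= events$t0_ms[i] &
                     recording$time_ms < events$t1_ms[i])
      mask[idx, events$trial[i]] <- TRUE
    }
  }
  if (!is.null(recording$clip_mask)) mask <- mask | recording$clip_mask
  recording$clip_mask <- mask
  recording
}

#' CSD computation settings
#'
#' @param diff_grid_n Differentiation grid `n` of the second spatial
#'   difference (channels; default 1).
#' @param smooth_len Hamming-kernel length in channels (odd; default 9,
#'   i.e. ~400 um at 50 um spacing). `1` disables smoothing.
#' @param boundary Edge policy for the spatial smoother: `"reflect"`
#'   (default, conserves the depth sum) or `"zero"`.
#' @param vaknin If `TRUE`, pad the LFP by duplicating the edge channels
#'   before differencing so no channels are trimmed; default `FALSE`
#'   (edge channels trimmed).
#' @return A `csd_config` object.
#' @export
csd_config <- function(diff_grid_n = 1, smooth_len = 9,
                       boundary = c("reflect", "zero"), vaknin = FALSE) {
  assert_that(is_count(diff_grid_n) && diff_grid_n >= 1, "`diff_grid_n` must be >= 1")
  assert_that(is_count(smooth_len) && smooth_len %% 2 == 1,
              "`smooth_len` must be odd")
  boundary <- match.arg(boundary)
  structure(list(diff_grid_n = as.integer(diff_grid_n),
                 smooth_len = as.integer(smooth_len),
                 boundary = boundary, vaknin = isTRUE(vaknin)),
            class = "csd_config")
}

hamming_window <- function(n) {
  if (n == 1) return(1)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  w / sum(w)
}

#' Spatial Hamming smoothing of an LFP profile
#'
#' Depth-convolution of each sample/trial with a unit-sum Hamming window
#' (default 9 channels). Under the `reflect` boundary the depth sum of the
#' profile is conserved.
#'
#' @param lfp `laminar_recording`, 3-D array or channels x samples matrix.
#' @param config A [csd_config()] (only `smooth_len` and `boundary` used).
#' @return Same shape as the input.
#' @export
spatial_smooth <- function(lfp, config = csd_config()) {
  if (inherits(lfp, "laminar_recording")) {
    lfp$lfp <- spatial_smooth(lfp$lfp, config)
    return(lfp)
  }
  n <- config$smooth_len
  if (n == 1) return(lfp)
  dm <- dim(lfp)
  nch <- dm[1]
  assert_that(n <= nch, "`smooth_len` exceeds channel count")
  h <- n %/% 2
  w <- hamming_window(n)
  # weight matrix W: out[i] = sum_j W[i, j] * in[j], boundary folded in
  W <- matrix(0, nch, nch)
  for (i in seq_len(nch)) {
    for (k in -h:h) {
      j <- i + k
      # half-sample reflection (edge included) keeps the depth sum exact
      if (j < 1) {
        j <- if (config$boundary == "reflect") 1 - j else NA
      } else if (j > nch) {
        j <- if (config$boundary == "reflect") 2 * nch + 1 - j else NA
      }
      if (!is.na(j)) W[i, j] <- W[i, j] + w[k + h + 1]
    }
  }
  if (length(dm) == 2) {
    W %*% lfp
  } else {
    array(W %*% matrix(lfp, dm[1]), dim = dm)
  }
}

#' Current source density from laminar LFP
#'
#' The CSD is estimated as the negative second spatial difference of the
#' (optionally depth-smoothed) field potential:
#' `CSD(z) = -[Phi(z + n dz) - 2 Phi(z) + Phi(z - n dz)] / (n dz)^2`,
#' so that current sinks (net inward transmembrane current) are negative.
#' Smoothing is applied to the LFP before differencing. Edge channels that
#' lack both neighbours are trimmed unless `config$vaknin` pads them.
#'
#' @param lfp A `laminar_recording` or 3-D array.
#' @param geometry A [probe_geometry()] (taken from the recording if
#'   omitted).
#' @param config A [csd_config()].
#' @return A `csd_profile` object: list with `csd`
#'   `[valid channels, samples, trials]` in V/mm^2, `valid_channels`
#'   (indices into the original channel numbering), `time_ms`,
#'   `sampling_rate`, `layer_map`, `clip_mask`.
#' @export
compute_csd <- function(lfp, geometry = NULL, config = csd_config()) {
  time_ms <- NULL; fs <- NA_real_; layer_map <- NULL; clip_mask <- NULL
  if (inherits(lfp, "laminar_recording")) {
    geometry <- geometry %||% lfp$geometry
    time_ms <- lfp$time_ms
    fs <- lfp$sampling_rate
    layer_map <- lfp$layer_map
    clip_mask <- lfp$clip_mask
    lfp <- lfp$lfp
  }
  assert_that(!is.null(geometry), "`geometry` required when `lfp` is an array")
  dm <- dim(lfp)
  n <- config$diff_grid_n
  assert_that(dm[1] >= 2 * n + 1,
              "need at least 2*diff_grid_n + 1 channels for the second difference")
  sm <- spatial_smooth(lfp, config)
  if (config$vaknin) {
    # duplicate edge channels so all original channels stay valid
    tmp <- array(0, dim = c(dm[1] + 2 * n, dm[2], dm[3]))
    tmp[n + seq_len(dm[1]), , ] <- sm
    for (k in seq_len(n)) {
      tmp[k, , ] <- sm[1, , ]
      tmp[dm[1] + n + k, , ] <- sm[dm[1], , ]
    }
    sm <- tmp
    valid <- seq_len(dm[1])
    offset <- n
  } else {
    valid <- (1 + n):(dm[1] - n)
    offset <- 0
  }
  dz_mm <- geometry$spacing_um / 1000
  denom <- (n * dz_mm)^2
  nv <- length(valid)
  # second spatial difference as one matrix product over flattened samples
  smM <- matrix(sm, dim(sm)[1])
  z <- valid + offset
  csd <- array(-(smM[z + n, , drop = FALSE] - 2 * smM[z, , drop = FALSE] +
                   smM[z - n, , drop = FALSE]) / denom,
               dim = c(nv, dm[2], dm[3]))
  structure(
    list(csd = csd, valid_channels = valid, time_ms = time_ms,
         sampling_rate = fs, layer_map = layer_map, clip_mask = clip_mask,
         geometry = geometry, config = config),
    class = "csd_profile"
  )
}

#' Averaged rectified CSD (AVREC)
#'
#' `AVREC(t) = sum_i |CSD_i(t)| / n` over the valid channels: a non-negative
#' scalar trace of overall columnar current flow, per trial.
#'
#' @param csd A `csd_profile` or a channels x samples (x trials) array.
#' @return Samples x trials matrix (or vector for one trial).
#' @export
compute_avrec <- function(csd) {
  x <- if (inherits(csd, "csd_profile")) csd$csd else csd
  if (is.matrix(x)) return(colMeans(abs(x)))
  apply(abs(x), c(2, 3), mean)
}

#' Assign cortical layers to channels
#'
#' Either passes through an explicit layer -> channel map (validated), or
#' anchors the map automatically on the earliest-sink channel of the
#' trial-averaged CSD: the channel whose sink first crosses a fraction of
#' the global minimum is taken as the granular/infragranular input anchor
#' and the template map is shifted so its `III/IV`--`Vb` input block centres
#' there.
#'
#' @param csd A `csd_profile`.
#' @param anchors Either a named list (explicit map, returned after
#'   validation) or `NULL` for automatic anchoring.
#' @param template Template map used for automatic anchoring
#'   (default [default_layer_map()]).
#' @return Named list of contiguous, disjoint channel ranges ordered
#'   I/II, III/IV, Va, Vb, VI.
#' @export
assign_layers <- function(csd, anchors = NULL, template = default_layer_map()) {
  if (is.list(anchors) && !is.null(names(anchors))) {
    validate_layer_map(anchors)
    return(anchors)
  }
  assert_that(inherits(csd, "csd_profile"), "`csd` must be a csd_profile")
  avg <- apply(csd$csd, c(1, 2), mean)      # channels x samples, trial mean
  peak <- min(avg)
  assert_that(peak < 0, "no sink found in the averaged CSD")
  thr <- 0.5 * peak
  onset <- apply(avg, 1, function(v) {
    i <- which(v <= thr)
    if (length(i)) i[1] else Inf
  })
  anchor_valid <- which.min(onset)
  anchor <- csd$valid_channels[anchor_valid]
  # centre of the template's input block (III/IV union Vb)
  input_centre <- round(mean(c(template[["III/IV"]], template[["Vb"]])))
  shift <- anchor - input_centre
  shifted <- lapply(template, function(r) r + shift)
  lo <- min(unlist(shifted)); hi <- max(unlist(shifted))
  rng <- range(csd$valid_channels)
  if (lo < rng[1]) shifted <- lapply(shifted, function(r) r + (rng[1] - lo))
  if (hi > rng[2]) shifted <- lapply(shifted, function(r) r - (hi - rng[2]))
  validate_layer_map(shifted)
  shifted
}

#' Windowed RMS features per layer and AVREC
#'
#' Root-mean-square of the layer-representative CSD trace (depth mean of
#' the layer's valid channels) and of the AVREC, in half-open 500 ms windows
#' `[onset, onset + 500 ms)` anchored at CS onsets. Anchors:
#' `"each_cs"` (one feature per CS position), `"cs4"` (the 4th CS only) and
#' `"pre_reaction"` (the last CS starting before the reaction time).
#' CS presentations after a conditioned response are excluded, as the CS
#' ends at the response; trials whose window intersects the clipping mask
#' or falls outside the recording are dropped (counted in the
#' `excluded` attribute). z-scores are computed per session x layer x CS
#' position across trials.
#'
#' @param csd A `csd_profile` (with `layer_map`; see [assign_layers()]).
#' @param trials Trial table from [generate_session()].
#' @param window_anchor `"each_cs"`, `"cs4"` or `"pre_reaction"`.
#' @param window_ms Window length (default 500).
#' @param layer_map Override the profile's layer map.
#' @return Tibble: trial_id, session_id, choice, cs_type, cs_position,
#'   layer (five layers plus `"AVREC"`), anchor, rms, z; attribute
#'   `excluded` tabulates dropped windows by rule.
#' @export
rms_features <- function(csd, trials,
                         window_anchor = c("each_cs", "cs4", "pre_reaction"),
                         window_ms = 500, layer_map = NULL) {
  assert_that(inherits(csd, "csd_profile"), "`csd` must be a csd_profile")
  window_anchor <- match.arg(window_anchor)
  layer_map <- layer_map %||% csd$layer_map
  assert_that(!is.null(layer_map), "no layer map available; run assign_layers()")
  validate_layer_map(layer_map)
  fs <- csd$sampling_rate
  t_ms <- csd$time_ms
  nsamp <- dim(csd$csd)[2]
  wlen <- round(window_ms / 1000 * fs)

  # layer-representative traces: depth means over valid channels per layer
  idx_of <- function(chs) which(csd$valid_channels %in% chs)
  layer_idx <- lapply(layer_map, idx_of)
  assert_that(all(lengths(layer_idx) > 0), "a layer has no valid CSD channels")

  onsets_all <- strsplit(trials$cs_onsets_ms[1], ";")[[1]] |> as.numeric()
  excl <- c(after_response = 0L, clipped = 0L, out_of_range = 0L,
            no_anchor = 0L)
  rows <- list()
  for (i in seq_len(nrow(trials))) {
    tr <- trials$trial_id[i]
    rt_ms <- trials$reaction_time_s[i] * 1000
    onsets <- as.numeric(strsplit(trials$cs_onsets_ms[i], ";")[[1]])
    pos_use <- switch(window_anchor,
      each_cs = seq_along(onsets),
      cs4 = if (length(onsets) >= 4) 4L else integer(0),
      pre_reaction = {
        if (is.na(rt_ms)) length(onsets) else {
          cand <- which(onsets < rt_ms)
          if (length(cand)) max(cand) else integer(0)
        }
      })
    if (length(pos_use) == 0) {
      excl["no_anchor"] <- excl["no_anchor"] + 1L
      next
    }
    for (p in pos_use) {
      on <- onsets[p]
      # CS presentations at/after the response never happened: exclude
      if (window_anchor != "pre_reaction" && !is.na(rt_ms) && on >= rt_ms) {
        excl["after_response"] <- excl["after_response"] + 1L
        next
      }
      i0 <- which(t_ms >= on)[1]
      if (is.na(i0) || i0 + wlen - 1 > nsamp) {
        excl["out_of_range"] <- excl["out_of_range"] + 1L
        next
      }
      win <- i0:(i0 + wlen - 1)
      if (!is.null(csd$clip_mask) && any(csd$clip_mask[win, tr])) {
        excl["clipped"] <- excl["clipped"] + 1L
        next
      }
      seg <- csd$csd[, win, tr]
      vals <- vapply(layer_idx, function(ix) {
        v <- colMeans(seg[ix, , drop = FALSE])
        sqrt(mean(v^2))
      }, numeric(1))
      av <- colMeans(abs(seg))
      rows[[length(rows) + 1]] <- tibble::tibble(
        trial_id = tr,
        session_id = trials$session_id[i],
        choice = trials$choice[i],
        cs_type = trials$cs_type[i],
        cs_position = p,
        layer = c(names(layer_map), "AVREC"),
        anchor = window_anchor,
        rms = unname(c(vals, sqrt(mean(av^2))))
      )
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(trial_id = integer(), session_id = integer(),
                   choice = character(), cs_type = character(),
                   cs_position = integer(), layer = character(),
                   anchor = character(), rms = numeric())
  out <- out |>
    dplyr::group_by(.data$session_id, .data$layer, .data$cs_position) |>
    dplyr::mutate(z = z_norm(.data$rms)) |>
    dplyr::ungroup()
  attr(out, "excluded") <- excl
  out
}

# z-score that tolerates degenerate groups (constant or singleton -> 0)
z_norm <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}
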