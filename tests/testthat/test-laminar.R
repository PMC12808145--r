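make_rec <- function(lfp, spacing_um = 50) {
  g <- probe_geometry(n_channels = dim(lfp)[1], spacing_um = spacing_um)
  new_laminar_recording(lfp, sampling_rate = 2000, geometry = g)
}

test_that("bad-channel screen flags outliers, not homogeneous channels", {
  set.seed(1)
  lfp <- array(rnorm(16 * 200 * 8), dim = c(16, 200, 8))
  rec <- make_rec(lfp)
  expect_length(detect_bad_channels(rec), 0)
  lfp2 <- lfp
  lfp2[5, , ] <- lfp2[5, , ] * 10
  expect_identical(detect_bad_channels(make_rec(lfp2)), 5L)
  expect_error(detect_bad_channels(make_rec(lfp[, , 1, drop = FALSE])),
               "2 trials")
})

test_that("a channel exactly at the screening threshold is not flagged", {
  # channels carry pure sinusoids, so peak-to-peak is exact; choose the last
  # amplitude so its stat equals mean + 3 sd of all stats exactly (needs
  # enough channels: one outlier among n can only reach z = (n-1)/sqrt(n))
  set.seed(11)
  base <- 1 + round(rnorm(15, sd = 0.05), 3)
  f <- function(x) {
    a <- c(base, x)
    x - mean(a) - 3 * sd(a)
  }
  x_star <- uniroot(f, c(1, 500), tol = 1e-14)$root
  a <- c(base, x_star)
  t_axis <- seq_len(400)
  lfp <- array(0, dim = c(16, 400, 4))
  for (ch in 1:16) lfp[ch, , ] <- a[ch] * sin(2 * pi * 5 * t_axis / 400)
  rec <- make_rec(lfp)
  expect_length(detect_bad_channels(rec), 0)   # strict >
  lfp[16, , ] <- (x_star * (1 + 1e-9)) * sin(2 * pi * 5 * t_axis / 400)
  expect_identical(detect_bad_channels(make_rec(lfp)), 16L)
})

test_that("interpolation is depth-linear between nearest good channels", {
  lfp <- array(0, dim = c(8, 10, 2))
  for (ch in 1:8) lfp[ch, , ] <- ch
  rec <- make_rec(lfp)
  expect_identical(interpolate_channels(rec, integer(0))$lfp, lfp)
  # single bad channel between 1.0 and 3.0
  lfp2 <- lfp
  lfp2[3, , ] <- 1; lfp2[5, , ] <- 3; lfp2[4, , ] <- 99
  out <- interpolate_channels(make_rec(lfp2), 4)
  expect_equal(unique(as.numeric(out$lfp[4, , ])), 2)
  # two adjacent bad channels between 0 and 3 -> 1 and 2
  lfp3 <- lfp
  lfp3[2, , ] <- 0; lfp3[5, , ] <- 3; lfp3[3, , ] <- 99; lfp3[4, , ] <- -99
  out3 <- interpolate_channels(make_rec(lfp3), c(3, 4))
  expect_equal(unique(as.numeric(out3$lfp[3, , ])), 1)
  expect_equal(unique(as.numeric(out3$lfp[4, , ])), 2)
  # good channels untouched
  expect_identical(out3$lfp[c(1, 2, 5:8), , ], lfp3[c(1, 2, 5:8), , ])
  expect_error(interpolate_channels(make_rec(lfp), 1:8), "all channels")
})

test_that("spatial smoothing preserves constants, impulses map to the kernel", {
  lfp <- array(2.5, dim = c(16, 5, 2))
  expect_equal(spatial_smooth(lfp, csd_config()), lfp, tolerance = 1e-12)
  # unit impulse at a middle channel reproduces the normalized Hamming taps
  imp <- array(0, dim = c(16, 1, 1))
  imp[8, 1, 1] <- 1
  sm <- spatial_smooth(imp, csd_config())
  w <- lamcsd:::hamming_window(9)
  expect_equal(as.numeric(sm[4:12, 1, 1]), rev(w), tolerance = 1e-12)
  expect_equal(sum(sm), 1, tolerance = 1e-12)
  # smooth_len 1 is the identity; even lengths are rejected
  x <- array(rnorm(16 * 5 * 2), dim = c(16, 5, 2))
  expect_identical(spatial_smooth(x, csd_config(smooth_len = 1)), x)
  expect_error(csd_config(smooth_len = 8), "odd")
})

test_that("reflect-boundary smoothing conserves the depth sum", {
  set.seed(2)
  x <- array(rnorm(32 * 20 * 3), dim = c(32, 20, 3))
  sm <- spatial_smooth(x, csd_config(boundary = "reflect"))
  expect_lt(max(abs(apply(sm, c(2, 3), sum) - apply(x, c(2, 3), sum))), 1e-9)
})

test_that("the CSD second difference is exact on polynomial depth profiles", {
  g <- probe_geometry(n_channels = 8, spacing_um = 1000)  # dz = 1 mm
  lin <- array(rep(2 * (0:7) + 3, 6), dim = c(8, 3, 2))
  csd_lin <- compute_csd(lin, g, csd_config(smooth_len = 1))
  expect_equal(max(abs(csd_lin$csd)), 0)
  expect_identical(csd_lin$valid_channels, 2:7)
  quad <- array(rep((0:7)^2, 6), dim = c(8, 3, 2))
  csd_quad <- compute_csd(quad, g, csd_config(smooth_len = 1))
  # second difference of z^2 is 2; sign convention flips it
  expect_equal(unique(as.numeric(csd_quad$csd)), -2, tolerance = 1e-12)
  expect_error(compute_csd(quad[1:2, , , drop = FALSE], probe_geometry(5),
                           csd_config(smooth_len = 1)), "channel")
})

test_that("the CSD operator is linear", {
  set.seed(3)
  g <- probe_geometry(n_channels = 12)
  x <- array(rnorm(12 * 30 * 2), dim = c(12, 30, 2))
  y <- array(rnorm(12 * 30 * 2), dim = c(12, 30, 2))
  cfg <- csd_config()
  cx <- compute_csd(x, g, cfg)$csd
  cy <- compute_csd(y, g, cfg)$csd
  cxy <- compute_csd(2 * x + 5 * y, g, cfg)$csd
  expect_equal(cxy, 2 * cx + 5 * cy, tolerance = 1e-9)
})

test_that("noiseless sinks are recovered at the injected input layers", {
  truth <- quiet_truth(noise_sd = 0)
  sess <- generate_session(tiny_config(n_trials = 4), c(1, 0), truth,
                           probe_geometry(), seed = 3)
  csd <- compute_csd(sess$recording)
  avg <- apply(csd$csd, c(1, 2), mean)
  sink_ch <- csd$valid_channels[which(avg == min(avg), arr.ind = TRUE)[1]]
  input_block <- c(default_layer_map()[["III/IV"]],
                   default_layer_map()[["Vb"]])
  expect_true(sink_ch %in% input_block)
})

test_that("AVREC is the mean absolute CSD", {
  expect_equal(compute_avrec(matrix(0, 4, 6)), rep(0, 6))
  expect_equal(compute_avrec(matrix(c(1, -1), 2, 5)), rep(1, 5))
  set.seed(4)
  x <- array(rnorm(5 * 7 * 3), dim = c(5, 7, 3))
  av <- compute_avrec(x)
  for (tr in 1:3) {
    for (s in 1:7) expect_equal(av[s, tr], mean(abs(x[, s, tr])))
  }
})

test_that("layer assignment passes explicit maps through and anchors sinks", {
  truth <- quiet_truth(noise_sd = 0)
  sess <- generate_session(tiny_config(n_trials = 4), c(1, 0), truth,
                           probe_geometry(), seed = 5)
  csd <- compute_csd(sess$recording)
  expect_identical(assign_layers(csd, anchors = default_layer_map()),
                   default_layer_map())
  auto <- assign_layers(csd)
  # automatic anchoring must land the input block on the injected one
  overlap <- intersect(c(auto[["III/IV"]], auto[["Vb"]]),
                       c(default_layer_map()[["III/IV"]],
                         default_layer_map()[["Vb"]]))
  expect_gt(length(overlap), 6)
  bad <- default_layer_map(); bad[["Vb"]] <- 16:24
  expect_error(assign_layers(csd, anchors = bad), "disjoint")
})

test_that("windowed RMS matches closed forms and brute force", {
  fs <- 2000
  ns <- 1400
  nch <- 32
  lfp <- array(0, dim = c(nch, ns, 4))
  rec <- new_laminar_recording(lfp, fs, probe_geometry(),
                               layer_map = default_layer_map())
  csd <- compute_csd(rec, config = csd_config(smooth_len = 1))
  # constant trace c -> |c|; sine with integer periods -> 1/sqrt(2)
  t_s <- (seq_len(ns) - 1) / fs
  csd$csd[, , 1] <- -3                      # constant
  csd$csd[, , 2] <- rep(sin(2 * pi * 40 * t_s), each = 30)
  set.seed(6)
  csd$csd[, , 3] <- rnorm(30 * ns)
  trials <- tibble::tibble(trial_id = 1:4, session_id = 1L,
                           cs_type = c("go", "go", "nogo", "nogo"),
                           responded = FALSE,
                           choice = c("miss", "miss", "correct_rejection",
                                      "correct_rejection"),
                           reaction_time_s = NA_real_,
                           cs_onsets_ms = "0")
  f <- rms_features(csd, trials, window_anchor = "each_cs")
  avrec1 <- f$rms[f$trial_id == 1 & f$layer == "AVREC"]
  expect_equal(avrec1, 3, tolerance = 1e-12)
  lay2 <- f$rms[f$trial_id == 2 & f$layer == "Vb"]
  expect_equal(lay2, 1 / sqrt(2), tolerance = 1e-3)
  # brute-force oracle for the random trial, layer I/II over [0, 500) ms
  win <- seq_len(1000)
  trace <- colMeans(csd$csd[which(csd$valid_channels %in% 2:6), win, 3])
  expect_equal(f$rms[f$trial_id == 3 & f$layer == "I/II"],
               sqrt(mean(trace^2)), tolerance = 1e-12)
})

test_that("z-scores are centered and scaled within session and feature", {
  sess <- generate_session(tiny_config(n_trials = 12), c(0.5, 0.5),
                           quiet_truth(), probe_geometry(), seed = 7)
  csd <- compute_csd(sess$recording)
  f <- rms_features(csd, sess$trials, window_anchor = "each_cs")
  chk <- f |>
    dplyr::group_by(.data$layer, .data$cs_position) |>
    dplyr::summarise(m = mean(.data$z), s = sd(.data$z), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::filter(.data$n >= 2)
  expect_lt(max(abs(chk$m)), 1e-9)
  expect_lt(max(abs(chk$s - 1)), 1e-9)
})

test_that("clipping masks remove intersecting feature windows", {
  sess <- generate_session(session_config(n_trials = 8, n_go = 4, n_nogo = 4),
                           c(0, 0), quiet_truth(), probe_geometry(), seed = 8)
  rec <- sess$recording
  # no events: identity on features
  f0 <- rms_features(compute_csd(rec), sess$trials, "cs4")
  rec_masked <- remove_clipping(
    rec, events = tibble::tibble(trial = 2, t0_ms = 5200, t1_ms = 5400))
  f1 <- rms_features(compute_csd(rec_masked), sess$trials, "cs4")
  # 4th CS window is [5100, 5600): trial 2 must be gone
  expect_true(2 %in% f0$trial_id)
  expect_false(2 %in% f1$trial_id)
  expect_equal(attr(f1, "excluded")[["clipped"]], 1L)
  # a mask outside every window changes nothing
  rec_out <- remove_clipping(
    rec, events = tibble::tibble(trial = 3, t0_ms = 4000, t1_ms = 4500))
  f2 <- rms_features(compute_csd(rec_out), sess$trials, "cs4")
  expect_equal(f2$rms, f0$rms)
})

test_that("pre-reaction anchoring picks the last CS before the response", {
  sess <- generate_session(session_config(n_trials = 6, n_go = 3, n_nogo = 3),
                           c(1, 0), quiet_truth(), probe_geometry(), seed = 9)
  trials <- sess$trials
  trials$reaction_time_s[trials$responded][1] <- 3.6  # after CS at 3400 ms
  csd <- compute_csd(sess$recording)
  f <- rms_features(csd, trials, window_anchor = "pre_reaction")
  tr <- trials$trial_id[trials$responded][1]
  expect_equal(unique(f$cs_position[f$trial_id == tr]), 3)
})

test_that("doubled layer-VI amplitude on hits shows up in layer-VI RMS", {
  evoked <- default_evoked_table()
  wins <- 0L
  for (s in 1:10) {
    # hits: double VI amplitude by generating go trials with doubled VI amp
    ev_hi <- dplyr::mutate(
      evoked, amp_go = ifelse(.data$layer == "VI", amp_go * 2, amp_go))
    truth <- laminar_ground_truth(evoked = ev_hi, burst_specs = list(),
                                  noise_sd = 0)
    sess <- generate_session(tiny_config(n_trials = 10), c(1, 0), truth,
                             probe_geometry(), seed = 200 + s)
    csd <- compute_csd(sess$recording)
    f <- rms_features(csd, sess$trials, "each_cs")
    hi <- mean(f$rms[f$layer == "VI" & f$cs_type == "go"])
    lo_truth <- laminar_ground_truth(evoked = evoked, burst_specs = list(),
                                     noise_sd = 0)
    sess2 <- generate_session(tiny_config(n_trials = 10), c(0, 0), lo_truth,
                              probe_geometry(), seed = 200 + s)
    f2 <- rms_features(compute_csd(sess2$recording), sess2$trials, "each_cs")
    lo <- mean(f2$rms[f2$layer == "VI" & f2$cs_type == "go"])
    wins <- wins + (hi > lo)
  }
  expect_equal(wins, 10L)
})
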