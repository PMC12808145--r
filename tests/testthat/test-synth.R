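test_that("constructors validate their invariants", {
  expect_error(probe_geometry(n_channels = 4), ">= 5")
  expect_error(probe_geometry(spacing_um = 0), "> 0")
  expect_true(all(diff(probe_geometry()$depths_um) > 0))
  expect_error(session_config(n_trials = 60, n_go = 20, n_nogo = 30),
               "must equal")
  expect_error(session_config(observation_window_s = 1), "observation window")
  expect_error(agent_params(initial_hit_rate = 1.2), "\\[0, 1\\]")
  expect_error(agent_params(reversal_schedule = c(5, 5)), "increasing")
  bad_map <- default_layer_map()
  bad_map[["Va"]] <- 12:17   # overlaps III/IV
  expect_error(laminar_ground_truth(layer_map = bad_map), "disjoint")
})

test_that("default session timing yields four CS per trial", {
  expect_equal(cs_onsets_ms(session_config()), c(0, 1700, 3400, 5100))
})

test_that("learning curves are flat without learning and drop at reversals", {
  frozen <- agent_params(initial_hit_rate = 0.4, initial_fa_rate = 0.3,
                         learning_rate = 0, perseveration_depth = 0,
                         fa_rise = 0, reversal_schedule = integer(0))
  cv <- simulate_learning_curves(frozen, 8, seed = 1)
  expect_true(all(cv$hit_rate == 0.4))
  expect_true(all(cv$fa_rate == 0.3))

  ag <- agent_params()
  cv <- simulate_learning_curves(ag, 30, seed = 1)
  expect_true(all(cv$hit_rate >= 0 & cv$hit_rate <= 1))
  expect_true(all(cv$fa_rate >= 0 & cv$fa_rate <= 1))
  for (r in ag$reversal_schedule) {
    expect_lt(cv$hit_rate[r], cv$hit_rate[r - 1])
    expect_gt(cv$fa_rate[r], cv$fa_rate[r - 1])
    expect_gt(cv$hit_rate[r + 2], cv$hit_rate[r])  # recovery under way
  }
  expect_identical(cv, simulate_learning_curves(ag, 30, seed = 1))
  expect_error(simulate_learning_curves(ag, 5, seed = 1), "beyond")
})

test_that("late-phase agent rates give d' above 1", {
  cv <- simulate_learning_curves(agent_params(), 30, seed = 1)
  last <- cv[cv$session == 30, ]
  d <- compute_dprime(round(last$hit_rate * 30), 30,
                      round(last$fa_rate * 30), 30)
  expect_gt(d, 1)
})

test_that("generated sessions honor the configured trial structure", {
  sess <- generate_session(session_config(), c(0.8, 0.2),
                           laminar_ground_truth(), probe_geometry(), seed = 7)
  expect_equal(nrow(sess$trials), 60)
  expect_equal(sum(sess$trials$cs_type == "go"), 30)
  expect_equal(sum(sess$trials$cs_type == "nogo"), 30)
  expect_equal(dim(sess$recording$lfp), c(32, 12000, 60))
  expect_equal(sess$recording$sampling_rate, 2000)
  # choice labels consistent with stimulus type
  with(sess$trials, {
    expect_true(all(choice[cs_type == "go"] %in% c("hit", "miss")))
    expect_true(all(choice[cs_type == "nogo"] %in%
                      c("false_alarm", "correct_rejection")))
  })
  # reaction times only on response trials, inside the window
  rt <- sess$trials$reaction_time_s
  expect_true(all(is.na(rt[!sess$trials$responded])))
  expect_true(all(rt[sess$trials$responded] >= 0.3 &
                    rt[sess$trials$responded] <= 6))
  expect_error(generate_session(session_config(), c(1.2, 0),
                                laminar_ground_truth(), probe_geometry(), 1),
               "\\[0, 1\\]")
})

test_that("generator output is a pure function of the seed", {
  cfg <- tiny_config()
  truth <- laminar_ground_truth()
  a <- generate_session(cfg, c(0.6, 0.3), truth, probe_geometry(), seed = 42)
  b <- generate_session(cfg, c(0.6, 0.3), truth, probe_geometry(), seed = 42)
  expect_identical(a$trials, b$trials)
  expect_identical(a$recording$lfp, b$recording$lfp)
  c <- generate_session(cfg, c(0.6, 0.3), truth, probe_geometry(), seed = 43)
  expect_false(identical(a$recording$lfp, c$recording$lfp))
})

test_that("zero noise and zero amplitudes give an identically zero recording", {
  truth <- laminar_ground_truth(
    evoked = dplyr::mutate(default_evoked_table(), amp_go = 0, amp_nogo = 0),
    burst_specs = list(), noise_sd = 0)
  sess <- generate_session(tiny_config(), c(0.5, 0.5), truth,
                           probe_geometry(), seed = 1)
  expect_true(all(sess$recording$lfp == 0))
})

test_that("an injected 40 Hz burst peaks at 40 Hz (FFT oracle)", {
  truth <- laminar_ground_truth(
    evoked = dplyr::mutate(default_evoked_table(), amp_go = 0, amp_nogo = 0),
    burst_specs = list(list(layer = "VI", band = "low_gamma", center_hz = 40,
                            window_ms = c(0, 1000), base_amp = 1e-4,
                            gains = NULL, phase_locked = TRUE)),
    noise_sd = 0)
  sess <- generate_session(tiny_config(n_trials = 2), c(1, 1), truth,
                           probe_geometry(), seed = 2)
  fs <- sess$recording$sampling_rate
  sig <- sess$recording$lfp[27, , 1]       # a layer-VI channel
  # FFT-peak oracle on the noiseless injected waveform
  spec <- Mod(fft(sig))[seq_len(length(sig) / 2)]
  f_axis <- (seq_along(spec) - 1) * fs / length(sig)
  keep <- f_axis >= 5
  f_peak <- f_axis[keep][which.max(spec[keep])]
  expect_lt(abs(f_peak - 40), 3)
  # the spectral module agrees
  sc <- cwt_scalogram(sig, fs)
  mag <- rowMeans(Mod(sc$coeffs))
  expect_lt(abs(sc$freqs[which.max(mag)] - 40), 3)
})

test_that("injected dipoles close across depth (Vaknin-padded CSD)", {
  truth <- quiet_truth(noise_sd = 0)
  sess <- generate_session(tiny_config(n_trials = 2), c(1, 0), truth,
                           probe_geometry(), seed = 3)
  csd <- compute_csd(sess$recording, config = csd_config(vaknin = TRUE))
  avg <- apply(csd$csd, c(1, 2), mean)
  expect_lt(max(abs(colSums(avg))), 1e-9 * max(abs(avg)))
})

test_that("artifact injection touches only the named channels and trials", {
  sess <- generate_session(tiny_config(), c(0.5, 0.5), quiet_truth(),
                           probe_geometry(), seed = 4)
  rec0 <- sess$recording
  # empty spec: unchanged
  rec1 <- inject_artifacts(rec0, list())
  expect_identical(rec1$lfp, rec0$lfp)
  expect_equal(nrow(rec1$artifact_log), 0)
  # scale event
  rec2 <- inject_artifacts(rec0, list(list(type = "scale", channel = 10,
                                           factor = 10)))
  expect_identical(rec2$lfp[-10, , ], rec0$lfp[-10, , ])
  expect_equal(rec2$lfp[10, , ], rec0$lfp[10, , ] * 10)
  expect_equal(rec2$artifact_log$channel, 10L)
  expect_identical(detect_bad_channels(rec2), 10L)
  # clipping event flagged by the clipping screen
  rec3 <- inject_artifacts(rec0, list(list(type = "clip", trial = 3,
                                           t_range_ms = c(400, 700),
                                           level = 5e-3)))
  mask <- detect_clipping(rec3)
  in_range <- rec3$time_ms >= 400 & rec3$time_ms < 700
  expect_gt(mean(mask[in_range, 3]), 0.95)
  expect_equal(sum(mask[, -3]), 0)
  expect_error(inject_artifacts(rec0, list(list(type = "scale", channel = 99,
                                                factor = 2))),
               "unknown channel")
})
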