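# Shared fixtures, all generated in code at test time.

# Small, fast session configuration: one CS per trial (1.7 s window covers
# exactly one tone + ISI), paper timing otherwise.
tiny_config <- function(n_trials = 20) {
  session_config(n_trials = n_trials, n_go = n_trials / 2,
                 n_nogo = n_trials / 2, observation_window_s = 1.7)
}

# Ground truth without stochastic bursts, optionally noiseless.
quiet_truth <- function(noise_sd = 5e-5, burst_specs = list()) {
  laminar_ground_truth(noise_sd = noise_sd, burst_specs = burst_specs)
}

# Ground truth with a choice-dependent gamma burst in one layer.
gamma_effect_truth <- function(layer = "VI", gain_hit = 3, center_hz = 40,
                               noise_sd = 5e-5) {
  specs <- default_burst_specs()
  specs[[length(specs) + 1]] <- list(
    layer = layer, band = "low_gamma", center_hz = center_hz,
    window_ms = c(50, 350), base_amp = 4e-5,
    gains = list(hit = gain_hit, miss = 1), phase_locked = FALSE)
  laminar_ground_truth(noise_sd = noise_sd, burst_specs = specs)
}

# Two groups of synthetic "scalogram" observations on an nf x nt grid drawn
# from N(0, 1), with an optional mean offset added to group A inside a block.
gauss_groups <- function(n_a, n_b, nf = 20, nt = 30, effect = 0,
                         block_f = NULL, block_t = NULL, seed = 1) {
  set.seed(seed)
  A <- array(rnorm(n_a * nf * nt), dim = c(n_a, nf, nt))
  B <- array(rnorm(n_b * nf * nt), dim = c(n_b, nf, nt))
  if (effect != 0) {
    A[, block_f, block_t] <- A[, block_f, block_t] + effect
  }
  list(A = A, B = B)
}

# Unconfounded feature table for GLMM tests: choices Bernoulli per
# (subject, trial), features z-scored-scale noise, optional additive effect
# on hits in one layer at chosen positions.
glmm_features <- function(seed, n_subjects = 6, n_trials = 30,
                          layers = c("I/II", "III/IV", "VI"),
                          positions = 1:4, eff_layer = "VI",
                          eff_positions = max(positions), effect = 1) {
  set.seed(seed)
  trials <- expand.grid(subject = paste0("s", seq_len(n_subjects)),
                        trial = seq_len(n_trials),
                        stringsAsFactors = FALSE)
  trials$choice <- sample(c("hit", "miss"), nrow(trials), replace = TRUE)
  grid <- merge(trials,
                expand.grid(layer = layers, cs_position = positions,
                            stringsAsFactors = FALSE))
  grid$z <- rnorm(nrow(grid))
  sel <- grid$layer == eff_layer & grid$cs_position %in% eff_positions &
    grid$choice == "hit"
  grid$z[sel] <- grid$z[sel] + effect
  grid
}

# Independent flood-fill oracle for connected components via igraph.
igraph_components <- function(mask, connectivity) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(integer(0))
  key <- paste(idx[, 1], idx[, 2])
  edges <- c()
  offs <- if (connectivity == 4) {
    list(c(1, 0), c(0, 1))
  } else {
    list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))
  }
  for (i in seq_len(nrow(idx))) {
    for (o in offs) {
      nb <- paste(idx[i, 1] + o[1], idx[i, 2] + o[2])
      if (nb %in% key) edges <- c(edges, key[i], nb)
    }
  }
  g <- igraph::graph_from_data_frame(
    if (length(edges)) data.frame(from = edges[c(TRUE, FALSE)],
                                  to = edges[c(FALSE, TRUE)]) else
      data.frame(from = character(), to = character()),
    directed = FALSE, vertices = data.frame(name = key))
  comp <- igraph::components(g)
  sort(as.integer(comp$csize), decreasing = TRUE)
}
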