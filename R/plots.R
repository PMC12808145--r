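#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_raster geom_hline
#'   geom_tile scale_fill_gradient2 scale_y_continuous labs facet_wrap
#'   autoplot theme_minimal scale_fill_viridis_c
#' @export
ggplot2::autoplot

#' Plot learning curves
#'
#' Hit and false-alarm rates by session with the derived d' trace and the
#' phase boundaries at d' = 0 and d' = 1.
#'
#' @param curves Tibble from [simulate_learning_curves()] or
#'   [summarize_behavior()] (needs `session`/`session_id`, `hit_rate`,
#'   `fa_rate`).
#' @param n_go,n_nogo Trial counts used to convert rates to d'.
#' @return A ggplot object.
#' @export
plot_learning_curves <- function(curves, n_go = 30, n_nogo = 30) {
  if (!"session" %in% names(curves) && "session_id" %in% names(curves)) {
    curves$session <- curves$session_id
  }
  long <- curves |>
    dplyr::mutate(dprime = purrr::map2_dbl(
      .data$hit_rate, .data$fa_rate,
      ~ compute_dprime(round(.x * n_go), n_go, round(.y * n_nogo), n_nogo))) |>
    tidyr::pivot_longer(c("hit_rate", "fa_rate", "dprime"),
                        names_to = "metric", values_to = "value")
  long$metric <- factor(long$metric, levels = c("hit_rate", "fa_rate", "dprime"))
  ggplot(long, aes(x = .data$session, y = .data$value,
                   colour = .data$metric)) +
    geom_line() + geom_point(size = 0.8) +
    geom_hline(data = data.frame(metric = factor("dprime"), y = c(0, 1)),
               aes(yintercept = .data$y), linetype = "dotted") +
    facet_wrap(~metric, ncol = 1, scales = "free_y") +
    labs(x = "session", y = NULL, colour = NULL) +
    theme_minimal()
}

#' Plot a trial-averaged CSD profile
#'
#' Depth x time raster of the trial-mean CSD with sinks (negative) in blue
#' and sources in red.
#'
#' @param csd A `csd_profile`.
#' @param trials Optional trial subset to average.
#' @return A ggplot object.
#' @export
plot_csd_profile <- function(csd, trials = NULL) {
  assert_that(inherits(csd, "csd_profile"), "`csd` must be a csd_profile")
  x <- csd$csd
  if (!is.null(trials)) x <- x[, , trials, drop = FALSE]
  avg <- apply(x, c(1, 2), mean)
  df <- tibble::tibble(
    channel = rep(csd$valid_channels, times = ncol(avg)),
    time_ms = rep(csd$time_ms, each = nrow(avg)),
    csd = as.numeric(avg)
  )
  ggplot(df, aes(x = .data$time_ms, y = .data$channel, fill = .data$csd)) +
    geom_raster() +
    scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                         midpoint = 0) +
    scale_y_continuous(trans = "reverse") +
    labs(x = "time (ms)", y = "channel (superficial on top)",
         fill = expression(CSD ~ (V / mm^2))) +
    theme_minimal()
}

#' @describeIn plot_csd_profile Scalogram raster (log frequency axis).
#' @param object A `lam_scalogram`.
#' @param ... Unused.
#' @export
autoplot.lam_scalogram <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$time_ms, y = .data$freq_hz, fill = .data$value)) +
    geom_raster() +
    scale_y_continuous(trans = "log2") +
    scale_fill_viridis_c() +
    labs(x = "time (ms)", y = "frequency (Hz)", fill = object$kind) +
    theme_minimal()
}

#' @describeIn plot_csd_profile t-map raster with significant-cluster bins
#'   overlaid.
#' @export
autoplot.lam_cluster_test <- function(object, ...) {
  tm <- attr(object, "t_map")
  freqs <- attr(object, "freqs") %||% seq_len(nrow(tm))
  tms <- attr(object, "time_ms") %||% seq_len(ncol(tm))
  df <- tibble::tibble(
    freq = rep(freqs, times = ncol(tm)),
    time = rep(tms, each = nrow(tm)),
    t = as.numeric(tm)
  )
  p <- ggplot(df, aes(x = .data$time, y = .data$freq, fill = .data$t)) +
    geom_raster() +
    scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                         midpoint = 0) +
    labs(x = "time (ms)", y = "frequency (Hz)", fill = "t") +
    theme_minimal()
  sig <- object[object$significant, , drop = FALSE]
  if (nrow(sig)) {
    bins <- dplyr::bind_rows(lapply(sig$bins, function(b) {
      tibble::tibble(freq = freqs[b[, "row"]], time = tms[b[, "col"]])
    }))
    p <- p + geom_tile(data = bins, aes(x = .data$time, y = .data$freq),
                       fill = NA, colour = "black", linewidth = 0.2,
                       inherit.aes = FALSE)
  }
  p
}

#' Plot a time-resolved effect-size series
#'
#' R2m by stimulus position per layer; filled points mark significant fixed
#' effects.
#'
#' @param series Tibble from [effect_size_series()].
#' @return A ggplot object.
#' @export
plot_effect_size_series <- function(series) {
  ggplot(series, aes(x = .data$cs_position, y = .data$r2m,
                     colour = .data$layer)) +
    geom_line() +
    geom_point(aes(shape = .data$significant), size = 2) +
    labs(x = "CS position before decision", y = expression(R[m]^2),
         colour = "layer", shape = "p < 0.05") +
    theme_minimal()
}
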