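#' Classify a Go/NoGo choice
#'
#' The four trial outcomes of a Go/NoGo task: a response to the CS+ is a hit
#' and withholding a miss; a response to the CS- is a false alarm and
#' withholding a correct rejection.
#'
#' @param cs_type `"CS+"`/`"go"` or `"CS-"`/`"nogo"`.
#' @param responded Logical: did the animal change compartment within the
#'   observation window?
#' @return One of `"hit"`, `"miss"`, `"false_alarm"`, `"correct_rejection"`.
#' @export
#' @examples
#' classify_choice("CS+", TRUE)   # hit
#' classify_choice("CS-", FALSE)  # correct_rejection
classify_choice <- function(cs_type, responded) {
  cs <- switch(as.character(cs_type),
               "CS+" = "go", "go" = "go",
               "CS-" = "nogo", "nogo" = "nogo",
               abort("`cs_type` must be CS+/CS- (or go/nogo)"))
  assert_that(is.logical(responded) && length(responded) == 1 &&
                !is.na(responded), "`responded` must be TRUE or FALSE")
  if (cs == "go") {
    if (responded) "hit" else "miss"
  } else {
    if (responded) "false_alarm" else "correct_rejection"
  }
}

#' Signal-detection sensitivity index d'
#'
#' d' is the difference between the standard-normal quantile transforms of
#' the hit rate and the false-alarm rate. Degenerate rates of 0 or 1 are
#' clipped to `1/(2N)` and `1 - 1/(2N)` (N = trials of that stimulus type),
#' the standard log-linear-style correction that keeps d' finite.
#'
#' @param n_hits,n_go Hit count and number of CS+ trials.
#' @param n_fas,n_nogo False-alarm count and number of CS- trials.
#' @return d' (unitless). 0 at equal rates; positive when hits exceed false
#'   alarms.
#' @export
#' @examples
#' compute_dprime(24, 30, 6, 30)  # ~1.683
compute_dprime <- function(n_hits, n_go, n_fas, n_nogo) {
  assert_that(is_count(n_go) && n_go > 0 && is_count(n_nogo) && n_nogo > 0,
              "`n_go` and `n_nogo` must be positive")
  assert_that(is_count(n_hits) && n_hits <= n_go, "`n_hits` must be in 0..n_go")
  assert_that(is_count(n_fas) && n_fas <= n_nogo, "`n_fas` must be in 0..n_nogo")
  hr <- clip_rate(n_hits / n_go, n_go)
  fr <- clip_rate(n_fas / n_nogo, n_nogo)
  qnorm(hr) - qnorm(fr)
}

clip_rate <- function(rate, n) {
  lo <- 1 / (2 * n)
  pmin(1 - lo, pmax(lo, rate))
}

#' Assign a performance phase from d'
#'
#' Reversal-learning performance is binned into three phases: early reversal
#' (d' < 0, perseverative errors), intermediate learning (0 <= d' < 1,
#' steepest improvement) and retrieval (d' >= 1, stable above-threshold
#' discrimination). The bins are half-open so every finite d' maps to exactly
#' one phase: d' = 0 falls in `learning`, d' = 1 in `retrieval`.
#'
#' @param dprime Finite numeric (vectorised).
#' @return Character vector in
#'   `c("early_reversal", "learning", "retrieval")`.
#' @export
assign_phase <- function(dprime) {
  assert_that(is.numeric(dprime) && length(dprime) >= 1, "`dprime` must be numeric")
  if (any(!is.finite(dprime))) abort("`dprime` must be finite (no NaN/NA)")
  dplyr::case_when(
    dprime < 0 ~ "early_reversal",
    dprime < 1 ~ "learning",
    TRUE ~ "retrieval"
  )
}

#' Learning-criterion detector
#'
#' The task criterion: d' above `threshold` for `run` consecutive sessions.
#'
#' @param dprime_series Numeric vector of per-session d' values (non-empty).
#' @param threshold Criterion level (default 1).
#' @param run Required consecutive sessions (default 3).
#' @return `TRUE` iff some run of `run` consecutive values all exceed
#'   `threshold`.
#' @export
criterion_reached <- function(dprime_series, threshold = 1.0, run = 3L) {
  assert_that(is.numeric(dprime_series) && length(dprime_series) >= 1,
              "`dprime_series` must be a non-empty numeric vector")
  assert_that(is_count(run) && run >= 1, "`run` must be a positive integer")
  above <- dprime_series > threshold
  if (length(above) < run) return(FALSE)
  any(vapply(seq_len(length(above) - run + 1),
             function(i) all(above[i:(i + run - 1)]), logical(1)))
}

#' Per-session behavioral summary
#'
#' Computes hit rate, false-alarm rate, d' and the performance phase for
#' each session of a trial table.
#'
#' @param trials Trial table (tibble) with columns `session_id`, `cs_type`
#'   (`go`/`nogo`) and `choice`.
#' @return Tibble: session_id, n_go, n_nogo, n_hits, n_fas, hit_rate,
#'   fa_rate, dprime, phase.
#' @export
summarize_behavior <- function(trials) {
  assert_that(all(c("session_id", "cs_type", "choice") %in% names(trials)),
              "`trials` needs session_id, cs_type, choice")
  trials |>
    dplyr::group_by(.data$session_id) |>
    dplyr::summarise(
      n_go = sum(.data$cs_type == "go"),
      n_nogo = sum(.data$cs_type == "nogo"),
      n_hits = sum(.data$choice == "hit"),
      n_fas = sum(.data$choice == "false_alarm"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      hit_rate = .data$n_hits / .data$n_go,
      fa_rate = .data$n_fas / .data$n_nogo,
      dprime = purrr::pmap_dbl(
        list(.data$n_hits, .data$n_go, .data$n_fas, .data$n_nogo),
        compute_dprime),
      phase = assign_phase(.data$dprime)
    )
}

#' Per-phase choice bookkeeping
#'
#' Tabulates choice counts within each performance phase and checks the
#' totals: each bin total is the sum of its four choice counts and the grand
#' total the sum of the bin totals.
#'
#' @param trials Trial table with columns `phase` and `choice` (every trial
#'   labeled).
#' @return Tibble with one row per phase: `phase`, `hit`, `false_alarm`,
#'   `correct_rejection`, `miss`, `total`; the grand total is attached as
#'   attribute `grand_total`.
#' @export
summarize_bins <- function(trials) {
  assert_that(all(c("phase", "choice") %in% names(trials)),
              "`trials` needs phase and choice columns")
  if (nrow(trials) > 0 &&
      (any(is.na(trials$phase)) || any(is.na(trials$choice)))) {
    abort("every trial must carry a phase and a choice label")
  }
  labs <- c("hit", "false_alarm", "correct_rejection", "miss")
  if (nrow(trials) > 0 && !all(trials$choice %in% labs)) {
    abort("unknown choice label in `trials`")
  }
  phases <- c("early_reversal", "learning", "retrieval")
  out <- tidyr::expand_grid(phase = phases, choice = labs) |>
    dplyr::left_join(
      dplyr::count(trials, .data$phase, .data$choice),
      by = c("phase", "choice")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L)) |>
    tidyr::pivot_wider(names_from = "choice", values_from = "n") |>
    dplyr::mutate(total = .data$hit + .data$false_alarm +
                    .data$correct_rejection + .data$miss)
  attr(out, "grand_total") <- sum(out$total)
  out
}
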