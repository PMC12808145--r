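#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a cluster test
#'
#' @param x A `lam_cluster_test`.
#' @param ... Unused.
#' @return Tibble of clusters without the `bins` list-column.
#' @export
tidy.lam_cluster_test <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$bins <- NULL
  out
}

#' @rdname tidy.lam_cluster_test
#' @export
glance.lam_cluster_test <- function(x, ...) {
  cmp <- attr(x, "comparison")
  tibble::tibble(
    n_clusters = nrow(x),
    n_significant = sum(x$significant),
    threshold = attr(x, "threshold"),
    n_permutations = cmp$n_permutations,
    min_extent = cmp$min_extent,
    min_mean_d = cmp$min_mean_d
  )
}

#' Tidy a fitted choice GLMM
#'
#' @param x A `lam_glmm`.
#' @param ... Unused.
#' @return Tibble of fixed effects (term, estimate, std.error, statistic,
#'   p.value).
#' @export
tidy.lam_glmm <- function(x, ...) {
  if (is.null(x$fit)) {
    return(tibble::tibble(term = character(), estimate = numeric(),
                          std.error = numeric(), statistic = numeric(),
                          p.value = numeric()))
  }
  cf <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(cf), estimate = cf[, "Estimate"],
                 std.error = cf[, "Std. Error"], statistic = cf[, "z value"],
                 p.value = cf[, "Pr(>|z|)"])
}

#' @rdname tidy.lam_glmm
#' @export
glance.lam_glmm <- function(x, ...) {
  tibble::tibble(
    converged = x$converged,
    singular = x$singular %||% NA,
    r2m = if (is.null(x$r2)) NA_real_ else x$r2$r2m,
    r2c = if (is.null(x$r2)) NA_real_ else x$r2$r2c,
    n = x$n
  )
}

#' Tidy a scalogram into long form
#'
#' @param x A `lam_scalogram`.
#' @param ... Unused.
#' @return Tibble: freq_hz, time_ms, value (magnitude/power; `Mod()` of
#'   complex coefficients), in_coi.
#' @export
tidy.lam_scalogram <- function(x, ...) {
  val <- if (is.complex(x$coeffs)) Mod(x$coeffs) else x$coeffs
  tibble::tibble(
    freq_hz = rep(x$freqs, times = length(x$time_ms)),
    time_ms = rep(x$time_ms, each = length(x$freqs)),
    value = as.numeric(val),
    in_coi = if (is.null(x$coi)) FALSE else as.logical(x$coi)
  )
}
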