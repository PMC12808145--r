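#' Read and write the trial-table CSV dialect
#'
#' Columns: trial_id, session_id, cs_type, responded, choice,
#' reaction_time_s, cs_onsets_ms (semicolon-separated onsets).
#'
#' @param trials Trial tibble.
#' @param path File path.
#' @return `read_trial_table` returns a tibble; the writers return the path
#'   invisibly.
#' @export
write_trial_table <- function(trials, path) {
  write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  tibble::as_tibble(df)
}

#' Write a per-session behavioral summary CSV
#'
#' @param summary Tibble from [summarize_behavior()].
#' @param path File path.
#' @export
write_behavior_summary <- function(summary, path) {
  write.csv(summary, path, row.names = FALSE)
  invisible(path)
}

#' Write cluster results as JSON plus a TSV summary
#'
#' The JSON carries, per cluster, the id, sign, size, mass, permutation p,
#' mean |d|, band annotation and the member bins; the TSV holds the same
#' rows without the bin lists.
#'
#' @param result A `lam_cluster_test`.
#' @param json_path,tsv_path Output paths (either may be `NULL` to skip).
#' @export
write_cluster_results <- function(result, json_path = NULL, tsv_path = NULL) {
  tbl <- tidy(result)
  if (!is.null(json_path)) {
    payload <- lapply(seq_len(nrow(result)), function(i) {
      list(cluster_id = result$cluster_id[i], sign = result$sign[i],
           size = result$size[i], mass = result$mass[i],
           p_perm = result$p_perm[i], mean_d = result$mean_d[i],
           significant = result$significant[i],
           bands_touched = result$bands_touched[i],
           bins = apply(result$bins[[i]], 1, as.list))
    })
    jsonlite::write_json(
      list(threshold = attr(result, "threshold"), clusters = payload),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(tsv_path)) {
    utils::write.table(tbl, tsv_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(result)
}

#' Write / read a run configuration as JSON
#'
#' @param config A validated run config (list).
#' @param path File path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
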