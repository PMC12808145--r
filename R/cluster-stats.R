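#' Time-frequency comparison settings
#'
#' Thresholds of the cluster-mass permutation pipeline: point-wise
#' two-tailed alpha 0.05, 1000 label permutations, a minimum extent of
#' 5 x 5 = 25 connected bins, a mean |Cohen's d| gate of 0.4, and a
#' one-tailed 95th-percentile cluster-size threshold.
#'
#' @param alpha_pointwise Two-tailed point-wise alpha.
#' @param n_permutations Number of label permutations (>= 1).
#' @param min_extent Minimum cluster area in bins.
#' @param min_mean_d Mean-|d| gate (strictly greater than).
#' @param cluster_alpha One-tailed alpha on cluster size.
#' @param connectivity 8 (default) or 4 neighbour connectivity.
#' @param null_statistic `"max"` (per-permutation maximum cluster size,
#'   family-wise control; default) or `"all"` (pool every cluster size).
#' @return A `tf_comparison` settings object.
#' @export
tf_comparison <- function(alpha_pointwise = 0.05, n_permutations = 1000,
                          min_extent = 25, min_mean_d = 0.4,
                          cluster_alpha = 0.05, connectivity = 8,
                          null_statistic = c("max", "all")) {
  assert_that(alpha_pointwise > 0 && alpha_pointwise < 1, "bad `alpha_pointwise`")
  assert_that(is_count(n_permutations) && n_permutations >= 1,
              "`n_permutations` must be >= 1")
  assert_that(connectivity %in% c(4, 8), "`connectivity` must be 4 or 8")
  structure(
    list(alpha_pointwise = alpha_pointwise,
         n_permutations = as.integer(n_permutations),
         min_extent = min_extent, min_mean_d = min_mean_d,
         cluster_alpha = cluster_alpha, connectivity = connectivity,
         null_statistic = match.arg(null_statistic)),
    class = "tf_comparison"
  )
}

# Coerce a group to an obs x bins matrix plus the map dimensions.
as_obs_matrix <- function(g) {
  if (is.list(g) && !is.array(g)) {
    dims <- dim(g[[1]])
    m <- t(vapply(g, as.numeric, numeric(prod(dims))))
    list(m = m, dims = dims)
  } else if (is.array(g) && length(dim(g)) == 3) {
    d <- dim(g)
    list(m = matrix(g, nrow = d[1]), dims = d[2:3])
  } else if (is.matrix(g)) {
    # single map per observation is ambiguous; treat rows as observations
    list(m = g, dims = c(1L, ncol(g)))
  } else {
    abort("groups must be 3-D arrays [obs, f, t] or lists of matrices")
  }
}

# Vectorised two-sample equal-variance t over columns of two matrices.
col_tstats <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  ma <- colMeans(a); mb <- colMeans(b)
  va <- (colSums(a * a) - na * ma^2) / (na - 1)
  vb <- (colSums(b * b) - nb * mb^2) / (nb - 1)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  t <- (ma - mb) / se
  t[se == 0] <- 0
  list(t = t, df = na + nb - 2)
}

#' Point-wise two-sample t-map
#'
#' Equal-variance two-sample Student t statistic and two-tailed p-value at
#' every time-frequency bin, observations (trials) as the sampling unit.
#' Bins with zero variance in both groups get t = 0, p = 1.
#'
#' @param group_a,group_b 3-D arrays `[obs, f, t]` or lists of matrices
#'   (at least 2 observations each).
#' @param alpha Two-tailed significance level for the mask (strict `<`).
#' @return List with matrices `t`, `p`, logical `mask` (p < alpha), `df`.
#' @export
pointwise_tmap <- function(group_a, group_b, alpha = 0.05) {
  A <- as_obs_matrix(group_a); B <- as_obs_matrix(group_b)
  assert_that(identical(A$dims, B$dims), "groups must share one grid")
  assert_that(nrow(A$m) >= 2 && nrow(B$m) >= 2,
              "need at least 2 observations per group")
  ts <- col_tstats(A$m, B$m)
  p <- 2 * pt(abs(ts$t), df = ts$df, lower.tail = FALSE)
  dims <- A$dims
  list(t = matrix(ts$t, dims[1], dims[2]),
       p = matrix(p, dims[1], dims[2]),
       mask = matrix(p < alpha, dims[1], dims[2]),
       df = ts$df)
}

#' Connected components of a binary mask
#'
#' Labels maximal connected components of a logical matrix under 4- or
#' 8-neighbour connectivity (a re-specification of boundary tracing as
#' component labeling). Every true bin belongs to exactly one cluster.
#'
#' @param mask Logical matrix.
#' @param connectivity 4 or 8.
#' @return List of clusters, each a list with `bins` (integer matrix of
#'   `[row, col]` members) and `size`.
#' @export
find_clusters <- function(mask, connectivity = 8) {
  assert_that(is.matrix(mask) && is.logical(mask), "`mask` must be a logical matrix")
  assert_that(connectivity %in% c(4, 8), "`connectivity` must be 4 or 8")
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  if (length(idx) == 0) return(list())
  lab <- integer(nr * nc)
  lab[idx] <- -1L                       # unvisited foreground
  offs <- if (connectivity == 4) {
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  } else {
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L),
         c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))
  }
  clusters <- list()
  nextlab <- 0L
  for (seed in idx) {
    if (lab[seed] != -1L) next
    nextlab <- nextlab + 1L
    queue <- seed
    lab[seed] <- nextlab
    members <- integer(0)
    while (length(queue)) {
      cur <- queue[[1]]
      queue <- queue[-1]
      members <- c(members, cur)
      r <- ((cur - 1L) %% nr) + 1L
      c0 <- ((cur - 1L) %/% nr) + 1L
      for (o in offs) {
        rr <- r + o[1]; cc <- c0 + o[2]
        if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
        j <- (cc - 1L) * nr + rr
        if (lab[j] == -1L) {
          lab[j] <- nextlab
          queue <- c(queue, j)
        }
      }
    }
    clusters[[nextlab]] <- list(
      bins = cbind(row = ((members - 1L) %% nr) + 1L,
                   col = ((members - 1L) %/% nr) + 1L),
      size = length(members))
  }
  clusters
}

# Max (or pooled) cluster size of a two-tailed mask split by t sign,
# restricted to non-excluded bins.
mask_cluster_sizes <- function(t, mask, connectivity, exclude = NULL) {
  if (!is.null(exclude)) mask <- mask & !exclude
  sizes <- integer(0)
  for (sgn in c(1, -1)) {
    m <- mask & (sign(t) == sgn)
    if (any(m)) {
      cl <- find_clusters(m, connectivity)
      sizes <- c(sizes, vapply(cl, `[[`, integer(1), "size"))
    }
  }
  sizes
}

#' Permutation null distribution of cluster size
#'
#' Shuffles the group labels (without replacement, preserving group sizes),
#' recomputes the point-wise t-map and its two-tailed significance mask,
#' splits the mask by t sign, measures the connected clusters and records
#' the per-permutation maximum cluster size (or pools all sizes). The
#' significance threshold is the one-tailed 95th percentile of the null
#' (configurable via `cluster_alpha`).
#'
#' @param group_a,group_b As in [pointwise_tmap()].
#' @param comparison A [tf_comparison()].
#' @param seed Integer seed; identical seeds give identical nulls.
#' @param exclude Optional logical matrix of bins to ignore (e.g. cone of
#'   influence).
#' @return List with `null_sizes` (numeric, one per permutation under
#'   `"max"`), `threshold` (size that must be exceeded), `n_permutations`.
#' @export
permutation_null <- function(group_a, group_b, comparison = tf_comparison(),
                             seed = 1L, exclude = NULL) {
  A <- as_obs_matrix(group_a); B <- as_obs_matrix(group_b)
  assert_that(identical(A$dims, B$dims), "groups must share one grid")
  na <- nrow(A$m); nb <- nrow(B$m)
  assert_that(na + nb >= 3, "need at least 3 observations in total")
  if (comparison$n_permutations > choose(na + nb, na)) {
    warn("more permutations than distinct label assignments; sampling with repeats")
  }
  C <- rbind(A$m, B$m)
  dims <- A$dims
  alpha <- comparison$alpha_pointwise
  df <- na + nb - 2
  tcrit <- stats::qt(1 - alpha / 2, df)
  with_seed(seed, {
    np <- comparison$n_permutations
    # all permuted group-A indicator rows at once -> one BLAS product for
    # the per-bin sums, then vectorised t statistics per permutation
    P <- matrix(0, np, na + nb)
    for (p in seq_len(np)) P[p, sample.int(na + nb, na)] <- 1
    C2 <- C * C
    tot <- colSums(C)
    tot2 <- colSums(C2)
    SA <- P %*% C
    SA2 <- P %*% C2
    null_sizes <- numeric(0)
    per_perm_max <- numeric(np)
    inv <- 1 / na + 1 / nb
    for (p in seq_len(np)) {
      ma <- SA[p, ] / na
      mb <- (tot - SA[p, ]) / nb
      va <- (SA2[p, ] - na * ma^2) / (na - 1)
      vb <- ((tot2 - SA2[p, ]) - nb * mb^2) / (nb - 1)
      se <- sqrt((((na - 1) * va + (nb - 1) * vb) / df) * inv)
      tv <- (ma - mb) / se
      tv[!is.finite(tv)] <- 0
      tm <- matrix(tv, dims[1], dims[2])
      sizes <- mask_cluster_sizes(tm, abs(tm) > tcrit,
                                  comparison$connectivity, exclude)
      per_perm_max[p] <- if (length(sizes)) max(sizes) else 0
      if (comparison$null_statistic == "all") {
        null_sizes <- c(null_sizes, if (length(sizes)) sizes else 0)
      }
    }
    if (comparison$null_statistic == "max") null_sizes <- per_perm_max
    list(null_sizes = null_sizes,
         threshold = as.numeric(quantile(null_sizes, 1 - comparison$cluster_alpha,
                                         names = FALSE, type = 7)),
         n_permutations = comparison$n_permutations)
  })
}

#' Cohen's d map
#'
#' Standardized mean difference `(mean_a - mean_b) / pooled SD` per bin;
#' bins with zero pooled SD get d = 0.
#'
#' @param group_a,group_b As in [pointwise_tmap()].
#' @return Numeric matrix of d values.
#' @export
cohens_d_map <- function(group_a, group_b) {
  A <- as_obs_matrix(group_a); B <- as_obs_matrix(group_b)
  assert_that(identical(A$dims, B$dims), "groups must share one grid")
  assert_that(nrow(A$m) >= 2 && nrow(B$m) >= 2,
              "need at least 2 observations per group")
  na <- nrow(A$m); nb <- nrow(B$m)
  ma <- colMeans(A$m); mb <- colMeans(B$m)
  va <- apply(A$m, 2, var); vb <- apply(B$m, 2, var)
  sp <- sqrt(((na - 1) * va + (nb - 1) * vb) / (na + nb - 2))
  d <- (ma - mb) / sp
  d[!is.finite(d)] <- 0
  matrix(d, A$dims[1], A$dims[2])
}

#' Gate observed clusters
#'
#' A cluster from the observed comparison is retained iff its size is at
#' least `min_extent` bins (the 5 x 5 rule), its mean |Cohen's d| over
#' member bins is strictly greater than `min_mean_d`, and its size strictly
#' exceeds the permutation-null threshold.
#'
#' @param clusters List from [find_clusters()].
#' @param d_map Matrix from [cohens_d_map()].
#' @param threshold Null 95th-percentile cluster size.
#' @param comparison A [tf_comparison()] (extent and d gates).
#' @param freqs Optional frequency axis to annotate bands touched.
#' @param sign Cluster sign (+1 sink of group_a > b, -1 otherwise).
#' @return Tibble with one row per input cluster: `cluster_id`, `size`,
#'   `mass` (left `NA` here; filled by [tf_cluster_test()]), `mean_d`,
#'   `exceeds_null`, `significant`, `bands_touched`, and a `bins`
#'   list-column.
#' @export
gate_clusters <- function(clusters, d_map, threshold,
                          comparison = tf_comparison(), freqs = NULL,
                          sign = NA_real_) {
  if (length(clusters) == 0) {
    return(tibble::tibble(cluster_id = integer(), sign = numeric(),
                          size = integer(), mass = numeric(),
                          mean_d = numeric(), p_perm = numeric(),
                          exceeds_null = logical(), significant = logical(),
                          bands_touched = character(), bins = list()))
  }
  rows <- lapply(seq_along(clusters), function(i) {
    cl <- clusters[[i]]
    dvals <- d_map[cl$bins]
    bands <- if (is.null(freqs)) NA_character_ else
      paste(sort(unique(stats::na.omit(annotate_bands(freqs[cl$bins[, "row"]])))),
            collapse = ",")
    tibble::tibble(
      cluster_id = i, sign = sign, size = cl$size, mass = NA_real_,
      mean_d = mean(abs(dvals)), p_perm = NA_real_,
      exceeds_null = cl$size > threshold,
      significant = cl$size >= comparison$min_extent &
        mean(abs(dvals)) > comparison$min_mean_d &
        cl$size > threshold,
      bands_touched = bands, bins = list(cl$bins))
  })
  dplyr::bind_rows(rows)
}

#' Full cluster-mass permutation test
#'
#' End-to-end comparison of two sets of time-frequency power maps:
#' point-wise two-tailed t-test, sign-split connected clusters, permutation
#' null of the maximum cluster size, Cohen's d map, and extent / effect-size
#' gating. Cluster mass (sum of |t| over members) and a permutation p-value
#' (fraction of null maxima at or above the observed size) are reported for
#' every observed cluster.
#'
#' @param group_a,group_b 3-D arrays `[obs, f, t]` or lists of matrices.
#' @param comparison A [tf_comparison()].
#' @param seed Integer seed for the permutation null.
#' @param freqs,time_ms Optional axes (band annotation / plotting).
#' @param exclude Optional logical matrix of excluded bins (e.g. cone of
#'   influence).
#' @return A `lam_cluster_test`: the gated cluster tibble plus attributes
#'   `t_map`, `d_map`, `threshold`, `null_sizes`, `comparison`, `freqs`,
#'   `time_ms`.
#' @export
tf_cluster_test <- function(group_a, group_b, comparison = tf_comparison(),
                            seed = 1L, freqs = NULL, time_ms = NULL,
                            exclude = NULL) {
  tm <- pointwise_tmap(group_a, group_b, comparison$alpha_pointwise)
  dm <- cohens_d_map(group_a, group_b)
  null <- permutation_null(group_a, group_b, comparison, seed, exclude)
  mask <- tm$mask
  if (!is.null(exclude)) mask <- mask & !exclude
  res <- list()
  for (sgn in c(1, -1)) {
    cl <- find_clusters(mask & (sign(tm$t) == sgn), comparison$connectivity)
    res[[length(res) + 1]] <-
      gate_clusters(cl, dm, null$threshold, comparison, freqs, sign = sgn)
  }
  out <- dplyr::bind_rows(res)
  if (nrow(out)) {
    out$mass <- vapply(out$bins, function(b) sum(abs(tm$t[b])), numeric(1))
    out$p_perm <- vapply(out$size, function(s) {
      (1 + sum(null$null_sizes >= s)) / (1 + length(null$null_sizes))
    }, numeric(1))
    out$cluster_id <- seq_len(nrow(out))
  }
  structure(out,
            class = c("lam_cluster_test", class(out)),
            t_map = tm$t, d_map = dm, threshold = null$threshold,
            null_sizes = null$null_sizes, comparison = comparison,
            freqs = freqs, time_ms = time_ms)
}

#' @export
print.lam_cluster_test <- function(x, ...) {
  cat(sprintf("<lam_cluster_test> %d cluster(s), %d significant; null threshold %g bins\n",
              nrow(x), sum(x$significant), attr(x, "threshold")))
  NextMethod()
}
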