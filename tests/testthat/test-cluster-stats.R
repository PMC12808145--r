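test_that("point-wise t-maps match the pooled-variance closed form", {
  g <- gauss_groups(5, 5, nf = 4, nt = 6, seed = 1)
  tm0 <- pointwise_tmap(g$A, g$A)
  expect_true(all(tm0$t == 0))
  expect_true(all(tm0$p == 1))
  a <- array(0, dim = c(3, 1, 1)); a[, 1, 1] <- c(1, 2, 3)
  b <- array(0, dim = c(3, 1, 1)); b[, 1, 1] <- c(4, 5, 6)
  tm <- pointwise_tmap(a, b)
  expect_equal(as.numeric(tm$t), -3.674235, tolerance = 1e-6)
  expect_equal(as.numeric(tm$p),
               2 * pt(3.674235, df = 4, lower.tail = FALSE), tolerance = 1e-6)
  # p exactly equal to alpha is not significant (strict <)
  p_obs <- as.numeric(tm$p)
  tm_at <- pointwise_tmap(a, b, alpha = p_obs)
  expect_false(any(tm_at$mask))
  # zero variance in both groups: t = 0, p = 1
  z1 <- array(1, dim = c(3, 1, 1)); z2 <- array(2, dim = c(3, 1, 1))
  tmz <- pointwise_tmap(z1, z1)
  expect_equal(as.numeric(tmz$t), 0)
  expect_equal(as.numeric(tmz$p), 1)
  expect_error(pointwise_tmap(a, b[1, , , drop = FALSE]), "2 observations")
})

test_that("connected components match a flood-fill oracle", {
  full <- matrix(TRUE, 10, 10)
  cl <- find_clusters(full, 8)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$size, 100)
  # checkerboard under 4-connectivity: every bin is its own cluster
  chk <- outer(1:6, 1:6, function(i, j) (i + j) %% 2 == 0)
  cl4 <- find_clusters(chk, 4)
  expect_length(cl4, sum(chk))
  expect_true(all(vapply(cl4, `[[`, integer(1), "size") == 1))
  # two blobs separated by a false row
  two <- matrix(FALSE, 9, 9)
  two[1:3, 2:5] <- TRUE
  two[6:8, 4:9] <- TRUE
  sizes <- sort(vapply(find_clusters(two, 8), `[[`, integer(1), "size"))
  expect_equal(sizes, c(12, 18))
  # random masks against the igraph oracle, both connectivities
  skip_if_not_installed("igraph")
  set.seed(5)
  for (rep in 1:6) {
    m <- matrix(runif(15 * 20) < 0.35, 15, 20)
    for (conn in c(4, 8)) {
      mine <- sort(vapply(find_clusters(m, conn), `[[`, integer(1), "size"),
                   decreasing = TRUE)
      expect_equal(mine, igraph_components(m, conn))
    }
  }
  # every true bin in exactly one cluster
  m <- matrix(runif(12 * 12) < 0.4, 12, 12)
  cl <- find_clusters(m, 8)
  bins <- do.call(rbind, lapply(cl, `[[`, "bins"))
  expect_equal(nrow(bins), sum(m))
  expect_false(anyDuplicated(bins) > 0)
})

test_that("the permutation null is seeded, reproducible and exchangeable", {
  g <- gauss_groups(12, 12, nf = 10, nt = 10, seed = 2)
  cmp <- tf_comparison(n_permutations = 100)
  n1 <- permutation_null(g$A, g$B, cmp, seed = 9)
  n2 <- permutation_null(g$A, g$B, cmp, seed = 9)
  expect_identical(n1, n2)
  n3 <- permutation_null(g$A, g$B, cmp, seed = 10)
  expect_false(identical(n1$null_sizes, n3$null_sizes))
  expect_warning(
    permutation_null(array(rnorm(8), dim = c(2, 2, 2)),
                     array(rnorm(8), dim = c(2, 2, 2)),
                     tf_comparison(n_permutations = 50), seed = 1),
    "permutations")
  # exchangeability: permuting the inputs leaves the null unchanged in law
  ks_ps <- vapply(1:10, function(s) {
    g <- gauss_groups(10, 10, nf = 8, nt = 8, seed = 100 + s)
    null_a <- permutation_null(g$A, g$B, cmp, seed = s)$null_sizes
    set.seed(1000 + s)
    C <- lamcsd:::abind3(g$A, g$B)
    idx <- sample(20)
    null_b <- permutation_null(C[idx[1:10], , , drop = FALSE],
                               C[idx[11:20], , , drop = FALSE],
                               cmp, seed = s + 5000)$null_sizes
    suppressWarnings(stats::ks.test(null_a, null_b)$p.value)
  }, numeric(1))
  expect_gt(min(ks_ps), 0.01)
})

test_that("Cohen's d maps follow the pooled-SD definition", {
  g <- gauss_groups(6, 6, nf = 3, nt = 3, seed = 3)
  expect_true(all(cohens_d_map(g$A, g$A) == 0))
  # degenerate zero pooled SD -> 0
  a <- array(0, dim = c(2, 1, 1)); b <- array(1, dim = c(2, 1, 1))
  expect_equal(as.numeric(cohens_d_map(a, b)), 0)
  # simulation: d ~ 1 for unit mean shift at n = 200
  set.seed(4)
  A <- array(rnorm(200 * 2 * 2, mean = 1), dim = c(200, 2, 2))
  B <- array(rnorm(200 * 2 * 2, mean = 0), dim = c(200, 2, 2))
  expect_lt(max(abs(cohens_d_map(A, B) - 1)), 0.2)
})

test_that("gating applies extent, effect-size and null rules strictly", {
  cmp <- tf_comparison()
  d_map <- matrix(0.9, 30, 30)
  mk <- function(n_bins) {
    # a single row-run of n_bins connected bins
    list(list(bins = cbind(row = rep(1:5, length.out = n_bins),
                           col = rep(1:6, each = 5)[seq_len(n_bins)]),
              size = n_bins))
  }
  # 24 bins, huge d, above null threshold: removed by extent
  g24 <- gate_clusters(mk(24), d_map, threshold = 3, cmp)
  expect_false(any(g24$significant))
  # 30 bins but mean |d| = 0.39: removed by the effect-size gate
  g39 <- gate_clusters(mk(30), matrix(0.39, 30, 30), threshold = 3, cmp)
  expect_false(any(g39$significant))
  expect_equal(g39$mean_d, 0.39)
  # d exactly 0.4 is also removed (strictly greater than)
  g40 <- gate_clusters(mk(30), matrix(0.4, 30, 30), threshold = 3, cmp)
  expect_false(any(g40$significant))
  # 30 bins, d = 0.6, above threshold: retained
  g60 <- gate_clusters(mk(30), matrix(0.6, 30, 30), threshold = 3, cmp)
  expect_true(all(g60$significant))
  # size equal to the threshold is not retained (strict exceedance)
  gth <- gate_clusters(mk(30), matrix(0.6, 30, 30), threshold = 30, cmp)
  expect_false(any(gth$significant))
  # 25 bins passes the extent rule
  g25 <- gate_clusters(mk(25), matrix(0.6, 30, 30), threshold = 3, cmp)
  expect_true(all(g25$significant))
})

test_that("raising either gate never adds a retained cluster", {
  g <- gauss_groups(25, 25, nf = 15, nt = 20, effect = 0.9,
                    block_f = 3:9, block_t = 5:12, seed = 6)
  base <- tf_comparison(n_permutations = 100)
  res <- tf_cluster_test(g$A, g$B, base, seed = 2)
  kept <- res$cluster_id[res$significant]
  for (cmp2 in list(tf_comparison(n_permutations = 100, min_extent = 40),
                    tf_comparison(n_permutations = 100, min_mean_d = 0.8))) {
    res2 <- tf_cluster_test(g$A, g$B, cmp2, seed = 2)
    expect_true(all(res2$cluster_id[res2$significant] %in% kept))
  }
})

test_that("an injected block effect is detected and band-annotated", {
  g <- gauss_groups(40, 40, nf = 20, nt = 25, effect = 1,
                    block_f = 5:14, block_t = 8:17, seed = 7)
  freqs <- lamcsd:::cwt_freq_grid(cwt_config(f_min = 30, f_max = 60,
                                             voices_per_octave = 19))
  res <- tf_cluster_test(g$A, g$B, tf_comparison(n_permutations = 200),
                         seed = 3, freqs = freqs[1:20])
  expect_gt(sum(res$significant), 0)
  top <- res[which.max(res$size), ]
  expect_equal(top$sign, 1)
  # the winning cluster overlaps the injected block
  bins <- top$bins[[1]]
  frac_in <- mean(bins[, "row"] %in% 5:14 & bins[, "col"] %in% 8:17)
  expect_gt(frac_in, 0.6)
  expect_match(top$bands_touched, "low_gamma")
  expect_gt(top$mean_d, 0.4)
  # mass is the sum of |t| over members
  tmap <- attr(res, "t_map")
  expect_equal(top$mass, sum(abs(tmap[bins])), tolerance = 1e-12)
})

test_that("repeated-measures ANOVA recovers effects and labels sizes", {
  expect_identical(effect_size_label(0.05), "small")
  expect_identical(effect_size_label(0.1), "small")
  expect_identical(effect_size_label(0.15), "medium")
  expect_identical(effect_size_label(0.30), "large")
  expect_identical(effect_size_label(0.25), "large")
  # Holm step-down: (0.01, 0.02, 0.04) -> (0.03, 0.04, 0.04)
  expect_equal(p.adjust(c(0.01, 0.02, 0.04), "holm"), c(0.03, 0.04, 0.04))
  set.seed(8)
  df <- expand.grid(subject = paste0("s", 1:8),
                    choice = c("hit", "miss", "false_alarm",
                               "correct_rejection"),
                    rep = 1:8, stringsAsFactors = FALSE)
  df$z <- rnorm(nrow(df)) + ifelse(df$choice == "hit", 1.2, 0)
  res <- rm_anova_stage(df)
  expect_lt(res$anova$p.value, 0.01)
  expect_true(res$eta2_gen > 0 && res$eta2_gen < 1)
  expect_true(all(res$posthoc$p.adj >= res$posthoc$p.value))
  hitrows <- grepl("hit", res$posthoc$contrast) &
    !grepl("false", res$posthoc$contrast)
  expect_true(all(res$posthoc$p.adj[hitrows] < 0.05))
  # null data: tiny eta2
  df$z <- rnorm(nrow(df))
  res0 <- rm_anova_stage(df)
  expect_lt(res0$eta2_gen, 0.1)
  expect_identical(res0$eta2_label, "small")
  # a subject missing a level is dropped and counted
  df2 <- df[!(df$subject == "s1" & df$choice == "miss"), ]
  res2 <- rm_anova_stage(df2)
  expect_equal(res2$n_dropped_subjects, 1L)
})
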