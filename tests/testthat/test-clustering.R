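# Standardization, Ward linkage, Hartigan-Wong k-means, gap statistic,
# silhouette, bootstrap stability and the sum-of-squares decomposition.

two_blobs <- function(n1 = 8, n2 = 8, sep = 10, sd = 0.2, seed = 1, p = 3) {
  withr::with_seed(seed, {
    rbind(matrix(rnorm(n1 * p, 0, sd), n1, p),
          matrix(rnorm(n2 * p, sep, sd), n2, p))
  })
}

test_that("standardization fixes the total sum of squares at (n-1)p", {
  set.seed(3)
  for (rep in 1:5) {
    m <- matrix(rnorm(39, sd = runif(1, 0.5, 20)), 13, 3)
    z <- standardize_features(m)
    expect_equal(sum(sweep(z, 2, colMeans(z))^2), 36, tolerance = 1e-10)
  }
  # idempotence
  z <- standardize_features(matrix(rnorm(39), 13, 3))
  expect_equal(unclass(standardize_features(z)), unclass(z),
               ignore_attr = TRUE, tolerance = 1e-12)
  # constant column is an error
  bad <- cbind(rnorm(10), rep(1, 10))
  expect_error(standardize_features(bad), class = "dyadsync_input_error")
})

test_that("Ward clustering separates constructed blobs and orders merges", {
  m <- two_blobs()
  w <- ward_cluster(m, k = 2)
  expect_equal(length(unique(w$labels[1:8])), 1)
  expect_equal(length(unique(w$labels[9:16])), 1)
  expect_true(all(diff(w$heights) >= -1e-12))
  # duplicate points merge first at height zero
  dup <- rbind(c(0, 0), c(0, 0), c(5, 5), c(9, 9))
  wd <- ward_cluster(dup)
  expect_equal(wd$heights[1], 0)
  # n = 2, k = 2: singletons
  expect_equal(sort(ward_cluster(rbind(c(0, 0), c(1, 1)), k = 2)$labels), 1:2)
  expect_error(ward_cluster(m, k = 20), class = "dyadsync_input_error")
})

test_that("k-means recovers generator clusters and degenerate k", {
  feats <- simulate_hrv_features(seed = 2)
  km <- kmeans_hw(standardize_features(feats), 2, seed = 1)
  expect_equal(adjusted_rand_index(km$labels, feats$cluster), 1)
  expect_equal(km$ssb + sum(km$ssw), km$sst, tolerance = 1e-8)
  # k = 1: no between variance
  km1 <- kmeans_hw(two_blobs(), 1, seed = 1)
  expect_equal(km1$ssb, 0, tolerance = 1e-10)
  # k = n: no within variance
  m <- two_blobs(3, 3)
  kmn <- kmeans_hw(m, nrow(m), seed = 1)
  expect_equal(sum(kmn$ssw), 0)
  expect_error(kmeans_hw(m, 10, seed = 1), class = "dyadsync_input_error")
})

test_that("sum-of-squares decomposition conserves total for any labeling", {
  set.seed(8)
  m <- standardize_features(matrix(rnorm(39), 13, 3))
  for (rep in 1:20) {
    labels <- sample(1:3, 13, replace = TRUE)
    if (length(unique(labels)) < 2) next
    dec <- ss_decomposition(m, labels)
    expect_equal(dec$ssb + sum(dec$ssw), dec$sst, tolerance = 1e-8)
    expect_equal(dec$sst, 36, tolerance = 1e-10)
  }
  one <- ss_decomposition(m, rep(1, 13))
  expect_equal(one$ssb, 0, tolerance = 1e-10)
  expect_equal(unname(one$ssw), one$sst)
  each <- ss_decomposition(m, 1:13)
  expect_equal(sum(each$ssw), 0)
  expect_equal(each$ssb, each$sst)
})

test_that("gap statistic finds constructed structure", {
  g2 <- gap_statistic(two_blobs(), k_max = 5, B = 50, seed = 1)
  expect_equal(g2$k_hat, 2)
  # single uniform blob: k = 1
  blob <- withr::with_seed(4, matrix(runif(60), 20, 3))
  g1 <- gap_statistic(blob, k_max = 5, B = 50, seed = 1)
  expect_equal(g1$k_hat, 1)
  expect_error(gap_statistic(two_blobs(), B = 5),
               class = "dyadsync_config_error")
  expect_error(gap_statistic(matrix(1, 10, 2), B = 50),
               class = "dyadsync_input_error")
})

test_that("silhouette agrees with the reference implementation", {
  m <- standardize_features(simulate_hrv_features(seed = 5))
  km <- kmeans_hw(m, 2, seed = 1)
  mine <- silhouette_mean(m, km$labels)
  ref <- mean(cluster::silhouette(km$labels, dist(m))[, 3])
  expect_equal(mine, ref, tolerance = 1e-12)
  expect_gt(silhouette_mean(two_blobs(), rep(1:2, each = 8)), 0.9)
  # random labels on a single blob: near zero
  blob <- withr::with_seed(6, matrix(rnorm(100 * 2), 100, 2))
  sil <- silhouette_mean(blob, withr::with_seed(7, sample(1:2, 100, TRUE)))
  expect_lt(abs(sil), 0.1)
  expect_error(silhouette_mean(blob, rep(1, 100)),
               class = "dyadsync_input_error")
})

test_that("bootstrap stability separates real from spurious structure", {
  expect_gt(bootstrap_stability(two_blobs(), 2, B = 100, seed = 1), 0.95)
  blob <- withr::with_seed(9, matrix(runif(40), 20, 2))
  expect_lt(bootstrap_stability(blob, 2, B = 100, seed = 1), 0.9)
  expect_error(bootstrap_stability(two_blobs(2, 1), 2, B = 100),
               class = "dyadsync_input_error")
  expect_error(bootstrap_stability(two_blobs(), 2, B = 1),
               class = "dyadsync_config_error")
  expect_warning(bootstrap_stability(two_blobs(), 2, B = 10, seed = 1))
})

test_that("adjusted Rand index behaves at its anchors", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 1, 1), c(1, 1, 1, 1)), 1)
  set.seed(10)
  r <- replicate(200, adjusted_rand_index(sample(1:2, 40, TRUE),
                                          sample(1:2, 40, TRUE)))
  expect_lt(abs(mean(r)), 0.05)
})

test_that("the two-stage workflow assembles a coherent solution", {
  feats <- simulate_hrv_features(seed = 1)
  fit <- cluster_hrv(feats, k = 2, gap_B = 50, boot_B = 100, seed = 1)
  expect_s3_class(fit, "hrv_clusters")
  expect_equal(fit$sst, 36, tolerance = 1e-10)
  expect_equal(fit$ssb + sum(fit$ssw), fit$sst, tolerance = 1e-8)
  expect_equal(adjusted_rand_index(fit$labels, feats$cluster), 1)
  expect_equal(fit$gap$k_hat, 2)
  expect_gte(fit$silhouette, -1)
  expect_lte(fit$silhouette, 1)
  expect_gte(fit$stability, 0.8)
  td <- tidy(fit)
  expect_equal(nrow(td), 13)
  expect_true(all(c("cluster", "hier_cluster") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$k, 2)
  # hierarchical stage reports 3 descriptive clusters
  expect_equal(length(unique(fit$hier_labels)), 3)
})
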