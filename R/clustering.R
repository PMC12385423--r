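# Two-stage cluster analysis of per-dyad phase-wise HRV synchrony:
# hierarchical Ward linkage for structure, Hartigan-Wong k-means for the
# final solution, validated by gap statistic, silhouette and bootstrap
# Jaccard stability.

as_feature_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  x <- as.data.frame(x)
  num <- vapply(x, is.numeric, logical(1))
  id <- if ("dyad" %in% names(x)) x$dyad else seq_len(nrow(x))
  # a table holding the phase triple uses exactly those columns; anything
  # else (cluster labels, questionnaire scores, ids) is not a feature
  cols <- if (all(task_phases() %in% names(x))) task_phases()
          else setdiff(names(x)[num], c("dyad", "cluster"))
  m <- as.matrix(x[, cols, drop = FALSE])
  rownames(m) <- id
  m
}

#' Standardize clustering features
#'
#' Centers each column and scales it to unit sample variance (divisor
#' `n - 1`). After standardization the total sum of squares about the grand
#' centroid is exactly `(n - 1) * p` for an `n x p` input -- 36 for the
#' canonical 13 dyads x 3 phases -- which anchors the sum-of-squares
#' decomposition reported with a cluster solution.
#'
#' @param x Numeric matrix or data frame (a `dyad` id column is preserved as
#'   row names); `n >= 2`, all values finite, no constant column.
#' @return Standardized numeric matrix with attributes `center` and `scale`.
#' @export
#' @examples
#' z <- standardize_features(matrix(rnorm(39), 13, 3))
#' sum(scale(z, scale = FALSE)^2) # 36
standardize_features <- function(x) {
  m <- as_feature_matrix(x)
  if (nrow(m) < 2) {
    abort("need at least 2 rows", class = "dyadsync_input_error")
  }
  check_finite(m, "features")
  s <- apply(m, 2, sd)
  if (any(s == 0)) {
    abort(paste0("zero-variance column(s): ",
                 paste(colnames(m)[s == 0], collapse = ", ")),
          class = "dyadsync_input_error")
  }
  out <- scale(m)
  attr_center <- attr(out, "scaled:center")
  attr_scale <- attr(out, "scaled:scale")
  out <- out[, , drop = FALSE]
  attr(out, "center") <- attr_center
  attr(out, "scale") <- attr_scale
  out
}

#' Hierarchical Ward clustering
#'
#' Agglomerative minimum-variance (Ward) linkage on Euclidean distances
#' (the `ward.D2` convention, which takes untransformed distances), with an
#' optional cut into `k` clusters.
#'
#' @param x Feature matrix (typically [standardize_features()] output).
#' @param k Optional number of clusters to cut the tree at (`k <= n`).
#' @return List with `hclust` (the tree), `heights` (merge heights,
#'   non-decreasing) and, when `k` is given, `labels`.
#' @export
ward_cluster <- function(x, k = NULL) {
  m <- as_feature_matrix(x)
  if (nrow(m) < 2) {
    abort("need at least 2 rows", class = "dyadsync_input_error")
  }
  hc <- hclust(dist(m), method = "ward.D2")
  out <- list(hclust = hc, heights = hc$height)
  if (!is.null(k)) {
    if (k > nrow(m)) {
      abort("k cannot exceed the number of rows",
            class = "dyadsync_input_error")
    }
    out$labels <- as.integer(cutree(hc, k = k))
  }
  out
}

#' Hartigan-Wong k-means
#'
#' Best-of-`n_start` k-means (Hartigan-Wong algorithm) by total
#' within-cluster sum of squares, deterministic given `seed`. Runs hitting
#' an empty cluster are retried with fresh starts.
#'
#' @param x Feature matrix.
#' @param k Number of clusters (`k <= n`).
#' @param n_start Number of random starts.
#' @param seed Integer seed.
#' @return Object of class `kmeans_solution`: list with `labels`,
#'   `centroids` (k x p), `ssw` (per cluster), `ssb`, `sst`, `sizes`, `k`.
#' @export
kmeans_hw <- function(x, k, n_start = 25, seed = 1L) {
  m <- as_feature_matrix(x)
  if (k > nrow(m)) {
    abort("k cannot exceed the number of rows", class = "dyadsync_input_error")
  }
  if (k == nrow(m)) {  # every point its own cluster; zero within variance
    grand <- colMeans(m)
    return(structure(list(labels = seq_len(nrow(m)), centroids = m,
                          ssw = rep(0, k), ssb = sum(sweep(m, 2, grand)^2),
                          sst = sum(sweep(m, 2, grand)^2),
                          sizes = rep(1L, k), k = k),
                     class = "kmeans_solution"))
  }
  km <- withr::with_seed(as.integer(seed), {
    fit <- NULL
    for (attempt in 1:5) {
      fit <- tryCatch(
        suppressWarnings(kmeans(m, centers = k, nstart = n_start,
                                iter.max = 100,
                                algorithm = "Hartigan-Wong")),
        error = function(e) NULL)
      if (!is.null(fit) && all(fit$size > 0)) break
    }
    if (is.null(fit)) {
      abort("k-means failed to produce k non-empty clusters",
            class = "dyadsync_cluster_error")
    }
    fit
  })
  structure(list(labels = as.integer(km$cluster), centroids = km$centers,
                 ssw = km$withinss, ssb = km$betweenss, sst = km$totss,
                 sizes = km$size, k = k),
            class = "kmeans_solution")
}

#' Sum-of-squares decomposition of a labeled data set
#'
#' Total sum of squares about the grand centroid, within-cluster sums of
#' squares about each cluster centroid, and their difference, the
#' between-cluster sum of squares. For every labeling,
#' `ssb + sum(ssw) = sst`.
#'
#' @param x Feature matrix.
#' @param labels Integer cluster labels covering all rows.
#' @return List with `ssw` (named per cluster), `ssb`, `sst`.
#' @export
ss_decomposition <- function(x, labels) {
  m <- as_feature_matrix(x)
  if (length(labels) != nrow(m)) {
    abort("labels must cover all rows", class = "dyadsync_input_error")
  }
  grand <- colMeans(m)
  sst <- sum(sweep(m, 2, grand)^2)
  ssw <- vapply(sort(unique(labels)), function(cl) {
    sub <- m[labels == cl, , drop = FALSE]
    sum(sweep(sub, 2, colMeans(sub))^2)
  }, numeric(1))
  names(ssw) <- sort(unique(labels))
  list(ssw = ssw, ssb = sst - sum(ssw), sst = sst)
}

kmeans_withinss <- function(m, k, n_start) {
  if (k == 1) {
    sum(sweep(m, 2, colMeans(m))^2)
  } else {
    suppressWarnings(
      kmeans(m, centers = k, nstart = n_start, iter.max = 100,
             algorithm = "Hartigan-Wong")$tot.withinss)
  }
}

# k-means labels robust to degenerate resamples (duplicated rows, k close to
# the number of distinct points); falls back to distinct-row labels or a
# Ward cut rather than failing
safe_kmeans_labels <- function(m, k, n_start) {
  u <- unique(m)
  if (nrow(u) <= k) {
    key <- apply(m, 1, paste, collapse = "\r")
    return(match(key, unique(key)))
  }
  fit <- tryCatch(
    suppressWarnings(kmeans(m, centers = k, nstart = n_start,
                            iter.max = 100, algorithm = "Hartigan-Wong")),
    error = function(e) NULL)
  if (is.null(fit)) {
    cutree(hclust(dist(m), method = "ward.D2"), k = k)
  } else {
    fit$cluster
  }
}

#' Gap statistic for choosing the number of clusters
#'
#' Tibshirani's gap: `mean_b log(W*_kb) - log(W_k)`, with `B` reference data
#' sets drawn uniformly in the principal-component-aligned bounding box of
#' the data.
#'
#' With `rule = "tibshirani"` (default) the chosen k is the smallest k whose
#' gap is within one simulation standard error of the next gap
#' (`gap(k) >= gap(k+1) - se(k+1)`), the selection rule proposed with the
#' statistic and the default of the R clustering ecosystem.
#' `rule = "global-max"` takes the curve's global maximum instead; at small
#' n that reading is unstable because splitting an already-tight cluster
#' keeps shrinking `log(W)` faster than the uniform reference does.
#'
#' @param x Feature matrix with `n > k_max` rows and positive dispersion.
#' @param k_max Largest k evaluated.
#' @param B Number of reference sets (`>= 10`).
#' @param seed Integer seed.
#' @param n_start Random starts per k-means run.
#' @param rule Selection rule, `"tibshirani"` or `"global-max"`.
#' @return List with `table` (tibble `k`, `log_w`, `gap`, `se`), `k_hat`
#'   (chosen by `rule`) and `k_global` (the global maximum).
#' @export
gap_statistic <- function(x, k_max = 6, B = 100, seed = 1L, n_start = 10,
                          rule = c("tibshirani", "global-max")) {
  rule <- match.arg(rule)
  m <- as_feature_matrix(x)
  if (nrow(m) <= k_max) {
    abort("need more rows than k_max", class = "dyadsync_input_error")
  }
  if (B < 10) {
    abort("B below 10 gives an unstable reference distribution",
          class = "dyadsync_config_error")
  }
  if (sum(sweep(m, 2, colMeans(m))^2) == 0) {
    abort("zero dispersion: all points identical",
          class = "dyadsync_input_error")
  }
  centered <- sweep(m, 2, colMeans(m))
  V <- svd(centered)$v
  proj <- centered %*% V
  lo <- apply(proj, 2, min)
  hi <- apply(proj, 2, max)
  withr::with_seed(as.integer(seed), {
    log_w <- vapply(seq_len(k_max), function(k) {
      log(kmeans_withinss(m, k, n_start))
    }, numeric(1))
    log_wref <- matrix(NA_real_, B, k_max)
    for (b in seq_len(B)) {
      ref <- sapply(seq_along(lo), function(j) runif(nrow(m), lo[j], hi[j]))
      ref <- ref %*% t(V)
      log_wref[b, ] <- vapply(seq_len(k_max), function(k) {
        log(kmeans_withinss(ref, k, n_start))
      }, numeric(1))
    }
    gap <- colMeans(log_wref) - log_w
    se <- apply(log_wref, 2, sd) * sqrt(1 + 1 / B)
    k_global <- which.max(gap)
    k_se <- k_max
    for (k in seq_len(k_max - 1)) {
      if (gap[k] >= gap[k + 1] - se[k + 1]) {
        k_se <- k
        break
      }
    }
    list(table = tibble(k = seq_len(k_max), log_w = log_w, gap = gap,
                        se = se),
         k_hat = if (rule == "tibshirani") k_se else k_global,
         k_global = k_global)
  })
}

#' Mean silhouette coefficient
#'
#' Mean over points of `(b - a) / max(a, b)` where `a` is the mean distance
#' to the point's own cluster and `b` the smallest mean distance to another
#' cluster; singleton points contribute 0. Requires at least two clusters.
#'
#' @param x Feature matrix.
#' @param labels Integer cluster labels.
#' @return Scalar in `[-1, 1]`.
#' @export
silhouette_mean <- function(x, labels) {
  m <- as_feature_matrix(x)
  labs <- as.integer(factor(labels))
  if (length(unique(labs)) < 2) {
    abort("silhouette needs at least 2 clusters",
          class = "dyadsync_input_error")
  }
  d <- as.matrix(dist(m))
  n <- nrow(m)
  s <- vapply(seq_len(n), function(i) {
    own <- labs == labs[i]
    if (sum(own) == 1) return(0)
    a <- sum(d[i, own]) / (sum(own) - 1)
    b <- min(vapply(setdiff(unique(labs), labs[i]), function(cl) {
      mean(d[i, labs == cl])
    }, numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(1)
  length(intersect(a, b)) / u
}

#' Bootstrap cluster stability (Jaccard index)
#'
#' For each of `B` bootstrap resamples, the resampled rows are re-clustered
#' with k-means and each original cluster is matched to the resampled
#' cluster with which it shares the largest Jaccard overlap (computed on the
#' original row indices present in the resample). The stability index is the
#' mean of those maximal overlaps over clusters and resamples; values near 1
#' indicate a highly replicable partition.
#'
#' @param x Feature matrix with `n >= 2k` rows.
#' @param k Number of clusters.
#' @param B Number of resamples (`>= 2`; below 50 a warning is issued).
#' @param seed Integer seed.
#' @param n_start Random starts per k-means run.
#' @return Scalar in `[0, 1]`.
#' @export
bootstrap_stability <- function(x, k, B = 1000, seed = 1L, n_start = 10) {
  m <- as_feature_matrix(x)
  if (nrow(m) < 2 * k) {
    abort("need at least 2k rows", class = "dyadsync_input_error")
  }
  if (B < 2) {
    abort("B must be at least 2", class = "dyadsync_config_error")
  }
  if (B < 50) warn("B below 50 gives a noisy stability index")
  base <- kmeans_hw(m, k, n_start = n_start, seed = seed)$labels
  orig_sets <- lapply(seq_len(k), function(cl) which(base == cl))
  withr::with_seed(substream_seed(seed, "bootstrap"), {
    per_rep <- vapply(seq_len(B), function(b) {
      idx <- sample(nrow(m), replace = TRUE)
      labs <- safe_kmeans_labels(m[idx, , drop = FALSE], k, n_start)
      present <- unique(idx)
      res_sets <- lapply(unique(labs), function(cl) {
        unique(idx[labs == cl])
      })
      mean(vapply(orig_sets, function(os) {
        os_present <- intersect(os, present)
        max(vapply(res_sets, function(rs) jaccard(os_present, rs),
                   numeric(1)))
      }, numeric(1)))
    }, numeric(1))
    mean(per_rep)
  })
}

#' Adjusted Rand index between two labelings
#'
#' Permutation-invariant agreement: 1 for identical partitions, ~0 for
#' independent ones.
#'
#' @param a,b Label vectors of equal length.
#' @return Scalar (at most 1).
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) {
    abort("labelings must have equal length", class = "dyadsync_input_error")
  }
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Two-stage cluster analysis of HRV synchrony profiles
#'
#' The full workflow applied to per-dyad phase-wise HRV synchrony features
#' (columns `IP`, `NCP`, `RP`): standardize, explore structure with
#' hierarchical Ward linkage (a 3-cluster hierarchical reading is reported
#' descriptively), then fit the final Hartigan-Wong k-means solution at `k`
#' clusters; validate with the gap statistic, mean silhouette, bootstrap
#' Jaccard stability and the within/between sum-of-squares decomposition.
#'
#' @param features Tibble with a `dyad` column and numeric phase columns, or
#'   a numeric matrix.
#' @param k Number of clusters for the final k-means stage (`"auto"` to use
#'   the gap-statistic choice).
#' @param hier_k Cluster count for the descriptive hierarchical reading.
#' @param n_start,gap_B,boot_B,k_max Tuning parameters forwarded to the
#'   stage functions.
#' @param seed Integer seed.
#' @return Object of class `hrv_clusters` with [tidy()], [glance()] and
#'   [autoplot()] methods.
#' @export
#' @examples
#' feats <- simulate_hrv_features(seed = 1)
#' fit <- cluster_hrv(feats, k = 2, boot_B = 100)
#' glance(fit)
cluster_hrv <- function(features, k = 2, hier_k = 3, n_start = 25,
                        gap_B = 100, boot_B = 1000, k_max = 6, seed = 1L) {
  m <- standardize_features(features)
  ward <- ward_cluster(m, k = min(hier_k, nrow(m)))
  gap <- gap_statistic(m, k_max = min(k_max, nrow(m) - 1), B = gap_B,
                       seed = substream_seed(seed, "gap"))
  if (identical(k, "auto")) k <- gap$k_hat
  km <- kmeans_hw(m, k, n_start = n_start, seed = substream_seed(seed, "km"))
  dec <- ss_decomposition(m, km$labels)
  sil <- if (k >= 2) silhouette_mean(m, km$labels) else NA_real_
  stab <- bootstrap_stability(m, k, B = boot_B,
                              seed = substream_seed(seed, "boot"),
                              n_start = n_start)
  structure(list(
    features = m, k = k, kmeans = km, ward = ward, gap = gap,
    labels = km$labels, centroids = km$centroids,
    ssw = dec$ssw, ssb = dec$ssb, sst = dec$sst,
    silhouette = sil, stability = stab,
    hier_labels = ward$labels),
    class = "hrv_clusters")
}

#' @export
print.hrv_clusters <- function(x, ...) {
  cat(sprintf("<hrv_clusters> k = %d (gap chose %d); sizes: %s\n",
              x$k, x$gap$k_hat, paste(x$kmeans$sizes, collapse = "/")))
  cat(sprintf("  SS: within %s | between %.2f | total %.2f\n",
              paste(sprintf("%.2f", x$ssw), collapse = " + "),
              x$ssb, x$sst))
  cat(sprintf("  silhouette %.2f, bootstrap stability %.2f\n",
              x$silhouette, x$stability))
  invisible(x)
}

#' @rdname cluster_hrv
#' @param x An `hrv_clusters` object.
#' @param ... Unused.
#' @export
tidy.hrv_clusters <- function(x, ...) {
  tibble(dyad = rownames(x$features) %||% seq_len(nrow(x$features)),
         cluster = x$labels,
         hier_cluster = x$hier_labels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname cluster_hrv
#' @export
glance.hrv_clusters <- function(x, ...) {
  tibble(k = x$k, k_gap = x$gap$k_hat,
         ssb = x$ssb, sst = x$sst, ssw_total = sum(x$ssw),
         silhouette = x$silhouette, stability = x$stability)
}
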