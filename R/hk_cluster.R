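#' Lloyd K-means with k-means++ seeding and an SSE trace
#'
#' Plain Lloyd iterations under the squared-Euclidean distance: assign each
#' point to its nearest centroid, recompute centroids as member means, stop
#' when assignments no longer change or after `max_iter` iterations.  An
#' empty cluster is re-seeded to the point farthest from its current
#' centroid.  The per-iteration sum of squared errors is recorded and is
#' non-increasing by construction; `stats::kmeans` is deliberately not used
#' because it exposes neither the trace nor the re-seeding rule.
#'
#' @param features Numeric vector or `N x d` matrix.
#' @param k Number of clusters (`2 <= k <= N` required, `k >= 1` accepted).
#' @param max_iter Maximum Lloyd iterations (default 20).
#' @param seed RNG seed for the k-means++ initialization.
#' @param n_restarts Independent restarts; the best final SSE wins.
#' @return List with `assignments` (length-N integers in `1..k`),
#'   `centroids` (`k x d`), `sse` (final), `sse_trace` (per iteration) and
#'   `iterations`.
#' @export
hk_kmeans <- function(features, k, max_iter = 20L, seed = 1L,
                      n_restarts = 1L) {
  x <- if (is.matrix(features)) features else matrix(features, ncol = 1)
  n <- nrow(x)
  if (k > n) stop(sprintf("k = %d exceeds the number of points (%d)", k, n),
                  call. = FALSE)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- kmeans_once(x, k, max_iter, seed + (r - 1L))
    if (is.null(best) || fit$sse < best$sse) best <- fit
  }
  best
}

kmeans_once <- function(x, k, max_iter, seed) {
  n <- nrow(x); d <- ncol(x)
  set.seed(seed)
  # k-means++ seeding
  cent <- matrix(0, k, d)
  cent[1, ] <- x[sample.int(n, 1), ]
  if (k > 1) {
    d2 <- rowSums((x - matrix(cent[1, ], n, d, byrow = TRUE))^2)
    for (j in 2:k) {
      p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      cent[j, ] <- x[sample.int(n, 1, prob = p), ]
      d2 <- pmin(d2, rowSums((x - matrix(cent[j, ], n, d, byrow = TRUE))^2))
    }
  }
  dist2 <- function(cent) {
    # N x k squared Euclidean distances
    dd <- matrix(rowSums(x^2), n, k) +
      matrix(rowSums(cent^2), n, k, byrow = TRUE) - 2 * x %*% t(cent)
    pmax(dd, 0)
  }
  dd <- dist2(cent)
  assign <- max.col(-dd, ties.method = "first")
  sse_trace <- numeric(0)
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    iterations <- it
    # update step
    for (j in seq_len(k)) {
      members <- assign == j
      if (!any(members)) {
        # re-seed an empty cluster to the point farthest from its centroid
        far <- which.max(dd[cbind(seq_len(n), assign)])
        cent[j, ] <- x[far, ]
      } else {
        cent[j, ] <- colMeans(x[members, , drop = FALSE])
      }
    }
    dd <- dist2(cent)
    new_assign <- max.col(-dd, ties.method = "first")
    sse_trace <- c(sse_trace, sum(dd[cbind(seq_len(n), new_assign)]))
    if (all(new_assign == assign) && it > 1L) { assign <- new_assign; break }
    assign <- new_assign
  }
  list(assignments = assign, centroids = cent,
       sse = if (length(sse_trace)) sse_trace[length(sse_trace)] else
         sum(dd[cbind(seq_len(n), assign)]),
       sse_trace = sse_trace, iterations = iterations)
}

#' Two-level hierarchical K-means on the fusion image
#'
#' Top-down scheme: level 1 clusters the valid pixels' fusion gray values
#' into `k1` groups; the lesion-candidate cluster (the one with the darker
#' centroid — lesions are dark in the fusion representation) is then
#' re-clustered into `k2` sub-clusters at level 2.  Pixels outside the
#' valid region are labeled `-1`, non-candidate pixels `0`, and candidate
#' pixels carry their level-2 sub-cluster id `1..k2`.
#'
#' @param f A `fusion_image`.
#' @param valid_region Logical `H x W` (from [remove_vignette()]), or
#'   `NULL` for all pixels.
#' @param k1,k2 Cluster counts at levels 1 and 2 (defaults 2 and 3).
#' @param max_iter Lloyd iterations per level (default 20).
#' @param seed RNG seed for centroid initialization.
#' @param n_restarts Restarts per level.
#' @param split_all Also split the non-candidate level-1 clusters?  (They
#'   keep background label 0 either way; kept for diagnostic parity.)
#' @return Object of class `hk_labels`: list with `labels` (`H x W`
#'   integer), `level`, `centroids1`, `centroids2`, `candidate`,
#'   `degenerate` flag and the SSE traces.
#' @export
hk_segment <- function(f, valid_region = NULL, k1 = 2L, k2 = 3L,
                       max_iter = 20L, seed = 1L, n_restarts = 1L,
                       split_all = FALSE) {
  stopifnot(inherits(f, "fusion_image"))
  gray <- f$gray
  if (is.null(valid_region)) valid_region <- matrix(TRUE, nrow(gray), ncol(gray))
  assert_mask(valid_region, dim(gray))
  v <- gray[valid_region]
  if (length(v) < k1 * k2)
    stop("valid region has fewer pixels than k1 * k2", call. = FALSE)
  labels <- matrix(-1L, nrow(gray), ncol(gray))
  if (diff(range(v)) < 1e-9) {
    warning("fusion image is constant inside the valid region; ",
            "returning a single cluster")
    labels[valid_region] <- 1L
    out <- list(labels = labels, level = 1L,
                centroids1 = mean(v), centroids2 = NULL,
                candidate = 1L, degenerate = TRUE,
                sse_trace1 = numeric(0), sse_trace2 = numeric(0))
    class(out) <- "hk_labels"
    return(out)
  }
  l1 <- hk_kmeans(v, k1, max_iter, seed, n_restarts)
  candidate <- which.min(l1$centroids[, 1])
  in_cand <- l1$assignments == candidate
  l2 <- hk_kmeans(v[in_cand], min(k2, sum(in_cand)), max_iter,
                  seed + 1L, n_restarts)
  lv <- integer(length(v))           # 0 = background
  lv[in_cand] <- l2$assignments
  if (split_all) {
    for (j in seq_len(k1)[-candidate]) {
      mem <- l1$assignments == j
      if (sum(mem) >= k2) hk_kmeans(v[mem], k2, max_iter, seed + 1L + j)
    }
  }
  labels[valid_region] <- lv
  out <- list(labels = labels, level = 2L,
              centroids1 = l1$centroids[, 1],
              centroids2 = l2$centroids[, 1],
              candidate = candidate, degenerate = FALSE,
              sse_trace1 = l1$sse_trace, sse_trace2 = l2$sse_trace)
  class(out) <- "hk_labels"
  out
}

#' Select the initial lesion region from the cluster labels
#'
#' Within the lesion-candidate cluster, keeps the lesion-like level-2
#' sub-clusters: those whose centroid gray is at least as close to the
#' candidate's level-1 centroid as to the background's (bright transition
#' rims fall to the background side and are dropped).  The kept pixels are
#' lightly closed (3 x 3) so sensor noise cannot fragment the region; the
#' lesion component is then the darkest-mean-gray component among those of
#' comparable size (at least a quarter of the largest — under a strong
#' illumination gradient the dark-side skin can form a kept component
#' larger than the lesion, but it is always paler).  Equal-darkness ties
#' go to the larger component, then the top-left-most one.  Enclosed holes
#' are filled.  If the filter empties the mask the whole candidate cluster
#' is used instead, with a warning.
#'
#' @param labels An `hk_labels` object.
#' @param f The `fusion_image` the labels were computed from.
#' @return Object of class `initial_region`: list with `mask` (logical),
#'   `bbox` (`c(row0, col0, row1, col1)`, 1-based inclusive) and
#'   `area_fraction` (mask area / image area).
#' @export
select_initial_region <- function(labels, f) {
  stopifnot(inherits(labels, "hk_labels"), inherits(f, "fusion_image"))
  lm <- labels$labels
  cand_mask <- lm >= 1L
  if (!any(cand_mask)) stop("cluster labels contain no candidate pixels",
                            call. = FALSE)
  if (labels$degenerate) {
    kept <- cand_mask
  } else {
    cand_c <- labels$centroids1[labels$candidate]
    bg_c <- max(labels$centroids1)
    keep_ids <- which(abs(labels$centroids2 - cand_c) <=
                        abs(labels$centroids2 - bg_c))
    kept <- cand_mask & matrix(lm %in% keep_ids, nrow(lm), ncol(lm))
    if (!any(kept)) {
      warning("no lesion-like sub-cluster; ",
              "falling back to the whole candidate cluster")
      kept <- cand_mask
    }
  }
  # 3x3 closing: bridge single-pixel noise gaps before component analysis
  kept <- window_filter_cpp(kept * 1, 3L, TRUE, 0, TRUE) > 0.5
  kept <- window_filter_cpp(kept * 1, 3L, FALSE, 0, FALSE) > 0.5
  comp <- label_components(kept, 8L)
  mask <- comp == select_lesion_component(comp, f$gray)
  mask <- fill_border_interior(mask)
  out <- list(mask = mask, bbox = mask_bbox(mask),
              area_fraction = mean(mask))
  class(out) <- "initial_region"
  out
}
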