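# Independent oracles (brute-force / closed-form) and fixture builders.
# Oracles never call the code paths they check.

# CIE 1976 L*a*b* from the published sRGB (D65) formulas
lab_oracle <- function(rgb) {
  v <- rgb / 255
  lin <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  X <- sum(c(0.4124564, 0.3575761, 0.1804375) * lin)
  Y <- sum(c(0.2126729, 0.7151522, 0.0721750) * lin)
  Z <- sum(c(0.0193339, 0.1191920, 0.9503041) * lin)
  f <- function(t) ifelse(t > (6 / 29)^3, t^(1 / 3), t / (3 * (6 / 29)^2) + 4 / 29)
  fx <- f(X / 0.95047); fy <- f(Y); fz <- f(Z / 1.08883)
  c(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
}

brute_confusion <- function(pred, truth) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_len(nrow(pred)))
    for (j in seq_len(ncol(pred))) {
      if (pred[i, j] && truth[i, j]) tp <- tp + 1L
      else if (!pred[i, j] && !truth[i, j]) tn <- tn + 1L
      else if (pred[i, j]) fp <- fp + 1L
      else fn <- fn + 1L
    }
  list(TP = tp, TN = tn, FP = fp, FN = fn)
}

# directed Hausdorff by exhaustive max-min over point matrices
brute_directed_hd <- function(a, b) {
  worst <- 0
  for (i in seq_len(nrow(a))) {
    d2 <- (b[, 1] - a[i, 1])^2 + (b[, 2] - a[i, 2])^2
    worst <- max(worst, min(d2))
  }
  sqrt(worst)
}

# w x w window max/min with window clipped at the border (pad = NULL)
# or padded with a constant
brute_window <- function(m, w, maximum = TRUE, pad = NULL) {
  h <- w %/% 2
  out <- m
  H <- nrow(m); W <- ncol(m)
  for (i in seq_len(H))
    for (j in seq_len(W)) {
      vals <- c()
      for (di in -h:h)
        for (dj in -h:h) {
          ii <- i + di; jj <- j + dj
          if (ii < 1 || ii > H || jj < 1 || jj > W) {
            if (!is.null(pad)) vals <- c(vals, pad)
          } else vals <- c(vals, m[ii, jj])
        }
      out[i, j] <- if (maximum) max(vals) else min(vals)
    }
  out
}

# hole filling by breadth-first flood fill from the border (4-connected
# background); anything unreachable is a hole and becomes TRUE
brute_fill <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  reach <- matrix(FALSE, H, W)
  queue <- list()
  for (i in seq_len(H)) for (j in c(1L, W))
    if (!mask[i, j] && !reach[i, j]) { reach[i, j] <- TRUE; queue[[length(queue) + 1L]] <- c(i, j) }
  for (j in seq_len(W)) for (i in c(1L, H))
    if (!mask[i, j] && !reach[i, j]) { reach[i, j] <- TRUE; queue[[length(queue) + 1L]] <- c(i, j) }
  while (length(queue)) {
    p <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      ni <- p[1] + d[1]; nj <- p[2] + d[2]
      if (ni >= 1 && ni <= H && nj >= 1 && nj <= W &&
          !mask[ni, nj] && !reach[ni, nj]) {
        reach[ni, nj] <- TRUE
        queue[[length(queue) + 1L]] <- c(ni, nj)
      }
    }
  }
  mask | !reach
}

# optimal 1-D 2-means SSE by enumerating all sorted splits
sorted_split_sse <- function(x) {
  xs <- sort(x); n <- length(xs); best <- Inf
  for (i in seq_len(n - 1)) {
    a <- xs[1:i]; b <- xs[(i + 1):n]
    best <- min(best, sum((a - mean(a))^2) + sum((b - mean(b))^2))
  }
  best
}

disk_mask <- function(H, W = H, cr = (H + 1) / 2, cc = (W + 1) / 2, r) {
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  sqrt((rows - cr)^2 + (cols - cc)^2) <= r
}

# irregular but connected random mask for metric/HD tests
rand_blob <- function(H, W = H, seed = 1) {
  set.seed(seed)
  m <- disk_mask(H, W, r = runif(1, H / 6, H / 3.5)) |
    disk_mask(H, W,
              cr = runif(1, H * 0.3, H * 0.7), cc = runif(1, W * 0.3, W * 0.7),
              r = runif(1, H / 8, H / 4))
  m
}

apply_gain <- function(img, lo = 0.7, hi = 1.3) {
  H <- dim(img)[1]; W <- dim(img)[2]
  ramp <- matrix(seq(lo, hi, length.out = W), H, W, byrow = TRUE)
  out <- img
  for (ch in 1:3) out[, , ch] <- pmin(pmax(round(img[, , ch] * ramp), 0), 255)
  out
}

dice_of <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# the default 20-image synthetic study suite, generated once per run
.fixture_env <- new.env()
get_suite20 <- function() {
  if (is.null(.fixture_env$suite))
    .fixture_env$suite <- generate_suite(20, synthetic_spec(), seed = 7)
  .fixture_env$suite
}

clean_ellipse_spec <- function(seed = 2)
  synthetic_spec(seed = seed, boundary_irregularity = 0, n_hairs = 0,
                 vignette_strength = 0, illumination_gradient = 0,
                 ruler_marks = FALSE, noise_sd = 0)
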