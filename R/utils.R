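# internal validators and small helpers

assert_rgb_image <- function(img, arg = "img") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop(sprintf("`%s` must be an H x W x 3 array", arg), call. = FALSE)
  d <- dim(img)
  if (d[1] < 32L || d[2] < 32L)
    stop(sprintf("image too small (%d x %d); need at least 32 x 32",
                 d[1], d[2]), call. = FALSE)
  if (anyNA(img) || min(img) < 0 || max(img) > 255)
    stop(sprintf("`%s` values must lie in [0, 255]", arg), call. = FALSE)
  invisible(img)
}

assert_mask <- function(mask, shape = NULL, arg = "mask") {
  if (!is.matrix(mask) || !is.logical(mask))
    stop(sprintf("`%s` must be a logical matrix", arg), call. = FALSE)
  if (!is.null(shape) && !identical(dim(mask), as.integer(shape)))
    stop(sprintf("`%s` shape (%s) does not match expected shape (%s)",
                 arg, paste(dim(mask), collapse = " x "),
                 paste(shape, collapse = " x ")), call. = FALSE)
  invisible(mask)
}

# 8-connected components of a logical matrix (labels 0 = background)
label_components <- function(mask, connectivity = 8L) {
  label_components_cpp(mask, as.integer(connectivity))
}

# largest component id with deterministic tie-breaks:
# size, then smaller mean of `gray` (if given), then top-left-most pixel
largest_component <- function(labels, gray = NULL) {
  n <- max(labels)
  if (n == 0L) return(0L)
  sizes <- tabulate(labels[labels > 0L], n)
  cand <- which(sizes == max(sizes))
  if (length(cand) > 1L && !is.null(gray)) {
    means <- vapply(cand, function(k) mean(gray[labels == k]), 0)
    cand <- cand[means == min(means)]
  }
  if (length(cand) > 1L) {
    first <- vapply(cand, function(k) which(labels == k)[1], 0L)
    cand <- cand[which.min(first)]
  }
  cand[1]
}

# lesion-candidate component: darkest mean gray among components of at
# least min_frac of the largest size (gradient-side skin bands can be
# larger than the lesion but are always paler); ties by size, then by
# top-left-most pixel
select_lesion_component <- function(labels, gray, min_frac = 0.25) {
  n <- max(labels)
  if (n == 0L) return(0L)
  sizes <- tabulate(labels[labels > 0L], n)
  cand <- which(sizes >= min_frac * max(sizes))
  means <- vapply(cand, function(k) mean(gray[labels == k]), 0)
  cand <- cand[abs(means - min(means)) < 1e-12]
  if (length(cand) > 1L) cand <- cand[sizes[cand] == max(sizes[cand])]
  if (length(cand) > 1L) {
    first <- vapply(cand, function(k) which(labels == k)[1], 0L)
    cand <- cand[which.min(first)]
  }
  cand[1]
}

# tight bounding box of a mask: c(row0, col0, row1, col1), 1-based inclusive
mask_bbox <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  c(min(idx[, 1]), min(idx[, 2]), max(idx[, 1]), max(idx[, 2]))
}

# Rec. 601 luma of an 8-bit RGB array, in [0, 1]
rgb_luminance <- function(img) {
  (0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]) / 255
}

# MATLAB-style central-difference gradient of a matrix
gradient2 <- function(f) {
  H <- nrow(f); W <- ncol(f)
  gr <- matrix(0, H, W); gc <- matrix(0, H, W)
  if (H > 1) {
    gr[2:(H - 1), ] <- (f[3:H, , drop = FALSE] - f[1:(H - 2), , drop = FALSE]) / 2
    gr[1, ] <- f[2, ] - f[1, ]
    gr[H, ] <- f[H, ] - f[H - 1, ]
  }
  if (W > 1) {
    gc[, 2:(W - 1)] <- (f[, 3:W, drop = FALSE] - f[, 1:(W - 2), drop = FALSE]) / 2
    gc[, 1] <- f[, 2] - f[, 1]
    gc[, W] <- f[, W] - f[, W - 1]
  }
  list(dr = gr, dc = gc)
}

# FNV-1a hash of a flat config list, for result records
config_hash <- function(cfg) {
  s <- paste(names(cfg),
             vapply(cfg, function(v) paste(format(v, digits = 12), collapse = ","), ""),
             sep = "=", collapse = ";")
  h <- 21661366
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (h * 16777.0 + 619) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

# seed for image i of a suite, order-independent, < 2^31
derive_seed <- function(seed, i) {
  (as.numeric(seed) * 48271 + 7919 * as.numeric(i)) %% 2147483647
}
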