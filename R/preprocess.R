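#' Convert an 8-bit RGB image to CIE L*a*b*
#'
#' Standard sRGB to CIE L*a*b* transform under the D65 white point.  `L` is
#' lightness in `[0, 100]`; `a` (green-red) and `b` (blue-yellow) are the
#' chromaticity axes.  Skin-lesion segmentation here uses only `a` and `b`:
#' lightness carries most of the illumination variation and is discarded
#' downstream.
#'
#' @param img `H x W x 3` array, values in `[0, 255]`.
#' @return An object of class `lab_image`: list of matrices `L`, `a`, `b`.
#' @export
rgb_to_lab <- function(img) {
  assert_rgb_image(img)
  d <- dim(img)
  m <- cbind(as.vector(img[, , 1]), as.vector(img[, , 2]),
             as.vector(img[, , 3])) / 255
  lab <- grDevices::convertColor(m, from = "sRGB", to = "Lab")
  out <- list(L = matrix(lab[, 1], d[1], d[2]),
              a = matrix(lab[, 2], d[1], d[2]),
              b = matrix(lab[, 3], d[1], d[2]))
  class(out) <- "lab_image"
  out
}

# discrete-CDF histogram equalization of one channel onto [0, 1];
# a constant channel degenerates to 0.5
equalize_channel <- function(ch, bins = 256L) {
  r <- range(ch)
  if (diff(r) < 1e-12) return(matrix(0.5, nrow(ch), ncol(ch)))
  u <- (ch - r[1]) / diff(r)
  idx <- pmin(as.integer(floor(u * bins)), bins - 1L) + 1L
  cdf <- cumsum(tabulate(idx, bins)) / length(idx)
  matrix(cdf[idx], nrow(ch), ncol(ch))
}

#' Histogram-equalize the chromaticity channels
#'
#' Each of the `a` and `b` channels is independently rescaled to `[0, 1]`
#' and histogram-equalized with a discrete cumulative-distribution mapping
#' (`bins` bins, ties broken by bin order).  The lightness channel is
#' discarded.
#'
#' @param lab A `lab_image`.
#' @param bins Number of histogram bins (default 256).
#' @return List with matrices `a_eq` and `b_eq`, values in `[0, 1]`.
#' @export
equalize_ab <- function(lab, bins = 256L) {
  stopifnot(inherits(lab, "lab_image"))
  list(a_eq = equalize_channel(lab$a, bins),
       b_eq = equalize_channel(lab$b, bins))
}

#' Build the 3-channel fusion image
#'
#' Stacks the two equalized chromaticity channels with their pixelwise mean
#' as the third channel; the scalar substrate used for clustering and level
#' set evolution is that mean, `gray = (a_eq + b_eq) / 2`.
#'
#' @param a_eq,b_eq Equalized channels from [equalize_ab()], same shape.
#' @return An object of class `fusion_image`: list with `gray` (`H x W` in
#'   `[0, 1]`) and `channels3` (`H x W x 3`).
#' @export
build_fusion <- function(a_eq, b_eq) {
  if (!identical(dim(a_eq), dim(b_eq)))
    stop(sprintf("channel shapes differ: (%s) vs (%s)",
                 paste(dim(a_eq), collapse = " x "),
                 paste(dim(b_eq), collapse = " x ")), call. = FALSE)
  gray <- (a_eq + b_eq) / 2
  f <- list(gray = gray,
            channels3 = array(c(a_eq, b_eq, gray), c(dim(a_eq), 3L)))
  class(f) <- "fusion_image"
  f
}

#' Suppress hair and other thin dark structures
#'
#' Applies a gray-level maximum filter (dilation by a square structuring
#' element, default 5 x 5) to each fusion channel.  In the fusion
#' representation lesions are broad dark regions and hair strokes are thin
#' dark curves, so the maximum filter erases structures narrower than the
#' kernel while eroding the lesion border by at most half the kernel width
#' — slack that the level-set stage recovers.  The scalar `gray` substrate
#' is recomputed from the filtered channels.
#'
#' @param f A `fusion_image`.
#' @param size Odd kernel width in pixels (default 5).
#' @return A `fusion_image`.
#' @export
suppress_hair <- function(f, size = 5L) {
  stopifnot(inherits(f, "fusion_image"), size >= 1, size %% 2 == 1)
  ch <- f$channels3
  for (k in 1:3)
    ch[, , k] <- window_filter_cpp(ch[, , k], as.integer(size),
                                   maximum = TRUE, pad = 0, pad_na = TRUE)
  out <- list(gray = (ch[, , 1] + ch[, , 2]) / 2, channels3 = ch)
  class(out) <- "fusion_image"
  out
}

#' Exclude vignetted / near-black frame regions
#'
#' Thresholds the RGB luminance at a dark cutoff, takes the largest
#' 8-connected component of non-dark pixels as the valid region, and
#' replaces fusion values outside it by the valid-region median so excluded
#' pixels cannot attract the clustering.
#'
#' @param f A `fusion_image`.
#' @param img The original `H x W x 3` image the fusion was built from.
#' @param cutoff Dark cutoff as a fraction of full scale (default 0.15,
#'   i.e. luminance below `0.15 * 255` counts as vignette/frame).
#' @return List with `fusion` (a `fusion_image`) and `valid_region`
#'   (logical `H x W`).  A valid region under 25% of the image raises a
#'   warning but processing proceeds.
#' @export
remove_vignette <- function(f, img, cutoff = 0.15) {
  stopifnot(inherits(f, "fusion_image"))
  assert_rgb_image(img)
  nondark <- rgb_luminance(img) >= cutoff
  if (!any(nondark)) {
    warning("image is entirely below the dark cutoff; keeping all pixels")
    return(list(fusion = f, valid_region = nondark | TRUE))
  }
  lab <- label_components(nondark, 8L)
  valid <- lab == largest_component(lab)
  if (mean(valid) < 0.25)
    warning(sprintf("valid region is only %.1f%% of the image",
                    100 * mean(valid)))
  if (!all(valid)) {
    ch <- f$channels3
    for (k in 1:3) {
      m <- ch[, , k]
      m[!valid] <- stats::median(m[valid])
      ch[, , k] <- m
    }
    f <- list(gray = (ch[, , 1] + ch[, , 2]) / 2, channels3 = ch)
    class(f) <- "fusion_image"
  }
  list(fusion = f, valid_region = valid)
}

#' Full preprocessing: fusion image + artifact suppression
#'
#' Runs the preprocessing chain: sRGB to CIELAB, histogram equalization of
#' the chromaticity channels, fusion-image construction, maximum-filter
#' hair suppression, and vignette exclusion.  With `substrate = "gray"` the
#' CIELAB/equalization steps are replaced by raw Rec. 601 luminance — an
#' ablation mode used to quantify the illumination robustness the
#' chromaticity fusion buys.
#'
#' @param img `H x W x 3` array in `[0, 255]`.
#' @param max_filter_size Hair-suppression kernel width (default 5).
#' @param vignette_cutoff Dark cutoff fraction (default 0.15).
#' @param equalize_bins Histogram bins (default 256).
#' @param substrate `"lab"` (default) or `"gray"` (ablation).
#' @return List with `fusion` (a `fusion_image`) and `valid_region`.
#' @export
preprocess_image <- function(img, max_filter_size = 5L,
                             vignette_cutoff = 0.15,
                             equalize_bins = 256L,
                             substrate = c("lab", "gray")) {
  substrate <- match.arg(substrate)
  if (substrate == "lab") {
    eq <- equalize_ab(rgb_to_lab(img), equalize_bins)
    f <- build_fusion(eq$a_eq, eq$b_eq)
  } else {
    u <- rgb_luminance(img)
    f <- build_fusion(u, u)
  }
  f <- suppress_hair(f, max_filter_size)
  remove_vignette(f, img, vignette_cutoff)
}
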