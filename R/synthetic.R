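#' Specification for a synthetic dermoscopy-style image
#'
#' Describes one seeded synthetic image: a darker reddish-brown lesion of
#' perturbed elliptical shape on lighter skin, with the artifact classes
#' typical of dermoscopic and clinical photographs — hair strokes, corner
#' vignetting, ruler marks and a smooth multiplicative illumination
#' gradient.  The generator is fully deterministic given the seed.
#'
#' @param seed Integer RNG seed for this image.
#' @param image_size `c(H, W)` in pixels (each >= 32).
#' @param lesion_center `c(row, col)` as fractions of the image size.
#' @param lesion_radii `c(r_row, r_col)` ellipse semi-axes in pixels.
#' @param boundary_irregularity Radial perturbation amplitude as a fraction
#'   of the local radius (>= 0); 0 gives an exact axis-aligned ellipse.
#' @param lesion_color_rgb,skin_color_rgb 8-bit RGB triples.  Defaults are a
#'   dark reddish brown on light skin; both CIELAB chromaticity channels of
#'   the lesion lie below the skin's, so the lesion is dark in the fusion
#'   representation.
#' @param contrast_scale In `[0, 1]`; multiplies the lesion/skin color
#'   difference (low values emulate low-contrast lesions; 0 renders the
#'   lesion invisible while the mask is unchanged).
#' @param n_hairs Number of dark hair strokes (>= 0).
#' @param hair_thickness_px Hair stroke thickness in pixels (>= 1).
#' @param vignette_strength In `[0, 1]`; radial darkening toward corners.
#' @param illumination_gradient In `[0, 1]`; amplitude of a smooth
#'   multiplicative linear gain field (total swing across the image).
#' @param ruler_marks Draw dark ruler ticks along the top edge?
#' @param noise_sd Additive Gaussian noise SD, 8-bit units.
#' @return An object of class `synthetic_spec` (a named list).
#' @export
synthetic_spec <- function(seed = 1L,
                           image_size = c(256L, 256L),
                           lesion_center = c(0.5, 0.5),
                           lesion_radii = c(55, 70),
                           boundary_irregularity = 0.15,
                           lesion_color_rgb = c(62, 48, 46),
                           skin_color_rgb = c(232, 170, 145),
                           contrast_scale = 1,
                           n_hairs = 8L,
                           hair_thickness_px = 2L,
                           vignette_strength = 0.3,
                           illumination_gradient = 0.3,
                           ruler_marks = TRUE,
                           noise_sd = 4) {
  spec <- list(seed = as.integer(seed),
               image_size = as.integer(image_size),
               lesion_center = as.numeric(lesion_center),
               lesion_radii = as.numeric(lesion_radii),
               boundary_irregularity = boundary_irregularity,
               lesion_color_rgb = as.numeric(lesion_color_rgb),
               skin_color_rgb = as.numeric(skin_color_rgb),
               contrast_scale = contrast_scale,
               n_hairs = as.integer(n_hairs),
               hair_thickness_px = as.integer(hair_thickness_px),
               vignette_strength = vignette_strength,
               illumination_gradient = illumination_gradient,
               ruler_marks = isTRUE(ruler_marks),
               noise_sd = noise_sd)
  class(spec) <- "synthetic_spec"
  validate_spec(spec)
  spec
}

validate_spec <- function(spec) {
  H <- spec$image_size[1]; W <- spec$image_size[2]
  stopifnot(H >= 32, W >= 32,
            spec$boundary_irregularity >= 0,
            spec$contrast_scale >= 0, spec$contrast_scale <= 1,
            spec$n_hairs >= 0, spec$hair_thickness_px >= 1,
            spec$vignette_strength >= 0, spec$vignette_strength <= 1,
            spec$illumination_gradient >= 0, spec$illumination_gradient <= 1,
            spec$noise_sd >= 0,
            all(spec$lesion_center > 0), all(spec$lesion_center < 1))
  cr <- spec$lesion_center[1] * H
  cc <- spec$lesion_center[2] * W
  rmax <- spec$lesion_radii * (1 + spec$boundary_irregularity)
  if (cr - rmax[1] < 6 || cr + rmax[1] > H - 5 ||
      cc - rmax[2] < 6 || cc + rmax[2] > W - 5)
    stop("lesion does not fit inside the image with a 5-px margin",
         call. = FALSE)
  invisible(spec)
}

#' Generate one synthetic image with its ground-truth mask
#'
#' The mask is exactly the set of pixels inside the perturbed ellipse
#' (normalized radius `rho <= 1 + irregularity * pert(theta)`, with a smooth
#' periodic perturbation built from low-order random harmonics).  The image
#' is rendered as skin base color, lesion fill blended by `contrast_scale`,
#' a multiplicative illumination gradient, anti-aliased dark hair strokes,
#' corner vignetting, optional ruler ticks, then additive Gaussian noise
#' clipped to `[0, 255]`.  Artifact layers never alter the mask.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with elements `image` (`H x W x 3`, values in 0..255),
#'   `mask` (logical `H x W`) and `spec`.
#' @export
generate_image <- function(spec) {
  validate_spec(spec)
  set.seed(spec$seed)
  H <- spec$image_size[1]; W <- spec$image_size[2]
  cr <- spec$lesion_center[1] * H
  cc <- spec$lesion_center[2] * W
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  dr <- rows - cr; dc <- cols - cc

  # smooth periodic radial perturbation from harmonics 2..5 (always drawn,
  # so the RNG stream does not depend on the irregularity value)
  amp <- runif(4, 0.2, 1)
  pha <- runif(4, 0, 2 * pi)
  theta <- atan2(dc, dr)
  pert <- matrix(0, H, W)
  for (k in 1:4) pert <- pert + amp[k] * cos((k + 1) * theta + pha[k])
  pert <- pert / max(abs(pert), sum(amp))   # |pert| <= 1
  rho <- sqrt((dr / spec$lesion_radii[1])^2 + (dc / spec$lesion_radii[2])^2)
  mask <- rho <= 1 + spec$boundary_irregularity * pert

  # base colors, lesion blended by contrast
  img <- array(0, c(H, W, 3))
  for (ch in 1:3) {
    base <- matrix(spec$skin_color_rgb[ch], H, W)
    delta <- spec$contrast_scale *
      (spec$lesion_color_rgb[ch] - spec$skin_color_rgb[ch])
    base[mask] <- base[mask] + delta
    img[, , ch] <- base
  }

  # multiplicative illumination gradient along a random direction
  psi <- runif(1, 0, 2 * pi)
  u <- (dr * cos(psi) + dc * sin(psi))
  u <- (u - min(u)) / max(max(u) - min(u), 1)
  gain <- 1 + spec$illumination_gradient * (u - 0.5)
  for (ch in 1:3) img[, , ch] <- img[, , ch] * gain

  # hair strokes: anti-aliased quadratic Bezier curves in dark brown
  if (spec$n_hairs > 0) {
    hair_col <- c(40, 30, 25)
    for (h in seq_len(spec$n_hairs)) {
      alpha <- render_hair(H, W, spec$hair_thickness_px)
      for (ch in 1:3)
        img[, , ch] <- (1 - alpha) * img[, , ch] + alpha * hair_col[ch]
    }
  }

  # vignette: quadratic radial darkening toward the corners
  if (spec$vignette_strength > 0) {
    d <- sqrt((dr / (H / 2))^2 + (dc / (W / 2))^2) / sqrt(2)
    vg <- 1 - spec$vignette_strength * pmax(0, (d - 0.5) / 0.5)^2
    for (ch in 1:3) img[, , ch] <- img[, , ch] * vg
  }

  # ruler ticks along the top edge
  if (spec$ruler_marks) {
    at <- seq(10L, W - 10L, by = 12L)
    for (i in seq_along(at)) {
      len <- if (i %% 5 == 1L) 9L else 5L
      img[4:(3 + len), at[i], ] <- 60
    }
  }

  if (spec$noise_sd > 0)
    img <- img + array(rnorm(H * W * 3, 0, spec$noise_sd), c(H, W, 3))
  img <- round(pmin(pmax(img, 0), 255))

  list(image = img, mask = mask, spec = spec)
}

# coverage matrix (H x W in [0,1]) of one random hair stroke
render_hair <- function(H, W, thickness) {
  p0 <- c(runif(1, 1, H), runif(1, 1, W))
  p2 <- c(runif(1, 1, H), runif(1, 1, W))
  mid <- (p0 + p2) / 2
  p1 <- mid + c(runif(1, -0.4, 0.4) * H, runif(1, -0.4, 0.4) * W)
  n <- max(64L, 2L * as.integer(sqrt(sum((p2 - p0)^2))))
  t <- seq(0, 1, length.out = n)
  pr <- (1 - t)^2 * p0[1] + 2 * t * (1 - t) * p1[1] + t^2 * p2[1]
  pc <- (1 - t)^2 * p0[2] + 2 * t * (1 - t) * p1[2] + t^2 * p2[2]
  rad <- thickness / 2
  alpha <- matrix(0, H, W)
  span <- ceiling(rad) + 1L
  for (s in seq_len(n)) {
    ri <- round(pr[s]); ci <- round(pc[s])
    if (ri < 1 - span || ri > H + span || ci < 1 - span || ci > W + span)
      next
    rr <- max(1L, ri - span):min(H, ri + span)
    cc <- max(1L, ci - span):min(W, ci + span)
    if (!length(rr) || !length(cc)) next
    d <- sqrt(outer((rr - pr[s])^2, (cc - pc[s])^2, "+"))
    a <- pmin(pmax(rad + 0.5 - d, 0), 1)   # linear anti-aliased falloff
    alpha[rr, cc] <- pmax(alpha[rr, cc], a)
  }
  alpha
}

#' Generate a seeded suite of synthetic images
#'
#' The first element is the base spec itself; subsequent elements jitter
#' lesion position, size, boundary irregularity, contrast, hair count and
#' artifact strengths.  Each image draws from its own RNG stream derived
#' from `(seed, index)`, so suites are order-independent and re-runs are
#' bit-identical.
#'
#' @param n Number of images (>= 1).
#' @param base_spec Base [synthetic_spec()].
#' @param seed Suite-level seed.
#' @return A list of `n` lists with elements `image`, `mask`, `spec`.
#' @export
generate_suite <- function(n, base_spec = synthetic_spec(), seed = 7L) {
  stopifnot(n >= 1)
  out <- vector("list", n)
  out[[1]] <- generate_image(base_spec)
  for (i in seq_len(n)[-1]) {
    si <- derive_seed(seed, i)
    set.seed(si)
    sp <- base_spec
    sp$seed <- as.integer(si %% 2147483647)
    sp$lesion_center <- pmin(pmax(base_spec$lesion_center +
                                    runif(2, -0.06, 0.06), 0.4), 0.6)
    sp$lesion_radii <- base_spec$lesion_radii * runif(2, 0.7, 1.05)
    sp$boundary_irregularity <- runif(1, 0.05, 0.18)
    sp$contrast_scale <- runif(1, 0.55, 1)
    sp$n_hairs <- sample(0:12, 1)
    sp$vignette_strength <- runif(1, 0, 0.45)
    sp$illumination_gradient <- runif(1, 0, 0.4)
    sp$noise_sd <- runif(1, 1, 6)
    sp$ruler_marks <- runif(1) < 0.5
    class(sp) <- "synthetic_spec"
    validate_spec(sp)
    out[[i]] <- generate_image(sp)
  }
  out
}
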