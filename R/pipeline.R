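#' Pipeline configuration
#'
#' Flat named list of every tunable parameter, keyed `<stage>.<name>`.
#' Defaults equal the published operating point of the method wherever one
#' exists (hierarchy `k1 = 2`, `k2 = 3`, 20 Lloyd iterations; DRLSE
#' `mu = 0.02`, `lambda = 5`, `eps = 1.5`, `c0 = 3`, `dt = 8`,
#' `sigma = 1.5`, 600 iterations, binarization threshold 80; 5 x 5 maximum
#' filter; 5-px erosion).  `preset = "nevus"` raises the iteration budget
#' to 1000 (benign nevi tend to have the smoother, lower-contrast borders
#' that converge more slowly); `"melanoma"` keeps 600.
#'
#' @param ... Overrides by key, e.g. `hkls_config(drlse.n_iter = 200)`.
#'   Unknown keys are an error.
#' @param preset Optional `"melanoma"` or `"nevus"`.
#' @return Named list of class `hkls_config`.
#' @export
hkls_config <- function(..., preset = NULL) {
  cfg <- list(
    preprocess.max_filter_size = 5L,
    preprocess.vignette_cutoff = 0.15,
    preprocess.equalize_bins = 256L,
    preprocess.substrate = "lab",
    hk.k1 = 2L, hk.k2 = 3L, hk.max_iter = 20L, hk.seed = 1L,
    hk.n_restarts = 1L, hk.split_all = FALSE,
    drlse.mu = 0.02, drlse.lambda = 5, drlse.alpha_small = 3,
    drlse.alpha_large = 5, drlse.area_threshold = 0.15,
    drlse.eps = 1.5, drlse.c0 = 3, drlse.dt = 8, drlse.sigma = 1.5,
    drlse.n_iter = 600L, drlse.margin_px = 10L, drlse.early_stop = TRUE,
    drlse.threshold = 80,
    post.erode_width = 5L, post.smooth = TRUE, post.lmax = 30)
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("melanoma", "nevus"))
    if (preset == "nevus") cfg$drlse.n_iter <- 1000L
  }
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(ov)] <- ov
  class(cfg) <- "hkls_config"
  cfg
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage %s: %s", stage, conditionMessage(e)), call. = FALSE))
}

#' Segment one lesion image
#'
#' Full pipeline: preprocessing (CIELAB fusion, hair suppression, vignette
#' exclusion) -> hierarchical K-means initial region -> DRLSE fine-border
#' evolution from the margin-expanded bounding rectangle -> morphological
#' postprocessing.  Deterministic given the image and configuration.  A
#' constant (featureless) image returns an empty mask with a warning
#' rather than an error.
#'
#' @param img `H x W x 3` array in `[0, 255]`.
#' @param cfg A [hkls_config()].
#' @param truth Optional reference mask; when given, the record carries
#'   the agreement metrics.
#' @param image_id Identifier stored in the result record.
#' @return List with `mask` (logical `H x W`) and `record` (image id,
#'   metrics or `NULL`, parameter snapshot, config hash, per-stage and
#'   total runtimes, warning flag).
#' @export
segment_lesion <- function(img, cfg = hkls_config(), truth = NULL,
                           image_id = "image") {
  assert_rgb_image(img)
  stopifnot(inherits(cfg, "hkls_config"))
  t_all <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function() proc.time()[["elapsed"]]

  t0 <- tick()
  pre <- run_stage("preprocess", preprocess_image(
    img, cfg$preprocess.max_filter_size, cfg$preprocess.vignette_cutoff,
    cfg$preprocess.equalize_bins, cfg$preprocess.substrate))
  timings["preprocess"] <- tick() - t0

  note <- NULL
  t0 <- tick()
  labels <- withCallingHandlers(
    run_stage("hk_cluster", hk_segment(
      pre$fusion, pre$valid_region, cfg$hk.k1, cfg$hk.k2, cfg$hk.max_iter,
      cfg$hk.seed, cfg$hk.n_restarts, cfg$hk.split_all)),
    warning = function(w) {
      note <<- conditionMessage(w)
      invokeRestart("muffleWarning")
    })
  timings["hk_cluster"] <- tick() - t0

  if (labels$degenerate) {
    warning("degenerate clustering (constant image); returning empty mask")
    mask <- matrix(FALSE, dim(img)[1], dim(img)[2])
    rec <- make_record(image_id, mask, truth, pre$valid_region, cfg,
                       timings, tick() - t_all,
                       warning = note %||% "degenerate clustering")
    return(list(mask = mask, record = rec))
  }

  t0 <- tick()
  region <- run_stage("select_region", select_initial_region(labels, pre$fusion))
  alpha <- choose_alpha(region, cfg$drlse.area_threshold,
                        cfg$drlse.alpha_small, cfg$drlse.alpha_large)
  timings["select_region"] <- tick() - t0

  t0 <- tick()
  # evolution substrate: complete the closing (min filter after the max
  # filter) so hair stays suppressed but the lesion border returns to its
  # true position; the max-filtered image alone carries a border eroded by
  # half the kernel, which the level set would otherwise lock onto
  closed <- window_filter_cpp(pre$fusion$gray,
                              as.integer(cfg$preprocess.max_filter_size),
                              maximum = FALSE, pad = 0, pad_na = TRUE)
  edge <- run_stage("edge_indicator",
                    edge_indicator(closed, cfg$drlse.sigma))
  phi0 <- run_stage("init_lsf", init_lsf(region, dim(img)[1:2],
                                         cfg$drlse.c0, cfg$drlse.margin_px))
  params <- drlse_params(mu = cfg$drlse.mu, lambda = cfg$drlse.lambda,
                         alpha = alpha, eps = cfg$drlse.eps,
                         c0 = cfg$drlse.c0, dt = cfg$drlse.dt,
                         sigma = cfg$drlse.sigma, n_iter = cfg$drlse.n_iter,
                         early_stop = cfg$drlse.early_stop)
  ev <- run_stage("drlse", drlse_evolve(phi0, edge, params))
  mask <- extract_mask(ev$phi, cfg$drlse.threshold, cfg$drlse.c0) &
    pre$valid_region
  timings["drlse"] <- tick() - t0

  t0 <- tick()
  mask <- run_stage("postprocess", finalize_mask(
    mask, cfg$post.erode_width, cfg$post.smooth, cfg$post.lmax))
  timings["postprocess"] <- tick() - t0

  rec <- make_record(image_id, mask, truth, pre$valid_region, cfg,
                     timings, tick() - t_all, warning = note,
                     extra = list(alpha = alpha,
                                  initial_area_fraction = region$area_fraction,
                                  drlse_iterations = ev$iterations))
  list(mask = mask, record = rec)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_record <- function(image_id, mask, truth, valid, cfg, timings, total,
                        warning = NULL, extra = list()) {
  metrics <- NULL
  if (!is.null(truth)) {
    assert_mask(truth, dim(mask), arg = "truth")
    metrics <- evaluate_masks(mask, truth, valid)
  }
  c(list(image_id = image_id,
         metrics = metrics,
         parameters = unclass(cfg),
         config_hash = config_hash(cfg),
         stage_seconds = as.list(timings),
         runtime_seconds = total,
         mask_area = sum(mask),
         warning = warning),
    extra)
}

#' Sweep the hierarchical cluster counts
#'
#' Runs the full pipeline over a synthetic suite for every `(k1, k2)`
#' combination and tabulates mean accuracy, mean Dice and mean runtime —
#' the experiment used to select the operating point `k1 = 2`, `k2 = 3`.
#'
#' @param suite A list from [generate_suite()] (elements with `image` and
#'   `mask`).
#' @param k1_values,k2_values Integer vectors of cluster counts.
#' @param cfg Base configuration; `hk.k1`/`hk.k2` are overridden per row.
#' @return Data frame with columns `k1`, `k2`, `mean_accuracy`,
#'   `mean_dice`, `mean_runtime_seconds`.
#' @export
sweep_clusters <- function(suite, k1_values = c(2L, 3L),
                           k2_values = c(2L, 3L, 4L, 5L),
                           cfg = hkls_config()) {
  stopifnot(length(suite) >= 1)
  rows <- list()
  for (k1 in k1_values)
    for (k2 in k2_values) {
      cfg2 <- cfg
      cfg2$hk.k1 <- as.integer(k1)
      cfg2$hk.k2 <- as.integer(k2)
      acc <- dice <- rt <- numeric(length(suite))
      for (i in seq_along(suite)) {
        res <- segment_lesion(suite[[i]]$image, cfg2, truth = suite[[i]]$mask,
                              image_id = sprintf("img_%03d", i))
        acc[i] <- res$record$metrics$accuracy
        dice[i] <- res$record$metrics$dice
        rt[i] <- res$record$runtime_seconds
      }
      rows[[length(rows) + 1L]] <-
        data.frame(k1 = k1, k2 = k2, mean_accuracy = mean(acc),
                   mean_dice = mean(dice), mean_runtime_seconds = mean(rt))
    }
  do.call(rbind, rows)
}
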