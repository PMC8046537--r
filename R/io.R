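#' Read an 8-bit color image
#'
#' Decodes a PNG/JPEG/BMP/TIFF file into an `H x W x 3` array of intensities
#' in `[0, 255]`, indexed `[row, col, channel]`.  Grayscale images are
#' replicated to three channels; an alpha channel, if present, is dropped.
#'
#' @param path Path to an image file.
#' @return An `H x W x 3` numeric array with values in `[0, 255]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path))
    stop("cannot read image: file does not exist: ", path, call. = FALSE)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e)
                    stop("cannot decode image ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L) {
    a <- aperm(array(rep(a, 3L), c(dim(a), 3L)), c(2L, 1L, 3L))
  } else {
    a <- aperm(a, c(2L, 1L, 3L))
    if (dim(a)[3] == 1L) a <- array(rep(a, 3L), c(dim(a)[1:2], 3L))
    if (dim(a)[3] >= 4L) a <- a[, , 1:3, drop = FALSE]  # drop alpha
    if (dim(a)[3] == 2L) a <- array(rep(a[, , 1], 3L), c(dim(a)[1:2], 3L))
  }
  a <- round(a * 255)
  if (dim(a)[1] < 32L || dim(a)[2] < 32L)
    stop(sprintf("image %s is %d x %d; need at least 32 x 32",
                 path, dim(a)[1], dim(a)[2]), call. = FALSE)
  a
}

#' Read a binary lesion mask
#'
#' Decodes an image file into a logical lesion mask.  Intensities above 127
#' (of 255) map to `TRUE`; color masks are reduced with an any-channel rule.
#'
#' @param path Path to a mask image file (0/255 or 0/1 encodings both work).
#' @param expected_shape Optional `c(H, W)`; a mismatch is an error naming
#'   both shapes.
#' @return An `H x W` logical matrix, `TRUE` = lesion.
#' @export
read_mask <- function(path, expected_shape = NULL) {
  if (!file.exists(path))
    stop("cannot read mask: file does not exist: ", path, call. = FALSE)
  a <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(a)) == 2L) {
    m <- t(a) > 0.5
  } else {
    a <- aperm(a, c(2L, 1L, 3L))
    nc <- min(dim(a)[3], 3L)
    m <- apply(a[, , seq_len(nc), drop = FALSE] > 0.5, c(1, 2), any)
  }
  if (!is.null(expected_shape) &&
      !identical(dim(m), as.integer(expected_shape)))
    stop(sprintf("mask shape (%s) does not match expected shape (%s)",
                 paste(dim(m), collapse = " x "),
                 paste(expected_shape, collapse = " x ")), call. = FALSE)
  m
}

#' Write a binary mask as a single-channel 0/255 PNG
#'
#' @param mask Logical `H x W` matrix.
#' @param path Output file path; the parent directory is created if needed.
#' @return Invisibly, `path`.
#' @export
write_mask <- function(mask, path) {
  assert_mask(mask)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  EBImage::writeImage(EBImage::Image(t(mask) * 1), path)
  invisible(path)
}

#' Write an 8-bit RGB image
#'
#' @param img `H x W x 3` array with values in `[0, 255]`.
#' @param path Output file path (format from extension, e.g. `.png`).
#' @return Invisibly, `path`.
#' @export
write_image <- function(img, path) {
  assert_rgb_image(img)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  EBImage::writeImage(EBImage::Image(aperm(img / 255, c(2L, 1L, 3L)),
                                     colormode = "Color"), path)
  invisible(path)
}

#' List image/mask pairs in dataset directories
#'
#' Pairs image files with mask files by shared base name (the mask file name
#' must contain the image base name).
#'
#' @param image_dir Directory of input images.
#' @param mask_dir Optional directory of ground-truth masks.
#' @param pattern Regular expression for image files.
#' @return A data frame with columns `image_id`, `image`, `mask` (`NA` when
#'   no mask was found).
#' @export
list_image_pairs <- function(image_dir, mask_dir = NULL,
                             pattern = "\\.(png|jpg|jpeg|bmp)$") {
  imgs <- sort(list.files(image_dir, pattern, ignore.case = TRUE))
  ids <- sub("\\.[^.]+$", "", imgs)
  masks <- rep(NA_character_, length(imgs))
  if (!is.null(mask_dir)) {
    cand <- sort(list.files(mask_dir, pattern, ignore.case = TRUE))
    for (i in seq_along(ids)) {
      hit <- cand[grepl(ids[i], cand, fixed = TRUE)]
      if (length(hit)) masks[i] <- file.path(mask_dir, hit[1])
    }
  }
  data.frame(image_id = ids, image = file.path(image_dir, imgs),
             mask = masks, stringsAsFactors = FALSE)
}

#' Serialize per-image result records
#'
#' Writes one CSV row per image (id, metrics, config hash, runtime) and a
#' JSON sidecar holding the full configuration snapshot, sufficient to
#' re-run the pipeline deterministically.
#'
#' @param records List of result records from [segment_lesion()].
#' @param csv_path Output CSV path; the JSON sidecar replaces the extension
#'   with `.json`.
#' @return Invisibly, the CSV path.
#' @export
write_results <- function(records, csv_path) {
  rows <- lapply(records, function(r) {
    m <- r$metrics
    data.frame(
      image_id = r$image_id,
      accuracy = if (is.null(m)) NA else m$accuracy,
      sensitivity = if (is.null(m)) NA else m$sensitivity,
      specificity = if (is.null(m)) NA else m$specificity,
      jaccard = if (is.null(m)) NA else m$jaccard,
      dice = if (is.null(m)) NA else m$dice,
      f_measure = if (is.null(m)) NA else m$f_measure,
      hausdorff_norm = if (is.null(m) || is.null(m$hausdorff_norm)) NA
                       else m$hausdorff_norm,
      config_hash = r$config_hash,
      runtime_seconds = r$runtime_seconds,
      stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  dir.create(dirname(csv_path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(df, csv_path, row.names = FALSE)
  side <- sub("\\.[^.]*$", ".json", csv_path)
  cfg <- if (length(records)) records[[1]]$parameters else list()
  jsonlite::write_json(cfg, side, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}
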