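#' Construct a worm image
#'
#' @param pixels Numeric array `height x width x 3` (red, green, blue), all
#'   intensities in `[0, 1]`.
#' @param mask Logical matrix of the same height/width; `TRUE` marks worm
#'   pixels. Must contain at least one worm pixel.
#' @return A `worm_image` list with elements `pixels` and `mask`.
#' @export
worm_image <- function(pixels, mask) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    abort("pixels must be a height x width x 3 array")
  }
  if (min(pixels) < 0 || max(pixels) > 1) abort("pixel intensities must lie in [0, 1]")
  mask <- as.matrix(mask)
  if (!identical(dim(mask), dim(pixels)[1:2])) abort("mask shape must equal image shape")
  mask <- mask != 0
  if (!any(mask)) abort("worm mask is empty")
  structure(list(pixels = pixels, mask = mask), class = "worm_image")
}

#' Read a worm micrograph (PNG or TIFF) with an optional mask
#'
#' Intensities are rescaled to `[0, 1]` on load (8- and 16-bit inputs alike)
#' so stain thresholds are portable across bit depths. Grayscale images are
#' expanded to three identical channels; an alpha channel is dropped. When
#' no mask file is given the worm is segmented with [segment_worm()].
#'
#' @param path Image path (`.png` or `.tif`/`.tiff`).
#' @param mask_path Optional mask image (nonzero = worm pixel).
#' @return A [worm_image()].
#' @export
read_worm_image <- function(path, mask_path = NULL) {
  px <- .read_raster(path)
  mask <- if (!is.null(mask_path)) {
    m <- .read_raster(mask_path)
    m[, , 1] > 0
  } else {
    NULL
  }
  if (is.null(mask)) {
    img <- structure(list(pixels = px, mask = matrix(TRUE, dim(px)[1], dim(px)[2])),
                     class = "worm_image")
    mask <- segment_worm(img)
  }
  worm_image(px, mask)
}

.read_raster <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    px <- png::readPNG(path)          # already [0, 1]
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE)) abort("TIFF input requires the tiff package")
    px <- tiff::readTIFF(path)        # already [0, 1]
  } else {
    abort(paste0("unsupported image format: ", path))
  }
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), c(dim(px), 3L))
  if (dim(px)[3] >= 4L) px <- px[, , 1:3, drop = FALSE]
  if (dim(px)[3] == 2L) px <- array(rep(px[, , 1], 3L), c(dim(px)[1:2], 3L))
  px
}

#' Red-excess stain signal of a worm image
#'
#' Per pixel, `max(red - blue, 0)` inside the worm mask and 0 outside:
#' the red channel's excess over blue carries the lipid-stain signal, and
#' blue-over-red carries none.
#'
#' @param image A [worm_image()].
#' @return A numeric matrix of per-pixel stain excess.
#' @export
stain_excess <- function(image) {
  ex <- pmax(image$pixels[, , 1] - image$pixels[, , 3], 0)
  ex[!image$mask] <- 0
  ex
}

#' Quantify Oil Red O staining of one worm
#'
#' The stained region is the set of worm pixels whose red excess is above
#' `stain_threshold`; the lipid index is the total excess over that region
#' normalised by the worm area (pixel count of the mask).
#'
#' @param image A [worm_image()].
#' @param stain_threshold Excess threshold defining stained pixels, in
#'   `[0, 1)` (default 0.05).
#' @param worm_id Optional identifier carried into the result.
#' @return A one-row tibble: `worm_id`, `worm_area`, `stained_area`,
#'   `total_excess`, `lipid_index`.
#' @export
quantify_oro <- function(image, stain_threshold = 0.05, worm_id = NA_character_) {
  if (stain_threshold < 0 || stain_threshold >= 1) abort("stain_threshold must be in [0, 1)")
  ex <- stain_excess(image)
  stained <- image$mask & ex > stain_threshold
  worm_area <- sum(image$mask)
  tibble(
    worm_id = as.character(worm_id),
    worm_area = worm_area,
    stained_area = sum(stained),
    total_excess = sum(ex[stained]),
    lipid_index = sum(ex[stained]) / worm_area
  )
}

#' Segment the worm from a light background
#'
#' Global Otsu threshold on inverted luminance (the worm is darker than the
#' background), keeping the largest connected component and filling its
#' holes. An explicitly supplied mask is passed through verbatim.
#'
#' @param image A `worm_image` (its mask is ignored) or a raw pixel array.
#' @param mask Optional precomputed logical mask returned unchanged.
#' @param min_pixels Minimum acceptable worm area (default 100).
#' @return A logical matrix marking worm pixels.
#' @export
segment_worm <- function(image, mask = NULL, min_pixels = 100L) {
  if (!is.null(mask)) return(as.matrix(mask) != 0)
  if (!requireNamespace("EBImage", quietly = TRUE)) {
    abort("segmentation requires the EBImage package (or supply a mask)")
  }
  px <- if (inherits(image, "worm_image")) image$pixels else image
  lum <- 1 - (0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3])
  if (diff(range(lum)) < 0.05) {
    abort("image has no foreground/background contrast; supply an explicit mask")
  }
  thr <- EBImage::otsu(EBImage::Image(lum), range = c(0, 1))
  bw <- lum > thr
  if (!any(bw)) abort("segmentation found no worm pixels; supply an explicit mask")
  lab <- EBImage::bwlabel(EBImage::Image(bw * 1))
  labm <- EBImage::imageData(lab)
  sizes <- tabulate(labm[labm > 0])
  keep <- which.max(sizes)
  comp <- labm == keep
  filled <- EBImage::imageData(EBImage::fillHull(EBImage::Image(comp * 1))) > 0
  if (sum(filled) < min_pixels) {
    abort(paste0("segmented worm has only ", sum(filled),
                 " pixels; supply an explicit mask"))
  }
  matrix(filled, nrow(lum), ncol(lum))
}

#' Group-relative Oil Red O report
#'
#' Normalises every worm's lipid index by the control group's mean index and
#' reports per-group n, mean and SD of the relative index (the control mean
#' is 1 by construction).
#'
#' @param measurements A tibble of per-worm measurements (from
#'   [quantify_oro()]) with an added `group` column.
#' @param control_group Label of the control group.
#' @return A list: `worms` (measurements with `relative_index`), `groups`
#'   (tibble group, n, mean_relative, sd_relative).
#' @export
relative_oro <- function(measurements, control_group) {
  if (!"group" %in% names(measurements)) abort("measurements need a `group` column")
  ctrl <- measurements$lipid_index[measurements$group == control_group]
  if (!length(ctrl)) abort(paste0("unknown or empty control group: ", control_group))
  ctrl_mean <- mean(ctrl)
  worms <- mutate(as_tibble(measurements), relative_index = .data$lipid_index / ctrl_mean)
  groups <- worms |>
    group_by(.data$group) |>
    summarise(n = dplyr::n(),
              mean_relative = mean(.data$relative_index),
              sd_relative = sd(.data$relative_index), .groups = "drop")
  list(worms = worms, groups = groups, control_group = control_group)
}
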