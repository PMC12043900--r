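# Step 1 of the measurement pipeline: region-of-interest extraction,
# denoising, normalization and local contrast enhancement.

#' Extract the fundus region of interest
#'
#' Removes the black surround of a fundus photograph: pixels whose
#' maximum channel exceeds a low-intensity threshold are kept, the mask
#' is morphologically closed and reduced to its largest connected
#' component, holes are filled, and the image is cropped to the mask's
#' bounding box.
#'
#' @param image An `EBImage::Image` (colour), a 3-d array `[x, y, 3]` with
#'   values in `[0, 1]`, or a file path readable by [EBImage::readImage()].
#' @param border_threshold Max-channel intensity below which a pixel is
#'   considered part of the black surround (default 20/255).
#' @return An object of class `roi_result`: list with `image` (cropped,
#'   colour), `mask` (logical matrix, `TRUE` inside the aperture), `bbox`
#'   (`c(x0, y0, x1, y1)`, 0-based half-open box in the original image).
#' @export
extract_roi <- function(image, border_threshold = 20 / 255) {
  img <- .as_rgb_array(image)
  maxchan <- pmax(img[, , 1], img[, , 2], img[, , 3])
  fg <- maxchan > border_threshold
  if (!any(fg)) {
    stop_vaangle("no pixel above the border threshold: empty ROI", "empty_roi")
  }
  closed <- EBImage::closing(fg * 1L, EBImage::makeBrush(7L, "disc"))
  lab <- EBImage::bwlabel(closed)
  labv <- EBImage::imageData(lab)
  if (max(labv) < 1) {
    stop_vaangle("no connected foreground component: empty ROI", "empty_roi")
  }
  sizes <- tabulate(labv[labv > 0])
  mask <- labv == which.max(sizes)
  mask <- EBImage::imageData(EBImage::fillHull(mask * 1L)) > 0

  xr <- range(which(rowSums(mask) > 0))
  yr <- range(which(colSums(mask) > 0))
  bbox <- c(xr[1] - 1L, yr[1] - 1L, xr[2], yr[2]) # 0-based half-open
  img_c <- img[xr[1]:xr[2], yr[1]:yr[2], , drop = FALSE]
  mask_c <- mask[xr[1]:xr[2], yr[1]:yr[2]]

  structure(list(image = img_c, mask = mask_c, bbox = bbox,
                 flags = character(0)),
            class = "roi_result")
}

#' Denoise, normalize and enhance the ROI
#'
#' Applies, in order and each individually switchable: a median filter
#' (edge-preserving denoising), per-channel normalization of the
#' inside-mask pixels to a fixed target mean and SD, and tile-based
#' adaptive histogram equalization (CLAHE) of the luminance channel with
#' the colour ratio preserved. Outside-mask pixels are set to zero and
#' the result is clamped to `[0, 1]`.
#'
#' @param roi A [extract_roi()] result.
#' @param target_mean,target_sd Normalization targets on the 8-bit scale
#'   (defaults 128 and 40).
#' @param median_size Median filter window (odd; 3 disables at 1).
#' @param clip_limit CLAHE clip limit (0 disables enhancement).
#' @param tile_size CLAHE tile grid (tiles per side).
#' @param denoise,normalize,enhance Logical switches for the three
#'   sub-steps (for ablation).
#' @return A `roi_result` with the processed image; `flags` gains
#'   `"degenerate_mask"` when the image is constant and normalization is
#'   skipped.
#' @export
normalize_enhance <- function(roi,
                              target_mean = 128, target_sd = 40,
                              median_size = 3L, clip_limit = 2,
                              tile_size = 8L,
                              denoise = TRUE, normalize = TRUE,
                              enhance = TRUE) {
  stopifnot(inherits(roi, "roi_result"))
  img <- roi$image
  mask <- roi$mask
  flags <- roi$flags

  if (denoise && median_size >= 3) {
    for (ch in 1:3) {
      img[, , ch] <- if (median_size == 3L) {
        .median3x3(img[, , ch])
      } else {
        EBImage::imageData(
          EBImage::medianFilter(pmin(pmax(img[, , ch], 0), 1),
                                size = (median_size - 1L) / 2L)
        )
      }
    }
  }

  if (normalize) {
    tm <- target_mean / 255
    tsd <- target_sd / 255
    for (ch in 1:3) {
      v <- img[, , ch][mask]
      m <- mean(v)
      s <- stats::sd(v)
      if (!is.finite(s) || s < 1e-6) {
        flags <- union(flags, "degenerate_mask")
      } else {
        img[, , ch] <- (img[, , ch] - m) / s * tsd + tm
      }
    }
  }

  if (enhance && clip_limit > 0) {
    lum <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    lum_c <- pmin(pmax(lum, 0), 1)
    if (stats::sd(lum_c[mask]) >= 1e-6) {
      nx <- max(2L, as.integer(tile_size))
      # CLAHE needs dimensions divisible by the tile grid: pad by
      # replication, equalize, crop back
      d <- dim(lum_c)
      pad <- (nx - d %% nx) %% nx
      lum_p <- lum_c
      if (pad[1] > 0) lum_p <- rbind(lum_p, lum_p[rep(d[1], pad[1]), , drop = FALSE])
      if (pad[2] > 0) lum_p <- cbind(lum_p, lum_p[, rep(d[2], pad[2]), drop = FALSE])
      eq <- EBImage::imageData(
        EBImage::clahe(EBImage::Image(lum_p), nx = nx, ny = nx,
                       limit = clip_limit)
      )[seq_len(d[1]), seq_len(d[2])]
      ratio <- eq / pmax(lum_c, 1e-3)
      ratio <- pmin(pmax(ratio, 0.25), 4)
      for (ch in 1:3) img[, , ch] <- img[, , ch] * ratio
    }
  }

  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[!mask] <- 0
    img[, , ch] <- plane
  }
  img[img < 0] <- 0
  img[img > 1] <- 1

  structure(list(image = img, mask = mask, bbox = roi$bbox, flags = flags),
            class = "roi_result")
}

#' @export
print.roi_result <- function(x, ...) {
  cat(sprintf("<roi_result %dx%d px, %.0f%% inside mask%s>\n",
              dim(x$image)[1], dim(x$image)[2], 100 * mean(x$mask),
              if (length(x$flags)) paste0(", flags: ", paste(x$flags, collapse = ",")) else ""))
  invisible(x)
}

# 3x3 median by a 19-exchange sorting network on edge-replicated shifts
# (much faster than a generic median filter for this fixed window)
.median3x3 <- function(m) {
  nx <- nrow(m)
  ny <- ncol(m)
  sh <- function(dx, dy) {
    xi <- pmin(pmax(seq_len(nx) + dx, 1), nx)
    yi <- pmin(pmax(seq_len(ny) + dy, 1), ny)
    m[xi, yi]
  }
  p <- list(sh(-1, -1), sh(0, -1), sh(1, -1),
            sh(-1, 0), sh(0, 0), sh(1, 0),
            sh(-1, 1), sh(0, 1), sh(1, 1))
  ex <- function(a, b) {
    lo <- pmin(p[[a]], p[[b]])
    p[[b]] <<- pmax(p[[a]], p[[b]])
    p[[a]] <<- lo
  }
  net <- list(c(2, 3), c(5, 6), c(8, 9), c(1, 2), c(4, 5), c(7, 8),
              c(2, 3), c(5, 6), c(8, 9), c(1, 4), c(6, 9), c(5, 8),
              c(4, 7), c(2, 5), c(3, 6), c(5, 8), c(5, 3), c(7, 5),
              c(5, 3))
  for (pr in net) ex(pr[1], pr[2])
  p[[5]]
}

# luminance of the ROI image (matrix [x, y])
.roi_luminance <- function(roi) {
  0.299 * roi$image[, , 1] + 0.587 * roi$image[, , 2] + 0.114 * roi$image[, , 3]
}

# coerce Image / array / path to an [x, y, 3] array in [0, 1]
.as_rgb_array <- function(image) {
  if (is.character(image)) {
    image <- EBImage::readImage(image)
  }
  if (inherits(image, "Image")) {
    image <- EBImage::imageData(image)
  }
  if (is.matrix(image)) {
    image <- array(rep(image, 3), dim = c(dim(image), 3))
  }
  if (length(dim(image)) == 3 && dim(image)[3] > 3) {
    image <- image[, , 1:3, drop = FALSE] # drop alpha
  }
  if (length(dim(image)) != 3 || dim(image)[3] != 3) {
    stop_vaangle("expected a 3-channel RGB image", "invalid_params")
  }
  if (max(image) > 1.001) image <- image / 255
  image
}
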