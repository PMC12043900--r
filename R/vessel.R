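# Vessel detection prerequisite to the arcade keypoints: multiscale
# Hessian ridge filtering on the inverted green channel, hysteresis
# binarization, topological skeletonization with per-pixel width from
# the distance transform, and greedy-radial tracing of the superior and
# inferior arcades from the disc margin out to the 3 PD circle.

#' Multiscale vessel ridge response
#'
#' Frangi-style tubularness of the inverted green channel: Gaussian
#' Hessian eigenvalues at several scales, combined into a blobness /
#' structureness response, maximized over scale and normalized to
#' `[0, 1]`. Scales default to vessel half-widths of about 1-4 pixels at
#' a 512-pixel image and scale with image size.
#'
#' @param roi A preprocessed [roi_result][extract_roi()].
#' @param scales Gaussian scales (pixels); `NULL` for the size-scaled
#'   default.
#' @param beta Blobness sensitivity (default 0.5).
#' @param c_frac Structureness scale as a fraction of the per-scale
#'   maximum (default 0.5).
#' @return A matrix in `[0, 1]`, zero outside (and near the rim of) the
#'   ROI mask.
#' @export
compute_vesselness <- function(roi, scales = NULL, beta = 0.5, c_frac = 0.5) {
  stopifnot(inherits(roi, "roi_result"))
  w <- dim(roi$image)[1]
  if (is.null(scales)) scales <- c(1, 1.75, 2.75, 4) * w / 512
  g <- roi$image[, , 2]
  inv <- 1 - g
  inside <- roi$mask
  inv[!inside] <- mean(inv[inside]) # avoid aperture-rim response

  best <- matrix(0, nrow(inv), ncol(inv))
  for (s in scales) {
    hw <- ceiling(3.5 * s)
    u <- seq(-hw, hw)
    g0 <- exp(-u^2 / (2 * s^2))
    g0 <- g0 / sum(g0)
    g2 <- (u^2 / s^4 - 1 / s^2) * exp(-u^2 / (2 * s^2))
    g2 <- g2 / sum(exp(-u^2 / (2 * s^2)))
    g2 <- g2 - mean(g2) # exact zero response to constants
    g1 <- (-u / s^2) * exp(-u^2 / (2 * s^2))
    g1 <- g1 / sum(exp(-u^2 / (2 * s^2)))
    f2 <- function(img, kx, ky) {
      EBImage::imageData(EBImage::filter2(EBImage::Image(img),
                                          outer(kx, ky)))
    }
    s2 <- s^2 # scale normalization
    Lxx <- s2 * f2(inv, g2, g0)
    Lyy <- s2 * f2(inv, g0, g2)
    Lxy <- s2 * f2(inv, g1, g1)

    tmp <- sqrt(((Lxx - Lyy) / 2)^2 + Lxy^2)
    m1 <- (Lxx + Lyy) / 2 + tmp
    m2 <- (Lxx + Lyy) / 2 - tmp
    # order by |.|: lam2 has the larger magnitude
    swap <- abs(m1) > abs(m2)
    lam1 <- ifelse(swap, m2, m1)
    lam2 <- ifelse(swap, m1, m2)

    S2 <- lam1^2 + lam2^2
    cc <- c_frac * sqrt(max(S2))
    if (cc <= 1e-6) next # numerically flat: no structure at this scale
    Rb2 <- (lam1 / ifelse(lam2 == 0, 1e-12, lam2))^2
    resp <- exp(-Rb2 / (2 * beta^2)) * (1 - exp(-S2 / (2 * cc^2)))
    resp[lam2 > 0] <- 0 # bright ridges on the inverted channel only
    best <- pmax(best, resp)
  }

  dm <- EBImage::imageData(EBImage::distmap(inside * 1L))
  best[dm <= 3 * max(scales)] <- 0
  mx <- max(best)
  if (mx > 0) best <- best / mx
  best
}

#' Binarize and skeletonize a vesselness map
#'
#' Hysteresis thresholding (components of the low-threshold mask are kept
#' only if they touch the high threshold), removal of small components,
#' morphological closing, topological thinning (Zhang-Suen), and width
#' estimation as twice the Euclidean distance transform sampled on the
#' skeleton.
#'
#' @param vesselness Matrix in `[0, 1]` from [compute_vesselness()].
#' @param high,low Hysteresis thresholds.
#' @param min_size Minimum component size in pixels; `NULL` scales with
#'   image area.
#' @return An object of class `vessel_map`: `vesselness`, `mask`,
#'   `skeleton` (logical matrices) and `width_px` (full vessel width on
#'   skeleton pixels, 0 elsewhere). An empty mask yields an empty map
#'   with the flag `"empty_vessels"`.
#' @export
binarize_and_skeletonize <- function(vesselness, high = 0.30, low = 0.12,
                                     min_size = NULL) {
  w <- nrow(vesselness)
  if (is.null(min_size)) min_size <- round(60 * (w / 512)^2)
  weak <- vesselness >= low
  flags <- character(0)
  if (!any(weak)) {
    z <- matrix(FALSE, nrow(vesselness), ncol(vesselness))
    return(structure(list(vesselness = vesselness, mask = z, skeleton = z,
                          width_px = z * 0, flags = "empty_vessels"),
                     class = "vessel_map"))
  }
  lab <- EBImage::imageData(EBImage::bwlabel(weak * 1L))
  strong_labels <- unique(lab[vesselness >= high & lab > 0])
  mask <- lab %in% strong_labels & lab > 0
  dim(mask) <- dim(lab)
  if (any(mask)) {
    mask <- EBImage::imageData(
      EBImage::closing(mask * 1L, EBImage::makeBrush(3L, "disc"))
    ) > 0
    lab2 <- EBImage::imageData(EBImage::bwlabel(mask * 1L))
    sizes <- tabulate(lab2[lab2 > 0])
    keep <- which(sizes >= min_size)
    mask <- lab2 %in% keep & lab2 > 0
    dim(mask) <- dim(lab2)
  }
  if (!any(mask)) {
    z <- matrix(FALSE, nrow(vesselness), ncol(vesselness))
    return(structure(list(vesselness = vesselness, mask = z, skeleton = z,
                          width_px = z * 0, flags = "empty_vessels"),
                     class = "vessel_map"))
  }
  skel <- .zhang_suen(mask)
  dm <- EBImage::imageData(EBImage::distmap(mask * 1L))
  width <- matrix(0, nrow(mask), ncol(mask))
  width[skel] <- 2 * dm[skel]
  structure(list(vesselness = vesselness, mask = mask, skeleton = skel,
                 width_px = width, flags = flags),
            class = "vessel_map")
}

#' @export
print.vessel_map <- function(x, ...) {
  cat(sprintf("<vessel_map> %d mask px, %d skeleton px%s\n",
              sum(x$mask), sum(x$skeleton),
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}

#' Trace the superior and inferior arcades
#'
#' On the selection ring (radius `ring_radius_pd` papillary diameters
#' from the disc centre, just outside the disc), skeleton crossings are
#' grouped, split by side (above / below the disc centre in image
#' coordinates), and the two widest crossings per side are taken as the
#' arcade's arteriovenous pair. Each is traced along the skeleton
#' greedily outward (the neighbour maximizing radial distance; ties by
#' width) until it reaches the 3 PD circle or a dead end.
#'
#' @param vmap A [binarize_and_skeletonize()] result.
#' @param disc A [segment_disc()] result.
#' @param ring_radius_pd Selection-ring radius in papillary diameters
#'   (default 0.75).
#' @param target_radius_pd Tracing target radius in papillary diameters
#'   (default 3).
#' @return A list of class `arcade_paths` with elements `superior` and
#'   `inferior`, each a list of 1-2 `arcade_path` objects ordered by
#'   decreasing width (`side`, `points_px`, `widths_px`,
#'   `mean_width_px`, `reaches_3pd`).
#' @export
trace_arcades <- function(vmap, disc, ring_radius_pd = 0.75,
                          target_radius_pd = 3) {
  stopifnot(inherits(vmap, "vessel_map"), inherits(disc, "disc_geometry"))
  if (!any(vmap$skeleton)) {
    stop_vaangle("empty vessel map: no arcade on either side",
                 "arcade_not_found", side = c("superior", "inferior"))
  }
  O <- disc$center_px
  pd <- disc$pd_px
  r_ring <- ring_radius_pd * pd
  r_target <- target_radius_pd * pd

  idx <- which(vmap$skeleton, arr.ind = TRUE)
  px <- idx[, 1] - 0.5
  py <- idx[, 2] - 0.5
  r <- sqrt((px - O[1])^2 + (py - O[2])^2)

  band <- abs(r - r_ring) <= 1.0
  crossings <- list()
  if (any(band)) {
    bm <- matrix(FALSE, nrow(vmap$skeleton), ncol(vmap$skeleton))
    bm[idx[band, , drop = FALSE]] <- TRUE
    # cluster with dilated connectivity so a crossing cut by the band is one group
    lab <- EBImage::imageData(EBImage::bwlabel(
      EBImage::imageData(EBImage::dilate(bm * 1L, EBImage::makeBrush(3L, "box")))
    ))
    lb <- lab[idx[band, , drop = FALSE]]
    for (g in unique(lb)) {
      sel <- which(band)[lb == g]
      rep_i <- sel[which.min(abs(r[sel] - r_ring))]
      crossings[[length(crossings) + 1L]] <- list(
        pixel = idx[rep_i, ],
        point = c(px[rep_i], py[rep_i]),
        width = max(vmap$width_px[idx[sel, , drop = FALSE]]),
        side = if (py[rep_i] <= O[2]) "superior" else "inferior"
      )
    }
  }

  pick_side <- function(side) {
    cs <- Filter(function(cr) cr$side == side, crossings)
    if (length(cs) == 0) return(NULL)
    wds <- vapply(cs, `[[`, numeric(1), "width")
    dx <- vapply(cs, function(cr) abs(cr$point[1] - O[1]), numeric(1))
    ord <- order(-wds, dx)
    cs[ord[seq_len(min(2L, length(cs)))]]
  }

  missing_sides <- character(0)
  out <- list()
  for (side in c("superior", "inferior")) {
    sel <- pick_side(side)
    if (is.null(sel)) {
      missing_sides <- c(missing_sides, side)
      next
    }
    out[[side]] <- lapply(sel, function(cr) {
      .trace_one(vmap, O, cr$pixel, r_target, side)
    })
  }
  if (length(missing_sides) > 0) {
    stop_vaangle(
      paste0("no arcade crossing on the selection ring: ",
             paste(missing_sides, collapse = ", ")),
      "arcade_not_found", side = missing_sides
    )
  }
  structure(out, class = "arcade_paths")
}

# greedy-radial walk along the skeleton from a start pixel: first inward
# to the disc margin (constrains the curve fit near O), then outward to
# the target circle; a shared visited set guarantees termination
.trace_one <- function(vmap, O, start, r_target, side) {
  S <- vmap$skeleton
  W <- vmap$width_px
  nx <- nrow(S)
  ny <- ncol(S)
  visited <- new.env(hash = TRUE, parent = emptyenv())

  walk <- function(from, direction, r_stop) {
    cur <- from
    min_r <- Inf
    pts <- matrix(NA_real_, 1024L, 2)
    wds <- numeric(1024L)
    npt <- 0L
    reached <- FALSE
    repeat {
      npt <- npt + 1L
      if (npt > nrow(pts)) {
        pts <- rbind(pts, matrix(NA_real_, nrow(pts), 2))
        wds <- c(wds, numeric(length(wds)))
      }
      pts[npt, ] <- c(cur[1] - 0.5, cur[2] - 0.5)
      wds[npt] <- W[cur[1], cur[2]]
      r_cur <- sqrt(sum((pts[npt, ] - O)^2))
      if (direction > 0 && r_cur >= r_stop) {
        reached <- TRUE
        break
      }
      if (direction < 0 && r_cur <= r_stop) break
      if (direction < 0 && r_cur > min_r + 2) break # turned back outward
      if (direction < 0) min_r <- min(min_r, r_cur)
      best <- NULL
      best_obj <- -Inf
      best_w <- -Inf
      for (dx in -1:1) for (dy in -1:1) {
        if (dx == 0 && dy == 0) next
        x <- cur[1] + dx
        y <- cur[2] + dy
        if (x < 1 || x > nx || y < 1 || y > ny) next
        if (!S[x, y]) next
        if (exists(sprintf("%d_%d", x, y), envir = visited, inherits = FALSE)) next
        rn <- sqrt((x - 0.5 - O[1])^2 + (y - 0.5 - O[2])^2)
        obj <- direction * rn
        wn <- W[x, y]
        if (obj > best_obj + 1e-9 || (abs(obj - best_obj) <= 1e-9 && wn > best_w)) {
          best <- c(x, y)
          best_obj <- obj
          best_w <- wn
        }
      }
      if (is.null(best)) break
      cur <- best
      assign(sprintf("%d_%d", cur[1], cur[2]), TRUE, envir = visited)
    }
    list(points = pts[seq_len(npt), , drop = FALSE],
         widths = wds[seq_len(npt)], reached = reached)
  }

  assign(sprintf("%d_%d", start[1], start[2]), TRUE, envir = visited)
  # inward only to the disc margin: inside the disc the branches merge
  inward <- walk(start, -1, 0.5 * r_target / 3)
  outward <- walk(start, +1, r_target)
  n_in <- nrow(inward$points)
  pts <- rbind(inward$points[rev(seq_len(n_in)), , drop = FALSE],
               outward$points[-1, , drop = FALSE])
  wds <- c(inward$widths[rev(seq_len(n_in))], outward$widths[-1])
  structure(list(side = side,
                 points_px = pts,
                 widths_px = wds,
                 mean_width_px = mean(wds),
                 reaches_3pd = outward$reached),
            class = "arcade_path")
}

#' @export
print.arcade_path <- function(x, ...) {
  cat(sprintf("<arcade_path %s> %d pts, mean width %.1f px, reaches 3PD: %s\n",
              x$side, nrow(x$points_px), x$mean_width_px, x$reaches_3pd))
  invisible(x)
}

# ---- Zhang-Suen thinning (vectorized over the whole image) ------------------

.zs_shift <- function(m, dx, dy) {
  nx <- nrow(m)
  ny <- ncol(m)
  out <- matrix(0L, nx, ny)
  xs <- max(1, 1 - dx):min(nx, nx - dx)
  ys <- max(1, 1 - dy):min(ny, ny - dy)
  out[xs, ys] <- m[xs + dx, ys + dy]
  out
}

.zhang_suen <- function(mask) {
  m <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  # neighbour order p2..p9 clockwise starting north (y - 1)
  offs <- list(c(0, -1), c(1, -1), c(1, 0), c(1, 1),
               c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      P <- lapply(offs, function(o) .zs_shift(m, o[1], o[2]))
      B <- Reduce(`+`, P)
      A <- matrix(0L, nrow(m), ncol(m))
      for (i in 1:8) {
        j <- if (i == 8) 1 else i + 1
        A <- A + (P[[i]] == 0L & P[[j]] == 1L)
      }
      if (step == 1) {
        c1 <- P[[1]] * P[[3]] * P[[5]] == 0L
        c2 <- P[[3]] * P[[5]] * P[[7]] == 0L
      } else {
        c1 <- P[[1]] * P[[3]] * P[[7]] == 0L
        c2 <- P[[1]] * P[[5]] * P[[7]] == 0L
      }
      del <- m == 1L & B >= 2L & B <= 6L & A == 1L & c1 & c2
      if (any(del)) {
        m[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m > 0L
}
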