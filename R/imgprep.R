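#' Maximum-intensity projection and 2x downsampling
#'
#' Reduces a confocal z stack to a single field-of-view image: maximum over
#' z first, then downsampling in x/y by a factor of two (2x2 block mean).
#'
#' @param volume 3D array `(y, x, z)` of non-negative intensities, or a 2D
#'   matrix (already projected; only downsampling is applied).
#' @return Matrix with half the spatial side of the input.
#' @export
project_and_downsample <- function(volume) {
  if (is.matrix(volume)) {
    proj <- volume
  } else {
    d <- dim(volume)
    if (length(d) != 3) stopf("volume must be a 2D matrix or 3D (y, x, z) array")
    m <- volume
    dim(m) <- c(d[1] * d[2], d[3])
    proj <- matrix(do.call(pmax, asplit(m, 2)), d[1], d[2])
  }
  if (any(!is.finite(proj))) stopf("non-finite intensities in volume")
  ny <- nrow(proj); nx <- ncol(proj)
  if (ny %% 2 != 0 || nx %% 2 != 0) {
    stopf("spatial dimensions must be even, got %d x %d", ny, nx)
  }
  o <- seq(1, ny, by = 2); e <- o + 1
  oc <- seq(1, nx, by = 2); ec <- oc + 1
  (proj[o, oc] + proj[e, oc] + proj[o, ec] + proj[e, ec]) / 4
}

#' Minimum cross-entropy (Li) threshold
#'
#' Iterative minimum cross-entropy thresholding: starting from the image
#' mean, the threshold is repeatedly replaced by
#' `(mu_bg - mu_fg) / (log(mu_bg) - log(mu_fg))`, where `mu_bg`/`mu_fg` are
#' the mean intensities below/above the current threshold, until it
#' converges.
#'
#' @param img Numeric matrix of non-negative intensities.
#' @param tol Convergence tolerance on the threshold.
#' @param max_iter Iteration cap.
#' @return Scalar threshold.
#' @export
threshold_li <- function(img, tol = 1e-6, max_iter = 200L) {
  x <- as.numeric(img)
  if (any(!is.finite(x))) stopf("non-finite pixels")
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  # work on a strictly positive copy; shift back at the end
  eps <- diff(rng) * 1e-6
  x <- x - rng[1] + eps
  t_cur <- mean(x)
  for (i in seq_len(max_iter)) {
    lo <- x[x <= t_cur]; hi <- x[x > t_cur]
    if (length(lo) == 0 || length(hi) == 0) break
    m0 <- mean(lo); m1 <- mean(hi)
    t_new <- (m0 - m1) / (log(m0) - log(m1))
    if (!is.finite(t_new)) break
    if (abs(t_new - t_cur) < tol) {
      t_cur <- t_new
      break
    }
    t_cur <- t_new
  }
  t_cur + rng[1] - eps
}

#' Segmentation parameters
#'
#' @param gaussian_sigma Low-pass sigma (px) before intensity thresholding.
#' @param log_sigma Laplacian-of-Gaussian sigma (px).
#' @param closing_radius Closing-disk radius (px); must be >= 4.
#' @param minima_percentile Percentile (0-100) of the LoG response used to
#'   mask its deepest local minima.
#' @return List of class `segmentation_params`.
#' @export
segmentation_params <- function(gaussian_sigma = 10, log_sigma = 5,
                                closing_radius = 4, minima_percentile = 1.0) {
  if (closing_radius < 4) stopf("closing_radius must be >= 4 px")
  structure(list(gaussian_sigma = gaussian_sigma, log_sigma = log_sigma,
                 closing_radius = closing_radius,
                 minima_percentile = minima_percentile),
            class = "segmentation_params")
}

## Laplacian-of-Gaussian response, computed as the discrete Laplacian of the
## Gaussian-smoothed image (negative over bright blobs)
log_filter <- function(img, sigma) {
  sm <- as.matrix(EBImage::gblur(img, sigma = sigma))
  k <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  as.matrix(EBImage::filter2(sm, k, boundary = "replicate"))
}

#' Segment nuclei from a nuclear-stain image
#'
#' Two-stage segmentation. Stage one thresholds a Gaussian low-pass of the
#' image at the minimum cross-entropy (Li) threshold, giving a background
#' mask. Stage two refines under-segmented (touching) nuclei:
#' (1) a second mask is the negative response of a Laplacian-of-Gaussian
#' filter (thresholded at zero) restricted to the stage-one foreground — the
#' LoG response changes sign over the neck between touching nuclei, which
#' splits them; (2) the second mask is morphologically closed and its holes
#' filled; (3) it is multiplied again by the stage-one mask so true
#' morphological holes survive; (4) the deepest local minima of the LoG
#' response are masked at a percentile threshold; (5) connected minima
#' regions that straddle the refined mask's background (at least one pixel
#' on each side) are removed from the mask. Connected components of the
#' result are the nucleus labels.
#'
#' @param nuclear Single-channel matrix (nuclear stain).
#' @param params A [segmentation_params].
#' @return Integer label matrix (0 background, 1..k nuclei).
#' @export
segment_nuclei <- function(nuclear, params = segmentation_params()) {
  if (!is.matrix(nuclear)) stopf("nuclear must be a 2D matrix")
  if (any(!is.finite(nuclear))) stopf("non-finite pixels in nuclear image")
  if (max(nuclear) == min(nuclear)) return(matrix(0L, nrow(nuclear), ncol(nuclear)))

  lowpass <- as.matrix(EBImage::gblur(nuclear, sigma = params$gaussian_sigma))
  bg_mask <- lowpass > threshold_li(lowpass)           # TRUE = foreground

  logimg <- log_filter(nuclear, params$log_sigma)
  mask2 <- (logimg < 0) & bg_mask
  mask2 <- EBImage::closing(mask2 * 1, disc_brush(params$closing_radius))
  mask2 <- EBImage::fillHull(mask2) > 0
  mask2 <- mask2 & bg_mask

  thr <- stats::quantile(logimg, params$minima_percentile / 100)
  minima <- logimg <= thr
  min_lab <- EBImage::bwlabel(minima * 1)
  n_reg <- max(min_lab)
  if (n_reg > 0) {
    for (r in seq_len(n_reg)) {
      px <- min_lab == r
      on_bg <- any(px & !mask2)
      on_fg <- any(px & mask2)
      if (on_bg && on_fg) mask2[px] <- FALSE
    }
  }
  matrix(as.integer(EBImage::bwlabel(mask2 * 1)), nrow(nuclear), ncol(nuclear))
}

#' Signed distance to the nuclear boundary
#'
#' Pixels inside a nucleus carry the (positive) Euclidean distance to the
#' nearest boundary; pixels outside carry the negative distance to the
#' nearest nucleus. Each side is divided by its own maximum, so the map
#' spans \[-1, 1\] with +1 at the most interior nuclear pixel whenever a
#' nucleus exists.
#'
#' @param mask Integer label matrix from [segment_nuclei] (any non-zero
#'   value counts as nucleus).
#' @return List with `values` (normalized map) and the normalization
#'   constants in px, `scale_inside` and `scale_outside`.
#' @export
signed_nuclear_distance <- function(mask) {
  fg <- mask > 0
  if (!any(fg)) {
    warning("empty nucleus mask: distance map is uniformly -1")
    return(list(values = matrix(-1, nrow(mask), ncol(mask)),
                scale_inside = 1, scale_outside = 1))
  }
  inside <- as.matrix(EBImage::distmap(fg * 1))        # dist to background
  outside <- as.matrix(EBImage::distmap((!fg) * 1))    # dist to foreground
  sc_in <- max(inside)
  sc_out <- max(max(outside), 1)
  values <- ifelse(fg, inside / sc_in, -outside / sc_out)
  list(values = values, scale_inside = sc_in, scale_outside = sc_out)
}

#' Extract per-nucleus crops
#'
#' Cuts one `crop_size` square window per nucleus, centered on the nucleus
#' centroid, stacking the fluorescence channel and the signed nuclear
#' distance channel. Nuclei whose window would cross the field border are
#' skipped.
#'
#' @param fluorescence Fluorescence matrix.
#' @param distance Signed distance map (`values` from
#'   [signed_nuclear_distance]).
#' @param mask Nucleus label matrix.
#' @param crop_size Window side in px (default 100).
#' @return A `crop_set`: list with `crops` (list of
#'   `crop_size x crop_size x 2` arrays), and a data frame `index`
#'   (nucleus label, centroid row/col, window start row/col).
#' @export
extract_crops <- function(fluorescence, distance, mask, crop_size = 100L) {
  stopifnot(all(dim(fluorescence) == dim(mask)), all(dim(distance) == dim(mask)))
  side <- nrow(mask)
  if (crop_size > side) stopf("crop_size (%d) exceeds FOV side (%d)", crop_size, side)
  half <- crop_size %/% 2
  labs <- setdiff(sort(unique(as.integer(mask))), 0L)
  crops <- list(); rows <- list()
  for (lab in labs) {
    w <- which(mask == lab, arr.ind = TRUE)
    cy <- round(mean(w[, 1])); cx <- round(mean(w[, 2]))
    r0 <- cy - half; c0 <- cx - half
    if (r0 < 1 || c0 < 1 || r0 + crop_size - 1 > side || c0 + crop_size - 1 > side) next
    rs <- r0:(r0 + crop_size - 1); cs <- c0:(c0 + crop_size - 1)
    crops[[length(crops) + 1]] <-
      array(c(fluorescence[rs, cs], distance[rs, cs]), dim = c(crop_size, crop_size, 2))
    rows[[length(rows) + 1]] <-
      data.frame(label = lab, centroid_row = cy, centroid_col = cx,
                 row_start = r0, col_start = c0)
  }
  idx <- if (length(rows)) do.call(rbind, rows)
         else data.frame(label = integer(0), centroid_row = integer(0),
                         centroid_col = integer(0), row_start = integer(0),
                         col_start = integer(0))
  structure(list(crops = crops, index = idx, crop_size = as.integer(crop_size)),
            class = "crop_set")
}

#' @export
print.crop_set <- function(x, ...) {
  cat(sprintf("<crop_set> %d crops of %d x %d x 2\n",
              length(x$crops), x$crop_size, x$crop_size))
  invisible(x)
}

#' Normalize a two-channel crop
#'
#' Min–max scales the fluorescence channel to \[0, 1\]; the distance channel
#' is already in \[-1, 1\] and passes through. Idempotent. A constant
#' fluorescence channel is mapped to all-zeros with a warning.
#'
#' @param crop `h x w x 2` array.
#' @return Normalized crop.
#' @export
normalize_crop <- function(crop) {
  stopifnot(length(dim(crop)) == 3, dim(crop)[3] == 2)
  if (any(!is.finite(crop))) stopf("non-finite values in crop")
  fl <- crop[, , 1]
  rng <- range(fl)
  if (diff(rng) == 0) {
    warning("constant fluorescence channel; normalized to zeros")
    crop[, , 1] <- 0
  } else {
    crop[, , 1] <- (fl - rng[1]) / diff(rng)
  }
  crop[, , 2] <- pmin(pmax(crop[, , 2], -1), 1)
  crop
}

#' Preprocess a synthetic dataset into model-ready crops
#'
#' Full preprocessing pipeline for each field of view: z projection and 2x
#' downsampling (volume mode), nucleus segmentation on the nuclear channel,
#' signed distance transform, per-FOV fluorescence min–max normalization,
#' and per-nucleus crop extraction.
#'
#' @param dataset A [generate_dataset] result.
#' @param crop_size Crop side in px.
#' @param params [segmentation_params].
#' @param normalize_per Either `"fov"` (default: fluorescence min–max over
#'   the whole field before cropping) or `"crop"`.
#' @return A `crop_set` whose `index` carries `protein_id`, `family` and
#'   `fov` columns.
#' @export
preprocess_dataset <- function(dataset, crop_size = 100L,
                               params = segmentation_params(),
                               normalize_per = c("fov", "crop")) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  normalize_per <- match.arg(normalize_per)
  all_crops <- list(); all_idx <- list()
  for (i in seq_along(dataset$fovs)) {
    fov <- dataset$fovs[[i]]
    if (length(dim(fov)) == 4) {
      fl <- project_and_downsample(fov[, , , 1])
      nu <- project_and_downsample(fov[, , , 2])
    } else {
      fl <- fov[, , 1]; nu <- fov[, , 2]
    }
    mask <- segment_nuclei(nu, params)
    dm <- suppressWarnings(signed_nuclear_distance(mask))
    if (normalize_per == "fov") {
      rng <- range(fl)
      fl <- if (diff(rng) > 0) (fl - rng[1]) / diff(rng) else fl * 0
    }
    cs <- extract_crops(fl, dm$values, mask, crop_size)
    if (normalize_per == "crop" && length(cs$crops)) {
      cs$crops <- lapply(cs$crops, function(cr) suppressWarnings(normalize_crop(cr)))
    }
    if (length(cs$crops)) {
      cs$index$fov <- i
      cs$index$protein_id <- dataset$protein_ids[i]
      cs$index$family <- unname(dataset$family_labels[dataset$protein_ids[i]])
      all_crops <- c(all_crops, cs$crops)
      all_idx[[length(all_idx) + 1]] <- cs$index
    }
  }
  idx <- if (length(all_idx)) do.call(rbind, all_idx) else NULL
  structure(list(crops = all_crops, index = idx, crop_size = as.integer(crop_size)),
            class = "crop_set")
}

#' Stack a crop set into a 4D batch array
#'
#' @param cropset A `crop_set`.
#' @param which Optional integer subset of crops.
#' @return Array `h x w x channels x n`.
#' @export
crops_to_batch <- function(cropset, which = NULL) {
  crops <- cropset$crops
  if (!is.null(which)) crops <- crops[which]
  d <- dim(crops[[1]])
  array(unlist(crops, use.names = FALSE), dim = c(d, length(crops)))
}

#' Write a crop set as TIFFs plus a CSV manifest
#'
#' Each crop becomes one two-page TIFF (page 1: fluorescence in \[0, 1\];
#' page 2: distance channel mapped from \[-1, 1\] to \[0, 1\] for storage).
#' The manifest records file, protein id, family, source FOV and centroid.
#'
#' @param cropset A `crop_set`.
#' @param dir Output directory.
#' @return Invisibly, the manifest data frame.
#' @export
write_crops <- function(cropset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(cropset$crops)
  manifest <- data.frame(file = sprintf("crop%05d.tif", seq_len(n)))
  for (col in c("protein_id", "family", "fov", "centroid_row", "centroid_col")) {
    if (!is.null(cropset$index[[col]])) manifest[[col]] <- cropset$index[[col]]
  }
  for (i in seq_len(n)) {
    cr <- cropset$crops[[i]]
    tiff::writeTIFF(list(pmin(pmax(cr[, , 1], 0), 1), (cr[, , 2] + 1) / 2),
                    file.path(dir, manifest$file[i]), bits.per.sample = 16L)
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a crop set written by [write_crops]
#'
#' @param dir Directory containing `manifest.csv` and crop TIFFs.
#' @return A `crop_set`.
#' @export
read_crops <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  crops <- lapply(manifest$file, function(f) {
    pages <- tiff::readTIFF(file.path(dir, f), all = TRUE)
    array(c(pages[[1]], pages[[2]] * 2 - 1), dim = c(dim(pages[[1]]), 2))
  })
  idx <- manifest[, setdiff(names(manifest), "file"), drop = FALSE]
  structure(list(crops = crops, index = idx,
                 crop_size = as.integer(nrow(crops[[1]]))),
            class = "crop_set")
}
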