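#' Localization pattern families
#'
#' Names of the supported subcellular localization pattern families. Each
#' family renders fluorescence only in its declared compartment relative to
#' the nucleus: nuclear families inside the nucleus, cytoplasmic families in
#' the cell body outside the nucleus.
#'
#' @format Character vector of family names.
#' @export
PATTERN_FAMILIES <- c(
  "NUCLEAR_DIFFUSE", "NUCLEOLAR", "CHROMATIN",
  "CYTO_DIFFUSE", "PUNCTATE", "RETICULAR", "FILAMENTOUS"
)

family_defaults <- function(name) {
  switch(name,
    NUCLEAR_DIFFUSE = list(intensity = 0.8, blur = 1),
    NUCLEOLAR       = list(intensity = 0.9, blur = 0.8, n_nucleoli = 2, nucleolus_radius = 5),
    CHROMATIN       = list(intensity = 0.8, blur = 0.6, texture_scale = 4),
    CYTO_DIFFUSE    = list(intensity = 0.6, blur = 1),
    PUNCTATE        = list(intensity = 0.9, blur = 0.6, n_puncta = 8, puncta_radius = 2.5),
    RETICULAR       = list(intensity = 0.7, blur = 0.5, texture_scale = 3),
    FILAMENTOUS     = list(intensity = 0.8, blur = 0.5, n_filaments = 6, filament_width = 1.5),
    stopf("unknown pattern family '%s'", name)
  )
}

#' Construct a localization pattern family
#'
#' A pattern family describes one class of protein localization (for example
#' nucleolar or punctate/vesicular) together with the shape parameters used
#' to render it. Parameters not supplied keep family defaults.
#'
#' @param name One of [PATTERN_FAMILIES].
#' @param params Named list overriding family-specific defaults: `intensity`,
#'   `blur` (px), and per family `n_nucleoli`, `nucleolus_radius`,
#'   `texture_scale`, `n_puncta`, `puncta_radius`, `n_filaments`,
#'   `filament_width`.
#' @return An object of class `pattern_family`.
#' @export
pattern_family <- function(name, params = list()) {
  name <- match.arg(name, PATTERN_FAMILIES)
  p <- family_defaults(name)
  for (k in names(params)) p[[k]] <- params[[k]]
  structure(list(name = name, params = p), class = "pattern_family")
}

#' @export
print.pattern_family <- function(x, ...) {
  cat("<pattern_family>", x$name, "\n")
  str(x$params, no.list = TRUE)
  invisible(x)
}

## ellipse membership on the pixel grid; a, b are semi-axes, theta radians
ellipse_mask <- function(side, cy, cx, a, b, theta, scale = 1) {
  yy <- matrix(seq_len(side), side, side) - cy
  xx <- matrix(seq_len(side), side, side, byrow = TRUE) - cx
  u <- (yy * cos(theta) + xx * sin(theta)) / (a * scale)
  v <- (-yy * sin(theta) + xx * cos(theta)) / (b * scale)
  u * u + v * v <= 1
}

disc_brush <- function(r) EBImage::makeBrush(2 * ceiling(r) + 1, shape = "disc")

## shrink a mask so that subsequent Gaussian blur stays (essentially) inside
## the original compartment
erode_mask <- function(mask, r) {
  if (r <= 0) return(mask)
  EBImage::erode(mask * 1, disc_brush(r)) > 0
}

place_nuclei <- function(n_nuclei, side, axis_range, max_tries = 200L) {
  if (n_nuclei == 0L) {
    return(data.frame(cy = numeric(0), cx = numeric(0), a = numeric(0),
                      b = numeric(0), theta = numeric(0)))
  }
  nuc <- data.frame(cy = numeric(0), cx = numeric(0), a = numeric(0),
                    b = numeric(0), theta = numeric(0))
  for (k in seq_len(n_nuclei)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      a <- stats::runif(1, axis_range[1], axis_range[2])
      b <- stats::runif(1, axis_range[1], axis_range[2])
      maj <- max(a, b)
      margin <- maj + 3
      if (2 * margin >= side) next
      cy <- stats::runif(1, margin, side - margin)
      cx <- stats::runif(1, margin, side - margin)
      ok <- TRUE
      if (nrow(nuc) > 0) {
        d <- sqrt((nuc$cy - cy)^2 + (nuc$cx - cx)^2)
        ok <- all(d > pmax(nuc$a, nuc$b) + maj + 6)
      }
      if (ok) {
        nuc <- rbind(nuc, data.frame(cy = cy, cx = cx, a = a, b = b,
                                     theta = stats::runif(1, 0, pi)))
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stopf("could not place %d non-overlapping nuclei in a %d px field after %d tries",
            n_nuclei, side, max_tries)
    }
  }
  nuc
}

## sample pixel positions from a logical mask, enforcing a minimum pairwise
## separation (used for puncta and nucleoli)
sample_in_mask <- function(mask, n, min_sep, max_tries = 2000L,
                           avoid = matrix(numeric(0), 0, 2)) {
  idx <- which(mask)
  if (length(idx) == 0L) return(cbind(y = numeric(0), x = numeric(0)))
  side <- nrow(mask)
  pts <- matrix(numeric(0), 0, 2)
  for (k in seq_len(n)) {
    for (try in seq_len(max_tries)) {
      i <- idx[sample.int(length(idx), 1)]
      y <- ((i - 1) %% side) + 1
      x <- ((i - 1) %/% side) + 1
      others <- rbind(pts, avoid)
      if (nrow(others) == 0 ||
          all(sqrt((others[, 1] - y)^2 + (others[, 2] - x)^2) >= min_sep)) {
        pts <- rbind(pts, c(y, x))
        break
      }
    }
  }
  colnames(pts) <- c("y", "x")
  pts
}

## Gaussian blob splat, vectorised over a bounding box
splat_blob <- function(img, cy, cx, radius, height) {
  side <- nrow(img)
  r <- ceiling(3 * radius)
  ys <- max(1, round(cy) - r):min(side, round(cy) + r)
  xs <- max(1, round(cx) - r):min(side, round(cx) + r)
  dy <- ys - cy
  dx <- xs - cx
  g <- exp(-0.5 * (outer(dy^2, dx^2, "+")) / radius^2)
  img[ys, xs] <- img[ys, xs] + height * g
  img
}

render_family_fluor <- function(family, nuc, truth, side) {
  p <- family$params
  nucmask <- truth > 0
  fluor <- matrix(0, side, side)
  cellmask <- matrix(FALSE, side, side)
  for (k in seq_len(nrow(nuc))) {
    cellmask <- cellmask | ellipse_mask(side, nuc$cy[k], nuc$cx[k],
                                        nuc$a[k], nuc$b[k], nuc$theta[k],
                                        scale = 1.8)
  }
  cyto <- cellmask & !EBImage::dilate(nucmask * 1, disc_brush(3)) > 0

  blur_into <- function(base) {
    if (p$blur > 0) EBImage::gblur(base, sigma = p$blur) else base
  }

  switch(family$name,
    NUCLEAR_DIFFUSE = {
      interior <- erode_mask(nucmask, 2 + p$blur)
      tex <- 0.85 + 0.3 * stats::runif(side * side)
      fluor <- blur_into(p$intensity * interior * matrix(tex, side, side))
    },
    NUCLEOLAR = {
      for (k in seq_len(nrow(nuc))) {
        inner <- ellipse_mask(side, nuc$cy[k], nuc$cx[k], nuc$a[k], nuc$b[k],
                              nuc$theta[k], scale = 0.55)
        pts <- sample_in_mask(inner, p$n_nucleoli, min_sep = 3 * p$nucleolus_radius)
        for (j in seq_len(nrow(pts))) {
          fluor <- splat_blob(fluor, pts[j, 1], pts[j, 2],
                              p$nucleolus_radius, p$intensity)
        }
      }
      fluor <- blur_into(fluor) * erode_mask(nucmask, 1)
    },
    CHROMATIN = {
      noise <- matrix(stats::runif(side * side), side, side)
      tex <- EBImage::gblur(noise, sigma = p$texture_scale)
      tex <- (tex - min(tex)) / max(1e-12, diff(range(tex)))
      interior <- erode_mask(nucmask, 2 + p$blur)
      fluor <- blur_into(p$intensity * (0.25 + 0.75 * tex^2) * interior)
    },
    CYTO_DIFFUSE = {
      support <- cyto & erode_mask(cellmask, 2 + p$blur)
      tex <- 0.85 + 0.3 * stats::runif(side * side)
      fluor <- blur_into(p$intensity * support * matrix(tex, side, side))
    },
    PUNCTATE = {
      safe <- cyto & erode_mask(cellmask, p$puncta_radius + 3)
      placed <- matrix(numeric(0), 0, 2)
      for (k in seq_len(nrow(nuc))) {
        cellk <- ellipse_mask(side, nuc$cy[k], nuc$cx[k], nuc$a[k], nuc$b[k],
                              nuc$theta[k], scale = 1.8)
        pts <- sample_in_mask(safe & cellk, p$n_puncta,
                              min_sep = 4 * p$puncta_radius + 6,
                              avoid = placed)
        placed <- rbind(placed, pts)
        for (j in seq_len(nrow(pts))) {
          fluor <- splat_blob(fluor, pts[j, 1], pts[j, 2],
                              p$puncta_radius, p$intensity)
        }
      }
      if (p$blur > 0) fluor <- EBImage::gblur(fluor, sigma = p$blur)
    },
    RETICULAR = {
      noise <- matrix(stats::rnorm(side * side), side, side)
      web <- EBImage::gblur(noise, sigma = p$texture_scale) -
        EBImage::gblur(noise, sigma = 2.5 * p$texture_scale)
      web <- web > stats::quantile(web, 0.55)
      support <- cyto & erode_mask(cellmask, 2 + p$blur)
      fluor <- blur_into(p$intensity * (web & support))
    },
    FILAMENTOUS = {
      acc <- matrix(0, side, side)
      for (k in seq_len(nrow(nuc))) {
        maj <- max(nuc$a[k], nuc$b[k])
        for (f in seq_len(p$n_filaments)) {
          ang <- stats::runif(1, 0, 2 * pi)
          r0 <- maj * stats::runif(1, 1.0, 1.15)
          r1 <- maj * stats::runif(1, 1.5, 1.75)
          tt <- seq(0, 1, length.out = ceiling(2 * (r1 - r0)))
          bend <- stats::runif(1, -0.3, 0.3)
          ys <- round(nuc$cy[k] + (r0 + tt * (r1 - r0)) * sin(ang + bend * tt))
          xs <- round(nuc$cx[k] + (r0 + tt * (r1 - r0)) * cos(ang + bend * tt))
          keep <- ys >= 1 & ys <= side & xs >= 1 & xs <= side
          acc[cbind(ys[keep], xs[keep])] <- p$intensity
        }
      }
      acc <- EBImage::gblur(acc, sigma = max(p$filament_width / 2, 0.5))
      support <- cyto & erode_mask(cellmask, 2)
      fluor <- acc * support
      if (p$blur > 0) fluor <- EBImage::gblur(fluor, sigma = p$blur)
    }
  )
  pmax(matrix(as.numeric(fluor), side, side), 0)
}

#' Render one synthetic two-channel cell scene
#'
#' Draws `n_nuclei` non-overlapping elliptical nuclei and renders the
#' fluorescence channel of the given localization pattern family relative to
#' them, noise-free. The nuclear channel emulates a DNA stain
#' (bright smooth nuclei); the truth mask labels each nucleus with its own
#' integer.
#'
#' @param family A [pattern_family] (or family name).
#' @param n_nuclei Number of nuclei to place (may be 0).
#' @param fov_size Field-of-view side in pixels (>= 128).
#' @param seed Integer seed; fully determines the scene.
#' @param axis_range Nuclear semi-axis range in pixels at 512 px scale;
#'   scaled linearly with `fov_size`.
#' @return List with elements `fluorescence`, `nuclear` (numeric matrices)
#'   and `truth` (integer label matrix), plus `nuclei` (data frame of
#'   ellipse parameters).
#' @export
render_scene <- function(family, n_nuclei, fov_size = 512L, seed = 1L,
                         axis_range = c(15, 30)) {
  if (is.character(family)) family <- pattern_family(family)
  stopifnot(inherits(family, "pattern_family"))
  if (fov_size < 128) stopf("fov_size must be >= 128, got %d", fov_size)
  if (n_nuclei < 0) stopf("n_nuclei must be >= 0")
  side <- as.integer(fov_size)
  scl <- side / 512

  with_seed(seed, {
    nuc <- place_nuclei(n_nuclei, side, axis_range * scl)
    truth <- matrix(0L, side, side)
    for (k in seq_len(nrow(nuc))) {
      m <- ellipse_mask(side, nuc$cy[k], nuc$cx[k], nuc$a[k], nuc$b[k], nuc$theta[k])
      truth[m] <- k
    }
    nuclear <- matrix(0, side, side)
    if (nrow(nuc) > 0) {
      bright <- stats::runif(nrow(nuc), 0.7, 1)
      for (k in seq_len(nrow(nuc))) nuclear[truth == k] <- bright[k]
      nuclear <- as.matrix(EBImage::gblur(nuclear, sigma = 1.5))
    }
    fluor <- if (nrow(nuc) > 0) render_family_fluor(family, nuc, truth, side)
             else matrix(0, side, side)
    list(fluorescence = fluor, nuclear = nuclear, truth = truth, nuclei = nuc)
  })
}

#' Apply a camera noise model
#'
#' Poisson shot noise on intensities scaled to photon counts, plus additive
#' Gaussian read noise. `poisson_scale` is the expected photon count at unit
#' intensity; 0 disables shot noise.
#'
#' @param img Numeric matrix.
#' @param poisson_scale Photons per unit intensity (default 200).
#' @param gaussian_sd Read-noise standard deviation (default 0.01).
#' @param seed Integer seed.
#' @return Noisy matrix, clamped at 0.
#' @export
apply_noise <- function(img, poisson_scale = 200, gaussian_sd = 0.01, seed = 1L) {
  with_seed(seed, {
    out <- img
    if (poisson_scale > 0) {
      out <- matrix(stats::rpois(length(img), pmax(img, 0) * poisson_scale),
                    nrow(img), ncol(img)) / poisson_scale
    }
    if (gaussian_sd > 0) {
      out <- out + matrix(stats::rnorm(length(img), sd = gaussian_sd),
                          nrow(img), ncol(img))
    }
    pmax(out, 0)
  })
}

#' Configuration for a synthetic dataset
#'
#' @param n_proteins Number of distinct (opaque) protein identifiers.
#' @param images_per_protein Fields of view per protein.
#' @param family_of Character vector of length `n_proteins` assigning each
#'   protein a [PATTERN_FAMILIES] entry; default recycles all families.
#' @param fov_size Field-of-view side in pixels.
#' @param nuclei_per_fov Length-2 integer range of nuclei per field.
#' @param noise List with `poisson_scale` and `gaussian_sd` (see
#'   [apply_noise]); set both to 0 for noiseless data.
#' @param volume If `TRUE`, store each channel as a 3D stack (2D scene
#'   replicated along z with a Gaussian axial profile, see [as_volume]).
#' @param n_z Number of z slices in volume mode.
#' @param seed Integer seed; fully determines the dataset.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_proteins, images_per_protein,
                         family_of = NULL, fov_size = 512L,
                         nuclei_per_fov = c(3L, 6L),
                         noise = list(poisson_scale = 200, gaussian_sd = 0.01),
                         volume = FALSE, n_z = 11L, seed = 1L) {
  if (n_proteins < 1) stopf("n_proteins must be >= 1")
  if (images_per_protein < 1) stopf("images_per_protein must be >= 1")
  if (is.null(family_of)) {
    family_of <- rep(PATTERN_FAMILIES, length.out = n_proteins)
  }
  if (length(family_of) != n_proteins) {
    stopf("family_of must have one family per protein (%d != %d)",
          length(family_of), n_proteins)
  }
  if (!all(family_of %in% PATTERN_FAMILIES)) {
    stopf("unknown families: %s",
          paste(setdiff(family_of, PATTERN_FAMILIES), collapse = ", "))
  }
  ids <- sprintf("P%03d", seq_len(n_proteins))
  structure(list(
    n_proteins = as.integer(n_proteins),
    images_per_protein = as.integer(images_per_protein),
    protein_ids = ids,
    family_of = stats::setNames(family_of, ids),
    fov_size = as.integer(fov_size),
    nuclei_per_fov = as.integer(nuclei_per_fov),
    noise = noise, volume = isTRUE(volume), n_z = as.integer(n_z),
    seed = as.integer(seed)
  ), class = "synth_config")
}

## per-protein parameter jitter: one draw per protein, reused for all of its
## images, so that images of a protein share pattern statistics
sample_protein_params <- function(family_name, seed) {
  with_seed(seed, {
    p <- family_defaults(family_name)
    p$intensity <- p$intensity * stats::runif(1, 0.85, 1.15)
    if (!is.null(p$n_puncta)) p$n_puncta <- sample(6:12, 1)
    if (!is.null(p$puncta_radius)) p$puncta_radius <- stats::runif(1, 2, 3)
    if (!is.null(p$n_nucleoli)) p$n_nucleoli <- sample(1:3, 1)
    if (!is.null(p$nucleolus_radius)) p$nucleolus_radius <- stats::runif(1, 4, 6)
    if (!is.null(p$texture_scale)) p$texture_scale <- p$texture_scale * stats::runif(1, 0.8, 1.2)
    if (!is.null(p$n_filaments)) p$n_filaments <- sample(4:9, 1)
    p
  })
}

#' Generate a synthetic labelled image dataset
#'
#' Renders `images_per_protein` fields of view for each protein. Pattern
#' parameters are drawn once per protein and reused across all of that
#' protein's images, so only cell pose and noise vary within a protein —
#' emulating a tagged-protein image collection where every image of a
#' protein shares its localization signature.
#'
#' @param config A [synth_config].
#' @return An object of class `synthetic_dataset`: list with `fovs` (list of
#'   `fov_size x fov_size x 2` arrays, channel 1 = protein fluorescence,
#'   channel 2 = nuclear stain; 4D in volume mode), `nucleus_truth` (list of
#'   label matrices), `protein_ids` (per fov), `family_labels` (per protein,
#'   named), and the `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n_fov <- config$n_proteins * config$images_per_protein
  fovs <- vector("list", n_fov)
  truth <- vector("list", n_fov)
  ids <- character(n_fov)
  i <- 0L
  for (p in seq_len(config$n_proteins)) {
    pid <- config$protein_ids[p]
    fam_name <- config$family_of[[pid]]
    fam <- pattern_family(fam_name,
                          sample_protein_params(fam_name, child_seed(config$seed, "protein", p)))
    for (im in seq_len(config$images_per_protein)) {
      i <- i + 1L
      sseed <- child_seed(config$seed, "scene", p, im)
      n_nuc <- with_seed(child_seed(config$seed, "nnuc", p, im),
                         sample(config$nuclei_per_fov[1]:config$nuclei_per_fov[2], 1))
      sc <- render_scene(fam, n_nuc, config$fov_size, seed = sseed)
      fl <- apply_noise(sc$fluorescence, config$noise$poisson_scale,
                        config$noise$gaussian_sd, child_seed(config$seed, "noiseF", p, im))
      nu <- apply_noise(sc$nuclear, config$noise$poisson_scale,
                        config$noise$gaussian_sd, child_seed(config$seed, "noiseN", p, im))
      if (config$volume) {
        fovs[[i]] <- array(c(as_volume(fl, config$n_z), as_volume(nu, config$n_z)),
                           dim = c(dim(fl), config$n_z, 2))
      } else {
        fovs[[i]] <- array(c(fl, nu), dim = c(dim(fl), 2))
      }
      truth[[i]] <- sc$truth
      ids[i] <- pid
    }
  }
  structure(list(fovs = fovs, nucleus_truth = truth, protein_ids = ids,
                 family_labels = config$family_of, config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d FOVs, %d proteins, %d px\n",
              length(x$fovs), x$config$n_proteins, x$config$fov_size))
  invisible(x)
}

#' Expand a 2D image into a confocal-like z stack
#'
#' Replicates a 2D scene along z with a Gaussian axial intensity profile
#' peaking at the central slice (weight 1), so a maximum-intensity
#' projection recovers the 2D scene exactly.
#'
#' @param img Numeric matrix.
#' @param n_z Number of slices.
#' @param z_sigma Axial profile standard deviation in slices.
#' @return 3D array `dim(img) x n_z`.
#' @export
as_volume <- function(img, n_z = 11L, z_sigma = n_z / 4) {
  zc <- (n_z + 1) / 2
  w <- exp(-0.5 * ((seq_len(n_z) - zc) / z_sigma)^2)
  w <- w / max(w)
  array(as.numeric(outer(as.numeric(img), w)), dim = c(dim(img), n_z))
}

#' Write a synthetic dataset to disk
#'
#' Fields of view are written as multi-page TIFF (page 1 protein
#' fluorescence, page 2 nuclear stain), truth masks as 16-bit label TIFF,
#' and metadata (fov file, protein id, family, seed) as CSV.
#'
#' @param dataset A [generate_dataset] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the metadata data frame.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(dataset$fovs)
  meta <- data.frame(
    fov = sprintf("fov%04d.tif", seq_len(n)),
    mask = sprintf("mask%04d.tif", seq_len(n)),
    protein_id = dataset$protein_ids,
    family = unname(dataset$family_labels[dataset$protein_ids]),
    seed = dataset$config$seed
  )
  for (i in seq_len(n)) {
    fov <- dataset$fovs[[i]]
    if (length(dim(fov)) == 4) fov <- apply(fov, c(1, 2, 4), max)  # store projected
    mx <- max(fov, 1e-9)
    tiff::writeTIFF(list(fov[, , 1] / mx, fov[, , 2] / mx),
                    file.path(dir, meta$fov[i]), bits.per.sample = 16L)
    tiff::writeTIFF(dataset$nucleus_truth[[i]] / 65535,
                    file.path(dir, meta$mask[i]), bits.per.sample = 16L)
  }
  utils::write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  invisible(meta)
}
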