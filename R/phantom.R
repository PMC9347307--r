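#' Render a synthetic autoradiogram phantom
#'
#' Builds a film image from per-region tissue activities: each region is a
#' rectangular patch whose pixels take `film(P*)` plus additive Gaussian OD
#' noise, and a graded calibration-standards strip is rendered in a reserved
#' right-hand margin through the same film response. Regions are geometric
#' patches, not anatomy; the phantom exists to exercise calibration and ROI
#' quantification with known truth.
#'
#' @param pstars named numeric vector: tissue labelled-protein concentration
#'   per region, nCi/g.
#' @param standards activities of the co-exposed standards, nCi/g
#'   (default [default_standards()]); must span the `pstars` range, otherwise
#'   a warning is recorded in the result for downstream extrapolation tests.
#' @param film a `film_response` (default [hill_film()]).
#' @param od_noise_sd additive Gaussian noise on OD, in OD units.
#' @param seed optional integer for reproducible noise.
#' @param patch_dim height and width of each region patch in pixels.
#' @param strip_width width of the reserved standards margin in pixels.
#' @return List of class `autoradiogram`: `image` (OD matrix), `mask`
#'   (integer labels; 0 = background/margin), `regions` (label/region table),
#'   `standards` (activity and noise-free OD), `warnings`, and
#'   `pixel_size_um` (11, the digitization pixel size).
#' @export
render_autoradiogram <- function(pstars, standards = default_standards(),
                                 film = hill_film(), od_noise_sd = 0,
                                 seed = NULL, patch_dim = c(16, 20),
                                 strip_width = 20) {
  stopifnot(inherits(film, "film_response"))
  if (is.null(names(pstars)) || any(!nzchar(names(pstars)))) {
    stop("'pstars' must be a named vector (one name per region)", call. = FALSE)
  }
  check_number(pstars, "pstars", lower = 0, len = length(pstars))
  check_number(od_noise_sd, "od_noise_sd", lower = 0)
  standards <- sort(unique(standards))
  std_od <- film(standards)
  if (any(diff(std_od) <= 0)) {
    stop("film response must be strictly increasing over the standards",
         call. = FALSE)
  }
  warnings <- character(0)
  if (any(pstars < min(standards)) || any(pstars > max(standards))) {
    out_rng <- names(pstars)[pstars < min(standards) | pstars > max(standards)]
    warnings <- sprintf(
      "region activity outside standards span [%g, %g]: %s",
      min(standards), max(standards), paste(out_rng, collapse = ", "))
  }

  n <- length(pstars)
  ncol_p <- ceiling(sqrt(n))
  nrow_p <- ceiling(n / ncol_p)
  h <- nrow_p * patch_dim[1]
  w <- ncol_p * patch_dim[2] + strip_width
  mask <- matrix(0L, h, w)
  for (i in seq_len(n)) {
    pr <- (i - 1) %/% ncol_p
    pc <- (i - 1) %% ncol_p
    mask[pr * patch_dim[1] + seq_len(patch_dim[1]),
         pc * patch_dim[2] + seq_len(patch_dim[2])] <- i
  }
  # graded standards strip stacked in the reserved margin
  strip_cols <- (w - strip_width + 1):w
  block_h <- h %/% length(standards)
  strip_label <- matrix(0L, h, w)   # internal: which standard shades a pixel
  for (k in seq_along(standards)) {
    rows <- ((k - 1) * block_h + 1):(if (k == length(standards)) h else k * block_h)
    strip_label[rows, strip_cols] <- k
  }

  image <- matrix(film(0), h, w)    # fog level everywhere
  for (i in seq_len(n)) image[mask == i] <- film(pstars[[i]])
  for (k in seq_along(standards)) image[strip_label == k] <- std_od[k]
  if (od_noise_sd > 0) {
    image <- with_seed(seed, image + matrix(stats::rnorm(h * w, 0, od_noise_sd), h, w))
    image[image < 0] <- 0
  }

  structure(
    list(image = image, mask = mask,
         regions = data.frame(label = seq_len(n), region = names(pstars)),
         standards = data.frame(activity_nCi_per_g = standards, od = std_od),
         warnings = warnings, pixel_size_um = 11),
    class = "autoradiogram")
}

# ---- TIFF encoding -------------------------------------------------------
# OD is stored in a 16-bit grayscale TIFF as round(OD * od_scale); the scale
# (default 10000) shrinks automatically when the brightest OD would overflow
# 16 bits, and is always recorded in a sidecar JSON next to the image.

#' Write an optical-density image as 16-bit TIFF with sidecar metadata
#'
#' @param image numeric OD matrix.
#' @param path output `.tif` path; a sidecar `<path>.json` records the
#'   encoding scale and the pixel size.
#' @param od_scale pixels = `round(OD * od_scale)`; default 10000, reduced
#'   automatically if the maximum OD would exceed the 16-bit range.
#' @param pixel_size_um pixel size recorded in the sidecar (default 11).
#' @return `path`, invisibly.
#' @export
write_autoradiogram <- function(image, path, od_scale = NULL, pixel_size_um = 11) {
  max_od <- max(image)
  if (is.null(od_scale)) {
    od_scale <- if (max_od * 10000 <= 65535) 10000 else 65000 / max_od
  }
  px <- round(image * od_scale)
  if (max(px) > 65535 || min(px) < 0) {
    stop("encoded pixel values exceed the 16-bit range; lower 'od_scale'",
         call. = FALSE)
  }
  tiff::writeTIFF(px / 65535, path, bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(list(od_scale = od_scale, pixel_size_um = pixel_size_um),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an optical-density image written by [write_autoradiogram()]
#'
#' @param path `.tif` path with its sidecar `<path>.json`.
#' @return Numeric OD matrix with attributes `od_scale` and `pixel_size_um`.
#' @export
read_autoradiogram <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    stop("missing sidecar metadata: ", sidecar, call. = FALSE)
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  px <- tiff::readTIFF(path, as.is = TRUE)
  od <- px / meta$od_scale
  attr(od, "od_scale") <- meta$od_scale
  attr(od, "pixel_size_um") <- meta$pixel_size_um
  od
}

#' Write / read an integer region-label mask as 16-bit TIFF
#' @param mask integer matrix of labels (0 = background).
#' @param path `.tif` path.
#' @return The path (write) or the integer matrix (read).
#' @export
write_mask <- function(mask, path) {
  storage.mode(mask) <- "integer"
  if (max(mask) > 65535L) stop("labels exceed 16-bit range", call. = FALSE)
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  tiff::readTIFF(path, as.is = TRUE)
}
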