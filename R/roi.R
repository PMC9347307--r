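#' Measure optical density over one labelled region of interest
#'
#' Mean and standard deviation (n-1 denominator) of the decoded optical
#' densities over exactly the pixels carrying `label` in the mask.
#'
#' @param image numeric matrix of optical densities (see
#'   [read_autoradiogram()] for decoding from 16-bit TIFF).
#' @param mask integer matrix of region labels, same shape as `image`.
#' @param label integer label to measure.
#' @return List with `mean_od`, `od_sd` (`NA` for a single pixel) and
#'   `n_pixels`.
#' @export
measure_roi <- function(image, mask, label) {
  if (!all(dim(image) == dim(mask))) {
    stop("image and mask dimensions differ", call. = FALSE)
  }
  sel <- mask == label
  n <- sum(sel)
  if (n == 0L) {
    stop("label ", label, " not present in mask", call. = FALSE)
  }
  v <- image[sel]
  list(mean_od = mean(v),
       od_sd = if (n > 1L) stats::sd(v) else NA_real_,
       n_pixels = n)
}

#' Quantify all named regions of an autoradiogram
#'
#' Measures mean OD per labelled region and converts it to tissue 14C
#' concentration through the calibration curve (convert-after-average, the
#' classical densitometry convention; set `convert_first = TRUE` to average
#' per-pixel converted activities instead for sensitivity checks).
#' Conversions outside the calibration domain carry `extrapolated = TRUE`;
#' downstream statistics exclude such regions by default.
#'
#' @param image numeric OD matrix.
#' @param mask integer label matrix of the same shape.
#' @param regions data frame with columns `label` and `region` naming every
#'   region to quantify; all labels must be present in the mask.
#' @param curve a [fit_calibration()] object.
#' @param subject identifier recorded on each row.
#' @param convert_first average per-pixel activities instead of converting
#'   the mean OD.
#' @return Data frame with one row per region: `subject`, `region`,
#'   `mean_od`, `od_sd`, `n_pixels`, `pstar_nCi_per_g`, `extrapolated`.
#' @export
quantify_regions <- function(image, mask, regions, curve, subject = "s1",
                             convert_first = FALSE) {
  stopifnot(is.data.frame(regions), all(c("label", "region") %in% names(regions)))
  present <- unique(as.vector(mask))
  absent <- setdiff(regions$label, present)
  if (length(absent)) {
    stop("region label(s) missing from mask: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    m <- measure_roi(image, mask, regions$label[i])
    if (convert_first) {
      a <- od_to_activity(curve, image[mask == regions$label[i]])
      pstar <- mean(a)
      extrap <- any(attr(a, "extrapolated"))
    } else {
      a <- od_to_activity(curve, m$mean_od)
      pstar <- as.numeric(a)
      extrap <- attr(a, "extrapolated")
    }
    data.frame(subject = subject, region = regions$region[i],
               mean_od = m$mean_od, od_sd = m$od_sd, n_pixels = m$n_pixels,
               pstar_nCi_per_g = pstar, extrapolated = extrap)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
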