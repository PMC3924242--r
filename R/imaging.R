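#' Derive a cell mask from a fluorescence channel
#'
#' When a mask is provided it is returned unchanged. Otherwise the channel is
#' thresholded automatically (Otsu on the rescaled intensity histogram), the
#' largest connected component is kept and its holes are filled.
#'
#' @param channel Numeric intensity matrix.
#' @param provided_mask Optional logical/0-1 matrix; takes precedence.
#' @return Logical cell mask.
#' @export
derive_mask <- function(channel, provided_mask = NULL) {
  if (!is.null(provided_mask)) {
    m <- provided_mask > 0
    if (!any(m)) stop("provided mask is empty")
    return(m)
  }
  rng <- range(channel)
  if (diff(rng) == 0) stop("blank image: cannot derive a mask")
  norm <- (channel - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(norm))
  bw <- norm > th
  lab <- EBImage::bwlabel(EBImage::Image(bw * 1))
  if (max(lab) == 0) stop("empty mask after thresholding")
  counts <- tabulate(as.integer(lab[lab > 0]))
  keep <- which.max(counts)
  mask <- EBImage::fillHull(EBImage::Image((lab == keep) * 1))
  matrix(as.logical(mask > 0), nrow(channel), ncol(channel))
}

#' Border-ring and cytoplasm-box regions of interest
#'
#' Reproduces the ROI geometry used for cortical versus cytoplasmic actin
#' quantification on an equatorial confocal section: a ring of width
#' `border_width` just inside the cell border (the mask minus the mask eroded
#' by `border_width`), and a `box[1] x box[2]` square placed at the interior
#' point farthest from the border (the maximum of the eroded mask's distance
#' transform), the reproducible analogue of placing the box by hand in open
#' cytoplasm.
#'
#' @param mask Logical cell mask.
#' @param border_width Ring width in px (default 24).
#' @param box Box size in px as `c(height, width)` (default `c(50, 50)`).
#' @return List with `ring` and `box` (logical matrices) and `box_center`
#'   (row, col).
#' @export
border_and_cytoplasm_rois <- function(mask, border_width = 24,
                                      box = c(50, 50)) {
  stopifnot(is.matrix(mask), any(mask))
  if (border_width < 1) stop("border_width must be >= 1")
  # Euclidean distance to the nearest background pixel defines the ring:
  # the erosion of the mask by a disc of radius border_width is dm > bw
  dm <- EBImage::distmap(EBImage::Image(mask * 1))
  dm <- matrix(as.numeric(dm), nrow(mask), ncol(mask))
  eroded <- dm > border_width
  if (!any(eroded))
    stop("cell too small: erosion by the border width leaves no interior")
  ring <- mask & !eroded
  ctr <- which(dm == max(dm), arr.ind = TRUE)[1, ]
  h <- box[1]; w <- box[2]
  r0 <- ctr[1] - floor((h - 1) / 2); r1 <- r0 + h - 1
  c0 <- ctr[2] - floor((w - 1) / 2); c1 <- c0 + w - 1
  if (r0 < 1 || c0 < 1 || r1 > nrow(mask) || c1 > ncol(mask))
    stop("cell too small: cytoplasm box does not fit in the image")
  boxm <- matrix(FALSE, nrow(mask), ncol(mask))
  boxm[r0:r1, c0:c1] <- TRUE
  if (!all(eroded[boxm]))
    stop("cell too small: cytoplasm box does not fit inside the eroded mask")
  list(ring = ring, box = boxm, box_center = unname(ctr))
}

#' Estimate the image background
#'
#' Median intensity outside the union of all cell masks; the median is robust
#' to stray cells or debris in the field.
#'
#' @param channel Numeric intensity matrix.
#' @param masks A logical mask or list of masks covering all cells in field.
#' @return Scalar background estimate.
#' @export
estimate_background <- function(channel, masks) {
  if (is.list(masks)) masks <- Reduce(`|`, masks)
  out <- channel[!masks]
  if (!length(out)) stop("no pixels outside the cell masks")
  stats::median(out)
}

#' Cortex/cytoplasm F-actin ratio and cytoplasmic G-actin
#'
#' Background-subtracted mean intensities:
#' `f_actin_ratio = (cortex_mean - background) / (cytoplasm_mean - background)`
#' from the F-actin channel, and the mean background-subtracted G-actin signal
#' in the cytoplasm box. Uniform additive offsets cancel exactly.
#'
#' @param f_channel,g_channel Intensity matrices (G may be `NULL`).
#' @param rois ROIs from [border_and_cytoplasm_rois()].
#' @param background Scalar background, or length-2 `c(f, g)` when the
#'   channels have different backgrounds.
#' @return List with `cortex_mean`, `cytoplasm_mean`, `f_actin_ratio`,
#'   `g_actin_mean` (`NA` without a G channel).
#' @export
quantify_actin <- function(f_channel, g_channel, rois, background) {
  bg <- if (length(background) == 2) background else rep(background, 2)
  cortex_mean <- mean(f_channel[rois$ring])
  cyto_mean <- mean(f_channel[rois$box])
  if (cyto_mean - bg[1] <= 0)
    stop("non-positive background-subtracted cytoplasm mean")
  g_mean <- if (is.null(g_channel)) NA_real_ else mean(g_channel[rois$box]) - bg[2]
  list(cortex_mean = cortex_mean, cytoplasm_mean = cyto_mean,
       f_actin_ratio = (cortex_mean - bg[1]) / (cyto_mean - bg[1]),
       g_actin_mean = g_mean)
}

#' Integrated transferrin uptake within a cell
#'
#' Because surface-bound transferrin is stripped by acid washing before
#' imaging, internalised signal is quantified as the integrated
#' background-subtracted intensity over the cell mask (negative residuals
#' clipped at zero).
#'
#' @param tf_channel Intensity matrix.
#' @param mask Logical cell mask.
#' @param background Scalar background.
#' @param normalizer Optional reference value (> 0), typically the mean raw
#'   uptake of the designated reference group; see [normalize_uptake()].
#' @return List with `tf_uptake_raw` and `tf_uptake_normalized` (`NA` when no
#'   normalizer is given).
#' @export
quantify_tf_uptake <- function(tf_channel, mask, background,
                               normalizer = NULL) {
  if (!any(mask)) stop("empty cell mask")
  raw <- sum(pmax(tf_channel[mask] - background, 0))
  norm <- NA_real_
  if (!is.null(normalizer)) {
    if (normalizer <= 0) stop("normalizer must be > 0")
    norm <- raw / normalizer
  }
  list(tf_uptake_raw = raw, tf_uptake_normalized = norm)
}

#' Normalize raw uptake values to a reference group
#'
#' Divides every raw uptake by the mean raw uptake of the reference group
#' (e.g., control interphase cells), whose own normalized mean is therefore
#' exactly 1.
#'
#' @param raw Numeric vector of raw uptake values.
#' @param group Character/factor vector of group labels, same length.
#' @param reference_group Label of the reference group.
#' @return Numeric vector of normalized uptakes.
#' @export
normalize_uptake <- function(raw, group, reference_group) {
  if (!reference_group %in% group)
    stop("reference group '", reference_group, "' absent from data")
  normalizer <- mean(raw[group == reference_group])
  if (normalizer <= 0) stop("reference-group mean uptake is not positive")
  raw / normalizer
}

#' Pick the equatorial plane of a z-stack
#'
#' The equatorial confocal section is taken as the plane whose cell mask has
#' maximal area.
#'
#' @param masks List of logical masks, one per z-plane.
#' @return Index of the equatorial plane.
#' @export
select_equatorial_plane <- function(masks) {
  which.max(vapply(masks, sum, numeric(1)))
}
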