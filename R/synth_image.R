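#' Specification for a synthetic mitotic-cell fluorescence image
#'
#' Emulates an equatorial confocal section of a rounded (mitotic-like) cell:
#' a disc of cytoplasm with a bright cortical ring (F-actin channel), a
#' uniform cytoplasmic fill (G-actin channel), punctate internalised
#' transferrin (uptake channel), a uniform background outside the cell, and
#' optional Gaussian noise.
#'
#' @param image_size Side length in pixels of the square image (default 256).
#' @param cell_radius Cell radius in px; the cell must fit in the image.
#' @param cortex_width Width of the cortical ring in px (>= 1, < cell_radius).
#' @param cortex_intensity,cytoplasm_intensity F-actin channel intensities of
#'   the cortical ring and the inner cytoplasm (arbitrary units).
#' @param g_intensity G-actin channel cytoplasmic intensity.
#' @param background_intensity Background added to every channel.
#' @param puncta_count Number of transferrin puncta inside the cell.
#' @param puncta_intensity Added intensity of each (single-pixel) punctum.
#' @param noise_sd SD of i.i.d. Gaussian noise added to every channel.
#' @param seed Integer seed.
#' @return An object of class `image_gen_spec`.
#' @export
image_gen_spec <- function(image_size = 256,
                           cell_radius = 80,
                           cortex_width = 24,
                           cortex_intensity = 200,
                           cytoplasm_intensity = 100,
                           g_intensity = 120,
                           background_intensity = 50,
                           puncta_count = 30,
                           puncta_intensity = 500,
                           noise_sd = 0,
                           seed = 1L) {
  if (cortex_width < 1) stop("cortex_width must be >= 1")
  if (cortex_width >= cell_radius) stop("cortex_width must be < cell_radius")
  if (2 * cell_radius >= image_size) stop("cell does not fit within the image")
  if (min(cortex_intensity, cytoplasm_intensity, g_intensity,
          background_intensity, puncta_intensity) < 0)
    stop("intensities must be >= 0")
  structure(as.list(environment()), class = "image_gen_spec")
}

#' Generate a synthetic two/three-channel cell image with ground truth
#'
#' @param spec An [image_gen_spec()].
#' @return List with:
#'   * `f_actin`, `g_actin`, `tf`: numeric intensity matrices;
#'   * `mask`: logical cell mask (the true disc);
#'   * `truth`: list with `f_actin_ratio`
#'     (`(cortex - background) / (cytoplasm - background)`, computed before
#'     noise), `g_actin_mean` (background-subtracted), `tf_total` (total
#'     added puncta signal), `center`, `cell_radius`.
#' @export
gen_cell_image <- function(spec) {
  stopifnot(inherits(spec, "image_gen_spec"))
  n <- spec$image_size
  cx <- (n + 1) / 2
  xy <- expand.grid(x = seq_len(n), y = seq_len(n))
  r <- matrix(sqrt((xy$x - cx)^2 + (xy$y - cx)^2), n, n)
  cell <- r <= spec$cell_radius
  cortex <- cell & r > spec$cell_radius - spec$cortex_width

  f <- matrix(spec$background_intensity, n, n)
  f[cell] <- spec$cytoplasm_intensity
  f[cortex] <- spec$cortex_intensity
  g <- matrix(spec$background_intensity, n, n)
  g[cell] <- spec$g_intensity
  tf <- matrix(spec$background_intensity, n, n)

  withr_seed(spec$seed, {
    if (spec$puncta_count > 0) {
      # puncta strictly inside the cytoplasm, clear of the cortex
      interior <- which(r <= spec$cell_radius - spec$cortex_width - 1)
      px <- sample(interior, spec$puncta_count, replace = FALSE)
      tf[px] <- tf[px] + spec$puncta_intensity
    }
    if (spec$noise_sd > 0) {
      f <- f + matrix(stats::rnorm(n * n, 0, spec$noise_sd), n, n)
      g <- g + matrix(stats::rnorm(n * n, 0, spec$noise_sd), n, n)
      tf <- tf + matrix(stats::rnorm(n * n, 0, spec$noise_sd), n, n)
    }
  })

  truth <- list(
    f_actin_ratio = (spec$cortex_intensity - spec$background_intensity) /
      (spec$cytoplasm_intensity - spec$background_intensity),
    g_actin_mean = spec$g_intensity - spec$background_intensity,
    tf_total = spec$puncta_count * spec$puncta_intensity,
    center = c(cx, cx), cell_radius = spec$cell_radius)
  list(f_actin = f, g_actin = g, tf = tf, mask = cell, truth = truth)
}
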