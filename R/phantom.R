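## Synthetic OCT B-scan phantoms.
##
## A phantom is a piecewise-constant "clean" reflectance image S -- a bright
## retinal band on a dark vitreous/choroid background, with hypo-reflective
## elliptical fluid cavities (edema) inside the band -- degraded by the
## standard coherent-imaging observation model
##
##     I = clip(S * N_s + N_b, 0, 1)
##
## where N_s is unit-mean multiplicative speckle and N_b is additive
## zero-mean Gaussian background noise. Ground-truth retina and edema masks
## come for free, so the enhancement and segmentation stages can be validated
## without clinical scans.

#' Specify a synthetic OCT B-scan phantom
#'
#' Defines the geometry, reflectance levels and noise of a synthetic B-scan:
#' a bright retinal band (optionally curved by a smooth per-column vertical
#' offset) containing dark elliptical fluid cavities, over a dark background.
#'
#' Intensities are mean reflectances in `[0, 1]` and must satisfy
#' `0 <= intensity_background < intensity_edema < intensity_retina <= 1`:
#' fluid cavities are hypo-reflective relative to retinal tissue but brighter
#' than the vitreous. Speckle is unit-mean gamma with shape `speckle_shape`
#' (variance `1/speckle_shape`); smaller shapes mean heavier speckle. The
#' defaults emulate a 128 x 256 macular B-scan with two intraretinal cavities
#' and fully-developed-looking speckle of shape 4.
#'
#' @param height,width Image size in pixels.
#' @param band_top,band_bottom First and last row (1-based) of the retinal
#'   band at zero offset.
#' @param band_offset Either a single amplitude in pixels for the built-in
#'   smooth sinusoidal curvature profile, or a numeric vector of length
#'   `width` of per-column vertical offsets (positive = down).
#' @param edema List of cavities, each `c(row, col, semi_row, semi_col)`:
#'   ellipse center and semi-axes in pixels. Every cavity must lie fully
#'   inside the (curved) retinal band.
#' @param intensity_retina,intensity_edema,intensity_background Mean
#'   reflectance of retinal tissue, intraretinal fluid and background.
#' @param speckle_shape Shape parameter of the unit-mean gamma speckle
#'   (must be positive).
#' @param background_noise_sd Standard deviation of the additive Gaussian
#'   background noise (non-negative).
#' @param seed Integer RNG seed; the phantom is a pure function of the spec.
#' @return An object of class `phantom_spec`.
#' @examples
#' spec <- phantom_spec(seed = 1)
#' ph <- generate_phantom(spec)
#' range(ph$image)
#' @export
phantom_spec <- function(height = 128L, width = 256L,
                         band_top = 34L, band_bottom = 98L,
                         band_offset = 5,
                         edema = list(c(66, 80, 14, 30), c(66, 180, 11, 22)),
                         intensity_retina = 0.72,
                         intensity_edema = 0.22,
                         intensity_background = 0.08,
                         speckle_shape = 4,
                         background_noise_sd = 0.02,
                         seed = 0L) {
  height <- as.integer(height); width <- as.integer(width)
  if (height < 8L || width < 8L)
    stop_octedema("phantom must be at least 8x8", class = "octedema_spec_error")
  if (length(band_offset) == 1L) {
    amp <- band_offset
    band_offset <- round(amp * sin(2 * pi * (seq_len(width) - 1) / width))
  }
  if (length(band_offset) != width)
    stop_octedema("band_offset must be scalar or length `width`",
                  class = "octedema_spec_error")
  if (!(intensity_background >= 0 && intensity_background < intensity_edema &&
        intensity_edema < intensity_retina && intensity_retina <= 1))
    stop_octedema("intensities must satisfy 0 <= background < edema < retina <= 1",
                  class = "octedema_spec_error")
  if (speckle_shape <= 0)
    stop_octedema("speckle_shape must be positive", class = "octedema_spec_error")
  if (background_noise_sd < 0)
    stop_octedema("background_noise_sd must be non-negative",
                  class = "octedema_spec_error")
  if (band_top < 1L || band_bottom > height || band_top >= band_bottom)
    stop_octedema("retina band must satisfy 1 <= band_top < band_bottom <= height",
                  class = "octedema_spec_error")
  edema <- lapply(edema, as.numeric)
  for (e in edema)
    if (length(e) != 4L || any(e[3:4] <= 0))
      stop_octedema("each edema entry must be c(row, col, semi_row, semi_col) with positive semi-axes",
                    class = "octedema_spec_error")
  structure(list(height = height, width = width,
                 band_top = as.integer(band_top),
                 band_bottom = as.integer(band_bottom),
                 band_offset = as.numeric(band_offset),
                 edema = edema,
                 intensity_retina = intensity_retina,
                 intensity_edema = intensity_edema,
                 intensity_background = intensity_background,
                 speckle_shape = speckle_shape,
                 background_noise_sd = background_noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

## Rasterize an ellipse at pixel centers (1-based row/col grid).
ellipse_mask <- function(height, width, center_row, center_col, a, b) {
  r <- matrix(seq_len(height), height, width)
  c <- matrix(seq_len(width), height, width, byrow = TRUE)
  ((r - center_row) / a)^2 + ((c - center_col) / b)^2 <= 1
}

#' Render the noise-free phantom image and ground-truth masks
#'
#' Deterministically rasterizes the spec's geometry into the clean
#' reflectance image S and the retina / edema masks. The retina mask covers
#' the whole band including the fluid cavities, so the edema mask is always
#' a subset of the retina mask.
#'
#' @param spec A [phantom_spec()].
#' @return A list with `clean` (numeric matrix), `retina_mask` and
#'   `edema_mask` (logical matrices).
#' @export
render_clean <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$height; w <- spec$width
  rows <- matrix(seq_len(h), h, w)
  off <- matrix(spec$band_offset, h, w, byrow = TRUE)
  retina <- rows >= (spec$band_top + off) & rows <= (spec$band_bottom + off)
  edema <- matrix(FALSE, h, w)
  for (i in seq_along(spec$edema)) {
    e <- spec$edema[[i]]
    m <- ellipse_mask(h, w, e[1], e[2], e[3], e[4])
    if (any(m & !retina))
      stop_octedema("edema ellipse ", i, " (center ", e[1], ",", e[2],
                    ") is not fully contained in the retina band",
                    class = "octedema_geometry_error")
    edema <- edema | m
  }
  clean <- matrix(spec$intensity_background, h, w)
  clean[retina] <- spec$intensity_retina
  clean[edema] <- spec$intensity_edema
  list(clean = clean, retina_mask = retina, edema_mask = edema)
}

#' Degrade a clean image with multiplicative speckle and background noise
#'
#' Applies the observation model `clip(clean * m + b, 0, 1)` where `m` is
#' i.i.d. unit-mean gamma noise (shape `speckle_shape`, scale
#' `1/speckle_shape`) and `b` is i.i.d. zero-mean Gaussian noise with
#' standard deviation `background_noise_sd`. Identical seeds give
#' bit-identical output; the caller's RNG state is left untouched.
#'
#' @param clean Numeric matrix with values in `[0, 1]`.
#' @param speckle_shape Positive gamma shape (variance of the speckle is
#'   `1/speckle_shape`).
#' @param background_noise_sd Non-negative additive noise SD.
#' @param seed Integer seed.
#' @return Numeric matrix in `[0, 1]`.
#' @export
apply_speckle <- function(clean, speckle_shape, background_noise_sd, seed) {
  assert_gray(clean)
  if (speckle_shape <= 0)
    stop_octedema("speckle_shape must be positive", class = "octedema_spec_error")
  if (background_noise_sd < 0)
    stop_octedema("background_noise_sd must be non-negative",
                  class = "octedema_spec_error")
  n <- length(clean)
  noisy <- withr::with_seed(as.integer(seed), {
    m <- rgamma(n, shape = speckle_shape, scale = 1 / speckle_shape)
    b <- if (background_noise_sd > 0) rnorm(n, 0, background_noise_sd) else 0
    clean * m + b
  })
  out <- pmin(pmax(noisy, 0), 1)
  dim(out) <- dim(clean)
  out
}

#' Generate a complete phantom pair
#'
#' Composes [render_clean()] and [apply_speckle()] into a `phantom_pair`:
#' the speckled image, the clean image, and the two ground-truth masks.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `phantom_pair` with elements `image`, `clean`,
#'   `retina_mask`, `edema_mask` and the originating `spec`.
#' @export
generate_phantom <- function(spec) {
  g <- render_clean(spec)
  img <- apply_speckle(g$clean, spec$speckle_shape, spec$background_noise_sd,
                       spec$seed)
  out <- structure(list(image = img, clean = g$clean,
                        retina_mask = g$retina_mask, edema_mask = g$edema_mask,
                        spec = spec),
                   class = "phantom_pair")
  stopifnot(!any(out$edema_mask & !out$retina_mask),
            all(out$image >= 0 & out$image <= 1))
  out
}

#' @export
print.phantom_pair <- function(x, ...) {
  cat(sprintf("phantom_pair: %d x %d B-scan, %d edema cavit%s, speckle shape %g, seed %d\n",
              nrow(x$image), ncol(x$image), length(x$spec$edema),
              if (length(x$spec$edema) == 1) "y" else "ies",
              x$spec$speckle_shape, x$spec$seed))
  invisible(x)
}

#' Ground-truth regions of interest for image-quality metrics
#'
#' Builds a homogeneous retinal-tissue ROI (retina band minus a safety
#' margin around the cavities and the band boundary) and a background ROI
#' (pixels far from the band), suitable for [cnr()] and [enl()] on phantom
#' images.
#'
#' @param pair A `phantom_pair`.
#' @param margin Erosion margin in pixels kept clear of every boundary.
#' @return A list with `rois` (list of one logical retina-tissue mask) and
#'   `background` (logical mask).
#' @export
phantom_rois <- function(pair, margin = 4L) {
  stopifnot(inherits(pair, "phantom_pair"))
  brush <- EBImage::makeBrush(2L * as.integer(margin) + 1L, shape = "disc")
  retina_core <- EBImage::erode(pair$retina_mask * 1L, brush) > 0
  edema_halo <- EBImage::dilate(pair$edema_mask * 1L, brush) > 0
  tissue <- retina_core & !edema_halo
  band_halo <- EBImage::dilate(pair$retina_mask * 1L, brush) > 0
  background <- !band_halo
  if (!any(tissue) || !any(background))
    stop_octedema("phantom too small for the requested ROI margin",
                  class = "octedema_spec_error")
  list(rois = list(tissue), background = background)
}
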