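# Raw frame -> watershed-ready inputs: a coarse cell/background mask, a
# contour-pixel mask, and a topography whose basins sit in cell interiors.
# Phase-contrast frames can be used directly (boundaries are bright); for
# bright-field the complement is top-hat filtered first; a fluorescent
# channel can be blended in to darken cell interiors.

local_mean <- function(image, window) {
  k <- matrix(1 / (window * window), window, window)
  as_mat(EBImage::filter2(image, k, boundary = "replicate"))
}

local_sd <- function(image, window) {
  m <- local_mean(image, window)
  m2 <- local_mean(image * image, window)
  sqrt(pmax(m2 - m * m, 0))
}

#' Coarse cell/background mask
#'
#' Separates colony regions from background by thresholding the local
#' standard deviation of the image (cell boundaries and interstices are
#' textured, background is flat), closing gaps, filling enclosed interiors
#' and discarding components smaller than `min_colony_area`. All downstream
#' labels are confined to this mask.
#'
#' @param image numeric matrix, finite, at least 64 x 64.
#' @param params a [prep_params()] object.
#' @return logical matrix of colony pixels.
#' @export
coarse_cell_mask <- function(image, params = prep_params()) {
  image <- assert_image(image)
  if (nrow(image) < 64L || ncol(image) < 64L)
    stop("image must be at least 64 x 64")
  s <- local_sd(image, params$std_window)
  # guard against pure numerical residue on (near-)constant images
  if (max(s) < 1e-6 * max(abs(image), 1))
    return(matrix(FALSE, nrow(image), ncol(image)))
  sn <- minmax01(s)
  thr <- EBImage::otsu(EBImage::Image(sn), range = c(0, 1))
  raw <- sn > thr
  m <- m_close(raw, 3L)
  m <- fill_holes(m)
  m <- m_erode(m, 2L)
  drop_small_components(m, params$min_colony_area)
}

#' Detect contour pixels
#'
#' Marks pixel `p` when `image(p) > local_mean(p) + contour_k * local_sd(p)`
#' and the excess over the local mean also clears the absolute
#' `min_contrast` floor. Cell contours and interstices are brighter than
#' both background and cell interiors in (preprocessed) input, so this
#' picks out the boundary network. When a coarse mask is supplied the
#' result is restricted to a small dilation of it.
#'
#' @param image numeric matrix with bright cell boundaries (phase-like
#'   contrast; run [brightfield_preprocess()] first for bright-field data).
#' @param params a [prep_params()] object.
#' @param cellmask optional coarse colony mask; contours are confined to
#'   its 3-pixel dilation.
#' @return logical matrix of contour pixels.
#' @export
detect_contour_pixels <- function(image, params = prep_params(),
                                  cellmask = NULL) {
  image <- assert_image(image)
  w <- max(params$mean_window, params$std_window)
  if (w > nrow(image) || w > ncol(image))
    stop("filter window exceeds image size")
  m <- local_mean(image, params$mean_window)
  s <- local_sd(image, params$std_window)
  excess <- image - m
  marked <- excess > params$contour_k * s & excess > params$min_contrast
  if (!is.null(cellmask)) marked <- marked & m_dilate(cellmask, 3L)
  marked
}

#' Build a watershed topography from contour pixels
#'
#' Computes the distance of every colony pixel to the nearest contour or
#' background pixel and negates it, so that each contour-enclosed cell
#' interior holds one deep regional minimum while background and contour
#' pixels form a plateau at 0 above all interior values. Shallow spurious
#' minima are suppressed at flood time (see [watershed_partition()]).
#'
#' @param contours logical matrix of contour pixels.
#' @param cellmask logical coarse colony mask.
#' @return numeric matrix; 0 outside cells, negative in cell interiors.
#' @export
make_topography <- function(contours, cellmask) {
  stopifnot(identical(dim(contours), dim(cellmask)))
  zero <- matrix(0, nrow(contours), ncol(contours))
  if (!any(cellmask) || !any(contours)) return(zero)
  barrier <- contours | !cellmask
  if (!any(!barrier)) return(zero)
  d <- as_mat(EBImage::distmap((!barrier) * 1))
  -d
}

#' Preprocess a bright-field frame for segmentation
#'
#' Bright-field yeast images are low contrast with thin dark boundary
#' rings. The frame is min-max rescaled (absorbing uneven illumination in
#' range), complemented so boundaries become bright, and filtered with a
#' white top-hat (disk of radius `tophat_radius`) that keeps bright
#' features thinner than the disk while flattening the background and any
#' smooth illumination gradient. The output feeds
#' [detect_contour_pixels()] like a phase image.
#'
#' @param image numeric matrix.
#' @param params a [prep_params()] object.
#' @return nonnegative numeric matrix with bright cell boundaries.
#' @export
brightfield_preprocess <- function(image, params = prep_params()) {
  image <- assert_image(image)
  comp <- 1 - minmax01(image)
  out <- as_mat(EBImage::whiteTopHat(comp, disk_brush(params$tophat_radius)))
  pmax(out, 0)
}

#' Blend a phase image with a cytoplasmic fluorescent channel
#'
#' Both images are min-max rescaled to `[0, 1]`; the composite is
#' `(1 - w) * phase + w * (1 - fluor)`, so cytoplasmic fluorescence darkens
#' cell interiors and raises the contrast between interior and the bright
#' boundary, without dedicating a channel to segmentation.
#'
#' @param phase,fluor numeric matrices of equal shape.
#' @param w mixing fraction in `[0, 1]`.
#' @return numeric matrix in `[0, 1]`.
#' @export
make_composite <- function(phase, fluor, w = 0.5) {
  phase <- assert_image(phase); fluor <- assert_image(fluor)
  if (!identical(dim(phase), dim(fluor)))
    stop("phase and fluorescence images must have the same shape")
  check_flag(w >= 0 && w <= 1, "w must be in [0, 1]")
  (1 - w) * minmax01(phase) + w * (1 - minmax01(fluor))
}

#' Contour-evidence image for a frame
#'
#' Dispatches on the imaging modality and returns the image the scoring
#' subroutine and contour detector operate on: bright boundaries, lightly
#' smoothed, robustly rescaled to `[0, 1]`.
#'
#' @param image numeric matrix (the phase image for `"composite"`).
#' @param modality one of `"phase"`, `"brightfield"`, `"composite"`.
#' @param params a [prep_params()] object.
#' @param fluor fluorescent channel, required for `"composite"`.
#' @return numeric matrix in `[0, 1]`.
#' @export
prep_evidence <- function(image, modality = c("phase", "brightfield",
                                              "composite"),
                          params = prep_params(), fluor = NULL) {
  modality <- match.arg(modality)
  image <- assert_image(image)
  x <- switch(modality,
    phase = image,
    brightfield = brightfield_preprocess(image, params),
    composite = {
      if (is.null(fluor))
        stop("composite modality requires a fluorescent channel")
      make_composite(image, fluor, params$composite_weight)
    })
  if (params$blur_sigma > 0)
    x <- as_mat(EBImage::gblur(x, sigma = params$blur_sigma))
  rescale01(x, c(0.001, 0.999))
}

#' Prepare a frame for segmentation
#'
#' Runs the full preparation for one frame and bundles the results: the
#' contour-evidence image, the coarse colony mask, and the detected
#' contour pixels (used both to build the watershed topography and as the
#' boundary barrier of the scoring subroutine).
#'
#' @inheritParams prep_evidence
#' @return object of class `prep_frame` with fields `evidence`,
#'   `cellmask`, `contours`.
#' @export
prep_frame <- function(image, modality = c("phase", "brightfield",
                                           "composite"),
                       params = prep_params(), fluor = NULL) {
  ev <- prep_evidence(image, modality, params, fluor)
  cm <- coarse_cell_mask(ev, params)
  contours <- detect_contour_pixels(ev, params, cellmask = cm)
  # wide bright interstices between packed cells are plateaus without
  # local contrast; their absolute brightness still marks them as boundary
  # material, and a radius-1 closing then seals one-pixel gaps so basins
  # and converged masks cannot leak between touching cells
  bright <- ev > params$barrier_evidence_min & m_dilate(cm, 3L)
  contours <- m_close(contours | bright, 1L)
  structure(list(evidence = ev, cellmask = cm, contours = contours),
            class = "prep_frame")
}

#' @export
print.prep_frame <- function(x, ...) {
  cat(sprintf("<prep_frame %d x %d: %.1f%% colony, %d contour px>\n",
              nrow(x$evidence), ncol(x$evidence),
              100 * mean(x$cellmask), sum(x$contours)))
  invisible(x)
}
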