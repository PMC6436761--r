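# Internal helpers shared across modules. Images are plain numeric matrices
# indexed [row, col]; masks are logical matrices; label masks are integer
# matrices with 0 = background.

#' @import EBImage
NULL

as_mat <- function(x) {
  if (inherits(x, "Image")) x <- EBImage::imageData(x)
  if (is.null(dim(x)) || length(dim(x)) != 2L)
    stop("expected a 2-D image")
  x <- as.matrix(x)
  x
}

assert_image <- function(x) {
  x <- as_mat(x)
  if (!all(is.finite(x))) stop("image contains non-finite pixels")
  storage.mode(x) <- "double"
  x
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# Pure min-max rescale to [0, 1]; constant input maps to 0.
minmax01 <- function(x) {
  r <- range(x)
  if (r[2] - r[1] < sqrt(.Machine$double.eps))
    return(matrix(0, nrow(x), ncol(x)))
  (x - r[1]) / (r[2] - r[1])
}

# Quantile-robust rescale: outliers beyond the quantile range are clipped.
rescale01 <- function(x, q = c(0, 1)) {
  if (identical(q, c(0, 1))) return(minmax01(x))
  r <- stats::quantile(x, q, names = FALSE)
  if (r[2] - r[1] < sqrt(.Machine$double.eps))
    return(matrix(0, nrow(x), ncol(x)))
  clip01((x - r[1]) / (r[2] - r[1]))
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Disk-shaped structuring elements, cached by radius.
.brush_cache <- new.env(parent = emptyenv())
disk_brush <- function(radius) {
  key <- as.character(radius)
  if (is.null(.brush_cache[[key]]))
    .brush_cache[[key]] <- EBImage::makeBrush(2L * as.integer(radius) + 1L,
                                              shape = "disc")
  .brush_cache[[key]]
}

m_erode  <- function(mask, r) as_mat(EBImage::erode(mask * 1, disk_brush(r))) > 0
m_dilate <- function(mask, r) as_mat(EBImage::dilate(mask * 1, disk_brush(r))) > 0
m_open   <- function(mask, r) as_mat(EBImage::opening(mask * 1, disk_brush(r))) > 0
m_close  <- function(mask, r) as_mat(EBImage::closing(mask * 1, disk_brush(r))) > 0

fill_holes <- function(mask) as_mat(EBImage::fillHull(mask * 1)) > 0

# Euclidean distance of every pixel to the nearest TRUE pixel of `mask`.
# Pixels inside `mask` get 0.
dist_to <- function(mask) {
  if (!any(mask)) return(matrix(Inf, nrow(mask), ncol(mask)))
  as_mat(EBImage::distmap((!mask) * 1))
}

# 4-connected component labelling.
components <- function(mask) {
  lab <- as_mat(EBImage::bwlabel(mask * 1))
  storage.mode(lab) <- "integer"
  lab
}

# Largest 4-connected component; ties broken by lowest component id.
largest_component <- function(mask) {
  lab <- components(mask)
  n <- max(lab)
  if (n == 0L) return(mask & FALSE)
  if (n == 1L) return(lab > 0L)
  areas <- tabulate(lab[lab > 0L], nbins = n)
  lab == which.max(areas)
}

# Component with the largest overlap with `seed`; components untouched by
# the seed only win when none overlaps (then: largest area, lowest id).
largest_component_seeded <- function(mask, seed) {
  lab <- components(mask)
  n <- max(lab)
  if (n == 0L) return(mask & FALSE)
  if (n == 1L) return(lab > 0L)
  ov <- tabulate(lab[seed & lab > 0L], nbins = n)
  if (any(ov > 0L)) return(lab == which.max(ov))
  areas <- tabulate(lab[lab > 0L], nbins = n)
  lab == which.max(areas)
}

# Drop connected components smaller than min_area pixels.
drop_small_components <- function(mask, min_area) {
  lab <- components(mask)
  n <- max(lab)
  if (n == 0L) return(mask)
  areas <- tabulate(lab[lab > 0L], nbins = n)
  keep <- which(areas >= min_area)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

mask_bbox <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  if (nrow(w) == 0L) return(NULL)
  c(r0 = min(w[, 1L]), c0 = min(w[, 2L]), r1 = max(w[, 1L]), c1 = max(w[, 2L]))
}

# Jaccard index between two logical masks of equal shape.
jaccard <- function(a, b) {
  u <- sum(a | b)
  if (u == 0L) return(1)
  sum(a & b) / u
}

label_areas <- function(labels) {
  n <- max(labels)
  if (n == 0L) return(integer(0))
  tabulate(labels[labels > 0L], nbins = n)
}

#' Centroids of a label mask
#'
#' @param labels integer label matrix; 0 = background.
#' @return numeric matrix with one row per label id present (row names are
#'   the ids) and columns `row`, `col`.
#' @export
label_centroids <- function(labels) {
  ids <- sort(unique(labels[labels > 0L]))
  if (length(ids) == 0L)
    return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("row", "col"))))
  w <- which(labels > 0L, arr.ind = TRUE)
  l <- labels[labels > 0L]
  rs <- rowsum(cbind(w[, 1L], w[, 2L]), l)
  cnt <- as.vector(rowsum(rep(1, length(l)), l))
  out <- rs / cnt
  dimnames(out) <- list(rownames(rs), c("row", "col"))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
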