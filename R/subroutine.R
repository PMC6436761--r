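# The iterative seeded segmentation core. Each cell is segmented inside a
# small subimage around its seed: a per-pixel score in [0,1] expresses how
# likely the pixel belongs to the cell, the score is thresholded, and the
# resulting mask is fed back as the seed of the next round. Coarse or
# perturbed seeds converge onto the true boundary in a few rounds. No RNG:
# identical inputs give identical outputs.

#' Subimage context around a seed
#'
#' Crops the contour-evidence frame to the seed bounding box plus a `pad`
#' margin and carries the crop-local seed and the crop origin, so that
#' per-cell segmentation touches only a neighborhood of the cell.
#'
#' @param frame full-frame contour-evidence image (see [prep_evidence()]),
#'   or a [prep_frame()] object (its contour mask then travels along as
#'   the boundary barrier).
#' @param seed nonempty logical mask in frame coordinates.
#' @param pad margin (pixels) around the seed bounding box; must cover the
#'   expected one-frame boundary motion.
#' @param barrier optional logical full-frame mask of detected contour
#'   pixels; treated as hard boundary evidence by [compute_score()].
#' @return an object of class `subimage_context` with fields `crop`,
#'   `seed`, `barrier` (all crop-local), `origin` (row, col of the crop
#'   within the frame) and `dim` (frame shape).
#' @export
subimage_context <- function(frame, seed, pad = 10L, barrier = NULL) {
  if (inherits(frame, "prep_frame")) {
    barrier <- barrier %||% frame$contours
    frame <- frame$evidence
  }
  frame <- as_mat(frame)
  stopifnot(identical(dim(frame), dim(seed)))
  bb <- mask_bbox(seed)
  if (is.null(bb)) stop("seed is empty")
  r0 <- max(1L, bb["r0"] - pad); c0 <- max(1L, bb["c0"] - pad)
  r1 <- min(nrow(frame), bb["r1"] + pad); c1 <- min(ncol(frame), bb["c1"] + pad)
  structure(list(crop = frame[r0:r1, c0:c1, drop = FALSE],
                 seed = seed[r0:r1, c0:c1, drop = FALSE],
                 barrier = if (is.null(barrier)) NULL else
                   barrier[r0:r1, c0:c1, drop = FALSE],
                 origin = c(row = unname(r0), col = unname(c0)),
                 dim = dim(frame)),
            class = "subimage_context")
}

# Insert a crop-local mask back into a full frame.
uncrop_mask <- function(local, origin, dim) {
  out <- matrix(FALSE, dim[1L], dim[2L])
  out[origin[1L]:(origin[1L] + nrow(local) - 1L),
      origin[2L]:(origin[2L] + ncol(local) - 1L)] <- local
  out
}

uncrop_image <- function(local, origin, dim, fill = 0) {
  out <- matrix(fill, dim[1L], dim[2L])
  out[origin[1L]:(origin[1L] + nrow(local) - 1L),
      origin[2L]:(origin[2L] + ncol(local) - 1L)] <- local
  out
}

#' Per-pixel cell score
#'
#' The score of pixel `p` for the cell seeded at `ctx$seed` mixes three
#' terms: `boundary_weight * (1 - evidence(p))` (contour evidence speaks
#' against membership), `seed_weight * max(0, 1 - d(p, seed)/reach_px)`
#' (proximity to the seed), and `interior_weight * connected(p)` where
#' `connected` marks the low-evidence region(s) the seed sits in (pixels
#' reachable from the seed without crossing a contour). Detected contour
#' pixels (`ctx$barrier`) are hard boundary evidence: their boundary and
#' connectivity terms are 0 whatever their raw intensity, which keeps the
#' mask from bleeding across faint but detected ridges between touching
#' cells. The score is clipped to `[0, 1]` and is 0 beyond `reach_px` of
#' the seed.
#'
#' @param ctx a [subimage_context()]; the crop must be contour evidence in
#'   `[0, 1]` (bright boundaries).
#' @param params a [subroutine_params()] object.
#' @return numeric matrix (crop-local score map in `[0, 1]`).
#' @export
compute_score <- function(ctx, params = subroutine_params()) {
  stopifnot(inherits(ctx, "subimage_context"))
  if (!any(ctx$seed)) stop("seed is empty")
  ev <- clip01(ctx$crop)
  if (!is.null(ctx$barrier)) ev[ctx$barrier] <- 1
  dseed <- dist_to(ctx$seed)
  prox <- pmax(0, 1 - dseed / params$reach_px)

  low <- ev < params$interior_evidence_max
  conn <- matrix(FALSE, nrow(ev), ncol(ev))
  lab <- components(low)
  n <- max(lab)
  if (n > 0L) {
    under_seed <- lab[ctx$seed & lab > 0L]
    if (length(under_seed) > 0L) {
      ov <- tabulate(under_seed, nbins = n)
      areas <- tabulate(lab[lab > 0L], nbins = n)
      # the component carrying most of the seed, plus any component the
      # seed covers at least half of (under-segmented seeds span several
      # interiors); grazing contact with large regions (e.g. background)
      # does not count
      keep <- union(which.max(ov), which(ov >= 0.5 * areas & ov > 0L))
      conn <- matrix(lab %in% keep, nrow(ev), ncol(ev))
    }
  }

  score <- params$boundary_weight * (1 - ev) +
    params$seed_weight * prox +
    params$interior_weight * conn
  score[dseed > params$reach_px] <- 0
  score <- clip01(score)
  attr(score, "conn") <- conn
  score
}

#' One refinement round
#'
#' Thresholds the score at `accept_threshold` (inclusive) and keeps the
#' component that is the cell: the connected component carrying the
#' seed-connected interior region (the score's connectivity term), falling
#' back to largest seed overlap and then to largest area when no interior
#' was identified. Interior holes are filled and the boundary is smoothed
#' by morphological closing then opening with a disk of radius
#' `smooth_radius` (skipped if it would erase a small cell).
#'
#' @inheritParams compute_score
#' @return list with `mask` (logical, crop-local; empty when no pixel
#'   reaches the threshold, which callers interpret as cell loss) and
#'   `score`.
#' @export
refine_once <- function(ctx, params = subroutine_params()) {
  score <- compute_score(ctx, params)
  conn <- attr(score, "conn")
  th <- score >= params$accept_threshold
  if (!any(th))
    return(list(mask = th, score = score))
  anchor <- if (any(conn & th)) conn else ctx$seed
  m <- largest_component_seeded(th, anchor)
  m <- fill_holes(m)
  if (params$smooth_radius > 0L) {
    sm <- m_open(m_close(m, params$smooth_radius), params$smooth_radius)
    if (any(sm)) m <- fill_holes(largest_component_seeded(sm, anchor))
  }
  list(mask = m, score = score)
}

#' Iterate the segmentation subroutine
#'
#' Applies [refine_once()] up to `n_rounds` times, feeding each output mask
#' back as the seed of the next round, and stops early when two successive
#' masks are identical. An empty mask at any round is propagated (the cell
#' is lost).
#'
#' @inheritParams compute_score
#' @return list with the final `mask` and `score` (both crop-local).
#' @export
iterate_subroutine <- function(ctx, params = subroutine_params()) {
  res <- NULL
  for (i in seq_len(params$n_rounds)) {
    res <- refine_once(ctx, params)
    if (!any(res$mask)) return(res)
    if (identical(res$mask, ctx$seed)) return(res)
    ctx$seed <- res$mask
  }
  res
}
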