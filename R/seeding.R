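# Fully automated seeding of the last frame: watershed over the prepped
# topography gives coarse putative cells; each is checked for
# under-segmentation by threshold voting, fine-tuned by the iterative
# subroutine, over-segmented fragments are merged by overlap, and remaining
# disputed pixels are distributed by score.

#' Watershed partition of the colony mask
#'
#' Floods the (negated) topography from its regional minima so that every
#' colony pixel receives exactly one label and each suppressed-minimum
#' basin becomes one putative cell. Basins shallower than `h` (depth from
#' minimum to the saddle where they meet a neighbor) are merged into that
#' neighbor, which removes spurious shallow minima; contour-plateau pixels
#' left unlabeled by the flood are attached to their nearest basin.
#'
#' @param topography output of [make_topography()].
#' @param cellmask logical coarse colony mask.
#' @param h minimum basin depth (distance units) for a separate label.
#' @return integer label matrix; 0 = background.
#' @export
watershed_partition <- function(topography, cellmask, h = 1) {
  stopifnot(identical(dim(topography), dim(cellmask)))
  x <- -as_mat(topography)
  x[!cellmask] <- 0
  out <- matrix(0L, nrow(x), ncol(x))
  if (all(x <= 0)) return(out)
  lab <- as_mat(EBImage::watershed(EBImage::Image(x), tolerance = h, ext = 1))
  if (max(lab) == 0L) return(out)
  if (any(cellmask & lab == 0)) {
    lab <- as_mat(EBImage::propagate(EBImage::Image(x), EBImage::Image(lab),
                                     mask = cellmask))
  }
  storage.mode(lab) <- "integer"
  lab
}

#' Split an under-segmented putative cell by threshold voting
#'
#' Re-runs contour detection on the region's subimage once per threshold in
#' `vote_thresholds`; each threshold votes a pixel "cell" when it is inside
#' the region and not a contour pixel at that threshold. Pixels with at
#' least `vote_majority` votes form the voted mask; its connected
#' components (at least `min_cell_area` pixels) become separate putative
#' cells. A stable region (one component, or an empty vote) is returned
#' unchanged.
#'
#' @param region logical mask of one watershed label (frame coordinates).
#' @param evidence full-frame contour evidence (see [prep_evidence()]).
#' @param cellmask coarse colony mask.
#' @param params a [seeding_params()] object.
#' @param prep a [prep_params()] object (its `contour_k` is replaced by
#'   each vote threshold in turn).
#' @return list of logical masks (frame coordinates), one per putative cell.
#' @export
split_undersegmented <- function(region, evidence, cellmask,
                                 params = seeding_params(),
                                 prep = prep_params()) {
  bb <- mask_bbox(region)
  if (is.null(bb)) return(list(region))
  pad <- max(prep$mean_window, prep$std_window)
  r0 <- max(1L, bb["r0"] - pad); c0 <- max(1L, bb["c0"] - pad)
  r1 <- min(nrow(region), bb["r1"] + pad); c1 <- min(ncol(region), bb["c1"] + pad)
  ev <- evidence[r0:r1, c0:c1, drop = FALSE]
  reg <- region[r0:r1, c0:c1, drop = FALSE]
  cm <- cellmask[r0:r1, c0:c1, drop = FALSE]
  votes <- matrix(0L, nrow(reg), ncol(reg))
  bright <- ev > prep$barrier_evidence_min & m_dilate(cm, 3L)
  for (k in params$vote_thresholds) {
    pk <- prep; pk$contour_k <- k
    cont <- m_close(detect_contour_pixels(ev, pk, cellmask = cm) | bright, 1L)
    votes <- votes + (reg & !cont)
  }
  voted <- votes >= params$vote_majority
  if (!any(voted)) return(list(region))
  lab <- components(voted)
  areas <- label_areas(lab)
  keep <- which(areas >= params$min_cell_area)
  if (length(keep) == 0L) keep <- which.max(areas)
  if (length(keep) <= 1L) return(list(region))
  lapply(keep, function(i)
    uncrop_mask(lab == i, c(r0, c0), dim(region)))
}

# Transitive merge grouping: indices of masks whose pairwise intersection
# exceeds theta * min(area) end up in one group (union-find).
merge_groups <- function(masks, theta, min_overlap_px = 1L) {
  n <- length(masks)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  areas <- vapply(masks, sum, numeric(1))
  bbs <- lapply(masks, mask_bbox)
  for (i in seq_len(n)) {
    if (is.null(bbs[[i]])) next
    for (j in seq_len(n)) {
      if (j <= i || is.null(bbs[[j]])) next
      bi <- bbs[[i]]; bj <- bbs[[j]]
      if (bi["r1"] < bj["r0"] || bj["r1"] < bi["r0"] ||
          bi["c1"] < bj["c0"] || bj["c1"] < bi["c0"]) next
      ov <- sum(masks[[i]] & masks[[j]])
      if (ov >= min_overlap_px && ov / min(areas[i], areas[j]) > theta) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  split(seq_len(n), roots)
}

#' Merge over-segmented fragments
#'
#' After the iterative subroutine, fragments of one cell have each
#' converged toward the whole cell and therefore overlap heavily, while
#' converged neighbors do not. Any pair of masks whose intersection exceeds
#' `merge_overlap_theta` of the smaller mask is unioned; merging is applied
#' transitively until stable.
#'
#' @param masks list of logical masks (frame coordinates).
#' @param params a [seeding_params()] object.
#' @return list of logical masks after merging, with an attribute
#'   `"groups"` giving the input indices combined into each output mask.
#' @export
merge_oversegmented <- function(masks, params = seeding_params()) {
  if (length(masks) <= 1L) {
    out <- masks
    attr(out, "groups") <- as.list(seq_along(masks))
    return(out)
  }
  groups <- merge_groups(masks, params$merge_overlap_theta)
  out <- lapply(groups, function(idx) Reduce(`|`, masks[idx]))
  names(out) <- NULL
  attr(out, "groups") <- unname(groups)
  out
}

# Mean score of a converged mask when it acts as its own seed: the
# proximity term saturates, so the mean reflects only boundary evidence
# and interior connectedness -- near 1 inside a real cell.
self_score_mean <- function(mask, ctx, sub) {
  ctx$seed <- mask
  mean(compute_score(ctx, sub)[mask])
}

# Fraction of a mask's boundary lying against detected contour pixels.
# Boundary pixels on the crop border are ignored (no contour information
# there); an edgeless mask passes trivially.
enclosure_frac <- function(mask, barrier) {
  if (is.null(barrier)) return(1)
  edge <- mask & !m_erode(mask, 1L)
  inner <- matrix(FALSE, nrow(mask), ncol(mask))
  if (nrow(mask) > 2L && ncol(mask) > 2L)
    inner[2:(nrow(mask) - 1L), 2:(ncol(mask) - 1L)] <- TRUE
  edge <- edge & inner
  if (!any(edge)) return(1)
  mean(m_dilate(barrier, 2L)[edge])
}

# Combined converged-mask acceptance: does this look like a cell?
is_cell_like <- function(mask, ctx, sub, score_min, enclosure_min) {
  self_score_mean(mask, ctx, sub) >= score_min &&
    enclosure_frac(mask, ctx$barrier) >= enclosure_min
}

# Internal per-cell segmentation record: crop-local mask and score with the
# crop origin, so full-frame score maps never need to be materialized.
cellseg_record <- function(mask, score, origin, dim, id = NA_integer_) {
  list(mask = mask, score = score, origin = origin, dim = dim, id = id)
}

record_from_full <- function(mask, score, id = NA_integer_) {
  bb <- mask_bbox(mask)
  if (is.null(bb))
    return(cellseg_record(matrix(FALSE, 0, 0), matrix(0, 0, 0),
                          c(1L, 1L), dim(mask), id))
  r <- bb["r0"]:bb["r1"]; cc <- bb["c0"]:bb["c1"]
  cellseg_record(mask[r, cc, drop = FALSE], score[r, cc, drop = FALSE],
                 c(bb["r0"], bb["c0"]), dim(mask), id)
}

# Score-argmax distribution over records. Exact score ties go to the
# lowest label id -- in backwards tracking the lower id is the older,
# established cell, which should keep disputed pixels against a vanishing
# bud's claim. The id comparison (not processing position) makes the
# result independent of the order records are supplied in. Pixels claimed
# by a single record keep it regardless of score. Returns an integer
# label matrix using each record's id.
distribute_records <- function(records, dim) {
  lab <- matrix(0L, dim[1L], dim[2L])
  best <- matrix(-Inf, dim[1L], dim[2L])
  for (rec in records) {
    if (!any(rec$mask)) next
    rr <- rec$origin[1L]:(rec$origin[1L] + nrow(rec$mask) - 1L)
    cc <- rec$origin[2L]:(rec$origin[2L] + ncol(rec$mask) - 1L)
    sub_b <- best[rr, cc, drop = FALSE]
    sub_l <- lab[rr, cc, drop = FALSE]
    upd <- rec$mask & (rec$score > sub_b |
                         (rec$score == sub_b &
                            (sub_l == 0L | rec$id < sub_l)))
    if (any(upd)) {
      sub_l[upd] <- rec$id
      sub_b[upd] <- rec$score[upd]
      lab[rr, cc] <- sub_l
      best[rr, cc] <- sub_b
    }
  }
  lab
}

#' Distribute overlapping segmentations by score
#'
#' Pixels claimed by two or more cell masks are assigned to the single cell
#' with the highest score at that pixel; pixels claimed by exactly one mask
#' keep their cell. No pixel is discarded and none is double-labeled, so
#' the output labels cover exactly the union of the input masks. Score
#' ties (including all-zero scores) go to the lower cell index. Overlaps
#' large enough to indicate over-segmentation should be routed through
#' [merge_oversegmented()] first, as [autoseed()] does.
#'
#' @param masks list of logical masks (frame coordinates).
#' @param scores list of numeric score maps, index-aligned with `masks`.
#' @return integer label matrix; label `i` marks pixels won by `masks[[i]]`.
#' @export
distribute_overlaps <- function(masks, scores) {
  stopifnot(length(masks) == length(scores))
  if (length(masks) == 0L) stop("no masks to distribute")
  d <- dim(masks[[1L]])
  records <- lapply(seq_along(masks), function(i) {
    stopifnot(identical(dim(masks[[i]]), d),
              identical(dim(scores[[i]]), d))
    record_from_full(masks[[i]], scores[[i]], id = i)
  })
  distribute_records(records, d)
}

#' Fully automated seeding of the last frame
#'
#' Runs the complete seeding pipeline on one frame: contour-evidence
#' preparation, coarse colony masking, contour detection, topography and
#' watershed, per-label under-segmentation splitting by threshold voting,
#' iterative score-based fine-tuning of every piece, overlap-based merging
#' of over-segmented fragments, and score-based distribution of the
#' remaining disputed pixels. Cells smaller than `min_cell_area` are
#' dropped and labels are renumbered 1..K. Deterministic: identical inputs
#' give identical labels.
#'
#' @param frame raw image of the last time point.
#' @param modality `"phase"`, `"brightfield"` or `"composite"`.
#' @param fluor fluorescent channel (required for `"composite"`).
#' @param prep,sub,seedp parameter objects ([prep_params()],
#'   [subroutine_params()], [seeding_params()]).
#' @param pad crop margin (pixels) around each putative cell.
#' @return object of class `autoseed` with `labels` (integer matrix) and
#'   `cells` (per-cell crop-local mask/score records).
#' @export
autoseed <- function(frame, modality = "phase", fluor = NULL,
                     prep = prep_params(), sub = subroutine_params(),
                     seedp = seeding_params(), pad = 10L) {
  pf <- if (inherits(frame, "prep_frame")) frame else
    prep_frame(frame, modality, prep, fluor)
  ev <- pf$evidence
  cm <- pf$cellmask
  empty <- structure(list(labels = matrix(0L, nrow(ev), ncol(ev)),
                          cells = list()), class = "autoseed")
  if (!any(cm)) {
    warning("no colony regions found; returning empty seed")
    return(empty)
  }
  topo <- make_topography(pf$contours, cm)
  ws <- watershed_partition(topo, cm)
  nlab <- max(ws)
  if (nlab == 0L) {
    warning("watershed found no basins; returning empty seed")
    return(empty)
  }

  # under-segmentation correction by threshold voting
  pieces <- list()
  for (L in seq_len(nlab)) {
    region <- ws == L
    if (sum(region) < seedp$min_cell_area) next
    pieces <- c(pieces, split_undersegmented(region, ev, cm, seedp, prep))
  }
  if (length(pieces) == 0L) {
    warning("no putative cells above the minimum area; returning empty seed")
    return(empty)
  }

  # fine-tune every piece with the iterative subroutine; discard pieces
  # that converge onto something that does not look like a cell interior
  segs <- vector("list", length(pieces))
  for (i in seq_along(pieces)) {
    ctx <- subimage_context(ev, pieces[[i]], pad = pad,
                            barrier = pf$contours)
    res <- iterate_subroutine(ctx, sub)
    if (any(res$mask) &&
        !is_cell_like(res$mask, ctx, sub, seedp$cell_score_min,
                      seedp$enclosure_min))
      res$mask[] <- FALSE
    segs[[i]] <- cellseg_record(res$mask, res$score, ctx$origin, ctx$dim, i)
  }
  segs <- segs[vapply(segs, function(s) any(s$mask), logical(1))]
  if (length(segs) == 0L) {
    warning("all putative cells vanished during fine-tuning")
    return(empty)
  }

  # over-segmentation correction: heavily overlapping converged fragments
  # are one cell
  full_masks <- lapply(segs, function(s) uncrop_mask(s$mask, s$origin, s$dim))
  groups <- merge_groups(full_masks, seedp$merge_overlap_theta)
  merged <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    mmask <- Reduce(`|`, full_masks[idx])
    mscore <- Reduce(pmax, lapply(segs[idx], function(s)
      uncrop_image(s$score, s$origin, s$dim)))
    merged[[g]] <- record_from_full(mmask, mscore, id = g)
  }

  lab <- distribute_records(merged, dim(ev))
  lab[!cm] <- 0L  # the coarse mask is a superset constraint on all labels
  lab[lab > 0L & tabulate_lookup(lab) < seedp$min_cell_area] <- 0L
  keep_ids <- sort(unique(lab[lab > 0L]))
  lab <- renumber_labels(lab)
  structure(list(labels = lab, cells = merged[keep_ids]), class = "autoseed")
}

# per-pixel area of own label (vectorized lookup)
tabulate_lookup <- function(lab) {
  n <- max(lab)
  if (n == 0L) return(matrix(0L, nrow(lab), ncol(lab)))
  areas <- tabulate(lab[lab > 0L], nbins = n)
  out <- matrix(0L, nrow(lab), ncol(lab))
  out[lab > 0L] <- areas[lab[lab > 0L]]
  out
}

renumber_labels <- function(lab) {
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids) == 0L) return(lab)
  map <- integer(max(ids)); map[ids] <- seq_along(ids)
  out <- lab
  out[lab > 0L] <- map[lab[lab > 0L]]
  out
}

#' @export
print.autoseed <- function(x, ...) {
  cat(sprintf("<autoseed: %d cells on a %d x %d frame>\n",
              max(x$labels), nrow(x$labels), ncol(x$labels)))
  invisible(x)
}
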