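# Backwards-in-time tracking. Yeast cells do not move far between frames,
# and every cell alive at frame t-1 is also present (larger) at frame t, so
# segmentation starts at the last frame and walks backwards: frame t's
# labels seed frame t-1, each cell is segmented independently inside its
# own subimage, and disputed pixels are reconciled by score. A cell that
# disappears going backwards has just been born.

#' Segment one frame from the adjacent later frame's labels
#'
#' For each label in `prev_labels` a subimage context (bounding box plus
#' `pad`) is built on the contour-evidence image, the iterative subroutine
#' converges the seed onto the cell's boundary in this frame, and the
#' resulting masks are reconciled with [distribute_overlaps()] semantics
#' (score argmax, ties to the lower label id). The result is independent of
#' the order in which cells are processed. Labels whose mask vanishes or
#' falls below `min_cell_area` are absent from the output (candidate
#' births).
#'
#' @param image raw frame to segment.
#' @param prev_labels integer label mask from the adjacent later frame.
#' @param modality `"phase"`, `"brightfield"` or `"composite"`.
#' @param prep,sub,trk parameter objects.
#' @param fluor optional fluorescent channel for `"composite"`.
#' @param prepped optional precomputed [prep_frame()] object (skips
#'   preparation; used by callers that segment one frame repeatedly).
#' @return list with `labels` (integer matrix, same ids as `prev_labels`)
#'   and `records` (per-cell crop-local mask/score records).
#' @export
segment_frame <- function(image, prev_labels, modality = "phase",
                          prep = prep_params(), sub = subroutine_params(),
                          trk = tracker_params(), fluor = NULL,
                          prepped = NULL) {
  pf <- prepped %||% prep_frame(image, modality, prep, fluor)
  ev <- pf$evidence
  stopifnot(identical(dim(ev), dim(prev_labels)))
  ids <- sort(unique(prev_labels[prev_labels > 0L]))
  if (length(ids) == 0L)
    return(list(labels = matrix(0L, nrow(ev), ncol(ev)), records = list()))
  records <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    seed <- prev_labels == ids[k]
    ctx <- subimage_context(ev, seed, pad = trk$pad, barrier = pf$contours)
    res <- iterate_subroutine(ctx, sub)
    culled <- any(res$mask) &&
      !is_cell_like(res$mask, ctx, sub, trk$cell_score_min,
                    trk$enclosure_min)
    if (!any(res$mask) || culled) {
      # the seed may have drifted off its cell (colony expansion between
      # distant frames); widen the search once before giving the cell up
      # -- if there really is no cell, score distribution hands the
      # retried mask to its rightful owner and this label stays absent
      ctx2 <- subimage_context(ev, m_dilate(seed, trk$pad %/% 2L),
                               pad = trk$pad, barrier = pf$contours)
      res2 <- iterate_subroutine(ctx2, sub)
      if (any(res2$mask) &&
          is_cell_like(res2$mask, ctx2, sub, trk$cell_score_min,
                       trk$enclosure_min)) {
        res <- res2
        ctx <- ctx2
      } else res$mask[] <- FALSE  # candidate birth
    }
    records[[k]] <- cellseg_record(res$mask, res$score, ctx$origin, ctx$dim,
                                   id = ids[k])
  }
  records <- records[vapply(records, function(r) any(r$mask), logical(1))]
  lab <- distribute_records(records, dim(ev))
  lab[!pf$cellmask] <- 0L  # labels stay within the coarse colony mask
  # distribution can shave a cell below the viability threshold
  areas <- if (max(lab) > 0L) tabulate(lab[lab > 0L], nbins = max(lab)) else integer(0)
  tiny <- which(areas > 0L & areas < trk$min_cell_area)
  if (length(tiny) > 0L) lab[lab %in% tiny] <- 0L
  list(labels = lab, records = records)
}

#' Track cells backwards in time
#'
#' Starting from a segmentation of the last frame, segments every earlier
#' frame with [segment_frame()], always using the segmentation of the
#' adjacent later frame as the seed. Labels persist along a track. A cell
#' absent (or below `min_cell_area`) for `lost_patience` consecutive
#' backward steps is declared born at the last frame it was present and is
#' removed from all earlier frames; while within patience it is re-seeded
#' from its most recent mask.
#'
#' @param stack list of frames in forward (acquisition) order.
#' @param seed integer label mask for the last frame (e.g. from
#'   [autoseed()] or ground truth).
#' @param modality,prep,sub,trk,fluor_stack as in [segment_frame()];
#'   `fluor_stack` is a list parallel to `stack`.
#' @param prepped_stack optional list of precomputed [prep_frame()]
#'   objects parallel to `stack`.
#' @return object of class `yeast_tracks`: `labels` (list of label masks in
#'   forward order), `table` (per frame and cell: area, centroid, bounding
#'   box, status), `birth_frame` (named integer vector, 1-based frame the
#'   cell first exists in).
#' @export
track_backwards <- function(stack, seed, modality = "phase",
                            prep = prep_params(), sub = subroutine_params(),
                            trk = tracker_params(), fluor_stack = NULL,
                            prepped_stack = NULL) {
  T <- length(stack)
  stopifnot(T >= 1L)
  d <- dim(as_mat(stack[[1L]]))
  for (t in seq_len(T))
    if (!identical(dim(as_mat(stack[[t]])), d))
      stop("frame ", t, " has a different shape than frame 1")
  stopifnot(identical(dim(seed), d))

  labels <- vector("list", T)
  labels[[T]] <- seed
  ids <- sort(unique(seed[seed > 0L]))
  missing_for <- stats::setNames(integer(length(ids)), ids)
  last_mask <- stats::setNames(vector("list", length(ids)), ids)
  birth <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  for (id in ids) last_mask[[as.character(id)]] <- seed == id

  if (T > 1L) {
    for (t in (T - 1L):1L) {
      active <- ids[is.na(birth[as.character(ids)])]
      if (length(active) == 0L) {
        labels[[t]] <- matrix(0L, d[1L], d[2L])
        next
      }
      # seed every active cell from its most recent mask
      seed_lab <- matrix(0L, d[1L], d[2L])
      for (id in active) {
        m <- last_mask[[as.character(id)]]
        seed_lab[m & seed_lab == 0L] <- id
      }
      pf <- if (!is.null(prepped_stack)) prepped_stack[[t]] else NULL
      fl <- if (!is.null(fluor_stack)) fluor_stack[[t]] else NULL
      seg <- segment_frame(stack[[t]], seed_lab, modality, prep, sub, trk,
                           fluor = fl, prepped = pf)
      lab <- seg$labels
      areas <- if (max(lab) > 0L) tabulate(lab[lab > 0L], nbins = max(lab)) else integer(0)
      for (id in active) {
        key <- as.character(id)
        present <- id <= length(areas) && areas[id] >= trk$min_cell_area
        if (present) {
          missing_for[key] <- 0L
          last_mask[[key]] <- lab == id
        } else {
          lab[lab == id] <- 0L
          missing_for[key] <- missing_for[key] + 1L
          if (missing_for[key] >= trk$lost_patience) {
            # born at the last frame it was present
            birth[key] <- t + missing_for[key]
          }
        }
      }
      labels[[t]] <- lab
    }
  }
  birth[is.na(birth)] <- 1L
  # remove any within-patience appearances before the birth frame
  for (id in ids) {
    b <- birth[[as.character(id)]]
    if (b > 1L) for (t in seq_len(b - 1L))
      labels[[t]][labels[[t]] == id] <- 0L
  }
  structure(list(labels = labels,
                 table = build_track_table(labels, ids, birth),
                 birth_frame = birth),
            class = "yeast_tracks")
}

build_track_table <- function(labels, ids, birth) {
  rows <- list()
  for (t in seq_along(labels)) {
    lab <- labels[[t]]
    for (id in ids) {
      key <- as.character(id)
      m <- lab == id
      a <- sum(m)
      if (a > 0L) {
        w <- which(m, arr.ind = TRUE)
        rows[[length(rows) + 1L]] <- data.frame(
          frame = t, label = id, area = a,
          centroid_row = mean(w[, 1L]), centroid_col = mean(w[, 2L]),
          bbox_r0 = min(w[, 1L]), bbox_c0 = min(w[, 2L]),
          bbox_r1 = max(w[, 1L]), bbox_c1 = max(w[, 2L]),
          status = "present", stringsAsFactors = FALSE)
      } else {
        status <- if (t < birth[[key]]) "born_after" else "lost"
        rows[[length(rows) + 1L]] <- data.frame(
          frame = t, label = id, area = 0L,
          centroid_row = NA_real_, centroid_col = NA_real_,
          bbox_r0 = NA_integer_, bbox_c0 = NA_integer_,
          bbox_r1 = NA_integer_, bbox_c1 = NA_integer_,
          status = status, stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  tab[order(tab$frame, tab$label), , drop = FALSE]
}

#' @export
print.yeast_tracks <- function(x, ...) {
  T <- length(x$labels)
  cat(sprintf("<yeast_tracks: %d cells over %d frames>\n",
              length(x$birth_frame), T))
  born <- sum(x$birth_frame > 1L)
  cat(sprintf("  %d cells present from frame 1, %d born during the movie\n",
              length(x$birth_frame) - born, born))
  invisible(x)
}

#' Seed-perturbation recovery record
#'
#' Re-runs backwards tracking from a perturbed last-frame seed and reports,
#' for every cell, whether the segmentation fully recovers (reaches a
#' Jaccard index of at least `jaccard_recovered` against the unperturbed
#' reference run) and how many backward steps that takes.
#'
#' @param stack list of frames in forward order.
#' @param seed unperturbed last-frame label mask.
#' @param perturbed_labels the same mask with per-cell area removed (see
#'   [perturb_seed()]).
#' @param reference optional precomputed `track_backwards(stack, seed, ...)`
#'   result to compare against.
#' @param jaccard_recovered recovery criterion (default 0.95).
#' @inheritParams track_backwards
#' @return data.frame with one row per cell: `label`, `removed_frac`
#'   (fraction of seed area missing), `recovered`, `frames_to_recovery`
#'   (0 when the perturbed seed already matches; NA when never recovered).
#' @export
recover_from_perturbation <- function(stack, seed, perturbed_labels,
                                      modality = "phase",
                                      prep = prep_params(),
                                      sub = subroutine_params(),
                                      trk = tracker_params(),
                                      reference = NULL,
                                      jaccard_recovered = 0.95,
                                      prepped_stack = NULL) {
  T <- length(stack)
  ref <- reference %||% track_backwards(stack, seed, modality, prep, sub, trk,
                                        prepped_stack = prepped_stack)
  per <- track_backwards(stack, perturbed_labels, modality, prep, sub, trk,
                         prepped_stack = prepped_stack)
  ids <- sort(unique(seed[seed > 0L]))
  out <- data.frame(label = ids, removed_frac = NA_real_,
                    recovered = FALSE, frames_to_recovery = NA_integer_)
  for (k in seq_along(ids)) {
    id <- ids[k]
    sm <- seed == id
    pm <- perturbed_labels == id
    out$removed_frac[k] <- 1 - sum(pm) / sum(sm)
    if (jaccard(pm, sm) >= jaccard_recovered) {
      out$recovered[k] <- TRUE
      out$frames_to_recovery[k] <- 0L
      next
    }
    if (T > 1L) for (t in (T - 1L):1L) {
      a <- per$labels[[t]] == id
      b <- ref$labels[[t]] == id
      if (!any(b)) break
      if (jaccard(a, b) >= jaccard_recovered) {
        out$recovered[k] <- TRUE
        out$frames_to_recovery[k] <- T - t
        break
      }
    }
  }
  out
}
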