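# Quantitative scoring: F-measure over matched elements, center-based
# matching, the correct/minor/major error classes, percent cell area gain,
# periphery intensity quantification, seed perturbation, and the
# inter-frame-interval robustness harness.

#' Evaluation counts
#'
#' @param G number of ground-truth elements.
#' @param R number of algorithm elements.
#' @param C number of correctly matched elements; `0 <= C <= min(G, R)`.
#' @return object of class `evaluation_counts`.
#' @export
evaluation_counts <- function(G, R, C) {
  check_flag(G >= 0 && R >= 0, "G and R must be nonnegative")
  check_flag(C >= 0 && C <= min(G, R), "need 0 <= C <= min(G, R)")
  structure(list(G = as.integer(G), R = as.integer(R), C = as.integer(C)),
            class = "evaluation_counts")
}

#' F-measure
#'
#' Combined precision/recall quality measure over matched segmentation or
#' tracking elements: `F = 2C / (R + G)`, the harmonic mean of `C/R`
#' (precision) and `C/G` (recall).
#'
#' @param counts an [evaluation_counts()] object.
#' @return fraction in `[0, 1]`.
#' @export
f_measure <- function(counts) {
  stopifnot(inherits(counts, "evaluation_counts"))
  if (counts$R + counts$G == 0L)
    stop("F-measure undefined when R + G = 0")
  2 * counts$C / (counts$R + counts$G)
}

#' Match predicted cells to ground-truth centers
#'
#' Maximum-cardinality matching between predicted and ground-truth centers
#' over the pairs closer than `d_max` (augmenting-path search, with pairs
#' tried nearest-first so the count is deterministic). Each element is
#' matched at most once; `C` is the size of the matching.
#'
#' @param pred integer label mask, or an n x 2 matrix of predicted centers
#'   (row, col).
#' @param truth_centers m x 2 matrix of ground-truth centers.
#' @param d_max maximal center distance (pixels) for a correct match.
#' @return an [evaluation_counts()] object with `G = m`, `R = n` and `C`
#'   the number of matched pairs.
#' @export
match_by_center <- function(pred, truth_centers, d_max = 8) {
  check_flag(d_max > 0, "d_max must be positive")
  pc <- if (is.matrix(pred) && ncol(pred) == 2L && is.double(pred))
    pred else label_centroids(pred)  # (row, col) centers, or a label mask
  tc <- truth_centers
  n <- nrow(pc); m <- nrow(tc)
  if (n == 0L || m == 0L)
    return(evaluation_counts(G = m, R = n, C = 0L))
  dmat <- outer(seq_len(n), seq_len(m), function(i, j)
    sqrt((pc[i, 1] - tc[j, 1])^2 + (pc[i, 2] - tc[j, 2])^2))
  # admissible truth partners per prediction, nearest first
  adj <- lapply(seq_len(n), function(i) {
    js <- which(dmat[i, ] < d_max)
    js[order(dmat[i, js])]
  })
  match_t <- integer(m)  # truth j -> matched prediction (0 = free)
  try_augment <- function(i, seen) {
    for (j in adj[[i]]) {
      if (seen[j]) next
      seen[j] <- TRUE
      if (match_t[j] == 0L || Recall(match_t[j], seen)) {
        match_t[j] <<- i
        seen <<- seen
        return(TRUE)
      }
    }
    FALSE
  }
  C <- 0L
  for (i in seq_len(n)) {
    seen <- logical(m)
    if (try_augment(i, seen)) C <- C + 1L
  }
  evaluation_counts(G = m, R = n, C = C)
}

#' Classify a segmentation against its ground-truth mask
#'
#' The correctness fraction is the symmetric
#' `f = min(|pred & truth| / |truth|, |pred & truth| / |pred|)` (pixel
#' recall and precision), so both omitted cell area and invasion of
#' foreign area count against the segmentation. `f > 0.95` is `"correct"`,
#' `0.90 <= f <= 0.95` is a `"minor"` error, anything worse (including a
#' lost cell with empty prediction) is a `"major"` error.
#'
#' @param pred,truth logical masks; `truth` must be nonempty.
#' @return one of `"correct"`, `"minor"`, `"major"`.
#' @export
classify_error <- function(pred, truth) {
  if (!any(truth)) stop("ground-truth mask is empty")
  if (!any(pred)) return("major")
  inter <- sum(pred & truth)
  f <- min(inter / sum(truth), inter / sum(pred))
  if (f > 0.95) "correct" else if (f >= 0.90) "minor" else "major"
}

#' Percent cell area gain
#'
#' Gain from distributing overlapping initial segmentations instead of
#' discarding them:
#' `100 * (area_with - area_without) / area_with`.
#'
#' @param area_with cell area (pixels) with overlap distribution.
#' @param area_without cell area without it (overlaps discarded).
#' @return percentage.
#' @export
pct_area_gain <- function(area_with, area_without) {
  check_flag(all(area_with > 0), "area_with must be positive")
  100 * (area_with - area_without) / area_with
}

#' Mean intensity on the cell periphery
#'
#' The periphery is the band of mask pixels within `thickness` pixels
#' (Euclidean) of the mask complement, i.e. the mask minus its erosion by
#' a disk of radius `thickness`; when the erosion would be empty the whole
#' mask is the periphery. Returns the mean of `fluor` over that band.
#'
#' @param mask nonempty logical cell mask.
#' @param fluor numeric intensity image of the same shape.
#' @param thickness band width in pixels (default 2).
#' @return mean intensity (arbitrary units).
#' @export
periphery_mean_intensity <- function(mask, fluor, thickness = 2) {
  if (!any(mask)) stop("mask is empty")
  stopifnot(identical(dim(mask), dim(fluor)))
  band <- periphery_band(mask, thickness)
  mean(fluor[band])
}

periphery_band <- function(mask, thickness) {
  d <- as_mat(EBImage::distmap(mask * 1))  # distance of mask pixels to complement
  band <- mask & d <= thickness
  if (!any(mask & d > thickness)) band <- mask  # erosion empty: whole mask
  band
}

#' Percent quantification difference
#'
#' `100 * |q_with - q_without| / q_with`; the reference is the
#' quantification with overlap distribution, so the formula is asymmetric
#' in its arguments.
#'
#' @param q_with quantification with overlap distribution (must be > 0).
#' @param q_without quantification without it.
#' @return percentage (always nonnegative).
#' @export
pct_quant_difference <- function(q_with, q_without) {
  check_flag(all(q_with > 0), "q_with must be positive")
  100 * abs(q_with - q_without) / q_with
}

#' Randomly remove a contiguous fraction of a seed mask
#'
#' Removes the requested fraction of the mask's area (to the nearest
#' pixel) as one contiguous piece: pixels are ranked by their projection
#' onto a random direction and the top fraction is cut off, which for the
#' convex-ish cell shapes this is used on leaves a connected remainder.
#'
#' @param mask nonempty logical mask.
#' @param fraction fraction of area to remove, in `[0, 1)`.
#' @param rng_seed optional integer; when given the perturbation is drawn
#'   under this seed (and is therefore reproducible), otherwise the
#'   current RNG stream is used.
#' @return logical mask with `round(fraction * area)` pixels removed.
#' @export
perturb_seed <- function(mask, fraction, rng_seed = NULL) {
  check_flag(fraction >= 0 && fraction < 1, "fraction must be in [0, 1)")
  if (!any(mask)) stop("mask is empty")
  if (fraction == 0) return(mask)
  cut <- function() {
    pts <- which(mask, arr.ind = TRUE)
    theta <- stats::runif(1, 0, 2 * pi)
    proj <- pts[, 1L] * cos(theta) + pts[, 2L] * sin(theta)
    n_remove <- round(fraction * nrow(pts))
    drop_idx <- order(proj, decreasing = TRUE)[seq_len(n_remove)]
    out <- mask
    out[pts[drop_idx, , drop = FALSE]] <- FALSE
    out
  }
  if (is.null(rng_seed)) cut() else with_seed(rng_seed, cut())
}

#' Segmentation accuracy versus inter-frame interval
#'
#' Emulates increasing acquisition intervals on a stack with known ground
#' truth: the true labels at frame `t` seed the segmentation of the frame
#' `delta` frames earlier, and every scored cell is classified with
#' [classify_error()] against its true mask at `t - delta`. By default the
#' same cohort of cells -- those already alive at the largest tested
#' offset -- is scored at every interval, so the accuracy-versus-interval
#' trend is a paired comparison and is not confounded by newborn buds
#' entering the population only at the short intervals.
#'
#' @param stack list of frames in forward order.
#' @param truth list of ground-truth label masks, parallel to `stack`.
#' @param deltas integer frame offsets to test (0 allowed; offsets beyond
#'   the stack are skipped with a warning).
#' @param t seed frame index (default: last frame).
#' @param cohort `"common"` scores the cells alive at `t - max(deltas)` at
#'   every interval; `"per_interval"` scores every cell alive at each
#'   `t - delta`.
#' @param modality,prep,sub,trk as in [segment_frame()].
#' @return data.frame with one row per offset: `delta`, `n_cells`,
#'   `frac_correct`, `frac_minor`, `frac_major`.
#' @export
interval_robustness_experiment <- function(stack, truth, deltas,
                                           t = length(stack),
                                           cohort = c("common",
                                                      "per_interval"),
                                           modality = "phase",
                                           prep = prep_params(),
                                           sub = subroutine_params(),
                                           trk = tracker_params()) {
  stopifnot(length(stack) == length(truth))
  cohort <- match.arg(cohort)
  deltas_ok <- deltas[t - deltas >= 1L]
  base <- truth[[t - max(c(deltas_ok, 0L))]]
  rows <- list()
  for (delta in deltas) {
    if (t - delta < 1L) {
      warning("delta = ", delta, " exceeds the stack span; skipped")
      next
    }
    seed <- truth[[t]]
    target <- truth[[t - delta]]
    pred <- if (delta == 0L) seed else
      segment_frame(stack[[t - delta]], seed, modality, prep, sub, trk)$labels
    ids <- sort(unique(seed[seed > 0L]))
    cls <- character(0)
    for (id in ids) {
      tm <- target == id
      if (!any(tm)) next  # born after t - delta: no truth to score against
      if (cohort == "common" && !any(base == id)) next
      cls <- c(cls, classify_error(pred == id, tm))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      delta = delta, n_cells = length(cls),
      frac_correct = mean(cls == "correct"),
      frac_minor = mean(cls == "minor"),
      frac_major = mean(cls == "major"))
  }
  do.call(rbind, rows)
}
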