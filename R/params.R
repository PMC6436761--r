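# Parameter containers. Every constant the pipeline uses that is not forced
# by the data lives here, with defaults calibrated against the built-in
# synthetic renderer at a 40X-like scale (cell radii ~8-15 px).

check_flag <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

#' Image preparation parameters
#'
#' Controls the coarse colony mask, contour-pixel detection and the
#' modality-specific preprocessing that turns a raw frame into contour
#' evidence (bright cell boundaries on a darker field).
#'
#' @param mean_window,std_window odd window sizes (pixels) of the local mean
#'   and local standard-deviation filters used for contour detection.
#' @param contour_k threshold multiplier: a pixel is a contour pixel when it
#'   exceeds its local mean by more than `contour_k` local standard
#'   deviations.
#' @param min_contrast absolute floor (in normalized intensity units) on the
#'   excess over the local mean; guards contour detection against marking
#'   pure noise in flat regions, where the local standard deviation is
#'   itself just the noise level.
#' @param barrier_evidence_min absolute evidence level above which a pixel
#'   near the colony counts as boundary material even without local
#'   contrast; the centers of wide bright interstices between packed cells
#'   are plateaus the mean/std filter cannot mark, yet they must act as
#'   barriers between cells.
#' @param blur_sigma Gaussian presmoothing sigma (pixels) applied when
#'   building the contour-evidence image; 0 disables.
#' @param tophat_radius radius (pixels) of the disk used by the white
#'   top-hat applied to the complement of bright-field frames; must exceed
#'   the boundary-ring width.
#' @param composite_weight mixing fraction `w` in `[0,1]` for phase /
#'   fluorescence composite images.
#' @param min_colony_area connected components of the coarse mask smaller
#'   than this (pixels) are discarded as debris.
#' @return an object of class `prep_params`.
#' @export
prep_params <- function(mean_window = 11L, std_window = 11L, contour_k = 0.5,
                        min_contrast = 0.04, barrier_evidence_min = 0.7,
                        blur_sigma = 1.0,
                        tophat_radius = 5L, composite_weight = 0.5,
                        min_colony_area = 100L) {
  mean_window <- as.integer(mean_window); std_window <- as.integer(std_window)
  check_flag(mean_window >= 3L && mean_window %% 2L == 1L,
             "mean_window must be odd and >= 3")
  check_flag(std_window >= 3L && std_window %% 2L == 1L,
             "std_window must be odd and >= 3")
  check_flag(tophat_radius >= 1, "tophat_radius must be >= 1")
  check_flag(composite_weight >= 0 && composite_weight <= 1,
             "composite_weight must be in [0, 1]")
  check_flag(min_contrast >= 0, "min_contrast must be >= 0")
  check_flag(blur_sigma >= 0, "blur_sigma must be >= 0")
  structure(list(mean_window = mean_window, std_window = std_window,
                 contour_k = contour_k, min_contrast = min_contrast,
                 barrier_evidence_min = barrier_evidence_min,
                 blur_sigma = blur_sigma,
                 tophat_radius = as.integer(tophat_radius),
                 composite_weight = composite_weight,
                 min_colony_area = as.integer(min_colony_area)),
            class = "prep_params")
}

#' Segmentation subroutine parameters
#'
#' Constants of the iterative per-cell segmentation core. The per-pixel cell
#' score is a convex mixture of three terms: absence of contour evidence,
#' proximity to the seed, and connectedness to the seed through
#' low-contour-evidence paths.
#'
#' @param n_rounds number of refinement rounds (each round reuses the
#'   previous mask as the seed); iteration stops early at a fixed point.
#' @param reach_px maximal distance (pixels) a cell may extend from its
#'   seed; the score is 0 beyond it.
#' @param boundary_weight,seed_weight,interior_weight mixture coefficients
#'   of the three score terms; must sum to 1.
#' @param accept_threshold score level (inclusive) above which a pixel is
#'   kept in the refined mask.
#' @param smooth_radius disk radius (pixels) of the morphological
#'   closing/opening that smooths the refined boundary.
#' @param interior_evidence_max contour-evidence level below which a pixel
#'   counts as cell interior for the connectedness term.
#' @return an object of class `subroutine_params`.
#' @export
subroutine_params <- function(n_rounds = 5L, reach_px = 15,
                              boundary_weight = 0.5, seed_weight = 0.3,
                              interior_weight = 0.2, accept_threshold = 0.5,
                              smooth_radius = 2L,
                              interior_evidence_max = 0.5) {
  check_flag(n_rounds >= 1, "n_rounds must be >= 1")
  check_flag(reach_px >= 1, "reach_px must be >= 1")
  w <- c(boundary_weight, seed_weight, interior_weight)
  check_flag(all(w >= 0) && abs(sum(w) - 1) < 1e-8,
             "boundary/seed/interior weights must be nonnegative and sum to 1")
  check_flag(accept_threshold > 0 && accept_threshold < 1,
             "accept_threshold must be in (0, 1)")
  check_flag(smooth_radius >= 0, "smooth_radius must be >= 0")
  structure(list(n_rounds = as.integer(n_rounds), reach_px = reach_px,
                 boundary_weight = boundary_weight, seed_weight = seed_weight,
                 interior_weight = interior_weight,
                 accept_threshold = accept_threshold,
                 smooth_radius = as.integer(smooth_radius),
                 interior_evidence_max = interior_evidence_max),
            class = "subroutine_params")
}

#' Automated seeding parameters
#'
#' Controls the self-correction steps of the automated seeding of the last
#' frame: threshold-voting under-segmentation splitting, overlap-based
#' over-segmentation merging, and score-based distribution of disputed
#' pixels.
#'
#' @param vote_thresholds contour-threshold multipliers (`contour_k` values)
#'   that each get a vote on whether a pixel is a cell pixel; at least 3.
#' @param vote_majority number of votes required to call a pixel a cell
#'   pixel during under-segmentation splitting.
#' @param merge_overlap_theta two converged putative cells whose
#'   intersection exceeds this fraction of the smaller one are merged
#'   (over-segmentation correction); smaller overlaps are distributed
#'   by score instead.
#' @param small_overlap_frac overlaps below this fraction of the smaller
#'   mask are always treated as boundary disputes (distributed by score),
#'   never as merge candidates.
#' @param min_cell_area putative cells smaller than this (pixels) are
#'   dropped.
#' @param cell_score_min converged putative cells whose mean self-score
#'   (score of the converged mask used as its own seed) falls below this
#'   are discarded; genuine cell interiors self-score near 1 while
#'   spurious basins in interstices or at the colony margin cannot exceed
#'   the boundary-plus-proximity terms.
#' @param enclosure_min minimum fraction of a converged mask's boundary
#'   that must touch detected contour pixels; a real cell is enclosed by
#'   its own boundary ring, a spurious background blob is bounded mostly
#'   by the score's reach and not by contours.
#' @return an object of class `seeding_params`.
#' @export
seeding_params <- function(vote_thresholds = c(0.25, 0.375, 0.5, 0.625, 0.75),
                           vote_majority = 3L, merge_overlap_theta = 0.5,
                           small_overlap_frac = 0.2, min_cell_area = 30L,
                           cell_score_min = 0.7, enclosure_min = 0.9) {
  check_flag(length(vote_thresholds) >= 3, "need at least 3 vote thresholds")
  check_flag(vote_majority >= 1 && vote_majority <= length(vote_thresholds),
             "vote_majority must be between 1 and length(vote_thresholds)")
  check_flag(merge_overlap_theta > 0 && merge_overlap_theta <= 1,
             "merge_overlap_theta must be in (0, 1]")
  check_flag(small_overlap_frac >= 0 && small_overlap_frac <= 1,
             "small_overlap_frac must be in [0, 1]")
  check_flag(cell_score_min >= 0 && cell_score_min <= 1,
             "cell_score_min must be in [0, 1]")
  check_flag(enclosure_min >= 0 && enclosure_min <= 1,
             "enclosure_min must be in [0, 1]")
  structure(list(vote_thresholds = vote_thresholds,
                 vote_majority = as.integer(vote_majority),
                 merge_overlap_theta = merge_overlap_theta,
                 small_overlap_frac = small_overlap_frac,
                 min_cell_area = as.integer(min_cell_area),
                 cell_score_min = cell_score_min,
                 enclosure_min = enclosure_min),
            class = "seeding_params")
}

#' Backwards-tracking parameters
#'
#' @param min_cell_area a tracked cell whose segmented area falls below this
#'   (pixels) counts as absent in that frame.
#' @param lost_patience number of consecutive backward steps a cell may be
#'   absent before it is declared born (buds disappear abruptly going
#'   backwards, so the default is 1).
#' @param pad margin (pixels) added around a cell's seed bounding box when
#'   cropping the subimage it is segmented in; must cover the expected
#'   one-frame boundary motion.
#' @param cell_score_min a tracked cell whose converged mask self-scores
#'   below this counts as absent (see [seeding_params()]); going
#'   backwards, a bud whose seed no longer finds a cell interior has just
#'   been born.
#' @param enclosure_min minimum boundary-contact fraction for a tracked
#'   mask to count as a cell (see [seeding_params()]).
#' @return an object of class `tracker_params`.
#' @export
tracker_params <- function(min_cell_area = 30L, lost_patience = 1L,
                           pad = 10L, cell_score_min = 0.7,
                           enclosure_min = 0.9) {
  check_flag(min_cell_area > 0, "min_cell_area must be positive")
  check_flag(lost_patience >= 1, "lost_patience must be >= 1")
  check_flag(pad >= 1, "pad must be >= 1")
  check_flag(cell_score_min >= 0 && cell_score_min <= 1,
             "cell_score_min must be in [0, 1]")
  check_flag(enclosure_min >= 0 && enclosure_min <= 1,
             "enclosure_min must be in [0, 1]")
  structure(list(min_cell_area = as.integer(min_cell_area),
                 lost_patience = as.integer(lost_patience),
                 pad = as.integer(pad), cell_score_min = cell_score_min,
                 enclosure_min = enclosure_min),
            class = "tracker_params")
}

#' @export
print.prep_params <- function(x, ...) print_params(x, "image preparation")
#' @export
print.subroutine_params <- function(x, ...) print_params(x, "segmentation subroutine")
#' @export
print.seeding_params <- function(x, ...) print_params(x, "automated seeding")
#' @export
print.tracker_params <- function(x, ...) print_params(x, "backwards tracking")

print_params <- function(x, what) {
  cat(sprintf("<%s parameters>\n", what))
  for (nm in names(x))
    cat(sprintf("  %-22s %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  invisible(x)
}
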