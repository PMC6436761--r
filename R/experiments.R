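# Scripted robustness studies on synthetic colonies. These wrap the
# tracker and evaluation modules into the two standard experiments: seed
# perturbation recovery and segmentation accuracy versus inter-frame
# interval, plus an automated-seeding quality measurement against ground
# truth.

#' Seed-perturbation recovery study
#'
#' Generates `n_fields` synthetic colony time-lapses, perturbs every
#' eligible cell's last-frame seed by removing a uniformly drawn 10-90% of
#' its area, re-runs backwards tracking from the perturbed seed, and
#' scores a cell as fully recovered when its segmentation reaches a
#' Jaccard index of at least 0.95 against the unperturbed reference run.
#' Cells are eligible when their reference track lives for at least
#' `min_backward_frames` backward steps: recovery is unobservable for a
#' bud that disappears (is born) almost immediately behind the seed frame.
#'
#' @param n_fields number of independent fields of view.
#' @param scene a [scene_params()] object for one field (its `rng_seed` is
#'   offset per field).
#' @param removal_range range the per-cell removed fraction is drawn from.
#' @param min_backward_frames minimum backward lifetime (frames) of the
#'   reference track for a cell to enter the experiment.
#' @param rng_seed seed for the perturbation draws.
#' @param prep,sub,trk pipeline parameters.
#' @return list with `cells` (per-cell data.frame: field, label,
#'   removed_frac, recovered, frames_to_recovery), `pct_recovered`, and
#'   `by_severity` (mean recovery and frames-to-recovery per 25%-wide
#'   severity bin).
#' @export
seed_perturbation_study <- function(n_fields = 4L,
                                    scene = scene_params(
                                      n_initial_cells = 55L, frames = 10L),
                                    removal_range = c(0.10, 0.90),
                                    min_backward_frames = 5L,
                                    rng_seed = 1L,
                                    prep = prep_params(),
                                    sub = subroutine_params(),
                                    trk = tracker_params()) {
  rows <- list()
  for (f in seq_len(n_fields)) {
    sp <- scene
    sp$rng_seed <- scene$rng_seed + 7919L * f
    truth <- simulate_geometry(sp)
    stack <- render_phase(truth, sp)
    T <- length(stack)
    pfs <- lapply(stack, prep_frame, modality = "phase", params = prep)
    seed <- truth$labels[[T]]
    ref <- track_backwards(stack, seed, modality = "phase", prep = prep,
                           sub = sub, trk = trk, prepped_stack = pfs)
    ids <- sort(unique(seed[seed > 0L]))
    ids <- ids[ref$birth_frame[as.character(ids)] <= T - min_backward_frames]
    fracs <- with_seed(rng_seed + f, stats::runif(length(ids),
                                                  removal_range[1],
                                                  removal_range[2]))
    # ineligible (short-lived) cells keep their correct seed so their
    # neighbors see the same context as in the reference run
    pert_seed <- seed
    pert_seed[seed %in% ids] <- 0L
    for (k in seq_along(ids)) {
      m <- perturb_seed(seed == ids[k], fracs[k],
                        rng_seed = rng_seed + 1000L * f + k)
      pert_seed[m] <- ids[k]
    }
    scored_seed <- seed
    scored_seed[!(seed %in% ids)] <- 0L
    rec <- recover_from_perturbation(stack, scored_seed,
                                     pert_seed, modality = "phase",
                                     prep = prep, sub = sub, trk = trk,
                                     reference = ref, prepped_stack = pfs)
    rec$field <- f
    rows[[f]] <- rec
  }
  cells <- do.call(rbind, rows)
  bins <- cut(100 * cells$removed_frac, breaks = c(0, 35, 60, 90),
              labels = c("10-35%", "35-60%", "60-90%"))
  by_sev <- do.call(rbind, lapply(levels(bins), function(b) {
    sel <- cells[!is.na(bins) & bins == b, ]
    data.frame(severity = b, n = nrow(sel),
               pct_recovered = 100 * mean(sel$recovered),
               mean_frames_to_recovery =
                 mean(sel$frames_to_recovery[sel$recovered]))
  }))
  list(cells = cells,
       pct_recovered = 100 * mean(cells$recovered),
       by_severity = by_sev)
}

#' Inter-frame interval robustness study
#'
#' Generates synthetic cycling-cell stacks (default: 90-minute doubling
#' imaged every 3 minutes), seeds the segmentation of earlier frames with
#' the ground-truth labels of the last frame, and classifies every
#' surviving cell with [classify_error()] at each tested interval.
#'
#' @param n_fields number of independent fields of view.
#' @param scene a [scene_params()] object for one field.
#' @param intervals_min intervals to test, in minutes (must be multiples
#'   of the scene's `frame_interval`).
#' @param prep,sub,trk pipeline parameters.
#' @return list with `by_interval` (data.frame: interval_min, n_cells,
#'   frac_correct/minor/major pooled over fields) and `pct_correct_all`
#'   (percent correct pooled over all tested intervals).
#' @export
interval_robustness_study <- function(n_fields = 2L,
                                      scene = scene_params(
                                        n_initial_cells = 60L, frames = 10L),
                                      intervals_min = c(3, 12, 24),
                                      prep = prep_params(),
                                      sub = subroutine_params(),
                                      trk = tracker_params()) {
  deltas <- intervals_min / scene$frame_interval
  stopifnot(all(abs(deltas - round(deltas)) < 1e-9))
  deltas <- as.integer(round(deltas))
  per_field <- list()
  for (f in seq_len(n_fields)) {
    sp <- scene
    sp$rng_seed <- scene$rng_seed + 104729L * f
    truth <- simulate_geometry(sp)
    stack <- render_phase(truth, sp)
    tab <- interval_robustness_experiment(stack, truth$labels, deltas,
                                          modality = "phase", prep = prep,
                                          sub = sub, trk = trk)
    tab$field <- f
    per_field[[f]] <- tab
  }
  all_tabs <- do.call(rbind, per_field)
  by_int <- do.call(rbind, lapply(deltas, function(dd) {
    sel <- all_tabs[all_tabs$delta == dd, ]
    n <- sum(sel$n_cells)
    data.frame(interval_min = dd * scene$frame_interval, n_cells = n,
               frac_correct = sum(sel$frac_correct * sel$n_cells) / n,
               frac_minor = sum(sel$frac_minor * sel$n_cells) / n,
               frac_major = sum(sel$frac_major * sel$n_cells) / n)
  }))
  list(by_interval = by_int,
       pct_correct_all = 100 * sum(by_int$frac_correct * by_int$n_cells) /
         sum(by_int$n_cells))
}

#' Automated-seeding quality against ground truth
#'
#' Runs [autoseed()] on the final frame of a synthetic colony and matches
#' every true cell to its best-overlapping predicted cell.
#'
#' @param scene a [scene_params()] object.
#' @param jaccard_ok Jaccard level counting a true cell as well segmented.
#' @param prep,sub,seedp pipeline parameters.
#' @return list with `per_cell` (data.frame: label, best Jaccard),
#'   `pct_segmented` (percent of true cells at or above `jaccard_ok`),
#'   `n_true`, `n_pred`.
#' @export
autoseed_quality_study <- function(scene = scene_params(
                                     n_initial_cells = 55L, frames = 3L),
                                   jaccard_ok = 0.90,
                                   prep = prep_params(),
                                   sub = subroutine_params(),
                                   seedp = seeding_params()) {
  truth <- simulate_geometry(scene)
  frame <- render_phase(truth, scene)[[length(truth$labels)]]
  tl <- truth$labels[[length(truth$labels)]]
  seg <- autoseed(frame, "phase", prep = prep, sub = sub, seedp = seedp)
  ids <- sort(unique(tl[tl > 0L]))
  best <- vapply(ids, function(id) {
    tm <- tl == id
    bb <- mask_bbox(tm)
    pred_ids <- unique(seg$labels[tm])
    pred_ids <- pred_ids[pred_ids > 0L]
    if (length(pred_ids) == 0L) return(0)
    max(vapply(pred_ids, function(pid) jaccard(seg$labels == pid, tm),
               numeric(1)))
  }, numeric(1))
  list(per_cell = data.frame(label = ids, best_jaccard = best),
       pct_segmented = 100 * mean(best >= jaccard_ok),
       n_true = length(ids), n_pred = max(seg$labels))
}
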