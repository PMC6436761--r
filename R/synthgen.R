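# Seeded synthetic yeast-colony time-lapses with ground truth. Cells are
# ellipses growing exponentially in area (doubling ~90 min in glucose);
# buds appear adjacent to their mothers and grow with the same law. The
# renderers emulate the three imaging modalities the segmentation pipeline
# supports: phase contrast (bright halo just outside every boundary, fused
# between near-touching cells), low-contrast unevenly illuminated
# bright-field, and a partially cytoplasmic fluorescent channel.

#' Synthetic scene parameters
#'
#' @param n_initial_cells cells present in the first frame.
#' @param frames number of frames.
#' @param frame_interval minutes between frames.
#' @param doubling_time minutes per area doubling (about 90 for budding
#'   yeast in glucose).
#' @param cell_radius_range range (pixels) of initial effective radii,
#'   40X-like scale.
#' @param bud_radius initial effective radius (pixels) of a new bud.
#' @param bud_rate budding events per cell per hour.
#' @param maturity_frames frames a cell must exist before it can bud.
#' @param gap_px rest gap (pixels) maintained between neighboring cell
#'   boundaries by lateral repulsion; near-touching cells closer than the
#'   halo width render with a fused bright ridge.
#' @param halo_width width (pixels) of the phase halo outside the boundary.
#' @param halo_gain,interior_level,background_level phase render levels
#'   (a.u.): halo > background > interior.
#' @param bf_ring_level,bf_background_level bright-field levels (a.u.);
#'   rings are thin and only mildly darker than the field.
#' @param illumination_gradient bright-field illumination slope (a.u. per
#'   pixel, applied along columns).
#' @param fluor_level,fluor_background,fluor_jitter fluorescent channel
#'   levels and per-cell multiplicative intensity jitter (sd, fraction).
#' @param noise_sigma Gaussian pixel noise sd (a.u.); the fluorescent
#'   channel uses it as shot-like noise scaled by sqrt(intensity).
#' @param frame_dim frame shape `c(rows, cols)`.
#' @param rng_seed integer seed making geometry and renders reproducible.
#' @return object of class `scene_params`.
#' @export
scene_params <- function(n_initial_cells = 12L, frames = 30L,
                         frame_interval = 3, doubling_time = 90,
                         cell_radius_range = c(8, 15), bud_radius = 4.5,
                         bud_rate = 0.46, maturity_frames = 4L,
                         gap_px = 2, halo_width = 2,
                         halo_gain = 1.0, interior_level = 0.2,
                         background_level = 0.55,
                         bf_ring_level = 0.32, bf_background_level = 0.5,
                         illumination_gradient = 4e-4,
                         fluor_level = 0.75, fluor_background = 0.005,
                         fluor_jitter = 0.15,
                         noise_sigma = 0.03, frame_dim = c(512L, 512L),
                         rng_seed = 1L) {
  check_flag(frames >= 1, "frames must be >= 1")
  check_flag(all(cell_radius_range > 0) && bud_radius > 0,
             "radii must be positive")
  check_flag(noise_sigma >= 0, "noise_sigma must be >= 0")
  check_flag(doubling_time > 0 && frame_interval > 0,
             "doubling_time and frame_interval must be positive")
  structure(as.list(environment()), class = "scene_params")
}

#' @export
print.scene_params <- function(x, ...) print_params(x, "synthetic scene")

#' Simulate colony geometry with ground truth
#'
#' Places elliptical cells near the frame center, grows every cell's area
#' exponentially at the stated doubling time, spawns buds adjacent to
#' mature mothers at `bud_rate`, and resolves crowding each frame by
#' pairwise centroid repulsion (colonies spread laterally). Ground-truth
#' label masks are rasterized per frame; a pixel inside several ellipses
#' goes to the cell whose normalized ellipse radius is smallest, so true
#' labels never overlap. If the colony would outgrow the frame, no further
#' buds are added and a warning is issued.
#'
#' @param params a [scene_params()] object.
#' @return object of class `ground_truth`: `labels` (list of integer label
#'   masks, forward order), `lineage` (data.frame child / mother /
#'   birth_frame), `geometry` (long data.frame of per-frame ellipses),
#'   `params`.
#' @export
simulate_geometry <- function(params = scene_params()) {
  p <- params
  with_seed(p$rng_seed, {
    g <- 2^(p$frame_interval / p$doubling_time)  # per-frame area factor
    d <- p$frame_dim
    # state: one row per cell
    cells <- data.frame(id = integer(0), mother = integer(0),
                        birth = integer(0), cx = numeric(0), cy = numeric(0),
                        area = numeric(0), elong = numeric(0),
                        angle = numeric(0))
    add_cell <- function(cells, mother, birth, cx, cy, r) {
      id <- nrow(cells) + 1L
      rbind(cells, data.frame(
        id = id, mother = mother, birth = birth, cx = cx, cy = cy,
        area = pi * r^2, elong = stats::runif(1, 1.05, 1.35),
        angle = stats::runif(1, 0, pi)))
    }
    # initial colony: first cell at center, others attached to a random
    # existing cell
    r0 <- stats::runif(p$n_initial_cells, p$cell_radius_range[1],
                       p$cell_radius_range[2])
    cells <- add_cell(cells, NA_integer_, 1L, d[1] / 2, d[2] / 2, r0[1])
    if (p$n_initial_cells > 1L) for (i in 2:p$n_initial_cells) {
      host <- cells[sample.int(nrow(cells), 1L), ]
      th <- stats::runif(1, 0, 2 * pi)
      dist <- sqrt(host$area * host$elong / pi) + r0[i] + p$gap_px
      cells <- add_cell(cells, NA_integer_, 1L,
                        host$cx + dist * cos(th), host$cy + dist * sin(th),
                        r0[i])
    }

    labels <- vector("list", p$frames)
    geo_rows <- vector("list", p$frames)
    crowded <- FALSE
    for (t in seq_len(p$frames)) {
      if (t > 1L) {
        cells$area <- cells$area * g
        # budding
        if (!crowded && p$bud_rate > 0) {
          p_bud <- p$bud_rate * p$frame_interval / 60
          mature <- which(t - cells$birth >= p$maturity_frames)
          for (m in mature) {
            if (stats::runif(1) < p_bud) {
              # bud where there is room: of several candidate directions,
              # keep the one farthest from all existing neighbors, so the
              # new bud shoves the colony as little as possible
              cand <- stats::runif(1, 0, 2 * pi) + 2 * pi * (0:7) / 8
              dist <- sqrt(cells$area[m] * cells$elong[m] / pi) +
                p$bud_radius + p$gap_px
              room <- vapply(cand, function(th) {
                bx <- cells$cx[m] + dist * cos(th)
                by <- cells$cy[m] + dist * sin(th)
                others <- setdiff(seq_len(nrow(cells)), m)
                min(sqrt((cells$cx[others] - bx)^2 +
                         (cells$cy[others] - by)^2) -
                    sqrt(cells$area[others] / pi))
              }, numeric(1))
              th <- cand[which.max(room)]
              cells <- add_cell(cells, cells$id[m], t,
                                cells$cx[m] + dist * cos(th),
                                cells$cy[m] + dist * sin(th), p$bud_radius)
            }
          }
        }
      }
      cells <- relax_positions(cells, p)
      margin <- sqrt(cells$area / pi) * sqrt(cells$elong) + p$halo_width + 2
      if (any(cells$cx < margin | cells$cx > d[1] - margin |
              cells$cy < margin | cells$cy > d[2] - margin)) {
        if (!crowded)
          warning("colony reached the frame boundary; no further buds added")
        crowded <- TRUE
      }
      labels[[t]] <- rasterize_cells(cells, d)
      geo_rows[[t]] <- cbind(frame = t, cells)
    }
    lineage <- cells[!is.na(cells$mother), c("id", "mother", "birth")]
    names(lineage) <- c("child", "mother", "birth_frame")
    rownames(lineage) <- NULL
    structure(list(labels = labels, lineage = lineage,
                   geometry = do.call(rbind, geo_rows), params = p),
              class = "ground_truth")
  })
}

# Radius of a cell's ellipse along an absolute direction phi.
ellipse_radius <- function(cells, k, phi) {
  a <- sqrt(cells$area[k] * cells$elong[k] / pi)
  b <- cells$area[k] / (pi * a)
  psi <- phi - cells$angle[k]
  a * b / sqrt((b * cos(psi))^2 + (a * sin(psi))^2)
}

# Pairwise repulsion: cells whose center distance falls below the sum of
# their ellipse radii along the center line plus the rest gap are pushed
# apart along that line; smaller cells move more. Centers are kept inside
# the frame.
relax_positions <- function(cells, p, rounds = 40L) {
  n <- nrow(cells)
  if (n <= 1L) return(cells)
  d <- p$frame_dim
  for (it in seq_len(rounds)) {
    moved <- FALSE
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      dx <- cells$cx[j] - cells$cx[i]; dy <- cells$cy[j] - cells$cy[i]
      dist <- sqrt(dx * dx + dy * dy)
      phi <- atan2(dy, dx)
      req <- ellipse_radius(cells, i, phi) + ellipse_radius(cells, j, phi) +
        p$gap_px
      if (dist < req - 1e-6) {
        if (dist < 1e-6) { dx <- 1; dy <- 0; dist <- 1 }
        push <- (req - dist)
        wi <- cells$area[j] / (cells$area[i] + cells$area[j])
        cells$cx[i] <- cells$cx[i] - dx / dist * push * wi
        cells$cy[i] <- cells$cy[i] - dy / dist * push * wi
        cells$cx[j] <- cells$cx[j] + dx / dist * push * (1 - wi)
        cells$cy[j] <- cells$cy[j] + dy / dist * push * (1 - wi)
        moved <- TRUE
      }
    }
    lim <- sqrt(cells$area / pi) * sqrt(cells$elong) + 2
    cells$cx <- pmin(pmax(cells$cx, lim), d[1] - lim)
    cells$cy <- pmin(pmax(cells$cy, lim), d[2] - lim)
    if (!moved) break
  }
  cells
}

# Rasterize ellipses to a label mask; disputed pixels go to the cell with
# the smallest normalized ellipse radius.
rasterize_cells <- function(cells, d) {
  lab <- matrix(0L, d[1], d[2])
  best <- matrix(Inf, d[1], d[2])
  for (k in seq_len(nrow(cells))) {
    a <- sqrt(cells$area[k] * cells$elong[k] / pi)
    b <- cells$area[k] / (pi * a)
    cx <- cells$cx[k]; cy <- cells$cy[k]; th <- cells$angle[k]
    rr <- max(1L, floor(cx - a)):min(d[1], ceiling(cx + a))
    cc <- max(1L, floor(cy - a)):min(d[2], ceiling(cy + a))
    if (length(rr) == 0L || length(cc) == 0L) next
    dx <- outer(rr - cx, rep(1, length(cc)))
    dy <- outer(rep(1, length(rr)), cc - cy)
    u <- dx * cos(th) + dy * sin(th)
    v <- -dx * sin(th) + dy * cos(th)
    rho <- sqrt((u / a)^2 + (v / b)^2)
    sub_best <- best[rr, cc]
    upd <- rho <= 1 & rho < sub_best
    if (any(upd)) {
      sub_lab <- lab[rr, cc]
      sub_lab[upd] <- cells$id[k]
      sub_best[upd] <- rho[upd]
      lab[rr, cc] <- sub_lab
      best[rr, cc] <- sub_best
    }
  }
  lab
}

halo_mask <- function(lab, width) {
  bg <- lab == 0L
  if (!any(!bg)) return(bg & FALSE)
  dbg <- as_mat(EBImage::distmap(bg * 1))  # distance of bg pixels to nearest cell
  bg & dbg > 0 & dbg <= width
}

render_noise <- function(dim, sigma) {
  if (sigma <= 0) return(matrix(0, dim[1], dim[2]))
  matrix(stats::rnorm(prod(dim), 0, sigma), dim[1], dim[2])
}

#' Render a phase-contrast stack
#'
#' Cell interiors are darker than the background; a bright halo of width
#' `halo_width` sits just outside every cell boundary, so near-touching
#' cells share a single fused bright ridge (the classic false-boundary
#' situation). Gaussian noise of sd `noise_sigma` is added. Deterministic
#' given the ground truth and `rng_seed`.
#'
#' @param truth a [simulate_geometry()] result.
#' @param params a [scene_params()] object (defaults to the scene's own).
#' @return list of numeric frames.
#' @export
render_phase <- function(truth, params = truth$params) {
  p <- params
  with_seed(p$rng_seed + 101L, lapply(truth$labels, function(lab) {
    img <- matrix(p$background_level, nrow(lab), ncol(lab))
    img[lab > 0L] <- p$interior_level
    img[halo_mask(lab, p$halo_width)] <- p$halo_gain
    img + render_noise(dim(lab), p$noise_sigma)
  }))
}

#' Render a bright-field stack
#'
#' Thin dark boundary rings on a flat field, cell interiors at the
#' background level, a linear illumination gradient along columns, and
#' Gaussian noise: low-contrast, unevenly illuminated frames that require
#' [brightfield_preprocess()] before contour detection.
#'
#' @inheritParams render_phase
#' @return list of numeric frames.
#' @export
render_brightfield <- function(truth, params = truth$params) {
  p <- params
  with_seed(p$rng_seed + 202L, lapply(truth$labels, function(lab) {
    img <- matrix(p$bf_background_level, nrow(lab), ncol(lab))
    ring <- halo_mask(lab, 1)
    img[ring] <- p$bf_ring_level
    grad <- outer(rep(1, nrow(lab)), seq_len(ncol(lab))) *
      p$illumination_gradient
    img + grad + render_noise(dim(lab), p$noise_sigma)
  }))
}

#' Render a cytoplasmic fluorescent channel
#'
#' Cell interiors are bright with a per-cell multiplicative intensity
#' jitter (constant along each cell's track), background is nearly dark,
#' and shot-like noise scales with the square root of the local intensity.
#'
#' @inheritParams render_phase
#' @return list of numeric frames.
#' @export
render_fluor <- function(truth, params = truth$params) {
  p <- params
  with_seed(p$rng_seed + 303L, {
    n_cells <- max(vapply(truth$labels, max, integer(1)))
    gain <- pmax(0.2, 1 + stats::rnorm(n_cells, 0, p$fluor_jitter))
    lapply(truth$labels, function(lab) {
      img <- matrix(p$fluor_background, nrow(lab), ncol(lab))
      sel <- lab > 0L
      img[sel] <- p$fluor_level * gain[lab[sel]]
      shot <- render_noise(dim(lab), p$noise_sigma) *
        sqrt(pmax(img, 0) / p$fluor_level)
      img + shot
    })
  })
}

#' Simulate and render a full synthetic scene
#'
#' Convenience wrapper returning the ground truth plus whichever rendered
#' channels are requested.
#'
#' @param params a [scene_params()] object.
#' @param channels subset of `c("phase", "brightfield", "fluor")`.
#' @return list with `truth` and one rendered stack per requested channel.
#' @export
synth_scene <- function(params = scene_params(),
                        channels = "phase") {
  truth <- simulate_geometry(params)
  out <- list(truth = truth)
  if ("phase" %in% channels) out$phase <- render_phase(truth, params)
  if ("brightfield" %in% channels)
    out$brightfield <- render_brightfield(truth, params)
  if ("fluor" %in% channels) out$fluor <- render_fluor(truth, params)
  out
}
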