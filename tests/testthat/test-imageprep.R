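test_that("constant images give empty masks and zero top-hat", {
  img <- matrix(0.4, 96, 96)
  expect_false(any(coarse_cell_mask(img)))
  expect_false(any(detect_contour_pixels(img)))
  expect_true(all(brightfield_preprocess(img) == 0))
})

test_that("non-finite pixels and undersized images are rejected", {
  bad <- matrix(0.5, 96, 96); bad[4, 7] <- NA
  expect_error(coarse_cell_mask(bad), "finite")
  expect_error(coarse_cell_mask(matrix(0.5, 20, 20)), "64")
  expect_error(detect_contour_pixels(matrix(0.5, 8, 8),
                                     prep_params(mean_window = 11L)),
               "window")
})

test_that("coarse mask covers the colony and little background", {
  sp <- scene_params(frames = 2L, rng_seed = 17L)  # default 512 x 512 scale
  truth <- simulate_geometry(sp)
  tl <- truth$labels[[2]]
  ev <- prep_evidence(render_phase(truth, sp)[[2]], "phase")
  cm <- coarse_cell_mask(ev)
  expect_gt(sum(cm & tl > 0) / sum(tl > 0), 0.90)
  expect_lt(sum(cm & tl == 0) / sum(tl == 0), 0.02)
})

test_that("three well-separated colonies give three components", {
  sp <- scene_params(n_initial_cells = 4L, frames = 1L,
                     frame_dim = c(128L, 128L), rng_seed = 3L)
  img <- matrix(sp$background_level, 384, 160)
  for (k in 0:2) {
    truth <- simulate_geometry(sp)
    sp$rng_seed <- sp$rng_seed + 1L
    block <- render_phase(truth, sp)[[1]]
    img[k * 128 + (1:128), 17:144] <- block
  }
  cm <- coarse_cell_mask(img)
  lab <- EBImage::bwlabel(cm * 1)
  expect_equal(max(lab), 3)
})

test_that("contour detection marks halos, spares interiors, is monotone in k", {
  sp <- scene_params(n_initial_cells = 12L, frames = 1L,
                     frame_dim = c(256L, 256L), rng_seed = 2L,
                     noise_sigma = 0)  # clean frame
  truth <- simulate_geometry(sp)
  tl <- truth$labels[[1]]
  ev <- prep_evidence(render_phase(truth, sp)[[1]], "phase")
  cm <- coarse_cell_mask(ev)
  bg <- tl == 0
  dbg <- as.matrix(EBImage::imageData(EBImage::distmap(bg * 1)))
  ring <- bg & dbg > 0 & dbg <= sp$halo_width
  interior <- tl > 0 & !ring
  cont <- detect_contour_pixels(ev, cellmask = cm)
  expect_gt(sum(cont & ring) / sum(ring), 0.80)
  expect_lt(sum(cont & interior) / sum(interior), 0.05)

  prev <- NULL
  for (k in c(0.25, 0.75, 2, 50)) {
    cur <- detect_contour_pixels(ev, prep_params(contour_k = k),
                                 cellmask = cm)
    if (!is.null(prev)) expect_true(all(prev | !cur))  # cur subset of prev
    prev <- cur
  }
  expect_false(any(prev))  # k -> infinity empties the marked set
})

test_that("topography has one regional minimum per enclosed ring interior", {
  n <- 48L
  one <- ring_mask(n, 24, 24, 9)
  cm1 <- disk_mask(n, 24, 24, 12)
  topo1 <- make_topography(one, cm1)
  interior1 <- disk_mask(n, 24, 24, 8) & !one
  expect_identical(count_regional_minima(topo1, within = interior1), 1L)

  two <- ring_mask(n, 14, 14, 7) | ring_mask(n, 34, 34, 7)
  cm2 <- disk_mask(n, 14, 14, 10) | disk_mask(n, 34, 34, 10)
  topo2 <- make_topography(two, cm2)
  inner2 <- (disk_mask(n, 14, 14, 6) | disk_mask(n, 34, 34, 6)) & !two
  expect_identical(count_regional_minima(topo2, within = inner2), 2L)

  expect_true(all(make_topography(matrix(FALSE, n, n), cm1) == 0))
})

test_that("bright-field preprocessing lifts rings, is nonnegative and shift-equivariant", {
  sc <- scene_small()
  sp <- sc$params
  bf <- render_brightfield(sc$truth, sp)[[5]]
  out <- brightfield_preprocess(bf)
  expect_true(all(out >= 0))
  tl <- sc$truth$labels[[5]]
  bg <- tl == 0
  dbg <- as.matrix(EBImage::imageData(EBImage::distmap(bg * 1)))
  ring <- bg & dbg > 0 & dbg <= 1
  far <- bg & dbg > 6
  expect_gt(mean(out[ring]), 3 * mean(out[far]))

  # translation equivariance away from the border
  sh <- 7L
  shifted <- bf * 0 + median(bf)
  shifted[(sh + 1):nrow(bf), (sh + 1):ncol(bf)] <-
    bf[1:(nrow(bf) - sh), 1:(ncol(bf) - sh)]
  out_sh <- brightfield_preprocess(shifted)
  crop_a <- out[30:200, 30:200]
  crop_b <- out_sh[30:200 + sh, 30:200 + sh]
  expect_lt(max(abs(crop_a - crop_b)), 1e-6)
})

test_that("composite blending behaves at its endpoints and stays in [0,1]", {
  set.seed(1)
  ph <- matrix(runif(96 * 96), 96, 96)
  fl <- matrix(runif(96 * 96), 96, 96)
  norm_ph <- (ph - min(ph)) / (max(ph) - min(ph))
  expect_equal(make_composite(ph, fl, w = 0), norm_ph)
  expect_true(all(abs(make_composite(ph, matrix(0.7, 96, 96), w = 1) - 1) < 1e-12))
  comp <- make_composite(ph, fl, w = 0.35)
  expect_true(all(comp >= 0 & comp <= 1))
  expect_error(make_composite(ph, fl[1:50, ]), "shape")
})

test_that("full preparation yields one basin per true cell for nearly all cells", {
  sc <- scene_small()
  tl <- sc$truth$labels[[5]]
  pf <- prep_frame(sc$phase[[5]], "phase")
  ws <- watershed_partition(make_topography(pf$contours, pf$cellmask),
                            pf$cellmask)
  ids <- sort(unique(tl[tl > 0]))
  nb <- vapply(ids, function(id) {
    u <- table(ws[tl == id])
    u <- u[names(u) != "0"]
    sum(u >= 5)  # basins with a real footprint in the cell
  }, numeric(1))
  expect_gte(mean(nb == 1), 0.95)
})
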