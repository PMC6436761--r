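test_that("geometry is deterministic and budding obeys its switches", {
  sp <- scene_params(n_initial_cells = 8L, frames = 6L,
                     frame_dim = c(256L, 256L), rng_seed = 4L, bud_rate = 0)
  a <- simulate_geometry(sp)
  b <- simulate_geometry(sp)
  expect_identical(a$labels, b$labels)
  expect_identical(a$geometry, b$geometry)
  # no budding: the cell count never grows
  expect_identical(max(a$labels[[6]]), 8L)
  expect_identical(nrow(a$lineage), 0L)

  sp2 <- sp; sp2$bud_rate <- 3; sp2$maturity_frames <- 1L
  withbuds <- simulate_geometry(sp2)
  expect_gt(max(withbuds$labels[[6]]), 8L)
  expect_true(all(withbuds$lineage$birth_frame > 1))
})

test_that("areas double over one doubling time and never overlap", {
  # frames spanning exactly one doubling: 10 frames x 10 min, 90-min doubling
  sp <- scene_params(n_initial_cells = 6L, frames = 10L,
                     frame_interval = 10, doubling_time = 90,
                     frame_dim = c(256L, 256L), rng_seed = 6L, bud_rate = 0)
  truth <- simulate_geometry(sp)
  g0 <- truth$geometry[truth$geometry$frame == 1, ]
  g1 <- truth$geometry[truth$geometry$frame == 10, ]
  ratio <- g1$area / g0$area  # 9 intervals = 90 min = one doubling
  expect_true(all(ratio > 1.9 & ratio < 2.1))
  # rasterized labels are disjoint by construction; geometric growth is
  # monotone per cell
  geo <- truth$geometry
  for (id in unique(geo$id)) {
    a <- geo$area[geo$id == id]
    expect_true(all(diff(a) >= 0))
  }
})

test_that("phase render puts the halo on top, interior at the bottom", {
  sp <- scene_params(n_initial_cells = 1L, frames = 1L,
                     frame_dim = c(96L, 96L), rng_seed = 2L, noise_sigma = 0)
  truth <- simulate_geometry(sp)
  img <- render_phase(truth, sp)[[1]]
  tl <- truth$labels[[1]]
  bg <- tl == 0
  dbg <- as.matrix(EBImage::imageData(EBImage::distmap(bg * 1)))
  ring <- bg & dbg > 0 & dbg <= sp$halo_width
  far <- bg & dbg > sp$halo_width
  # ring pixels are strictly the brightest; level ordering holds
  expect_true(min(img[ring]) > max(img[!ring]))
  expect_lt(mean(img[tl > 0]), mean(img[far]))
  expect_lt(mean(img[far]), mean(img[ring]))
})

test_that("near-touching cells share one fused bright ridge", {
  sp <- scene_params(n_initial_cells = 2L, frames = 1L,
                     frame_dim = c(96L, 96L), rng_seed = 21L,
                     noise_sigma = 0, cell_radius_range = c(10, 12))
  truth <- simulate_geometry(sp)
  img <- render_phase(truth, sp)[[1]]
  tl <- truth$labels[[1]]
  c1 <- colMeans(which(tl == 1L, arr.ind = TRUE))
  c2 <- colMeans(which(tl == 2L, arr.ind = TRUE))
  # walk the centroid line: the maximum between the two interiors must be
  # at the halo level (fused ridge), not at the background level
  steps <- seq(0, 1, length.out = 50)
  line <- vapply(steps, function(s) {
    p <- round(c1 + s * (c2 - c1))
    img[p[1], p[2]]
  }, numeric(1))
  interiors <- line[c(5, 45)]
  expect_gte(max(line), sp$halo_gain)
  expect_true(all(interiors < sp$background_level))
})

test_that("bright-field render is flat without gradient and noise", {
  sp <- scene_params(n_initial_cells = 3L, frames = 1L,
                     frame_dim = c(128L, 128L), rng_seed = 3L,
                     noise_sigma = 0, illumination_gradient = 0)
  truth <- simulate_geometry(sp)
  img <- render_brightfield(truth, sp)[[1]]
  tl <- truth$labels[[1]]
  bg <- tl == 0
  dbg <- as.matrix(EBImage::imageData(EBImage::distmap(bg * 1)))
  outside_rows <- which(apply(tl > 0 | (bg & dbg <= 1), 1, sum) == 0)
  rm <- rowMeans(img[outside_rows, , drop = FALSE])
  expect_lt(max(rm) - min(rm), 1e-12)
  # boundary contrast is weaker than in phase at matched params
  ring <- bg & dbg > 0 & dbg <= 1
  ph <- render_phase(truth, sp)[[1]]
  contrast_bf <- abs(mean(img[ring]) - sp$bf_background_level)
  contrast_ph <- abs(mean(ph[bg & dbg > 0 & dbg <= sp$halo_width]) -
                       sp$background_level)
  expect_lt(contrast_bf, contrast_ph)
  # determinism by seed
  expect_identical(render_brightfield(truth, sp),
                   render_brightfield(truth, sp))
})

test_that("fluorescent render concentrates signal inside the true cells", {
  sp <- scene_params(n_initial_cells = 30L, frames = 2L,
                     frame_dim = c(256L, 256L), rng_seed = 13L)
  truth <- simulate_geometry(sp)
  img <- render_fluor(truth, sp)[[2]]
  tl <- truth$labels[[2]]
  expect_lt(mean(img[tl == 0]), mean(img[tl > 0]))
  # above-background signal is recovered almost entirely by the true masks
  signal <- pmax(img - sp$fluor_background, 0)
  expect_gte(sum(signal[tl > 0]) / sum(signal), 0.95)
  expect_identical(render_fluor(truth, sp), render_fluor(truth, sp))
})

test_that("renders do not disturb the caller's RNG stream", {
  sp <- scene_params(n_initial_cells = 3L, frames = 1L,
                     frame_dim = c(96L, 96L), rng_seed = 1L)
  set.seed(123)
  before <- runif(3)
  set.seed(123)
  invisible(render_phase(simulate_geometry(sp), sp))
  after <- runif(3)
  expect_identical(before, after)
})
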