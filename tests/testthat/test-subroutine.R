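# One isolated clean cell rendered through the real pipeline: evidence
# crop, ground-truth mask, and a context builder.
one_cell_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    sp <- scene_params(n_initial_cells = 1L, frames = 1L,
                       frame_dim = c(96L, 96L), rng_seed = 9L,
                       noise_sigma = 0)
    truth <- simulate_geometry(sp)
    pf <- prep_frame(render_phase(truth, sp)[[1]], "phase")
    cache <<- list(truth_mask = truth$labels[[1]] > 0, pf = pf)
    cache
  }
})

test_that("score saturates inside the seed and vanishes beyond reach", {
  fx <- one_cell_fixture()
  ctx <- subimage_context(fx$pf, fx$truth_mask, pad = 20L)
  prm <- subroutine_params()
  s <- compute_score(ctx, prm)
  # deep-interior pixels: no contour evidence, in-seed, connected
  deep <- ctx$seed &
    as.matrix(EBImage::imageData(EBImage::distmap(ctx$seed * 1))) > 4
  expect_true(all(s[deep] >= prm$accept_threshold))
  dseed <- as.matrix(EBImage::imageData(EBImage::distmap((!ctx$seed) * 1)))
  expect_true(all(s[dseed > prm$reach_px] == 0))
  expect_error(subimage_context(fx$pf, matrix(FALSE, 96, 96)), "empty")
})

test_that("thresholding the score with the exact seed reproduces the cell", {
  fx <- one_cell_fixture()
  ctx <- subimage_context(fx$pf, fx$truth_mask, pad = 20L)
  s <- compute_score(ctx, subroutine_params())
  got <- s >= subroutine_params()$accept_threshold
  expect_gte(jaccard_masks(got, ctx$seed), 0.95)
})

test_that("refine_once keeps the seeded blob, fills holes, smooths", {
  # synthetic context: two above-threshold blobs, seed on the larger
  n <- 60L
  ev <- matrix(1, n, n)  # bright everywhere: boundary term 0
  big <- disk_mask(n, 20, 20, 10)
  small <- disk_mask(n, 45, 45, 5)
  ev[big | small] <- 0
  ev[disk_mask(n, 20, 20, 2)] <- 1  # a hole inside the big blob
  seed <- disk_mask(n, 20, 20, 12)
  ctx <- subimage_context(ev, seed, pad = 60L)  # crop spans the frame
  res <- refine_once(ctx, subroutine_params(smooth_radius = 1L))
  expect_true(all(res$mask[disk_mask(n, 20, 20, 2)]))    # hole filled
  expect_false(any(res$mask & small))                    # other blob dropped
  # empty result when nothing reaches the threshold
  ctx2 <- subimage_context(matrix(1, 30, 30) * 0 + 1,
                           disk_mask(30, 15, 15, 4), pad = 0L)
  ctx2$crop[] <- 1
  res2 <- refine_once(ctx2, subroutine_params(seed_weight = 0.05,
                                              boundary_weight = 0.9,
                                              interior_weight = 0.05))
  expect_false(any(res2$mask))
})

test_that("iteration converges a perturbed seed back onto the cell", {
  fx <- one_cell_fixture()
  prm <- subroutine_params()
  # coarse seed: eroded truth (watershed-line-like underestimate)
  coarse <- EBImage::erode(fx$truth_mask * 1, EBImage::makeBrush(7, "disc")) > 0
  ctx <- subimage_context(fx$pf, coarse, pad = 20L)
  res <- iterate_subroutine(ctx, prm)
  truth_local <- fx$truth_mask[
    ctx$origin[1]:(ctx$origin[1] + nrow(ctx$crop) - 1),
    ctx$origin[2]:(ctx$origin[2] + ncol(ctx$crop) - 1)]
  expect_gte(jaccard_masks(res$mask, truth_local), 0.95)

  # 40% removed: recovered within <= 3 refinement rounds
  cut <- perturb_seed(fx$truth_mask, 0.40, rng_seed = 77L)
  ctx3 <- subimage_context(fx$pf, cut, pad = 20L)
  prm3 <- subroutine_params(n_rounds = 3L)
  res3 <- iterate_subroutine(ctx3, prm3)
  tr_local <- fx$truth_mask[
    ctx3$origin[1]:(ctx3$origin[1] + nrow(ctx3$crop) - 1),
    ctx3$origin[2]:(ctx3$origin[2] + ncol(ctx3$crop) - 1)]
  expect_gte(jaccard_masks(res3$mask, tr_local), 0.95)
})

test_that("one round equals refine_once and the exact seed is near a fixed point", {
  fx <- one_cell_fixture()
  ctx <- subimage_context(fx$pf, fx$truth_mask, pad = 20L)
  one <- iterate_subroutine(ctx, subroutine_params(n_rounds = 1L))
  ref <- refine_once(ctx, subroutine_params())
  expect_identical(one$mask, ref$mask)
  expect_gte(jaccard_masks(ref$mask, ctx$seed), 0.98)
})

test_that("iterates are deterministic, local, and converge monotonically", {
  sc <- scene_small()
  tl <- sc$truth$labels[[5]]
  pf <- prep_frame(sc$phase[[5]], "phase")
  prm <- subroutine_params()
  ids <- sort(unique(tl[tl > 0]))
  set.seed(31)
  picks <- sample(ids, 8L)
  n_improving <- 0L; n_tested <- 0L
  for (id in picks) {
    truth_mask <- tl == id
    cut <- perturb_seed(truth_mask, runif(1, 0.05, 0.5))
    ctx <- subimage_context(pf, cut, pad = 12L)
    a <- iterate_subroutine(ctx, prm)
    b <- iterate_subroutine(ctx, prm)
    expect_identical(a$mask, b$mask)  # no RNG in the subroutine
    # locality: never beyond reach of the initial seed
    dseed <- as.matrix(EBImage::imageData(EBImage::distmap((!ctx$seed) * 1)))
    expect_false(any(a$mask & dseed > prm$reach_px))
    # successive iterates approach the converged mask
    prev_j <- -1; ok <- TRUE
    cur <- ctx
    for (r in seq_len(prm$n_rounds)) {
      step <- refine_once(cur, prm)
      if (!any(step$mask)) break
      jj <- jaccard_masks(step$mask, a$mask)
      if (jj < prev_j - 1e-9) ok <- FALSE
      prev_j <- jj
      if (identical(step$mask, cur$seed)) break
      cur$seed <- step$mask
    }
    n_tested <- n_tested + 1L
    if (ok) n_improving <- n_improving + 1L
  }
  expect_gte(n_improving / n_tested, 0.95)
})
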