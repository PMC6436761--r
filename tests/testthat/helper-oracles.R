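# Independent oracles used to check the package's image operations, plus
# cached synthetic scenes shared across test files.

# --- brute-force flooding oracle ------------------------------------------
# Catchment-basin labelling of a height map x (flooded from its maxima):
# pixels are processed in decreasing height; each starts a new basin when
# no strictly higher neighbor is labelled, otherwise it drains to the
# basin of its steepest ascending neighbor. Pixels whose higher neighbors
# belong to several basins are ridge-ambiguous: any watershed
# implementation may assign them to either side, so comparisons skip them.
flood_oracle <- function(x) {
  n <- nrow(x); m <- ncol(x)
  lab <- matrix(0L, n, m); amb <- matrix(FALSE, n, m)
  ord <- order(x, decreasing = TRUE)
  nxt <- 0L
  for (idx in ord) {
    if (x[idx] <= 0) break
    i <- (idx - 1L) %% n + 1L; j <- (idx - 1L) %/% n + 1L
    best_h <- -Inf; best_lab <- 0L; labs_higher <- integer(0)
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0L && dj == 0L) next
      ii <- i + di; jj <- j + dj
      if (ii < 1L || jj < 1L || ii > n || jj > m) next
      if (lab[ii, jj] > 0L && x[ii, jj] > x[i, j]) {
        labs_higher <- c(labs_higher, lab[ii, jj])
        if (x[ii, jj] > best_h) { best_h <- x[ii, jj]; best_lab <- lab[ii, jj] }
      }
    }
    if (best_lab == 0L) { nxt <- nxt + 1L; lab[idx] <- nxt }
    else { lab[idx] <- best_lab
           if (length(unique(labs_higher)) > 1L) amb[idx] <- TRUE }
  }
  list(lab = lab, amb = amb, n = nxt)
}

# Random cone-peak height map on an n x n grid (k basins of depth ~8).
random_cone_topography <- function(n = 28L, k = 3L) {
  ctr <- cbind(stats::runif(k, 5, n - 4), stats::runif(k, 5, n - 4))
  x <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d <- sqrt((ctr[, 1] - i)^2 + (ctr[, 2] - j)^2)
    x[i, j] <- max(pmax(0, 8 - d))
  }
  x
}

# --- exhaustive regional-minima counter -----------------------------------
# Counts connected equal-value plateaus (8-connectivity) none of whose
# neighbors is lower; optionally only plateaus intersecting `within`.
count_regional_minima <- function(topo, within = NULL) {
  n <- nrow(topo); m <- ncol(topo)
  visited <- matrix(FALSE, n, m)
  cnt <- 0L
  for (si in seq_len(n)) for (sj in seq_len(m)) {
    if (visited[si, sj]) next
    val <- topo[si, sj]
    queue <- matrix(c(si, sj), 1L)
    visited[si, sj] <- TRUE
    plateau <- matrix(integer(0), 0L, 2L)
    is_min <- TRUE
    while (nrow(queue) > 0L) {
      p <- queue[1L, ]; queue <- queue[-1L, , drop = FALSE]
      plateau <- rbind(plateau, p)
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0L && dj == 0L) next
        ii <- p[1L] + di; jj <- p[2L] + dj
        if (ii < 1L || jj < 1L || ii > n || jj > m) next
        if (topo[ii, jj] == val) {
          if (!visited[ii, jj]) {
            visited[ii, jj] <- TRUE
            queue <- rbind(queue, c(ii, jj))
          }
        } else if (topo[ii, jj] < val) is_min <- FALSE
      }
    }
    if (is_min) {
      if (is.null(within) ||
          any(within[plateau])) cnt <- cnt + 1L
    }
  }
  cnt
}

# --- exhaustive optimal matching ------------------------------------------
# Maximum-cardinality matching between point sets under distance d_max,
# by brute-force recursion (feasible for <= 10 points).
optimal_match_count <- function(P, T, d_max) {
  if (nrow(P) == 0L || nrow(T) == 0L) return(0L)
  dm <- outer(seq_len(nrow(P)), seq_len(nrow(T)), function(i, j)
    sqrt((P[i, 1] - T[j, 1])^2 + (P[i, 2] - T[j, 2])^2))
  rec <- function(i, used) {
    if (i > nrow(P)) return(0L)
    best <- rec(i + 1L, used)
    for (j in seq_len(nrow(T))) {
      if (!used[j] && dm[i, j] < d_max) {
        used[j] <- TRUE
        best <- max(best, 1L + rec(i + 1L, used))
        used[j] <- FALSE
      }
    }
    best
  }
  rec(1L, logical(nrow(T)))
}

# --- brute-force periphery ------------------------------------------------
# Mask pixels within `thickness` (Euclidean) of some complement pixel.
periphery_bruteforce <- function(mask, thickness) {
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  comp <- which(!mask, arr.ind = TRUE)
  for (p in seq_len(nrow(mask) * ncol(mask))) {
    if (!mask[p]) next
    i <- (p - 1L) %% nrow(mask) + 1L; j <- (p - 1L) %/% nrow(mask) + 1L
    if (nrow(comp) == 0L) next
    d <- sqrt((comp[, 1] - i)^2 + (comp[, 2] - j)^2)
    out[p] <- min(d) <= thickness
  }
  out
}

# --- misc helpers ----------------------------------------------------------
jaccard_masks <- function(a, b) {
  u <- sum(a | b)
  if (u == 0L) return(1)
  sum(a & b) / u
}

# Best Jaccard between every true cell and any overlapping predicted cell.
per_cell_best_jaccard <- function(pred_labels, true_labels) {
  ids <- sort(unique(true_labels[true_labels > 0L]))
  vapply(ids, function(id) {
    tm <- true_labels == id
    pids <- setdiff(unique(pred_labels[tm]), 0L)
    if (length(pids) == 0L) return(0)
    max(vapply(pids, function(p)
      jaccard_masks(pred_labels == p, tm), numeric(1)))
  }, numeric(1))
}

# A small synthetic disk mask for mask-level tests.
disk_mask <- function(n, cx, cy, r) {
  outer(seq_len(n), seq_len(n), function(i, j)
    (i - cx)^2 + (j - cy)^2 <= r^2)
}

# Closed ring of radius r (1 px thick) around (cx, cy).
ring_mask <- function(n, cx, cy, r) {
  d <- outer(seq_len(n), seq_len(n), function(i, j)
    sqrt((i - cx)^2 + (j - cy)^2))
  abs(d - r) <= 0.6
}

# --- cached scenes ---------------------------------------------------------
.scene_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.scene_cache[[key]])) .scene_cache[[key]] <- force(expr)
  .scene_cache[[key]]
}

# one small colony, 5 frames (final-frame segmentation tests)
scene_small <- function() cached("small", {
  sp <- scene_params(n_initial_cells = 20L, frames = 5L,
                     frame_dim = c(320L, 320L), rng_seed = 42L)
  truth <- simulate_geometry(sp)
  list(params = sp, truth = truth, phase = render_phase(truth, sp))
})

# budding colony, 10 frames (tracking tests)
scene_track <- function() cached("track", {
  sp <- scene_params(n_initial_cells = 15L, frames = 10L,
                     frame_dim = c(320L, 320L), rng_seed = 5L,
                     bud_rate = 1.5)
  truth <- simulate_geometry(sp)
  list(params = sp, truth = truth, phase = render_phase(truth, sp))
})
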