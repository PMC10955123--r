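#' Tensor volume container
#'
#' A 3-D voxel grid of symmetric diffusion tensors with a binary muscle
#' mask. Tensors are stored as a 4-D array `[x, y, z, 6]` holding the unique
#' upper-triangle elements `(xx, xy, xz, yy, yz, zz)` in mm^2/s. World
#' coordinates are voxel index times voxel size with voxel centers at
#' `(i - 0.5) * voxel_size` (1-based indices).
#'
#' @param tensors numeric array `[nx, ny, nz, 6]`.
#' @param mask logical/0-1 array `[nx, ny, nz]`, non-empty.
#' @param voxel_size scalar or length-3 voxel edge length in mm.
#' @return an object of class `tensor_volume`.
#' @export
tensor_volume <- function(tensors, mask, voxel_size) {
  stopifnot(length(dim(tensors)) == 4L, dim(tensors)[4] == 6L)
  stopifnot(all(dim(mask) == dim(tensors)[1:3]))
  if (!any(mask != 0)) stop("mask is empty", call. = FALSE)
  voxel_size <- rep_len(voxel_size, 3L)
  structure(list(tensors = tensors, mask = (mask != 0) * 1L,
                 voxel_size = voxel_size, dim = dim(tensors)[1:3]),
            class = "tensor_volume")
}

#' @export
print.tensor_volume <- function(x, ...) {
  cat(sprintf("<tensor_volume> %d x %d x %d voxels @ %g mm, %d in mask\n",
              x$dim[1], x$dim[2], x$dim[3], x$voxel_size[1], sum(x$mask)))
  invisible(x)
}

# world point (mm) -> fractional 1-based voxel-center coordinates
world_to_vox <- function(p, voxel_size) p / voxel_size + 0.5

# voxel (1-based index) containing world point, or NA outside the grid
containing_voxel <- function(p, vol) {
  i <- as.integer(floor(p / vol$voxel_size)) + 1L
  if (any(i < 1L) || any(i > vol$dim)) return(NULL)
  i
}

in_mask <- function(p, vol) {
  i <- containing_voxel(p, vol)
  !is.null(i) && vol$mask[i[1], i[2], i[3]] == 1L
}

# trilinear interpolation of the 6 tensor components at world point p
interp_tensor <- function(p, vol) {
  f <- world_to_vox(p, vol$voxel_size)
  i0 <- pmin(pmax(floor(f), 1), vol$dim - 1L)
  w <- f - i0
  w <- pmin(pmax(w, 0), 1)
  d6 <- numeric(6)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wt <- (if (dx) w[1] else 1 - w[1]) *
          (if (dy) w[2] else 1 - w[2]) *
          (if (dz) w[3] else 1 - w[3])
    if (wt > 0)
      d6 <- d6 + wt * vol$tensors[i0[1] + dx, i0[2] + dy, i0[3] + dz, ]
  }
  d6
}

# principal eigenvector (sign-aligned to prev) and FA at world point p
direction_at <- function(p, vol, prev = NULL) {
  D <- tensor6_to_mat(interp_tensor(p, vol))
  e <- eigen(D, symmetric = TRUE)
  v <- e$vectors[, 1]
  if (!is.null(prev) && sum(v * prev) < 0) v <- -v
  list(dir = v, fa = fractional_anisotropy(pmax(e$values, 0)))
}

#' Fixed-step integration of a unit direction field
#'
#' Core geometric integrator used by [track_streamline()]: advances a point
#' through a direction field `dirfun(p, prev)` (returning a unit vector,
#' sign-aligned with the previous direction) with classical 4th-order
#' Runge-Kutta or, for reference, forward Euler.
#'
#' @param dirfun function of `(point, prev_direction)` returning a unit
#'   3-vector, or `NULL` to stop.
#' @param seed_point numeric 3-vector starting point (mm).
#' @param step step size in mm.
#' @param n_steps maximum number of steps.
#' @param method `"rk4"` or `"euler"`.
#' @param init_dir optional initial direction for sign alignment.
#' @return matrix of points (rows), starting at `seed_point`.
#' @export
integrate_direction_field <- function(dirfun, seed_point, step, n_steps,
                                      method = c("rk4", "euler"),
                                      init_dir = NULL) {
  method <- match.arg(method)
  pts <- matrix(NA_real_, n_steps + 1L, 3L)
  pts[1L, ] <- seed_point
  p <- seed_point
  prev <- init_dir
  for (k in seq_len(n_steps)) {
    k1 <- dirfun(p, prev)
    if (is.null(k1)) break
    if (method == "euler") {
      delta <- k1
    } else {
      k2 <- dirfun(p + step / 2 * k1, k1)
      if (is.null(k2)) break
      k3 <- dirfun(p + step / 2 * k2, k1)
      if (is.null(k3)) break
      k4 <- dirfun(p + step * k3, k1)
      if (is.null(k4)) break
      delta <- (k1 + 2 * k2 + 2 * k3 + k4) / 6
    }
    p <- p + step * delta
    pts[k + 1L, ] <- p
    prev <- delta
  }
  pts[stats::complete.cases(pts), , drop = FALSE]
}

#' Deterministic RK4 streamline tracking of a tensor volume
#'
#' Tracks the principal-eigenvector direction field of the diffusion tensors
#' bidirectionally from a seed point with classical 4th-order Runge-Kutta at
#' a fixed step. Tensors are interpolated component-wise (trilinearly) and
#' eigen-decomposed at each evaluation point, with the eigenvector sign
#' aligned to the previous direction. Tracking halts when the point leaves
#' the mask, local FA falls outside `[fa_min, fa_max]`, the per-step turning
#' angle exceeds `angle_max`, or the streamline reaches `length_max`.
#'
#' @param volume a [tensor_volume()].
#' @param seed_point numeric 3-vector in mm, inside the mask.
#' @param step step size in mm (default 1).
#' @param fa_min,fa_max FA tracking bounds (defaults 0.05 and 0.6).
#' @param angle_max maximal turning angle per step in degrees (default 30).
#' @param length_max maximal streamline length in mm (default 200).
#' @return an object of class `streamline`: `points` (world mm), `length`
#'   (mm), `mean_fa`, and `voxels` (unique 1-based voxel indices traversed).
#' @export
track_streamline <- function(volume, seed_point, step = 1,
                             fa_min = 0.05, fa_max = 0.6,
                             angle_max = 30, length_max = 200) {
  stopifnot(inherits(volume, "tensor_volume"))
  if (!in_mask(seed_point, volume))
    stop("seed point outside the mask", call. = FALSE)
  seed_info <- direction_at(seed_point, volume)
  if (seed_info$fa < fa_min || seed_info$fa > fa_max) {
    return(new_streamline(matrix(seed_point, 1, 3), volume))
  }
  cos_max <- cos(angle_max * pi / 180)
  max_steps <- ceiling(length_max / step)

  eval_dir <- function(p, prev) {
    if (!in_mask(p, volume)) return(NULL)
    info <- direction_at(p, volume, prev)
    if (info$fa < fa_min || info$fa > fa_max) return(NULL)
    info$dir
  }

  track_half <- function(sign_dir) {
    pts <- matrix(seed_point, 1, 3)
    p <- seed_point
    prev <- sign_dir * seed_info$dir
    for (k in seq_len(floor(max_steps / 2))) {
      k1 <- eval_dir(p, prev)
      if (is.null(k1)) break
      k2 <- eval_dir(p + step / 2 * k1, k1)
      if (is.null(k2)) break
      k3 <- eval_dir(p + step / 2 * k2, k1)
      if (is.null(k3)) break
      k4 <- eval_dir(p + step * k3, k1)
      if (is.null(k4)) break
      delta <- (k1 + 2 * k2 + 2 * k3 + k4) / 6
      nd <- sqrt(sum(delta^2))
      if (nd == 0) break
      delta <- delta / nd
      if (sum(delta * prev) < cos_max) break  # turning-angle stop rule
      p_new <- p + step * delta
      if (!in_mask(p_new, volume)) break
      pts <- rbind(pts, p_new)
      p <- p_new
      prev <- delta
    }
    pts
  }

  fwd <- track_half(1)
  bwd <- track_half(-1)
  pts <- rbind(bwd[rev(seq_len(nrow(bwd))), , drop = FALSE],
               fwd[-1, , drop = FALSE])
  new_streamline(pts, volume)
}

new_streamline <- function(points, volume) {
  n <- nrow(points)
  len <- if (n < 2L) 0 else sum(sqrt(rowSums(diff(points)^2)))
  fa <- vapply(seq_len(n), function(i)
    direction_at(points[i, ], volume)$fa, numeric(1))
  vox <- t(vapply(seq_len(n), function(i) {
    v <- containing_voxel(points[i, ], volume)
    if (is.null(v)) rep(NA_integer_, 3L) else v
  }, integer(3)))
  vox <- unique(vox[stats::complete.cases(vox), , drop = FALSE])
  structure(list(points = points, length = len, mean_fa = mean(fa),
                 voxels = vox),
            class = "streamline")
}

#' @export
print.streamline <- function(x, ...) {
  cat(sprintf("<streamline> %d points, %0.2f mm, mean FA %0.3f, %d voxels\n",
              nrow(x$points), x$length, x$mean_fa, nrow(x$voxels)))
  invisible(x)
}

#' Whole-mask tractography
#'
#' Seeds one streamline per masked voxel center in deterministic index
#' order and keeps those within the length acceptance window.
#'
#' @inheritParams track_streamline
#' @param length_range accepted streamline lengths in mm
#'   (default `c(10, 200)`); the upper bound is also the tracking stop
#'   length.
#' @param max_seeds cap on the number of seeds; when the mask holds more
#'   voxels an evenly spaced deterministic subset is used.
#' @return list of `streamline` objects.
#' @export
track_volume <- function(volume, step = 1, fa_min = 0.05, fa_max = 0.6,
                         angle_max = 30, length_range = c(10, 200),
                         max_seeds = Inf) {
  idx <- which(volume$mask == 1L, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2], idx[, 3]), , drop = FALSE]
  if (nrow(idx) > max_seeds)
    idx <- idx[round(seq(1L, nrow(idx), length.out = max_seeds)), , drop = FALSE]
  out <- list()
  for (r in seq_len(nrow(idx))) {
    seed <- (idx[r, ] - 0.5) * volume$voxel_size
    sl <- track_streamline(volume, seed, step, fa_min, fa_max,
                           angle_max, length_range[2])
    if (sl$length >= length_range[1] && sl$length <= length_range[2])
      out[[length(out) + 1L]] <- sl
  }
  out
}

#' Fascicle metrics of a streamline bundle
#'
#' Mean fascicle length (mean streamline arc length), fascicle volume
#' (count of unique voxels traversed by any streamline times the voxel
#' volume) and the length-weighted mean FA along the bundle.
#'
#' @param streamlines list of `streamline` objects (>= 1).
#' @param volume the `tensor_volume` they were tracked in.
#' @return list with `fascicle_length` (mm), `fascicle_volume` (mm^3),
#'   `mean_fa`, `n_streamlines`.
#' @export
tract_statistics <- function(streamlines, volume) {
  if (length(streamlines) == 0L) stop("empty streamline set", call. = FALSE)
  lens <- vapply(streamlines, function(s) s$length, numeric(1))
  fas <- vapply(streamlines, function(s) s$mean_fa, numeric(1))
  vox <- unique(do.call(rbind, lapply(streamlines, function(s) s$voxels)))
  wts <- if (sum(lens) > 0) lens / sum(lens) else rep(1 / length(lens), length(lens))
  list(fascicle_length = mean(lens),
       fascicle_volume = nrow(vox) * prod(volume$voxel_size),
       mean_fa = sum(wts * fas),
       n_streamlines = length(streamlines))
}
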