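#' Specification of a muscle DTI phantom
#'
#' Describes a synthetic pennate-muscle diffusion phantom: a cylindrical
#' muscle-shaped mask filled with parallel fascicle paths of known geometry,
#' each voxel carrying a symmetric positive-definite tensor whose principal
#' eigenvector is tangent to the local path and whose eigenvalues realize a
#' target fractional anisotropy.
#'
#' @param grid_shape integer voxel counts along x, y, z.
#' @param voxel_size voxel edge length in mm.
#' @param fascicle_length_true true fascicle path length in mm.
#' @param pennation_angle fascicle tilt from the cylinder axis in degrees.
#' @param fa_target target FA in `[0, 1)`.
#' @param eigenvalue_scale principal eigenvalue in mm^2/s (muscle-typical
#'   ~1.7e-3).
#' @param n_directions DWI gradient count (default 48).
#' @param b_value diffusion weighting in s/mm^2 (default 400).
#' @param noise_sd_signal DWI noise sd as a fraction of S0.
#' @param geometry `"straight"` fibers along the cylinder axis or `"arc"`
#'   fibers on circles around the y-axis.
#' @param arc_radius radius in mm of the arc geometry.
#' @param seed integer seed.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(24L, 24L, 28L), voxel_size = 2,
                         fascicle_length_true = 40, pennation_angle = 0,
                         fa_target = 0.3, eigenvalue_scale = 1.7e-3,
                         n_directions = 48L, b_value = 400,
                         noise_sd_signal = 0,
                         geometry = c("straight", "arc"), arc_radius = 30,
                         seed = NULL) {
  geometry <- match.arg(geometry)
  if (fa_target < 0 || fa_target >= 1)
    stop("fa_target must be in [0, 1)", call. = FALSE)
  stop_if_not_scalar_num(voxel_size, "voxel_size", positive = TRUE)
  stop_if_not_scalar_num(fascicle_length_true, "fascicle_length_true", positive = TRUE)
  structure(list(grid_shape = as.integer(grid_shape), voxel_size = voxel_size,
                 fascicle_length_true = fascicle_length_true,
                 pennation_angle = pennation_angle, fa_target = fa_target,
                 eigenvalue_scale = eigenvalue_scale,
                 n_directions = as.integer(n_directions), b_value = b_value,
                 noise_sd_signal = noise_sd_signal, geometry = geometry,
                 arc_radius = arc_radius, seed = seed),
            class = "phantom_spec")
}

# eigenvalues (l1, lt, lt) realizing FA = f with principal eigenvalue l1
eigenvalues_for_fa <- function(f, l1) {
  if (f == 0) return(c(l1, l1, l1))
  den <- 1 - 2 * f^2
  lt <- if (abs(den) < 1e-12) l1 * (1 - f^2) / 2
        else l1 * (1 - sqrt(1 - den * (1 - f^2))) / den
  c(l1, lt, lt)
}

#' Simulate a muscle DTI phantom with known ground truth
#'
#' Builds a cylindrical muscle mask containing parallel fascicles of known
#' arc length, fills each masked voxel with a tensor whose principal
#' eigenvector is tangent to the local fascicle direction and whose
#' eigenvalues realize `fa_target` exactly, and (optionally) synthesizes
#' diffusion-weighted signals `S_i = S0 * exp(-b g_i' D g_i)` over a
#' quasi-uniform gradient table, with Gaussian or Rician noise.
#'
#' @param spec a [phantom_spec()].
#' @param with_dwi also return DWI signals and the gradient table.
#' @param noise_model `"gaussian"` (default) or `"rician"`.
#' @return list with `volume` (a [tensor_volume()]), `ground_truth` (true
#'   eigenvalues, FA, fascicle length, direction), and with `with_dwi` the
#'   `dwi` array `[nx, ny, nz, n_directions]`, `gradients`, `s0`, `b`.
#' @export
simulate_phantom <- function(spec, with_dwi = FALSE,
                             noise_model = c("gaussian", "rician")) {
  stopifnot(inherits(spec, "phantom_spec"))
  noise_model <- match.arg(noise_model)
  dm <- spec$grid_shape
  vs <- spec$voxel_size
  ev <- eigenvalues_for_fa(spec$fa_target, spec$eigenvalue_scale)

  # voxel-center world coordinates
  cx <- (seq_len(dm[1]) - 0.5) * vs
  cy <- (seq_len(dm[2]) - 0.5) * vs
  cz <- (seq_len(dm[3]) - 0.5) * vs
  ctr <- c(mean(range(cx)), mean(range(cy)), mean(range(cz)))

  mask <- array(0L, dm)
  tensors <- array(0, c(dm, 6L))
  pen <- spec$pennation_angle * pi / 180

  if (spec$geometry == "straight") {
    # cylinder along z; z extent chosen so the tilted fascicle path spanning
    # it has arc length fascicle_length_true
    z_half <- spec$fascicle_length_true * cos(pen) / 2
    radius <- 0.4 * min(diff(range(cx)), diff(range(cy)))
    dir <- c(sin(pen), 0, cos(pen))
    D6 <- mat_to_tensor6(tensor_from_dir(dir, ev))
    for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) {
      rr <- sqrt((cx[i] - ctr[1])^2 + (cy[j] - ctr[2])^2)
      if (rr > radius) next
      inz <- which(abs(cz - ctr[3]) <= z_half)
      mask[i, j, inz] <- 1L
      for (k in inz) tensors[i, j, k, ] <- D6
    }
    truth_dir <- dir
    truth_len <- 2 * z_half / cos(pen)
  } else {
    # fibers on circles of radius arc_radius around the axis x = ctr[1] (in
    # the x-z plane), mask an annular shell subtending the requested length
    R <- spec$arc_radius
    half_angle <- spec$fascicle_length_true / (2 * R)
    shell <- 0.25 * min(diff(range(cx)), diff(range(cz)))
    y_half <- 0.3 * diff(range(cy))
    c0 <- c(ctr[1], ctr[3] - R * cos(half_angle) - shell)  # (x, z) arc center
    for (i in seq_len(dm[1])) for (k in seq_len(dm[3])) {
      dxz <- c(cx[i] - c0[1], cz[k] - c0[2])
      rr <- sqrt(sum(dxz^2))
      ang <- atan2(dxz[1], dxz[2])   # 0 at +z, grows toward +x
      if (abs(rr - R) > shell || abs(ang) > half_angle) next
      tang <- c(dxz[2], 0, -dxz[1]) / rr
      D6 <- mat_to_tensor6(tensor_from_dir(tang, ev))
      for (j in which(abs(cy - ctr[2]) <= y_half)) {
        mask[i, j, k] <- 1L
        tensors[i, j, k, ] <- D6
      }
    }
    truth_dir <- NA
    truth_len <- 2 * half_angle * R
  }

  vol <- tensor_volume(tensors, mask, vs)
  out <- list(volume = vol,
              ground_truth = list(eigenvalues = ev,
                                  fa = fractional_anisotropy(ev),
                                  fascicle_length = truth_len,
                                  direction = truth_dir,
                                  mask_volume = sum(mask) * vs^3))
  if (with_dwi) {
    g <- sphere_directions(spec$n_directions)
    X <- dti_design(g)
    idx <- which(mask == 1L, arr.ind = TRUE)
    dwi <- array(0, c(dm, spec$n_directions))
    s0 <- 1
    noise <- spec$noise_sd_signal
    with_seed(spec$seed, {
      for (r in seq_len(nrow(idx))) {
        d6 <- tensors[idx[r, 1], idx[r, 2], idx[r, 3], ]
        s <- s0 * exp(-spec$b_value * as.numeric(X %*% d6))
        if (noise > 0) {
          if (noise_model == "gaussian") {
            s <- s + stats::rnorm(length(s), 0, noise * s0)
          } else {
            s <- sqrt((s + stats::rnorm(length(s), 0, noise * s0))^2 +
                      stats::rnorm(length(s), 0, noise * s0)^2)
          }
        }
        dwi[idx[r, 1], idx[r, 2], idx[r, 3], ] <- s
      }
    })
    out$dwi <- dwi
    out$gradients <- g
    out$s0 <- s0
    out$b <- spec$b_value
  }
  out
}

# symmetric tensor with principal direction v (unit) and eigenvalues ev
tensor_from_dir <- function(v, ev) {
  v <- v / sqrt(sum(v^2))
  ev[2] * diag(3) + (ev[1] - ev[2]) * tcrossprod(v)
}

#' Write a phantom to NIfTI with a JSON ground-truth sidecar
#'
#' The tensor volume is stored as a 4-D NIfTI image of the six unique
#' upper-triangle components, the mask as a uint8 image, and the ground
#' truth as a JSON sidecar.
#'
#' @param phantom result of [simulate_phantom()].
#' @param prefix output path prefix; writes `<prefix>_tensor.nii.gz`,
#'   `<prefix>_mask.nii.gz`, `<prefix>_truth.json`.
#' @return invisible vector of file paths.
#' @export
write_phantom_nifti <- function(phantom, prefix) {
  vs <- phantom$volume$voxel_size
  tpath <- paste0(prefix, "_tensor.nii.gz")
  mpath <- paste0(prefix, "_mask.nii.gz")
  jpath <- paste0(prefix, "_truth.json")
  RNifti::writeNifti(RNifti::asNifti(phantom$volume$tensors,
                                     pixdim = c(vs, 1)), tpath)
  mask <- phantom$volume$mask
  storage.mode(mask) <- "integer"
  RNifti::writeNifti(RNifti::asNifti(mask, pixdim = vs, datatype = "uint8"),
                     mpath)
  gt <- phantom$ground_truth
  gt$direction <- if (all(is.na(gt$direction))) NULL else gt$direction
  jsonlite::write_json(gt, jpath, auto_unbox = TRUE, digits = NA)
  invisible(c(tpath, mpath, jpath))
}

#' Read a phantom written by [write_phantom_nifti()]
#' @param prefix path prefix used when writing.
#' @return list with `volume` and `ground_truth`.
#' @export
read_phantom_nifti <- function(prefix) {
  tens <- RNifti::readNifti(paste0(prefix, "_tensor.nii.gz"))
  mask <- RNifti::readNifti(paste0(prefix, "_mask.nii.gz"))
  vs <- RNifti::pixdim(mask)[1]
  gt <- jsonlite::read_json(paste0(prefix, "_truth.json"), simplifyVector = TRUE)
  list(volume = tensor_volume(unclass(tens), unclass(mask), vs),
       ground_truth = gt)
}
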