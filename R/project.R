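#' Construct a projection set
#'
#' Container for an angle-indexed stack of 2-D projections. Images are stored
#' as a 3-D array `(detector rows, detector columns, angles)`; pixel values
#' are line integrals of the attenuation (Radon transform values).
#'
#' @param images numeric 3-D array `(rows, cols, n_angles)`.
#' @param angles rotation angles in degrees over `[0, 180]`, one per image.
#' @param role one of `"clean"`, `"noisy"`, `"enhanced"`, `"measured_short"`,
#'   `"measured_long"`.
#' @param noise_level noise fraction (0 for clean data).
#' @param exposure_s exposure time in seconds, or `NULL` for synthetic data.
#' @export
projection_set <- function(images, angles,
                           role = c("clean", "noisy", "enhanced",
                                    "measured_short", "measured_long"),
                           noise_level = 0, exposure_s = NULL) {
  role <- match.arg(role)
  if (length(dim(images)) != 3) stop("images must be a 3-D array")
  if (dim(images)[3] != length(angles)) {
    stop("number of images must equal number of angles")
  }
  if (role == "noisy" && noise_level <= 0) {
    stop("role 'noisy' requires noise_level > 0")
  }
  structure(list(images = images, angles = as.numeric(angles), role = role,
                 noise_level = noise_level, exposure_s = exposure_s),
            class = "projection_set")
}

#' @export
print.projection_set <- function(x, ...) {
  d <- dim(x$images)
  cat("<projection_set> ", d[3], " x ", d[1], "x", d[2], " [", x$role, "]",
      if (x$noise_level > 0) paste0(" noise ", x$noise_level * 100, "%"),
      ", angles [", round(min(x$angles), 2), ", ", round(max(x$angles), 2),
      "] deg\n", sep = "")
  invisible(x)
}

#' Number of projections
#' @param ps a `projection_set`.
#' @export
n_projections <- function(ps) dim(ps$images)[3]

#' Forward Radon projection of a phantom
#'
#' Computes parallel-beam projections of the phantom at the requested angles,
#' slice by slice: the value at detector row z, column t of the projection at
#' angle theta is the line integral of the voxel values along the ray
#' `x cos(theta) + y sin(theta) = t` within slice z. Angles are degrees,
#' counter-clockwise, 0 along the +x axis; the detector pixel pitch equals the
#' voxel pitch and the rotation centre is the volume centre.
#'
#' Two evaluation paths give the same transform:
#' \describe{
#'   \item{`"discrete"`}{sums the voxel array, splatting each voxel linearly
#'     onto the two nearest detector bins. Works for any voxel content; the
#'     reference path.}
#'   \item{`"analytic"`}{evaluates the Radon transform of the *parametric*
#'     cube+spheres model in closed form (trapezoid chord for the square
#'     section, circle chord for each sphere). No voxelisation is needed, so
#'     it scales to large volumes; sphere chords are additive, so in the rare
#'     event of overlapping particles the overlap region is counted twice
#'     (a sub-percent effect at the benchmark's particle density).}
#' }
#'
#' @param phantom a `tomo_phantom`.
#' @param angles rotation angles in degrees within `[0, 180]`.
#' @param method `"auto"` (analytic for parametric phantoms, discrete
#'   otherwise), `"discrete"` or `"analytic"`.
#' @return a `projection_set` with role `"clean"`.
#' @examples
#' ph <- generate_phantom(32, 2, d_min = 4, d_max = 8, seed = 7)
#' ps <- forward_project(ph, seq(0, 180, by = 15))
#' @export
forward_project <- function(phantom, angles,
                            method = c("auto", "discrete", "analytic")) {
  stopifnot(inherits(phantom, "tomo_phantom"))
  method <- match.arg(method)
  if (length(angles) == 0) stop("empty angle list")
  if (any(angles < 0 | angles > 180)) stop("angles must lie within [0, 180]")
  if (method == "auto") {
    method <- if (is.null(phantom$voxels)) "analytic" else "discrete"
  }
  s <- phantom$size
  if (method == "discrete") {
    imgs <- cpp_forward_project(phantom_voxels(phantom), angles)
  } else {
    imgs <- array(0, dim = c(s, s, length(angles)))
    for (z in seq_len(s)) {
      imgs[z, , ] <- analytic_slice_sinogram(phantom, z, angles)
    }
  }
  projection_set(imgs, angles, role = "clean")
}

#' Closed-form sinogram of one phantom slice
#'
#' Radon transform of horizontal slice `z` of the parametric phantom at the
#' given angles, evaluated in closed form. Used by [forward_project()] and by
#' the streaming large-volume benchmark.
#'
#' @param phantom a `tomo_phantom`.
#' @param z slice index (1-based).
#' @param angles degrees within `[0, 180]`.
#' @return numeric matrix `(detector columns x angles)`.
#' @export
analytic_slice_sinogram <- function(phantom, z, angles) {
  stopifnot(inherits(phantom, "tomo_phantom"))
  sp <- phantom$spheres
  m <- cbind(sp$x, sp$y, sp$z, sp$d / 2)
  if (nrow(sp) == 0) m <- matrix(0, 0, 4)
  cpp_analytic_sino(m, phantom$cube_lo, phantom$cube_hi,
                    phantom$values[["cube"]], phantom$values[["particle"]],
                    z - 1, angles, phantom$size)
}

#' Add percentage-scaled Gaussian noise to clean projections
#'
#' Emulates a low-dose (short-exposure) acquisition by adding zero-mean
#' Gaussian noise to every pixel of a clean projection stack. The noise
#' standard deviation is `level * (max - min)` of the whole clean stack, so
#' "5% noise" means a sigma of 5% of the stack's global dynamic range, applied
#' identically to all projections.
#'
#' @param projections a `projection_set` with role `"clean"`.
#' @param level noise fraction in `[0, 1]`.
#' @param seed RNG seed; the realisation is deterministic given the seed.
#' @return a `projection_set` with role `"noisy"` (the input unchanged when
#'   `level` is 0).
#' @export
add_noise <- function(projections, level, seed = 1) {
  stopifnot(inherits(projections, "projection_set"))
  if (projections$role != "clean") stop("add_noise expects clean projections")
  if (level < 0) stop("noise level must be >= 0")
  if (level == 0) return(projections)
  rng <- range(projections$images)
  sigma <- level * (rng[2] - rng[1])
  noisy <- with_seed(seed, {
    projections$images + array(rnorm(length(projections$images), 0, sigma),
                               dim = dim(projections$images))
  })
  projection_set(noisy, projections$angles, role = "noisy",
                 noise_level = level)
}
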