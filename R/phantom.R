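#' Generate the synthetic sphere-in-cube phantom
#'
#' Builds the three-phase test object used throughout the synthetic benchmark:
#' empty space (gray value 0) surrounding a solid centred cube (0.3) that
#' contains randomly placed spherical particles (1.0). Sphere centres are
#' sampled uniformly inside the cube with a margin of one radius so every
#' particle lies fully inside the cube; diameters are uniform on
#' `[d_min, d_max]` and particles may overlap (later spheres overwrite earlier
#' ones in the voxelisation, which is immaterial since all particles share the
#' value 1).
#'
#' The cube edge is `round(cube_frac * size)` voxels; the default 0.625 is the
#' largest centred cube whose rotation diagonal stays comfortably inside the
#' detector width, so the object never leaves the field of view during a scan.
#'
#' For large volumes the phantom can stay *parametric* (`materialize = FALSE`):
#' all geometry is kept as a sphere table and voxels are produced on demand by
#' [phantom_voxels()], while projections can be computed in closed form by
#' [forward_project()] with `method = "analytic"`.
#'
#' @param size cube-volume edge length in voxels.
#' @param n_spheres number of spherical particles.
#' @param d_min,d_max particle diameter range in voxels.
#' @param seed integer RNG seed; the phantom is deterministic given the seed.
#' @param cube_frac cube edge as a fraction of `size`.
#' @param materialize build the voxel array now (default for `size <= 256`).
#' @return A `tomo_phantom` object: the voxel array (or `NULL` when
#'   parametric), `size`, cube index bounds, and a tibble of sphere
#'   parameters (`x`, `y`, `z` centre in 0-based voxel coordinates, `d`).
#' @examples
#' ph <- generate_phantom(48, 4, d_min = 4, d_max = 8, seed = 1)
#' table(phantom_voxels(ph))
#' @export
generate_phantom <- function(size, n_spheres, d_min = 4, d_max = 20, seed = 1,
                             cube_frac = 0.625,
                             materialize = size <= 256) {
  if (n_spheres < 0) stop("n_spheres must be >= 0")
  if (d_min <= 0 || d_min > d_max) stop("need 0 < d_min <= d_max")
  if (size < d_max) stop("phantom size must be at least d_max")
  cube_edge <- round(cube_frac * size)
  if (d_max > cube_edge) stop("d_max exceeds the cube edge (", cube_edge, ")")
  lo <- floor((size - cube_edge) / 2)          # 0-based voxel indices
  hi <- lo + cube_edge - 1
  spheres <- with_seed(seed, {
    d <- runif(n_spheres, d_min, d_max)
    r <- d / 2
    tibble::tibble(
      x = runif(n_spheres, lo - 0.5 + r, hi + 0.5 - r),
      y = runif(n_spheres, lo - 0.5 + r, hi + 0.5 - r),
      z = runif(n_spheres, lo - 0.5 + r, hi + 0.5 - r),
      d = d
    )
  })
  ph <- structure(
    list(size = size, cube_lo = lo, cube_hi = hi,
         values = c(background = 0, cube = 0.3, particle = 1),
         spheres = spheres, seed = seed, voxels = NULL),
    class = "tomo_phantom"
  )
  if (materialize) ph$voxels <- phantom_voxels(ph)
  ph
}

#' Voxelise a phantom
#'
#' Rasterises the parametric phantom onto its `size^3` grid: voxels whose
#' centre lies inside a sphere get value 1, remaining cube voxels 0.3,
#' everything else 0.
#'
#' @param phantom a `tomo_phantom`.
#' @return numeric 3-D array of dimension `c(size, size, size)`.
#' @export
phantom_voxels <- function(phantom) {
  stopifnot(inherits(phantom, "tomo_phantom"))
  if (!is.null(phantom$voxels)) return(phantom$voxels)
  s <- phantom$size
  v <- array(0, dim = c(s, s, s))
  idx <- (phantom$cube_lo:phantom$cube_hi) + 1L
  v[idx, idx, idx] <- phantom$values[["cube"]]
  sp <- phantom$spheres
  if (nrow(sp) > 0) {
    for (i in seq_len(nrow(sp))) {
      r <- sp$d[i] / 2
      xs <- max(0, floor(sp$x[i] - r)):min(s - 1, ceiling(sp$x[i] + r))
      ys <- max(0, floor(sp$y[i] - r)):min(s - 1, ceiling(sp$y[i] + r))
      zs <- max(0, floor(sp$z[i] - r)):min(s - 1, ceiling(sp$z[i] + r))
      dx2 <- (xs - sp$x[i])^2
      dy2 <- (ys - sp$y[i])^2
      dz2 <- (zs - sp$z[i])^2
      mask <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= r^2
      sub <- v[xs + 1L, ys + 1L, zs + 1L]
      sub[mask] <- phantom$values[["particle"]]
      v[xs + 1L, ys + 1L, zs + 1L] <- sub
    }
  }
  v
}

#' @export
print.tomo_phantom <- function(x, ...) {
  drange <- if (nrow(x$spheres) > 0) {
    paste0(" (d in [", round(min(x$spheres$d), 1), ", ",
           round(max(x$spheres$d), 1), "])")
  } else ""
  cat("<tomo_phantom> ", x$size, "^3, ", nrow(x$spheres), " spheres", drange,
      ", cube [", x$cube_lo, ", ", x$cube_hi, "], ",
      if (is.null(x$voxels)) "parametric" else "voxelised", "\n", sep = "")
  invisible(x)
}
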