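#' Two-step image normalization
#'
#' Standardises an image and rescales it onto `[0, 1]`:
#' step 1 subtracts the image mean and divides by its standard deviation
#' (`I1 = (I - mean(I)) / sd(I)`); step 2 maps the result affinely onto the
#' unit interval (`I2 = (I1 - min(I1)) / (max(I1) - min(I1))`). The returned
#' parameters allow exact inversion with [denormalize_two_step()]. The
#' composition is invariant to any positive affine rescaling of the input, so
#' projections taken at different exposures land on a common scale.
#'
#' @param image numeric matrix with at least two distinct values.
#' @return list with `image` (normalized matrix, min 0 and max 1) and
#'   `params` (`mean`, `sd`, `post_min`, `post_max`).
#' @export
normalize_two_step <- function(image) {
  stop_if_not_matrix(image, "image")
  mu <- mean(image)
  sigma <- sd(image)
  if (!is.finite(sigma) || sigma == 0) {
    stop("constant image: two-step normalization needs sd > 0")
  }
  i1 <- (image - mu) / sigma
  mn <- min(i1)
  mx <- max(i1)
  list(image = (i1 - mn) / (mx - mn),
       params = list(mean = mu, sd = sigma, post_min = mn, post_max = mx))
}

# apply an existing normalization (e.g. the low-dose image's) to another
# image of the same scene, so input and target share one intensity frame
apply_normalization <- function(image, params) {
  i1 <- (image - params$mean) / params$sd
  (i1 - params$post_min) / (params$post_max - params$post_min)
}

#' Invert the two-step normalization
#'
#' @param image normalized matrix.
#' @param params parameter list returned by [normalize_two_step()].
#' @return matrix on the original intensity scale.
#' @export
denormalize_two_step <- function(image, params) {
  i1 <- image * (params$post_max - params$post_min) + params$post_min
  i1 * params$sd + params$mean
}

# 1-based anchor positions along one dimension; the final anchor is clamped
# to the edge so the last row/column is always covered
patch_anchors <- function(extent, patch_edge, stride) {
  last <- extent - patch_edge + 1L
  a <- seq.int(1L, last, by = stride)
  if (a[length(a)] != last) a <- c(a, last)
  a
}

#' Extract overlapping patches from an image
#'
#' Decomposes an image into overlapping square patches on a regular anchor
#' grid (anchors advance by `stride`; a final anchor is clamped to the image
#' edge so every pixel is covered). The returned grid records the anchors for
#' [reassemble_patches()]. A couple of projections decomposed at a small
#' stride yield the ~1e5 training examples that make few-angle training
#' feasible.
#'
#' @param image numeric matrix.
#' @param patch_edge patch side length in pixels; must be a multiple of 8 so
#'   the network's three 2x2-stride stages divide it evenly.
#' @param stride anchor step in pixels (>= 1).
#' @return list with `patches` (array `patch_edge x patch_edge x n`) and
#'   `grid` (a `patch_grid`).
#' @export
extract_patches <- function(image, patch_edge = 64, stride = 16) {
  stop_if_not_matrix(image, "image")
  if (patch_edge %% 8 != 0) stop("patch_edge must be a multiple of 8")
  if (stride < 1) stop("stride must be >= 1")
  d <- dim(image)
  if (patch_edge > min(d)) stop("patch_edge exceeds image size")
  ra <- patch_anchors(d[1], patch_edge, stride)
  ca <- patch_anchors(d[2], patch_edge, stride)
  anchors <- expand.grid(row = ra, col = ca, KEEP.OUT.ATTRS = FALSE)
  n <- nrow(anchors)
  patches <- array(0, dim = c(patch_edge, patch_edge, n))
  for (i in seq_len(n)) {
    r <- anchors$row[i]; c <- anchors$col[i]
    patches[, , i] <- image[r:(r + patch_edge - 1), c:(c + patch_edge - 1)]
  }
  grid <- structure(list(patch_edge = patch_edge, stride = stride,
                         anchors = tibble::as_tibble(anchors),
                         source_shape = d),
                    class = "patch_grid")
  list(patches = patches, grid = grid)
}

#' Reassemble an image from overlapping patches
#'
#' Inverse of [extract_patches()]: every output pixel is the plain average of
#' all patches covering it, which makes extract-then-reassemble an exact
#' identity for untouched patches.
#'
#' @param patches array `patch_edge x patch_edge x n`.
#' @param grid the `patch_grid` returned by [extract_patches()].
#' @return numeric matrix of the original image shape.
#' @export
reassemble_patches <- function(patches, grid) {
  stopifnot(inherits(grid, "patch_grid"))
  e <- grid$patch_edge
  if (any(dim(patches)[1:2] != e) ||
      dim(patches)[3] != nrow(grid$anchors)) {
    stop("patch stack does not match the grid")
  }
  acc <- matrix(0, grid$source_shape[1], grid$source_shape[2])
  cnt <- matrix(0, grid$source_shape[1], grid$source_shape[2])
  for (i in seq_len(dim(patches)[3])) {
    r <- grid$anchors$row[i]; c <- grid$anchors$col[i]
    ri <- r:(r + e - 1); ci <- c:(c + e - 1)
    acc[ri, ci] <- acc[ri, ci] + patches[, , i]
    cnt[ri, ci] <- cnt[ri, ci] + 1
  }
  acc / cnt
}
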