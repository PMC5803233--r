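#' Enhance a projection stack with a trained network
#'
#' Applies the trained image-to-image network to every projection: each image
#' is normalized with the two-step scheme, decomposed into overlapping
#' patches, pushed through the network, reassembled by overlap averaging, and
#' de-normalized with the *same* parameters estimated from that input image —
#' so the enhanced stack returns to the input's physical intensity scale.
#' Geometry and angle list are preserved.
#'
#' @param model a trained `tomo_cnn`.
#' @param projections a `projection_set` to enhance.
#' @param patch_stride inference anchor stride; defaults to half the patch
#'   edge, a good trade between overlap averaging and speed.
#' @param batch_size forward-pass batch size.
#' @return a `projection_set` with role `"enhanced"`.
#' @export
enhance <- function(model, projections,
                    patch_stride = model$patch_edge / 2, batch_size = 64) {
  stopifnot(inherits(model, "tomo_cnn"),
            inherits(projections, "projection_set"))
  if (!model$trained) stop("model is untrained; call train_cnn() first")
  e <- model$patch_edge
  imgs <- projections$images
  out <- array(0, dim = dim(imgs))
  for (k in seq_len(dim(imgs)[3])) {
    nz <- normalize_two_step(imgs[, , k])
    px <- extract_patches(nz$image, e, patch_stride)
    n <- dim(px$patches)[3]
    pred <- predict_batched(model, matrix(px$patches, e * e, n), batch_size)
    rec <- reassemble_patches(array(pred, dim = c(e, e, n)), px$grid)
    out[, , k] <- denormalize_two_step(rec, nz$params)
  }
  projection_set(out, projections$angles, role = "enhanced",
                 noise_level = projections$noise_level,
                 exposure_s = projections$exposure_s)
}
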