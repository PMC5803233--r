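#' Write a float32 multi-page TIFF
#'
#' Minimal little-endian uncompressed TIFF writer storing one 32-bit IEEE
#' float grayscale page per matrix (SampleFormat 3). Written because CRAN
#' TIFF bindings clamp float samples to `[0, 1]`, which would destroy
#' line-integral-scale projection data.
#'
#' @param images list of numeric matrices (or a 3-D array, pages along the
#'   third dimension), all of one shape.
#' @param path output file.
#' @export
write_float_tiff <- function(images, path) {
  if (is.array(images) && length(dim(images)) == 3) {
    images <- lapply(seq_len(dim(images)[3]), function(k) images[, , k])
  }
  stopifnot(length(images) >= 1)
  h <- nrow(images[[1]]); w <- ncol(images[[1]])
  npages <- length(images)
  data_bytes <- h * w * 4
  ifd_bytes <- 2 + 10 * 12 + 4
  page_bytes <- data_bytes + ifd_bytes
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(c(42L), con, size = 2, endian = "little")
  writeBin(as.integer(8 + data_bytes), con, size = 4, endian = "little")
  entry <- function(tag, type, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(1L, con, size = 4, endian = "little")
    if (type == 3) {  # SHORT padded to 4 bytes
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  for (p in seq_len(npages)) {
    m <- images[[p]]
    if (nrow(m) != h || ncol(m) != w) stop("inconsistent page shapes")
    writeBin(as.numeric(t(m)), con, size = 4, endian = "little")
    data_off <- 8 + (p - 1) * page_bytes
    writeBin(10L, con, size = 2, endian = "little")
    entry(256, 4, w)                    # ImageWidth
    entry(257, 4, h)                    # ImageLength
    entry(258, 3, 32)                   # BitsPerSample
    entry(259, 3, 1)                    # Compression: none
    entry(262, 3, 1)                    # Photometric: BlackIsZero
    entry(273, 4, data_off)             # StripOffsets
    entry(277, 3, 1)                    # SamplesPerPixel
    entry(278, 4, h)                    # RowsPerStrip
    entry(279, 4, data_bytes)           # StripByteCounts
    entry(339, 3, 3)                    # SampleFormat: IEEE float
    next_ifd <- if (p < npages) 8 + p * page_bytes + data_bytes else 0
    writeBin(as.integer(next_ifd), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a float32 multi-page TIFF
#'
#' Reads files produced by [write_float_tiff()] (and any little-endian
#' uncompressed single-sample float/int TIFF with one strip per page).
#'
#' @param path file path.
#' @return list of numeric matrices, one per page.
#' @export
read_float_tiff <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  u16 <- function(off) sum(as.integer(raw[off + 1:2]) * c(1, 256))
  u32 <- function(off) sum(as.numeric(raw[off + 1:4]) * c(1, 256, 65536,
                                                          16777216))
  if (rawToChar(raw[1:2]) != "II" || u16(2) != 42) {
    stop("not a little-endian TIFF")
  }
  ifd <- u32(4)
  pages <- list()
  while (ifd != 0) {
    n <- u16(ifd)
    tags <- list()
    for (i in seq_len(n)) {
      e <- ifd + 2 + (i - 1) * 12
      tag <- u16(e); type <- u16(e + 2)
      val <- if (type == 3) u16(e + 8) else u32(e + 8)
      tags[[as.character(tag)]] <- val
    }
    w <- tags[["256"]]; h <- tags[["257"]]
    if ((tags[["259"]] %||% 1) != 1) stop("compressed TIFF not supported")
    if ((tags[["258"]] %||% 32) != 32 || (tags[["339"]] %||% 3) != 3) {
      stop("only 32-bit float samples supported")
    }
    off <- tags[["273"]]
    v <- readBin(raw[off + seq_len(h * w * 4)], "numeric", n = h * w,
                 size = 4, endian = "little")
    pages[[length(pages) + 1]] <- matrix(v, h, w, byrow = TRUE)
    ifd <- u32(ifd + 2 + n * 12)
  }
  pages
}

#' Write a projection stack to disk
#'
#' TIFF path (`.tif`/`.tiff`): one float32 page per angle plus two sidecars,
#' `<path>.angles.txt` (one angle in degrees per line) and `<path>.meta.json`
#' (role, noise level, exposure). HDF5 path (`.h5`/`.hdf5`): Scientific Data
#' Exchange layout with `/exchange/data` (angle x row x column) and
#' `/exchange/theta` in degrees, written through the environment's Python
#' h5py.
#'
#' @param projections a `projection_set`.
#' @param path output file; the extension selects the format.
#' @export
write_stack <- function(projections, path) {
  stopifnot(inherits(projections, "projection_set"))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("h5", "hdf5", "hdf")) {
    return(write_stack_h5(projections, path))
  }
  imgs <- projections$images
  write_float_tiff(imgs, path)
  writeLines(format(projections$angles, digits = 12),
             paste0(path, ".angles.txt"))
  jsonlite::write_json(
    list(role = projections$role, noise_level = projections$noise_level,
         exposure_s = projections$exposure_s),
    paste0(path, ".meta.json"), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Read a projection stack from disk
#'
#' Inverse of [write_stack()]: multi-page TIFF plus `.angles.txt` sidecar, or
#' HDF5 Scientific Data Exchange (`/exchange/data`, `/exchange/theta`; a
#' `units` attribute of `"radian"`/`"rad"` on theta is converted to degrees).
#' Pixels are returned as numeric (values were stored as 32-bit float).
#'
#' @param path stack file.
#' @return a `projection_set`.
#' @export
read_stack <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("h5", "hdf5", "hdf")) return(read_stack_h5(path))
  pages <- read_float_tiff(path)
  afile <- paste0(path, ".angles.txt")
  if (!file.exists(afile)) stop("missing angle sidecar ", afile)
  angles <- as.numeric(readLines(afile))
  if (length(angles) != length(pages)) {
    stop("angle count does not match page count")
  }
  meta <- list(role = "clean", noise_level = 0, exposure_s = NULL)
  mfile <- paste0(path, ".meta.json")
  if (file.exists(mfile)) {
    meta <- modifyList(meta, jsonlite::read_json(mfile, simplifyVector = TRUE))
  }
  imgs <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]),
                           length(pages)))
  for (k in seq_along(pages)) imgs[, , k] <- pages[[k]]
  projection_set(imgs, angles, role = meta$role,
                 noise_level = meta$noise_level %||% 0,
                 exposure_s = meta$exposure_s)
}

find_python <- function() {
  for (cand in c("python", "python3")) {
    p <- Sys.which(cand)
    if (nzchar(p)) return(p)
  }
  stop("no python interpreter found on PATH (needed for HDF5 IO)")
}

sdx_bridge <- function() {
  system.file("python", "sdx_bridge.py", package = "tomodenoise",
              mustWork = TRUE)
}

write_stack_h5 <- function(projections, path, units = "degree") {
  d <- dim(projections$images)
  tmp <- tempfile(fileext = ".bin")
  on.exit(unlink(tmp))
  con <- file(tmp, "wb")
  # (angle, row, col) C-order = col fastest: write per angle, row-major page
  for (k in seq_len(d[3])) {
    writeBin(as.numeric(t(projections$images[, , k])), con, size = 4,
             endian = "little")
  }
  close(con)
  theta <- paste(format(projections$angles, digits = 12), collapse = ",")
  status <- system2(find_python(),
                    c(sdx_bridge(), "write", shQuote(path), shQuote(tmp),
                      d[3], d[1], d[2], shQuote(theta), units),
                    stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(status, "status"))) {
    stop("HDF5 write failed: ", paste(status, collapse = "\n"))
  }
  invisible(path)
}

read_stack_h5 <- function(path) {
  tmp <- tempfile(fileext = ".bin")
  on.exit(unlink(tmp))
  out <- system2(find_python(), c(sdx_bridge(), "read", shQuote(path),
                                  shQuote(tmp)),
                 stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(out, "status"))) {
    stop("HDF5 read failed: ", paste(out, collapse = "\n"))
  }
  hdr <- jsonlite::fromJSON(paste(out, collapse = ""))
  d <- as.integer(hdr$shape)  # (angles, rows, cols)
  v <- readBin(tmp, "numeric", n = prod(d), size = 4, endian = "little")
  imgs <- array(0, dim = c(d[2], d[3], d[1]))
  arr <- aperm(array(v, dim = c(d[3], d[2], d[1])), c(2, 1, 3))
  imgs[] <- arr
  theta <- as.numeric(hdr$theta)
  if (!is.null(hdr$units) && grepl("^rad", tolower(hdr$units))) {
    theta <- theta * 180 / pi
  }
  projection_set(imgs, theta, role = "measured_short")
}
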