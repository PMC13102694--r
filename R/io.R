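## Volume I/O: multi-page 32-bit float TIFF (baseline, uncompressed,
## little-endian) plus a JSON sidecar carrying voxel spacing and channel
## names. No TIFF package is available in this R stack, so a minimal
## baseline reader/writer is provided; it round-trips its own files and
## reads uncompressed single-strip-per-row or whole-page-strip grayscale
## TIFFs (8/16-bit unsigned, 32-bit float).

sidecar_path <- function(path) paste0(path, ".json")

#' Write a multi-channel volume as multi-page TIFF + JSON sidecar
#'
#' Pages are written channel-major (all z-slices of channel 1, then
#' channel 2, ...) as 32-bit float. The sidecar records `spacing_um`,
#' `channels` and `shape`.
#'
#' @param vol an [image_volume()].
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  dims <- vol$dim # (nz, ny, nx)
  con <- file(path, "wb")
  on.exit(close(con))
  w <- function(x, size) writeBin(as.integer(x), con, size = size,
                                  endian = "little")
  # header
  writeChar("II", con, eos = NULL)
  w(42L, 2)
  w(0L, 4) # first-IFD offset, patched after the pages are written
  n_pages <- length(vol$channels) * dims[1]
  height <- dims[2]; width <- dims[3]
  page_bytes <- height * width * 4
  n_tags <- 9L
  ifd_bytes <- 2 + n_tags * 12 + 4
  # layout: header(8) | for each page: pixel data then IFD
  offset <- 8
  page_offsets <- offset + (seq_len(n_pages) - 1) * (page_bytes + ifd_bytes)
  for (p in seq_len(n_pages)) {
    ch <- (p - 1) %/% dims[1] + 1
    z <- (p - 1) %% dims[1] + 1
    slice <- vol$data[[ch]][z, , ] # ny x nx
    # TIFF samples are row-major: row y holds slice[y, 1..nx]
    writeBin(as.numeric(t(slice)), con, size = 4, endian = "little")
    tag <- function(id, type, count, value) {
      w(id, 2); w(type, 2); w(count, 4)
      if (type == 3 && count == 1) { w(value, 2); w(0L, 2) } else w(value, 4)
    }
    w(n_tags, 2)
    tag(256, 3, 1, width)                    # ImageWidth
    tag(257, 3, 1, height)                   # ImageLength
    tag(258, 3, 1, 32L)                      # BitsPerSample
    tag(259, 3, 1, 1L)                       # Compression: none
    tag(262, 3, 1, 1L)                       # Photometric: BlackIsZero
    tag(273, 4, 1, page_offsets[p])          # StripOffsets
    tag(277, 3, 1, 1L)                       # SamplesPerPixel
    tag(279, 4, 1, page_bytes)               # StripByteCounts
    tag(339, 3, 1, 3L)                       # SampleFormat: IEEE float
    next_ifd <- if (p < n_pages) page_offsets[p + 1] + page_bytes else 0
    w(next_ifd, 4)
  }
  # fix first IFD offset in the header
  seek(con, 4, rw = "write")
  w(page_offsets[1] + page_bytes, 4)
  jsonlite::write_json(list(spacing_um = vol$spacing,
                            channels = vol$channels,
                            shape = as.integer(dims)),
                       sidecar_path(path), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

read_uint <- function(con, size) {
  if (size == 4) {
    lo <- readBin(con, "integer", size = 2, signed = FALSE,
                  endian = "little")
    hi <- readBin(con, "integer", size = 2, signed = FALSE,
                  endian = "little")
    lo + hi * 65536
  } else {
    readBin(con, "integer", size = size, signed = FALSE, endian = "little")
  }
}

read_tiff_pages <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2)
  if (!identical(magic, "II")) stop("unreadable file (not little-endian TIFF)")
  if (read_uint(con, 2) != 42) stop("unreadable file (bad TIFF magic)")
  ifd_off <- read_uint(con, 4)
  pages <- list()
  while (ifd_off != 0) {
    seek(con, ifd_off)
    n_tags <- read_uint(con, 2)
    tags <- list()
    for (i in seq_len(n_tags)) {
      id <- read_uint(con, 2)
      type <- read_uint(con, 2)
      count <- read_uint(con, 4)
      type_size <- c(1, 1, 2, 4, 8, 1, 1, 2, 4, 8, 4, 8)[type]
      if (count * type_size <= 4) {
        if (type == 3 && count == 1) {
          val <- read_uint(con, 2); read_uint(con, 2)
        } else if (count == 1) {
          val <- read_uint(con, 4)
        } else {
          val <- vapply(seq_len(count), function(j)
            read_uint(con, type_size), 1)
          pad <- 4 - count * type_size
          if (pad > 0) readBin(con, "raw", pad)
        }
      } else {
        off <- read_uint(con, 4)
        here <- seek(con)
        seek(con, off)
        val <- vapply(seq_len(count), function(j)
          read_uint(con, min(type_size, 4)), 1)
        seek(con, here)
      }
      tags[[as.character(id)]] <- val
    }
    next_ifd <- read_uint(con, 4)
    g <- function(id, default = NULL) tags[[as.character(id)]] %||% default
    width <- g(256); height <- g(257)
    bits <- g(258, 8)[1]
    if (g(259, 1) != 1) stop("unreadable file: compressed TIFF not supported")
    fmt <- g(339, 1)[1]
    offsets <- g(273)
    counts <- g(279, width * height * bits / 8)
    vals <- numeric(0)
    for (s in seq_along(offsets)) {
      seek(con, offsets[s])
      nsamp <- counts[s] / (bits / 8)
      v <- if (fmt == 3 && bits == 32) {
        readBin(con, "numeric", n = nsamp, size = 4, endian = "little")
      } else if (bits == 8) {
        readBin(con, "integer", n = nsamp, size = 1, signed = FALSE,
                endian = "little")
      } else if (bits == 16) {
        readBin(con, "integer", n = nsamp, size = 2, signed = FALSE,
                endian = "little")
      } else stop("unreadable file: unsupported TIFF sample format")
      vals <- c(vals, v)
    }
    pages[[length(pages) + 1L]] <- matrix(vals, nrow = height,
                                          ncol = width, byrow = TRUE)
    ifd_off <- next_ifd
  }
  pages
}

#' Read a multi-channel volume (multi-page TIFF + JSON sidecar)
#'
#' @param path `.tif` path; voxel spacing must be available from the
#'   sidecar `<path>.json` (`spacing_um`; optional `channels`, `shape`).
#' @return An [image_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("unreadable file: ", path)
  sc_path <- sidecar_path(path)
  if (!file.exists(sc_path))
    stop("missing spacing: no sidecar JSON found at ", sc_path)
  sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  if (is.null(sc$spacing_um))
    stop("missing spacing: sidecar has no `spacing_um`")
  pages <- read_tiff_pages(path)
  n_pages <- length(pages)
  nz <- if (!is.null(sc$shape)) sc$shape[1] else n_pages
  nc <- n_pages / nz
  if (nc != round(nc)) stop("page count inconsistent with sidecar shape")
  nc <- as.integer(nc)
  if (nz < 2) stop("dimension error: expected a 3D volume (>= 2 z-slices)")
  channels <- sc$channels
  auto_named <- FALSE
  if (is.null(channels) || length(channels) != nc) {
    channels <- paste0("ch", seq_len(nc) - 1L)
    auto_named <- TRUE
  }
  height <- nrow(pages[[1]]); width <- ncol(pages[[1]])
  data <- lapply(seq_len(nc), function(ci) {
    arr <- array(0, c(nz, height, width))
    for (z in seq_len(nz)) arr[z, , ] <- pages[[(ci - 1) * nz + z]]
    arr
  })
  names(data) <- channels
  if (auto_named) {
    vol <- image_volume(data, spacing = sc$spacing_um, channels = channels)
    warning("missing channel names; auto-named ", paste(channels,
                                                        collapse = ", "))
    vol
  } else {
    image_volume(data, spacing = sc$spacing_um, channels = channels)
  }
}

#' Write a label volume as multi-page 16-bit TIFF + sidecar
#' @param lab a [label_volume()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(lab, path) {
  vol <- image_volume(list(labels = lab$labels * 1.0), lab$spacing,
                      channels = "labels")
  write_volume(vol, path)
}
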