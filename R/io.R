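# File I/O: multi-page 16-bit TIFF stacks (plane order z ascending), CSV
# tables with a provenance comment header, and JSON configs.  The TIFF
# codec is deliberately minimal — baseline little-endian, uncompressed,
# single-sample grayscale — because no TIFF package is available in the
# target environment; it round-trips its own output and reads equivalent
# exports from common tools.

#' Write a volume as a multi-page 16-bit TIFF stack
#'
#' Planes are written in ascending z.  Intensities are clamped to
#' `[0, 65535]` and rounded.
#'
#' @param volume an [lc_volume()], [lc_mask()] or [region_mask()] (masks
#'   and labels are written as integer grayscale).
#' @param path output file.
#' @export
write_tiff_stack <- function(volume, path) {
  a <- if (inherits(volume, "lc_regionmask")) volume$labels else volume$data
  stopifnot(is.array(a), length(dim(a)) == 3)
  a <- round(pmin(pmax(a, 0), 65535))
  d <- dim(a) # (nz, ny, nx)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeBin(charToRaw("II"), con)
  w2(42L)
  n_entries <- 9L
  ifd_bytes <- 2 + n_entries * 12 + 4
  plane_bytes <- nx * ny * 2
  # layout: 8-byte header, then per plane: pixel data followed by its IFD
  data_off <- function(z) 8 + (z - 1) * (plane_bytes + ifd_bytes)
  ifd_off <- function(z) data_off(z) + plane_bytes
  w4(ifd_off(1))
  entry <- function(tag, type, count, value) {
    w2(tag); w2(type); w4(count); w4(value)
  }
  for (z in seq_len(nz)) {
    # a[z, , ] is [y, x]; TIFF strips are row-major (x fastest within row y)
    px <- as.integer(t(matrix(a[z, , ], ny, nx)))
    writeBin(px, con, size = 2, endian = "little")
    w2(n_entries)
    entry(256L, 3L, 1L, nx)               # ImageWidth
    entry(257L, 3L, 1L, ny)               # ImageLength
    entry(258L, 3L, 1L, 16L)              # BitsPerSample
    entry(259L, 3L, 1L, 1L)               # Compression: none
    entry(262L, 3L, 1L, 1L)               # Photometric: BlackIsZero
    entry(273L, 4L, 1L, data_off(z))      # StripOffsets
    entry(277L, 3L, 1L, 1L)               # SamplesPerPixel
    entry(278L, 3L, 1L, ny)               # RowsPerStrip
    entry(279L, 4L, 1L, plane_bytes)      # StripByteCounts
    w4(if (z < nz) ifd_off(z + 1) else 0L)
  }
  invisible(path)
}

#' Read a multi-page grayscale TIFF stack
#'
#' Supports baseline uncompressed little- or big-endian grayscale TIFF with
#' 8 or 16 bits per sample (the format written by [write_tiff_stack()]).
#'
#' @param path TIFF file.
#' @param voxel_size_um voxel size to attach.
#' @param channel channel name for the returned [lc_volume()].
#' @return an [lc_volume()].
#' @export
read_tiff_stack <- function(path, voxel_size_um = c(2, 1.51, 1.51),
                            channel = "TH") {
  raw <- readBin(path, "raw", file.size(path))
  endian <- if (rawToChar(raw[1:2]) == "II") "little" else "big"
  rd <- function(off, size, n = 1, signed = TRUE)
    readBin(raw[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = endian, signed = signed)
  magic <- rd(2, 2, signed = FALSE)
  if (magic != 42) stop("not a baseline TIFF file")
  ifd <- rd(4, 4)
  planes <- list()
  while (ifd != 0) {
    n_ent <- rd(ifd, 2, signed = FALSE)
    tags <- list()
    for (e in seq_len(n_ent)) {
      base <- ifd + 2 + (e - 1) * 12
      tag <- rd(base, 2, signed = FALSE)
      type <- rd(base + 2, 2, signed = FALSE)
      count <- rd(base + 4, 4)
      val <- if (type == 3 && count == 1) rd(base + 8, 2, signed = FALSE)
             else rd(base + 8, 4)
      tags[[as.character(tag)]] <- c(value = val, type = type, count = count)
    }
    gettag <- function(t, default = NULL) {
      v <- tags[[as.character(t)]]
      if (is.null(v)) default else unname(v["value"])
    }
    nx <- gettag(256); ny <- gettag(257)
    bits <- gettag(258, 8)
    comp <- gettag(259, 1)
    if (comp != 1) stop("compressed TIFF not supported")
    spp <- gettag(277, 1)
    if (spp != 1) stop("multi-sample TIFF not supported")
    off <- gettag(273)
    cnt_tag <- tags[["273"]]
    n_strips <- unname(cnt_tag["count"])
    offs <- if (n_strips == 1) off else rd(off, 4, n = n_strips)
    bts <- tags[["279"]]
    bcs <- if (is.null(bts)) nx * ny * bits / 8
           else if (unname(bts["count"]) == 1) unname(bts["value"])
           else rd(unname(bts["value"]), 4, n = n_strips)
    px <- integer(0)
    for (s in seq_len(n_strips)) {
      nbytes <- if (length(bcs) == 1) bcs else bcs[s]
      npx <- nbytes / (bits / 8)
      px <- c(px, readBin(raw[(offs[s] + 1):(offs[s] + nbytes)], "integer",
                          n = npx, size = bits / 8, endian = endian,
                          signed = FALSE))
    }
    planes[[length(planes) + 1]] <- matrix(px, nrow = nx, ncol = ny)[, , drop = FALSE]
    ifd <- rd(ifd + 2 + n_ent * 12, 4)
  }
  nz <- length(planes)
  nx <- nrow(planes[[1]]); ny <- ncol(planes[[1]])
  a <- array(0, dim = c(nz, ny, nx))
  for (z in seq_len(nz)) a[z, , ] <- t(planes[[z]])
  lc_volume(a, voxel_size_um, channel)
}

#' Write a table as CSV with a provenance comment header
#'
#' First line: `# lctau seed=<seed> config_hash=<hash>`; then a standard
#' header row.  Comma separator, '.' decimal, UTF-8.
#'
#' @param tbl data frame.
#' @param path output file.
#' @param seed,config_hash provenance recorded in the header.
#' @export
write_table_csv <- function(tbl, path, seed = NA, config_hash = "") {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# lctau seed=%s config_hash=%s", seed, config_hash), con)
  utils::write.table(tbl, con, sep = ",", row.names = FALSE, qmethod = "double")
  invisible(path)
}

#' Read a CSV written by [write_table_csv()]
#' @param path CSV file.
#' @return data frame; provenance available as attribute `"provenance"`.
#' @export
read_table_csv <- function(path) {
  first <- readLines(path, n = 1)
  out <- utils::read.csv(path, comment.char = "#")
  attr(out, "provenance") <- sub("^# *", "", first)
  out
}

# md5 of the canonical JSON serialization of a config (provenance hash)
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Write a configuration object as JSON
#' @param cfg configuration list (e.g. a [phantom_config()]).
#' @param path output file.
#' @export
write_json_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  invisible(path)
}
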