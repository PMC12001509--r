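# Minimal baseline-TIFF support: uncompressed grayscale, 8- or 16-bit,
# multi-page, single sample per pixel. The environment provides no TIFF
# package, so the few tags the pipeline needs are read and written here;
# the writer emits little-endian files, the reader accepts both byte
# orders and multi-strip layouts. Cross-validated against Python
# `tifffile` in the test suite.

TIFF_TAGS <- c(width = 256L, length = 257L, bits = 258L, compression = 259L,
               photometric = 262L, strip_offsets = 273L, spp = 277L,
               rows_per_strip = 278L, strip_bytes = 279L)

# -- low-level byte helpers (offsets are 0-based) ---------------------------

rd_uint <- function(raw, off, size, endian) {
  b <- raw[(off + 1):(off + size)]
  if (size == 2L) {
    readBin(b, "integer", n = 1L, size = 2L, signed = FALSE, endian = endian)
  } else {
    v <- readBin(b, "integer", n = 1L, size = 4L, signed = TRUE, endian = endian)
    if (v < 0) stop("TIFF offset beyond 2 GiB is not supported")
    v
  }
}

rd_uint_vec <- function(raw, off, n, size, endian) {
  b <- raw[(off + 1):(off + n * size)]
  if (size == 2L) {
    readBin(b, "integer", n = n, size = 2L, signed = FALSE, endian = endian)
  } else {
    v <- readBin(b, "integer", n = n, size = 4L, signed = TRUE, endian = endian)
    if (any(v < 0)) stop("TIFF offset beyond 2 GiB is not supported")
    v
  }
}

# value field of one IFD entry -> integer vector
tiff_entry_values <- function(raw, entry_off, endian) {
  type <- rd_uint(raw, entry_off + 2, 2L, endian)
  count <- rd_uint(raw, entry_off + 4, 4L, endian)
  size <- switch(as.character(type), "1" = 1L, "3" = 2L, "4" = 4L, NA_integer_)
  if (is.na(size)) return(NULL)  # type we do not interpret
  total <- size * count
  val_off <- if (total <= 4L) entry_off + 8 else rd_uint(raw, entry_off + 8, 4L, endian)
  if (size == 1L) {
    as.integer(raw[(val_off + 1):(val_off + count)])
  } else {
    rd_uint_vec(raw, val_off, count, size, endian)
  }
}

#' Read a grayscale multi-page TIFF
#'
#' Supports uncompressed baseline TIFF, 8- or 16-bit unsigned, one sample
#' per pixel, either byte order, one or more strips per page.
#'
#' @param path path to the TIFF file.
#' @return a list with one element per page: `pixels` (integer matrix,
#'   row/column indexed) and `bit_depth`.
#' @export
read_tiff <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 8) stop("not a TIFF file (too short): ", path)
  order <- rawToChar(raw[1:2])
  endian <- if (order == "II") "little" else if (order == "MM") "big" else
    stop("not a TIFF file (bad byte-order mark): ", path)
  if (rd_uint(raw, 2, 2L, endian) != 42L)
    stop("not a TIFF file (bad magic number): ", path)

  pages <- list()
  ifd <- rd_uint(raw, 4, 4L, endian)
  while (ifd != 0L) {
    n_entries <- rd_uint(raw, ifd, 2L, endian)
    tags <- list()
    for (k in seq_len(n_entries)) {
      eo <- ifd + 2 + (k - 1) * 12
      tag <- rd_uint(raw, eo, 2L, endian)
      if (tag %in% TIFF_TAGS) tags[[as.character(tag)]] <- tiff_entry_values(raw, eo, endian)
    }
    g <- function(id, default = NULL) tags[[as.character(id)]] %||% default

    width <- g(256L); height <- g(257L)
    if (is.null(width) || is.null(height)) stop("TIFF page lacks dimensions: ", path)
    bits <- g(258L, 1L)[1]
    if (!bits %in% c(8L, 16L))
      stop("unsupported TIFF bit depth ", bits, " in ", path)
    if (g(259L, 1L)[1] != 1L) stop("compressed TIFF not supported: ", path)
    if (g(277L, 1L)[1] != 1L) stop("only single-sample (grayscale) TIFF supported: ", path)
    offs <- g(273L); bytes <- g(279L)
    if (is.null(offs)) stop("TIFF page lacks strip offsets: ", path)
    if (is.null(bytes)) bytes <- rep((bits / 8) * width * height / length(offs), length(offs))

    data <- raw(0)
    for (s in seq_along(offs))
      data <- c(data, raw[(offs[s] + 1):(offs[s] + bytes[s])])
    vals <- if (bits == 16L) {
      readBin(data, "integer", n = width * height, size = 2L,
              signed = FALSE, endian = endian)
    } else {
      as.integer(data[seq_len(width * height)])
    }
    pages[[length(pages) + 1]] <- list(
      pixels = matrix(vals, nrow = height, ncol = width, byrow = TRUE),
      bit_depth = bits)
    ifd <- rd_uint(raw, ifd + 2 + n_entries * 12, 4L, endian)
  }
  pages
}

# one 12-byte IFD entry; type 3 = SHORT, 4 = LONG
wr_entry <- function(con, tag, type, value) {
  writeBin(as.integer(tag), con, size = 2L, endian = "little")
  writeBin(as.integer(type), con, size = 2L, endian = "little")
  writeBin(1L, con, size = 4L, endian = "little")
  if (type == 3L) {
    v <- as.integer(value)
    if (v > 32767L) v <- v - 65536L
    writeBin(v, con, size = 2L, endian = "little")
    writeBin(0L, con, size = 2L, endian = "little")
  } else {
    writeBin(as.integer(value), con, size = 4L, endian = "little")
  }
}

#' Write a grayscale multi-page 16-bit TIFF
#'
#' @param pages a single integer matrix or a list of integer matrices
#'   (values in `[0, 65535]`); each matrix becomes one page.
#' @param path output path; written atomically (temp file + rename).
#' @return `path`, invisibly.
#' @export
write_tiff <- function(pages, path) {
  if (is.matrix(pages)) pages <- list(pages)
  for (p in pages) {
    if (!is.matrix(p)) stop("each page must be a matrix")
    if (min(p) < 0 || max(p) > 65535) stop("pixel values must be in [0, 65535]")
  }
  n_entries <- 9L
  ifd_size <- 2L + n_entries * 12L + 4L
  write_atomic(path, function(tmp) {
    con <- file(tmp, "wb")
    on.exit(close(con))
    writeChar("II", con, eos = NULL)
    writeBin(42L, con, size = 2L, endian = "little")
    writeBin(8L, con, size = 4L, endian = "little")
    offset <- 8L
    for (i in seq_along(pages)) {
      m <- pages[[i]]
      h <- nrow(m); w <- ncol(m)
      nbytes <- 2L * h * w
      data_off <- offset + ifd_size
      next_ifd <- if (i < length(pages)) data_off + nbytes else 0L
      writeBin(n_entries, con, size = 2L, endian = "little")
      wr_entry(con, 256L, 4L, w)
      wr_entry(con, 257L, 4L, h)
      wr_entry(con, 258L, 3L, 16L)
      wr_entry(con, 259L, 3L, 1L)   # no compression
      wr_entry(con, 262L, 3L, 1L)   # black is zero
      wr_entry(con, 273L, 4L, data_off)
      wr_entry(con, 277L, 3L, 1L)
      wr_entry(con, 278L, 4L, h)
      wr_entry(con, 279L, 4L, nbytes)
      writeBin(as.integer(next_ifd), con, size = 4L, endian = "little")
      v <- as.integer(t(m))          # row-major strip order
      v[v > 32767L] <- v[v > 32767L] - 65536L
      writeBin(v, con, size = 2L, endian = "little")
      offset <- data_off + nbytes
    }
  })
}

#' Construct an image channel
#'
#' @param pixels integer matrix of pixel values (row, column indexed).
#' @param role `"nuclei"` or `"signal"`.
#' @param bit_depth camera bit depth; pixel values must be below
#'   `2^bit_depth`.
#' @param pixel_size_um physical pixel size in micrometres.
#' @return an object of class `image_channel`.
#' @export
image_channel <- function(pixels, role, bit_depth = 16L, pixel_size_um = 0.082) {
  role <- match.arg(role, c("nuclei", "signal"))
  if (!is.matrix(pixels) || length(pixels) == 0)
    stop("pixels must be a non-empty matrix")
  if (min(pixels) < 0) stop("pixel values must be non-negative")
  if (max(pixels) >= 2^bit_depth)
    stop("pixel values exceed the configured bit depth (", bit_depth, ")")
  if (pixel_size_um <= 0) stop("pixel_size_um must be positive")
  structure(list(pixels = pixels, role = role, bit_depth = as.integer(bit_depth),
                 pixel_size_um = pixel_size_um),
            class = "image_channel")
}

#' Read a two-channel scene from a multi-page TIFF
#'
#' Channels are identified by configured page order (`config$channel_order`),
#' not by wavelength metadata; the observed bit depth must match
#' `config$bit_depth`.
#'
#' @param path TIFF path.
#' @param config a [run_config()].
#' @return named list of [image_channel()] objects (`nuclei`, `signal`).
#' @export
read_scene <- function(path, config = run_config()) {
  pages <- read_tiff(path)
  order <- config$channel_order
  if (length(pages) < length(order))
    stop("expected a TIFF with >= ", length(order), " pages, got ",
         length(pages), ": ", path)
  out <- list()
  for (i in seq_along(order)) {
    pg <- pages[[i]]
    if (pg$bit_depth != config$bit_depth)
      stop("bit depth mismatch in ", path, ": file has ", pg$bit_depth,
           "-bit pages, config demands ", config$bit_depth, "-bit")
    out[[order[i]]] <- image_channel(pg$pixels, role = order[i],
                                     bit_depth = pg$bit_depth,
                                     pixel_size_um = config$pixel_size_um)
  }
  out
}

#' Export per-fragment measurements as CSV
#'
#' CSV is the canonical, testable export format. One row per retained
#' fragment; written atomically.
#'
#' @param records data.frame of fragment records (see
#'   [quantify_fragments()]).
#' @param path output CSV path.
#' @param allow_empty write a header-only file when `records` has no rows.
#' @return `path`, invisibly.
#' @export
export_measurements <- function(records, path, allow_empty = FALSE) {
  cols <- c("image_id", "condition", "label", "area_px", "perimeter_px",
            "circularity", "upq_intensity", "upq_normalized")
  if (nrow(records) == 0 && !allow_empty)
    stop("no fragment records to export (set allow_empty = TRUE for a header-only file)")
  missing <- setdiff(cols, names(records))
  if (length(missing))
    stop("records lack required columns: ", paste(missing, collapse = ", "))
  write_atomic(path, function(tmp)
    write.csv(records[, cols, drop = FALSE], tmp, row.names = FALSE))
}
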